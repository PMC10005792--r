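# Fingerprint comparison of dispersion profiles: turn the visual
# "profiles overlap" judgement used for authentication into a number
# (mean absolute log10 R1 difference on a common grid) and a grouping.

span_uncensored <- function(profile) {
  f <- profile$frequency_hz[!profile$censored & is.finite(profile$r1)]
  if (!length(f)) stop("profile has no uncensored points", call. = FALSE)
  range(f)
}

#' Resample a profile onto a frequency grid
#'
#' Log-log linear interpolation of R1 over the profile's uncensored
#' frequency span. No extrapolation: a grid point outside the span is an
#' error (reporting the valid span). Power laws are exact under this
#' interpolation.
#'
#' @param profile Profile table holding exactly one profile.
#' @param grid Frequencies to resample onto, Hz.
#' @return A tibble with `frequency_hz` and `r1`.
#' @export
resample_profile <- function(profile, grid) {
  profile <- validate_profiles(profile)
  check_frequency_grid(grid)
  keep <- !profile$censored & is.finite(profile$r1)
  sp <- span_uncensored(profile)
  if (any(grid < sp[1] * (1 - 1e-12) | grid > sp[2] * (1 + 1e-12))) {
    stop(sprintf(
      "grid outside the profile's uncensored span [%.6g, %.6g] Hz",
      sp[1], sp[2]), call. = FALSE)
  }
  out <- stats::approx(log(profile$frequency_hz[keep]),
                       log(profile$r1[keep]),
                       xout = log(grid), rule = 1)
  tibble::tibble(frequency_hz = grid, r1 = exp(out$y))
}

common_grid <- function(profiles_list, n = 24) {
  spans <- purrr::map(profiles_list, span_uncensored)
  lo <- max(purrr::map_dbl(spans, 1))
  hi <- min(purrr::map_dbl(spans, 2))
  if (!(hi > lo)) stop("profiles have no overlapping frequency span", call. = FALSE)
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Distance between two dispersion profiles
#'
#' Mean absolute difference of log10 R1 over a common frequency grid
#' (dimensionless); 0.01 corresponds to about a 2.3% relative R1
#' difference. By default the grid is 24 log-spaced points over the
#' intersection of the two uncensored spans.
#'
#' @param p,q Profile tables, one profile each.
#' @param grid Optional common grid, Hz; must lie inside both spans.
#' @param n_grid Grid size when `grid` is `NULL`.
#' @return A non-negative scalar.
#' @export
profile_distance <- function(p, q, grid = NULL, n_grid = 24) {
  if (is.null(grid)) grid <- common_grid(list(p, q), n_grid)
  rp <- resample_profile(p, grid)$r1
  rq <- resample_profile(q, grid)$r1
  mean(abs(log10(rp) - log10(rq)))
}

#' Pairwise profile distance matrix
#'
#' Computes [profile_distance()] for every pair over a single common grid
#' (the intersection of all uncensored spans).
#'
#' @param profiles Stacked profile table.
#' @param n_grid Number of log-spaced grid points.
#' @return A symmetric matrix with zero diagonal, dimnames = profile ids.
#' @export
profile_distance_matrix <- function(profiles, n_grid = 24) {
  per <- split_profiles(profiles)
  ids <- names(per)
  grid <- common_grid(per, n_grid)
  resampled <- purrr::map(per, ~ log10(resample_profile(.x, grid)$r1))
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        d[i, j] <- d[j, i] <- mean(abs(resampled[[i]] - resampled[[j]]))
      }
    }
  }
  d
}

#' Group profiles by fingerprint similarity
#'
#' Single-linkage clustering on the profile distance matrix, cut at
#' `threshold`: two profiles end up in the same group when they are
#' connected by a chain of pairwise distances below the threshold.
#' Deterministic and invariant to input order.
#'
#' @param profiles Stacked profile table.
#' @param threshold Distance cut (default 0.03, roughly a 7% relative R1
#'   difference).
#' @param n_grid Grid size for the distance matrix.
#' @return A tibble with `profile` and integer `group` (numbered by first
#'   appearance in the input).
#' @export
group_profiles <- function(profiles, threshold = 0.03, n_grid = 24) {
  d <- profile_distance_matrix(profiles, n_grid)
  ids <- rownames(d)
  if (length(ids) == 1) {
    return(tibble::tibble(profile = ids, group = 1L))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  grp <- stats::cutree(hc, h = threshold)
  # renumber groups by order of first appearance for determinism
  grp <- match(grp, unique(grp[ids]))
  tibble::tibble(profile = ids, group = as.integer(grp))
}
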