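# The parsimony strategy: explain the difference between two dispersion
# profiles (e.g. the same sample at 298 K and 323 K) with as few free
# parameters as possible. Start from a fully-shared fit and greedily free
# parameter blocks in a fixed order, keeping a block only when it improves
# the fit decisively (a drop in AIC of at least `delta_aic`).

default_parsimony_blocks <- function() {
  list(
    intermediate = c("c_i_dd", "tau_i"),
    tau_s = "tau_s",
    c_f_dd = "c_f_dd",
    c_s_dd = "c_s_dd",
    a = "a"
  )
}

#' Parsimony search over shared parameters for a profile pair
#'
#' Fits the pair with every parameter shared (the baseline), then frees
#' parameter blocks in the order: intermediate dynamics (`c_i_dd`,
#' `tau_i`), then `tau_s`, `c_f_dd`, `c_s_dd`, `a`. A block stays free
#' only if the AIC drops by at least `delta_aic`; otherwise it is shared
#' again. The intermediate-dynamics block leads because temperature mostly
#' acts on the dynamics of water confined in the gel network.
#'
#' @param profiles Profile table holding exactly two profiles.
#' @param baseline Optional precomputed fully-shared `nmrd_fit`.
#' @param delta_aic Acceptance threshold on the AIC improvement
#'   (default 10).
#' @param blocks Named list of parameter blocks tried in order.
#' @inheritParams global_fit
#' @return A list of class `parsimony_result`: `fit` (the accepted
#'   `nmrd_fit`), `constraints`, `freed` (names of accepted blocks) and
#'   `trace` (tibble of every step with AIC before/after).
#' @export
parsimony_search <- function(profiles, baseline = NULL, delta_aic = 10,
                             blocks = default_parsimony_blocks(),
                             n_starts = 3, seed = NULL) {
  profiles <- validate_profiles(profiles)
  ids <- unique(profile_id(profiles))
  if (length(ids) != 2) {
    stop("`parsimony_search()` expects exactly two profiles", call. = FALSE)
  }
  cm <- constraint_map(profiles)
  cm <- cm_share(cm, unique(cm$parameter))
  if (is.null(baseline)) {
    baseline <- global_fit(profiles, cm, n_starts = max(n_starts, 5),
                           seed = seed)
  }
  cur_fit <- baseline
  cur_cm <- cm
  freed <- character(0)
  trace <- list()
  for (bi in seq_along(blocks)) {
    bname <- names(blocks)[bi]
    try_cm <- cm_free(cur_cm, blocks[[bi]])
    # warm start at the current solution so freeing can only reduce chi-square
    try_fit <- global_fit(profiles, try_cm, init = cur_fit$models,
                          n_starts = n_starts,
                          seed = child_seed(seed, bi))
    accepted <- (cur_fit$aic - try_fit$aic) >= delta_aic
    trace[[bi]] <- tibble::tibble(
      block = bname, aic_before = cur_fit$aic, aic_after = try_fit$aic,
      delta_aic = cur_fit$aic - try_fit$aic, accepted = accepted
    )
    if (accepted) {
      cur_fit <- try_fit
      cur_cm <- try_cm
      freed <- c(freed, bname)
    }
  }
  structure(
    list(fit = cur_fit, constraints = cur_cm, freed = freed,
         trace = dplyr::bind_rows(trace), delta_aic = delta_aic),
    class = "parsimony_result"
  )
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("<parsimony_result> freed blocks:",
      if (length(x$freed)) paste(x$freed, collapse = ", ") else "(none)", "\n")
  print(x$trace)
  invisible(x)
}

#' Select the number of relaxation components by AIC
#'
#' Fits the profile with `k = 1 .. k_max` Lorentzian components and picks
#' the AIC minimizer; when models lie within 2 AIC units of the minimum
#' the smallest such `k` wins (ties resolve toward parsimony).
#'
#' @param profile Profile table holding exactly one profile.
#' @param k_max Largest component count tried (1--4).
#' @inheritParams global_fit
#' @return A list of class `component_selection`: `k` (selected), `table`
#'   (tibble of k, AIC, chi-square, convergence) and `fits` (per-k
#'   `nmrd_fit`s, `NULL` where the fit failed).
#' @export
select_components <- function(profile, k_max = 4, n_starts = 5, seed = NULL) {
  stopifnot(k_max >= 1, k_max <= 4)
  fits <- vector("list", k_max)
  rows <- list()
  for (k in seq_len(k_max)) {
    f <- tryCatch(
      suppressWarnings(fit_single(profile, n_components = k,
                                  n_starts = n_starts,
                                  seed = child_seed(seed, k))),
      error = function(e) NULL
    )
    fits[[k]] <- f
    rows[[k]] <- tibble::tibble(
      k = k,
      aic = if (is.null(f)) NA_real_ else f$aic,
      chisq = if (is.null(f)) NA_real_ else f$chisq,
      n_free = if (is.null(f)) NA_integer_ else f$n_free,
      converged = !is.null(f)
    )
  }
  tab <- dplyr::bind_rows(rows)
  if (all(is.na(tab$aic))) stop("no component count could be fitted", call. = FALSE)
  amin <- min(tab$aic, na.rm = TRUE)
  k_sel <- min(tab$k[!is.na(tab$aic) & tab$aic - amin < 2])
  structure(list(k = k_sel, table = tab, fits = fits),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat("<component_selection> k =", x$k, "\n")
  print(x$table)
  invisible(x)
}
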