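# Seeded synthetic-data generator: dispersion profiles and magnetization
# recovery curves with the statistical structure the analysis assumes,
# parameterized by the packaged jelly parameter catalog.

#' The packaged jelly parameter catalog
#'
#' Relaxation-model parameters for gelatin-based jelly candies: eight
#' Haribo rows (four jelly groups at 298 K and 323 K) and four Vidal rows
#' at 323 K. Jellies whose profiles overlap share a single parameter row
#' (`bear|phantasia`, `tropifruity|color-rado`, `coke|fish|pizza`).
#' A parameter without a quoted uncertainty was fixed, not fitted; the
#' `fixed_*` flags record this.
#'
#' @param expand If `TRUE`, one row per individual jelly (shared rows
#'   duplicated, with `parameter_group` recording the original row); if
#'   `FALSE` (default) one row per parameter group, as tabulated.
#' @param path Catalog CSV to read; defaults to the packaged file.
#' @return A tibble with `brand`, `jellies`, `temperature_k`, the seven
#'   model parameters (`c_s_dd`, `tau_s`, `c_i_dd`, `tau_i`, `c_f_dd`,
#'   `tau_f`, `a`), their `*_unc` uncertainties (`NA` where fixed) and
#'   `fixed_*` logical flags.
#' @export
jelly_catalog <- function(expand = FALSE, path = NULL) {
  path <- path %||% system.file("extdata", "jelly_parameters.csv",
                                package = "nmrdfit", mustWork = TRUE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  num_cols <- setdiff(names(raw), c("brand", "jellies"))
  cat <- tibble::as_tibble(raw)
  for (cc in num_cols) cat[[cc]] <- as.numeric(cat[[cc]])
  for (p in c("c_s_dd", "tau_s", "c_i_dd", "tau_i", "c_f_dd", "tau_f", "a")) {
    cat[[paste0("fixed_", p)]] <- is.na(cat[[paste0(p, "_unc")]])
  }
  if (!expand) return(cat)
  expand_catalog(cat)
}

expand_catalog <- function(cat) {
  cat$parameter_group <- cat$jellies
  cat |>
    dplyr::mutate(jellies = strsplit(.data$jellies, "|", fixed = TRUE)) |>
    tidyr::unnest("jellies") |>
    dplyr::rename(jelly = "jellies")
}

#' @rdname jelly_catalog
#' @param row One catalog row (a 1-row tibble or named list).
#' @return `catalog_model()` returns the row's [relaxation_model()].
#' @export
catalog_model <- function(row) {
  relaxation_model(
    c_dd = c(row$c_s_dd, row$c_i_dd, row$c_f_dd),
    tau = c(row$tau_s, row$tau_i, row$tau_f),
    offset_a = row$a
  )
}

#' Noise specification for the generators
#'
#' Gaussian multiplicative noise for dispersion profiles (relative
#' standard deviation `cv`) and, for recovery curves, additive noise of
#' amplitude `cv` times the recovery amplitude.
#'
#' @param cv Coefficient of variation (default 0.02, a typical fast
#'   field-cycling instrument spec).
#' @param seed Integer seed, or `NULL` to use the ambient RNG stream.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(cv = 0.02, seed = NULL) {
  stopifnot(cv >= 0)
  structure(list(cv = cv, seed = seed, distribution = "gaussian"),
            class = "noise_spec")
}

#' Simulate one NMRD profile
#'
#' Evaluates the model on the grid, applies independent multiplicative
#' Gaussian noise per point, and marks points whose *true* rate fails
#' [assess_measurability()] at the given dead time as censored (the
#' mechanism behind missing low-frequency data when relaxation is too
#' fast). `dead_time = 0` disables censoring. Reproducible given
#' `noise$seed`.
#'
#' @param model A [relaxation_model()].
#' @param freq_hz Frequency grid, Hz.
#' @param noise A [noise_spec()].
#' @param dead_time Instrument dead time, s (default 3 ms).
#' @param sample_id,temperature_k Metadata for the profile rows.
#' @return A profile tibble (see [nmrd_profile()]); `r1_err` is set to
#'   `cv * true R1` (the generating 1-sigma) when `cv > 0`.
#' @export
make_profile <- function(model, freq_hz = default_grid(),
                         noise = noise_spec(), dead_time = 3e-3,
                         sample_id = "synthetic", temperature_k = 298) {
  check_frequency_grid(freq_hz)
  r1_true <- evaluate_r1(model, freq_hz)
  eps <- with_seed(noise$seed, stats::rnorm(length(freq_hz), 0, noise$cv))
  r1 <- r1_true * (1 + eps)
  censored <- if (dead_time > 0) !assess_measurability(r1_true, dead_time) else
    rep(FALSE, length(freq_hz))
  nmrd_profile(
    frequency_hz = freq_hz,
    r1 = r1,
    r1_err = if (noise$cv > 0) noise$cv * r1_true else NA_real_,
    censored = censored,
    sample_id = sample_id,
    temperature_k = temperature_k
  )
}

#' Simulate a magnetization recovery curve
#'
#' `M(t) = m_eq + (m_init - m_eq) * exp(-r1 * t)` plus additive Gaussian
#' noise of standard deviation `cv * |m_init - m_eq|`.
#'
#' @param r1 Relaxation rate, 1/s (> 0).
#' @param m_init,m_eq Initial and equilibrium magnetization, arbitrary
#'   units.
#' @param t_grid Sampling times, s, strictly increasing.
#' @param noise A [noise_spec()].
#' @return A tibble with `time_s` and `magnetization`.
#' @export
make_recovery <- function(r1, m_init = 0, m_eq = 1,
                          t_grid = seq(0, 5 / r1, length.out = 20),
                          noise = noise_spec()) {
  stopifnot(r1 > 0)
  m <- m_eq + (m_init - m_eq) * exp(-r1 * t_grid)
  eps <- with_seed(noise$seed,
                   stats::rnorm(length(t_grid), 0, noise$cv * abs(m_init - m_eq)))
  tibble::tibble(time_s = t_grid, magnetization = m + eps)
}

#' Simulate the full jelly dataset
#'
#' One profile per jelly and temperature in the expanded catalog. Because
#' the catalog has no 298 K entries for Vidal jelly (at room temperature
#' its low-frequency relaxation was too fast to measure), 298 K Vidal
#' profiles are *emulated* by reusing the 323 K parameters with all
#' correlation times scaled up by `vidal_tau_scale`, a synthetic-only
#' convention that makes low-frequency censoring emerge; these rows are
#' flagged `emulated = TRUE`.
#'
#' @param catalog Parameter catalog (see [jelly_catalog()]); expanded
#'   internally.
#' @param freq_hz Frequency grid, Hz.
#' @param noise A [noise_spec()]; per-profile seeds are derived from
#'   `noise$seed`.
#' @param dead_time Dead time used for the censoring mechanism, s.
#' @param emulate_vidal_298 Generate the synthetic 298 K Vidal profiles?
#' @param vidal_tau_scale Correlation-time scale factor for the emulation.
#' @return A stacked profile tibble with additional columns `brand`,
#'   `parameter_group` and `emulated`.
#' @export
make_dataset <- function(catalog = jelly_catalog(), freq_hz = default_grid(),
                         noise = noise_spec(), dead_time = 3e-3,
                         emulate_vidal_298 = TRUE, vidal_tau_scale = 2) {
  if (!"jelly" %in% names(catalog)) catalog <- expand_catalog(catalog)
  rows <- catalog
  if (emulate_vidal_298) {
    vid <- rows[rows$brand == "Vidal" & rows$temperature_k == 323, ]
    if (nrow(vid)) {
      vid$temperature_k <- 298
      vid$tau_s <- vid$tau_s * vidal_tau_scale
      vid$tau_i <- vid$tau_i * vidal_tau_scale
      vid$tau_f <- vid$tau_f * vidal_tau_scale
      vid$emulated <- TRUE
      rows$emulated <- FALSE
      rows <- dplyr::bind_rows(rows, vid)
    }
  } else {
    rows$emulated <- FALSE
  }
  profs <- purrr::map(seq_len(nrow(rows)), function(i) {
    row <- rows[i, ]
    p <- make_profile(
      catalog_model(row), freq_hz,
      noise = noise_spec(noise$cv, child_seed(noise$seed, i)),
      dead_time = dead_time,
      sample_id = paste(tolower(row$brand), row$jelly),
      temperature_k = row$temperature_k
    )
    p$brand <- row$brand
    p$parameter_group <- row$parameter_group
    p$emulated <- row$emulated
    p
  })
  dplyr::bind_rows(profs)
}
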