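# Tidy representation of NMRD profiles: one row per (sample, temperature,
# frequency) with the measured relaxation rate.

#' Assemble an NMRD profile table
#'
#' An NMRD profile is stored as a plain tibble with one row per measured
#' frequency and columns `sample_id`, `temperature_k`, `frequency_hz`,
#' `r1`, `r1_err` and `censored`. Several profiles are simply stacked with
#' `dplyr::bind_rows()`; a profile is identified by the
#' (`sample_id`, `temperature_k`) pair.
#'
#' @param frequency_hz Larmor frequencies, Hz, strictly increasing, > 0.
#' @param r1 Spin-lattice relaxation rates, 1/s; must be > 0 where not
#'   censored.
#' @param r1_err Optional 1-sigma uncertainties, 1/s.
#' @param censored Logical; `TRUE` marks points where the relaxation was too
#'   fast to measure. Censored points are kept for bookkeeping but excluded
#'   from every fit and distance computation.
#' @param sample_id Sample identifier.
#' @param temperature_k Temperature, K.
#' @return A tibble with the six profile columns.
#' @export
nmrd_profile <- function(frequency_hz, r1, r1_err = NA_real_,
                         censored = FALSE, sample_id = "sample",
                         temperature_k = 298) {
  n <- length(frequency_hz)
  if (length(r1) != n) stop("`frequency_hz` and `r1` lengths differ", call. = FALSE)
  check_frequency_grid(frequency_hz)
  if (is.unsorted(frequency_hz, strictly = TRUE)) {
    stop("`frequency_hz` must be strictly increasing", call. = FALSE)
  }
  censored <- rep_len(as.logical(censored), n)
  if (any(r1[!censored] <= 0, na.rm = TRUE)) {
    stop("`r1` must be positive at uncensored points", call. = FALSE)
  }
  tibble::tibble(
    sample_id = as.character(sample_id),
    temperature_k = as.numeric(temperature_k),
    frequency_hz = as.numeric(frequency_hz),
    r1 = as.numeric(r1),
    r1_err = rep_len(as.numeric(r1_err), n),
    censored = censored
  )
}

#' @rdname nmrd_profile
#' @param profiles A stacked profile table.
#' @return `profile_id()` returns the `"<sample_id>@<temperature_k>K"` key
#'   for each row.
#' @export
profile_id <- function(profiles) {
  paste0(profiles$sample_id, "@", profiles$temperature_k, "K")
}

split_profiles <- function(profiles) {
  validate_profiles(profiles)
  ids <- profile_id(profiles)
  split(profiles, factor(ids, levels = unique(ids)))
}

validate_profiles <- function(profiles) {
  needed <- c("sample_id", "temperature_k", "frequency_hz", "r1")
  missing <- setdiff(needed, names(profiles))
  if (length(missing)) {
    stop("profile table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"censored" %in% names(profiles)) profiles$censored <- FALSE
  if (!"r1_err" %in% names(profiles)) profiles$r1_err <- NA_real_
  invisible(profiles)
}

#' Default logarithmic frequency grid
#'
#' 32 log-spaced Larmor frequencies spanning 10 kHz to 10 MHz, the range a
#' fast field-cycling relaxometer typically covers.
#'
#' @param n Number of points.
#' @param from,to Frequency span, Hz.
#' @return Numeric vector of frequencies, Hz.
#' @export
default_grid <- function(n = 32, from = 1e4, to = 1e7) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Plot NMRD profiles
#'
#' Log-log scatter of R1 versus frequency, one colour per profile; censored
#' points are hollow.
#'
#' @param profiles Stacked profile table (see [nmrd_profile()]).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  profiles <- validate_profiles(profiles)
  profiles$profile <- profile_id(profiles)
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$frequency_hz / 1e6, y = .data$r1,
                               colour = .data$profile,
                               shape = .data$censored)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "frequency (MHz)", y = expression(R[1] ~ (s^-1)),
                  colour = NULL)
}
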