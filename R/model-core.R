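# Relaxation model: sum of Lorentzian spectral-density terms plus an offset.

.component_labels <- c("slow", "intermediate", "fast", "other")
.label_abbrev <- c(slow = "s", intermediate = "i", fast = "f", other = "o")

#' Construct a relaxation model
#'
#' A relaxation model is an ordered set of 1--4 Lorentzian relaxation
#' components, each defined by a dipolar relaxation constant `c_dd` (Hz^2)
#' and a correlation time `tau` (s), plus a frequency-independent offset
#' `offset_a` (1/s). Components are stored sorted by strictly decreasing
#' correlation time (slowest motion first). When labels are not supplied
#' they are assigned by rank: `slow`, `intermediate`, `fast`, `other`.
#'
#' @param c_dd Numeric vector of dipolar relaxation constants, Hz^2 (>= 0).
#' @param tau Numeric vector of correlation times, s (> 0), same length.
#' @param offset_a Frequency-independent relaxation rate, 1/s (>= 0).
#' @param labels Optional character labels, unique, drawn from
#'   `slow`, `intermediate`, `fast`, `other`.
#' @return An object of class `relaxation_model` with a `components` tibble
#'   (`label`, `c_dd`, `tau`) and `offset_a`.
#' @examples
#' m <- relaxation_model(
#'   c_dd = c(1.46e8, 1.00e9, 1.25e9),
#'   tau = c(2.43e-6, 4.83e-7, 5.21e-8),
#'   offset_a = 27.0
#' )
#' evaluate_r1(m, c(1e4, 1e6, 1e7))
#' @export
relaxation_model <- function(c_dd, tau, offset_a = 0, labels = NULL) {
  if (length(c_dd) != length(tau)) {
    stop("`c_dd` and `tau` must have the same length", call. = FALSE)
  }
  n <- length(tau)
  if (n < 1L || n > 4L) {
    stop("a relaxation model holds between 1 and 4 components", call. = FALSE)
  }
  if (!all(is.finite(c_dd)) || !all(is.finite(tau)) || !is.finite(offset_a)) {
    stop("model parameters must be finite", call. = FALSE)
  }
  if (any(c_dd < 0)) stop("`c_dd` must be >= 0", call. = FALSE)
  if (any(tau <= 0)) stop("`tau` must be > 0", call. = FALSE)
  if (offset_a < 0) stop("`offset_a` must be >= 0", call. = FALSE)

  ord <- order(tau, decreasing = TRUE)
  c_dd <- c_dd[ord]
  tau <- tau[ord]
  if (is.null(labels)) {
    labels <- default_component_labels(n)
  } else {
    labels <- labels[ord]
    if (anyDuplicated(labels)) stop("component labels must be unique", call. = FALSE)
    if (!all(labels %in% .component_labels)) {
      stop("labels must be drawn from: ", paste(.component_labels, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(
      components = tibble::tibble(label = labels, c_dd = c_dd, tau = tau),
      offset_a = offset_a
    ),
    class = "relaxation_model"
  )
}

default_component_labels <- function(n) {
  switch(n,
    "slow",
    c("slow", "fast"),
    c("slow", "intermediate", "fast"),
    c("slow", "intermediate", "fast", "other")
  )
}

#' @export
print.relaxation_model <- function(x, ...) {
  cat("<relaxation_model>", nrow(x$components), "component(s), offset A =",
      format(x$offset_a), "1/s\n")
  print(x$components)
  invisible(x)
}

#' Lorentzian spectral-density bracket
#'
#' Evaluates `tau / (1 + (omega * tau)^2) + 4 * tau / (1 + (2 * omega * tau)^2)`,
#' the combination of the spectral density at `omega` and `2 * omega` that
#' drives homonuclear dipolar spin-lattice relaxation. At `omega = 0` the
#' value is exactly `5 * tau`; it decreases strictly with `omega`.
#'
#' @param tau Correlation time(s), s (> 0).
#' @param omega Angular frequency(ies), rad/s (>= 0).
#' @return Numeric vector (seconds), recycled over the longer argument.
#' @export
lorentzian_bracket <- function(tau, omega) {
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("`tau` must be positive and finite", call. = FALSE)
  }
  if (any(omega < 0)) stop("`omega` must be >= 0", call. = FALSE)
  wt <- omega * tau
  tau / (1 + wt^2) + 4 * tau / (1 + (2 * wt)^2)
}

check_frequency_grid <- function(freq_hz) {
  if (length(freq_hz) == 0) stop("frequency grid is empty", call. = FALSE)
  if (any(!is.finite(freq_hz)) || any(freq_hz <= 0)) {
    stop("frequencies must be positive and finite (Hz)", call. = FALSE)
  }
  invisible(freq_hz)
}

#' Evaluate the dispersion model R1(nu)
#'
#' Computes `R1(nu) = sum_k c_dd_k * B(tau_k, 2 * pi * nu) + offset_a` where
#' `B` is [lorentzian_bracket()]. Frequencies are Larmor frequencies in Hz;
#' the angular-frequency conversion `omega = 2 * pi * nu` is applied
#' internally.
#'
#' @param model A [relaxation_model()].
#' @param freq_hz Numeric vector of Larmor frequencies, Hz (> 0).
#' @return Numeric vector of relaxation rates, 1/s.
#' @export
evaluate_r1 <- function(model, freq_hz) {
  stopifnot(inherits(model, "relaxation_model"))
  check_frequency_grid(freq_hz)
  omega <- 2 * pi * freq_hz
  out <- rep(model$offset_a, length(freq_hz))
  for (k in seq_len(nrow(model$components))) {
    out <- out + model$components$c_dd[k] *
      lorentzian_bracket(model$components$tau[k], omega)
  }
  out
}

#' Decompose R1(nu) into per-process contributions
#'
#' Splits the model prediction into one curve per relaxation component
#' (e.g. `R1s`, `R1i`, `R1f` for a three-component model) plus the constant
#' offset; the curves sum to [evaluate_r1()] at every frequency.
#'
#' @inheritParams evaluate_r1
#' @return A tibble with columns `frequency_hz`, `component`
#'   (component labels plus `"offset"`) and `r1`.
#' @export
decompose_r1 <- function(model, freq_hz) {
  stopifnot(inherits(model, "relaxation_model"))
  check_frequency_grid(freq_hz)
  omega <- 2 * pi * freq_hz
  parts <- purrr::pmap(model$components, function(label, c_dd, tau) {
    tibble::tibble(
      frequency_hz = freq_hz,
      component = label,
      r1 = c_dd * lorentzian_bracket(tau, omega)
    )
  })
  dplyr::bind_rows(
    parts,
    tibble::tibble(frequency_hz = freq_hz, component = "offset",
                   r1 = model$offset_a)
  )
}

# --- flat parameter-name representation ------------------------------------

param_names_for <- function(labels) {
  ab <- .label_abbrev[labels]
  as.vector(rbind(paste0("c_", ab, "_dd"), paste0("tau_", ab)))
}

#' Flatten a relaxation model to named parameters
#'
#' Uses the conventional flat names `c_s_dd`, `tau_s`, `c_i_dd`, `tau_i`,
#' `c_f_dd`, `tau_f` (and `c_o_dd`/`tau_o` for a fourth component) plus `a`.
#'
#' @param model A [relaxation_model()].
#' @return A named numeric vector.
#' @export
model_to_params <- function(model) {
  stopifnot(inherits(model, "relaxation_model"))
  vals <- as.vector(rbind(model$components$c_dd, model$components$tau))
  names(vals) <- param_names_for(model$components$label)
  c(vals, a = model$offset_a)
}

#' Build a relaxation model from named parameters
#'
#' Inverse of [model_to_params()]: accepts a named vector or list with
#' entries `c_<x>_dd` / `tau_<x>` pairs (`x` in `s`, `i`, `f`, `o`) and `a`.
#'
#' @param params Named numeric vector or list.
#' @return A [relaxation_model()].
#' @export
model_from_params <- function(params) {
  params <- unlist(params)
  ab <- .label_abbrev
  present <- names(ab)[paste0("tau_", ab) %in% names(params)]
  if (length(present) == 0) stop("no `tau_*` parameters found", call. = FALSE)
  tau <- unname(params[paste0("tau_", ab[present])])
  c_dd <- unname(params[paste0("c_", ab[present], "_dd")])
  a <- if ("a" %in% names(params)) unname(params[["a"]]) else 0
  relaxation_model(c_dd = c_dd, tau = tau, offset_a = a, labels = present)
}

# --- JSON parameter files ---------------------------------------------------

#' Read / write a flat parameter file (JSON)
#'
#' The file is a JSON object keyed by flat parameter name (`c_s_dd`,
#' `tau_s`, ..., `a`), each entry holding `value` and optional
#' `uncertainty` and `fixed` attributes. Values are carried as decimal
#' strings so that catalog entries round-trip exactly as printed.
#'
#' @param path File path.
#' @return `read_parameter_json()` returns a tibble with columns
#'   `parameter`, `value` (string), `uncertainty` (string or `NA`) and
#'   `fixed` (logical).
#' @export
read_parameter_json <- function(path) {
  obj <- jsonlite::read_json(path)
  tibble::tibble(
    parameter = names(obj),
    value = unname(purrr::map_chr(obj, ~ as.character(.x$value))),
    uncertainty = unname(purrr::map_chr(obj, ~ {
      u <- .x$uncertainty
      if (is.null(u)) NA_character_ else as.character(u)
    })),
    fixed = unname(purrr::map_lgl(obj, ~ isTRUE(.x$fixed)))
  )
}

#' @rdname read_parameter_json
#' @param params Tibble as returned by `read_parameter_json()`, or a named
#'   numeric vector (converted with `fixed = FALSE`, no uncertainties).
#' @export
write_parameter_json <- function(params, path) {
  if (is.numeric(params)) {
    params <- tibble::tibble(
      parameter = names(params),
      value = vapply(params, format_decimal, character(1)),
      uncertainty = NA_character_,
      fixed = FALSE
    )
  }
  entries <- purrr::pmap(params, function(parameter, value, uncertainty, fixed) {
    e <- list(value = value)
    if (!is.na(uncertainty)) e$uncertainty <- uncertainty
    e$fixed <- fixed
    e
  })
  names(entries) <- params$parameter
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# compact decimal-string form, e.g. 1.46e8, 27.0
format_decimal <- function(x) {
  if (is.na(x)) return(NA_character_)
  format(x, scientific = abs(x) >= 1e4 || (x != 0 && abs(x) < 1e-3), trim = TRUE)
}
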