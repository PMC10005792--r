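# Weighted nonlinear least-squares engine for dispersion profiles.
# All dipolar constants and correlation times are optimized in log10 space
# (they are positive and span many decades); the offset A stays linear with
# a lower bound of zero. Multi-start Levenberg-Marquardt via minpack.lm.

.log_bounds <- list(c = c(2, 13), tau = c(-11, -3), a = c(0, 1e6))

param_is_log <- function(p) p != "a"

to_internal <- function(p, value) ifelse(param_is_log(p), log10(value), value)
from_internal <- function(p, theta) ifelse(param_is_log(p), 10^theta, theta)

param_bounds <- function(p) {
  if (p == "a") return(.log_bounds$a)
  if (startsWith(p, "tau")) .log_bounds$tau else .log_bounds$c
}

# Index the free/shared slots of a constraint map into a single parameter
# vector. Returns cm with an `idx` column (NA for fixed) and the slot table
# of distinct optimized entries.
index_constraints <- function(cm) {
  validate_constraint_map(cm)
  cm$idx <- NA_integer_
  slots <- list()
  nxt <- 0L
  group_idx <- list()
  for (i in seq_len(nrow(cm))) {
    kind <- cm$kind[i]
    if (kind == "fixed") next
    if (kind == "free") {
      nxt <- nxt + 1L
      cm$idx[i] <- nxt
      slots[[nxt]] <- list(parameter = cm$parameter[i], label = paste0(
        cm$parameter[i], "[", cm$profile[i], "]"))
    } else { # shared
      g <- cm$group[i]
      if (is.null(group_idx[[g]])) {
        nxt <- nxt + 1L
        group_idx[[g]] <- nxt
        slots[[nxt]] <- list(parameter = cm$parameter[i],
                             label = paste0(cm$parameter[i], "{", g, "}"))
      }
      cm$idx[i] <- group_idx[[g]]
    }
  }
  list(cm = cm, n_free = nxt,
       slot_param = vapply(slots, `[[`, "", "parameter"),
       slot_label = vapply(slots, `[[`, "", "label"))
}

# precompute linear indices for fast theta -> matrix unpacking
finalize_index <- function(idx, params, ids) {
  cm <- idx$cm
  pos <- match(cm$parameter, params) +
    (match(cm$profile, ids) - 1L) * length(params)
  fixed <- cm$kind == "fixed"
  idx$fix_pos <- pos[fixed]
  idx$fix_val <- cm$value[fixed]
  idx$free_pos <- pos[!fixed]
  idx$free_theta <- cm$idx[!fixed]
  idx$free_log <- param_is_log(cm$parameter[!fixed])
  idx$dim <- c(length(params), length(ids))
  idx$dimnames <- list(params, ids)
  idx
}

# theta -> named parameter matrix [parameter x profile]
unpack_theta <- function(theta, idx, params, ids) {
  m <- matrix(NA_real_, nrow = idx$dim[1], ncol = idx$dim[2],
              dimnames = idx$dimnames)
  m[idx$fix_pos] <- idx$fix_val
  vals <- theta[idx$free_theta]
  vals[idx$free_log] <- 10^vals[idx$free_log]
  m[idx$free_pos] <- vals
  m
}

fit_sigma <- function(prof) {
  s <- prof$r1_err
  bad <- !is.finite(s) | s <= 0
  s[bad] <- prof$r1[bad]  # relative weighting fallback
  s
}

# Heuristic starting model for one profile: offset from the high-frequency
# plateau, correlation times at the decades the dispersion window covers,
# constants sized so the components sum to the low-frequency rate.
init_heuristic <- function(prof, k) {
  r1 <- prof$r1
  a0 <- max(0.8 * min(r1), 1e-3)
  taus <- if (k == 1) 1e-7 else 10^seq(-6, -8, length.out = k)
  amp <- max(max(r1) - a0, 0.1 * max(r1))
  c0 <- pmin(pmax(amp / (5 * taus * k), 1e3), 1e12)
  stats::setNames(
    c(as.vector(rbind(c0, taus)), a0),
    c(param_names_for(default_component_labels(k)), "a")
  )
}

#' Global fit of one or more NMRD profiles under a constraint map
#'
#' Runs a single weighted least-squares optimization over the union of all
#' free and shared parameter slots: shared slots take one value across
#' their group, fixed slots never move. Weights are `1/r1_err^2` where
#' uncertainties are supplied and `1/r1^2` (relative) otherwise; censored
#' points are excluded. A seeded multi-start (log-space jitter around the
#' initialization) guards against local minima.
#'
#' @param profiles Stacked profile table (see [nmrd_profile()]).
#' @param constraints A [constraint_map()]; defaults to all-free
#'   three-component models per profile.
#' @param init Optional initialization: a single [relaxation_model()], a
#'   named list of models keyed by profile id, or `NULL` for the built-in
#'   heuristic.
#' @param n_starts Number of optimizer starts (first start unjittered).
#' @param seed Seed for the start jitter; `NULL` leaves the RNG alone.
#' @return An object of class `nmrd_fit`: per-profile models, a tidy
#'   parameter table with 1-sigma uncertainties and shared/fixed/free
#'   status, chi-square, reduced chi-square, AIC and convergence
#'   diagnostics. Use `tidy()`, `glance()` and `autoplot()`.
#' @export
global_fit <- function(profiles, constraints = NULL, init = NULL,
                       n_starts = 5, seed = NULL) {
  profiles <- validate_profiles(profiles)
  per <- split_profiles(profiles)
  ids <- names(per)
  if (is.null(constraints)) constraints <- constraint_map(profiles)
  if (!all(constraints$profile %in% ids) || !all(ids %in% constraints$profile)) {
    stop("constraint map and profile table disagree on profile ids", call. = FALSE)
  }
  params <- unique(constraints$parameter)
  idx <- finalize_index(index_constraints(constraints), params, ids)
  k_comp <- sum(startsWith(params, "tau"))

  dat <- purrr::map(per, function(pr) {
    pr <- pr[!pr$censored & is.finite(pr$r1), ]
    list(f = pr$frequency_hz, r1 = pr$r1, sigma = fit_sigma(pr))
  })
  n_obs <- sum(vapply(dat, function(d) length(d$f), 1L))
  n_free <- idx$n_free
  if (n_obs == 0) stop("no uncensored observations to fit", call. = FALSE)

  # fast evaluation path: work on the raw parameter matrix, no model
  # objects inside the optimizer loop
  c_rows <- grep("^c_", params)
  tau_rows <- grep("^tau_", params)
  for (id in ids) dat[[id]]$omega <- 2 * pi * dat[[id]]$f
  residual_fn <- function(theta) {
    m <- unpack_theta(theta, idx, params, ids)
    out <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      d <- dat[[ids[j]]]
      pred <- rep(m["a", j], length(d$omega))
      for (k in seq_along(c_rows)) {
        wt <- d$omega * m[tau_rows[k], j]
        pred <- pred + m[c_rows[k], j] * m[tau_rows[k], j] *
          (1 / (1 + wt^2) + 4 / (1 + 4 * wt^2))
      }
      out[[j]] <- (pred - d$r1) / d$sigma
    }
    unlist(out, use.names = FALSE)
  }

  if (n_free == 0) {
    warning("constraint map leaves no free parameters; evaluating only",
            call. = FALSE)
    r <- residual_fn(numeric(0))
    return(build_fit_result(theta = numeric(0), covar = matrix(0, 0, 0),
                            idx = idx, params = params, ids = ids,
                            chisq = sum(r^2), n_obs = n_obs,
                            converged = TRUE, info = 0L,
                            profiles = profiles, seed = seed))
  }
  if (n_free > n_obs) {
    warning("more free parameters (", n_free, ") than observations (",
            n_obs, "): fit is under-determined", call. = FALSE)
  }

  # initialization matrix [parameter x profile]; for multi-profile fits a
  # quick unconstrained prefit per profile beats the raw heuristic
  init_mat <- matrix(NA_real_, length(params), length(ids),
                     dimnames = list(params, ids))
  for (id in ids) {
    mod <- if (inherits(init, "relaxation_model")) init
           else if (is.list(init) && !is.null(init[[id]])) init[[id]]
           else NULL
    if (is.null(mod) && length(ids) > 1) {
      pre <- tryCatch(
        suppressWarnings(fit_single(per[[id]], n_components = k_comp,
                                    n_starts = 3, seed = seed)),
        error = function(e) NULL
      )
      if (!is.null(pre)) mod <- pre$models[[1]]
    }
    p0 <- if (is.null(mod)) init_heuristic(per[[id]][!per[[id]]$censored, ], k_comp)
          else model_to_params(mod)
    init_mat[params, id] <- p0[params]
  }
  theta0 <- numeric(n_free)
  for (i in seq_len(nrow(idx$cm))) {
    j <- idx$cm$idx[i]
    if (!is.na(j)) {
      theta0[j] <- to_internal(idx$cm$parameter[i],
                               init_mat[idx$cm$parameter[i], idx$cm$profile[i]])
    }
  }
  lower <- vapply(idx$slot_param, function(p) param_bounds(p)[1], 1)
  upper <- vapply(idx$slot_param, function(p) param_bounds(p)[2], 1)
  theta0 <- pmin(pmax(theta0, lower), upper)

  starts <- with_seed(seed, {
    purrr::map(seq_len(n_starts), function(s) {
      if (s == 1) return(theta0)
      jit <- ifelse(param_is_log(idx$slot_param),
                    stats::rnorm(n_free, 0, 0.4),
                    0)
      th <- theta0 + jit
      th[!param_is_log(idx$slot_param)] <-
        theta0[!param_is_log(idx$slot_param)] *
        stats::runif(sum(!param_is_log(idx$slot_param)), 0.6, 1.4)
      pmin(pmax(th, lower), upper)
    })
  })

  best <- NULL
  for (th in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th, fn = residual_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$info %in% c(1:4)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("profile fit failed: no optimizer start converged", call. = FALSE)
  }

  covar <- fit_covariance(best, n_obs, n_free)
  res <- build_fit_result(theta = best$par, covar = covar, idx = idx,
                          params = params, ids = ids,
                          chisq = best$deviance, n_obs = n_obs,
                          converged = TRUE, info = best$info,
                          profiles = profiles, seed = seed)
  res <- canonicalize_components(res)
  warn_tau_collision(res)
  res
}

fit_covariance <- function(fit, n_obs, n_free) {
  s2 <- fit$deviance / max(n_obs - n_free, 1)
  cv <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(cv)) {
    warning("singular information matrix: parameter uncertainties unavailable ",
            "(rank-deficient fit)", call. = FALSE)
    cv <- matrix(NA_real_, n_free, n_free)
  }
  cv
}

build_fit_result <- function(theta, covar, idx, params, ids, chisq, n_obs,
                             converged, info, profiles, seed) {
  m <- unpack_theta(theta, idx, params, ids)
  se_theta <- if (length(theta)) sqrt(pmax(diag(covar), 0)) else numeric(0)

  rows <- purrr::pmap_dfr(idx$cm, function(parameter, profile, kind, value,
                                           group, idx, ...) {
    est <- m[parameter, profile]
    se <- if (kind == "fixed" || is.na(idx)) NA_real_ else {
      s <- se_theta[idx]
      if (param_is_log(parameter)) log(10) * est * s else s
    }
    tibble::tibble(profile = profile, parameter = parameter,
                   estimate = est, std_error = se, status = kind,
                   group = group)
  })

  models <- purrr::map(ids, ~ model_from_params(m[, .x]))
  names(models) <- ids
  n_free <- idx$n_free
  structure(
    list(
      models = models,
      params = rows,
      constraints = idx$cm[, c("parameter", "profile", "kind", "value", "group")],
      chisq = chisq,
      red_chisq = chisq / max(n_obs - n_free, 1),
      aic = n_obs * log(chisq / n_obs) + 2 * n_free,
      n_free = n_free,
      n_points = n_obs,
      converged = converged,
      info = info,
      seed = seed,
      data = profiles
    ),
    class = "nmrd_fit"
  )
}

warn_tau_collision <- function(fit, ratio = 3) {
  for (id in names(fit$models)) {
    tau <- sort(fit$models[[id]]$components$tau, decreasing = TRUE)
    if (length(tau) > 1 && any(tau[-length(tau)] / tau[-1] < ratio)) {
      warning("correlation times nearly collide in profile ", id,
              ": consider merging components (fewer components may suffice)",
              call. = FALSE)
    }
  }
  invisible(fit)
}

#' Fit a single NMRD profile
#'
#' Convenience wrapper around [global_fit()] for one profile with all
#' parameters free (optionally some fixed). Requires at least
#' `2 * n_components + 2` uncensored points. When all component parameters
#' are free, fitted components are relabelled by descending correlation
#' time (slow, intermediate, fast, other).
#'
#' @param profile Profile table holding exactly one profile.
#' @param n_components Number of Lorentzian components to fit (1--4).
#' @param init Optional [relaxation_model()] initialization.
#' @param fixed Optional named vector of parameters to pin
#'   (e.g. `c(tau_s = 2.43e-6, a = 27)`).
#' @inheritParams global_fit
#' @return An `nmrd_fit` (see [global_fit()]).
#' @export
fit_single <- function(profile, n_components = 3, init = NULL, fixed = NULL,
                       n_starts = 5, seed = NULL) {
  profile <- validate_profiles(profile)
  if (length(unique(profile_id(profile))) != 1) {
    stop("`fit_single()` expects exactly one profile; use `global_fit()`",
         call. = FALSE)
  }
  n_use <- sum(!profile$censored)
  if (n_use < 2 * n_components + 2) {
    stop("insufficient data: ", n_use, " uncensored points for a ",
         n_components, "-component fit (need >= ", 2 * n_components + 2, ")",
         call. = FALSE)
  }
  cm <- constraint_map(profile, n_components)
  if (!is.null(fixed)) {
    cm <- cm_fix(cm, names(fixed), unname(fixed))
  }
  fit <- global_fit(profile, cm, init = init, n_starts = n_starts, seed = seed)
  canonicalize_components(fit)
}

# Relabel components by descending tau. Labels are rank conventions, not
# physical constraints, so a fit may legitimately return them permuted.
# Per-profile relabelling is safe when every component slot is free; a
# single common permutation is safe when no component slot is fixed
# (shared groups then move wholesale). Otherwise labels are left alone.
canonicalize_components <- function(fit) {
  cm <- fit$constraints
  comp_kinds <- cm$kind[cm$parameter != "a"]
  if (any(comp_kinds == "fixed")) return(fit)
  remaps <- lapply(fit$models, function(m) {
    comp <- m$components  # already sorted by descending tau
    labs <- default_component_labels(nrow(comp))
    stats::setNames(param_names_for(labs), param_names_for(comp$label))
  })
  all_free <- all(comp_kinds == "free")
  common <- length(unique(lapply(remaps, function(r) r[sort(names(r))]))) == 1
  if (!all_free && !common) return(fit)
  for (id in names(fit$models)) {
    remap <- remaps[[id]]
    sel <- fit$params$profile == id & fit$params$parameter != "a"
    fit$params$parameter[sel] <- unname(remap[fit$params$parameter[sel]])
    comp <- fit$models[[id]]$components
    fit$models[[id]] <- relaxation_model(
      c_dd = comp$c_dd, tau = comp$tau,
      offset_a = fit$models[[id]]$offset_a,
      labels = default_component_labels(nrow(comp))
    )
  }
  ordering <- c(as.vector(rbind(paste0("c_", .label_abbrev, "_dd"),
                                paste0("tau_", .label_abbrev))), "a")
  fit$params <- dplyr::arrange(
    fit$params, .data$profile,
    match(.data$parameter, ordering)
  )
  fit
}

#' @export
print.nmrd_fit <- function(x, ...) {
  cat("<nmrd_fit> ", length(x$models), " profile(s), ", x$n_free,
      " free parameter(s), ", x$n_points, " points\n",
      "  chi-square = ", format(x$chisq, digits = 4),
      ", reduced = ", format(x$red_chisq, digits = 4),
      ", AIC = ", format(x$aic, digits = 5), "\n", sep = "")
  print(x$params, n = 20)
  invisible(x)
}

#' Tidy methods for dispersion fits
#'
#' `tidy()` returns the per-profile parameter table (estimate, 1-sigma
#' standard error, free/fixed/shared status, sharing group); `glance()`
#' returns the one-row goodness-of-fit summary; `augment()` returns the
#' data with fitted values and weighted residuals.
#'
#' @param x An `nmrd_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nmrd_fit <- function(x, ...) x$params

#' @rdname tidy.nmrd_fit
#' @export
glance.nmrd_fit <- function(x, ...) {
  tibble::tibble(
    chisq = x$chisq, red_chisq = x$red_chisq, aic = x$aic,
    n_free = x$n_free, n_points = x$n_points,
    converged = x$converged, info = x$info,
    seed = if (is.null(x$seed)) NA_real_ else x$seed
  )
}

#' @rdname tidy.nmrd_fit
#' @export
augment.nmrd_fit <- function(x, ...) {
  d <- validate_profiles(x$data)
  d$profile <- profile_id(d)
  d$fitted <- NA_real_
  for (id in names(x$models)) {
    sel <- d$profile == id
    d$fitted[sel] <- evaluate_r1(x$models[[id]], d$frequency_hz[sel])
  }
  d$resid <- d$r1 - d$fitted
  sig <- fit_sigma(d)
  d$wresid <- ifelse(d$censored, NA_real_, d$resid / sig)
  tibble::as_tibble(d)
}

#' Plot a dispersion fit with its decomposition
#'
#' Data points plus the total fitted curve and the per-component
#' contributions (slow, intermediate, fast dynamics and the constant
#' offset), one panel per profile, on log-log axes.
#'
#' @param object An `nmrd_fit`.
#' @param n_curve Number of points for the smooth curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmrd_fit <- function(object, n_curve = 200, ...) {
  d <- validate_profiles(object$data)
  d$profile <- profile_id(d)
  curves <- purrr::imap_dfr(object$models, function(mod, id) {
    sel <- d$profile == id
    grid <- 10^seq(log10(min(d$frequency_hz[sel])),
                   log10(max(d$frequency_hz[sel])), length.out = n_curve)
    dec <- decompose_r1(mod, grid)
    tot <- tibble::tibble(frequency_hz = grid, component = "total",
                          r1 = evaluate_r1(mod, grid))
    dplyr::bind_rows(dec, tot) |> dplyr::mutate(profile = id)
  })
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$frequency_hz / 1e6)) +
    ggplot2::geom_point(data = d,
                        ggplot2::aes(y = .data$r1, shape = .data$censored)) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$r1, colour = .data$component)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::facet_wrap(~profile) +
    ggplot2::labs(x = "frequency (MHz)", y = expression(R[1] ~ (s^-1)),
                  colour = NULL)
}
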