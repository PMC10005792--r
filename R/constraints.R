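# Constraint maps: the data structure behind the shared-parameter fitting
# strategy. Every (model parameter x profile) slot is declared free, fixed
# at a value, or shared within a named group that takes a single value
# across its members.

#' Build a constraint map
#'
#' Creates the full (parameter x profile) grid with every slot `free`.
#' Modify it with [cm_share()], [cm_fix()] and [cm_free()]. For a
#' three-component model the parameters are `c_s_dd`, `tau_s`, `c_i_dd`,
#' `tau_i`, `c_f_dd`, `tau_f` and `a`.
#'
#' @param profiles Stacked profile table (see [nmrd_profile()]).
#' @param n_components Number of Lorentzian components (1--4).
#' @return A tibble of class `constraint_map` with columns `parameter`,
#'   `profile`, `kind` (`"free"`, `"fixed"`, `"shared"`), `value` (for
#'   fixed slots) and `group` (for shared slots).
#' @export
constraint_map <- function(profiles, n_components = 3) {
  profiles <- validate_profiles(profiles)
  ids <- unique(profile_id(profiles))
  params <- c(param_names_for(default_component_labels(n_components)), "a")
  cm <- tidyr::expand_grid(parameter = params, profile = ids)
  cm$kind <- "free"
  cm$value <- NA_real_
  cm$group <- NA_character_
  class(cm) <- c("constraint_map", class(cm))
  cm
}

cm_rows <- function(cm, parameters, profiles = NULL) {
  sel <- cm$parameter %in% parameters
  if (!is.null(profiles)) sel <- sel & cm$profile %in% profiles
  if (!any(sel)) stop("no constraint slots match the selection", call. = FALSE)
  sel
}

#' Modify a constraint map
#'
#' `cm_share()` ties a parameter to a single value across profiles (one
#' group per parameter unless `group` is given); `cm_fix()` pins a
#' parameter at a value; `cm_free()` reverts slots to free.
#'
#' @param cm A [constraint_map()].
#' @param parameters Character vector of parameter names.
#' @param profiles Optional character vector of profile ids
#'   (`"<sample>@<temp>K"`); default all.
#' @param group Optional group label (shared slots only).
#' @param value Value for fixed slots (recycled across selected slots).
#' @return The modified constraint map.
#' @export
cm_share <- function(cm, parameters, profiles = NULL, group = NULL) {
  for (p in parameters) {
    sel <- cm_rows(cm, p, profiles)
    cm$kind[sel] <- "shared"
    cm$group[sel] <- group %||% p
    cm$value[sel] <- NA_real_
  }
  cm
}

#' @rdname cm_share
#' @export
cm_fix <- function(cm, parameters, value, profiles = NULL) {
  value <- rep_len(value, length(parameters))
  for (i in seq_along(parameters)) {
    sel <- cm_rows(cm, parameters[i], profiles)
    cm$kind[sel] <- "fixed"
    cm$value[sel] <- value[i]
    cm$group[sel] <- NA_character_
  }
  cm
}

#' @rdname cm_share
#' @export
cm_free <- function(cm, parameters, profiles = NULL) {
  sel <- cm_rows(cm, parameters, profiles)
  cm$kind[sel] <- "free"
  cm$value[sel] <- NA_real_
  cm$group[sel] <- NA_character_
  cm
}

validate_constraint_map <- function(cm) {
  stopifnot(all(c("parameter", "profile", "kind", "value", "group") %in% names(cm)))
  if (!all(cm$kind %in% c("free", "fixed", "shared"))) {
    stop("constraint kinds must be free/fixed/shared", call. = FALSE)
  }
  sh <- cm[cm$kind == "shared", ]
  if (nrow(sh)) {
    sizes <- table(sh$group)
    if (any(sizes < 2)) {
      stop("shared group(s) with fewer than 2 members: ",
           paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
    }
  }
  fx <- cm[cm$kind == "fixed", ]
  if (nrow(fx)) {
    if (any(!is.finite(fx$value))) stop("fixed slots need finite values", call. = FALSE)
    needs_pos <- !fx$parameter %in% "a"
    if (any(fx$value[needs_pos] <= 0) || any(fx$value[!needs_pos] < 0)) {
      stop("fixed values must be positive (>= 0 for `a`)", call. = FALSE)
    }
  }
  invisible(cm)
}

# --- catalog-derived fitting scenario --------------------------------------

#' Constraint map reproducing the catalog's fitting scenario
#'
#' Derives shared/fixed/free declarations from the parameter catalog:
#' a slot flagged fixed in the catalog (no quoted uncertainty) is fixed at
#' its catalog value, and a parameter printed with an identical
#' value-and-uncertainty pair in two or more rows was one jointly fitted
#' parameter, so those slots form a shared group. Everything else is
#' free. For the packaged catalog this reproduces the published scenario:
#' `c_s_dd`, `c_f_dd` and `tau_f` shared across the Haribo profiles (with
#' the one raspberry 323 K exception for `c_f_dd`), `tau_s` fixed for
#' bear/phantasia at 323 K, the offset fixed at its 298 K value at 323 K,
#' and the no-uncertainty Vidal entries fixed.
#'
#' @param profiles Stacked profile table whose `sample_id` values are
#'   either catalog group labels (e.g. `"bear|phantasia"`) or
#'   `"<brand> <jelly>"` names as produced by [make_dataset()].
#' @param catalog Parameter catalog (see [jelly_catalog()]).
#' @return A [constraint_map()].
#' @export
catalog_constraint_map <- function(profiles, catalog = jelly_catalog()) {
  profiles <- validate_profiles(profiles)
  ids <- unique(profile_id(profiles))
  expanded <- if ("jelly" %in% names(catalog)) catalog else expand_catalog(catalog)
  keys <- tibble::tibble(
    key = c(paste0(expanded$parameter_group, "@", expanded$temperature_k, "K"),
            paste0(tolower(expanded$brand), " ", expanded$jelly, "@",
                   expanded$temperature_k, "K")),
    row = rep(seq_len(nrow(expanded)), 2)
  )
  hit <- keys$row[match(ids, keys$key)]
  if (anyNA(hit)) {
    stop("profile(s) not found in catalog: ",
         paste(ids[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  cm <- constraint_map(profiles)
  pn <- c("c_s_dd", "tau_s", "c_i_dd", "tau_i", "c_f_dd", "tau_f", "a")
  for (p in pn) {
    val <- expanded[[p]][hit]
    unc <- expanded[[paste0(p, "_unc")]][hit]
    fx <- expanded[[paste0("fixed_", p)]][hit]
    for (i in which(fx)) cm <- cm_fix(cm, p, val[i], ids[i])
    sig <- paste(val, unc)
    sig[fx] <- NA
    for (s in unique(sig[!is.na(sig)])) {
      members <- ids[!is.na(sig) & sig == s]
      if (length(members) >= 2) {
        cm <- cm_share(cm, p, members,
                       group = paste0(p, "=", val[match(s, sig)]))
      }
    }
  }
  validate_constraint_map(cm)
  cm
}

# --- JSON round-trip --------------------------------------------------------

#' Read / write constraint maps as JSON
#'
#' The file is a JSON array of entries `{parameter, profile, kind, value,
#' group}`; `profile` may be `"*"` to address every profile when reading
#' against a profile set.
#'
#' @param path File path.
#' @param profiles Profile table the constraints apply to (needed on read
#'   to expand `"*"` entries).
#' @param n_components Number of components of the underlying model.
#' @return A [constraint_map()].
#' @export
read_constraints_json <- function(path, profiles, n_components = 3) {
  cm <- constraint_map(profiles, n_components)
  entries <- jsonlite::read_json(path)
  for (e in entries) {
    prof <- if (identical(e$profile %||% "*", "*")) NULL else as.character(e$profile)
    cm <- switch(e$kind,
      shared = cm_share(cm, e$parameter, prof, group = e$group %||% NULL),
      fixed = cm_fix(cm, e$parameter, as.numeric(e$value), prof),
      free = cm_free(cm, e$parameter, prof),
      stop("unknown constraint kind: ", e$kind, call. = FALSE)
    )
  }
  validate_constraint_map(cm)
  cm
}

#' @rdname read_constraints_json
#' @param cm A [constraint_map()].
#' @export
write_constraints_json <- function(cm, path) {
  entries <- purrr::pmap(cm, function(parameter, profile, kind, value, group) {
    e <- list(parameter = parameter, profile = profile, kind = kind)
    if (kind == "fixed") e$value <- value
    if (kind == "shared") e$group <- group
    e
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
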