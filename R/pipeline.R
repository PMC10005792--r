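# Config-driven pipeline stages. These functions are the programmatic
# face of the command-line tool shipped in inst/scripts/nmrd: simulate a
# dataset, fit profiles (with optional component selection and parsimony
# search across temperature pairs), and compare profiles by fingerprint.

#' Build and validate a run configuration
#'
#' @param input Input directory of profile CSVs (fit/compare stages).
#' @param output Output directory; created if needed.
#' @param seed Integer seed threaded to every stochastic step.
#' @param cv Multiplicative noise level for simulation.
#' @param dead_time Instrument dead time, s.
#' @param k_max Largest component count for selection.
#' @param select_k If `TRUE`, choose the component count per profile by
#'   AIC; otherwise fit `n_components`.
#' @param n_components Component count when `select_k = FALSE`.
#' @param parsimony Run the shared-parameter parsimony search on each
#'   sample measured at exactly two temperatures?
#' @param delta_aic Parsimony acceptance threshold.
#' @param n_starts Optimizer starts.
#' @param grouping_threshold Fingerprint grouping cut.
#' @param grid_n,grid_from,grid_to Simulation frequency grid.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input = NULL, output = "nmrd-out", seed = 1,
                       cv = 0.02, dead_time = 3e-3, k_max = 4,
                       select_k = FALSE, n_components = 3,
                       parsimony = TRUE, delta_aic = 10, n_starts = 5,
                       grouping_threshold = 0.03,
                       grid_n = 32, grid_from = 1e4, grid_to = 1e7) {
  cfg <- list(
    input = input, output = output, seed = as.integer(seed), cv = cv,
    dead_time = dead_time, k_max = as.integer(k_max),
    select_k = isTRUE(select_k), n_components = as.integer(n_components),
    parsimony = isTRUE(parsimony), delta_aic = delta_aic,
    n_starts = as.integer(n_starts),
    grouping_threshold = grouping_threshold,
    grid_n = as.integer(grid_n), grid_from = grid_from, grid_to = grid_to
  )
  stopifnot(cfg$cv >= 0, cfg$dead_time >= 0, cfg$k_max >= 1, cfg$k_max <= 4,
            cfg$n_components >= 1, cfg$n_components <= 4,
            cfg$delta_aic > 0, cfg$n_starts >= 1,
            cfg$grouping_threshold > 0, cfg$grid_n >= 4,
            cfg$grid_from > 0, cfg$grid_to > cfg$grid_from)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file with configuration fields.
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

snapshot_config <- function(cfg, dir) {
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
}

#' Pipeline stages
#'
#' `run_simulate()` writes one profile CSV per catalog row (plus the
#' emulated 298 K Vidal profiles), the catalog (CSV + JSON) and a config
#' snapshot. `run_fit()` reads profile CSVs, fits each profile (component
#' selection optional), runs the parsimony search on two-temperature
#' sample pairs, and writes per-profile reports and decomposition curves.
#' `run_compare()` writes the fingerprint distance matrix and grouping.
#'
#' @param config A [run_config()].
#' @return A list of result objects, invisibly for the file-writing
#'   stages.
#' @export
run_simulate <- function(config = run_config()) {
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  grid <- default_grid(config$grid_n, config$grid_from, config$grid_to)
  ds <- make_dataset(freq_hz = grid,
                     noise = noise_spec(config$cv, config$seed),
                     dead_time = config$dead_time)
  paths <- write_dataset(ds, file.path(config$output, "profiles"))
  file.copy(system.file("extdata", "jelly_parameters.csv",
                        package = "nmrdfit", mustWork = TRUE),
            file.path(config$output, "jelly_parameters.csv"),
            overwrite = TRUE)
  write_catalog_json(file.path(config$output, "jelly_parameters.json"))
  snapshot_config(config, config$output)
  message("simulated ", length(paths), " profiles (seed ", config$seed, ")")
  invisible(list(dataset = ds, paths = paths))
}

#' @rdname run_simulate
#' @export
run_fit <- function(config) {
  stopifnot(!is.null(config$input))
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  profiles <- read_dataset(config$input)
  per <- split_profiles(profiles)
  fits <- list()
  selections <- list()
  for (id in names(per)) {
    pr <- per[[id]]
    n_cens <- sum(pr$censored)
    if (n_cens) message(id, ": ", n_cens,
                        " censored point(s) excluded from the fit")
    if (config$select_k) {
      sel <- select_components(pr, k_max = config$k_max,
                               n_starts = config$n_starts, seed = config$seed)
      selections[[id]] <- sel
      fits[[id]] <- sel$fits[[sel$k]]
    } else {
      fits[[id]] <- fit_single(pr, n_components = config$n_components,
                               n_starts = config$n_starts, seed = config$seed)
    }
    slug <- gsub("[^A-Za-z0-9._-]", "-", id)
    write_fit_report(fits[[id]], file.path(config$output,
                                           paste0("fit_", slug, ".csv")))
    mod <- fits[[id]]$models[[id]]
    dec <- decompose_r1(mod, pr$frequency_hz)
    dec$total <- rep(evaluate_r1(mod, pr$frequency_hz),
                     length.out = nrow(dec))
    utils::write.csv(dec, file.path(config$output,
                                    paste0("decomposition_", slug, ".csv")),
                     row.names = FALSE)
  }
  # parsimony across temperature pairs of the same sample
  pairs <- list()
  if (config$parsimony) {
    by_sample <- split(profiles, profiles$sample_id)
    for (sid in names(by_sample)) {
      temps <- unique(by_sample[[sid]]$temperature_k)
      if (length(temps) == 2) {
        res <- parsimony_search(by_sample[[sid]],
                                delta_aic = config$delta_aic,
                                n_starts = config$n_starts,
                                seed = config$seed)
        pairs[[sid]] <- res
        slug <- gsub("[^A-Za-z0-9._-]", "-", sid)
        write_fit_report(res$fit,
                         file.path(config$output,
                                   paste0("parsimony_", slug, ".csv")))
        utils::write.csv(as.data.frame(res$trace),
                         file.path(config$output,
                                   paste0("parsimony_", slug, "_trace.csv")),
                         row.names = FALSE)
      }
    }
  }
  snapshot_config(config, config$output)
  invisible(list(fits = fits, selections = selections, parsimony = pairs))
}

#' @rdname run_simulate
#' @export
run_compare <- function(config) {
  stopifnot(!is.null(config$input))
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  profiles <- read_dataset(config$input)
  d <- profile_distance_matrix(profiles)
  groups <- group_profiles(profiles, threshold = config$grouping_threshold)
  utils::write.csv(as.data.frame(d), file.path(config$output,
                                               "distance_matrix.csv"))
  jsonlite::write_json(
    split(groups$profile, groups$group),
    file.path(config$output, "groups.json"), pretty = TRUE
  )
  txt <- c("fingerprint grouping",
           paste0("threshold: ", config$grouping_threshold),
           purrr::imap_chr(split(groups$profile, groups$group),
                           ~ paste0("group ", .y, ": ",
                                    paste(.x, collapse = ", "))))
  writeLines(txt, file.path(config$output, "groups.txt"))
  snapshot_config(config, config$output)
  invisible(list(distance = d, groups = groups))
}
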