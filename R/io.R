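# CSV interchange. One dialect throughout: comma-separated, "." decimal,
# UTF-8, metadata as leading "# key: value" lines. Frequencies are stored
# in Hz (display layers may prefer MHz).

#' Write / read one NMRD profile as CSV
#'
#' Columns `frequency_hz`, `r1_per_s`, `r1_err_per_s`, `censored` (0/1);
#' `sample_id` and `temperature_k` travel as `# key: value` metadata
#' lines. Writer and reader round-trip losslessly.
#'
#' @param profile Profile table holding exactly one profile.
#' @param path File path.
#' @return `read_profile_csv()` returns a profile tibble;
#'   `write_profile_csv()` returns `path` invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  profile <- validate_profiles(profile)
  if (length(unique(profile_id(profile))) != 1) {
    stop("`write_profile_csv()` writes one profile per file", call. = FALSE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# sample_id: ", profile$sample_id[1]),
    paste0("# temperature_k: ", format(profile$temperature_k[1], digits = 15))
  ), con)
  out <- data.frame(
    frequency_hz = format(profile$frequency_hz, digits = 15, trim = TRUE,
                          scientific = TRUE),
    r1_per_s = format(profile$r1, digits = 15, trim = TRUE),
    r1_err_per_s = ifelse(is.na(profile$r1_err), "",
                          format(profile$r1_err, digits = 15, trim = TRUE)),
    censored = as.integer(profile$censored)
  )
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_sel <- grepl("^#", lines)
  meta <- lines[meta_sel]
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), meta, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1]))
  }
  body <- lines[!meta_sel]
  df <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE),
    error = function(e) stop("malformed profile CSV ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  needed <- c("frequency_hz", "r1_per_s")
  if (!all(needed %in% names(df))) {
    stop("malformed profile CSV ", path, ": missing column(s) ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$frequency_hz))))
  if (length(bad)) {
    stop("malformed profile CSV ", path, ": bad frequency at data line ",
         bad[1], call. = FALSE)
  }
  nmrd_profile(
    frequency_hz = as.numeric(df$frequency_hz),
    r1 = as.numeric(df$r1_per_s),
    r1_err = if ("r1_err_per_s" %in% names(df))
      suppressWarnings(as.numeric(df$r1_err_per_s)) else NA_real_,
    censored = if ("censored" %in% names(df)) df$censored == 1 else FALSE,
    sample_id = get_meta("sample_id"),
    temperature_k = as.numeric(get_meta("temperature_k"))
  )
}

#' Write a whole dataset, one CSV per profile
#'
#' File names follow `<sample_id>_<temperature>K.csv` with spaces replaced
#' by `-`.
#'
#' @param profiles Stacked profile table.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_dataset <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per <- split_profiles(profiles)
  paths <- purrr::imap_chr(per, function(pr, id) {
    fname <- paste0(gsub("[^A-Za-z0-9._-]", "-", id), ".csv")
    write_profile_csv(pr, file.path(dir, fname))
    file.path(dir, fname)
  })
  invisible(unname(paths))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(paths)) stop("no profile CSV files in ", dir, call. = FALSE)
  dplyr::bind_rows(purrr::map(paths, read_profile_csv))
}

#' Write a fit report
#'
#' Parameter table in the layout of the catalog tables (one row per
#' profile and parameter with estimate, 1-sigma uncertainty and
#' free/fixed/shared status) preceded by `#` goodness-of-fit lines
#' (chi-square, reduced chi-square, AIC, free-parameter and point counts).
#'
#' @param fit An `nmrd_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "nmrd_fit"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  g <- glance(fit)
  writeLines(sprintf("# %s: %s", names(g),
                     vapply(g, function(v) format(v, digits = 8), "")), con)
  utils::write.csv(as.data.frame(tidy(fit)), con, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Write the packaged catalog as JSON
#'
#' JSON mirror of the catalog CSV (values as decimal strings, `null`
#' uncertainty where a parameter was fixed).
#'
#' @param path Output path.
#' @param csv_path Catalog CSV to mirror; defaults to the packaged file.
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(path, csv_path = NULL) {
  csv_path <- csv_path %||% system.file("extdata", "jelly_parameters.csv",
                                        package = "nmrdfit", mustWork = TRUE)
  raw <- utils::read.csv(csv_path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  rows <- purrr::pmap(raw, function(...) {
    e <- list(...)
    lapply(e, function(v) if (identical(v, "")) NULL else v)
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
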