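# Single and global dispersion fits, constraint handling, parsimony and
# component-count selection.

test_that("noise-free profiles round-trip their generating parameters", {
  m <- bear_298_model()
  p <- make_profile(m, noise = noise_spec(0, 1), dead_time = 0)
  fit <- fit_single(p, 3, seed = 1)
  truth <- model_to_params(m)
  est <- stats::setNames(tidy(fit)$estimate, tidy(fit)$parameter)
  expect_lt(max(abs(est[names(truth)] / truth - 1)), 1e-3)
  expect_lt(fit$red_chisq, 1e-10)
})

test_that("offset-only data fitted with one component leaves the offset", {
  flat <- relaxation_model(0, 1e-7, offset_a = 27)
  p <- make_profile(flat, noise = noise_spec(0, 2), dead_time = 0)
  fit <- suppressWarnings(fit_single(p, 1, seed = 2))
  est <- stats::setNames(tidy(fit)$estimate, tidy(fit)$parameter)
  expect_equal(unname(est["a"]), 27, tolerance = 1e-4)
  # the fitted component's dispersion amplitude is negligible
  expect_lt(5 * est["c_s_dd"] * est["tau_s"], 1e-3 * 27)
})

test_that("single-profile recovery at 2% noise stays within 15% per parameter", {
  m <- bear_298_model()
  truth <- model_to_params(m)
  errs <- vapply(1:10, function(s) {
    p <- make_profile(m, noise = noise_spec(0.02, 100 + s), dead_time = 0)
    f <- suppressWarnings(fit_single(p, 3, seed = s))
    e <- stats::setNames(tidy(f)$estimate, tidy(f)$parameter)
    abs(e[names(truth)] / truth - 1)
  }, numeric(7))
  expect_lt(max(apply(errs, 1, median)), 0.15)
})

test_that("insufficient uncensored points are refused", {
  m <- bear_298_model()
  p <- make_profile(m, default_grid(7), noise = noise_spec(0, 1), dead_time = 0)
  expect_error(fit_single(p, 3), "insufficient")
  p2 <- make_profile(m, default_grid(12), noise = noise_spec(0, 1), dead_time = 0)
  p2$censored[1:6] <- TRUE
  expect_error(fit_single(p2, 3), "insufficient")
})

test_that("shared slots are bit-identical and fixed slots never move", {
  m <- bear_298_model()
  profs <- dplyr::bind_rows(
    make_profile(m, noise = noise_spec(0.02, 11), dead_time = 0,
                 sample_id = "a"),
    make_profile(m, noise = noise_spec(0.02, 12), dead_time = 0,
                 sample_id = "b")
  )
  cm <- constraint_map(profs)
  cm <- cm_share(cm, c("c_s_dd", "tau_s", "c_f_dd", "tau_f"))
  cm <- cm_fix(cm, "a", 27.0)
  fit <- suppressWarnings(global_fit(profs, cm, seed = 5))
  td <- tidy(fit)
  for (p in c("c_s_dd", "tau_s", "c_f_dd", "tau_f")) {
    vals <- td$estimate[td$parameter == p]
    expect_identical(vals[1], vals[2])
  }
  expect_identical(unique(td$estimate[td$parameter == "a"]), 27.0)
  expect_true(all(is.na(td$std_error[td$status == "fixed"])))
})

test_that("two identical-parameter profiles under full sharing recover one set", {
  m <- bear_298_model()
  profs <- dplyr::bind_rows(
    make_profile(m, noise = noise_spec(0.01, 21), dead_time = 0,
                 sample_id = "x"),
    make_profile(m, noise = noise_spec(0.01, 22), dead_time = 0,
                 sample_id = "y")
  )
  cm <- cm_share(constraint_map(profs), unique(constraint_map(profs)$parameter))
  fit <- suppressWarnings(global_fit(profs, cm, seed = 3))
  truth <- model_to_params(m)
  est <- stats::setNames(
    tidy(fit)$estimate[tidy(fit)$profile == "x@298K"],
    tidy(fit)$parameter[tidy(fit)$profile == "x@298K"]
  )
  expect_lt(max(abs(est[names(truth)] / truth - 1)), 0.12)
  expect_equal(fit$n_free, 7L)
})

test_that("over-constrained maps evaluate without fitting, with a warning", {
  m <- bear_298_model()
  p <- make_profile(m, noise = noise_spec(0, 1), dead_time = 0)
  cm <- constraint_map(p)
  truth <- model_to_params(m)
  for (nm in names(truth)) cm <- cm_fix(cm, nm, unname(truth[nm]))
  expect_warning(fit <- global_fit(p, cm), "no free parameters")
  expect_equal(fit$n_free, 0L)
  expect_lt(fit$chisq, 1e-12)
})

test_that("constraint maps validate sharing and fixing rules", {
  m <- bear_298_model()
  p <- make_profile(m, noise = noise_spec(0, 1), dead_time = 0)
  cm <- constraint_map(p)
  # single-member shared group is rejected
  expect_error(global_fit(p, cm_share(cm, "tau_s")), "fewer than 2")
  expect_error(global_fit(p, cm_fix(cm, "tau_s", -1)), "positive")
})

test_that("parsimony search frees nothing for equal generators", {
  m <- bear_298_model()
  pair <- dplyr::bind_rows(
    make_profile(m, noise = noise_spec(0.02, 31), dead_time = 0,
                 sample_id = "bear", temperature_k = 298),
    make_profile(m, noise = noise_spec(0.02, 32), dead_time = 0,
                 sample_id = "bear", temperature_k = 323)
  )
  res <- suppressWarnings(parsimony_search(pair, seed = 1))
  expect_length(res$freed, 0)
  expect_identical(nrow(res$trace), 5L)
})

test_that("parsimony search finds the intermediate-dynamics difference", {
  b298 <- catalog_row("bear|phantasia", 298)
  b323 <- catalog_row("bear|phantasia", 323)
  # construct a pair differing ONLY in (c_i_dd, tau_i)
  gen323 <- relaxation_model(
    c_dd = c(b298$c_s_dd, b323$c_i_dd, b298$c_f_dd),
    tau = c(b298$tau_s, b323$tau_i, b298$tau_f),
    offset_a = b298$a
  )
  hits <- vapply(1:5, function(s) {
    pair <- dplyr::bind_rows(
      make_profile(catalog_model(b298), noise = noise_spec(0.02, 600 + s),
                   dead_time = 0, sample_id = "bear", temperature_k = 298),
      make_profile(gen323, noise = noise_spec(0.02, 700 + s),
                   dead_time = 0, sample_id = "bear", temperature_k = 323)
    )
    res <- suppressWarnings(parsimony_search(pair, seed = s))
    identical(res$freed, "intermediate")
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("freeing a block never increases chi-square (warm start)", {
  b298 <- catalog_row("bear|phantasia", 298)
  b323 <- catalog_row("bear|phantasia", 323)
  pair <- dplyr::bind_rows(
    make_profile(catalog_model(b298), noise = noise_spec(0.02, 81),
                 dead_time = 0, sample_id = "bear", temperature_k = 298),
    make_profile(catalog_model(b323), noise = noise_spec(0.02, 82),
                 dead_time = 0, sample_id = "bear", temperature_k = 323)
  )
  cm <- cm_share(constraint_map(pair), unique(constraint_map(pair)$parameter))
  base <- suppressWarnings(global_fit(pair, cm, seed = 1))
  freed <- cm_free(cm, c("c_i_dd", "tau_i"))
  refit <- suppressWarnings(global_fit(pair, freed, init = base$models,
                                       seed = 1))
  expect_lte(refit$chisq, base$chisq + 1e-9)
})

test_that("component count is selected by AIC with ties toward fewer", {
  # noise-free three-component profile: k = 3 deterministically
  p3 <- make_profile(bear_298_model(), noise = noise_spec(0, 1), dead_time = 0)
  sel3 <- suppressWarnings(select_components(p3, k_max = 4, seed = 1))
  expect_identical(sel3$k, 3L)
  # one-Lorentzian-plus-offset generator: k = 1
  m1 <- relaxation_model(5e8, 3e-7, offset_a = 20)
  p1 <- make_profile(m1, noise = noise_spec(0.02, 9), dead_time = 0)
  sel1 <- suppressWarnings(select_components(p1, k_max = 3, seed = 2))
  expect_identical(sel1$k, 1L)
})

test_that("constraint JSON files reproduce the catalog scenarios", {
  profs <- gen_brand_profiles("Haribo", 1, cv = 0)
  path <- system.file("extdata", "constraints_haribo.json", package = "nmrdfit")
  cm_file <- read_constraints_json(path, profs)
  cm_built <- catalog_constraint_map(profs)
  expect_equal(
    dplyr::arrange(as.data.frame(cm_file), parameter, profile),
    dplyr::arrange(as.data.frame(cm_built), parameter, profile)
  )
  # the published scenario: c_s_dd, tau_f shared everywhere
  shared_cs <- cm_built[cm_built$parameter == "c_s_dd", ]
  expect_true(all(shared_cs$kind == "shared"))
  # tau_s fixed for bear/phantasia at 323 K
  fx <- cm_built[cm_built$parameter == "tau_s" &
                   cm_built$profile == "bear|phantasia@323K", ]
  expect_identical(fx$kind, "fixed")
  expect_identical(fx$value, 2.43e-6)
})
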