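# Fingerprint distances and grouping.

test_that("resampling is the identity on the profile's own grid", {
  p <- make_profile(bear_298_model(), noise = noise_spec(0.02, 5),
                    dead_time = 0)
  rs <- resample_profile(p, p$frequency_hz)
  expect_equal(rs$r1, p$r1, tolerance = 1e-12)
})

test_that("power laws are exact under log-log interpolation", {
  f <- default_grid(16)
  p <- nmrd_profile(f, f^(-0.5) * 1e5)
  inner <- 10^seq(log10(f[2]), log10(f[15]), length.out = 40)
  rs <- resample_profile(p, inner)
  expect_equal(rs$r1, inner^(-0.5) * 1e5, tolerance = 1e-10)
})

test_that("interpolation error against the model stays below 2%", {
  m <- bear_298_model()
  p <- make_profile(m, default_grid(32), noise = noise_spec(0, 1),
                    dead_time = 0)
  grid16 <- default_grid(16, 1.2e4, 9e6)
  rs <- resample_profile(p, grid16)
  expect_lt(max(abs(rs$r1 / evaluate_r1(m, grid16) - 1)), 0.02)
})

test_that("resampling refuses extrapolation and names the span", {
  p <- make_profile(bear_298_model(), default_grid(16, 1e5, 1e7),
                    noise = noise_spec(0, 1), dead_time = 0)
  expect_error(resample_profile(p, c(1e4, 1e6)), "span")
})

test_that("profile distance is a pseudo-metric", {
  p <- make_profile(bear_298_model(), noise = noise_spec(0.02, 6),
                    dead_time = 0)
  expect_identical(profile_distance(p, p), 0)
  set.seed(71)
  for (rep in 1:10) {
    ms <- replicate(3, {
      pr <- random_model_params()
      relaxation_model(pr$c_dd, pr$tau, pr$a)
    }, simplify = FALSE)
    ps <- lapply(ms, function(m) make_profile(m, noise = noise_spec(0),
                                              dead_time = 0))
    g <- default_grid(24)
    dab <- profile_distance(ps[[1]], ps[[2]], g)
    dbc <- profile_distance(ps[[2]], ps[[3]], g)
    dac <- profile_distance(ps[[1]], ps[[3]], g)
    expect_equal(dab, profile_distance(ps[[2]], ps[[1]], g))
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("distance separates distinct generators above the noise floor", {
  # noise floor: two independent 2% realizations of the same generator
  floor_d <- median(vapply(1:20, function(s) {
    p1 <- make_profile(bear_298_model(), noise = noise_spec(0.02, 2 * s),
                       dead_time = 0)
    p2 <- make_profile(bear_298_model(), noise = noise_spec(0.02, 2 * s + 1),
                       dead_time = 0)
    profile_distance(p1, p2)
  }, 1))
  expect_lt(floor_d, 0.02)
  rasp <- catalog_model(catalog_row("balla raspberry", 298))
  pb <- make_profile(bear_298_model(), noise = noise_spec(0), dead_time = 0)
  pr <- make_profile(rasp, noise = noise_spec(0), dead_time = 0)
  expect_gt(profile_distance(pb, pr), 3 * floor_d)
})

test_that("distance matrix is symmetric with zero diagonal", {
  ds <- make_dataset(noise = noise_spec(0.02, 4), dead_time = 0)
  h <- ds[ds$brand == "Haribo" & ds$temperature_k == 298, ]
  d <- profile_distance_matrix(h)
  expect_identical(d, t(d))
  expect_identical(unname(diag(d)), rep(0, nrow(d)))
  expect_true(all(d >= 0))
})

test_that("grouping reproduces the catalog's shared-row structure", {
  ds <- make_dataset(noise = noise_spec(0, 1), dead_time = 0)
  h <- ds[ds$brand == "Haribo" & ds$temperature_k == 298, ]
  gh <- group_profiles(h)
  gm <- stats::setNames(gh$group, sub("@.*", "", gh$profile))
  expect_identical(gm[["haribo bear"]], gm[["haribo phantasia"]])
  expect_identical(gm[["haribo tropifruity"]], gm[["haribo color-rado"]])
  v <- ds[ds$brand == "Vidal" & ds$temperature_k == 323, ]
  gv <- group_profiles(v)
  vm <- stats::setNames(gv$group, sub("@.*", "", gv$profile))
  expect_identical(vm[["vidal coke"]], vm[["vidal fish"]])
  expect_identical(vm[["vidal fish"]], vm[["vidal pizza"]])
  others <- setdiff(names(vm), "vidal cherry")
  expect_false(any(vm[["vidal cherry"]] == vm[others]))
})

test_that("grouping is order-invariant and monotone in the threshold", {
  ds <- make_dataset(noise = noise_spec(0.02, 8), dead_time = 0)
  h <- ds[ds$brand == "Haribo" & ds$temperature_k == 298, ]
  g1 <- group_profiles(h)
  per <- split(h, profile_id(h))
  shuffled <- dplyr::bind_rows(per[c(4, 1, 6, 2, 5, 3)])
  g2 <- group_profiles(shuffled)
  part1 <- unname(split(g1$profile, g1$group))
  part2 <- unname(split(g2$profile, g2$group))
  expect_setequal(lapply(part1, sort), lapply(part2, sort))
  # raising the threshold never increases the group count
  counts <- vapply(c(0.005, 0.02, 0.05, 0.2, 1),
                   function(th) max(group_profiles(h, threshold = th)$group),
                   1L)
  expect_false(is.unsorted(rev(counts)))
})

test_that("all-identical profiles form a single group", {
  p <- make_profile(bear_298_model(), noise = noise_spec(0, 1), dead_time = 0)
  trio <- dplyr::bind_rows(
    dplyr::mutate(p, sample_id = "a"),
    dplyr::mutate(p, sample_id = "b"),
    dplyr::mutate(p, sample_id = "c")
  )
  g <- group_profiles(trio)
  expect_identical(unique(g$group), 1L)
})
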