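# Model construction, the Lorentzian bracket, evaluation and decomposition.

test_that("lorentzian bracket matches its closed forms and limits", {
  # zero-frequency limit is exactly 5*tau for any tau
  for (tau in c(1e-9, 5.21e-8, 2.43e-6, 1)) {
    expect_identical(lorentzian_bracket(tau, 0), 5 * tau)
  }
  # omega*tau = 1 by construction: 1/2 + 4/5
  expect_equal(lorentzian_bracket(1, 1), 1.3)
  # direct arithmetic substitution at the fast-component dispersion point
  tau <- 5.21e-8
  w <- 2 * pi * 1e7
  by_hand <- tau / (1 + (w * tau)^2) + 4 * tau / (1 + (2 * w * tau)^2)
  expect_equal(lorentzian_bracket(tau, w), by_hand, tolerance = 1e-14)
  expect_equal(by_hand, 9.20e-9, tolerance = 1e-3)
  # strictly decreasing in omega
  omegas <- 10^seq(0, 9, length.out = 200)
  vals <- lorentzian_bracket(3e-7, omegas)
  expect_true(all(diff(vals) < 0))
  expect_error(lorentzian_bracket(-1e-9, 1), "positive")
  expect_error(lorentzian_bracket(0, 1), "positive")
})

test_that("model construction enforces invariants and sorts components", {
  m <- relaxation_model(c(3, 1, 2), c(1e-8, 1e-6, 1e-7), offset_a = 5)
  expect_equal(m$components$tau, c(1e-6, 1e-7, 1e-8))
  expect_equal(m$components$c_dd, c(1, 2, 3))
  expect_equal(m$components$label, c("slow", "intermediate", "fast"))
  expect_error(relaxation_model(1, -1e-6), "tau")
  expect_error(relaxation_model(-1, 1e-6), "c_dd")
  expect_error(relaxation_model(1, 1e-6, offset_a = -1), "offset_a")
  expect_error(relaxation_model(rep(1, 5), rep(1e-6, 5) * 1:5), "between 1 and 4")
  expect_error(relaxation_model(c(1, 1), c(1e-6, 1e-7),
                                labels = c("slow", "slow")), "unique")
})

test_that("evaluate_r1 reproduces hand-computed catalog values", {
  m <- bear_298_model()
  # zero-frequency closed form 5*sum(C*tau) + A
  lf <- 5 * sum(c(1.46e8, 1.00e9, 1.25e9) * c(2.43e-6, 4.83e-7, 5.21e-8)) + 27
  expect_equal(evaluate_r1(m, 1e-3), lf, tolerance = 1e-12)
  expect_equal(lf, 4.54e3, tolerance = 1e-2)
  # term-by-term arithmetic at 10 MHz
  expect_equal(evaluate_r1(m, 1e7),
               scalar_r1_oracle(c(1.46e8, 1.00e9, 1.25e9),
                                c(2.43e-6, 4.83e-7, 5.21e-8), 27, 1e7),
               tolerance = 1e-14)
  expect_equal(evaluate_r1(m, 1e7), 39.6, tolerance = 2e-3)
  # offset-only model is flat
  flat <- relaxation_model(0, 1e-7, offset_a = 27)
  expect_equal(evaluate_r1(flat, default_grid()), rep(27, 32))
  expect_error(evaluate_r1(m, numeric(0)), "empty")
})

test_that("R1 is non-increasing in frequency and approaches the offset", {
  set.seed(41)
  for (rep in 1:20) {
    p <- random_model_params()
    m <- relaxation_model(p$c_dd, p$tau, p$a)
    grid <- 10^seq(2, 9, length.out = 100)
    r1 <- evaluate_r1(m, grid)
    expect_true(all(diff(r1) <= 1e-12 * r1[-length(r1)]))
    # high-frequency bound: R1 - A <= 5*sum(C tau) / (omega*tau_min)^2
    nu_hi <- 1e3 / (2 * pi * min(p$tau))
    bound <- 5 * sum(p$c_dd * p$tau) / (2 * pi * nu_hi * min(p$tau))^2
    expect_lt(evaluate_r1(m, nu_hi) - p$a, bound + 1e-12)
  }
})

test_that("time-frequency scaling law holds", {
  set.seed(42)
  for (rep in 1:10) {
    p <- random_model_params()
    s <- 10^stats::runif(1, -2, 2)
    nu <- 10^stats::runif(5, 3, 8)
    m1 <- relaxation_model(p$c_dd, p$tau, 0)
    m2 <- relaxation_model(p$c_dd, p$tau * s, 0)
    expect_equal(evaluate_r1(m2, nu / s), s * evaluate_r1(m1, nu),
                 tolerance = 1e-12)
  }
})

test_that("decomposition reconstructs the total exactly", {
  set.seed(43)
  grid <- default_grid(16)
  for (rep in 1:10) {
    p <- random_model_params()
    m <- relaxation_model(p$c_dd, p$tau, p$a)
    dec <- decompose_r1(m, grid)
    total <- dec |>
      dplyr::group_by(frequency_hz) |>
      dplyr::summarise(r1 = sum(r1)) |>
      dplyr::pull(r1)
    expect_equal(total, evaluate_r1(m, grid), tolerance = 1e-12)
  }
  # slow component of the bear generator at low frequency: 5*C_s*tau_s
  dec <- decompose_r1(bear_298_model(), 1e-3)
  expect_equal(dec$r1[dec$component == "slow"], 5 * 1.46e8 * 2.43e-6,
               tolerance = 1e-10)
  expect_equal(dec$r1[dec$component == "slow"], 1.77e3, tolerance = 3e-3)
  # single-component model decomposes into itself plus offset
  m1 <- relaxation_model(1e9, 1e-7, 10)
  d1 <- decompose_r1(m1, grid)
  expect_setequal(unique(d1$component), c("slow", "offset"))
})

test_that("flat parameter names round-trip through model objects", {
  m <- bear_298_model()
  p <- model_to_params(m)
  expect_named(p, c("c_s_dd", "tau_s", "c_i_dd", "tau_i",
                    "c_f_dd", "tau_f", "a"))
  m2 <- model_from_params(p)
  expect_equal(m2$components, m$components)
  expect_equal(m2$offset_a, m$offset_a)
})

test_that("parameter JSON files round-trip decimal strings exactly", {
  tbl <- tibble::tibble(
    parameter = c("c_s_dd", "tau_s", "a"),
    value = c("1.46e8", "2.43e-6", "27.0"),
    uncertainty = c("6.1e7", NA, "3.2"),
    fixed = c(FALSE, TRUE, FALSE)
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_parameter_json(tbl, path)
  back <- read_parameter_json(path)
  expect_identical(back$value, tbl$value)
  expect_identical(back$uncertainty, tbl$uncertainty)
  expect_identical(back$fixed, tbl$fixed)
})
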