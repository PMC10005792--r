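# Shared fixtures: catalog-derived generator models and small generators
# used across the suite. Everything is built in code at test time.

param_names <- c("c_s_dd", "tau_s", "c_i_dd", "tau_i", "c_f_dd", "tau_f", "a")

bear_298_model <- function() {
  relaxation_model(
    c_dd = c(1.46e8, 1.00e9, 1.25e9),
    tau = c(2.43e-6, 4.83e-7, 5.21e-8),
    offset_a = 27.0
  )
}

catalog_row <- function(jellies, temperature_k) {
  ct <- jelly_catalog()
  ct[ct$jellies == jellies & ct$temperature_k == temperature_k, ][1, ]
}

# one profile per catalog row for a brand, generated uncensored
gen_brand_profiles <- function(brand, seed, cv = 0.02, catalog = jelly_catalog()) {
  rows <- catalog[catalog$brand == brand, ]
  dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(i) {
    row <- rows[i, ]
    make_profile(catalog_model(row), noise = noise_spec(cv, seed * 1000 + i),
                 dead_time = 0, sample_id = row$jellies,
                 temperature_k = row$temperature_k)
  }))
}

# per-slot relative errors of a catalog-scenario global fit vs generator truth
scenario_errors <- function(brand, seed, cv = 0.02, n_starts = 3) {
  catalog <- jelly_catalog()
  profs <- gen_brand_profiles(brand, seed, cv, catalog)
  cm <- catalog_constraint_map(profs, catalog)
  f <- suppressWarnings(global_fit(profs, cm, n_starts = n_starts, seed = seed))
  td <- tidy(f)
  rows <- catalog[catalog$brand == brand, ]
  truth <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    data.frame(profile = paste0(rows$jellies[i], "@", rows$temperature_k[i], "K"),
               parameter = param_names,
               truth = unlist(rows[i, param_names]))
  }))
  td <- merge(td, truth)
  td <- td[td$status != "fixed", ]
  data.frame(slot = paste0(td$parameter, "|", td$profile),
             err = abs(td$estimate / td$truth - 1))
}

# plain-arithmetic scalar oracle for the dispersion model (independent of
# the vectorized implementation path)
scalar_r1_oracle <- function(c_dd, tau, a, freq_hz) {
  out <- numeric(length(freq_hz))
  for (i in seq_along(freq_hz)) {
    w <- 2 * pi * freq_hz[i]
    acc <- a
    for (k in seq_along(c_dd)) {
      acc <- acc + c_dd[k] * (tau[k] / (1 + (w * tau[k])^2) +
                                4 * tau[k] / (1 + (2 * w * tau[k])^2))
    }
    out[i] <- acc
  }
  out
}

random_model_params <- function() {
  k <- sample(1:4, 1)
  list(c_dd = 10^stats::runif(k, 6, 10),
       tau = sort(10^stats::runif(k, -9, -5), decreasing = TRUE),
       a = stats::runif(1, 0, 50))
}
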