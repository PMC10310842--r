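test_that("the gaussian-scatter study is unbiased and its SEM scales as 1/sqrt(n)", {
  st <- gaussian_pf_study(sigma_pf = 0.1, replicates = 3000, n_max = 100,
                          seed = 42)
  # unbiased within 3 SEM of the full sample
  sem_full <- st$sd_Ea / sqrt(st$replicates)
  expect_lt(abs(mean(st$samples) - st$truth_Ea), 3 * sem_full)
  # SEM column follows sd/sqrt(n) exactly, i.e. proportional to 1/sqrt(n)
  s <- st$summary
  expect_equal(s$sem_kcal * sqrt(s$n), rep(J_to_kcal(st$sd_Ea), nrow(s)),
               tolerance = 1e-12)
  # SEM(n=4)/SEM(n=100) = 5 by construction
  expect_equal(s$sem_kcal[s$n == 4] / s$sem_kcal[s$n == 100], 5,
               tolerance = 1e-10)
})

test_that("the empirical Ea spread matches the closed-form OLS prediction", {
  st <- gaussian_pf_study(sigma_pf = 0.1, replicates = 4000, seed = 7)
  x <- 1 / st$temperatures
  sxx <- sum((x - mean(x))^2)
  # analytic CLT oracle with the exact sd of log(1 + eps)
  set.seed(1); eps <- rnorm(2e5, 0, 0.1)
  sd_ln <- sd(log(1 + eps[eps > -1]))
  expected <- aquaflux_constants$R * sd_ln / sqrt(sxx)
  expect_lt(abs(st$sd_Ea / expected - 1), 0.05)
})

test_that("measurements needed for 5% precision increase with the permeability scatter", {
  n_needed <- vapply(c(0.05, 0.1, 0.2, 0.3), function(sig) {
    st <- gaussian_pf_study(sigma_pf = sig, replicates = 1500,
                            n_max = 1500, seed = 100)
    thr <- 0.05 * abs(mean(st$samples))
    idx <- which(st$summary$sem_kcal * aquaflux_constants$kcal <= thr)
    if (length(idx)) min(st$summary$n[idx]) else Inf
  }, 0)
  expect_true(all(diff(n_needed) > 0))
})

test_that("widening the temperature range shrinks the Ea spread as OLS leverage predicts", {
  ranges <- list(seq(288, 292),                 #  4 K
                 c(283, 287, 291, 295, 299),    # 16 K
                 c(277, 287, 297, 307, 317))    # 40 K
  st <- temperature_range_study(ranges = ranges, sigma_pf = 0.1,
                                replicates = 3000, seed = 3)
  s <- st$summary
  expect_true(all(diff(s$sd_Ea_kcal) < 0))
  expect_true(all(diff(s$ci_hi_kcal - s$ci_lo_kcal) < 0))
  # empirical spread ratio 4 K vs 40 K matches the 1/T leverage ratio
  ratio_emp <- s$sd_Ea_kcal[1] / s$sd_Ea_kcal[3]
  ratio_ols <- s$closed_form_se_kcal[1] / s$closed_form_se_kcal[3]
  expect_lt(abs(ratio_emp / ratio_ols - 1), 0.05)

  # identical ranges give identical sampling distributions under one seed
  st2 <- temperature_range_study(ranges = ranges[c(2, 2)], sigma_pf = 0.1,
                                 replicates = 200, seed = 9)
  expect_identical(st2$summary$sd_Ea_kcal[1], st2$summary$sd_Ea_kcal[2])
})

test_that("temperature bias inflates Ea monotonically and independently of the true Ea", {
  st <- temperature_bias_study(ddt_list = c(0, 2, 4, 6), sigma_pf = 0,
                               replicates = 1, seed = 1)
  err <- st$summary$rel_error
  expect_lt(abs(err[1]), 1e-10)          # no bias, no error
  expect_true(all(diff(err) > 0))        # monotone in ddt
  expect_true(all(err[-1] > 0))          # overestimation

  # the relative error is an algebraic ratio of 1/T spreads: independent
  # of the true activation energy
  hot <- population_model(N_mean = 20, X = 0.4, Ea_c_kcal = 10)
  st2 <- temperature_bias_study(ddt_list = c(0, 2, 4, 6), sigma_pf = 0,
                                replicates = 1, true_model = hot, seed = 1)
  expect_equal(st2$summary$rel_error, err, tolerance = 1e-9)
})

test_that("with noise, the Ea error still grows monotonically with the temperature bias", {
  st <- temperature_bias_study(ddt_list = c(0, 3, 6), sigma_pf = 0.05,
                               replicates = 400, seed = 17)
  expect_true(all(diff(st$summary$rel_error) > 0))
})

test_that("reconstitution heterogeneity: error falls with N_mean and the global fit wins", {
  st <- reconstitution_study(N_mean_grid = c(5, 40), X_grid = 0.5,
                             methods = c("global", "analytical",
                                         "exponential"),
                             replicates = 12, seed = 2)
  s <- st$summary
  for (m in unique(s$method)) {
    e <- s[s$method == m, ]
    expect_lt(e$rms_rel_error[e$N_mean == 40],
              e$rms_rel_error[e$N_mean == 5])
  }
  agg <- tapply(s$rms_rel_error, s$method, mean)
  expect_lte(agg[["global"]], agg[["analytical"]])
  expect_lte(agg[["analytical"]], agg[["exponential"]])
})

test_that("a slow channel is harder: smaller pf gives larger Ea error", {
  st <- reconstitution_study(N_mean_grid = 10, X_grid = 0.5,
                             pf_grid_cm3_s = c(2.0e-14, 3.2e-13),
                             methods = "global", replicates = 8, seed = 4)
  s <- st$summary
  expect_gt(s$rms_rel_error[s$pf_cm3_s == 2.0e-14],
            s$rms_rel_error[s$pf_cm3_s == 3.2e-13])
})
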