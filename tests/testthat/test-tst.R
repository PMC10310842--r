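R <- aquaflux_constants$R

test_that("enthalpy of activation reproduces the reported AQP1 value", {
  # Ea = 3.75 kcal/mol at 298 K -> dH = 3.16 kcal/mol
  dH <- enthalpy_of_activation(kcal_to_J(3.75), 298)
  expect_equal(J_to_kcal(dH), 3.16, tolerance = 0.002)
  # dH at the measurement temperature, scalar arithmetic
  expect_equal(enthalpy_of_activation(kcal_to_J(3.75), 278),
               kcal_to_J(3.75) - R * 278, tolerance = 1e-10)
  # Ea = RT boundary
  expect_equal(enthalpy_of_activation(R * 298, 298), 0)
})

test_that("Gibbs energy from pf obeys its defining identities", {
  nu0 <- attempt_frequency(278)
  vw <- aquaflux_constants$V_w / aquaflux_constants$NA_
  expect_equal(gibbs_from_pf(nu0 * vw, 278), 0, tolerance = 1e-9)
  # halving pf raises dG by RT ln 2
  expect_equal(gibbs_from_pf(1e-19, 278) - gibbs_from_pf(2e-19, 278),
               R * 278 * log(2), tolerance = 1e-9)
  # the AQP1 number against independent scalar arithmetic
  pf <- cm3_s_to_m3_s(3.2e-13)
  expect_equal(gibbs_from_pf(pf, 278), R * 278 * log(nu0 * vw / pf),
               tolerance = 1e-12)
})

test_that("entropy from pf hits the AQP1 value and its algebraic identities", {
  pf <- cm3_s_to_m3_s(3.2e-13); Ea <- kcal_to_J(3.75)
  dS <- entropy_from_pf(pf, Ea, 278, 0.48)
  # reported: 2.01 +- 0.82; the printed inputs land within +-0.15 of it
  expect_lt(abs(dS - 2.01), 0.15)

  # prefactor identity: pf = e * kappa * nu0 * vw * exp(-Ea/RT) -> dS = 0
  nu0 <- attempt_frequency(278)
  vw <- aquaflux_constants$V_w / aquaflux_constants$NA_
  pf0 <- exp(1) * 0.48 * nu0 * vw * exp(-Ea / (R * 278))
  expect_equal(entropy_from_pf(pf0, Ea, 278, 0.48), 0, tolerance = 1e-9)

  expect_error(entropy_from_pf(pf, Ea, 278, 1.2), "kappa")
  expect_error(entropy_from_pf(pf, Ea, 278, 0), "kappa")
})

test_that("kappa rescaling matches the exact identity and the reported sweep", {
  pf <- cm3_s_to_m3_s(3.2e-13); Ea <- kcal_to_J(3.75)
  dS48 <- entropy_from_pf(pf, Ea, 278, 0.48)
  expect_identical(entropy_rescale_kappa(dS48, 0.48, 0.48), dS48)

  # rescaling is exactly equivalent to recomputing at the new kappa
  for (k2 in c(0.1, 0.25, 0.75, 1)) {
    expect_equal(entropy_rescale_kappa(dS48, 0.48, k2),
                 entropy_from_pf(pf, Ea, 278, k2), tolerance = 1e-12)
  }
  # reported sweep values 15.05 / 7.44 / -1.7 / -4.09 J/(mol K)
  expect_lt(abs(entropy_rescale_kappa(dS48, 0.48, 0.1) - 15.05), 0.15)
  expect_lt(abs(entropy_rescale_kappa(dS48, 0.48, 0.25) - 7.44), 0.15)
  expect_lt(abs(entropy_rescale_kappa(dS48, 0.48, 0.75) - (-1.7)), 0.15)
  expect_lt(abs(entropy_rescale_kappa(dS48, 0.48, 1) - (-4.09)), 0.15)
})

test_that("Gibbs decomposition reproduces the reported free-energy split", {
  # dH = 3.16 kcal/mol, dS = 2.01 J/(mol K) at 298 K
  dH <- kcal_to_J(3.16)
  expect_lt(abs(J_to_kcal(298 * 2.01) - 0.14), 0.005)
  expect_lt(abs(J_to_kcal(gibbs_decomposition(dH, 2.01, 298)) - 3.02),
            0.01)
  expect_equal(gibbs_decomposition(dH, 0, 298), dH)
})

test_that("Gibbs from pf equals the kappa = 1 decomposition route", {
  # algebraic identity: RT ln(nu0 vw / pf) == (Ea - RT) - T dS(kappa = 1)
  set.seed(5)
  for (i in 1:20) {
    pf <- 10^runif(1, -21, -17); Ea <- kcal_to_J(runif(1, 1, 10))
    Tk <- runif(1, 270, 310)
    dG_direct <- gibbs_from_pf(pf, Tk)
    dS1 <- entropy_from_pf(pf, Ea, Tk, 1)
    dG_decomp <- gibbs_decomposition(enthalpy_of_activation(Ea, Tk),
                                     dS1, Tk)
    expect_equal(dG_direct, dG_decomp, tolerance = 1e-9)
  }
})

test_that("entropy error propagation evaluates its closed form", {
  expect_equal(entropy_error(0, 0, 0, 0.48, 278), 0)
  # single-term reduction: only the kappa uncertainty
  expect_equal(entropy_error(0, 0, 0.04, 0.48, 278), R * 0.04 / 0.48,
               tolerance = 1e-12)
  # all three terms vs scalar arithmetic
  expect_equal(entropy_error(0.05, 669, 0.04, 0.48, 278),
               R * sqrt(0.05^2 + (669 / (R * 278))^2 + (0.04 / 0.48)^2),
               tolerance = 1e-12)
})

test_that("the Eyring linear fit inverts exact Eyring data and matches the prefactor route", {
  kB <- aquaflux_constants$kB; h <- aquaflux_constants$h
  vw <- aquaflux_constants$V_w / aquaflux_constants$NA_
  dH <- kcal_to_J(3.2); dS <- 2.0; kap <- 0.48
  Tk <- c(277, 283, 289, 295, 301)
  pf <- kap * kB * Tk / h * vw * exp(dS / R) * exp(-dH / (R * Tk))
  fit <- eyring_linear_fit(pf, Tk, kappa = kap)
  expect_equal(fit$dH, dH, tolerance = 1e-9)
  expect_equal(fit$dS, dS, tolerance = 1e-9)

  # route consistency: the prefactor (Arrhenius) route gives the same
  # entropy at each temperature after the Ea <-> dH conversion
  for (Tk_i in Tk) {
    pf_i <- kap * kB * Tk_i / h * vw * exp(dS / R) * exp(-dH / (R * Tk_i))
    dS_i <- entropy_from_pf(pf_i, dH + R * Tk_i, Tk_i, kap)
    expect_equal(dS_i, dS, tolerance = 1e-6)
  }
})

test_that("the Eyring fit is unbiased under multiplicative noise", {
  kB <- aquaflux_constants$kB; h <- aquaflux_constants$h
  vw <- aquaflux_constants$V_w / aquaflux_constants$NA_
  dH <- kcal_to_J(3.2); dS <- 2.0; kap <- 0.48
  Tk <- c(277, 283, 289, 295, 301)
  pf0 <- kap * kB * Tk / h * vw * exp(dS / R) * exp(-dH / (R * Tk))
  set.seed(31)
  n_rep <- 1000
  est <- t(vapply(seq_len(n_rep), function(r) {
    f <- exp(rnorm(5, 0, 0.05))   # 5% multiplicative noise
    coef(eyring_linear_fit(pf0 * f, Tk, kappa = kap))
  }, c(dH = 0, dS = 0)))
  expect_lt(abs(mean(est[, "dH"]) - dH),
            3 * sd(est[, "dH"]) / sqrt(n_rep))
  expect_lt(abs(mean(est[, "dS"]) - dS),
            3 * sd(est[, "dS"]) / sqrt(n_rep))
})

test_that("tst_decompose chains the pieces consistently", {
  res <- tst_decompose(pf = cm3_s_to_m3_s(3.2e-13), Ea = kcal_to_J(3.75),
                       kappa = 0.48, temperature = 278, T_eval = 298,
                       rel_dpf = 0.05, dEa = kcal_to_J(0.16),
                       dkappa = 0.04)
  expect_equal(res$dG, res$dH - 298 * res$dS, tolerance = 1e-10)
  expect_lt(abs(res$dS - 2.01), 0.15)
  expect_equal(J_to_kcal(res$dH), 3.16, tolerance = 0.002)
  expect_true(is.finite(res$dS_err) && res$dS_err > 0)
  # the sensitivity helper covers the experimental window
  # the evaluation-temperature choice moves dS by well under the
  # propagated uncertainty across the experimental window
  sens <- entropy_temperature_sensitivity(cm3_s_to_m3_s(3.2e-13),
                                          kcal_to_J(3.75), 0.48,
                                          pf_temperature = 278)
  expect_equal(nrow(sens), 7)
  expect_lt(diff(range(sens$dS_J_molK)), res$dS_err)
})
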