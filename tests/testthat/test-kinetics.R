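test_that("shrinkage rate vanishes at isotonic equilibrium and carries the right sign", {
  spec <- vesicle_spec(c_in0 = 300, c_out = 300)
  expect_equal(shrinkage_rate(spec$V0, spec, 6e-6), 0)

  spec2 <- vesicle_spec()   # hyperosmotic exterior
  expect_lt(shrinkage_rate(spec2$V0, spec2, 6e-6), 0)
  # swollen vesicle in hypoosmotic bath swells further
  spec3 <- vesicle_spec(c_in0 = 360, c_out = 210)
  expect_gt(shrinkage_rate(spec3$V0, spec3, 6e-6), 0)
})

test_that("shrinkage rate equals the product of its four factors", {
  # r0 = 50 nm, Pf = 6 um/s, 210 -> 360 mosmol/L, V = V0
  spec <- vesicle_spec(r0_nm = 50, c_in0 = 210, c_out = 360)
  S <- 4 * pi * (50e-9)^2
  expected <- S * 6e-6 * 18e-6 * (210 - 360)   # hand-computed, m3/s
  expect_equal(shrinkage_rate(spec$V0, spec, 6e-6), expected,
               tolerance = 1e-12)
})

test_that("shrinkage rate rejects invalid input", {
  spec <- vesicle_spec()
  expect_error(shrinkage_rate(0, spec, 6e-6), "positive")
  expect_error(shrinkage_rate(spec$V0, spec, -1e-6), "non-negative")
})

test_that("closed-form volume hits the t = 0 and t -> Inf limits", {
  spec <- vesicle_spec()
  expect_equal(volume_analytic(0, spec, 6e-6), spec$V0, tolerance = 1e-12)
  expect_equal(volume_analytic(1e9, spec, 6e-6),
               spec$V0 * spec$c_in0 / spec$c_out, tolerance = 1e-10)
})

test_that("closed-form volume is strictly decreasing and bounded below", {
  spec <- vesicle_spec()
  tg <- seq(0, 0.15, length.out = 150)   # about 4 relaxation times
  V <- volume_analytic(tg, spec, 50e-6)
  expect_true(all(diff(V) < 0))
  Vlong <- volume_analytic(seq(0, 2, length.out = 100), spec, 50e-6)
  expect_true(all(diff(Vlong) <= 0))
  expect_true(all(Vlong >= spec$V0 * spec$c_in0 / spec$c_out))
})

test_that("closed form agrees with adaptive ODE integration mid-course", {
  # the conditions of the reconstitution scenario: PLE membrane 6 um/s
  spec <- vesicle_spec(r0_nm = 50, c_in0 = 210, c_out = 360)
  tg <- seq(0, 1.5, length.out = 40)
  Va <- volume_analytic(tg, spec, 6e-6)
  Vn <- volume_numeric(tg, spec, 6e-6)
  expect_equal(Va, Vn, tolerance = 1e-8)
})

test_that("numeric solver is constant for isotonic input, decreasing otherwise", {
  iso <- vesicle_spec(c_in0 = 250, c_out = 250)
  tg <- seq(0, 1, length.out = 30)
  expect_equal(volume_numeric(tg, iso, 6e-6), rep(iso$V0, 30),
               tolerance = 1e-9)
  hyper <- vesicle_spec()
  expect_true(all(diff(volume_numeric(tg, hyper, 20e-6)) < 0))
})

test_that("both solvers agree over a randomized parameter sweep", {
  # Pf in [1, 500] um/s, r0 in [40, 80] nm, gradients up to 0.5 osmol/L
  set.seed(7)
  tg <- seq(0, 1, length.out = 12)
  worst <- 0
  for (i in 1:100) {
    spec <- vesicle_spec(r0_nm = runif(1, 40, 80),
                         c_in0 = runif(1, 100, 400),
                         c_out = runif(1, 100, 400) + runif(1, 10, 500))
    Pf <- um_s_to_m_s(runif(1, 1, 500))
    rel <- max(abs(volume_analytic(tg, spec, Pf) /
                     volume_numeric(tg, spec, Pf) - 1))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("intensity map is the stated affine transform", {
  spec <- vesicle_spec()
  b <- 1 / spec$V0
  expect_equal(intensity_from_volume(spec$V0, b), 0)
  expect_equal(intensity_from_volume(spec$V0 / 2, b), 0.5)
  expect_error(intensity_from_volume(spec$V0, -1), "b must be")
})

test_that("mixture volume handles the degenerate fractions", {
  spec <- vesicle_spec()
  tg <- seq(0, 1, length.out = 25)
  expect_identical(mixture_volume(tg, 1, spec, 6e-6, 2e-4),
                   volume_analytic(tg, spec, 6e-6))
  expect_identical(mixture_volume(tg, 0, spec, 6e-6, 2e-4),
                   volume_analytic(tg, spec, 2e-4))
  # equal permeabilities collapse to a single population
  expect_equal(mixture_volume(tg, 0.5, spec, 6e-6, 6e-6),
               volume_analytic(tg, spec, 6e-6), tolerance = 1e-15)
  expect_error(mixture_volume(tg, 1.2, spec, 6e-6, 2e-4), "\\[0, 1\\]")
})

test_that("single-channel and total permeability invert each other", {
  # Pf_c = 10 um/s, d = 100 nm, n = 10 -> pi * 1e-3 um/s * (1e-5 cm)^2 ...
  pf <- pf_single_channel(um_s_to_m_s(10), 10, 100e-9)
  expect_equal(m3_s_to_cm3_s(pf), pi * 1e-3 * (1e-5)^2 / 10,
               tolerance = 1e-12)  # 3.1416e-14 cm3/s
  expect_equal(m3_s_to_cm3_s(pf), 3.1416e-14, tolerance = 1e-4)
  expect_equal(pf_single_channel(0, 5, 100e-9), 0)

  # reported AQP1-like value: pf = 3.2e-13 cm3/s, n = 100, d = 100 nm
  Pf <- total_pf(um_s_to_m_s(6), cm3_s_to_m3_s(3.2e-13), 100, 100e-9)
  expect_equal(Pf, 6e-6 + 100 * 3.2e-19 / (pi * (100e-9)^2),
               tolerance = 1e-12)

  # round trip and linearity in n
  set.seed(11)
  for (i in 1:20) {
    Pfc <- runif(1, 1e-6, 1e-3); n <- sample(1:200, 1); d <- runif(1, 5e-8, 2e-7)
    pf_i <- pf_single_channel(Pfc, n, d)
    expect_equal(total_pf(0, pf_i, n, d), Pfc, tolerance = 1e-12)
  }
  n1 <- 7; n2 <- 13; pf0 <- 3.2e-19; d <- 1e-7; Pfm <- 6e-6
  expect_equal(total_pf(Pfm, pf0, n1 + n2, d),
               Pfm + (total_pf(0, pf0, n1, d) + total_pf(0, pf0, n2, d)),
               tolerance = 1e-12)
  expect_equal(total_pf(Pfm, pf0, 0, d), Pfm)
})
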