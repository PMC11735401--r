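test_that("trait shift sums per-locus gains in the requested direction", {
  loci <- toy_oriented()  # (p .5, b .1), (p .1, b .2)
  expect_equal(trait_shift(loci, 2, "decrease"), -0.14)
  expect_equal(trait_shift(loci, 1, "decrease"), -0.10)
  expect_equal(trait_shift(loci, 2, "increase"),
               2 * (1 - 0.5) * 0.1 + 2 * (1 - 0.1) * 0.2)
  near_zero <- toy_oriented(p = c(1e-12, 1e-12), beta = c(0.1, 0.2))
  expect_equal(trait_shift(near_zero, 2, "decrease"), 0, tolerance = 1e-10)
  near_one <- toy_oriented(p = c(1 - 1e-12, 1 - 1e-12), beta = c(0.1, 0.2))
  expect_equal(trait_shift(near_one, 2, "increase"), 0, tolerance = 1e-10)
  expect_error(trait_shift(loci, 3), "exceeds")
})

test_that("sd of gain is the root variance explained and matches HWE simulation", {
  loci <- toy_oriented()
  expect_equal(sd_of_gain(loci, 2), sqrt(0.005 + 0.0072), tolerance = 1e-12)
  set.seed(3)
  g <- rbinom(4e5, 2, 0.5) * 0.1 + rbinom(4e5, 2, 0.1) * 0.2
  expect_equal(sd_of_gain(loci, 2), sd(g), tolerance = 0.01)
})

test_that("disease curve reproduces the closed form with consistent bands", {
  trait <- trait_config("toy", "binary", prevalence_K = 0.05)
  loci <- toy_oriented(p = 0.2, beta = 0.3, ids = "only")
  cv <- disease_curve(edit_plan(trait, loci, max_m = 1))
  expect_equal(cv$delta, 0.12)
  expect_equal(cv$K_g, 0.038794, tolerance = 1e-4)  # MC-oracle frozen value
  expect_equal(cv$fold_change, 0.05 / cv$K_g)
  expect_true(cv$band_low <= cv$K_g && cv$K_g <= cv$band_high)
  expect_error(quantitative_curve(edit_plan(trait, loci)), "quantitative")
})

test_that("disease curve is monotone in m and attenuates with rg", {
  trait <- trait_config("toy", "binary", prevalence_K = 0.1)
  set.seed(9)
  loci <- rank_loci(toy_oriented(p = runif(10, 0.05, 0.95),
                                 beta = runif(10, 0.02, 0.3)), 10)
  full <- disease_curve(edit_plan(trait, loci, max_m = 10, rg = 1))
  expect_true(all(diff(full$K_g) < 0))
  expect_true(all(diff(full$fold_change) > 0))
  expect_true(all(full$band_low <= full$K_g & full$K_g <= full$band_high))
  # rg = 0 leaves prevalence at baseline for every m
  flat <- disease_curve(edit_plan(trait, loci, max_m = 10, rg = 0))
  expect_equal(flat$K_g, rep(0.1, 10))
  expect_equal(flat$fold_change, rep(1, 10))
  # K_g nondecreasing as rg decreases; delta scales linearly in rg
  for (rg in c(0.25, 0.5, 0.75)) {
    att <- disease_curve(edit_plan(trait, loci, max_m = 10, rg = rg))
    expect_true(all(att$K_g >= full$K_g))
    expect_equal(att$delta, full$delta)  # delta column is the raw shift
    expect_equal(att$K_g, prevalence_from_shift(0.1, rg * full$delta))
  }
})

test_that("quantitative curve combines shift, band and units; rg scales linearly", {
  trait <- trait_config("toy", "quantitative", phenotypic_sd = 0.4,
                        units = "mmol/l")
  loci <- toy_oriented()
  cv <- quantitative_curve(edit_plan(trait, loci, max_m = 2))
  expect_equal(cv$delta[2], -0.14)
  expect_equal(cv$sd_gain[2], sqrt(0.0122), tolerance = 1e-12)
  expect_equal(cv$band_low[2], -0.14 - sqrt(0.0122))
  expect_equal(cv$delta_units[2], -0.14 * 0.4)
  half <- quantitative_curve(edit_plan(trait, loci, max_m = 2, rg = 0.5))
  expect_equal(half$delta, 0.5 * cv$delta)
})

test_that("population mean shift is the edited-fraction identity", {
  expect_identical(population_mean_shift(-5, 0.01), -0.05)
  expect_identical(population_mean_shift(-5, 0), 0)
  expect_identical(population_mean_shift(-5, 1), -5)
  expect_error(population_mean_shift(-5, 1.2), "fraction")
})

test_that("protective genotype probability equals brute-force enumeration", {
  one <- toy_oriented(p = 0.5, beta = 0.1, ids = "x")
  expect_equal(protective_genotype_probability(one, "hom_protective"), 0.25)
  expect_equal(protective_genotype_probability(one, "at_least_one_copy"),
               1 - 0.25)
  set.seed(21)
  ten <- toy_oriented(p = runif(10, 0.1, 0.9), beta = rep(0.1, 10))
  # enumeration over all 3^10 genotypes
  grid <- as.matrix(expand.grid(rep(list(0:2), 10)))
  joint <- apply(grid, 1, function(cnt) prod(dbinom(cnt, 2, ten$p_undesirable)))
  expect_equal(protective_genotype_probability(ten, "hom_protective"),
               sum(joint[rowSums(grid) == 0]), tolerance = 1e-12)
  expect_equal(protective_genotype_probability(ten, "at_least_one_copy"),
               sum(joint[apply(grid, 1, function(cnt) all(cnt < 2))]),
               tolerance = 1e-10)
})

test_that("disease predictions agree with the explicit-genotype oracle at ten loci", {
  set.seed(5)
  p <- runif(10, 0.05, 0.9)
  # small effects keep the explained variance share well below 1%, where
  # the unit-residual-variance closed form matches the exact simulation
  beta <- abs(rnorm(10, sd = 0.02))
  K <- 0.06
  orc <- mc_liability_oracle(K, p, beta, n_sim = 1e6, seed = 11)
  trait <- trait_config("toy", "binary", prevalence_K = K)
  cv <- disease_curve(edit_plan(trait, rank_loci(toy_oriented(p, beta), 10)))
  expect_lt(abs(orc$K_g_hat - cv$K_g[10]), 3 * orc$mc_se)
})
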