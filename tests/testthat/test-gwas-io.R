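test_that("a well-formed table round-trips with count preserved", {
  path <- write_locus_tsv(toy_records())
  tab <- read_locus_table(path, trait_presets("AD"))
  expect_s3_class(tab, "locus_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$locus_id, c("rs1", "rs2", "rs3"))
})

test_that("validation rejects boundary frequencies and bad schema", {
  rec <- toy_records()
  rec$eaf[2] <- 1.0
  expect_error(read_locus_table(write_locus_tsv(rec), trait_presets("AD")),
               "eaf outside \\(0, 1\\).*rs2")
  rec <- toy_records()
  rec$beta_raw <- NULL
  expect_error(read_locus_table(write_locus_tsv(rec), trait_presets("AD")),
               "missing required column.*beta_raw")
  rec <- toy_records()
  rec$other_allele[1] <- "A"
  expect_error(read_locus_table(write_locus_tsv(rec), trait_presets("AD")),
               "effect_allele equals other_allele.*rs1")
  # quantitative traits additionally need se and n_samples
  rec <- toy_records()
  rec$n_samples <- NULL
  expect_error(read_locus_table(write_locus_tsv(rec), trait_presets("LDL")),
               "n_samples")
})

test_that("heterogeneous headers are handled through the column mapping", {
  rec <- toy_records()
  names(rec)[names(rec) == "eaf"] <- "EAF"
  names(rec)[names(rec) == "beta_raw"] <- "BETA"
  tab <- read_locus_table(write_locus_tsv(rec), trait_presets("AD"),
                          col_map = c(eaf = "EAF", beta_raw = "BETA"))
  expect_equal(tab$eaf, c(0.3, 0.6, 0.15))
})

test_that("log-OR-to-liability conversion is linear with the quadrature multiplier", {
  # frozen oracle: K(1-K)/phi(Phi^-1(1-K)) at K = 0.05 from independent
  # quadrature/bisection = 0.460559
  expect_equal(logor_to_liability(0, 0.3), 0)
  expect_equal(logor_to_liability(1, 0.05), 0.460559, tolerance = 1e-6)
  expect_equal(logor_to_liability(2, 0.05), 2 * logor_to_liability(1, 0.05))
  expect_equal(logor_to_liability(-0.4, 0.1), -logor_to_liability(0.4, 0.1))
  expect_error(logor_to_liability(1, 1.2), "in \\(0, 1\\)")
})

test_that("phenotypic sd estimator satisfies the standardized-trait identity", {
  rec <- toy_records()
  rec$se <- 1 / sqrt(2 * rec$eaf * (1 - rec$eaf) * rec$n_samples)
  expect_equal(estimate_phenotypic_sd(rec), 1, tolerance = 1e-12)
  # scaling all s.e. by c scales the estimate by c
  rec2 <- rec
  rec2$se <- 3.7 * rec$se
  expect_equal(estimate_phenotypic_sd(rec2), 3.7, tolerance = 1e-12)
  # single locus with 2p(1-p)N se^2 = 4 gives sd 2
  one <- data.frame(locus_id = "rs9", eaf = 0.25, n_samples = 1e5,
                    se = sqrt(4 / (2 * 0.25 * 0.75 * 1e5)))
  expect_equal(estimate_phenotypic_sd(one), 2, tolerance = 1e-12)
  rec$se[2] <- NA
  expect_error(estimate_phenotypic_sd(rec), "rs2")
})

test_that("orientation always yields a non-negative effect of the undesirable allele", {
  trait <- trait_presets("LDL")
  rec <- toy_records()
  or <- orient_loci(rec, trait, phenotypic_sd = 1)
  expect_true(all(or$beta >= 0))
  expect_equal(or$p_undesirable, c(0.3, 1 - 0.6, 0.15))
  expect_equal(or$beta, abs(rec$beta_raw))
  expect_equal(or$rank_score, or$p_undesirable * or$beta)
  rec$beta_raw[1] <- 0
  expect_warning(orient_loci(rec, trait, phenotypic_sd = 1), "zero effect")
})

test_that("downstream predictions are invariant to which allele is reported", {
  trait <- trait_presets("CAD")
  rec <- toy_records()
  flipped <- rec
  flipped$eaf <- 1 - rec$eaf
  flipped$beta_raw <- -rec$beta_raw
  flipped$effect_allele <- rec$other_allele
  flipped$other_allele <- rec$effect_allele
  cv <- function(r) {
    or <- rank_loci(orient_loci(r, trait), max_m = 3)
    disease_curve(edit_plan(trait, or, max_m = 3))
  }
  expect_equal(cv(rec)$K_g, cv(flipped)$K_g, tolerance = 1e-14)
  expect_equal(cv(rec)$band_low, cv(flipped)$band_low, tolerance = 1e-14)
})

test_that("ranking sorts by p * beta with deterministic ties and truncation", {
  loci <- toy_oriented(p = c(0.5, 0.1, 0.4), beta = c(0.1, 0.3, 0.2),
                       ids = c("a", "b", "c"))
  ranked <- rank_loci(loci, max_m = 3)
  expect_equal(ranked$locus_id, c("c", "a", "b"))  # 0.08, 0.05, 0.03
  expect_equal(rank_loci(loci, max_m = 2)$locus_id, c("c", "a"))
  # ties broken lexicographically on locus_id
  tie <- toy_oriented(p = c(0.2, 0.4), beta = c(0.2, 0.1), ids = c("z", "a"))
  expect_equal(rank_loci(tie, 2)$locus_id, c("a", "z"))
  expect_warning(empty <- rank_loci(toy_oriented(numeric(0), numeric(0)), 5),
                 "empty")
  expect_equal(nrow(empty), 0L)
  # stable under monotone rescaling of all effects
  scaled <- loci
  scaled$beta <- scaled$beta * 10
  scaled$rank_score <- scaled$p_undesirable * scaled$beta
  expect_equal(rank_loci(scaled, 3)$locus_id, ranked$locus_id)
})
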