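test_that("allele library honors requested counts and the locus class rules", {
  lib <- generate_allele_library(seed = 1)
  expect_equal(nrow(lib), 128)   # 46 + 39 + 43
  expect_equal(as.vector(table(lib$locus)[c("GAL3", "GAL80", "GAL4")]),
               c(46, 39, 43))
  # GAL3 singles only ever fall into two classes
  expect_setequal(unique(lib$true_class[lib$locus == "GAL3"]),
                  c("Inducible", "Uninducible"))
  expect_true(all(lib$fracON_glu >= 0 & lib$fracON_glu <= 1))
  expect_true(all(lib$fracON_gal >= 0 & lib$fracON_gal <= 1))

  # all-zero request gives an empty library
  empty <- generate_allele_library(list(GAL3 = c(Inducible = 0)), seed = 1)
  expect_equal(nrow(empty), 0)

  # inadmissible class names the locus and class
  expect_error(generate_allele_library(list(GAL3 = c(Leaky = 2)), seed = 1),
               "GAL3.*Leaky")

  # identical seeds give byte-identical libraries
  expect_identical(lib, generate_allele_library(seed = 1))
  expect_false(identical(lib, generate_allele_library(seed = 2)))
})

test_that("pairwise design enumerates WT, singles and all cross-locus pairs", {
  lib <- generate_allele_library(seed = 1)
  des <- generate_design(lib, dropout_rate = 0, seed = 1)
  # brute-force enumeration oracle over the library itself
  expected_pairs <- 0L
  for (i in seq_len(nrow(lib))) {
    for (j in seq_len(nrow(lib))) {
      if (i < j && lib$locus[i] != lib$locus[j]) expected_pairs <- expected_pairs + 1L
    }
  }
  expect_equal(expected_pairs, 46 * 39 + 46 * 43 + 39 * 43)  # 5449
  expect_equal(sum(des$n_mutant_loci == 2), expected_pairs)
  expect_equal(sum(des$n_mutant_loci == 1), nrow(lib))
  expect_equal(sum(des$n_mutant_loci == 0), 1)
  # never two alleles at the same locus: every double mutates two distinct loci
  dbl <- des[des$n_mutant_loci == 2, ]
  expect_true(all(rowSums(dbl[, c("GAL3", "GAL80", "GAL4")] != "WT") == 2))

  # smallest design: one allele per locus
  lib1 <- generate_allele_library(list(GAL3 = c(Uninducible = 1),
                                       GAL80 = c(Constitutive = 1),
                                       GAL4 = c(Uninducible = 1)), seed = 1)
  des1 <- generate_design(lib1, dropout_rate = 0, seed = 1)
  expect_equal(as.vector(table(des1$n_mutant_loci)), c(1, 3, 3))

  expect_error(generate_design(lib, dropout_rate = 1), "dropout_rate")
  expect_error(generate_design(lib[0, ], dropout_rate = 0), "empty")

  # dropout is reproducible under the seed and touches only doubles
  d1 <- generate_design(lib, dropout_rate = 0.02, seed = 5)
  d2 <- generate_design(lib, dropout_rate = 0.02, seed = 5)
  expect_identical(d1, d2)
  expect_true(all(d1$n_mutant_loci[d1$dropout] == 2))
  expect_gt(sum(d1$dropout), 0)
})

test_that("the 2^3 deletion design has all 8 genotypes", {
  del <- deletion_design(seed = 1)
  expect_equal(nrow(del$design), 8)
  expect_equal(sort(unique(del$design$n_mutant_loci)), 0:3)
})

test_that("truth table follows the growth model and the class rules", {
  lib <- generate_allele_library(seed = 2)
  des <- generate_design(lib, dropout_rate = 0, seed = 2)
  tr <- truth_table(des, lib, seed = 2)
  expect_true(all(is.finite(tr$mu_true)))
  expect_true(all(tr$mu_true >= 0))
  # single mutants carry their allele's class and parameters
  sing <- des$genotype_id[des$n_mutant_loci == 1]
  aid <- sub("_?WT_?", "", gsub("WT_|_WT", "", sing))
  i <- match(sing, tr$genotype_id)
  j <- match(aid, lib$allele_id)
  expect_equal(tr$true_class[i], lib$true_class[j])
  expect_equal(tr$fracON_gal[i], lib$fracON_gal[j])
  # deterministic under seed
  expect_identical(tr, truth_table(des, lib, seed = 2))
})

test_that("stereotyped class combination rules match the planted network logic", {
  expect_equal(combine_classes("GAL3", "Inducible", "GAL80", "Leaky"), "Leaky")
  expect_equal(combine_classes("GAL3", "Uninducible", "GAL80", "Constitutive"),
               "Constitutive")
  expect_equal(combine_classes("GAL3", "Uninducible", "GAL4", "Constitutive"),
               "Constitutive")
  expect_equal(combine_classes("GAL3", "Uninducible", "GAL80", "Leaky", u = 0.5),
               "Leaky")
  expect_equal(combine_classes("GAL3", "Uninducible", "GAL80", "Leaky", u = 0.99),
               "Inducible")
  expect_equal(combine_classes("GAL80", "Constitutive", "GAL4", "Uninducible"),
               "Uninducible")
  # argument order never matters
  expect_equal(combine_classes("GAL4", "Constitutive", "GAL3", "Uninducible"),
               combine_classes("GAL3", "Uninducible", "GAL4", "Constitutive"))
  # the stochastic GAL80S x GAL4C pairing spans all five classes
  u <- seq(0.005, 0.995, by = 0.01)
  got <- vapply(u, function(ui) {
    combine_classes("GAL80", "Uninducible", "GAL4", "Constitutive", u = ui)
  }, character(1))
  expect_setequal(unique(got),
                  c("Constitutive", "Inducible", "Uninducible", "Leaky",
                    "WeakExpression"))
  expect_equal(mean(got == "Constitutive"), 0.56, tolerance = 0.01)
})

test_that("simulated densities follow exponential growth after the 9/150 dilution", {
  cfg <- galcomb_config()
  tr0 <- data.frame(mu_true = 0)
  d0 <- simulate_growth(tr0, glu_density = 3000, config = cfg)
  expect_equal(d0$density_gal, 3000 * 9 / 150)
  tr <- data.frame(mu_true = 0.2)
  d <- simulate_growth(tr, glu_density = 3000, config = cfg)
  expect_equal(d$density_gal / (3000 * 9 / 150), exp(2.4))
  expect_error(simulate_growth(tr, glu_density = 0), "positive")
  expect_error(simulate_growth(data.frame(mu_true = Inf), glu_density = 10),
               "finite")
})

test_that("event mixtures are calibrated to the planted fraction ON", {
  cfg <- galcomb_config()
  truth <- data.frame(genotype_id = c("off", "on", "mid"),
                      true_class = "Inducible",
                      fracON_glu = c(0, 1, 0.3), fracON_gal = c(0, 1, 0.3),
                      on_mean_glu = 2, on_mean_gal = 2, on_sd = 0.25,
                      mu_true = 0.1, stringsAsFactors = FALSE)
  cutoff <- 0.25
  ev_off <- simulate_events("off", "glucose", truth, n_events = 5000, seed = 1,
                            density = 2000, config = cfg)
  # degenerate mixture: everything is autofluorescence
  expect_true(all(pseudolog(ev_off$FITC) < cutoff + 0.2))
  expect_equal(mean(pseudolog(ev_off$FITC) > cutoff), 0, tolerance = 2e-3)

  ev_on <- simulate_events("on", "galactose", truth, n_events = 20000, seed = 1,
                           density = 2000, config = cfg)
  expect_gt(mean(pseudolog(ev_on$FITC) > cutoff), 0.999)

  # binomial sampling bound at fracON = 0.3, n = 20000
  ev_mid <- simulate_events("mid", "galactose", truth, n_events = 20000, seed = 1,
                            density = 2000, config = cfg)
  expect_equal(mean(pseudolog(ev_mid$FITC) > cutoff), 0.3, tolerance = 0.02)

  # property: calibration holds across planted fractions (95% binomial CI)
  for (f in c(0.1, 0.5, 0.8)) {
    tr <- truth; tr$fracON_gal <- f
    ev <- simulate_events("mid", "galactose", tr, n_events = 20000, seed = 2,
                          density = 2000, config = cfg)
    phat <- mean(pseudolog(ev$FITC) > cutoff)
    expect_lt(abs(phat - f), 3 * sqrt(f * (1 - f) / 20000) + 0.003)
  }

  expect_error(simulate_events("nope", "glucose", truth, 100, 1, config = cfg),
               "unknown genotype")
  # timestamps are nondecreasing Poisson arrivals
  expect_true(all(diff(ev_mid$time_ms) >= 0))
  # determinism
  expect_identical(ev_mid,
                   simulate_events("mid", "galactose", truth, n_events = 20000,
                                   seed = 1, density = 2000, config = cfg))
})
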