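test_that("multiplicative expectation matches closed forms and is symmetric", {
  # identity mutant: pairing with a WT-equivalent single returns the other single
  m <- multiplicative_expectation(0.12, 0, 0.20, 0, 0.20, 0)
  expect_equal(m$mu_expected, 0.12)
  # closed form
  m2 <- multiplicative_expectation(0.12, 0, 0.15, 0, 0.20, 0)
  expect_equal(m2$mu_expected, 0.09)
  # error-free limit propagates zero SE
  expect_equal(m2$se, 0)
  # symmetry in the two mutants
  m3 <- multiplicative_expectation(0.15, 0.01, 0.12, 0.02, 0.20, 0.01)
  m4 <- multiplicative_expectation(0.12, 0.02, 0.15, 0.01, 0.20, 0.01)
  expect_equal(m3$mu_expected, m4$mu_expected)
  expect_equal(m3$se, m4$se)
  # background is subtracted before and re-added after
  m5 <- multiplicative_expectation(0.17, 0, 0.20, 0, 0.25, 0, background = 0.05)
  expect_equal(m5$mu_expected, 0.05 + 0.12 * 0.15 / 0.20)
  # zero WT (after background) is flagged
  m6 <- multiplicative_expectation(0.1, 0, 0.1, 0, 0.05, 0, background = 0.05)
  expect_true(m6$flagged)
  expect_true(is.na(m6$mu_expected))
})

test_that("SE propagation modes behave as documented", {
  # error-free limit: zero in every mode
  for (mode in c("delta", "as_printed", "typo_fixed")) {
    expect_equal(propagate_se(0.09, 0.12, 0, 0.15, 0, 0.2, 0, N = 2, mode = mode), 0)
  }
  # N = 1 makes the WT term vanish in the printed formula
  a <- propagate_se(0.09, 0.12, 0.01, 0.15, 0.02, 0.2, 0.5, N = 1,
                    mode = "as_printed")
  b <- propagate_se(0.09, 0.12, 0.01, 0.15, 0.02, 0.2, 0, N = 1,
                    mode = "as_printed")
  expect_equal(a, b)
  # as-printed repeats mu_mut1 in the last denominator; typo-fixed does not
  ap <- propagate_se(0.09, 0.12, 0.01, 0.15, 0.02, 0.2, 0.01, N = 2,
                     mode = "as_printed")
  expect_equal(ap, 0.09 * sqrt(((0.01 / 0.2) + 0.01 / 0.12 + 0.02 / 0.12)^2))
  tf <- propagate_se(0.09, 0.12, 0.01, 0.15, 0.02, 0.2, 0.01, N = 2,
                     mode = "typo_fixed")
  expect_equal(tf, 0.09 * sqrt(((0.01 / 0.2) + 0.01 / 0.12 + 0.02 / 0.15)^2))
  # zero denominators are flagged as NA
  expect_true(is.na(propagate_se(0, 0, 0.01, 0.15, 0.02, 0.2, 0.01)))
})

test_that("delta-mode SE agrees with Monte-Carlo to first order", {
  mu1 <- 0.12; se1 <- 0.004; mu2 <- 0.15; se2 <- 0.005; muw <- 0.20; sew <- 0.003
  mu_mut <- mu1 * mu2 / muw
  se_hat <- propagate_se(mu_mut, mu1, se1, mu2, se2, muw, sew, mode = "delta")
  set.seed(123)
  n <- 1e5
  draws <- rnorm(n, mu1, se1) * rnorm(n, mu2, se2) / rnorm(n, muw, sew)
  expect_equal(se_hat / sd(draws), 1, tolerance = 0.15)
})

test_that("class model parameter counts match the design's combinatorics", {
  td <- truth_doubles()
  d <- td$doubles
  expect_equal(nrow(d), 5449)
  m23 <- fit_class_model(d, scheme = "intermediate5", locus_aware = TRUE)
  expect_equal(m23$n_parameters, 23)
  m14 <- fit_class_model(d, scheme = "broad3", locus_aware = TRUE)
  expect_equal(m14$n_parameters, 14)
  m6 <- fit_class_model(d, scheme = "broad3", locus_aware = FALSE)
  expect_equal(m6$n_parameters, 6)
  m13 <- fit_class_model(d, scheme = "intermediate5", locus_aware = FALSE)
  expect_equal(m13$n_parameters, 13)
  # parameters are exactly the per-key group means (brute-force oracle)
  keys <- class_key(d$locus1, d$class1, d$locus2, d$class2, TRUE)
  for (k in names(coef(m23))[1:5]) {
    expect_equal(unname(coef(m23)[k]), mean(d$mu[keys == k]))
  }
  # doubles with an unclassified single are excluded, not silently kept
  d2 <- d
  d2$class1[1:10] <- NA
  m <- fit_class_model(d2, "intermediate5")
  expect_equal(m$n_excluded, 10)
})

test_that("every locus-aware key coarsens to exactly one locus-blinded key", {
  td <- truth_doubles()
  d <- td$doubles
  aware <- class_key(d$locus1, d$class1, d$locus2, d$class2, TRUE)
  blind_direct <- class_key(d$locus1, d$class1, d$locus2, d$class2, FALSE)
  blind_via <- blind_key(aware, d$locus1, d$locus2)
  expect_equal(blind_via, blind_direct)
  # surjection: each aware key maps to a single blinded key
  map <- tapply(blind_via, aware, function(x) length(unique(x)))
  expect_true(all(map == 1))
})

test_that("training-set variance explained equals the one-way between-group share", {
  td <- truth_doubles()
  d <- td$doubles
  m <- fit_class_model(d, "intermediate5", TRUE)
  pred <- predict(m, d)
  expect_true(all(pred$covered))
  ve <- predict_and_score(pred, d$mu)$variance_explained[1]
  # brute-force decomposition oracle
  keys <- class_key(d$locus1, d$class1, d$locus2, d$class2, TRUE)
  gm <- ave(d$mu, keys)
  expect_equal(ve, sum((gm - mean(d$mu))^2) / sum((d$mu - mean(d$mu))^2),
               tolerance = 1e-12)
})

test_that("scoring anchors: perfect and null predictors", {
  obs <- c(0.1, 0.2, 0.3, 0.25)
  expect_equal(predict_and_score(obs, obs)$variance_explained[1], 1)
  expect_equal(predict_and_score(rep(mean(obs), 4), obs)$variance_explained[1], 0)
  expect_error(predict_and_score(numeric(), numeric()), "no finite")
})

test_that("planted class-mean structure is recovered at the noise-implied ceiling", {
  td <- truth_doubles()
  d <- td$doubles
  m <- fit_class_model(d, "intermediate5", TRUE)
  ve <- predict_and_score(predict(m, d), d$mu)$variance_explained[1]
  expected <- 1 - td$sigma^2 / var(d$mu)
  expect_equal(ve, expected, tolerance = 0.03)
})

test_that("downsampled cross-validation is seeded and degenerates to the full fit", {
  td <- truth_doubles()
  cv1 <- downsample_cv(td$doubles, td$singles, k_alleles_per_class = 1L,
                       iterations = 30L, seed = 9, scheme = "intermediate5")
  cv2 <- downsample_cv(td$doubles, td$singles, k_alleles_per_class = 1L,
                       iterations = 30L, seed = 9, scheme = "intermediate5")
  expect_identical(cv1$variance_explained, cv2$variance_explained)
  expect_identical(cv1$median, cv2$median)
  # k covering every allele leaves no holdout: defined as the full-fit value
  eq <- truth_doubles(list(GAL3 = c(Inducible = 2, Uninducible = 2),
                           GAL80 = c(Inducible = 2, Constitutive = 2,
                                     Uninducible = 2, Leaky = 2),
                           GAL4 = c(Inducible = 2, Constitutive = 2,
                                    Uninducible = 2, WeakExpression = 2)))
  cv_all <- downsample_cv(eq$doubles, eq$singles, k_alleles_per_class = 2L,
                          iterations = 5L, seed = 1)
  full <- fit_class_model(eq$doubles, "intermediate5", TRUE)
  ve_full <- predict_and_score(predict(full, eq$doubles),
                               eq$doubles$mu)$variance_explained[1]
  expect_equal(cv_all$median, ve_full)
  # a class with too few alleles is named in the error
  few <- td$singles[-(which(td$singles$class == "WeakExpression")[1:2]), ]
  expect_error(downsample_cv(td$doubles, few, k_alleles_per_class = 2L,
                             iterations = 2L, seed = 1),
               "WeakExpression")
})

test_that("class enrichment is a plain chi-squared goodness of fit", {
  # dominance of one class among 36 pairings vs a uniform expectation
  obs <- c(Constitutive = 20, Inducible = 4, Uninducible = 7, Leaky = 2,
           WeakExpression = 3)
  ht <- class_enrichment_test(obs)
  # brute-force statistic: sum (O - E)^2 / E
  e <- rep(sum(obs) / 5, 5)
  expect_equal(unname(ht$statistic), sum((obs - e)^2 / e))
  expect_lt(ht$p.value, 0.01)
  expect_error(class_enrichment_test(c(5)), "two outcome")
})

test_that("design accounting equals brute-force enumeration with the constraint", {
  acc <- design_accounting("intermediate5")
  # independent loop oracle over all class triples
  c3 <- c("Inducible", "Uninducible")
  c80 <- c("Inducible", "Constitutive", "Uninducible", "Leaky")
  c4 <- c("Inducible", "Constitutive", "Uninducible", "WeakExpression")
  n_poss <- 0L; n_excl <- 0L
  for (a in c4) for (b in c80) for (cc in c3) {
    n_poss <- n_poss + 1L
    if (cc == "Uninducible" && a != "Inducible" && b != "Inducible") {
      n_excl <- n_excl + 1L
    }
  }
  expect_equal(acc$possible, n_poss)
  expect_equal(acc$excluded, n_excl)
  expect_equal(acc$realizable, n_poss - n_excl)
  # singleton class sets
  one <- design_accounting(list(GAL3 = "Inducible", GAL80 = "Inducible",
                                GAL4 = "Inducible"))
  expect_equal(one[c("possible", "excluded", "realizable")],
               list(possible = 1L, excluded = 0L, realizable = 1L))
  expect_error(design_accounting(list(GAL3 = character(), GAL80 = "I", GAL4 = "I")),
               "empty")
})
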