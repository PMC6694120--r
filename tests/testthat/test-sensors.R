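make_records <- function(pairs, N = 8, seed = 1) {
  # pairs: data frame pair_id, mu_intact, mu_arm (one non-reference arm)
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    data.frame(pair_id = pairs$pair_id[i],
               arm = rep(c("intact", "dGAL3"), each = N),
               mu = c(rnorm(N, pairs$mu_intact[i], pairs$sd[i]),
                      rnorm(N, pairs$mu_arm[i], pairs$sd[i])))
  }))
}

test_that("background contrasts: null, planted effect, and exclusion paths", {
  # identical arms (zero variance, equal means): p = 1, not significant
  recs <- data.frame(pair_id = "p1", arm = rep(c("intact", "dGAL3"), each = 4),
                     mu = rep(0.2, 8))
  out <- contrast_backgrounds(recs, alpha = 0.05, min_effect = 0.03)
  expect_equal(out$p, 1)
  expect_false(out$significant)

  # planted effect 0.05/h, replicate sd 0.014 (se ~0.005), N = 8: significant
  pairs <- data.frame(pair_id = sprintf("p%d", 1:6),
                      mu_intact = 0.30,
                      mu_arm = c(0.25, 0.25, 0.30, 0.30, 0.30, 0.30),
                      sd = 0.014)
  out2 <- contrast_backgrounds(make_records(pairs, N = 8, seed = 2),
                               alpha = 0.05, min_effect = 0.03)
  expect_true(all(out2$significant[out2$pair_id %in% c("p1", "p2")]))
  expect_false(any(out2$significant[!out2$pair_id %in% c("p1", "p2")]))
  # effect sign: arm minus reference
  expect_lt(out2$effect[out2$pair_id == "p1"], 0)

  # single-replicate arms are excluded with a log entry
  recs3 <- rbind(recs,
                 data.frame(pair_id = "p2", arm = c("intact", "dGAL3", "dGAL3"),
                            mu = c(0.2, 0.1, 0.11)))
  out3 <- contrast_backgrounds(recs3)
  expect_false("p2" %in% out3$pair_id)
  expect_match(attr(out3, "excluded"), "p2")
})

test_that("BH adjustment matches the sorted-p brute force and is monotone", {
  # the classic worked example: all adjust to 0.04
  expect_equal(bh_bruteforce(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(10)
  for (i in 1:5) {
    p <- runif(20)^2
    q_ours <- p.adjust(p, "BH")       # the adjustment the package applies
    expect_equal(q_ours, bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(q_ours >= p))
    # monotone: p_i <= p_j implies q_i <= q_j
    o <- order(p)
    expect_true(all(diff(q_ours[o]) >= -1e-12))
  }
  # q values produced by contrast_backgrounds obey the same brute force
  pairs <- data.frame(pair_id = sprintf("p%d", 1:8), mu_intact = 0.3,
                      mu_arm = seq(0.24, 0.31, by = 0.01), sd = 0.02)
  out <- contrast_backgrounds(make_records(pairs, seed = 3))
  expect_equal(out$q, bh_bruteforce(out$p), tolerance = 1e-12)
})

test_that("Welch t-test p-values agree with a permutation test", {
  set.seed(21)
  x <- rnorm(8, 0.30, 0.02)
  y <- rnorm(8, 0.27, 0.02)
  p_t <- t.test(x, y, var.equal = FALSE)$p.value
  # permutation oracle on |difference of means|
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  nperm <- 1e4
  exceed <- replicate(nperm, {
    idx <- sample(16, 8)
    abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12
  })
  p_perm <- mean(exceed)
  expect_lt(abs(p_t - p_perm), 0.03)
})

test_that("logistic leakiness null is recovered from planted parameters", {
  set.seed(31)
  x <- runif(40, 0, 3)
  mu <- 0.30 / (1 + exp((1.5 - x) / 0.30)) + rnorm(40, 0, 0.01)
  fit <- fit_leakiness_null(x, mu)
  cf <- fit$fits$all$coef
  expect_false(fit$fits$all$flagged)
  expect_equal(unname(cf["Asym"]), 0.30, tolerance = 0.10)
  expect_equal(unname(cf["xmid"]), 1.5, tolerance = 0.10)
  expect_equal(unname(cf["scal"]), 0.30, tolerance = 0.10)
  # saturation limit: far above xmid the prediction approaches Asym
  expect_equal(predict(fit, 30), unname(cf["Asym"]), tolerance = 1e-6)
  # flat growth has no sigmoidal signal: flagged
  flat <- fit_leakiness_null(x, rep(0.1, 40))
  expect_true(flat$fits$all$flagged)
  # per-group fits are independent
  g <- rep(c("ecoli", "calbicans"), each = 20)
  mu2 <- ifelse(g == "ecoli", 0.30, 0.24) / (1 + exp((1.5 - x) / 0.30)) +
    rnorm(40, 0, 0.005)
  fit2 <- fit_leakiness_null(x, mu2, group = g)
  expect_gt(fit2$fits$ecoli$coef["Asym"], fit2$fits$calbicans$coef["Asym"])
})

test_that("growth above the leakiness null is detected one-tailed", {
  set.seed(41)
  x <- runif(30, 0, 3)
  mu <- 0.30 / (1 + exp((1.5 - x) / 0.30)) + rnorm(30, 0, 0.005)
  null <- fit_leakiness_null(x, mu)
  # replicates exactly at the prediction: not significant
  at <- data.frame(pair_id = "at", x_glu = 1.0, galk_source = "all",
                   mu = rep(predict(null, 1.0), 6))
  # replicates 0.10/h above with se 0.01: significant
  above <- data.frame(pair_id = "up", x_glu = 1.0, galk_source = "all",
                      mu = predict(null, 1.0) + rnorm(8, 0.10, 0.028))
  out <- test_above_null(rbind(at, above), null, alpha = 0.05)
  expect_false(out$significant[out$pair_id == "at"])
  expect_true(out$significant[out$pair_id == "up"])
  # empty input gives an empty result
  empty <- test_above_null(at[0, ], null)
  expect_equal(nrow(empty), 0)
})

test_that("dependency calls reproduce the landmark rewiring patterns", {
  cfg <- galcomb_config()
  panel <- simulate_sensor_panel(n_per_type = 3, N = 8, seed = 5, config = cfg)
  contr <- contrast_backgrounds(panel$records, alpha = cfg$sensors$alpha,
                                min_effect = cfg$sensors$min_effect)
  calls <- call_dependencies(contr, panel$pairs, wt_mu = 0.35,
                             background = 0.05, config = cfg)
  by_type <- split(calls, calls$type)
  # WT-like switch: GAL3 essential, GAL1 sensing dispensable
  expect_true(all(by_type$wt_like$gal3_verdict == "essential"))
  expect_true(all(by_type$wt_like$gal1_verdict == "dispensable"))
  # flipped switch: GAL1 essential, GAL3 dispensable
  expect_true(all(by_type$flipped$gal1_verdict == "essential"))
  expect_true(all(by_type$flipped$gal3_verdict == "dispensable"))
  # constitutive activator: GAL1 sensing deleterious (causes glucose expression)
  expect_true(all(by_type$gal4c$gal1_verdict == "deleterious"))
  # leaky repressor: neither sensor needed on its own
  expect_true(all(by_type$leaky80$gal3_verdict == "dispensable"))
  expect_true(all(by_type$leaky80$gal1_verdict == "dispensable"))
  # harmonious flag: flipped pairs are harmonious (non-Inducible singles,
  # Inducible double, high growth); dead pairs are not
  expect_true(all(by_type$flipped$harmonious))
  expect_false(any(by_type$dead$harmonious))

  # order invariance: shuffling replicate records changes nothing
  set.seed(6)
  perm <- sample(nrow(panel$records))
  contr2 <- contrast_backgrounds(panel$records[perm, ], alpha = cfg$sensors$alpha,
                                 min_effect = cfg$sensors$min_effect)
  calls2 <- call_dependencies(contr2, panel$pairs, wt_mu = 0.35,
                              background = 0.05, config = cfg)
  calls2 <- calls2[match(calls$pair_id, calls2$pair_id), ]
  expect_equal(calls2$gal3_verdict, calls$gal3_verdict)
  expect_equal(calls2$gal1_verdict, calls$gal1_verdict)

  # incomplete arm set: indeterminate
  pr <- panel$pairs[1, ]
  pr$mu_dGAL3 <- NA
  one <- call_dependencies(contr, pr, wt_mu = 0.35, background = 0.05,
                           config = cfg)
  expect_equal(one$gal3_verdict, "indeterminate")
})
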