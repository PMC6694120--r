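# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixtures)) assign(key, force(expr), .fixtures)
  get(key, .fixtures)
}

# a reduced allele library that still populates every (locus, class) group
small_cfg <- function(seed = 7L) {
  cfg <- galcomb_config(seed = seed)
  cfg$alleles$counts <- list(
    GAL3  = c(Inducible = 3, Uninducible = 3),
    GAL80 = c(Inducible = 2, Constitutive = 2, Uninducible = 2, Leaky = 2),
    GAL4  = c(Inducible = 2, Constitutive = 2, Uninducible = 2, WeakExpression = 2))
  cfg$epistasis$cv_iterations <- 50L
  cfg
}

small_run <- function() {
  memo("small_run", run_pipeline(small_cfg(), n_events = 2000, quiet = TRUE))
}

# deletion-style simulation: replicate genotypes of the three archetypal
# deletion classes (fixed class parameters, pure measurement noise), pushed
# through events -> summaries -> features
archetype_sim <- function(n_per_class = 40L, n_events = 10000L, seed = 11L) {
  memo(sprintf("archetype_sim_%d_%d_%d", n_per_class, n_events, seed), {
    cfg <- galcomb_config(seed = seed)
    classes <- rep(c("Inducible", "Constitutive", "Uninducible"),
                   each = n_per_class)
    # N = 4 replicates as in the deletion experiment, generous event counts
    sim_class_library(classes, cfg, n_events = n_events, seed = seed,
                      replicates = 4L, fixed_params = TRUE)
  })
}

# simulate one pseudo-genotype per entry of `classes` through the cytometry
# path and return features + records + planted labels; `fixed_params` uses
# the nominal class parameters for every genotype (deletion-experiment
# style) instead of per-genotype draws
sim_class_library <- function(classes, cfg, n_events = 2000L, seed = 11L,
                              replicates = 2L, fixed_params = FALSE) {
  n <- length(classes)
  lib <- data.frame(locus = "GAL80",
                    allele_id = sprintf("a%03d", seq_len(n)),
                    true_class = classes, stringsAsFactors = FALSE)
  design <- data.frame(genotype_id = lib$allele_id, GAL3 = "WT",
                       GAL80 = lib$allele_id, GAL4 = "WT",
                       n_mutant_loci = 1L, N = replicates, dropout = FALSE,
                       stringsAsFactors = FALSE)
  # per-genotype truth drawn from the class parameter distributions (or the
  # nominal parameters for every genotype, deletion-experiment style)
  truth <- galcomb:::with_seed(sub_seed(seed, "simlib"), {
    out <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (fixed_params) {
        p <- cfg$alleles$class_params[[classes[i]]]
        data.frame(fracON_glu = mean(p$fglu), fracON_gal = mean(p$fgal),
                   on_mean_glu = p$mean_glu, on_mean_gal = p$mean_gal,
                   on_sd = p$sd)
      } else {
        galcomb:::draw_class_params(1, classes[i], cfg)
      }
    }))
    g <- cfg$growth
    mu <- pmax(0, g$beta0 + g$beta_gal * out$fracON_gal +
                    g$beta_glu * out$fracON_glu + rnorm(n, 0, g$noise_sd))
    cbind(data.frame(genotype_id = design$genotype_id,
                     true_class = classes, stringsAsFactors = FALSE),
          out, mu_true = mu)
  })
  cfg$design$replicates <- replicates
  summ <- simulate_summaries(design, truth, seed = seed, n_events = n_events,
                             n_controls = 4L, config = cfg)
  rec <- genotype_records(summ, config = cfg)
  feats <- build_features(rec$dens_glu, rec$dens_gal)
  list(cfg = cfg, design = design, truth = truth, summaries = summ,
       records = rec, features = feats, classes = classes)
}

# planted doubles table with classes taken from the generator's truth
# (no cytometry), for the epistasis model tests
truth_doubles <- function(counts = NULL, seed = 3L, sigma = 0.02) {
  key <- sprintf("truth_doubles_%s_%d", paste(unlist(counts), collapse = "."), seed)
  memo(key, {
    cfg <- galcomb_config(seed = seed)
    if (!is.null(counts)) cfg$alleles$counts <- counts
    lib <- generate_allele_library(seed = seed, config = cfg)
    des <- generate_design(lib, dropout_rate = 0, seed = seed, config = cfg)
    rownames(lib) <- lib$allele_id
    dbl <- des[des$n_mutant_loci == 2, ]
    mut <- as.matrix(dbl[, c("GAL3", "GAL80", "GAL4")]) != "WT"
    l1 <- c("GAL3", "GAL80", "GAL4")[apply(mut, 1, function(r) which(r)[1])]
    l2 <- c("GAL3", "GAL80", "GAL4")[apply(mut, 1, function(r) which(r)[2])]
    a1 <- dbl[cbind(seq_len(nrow(dbl)), match(l1, names(dbl)))]
    a2 <- dbl[cbind(seq_len(nrow(dbl)), match(l2, names(dbl)))]
    doubles <- data.frame(genotype_id = dbl$genotype_id,
                          locus1 = l1, allele1 = a1, class1 = lib[a1, "true_class"],
                          locus2 = l2, allele2 = a2, class2 = lib[a2, "true_class"],
                          pair = paste(l1, l2, sep = ":"),
                          stringsAsFactors = FALSE)
    doubles$key <- class_key(doubles$locus1, doubles$class1,
                             doubles$locus2, doubles$class2, locus_aware = TRUE)
    planted <- plant_class_growth(doubles$key, sigma = sigma, seed = seed)
    doubles$mu <- planted$mu
    doubles$mu_class <- planted$mu_class
    singles <- data.frame(allele_id = lib$allele_id, locus = lib$locus,
                          class = lib$true_class, stringsAsFactors = FALSE)
    list(doubles = doubles, singles = singles, sigma = sigma,
         class_means = tapply(planted$mu_class, doubles$key, function(x) x[1]))
  })
}

# brute-force Benjamini-Hochberg: sorted p * m / i with a cumulative minimum
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
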