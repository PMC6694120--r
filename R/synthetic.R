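# Synthetic emulation of a combinatorially complete GALR mutant library:
# seeded allele libraries, pairwise genotype designs, per-genotype truth
# (expression class, fraction ON, growth rate) and per-sample cytometry
# event streams with the statistical structure the downstream analysis
# assumes.

GALR_LOCI <- c("GAL3", "GAL80", "GAL4")
EXPR_CLASSES <- c("Inducible", "Constitutive", "Uninducible", "Leaky", "WeakExpression")

# admissible single-mutant classes per locus; GAL3 singles only ever fall
# into Inducible or Uninducible
admissible_classes <- function(locus) {
  switch(locus,
         GAL3  = c("Inducible", "Uninducible"),
         GAL80 = c("Inducible", "Constitutive", "Uninducible", "Leaky"),
         GAL4  = c("Inducible", "Constitutive", "Uninducible", "WeakExpression"),
         stopf("unknown locus '%s'", locus))
}

#' Generate a seeded allele library
#'
#' Draws, for each locus, the requested number of alleles per expression
#' class, with per-allele fraction-ON and ON-component location/scale drawn
#' from the configured per-class distributions.
#'
#' @param counts named list (per locus) of named integer vectors
#'   (per class); defaults to the 46/39/43 split in `config`.
#' @param seed integer seed (a dedicated substream is derived from it).
#' @param config a [galcomb_config()] list.
#' @return data frame with one row per allele: `locus`, `allele_id`,
#'   `true_class`, `fracON_glu`, `fracON_gal`, `on_mean_glu`, `on_mean_gal`
#'   (pseudo-log A.U.), `on_sd`.
#' @export
generate_allele_library <- function(counts = NULL, seed = 1L, config = galcomb_config()) {
  counts <- counts %||% config$alleles$counts
  for (locus in names(counts)) {
    if (!locus %in% GALR_LOCI) stopf("unknown locus '%s'", locus)
    cl <- names(counts[[locus]])
    bad <- setdiff(cl, admissible_classes(locus))
    if (length(bad)) {
      stopf("inadmissible class for locus %s: %s", locus, paste(bad, collapse = ", "))
    }
    if (any(counts[[locus]] < 0)) stopf("negative allele count for locus %s", locus)
  }
  rows <- list()
  for (locus in names(counts)) {
    k <- 0L
    for (cls in names(counts[[locus]])) {
      n <- counts[[locus]][[cls]]
      if (n == 0) next
      pars <- with_seed(sub_seed(seed, paste0("alleles/", locus, "/", cls)),
                        draw_class_params(n, cls, config))
      ids <- sprintf("%s.%02d", locus, k + seq_len(n))
      k <- k + n
      rows[[paste(locus, cls)]] <- data.frame(
        locus = locus, allele_id = ids, true_class = cls, pars,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(locus = character(), allele_id = character(),
                      true_class = character(), fracON_glu = numeric(),
                      fracON_gal = numeric(), on_mean_glu = numeric(),
                      on_mean_gal = numeric(), on_sd = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# draw n per-allele (or per-genotype) parameter sets for one class
draw_class_params <- function(n, cls, config) {
  p <- config$alleles$class_params[[cls]]
  jit <- config$alleles$mean_jitter_sd
  data.frame(
    fracON_glu = stats::runif(n, p$fglu[1], p$fglu[2]),
    fracON_gal = stats::runif(n, p$fgal[1], p$fgal[2]),
    on_mean_glu = p$mean_glu + stats::rnorm(n, 0, jit),
    on_mean_gal = p$mean_gal + stats::rnorm(n, 0, jit),
    on_sd = rep(p$sd, n))
}

#' Enumerate a pairwise combinatorial genotype design
#'
#' The design contains the wild type, every single mutant, and every
#' cross-locus allele pair (never two alleles at the same locus); a seeded
#' dropout fraction of the pairs is flagged `dropout = TRUE` to mirror the
#' incompleteness of a real transformation library.
#'
#' @param library allele library from [generate_allele_library()].
#' @param dropout_rate proportion in `[0, 1)` of double mutants flagged as
#'   failed constructions.
#' @param seed integer seed.
#' @param include_triples also enumerate all-locus triples (used for the
#'   2^3 deletion design; only sensible for one allele per locus).
#' @return data frame: `genotype_id`, `GAL3`, `GAL80`, `GAL4` (allele id or
#'   `"WT"`), `n_mutant_loci`, `N` (replicate count), `dropout`.
#' @export
generate_design <- function(library, dropout_rate = 0, seed = 1L,
                            include_triples = FALSE,
                            config = galcomb_config()) {
  if (nrow(library) == 0) stopf("allele library is empty")
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  by_locus <- split(library$allele_id, factor(library$locus, levels = GALR_LOCI))

  gid <- function(a3, a80, a4) paste(a3, a80, a4, sep = "_")
  wt <- data.frame(GAL3 = "WT", GAL80 = "WT", GAL4 = "WT", stringsAsFactors = FALSE)
  singles <- do.call(rbind, lapply(GALR_LOCI, function(locus) {
    a <- by_locus[[locus]]
    if (!length(a)) return(NULL)
    d <- wt[rep(1, length(a)), , drop = FALSE]
    d[[locus]] <- a
    d
  }))
  pair_block <- function(l1, l2) {
    a1 <- by_locus[[l1]]; a2 <- by_locus[[l2]]
    if (!length(a1) || !length(a2)) return(NULL)
    g <- expand.grid(x = a1, y = a2, stringsAsFactors = FALSE)
    d <- wt[rep(1, nrow(g)), , drop = FALSE]
    d[[l1]] <- g$x; d[[l2]] <- g$y
    d
  }
  doubles <- rbind(pair_block("GAL3", "GAL80"),
                   pair_block("GAL3", "GAL4"),
                   pair_block("GAL80", "GAL4"))
  design <- rbind(wt, singles, doubles)
  if (include_triples) {
    g <- expand.grid(GAL3 = by_locus$GAL3, GAL80 = by_locus$GAL80,
                     GAL4 = by_locus$GAL4, stringsAsFactors = FALSE)
    design <- rbind(design, g[, c("GAL3", "GAL80", "GAL4")])
  }
  design$n_mutant_loci <- rowSums(design[, GALR_LOCI] != "WT")
  design$genotype_id <- gid(design$GAL3, design$GAL80, design$GAL4)
  design$N <- config$design$replicates
  design$dropout <- FALSE
  if (dropout_rate > 0) {
    idx <- which(design$n_mutant_loci == 2)
    drop <- with_seed(sub_seed(seed, "design/dropout"),
                      stats::runif(length(idx)) < dropout_rate)
    design$dropout[idx[drop]] <- TRUE
  }
  rownames(design) <- NULL
  design[, c("genotype_id", "GAL3", "GAL80", "GAL4", "n_mutant_loci", "N", "dropout")]
}

#' The 2^3 combinatorially complete deletion design
#'
#' One null allele per locus (Uninducible GAL3, Constitutive GAL80,
#' Uninducible GAL4), all 8 presence/absence combinations including the
#' triple deletion.
#'
#' @inheritParams generate_design
#' @return list with `library` and `design` data frames.
#' @export
deletion_design <- function(seed = 1L, config = galcomb_config()) {
  counts <- list(GAL3 = c(Uninducible = 1),
                 GAL80 = c(Constitutive = 1),
                 GAL4 = c(Uninducible = 1))
  lib <- generate_allele_library(counts, seed = seed, config = config)
  lib$allele_id <- paste0("d", sub("GAL", "", lib$locus))  # d3, d80, d4
  des <- generate_design(lib, dropout_rate = 0, seed = seed,
                         include_triples = TRUE, config = config)
  list(library = lib, design = des)
}

# Stereotypical double-mutant class from the two single-mutant classes.
# `u` is a uniform draw in [0,1) used only for the two class combinations
# the study found to be stochastic across genotypes (Uninducible GAL80 x
# Constitutive GAL4, and the 96/4 Leaky split of Uninducible GAL3 x Leaky
# GAL80); everything else is deterministic.
combine_classes <- function(locus1, class1, locus2, class2, u = 0) {
  # order so locus1 is the earlier locus in GAL3 < GAL80 < GAL4
  o <- match(c(locus1, locus2), GALR_LOCI)
  if (o[1] > o[2]) {
    tmp <- locus1; locus1 <- locus2; locus2 <- tmp
    tmp <- class1; class1 <- class2; class2 <- tmp
  }
  if (class1 == "Inducible") return(class2)
  if (class2 == "Inducible") return(class1)
  if (locus1 == "GAL3") {                    # class1 is Uninducible here
    if (class2 == "Constitutive") return("Constitutive")
    if (class2 == "Leaky") return(if (u < 0.96) "Leaky" else "Inducible")
    return("Uninducible")                    # U or WeakExpression partner
  }
  # GAL80 x GAL4
  key <- paste(class1, class2, sep = "+")
  switch(key,
         "Constitutive+Constitutive" = "Constitutive",
         "Constitutive+Uninducible" = "Uninducible",
         "Constitutive+WeakExpression" = "Constitutive",
         "Uninducible+Constitutive" = {
           # the study's most diverse pairing: GAL80S x GAL4C
           cut <- cumsum(c(Constitutive = 0.56, Inducible = 0.12,
                           Uninducible = 0.20, Leaky = 0.06, WeakExpression = 0.06))
           names(cut)[which(u < cut)[1]]
         },
         "Uninducible+Uninducible" = "Uninducible",
         "Uninducible+WeakExpression" = "Uninducible",
         "Leaky+Constitutive" = "Constitutive",
         "Leaky+Uninducible" = "Uninducible",
         "Leaky+WeakExpression" = "WeakExpression",
         stopf("no combination rule for %s x %s", class1, class2))
}

#' Build the per-genotype truth table
#'
#' Assigns every genotype in a design its true expression class (single
#' mutants inherit the allele class; double mutants follow the stereotyped
#' combination rules of the network, with the two empirically stochastic
#' pairings drawn under a seeded substream), draws its true fraction ON and
#' ON-component location, and computes the true Malthusian growth rate
#' `mu_true = beta0 + beta_gal * fracON_gal + beta_glu * fracON_glu + noise`
#' truncated at zero.
#'
#' @param design from [generate_design()].
#' @param library from [generate_allele_library()].
#' @param seed integer seed.
#' @param config a [galcomb_config()] list.
#' @return data frame keyed by `genotype_id` with `true_class`,
#'   `fracON_glu`, `fracON_gal`, `on_mean_glu`, `on_mean_gal`, `on_sd`,
#'   `mu_true`, plus attributes `beta` and `mu_bg`.
#' @export
truth_table <- function(design, library, seed = 1L, config = galcomb_config()) {
  lib <- library
  rownames(lib) <- lib$allele_id
  n <- nrow(design)
  cls <- character(n)
  u <- with_seed(sub_seed(seed, "truth/combine"), stats::runif(n))
  mut <- as.matrix(design[, GALR_LOCI]) != "WT"
  for (i in seq_len(n)) {
    k <- which(mut[i, ])
    cls[i] <- if (length(k) == 0) {
      "Inducible"
    } else if (length(k) == 1) {
      lib[design[[GALR_LOCI[k]]][i], "true_class"]
    } else if (length(k) == 2) {
      l1 <- GALR_LOCI[k[1]]; l2 <- GALR_LOCI[k[2]]
      combine_classes(l1, lib[design[[l1]][i], "true_class"],
                      l2, lib[design[[l2]][i], "true_class"], u[i])
    } else {
      "Uninducible"  # no functional regulator set
    }
  }
  # parameters: single mutants keep their allele's draws so the single and
  # its library entry agree; everything else draws fresh from its class
  pars <- with_seed(sub_seed(seed, "truth/params"), {
    out <- data.frame(fracON_glu = numeric(n), fracON_gal = numeric(n),
                      on_mean_glu = numeric(n), on_mean_gal = numeric(n),
                      on_sd = numeric(n))
    for (cl in EXPR_CLASSES) {
      idx <- which(cls == cl)
      if (length(idx)) out[idx, ] <- draw_class_params(length(idx), cl, config)
    }
    out
  })
  single <- which(design$n_mutant_loci == 1)
  if (length(single)) {
    aid <- apply(as.matrix(design[single, GALR_LOCI]), 1,
                 function(r) r[r != "WT"])
    pars[single, ] <- lib[aid, c("fracON_glu", "fracON_gal",
                                 "on_mean_glu", "on_mean_gal", "on_sd")]
  }
  g <- config$growth
  eps <- with_seed(sub_seed(seed, "truth/growth"), stats::rnorm(n, 0, g$noise_sd))
  mu <- pmax(0, g$beta0 + g$beta_gal * pars$fracON_gal +
                  g$beta_glu * pars$fracON_glu + eps)
  out <- data.frame(genotype_id = design$genotype_id, true_class = cls,
                    pars, mu_true = mu, stringsAsFactors = FALSE)
  attr(out, "beta") <- c(beta0 = g$beta0, beta_gal = g$beta_gal, beta_glu = g$beta_glu)
  attr(out, "mu_bg") <- g$background
  out
}

#' True culture densities implied by a genotype's growth rate
#'
#' Inverts the growth-rate computation: the galactose culture is inoculated
#' at the glucose density times the dilution factor (9/150) and grows
#' exponentially for `hours` hours at `mu_true`.
#'
#' @param truth truth table row(s) (needs `mu_true`).
#' @param glu_density saturated glucose culture density, cells/ul.
#' @param config a [galcomb_config()] list.
#' @return data frame with `density_glu` and `density_gal` (cells/ul).
#' @export
simulate_growth <- function(truth, glu_density = NULL, config = galcomb_config()) {
  glu_density <- glu_density %||% config$events$glu_density
  if (any(glu_density <= 0)) stopf("inoculum density must be positive")
  if (any(!is.finite(truth$mu_true))) stopf("mu_true must be finite")
  inoc <- glu_density * config$growth$dilution
  data.frame(density_glu = rep_len(glu_density, nrow(truth)),
             density_gal = inoc * exp(truth$mu_true * config$growth$hours))
}

#' Simulate a flow-cytometry event table for one sample
#'
#' FITC-A is a two-component mixture: OFF events from the autofluorescence
#' distribution (normal on the raw scale, centered near raw 0) and ON events
#' log-normal around the genotype's ON location, mixed by the true fraction
#' ON for the condition.  PE-A is tied to the pre-saturation FITC-A through
#' the configured log-log relation; FITC-A is then clipped at the machine
#' ceiling.  Event timestamps are Poisson arrivals at a rate proportional to
#' the true cell density and the sampling rate.
#'
#' @param genotype_id genotype identifier (looked up in `truth`).
#' @param condition `"glucose"` or `"galactose"`.
#' @param truth truth table from [truth_table()].
#' @param n_events number of events to draw.
#' @param seed integer seed.
#' @param density true cell density (cells/ul); defaults to the value from
#'   [simulate_growth()] for the condition.
#' @param config a [galcomb_config()] list.
#' @return data frame `FSC`, `SSC`, `FITC`, `PE`, `time_ms` with attributes
#'   `sampling_rate` (ul/s) and `sample_id`.
#' @export
simulate_events <- function(genotype_id, condition = c("glucose", "galactose"),
                            truth, n_events = NULL, seed = 1L, density = NULL,
                            config = galcomb_config()) {
  condition <- match.arg(condition)
  n_events <- n_events %||% config$events$n_events
  if (n_events <= 0) stopf("n_events must be positive")
  i <- match(genotype_id, truth$genotype_id)
  if (is.na(i)) stopf("unknown genotype_id '%s'", genotype_id)
  tr <- truth[i, ]
  if (is.null(density)) {
    dens <- simulate_growth(tr, config = config)
    density <- if (condition == "glucose") dens$density_glu else dens$density_gal
  }
  fracon <- if (condition == "glucose") tr$fracON_glu else tr$fracON_gal
  on_mean <- if (condition == "glucose") tr$on_mean_glu else tr$on_mean_gal
  ev <- config$events
  with_seed(sub_seed(seed, paste0("events/", genotype_id, "/", condition)), {
    on <- stats::runif(n_events) < fracon
    # instruments clip dim events just above -1000 A.U.
    fitc <- pmax(stats::rnorm(n_events, ev$autofluor_mean, ev$autofluor_sd), -999)
    n_on <- sum(on)
    if (n_on) {
      # ON component: normal on the pseudo-log scale around on_mean
      fitc[on] <- pseudolog_inv(stats::rnorm(n_on, on_mean, tr$on_sd))
    }
    # PE tied to pre-clip FITC: log(FITC) = a*log(PE) + b  (+ noise)
    lpe <- (log(pmax(fitc, 1)) - ev$pe_intercept) / ev$pe_slope
    pe <- exp(lpe + stats::rnorm(n_events, 0, ev$pe_noise_sd))
    fitc <- pmin(fitc, ev$saturation_ceiling)
    # correlated FSC/SSC cloud, log-normal
    z1 <- stats::rnorm(n_events); z2 <- stats::rnorm(n_events)
    r <- ev$fsc_ssc_cor
    fsc <- exp(ev$fsc_meanlog + ev$fsc_sdlog * z1)
    ssc <- exp(ev$ssc_meanlog + ev$ssc_sdlog * (r * z1 + sqrt(1 - r^2) * z2))
    rate_ul_s <- if (density < ev$density_rate_cut) ev$rate_low else ev$rate_high
    rate_ms <- density * rate_ul_s / 1000   # events per millisecond
    t_ms <- cumsum(stats::rexp(n_events, rate_ms))
    out <- data.frame(FSC = fsc, SSC = ssc, FITC = fitc, PE = pe, time_ms = t_ms)
    attr(out, "sampling_rate") <- rate_ul_s
    attr(out, "sample_id") <- paste(genotype_id, condition, sep = ":")
    out
  })
}

#' Simulate an autofluorescent control sample (no reporter)
#' @inheritParams simulate_events
#' @export
simulate_control_events <- function(n_events = 5000L, seed = 1L,
                                    config = galcomb_config()) {
  truth <- data.frame(genotype_id = "control", true_class = "Uninducible",
                      fracON_glu = 0, fracON_gal = 0, on_mean_glu = 2,
                      on_mean_gal = 2, on_sd = 0.25, mu_true = 0,
                      stringsAsFactors = FALSE)
  simulate_events("control", "glucose", truth, n_events = n_events,
                  seed = seed, density = config$events$glu_density,
                  config = config)
}

#' Plant growth rates with pure class-mean structure
#'
#' Used to generate datasets where the class-mean model is exactly the true
#' model: every genotype's growth rate is its class-combination mean plus
#' independent Gaussian noise.
#'
#' @param keys character vector of class-combination keys, one per genotype.
#' @param class_means named numeric vector of true means per key; keys
#'   absent from it are drawn uniformly in `[0.05, 0.35]` under the seed.
#' @param sigma noise standard deviation (per hour).
#' @param seed integer seed.
#' @return data frame `key`, `mu_class` (true class mean), `mu` (observed).
#' @export
plant_class_growth <- function(keys, class_means = NULL, sigma = 0.02, seed = 1L) {
  uk <- unique(keys)
  if (is.null(class_means)) {
    class_means <- with_seed(sub_seed(seed, "plant/means"),
                             stats::setNames(stats::runif(length(uk), 0.05, 0.35), uk))
  }
  missing <- setdiff(uk, names(class_means))
  if (length(missing)) stopf("no class mean for key(s): %s", paste(missing, collapse = ", "))
  mu_class <- unname(class_means[keys])
  noise <- with_seed(sub_seed(seed, "plant/noise"), stats::rnorm(length(keys), 0, sigma))
  data.frame(key = keys, mu_class = mu_class, mu = mu_class + noise,
             stringsAsFactors = FALSE)
}
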