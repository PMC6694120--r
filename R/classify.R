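# Expression-distribution classification: 120-dimensional glucose+galactose
# density features, HDBSCAN* clustering across a minPts grid, linear-model
# cluster evaluation, deterministic archetype curation into the named
# phenotypic classes, and rescue of unclustered genotypes.

#' Build the genotype feature matrix
#'
#' Pairs each genotype's replicate-mean 60-bin expression density in glucose
#' with the one in galactose into a 120-unit vector, applies the
#' low-density-exaggerating transform `V = log10(round(v, 3) + 0.001)`
#' (R's `round()` rounds half to even, which is the documented rule at the
#' 0.0005 boundary), and z-scales each of the 120 columns across genotypes
#' (constant columns are set to 0).
#'
#' @param dens_glu,dens_gal numeric matrices, genotypes x 60 bins, of raw
#'   replicate-mean densities; rownames are genotype ids.
#' @return matrix with attributes `center` and `scale` of class
#'   `gal_features`.
#' @export
build_features <- function(dens_glu, dens_gal) {
  stopifnot(nrow(dens_glu) == nrow(dens_gal))
  v <- cbind(dens_glu, dens_gal)
  colnames(v) <- c(paste0("glu", seq_len(ncol(dens_glu))),
                   paste0("gal", seq_len(ncol(dens_gal))))
  V <- v_transform(v)
  ctr <- colMeans(V)
  sc <- apply(V, 2, stats::sd)
  sc[!is.finite(sc) | sc == 0] <- Inf   # constant columns scale to 0
  out <- sweep(sweep(V, 2, ctr), 2, sc, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sc
  class(out) <- c("gal_features", class(out))
  out
}

#' The V transform of a raw bin density
#' @param v raw density value(s).
#' @return `log10(round(v, 3) + 0.001)`.
#' @export
v_transform <- function(v) log10(round(v, 3) + 0.001)

# apply a dataset's V/z transform to new raw density vectors
transform_like <- function(v, features) {
  V <- v_transform(v)
  sweep(sweep(V, 2, attr(features, "center")), 2, attr(features, "scale"), "/")
}

#' Expected class archetype profiles
#'
#' Deterministic reference 120-bin raw density vectors for the five
#' expression classes, computed by a large seeded simulation from the
#' generator's nominal class parameters (midpoint fraction ON, nominal ON
#' location).  These play the role of the archetypal deletion-experiment
#' profiles: curation maps each cluster to its nearest archetype, and
#' rescue anchors unclustered genotypes to them.
#'
#' @param config a [galcomb_config()] list.
#' @param n_draws events per archetype per condition.
#' @return 5 x 120 matrix, rownames = class names.
#' @export
archetype_features <- function(config = galcomb_config(), n_draws = 2e5) {
  edges <- bin_edges(config$bins$n, config$bins$range)
  nb <- config$bins$n
  binwidth <- diff(range(edges)) / nb
  ev <- config$events
  one <- function(fracon, on_mean, on_sd, seed) {
    with_seed(seed, {
      on <- stats::runif(n_draws) < fracon
      x <- pmax(stats::rnorm(n_draws, ev$autofluor_mean, ev$autofluor_sd), -999)
      if (any(on)) x[on] <- pseudolog_inv(stats::rnorm(sum(on), on_mean, on_sd))
      pl <- pseudolog(pmin(x, ev$saturation_ceiling))
      idx <- pmin(pmax(findInterval(pl, edges, rightmost.closed = TRUE), 1L), nb)
      tabulate(idx, nbins = nb) / (n_draws * binwidth)
    })
  }
  out <- t(vapply(EXPR_CLASSES, function(cl) {
    p <- config$alleles$class_params[[cl]]
    c(one(mean(p$fglu), p$mean_glu, p$sd, sub_seed(97L, paste0("arch/", cl, "/glu"))),
      one(mean(p$fgal), p$mean_gal, p$sd, sub_seed(97L, paste0("arch/", cl, "/gal"))))
  }, numeric(2 * nb)))
  rownames(out) <- EXPR_CLASSES
  out
}

#' Evaluate a labeling by explained phenotypic variance
#'
#' Fits the saturated interaction model
#' `value ~ cluster * phenotype_id` to the long-format stack of the five
#' per-genotype phenotypes (fraction ON and mean YFP in both conditions,
#' and growth rate), each z-scaled across genotypes, and reports
#' `1 - SSR/SST`.  The fitted values of that model are exactly the
#' (cluster, phenotype) cell means, which is how the quantity is computed.
#' Noise points (label 0) enter as their own singleton labels so the
#' quantity is defined for every labeling.
#'
#' @param labels integer labels (0 = noise).
#' @param phenotypes data frame / matrix of per-genotype phenotype means,
#'   one column per phenotype.
#' @return list of class `cluster_evaluation`: `variance_explained`,
#'   `n_clusters`, `n_noise`.
#' @export
evaluate_clusters <- function(labels, phenotypes) {
  ph <- as.matrix(phenotypes)
  stopifnot(nrow(ph) == length(labels))
  lab <- as.integer(labels)
  noise <- lab == 0L
  if (any(noise)) lab[noise] <- max(lab) + seq_len(sum(noise))
  z <- apply(ph, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  y <- as.vector(z)
  cell <- interaction(rep(lab, ncol(z)), rep(seq_len(ncol(z)), each = nrow(z)),
                      drop = TRUE)
  fitted <- stats::ave(y, cell)
  sst <- sum((y - mean(y))^2)
  ssr <- sum((y - fitted)^2)
  ve <- if (sst > 0) 1 - ssr / sst else NA_real_
  structure(list(variance_explained = ve,
                 n_clusters = length(unique(labels[labels > 0])),
                 n_noise = sum(noise)),
            class = "cluster_evaluation")
}

#' Cluster expression profiles across a minPts grid
#'
#' Runs HDBSCAN* once per minPts value, scores each labeling with
#' [evaluate_clusters()], and keeps the labeling that maximizes explained
#' variance; among labelings within `parsimony_tol` of the best, the one
#' with fewest clusters wins.
#'
#' @param features matrix from [build_features()].
#' @param phenotypes per-genotype phenotype means (see
#'   [evaluate_clusters()]).
#' @param minPts_grid integer vector.
#' @param parsimony_tol tolerance (in variance-explained units) of the
#'   fewest-clusters tie-break.
#' @return list of class `gal_clustering`: `labels` (chosen), `minPts`
#'   (chosen), `evaluations` (data frame per minPts), `all_labels`.
#' @export
cluster_profiles <- function(features, phenotypes,
                             minPts_grid = c(5L, 10L, 15L, 25L),
                             parsimony_tol = 0.005) {
  if (nrow(features) < 2) stopf("cluster_profiles: need >= 2 genotypes")
  dm <- as.matrix(stats::dist(features))
  all_labels <- list()
  evals <- data.frame(minPts = integer(), n_clusters = integer(),
                      n_noise = integer(), variance_explained = numeric())
  for (mp in minPts_grid) {
    fit <- hdbscan_dm(dm, minPts = mp)
    ev <- evaluate_clusters(fit$labels, phenotypes)
    all_labels[[as.character(mp)]] <- fit$labels
    evals <- rbind(evals, data.frame(minPts = mp, n_clusters = ev$n_clusters,
                                     n_noise = ev$n_noise,
                                     variance_explained = ev$variance_explained))
  }
  if (all(evals$n_clusters == 0)) {
    stopf("cluster_profiles: every point is noise at every minPts in {%s}",
          paste(minPts_grid, collapse = ", "))
  }
  ok <- evals$n_clusters > 0
  best_ve <- max(evals$variance_explained[ok])
  cand <- which(ok & evals$variance_explained >= best_ve - parsimony_tol)
  # parsimony counts every label the evaluation model used, noise singletons
  # included, so labelings that shed points as noise are not rewarded
  effective <- evals$n_clusters[cand] + evals$n_noise[cand]
  chosen <- cand[which.min(effective)]
  structure(list(labels = all_labels[[chosen]],
                 minPts = evals$minPts[chosen],
                 evaluations = evals,
                 all_labels = all_labels),
            class = "gal_clustering")
}

#' @export
print.gal_clustering <- function(x, ...) {
  cat(sprintf("expression-profile clustering: chose minPts = %d (%d clusters, %d noise)\n",
              x$minPts, max(x$labels), sum(x$labels == 0)))
  print(x$evaluations, row.names = FALSE)
  invisible(x)
}

#' Curate clusters into named expression classes
#'
#' Maps each cluster to the expression class of its nearest archetype
#' profile (Euclidean distance in the transformed feature space), then
#' applies the per-genotype induction-ratio overrides: a Constitutive call
#' with raw-mean induction ratio (gal/glu) at or above `induction_hi`
#' becomes Leaky when a detectable-but-partial fraction of cells is ON in
#' glucose and Inducible otherwise; an Inducible call with ratio at or below
#' `induction_lo` becomes Uninducible; an Uninducible call with more than
#' 40\% of cells ON in galactose at a high ON mode becomes Inducible.
#'
#' @param labels labels from [cluster_profiles()] (0 = unclustered).
#' @param features matrix from [build_features()].
#' @param summaries per-genotype data frame with `fracON_glu`, `fracON_gal`,
#'   `mean_raw_glu`, `mean_raw_gal`, `on_mode_gal` columns (row order =
#'   feature rows).
#' @param archetypes raw archetype profiles from [archetype_features()].
#' @param config a [galcomb_config()] list.
#' @return data frame of class assignments: `genotype_id`, `cluster`,
#'   `class_intermediate` (NA where unclustered), `class_broad`,
#'   `induction_ratio`, `provenance`.
#' @export
curate_classes <- function(labels, features, summaries,
                           archetypes = archetype_features(config),
                           config = galcomb_config()) {
  cc <- config$classify
  arch_t <- transform_like(archetypes, features)
  k <- max(labels)
  cluster_class <- rep(NA_character_, k)
  for (cl in seq_len(k)) {
    centroid <- colMeans(features[labels == cl, , drop = FALSE])
    dists <- sqrt(colSums((t(arch_t) - centroid)^2))
    if (min(dists) <= cc$archetype_ceiling) {
      cluster_class[cl] <- rownames(archetypes)[which.min(dists)]
    }
  }
  cls <- rep(NA_character_, length(labels))
  cls[labels > 0] <- cluster_class[labels[labels > 0]]
  ratio <- induction_ratio(summaries$mean_raw_glu, summaries$mean_raw_gal)
  cls <- apply_overrides(cls, ratio, summaries, cc)
  data.frame(genotype_id = rownames(features),
             cluster = labels,
             class_intermediate = cls,
             class_broad = broaden_class(cls),
             induction_ratio = ratio,
             provenance = ifelse(is.na(cls), NA_character_, "primary_cluster"),
             stringsAsFactors = FALSE)
}

induction_ratio <- function(mean_raw_glu, mean_raw_gal) {
  ifelse(mean_raw_glu > 0, mean_raw_gal / mean_raw_glu,
         ifelse(mean_raw_gal > 0, Inf, NA_real_))
}

apply_overrides <- function(cls, ratio, summaries, cc) {
  hi <- !is.na(cls) & cls == "Constitutive" & !is.na(ratio) & ratio >= cc$induction_hi
  leaky <- hi & summaries$fracON_glu > 0.02 & summaries$fracON_glu <= cc$leaky_fglu_max
  cls[hi & leaky] <- "Leaky"
  cls[hi & !leaky] <- "Inducible"
  lo <- !is.na(cls) & cls == "Inducible" & !is.na(ratio) & ratio <= cc$induction_lo
  cls[lo] <- "Uninducible"
  resc <- !is.na(cls) & cls == "Uninducible" &
          summaries$fracON_gal > cc$fracon_rescue &
          !is.na(summaries$on_mode_gal) & summaries$on_mode_gal > cc$high_mode
  cls[resc] <- "Inducible"
  cls
}

#' Coarsen intermediate classes to the broad three-class scheme
#'
#' Leaky profiles are a flavour of Inducible; the weak-expression GAL4
#' alleles behaved WT-like apart from their low peak signal, so
#' WeakExpression also coarsens to Inducible.
#'
#' @param cls character vector of intermediate class names.
#' @return character vector over Inducible/Constitutive/Uninducible.
#' @export
broaden_class <- function(cls) {
  map <- c(Inducible = "Inducible", Constitutive = "Constitutive",
           Uninducible = "Uninducible", Leaky = "Inducible",
           WeakExpression = "Inducible")
  unname(map[cls])
}

#' Rescue unclustered genotypes
#'
#' Genotypes left without a class (noise points or clusters with no
#' archetype within the ceiling) are re-clustered together with anchor
#' exemplars: first with the WeakExpression exemplars alone, then with
#' exemplars of the three archetypal deletion classes; re-clustered groups
#' inherit the majority anchor class of their cluster, and any residue is
#' assigned to the nearest anchor in feature space.  Every genotype ends
#' with a class.
#'
#' @param assignments data frame from [curate_classes()].
#' @param features matrix from [build_features()].
#' @param archetypes raw archetype profiles.
#' @param n_exemplars per class, taken from the already-assigned genotypes
#'   nearest to their class archetype (the archetype row itself always
#'   anchors).
#' @param config a [galcomb_config()] list.
#' @return the completed assignment data frame (provenance `"rescued"` for
#'   rescued rows).
#' @export
rescue_unclustered <- function(assignments, features,
                               archetypes = archetype_features(config),
                               n_exemplars = 10L,
                               config = galcomb_config()) {
  un <- which(is.na(assignments$class_intermediate))
  if (!length(un)) return(assignments)
  arch_t <- transform_like(archetypes, features)
  anchor_feat <- list(); anchor_cls <- list()
  for (cl in EXPR_CLASSES) {
    rows <- which(assignments$class_intermediate == cl)
    feat <- arch_t[cl, , drop = FALSE]
    if (length(rows)) {
      d <- sqrt(colSums((t(features[rows, , drop = FALSE]) - arch_t[cl, ])^2))
      take <- rows[order(d)][seq_len(min(n_exemplars, length(rows)))]
      feat <- rbind(feat, features[take, , drop = FALSE])
    }
    anchor_feat[[cl]] <- feat
    anchor_cls[[cl]] <- rep(cl, nrow(feat))
  }
  assign_stage <- function(un_idx, classes) {
    af <- do.call(rbind, anchor_feat[classes])
    ac <- unlist(anchor_cls[classes], use.names = FALSE)
    x <- rbind(features[un_idx, , drop = FALSE], af)
    mp <- min(config$classify$rescue_minPts, nrow(x) - 1L)
    got <- rep(NA_character_, length(un_idx))
    if (mp >= 2) {
      fit <- tryCatch(hdbscan(x, minPts = mp), error = function(e) NULL)
      if (!is.null(fit) && fit$n_clusters > 0) {
        lab_un <- fit$labels[seq_along(un_idx)]
        lab_anchor <- fit$labels[-seq_along(un_idx)]
        for (cl in unique(lab_un[lab_un > 0])) {
          hits <- ac[lab_anchor == cl]
          if (length(hits)) {
            got[lab_un == cl] <- names(which.max(table(hits)))
          }
        }
      }
    }
    got
  }
  # stage 1: weak-expression exemplars alone; stage 2: the three archetypes
  got <- assign_stage(un, "WeakExpression")
  still <- is.na(got)
  if (any(still)) {
    got2 <- assign_stage(un[still], c("Inducible", "Constitutive", "Uninducible"))
    got[still] <- got2
  }
  # residue: nearest anchor of any class
  still <- is.na(got)
  if (any(still)) {
    af <- do.call(rbind, anchor_feat)
    ac <- unlist(anchor_cls, use.names = FALSE)
    for (i in which(still)) {
      d <- sqrt(colSums((t(af) - features[un[i], ])^2))
      got[i] <- ac[which.min(d)]
    }
  }
  assignments$class_intermediate[un] <- got
  assignments$provenance[un] <- "rescued"
  assignments$class_broad <- broaden_class(assignments$class_intermediate)
  assignments
}

#' Classify every genotype: cluster, curate, rescue
#'
#' @param features matrix from [build_features()].
#' @param summaries per-genotype phenotype data frame (see
#'   [curate_classes()]); must also contain `mu` for cluster evaluation.
#' @param config a [galcomb_config()] list.
#' @return list of class `gal_classification` with `assignments`,
#'   `clustering`, `archetypes`.
#' @export
classify_genotypes <- function(features, summaries, config = galcomb_config()) {
  phen <- summaries[, c("fracON_glu", "fracON_gal", "mean_yfp_glu",
                        "mean_yfp_gal", "mu")]
  clus <- cluster_profiles(features, phen,
                           minPts_grid = config$classify$minPts_grid,
                           parsimony_tol = config$classify$parsimony_tol)
  arch <- archetype_features(config)
  asn <- curate_classes(clus$labels, features, summaries, arch, config)
  asn <- rescue_unclustered(asn, features, arch, config = config)
  stopifnot(!anyNA(asn$class_intermediate))   # total assignment is guaranteed
  structure(list(assignments = asn, clustering = clus, archetypes = arch),
            class = "gal_classification")
}

#' @export
print.gal_classification <- function(x, ...) {
  cat("expression classification of", nrow(x$assignments), "genotypes\n")
  print(table(x$assignments$class_intermediate))
  cat(sprintf("rescued: %d; chosen minPts: %d\n",
              sum(x$assignments$provenance == "rescued"), x$clustering$minPts))
  invisible(x)
}
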