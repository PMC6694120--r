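# Orchestration: simulate -> preprocess -> classify -> predict -> sensors
# under one config, with TSV artifacts per stage and a machine-readable run
# report.

#' Assemble the double-mutant prediction table
#'
#' Joins every double mutant with the classes and replicate statistics of
#' its two single mutants and with the observed double-mutant growth.
#'
#' @param design from [generate_design()].
#' @param records per-genotype records (from [genotype_records()]).
#' @param assignments class assignments (from [classify_genotypes()]).
#' @return list: `doubles` (one row per double with `locus1`, `allele1`,
#'   `class1`, `mu1`, `se1`, ... and observed `mu`, `pair`), `singles`
#'   (`allele_id`, `locus`, `class`, `mu`, `se`), `wt` (`mu`, `se`, `N`).
#' @export
double_table <- function(design, records, assignments) {
  rec <- records$records
  rownames(rec) <- rec$genotype_id
  cls <- assignments
  rownames(cls) <- cls$genotype_id
  sing <- design[design$n_mutant_loci == 1 & !design$dropout, , drop = FALSE]
  s_locus <- apply(as.matrix(sing[, GALR_LOCI]) != "WT", 1, which)
  singles <- data.frame(
    genotype_id = sing$genotype_id,
    locus = GALR_LOCI[s_locus],
    allele_id = mapply(function(i, l) sing[[l]][i], seq_len(nrow(sing)),
                       GALR_LOCI[s_locus]),
    class = cls[sing$genotype_id, "class_intermediate"],
    mu = rec[sing$genotype_id, "mu"],
    se = rec[sing$genotype_id, "mu_se"],
    N = rec[sing$genotype_id, "N"],
    stringsAsFactors = FALSE)
  rownames(singles) <- NULL
  by_allele <- singles
  rownames(by_allele) <- by_allele$allele_id

  dbl <- design[design$n_mutant_loci == 2 & !design$dropout, , drop = FALSE]
  dbl <- dbl[dbl$genotype_id %in% rownames(rec), , drop = FALSE]
  mut <- as.matrix(dbl[, GALR_LOCI]) != "WT"
  l1 <- GALR_LOCI[apply(mut, 1, function(r) which(r)[1])]
  l2 <- GALR_LOCI[apply(mut, 1, function(r) which(r)[2])]
  a1 <- dbl[cbind(seq_len(nrow(dbl)), match(l1, names(dbl)))]
  a2 <- dbl[cbind(seq_len(nrow(dbl)), match(l2, names(dbl)))]
  doubles <- data.frame(
    genotype_id = dbl$genotype_id,
    locus1 = l1, allele1 = a1, class1 = by_allele[a1, "class"],
    mu1 = by_allele[a1, "mu"], se1 = by_allele[a1, "se"],
    locus2 = l2, allele2 = a2, class2 = by_allele[a2, "class"],
    mu2 = by_allele[a2, "mu"], se2 = by_allele[a2, "se"],
    mu = rec[dbl$genotype_id, "mu"],
    pair = paste(l1, l2, sep = ":"),
    class_double = cls[dbl$genotype_id, "class_intermediate"],
    stringsAsFactors = FALSE)
  rownames(doubles) <- NULL
  wt_id <- design$genotype_id[design$n_mutant_loci == 0][1]
  wt <- list(mu = rec[wt_id, "mu"], se = rec[wt_id, "mu_se"], N = rec[wt_id, "N"])
  list(doubles = doubles, singles = singles, wt = wt)
}

#' Run the full pipeline under one configuration
#'
#' Executes the enabled stages in order (`simulate`, `preprocess`,
#' `classify`, `predict`, `sensors`); each stage consumes the previous
#' stage's in-memory artifact, and everything is reproducible under the
#' config's master seed.  When `out_dir` is given, every stage writes its
#' TSV artifact there together with the serialized config and the run
#' report.
#'
#' @param config a [galcomb_config()] list.
#' @param out_dir optional output directory.
#' @param n_events events per sample (defaults from config).
#' @param quiet suppress progress messages.
#' @return a `galcomb_report` list: per-stage counts, variance reports,
#'   dependency calls, config hash, and the stage artifacts in `$artifacts`.
#' @export
run_pipeline <- function(config = galcomb_config(), out_dir = NULL,
                         n_events = NULL, quiet = FALSE) {
  validate_config(config)
  stages <- config$pipeline$stages
  order_all <- c("simulate", "preprocess", "classify", "predict", "sensors")
  stages <- order_all[order_all %in% stages]
  # stage dependency check: each enabled stage needs its predecessors
  need <- list(preprocess = "simulate", classify = "preprocess",
               predict = "classify", sensors = "simulate")
  for (st in stages) {
    missing <- setdiff(need[[st]], stages)
    if (length(missing)) {
      stopf("stage '%s' requires stage '%s' to be enabled", st, missing[1])
    }
  }
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  art <- list()
  report <- list(config_hash = config_hash(config), seed = seed,
                 version = as.character(utils::packageVersion("galcomb")),
                 stages = character())

  if ("simulate" %in% stages) {
    say("simulate: allele library, design, truth")
    art$library <- generate_allele_library(seed = seed, config = config)
    art$design <- generate_design(art$library, dropout_rate = config$design$dropout,
                                  seed = seed, config = config)
    art$truth <- truth_table(art$design, art$library, seed = seed, config = config)
    del <- deletion_design(seed = seed, config = config)
    art$deletion <- del
    art$deletion_truth <- truth_table(del$design, del$library, seed = seed,
                                      config = config)
    report$n_alleles <- nrow(art$library)
    report$n_genotypes <- sum(!art$design$dropout)
    report$n_doubles <- sum(art$design$n_mutant_loci == 2 & !art$design$dropout)
    report$stages <- c(report$stages, "simulate")
  }

  if ("preprocess" %in% stages) {
    say("preprocess: %d genotypes x 2 conditions x %d replicates",
        report$n_genotypes, config$design$replicates)
    art$summaries <- simulate_summaries(art$design, art$truth, seed = seed,
                                        n_events = n_events, config = config)
    art$records <- genotype_records(art$summaries, config = config)
    del_sum <- simulate_summaries(art$deletion$design, art$deletion_truth,
                                  seed = sub_seed(seed, "deletion"),
                                  n_events = n_events, config = config)
    art$deletion_records <- genotype_records(del_sum, config = config)
    trip <- art$deletion$design$genotype_id[art$deletion$design$n_mutant_loci == 3]
    art$background <- mean(art$deletion_records$records$mu[
      art$deletion_records$records$genotype_id %in% trip])
    report$n_samples <- nrow(art$summaries$samples)
    report$n_censored <- sum(art$summaries$samples$censored)
    report$on_cutoff <- art$summaries$on_cutoff
    report$background_mu <- art$background
    report$stages <- c(report$stages, "preprocess")
  }

  if ("classify" %in% stages) {
    say("classify: clustering %d genotypes", nrow(art$records$records))
    feats <- build_features(art$records$dens_glu, art$records$dens_gal)
    art$features <- feats
    art$classification <- classify_genotypes(feats, art$records$records,
                                             config = config)
    report$class_counts <- as.list(table(art$classification$assignments$class_intermediate))
    report$n_rescued <- sum(art$classification$assignments$provenance == "rescued")
    report$clustering_minPts <- art$classification$clustering$minPts
    report$stages <- c(report$stages, "classify")
  }

  if ("predict" %in% stages) {
    say("predict: multiplicative and class-mean models")
    dt <- double_table(art$design, art$records, art$classification$assignments)
    art$doubles <- dt
    bg <- art$background %||% config$growth$background
    mp <- multiplicative_expectation(dt$doubles$mu1, dt$doubles$se1,
                                     dt$doubles$mu2, dt$doubles$se2,
                                     dt$wt$mu, dt$wt$se, N = dt$wt$N,
                                     background = bg,
                                     se_mode = config$epistasis$se_mode)
    art$multiplicative <- cbind(dt$doubles[, c("genotype_id", "pair")], mp)
    reports <- predict_and_score(mp$mu_expected, dt$doubles$mu, dt$doubles$pair,
                                 model = "multiplicative")
    art$class_models <- list()
    for (sc in c("intermediate5", "broad3")) {
      for (aware in c(TRUE, FALSE)) {
        m <- fit_class_model(dt$doubles, scheme = sc, locus_aware = aware)
        nm <- paste0(sc, if (aware) "_aware" else "_blinded")
        art$class_models[[nm]] <- m
        pr <- predict(m, dt$doubles)
        reports <- rbind(reports,
                         predict_and_score(pr, dt$doubles$mu, dt$doubles$pair,
                                           model = nm))
      }
    }
    art$variance_reports <- reports
    art$cv <- list(
      broad3 = downsample_cv(dt$doubles, dt$singles[, c("allele_id", "locus", "class")],
                             k_alleles_per_class = 1L,
                             iterations = config$epistasis$cv_iterations,
                             seed = seed, scheme = "broad3"),
      intermediate5 = downsample_cv(dt$doubles,
                                    dt$singles[, c("allele_id", "locus", "class")],
                                    k_alleles_per_class = 1L,
                                    iterations = config$epistasis$cv_iterations,
                                    seed = seed, scheme = "intermediate5"))
    report$variance_explained <- stats::setNames(
      reports$variance_explained[reports$scope == "overall"],
      reports$model[reports$scope == "overall"])
    report$cv_median <- c(broad3 = art$cv$broad3$median,
                          intermediate5 = art$cv$intermediate5$median)
    report$n_predicted <- nrow(dt$doubles)
    report$stages <- c(report$stages, "predict")
  }

  if ("sensors" %in% stages) {
    say("sensors: four-arm dependency panel")
    panel <- simulate_sensor_panel(seed = seed, config = config)
    art$sensor_panel <- panel
    art$contrasts <- contrast_backgrounds(panel$records,
                                          alpha = config$sensors$alpha,
                                          min_effect = config$sensors$min_effect)
    both <- panel$records[panel$records$arm == "both", ]
    art$leakiness_null <- fit_leakiness_null(both$x_glu, both$mu,
                                             group = both$galk_source)
    art$above_null <- test_above_null(both, art$leakiness_null,
                                      alpha = config$sensors$alpha)
    wt_mu <- if (!is.null(art$doubles)) art$doubles$wt$mu else
      max(panel$pairs$mu_intact)
    bg <- art$background %||% config$growth$background
    art$dependency_calls <- call_dependencies(art$contrasts, panel$pairs,
                                              wt_mu = wt_mu, background = bg,
                                              config = config)
    report$n_pairs <- nrow(panel$pairs)
    report$n_harmonious <- sum(art$dependency_calls$harmonious)
    report$dependency_verdicts <- as.list(table(
      paste(art$dependency_calls$gal3_verdict, art$dependency_calls$gal1_verdict,
            sep = "/")))
    report$stages <- c(report$stages, "sensors")
  }

  out <- structure(c(report, list(artifacts = art)), class = "galcomb_report")
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  out
}

write_pipeline_outputs <- function(report, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- report$artifacts
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(art$library)) write_tsv(art$library, file.path(out_dir, "alleles.tsv"))
  if (!is.null(art$design)) write_tsv(art$design, file.path(out_dir, "design.tsv"))
  if (!is.null(art$truth)) write_tsv(art$truth, file.path(out_dir, "truth.tsv"))
  if (!is.null(art$summaries)) {
    write_tsv(art$summaries$samples, file.path(out_dir, "samples.tsv"))
  }
  if (!is.null(art$records)) {
    write_tsv(art$records$records, file.path(out_dir, "records.tsv"))
  }
  if (!is.null(art$classification)) {
    write_tsv(art$classification$assignments, file.path(out_dir, "classes.tsv"))
    write_tsv(art$classification$clustering$evaluations,
              file.path(out_dir, "cluster_evaluations.tsv"))
  }
  if (!is.null(art$multiplicative)) {
    write_tsv(art$multiplicative, file.path(out_dir, "predictions_multiplicative.tsv"))
    write_tsv(art$variance_reports, file.path(out_dir, "variance_reports.tsv"))
  }
  if (!is.null(art$dependency_calls)) {
    write_tsv(art$contrasts, file.path(out_dir, "sensor_contrasts.tsv"))
    write_tsv(art$dependency_calls, file.path(out_dir, "dependency_calls.tsv"))
  }
  rep_small <- report[setdiff(names(report), "artifacts")]
  jsonlite::write_json(rep_small, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.galcomb_report <- function(x, ...) {
  cat("galcomb pipeline report (config ", x$config_hash, ", seed ", x$seed, ")\n",
      sep = "")
  cat("stages run:", paste(x$stages, collapse = " -> "), "\n")
  if (!is.null(x$n_genotypes)) {
    cat(sprintf("  %d alleles, %d genotypes (%d doubles)\n",
                x$n_alleles, x$n_genotypes, x$n_doubles))
  }
  if (!is.null(x$n_samples)) {
    cat(sprintf("  %d samples summarized (%d censored), ON cutoff %.3f, background mu %.3f/h\n",
                x$n_samples, x$n_censored, x$on_cutoff, x$background_mu))
  }
  if (!is.null(x$class_counts)) {
    cat("  classes:", paste(names(x$class_counts), unlist(x$class_counts),
                            sep = "=", collapse = ", "),
        sprintf("(%d rescued)\n", x$n_rescued))
  }
  if (!is.null(x$variance_explained)) {
    cat("  variance explained:\n")
    for (nm in names(x$variance_explained)) {
      cat(sprintf("    %-22s %.3f\n", nm, x$variance_explained[[nm]]))
    }
  }
  if (!is.null(x$n_pairs)) {
    cat(sprintf("  sensor panel: %d pairs, %d harmonious\n",
                x$n_pairs, x$n_harmonious))
  }
  invisible(x)
}
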