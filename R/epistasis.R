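# Double-mutant growth prediction: the multiplicative (independent-effects)
# null with standard-error propagation, expression-class-mean models
# (locus-aware and locus-blinded) with variance partitioning and
# downsampled cross-validation, and the combinatorial accounting of class
# combinations.

#' Multiplicative expectation for a double mutant
#'
#' Growth rates are first background-subtracted (the growth observed with
#' no functional GAL regulator), the independent-effects null
#' `mu_MUT = mu_mut1 * mu_mut2 / mu_WT` is applied, the standard error is
#' propagated (see [propagate_se()]), and the background is re-added for
#' reporting.
#'
#' @param mu1,mu2 single-mutant growth rates (per hour, raw scale).
#' @param se1,se2 their standard errors.
#' @param mu_wt,se_wt wild-type growth rate and standard error.
#' @param N replicate count entering the as-printed SE formula.
#' @param background background growth rate (per hour).
#' @param se_mode SE propagation mode, see [propagate_se()].
#' @return data frame `mu_expected` (raw scale), `se`, `flagged`.
#' @export
multiplicative_expectation <- function(mu1, se1, mu2, se2, mu_wt, se_wt,
                                       N = 2L, background = 0,
                                       se_mode = c("delta", "as_printed", "typo_fixed")) {
  se_mode <- match.arg(se_mode)
  m1 <- mu1 - background
  m2 <- mu2 - background
  mw <- mu_wt - background
  flagged <- !is.finite(mw) | mw == 0
  mu_mut <- ifelse(flagged, NA_real_, m1 * m2 / mw)
  se <- propagate_se(mu_mut, m1, se1, m2, se2, mw, se_wt, N, mode = se_mode)
  data.frame(mu_expected = mu_mut + background, se = se, flagged = flagged)
}

#' Propagate the standard error of the multiplicative expectation
#'
#' Three modes are shipped because the study's printed formula cannot be
#' reconciled with first-order error propagation:
#' \describe{
#'   \item{`"as_printed"`}{the formula exactly as printed:
#'     `abs(mu_mut) * sqrt((((N-1)*(se_WT/mu_WT) + se_mut1/mu_mut1 +
#'     se_mut2/mu_mut1))^2)` — note the `(N-1)` factor and the repeated
#'     `mu_mut1` in the last denominator.}
#'   \item{`"typo_fixed"`}{the same with the last denominator read as
#'     `mu_mut2`.}
#'   \item{`"delta"`}{standard first-order (delta-method) propagation for a
#'     product/quotient, `abs(mu_mut) * sqrt((se_WT/mu_WT)^2 +
#'     (se_mut1/mu_mut1)^2 + (se_mut2/mu_mut2)^2)`; the default, and the
#'     mode checked against Monte-Carlo simulation.}
#' }
#'
#' @param mu_mut the multiplicative expectation (background-subtracted).
#' @param mu1,se1,mu2,se2,mu_wt,se_wt background-subtracted single/WT rates
#'   and standard errors.
#' @param N replicate count (only the as-printed/typo-fixed modes use it).
#' @param mode one of `"delta"`, `"as_printed"`, `"typo_fixed"`.
#' @return nonnegative standard errors (NA where a denominator is zero).
#' @export
propagate_se <- function(mu_mut, mu1, se1, mu2, se2, mu_wt, se_wt, N = 2L,
                         mode = c("delta", "as_printed", "typo_fixed")) {
  mode <- match.arg(mode)
  bad <- mu1 == 0 | mu2 == 0 | mu_wt == 0
  se <- switch(mode,
    delta = abs(mu_mut) * sqrt((se_wt / mu_wt)^2 + (se1 / mu1)^2 + (se2 / mu2)^2),
    as_printed = abs(mu_mut) *
      sqrt((((N - 1) * (se_wt / mu_wt) + se1 / mu1 + se2 / mu1))^2),
    typo_fixed = abs(mu_mut) *
      sqrt((((N - 1) * (se_wt / mu_wt) + se1 / mu1 + se2 / mu2))^2))
  se[bad] <- NA_real_
  se
}

# ---- class-combination keys ------------------------------------------------

#' Class-combination key of a double mutant
#'
#' Locus-aware keys are ordered class triples over (GAL3, GAL80, GAL4) with
#' the unmutated locus carrying the Inducible class (a wild-type locus is
#' phenotypically Inducible); locus-blinded keys are the unordered pair of
#' the two single-mutant classes.
#'
#' @param locus1,locus2 the two mutated loci.
#' @param class1,class2 their single-mutant expression classes.
#' @param locus_aware logical.
#' @return character key(s).
#' @export
class_key <- function(locus1, class1, locus2, class2, locus_aware = TRUE) {
  if (locus_aware) {
    n <- length(locus1)
    tri <- matrix("Inducible", n, 3, dimnames = list(NULL, GALR_LOCI))
    tri[cbind(seq_len(n), match(locus1, GALR_LOCI))] <- class1
    tri[cbind(seq_len(n), match(locus2, GALR_LOCI))] <- class2
    paste(tri[, "GAL3"], tri[, "GAL80"], tri[, "GAL4"], sep = "/")
  } else {
    mapply(function(a, b) paste(sort(c(a, b)), collapse = "+"), class1, class2,
           USE.NAMES = FALSE)
  }
}

#' Coarsen a locus-aware key to its locus-blinded key
#' @param key locus-aware key(s) (`"c3/c80/c4"` triples).
#' @param locus1,locus2 the mutated loci of each genotype.
#' @return locus-blinded key(s).
#' @export
blind_key <- function(key, locus1, locus2) {
  parts <- strsplit(key, "/", fixed = TRUE)
  mapply(function(p, l1, l2) {
    cls <- stats::setNames(p, GALR_LOCI)[c(l1, l2)]
    paste(sort(unname(cls)), collapse = "+")
  }, parts, locus1, locus2, USE.NAMES = FALSE)
}

#' Fit the expression-class-mean growth model
#'
#' Groups double mutants by their class-combination key and takes each
#' group's mean observed growth rate as its parameter.
#'
#' @param doubles data frame with columns `mu` (observed growth),
#'   `locus1`, `class1`, `locus2`, `class2`; rows whose single mutants lack
#'   a class are excluded (and counted in the returned object).
#' @param scheme `"intermediate5"` or `"broad3"`; with `"broad3"` the
#'   single-mutant classes are first coarsened via [broaden_class()].
#' @param locus_aware logical (see [class_key()]).
#' @return object of class `class_model`: `parameters` (named means),
#'   `n_parameters`, `scheme`, `locus_aware`, `grand_mean`, `n_fit`,
#'   `n_excluded`.
#' @export
fit_class_model <- function(doubles, scheme = c("intermediate5", "broad3"),
                            locus_aware = TRUE) {
  scheme <- match.arg(scheme)
  c1 <- doubles$class1; c2 <- doubles$class2
  if (scheme == "broad3") { c1 <- broaden_class(c1); c2 <- broaden_class(c2) }
  ok <- !is.na(c1) & !is.na(c2) & is.finite(doubles$mu)
  keys <- class_key(doubles$locus1[ok], c1[ok], doubles$locus2[ok], c2[ok],
                    locus_aware = locus_aware)
  pars <- tapply(doubles$mu[ok], keys, mean)
  structure(list(parameters = pars,
                 n_parameters = length(pars),
                 scheme = scheme, locus_aware = locus_aware,
                 grand_mean = mean(doubles$mu[ok]),
                 n_fit = sum(ok), n_excluded = sum(!ok)),
            class = "class_model")
}

#' @export
coef.class_model <- function(object, ...) object$parameters

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("expression-class growth model (%s, locus-%s): %d parameters from %d doubles\n",
              x$scheme, if (x$locus_aware) "aware" else "blinded",
              x$n_parameters, x$n_fit))
  print(round(x$parameters, 4))
  invisible(x)
}

#' Predict double-mutant growth from a class model
#'
#' @param object a `class_model`.
#' @param newdata data frame with the same columns as in
#'   [fit_class_model()].
#' @param ... unused.
#' @return data frame `key`, `mu_expected`, `covered` (FALSE where the key
#'   was unseen in training and the grand mean was used).
#' @export
predict.class_model <- function(object, newdata, ...) {
  c1 <- newdata$class1; c2 <- newdata$class2
  if (object$scheme == "broad3") { c1 <- broaden_class(c1); c2 <- broaden_class(c2) }
  keys <- class_key(newdata$locus1, c1, newdata$locus2, c2,
                    locus_aware = object$locus_aware)
  mu <- unname(object$parameters[keys])
  covered <- !is.na(mu)
  mu[!covered] <- object$grand_mean
  data.frame(key = keys, mu_expected = mu, covered = covered,
             stringsAsFactors = FALSE)
}

#' Score predictions by explained growth-rate variance
#'
#' `1 - SSR/SST` with SST about the grand mean of the observed
#' within-genotype mean growth rates, overall and per locus pair.
#'
#' @param predicted numeric predictions (or a data frame with
#'   `mu_expected`).
#' @param observed observed growth rates.
#' @param pair optional factor of locus pairs for the per-pair breakdown.
#' @param model name recorded in the report.
#' @return data frame of class `variance_report`: one `overall` row plus
#'   one per locus pair, columns `scope`, `variance_explained`, `n`.
#' @export
predict_and_score <- function(predicted, observed, pair = NULL, model = "model") {
  if (is.data.frame(predicted)) predicted <- predicted$mu_expected
  ok <- is.finite(predicted) & is.finite(observed)
  if (!any(ok)) stopf("predict_and_score: no finite prediction/observation pairs")
  ve <- function(p, o) {
    sst <- sum((o - mean(o))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((o - p)^2) / sst
  }
  out <- data.frame(model = model, scope = "overall",
                    variance_explained = ve(predicted[ok], observed[ok]),
                    n = sum(ok), stringsAsFactors = FALSE)
  if (!is.null(pair)) {
    for (pp in sort(unique(pair[ok]))) {
      sel <- ok & pair == pp
      out <- rbind(out, data.frame(model = model, scope = as.character(pp),
                                   variance_explained = ve(predicted[sel], observed[sel]),
                                   n = sum(sel), stringsAsFactors = FALSE))
    }
  }
  class(out) <- c("variance_report", class(out))
  out
}

#' Downsampled cross-validation of the class-mean model
#'
#' Per iteration, `k_alleles_per_class` alleles are sampled from every
#' (locus, class) group of single mutants, the class model is fitted on the
#' double mutants involving only sampled alleles, and the held-out doubles
#' are scored.
#'
#' @param doubles as in [fit_class_model()], plus columns `allele1`,
#'   `allele2`.
#' @param singles data frame of single mutants: `allele_id`, `locus`,
#'   `class`.
#' @param k_alleles_per_class integer >= 1.
#' @param iterations number of resampling iterations.
#' @param seed integer seed.
#' @inheritParams fit_class_model
#' @return list of class `cv_result`: `variance_explained` (per iteration),
#'   `median`, `iqr`, `k`, `iterations`.
#' @export
downsample_cv <- function(doubles, singles, k_alleles_per_class = 1L,
                          iterations = 1000L, seed = 1L,
                          scheme = c("intermediate5", "broad3"),
                          locus_aware = TRUE) {
  scheme <- match.arg(scheme)
  grp <- split(singles$allele_id, paste(singles$locus, singles$class))
  short <- names(grp)[vapply(grp, length, 1L) < k_alleles_per_class]
  if (length(short)) {
    stopf("downsample_cv: class group(s) with fewer than %d alleles: %s",
          k_alleles_per_class, paste(short, collapse = ", "))
  }
  if (k_alleles_per_class >= max(vapply(grp, length, 1L))) {
    # no holdout possible: defined as the full-fit variance explained
    fit <- fit_class_model(doubles, scheme, locus_aware)
    ve <- predict_and_score(predict(fit, doubles), doubles$mu)$variance_explained[1]
    return(structure(list(variance_explained = ve, median = ve,
                          iqr = c(ve, ve), k = k_alleles_per_class,
                          iterations = 0L), class = "cv_result"))
  }
  ves <- with_seed(sub_seed(seed, "cv"), {
    vapply(seq_len(iterations), function(it) {
      picked <- unlist(lapply(grp, function(a) {
        if (length(a) == 1) a else sample(a, k_alleles_per_class)
      }), use.names = FALSE)
      train <- doubles$allele1 %in% picked & doubles$allele2 %in% picked
      if (!any(train) || all(train)) return(NA_real_)
      fit <- fit_class_model(doubles[train, ], scheme, locus_aware)
      pred <- predict(fit, doubles[!train, ])
      predict_and_score(pred, doubles$mu[!train])$variance_explained[1]
    }, numeric(1))
  })
  structure(list(variance_explained = ves,
                 median = stats::median(ves, na.rm = TRUE),
                 iqr = unname(stats::quantile(ves, c(0.25, 0.75), na.rm = TRUE)),
                 k = k_alleles_per_class, iterations = iterations),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("downsampled CV (k = %d, %d iterations): median VE %.3f (IQR %.3f-%.3f)\n",
              x$k, x$iterations, x$median, x$iqr[1], x$iqr[2]))
  invisible(x)
}

#' Combinatorial accounting of double-mutant class combinations
#'
#' Enumerates the class triples over (GAL3, GAL80, GAL4) reachable in a
#' pairwise design (the unmutated locus carries the Inducible class) and
#' counts: `possible` = the product of per-locus class-set sizes,
#' `excluded` = triples with an Uninducible GAL3 class and non-Inducible
#' classes at both other loci (triple-mutant classes never constructed),
#' `realizable` = their difference, and `blinded` = the number of distinct
#' unordered single-mutant class pairs among the realizable double-mutant
#' keys.
#'
#' @param scheme `"intermediate5"` or `"broad3"`, or a named list of
#'   per-locus class sets.
#' @return list `possible`, `excluded`, `realizable`, `blinded`,
#'   `realizable_keys`.
#' @export
design_accounting <- function(scheme = c("intermediate5", "broad3")) {
  if (is.character(scheme)) {
    scheme <- match.arg(scheme)
    sets <- lapply(GALR_LOCI, admissible_classes)
    names(sets) <- GALR_LOCI
    if (scheme == "broad3") sets <- lapply(sets, function(s) unique(broaden_class(s)))
  } else {
    sets <- scheme
    if (!all(GALR_LOCI %in% names(sets))) stopf("class sets must name all three loci")
  }
  if (any(vapply(sets, length, 1L) == 0)) stopf("empty class set")
  g <- expand.grid(GAL3 = sets$GAL3, GAL80 = sets$GAL80, GAL4 = sets$GAL4,
                   stringsAsFactors = FALSE)
  excluded <- g$GAL3 == "Uninducible" & g$GAL80 != "Inducible" & g$GAL4 != "Inducible"
  keep <- g[!excluded, ]
  keys <- paste(keep$GAL3, keep$GAL80, keep$GAL4, sep = "/")
  # blinded keys: every realizable triple read as each admissible double
  # mutant (the WT locus is one of the Inducible-classed loci)
  blinded <- unique(unlist(lapply(seq_len(nrow(keep)), function(i) {
    tri <- unlist(keep[i, GALR_LOCI])
    wt <- which(tri == "Inducible")
    if (!length(wt)) return(character())
    vapply(wt, function(w) paste(sort(tri[-w]), collapse = "+"), character(1))
  })))
  list(possible = nrow(g), excluded = sum(excluded),
       realizable = nrow(keep), blinded = length(blinded),
       realizable_keys = sort(keys))
}

#' Goodness-of-fit test for class-frequency enrichment
#'
#' Generic chi-squared goodness-of-fit of observed double-mutant class
#' counts against expected proportions (uniform when omitted), e.g. to ask
#' whether one outcome class dominates a single-mutant class pairing.
#'
#' @param counts observed counts per outcome class.
#' @param p expected proportions (default uniform).
#' @return `htest` object from [stats::chisq.test()].
#' @export
class_enrichment_test <- function(counts, p = NULL) {
  counts <- counts[counts >= 0]
  if (length(counts) < 2) stopf("need at least two outcome classes")
  if (is.null(p)) p <- rep(1 / length(counts), length(counts))
  stats::chisq.test(counts, p = p)
}

#' Pairwise double-mutant count of an allele design
#' @param counts per-locus allele counts, e.g. `c(GAL3 = 46, GAL80 = 39,
#'   GAL4 = 43)`.
#' @return total cross-locus pairs.
#' @export
pairwise_double_count <- function(counts) {
  stopifnot(length(counts) == 3)
  unname(counts[1] * counts[2] + counts[1] * counts[3] + counts[2] * counts[3])
}
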