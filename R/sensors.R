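# Higher-order sensor dependency: how deleting GAL3 or replacing GAL1 by a
# sensing-deficient galactokinase (GAL1::GALK) changes growth across
# GAL4-GAL80 backgrounds.  Welch t-tests with BH-FDR per contrast family, a
# logistic "leakiness" null for sensorless growth, and per-pair dependency
# verdicts.

SENSOR_ARMS <- c("intact", "dGAL3", "galk", "both")

# per-pair-archetype truth for the synthetic sensor panel: expression class,
# glucose mean expression (pseudo-log; the leakiness axis) and mean growth
# rate for each of the four arms, plus the broad classes of the two single
# mutants.  Patterns mirror the landmark dependency patterns of the study
# system: the WT-like switch (GAL3-dependent), the leaky-repressor switch
# (either sensor suffices), the constitutive-activator case (GAL1 sensing
# deleterious for repression), the rewired super-repressor x constitutive
# double (flipped GAL1/GAL3 dependence), plus constitutive and dead pairs.
sensor_pair_types <- function(cfg = galcomb_config()) {
  ls <- cfg$sensors$logistic
  leak_mu <- function(x) ls$Asym / (1 + exp((ls$xmid - x) / ls$scal))
  list(
    wt_like = list(singles = c("Inducible", "Inducible"),
      arms = data.frame(arm = SENSOR_ARMS,
        class = c("Inducible", "Uninducible", "Inducible", "Uninducible"),
        x_glu = c(0.05, 0.05, 0.05, 0.05),
        mu = c(0.35, 0.05, 0.35, leak_mu(0.05)))),
    leaky80 = list(singles = c("Uninducible", "Inducible"),
      arms = data.frame(arm = SENSOR_ARMS,
        class = c("Leaky", "Leaky", "Leaky", "Leaky"),
        x_glu = c(1.2, 1.2, 1.2, 1.2),
        mu = c(0.33, 0.32, 0.33, leak_mu(1.2)))),
    gal4c = list(singles = c("Inducible", "Constitutive"),
      arms = data.frame(arm = SENSOR_ARMS,
        class = c("Constitutive", "Constitutive", "Leaky", "Uninducible"),
        x_glu = c(2.0, 2.0, 0.8, 0.8),
        mu = c(0.33, 0.33, 0.30, leak_mu(0.8)))),
    flipped = list(singles = c("Uninducible", "Constitutive"),
      arms = data.frame(arm = SENSOR_ARMS,
        class = c("Inducible", "Inducible", "Uninducible", "Uninducible"),
        x_glu = c(0.05, 0.05, 0.05, 0.05),
        mu = c(0.32, 0.31, 0.06, leak_mu(0.05)))),
    constitutive = list(singles = c("Constitutive", "Inducible"),
      arms = data.frame(arm = SENSOR_ARMS,
        class = c("Constitutive", "Constitutive", "Constitutive", "Constitutive"),
        x_glu = c(2.0, 2.0, 2.0, 2.0),
        mu = c(0.33, 0.33, 0.33, leak_mu(2.0)))),
    dead = list(singles = c("Uninducible", "Uninducible"),
      arms = data.frame(arm = SENSOR_ARMS,
        class = c("Uninducible", "Uninducible", "Uninducible", "Uninducible"),
        x_glu = c(0.05, 0.05, 0.05, 0.05),
        mu = c(0.05, 0.05, 0.05, leak_mu(0.05))))
  )
}

#' Simulate the four-arm sensor panel
#'
#' Generates replicate growth rates for GAL4-GAL80 pairs across the four
#' sensor backgrounds (intact, delta-GAL3, GAL1::GALK, and the double).
#' The sensorless (double) arm grows according to the logistic leakiness
#' null; the other arms follow the pair archetype.  GALK arms alternate
#' between the two heterologous galactokinase sources, whose maximal growth
#' differs slightly.
#'
#' @param n_per_type pairs simulated per archetype.
#' @param N replicates per pair x arm.
#' @param seed integer seed.
#' @param config a [galcomb_config()] list.
#' @return list with `records` (one row per pair x arm x replicate:
#'   `pair_id`, `type`, `arm`, `galk_source`, `class`, `x_glu`, `mu`,
#'   `replicate`) and `pairs` (per-pair metadata incl. the single-mutant
#'   broad classes and the true arm means).
#' @export
simulate_sensor_panel <- function(n_per_type = 3L, N = 8L, seed = 1L,
                                  config = galcomb_config()) {
  types <- sensor_pair_types(config)
  noise <- config$sensors$logistic$noise_sd
  rec <- list(); pairs <- list()
  for (ty in names(types)) {
    for (j in seq_len(n_per_type)) {
      pid <- sprintf("%s.%d", ty, j)
      galk_source <- if (j %% 2 == 0) "calbicans" else "ecoli"
      arms <- types[[ty]]$arms
      # the two GALK orthologs support slightly different maximal growth
      adj <- ifelse(arms$arm %in% c("galk", "both") & galk_source == "calbicans",
                    0.97, 1)
      mu_arm <- arms$mu * adj
      draws <- with_seed(sub_seed(seed, paste0("sensor/", pid)),
                         stats::rnorm(N * nrow(arms), rep(mu_arm, each = N), noise))
      rec[[pid]] <- data.frame(
        pair_id = pid, type = ty,
        arm = rep(arms$arm, each = N),
        galk_source = ifelse(rep(arms$arm, each = N) %in% c("galk", "both"),
                             galk_source, "native"),
        class = rep(arms$class, each = N),
        x_glu = rep(arms$x_glu, each = N),
        replicate = rep(seq_len(N), nrow(arms)),
        mu = pmax(0, draws), stringsAsFactors = FALSE)
      pairs[[pid]] <- data.frame(
        pair_id = pid, type = ty, galk_source = galk_source,
        gal80_class = types[[ty]]$singles[1], gal4_class = types[[ty]]$singles[2],
        t(stats::setNames(mu_arm, paste0("mu_", arms$arm))),
        t(stats::setNames(arms$class, paste0("class_", arms$arm))),
        stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, c(rec, make.row.names = FALSE)),
       pairs = do.call(rbind, c(pairs, make.row.names = FALSE)))
}

#' Contrast each sensor arm against the reference arm
#'
#' Welch two-sample t-test of replicate growth rates per pair, BH-adjusted
#' within each contrast family (one family per non-reference arm).
#' Significance requires both the FDR threshold and a minimum absolute mean
#' effect.
#'
#' @param records long data frame: `pair_id`, `arm`, `mu` (one row per
#'   replicate).
#' @param reference reference arm name.
#' @param alpha FDR level.
#' @param min_effect minimum absolute mean difference (per hour).
#' @return data frame: `pair_id`, `arm`, `effect` (arm minus reference),
#'   `p`, `q`, `significant`, `n_arm`, `n_ref`; single-replicate arms are
#'   excluded (attribute `excluded`).
#' @export
contrast_backgrounds <- function(records, reference = "intact", alpha = 0.05,
                                 min_effect = 0.03) {
  arms <- setdiff(unique(records$arm), reference)
  out <- list(); excluded <- character()
  for (a in arms) {
    rows <- list()
    for (pid in unique(records$pair_id)) {
      x <- records$mu[records$pair_id == pid & records$arm == a]
      y <- records$mu[records$pair_id == pid & records$arm == reference]
      if (length(x) < 2 || length(y) < 2) {
        if (length(x) > 0) excluded <- c(excluded, paste(pid, a))
        next
      }
      tt <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        list(p.value = if (mean(x) == mean(y)) 1 else 0)
      } else {
        stats::t.test(x, y, var.equal = FALSE)
      }
      rows[[pid]] <- data.frame(pair_id = pid, arm = a,
                                effect = mean(x) - mean(y), p = tt$p.value,
                                n_arm = length(x), n_ref = length(y),
                                stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    fam <- do.call(rbind, c(rows, make.row.names = FALSE))
    fam$q <- stats::p.adjust(fam$p, method = "BH")
    fam$significant <- fam$q < alpha & abs(fam$effect) >= min_effect
    out[[a]] <- fam
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "excluded") <- excluded
  res
}

#' Fit the logistic leakiness null for sensorless growth
#'
#' For backgrounds with both sensors removed, growth from an uninduced
#' state is driven by how leaky the pathway already is in glucose.  Fits
#' the 3-parameter logistic `mu = Asym / (1 + exp((xmid - x) / scal))` of
#' growth rate on mean glucose expression (pseudo-log) by nonlinear least
#' squares with self-starting initialization (`SSlogis`), one fit per GALK
#' ortholog group, with a grid-initialized restart on non-convergence.
#'
#' @param x leakiness values (pseudo-log mean glucose expression).
#' @param mu growth rates (per hour).
#' @param group GALK ortholog per observation (single group if omitted).
#' @param min_points minimum observations per group.
#' @return object of class `leakiness_null`: per-group list with `coef`
#'   (Asym, xmid, scal), `flagged`, `n`; `predict()` dispatches on it.
#' @export
fit_leakiness_null <- function(x, mu, group = NULL, min_points = 6L) {
  if (is.null(group)) group <- rep("all", length(x))
  fits <- list()
  for (g in unique(group)) {
    sel <- group == g
    xi <- x[sel]; yi <- mu[sel]
    fit <- list(coef = c(Asym = NA, xmid = NA, scal = NA), flagged = TRUE,
                n = sum(sel))
    if (sum(sel) >= min_points && stats::sd(yi) > 0) {
      df <- data.frame(x = xi, y = yi)
      m <- tryCatch(stats::nls(y ~ SSlogis(x, Asym, xmid, scal), data = df),
                    error = function(e) NULL)
      if (is.null(m)) {
        # grid-initialized restarts
        for (start in list(c(max(yi), stats::median(xi), 0.3),
                           c(max(yi), mean(range(xi)), 0.1),
                           c(max(yi) * 1.1, stats::quantile(xi, 0.6), 0.5))) {
          m <- tryCatch(stats::nls(y ~ Asym / (1 + exp((xmid - x) / scal)),
                                   data = df,
                                   start = list(Asym = start[1], xmid = start[2],
                                                scal = start[3])),
                        error = function(e) NULL)
          if (!is.null(m)) break
        }
      }
      if (!is.null(m)) {
        rss <- sum(stats::resid(m)^2)
        null_ss <- sum((yi - mean(yi))^2)
        fit <- list(coef = stats::coef(m), flagged = !(rss < null_ss),
                    n = sum(sel))
      }
    }
    fits[[g]] <- fit
  }
  structure(list(fits = fits), class = "leakiness_null")
}

#' @export
predict.leakiness_null <- function(object, x, group = NULL, ...) {
  if (is.null(group)) group <- rep(names(object$fits)[1], length(x))
  vapply(seq_along(x), function(i) {
    f <- object$fits[[group[i]]]
    if (is.null(f) || f$flagged) return(NA_real_)
    unname(f$coef["Asym"] / (1 + exp((f$coef["xmid"] - x[i]) / f$coef["scal"])))
  }, numeric(1))
}

#' @export
print.leakiness_null <- function(x, ...) {
  for (g in names(x$fits)) {
    f <- x$fits[[g]]
    cat(sprintf("%s: Asym %.3f, xmid %.2f, scal %.2f (n = %d%s)\n", g,
                f$coef[1], f$coef[2], f$coef[3], f$n,
                if (f$flagged) ", flagged" else ""))
  }
  invisible(x)
}

#' Test growth above the leakiness null
#'
#' One-sample, one-tailed (greater) t-test of each pair's replicate growth
#' rates against the null prediction at its glucose leakiness, BH-adjusted
#' across pairs.
#'
#' @param records long data frame: `pair_id`, `mu` (replicates), `x_glu`,
#'   and `galk_source` matching the null's groups.
#' @param null a `leakiness_null`.
#' @param alpha FDR level.
#' @return data frame: `pair_id`, `mean_mu`, `expected`, `p`, `q`,
#'   `significant`.
#' @export
test_above_null <- function(records, null, alpha = 0.05) {
  pids <- unique(records$pair_id)
  rows <- list()
  for (pid in pids) {
    sel <- records$pair_id == pid
    x <- unique(records$x_glu[sel])[1]
    g <- unique(records$galk_source[sel])[1]
    if (is.na(x)) next
    pred <- predict(null, x, group = g)
    mu <- records$mu[sel]
    if (is.na(pred) || length(mu) < 2) next
    se <- stats::sd(mu) / sqrt(length(mu))
    p <- if (se == 0) {
      if (mean(mu) > pred) 0 else 1
    } else {
      stats::pt((mean(mu) - pred) / se, df = length(mu) - 1, lower.tail = FALSE)
    }
    rows[[pid]] <- data.frame(pair_id = pid, mean_mu = mean(mu), expected = pred,
                              p = p, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(pair_id = character(), mean_mu = numeric(),
                      expected = numeric(), p = numeric(), q = numeric(),
                      significant = logical()))
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  out
}

#' Call sensor dependencies and harmonious combinations per pair
#'
#' Per-sensor verdicts against the intact arm:
#' \itemize{
#'   \item essential — significant growth loss, the sensorless arm falls
#'     below the growth floor (background + margin) while the intact arm
#'     grows;
#'   \item contributing — significant loss but the arm still grows;
#'   \item deleterious — significant growth gain, or the arm reverts a
#'     Constitutive intact class to Inducible/Leaky (sensing was causing
#'     glucose expression);
#'   \item dispensable — no significant change;
#'   \item indeterminate — the arm was not measured.
#' }
#' A pair is harmonious when both single mutants are non-Inducible under
#' the broad scheme, the double is Inducible or Leaky, and its galactose
#' growth reaches `harmonious_frac` of the wild-type rate.
#'
#' @param contrasts data frame from [contrast_backgrounds()].
#' @param pairs per-pair table with `pair_id`, `gal80_class`, `gal4_class`,
#'   arm means `mu_intact`, `mu_dGAL3`, `mu_galk`, and intact/arm classes in
#'   `class_intact`, `class_dGAL3`, `class_galk` (missing class columns are
#'   tolerated).
#' @param wt_mu wild-type galactose growth rate (per hour).
#' @param background background growth rate.
#' @param config a [galcomb_config()] list.
#' @return data frame (the per-pair "snowflake" table): `pair_id`,
#'   `gal3_verdict`, `gal1_verdict`, `harmonious`, plus the inputs carried
#'   through.
#' @export
call_dependencies <- function(contrasts, pairs, wt_mu, background = 0.05,
                              config = galcomb_config()) {
  sn <- config$sensors
  floor <- background + sn$growth_floor_margin
  verdict <- function(pid, arm) {
    row <- contrasts[contrasts$pair_id == pid & contrasts$arm == arm, ]
    pr <- pairs[pairs$pair_id == pid, ]
    mu_arm <- pr[[paste0("mu_", arm)]]
    if (nrow(row) == 0 || is.null(mu_arm) || is.na(mu_arm)) return("indeterminate")
    cls_int <- pr[["class_intact"]]
    cls_arm <- pr[[paste0("class_", arm)]]
    reverts <- !is.null(cls_int) && !is.null(cls_arm) && !is.na(cls_int) &&
               !is.na(cls_arm) && cls_int == "Constitutive" &&
               cls_arm %in% c("Inducible", "Leaky")
    if (row$significant && row$effect > 0) return("deleterious")
    if (reverts) return("deleterious")
    if (row$significant && row$effect < 0) {
      if (mu_arm < floor && pr$mu_intact >= floor) return("essential")
      return("contributing")
    }
    "dispensable"
  }
  out <- pairs
  out$gal3_verdict <- vapply(pairs$pair_id, verdict, character(1), arm = "dGAL3")
  out$gal1_verdict <- vapply(pairs$pair_id, verdict, character(1), arm = "galk")
  singles_nonind <- broaden_class(pairs$gal80_class) != "Inducible" &
                    broaden_class(pairs$gal4_class) != "Inducible"
  dbl_cls <- if ("class_intact" %in% names(pairs)) pairs$class_intact else NA
  out$harmonious <- singles_nonind &
    !is.na(dbl_cls) & dbl_cls %in% c("Inducible", "Leaky") &
    pairs$mu_intact >= sn$harmonious_frac * wt_mu
  rownames(out) <- NULL
  out
}
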