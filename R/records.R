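# Aggregation of per-sample summaries into per-genotype records: paired
# glucose/galactose expression summaries, replicate-mean density vectors
# and Malthusian growth rates with replicate statistics.

#' Simulate and summarize every sample of a design
#'
#' Streams through the sample layout (non-dropout genotype x condition x
#' replicate), simulating each event table and reducing it immediately to a
#' sample summary, so full-scale designs never hold raw events in memory.
#' Autofluorescent control samples are simulated first and set the ON
#' cutoff.
#'
#' @param design from [generate_design()].
#' @param truth from [truth_table()].
#' @param seed integer seed.
#' @param n_events events per sample.
#' @param n_controls autofluorescent control samples.
#' @param config a [galcomb_config()] list.
#' @return list: `samples` (per-sample summary data frame), `dens`
#'   (samples x bins density matrix), `on_cutoff`, `layout`.
#' @export
simulate_summaries <- function(design, truth, seed = 1L, n_events = NULL,
                               n_controls = 8L, config = galcomb_config()) {
  n_events <- n_events %||% config$events$n_events
  keep <- design[!design$dropout, , drop = FALSE]
  layout <- expand.grid(replicate = seq_len(config$design$replicates),
                        condition = c("glucose", "galactose"),
                        genotype_id = keep$genotype_id,
                        stringsAsFactors = FALSE)[, c(3, 2, 1)]
  layout$sample_id <- sprintf("%s.%s.r%d", layout$genotype_id,
                              substr(layout$condition, 1, 3), layout$replicate)

  ctrl <- lapply(seq_len(n_controls), function(i) {
    ev <- simulate_control_events(n_events, seed = sub_seed(seed, paste0("ctrl/", i)),
                                  config = config)
    g <- config$gating
    gate_events(ev, g$rect_quantile, g$centroid_exclusion, g$grid, g$min_events)
  })
  cutoff <- on_cutoff_from_controls(ctrl, config$on_cutoff$quantile)

  dens_truth <- simulate_growth(truth, config = config)
  rownames(dens_truth) <- truth$genotype_id
  cv <- config$events$density_rep_cv
  edges <- bin_edges(config$bins$n, config$bins$range)
  n_s <- nrow(layout)
  dens_mat <- matrix(NA_real_, n_s, config$bins$n)
  cols <- list(n_gated = integer(n_s), fracON = numeric(n_s),
               mean_yfp = numeric(n_s), mean_raw = numeric(n_s),
               density = numeric(n_s), censored = logical(n_s),
               sampling_rate_ul_per_s = numeric(n_s))
  rep_jit <- with_seed(sub_seed(seed, "repjitter"),
                       exp(stats::rnorm(n_s, 0, cv)))
  for (i in seq_len(n_s)) {
    gid <- layout$genotype_id[i]
    cond <- layout$condition[i]
    d_true <- dens_truth[gid, if (cond == "glucose") "density_glu" else "density_gal"]
    d_true <- d_true * rep_jit[i]
    ev <- simulate_events(gid, cond, truth, n_events = n_events,
                          seed = sub_seed(seed, layout$sample_id[i]),
                          density = d_true, config = config)
    sm <- process_sample(ev, on_cutoff = cutoff, config = config)
    sm$sampling_rate_ul_per_s <- attr(ev, "sampling_rate")
    for (nm in names(cols)) cols[[nm]][i] <- sm[[nm]]
    dens_mat[i, ] <- attr(sm, "density_vector")
  }
  samples <- cbind(layout, as.data.frame(cols))
  list(samples = samples, dens = dens_mat, on_cutoff = cutoff, layout = layout)
}

#' Summarize event tables read from disk
#'
#' File-based counterpart of [simulate_summaries()] for the delimited
#' event-table dialect written by [write_event_table()].
#'
#' @param layout data frame with `sample_id`, `genotype_id`, `condition`,
#'   `replicate`, `sampling_rate_ul_per_s`, `censored`, and `file` (path to
#'   the event table).
#' @param on_cutoff pseudo-log ON threshold (e.g. from controls).
#' @param config a [galcomb_config()] list.
#' @return as [simulate_summaries()].
#' @export
preprocess_samples <- function(layout, on_cutoff, config = galcomb_config()) {
  n_s <- nrow(layout)
  dens_mat <- matrix(NA_real_, n_s, config$bins$n)
  rows <- vector("list", n_s)
  for (i in seq_len(n_s)) {
    ev <- read_event_table(layout$file[i],
                           sampling_rate = layout$sampling_rate_ul_per_s[i],
                           sample_id = layout$sample_id[i])
    sm <- process_sample(ev, on_cutoff = on_cutoff, config = config)
    dens_mat[i, ] <- attr(sm, "density_vector")
    rows[[i]] <- sm
  }
  samples <- cbind(layout[, c("sample_id", "genotype_id", "condition", "replicate")],
                   do.call(rbind, rows))
  list(samples = samples, dens = dens_mat, on_cutoff = on_cutoff, layout = layout)
}

#' Aggregate per-sample summaries into per-genotype records
#'
#' Pairs each genotype's glucose and galactose samples, averages expression
#' summaries and density vectors over replicates, computes the Malthusian
#' growth rate per replicate pair (`mu = ln(gal density / inoculum) / hours`
#' with the 9/150 inoculum dilution) and its replicate mean, standard error
#' and count, and records the galactose ON-mode (pseudo-log midpoint of the
#' densest above-cutoff bin) used by curation.
#'
#' @param summaries list from [simulate_summaries()] /
#'   [preprocess_samples()].
#' @param on_cutoff pseudo-log ON threshold (defaults to the one in
#'   `summaries`).
#' @param config a [galcomb_config()] list.
#' @return list: `records` (one row per genotype), `dens_glu`, `dens_gal`
#'   (genotype x bin matrices of replicate-mean densities); genotypes
#'   missing a condition are excluded and listed in attribute `excluded`.
#' @export
genotype_records <- function(summaries, on_cutoff = NULL,
                             config = galcomb_config()) {
  on_cutoff <- on_cutoff %||% summaries$on_cutoff
  s <- summaries$samples
  dens <- summaries$dens
  edges <- bin_edges(config$bins$n, config$bins$range)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  gids <- unique(s$genotype_id)
  glu_i <- split(which(s$condition == "glucose"), s$genotype_id[s$condition == "glucose"])
  gal_i <- split(which(s$condition == "galactose"), s$genotype_id[s$condition == "galactose"])
  excluded <- gids[!(gids %in% names(glu_i)) | !(gids %in% names(gal_i))]
  gids <- setdiff(gids, excluded)
  n_g <- length(gids)
  dg <- matrix(NA_real_, n_g, config$bins$n, dimnames = list(gids, NULL))
  dl <- dg
  rec <- data.frame(genotype_id = gids,
                    fracON_glu = NA_real_, fracON_gal = NA_real_,
                    mean_yfp_glu = NA_real_, mean_yfp_gal = NA_real_,
                    mean_raw_glu = NA_real_, mean_raw_gal = NA_real_,
                    density_glu = NA_real_, density_gal = NA_real_,
                    mu = NA_real_, mu_se = NA_real_, generations = NA_real_,
                    N = NA_integer_, on_mode_gal = NA_real_,
                    censored = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(n_g)) {
    gi <- glu_i[[gids[j]]]; ai <- gal_i[[gids[j]]]
    rec$fracON_glu[j] <- mean(s$fracON[gi]); rec$fracON_gal[j] <- mean(s$fracON[ai])
    rec$mean_yfp_glu[j] <- mean(s$mean_yfp[gi]); rec$mean_yfp_gal[j] <- mean(s$mean_yfp[ai])
    rec$mean_raw_glu[j] <- mean(s$mean_raw[gi]); rec$mean_raw_gal[j] <- mean(s$mean_raw[ai])
    rec$density_glu[j] <- mean(s$density[gi]); rec$density_gal[j] <- mean(s$density[ai])
    rec$censored[j] <- any(s$censored[c(gi, ai)])
    dglu <- colMeans(dens[gi, , drop = FALSE])
    dgal <- colMeans(dens[ai, , drop = FALSE])
    dg[j, ] <- dglu; dl[j, ] <- dgal
    on_bins <- which(mids > on_cutoff)
    rec$on_mode_gal[j] <- if (any(dgal[on_bins] > 0)) {
      mids[on_bins[which.max(dgal[on_bins])]]
    } else NA_real_
    # replicate-paired growth rates
    r_glu <- s$replicate[gi]; r_gal <- s$replicate[ai]
    common <- intersect(r_glu, r_gal)
    gr <- growth_rate(s$density[gi[match(common, r_glu)]],
                      s$density[ai[match(common, r_gal)]],
                      dilution = config$growth$dilution,
                      hours = config$growth$hours)
    mu <- gr$mu[is.finite(gr$mu)]
    rec$N[j] <- length(mu)
    if (length(mu)) {
      rec$mu[j] <- mean(mu)
      rec$mu_se[j] <- if (length(mu) > 1) stats::sd(mu) / sqrt(length(mu)) else NA_real_
      rec$generations[j] <- mean(gr$generations[is.finite(gr$generations)])
    }
  }
  out <- list(records = rec, dens_glu = dg, dens_gal = dl)
  attr(out, "excluded") <- excluded
  out
}
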