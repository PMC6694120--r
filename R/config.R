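#' Default pipeline configuration
#'
#' One nested list holds every tunable of the pipeline: the synthetic-data
#' generator (allele class counts and parameters, growth-model coefficients,
#' event simulation), cytometry preprocessing (gating, saturation ceiling,
#' binning, ON cutoff), classification (minPts grid, curation thresholds),
#' the epistasis models and the sensor-dependency tests.  Values not taken
#' from the study design are the package's declared defaults; see the
#' methods vignette for the rationale behind each.
#'
#' @param seed master seed; every randomized operation derives a named
#'   substream from it via [sub_seed()].
#' @return a list of class `galcomb_config`.
#' @export
galcomb_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    alleles = list(
      # per-locus allele counts by expression class; totals 46/39/43
      counts = list(
        GAL3  = c(Inducible = 26, Uninducible = 20),
        GAL80 = c(Inducible = 12, Constitutive = 9, Uninducible = 10, Leaky = 8),
        GAL4  = c(Inducible = 18, Constitutive = 10, Uninducible = 12, WeakExpression = 3)
      ),
      # class -> distribution of (fracON glu, fracON gal, ON mean/sd on the
      # pseudo-log scale, per condition); ranges are uniform draws per allele
      class_params = list(
        Inducible      = list(fglu = c(0.000, 0.020), fgal = c(0.95, 1.00),
                              mean_glu = 2.0, mean_gal = 2.0, sd = 0.25),
        Constitutive   = list(fglu = c(0.900, 1.000), fgal = c(0.90, 1.00),
                              mean_glu = 2.0, mean_gal = 2.0, sd = 0.25),
        Uninducible    = list(fglu = c(0.000, 0.010), fgal = c(0.00, 0.04),
                              mean_glu = 2.0, mean_gal = 2.0, sd = 0.25),
        Leaky          = list(fglu = c(0.050, 0.300), fgal = c(0.90, 1.00),
                              mean_glu = 1.2, mean_gal = 2.0, sd = 0.25),
        WeakExpression = list(fglu = c(0.000, 0.020), fgal = c(0.85, 1.00),
                              mean_glu = 1.0, mean_gal = 1.0, sd = 0.20)
      ),
      mean_jitter_sd = 0.04   # per-allele jitter of the ON location
    ),
    design = list(
      dropout = 0.02,          # mirrors "98% of the possible pairwise genotypes"
      replicates = 2L          # median N = 2 in the study
    ),
    growth = list(
      beta0 = 0.05,            # per-hour intercept = background rate
      beta_gal = 0.30,         # effect of fraction ON in galactose
      beta_glu = 0.02,         # head-start effect of fraction ON in glucose
      noise_sd = 0.01,         # genotype-level growth noise, per hour
      background = 0.05,       # growth without any functional GAL regulator
      hours = 12,              # galactose growth window
      dilution = 9 / 150       # glucose -> galactose inoculum dilution factor
    ),
    events = list(
      n_events = 5000L,
      autofluor_mean = 50,     # raw A.U. location of the OFF component
      autofluor_sd = 200,
      fsc_meanlog = 10, fsc_sdlog = 0.35,
      ssc_meanlog = 9.5, ssc_sdlog = 0.35,
      fsc_ssc_cor = 0.6,
      pe_slope = 1.1,          # log(FITC) = pe_slope * log(PE) + pe_intercept
      pe_intercept = 0.2,
      pe_noise_sd = 0.10,
      saturation_ceiling = 2^18 - 1,
      glu_density = 2000,      # cells/ul of a saturated glucose culture
      density_rep_cv = 0.02,   # replicate-to-replicate density variation
      rate_high = 0.5,         # ul/s sampling for dense cultures
      rate_low = 2.0,          # ul/s sampling for sparse cultures
      density_rate_cut = 1000  # cells/ul below which the low-density rate is used
    ),
    gating = list(
      rect_quantile = 0.95,
      centroid_exclusion = 0.40,
      grid = 64L,              # 2-D histogram used for the density centroid
      min_events = 100L        # fewer gated events => sample flagged censored
    ),
    bins = list(n = 60L, range = c(-0.5, 3.5)),   # pseudo-log histogram grid
    on_cutoff = list(
      quantile = 0.999,        # of pooled autofluorescent controls
      default = 0.25           # pseudo-log fallback when no controls present
    ),
    classify = list(
      minPts_grid = c(5L, 10L, 15L, 25L),
      parsimony_tol = 0.005,   # "within 0.5 percentage points" tie-break
      induction_hi = 3,        # raw-mean gal/glu ratio: Constitutive -> Inducible/Leaky
      induction_lo = 1.5,      # Inducible -> Uninducible below this
      high_mode = 1.0,         # pseudo-log ON-mode for the >40% rescue rule
      fracon_rescue = 0.40,
      leaky_fglu_max = 0.40,   # fracON glu below this (and > 0) => Leaky not Constitutive
      archetype_ceiling = Inf, # distance ceiling for cluster -> archetype mapping
      rescue_minPts = 5L
    ),
    epistasis = list(
      se_mode = "delta",       # "delta", "as_printed" or "typo_fixed"
      cv_iterations = 1000L,
      cv_fast_iterations = 200L
    ),
    sensors = list(
      alpha = 0.05,
      min_effect = 0.03,       # per hour
      growth_floor_margin = 0.02,
      harmonious_frac = 0.75,  # galactose mu >= this fraction of WT mu
      logistic = list(Asym = 0.30, xmid = 1.5, scal = 0.30, noise_sd = 0.01)
    ),
    pipeline = list(
      store_events = FALSE,
      input_mode = "synthetic",
      stages = c("simulate", "preprocess", "classify", "predict", "sensors")
    )
  )
  class(cfg) <- "galcomb_config"
  cfg
}

#' Validate a configuration list against the default schema
#'
#' Unknown keys at any level are rejected, so typos in a config file fail
#' loudly instead of being silently ignored.
#'
#' @param cfg a configuration list (e.g. from [read_config()]).
#' @return the validated config, invisibly.
#' @export
validate_config <- function(cfg) {
  ref <- unclass(galcomb_config())
  check <- function(x, r, path) {
    if (!is.list(r)) return(invisible())
    extra <- setdiff(names(x), names(r))
    if (length(extra)) {
      stopf("unknown config key%s under '%s': %s",
            if (length(extra) > 1) "s" else "", path,
            paste(extra, collapse = ", "))
    }
    for (nm in names(x)) {
      if (is.list(r[[nm]]) && !is.null(names(r[[nm]])) &&
          !nm %in% c("counts", "class_params")) {
        check(x[[nm]], r[[nm]], paste0(path, "$", nm))
      }
    }
    invisible()
  }
  check(unclass(cfg), ref, "config")
  invisible(cfg)
}

#' Read a configuration file (JSON), merged over the defaults
#'
#' @param path JSON file with any subset of the keys of [galcomb_config()].
#' @return a `galcomb_config` list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- merge_config(galcomb_config(), user)
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) && !is.null(names(user[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Hash of a configuration, recorded in every pipeline artifact
#' @param cfg a config list.
#' @return an 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 12, list.len = 1e6)),
             collapse = "\n")
  h <- fnv1a32(s)   # may exceed .Machine$integer.max; format in two halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
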