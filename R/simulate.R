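rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(rpois(n, mu))
  rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate an nCounter-style count matrix
#'
#' Draws digital counts for every probe and sample under the model described
#' in [simulation_truth()]: endogenous probes are negative-binomial around a
#' log-normal baseline, scaled by the planted group fold change, the probe's
#' batch shift, and per-sample library-size and lane-efficiency factors;
#' housekeeping probes track library size with low dispersion; positive
#' spike-ins are proportional to their nominal concentration (lane effect
#' only); negative spike-ins are Poisson background.
#'
#' @param panel panel design from [make_panel()].
#' @param sheet sample sheet (see [make_sample_sheet()]).
#' @param truth a `sim_truth`; all randomness flows from `truth$seed`.
#' @return an [ncounter_set()].
#' @export
simulate_counts <- function(panel, sheet, truth) {
  sheet <- validate_sample_sheet(sheet)
  n_s <- nrow(sheet)
  endo <- panel$probe_id[panel$class == "Endogenous"]
  hk <- panel$probe_id[panel$class == "Housekeeping"]
  pos <- panel$probe_id[panel$class == "Positive"]
  neg <- panel$probe_id[panel$class == "Negative"]

  libsize <- with_substream(truth$seed, "libsize",
                            rlnorm(n_s, 0, truth$libsize_sdlog))
  lane <- with_substream(truth$seed, "lane", rlnorm(n_s, 0, truth$lane_sdlog))

  # expected endogenous counts: baseline x group FC x batch shift x sample scale
  mu <- matrix(truth$baseline_mean[endo], nrow = length(endo), ncol = n_s,
               dimnames = list(endo, sheet$sample_id))
  if (nrow(truth$planted_dems)) {
    idx <- match(truth$planted_dems$probe_id, endo)
    mu[idx, sheet$group == "Early"] <-
      mu[idx, sheet$group == "Early", drop = FALSE] * 2^truth$planted_dems$lfc_early
    mu[idx, sheet$group == "Advanced"] <-
      mu[idx, sheet$group == "Advanced", drop = FALSE] * 2^truth$planted_dems$lfc_advanced
  }
  if (nrow(truth$batch_shifts)) {
    for (b in unique(truth$batch_shifts$batch)) {
      sh <- truth$batch_shifts[truth$batch_shifts$batch == b, ]
      in_b <- sheet$batch == b
      if (any(in_b)) {
        mu[match(sh$probe_id, endo), in_b] <-
          mu[match(sh$probe_id, endo), in_b, drop = FALSE] * 2^sh$log2_shift
      }
    }
  }
  mu <- sweep(mu, 2, libsize * lane, `*`)
  counts_endo <- with_substream(truth$seed, "counts_endo", {
    matrix(rnbinom_mu(length(mu), mu, truth$dispersion), nrow = nrow(mu),
           dimnames = dimnames(mu))
  })

  mu_hk <- outer(truth$hk_mean[hk], libsize * lane)
  counts_hk <- with_substream(truth$seed, "counts_hk", {
    matrix(rnbinom_mu(length(mu_hk), mu_hk, truth$hk_dispersion),
           nrow = length(hk), dimnames = list(hk, sheet$sample_id))
  })

  conc <- panel$concentration[match(pos, panel$probe_id)]
  mu_pos <- outer(truth$pos_scale * conc, lane)
  counts_pos <- with_substream(truth$seed, "counts_pos", {
    matrix(rnbinom_mu(length(mu_pos), mu_pos, 0.01),
           nrow = length(pos), dimnames = list(pos, sheet$sample_id))
  })

  counts_neg <- with_substream(truth$seed, "counts_neg", {
    matrix(rpois(length(neg) * n_s, truth$neg_mean),
           nrow = length(neg), dimnames = list(neg, sheet$sample_id))
  })

  counts <- rbind(counts_endo, counts_hk, counts_pos, counts_neg)
  counts <- counts[panel$probe_id, , drop = FALSE]
  ncounter_set(counts, panel)
}

#' Plant monotone clinical correlations into simulated counts
#'
#' For each planted effect, expected counts of the probe shift monotonically
#' across the coded clinical variable (tumor grade 1-3 or lymph-node status
#' 1-2) in the planted direction: counts are multiplied by
#' `2^(sign * magnitude * (code - mean(code)))` over tumor samples. Probes
#' without a planted effect are untouched; a cohort with no planted effects
#' is returned unchanged.
#'
#' @param x an [ncounter_set()] of simulated counts.
#' @param sheet sample sheet with `grade_code`/`ln_code` for tumor samples.
#' @param truth a `sim_truth` carrying `clinical_effects`.
#' @return an [ncounter_set()] with shifted counts.
#' @export
plant_clinical_correlations <- function(x, sheet, truth) {
  eff <- truth$clinical_effects
  if (!nrow(eff)) return(x)
  sheet <- validate_sample_sheet(sheet)
  endo <- probes_of_class(x, "Endogenous")
  if (!all(eff$probe_id %in% endo)) {
    abort("clinical effects may only target endogenous probes.",
          class = "mirstage_schema_error")
  }
  tumor <- sheet$group != "GSD"
  if (any(is.na(sheet$grade_code[tumor])) || any(is.na(sheet$ln_code[tumor]))) {
    abort("tumor samples must carry grade and LN codes to plant clinical effects.",
          class = "mirstage_schema_error")
  }
  counts <- x$counts
  for (i in seq_len(nrow(eff))) {
    code <- if (eff$variable[i] == "grade") sheet$grade_code else sheet$ln_code
    code <- code[tumor]
    shift <- 2^(eff$sign[i] * eff$magnitude[i] * (code - mean(code)))
    counts[eff$probe_id[i], sheet$sample_id[tumor]] <-
      round(counts[eff$probe_id[i], sheet$sample_id[tumor]] * shift)
  }
  ncounter_set(counts, x$probes)
}

#' One-call synthetic cohort
#'
#' Convenience wrapper: panel + sample sheet + truth + counts (with clinical
#' effects applied) in one deterministic call.
#'
#' @param n_endogenous endogenous panel size.
#' @param seed master seed.
#' @param planted_dems,clinical_effects passed to [simulation_truth()].
#' @param ... further arguments to [simulation_truth()].
#' @inheritParams make_sample_sheet
#' @return list with `panel`, `sheet`, `truth`, `counts`.
#' @export
simulate_cohort <- function(n_endogenous = 800, seed = 1L,
                            n_gsd = 10, n_early = 14, n_advanced = 17,
                            planted_dems = NULL, clinical_effects = NULL, ...) {
  panel <- make_panel(n_endogenous, seed = seed)
  sheet <- make_sample_sheet(n_gsd, n_early, n_advanced, seed = seed)
  truth <- simulation_truth(panel, planted_dems = planted_dems,
                            clinical_effects = clinical_effects,
                            seed = seed, ...)
  counts <- simulate_counts(panel, sheet, truth)
  counts <- plant_clinical_correlations(counts, sheet, truth)
  list(panel = panel, sheet = sheet, truth = truth, counts = counts)
}
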