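#' Normalization configuration
#'
#' Defaults follow the published pipeline: housekeeping probes qualify when
#' every raw count exceeds 50 and the cross-sample coefficient of variation
#' is below 20%; low-expression filtering keeps probes reaching a count-10
#' equivalent CPM in at least as many samples as the smallest group; the TMM
#' step trims 30% of M-values and 5% of A-values from each tail.
#'
#' @param hk_min_count minimum raw count for a housekeeping probe (every sample).
#' @param hk_max_cv maximum coefficient of variation (sd/mean of raw counts).
#' @param min_cpm_count count-scale expression floor, converted to CPM against
#'   the median library size.
#' @param min_samples number of samples that must reach the floor; `NULL`
#'   means the size of the smallest group.
#' @param logratio_trim,abs_trim two-sided trim fractions for M and A values.
#' @param pseudocount offset used in log-CPM.
#' @return list of class `norm_config`.
#' @export
norm_config <- function(hk_min_count = 50, hk_max_cv = 0.20,
                        min_cpm_count = 10, min_samples = NULL,
                        logratio_trim = 0.3, abs_trim = 0.05,
                        pseudocount = 0.5) {
  stopifnot(hk_min_count > 0, hk_max_cv > 0, min_cpm_count > 0,
            logratio_trim > 0, logratio_trim < 0.5,
            abs_trim > 0, abs_trim < 0.5, pseudocount > 0)
  structure(list(hk_min_count = hk_min_count, hk_max_cv = hk_max_cv,
                 min_cpm_count = min_cpm_count, min_samples = min_samples,
                 logratio_trim = logratio_trim, abs_trim = abs_trim,
                 pseudocount = pseudocount), class = "norm_config")
}

#' Background-correct counts against negative controls
#'
#' Per sample, the background threshold is the mean of the negative-control
#' counts plus two sample standard deviations (n-1 denominator). Endogenous
#' counts are reduced by the threshold, floored at zero, and rounded half-up
#' back to integers; control-class probes are retained unmodified for audit.
#'
#' @param x an [ncounter_set()] with at least 2 negative probes.
#' @return an [ncounter_set()]; per-sample thresholds in `attr(, "background")`.
#' @export
background_correct <- function(x) {
  neg <- x$counts[probes_of_class(x, "Negative"), , drop = FALSE]
  if (nrow(neg) < 2) {
    abort("background correction needs at least 2 negative probes.",
          class = "mirstage_qc_impossible")
  }
  thr <- apply(neg, 2, function(v) mean(v) + 2 * sd(v))
  endo <- probes_of_class(x, "Endogenous")
  counts <- x$counts
  corrected <- sweep(counts[endo, , drop = FALSE], 2, thr, `-`)
  counts[endo, ] <- floor(pmax(corrected, 0) + 0.5)  # round half-up
  if (is.integer(x$counts)) storage.mode(counts) <- "integer"
  out <- ncounter_set(counts, x$probes)
  attr(out, "background") <- setNames(thr, colnames(counts))
  out
}

#' Select qualifying housekeeping probes
#'
#' Keeps housekeeping-class probes whose raw count exceeds `hk_min_count` in
#' every sample and whose coefficient of variation across samples is below
#' `hk_max_cv`. Optionally, endogenous probes can augment the candidate pool.
#'
#' @param x an [ncounter_set()] (raw counts).
#' @param config a [norm_config()].
#' @param augment_endogenous also consider endogenous probes as candidates.
#' @return character vector of selected probe ids.
#' @export
select_housekeeping <- function(x, config = norm_config(),
                                augment_endogenous = FALSE) {
  cand <- probes_of_class(x, "Housekeeping")
  if (!length(cand)) {
    abort("no housekeeping-class probes in panel.", class = "mirstage_norm_impossible")
  }
  if (augment_endogenous) cand <- c(cand, probes_of_class(x, "Endogenous"))
  m <- x$counts[cand, , drop = FALSE]
  min_ok <- apply(m, 1, function(v) all(v > config$hk_min_count))
  cv <- apply(m, 1, function(v) sd(v) / mean(v))
  keep <- cand[min_ok & cv < config$hk_max_cv]
  if (!length(keep)) {
    abort(paste0(
      "no housekeeping probe passes raw count > ", config$hk_min_count,
      " in all samples and CV < ", config$hk_max_cv,
      " (min counts: ", paste(round(apply(m, 1, min)), collapse = ","),
      "; CVs: ", paste(round(cv, 3), collapse = ","), ")."),
      class = "mirstage_norm_impossible")
  }
  keep
}

# factor_s = (cohort arithmetic mean of per-sample geometric means) /
#            (per-sample geometric mean); +1 guards zero counts
scaling_factors <- function(m) {
  gm <- apply(m, 2, function(v) geomean(v + 1))
  mean(gm) / gm
}

#' Positive-control and housekeeping scaling
#'
#' Two sequential per-sample scalings in the nSolver tradition: first against
#' the geometric mean of the positive spike-ins, then against the geometric
#' mean of the selected housekeeping probes (computed on the
#' positive-scaled counts). Each factor is the cohort arithmetic mean of the
#' per-sample geometric means over that sample's geometric mean, applied
#' multiplicatively to endogenous (and housekeeping) counts.
#'
#' @param x an [ncounter_set()].
#' @param hk housekeeping probe ids from [select_housekeeping()].
#' @return an [ncounter_set()] (continuous counts) with a `factors` attribute:
#'   tibble `sample_id`, `pos_factor`, `hk_factor`.
#' @export
control_normalize <- function(x, hk) {
  if (!length(hk)) abort("housekeeping probe list must be non-empty.")
  pos <- probes_of_class(x, "Positive")
  if (!length(pos)) abort("no positive control probes.", class = "mirstage_qc_impossible")
  counts <- x$counts
  scale_rows <- c(probes_of_class(x, "Endogenous"), probes_of_class(x, "Housekeeping"))
  pf <- scaling_factors(counts[pos, , drop = FALSE])
  counts[scale_rows, ] <- sweep(counts[scale_rows, , drop = FALSE], 2, pf, `*`)
  hf <- scaling_factors(counts[hk, , drop = FALSE])
  counts[scale_rows, ] <- sweep(counts[scale_rows, , drop = FALSE], 2, hf, `*`)
  out <- ncounter_set(counts, x$probes, integer_counts = FALSE)
  attr(out, "factors") <- tibble::tibble(
    sample_id = colnames(counts), pos_factor = unname(pf), hk_factor = unname(hf))
  attr(out, "background") <- attr(x, "background")
  out
}

endo_lib_sizes <- function(x) {
  colSums(x$counts[probes_of_class(x, "Endogenous"), , drop = FALSE])
}

#' Filter lowly expressed endogenous probes
#'
#' Keeps an endogenous probe when its CPM reaches
#' `min_cpm_count * 1e6 / median(library size)` in at least `min_samples`
#' samples, where `min_samples` defaults to the size of the smallest group
#' and library sizes are endogenous column sums.
#'
#' @param x an [ncounter_set()].
#' @param sheet sample sheet (groups define `min_samples`).
#' @param config a [norm_config()].
#' @return an [ncounter_set()] with failing endogenous probes removed;
#'   attributes `kept`/`dropped` list the probe ids.
#' @export
filter_low_expression <- function(x, sheet, config = norm_config()) {
  sheet <- validate_sample_sheet(sheet)
  endo <- probes_of_class(x, "Endogenous")
  lib <- endo_lib_sizes(x)
  cpm <- sweep(x$counts[endo, , drop = FALSE], 2, lib, `/`) * 1e6
  cutoff <- config$min_cpm_count * 1e6 / median(lib)
  min_samples <- config$min_samples %||% min(table(sheet$group))
  keep <- rowSums(cpm >= cutoff) >= min_samples
  if (!any(keep)) abort("all endogenous probes filtered out.", class = "mirstage_norm_impossible")
  kept <- endo[keep]
  drop_ids <- endo[!keep]
  rows <- setdiff(rownames(x$counts), drop_ids)
  out <- ncounter_set(x$counts[rows, , drop = FALSE],
                      x$probes[x$probes$probe_id %in% rows, ],
                      integer_counts = FALSE)
  attr(out, "factors") <- attr(x, "factors")
  attr(out, "background") <- attr(x, "background")
  attr(out, "kept") <- kept
  attr(out, "dropped") <- drop_ids
  out
}

tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref,
                            logratio_trim = 0.3, abs_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    abort("sample shares no expressed probes with the TMM reference.",
          class = "mirstage_norm_impossible")
  }
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / lib_obs) / (ref / lib_ref))
  a <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  # asymptotic variance of M (delta method on binomial counts)
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  use <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(use)) return(1)
  f <- sum(m[use] / v[use]) / sum(1 / v[use])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values scaling factors
#'
#' Between-sample normalization for compositional bias. The reference sample
#' is the one whose upper-quartile CPM is closest to the cohort mean
#' upper-quartile. For each sample, the log2 factor is the precision-weighted
#' mean of the log2 count ratios to the reference (M-values), after
#' discarding probes with a zero in either sample, the top and bottom
#' `logratio_trim` of M-values, and the top and bottom `abs_trim` of average
#' log intensities (A-values). Factors are rescaled so their log2 values sum
#' to zero.
#'
#' @param x an [ncounter_set()] of filtered endogenous probes (controls are
#'   ignored), or a plain counts matrix.
#' @param config a [norm_config()].
#' @return named numeric vector of per-sample factors (product 1).
#' @export
tmm_factors <- function(x, config = norm_config()) {
  counts <- if (inherits(x, "ncounter_set")) {
    x$counts[probes_of_class(x, "Endogenous"), , drop = FALSE]
  } else as.matrix(x)
  if (ncol(counts) < 2) abort("TMM needs at least 2 samples.")
  lib <- colSums(counts)
  uq <- vapply(seq_len(ncol(counts)),
               function(j) quantile(counts[, j], 0.75) / lib[j] * 1e6, 0)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                    config$logratio_trim, config$abs_trim)
  }, 0)
  f <- f / 2^(mean(log2(f)))
  setNames(f, colnames(counts))
}

#' Log2 counts per million
#'
#' `log2((count + pseudocount) / (effective library size + 1) * 1e6)` with the
#' effective library size equal to the endogenous column sum times the
#' sample's TMM factor.
#'
#' @param x an [ncounter_set()] (endogenous rows are used).
#' @param factors per-sample TMM factors (1 for the control-only pipeline).
#' @param config a [norm_config()].
#' @return numeric matrix of log2-CPM, endogenous probes x samples.
#' @export
log_cpm <- function(x, factors = NULL, config = norm_config()) {
  endo <- probes_of_class(x, "Endogenous")
  counts <- x$counts[endo, , drop = FALSE]
  lib <- colSums(counts)
  if (is.null(factors)) factors <- setNames(rep(1, ncol(counts)), colnames(counts))
  eff <- lib * factors[colnames(counts)]
  log2(sweep(counts + config$pseudocount, 2, eff + 1, `/`) * 1e6)
}

#' Remove batch effects from log expression
#'
#' Fits, per probe, a least-squares model with the biological groups retained
#' and batch encoded with sum-to-zero contrasts, then subtracts only the
#' fitted batch contribution. Fitted group effects are untouched, so
#' between-group contrasts are preserved; the operation is idempotent.
#' Designs where batch is confounded with group (rank-deficient joint
#' design) are refused.
#'
#' @param log2_expr numeric matrix, probes x samples.
#' @param sheet sample sheet supplying `group` and `batch`.
#' @return corrected matrix of the same shape.
#' @export
batch_correct <- function(log2_expr, sheet) {
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(log2_expr), sheet$sample_id), ]
  if (length(unique(sheet$batch)) < 2) return(log2_expr)
  grp <- factor(sheet$group)
  bat <- factor(sheet$batch)
  g_mat <- model.matrix(~grp)
  b_mat <- model.matrix(~bat, contrasts.arg = list(bat = contr.sum))[, -1, drop = FALSE]
  design <- cbind(g_mat, b_mat)
  if (qr(design)$rank < ncol(design)) {
    abort(paste0("batch is confounded with group (batches: ",
                 paste(levels(bat), collapse = ", "), ")."),
          class = "mirstage_confounded")
  }
  fit <- lm.fit(design, t(log2_expr))
  beta_b <- fit$coefficients[colnames(b_mat), , drop = FALSE]
  log2_expr - t(b_mat %*% beta_b)
}

#' Relative log expression diagnostics
#'
#' RLE value = log2 expression minus the probe's median across samples.
#' The summary reports each sample's median and IQR of RLE values, plus the
#' cohort spread of the per-sample medians — the statistic used to compare
#' normalization pipelines (tighter is better).
#'
#' @param log2_expr matrix or a `mir_norm` object.
#' @return list with `values` (matrix), `per_sample` (tibble `sample_id`,
#'   `median`, `iqr`) and `summary` (tibble `median_of_medians`,
#'   `iqr_of_medians`).
#' @export
rle_stats <- function(log2_expr) {
  if (inherits(log2_expr, "mir_norm")) log2_expr <- log2_expr$log2_expr
  vals <- log2_expr - apply(log2_expr, 1, median)
  med <- apply(vals, 2, median)
  per_sample <- tibble::tibble(sample_id = colnames(vals),
                               median = unname(med),
                               iqr = unname(apply(vals, 2, IQR)))
  list(values = vals, per_sample = per_sample,
       summary = tibble::tibble(median_of_medians = median(med),
                                iqr_of_medians = IQR(med)))
}

#' Run a full normalization pipeline
#'
#' Shared pre-processing (background correction, positive-control scaling,
#' housekeeping scaling, low-expression filtering) followed by either
#' pipeline `P1` (log-CPM then batch correction) or `P2` (TMM factors, then
#' log-CPM against the effective library size, then batch correction).
#'
#' @param x raw [ncounter_set()].
#' @param sheet sample sheet.
#' @param pipeline `"P1"` or `"P2"`.
#' @param config a [norm_config()].
#' @return a [mir_norm()]; `$log2_expr` is the batch-corrected matrix,
#'   `$log2_uncorrected` the log-CPM before batch subtraction (used with a
#'   batch covariate in differential expression).
#' @export
normalize_pipeline <- function(x, sheet, pipeline = c("P2", "P1"),
                               config = norm_config()) {
  pipeline <- match.arg(pipeline)
  sheet <- validate_sample_sheet(sheet)
  hk <- select_housekeeping(x, config)
  bg <- background_correct(x)
  cn <- control_normalize(bg, hk)
  flt <- filter_low_expression(cn, sheet, config)
  tf <- if (pipeline == "P2") tmm_factors(flt, config) else {
    setNames(rep(1, ncol(flt$counts)), colnames(flt$counts))
  }
  lc <- log_cpm(flt, tf, config)
  corrected <- batch_correct(lc, sheet)
  factors <- attr(flt, "factors")
  factors$tmm_factor <- unname(tf[factors$sample_id])
  factors$lib_size <- unname(endo_lib_sizes(flt)[factors$sample_id])
  out <- mir_norm(corrected, factors, pipeline, hk)
  out$log2_uncorrected <- lc
  out$dropped <- attr(flt, "dropped")
  out
}
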