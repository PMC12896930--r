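geomean <- function(x) exp(mean(log(x)))

#' Per-sample quality control from spike-in controls
#'
#' Computes, per sample: the background level (mean of negative-control
#' counts plus two sample standard deviations), the positive-control scaling
#' factor (geometric mean of positive counts divided by the cohort mean of
#' those geometric means — so the factors have geometric mean 1 by
#' construction), and the linearity of the positive titration series (R^2 of
#' log2(count + 1) on log2 nominal concentration). Samples whose scaling
#' factor falls outside `flag_limits` are flagged.
#'
#' @param x an [ncounter_set()] with at least 2 negative and 3 positive probes.
#' @param flag_limits acceptable positive scaling-factor range.
#' @return tibble: `sample_id`, `background`, `pos_scaling_factor`,
#'   `pos_linearity_r2`, `flagged`, `flags`.
#' @export
qc_samples <- function(x, flag_limits = c(0.3, 3)) {
  neg <- x$counts[probes_of_class(x, "Negative"), , drop = FALSE]
  pos_ids <- probes_of_class(x, "Positive")
  pos <- x$counts[pos_ids, , drop = FALSE]
  if (nrow(neg) < 2 || nrow(pos) < 3) {
    abort("QC needs at least 2 negative and 3 positive control probes.",
          class = "mirstage_qc_impossible")
  }
  background <- apply(neg, 2, function(v) mean(v) + 2 * sd(v))
  gm <- apply(pos + 0, 2, function(v) geomean(v + 1))
  sf <- gm / geomean(gm)
  conc <- x$probes$concentration[match(pos_ids, x$probes$probe_id)]
  r2 <- apply(pos, 2, function(v) {
    f <- stats::lm(log2(v + 1) ~ log2(conc))
    summary(f)$r.squared
  })
  flagged <- sf < flag_limits[1] | sf > flag_limits[2]
  tibble::tibble(
    sample_id = colnames(x$counts),
    background = unname(background),
    pos_scaling_factor = unname(sf),
    pos_linearity_r2 = unname(r2),
    flagged = unname(flagged),
    flags = ifelse(flagged, "positive-scaling-outside-limits", "")
  )
}

#' Write a QC report as TSV plus JSON
#' @param qc tibble from [qc_samples()].
#' @param path_tsv,path_json output paths.
#' @export
write_qc <- function(qc, path_tsv, path_json) {
  readr::write_tsv(qc, path_tsv)
  jsonlite::write_json(qc, path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_tsv)
}
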