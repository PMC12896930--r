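#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, elementwise at least `p` and capped at 1.
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (!n) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
}

#' The DEM call predicate
#'
#' A probe is a differentially expressed miRNA in a contrast when its
#' adjusted p-value is strictly below `alpha` and its |log2 fold change| is
#' at least `lfc_cut` (fold change of at least 2 at the default). A probe
#' sitting exactly at `alpha` is not called.
#'
#' @param log2fc,adj_p numeric vectors.
#' @param alpha,lfc_cut thresholds.
#' @return logical vector.
#' @export
dem_call <- function(log2fc, adj_p, alpha = 0.05, lfc_cut = 1) {
  adj_p < alpha & abs(log2fc) >= lfc_cut
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone convex).
trigamma_inverse <- function(y, tol = 1e-8, maxit = 50L) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(maxit)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < tol) break
  }
  x
}

# Method-of-moments fit of a scaled-F prior to residual variances s2 with df
# d each: returns prior df d0 and prior variance s0_2. d0 = Inf when the
# observed spread of log variances is no wider than chi-square sampling noise.
fit_variance_prior <- function(s2, d) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # log-variance spread no wider than chi-square noise: complete shrinkage
    d0 <- Inf
    s0_2 <- mean(s2[ok])
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated differential expression across tumor stages
#'
#' Per-probe least squares of log2 expression on group (reference level GSD,
#' so coefficients are the Early-vs-GSD and Advanced-vs-GSD log2 fold
#' changes), with batch as a covariate by default. Residual variances are
#' shrunk towards a common prior fitted by method of moments on the log
#' variances (inverting the trigamma function by Newton iteration); the
#' moderated t uses the posterior variance and `d0 + d` degrees of freedom
#' (capped at the pooled residual df; `d0 = Inf` is the z-limit). Probes are
#' called significant in a contrast when the Benjamini-Hochberg adjusted p is
#' below `alpha` and |log2FC| is at least `lfc_cut`.
#'
#' @param norm a [mir_norm()] from [normalize_pipeline()], or a plain log2
#'   expression matrix.
#' @param sheet sample sheet with `group` (and `batch` if `include_batch`).
#' @param include_batch adjust for batch in the design.
#' @param use_corrected fit on the batch-subtracted matrix instead of
#'   modelling batch as a covariate (reproduces pipelines that feed corrected
#'   data forward).
#' @param d0_override force the prior df (0 gives the ordinary t-test).
#' @param alpha adjusted-p threshold for the DEM call.
#' @param lfc_cut absolute log2-fold-change threshold (1, i.e. fold change 2).
#' @return object of class `mir_de`; `tidy()` gives the per-probe,
#'   per-contrast table, `glance()` the prior and model summary.
#' @export
fit_moderated <- function(norm, sheet, include_batch = TRUE,
                          use_corrected = FALSE, d0_override = NULL,
                          alpha = 0.05, lfc_cut = 1) {
  y <- if (inherits(norm, "mir_norm")) {
    if (use_corrected || is.null(norm$log2_uncorrected)) norm$log2_expr
    else norm$log2_uncorrected
  } else as.matrix(norm)
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(y), sheet$sample_id), ]
  if (any(table(sheet$group) < 2)) {
    abort("each group needs at least 2 samples.", class = "mirstage_design_error")
  }
  grp <- factor(sheet$group, levels = intersect(c("GSD", "Early", "Advanced"),
                                                unique(sheet$group)))
  design <- if (include_batch && !use_corrected &&
                length(unique(sheet$batch)) > 1) {
    bat <- factor(sheet$batch)
    model.matrix(~ grp + bat, contrasts.arg = list(bat = contr.sum))
  } else {
    model.matrix(~grp)
  }
  if (qr(design)$rank < ncol(design)) {
    abort("design matrix is rank deficient (group confounded with batch).",
          class = "mirstage_confounded")
  }
  fit <- lm.fit(design, t(y))
  d <- nrow(design) - fit$rank
  s2 <- colSums(fit$residuals^2) / d
  xtx_inv <- solve(crossprod(design))

  if (!is.null(d0_override)) {
    d0 <- d0_override
    s0_2 <- if (d0 > 0) fit_variance_prior(s2, d)$s0_2 else 0
  } else {
    prior <- fit_variance_prior(s2, d)
    d0 <- prior$d0
    s0_2 <- prior$s0_2
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else {
    (d0 * s0_2 + d * s2) / (d0 + d)
  }
  df_total <- min(d0 + d, length(s2) * d)

  contrasts <- c(early = "grpEarly", advanced = "grpAdvanced")
  contrasts <- contrasts[contrasts %in% rownames(fit$coefficients)]
  res <- purrr::imap_dfr(contrasts, function(cf, label) {
    b <- fit$coefficients[cf, ]
    se <- sqrt(xtx_inv[cf, cf] * s2_post)
    tt <- ifelse(se == 0, ifelse(b == 0, 0, sign(b) * Inf), b / se)
    p <- 2 * pt(-abs(tt), df = df_total)
    tibble::tibble(
      probe_id = rownames(y), contrast = label,
      log2fc = unname(b), t = unname(tt), p = unname(p),
      adj_p = bh_adjust(unname(p))
    )
  })
  res$significant <- dem_call(res$log2fc, res$adj_p, alpha, lfc_cut)
  res$at_boundary <- abs(abs(res$log2fc) - lfc_cut) < 1e-12 |
    abs(res$adj_p - alpha) < 1e-12
  structure(list(results = res, d0 = d0, s0_2 = s0_2, df_resid = d,
                 df_total = df_total, alpha = alpha, lfc_cut = lfc_cut),
            class = "mir_de")
}

#' @export
print.mir_de <- function(x, ...) {
  n_sig <- table(x$results$contrast[x$results$significant])
  cat("<mir_de> ", length(unique(x$results$probe_id)), " probes; prior df ",
      signif(x$d0, 4), ", prior var ", signif(x$s0_2, 4), "\n", sep = "")
  cat("  significant: ", paste(names(n_sig), n_sig, sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_moderated per-probe, per-contrast results tibble.
#' @param x a `mir_de` object.
#' @param ... unused.
#' @export
tidy.mir_de <- function(x, ...) x$results

#' @describeIn fit_moderated one-row model summary (prior df and variance,
#'   residual df, DEM counts).
#' @export
glance.mir_de <- function(x, ...) {
  tibble::tibble(
    d0 = x$d0, s0_2 = x$s0_2, df_resid = x$df_resid,
    n_probes = length(unique(x$results$probe_id)),
    n_sig_early = sum(x$results$significant & x$results$contrast == "early"),
    n_sig_advanced = sum(x$results$significant & x$results$contrast == "advanced")
  )
}

#' Extract one contrast's calls from a fitted DE object
#' @param de a `mir_de`.
#' @param contrast `"early"` or `"advanced"`.
#' @return tibble `probe_id`, `log2fc`, `adj_p`, `significant`.
#' @export
de_contrast <- function(de, contrast = c("early", "advanced")) {
  contrast <- match.arg(contrast)
  out <- de$results[de$results$contrast == contrast,
                    c("probe_id", "log2fc", "adj_p", "significant")]
  tibble::as_tibble(out)
}

#' Stage-wise Venn partition of DEM calls
#'
#' Splits significant probes into early-only, advanced-only and shared sets
#' and emits a publication-style long table (log2 fold change and adjusted p
#' per contrast, `NA` where a probe is not significant in that contrast).
#'
#' @param de_early tibble with `probe_id`, `log2fc`, `significant` (and
#'   optionally `adj_p`) for the Early-vs-GSD contrast, or a `mir_de` object
#'   (then `de_advanced` is taken from it too).
#' @param de_advanced same for Advanced-vs-GSD.
#' @return object of class `venn_partition`: disjoint probe-id sets
#'   `early_only`, `advanced_only`, `shared`, their counts, `union_size` and
#'   the wide `table`.
#' @export
classify_and_partition <- function(de_early, de_advanced = NULL) {
  if (inherits(de_early, "mir_de")) {
    de <- de_early
    de_early <- de_contrast(de, "early")
    de_advanced <- de_contrast(de, "advanced")
  }
  sig_e <- de_early$probe_id[de_early$significant]
  sig_a <- de_advanced$probe_id[de_advanced$significant]
  shared <- sort(intersect(sig_e, sig_a))
  early_only <- sort(setdiff(sig_e, sig_a))
  advanced_only <- sort(setdiff(sig_a, sig_e))
  all_sig <- c(early_only, advanced_only, shared)
  tab <- tibble::tibble(probe_id = sort(all_sig)) |>
    dplyr::left_join(stats_cols(de_early, "early"), by = "probe_id") |>
    dplyr::left_join(stats_cols(de_advanced, "advanced"), by = "probe_id")
  structure(list(
    early_only = early_only, advanced_only = advanced_only, shared = shared,
    n_early = length(sig_e), n_advanced = length(sig_a),
    n_early_only = length(early_only), n_advanced_only = length(advanced_only),
    n_shared = length(shared), union_size = length(all_sig), table = tab
  ), class = "venn_partition")
}

stats_cols <- function(d, label) {
  d <- d[d$significant, , drop = FALSE]
  out <- tibble::tibble(probe_id = d$probe_id)
  out[[paste0("log2fc_", label)]] <- d$log2fc
  out[[paste0("adj_p_", label)]] <- if ("adj_p" %in% names(d)) d$adj_p else NA_real_
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> early ", x$n_early, " (", x$n_early_only, " only), ",
      "advanced ", x$n_advanced, " (", x$n_advanced_only, " only), shared ",
      x$n_shared, "; union ", x$union_size, "\n", sep = "")
  invisible(x)
}

#' Read a published-style DEM table
#'
#' TSV with columns `mirna`, `log2fc_early`, `adj_p_early`,
#' `log2fc_advanced`, `adj_p_advanced`; empty or `NS` cells mean the probe
#' was not significant in that contrast.
#'
#' @param path TSV path.
#' @return list of two tibbles (`early`, `advanced`) each with `probe_id`,
#'   `log2fc`, `adj_p`, `significant`, ready for [classify_and_partition()].
#' @export
read_dem_table <- function(path) {
  tab <- readr::read_tsv(path, na = c("", "NA", "NS"), show_col_types = FALSE)
  need <- c("mirna", "log2fc_early", "adj_p_early", "log2fc_advanced", "adj_p_advanced")
  if (!all(need %in% names(tab))) {
    abort(paste0("DEM table needs columns: ", paste(need, collapse = ", ")),
          class = "mirstage_format_error")
  }
  one <- function(lfc, p) tibble::tibble(
    probe_id = tab$mirna, log2fc = lfc, adj_p = p, significant = !is.na(lfc))
  list(early = one(tab$log2fc_early, tab$adj_p_early),
       advanced = one(tab$log2fc_advanced, tab$adj_p_advanced))
}

#' Export volcano-plot data
#' @param de a `mir_de`.
#' @return tibble `probe_id`, `contrast`, `log2fc`, `neg_log10_adj_p`,
#'   `significant`.
#' @export
volcano_data <- function(de) {
  dplyr::mutate(tidy(de), neg_log10_adj_p = -log10(.data$adj_p)) |>
    dplyr::select("probe_id", "contrast", "log2fc", "neg_log10_adj_p", "significant")
}
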