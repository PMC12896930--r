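GRADE_CODES <- c(WDAC = 1, MDAC = 2, PDAC = 3)
LN_CODES <- c("LN-" = 1, "LN+" = 2)

#' Numerically code clinicopathological variables
#'
#' Tumor grade: well / moderately / poorly differentiated adenocarcinoma
#' (WDAC, MDAC, PDAC) -> 1, 2, 3. Lymph-node status: negative -> 1,
#' positive -> 2. Already-numeric codes pass through after range checks.
#' Non-tumor (GSD) samples are excluded. A variable that is missing for all
#' tumor samples is dropped with a warning.
#'
#' @param sheet sample sheet; `grade_code`/`ln_code` may be numeric codes or
#'   the string labels above.
#' @return tibble `sample_id`, `grade`, `ln` (tumor samples only; dropped
#'   variables absent).
#' @export
encode_clinical <- function(sheet) {
  sheet <- tibble::as_tibble(sheet)
  tum <- sheet[sheet$group != "GSD", , drop = FALSE]
  code_one <- function(x, map, what, range) {
    if (is.numeric(x)) {
      if (any(!is.na(x) & !x %in% range)) {
        abort(paste0(what, " codes must be in {", paste(range, collapse = ","), "}."),
              class = "mirstage_schema_error")
      }
      return(as.numeric(x))
    }
    known <- is.na(x) | x %in% names(map)
    if (!all(known)) {
      abort(paste0("unknown ", what, " label: ",
                   paste(unique(x[!known]), collapse = ", ")),
            class = "mirstage_schema_error")
    }
    unname(map[x])
  }
  out <- tibble::tibble(sample_id = tum$sample_id)
  grade <- code_one(tum$grade_code, GRADE_CODES, "grade", 1:3)
  ln <- code_one(tum$ln_code, LN_CODES, "LN", 1:2)
  if (all(is.na(grade))) warn("grade missing for all tumor samples; variable skipped.")
  else out$grade <- grade
  if (all(is.na(ln))) warn("LN status missing for all tumor samples; variable skipped.")
  else out$ln <- ln
  out
}

midrank_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)  # mid-ranks for ties
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / (sx * sy)
}

spearman_p <- function(r, n, exact = FALSE, x = NULL, y = NULL) {
  if (is.na(r)) return(NA_real_)
  if (exact) {
    if (n > 8) abort("exact permutation p is supported for n <= 8 only.")
    perms <- permutations_of(n)
    ry <- rank(y)
    obs <- abs(r)
    rs <- apply(perms, 1, function(idx) abs(midrank_spearman(x, ry[idx])))
    return(mean(rs >= obs - 1e-12))
  }
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tt), df = n - 2)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Correlate every probe with coded clinical variables
#'
#' Mid-rank (average-rank) Spearman correlation of normalized log2
#' expression with the coded tumor grade and lymph-node status, over tumor
#' samples with a non-missing code. The p-value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` df (two-sided); an exact
#' permutation p is available for very small cohorts. A probe-variable pair
#' is significant when `p < 0.05` and `|r| >= 0.4` (no multiplicity
#' correction, mirroring the raw-p convention of the source workflow).
#'
#' @param norm a [mir_norm()] (the batch-corrected matrix is used) or a log2
#'   expression matrix.
#' @param codes tibble from [encode_clinical()].
#' @param variables which coded variables to test.
#' @param complete_only restrict to samples with all tested codes present.
#' @param exact use the exact permutation p (n <= 8 only).
#' @param alpha,r_cut significance thresholds.
#' @return tibble: `probe_id`, `variable`, `r`, `p`, `n_used`, `significant`.
#' @export
spearman_all <- function(norm, codes, variables = c("grade", "ln"),
                         complete_only = FALSE, exact = FALSE,
                         alpha = 0.05, r_cut = 0.4) {
  y <- if (inherits(norm, "mir_norm")) norm$log2_expr else as.matrix(norm)
  variables <- intersect(variables, names(codes))
  if (complete_only) {
    keep <- complete.cases(codes[variables])
    codes <- codes[keep, , drop = FALSE]
  }
  purrr::map_dfr(variables, function(v) {
    code <- codes[[v]]
    use <- codes$sample_id[!is.na(code)]
    use <- intersect(use, colnames(y))
    code <- code[match(use, codes$sample_id)]
    if (length(use) < 5) {
      abort(paste0("need at least 5 tumor samples with a ", v, " code."),
            class = "mirstage_design_error")
    }
    r <- apply(y[, use, drop = FALSE], 1, midrank_spearman, y = code)
    p <- vapply(seq_along(r), function(i) {
      spearman_p(r[i], length(use), exact = exact,
                 x = y[i, use], y = code)
    }, 0)
    tibble::tibble(probe_id = rownames(y), variable = v, r = unname(r),
                   p = unname(p), n_used = length(use),
                   significant = !is.na(r) & p < alpha & abs(r) >= r_cut)
  })
}

#' Top clinical associations per variable
#'
#' Significant correlations ranked by |r| descending (p ascending breaks
#' ties); at most `per_variable` rows per clinical variable. Fewer
#' significant results than requested are all returned.
#'
#' @param results tibble from [spearman_all()].
#' @param per_variable rows to keep per variable.
#' @return ranked tibble subset.
#' @export
top_associations <- function(results, per_variable = 5) {
  results |>
    dplyr::filter(.data$significant) |>
    dplyr::group_by(.data$variable) |>
    dplyr::arrange(dplyr::desc(abs(.data$r)), .data$p, .by_group = TRUE) |>
    dplyr::slice_head(n = per_variable) |>
    dplyr::ungroup()
}

#' Tidy expression-by-clinical-level data for box plots
#' @param norm a [mir_norm()] or matrix.
#' @param codes tibble from [encode_clinical()].
#' @param probes probe ids to export (default all).
#' @return tibble `probe_id`, `sample_id`, `log2_expr`, `variable`, `level`.
#' @export
boxplot_data <- function(norm, codes, probes = NULL) {
  y <- if (inherits(norm, "mir_norm")) norm$log2_expr else as.matrix(norm)
  probes <- probes %||% rownames(y)
  long <- tidy(structure(list(log2_expr = y[probes, , drop = FALSE]),
                         class = "mir_norm"))
  codes_long <- tidyr::pivot_longer(codes, -"sample_id",
                                    names_to = "variable", values_to = "level")
  dplyr::inner_join(long, codes_long, by = "sample_id",
                    relationship = "many-to-many")
}
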