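#' nCounter-style probe count container
#'
#' Bundles an integer count matrix (probes x samples) with its probe
#' annotation. Probe classes follow the nCounter convention: `Endogenous`
#' panel probes, `Housekeeping` reference transcripts, `Positive` spike-ins
#' (a titration series with nominal concentrations in fM) and `Negative`
#' spike-ins that measure background.
#'
#' @param counts numeric matrix, probes x samples, non-negative; rownames are
#'   probe ids, colnames sample ids.
#' @param probes tibble with columns `probe_id`, `class` and (for positive
#'   controls) `concentration` in fM.
#' @param integer_counts require counts to be whole numbers (raw data). Scaled
#'   intermediates set this to `FALSE`.
#' @return An object of class `ncounter_set`.
#' @export
ncounter_set <- function(counts, probes, integer_counts = TRUE) {
  counts <- as.matrix(counts)
  probes <- tibble::as_tibble(probes)
  if (!all(c("probe_id", "class") %in% names(probes))) {
    abort("`probes` needs columns `probe_id` and `class`.", class = "mirstage_schema_error")
  }
  if (!"concentration" %in% names(probes)) probes$concentration <- NA_real_
  if (anyDuplicated(probes$probe_id)) {
    abort("duplicate probe ids in annotation.", class = "mirstage_format_error")
  }
  if (is.null(rownames(counts))) rownames(counts) <- probes$probe_id
  if (!setequal(rownames(counts), probes$probe_id)) {
    abort("count matrix rows and probe annotation disagree.", class = "mirstage_schema_error")
  }
  probes <- probes[match(rownames(counts), probes$probe_id), ]
  bad_class <- setdiff(unique(probes$class), PROBE_CLASSES)
  if (length(bad_class)) {
    abort(paste0("unknown probe class: ", paste(bad_class, collapse = ", ")),
          class = "mirstage_schema_error")
  }
  if (is.null(colnames(counts))) {
    abort("count matrix must carry sample ids as colnames.", class = "mirstage_schema_error")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("duplicate sample ids.", class = "mirstage_format_error")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("counts must be finite and non-negative.", class = "mirstage_format_error")
  }
  if (integer_counts) {
    if (any(abs(counts - round(counts)) > 1e-8)) {
      abort("counts must be whole numbers.", class = "mirstage_format_error")
    }
    if (max(counts) < .Machine$integer.max) storage.mode(counts) <- "integer"
  }
  structure(list(counts = counts, probes = probes), class = "ncounter_set")
}

PROBE_CLASSES <- c("Endogenous", "Housekeeping", "Positive", "Negative")

#' @export
print.ncounter_set <- function(x, ...) {
  cls <- table(factor(x$probes$class, PROBE_CLASSES))
  cat("<ncounter_set> ", nrow(x$counts), " probes x ", ncol(x$counts), " samples\n", sep = "")
  cat("  ", paste(names(cls), cls, sep = ": ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.ncounter_set <- function(x) dim(x$counts)

#' Probe ids of a given class
#' @param x an `ncounter_set`.
#' @param class one of `"Endogenous"`, `"Housekeeping"`, `"Positive"`, `"Negative"`.
#' @return character vector of probe ids.
#' @export
probes_of_class <- function(x, class) {
  x$probes$probe_id[x$probes$class %in% class]
}

#' Long tidy view of a count set
#'
#' @param x an `ncounter_set`.
#' @param ... unused.
#' @return tibble with columns `probe_id`, `class`, `sample_id`, `count`.
#' @export
tidy.ncounter_set <- function(x, ...) {
  tibble::tibble(
    probe_id  = rep(rownames(x$counts), times = ncol(x$counts)),
    class     = rep(x$probes$class, times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count     = as.vector(x$counts)
  )
}

#' Normalized log2 expression container
#'
#' Holds the endogenous-probe log2 expression matrix produced by one of the
#' two normalization pipelines, together with the per-sample scaling factors
#' and the housekeeping probes the pipeline selected.
#'
#' @param log2_expr numeric matrix (endogenous probes x samples), finite.
#' @param factors tibble with one row per sample: `sample_id`, `pos_factor`,
#'   `hk_factor`, `tmm_factor`, `lib_size`.
#' @param pipeline `"P1"` (control normalization only) or `"P2"` (adds TMM).
#' @param housekeeping character vector of selected housekeeping probe ids.
#' @return object of class `mir_norm`.
#' @export
mir_norm <- function(log2_expr, factors, pipeline, housekeeping) {
  stopifnot(pipeline %in% c("P1", "P2"))
  if (any(!is.finite(log2_expr))) abort("log2 expression must be finite.")
  factors <- tibble::as_tibble(factors)
  if (any(factors$pos_factor <= 0) || any(factors$hk_factor <= 0) ||
      any(factors$tmm_factor <= 0)) {
    abort("scaling factors must be positive.")
  }
  if (!length(housekeeping)) abort("housekeeping probe list must be non-empty.")
  structure(
    list(log2_expr = log2_expr, factors = factors, pipeline = pipeline,
         housekeeping = housekeeping),
    class = "mir_norm"
  )
}

#' @export
print.mir_norm <- function(x, ...) {
  cat("<mir_norm> pipeline ", x$pipeline, ": ", nrow(x$log2_expr), " probes x ",
      ncol(x$log2_expr), " samples; HK = {",
      paste(x$housekeeping, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @describeIn mir_norm long tibble of log2 expression values.
#' @param x a `mir_norm` object.
#' @param ... unused.
#' @export
tidy.mir_norm <- function(x, ...) {
  tibble::tibble(
    probe_id  = rep(rownames(x$log2_expr), times = ncol(x$log2_expr)),
    sample_id = rep(colnames(x$log2_expr), each = nrow(x$log2_expr)),
    log2_expr = as.vector(x$log2_expr)
  )
}
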