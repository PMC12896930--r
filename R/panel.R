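# Counter-based substreams: every random draw in the generator runs under a
# seed derived from (master seed, stream label), so adding a stage never
# perturbs the draws of another.
substream_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) * 69621 + h) %% 2147480009)
}

with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, key))
  force(expr)
}

# Nominal spike-in concentrations (fM) of the positive titration series.
POSITIVE_CONCENTRATIONS <- c(128, 32, 8, 2, 0.5, 0.125)

#' Build a synthetic nCounter-style miRNA panel design
#'
#' Emulates the layout of a human miRNA expression panel: `n_endogenous`
#' miRNA probes, five housekeeping transcripts, six positive spike-ins
#' forming a four-fold titration series (128 down to 0.125 fM) and eight
#' negative spike-ins.
#'
#' @param n_endogenous number of endogenous miRNA probes (default 800, the
#'   scale of the commercial panel); must be at least 10.
#' @param seed integer seed; the probe id list is deterministic given
#'   `(n_endogenous, seed)`.
#' @return tibble with columns `probe_id`, `class`, `concentration` (fM, only
#'   for positive controls).
#' @export
make_panel <- function(n_endogenous = 800, seed = 1L) {
  if (!is.numeric(n_endogenous) || n_endogenous < 10) {
    abort("`n_endogenous` must be at least 10.", class = "mirstage_invalid_panel")
  }
  n_endogenous <- as.integer(n_endogenous)
  endo <- with_substream(seed, "panel", {
    # synthetic hsa-miR-style ids; suffix keeps them unique and sortable
    sprintf("syn-miR-%04d-%s", seq_len(n_endogenous),
            sample(c("3p", "5p"), n_endogenous, replace = TRUE))
  })
  tibble::tibble(
    probe_id = c(endo,
                 c("HK-ACTB", "HK-B2M", "HK-GAPDH", "HK-RPL19", "HK-RPLP0"),
                 paste0("POS_", LETTERS[1:6]),
                 paste0("NEG_", LETTERS[1:8])),
    class = rep(PROBE_CLASSES, c(n_endogenous, 5L, 6L, 8L)),
    concentration = c(rep(NA_real_, n_endogenous + 5L),
                      POSITIVE_CONCENTRATIONS, rep(NA_real_, 8L))
  )
}

#' Simulated cohort sample sheet
#'
#' One row per sample: group (`GSD` non-tumor control, `Early` stage I/II
#' tumor, `Advanced` stage III/IV tumor), processing batch, and for tumor
#' samples the coded tumor grade (1 = well, 2 = moderately, 3 = poorly
#' differentiated) and lymph-node status (1 = negative, 2 = positive).
#' Group sizes default to the study design this generator emulates
#' (10 controls, 14 early, 17 advanced).
#'
#' @param n_gsd,n_early,n_advanced group sizes.
#' @param n_batches number of processing batches, assigned round-robin.
#' @param seed integer seed for the grade/LN draws.
#' @return tibble with columns `sample_id`, `group`, `batch`, `grade_code`,
#'   `ln_code`.
#' @export
make_sample_sheet <- function(n_gsd = 10, n_early = 14, n_advanced = 17,
                              n_batches = 2, seed = 1L) {
  n <- n_gsd + n_early + n_advanced
  group <- rep(c("GSD", "Early", "Advanced"), c(n_gsd, n_early, n_advanced))
  sheet <- tibble::tibble(
    sample_id = sprintf("S%02d_%s", seq_len(n), group),
    group = group,
    batch = paste0("B", (seq_len(n) - 1L) %% n_batches + 1L)
  )
  tumor <- sheet$group != "GSD"
  with_substream(seed, "sheet", {
    # grade mix leans moderately-differentiated, as in typical cohorts
    sheet$grade_code <- ifelse(
      tumor, sample(1:3, n, replace = TRUE, prob = c(0.2, 0.6, 0.2)), NA_integer_)
    sheet$ln_code <- ifelse(
      tumor, sample(1:2, n, replace = TRUE, prob = c(0.55, 0.45)), NA_integer_)
  })
  sheet
}

validate_sample_sheet <- function(sheet) {
  sheet <- tibble::as_tibble(sheet)
  need <- c("sample_id", "group", "batch")
  if (!all(need %in% names(sheet))) {
    abort(paste0("sample sheet needs columns: ", paste(need, collapse = ", ")),
          class = "mirstage_schema_error")
  }
  bad <- setdiff(unique(sheet$group), c("GSD", "Early", "Advanced"))
  if (length(bad)) {
    abort(paste0("unknown group label: ", paste(bad, collapse = ", ")),
          class = "mirstage_schema_error")
  }
  if (anyDuplicated(sheet$sample_id)) {
    abort("duplicate sample ids in sample sheet.", class = "mirstage_format_error")
  }
  if (!"grade_code" %in% names(sheet)) sheet$grade_code <- NA_integer_
  if (!"ln_code" %in% names(sheet)) sheet$ln_code <- NA_integer_
  ok_grade <- is.na(sheet$grade_code) | sheet$grade_code %in% 1:3
  ok_ln <- is.na(sheet$ln_code) | sheet$ln_code %in% 1:2
  if (!all(ok_grade) || !all(ok_ln)) {
    abort("grade codes must be in {1,2,3} and LN codes in {1,2}.",
          class = "mirstage_schema_error")
  }
  sheet
}
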