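#' Ground truth for a simulated nCounter cohort
#'
#' Collects every parameter of the synthetic-count model: per-probe baseline
#' means, negative-binomial dispersion, planted stage-wise log2 fold changes,
#' multiplicative batch shifts on a subset of probes, per-sample library-size
#' and lane-efficiency spreads, and planted monotone clinical effects. The
#' object is the generator's single source of randomness (all draws run off
#' `seed` through labelled substreams) and serializes losslessly to JSON.
#'
#' @param panel panel design from [make_panel()].
#' @param planted_dems tibble `probe_id`, `lfc_early`, `lfc_advanced` (log2
#'   fold changes vs the GSD control group), or `NULL` for a null cohort.
#' @param clinical_effects tibble `probe_id`, `variable` (`"grade"` or
#'   `"ln"`), `sign` (+1/-1), `magnitude` (log2 shift per code step), or
#'   `NULL`.
#' @param dispersion negative-binomial dispersion of endogenous probes
#'   (variance = mu + dispersion * mu^2).
#' @param baseline_meanlog,baseline_sdlog log-normal law for endogenous
#'   baseline means (defaults give a median of ~200 counts).
#' @param libsize_sdlog per-sample RNA-input (library size) spread, log-normal
#'   sdlog; affects endogenous and housekeeping probes only.
#' @param lane_sdlog per-sample lane-efficiency spread; affects all
#'   hybridized probes including positive spike-ins.
#' @param batches batch labels that receive probe-wise shifts (all but the
#'   first listed batch get shifted relative to it).
#' @param batch_frac fraction of probes given a batch shift.
#' @param batch_sdlog2 SD of the per-probe log2 batch shift.
#' @param neg_mean Poisson mean of negative spike-ins.
#' @param pos_scale counts per fM for positive spike-ins (156.25 puts the
#'   128 fM probe near 20,000 counts).
#' @param hk_dispersion dispersion of housekeeping probes (kept small: these
#'   transcripts are chosen for stability).
#' @param seed master integer seed.
#' @return object of class `sim_truth`.
#' @export
simulation_truth <- function(panel,
                             planted_dems = NULL,
                             clinical_effects = NULL,
                             dispersion = 0.08,
                             baseline_meanlog = log(200),
                             baseline_sdlog = 1.3,
                             libsize_sdlog = 0.12,
                             lane_sdlog = 0.08,
                             batches = c("B1", "B2"),
                             batch_frac = 0.2,
                             batch_sdlog2 = 0.6,
                             neg_mean = 15,
                             pos_scale = 156.25,
                             hk_dispersion = 0.005,
                             seed = 1L) {
  if (dispersion < 0) abort("`dispersion` must be > 0 (0 is treated as Poisson).")
  endo <- panel$probe_id[panel$class == "Endogenous"]
  if (is.null(planted_dems)) {
    planted_dems <- tibble::tibble(probe_id = character(),
                                   lfc_early = numeric(),
                                   lfc_advanced = numeric())
  }
  planted_dems <- tibble::as_tibble(planted_dems)
  if (nrow(planted_dems)) {
    if (!all(planted_dems$probe_id %in% endo)) {
      abort("planted DEM probes must be endogenous panel probes.",
            class = "mirstage_schema_error")
    }
    if (!all(is.finite(planted_dems$lfc_early)) ||
        !all(is.finite(planted_dems$lfc_advanced))) {
      abort("planted log2 fold changes must be finite.")
    }
  }
  if (is.null(clinical_effects)) {
    clinical_effects <- tibble::tibble(probe_id = character(),
                                       variable = character(),
                                       sign = numeric(), magnitude = numeric())
  }
  clinical_effects <- tibble::as_tibble(clinical_effects)

  baseline <- with_substream(seed, "baseline", {
    setNames(rlnorm(length(endo), baseline_meanlog, baseline_sdlog), endo)
  })
  hk_ids <- panel$probe_id[panel$class == "Housekeeping"]
  hk_mean <- with_substream(seed, "hk", {
    setNames(round(rlnorm(length(hk_ids), log(4000), 0.4)), hk_ids)
  })
  # per-probe multiplicative batch shifts on a random subset, relative to
  # the first batch
  batch_shifts <- with_substream(seed, "batch", {
    purrr::map_dfr(setdiff(batches, batches[1]), function(b) {
      hit <- sample(endo, size = round(batch_frac * length(endo)))
      tibble::tibble(batch = b, probe_id = hit,
                     log2_shift = rnorm(length(hit), 0, batch_sdlog2))
    })
  })
  structure(list(
    planted_dems = planted_dems,
    clinical_effects = clinical_effects,
    batch_shifts = batch_shifts,
    dispersion = dispersion,
    baseline_mean = baseline,
    hk_mean = hk_mean,
    libsize_sdlog = libsize_sdlog,
    lane_sdlog = lane_sdlog,
    neg_mean = neg_mean,
    pos_scale = pos_scale,
    hk_dispersion = hk_dispersion,
    seed = as.integer(seed)
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> seed ", x$seed, "; ", nrow(x$planted_dems),
      " planted DEMs; ", nrow(x$clinical_effects), " clinical effects; ",
      "dispersion ", x$dispersion, "\n", sep = "")
  invisible(x)
}

#' Write / read simulation truth as a JSON sidecar
#' @param truth a `sim_truth` object.
#' @param path file path.
#' @return `read_truth` returns the reconstructed `sim_truth`.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$baseline_mean <- as.list(x$baseline_mean)
  x$hk_mean <- as.list(x$hk_mean)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  retype <- function(d, proto) {
    out <- purrr::imap(proto, function(p, nm) {
      v <- unlist(d[[nm]]) %||% p
      if (is.character(p)) as.character(v) else as.numeric(v)
    })
    tibble::as_tibble(out)
  }
  x$planted_dems <- retype(x$planted_dems, list(
    probe_id = character(), lfc_early = numeric(), lfc_advanced = numeric()))
  x$clinical_effects <- retype(x$clinical_effects, list(
    probe_id = character(), variable = character(), sign = numeric(),
    magnitude = numeric()))
  x$batch_shifts <- retype(x$batch_shifts, list(
    batch = character(), probe_id = character(), log2_shift = numeric()))
  x$baseline_mean <- unlist(x$baseline_mean)
  x$hk_mean <- unlist(x$hk_mean)
  x$seed <- as.integer(x$seed)
  structure(x, class = "sim_truth")
}
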