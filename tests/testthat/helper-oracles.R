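# Independent brute-force oracles. These are deliberately coded differently
# from the package internals (loops, sort-based trimming, closed forms) so
# the two routes can disagree if either is wrong.

# TMM factors: sort-based double trim, explicit loops.
oracle_tmm <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  uq <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) uq[j] <- quantile(counts[, j], 0.75) / lib[j]
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref) { f[j] <- 1; next }
    num <- 0; den <- 0
    obs <- counts[, j]; rf <- counts[, ref]
    ok <- which(obs > 0 & rf > 0)
    m <- log2((obs[ok] / lib[j]) / (rf[ok] / lib[ref]))
    a <- 0.5 * log2((obs[ok] / lib[j]) * (rf[ok] / lib[ref]))
    n <- length(m)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * abs_trim) + 1; hi_a <- n + 1 - lo_a
    # mid-ranks by explicit counting (ties share the average position)
    midrank <- function(v, i) sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    for (i in seq_len(n)) {
      rm_i <- midrank(m, i); ra_i <- midrank(a, i)
      if (rm_i < lo_m || rm_i > hi_m) next
      if (ra_i < lo_a || ra_i > hi_a) next
      w <- (lib[j] - obs[ok[i]]) / (lib[j] * obs[ok[i]]) +
        (lib[ref] - rf[ok[i]]) / (lib[ref] * rf[ok[i]])
      num <- num + m[i] / w
      den <- den + 1 / w
    }
    f[j] <- if (den > 0) 2^(num / den) else 1
  }
  f / exp(mean(log(f)))
}

# Low-expression filter: literal restatement of the rule with loops.
oracle_filter_keep <- function(counts, group, min_cpm_count = 10,
                               min_samples = NULL) {
  lib <- colSums(counts)
  cutoff <- min_cpm_count * 1e6 / median(lib)
  if (is.null(min_samples)) min_samples <- min(table(group))
  keep <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    n_ok <- 0
    for (j in seq_len(ncol(counts))) {
      if (counts[i, j] / lib[j] * 1e6 >= cutoff) n_ok <- n_ok + 1
    }
    keep[i] <- n_ok >= min_samples
  }
  rownames(counts)[keep]
}

# BH step-up by the textbook definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Cumulative scores by explicit iteration over (gene, mirna) pairs.
oracle_scores <- function(mirna_lfc, interactions) {
  genes <- unique(interactions$target_gene)
  out <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    seen <- character(0)
    rows <- which(interactions$target_gene == g)
    for (r in rows) {
      m <- interactions$mirna[r]
      if (m %in% seen || !m %in% names(mirna_lfc)) next
      seen <- c(seen, m)
      out[g] <- out[g] + mirna_lfc[[m]]
    }
  }
  out[vapply(genes, function(g) any(interactions$mirna[interactions$target_gene == g]
                                    %in% names(mirna_lfc)), TRUE)]
}

# Hypergeometric upper tail by direct summation of the pmf (log-scale
# binomials, no phyper).
oracle_hyper_upper <- function(k, K, N, n) {
  ks <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Spearman r as Pearson on mid-ranks, written out.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# -- shared fixtures ---------------------------------------------------------

tiny_panel <- function(n_endo = 3) {
  tibble::tibble(
    probe_id = c(paste0("mir-", seq_len(n_endo)),
                 paste0("HK", 1:2), paste0("POS_", LETTERS[1:3]), paste0("NEG_", 1:3)),
    class = rep(c("Endogenous", "Housekeeping", "Positive", "Negative"),
                c(n_endo, 2, 3, 3)),
    concentration = c(rep(NA, n_endo + 2), 128, 32, 8, rep(NA, 3))
  )
}

tiny_set <- function(counts_endo, hk = 100, pos = c(2000, 500, 125), neg = 0) {
  n_s <- ncol(counts_endo)
  panel <- tiny_panel(nrow(counts_endo))
  counts <- rbind(
    counts_endo,
    matrix(hk, 2, n_s), matrix(pos, 3, n_s), matrix(neg, 3, n_s))
  rownames(counts) <- panel$probe_id
  colnames(counts) <- paste0("S", seq_len(n_s))
  if (all(counts == round(counts))) storage.mode(counts) <- "integer"
  ncounter_set(counts, panel)
}

# probes safely above the detection limit, usable for planting effects
plantable_probes <- function(truth, n, min_baseline = 50) {
  ids <- names(truth$baseline_mean)[truth$baseline_mean >= min_baseline]
  head(ids, n)
}

# cohort with planted stage effects on well-expressed probes
planted_cohort <- function(n_endogenous, seed, n_planted, lfc = 2.5,
                           dispersion = 0.08, ...) {
  panel <- make_panel(n_endogenous, seed = seed)
  truth0 <- simulation_truth(panel, seed = seed, dispersion = dispersion, ...)
  ids <- plantable_probes(truth0, n_planted)
  signs <- rep(c(1, -1), length.out = length(ids))
  mags <- rep(lfc, length.out = length(ids))
  pd <- tibble::tibble(probe_id = ids,
                       lfc_early = signs * mags,
                       lfc_advanced = rev(signs) * mags)
  co <- simulate_cohort(n_endogenous, seed = seed, planted_dems = pd,
                        dispersion = dispersion, ...)
  co$planted <- pd
  co
}
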