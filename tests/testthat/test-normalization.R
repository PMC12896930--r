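test_that("background correction subtracts mean(neg) + 2 sd and floors at zero", {
  x <- tiny_set(matrix(c(100L, 5L, 0L), 3, 1))
  # negatives all zero: unchanged
  expect_identical(background_correct(x)$counts, x$counts)

  counts <- rbind(x$counts, NEG_extra = 8L)
  probes <- dplyr::bind_rows(x$probes,
                             tibble::tibble(probe_id = "NEG_extra",
                                            class = "Negative",
                                            concentration = NA_real_))
  x4 <- ncounter_set(counts, probes)
  x4$counts[c("NEG_1", "NEG_2", "NEG_3"), 1] <- c(2L, 4L, 6L)
  out <- background_correct(x4)
  # threshold 10.16398: 100 -> round(89.836) = 90, 5 -> 0, 0 -> 0
  expect_equal(unname(out$counts[c("mir-1", "mir-2", "mir-3"), 1]), c(90, 0, 0))
  # control probes retained unmodified
  expect_identical(out$counts["NEG_extra", ], x4$counts["NEG_extra", ])
  expect_identical(out$counts["HK1", ], x4$counts["HK1", ])

  one_neg <- ncounter_set(x$counts[1:9, , drop = FALSE], x$probes[1:9, ])
  expect_error(background_correct(one_neg), class = "mirstage_qc_impossible")
})

test_that("housekeeping selection applies the count and CV criteria literally", {
  m <- matrix(10L, 2, 5)
  x <- tiny_set(m)
  hk <- probes_of_class(x, "Housekeeping")
  # HK1 constant at 100 (CV 0): selected. HK2 has one count at 49: excluded.
  x$counts[hk[1], ] <- 100L
  x$counts[hk[2], ] <- c(100L, 49L, 200L, 150L, 120L)
  expect_equal(select_housekeeping(x), hk[1])

  # CV boundary: {60,80,100,120,140} has CV 0.316 -> excluded
  x$counts[hk[1], ] <- c(60L, 80L, 100L, 120L, 140L)
  x$counts[hk[2], ] <- 40L
  err <- expect_error(select_housekeeping(x), class = "mirstage_norm_impossible")
  expect_match(conditionMessage(err), "CV")
  expect_equal(sd(c(60, 80, 100, 120, 140)) / 100, 0.3162278, tolerance = 1e-6)
})

test_that("control normalization scales each sample to the cohort mean geomean", {
  # identical samples: all factors 1, counts unchanged
  x <- tiny_set(matrix(50L, 3, 3))
  out <- control_normalize(x, probes_of_class(x, "Housekeeping"))
  f <- attr(out, "factors")
  expect_equal(f$pos_factor, rep(1, 3))
  expect_equal(f$hk_factor, rep(1, 3))
  expect_equal(out$counts, x$counts + 0)

  # sample B's controls exactly 2x sample A's
  x2 <- tiny_set(matrix(50L, 3, 2))
  ctrl <- c(probes_of_class(x2, "Housekeeping"), probes_of_class(x2, "Positive"))
  x2$counts[ctrl, 2] <- 2L * x2$counts[ctrl, 1]
  out2 <- control_normalize(x2, probes_of_class(x2, "Housekeeping"))
  f2 <- attr(out2, "factors")
  expect_equal(f2$pos_factor[2] / f2$pos_factor[1], 0.5, tolerance = 0.01)

  # by construction: geomean x factor equal across samples
  set.seed(1)
  x3 <- tiny_set(matrix(rpois(9, 200), 3, 3))
  pos <- probes_of_class(x3, "Positive")
  x3$counts[pos, ] <- matrix(rpois(9, 900), 3, 3)
  out3 <- control_normalize(x3, probes_of_class(x3, "Housekeeping"))
  f3 <- attr(out3, "factors")
  gm <- apply(x3$counts[pos, ] + 1, 2, function(v) exp(mean(log(v))))
  expect_equal(diff(range(gm * f3$pos_factor)), 0, tolerance = 1e-9)
})

test_that("low-expression filtering matches a brute-force coding of the rule", {
  set.seed(42)
  m <- matrix(rpois(50 * 8, 30), 50, 8)
  m[1:10, ] <- 0L                               # all-zero probes must drop
  x <- tiny_set(m)
  group <- rep(c("GSD", "Early", "Advanced"), c(2, 3, 3))
  sheet <- tibble::tibble(sample_id = colnames(x$counts), group = group, batch = "B1")
  out <- filter_low_expression(x, sheet)
  endo <- x$counts[probes_of_class(x, "Endogenous"), ]
  expect_setequal(attr(out, "kept"), oracle_filter_keep(endo, group))
  expect_true(all(paste0("mir-", 1:10) %in% attr(out, "dropped")))
  expect_error(filter_low_expression(x, sheet, norm_config(min_cpm_count = 1e9)),
               class = "mirstage_norm_impossible")
})

test_that("a probe exactly at the cutoff in exactly min_samples samples is kept", {
  # equal library sizes (200) so the CPM cutoff is easy to place exactly
  m <- rbind(c(60L, 60L, 1L, 1L, 1L, 1L),
             c(40L, 40L, 99L, 99L, 99L, 99L),
             rep(100L, 6))
  x <- tiny_set(m)
  sheet <- tibble::tibble(sample_id = colnames(x$counts),
                          group = rep(c("GSD", "Early", "Advanced"), c(2, 2, 2)),
                          batch = "B1")
  # cutoff = 60e6/200 = 300000 CPM: probe 1 sits exactly at it in 2 samples,
  # the size of the smallest group -> kept (boundary inclusive)
  out <- filter_low_expression(x, sheet, norm_config(min_cpm_count = 60))
  expect_true("mir-1" %in% attr(out, "kept"))
  expect_setequal(attr(out, "kept"),
                  oracle_filter_keep(x$counts[probes_of_class(x, "Endogenous"), ],
                                     sheet$group, min_cpm_count = 60))
  # nudge the cutoff up: probe 1 now falls short everywhere but 2 samples is
  # still needed, so it drops
  out2 <- filter_low_expression(x, sheet, norm_config(min_cpm_count = 60.1))
  expect_false("mir-1" %in% attr(out2, "kept"))
})

test_that("TMM factors match the brute-force doubly trimmed weighted mean", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(rnbinom(50 * 6, mu = exp(rnorm(50, 5, 1)), size = 10), 50, 6)
    rownames(m) <- paste0("g", 1:50); colnames(m) <- paste0("s", 1:6)
    f <- tmm_factors(m)
    expect_equal(unname(f), oracle_tmm(m), tolerance = 1e-6)
    expect_equal(sum(log2(f)), 0, tolerance = 1e-9)
  }
})

test_that("TMM agrees with edgeR and is 1 under pure library-size shifts", {
  # sample B = 2 x sample A elementwise: equal M everywhere, both factors 1
  set.seed(3)
  a <- rpois(100, 200)
  m <- cbind(s1 = a, s2 = 2L * a)
  rownames(m) <- paste0("g", 1:100)
  expect_equal(unname(tmm_factors(m)), c(1, 1), tolerance = 1e-9)
  # identical samples
  m2 <- cbind(s1 = a, s2 = a, s3 = a); rownames(m2) <- paste0("g", 1:100)
  expect_equal(unname(tmm_factors(m2)), c(1, 1, 1), tolerance = 1e-12)
  # independent implementation in edgeR
  set.seed(8)
  m3 <- matrix(rnbinom(200 * 8, mu = exp(rnorm(200, 5, 1.2)), size = 5), 200, 8)
  rownames(m3) <- paste0("g", 1:200); colnames(m3) <- paste0("s", 1:8)
  f_edger <- edgeR::calcNormFactors(m3, method = "TMM")
  expect_equal(unname(tmm_factors(m3)), unname(f_edger), tolerance = 1e-8)
})

test_that("log-CPM uses the effective library size and handles zeros", {
  x <- tiny_set(matrix(c(0L, 7L, 100L), 3, 1))
  lc <- log_cpm(x)
  expect_true(all(is.finite(lc)))
  lib <- sum(c(0, 7, 100))
  expect_equal(lc["mir-2", 1], log2((7 + 0.5) / (lib + 1) * 1e6), tolerance = 1e-12)
  # doubling the library (same probe counts) lowers CPM by ~1 on log2 scale
  x2 <- tiny_set(cbind(c(10L, 20L, 30L), c(20L, 40L, 60L)))
  lc2 <- log_cpm(x2)
  expect_equal(unname(lc2[2, 1] - lc2[2, 2]),
               log2(20.5 / 61) - log2(40.5 / 121), tolerance = 1e-12)
})

test_that("batch correction removes planted offsets exactly and is idempotent", {
  sheet <- tibble::tibble(sample_id = paste0("s", 1:8),
                          group = rep(c("GSD", "Early"), each = 4),
                          batch = rep(c("B1", "B2"), 4))
  # noise-free: y = group effect + batch offset
  g <- ifelse(sheet$group == "Early", 2, 0)
  b <- ifelse(sheet$batch == "B2", 0.7, 0)
  y <- rbind(p1 = 5 + g + b, p2 = 3 - g + 2 * b)
  colnames(y) <- sheet$sample_id
  out <- batch_correct(y, sheet)
  grp_means <- function(m) sapply(split(sheet$sample_id, sheet$group),
                                  function(s) rowMeans(m[, s, drop = FALSE]))
  expect_equal(grp_means(out)[, "Early"] - grp_means(out)[, "GSD"],
               grp_means(y)[, "Early"] - grp_means(y)[, "GSD"], tolerance = 1e-10)
  expect_equal(unname(apply(out[, sheet$batch == "B2"] - out[, sheet$batch == "B1"], 1, var)),
               c(0, 0), tolerance = 1e-20)
  expect_equal(batch_correct(out, sheet), out, tolerance = 1e-12)

  # single batch: unchanged
  one <- sheet; one$batch <- "B1"
  expect_identical(batch_correct(y, one), y)

  # confounded design refused
  conf <- sheet; conf$batch <- ifelse(conf$group == "GSD", "B1", "B2")
  expect_error(batch_correct(y, conf), class = "mirstage_confounded")

  # agrees with the reference implementation on noisy data
  set.seed(5)
  yn <- y + matrix(rnorm(16, 0, 0.3), 2)
  ours <- batch_correct(yn, sheet)
  ref <- limma::removeBatchEffect(yn, batch = factor(sheet$batch),
                                  design = model.matrix(~factor(sheet$group)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("RLE values subtract the per-probe median and flag tighter pipelines", {
  # identical samples: all zero
  y <- matrix(5, 4, 3, dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
  expect_true(all(rle_stats(y)$values == 0))
  # hand 2x3 case
  y2 <- rbind(a = c(1, 2, 3), b = c(10, 10, 16))
  colnames(y2) <- paste0("s", 1:3)
  expect_equal(unname(rle_stats(y2)$values),
               rbind(c(-1, 0, 1), c(0, 0, 6)))

  # P2 (TMM) tightens the spread of per-sample medians relative to P1
  co <- planted_cohort(200, seed = 21, n_planted = 24, lfc = 2.5)
  r1 <- rle_stats(normalize_pipeline(co$counts, co$sheet, "P1"))
  r2 <- rle_stats(normalize_pipeline(co$counts, co$sheet, "P2"))
  expect_lte(r2$summary$iqr_of_medians, r1$summary$iqr_of_medians)
})

test_that("pipeline P1 equals P2 with TMM factors forced to 1", {
  co <- simulate_cohort(n_endogenous = 60, seed = 13, n_gsd = 4, n_early = 4,
                        n_advanced = 4)
  p1 <- normalize_pipeline(co$counts, co$sheet, "P1")
  # rebuild P1 by composing the stages with unit factors
  hk <- select_housekeeping(co$counts)
  flt <- filter_low_expression(control_normalize(background_correct(co$counts), hk),
                               co$sheet)
  manual <- batch_correct(log_cpm(flt, NULL), co$sheet)
  expect_equal(p1$log2_expr, manual, tolerance = 1e-12)
  expect_true(all(p1$factors$tmm_factor == 1))
})
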