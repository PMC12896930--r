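write_interactions <- function(rows) {
  header <- paste("miRTarBase ID", "miRNA", "Species (miRNA)", "Target Gene",
                  "Species (Target Gene)", "Experiments", "Support Type",
                  "References (PMID)", sep = "\t")
  withr::local_tempfile(lines = c(header, rows), .local_envir = parent.frame())
}

rec <- function(id, mirna, gene, exp, sp = "Homo sapiens") {
  paste(id, mirna, sp, gene, sp, exp, "Functional MTI", "1", sep = "\t")
}

test_that("interaction tables parse, flag species and reject bad input", {
  f <- write_interactions(c(
    rec("I1", "hsa-miR-1-3p", "GENE1", "Western blot;qRT-PCR"),
    rec("I2", "hsa-miR-2-5p", "GENE2", "Luciferase reporter assay"),
    rec("I3", "miR-3-5p", "GENE3", "qRT-PCR//Western blot"),
    rec("I4", "mmu-miR-4", "Gene4", "Western blot", sp = "Mus musculus"),
    rec("I5", "hsa-miR-5", "GENE5", "Microarray")))
  r <- load_interactions(f)
  expect_equal(nrow(r), 5)
  expect_equal(r$mirna[1:3], c("mir-1-3p", "mir-2-5p", "mir-3-5p"))
  expect_equal(r$evidence[[3]], c("qRT-PCR", "Western blot"))
  expect_equal(r$human, c(TRUE, TRUE, TRUE, FALSE, TRUE))

  empty <- write_interactions(rec("I1", "hsa-miR-1", "G", ""))
  expect_error(load_interactions(empty), class = "mirstage_evidence_empty")

  nohead <- withr::local_tempfile(lines = c("a\tb", "1\t2"))
  expect_error(load_interactions(nohead), class = "mirstage_format_error")
})

test_that("high-confidence filtering honours the evidence modes", {
  f <- write_interactions(c(
    rec("I1", "hsa-miR-1", "G1", "Western blot;qRT-PCR;Luciferase reporter assay"),
    rec("I2", "hsa-miR-2", "G2", "qRT-PCR"),
    rec("I3", "hsa-miR-3", "G3", "Microarray;Sequencing"),
    rec("I4", "hsa-miR-4", "G4", "Western blot;qPCR;reporter assay"),
    rec("I5", "hsa-miR-5", "G5", "Western blot;Luciferase reporter assay"),
    rec("I6", "mmu-miR-6", "G6", "Western blot;qRT-PCR;Luciferase reporter assay",
        sp = "Mus musculus")))
  r <- load_interactions(f)
  strict <- filter_high_confidence(r, "all_three")
  expect_setequal(strict$source_id, c("I1", "I4"))  # hand enumeration
  loose <- filter_high_confidence(r, "any_strong")
  expect_setequal(loose$source_id, c("I1", "I2", "I4", "I5"))
})

test_that("composite probes split their fold change across both miRNAs", {
  lfc <- expand_composite_probes(tibble::tibble(
    probe_id = c("miR-20a-5p + miR-20b-5p", "miR-135b-5p"),
    log2fc = c(3.2894, 5.6076)))
  expect_equal(unname(lfc[c("mir-20a-5p", "mir-20b-5p")]), c(3.2894, 3.2894))
  expect_equal(unname(lfc[["mir-135b-5p"]]), 5.6076)
  expect_error(expand_composite_probes(tibble::tibble(probe_id = "miR-1 + ",
                                                      log2fc = 1)),
               class = "mirstage_name_error")
})

test_that("cumulative scores sum distinct regulating miRNAs per gene", {
  f <- write_interactions(c(
    rec("I1", "hsa-miR-135b-5p", "APC", "Western blot;qRT-PCR;reporter assay"),
    rec("I2", "hsa-miR-135b-5p", "APC", "qRT-PCR;Luciferase reporter assay;Western blot"),
    rec("I3", "hsa-miR-a", "GX", "Western blot;qPCR;reporter assay"),
    rec("I4", "hsa-miR-b", "GX", "Western blot;qPCR;reporter assay")))
  r <- load_interactions(f)
  # gene regulated only by miR-135b-5p at its early-contrast fold change:
  # duplicate evidence rows collapse, score equals the single log2FC
  s <- cumulative_scores(c("mir-135b-5p" = 5.6076), r)
  expect_equal(s$cumulative_score[s$target_gene == "APC"], 5.6076)
  expect_true(s$strongly_regulated[s$target_gene == "APC"])
  expect_equal(s$inferred_direction[s$target_gene == "APC"], "down")
  # +2 and -2 cancel
  s2 <- cumulative_scores(c("mir-a" = 2, "mir-b" = -2), r)
  expect_equal(s2$cumulative_score[s2$target_gene == "GX"], 0)
  expect_false(s2$strongly_regulated[s2$target_gene == "GX"])
})

test_that("scores equal brute-force summation and are order invariant", {
  set.seed(10)
  for (i in 1:5) {
    mirnas <- paste0("mir-", 1:8)
    genes <- paste0("G", 1:6)
    tab <- tibble::tibble(
      source_id = paste0("I", 1:30),
      mirna = sample(mirnas, 30, replace = TRUE),
      target_gene = sample(genes, 30, replace = TRUE),
      evidence = replicate(30, "qPCR", simplify = FALSE),
      human = TRUE)
    lfc <- setNames(round(rnorm(5), 3), sample(mirnas, 5))
    s <- cumulative_scores(lfc, tab)
    o <- oracle_scores(lfc, tab)
    expect_equal(setNames(s$cumulative_score, s$target_gene)[names(o)], o,
                 tolerance = 1e-12)
    # permuting rows changes nothing
    s_perm <- cumulative_scores(lfc, tab[sample(30), ])
    expect_equal(dplyr::arrange(s, target_gene), dplyr::arrange(s_perm, target_gene))
  }
})

test_that("score additivity over a split interaction file", {
  tab <- tibble::tibble(
    source_id = paste0("I", 1:6),
    mirna = paste0("mir-", 1:6),
    target_gene = rep(c("G1", "G2"), each = 3),
    evidence = replicate(6, "qPCR", simplify = FALSE), human = TRUE)
  lfc <- setNames(c(1, 2, 3, -1, -2, -3), paste0("mir-", 1:6))
  whole <- cumulative_scores(lfc, tab)
  part1 <- cumulative_scores(lfc, tab[1:3, ])
  part2 <- cumulative_scores(lfc, tab[4:6, ])
  merged <- dplyr::bind_rows(part1, part2) |>
    dplyr::group_by(target_gene) |>
    dplyr::summarise(cumulative_score = sum(cumulative_score))
  expect_equal(dplyr::arrange(whole[c("target_gene", "cumulative_score")], target_gene),
               dplyr::arrange(merged, target_gene))
})

test_that("a cumulative score of exactly +/-4 is not strongly regulated", {
  tab <- tibble::tibble(source_id = c("I1", "I2"), mirna = c("mir-x", "mir-y"),
                        target_gene = c("GP", "GN"),
                        evidence = replicate(2, "qPCR", simplify = FALSE),
                        human = TRUE)
  s <- cumulative_scores(c("mir-x" = 4, "mir-y" = -4), tab)
  expect_false(any(s$strongly_regulated))
  s2 <- cumulative_scores(c("mir-x" = 4 + 1e-9, "mir-y" = -4 - 1e-9), tab)
  expect_true(all(s2$strongly_regulated))
})

test_that("network construction sizes nodes and breaks ties lexicographically", {
  tab <- tibble::tibble(
    source_id = paste0("I", 1:5),
    mirna = c("mir-1", "mir-2", "mir-1", "mir-3", "mir-2"),
    target_gene = c("GA", "GA", "GB", "GB", "GC"),
    evidence = replicate(5, "qPCR", simplify = FALSE), human = TRUE)
  lfc <- c("mir-1" = 3, "mir-2" = -2, "mir-3" = 1)
  s <- cumulative_scores(lfc, tab)
  # 3 genes, top_n = 10: all included
  net <- build_network(s, lfc, top_n = 10)
  expect_equal(sum(net$nodes$kind == "gene"), 3)
  # gene node size = sum |log2fc| of incident miRNAs (hand-computed)
  expect_equal(net$nodes$size[net$nodes$id == "GA"], 5)   # |3| + |-2|
  expect_equal(net$nodes$size[net$nodes$id == "GB"], 4)   # |3| + |1|
  expect_equal(net$nodes$size[net$nodes$id == "GC"], 2)
  expect_equal(net$nodes$size[net$nodes$id == "mir-1"], 3)
  expect_equal(net$nodes$direction[net$nodes$id == "mir-2"], "down")
  # tie at the cut: |score(GB)| = |4| ties nothing here; force a tie
  s_tie <- tibble::tibble(target_gene = c("GZ", "GA"), cumulative_score = c(2, 2),
                          n_mirnas = 1,
                          contributing = replicate(2, tibble::tibble(
                            mirna = "mir-1", log2fc = 2), simplify = FALSE),
                          strongly_regulated = FALSE, inferred_direction = "down")
  net_tie <- build_network(s_tie, c("mir-1" = 2), top_n = 1)
  expect_equal(net_tie$nodes$id[net_tie$nodes$kind == "gene"], "GA")
})

test_that("network exports round-trip and handle the empty network", {
  tab <- tibble::tibble(source_id = "I1", mirna = "mir-1", target_gene = "GA",
                        evidence = list("qPCR"), human = TRUE)
  lfc <- c("mir-1" = 2.5)
  net <- build_network(cumulative_scores(lfc, tab), lfc)
  dir <- withr::local_tempdir()
  g <- file.path(dir, "net.graphml")
  export_network(net, g, "graphml")
  back <- import_network(g)
  expect_setequal(back$nodes$id, net$nodes$id)
  expect_equal(back$nodes$size[match(net$nodes$id, back$nodes$id)], net$nodes$size)
  expect_equal(back$nodes$direction[match(net$nodes$id, back$nodes$id)],
               net$nodes$direction)
  expect_equal(nrow(back$edges), 1)

  s <- file.path(dir, "net.sif")
  export_network(net, s, "sif")
  expect_equal(readLines(s), "mir-1 targets GA")
  export_network(net, file.path(dir, "nodes.tsv"), "tsv")
  expect_equal(nrow(readr::read_tsv(file.path(dir, "nodes.tsv"),
                                    show_col_types = FALSE)), 2)

  empty <- build_network(cumulative_scores(setNames(numeric(0), character(0)), tab),
                         setNames(numeric(0), character(0)))
  export_network(empty, file.path(dir, "empty.sif"), "sif")
  expect_length(readLines(file.path(dir, "empty.sif")), 0)
  export_network(empty, file.path(dir, "empty.graphml"), "graphml")
  expect_equal(nrow(import_network(file.path(dir, "empty.graphml"))$nodes), 0)
})
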