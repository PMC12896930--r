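INTERACTION_COLS <- c("mirtarbase_id", "mirna", "species_mirna", "target_gene",
                      "species_target", "experiments", "support_type", "references")

#' Load a validated miRNA-target interaction table
#'
#' Reads a miRTarBase-style TSV (columns: interaction id, miRNA, miRNA
#' species, target gene, target species, experiments, support type,
#' reference). Evidence strings are split on `;` or `//` into an assay set.
#' Non-human rows are retained but flagged `human = FALSE`.
#'
#' @param path TSV path with a header.
#' @return tibble with one row per record: `source_id`, `mirna`,
#'   `target_gene`, `evidence` (list column of assay labels), `human`.
#' @export
load_interactions <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         name_repair = ~tolower(gsub("[ ()]+", "_", .x)))
  names(tab) <- sub("_$", "", names(tab))
  names(tab)[names(tab) == "species_target_gene"] <- "species_target"
  names(tab)[names(tab) == "references_pmid"] <- "references"
  missing <- setdiff(INTERACTION_COLS, names(tab))
  if (length(missing)) {
    abort(paste0("interaction table lacks columns: ", paste(missing, collapse = ", ")),
          class = "mirstage_format_error")
  }
  if (anyNA(tab$experiments)) {
    abort("interaction records must carry a non-empty evidence set.",
          class = "mirstage_evidence_empty")
  }
  evidence <- strsplit(as.character(tab$experiments), "\\s*(;|//)\\s*")
  evidence <- purrr::map(evidence, ~trimws(.x[nzchar(trimws(.x))]))
  if (any(lengths(evidence) == 0)) {
    abort("interaction records must carry a non-empty evidence set.",
          class = "mirstage_evidence_empty")
  }
  tibble::tibble(
    source_id = tab$mirtarbase_id,
    mirna = normalize_mirna(tab$mirna),
    target_gene = toupper(tab$target_gene),
    evidence = evidence,
    human = tolower(tab$species_mirna) == "homo sapiens" &
      tolower(tab$species_target) == "homo sapiens"
  )
}

# canonical lower-case id without the species prefix: "hsa-miR-20a-5p",
# "miR-20a-5p" and "MIR-20A-5P" all map to "mir-20a-5p"
normalize_mirna <- function(x) {
  x <- tolower(trimws(x))
  sub("^hsa-", "", x)
}

evidence_matches <- function(ev, patterns) {
  any(vapply(patterns, function(p) any(grepl(p, ev, ignore.case = TRUE)), TRUE))
}

#' Filter interactions to high-confidence validated records
#'
#' High confidence means validated by Western blot, qPCR and a reporter
#' assay. Assay names are synonym-normalized: "luciferase reporter assay"
#' counts as reporter, "qRT-PCR" as qPCR. Mode `all_three` (default)
#' requires all three assay families; `any_strong` accepts any one. Records
#' are restricted to human-human pairs.
#'
#' @param records tibble from [load_interactions()].
#' @param mode `"all_three"` or `"any_strong"`.
#' @return filtered tibble.
#' @export
filter_high_confidence <- function(records, mode = c("all_three", "any_strong")) {
  mode <- match.arg(mode)
  fam <- list(western = c("western"),
              qpcr = c("q\\s*rt?-?\\s*pcr", "qpcr", "quantitative.*pcr"),
              reporter = c("reporter", "luciferase"))
  hits <- purrr::map(records$evidence, function(ev) {
    vapply(fam, evidence_matches, TRUE, ev = ev)
  })
  keep <- vapply(hits, if (mode == "all_three") all else any, TRUE)
  records[keep & records$human, , drop = FALSE]
}

#' Expand composite probes into per-miRNA fold changes
#'
#' Panel probes that interrogate two mature miRNAs are named `"A + B"`; the
#' probe's log2 fold change is attributed to both A and B. Names are
#' normalized (lower case, optional `hsa-` prefix dropped) so they key into
#' interaction tables.
#'
#' @param de tibble with `probe_id` and `log2fc` (e.g. the significant rows
#'   of one contrast from [de_contrast()]), or a named numeric vector.
#' @return named numeric vector: normalized miRNA id -> log2 fold change.
#' @export
expand_composite_probes <- function(de) {
  if (is.numeric(de)) de <- tibble::tibble(probe_id = names(de), log2fc = unname(de))
  if (any(grepl("^\\s*\\+|\\+\\s*$|\\+\\s*\\+", de$probe_id))) {
    abort("empty miRNA name beside '+' in a composite probe id.",
          class = "mirstage_name_error")
  }
  parts <- strsplit(de$probe_id, "\\s*\\+\\s*")
  if (any(vapply(parts, function(p) any(!nzchar(p)) || !length(p), TRUE))) {
    abort("empty miRNA name beside '+' in a composite probe id.",
          class = "mirstage_name_error")
  }
  out <- tibble::tibble(
    mirna = normalize_mirna(unlist(parts)),
    log2fc = rep(de$log2fc, lengths(parts))
  )
  if (anyDuplicated(out$mirna)) {
    out <- dplyr::summarise(dplyr::group_by(out, .data$mirna),
                            log2fc = .data$log2fc[1], .groups = "drop")
  }
  setNames(out$log2fc, out$mirna)
}

#' Cumulative regulatory scores of target genes
#'
#' For each gene, the score is the sum of the log2 fold changes of its
#' distinct significant regulating miRNAs (multiple evidence rows for the
#' same miRNA-gene pair count once). Genes with |score| > 4 are called
#' strongly regulated; the inferred direction is `down` when the net miRNA
#' pressure is up (repression assumption) and `up` otherwise.
#'
#' @param mirna_lfc named vector from [expand_composite_probes()] holding
#'   only significant DEMs.
#' @param interactions tibble from [load_interactions()] /
#'   [filter_high_confidence()].
#' @param score_cut strong-regulation threshold (strict inequality).
#' @return tibble: `target_gene`, `cumulative_score`, `n_mirnas`,
#'   `contributing` (list of `mirna`, `log2fc`), `strongly_regulated`,
#'   `inferred_direction`.
#' @export
cumulative_scores <- function(mirna_lfc, interactions, score_cut = 4) {
  pairs <- dplyr::distinct(interactions[c("mirna", "target_gene")])
  pairs <- pairs[pairs$mirna %in% names(mirna_lfc), , drop = FALSE]
  pairs$log2fc <- unname(mirna_lfc[pairs$mirna])
  pairs <- pairs[order(pairs$mirna), , drop = FALSE]  # row-order invariance
  by_gene <- split(pairs[c("mirna", "log2fc")], pairs$target_gene)
  scores <- tibble::tibble(
    target_gene = names(by_gene),
    cumulative_score = unname(vapply(by_gene, function(d) sum(d$log2fc), 0)),
    n_mirnas = unname(vapply(by_gene, nrow, 0L)),
    contributing = unname(purrr::map(by_gene, tibble::as_tibble))
  )
  scores <- dplyr::arrange(scores, dplyr::desc(abs(.data$cumulative_score)),
                           .data$target_gene)
  scores$strongly_regulated <- abs(scores$cumulative_score) > score_cut
  scores$inferred_direction <- ifelse(scores$cumulative_score > 0, "down", "up")
  scores
}

#' Build the miRNA-target regulatory network
#'
#' Selects the `top_n` genes by absolute cumulative score (ties broken by
#' gene symbol, ascending) together with all their significant regulating
#' miRNAs. Node sizes encode regulatory influence: |log2FC| for miRNAs, the
#' sum of |log2FC| of incident miRNAs for genes. Node direction encodes up /
#' down status (measured for miRNAs, inferred for genes).
#'
#' @param scores tibble from [cumulative_scores()].
#' @param mirna_lfc named log2-fold-change vector of significant DEMs.
#' @param top_n number of genes to display.
#' @param contrast label stored on the network.
#' @return list of class `mir_network` with tibbles `nodes` (`id`, `kind`,
#'   `direction`, `size`, `score`) and `edges` (`mirna`, `target_gene`,
#'   `log2fc`).
#' @export
build_network <- function(scores, mirna_lfc, top_n = 10, contrast = "early") {
  ord <- order(-abs(scores$cumulative_score), scores$target_gene)
  top <- scores[ord, ][seq_len(min(top_n, nrow(scores))), , drop = FALSE]
  if (nrow(top)) {
    edges <- tidyr::unnest(top[c("target_gene", "contributing")], "contributing")
    edges <- edges[c("mirna", "target_gene", "log2fc")]
  } else {
    edges <- tibble::tibble(mirna = character(), target_gene = character(),
                            log2fc = numeric())
  }
  gene_nodes <- top |>
    dplyr::transmute(id = .data$target_gene, kind = "gene",
                     direction = .data$inferred_direction,
                     size = purrr::map_dbl(.data$contributing, ~sum(abs(.x$log2fc))),
                     score = .data$cumulative_score)
  mirnas <- unique(edges$mirna)
  mirna_nodes <- tibble::tibble(
    id = mirnas, kind = "mirna",
    direction = unname(ifelse(mirna_lfc[mirnas] > 0, "up", "down")),
    size = abs(unname(mirna_lfc[mirnas])),
    score = unname(mirna_lfc[mirnas]))
  structure(list(nodes = dplyr::bind_rows(mirna_nodes, gene_nodes),
                 edges = edges, contrast = contrast),
            class = "mir_network")
}

#' @export
print.mir_network <- function(x, ...) {
  cat("<mir_network> [", x$contrast, "] ",
      sum(x$nodes$kind == "mirna"), " miRNAs -> ",
      sum(x$nodes$kind == "gene"), " genes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Export a regulatory network
#'
#' GraphML (via igraph, with node attributes `kind`, `direction`, `size`),
#' SIF (`mirna targets gene`) or a node-attribute TSV.
#'
#' @param net a `mir_network`.
#' @param path output file.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return the path, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      net$edges[c("mirna", "target_gene")], directed = TRUE,
      vertices = as.data.frame(net$nodes))
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    writeLines(sprintf("%s targets %s", net$edges$mirna, net$edges$target_gene), path)
  } else {
    readr::write_tsv(net$nodes, path)
  }
  invisible(path)
}

#' Re-import a GraphML network export
#' @param path GraphML file written by [export_network()].
#' @return a `mir_network`.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble::tibble(
    id = igraph::V(g)$name, kind = igraph::V(g)$kind,
    direction = igraph::V(g)$direction, size = igraph::V(g)$size,
    score = igraph::V(g)$score)
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(mirna = el[, 1], target_gene = el[, 2])
  structure(list(nodes = nodes, edges = edges, contrast = NA_character_),
            class = "mir_network")
}
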