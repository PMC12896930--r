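# A deliberately small, fully specified sectioned-CSV dialect for per-lane
# digital counts. Grammar:
#   <Header>        lines "key,value"; must contain "FileVersion"
#   <Lane_Attributes>  lines "key,value"; must contain "ID,<sample id>"
#   <Code_Summary>  header "CodeClass,Name,Accession,Count", then one CSV
#                   line per probe; Count must be a non-negative integer
# Each section closes with </Section_Name>. One file = one lane/sample.

#' Read a sectioned per-lane count file
#'
#' Parses the package's documented RCC-like dialect (see the file grammar in
#' the source and the methods vignette) into a one-sample [ncounter_set()].
#' Probe class labels are matched case-insensitively; positive-control
#' concentrations are recovered from names of the form `POS_X(128)` when
#' present, else from the built-in titration series by probe order.
#'
#' @param path path to a dialect file.
#' @return an [ncounter_set()] with a single sample.
#' @export
read_rcc_dialect <- function(path) {
  lines <- readLines(path)
  section <- function(name) {
    open <- grep(paste0("^<", name, ">$"), lines)
    close <- grep(paste0("^</", name, ">$"), lines)
    if (length(open) != 1 || length(close) != 1 || close < open) {
      abort(paste0("missing or malformed <", name, "> section in ", path),
            class = "mirstage_format_error")
    }
    lines[(open + 1):(close - 1)]
  }
  section("Header")
  lane <- section("Lane_Attributes")
  kv <- strsplit(lane, ",", fixed = TRUE)
  ids <- vapply(kv, `[`, "", 1)
  if (!"ID" %in% ids) {
    abort("Lane_Attributes must carry an ID line.", class = "mirstage_format_error")
  }
  sample_id <- kv[[match("ID", ids)]][2]

  body <- section("Code_Summary")
  if (!length(body) || !grepl("^CodeClass,", body[1])) {
    abort("Code_Summary must start with a CodeClass header line.",
          class = "mirstage_format_error")
  }
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  if (any(lengths(rows) != 4)) {
    abort("Code_Summary rows must have 4 fields.", class = "mirstage_format_error")
  }
  cls_raw <- vapply(rows, `[`, "", 1)
  probe <- vapply(rows, `[`, "", 2)
  count_chr <- vapply(rows, `[`, "", 4)
  if (any(!grepl("^[0-9]+$", count_chr))) {
    abort("counts in Code_Summary must be non-negative integers.",
          class = "mirstage_format_error")
  }
  cls <- PROBE_CLASSES[match(tolower(cls_raw), tolower(PROBE_CLASSES))]
  if (anyNA(cls)) {
    abort(paste0("unknown probe class: ", paste(unique(cls_raw[is.na(cls)]), collapse = ", ")),
          class = "mirstage_format_error")
  }
  if (anyDuplicated(probe)) {
    abort("duplicate probe id in Code_Summary.", class = "mirstage_format_error")
  }
  conc <- rep(NA_real_, length(probe))
  pos <- cls == "Positive"
  embedded <- regmatches(probe, regexec("\\(([0-9.]+)\\)$", probe))
  has_conc <- lengths(embedded) == 2
  conc[pos & has_conc] <- as.numeric(vapply(embedded[pos & has_conc], `[`, "", 2))
  probe[pos & has_conc] <- sub("\\([0-9.]+\\)$", "", probe[pos & has_conc])
  if (any(pos & !has_conc)) {
    conc[pos & !has_conc] <- POSITIVE_CONCENTRATIONS[seq_len(sum(pos & !has_conc))]
  }
  counts <- matrix(as.integer(count_chr), ncol = 1,
                   dimnames = list(probe, sample_id))
  ncounter_set(counts, tibble::tibble(probe_id = probe, class = cls,
                                      concentration = conc))
}

#' @rdname read_rcc_dialect
#' @param x an [ncounter_set()].
#' @param dir output directory; one file per sample, named `<sample>.rcc`.
#' @return `write_rcc_dialect` invisibly returns the written paths.
#' @export
write_rcc_dialect <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in colnames(x$counts)) {
    probe <- x$probes$probe_id
    name <- ifelse(x$probes$class == "Positive" & !is.na(x$probes$concentration),
                   sprintf("%s(%g)", probe, x$probes$concentration), probe)
    out <- c(
      "<Header>", "FileVersion,1.0", "</Header>",
      "<Lane_Attributes>", paste0("ID,", s), "</Lane_Attributes>",
      "<Code_Summary>", "CodeClass,Name,Accession,Count",
      sprintf("%s,%s,NA,%d", x$probes$class, name,
              as.integer(x$counts[probe, s])),
      "</Code_Summary>")
    p <- file.path(dir, paste0(s, ".rcc"))
    writeLines(out, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read / write a probes-by-samples count table with probe annotation
#'
#' The TSV holds one probe per row (`probe_id` first column, one column per
#' sample); the annotation CSV maps `probe_id` to `class` and optional
#' `concentration`. `write_counts()` then `read_counts()` is the identity.
#'
#' @param path counts TSV path.
#' @param annotation probe annotation CSV path.
#' @return an [ncounter_set()].
#' @export
read_counts <- function(path, annotation) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  ann <- readr::read_csv(annotation, show_col_types = FALSE)
  if (!"concentration" %in% names(ann)) ann$concentration <- NA_real_
  missing <- setdiff(tab$probe_id, ann$probe_id)
  if (length(missing)) {
    abort(paste0("probes missing from annotation: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "mirstage_schema_error")
  }
  counts <- as.matrix(tab[-1])
  rownames(counts) <- tab$probe_id
  if (all(counts == round(counts))) storage.mode(counts) <- "integer"
  ncounter_set(counts, ann[match(tab$probe_id, ann$probe_id), ],
               integer_counts = all(counts == round(counts)))
}

#' @rdname read_counts
#' @param x an [ncounter_set()].
#' @export
write_counts <- function(x, path, annotation) {
  tab <- tibble::as_tibble(x$counts, rownames = "probe_id")
  readr::write_tsv(tab, path)
  readr::write_csv(x$probes, annotation)
  invisible(path)
}

#' Read / write a sample sheet CSV
#' @param path CSV path.
#' @return tibble validated against the sample-sheet schema.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(validate_sample_sheet(sheet), path)
  invisible(path)
}

#' Write / read a full simulated dataset
#'
#' Persists counts (TSV), probe annotation (CSV), sample sheet (CSV) and the
#' simulation truth (JSON sidecar) under one directory; `read_dataset()`
#' restores all four.
#'
#' @param cohort list as returned by [simulate_cohort()].
#' @param dir target directory.
#' @return `read_dataset` returns a list `counts`, `sheet`, `truth`.
#' @export
write_dataset <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts(cohort$counts, file.path(dir, "counts.tsv"),
               file.path(dir, "probes.csv"))
  write_sample_sheet(cohort$sheet, file.path(dir, "samples.csv"))
  write_truth(cohort$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  list(
    counts = read_counts(file.path(dir, "counts.tsv"), file.path(dir, "probes.csv")),
    sheet = read_sample_sheet(file.path(dir, "samples.csv")),
    truth = read_truth(file.path(dir, "truth.json"))
  )
}
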