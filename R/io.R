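#' Read protein chains from a FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) amino-acid FASTA file.
#' @return Named list of [protein_chain()] objects; chain ids are taken from
#'   the first whitespace-delimited token of each FASTA header.
#' @export
read_chains_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  chains <- Map(protein_chain, ids, as.character(seqs))
  names(chains) <- ids
  chains
}

as_peak_list <- function(peaks) {
  stopifnot(is.data.frame(peaks), "mz" %in% names(peaks))
  if (!"intensity" %in% names(peaks)) {
    peaks$intensity <- rep(NA_real_, nrow(peaks))
  }
  peaks <- peaks[, c("mz", "intensity")]
  if (nrow(peaks) && any(!is.finite(peaks$mz) | peaks$mz <= 0)) {
    stop("all m/z values must be positive and finite", call. = FALSE)
  }
  peaks[order(peaks$mz), , drop = FALSE]
}

#' Read a positive-mode peak list (two-column TSV or MGF)
#'
#' TSV files carry m/z in the first column and an optional intensity in the
#' second, with or without a header line. MGF files contribute one peak per
#' `BEGIN IONS` entry, taken from its `PEPMASS=` line (m/z and optional
#' intensity), matching MALDI-TOF usage where each precursor is a singly
#' protonated ion.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"mgf"`.
#' @return data.frame with columns `mz`, `intensity`, sorted by ascending m/z.
#' @export
read_peak_list <- function(path, format = c("auto", "tsv", "mgf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "tsv"
  }
  if (format == "mgf") {
    lines <- readLines(path)
    pep <- grep("^PEPMASS=", lines, value = TRUE)
    fields <- strsplit(sub("^PEPMASS=", "", pep), "[ \t]+")
    df <- data.frame(
      mz = vapply(fields, function(f) as.numeric(f[1L]), numeric(1)),
      intensity = vapply(fields, function(f)
        if (length(f) > 1L) as.numeric(f[2L]) else NA_real_, numeric(1))
    )
    return(as_peak_list(df))
  }
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "[\t ,]+")[[1L]][1L])))
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- data.frame(mz = as.numeric(df[[1L]]),
                    intensity = if (ncol(df) > 1L) as.numeric(df[[2L]])
                                else NA_real_)
  as_peak_list(out)
}

#' Write a peak list to TSV or MGF
#'
#' @param peaks data.frame with columns `mz` and optionally `intensity`.
#' @param path Output path.
#' @param format `"tsv"` or `"mgf"`.
#' @export
write_peak_list <- function(peaks, path, format = c("tsv", "mgf")) {
  format <- match.arg(format)
  peaks <- as_peak_list(peaks)
  if (format == "tsv") {
    utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(peaks))) {
      inten <- if (is.na(peaks$intensity[i])) "" else
        paste0(" ", format(peaks$intensity[i], scientific = FALSE))
      writeLines(c("BEGIN IONS",
                   sprintf("TITLE=peak_%d", i),
                   sprintf("PEPMASS=%.6f%s", peaks$mz[i], inten),
                   "CHARGE=1+",
                   "END IONS"), con)
    }
  }
  invisible(path)
}

#' Write candidate peptides to TSV
#'
#' Citrullination positions are serialized as a semicolon-joined list.
#'
#' @param candidates data.frame from [enumerate_candidates()].
#' @param path Output path.
#' @export
write_candidates <- function(candidates, path) {
  df <- candidates
  df$cit <- vapply(df$cit, cit_key, character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a citrullination-site report to TSV
#'
#' @param sites data.frame from [assign_sites()].
#' @param path Output path.
#' @export
write_site_report <- function(sites, path) {
  df <- sites
  df$peaks <- vapply(df$peaks, function(p) paste(p, collapse = ";"),
                     character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site report written by [write_site_report()]
#'
#' @param path TSV path.
#' @return data.frame with at least `chain_id` and `position`.
#' @export
read_site_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a run comparison as JSON
#'
#' @param comparison A `site_comparison` from [compare_runs()].
#' @param path Output path.
#' @export
write_comparison_json <- function(comparison, path) {
  jsonlite::write_json(unclass(comparison), path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix and its sample-annotation sidecar
#'
#' @param expr_path CSV/TSV of genes (rows, first column = gene id) by
#'   samples (columns), log2 scale.
#' @param design_path CSV/TSV with columns `sample`, `condition`
#'   (`vehicle` / `fibrinogen` / `cit_fibrinogen`) and `donor`.
#' @return List with `expr` (numeric matrix, genes x samples) and `design`
#'   (data.frame).
#' @export
read_expression <- function(expr_path, design_path) {
  sep <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(expr_path, header = TRUE, sep = sep(expr_path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(df[, -1L, drop = FALSE])
  rownames(expr) <- df[[1L]]
  design <- utils::read.table(design_path, header = TRUE,
                              sep = sep(design_path),
                              stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "condition", "donor") %in% names(design)))
  missing <- setdiff(design$sample, colnames(expr))
  if (length(missing)) {
    stop("design samples absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  list(expr = expr[, design$sample, drop = FALSE], design = design)
}
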