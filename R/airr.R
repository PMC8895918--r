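#' Column mapping between internal and AIRR rearrangement names
#'
#' Clone tables use short internal column names; on disk they are AIRR
#' Rearrangement TSVs. The mapping is a named character vector from internal
#' name to file column name and can be overridden to consume tables from
#' other clone callers.
#'
#' @return Named character vector (internal -> AIRR column).
#' @export
airr_default_mapping <- function() {
  c(v_gene = "v_call", d_gene = "d_call", j_gene = "j_call",
    cdr3_nt = "junction", cdr3_aa = "junction_aa",
    count = "duplicate_count")
}

#' Read an AIRR rearrangement TSV into a clone table
#'
#' Reads a tab-separated rearrangement file and renames the mapped columns to
#' the internal names used throughout the package (`v_gene`, `d_gene`,
#' `j_gene`, `cdr3_nt`, `cdr3_aa`, `count`). Unmapped columns (sample
#' metadata such as `sample_id`, `mouse_id`, `strain`, `tissue`, `batch`,
#' `isotype`) pass through unchanged.
#'
#' @param path Path to a TSV file.
#' @param mapping Named character vector, internal name -> file column; see
#'   [airr_default_mapping()].
#' @return A tibble clone table.
#' @export
read_airr <- function(path, mapping = airr_default_mapping()) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  present <- mapping[mapping %in% names(tab)]
  missing <- setdiff(mapping, names(tab))
  if (length(missing) > 0 && any(c("junction", "junction_aa") %in% missing)) {
    abort(sprintf(
      "required column(s) missing from %s: %s (check the column mapping)",
      basename(path), paste(missing, collapse = ", ")))
  }
  names(tab)[match(present, names(tab))] <- names(present)
  if ("d_gene" %in% names(tab)) {
    # an absent D segment is written as an empty d_call
    tab$d_gene[is.na(tab$d_gene)] <- ""
  }
  if ("count" %in% names(tab)) {
    tab$count <- as.integer(tab$count)
  } else {
    tab$count <- 1L
  }
  tab
}

#' Write a clone table as an AIRR rearrangement TSV
#'
#' Inverse of [read_airr()]: internal columns are renamed through the
#' mapping and the table is written tab-separated. Reading the file back
#' with the same mapping reproduces the table.
#'
#' @param clones Clone table.
#' @param path Output path.
#' @param mapping Named character vector, internal name -> file column.
#' @return `path`, invisibly.
#' @export
write_airr <- function(clones, path, mapping = airr_default_mapping()) {
  stopifnot(is.data.frame(clones))
  out <- clones
  present <- mapping[names(mapping) %in% names(out)]
  names(out)[match(names(present), names(out))] <- unname(present)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read sequences from a FASTQ file
#'
#' Thin wrapper returning the read sequences of a (possibly gzipped) FASTQ
#' file as a named character vector, for isotype demultiplexing.
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTQ file
#'
#' Writes reads with uniform maximum base quality; used by the read
#' simulator.
#'
#' @param seqs Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n) {
    paste(rep("I", n), collapse = "")
  }, character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(x, Biostrings::PhredQuality(q))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
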