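#' Isotype-specific primer sets
#'
#' A primer set describes how raw reads are assigned to antibody isotypes:
#' each entry pairs an isotype label with the constant-region primer expected
#' at a fixed position of the read, and classification compares a prefix
#' window of the read against every primer by positional (Hamming) mismatch
#' counting. Degenerate IUPAC codes in a primer (e.g. `S`, `Y`) match any of
#' the bases they stand for.
#'
#' `primers_inhouse()` returns the IgA/IgG/IgM second-round PCR primers used
#' for 5'RACE mouse IgH libraries, compared over the first 20 nt of read 1
#' with reads assigned when fewer than 5 mismatches separate them from the
#' closest primer. `primers_public()` returns the single IgM primer variant
#' used for multi-primer public datasets, compared over 20 nt of read 2 with
#' a fewer-than-6-mismatch cut-off.
#'
#' @param entries Named character vector of primer sequences; names are
#'   isotype labels (e.g. `c(IgM = "AAGACATTTGGG...")`).
#' @param max_mismatch Strict upper bound on tolerated mismatches: a read is
#'   assignable to a primer only when its mismatch count is strictly less
#'   than `max_mismatch`.
#' @param window_len Number of bases from the start of the read compared
#'   against each primer. Primers longer than the window are compared over
#'   their first `window_len` bases.
#' @param read_end Which mate the window is taken from (`"R1"` or `"R2"`);
#'   informational, used by the simulator and pipeline.
#'
#' @return An object of class `primer_set`.
#' @examples
#' ps <- primers_inhouse()
#' classify_isotype("AAGACATTTGGGAAGGACTG", ps)  # exact IgM match
#' @export
primer_set <- function(entries, max_mismatch, window_len = 20L,
                       read_end = c("R1", "R2")) {
  read_end <- match.arg(read_end)
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    abort("`entries` must be a named character vector (names are isotype labels)")
  }
  entries <- toupper(entries)
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", entries)
  if (any(bad)) {
    abort(paste0("primer sequences must be IUPAC nucleotide codes: ",
                 paste(names(entries)[bad], collapse = ", ")))
  }
  window_len <- as.integer(window_len)
  max_mismatch <- as.integer(max_mismatch)
  if (max_mismatch < 1L || max_mismatch >= window_len) {
    abort("`max_mismatch` must be in [1, window_len)")
  }
  structure(
    list(entries = entries, max_mismatch = max_mismatch,
         window_len = window_len, read_end = read_end),
    class = "primer_set"
  )
}

#' @rdname primer_set
#' @export
primers_inhouse <- function() {
  primer_set(
    c(IgG = "TAGACAGATGGGGSTGTYGTT",
      IgM = "AAGACATTTGGGAAGGACTG",
      IgA = "GTCAGTGGGTAGATGGTGGG"),
    max_mismatch = 5L, window_len = 20L, read_end = "R1"
  )
}

#' @rdname primer_set
#' @export
primers_public <- function() {
  primer_set(c(IgM = "CGAGGGGGAAGACATTTGGG"),
             max_mismatch = 6L, window_len = 20L, read_end = "R2")
}

#' @export
print.primer_set <- function(x, ...) {
  cat("Isotype primer set (", x$read_end, ", window ", x$window_len,
      " nt, < ", x$max_mismatch, " mismatches)\n", sep = "")
  for (i in seq_along(x$entries)) {
    cat(" ", format(names(x$entries)[i], width = 4), x$entries[[i]], "\n")
  }
  invisible(x)
}

# Mismatch counts of each read prefix against one primer (IUPAC-aware on the
# primer side; any read character outside the primer's allowed set, including
# N, counts as a mismatch).
primer_mismatch_counts <- function(reads, primer, window_len) {
  span <- min(nchar(primer), window_len)
  allowed <- IUPAC_BASES[strsplit(substr(primer, 1L, span), "")[[1]]]
  pref <- substr(reads, 1L, span)
  mat <- seq_matrix(pref)
  mm <- integer(length(reads))
  for (j in seq_len(span)) {
    mm <- mm + !(mat[, j] %in% allowed[[j]])
  }
  mm
}

#' Classify reads into isotypes by primer matching
#'
#' Compares the first `window_len` bases of each read against every primer in
#' the set and assigns the isotype whose primer has the fewest mismatches,
#' provided that count is strictly below the set's `max_mismatch`. Reads that
#' meet no primer under the threshold, tie between two isotypes, or are
#' shorter than the comparison window are returned as `"unassigned"`.
#'
#' @param reads Character vector of read sequences (or read prefixes).
#' @param primers A [primer_set].
#' @return Character vector of isotype labels, `"unassigned"` where no
#'   unambiguous assignment exists.
#' @examples
#' classify_isotype(c("AAGACATTTGGGAAGGACTGCCC", "ACGTACGTACGTACGTACGT"),
#'                  primers_inhouse())
#' @export
classify_isotype <- function(reads, primers) {
  stopifnot(inherits(primers, "primer_set"))
  reads <- toupper(reads)
  out <- rep("unassigned", length(reads))
  ok <- nchar(reads) >= primers$window_len
  if (any(!ok)) {
    warn(sprintf("%d read(s) shorter than the %d nt comparison window left unassigned",
                 sum(!ok), primers$window_len))
  }
  if (!any(ok)) return(out)
  mm <- vapply(primers$entries, primer_mismatch_counts,
               integer(sum(ok)), reads = reads[ok],
               window_len = primers$window_len)
  mm <- matrix(mm, nrow = sum(ok),
               dimnames = list(NULL, names(primers$entries)))
  best <- apply(mm, 1L, min)
  hit <- best < primers$max_mismatch
  # ties between two primers both under threshold are discarded as ambiguous
  n_best <- rowSums(mm == best)
  assign_ok <- hit & n_best == 1L
  label <- colnames(mm)[apply(mm, 1L, which.min)]
  res <- rep("unassigned", sum(ok))
  res[assign_ok] <- label[assign_ok]
  out[ok] <- res
  out
}

#' Trim the synthesis overhang preceding a primer
#'
#' Removes every base before the primer start position, so the returned read
#' begins at the primer. Positions are 1-based; a position of 1 returns the
#' read unchanged. Reads whose primer was not located (`NA` position) are
#' returned untrimmed and flagged in the `"untrimmed"` attribute so callers
#' can route them to `"unassigned"`.
#'
#' @param reads Character vector of reads.
#' @param primer_location Integer vector (recycled) of 1-based primer start
#'   positions; `NA` marks reads where the primer was not found.
#' @return Character vector of trimmed reads with attribute `untrimmed`, a
#'   logical vector marking reads left untouched because the primer was
#'   missing.
#' @seealso [locate_primer()]
#' @export
trim_overhang <- function(reads, primer_location) {
  primer_location <- rep_len(as.integer(primer_location), length(reads))
  missing <- is.na(primer_location) | primer_location < 1L |
    primer_location > nchar(reads)
  out <- reads
  out[!missing] <- substring(reads[!missing], primer_location[!missing])
  attr(out, "untrimmed") <- missing
  out
}

#' Locate a primer within reads by sliding mismatch search
#'
#' Slides the primer along each read and reports the 1-based offset with the
#' fewest mismatches, or `NA` when no offset achieves fewer than
#' `max_mismatch` mismatches. Ties resolve to the leftmost best offset.
#'
#' @param reads Character vector of reads.
#' @param primer Single primer sequence (IUPAC codes allowed).
#' @param max_mismatch Strict mismatch bound for accepting a location.
#' @return Integer vector of primer start positions (`NA` = not found).
#' @export
locate_primer <- function(reads, primer, max_mismatch) {
  primer <- toupper(primer)
  allowed <- IUPAC_BASES[strsplit(primer, "")[[1]]]
  plen <- length(allowed)
  vapply(toupper(reads), function(r) {
    n <- nchar(r)
    if (n < plen) return(NA_integer_)
    chars <- strsplit(r, "")[[1]]
    best_pos <- NA_integer_
    best_mm <- max_mismatch
    for (start in seq_len(n - plen + 1L)) {
      mm <- 0L
      for (j in seq_len(plen)) {
        if (!(chars[start + j - 1L] %in% allowed[[j]])) mm <- mm + 1L
        if (mm >= best_mm) break
      }
      if (mm < best_mm) {
        best_mm <- mm
        best_pos <- start
        if (mm == 0L) break
      }
    }
    best_pos
  }, integer(1), USE.NAMES = FALSE)
}

#' Filter clone tables down to qualified clones
#'
#' Applies the qualified-clone rules to a rearrangement table: the CDR3 amino
#' acid sequence must be at least 4 aa, contain no stop (`*`) or frame-break
#' (`_`) symbol, the CDR3 nucleotide length must equal three times the amino
#' acid length (in-frame), and the clone abundance must be a positive count.
#' Rows failing any rule are dropped and tallied by the first failing reason.
#' The filter is idempotent: filtering an already-filtered table drops
#' nothing.
#'
#' @param clones Data frame with at least `cdr3_nt`, `cdr3_aa` and `count`
#'   columns (a missing `count` column is treated as 1 per row).
#' @param min_aa_len Minimum CDR3 amino-acid length (default 4).
#' @return The qualified subset as a tibble, with attribute `drop_counts`, a
#'   named integer vector of dropped-row tallies by reason
#'   (`missing_cdr3`, `short_cdr3`, `stop_codon`, `out_of_frame`,
#'   `bad_count`).
#' @examples
#' tab <- tibble::tibble(
#'   cdr3_nt = c("TGTGCAAGATGG", "TGTGCAAGA", "TGTGCAAGATG"),
#'   cdr3_aa = c("CARW", "CAR", "CARW"),
#'   count   = c(3L, 1L, 2L))
#' qualified <- filter_qualified(tab)
#' attr(qualified, "drop_counts")
#' @export
filter_qualified <- function(clones, min_aa_len = 4L) {
  stopifnot(is.data.frame(clones))
  clones <- tibble::as_tibble(clones)
  if (!all(c("cdr3_nt", "cdr3_aa") %in% names(clones))) {
    abort("`clones` must have `cdr3_nt` and `cdr3_aa` columns")
  }
  if (!"count" %in% names(clones)) clones$count <- 1L
  nt <- as.character(clones$cdr3_nt)
  aa <- as.character(clones$cdr3_aa)
  cnt <- suppressWarnings(as.numeric(clones$count))

  missing_cdr3 <- is.na(nt) | is.na(aa) | !nzchar(nt) | !nzchar(aa)
  short_cdr3 <- !missing_cdr3 & nchar(aa) < min_aa_len
  stop_codon <- !missing_cdr3 & !short_cdr3 & grepl("[*_]", aa)
  out_of_frame <- !missing_cdr3 & !short_cdr3 & !stop_codon &
    nchar(nt) != 3L * nchar(aa)
  bad_count <- !missing_cdr3 & !short_cdr3 & !stop_codon & !out_of_frame &
    (is.na(cnt) | cnt < 1)

  keep <- !(missing_cdr3 | short_cdr3 | stop_codon | out_of_frame | bad_count)
  res <- clones[keep, , drop = FALSE]
  drop_counts <- c(
    missing_cdr3 = sum(missing_cdr3), short_cdr3 = sum(short_cdr3),
    stop_codon = sum(stop_codon), out_of_frame = sum(out_of_frame),
    bad_count = sum(bad_count)
  )
  if (sum(drop_counts) > 0) {
    inform(sprintf("filter_qualified: dropped %d of %d rows (%s)",
                   sum(drop_counts), nrow(clones),
                   paste(names(drop_counts)[drop_counts > 0],
                         drop_counts[drop_counts > 0],
                         sep = "=", collapse = ", ")))
  }
  attr(res, "drop_counts") <- drop_counts
  res
}

#' Select one member of a technical-replicate pair
#'
#' When a sample was sequenced in technical duplicate, downstream statistics
#' use only the replicate with the larger value of the chosen criterion
#' (number of clones, i.e. summed abundance, or number of unique CDR3 aa
#' clonotypes). Exact ties resolve to the lexicographically smallest
#' replicate name for determinism.
#'
#' @param replicates Named list of clone tables (one per technical
#'   replicate). Names act as the sample identifiers used for tie-breaking;
#'   unnamed lists fall back to a `sample_id` column, then list position.
#' @param criterion `"clones"` (summed `count`) or `"clonotypes"` (unique
#'   `cdr3_aa`).
#' @return The selected clone table, with attribute `selected` giving its
#'   name.
#' @export
select_technical_duplicate <- function(replicates,
                                       criterion = c("clones", "clonotypes")) {
  criterion <- match.arg(criterion)
  if (!is.list(replicates) || length(replicates) == 0) {
    abort("`replicates` must be a nonempty list of clone tables")
  }
  ids <- names(replicates)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- vapply(seq_along(replicates), function(i) {
      tab <- replicates[[i]]
      if (is.data.frame(tab) && "sample_id" %in% names(tab) && nrow(tab) > 0) {
        as.character(tab$sample_id[1])
      } else {
        sprintf("replicate_%03d", i)
      }
    }, character(1))
  }
  score <- vapply(replicates, function(tab) {
    if (!is.data.frame(tab)) abort("each replicate must be a data frame")
    if (criterion == "clones") {
      if ("count" %in% names(tab)) sum(tab$count) else nrow(tab)
    } else {
      length(unique(tab$cdr3_aa))
    }
  }, numeric(1))
  best <- which(score == max(score))
  pick <- best[order(ids[best])][1]
  out <- replicates[[pick]]
  attr(out, "selected") <- ids[pick]
  out
}
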