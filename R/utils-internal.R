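# Internal helpers shared across modules. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom rlang abort warn inform
NULL

# IUPAC nucleotide codes -> the set of concrete bases each code stands for.
# Primers may carry degenerate positions (e.g. S = G/C); reads are expected
# to be concrete ACGTN.
IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Standard genetic code (DNA codons). A fixed biological constant.
GENETIC_CODE_DNA <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

CODONS_NO_STOP <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA != "*"]

# Translate in-frame DNA strings to amino acids (vectorized).
translate_nt <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s)
    if (n %% 3L != 0L) {
      abort("sequence length is not a multiple of 3; cannot translate in frame")
    }
    codons <- substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
    aa <- GENETIC_CODE_DNA[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# One draw from a symmetric Dirichlet via normalized gammas.
rdirichlet1 <- function(k, concentration) {
  g <- stats::rgamma(k, shape = concentration, rate = 1)
  if (sum(g) <= 0) g <- rep(1, k)
  g / sum(g)
}

# Hamming mismatch count between two equal-length strings.
str_mismatches <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Split equal-length sequences into an n x L character matrix.
seq_matrix <- function(seqs) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

is_count_vector <- function(x) {
  is.numeric(x) && length(x) > 0 && all(is.finite(x)) && all(x > 0)
}
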