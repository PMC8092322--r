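#' The standard nuclear genetic code over RNA codons
#'
#' Returns the standard genetic code as a named character vector mapping the 64
#' RNA codons to one-letter amino-acid symbols, with `"*"` for the three stop
#' codons. The table is taken from [Biostrings::GENETIC_CODE] and re-keyed to
#' the RNA alphabet; mitochondrial and other alternative codes are out of
#' scope.
#'
#' @return Named character vector of length 64 (names are RNA codons).
#' @examples
#' code <- genetic_code()
#' sum(code != "*") # 61 sense codons
#' @export
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), chartr("T", "U", names(gc)))
}

#' @rdname genetic_code
#' @param code a genetic code as returned by [genetic_code()].
#' @export
stop_codons <- function(code = genetic_code()) names(code)[code == "*"]

#' @rdname genetic_code
#' @export
sense_codons <- function(code = genetic_code()) names(code)[code != "*"]

RNA_BASES <- c("A", "C", "G", "U")

#' Normalise a nucleotide string to the RNA alphabet
#'
#' DNA input (`T`/`t`) is converted to `U` on ingest; all internal sequence in
#' this package is uppercase RNA.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over `{A,C,G,U}` (unvalidated).
#' @export
normalize_rna <- function(x) chartr("Ttacgu", "UUACGU", x)

.assert_rna <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]), RNA_BASES)
  if (length(bad) > 0L) {
    stop("invalid alphabet in ", what, ": non-RNA character(s) ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of RNA strings
#'
#' @param x character vector of RNA strings (after [normalize_rna()]).
#' @return character vector of reverse complements.
#' @export
rna_revcomp <- function(x) {
  x <- normalize_rna(x)
  .assert_rna(x)
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

.rna_complement_base <- function(b) c(A = "U", C = "G", G = "C", U = "A")[b]

#' Decode an anticodon into its codon and amino acid
#'
#' The codon read by a tRNA is the reverse complement of its anticodon
#' (antiparallel pairing); the amino acid is looked up in the genetic code.
#' Anticodons whose reverse-complement codon is a stop codon are flagged
#' (`is_stop = TRUE`) rather than silently decoded.
#'
#' @param anticodon 3-mer RNA (or DNA) string, wobble base first (position 34).
#' @param code genetic code from [genetic_code()].
#' @return list with `anticodon`, `codon`, `aa` (one-letter symbol, `"*"` for a
#'   stop-decoding anticodon) and `is_stop`.
#' @examples
#' decode_anticodon("CGU") # codon ACG, Thr
#' @export
decode_anticodon <- function(anticodon, code = genetic_code()) {
  anticodon <- normalize_rna(anticodon)
  if (length(anticodon) != 1L || nchar(anticodon) != 3L) {
    stop("anticodon must be a single 3-mer", call. = FALSE)
  }
  .assert_rna(anticodon, "anticodon")
  codon <- rna_revcomp(anticodon)
  aa <- unname(code[[codon]])
  list(anticodon = anticodon, codon = codon, aa = aa, is_stop = identical(aa, "*"))
}

AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q", Glu = "E",
  Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K", Met = "M", Phe = "F",
  Pro = "P", Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  iMet = "M", eMet = "M", fMet = "M", SeC = "U", Sup = "*", Und = "*"
)

AA_ONE_TO_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln", E = "Glu",
  G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys", M = "Met", F = "Phe",
  P = "Pro", S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val", `*` = "Sup"
)

AA_FULL_NAME <- c(
  A = "Alanine", R = "Arginine", N = "Asparagine", D = "Aspartate",
  C = "Cysteine", Q = "Glutamine", E = "Glutamate", G = "Glycine",
  H = "Histidine", I = "Isoleucine", L = "Leucine", K = "Lysine",
  M = "Methionine", F = "Phenylalanine", P = "Proline", S = "Serine",
  T = "Threonine", W = "Tryptophan", Y = "Tyrosine", V = "Valine",
  `*` = "Stop"
)
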