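#' Construct a tRNA gene record
#'
#' A `trna_gene` bundles a tRNA gene's identifier (gtRNAdb-style), its RNA
#' sequence, an optional dot-bracket secondary structure, and an optional
#' genomic location (0-based half-open interval with strand, the BED
#' convention).
#'
#' @param gene_id gene identifier; gtRNAdb dash dialect (`"tRNA-Thr-CGT-1-1"`)
#'   or locus-style (`"tK(CUU)K"`) identifiers are parsed for isotype and
#'   anticodon where possible.
#' @param sequence nucleotide string; DNA `T` is normalised to RNA `U`.
#' @param structure optional dot-bracket string, same length as `sequence`.
#' @param chrom,start,end optional genomic interval (0-based half-open).
#' @param strand `"+"` or `"-"` when a location is given.
#' @param species_tag free-text provenance tag.
#' @param validate enforce the length invariant (60-100 nt) and structure
#'   checks; disable only for deliberately degenerate test inputs.
#' @return object of class `trna_gene`.
#' @export
trna_gene <- function(gene_id, sequence, structure = NULL, chrom = NA_character_,
                      start = NA_integer_, end = NA_integer_, strand = NA_character_,
                      species_tag = "", validate = TRUE) {
  sequence <- normalize_rna(sequence)
  .assert_rna(sequence, paste0("sequence of ", gene_id))
  if (validate) {
    n <- nchar(sequence)
    if (n < 60L || n > 100L) {
      stop("sequence of ", gene_id, " has length ", n,
           "; tRNA genes must be 60-100 nt", call. = FALSE)
    }
  }
  if (!is.null(structure)) {
    if (nchar(structure) != nchar(sequence)) {
      stop("structure and sequence of ", gene_id, " differ in length", call. = FALSE)
    }
    parse_cloverleaf(sequence, structure)  # errors on unbalanced brackets
  }
  if (!is.na(chrom) && !is.na(start) && !is.na(end)) {
    if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
    if (end - start != nchar(sequence)) {
      stop("location length of ", gene_id, " (", end - start,
           ") does not equal sequence length (", nchar(sequence), ")", call. = FALSE)
    }
  }
  hdr <- parse_gene_id(gene_id)
  structure(
    list(gene_id = gene_id, sequence = sequence, structure = structure,
         annotated_isotype = hdr$aa, header_anticodon = hdr$anticodon,
         chrom = chrom, start = start, end = end, strand = strand,
         species_tag = species_tag),
    class = "trna_gene"
  )
}

#' @export
print.trna_gene <- function(x, ...) {
  cat("<trna_gene>", x$gene_id, "\n")
  cat("  sequence  (", nchar(x$sequence), " nt): ", x$sequence, "\n", sep = "")
  if (!is.null(x$structure)) cat("  structure          : ", x$structure, "\n", sep = "")
  if (!is.na(x$chrom)) {
    cat("  location : ", x$chrom, ":", x$start, "-", x$end, " (", x$strand, ")\n", sep = "")
  }
  invisible(x)
}

#' Parse isotype and anticodon out of a tRNA gene identifier
#'
#' Understands the gtRNAdb dash dialect (`tRNA-<Isotype>-<Anticodon>-...`,
#' second and third dash-separated tokens) and the budding-yeast locus dialect
#' (`t<X>(<anticodon>)<chromosome>` with a one-letter isotype). Unparseable
#' identifiers return `NULL` fields; callers then fall back to structure-based
#' anticodon localisation.
#'
#' @param gene_id identifier string.
#' @return list with `aa` (one-letter isotype or `NA`) and `anticodon`
#'   (RNA 3-mer or `NA`).
#' @export
parse_gene_id <- function(gene_id) {
  # gtRNAdb dash dialect: tRNA-Thr-CGT-1-1
  m <- regmatches(gene_id, regexec("^tRNA-([A-Za-z]{3,4})-([ACGTUacgtu]{3})(-|$)", gene_id))[[1]]
  if (length(m) > 0L) {
    aa3 <- m[2]
    aa <- unname(AA_THREE_TO_ONE[aa3])
    return(list(aa = if (is.null(aa) || is.na(aa)) NA_character_ else aa,
                anticodon = normalize_rna(m[3])))
  }
  # locus dialect: tK(CUU)K, tT(AGU)H
  m <- regmatches(gene_id, regexec("^t([A-Z])\\(([ACGTUacgtu]{3})\\)", gene_id))[[1]]
  if (length(m) > 0L) {
    return(list(aa = m[2], anticodon = normalize_rna(m[3])))
  }
  list(aa = NA_character_, anticodon = NA_character_)
}

#' Read a tRNA gene pool from FASTA (with optional structure sidecar)
#'
#' Headers are preserved verbatim as gene identifiers. The optional sidecar
#' file contains one dot-bracket line per FASTA record, in the same order.
#'
#' @param fasta path to a FASTA file of tRNA gene sequences.
#' @param structures optional path to a sidecar dot-bracket file.
#' @param ... passed to [trna_gene()] (e.g. `validate = FALSE`).
#' @return list of [trna_gene()] objects.
#' @export
read_trna_fasta <- function(fasta, structures = NULL, ...) {
  seqs <- Biostrings::readBStringSet(fasta)
  structs <- NULL
  if (!is.null(structures)) {
    structs <- readLines(structures)
    structs <- structs[nzchar(structs) & !startsWith(structs, "#")]
    if (length(structs) != length(seqs)) {
      stop("structure sidecar has ", length(structs), " records but FASTA has ",
           length(seqs), call. = FALSE)
    }
  }
  lapply(seq_along(seqs), function(i) {
    trna_gene(names(seqs)[i], as.character(seqs[[i]]),
              structure = if (is.null(structs)) NULL else structs[i], ...)
  })
}

#' Write a tRNA gene pool to FASTA (with optional structure sidecar)
#'
#' @param pool list of [trna_gene()] objects.
#' @param fasta output FASTA path.
#' @param structures optional output path for the dot-bracket sidecar (one
#'   line per record, FASTA order). Records without a structure get an
#'   all-dots placeholder.
#' @return `fasta`, invisibly.
#' @export
write_trna_fasta <- function(pool, fasta, structures = NULL) {
  seqs <- Biostrings::BStringSet(vapply(pool, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(pool, `[[`, character(1), "gene_id")
  Biostrings::writeXStringSet(seqs, fasta, width = 120L)
  if (!is.null(structures)) {
    lines <- vapply(pool, function(g) {
      if (is.null(g$structure)) strrep(".", nchar(g$sequence)) else g$structure
    }, character(1))
    writeLines(lines, structures)
  }
  invisible(fasta)
}
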