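#' Genomic coordinates of a tRNA gene's anticodon bases
#'
#' Maps the 1-based transcript positions of the anticodon onto 1-based genomic
#' positions. On the minus strand, transcript order maps to descending genomic
#' coordinates and allele comparison must use the reverse complement.
#' Intron-containing genes are not supported (the mapping assumes a contiguous
#' gene body).
#'
#' @param gene a [trna_gene()] with a genomic location.
#' @param call anticodon call; located automatically when omitted.
#' @return integer vector of 3 genomic positions (1-based), in transcript
#'   (anticodon 5'-to-3') order.
#' @export
anticodon_genomic_coordinates <- function(gene, call = locate_anticodon(gene)) {
  if (is.na(gene$chrom) || is.na(gene$start) || is.na(gene$end)) {
    stop("gene ", gene$gene_id, " has no genomic location", call. = FALSE)
  }
  span <- call$span  # 1-based transcript positions
  if (gene$strand == "+") {
    gene$start + span        # start is 0-based; result is 1-based
  } else {
    gene$end - span + 1L
  }
}

#' Read tRNA gene annotations from a BED file
#'
#' Standard 6-column BED (0-based half-open, strand in column 6), read through
#' [rtracklayer::import()]. Sequences are attached from a matching gene pool
#' (by name) or extracted from a genome FASTA (reverse-complemented on the
#' minus strand).
#'
#' @param bed path to the BED file.
#' @param pool optional list of [trna_gene()] objects supplying sequences and
#'   structures by gene id.
#' @param genome optional path to a genome FASTA used to extract sequences
#'   when `pool` is not given.
#' @return list of [trna_gene()] objects with locations.
#' @export
read_trna_bed <- function(bed, pool = NULL, genome = NULL) {
  gr <- rtracklayer::import(bed, format = "BED")
  byid <- if (!is.null(pool)) {
    stats::setNames(pool, vapply(pool, `[[`, character(1), "gene_id"))
  }
  gen <- if (is.null(pool)) {
    if (is.null(genome)) stop("need either a gene pool or a genome FASTA", call. = FALSE)
    Biostrings::readDNAStringSet(genome)
  }
  if (!is.null(gen)) names(gen) <- sub("\\s.*$", "", names(gen))
  lapply(seq_along(gr), function(i) {
    g <- gr[i]
    id <- g$name
    chrom <- as.character(GenomicRanges::seqnames(g))
    start0 <- GenomicRanges::start(g) - 1L   # GRanges is 1-based
    end <- GenomicRanges::end(g)
    strand <- as.character(GenomicRanges::strand(g))
    if (!is.null(byid)) {
      src <- byid[[id]]
      if (is.null(src)) stop("BED gene ", id, " not present in pool", call. = FALSE)
      trna_gene(id, src$sequence, structure = src$structure, chrom = chrom,
                start = start0, end = end, strand = strand)
    } else {
      seq <- Biostrings::subseq(gen[[chrom]], start0 + 1L, end)
      if (strand == "-") seq <- Biostrings::reverseComplement(seq)
      trna_gene(id, as.character(seq), chrom = chrom, start = start0,
                end = end, strand = strand)
    }
  })
}

#' Scan a multi-sample variant set for anticodon substitutions
#'
#' Reports every single-nucleotide substitution whose genomic position falls
#' on an anticodon base of an annotated tRNA gene, with the reference and
#' mutated anticodon, the decoded amino-acid change, and the carrier samples.
#' Multi-allelic records are decomposed; indels are logged and skipped;
#' records on chromosomes absent from the annotation are skipped with a
#' warning. A sample is a carrier when its genotype contains at least
#' `min_allele_count` copies of the alternate allele (so `1` counts
#' heterozygous carriers, `2` only homozygous ones). Synonymous anticodon
#' changes are retained and flagged, never dropped.
#'
#' @param vcf path to a VCF (v4.x) file, or a `vcfR` object.
#' @param genes list of [trna_gene()] objects with genomic locations (e.g.
#'   from [read_trna_bed()]).
#' @param min_allele_count minimum alternate-allele count per sample for
#'   carrier status.
#' @param include_uncarried keep events carried by no sample (default drops
#'   them when the VCF has genotype columns; a VCF without samples always
#'   reports all events).
#' @param code genetic code.
#' @return data.frame of `AnticodonVariant` rows (`gene_id`, `chrom`, `pos`,
#'   `transcript_pos`, `anticodon_offset`, `ref`, `alt` (genomic),
#'   `ref_anticodon`, `alt_anticodon`, `ref_aa`, `alt_aa`, `synonymous`,
#'   `to_stop`, `carrier_samples` comma-joined, `n_carriers`), with a
#'   `skipped` attribute listing indel and mismatch records.
#' @export
scan_variants <- function(vcf, genes, min_allele_count = 1L,
                          include_uncarried = FALSE, code = genetic_code()) {
  v <- if (inherits(vcf, "vcfR")) vcf else vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- if (ncol(v@gt) > 1L) v@gt[, -1L, drop = FALSE] else NULL
  if (!is.null(gt) && nrow(fix) == 1L && is.null(dim(gt))) {
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, colnames(v@gt)[-1L]))
  }

  # map (chrom, genomic pos) -> (gene index, anticodon offset)
  calls <- lapply(genes, locate_anticodon)
  keymap <- new.env(parent = emptyenv())
  for (i in seq_along(genes)) {
    gpos <- anticodon_genomic_coordinates(genes[[i]], calls[[i]])
    for (k in 1:3) {
      assign(paste0(genes[[i]]$chrom, ":", gpos[k]), c(i, k), envir = keymap)
    }
  }
  known_chroms <- unique(vapply(genes, `[[`, character(1), "chrom"))

  rows <- list()
  skipped_indels <- list()
  n_chrom_mismatch <- 0L
  n_ref_mismatch <- 0L

  for (r in seq_len(nrow(fix))) {
    chrom <- fix[r, "CHROM"]; pos <- as.integer(fix[r, "POS"])
    ref <- fix[r, "REF"]
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    if (!chrom %in% known_chroms) {
      n_chrom_mismatch <- n_chrom_mismatch + 1L
      next
    }
    for (ai in seq_along(alts)) {
      alt <- alts[ai]
      if (nchar(ref) != 1L || nchar(alt) != 1L || !alt %in% c("A", "C", "G", "T")) {
        skipped_indels[[length(skipped_indels) + 1L]] <- data.frame(
          chrom = chrom, pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
        next
      }
      hit <- mget(paste0(chrom, ":", pos), envir = keymap, ifnotfound = list(NULL))[[1]]
      if (is.null(hit)) next
      gene <- genes[[hit[1]]]; call <- calls[[hit[1]]]; offset <- hit[2]
      # transcript-oriented alleles
      tref <- normalize_rna(ref); talt <- normalize_rna(alt)
      if (gene$strand == "-") {
        tref <- .rna_complement_base(tref)
        talt <- .rna_complement_base(talt)
      }
      have <- substr(call$anticodon, offset, offset)
      if (have != tref) {
        n_ref_mismatch <- n_ref_mismatch + 1L
        warning("REF allele at ", chrom, ":", pos, " does not match the ",
                gene$gene_id, " anticodon base (", have, " vs ", tref, "); skipped",
                call. = FALSE)
        next
      }
      alt_anticodon <- call$anticodon
      substr(alt_anticodon, offset, offset) <- talt
      dec_ref <- decode_anticodon(call$anticodon, code)
      dec_alt <- decode_anticodon(alt_anticodon, code)
      carriers <- character(0)
      if (!is.null(gt)) {
        gfield <- sub(":.*$", "", gt[r, ])
        n_alt <- vapply(strsplit(gfield, "[/|]"), function(a) sum(a == ai), integer(1))
        carriers <- colnames(gt)[n_alt >= min_allele_count]
        if (length(carriers) == 0L && !include_uncarried) next
      }
      tpos <- if (gene$strand == "+") pos - gene$start else gene$end - pos + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene$gene_id, chrom = chrom, pos = pos,
        transcript_pos = as.integer(tpos), anticodon_offset = offset,
        ref = ref, alt = alt,
        ref_anticodon = call$anticodon, alt_anticodon = alt_anticodon,
        ref_aa = dec_ref$aa, alt_aa = dec_alt$aa,
        synonymous = dec_ref$aa == dec_alt$aa, to_stop = dec_alt$is_stop,
        carrier_samples = paste(carriers, collapse = ","),
        n_carriers = length(carriers), stringsAsFactors = FALSE)
    }
  }
  if (n_chrom_mismatch > 0L && n_chrom_mismatch == nrow(fix)) {
    # every record is on a chromosome the annotation has never heard of:
    # almost certainly a naming-convention mismatch, not sparse annotation
    warning("all ", n_chrom_mismatch, " VCF record(s) are on chromosomes ",
            "absent from the annotation; check chromosome naming", call. = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else data.frame(
    gene_id = character(0), chrom = character(0), pos = integer(0),
    transcript_pos = integer(0), anticodon_offset = integer(0),
    ref = character(0), alt = character(0), ref_anticodon = character(0),
    alt_anticodon = character(0), ref_aa = character(0), alt_aa = character(0),
    synonymous = logical(0), to_stop = logical(0),
    carrier_samples = character(0), n_carriers = integer(0),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- list(
    indels = if (length(skipped_indels) > 0L) do.call(rbind, skipped_indels)
             else data.frame(chrom = character(0), pos = integer(0),
                             ref = character(0), alt = character(0)),
    chrom_mismatch = n_chrom_mismatch, ref_mismatch = n_ref_mismatch)
  out
}

.rename_gene_id <- function(gene_id, alt_anticodon, alt_aa) {
  # locus dialect: tK(CUU)K -> tT(CGU)K
  m <- regexec("^t([A-Z])\\(([ACGTUacgtu]{3})\\)(.*)$", gene_id)
  g <- regmatches(gene_id, m)[[1]]
  if (length(g) > 0L) {
    return(sprintf("t%s(%s)%s", alt_aa, alt_anticodon, g[4]))
  }
  # gtRNAdb dash dialect: tRNA-Lys-CTT-1-1 -> tRNA-Thr-CGT-1-1
  parts <- strsplit(gene_id, "-", fixed = TRUE)[[1]]
  if (length(parts) >= 3L && parts[1] == "tRNA") {
    parts[2] <- unname(AA_ONE_TO_THREE[alt_aa])
    parts[3] <- chartr("U", "T", alt_anticodon)
    return(paste(parts, collapse = "-"))
  }
  paste0(gene_id, ">", alt_anticodon)
}

#' Tabulate anticodon-switch variants as a strain report
#'
#' Formats [scan_variants()] events as one row per event with the original
#' gene, the renamed anticodon-mutated gene (the mutated anticodon substituted
#' into the gene-naming convention), the new amino acid, and the comma-joined
#' carrier strains. Rows are ordered by chromosome then position.
#'
#' @param events data.frame from [scan_variants()].
#' @return data.frame with `original_trna`, `original_aa`, `mutated_trna`,
#'   `new_aa`, `strains`, `chrom`, `pos`.
#' @export
tabulate_anticodon_switches <- function(events) {
  if (nrow(events) == 0L) {
    return(data.frame(original_trna = character(0), original_aa = character(0),
                      mutated_trna = character(0), new_aa = character(0),
                      strains = character(0), chrom = character(0),
                      pos = integer(0), stringsAsFactors = FALSE))
  }
  events <- events[order(events$chrom, events$pos), , drop = FALSE]
  data.frame(
    original_trna = events$gene_id,
    original_aa = unname(AA_FULL_NAME[events$ref_aa]),
    mutated_trna = mapply(.rename_gene_id, events$gene_id,
                          events$alt_anticodon, events$alt_aa,
                          USE.NAMES = FALSE),
    new_aa = unname(AA_FULL_NAME[events$alt_aa]),
    strains = events$carrier_samples,
    chrom = events$chrom, pos = events$pos,
    stringsAsFactors = FALSE
  )
}
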