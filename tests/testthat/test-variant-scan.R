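test_that("anticodon genomic coordinates follow strand orientation", {
  tmpl <- make_cloverleaf("CGU")
  # span 34-36 (1-based) on a gene at [1000, 1076)
  gplus <- trna_gene("tRNA-Thr-CGT-1-1", tmpl$sequence, structure = tmpl$structure,
                     chrom = "chrI", start = 1000L, end = 1076L, strand = "+")
  expect_equal(anticodon_genomic_coordinates(gplus), c(1034L, 1035L, 1036L))

  gminus <- trna_gene("tRNA-Thr-CGT-1-1", tmpl$sequence, structure = tmpl$structure,
                      chrom = "chrI", start = 1000L, end = 1076L, strand = "-")
  expect_equal(anticodon_genomic_coordinates(gminus), c(1043L, 1042L, 1041L))

  # minus-strand oracle: embed the reverse complement and read positions off
  # the full base-by-base mapping of the embedded gene
  gene_dna <- chartr("U", "T", tmpl$sequence)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_dna)))
  span <- locate_anticodon(gminus)$span
  for (k in 1:3) {
    gpos <- anticodon_genomic_coordinates(gminus)[k]
    base_on_genome <- substr(rc, gpos - 1000L, gpos - 1000L)
    expect_equal(chartr("ACGT", "UGCA", base_on_genome),
                 substr(tmpl$sequence, span[k], span[k]))
  }

  gnone <- trna_gene("tRNA-Thr-CGT-1-1", tmpl$sequence, structure = tmpl$structure)
  expect_error(anticodon_genomic_coordinates(gnone), "no genomic location")
})

test_that("planted anticodon variants are recovered with decoded changes", {
  fams <- data.frame(aa = c("K", "M"), anticodon = c("CUU", "CAU"), copies = c(3L, 3L))
  gp <- gen_trna_pool(fams, seed = 2)
  target <- gp$pool[[1]]$gene_id   # a Lys gene; anticodon CUU, offset 2 U>G
  gg <- gen_genome_with_trnas(gp$pool,
    planted_variants = data.frame(gene_id = target, offset = 2L, alt = "G",
                                  n_carriers = 2L),
    n_decoys = 8L, seed = 3, dir = tempfile())
  genes <- read_trna_bed(gg$files$bed, genome = gg$files$genome)
  ev <- scan_variants(gg$files$vcf, genes)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gene_id, target)
  expect_equal(ev$ref_anticodon, "CUU")
  expect_equal(ev$alt_anticodon, "CGU")
  expect_equal(c(ev$ref_aa, ev$alt_aa), c("K", "T"))
  expect_equal(ev$anticodon_offset, 2L)
  expect_equal(ev$n_carriers, 2L)
  expect_equal(ev$carrier_samples,
               gg$ground_truth$carriers)

  # oracle: the decoded change equals applying the point mutation on the
  # transcript at the recovered transcript position
  src <- genes[[which(vapply(genes, `[[`, character(1), "gene_id") == target)]]
  talt <- if (src$strand == "+") normalize_rna(ev$alt) else
    rna_revcomp(normalize_rna(ev$alt))
  m <- apply_point_mutation(src, sprintf("c.%d %s>%s", ev$transcript_pos,
                                         substr(src$sequence, ev$transcript_pos,
                                                ev$transcript_pos), talt))
  expect_equal(m$after$anticodon, ev$alt_anticodon)
  expect_equal(m$effect, "anticodon_change")
})

test_that("variants outside anticodons, indels and foreign chromosomes are skipped", {
  fams <- data.frame(aa = "K", anticodon = "CUU", copies = 3L)
  gp <- gen_trna_pool(fams, seed = 4)
  gg <- gen_genome_with_trnas(gp$pool, n_decoys = 10L, seed = 5, dir = tempfile())
  genes <- read_trna_bed(gg$files$bed, genome = gg$files$genome)
  ev <- scan_variants(gg$files$vcf, genes)
  expect_equal(nrow(ev), 0L)   # decoys only

  # splice in an indel record and a record on an unknown chromosome
  lines <- readLines(gg$files$vcf)
  body <- grep("^#", lines, invert = TRUE)
  n_samp <- length(gg$strains)
  extra <- c(paste(c("chrI", 5, ".", "ATG", "A", ".", "PASS", ".", "GT",
                     rep("0/1", n_samp)), collapse = "\t"),
             paste(c("chrZ", 10, ".", "A", "C", ".", "PASS", ".", "GT",
                     rep("0/1", n_samp)), collapse = "\t"))
  writeLines(c(lines[-body], lines[body], extra[1],
               sub("^chrI", "chrZ", extra[2])), gg$files$vcf)
  ev2 <- scan_variants(gg$files$vcf, genes)
  sk <- attr(ev2, "skipped")
  expect_equal(nrow(sk$indels), 1L)
  expect_equal(sk$chrom_mismatch, 1L)

  # wholesale chromosome-naming mismatch warns
  lines3 <- readLines(gg$files$vcf)
  body3 <- grep("^#", lines3, invert = TRUE)
  lines3[body3] <- sub("^chr", "CHROMOSOME_", lines3[body3])
  writeLines(lines3, gg$files$vcf)
  expect_warning(scan_variants(gg$files$vcf, genes), "chromosome naming")
})

test_that("carrier counting honours the allele-count threshold", {
  fams <- data.frame(aa = "M", anticodon = "CAU", copies = 2L)
  gp <- gen_trna_pool(fams, seed = 6)
  target <- gp$pool[[1]]$gene_id
  gg <- gen_genome_with_trnas(gp$pool,
    planted_variants = data.frame(gene_id = target, offset = 2L, alt = "G",
                                  n_carriers = 3L),
    n_decoys = 0L, seed = 7, dir = tempfile())
  # make one carrier homozygous
  lines <- readLines(gg$files$vcf)
  i <- grep("0/1", lines)[1]
  lines[i] <- sub("0/1", "1/1", lines[i])
  writeLines(lines, gg$files$vcf)
  genes <- read_trna_bed(gg$files$bed, genome = gg$files$genome)
  het <- scan_variants(gg$files$vcf, genes, min_allele_count = 1L)
  hom <- scan_variants(gg$files$vcf, genes, min_allele_count = 2L)
  expect_equal(het$n_carriers, 3L)
  expect_equal(hom$n_carriers, 1L)

  # an event carried by nobody is dropped unless asked for
  lines2 <- gsub("1/1|0/1", "0/0", lines)
  writeLines(lines2, gg$files$vcf)
  expect_equal(nrow(scan_variants(gg$files$vcf, genes)), 0L)
  kept <- scan_variants(gg$files$vcf, genes, include_uncarried = TRUE)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$n_carriers, 0L)
})

test_that("synonymous anticodon changes are retained and flagged", {
  # Arg CCU -> UCU: both decode arginine (AGG / AGA)
  fams <- data.frame(aa = "R", anticodon = "CCU", copies = 2L)
  gp <- gen_trna_pool(fams, seed = 8)
  target <- gp$pool[[1]]$gene_id
  gg <- gen_genome_with_trnas(gp$pool,
    planted_variants = data.frame(gene_id = target, offset = 1L, alt = "U",
                                  n_carriers = 1L),
    n_decoys = 0L, seed = 9, dir = tempfile())
  genes <- read_trna_bed(gg$files$bed, genome = gg$files$genome)
  ev <- scan_variants(gg$files$vcf, genes)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$synonymous)
  expect_equal(ev$ref_aa, ev$alt_aa)
})

test_that("round trip recovers exactly the planted variants across seeds", {
  for (seed in 1:8) {
    fams <- data.frame(aa = c("K", "M", "T"), anticodon = c("CUU", "CAU", "UGU"),
                       copies = c(3L, 3L, 2L))
    gp <- gen_trna_pool(fams, seed = seed)
    ids <- vapply(gp$pool, `[[`, character(1), "gene_id")
    pv <- data.frame(gene_id = ids[c(1, 5)], offset = c(2L, 3L),
                     alt = c("G", "C"), n_carriers = c(1L, 2L))
    gg <- gen_genome_with_trnas(gp$pool, planted_variants = pv, n_decoys = 12L,
                                seed = seed + 100, dir = tempfile())
    genes <- read_trna_bed(gg$files$bed, genome = gg$files$genome)
    ev <- scan_variants(gg$files$vcf, genes)
    expect_equal(nrow(ev), 2L, info = paste("seed", seed))
    got <- ev[order(match(ev$gene_id, pv$gene_id)), ]
    expect_equal(got$gene_id, pv$gene_id)
    expect_equal(got$anticodon_offset, pv$offset)
    expect_equal(vapply(seq_len(2), function(i)
      substr(got$alt_anticodon[i], got$anticodon_offset[i],
             got$anticodon_offset[i]), character(1)),
      pv$alt)
  }
})

test_that("scanning the reverse-complemented genome yields identical events", {
  fams <- data.frame(aa = c("K", "M"), anticodon = c("CUU", "CAU"), copies = c(3L, 2L))
  gp <- gen_trna_pool(fams, seed = 10)
  ids <- vapply(gp$pool, `[[`, character(1), "gene_id")
  pv <- data.frame(gene_id = ids[c(2, 4)], offset = c(1L, 2L), alt = c("U", "G"),
                   n_carriers = c(2L, 1L))
  dirA <- tempfile()
  gg <- gen_genome_with_trnas(gp$pool, planted_variants = pv, n_decoys = 6L,
                              seed = 11, dir = dirA)
  # flip: reverse-complement every chromosome, mirror BED and VCF coordinates
  genome <- Biostrings::readDNAStringSet(gg$files$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  flipped <- Biostrings::reverseComplement(genome)
  L <- stats::setNames(Biostrings::width(genome), names(genome))
  dirB <- tempfile(); dir.create(dirB)
  Biostrings::writeXStringSet(flipped, file.path(dirB, "genome.fa"))
  bed <- utils::read.delim(gg$files$bed, header = FALSE)
  bed2 <- bed
  bed2$V2 <- L[bed$V1] - bed$V3
  bed2$V3 <- L[bed$V1] - bed$V2
  bed2$V6 <- ifelse(bed$V6 == "+", "-", "+")
  utils::write.table(bed2, file.path(dirB, "trnas.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  vcf <- readLines(gg$files$vcf)
  body <- grep("^#", vcf, invert = TRUE)
  flip_rec <- function(line) {
    f <- strsplit(line, "\t")[[1]]
    f[2] <- as.character(L[f[1]] - as.integer(f[2]) + 1L)
    f[4] <- chartr("ACGT", "TGCA", f[4])
    f[5] <- chartr("ACGT", "TGCA", f[5])
    paste(f, collapse = "\t")
  }
  vcf[body] <- vapply(vcf[body], flip_rec, character(1), USE.NAMES = FALSE)
  writeLines(vcf, file.path(dirB, "variants.vcf"))

  evA <- scan_variants(gg$files$vcf,
                       read_trna_bed(gg$files$bed, genome = gg$files$genome))
  evB <- scan_variants(file.path(dirB, "variants.vcf"),
                       read_trna_bed(file.path(dirB, "trnas.bed"),
                                     genome = file.path(dirB, "genome.fa")))
  cols <- c("gene_id", "anticodon_offset", "ref_anticodon", "alt_anticodon",
            "ref_aa", "alt_aa", "carrier_samples")
  ordA <- evA[order(evA$gene_id), cols]; ordB <- evB[order(evB$gene_id), cols]
  rownames(ordA) <- rownames(ordB) <- NULL
  expect_equal(ordA, ordB)
})

test_that("switch tabulation renames genes and groups carrier strains", {
  ev <- data.frame(
    gene_id = c("tK(CUU)K", "tRNA-Lys-CTT-2-1"), chrom = c("chrXI", "chrII"),
    pos = c(100L, 50L), transcript_pos = c(35L, 35L), anticodon_offset = c(2L, 2L),
    ref = c("T", "T"), alt = c("G", "G"),
    ref_anticodon = c("CUU", "CUU"), alt_anticodon = c("CGU", "CGU"),
    ref_aa = c("K", "K"), alt_aa = c("T", "T"),
    synonymous = c(FALSE, FALSE), to_stop = c(FALSE, FALSE),
    carrier_samples = c("S01,S07", "S03"), n_carriers = c(2L, 1L),
    stringsAsFactors = FALSE)
  tab <- tabulate_anticodon_switches(ev)
  expect_equal(tab$mutated_trna, c("tRNA-Thr-CGT-2-1", "tT(CGU)K"))  # chrom order
  expect_equal(tab$original_aa, c("Lysine", "Lysine"))
  expect_equal(tab$new_aa, c("Threonine", "Threonine"))
  expect_equal(tab$strains, c("S03", "S01,S07"))

  empty <- tabulate_anticodon_switches(ev[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("original_trna", "mutated_trna", "new_aa", "strains") %in%
                    names(empty)))
})
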