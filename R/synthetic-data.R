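# Generators for every input the pipeline consumes, with exported ground
# truth so each stage can be scored exactly. All generators are deterministic
# under `seed` and write standard plain-text formats when `dir` is given.

.random_substitute <- function(seq, positions, n) {
  if (n == 0L || length(positions) == 0L) return(seq)
  pos <- sample(positions, min(n, length(positions)))
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(RNA_BASES, cur), 1L)
  }
  seq
}

#' Generate a synthetic tRNA gene pool with planted anticodon switches
#'
#' Builds isoacceptor families on a shared cloverleaf template. Every family
#' receives a disjoint block of four diagnostic substitutions at unpaired
#' non-anticodon positions that copy noise never touches, so cross-family
#' distances exceed within-family distances by at least 3 by construction;
#' each gene copy receives `Poisson(mutation_rate * L)` private substitutions
#' (truncated at 3 to preserve that margin) at the remaining free positions,
#' and planted switches substitute anticodon bases only. Family anticodons
#' must be distinct. Headers follow the
#' gtRNAdb dash dialect and name each gene by its actual (possibly switched)
#' anticodon. Switches that would create a stop-decoding anticodon are
#' rejected unless `force` is set.
#'
#' @param families data.frame with columns `aa` (one-letter isotype),
#'   `anticodon` (RNA/DNA 3-mer consistent with `aa`) and `copies`.
#' @param mutation_rate per-base substitution rate for private copy mutations
#'   (default 0.02).
#' @param planted_switches data.frame with columns `family` (index into
#'   `families`), `copy` (copy index) and `to_anticodon`; or `NULL`.
#' @param seed integer seed.
#' @param force allow switches to stop-decoding anticodons.
#' @param dir optional output directory; writes `pool.fa`, `pool.dot`
#'   (structure sidecar) and `ground_truth.json`.
#' @return list with `pool` (list of [trna_gene()]), `ground_truth`
#'   (data.frame of planted events: `gene_id`, `parent_id`,
#'   `from_anticodon`, `to_anticodon`, `from_aa`, `to_aa`) and `files`.
#' @export
gen_trna_pool <- function(families, mutation_rate = 0.02,
                          planted_switches = NULL, seed = 1L, force = FALSE,
                          dir = NULL) {
  stopifnot(all(c("aa", "anticodon", "copies") %in% names(families)))
  if (anyDuplicated(normalize_rna(families$anticodon))) {
    stop("family anticodons must be distinct", call. = FALSE)
  }
  code <- genetic_code()
  tmpl <- make_cloverleaf("CGU")
  span <- tmpl$anticodon_span
  # disjoint diagnostic blocks of 4 mutable positions per family, reserved
  # from copy noise so families stay >= 8 (+ anticodon) substitutions apart
  need <- 4L * nrow(families)
  if (need + 4L > length(tmpl$mutable)) {
    stop("too many families for the template's mutable positions", call. = FALSE)
  }
  free <- tmpl$mutable[-seq_len(need)]
  with_seed(seed, {
    pool <- list()
    truth <- list()
    for (f in seq_len(nrow(families))) {
      ac <- normalize_rna(families$anticodon[f])
      dec <- decode_anticodon(ac, code)
      if (dec$is_stop) stop("family anticodon ", ac, " decodes a stop codon", call. = FALSE)
      if (dec$aa != families$aa[f]) {
        stop("anticodon ", ac, " decodes ", dec$aa, ", not ", families$aa[f], call. = FALSE)
      }
      cons <- tmpl$sequence
      substr(cons, span[1], span[3]) <- ac
      diag_pos <- tmpl$mutable[4L * (f - 1L) + 1:4]
      for (p in diag_pos) {
        cur <- substr(cons, p, p)
        substr(cons, p, p) <- setdiff(RNA_BASES, cur)[(f - 1L) %% 3L + 1L]
      }
      for (k in seq_len(families$copies[f])) {
        seq <- .random_substitute(cons, free,
                                  min(stats::rpois(1L, mutation_rate * nchar(cons)), 3L))
        id <- sprintf("tRNA-%s-%s-%d-%d", AA_ONE_TO_THREE[[families$aa[f]]],
                      chartr("U", "T", ac), f, k)
        pool[[id]] <- trna_gene(id, seq, structure = tmpl$structure)
      }
    }
    if (!is.null(planted_switches)) {
      for (r in seq_len(nrow(planted_switches))) {
        f <- planted_switches$family[r]
        k <- planted_switches$copy[r]
        to <- normalize_rna(planted_switches$to_anticodon[r])
        dec_to <- decode_anticodon(to, code)
        if (dec_to$is_stop && !force) {
          stop("planted switch to ", to, " would decode a stop codon; ",
               "use force = TRUE to allow it", call. = FALSE)
        }
        from <- normalize_rna(families$anticodon[f])
        old_id <- sprintf("tRNA-%s-%s-%d-%d", AA_ONE_TO_THREE[[families$aa[f]]],
                          chartr("U", "T", from), f, k)
        g <- pool[[old_id]]
        if (is.null(g)) stop("planted switch references missing copy ", old_id, call. = FALSE)
        substr(g$sequence, span[1], span[3]) <- to
        new_id <- sprintf("tRNA-%s-%s-%d-%d",
                          if (dec_to$is_stop) "Sup" else AA_ONE_TO_THREE[[dec_to$aa]],
                          chartr("U", "T", to), f, k)
        g$gene_id <- new_id
        hdr <- parse_gene_id(new_id)
        g$annotated_isotype <- hdr$aa
        g$header_anticodon <- hdr$anticodon
        pool[[old_id]] <- NULL
        pool[[new_id]] <- g
        # parent: another copy of the same family (smallest other copy index)
        sibs <- setdiff(seq_len(families$copies[f]), k)
        parent_id <- if (length(sibs) > 0L) {
          sprintf("tRNA-%s-%s-%d-%d", AA_ONE_TO_THREE[[families$aa[f]]],
                  chartr("U", "T", from), f, min(sibs))
        } else NA_character_
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = new_id, parent_id = parent_id,
          from_anticodon = from, to_anticodon = to,
          from_aa = families$aa[f], to_aa = dec_to$aa,
          stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(truth) > 0L) do.call(rbind, truth) else data.frame(
      gene_id = character(0), parent_id = character(0),
      from_anticodon = character(0), to_anticodon = character(0),
      from_aa = character(0), to_aa = character(0), stringsAsFactors = FALSE)
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      files <- list(fasta = file.path(dir, "pool.fa"),
                    structures = file.path(dir, "pool.dot"),
                    ground_truth = file.path(dir, "ground_truth.json"))
      write_trna_fasta(unname(pool), files$fasta, files$structures)
      jsonlite::write_json(truth, files$ground_truth, dataframe = "rows")
    }
    list(pool = unname(pool), ground_truth = truth, files = files)
  })
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome, tRNA annotation and multi-sample variant set
#'
#' Places the genes of a tRNA pool at non-overlapping positions on random
#' chromosome sequences (random strand per gene unless fixed), then emits a
#' multi-sample VCF containing planted single-nucleotide variants at known
#' anticodon coordinates plus decoy variants outside anticodons. Carrier
#' strains are assigned per planted variant. Outputs are standard formats:
#' genome FASTA, 6-column BED (0-based half-open) and VCF v4.2 with GT
#' genotypes.
#'
#' @param pool list of [trna_gene()] objects (from [gen_trna_pool()]).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param n_strains number of samples in the VCF.
#' @param planted_variants data.frame with columns `gene_id`, `offset`
#'   (anticodon position 1-3), `alt` (transcript-strand RNA base) and
#'   `n_carriers`; or `NULL`.
#' @param n_decoys number of decoy SNPs outside anticodon spans.
#' @param strand strand policy: `"random"`, `"+"` or `"-"`.
#' @param seed integer seed.
#' @param dir optional output directory; writes `genome.fa`, `trnas.bed`,
#'   `variants.vcf`, `ground_truth.json`.
#' @return list with `genes` (located [trna_gene()]s), `ground_truth`
#'   (data.frame: `gene_id`, `offset`, `alt`, `chrom`, `pos`, `ref_genomic`,
#'   `alt_genomic`, `carriers`), `strains` and `files`.
#' @export
gen_genome_with_trnas <- function(pool, chrom_sizes = c(chrI = 20000L, chrII = 20000L),
                                  n_strains = 8L, planted_variants = NULL,
                                  n_decoys = 10L, strand = "random", seed = 1L,
                                  dir = NULL) {
  with_seed(seed, {
    chroms <- lapply(chrom_sizes, .random_dna)
    # non-overlapping placement
    placed <- list()
    occupied <- lapply(chrom_sizes, function(n) integer(0))
    for (g in pool) {
      L <- nchar(g$sequence)
      ok <- FALSE
      for (try in 1:200) {
        ci <- sample(seq_along(chrom_sizes), 1L)
        start0 <- sample.int(chrom_sizes[ci] - L - 2L, 1L)
        span <- start0:(start0 + L)
        if (length(intersect(span, occupied[[ci]])) == 0L) { ok <- TRUE; break }
      }
      if (!ok) stop("placement overflow: could not place ", g$gene_id, call. = FALSE)
      occupied[[ci]] <- c(occupied[[ci]], span)
      st <- if (strand == "random") sample(c("+", "-"), 1L) else strand
      gene_dna <- chartr("U", "T", g$sequence)
      emb <- if (st == "+") gene_dna else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_dna)))
      substr(chroms[[ci]], start0 + 1L, start0 + L) <- emb
      placed[[g$gene_id]] <- trna_gene(g$gene_id, g$sequence, structure = g$structure,
                                       chrom = names(chrom_sizes)[ci],
                                       start = start0, end = start0 + L, strand = st)
    }
    genes <- unname(placed)
    strains <- sprintf("S%02d", seq_len(n_strains))

    # anticodon coordinate map, for decoy exclusion and planting
    ac_pos <- new.env(parent = emptyenv())
    for (g in genes) {
      for (p in anticodon_genomic_coordinates(g)) {
        assign(paste0(g$chrom, ":", p), TRUE, envir = ac_pos)
      }
    }
    variants <- list()
    truth <- list()
    if (!is.null(planted_variants)) {
      for (r in seq_len(nrow(planted_variants))) {
        gid <- planted_variants$gene_id[r]
        off <- planted_variants$offset[r]
        alt_t <- normalize_rna(planted_variants$alt[r])
        g <- placed[[gid]]
        if (is.null(g)) stop("planted variant references unknown gene ", gid, call. = FALSE)
        call <- locate_anticodon(g)
        if (substr(call$anticodon, off, off) == alt_t) {
          stop("planted alt equals the reference anticodon base", call. = FALSE)
        }
        gpos <- anticodon_genomic_coordinates(g, call)[off]
        ref_g <- substr(chroms[[g$chrom]], gpos, gpos)
        alt_g <- chartr("U", "T", if (g$strand == "+") alt_t else .rna_complement_base(alt_t))
        nc <- planted_variants$n_carriers[r]
        carriers <- if (nc > 0L) sample(strains, nc) else character(0)
        variants[[length(variants) + 1L]] <- list(chrom = g$chrom, pos = gpos,
                                                  ref = ref_g, alt = alt_g,
                                                  carriers = carriers)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gid, offset = off, alt = alt_t, chrom = g$chrom, pos = gpos,
          ref_genomic = ref_g, alt_genomic = alt_g,
          carriers = paste(sort(carriers), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    for (dd in seq_len(n_decoys)) {
      repeat {
        ci <- sample(seq_along(chrom_sizes), 1L)
        pos <- sample.int(chrom_sizes[ci], 1L)
        if (!isTRUE(mget(paste0(names(chrom_sizes)[ci], ":", pos),
                         envir = ac_pos, ifnotfound = FALSE)[[1]])) break
      }
      ref <- substr(chroms[[ci]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      variants[[length(variants) + 1L]] <- list(chrom = names(chrom_sizes)[ci],
                                                pos = pos, ref = ref, alt = alt,
                                                carriers = sample(strains, 1L))
    }
    truth <- if (length(truth) > 0L) do.call(rbind, truth) else data.frame(
      gene_id = character(0), offset = integer(0), alt = character(0),
      chrom = character(0), pos = integer(0), ref_genomic = character(0),
      alt_genomic = character(0), carriers = character(0), stringsAsFactors = FALSE)

    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      files <- list(genome = file.path(dir, "genome.fa"),
                    bed = file.path(dir, "trnas.bed"),
                    vcf = file.path(dir, "variants.vcf"),
                    ground_truth = file.path(dir, "ground_truth.json"))
      gseq <- Biostrings::DNAStringSet(unlist(chroms))
      names(gseq) <- names(chrom_sizes)
      Biostrings::writeXStringSet(gseq, files$genome, width = 80L)
      bed <- do.call(rbind, lapply(genes, function(g) data.frame(
        chrom = g$chrom, start = g$start, end = g$end, name = g$gene_id,
        score = 0L, strand = g$strand, stringsAsFactors = FALSE)))
      utils::write.table(bed, files$bed, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      write_vcf(variants, strains, chrom_sizes, files$vcf)
      jsonlite::write_json(truth, files$ground_truth, dataframe = "rows")
    }
    list(genes = genes, variants = variants, ground_truth = truth,
         strains = strains, chrom_sizes = chrom_sizes, files = files)
  })
}

# Emit a minimal, valid multi-sample VCF v4.2 with GT-only genotypes.
# (Heterozygous 0/1 carriers; records sorted by chromosome then position.)
write_vcf <- function(variants, strains, chrom_sizes, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(chrom_sizes),
                   as.integer(chrom_sizes)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", strains), collapse = "\t"))
  if (length(variants) > 0L) {
    ord <- order(vapply(variants, `[[`, character(1), "chrom"),
                 vapply(variants, function(v) v$pos, numeric(1)))
    recs <- vapply(variants[ord], function(v) {
      gts <- ifelse(strains %in% v$carriers, "0/1", "0/0")
      paste(c(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT", gts),
            collapse = "\t")
    }, character(1))
  } else recs <- character(0)
  atomic_writelines(c(hdr, recs), path)
  invisible(path)
}

.AA_LETTERS <- setdiff(names(AA_ONE_TO_THREE), "*")

# deterministic largest-remainder allocation of n items to probabilities p
.largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a synthetic heat-shock expression time course with codon-enriched
#' induced genes
#'
#' Emits a CDS set and a log2-fold-change matrix over an induction time
#' course. A designated induced gene set is constructed with the focal
#' codon's relative frequency (within its synonymous family) multiplied by
#' `codon_enrichment` and the family re-normalised; codons are allocated
#' deterministically (largest-remainder rounding) so the planted enrichment
#' is recoverable exactly up to rounding. Induced genes receive an elevated
#' log2 fold change with Gaussian noise; the default five time points mirror
#' a typical heat-shock course (4, 11, 16, 26, 40 min).
#'
#' @param n_genes total number of genes.
#' @param induced_set_size number of induced genes (default 25).
#' @param codon_enrichment multiplicative enrichment of the focal codon's
#'   within-family share in induced genes.
#' @param timepoints labels (minutes) for the course.
#' @param noise_sd Gaussian noise on log2 fold changes.
#' @param focal_codon focal codon.
#' @param n_codons codons per CDS (amino-acid length).
#' @param induced_log2fc peak log2 fold change of induced genes.
#' @param seed integer seed.
#' @param dir optional output directory; writes `cds.fa`, `expression.tsv`,
#'   `ground_truth.json`.
#' @return list with `cds` (named character), `expr` (matrix genes x
#'   timepoints), `ground_truth` (list: `induced`, `codon_enrichment`,
#'   `focal_codon`, `expected_rel_freq`), `files`.
#' @export
gen_expression_timecourse <- function(n_genes = 1000L, induced_set_size = 25L,
                                      codon_enrichment = 2, timepoints = c(4, 11, 16, 26, 40),
                                      noise_sd = 0.25, focal_codon = "ACG",
                                      n_codons = 500L, induced_log2fc = 4,
                                      seed = 1L, dir = NULL) {
  code <- genetic_code()
  focal_codon <- normalize_rna(focal_codon)
  focal_aa <- code[[focal_codon]]
  fam <- sense_codons(code)[code[sense_codons(code)] == focal_aa]
  base_p <- rep(1 / length(fam), length(fam))
  names(base_p) <- fam
  enr_p <- base_p
  enr_p[focal_codon] <- min(base_p[focal_codon] * codon_enrichment, 1)
  others <- setdiff(fam, focal_codon)
  enr_p[others] <- (1 - enr_p[focal_codon]) / length(others)
  with_seed(seed, {
    ids <- sprintf("G%04d", seq_len(n_genes))
    induced <- ids[seq_len(induced_set_size)]
    cds <- stats::setNames(vapply(seq_len(n_genes), function(i) {
      aas <- sample(.AA_LETTERS, n_codons, replace = TRUE)
      p <- if (ids[i] %in% induced) enr_p else base_p
      codons <- character(n_codons)
      for (aa in unique(aas)) {
        idx <- which(aas == aa)
        aafam <- sense_codons(code)[code[sense_codons(code)] == aa]
        pp <- if (aa == focal_aa) p else rep(1 / length(aafam), length(aafam))
        counts <- .largest_remainder(pp, length(idx))
        codons[idx] <- sample(rep(aafam, counts))
      }
      chartr("U", "T", paste(codons, collapse = ""))
    }, character(1)), ids)
    # induced genes peak early and decay across the course
    profile <- induced_log2fc * seq(1, 0.25, length.out = length(timepoints))
    expr <- matrix(stats::rnorm(n_genes * length(timepoints), 0, noise_sd),
                   n_genes, length(timepoints),
                   dimnames = list(ids, paste0("t", timepoints)))
    expr[induced, ] <- expr[induced, ] +
      matrix(profile, induced_set_size, length(timepoints), byrow = TRUE)
    expr <- round(expr, 5)
    truth <- list(induced = induced, codon_enrichment = codon_enrichment,
                  focal_codon = focal_codon,
                  expected_rel_freq = unname(enr_p[focal_codon]))
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      files <- list(cds = file.path(dir, "cds.fa"),
                    expr = file.path(dir, "expression.tsv"),
                    ground_truth = file.path(dir, "ground_truth.json"))
      ss <- Biostrings::DNAStringSet(cds)
      Biostrings::writeXStringSet(ss, files$cds, width = 80L)
      df <- data.frame(gene_id = ids, expr, check.names = FALSE)
      utils::write.table(df, files$expr, sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(truth, files$ground_truth, auto_unbox = TRUE)
    }
    list(cds = cds, expr = expr, ground_truth = truth, files = files)
  })
}

.random_peptide <- function(n, force_thr = FALSE) {
  len <- sample(8:20, n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    aa <- sample(.AA_LETTERS, len[i], replace = TRUE)
    if (force_thr && !"T" %in% aa) aa[sample.int(len[i], 1L)] <- "T"
    paste(aa, collapse = "")
  }, character(1))
}

#' Generate a synthetic peptide quantification table
#'
#' Emulates a label-free peptide/protein quantification experiment across a
#' set of strains with replicates: log2-normal feature intensities,
#' intensity-dependent missingness (logistic in log2 intensity, concentrated
#' near the detection limit), threonine-substitution variant rows injected at
#' per-strain rates (an observation of a Thr-containing base peptide spawns a
#' substituted observation with the strain's rate), and a planted
#' differentially-abundant feature set with a stated log2 effect in one
#' strain (a configurable fraction of effects negative, mirroring a
#' predominance of down-regulation).
#'
#' @param strains character vector of strain names; the first is the control.
#' @param n_replicates replicates per strain.
#' @param n_features number of base features.
#' @param thr_fraction fraction of features whose peptide contains threonine.
#' @param substitution_rates named per-strain substitution rate (applied to
#'   both T>K and T>M), or a single number recycled.
#' @param missing_rate overall target missingness fraction.
#' @param n_differential number of differential features.
#' @param differential_strain strain carrying the differential effect.
#' @param effect_log2 absolute log2 effect size of differential features.
#' @param frac_down fraction of differential features with a negative effect.
#' @param replicate_sd replicate noise sd on the log2 scale.
#' @param seed integer seed.
#' @param dir optional output directory; writes `peptides.tsv`, `groups.tsv`,
#'   `ground_truth.json`.
#' @return list with `table` (a [peptide_table()]), `ground_truth` (list:
#'   `differential` ids, `effects`, `substitution_rates`, `missing_mask`
#'   summary) and `files`.
#' @export
gen_peptide_table <- function(strains = c("control", "host", "tx1", "tx2", "tx3"),
                              n_replicates = 3L, n_features = 600L,
                              thr_fraction = 0.2, substitution_rates = 0.001,
                              missing_rate = 0.1, n_differential = 40L,
                              differential_strain = "host", effect_log2 = 2,
                              frac_down = 0.6, replicate_sd = 0.5, seed = 1L,
                              dir = NULL) {
  if (length(substitution_rates) == 1L) {
    substitution_rates <- stats::setNames(rep(substitution_rates, length(strains)), strains)
  }
  stopifnot(all(strains %in% names(substitution_rates)),
            differential_strain %in% strains)
  with_seed(seed, {
    samples <- as.vector(t(outer(strains, seq_len(n_replicates),
                                 function(s, r) paste0(s, "_r", r))))
    groups <- data.frame(sample = samples,
                         group = rep(strains, each = n_replicates),
                         replicate = rep(seq_len(n_replicates), length(strains)),
                         stringsAsFactors = FALSE)
    n_thr <- round(thr_fraction * n_features)
    seqs <- c(.random_peptide(n_thr, force_thr = TRUE),
              vapply(.random_peptide(n_features - n_thr), function(s)
                chartr("T", "S", s), character(1)))
    prot <- sprintf("P%04d", seq_len(n_features))
    mu <- stats::rnorm(n_features, 25, 2)
    diff_ids <- sample(prot, n_differential)
    effects <- stats::setNames(
      ifelse(seq_len(n_differential) <= round(frac_down * n_differential),
             -effect_log2, effect_log2), diff_ids)
    x <- matrix(round(stats::rnorm(n_features * length(samples), mu, replicate_sd), 4),
                n_features, length(samples), dimnames = list(prot, samples))
    dcols <- groups$group == differential_strain
    x[diff_ids, dcols] <- x[diff_ids, dcols] + effects[diff_ids]
    # intensity-dependent missingness: logistic around the missing_rate quantile
    lod <- stats::quantile(x, missing_rate)
    pmiss <- stats::plogis(-(x - lod) / 0.8)
    pmiss <- pmiss * (missing_rate / mean(pmiss))
    mask <- matrix(stats::runif(length(x)) < pmiss, nrow(x), ncol(x))
    x[mask] <- NA_real_

    feats <- data.frame(sequence = seqs, protein = prot,
                        variant_class = "base", site = NA_integer_,
                        stringsAsFactors = FALSE)
    # substitution variant rows: an observed Thr-containing base peptide
    # spawns a substituted observation with its strain's rate
    sub_rows <- list(); sub_vals <- list()
    thr_idx <- which(grepl("T", seqs, fixed = TRUE))
    col_rate <- unlist(substitution_rates[groups$group])
    for (sub in c("T>K", "T>M")) {
      xb <- x[thr_idx, , drop = FALSE]
      event <- !is.na(xb) &
        matrix(stats::runif(length(xb)), nrow(xb)) <
          matrix(col_rate, nrow(xb), ncol(xb), byrow = TRUE)
      vals <- matrix(NA_real_, nrow(xb), ncol(xb))
      vals[event] <- round(xb[event] - 3 + stats::rnorm(sum(event), 0, 0.3), 4)
      hit <- which(rowSums(event) > 0L)
      if (length(hit) > 0L) {
        i <- thr_idx[hit]
        site <- vapply(seqs[i], function(s) regexpr("T", s, fixed = TRUE)[1],
                       integer(1), USE.NAMES = FALSE)
        newseq <- seqs[i]
        for (r in seq_along(newseq)) {
          substr(newseq[r], site[r], site[r]) <- if (sub == "T>K") "K" else "M"
        }
        sub_rows[[sub]] <- data.frame(sequence = newseq, protein = prot[i],
                                      variant_class = sub, site = site,
                                      stringsAsFactors = FALSE)
        sub_vals[[sub]] <- vals[hit, , drop = FALSE]
      }
    }
    if (length(sub_rows) > 0L) {
      feats <- rbind(feats, do.call(rbind, sub_rows))
      x <- rbind(x, do.call(rbind, sub_vals))
    }
    rownames(x) <- NULL
    tab <- peptide_table(x, feats, groups)
    truth <- list(differential = diff_ids, effects = as.list(effects),
                  substitution_rates = as.list(substitution_rates),
                  differential_strain = differential_strain,
                  control = strains[1], missing_rate = missing_rate)
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      files <- list(peptides = file.path(dir, "peptides.tsv"),
                    groups = file.path(dir, "groups.tsv"),
                    ground_truth = file.path(dir, "ground_truth.json"))
      df <- cbind(feats, as.data.frame(x))
      utils::write.table(df, files$peptides, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
      utils::write.table(groups, files$groups, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(truth, files$ground_truth, auto_unbox = TRUE)
    }
    list(table = tab, ground_truth = truth, files = files)
  })
}

#' Read a peptide quantification table and group map from TSV
#'
#' Inverse of the files written by [gen_peptide_table()]: a TSV with columns
#' `sequence`, `protein`, `variant_class`, `site`, then one intensity column
#' per sample (empty cell = missing), plus a sample-to-group map TSV.
#'
#' @param peptides path to the peptide TSV.
#' @param groups path to the group map TSV.
#' @return a [peptide_table()].
#' @export
read_peptide_table <- function(peptides, groups) {
  df <- utils::read.delim(peptides, stringsAsFactors = FALSE, check.names = FALSE)
  gr <- utils::read.delim(groups, stringsAsFactors = FALSE)
  meta_cols <- c("sequence", "protein", "variant_class", "site")
  x <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  storage.mode(x) <- "double"
  peptide_table(x, df[, meta_cols], gr)
}
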