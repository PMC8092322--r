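# Thin orchestration layer over the analysis modules: named stages with a
# flat config list, deterministic execution (every stochastic step takes an
# explicit seed), atomic outputs stamped with version/seed/config hash.

.stage_names <- c("simulate", "switch-scan", "vcf-scan", "demand", "stability",
                  "proteome", "tetrad", "replay-all")

.cfg <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

.require_inputs <- function(config, keys) {
  for (k in keys) {
    path <- config[[k]]
    if (is.null(path)) stop("missing required config key: ", k, call. = FALSE)
    if (!file.exists(path)) stop("input file not found: ", path, " (", k, ")",
                                 call. = FALSE)
  }
}

#' Run one pipeline stage
#'
#' Dispatches a named stage on a flat config list (as parsed from a YAML
#' config and/or command-line flags). Outputs are written atomically into
#' `out_dir`, every tabular output starting with a comment header carrying
#' the tool version, the seed and a config fingerprint. Unknown stage names
#' and unknown config keys raise errors listing the valid choices.
#'
#' Stages and their main config keys:
#' \describe{
#'   \item{simulate}{`generator` (pool / genome / expression / peptides),
#'     `seed`; generator outputs under `out_dir`.}
#'   \item{switch-scan}{`pool` FASTA, optional `structures` sidecar,
#'     optional `bootstrap` replicate count; writes `switch_events.tsv`,
#'     per-isotype Newick trees and `bootstrap_support.tsv`.}
#'   \item{vcf-scan}{`vcf`, `bed`, `genome`; writes `anticodon_variants.tsv`
#'     and `switch_table.tsv`.}
#'   \item{demand}{`cds` FASTA, `expr` TSV, `codon`, `top`; writes
#'     `demand.tsv`.}
#'   \item{stability}{`fasta` + `structures` (first record = reference) or
#'     nothing (packaged fixtures); writes `stability.tsv`.}
#'   \item{proteome}{`table`, `groups`, `control`, `s0`, `fdr`, `seed`;
#'     writes `differential.tsv`, `substitutions.tsv`, `summary.json`.}
#'   \item{tetrad}{`model` YAML (list of loci), `n`, `seed`; writes
#'     `tetrads.tsv` and `summary.json`.}
#'   \item{replay-all}{`seed`; full synthetic replay of every stage.}
#' }
#'
#' @param name stage name.
#' @param config named list of stage parameters.
#' @param out_dir output directory (created if needed).
#' @return invisible list of written file paths.
#' @export
run_stage <- function(name, config = list(), out_dir = ".") {
  if (!name %in% .stage_names) {
    stop("unknown stage ", sQuote(name), "; valid stages: ",
         paste(.stage_names, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- .cfg(config, "seed", 1L)
  switch(name,
    "simulate" = .stage_simulate(config, out_dir, seed),
    "switch-scan" = .stage_switch_scan(config, out_dir, seed),
    "vcf-scan" = .stage_vcf_scan(config, out_dir, seed),
    "demand" = .stage_demand(config, out_dir, seed),
    "stability" = .stage_stability(config, out_dir, seed),
    "proteome" = .stage_proteome(config, out_dir, seed),
    "tetrad" = .stage_tetrad(config, out_dir, seed),
    "replay-all" = replay_all(seed = seed, out_dir = out_dir)
  )
}

.stage_simulate <- function(config, out_dir, seed) {
  gen <- .cfg(config, "generator", "pool")
  res <- switch(gen,
    pool = {
      fams <- data.frame(aa = c("T", "K", "M"),
                         anticodon = c("CGU", "CUU", "CAU"),
                         copies = c(1L, 14L, 5L))
      sw <- data.frame(family = c(2L, 3L), copy = c(1L, 1L),
                       to_anticodon = c("CGU", "CGU"))
      gen_trna_pool(fams, planted_switches = sw, seed = seed, dir = out_dir)
    },
    genome = {
      fams <- data.frame(aa = c("K", "M"), anticodon = c("CUU", "CAU"),
                         copies = c(4L, 4L))
      gp <- gen_trna_pool(fams, seed = seed)
      pv <- data.frame(gene_id = gp$pool[[1]]$gene_id, offset = 2L,
                       alt = "G", n_carriers = 2L)
      gen_genome_with_trnas(gp$pool, planted_variants = pv, seed = seed,
                            dir = out_dir)
    },
    expression = gen_expression_timecourse(seed = seed, dir = out_dir),
    peptides = gen_peptide_table(seed = seed, dir = out_dir),
    stop("unknown generator ", sQuote(gen),
         "; valid: pool, genome, expression, peptides", call. = FALSE)
  )
  invisible(res$files)
}

.stage_switch_scan <- function(config, out_dir, seed) {
  .require_inputs(config, "pool")
  pool <- read_trna_fasta(config$pool, structures = .cfg(config, "structures"))
  cs <- count_switches(pool)
  out <- list(events = file.path(out_dir, "switch_events.tsv"))
  write_tsv_with_header(cs$events, out$events, "switch-scan", seed, config)
  n_boot <- .cfg(config, "bootstrap", 0L)
  isotypes <- vapply(pool, function(g) locate_anticodon(g)$aa, character(1))
  # per-isotype NJ trees over families with enough members
  sup_rows <- list()
  for (aa in unique(isotypes)) {
    members <- pool[isotypes == aa]
    if (length(members) < 3L) next
    seqs <- stats::setNames(vapply(members, `[[`, character(1), "sequence"),
                            vapply(members, `[[`, character(1), "gene_id"))
    if (length(unique(nchar(seqs))) > 1L) next  # unaligned; skip tree
    bs <- bootstrap_support(seqs, n_replicates = n_boot, seed = seed)
    nwk <- file.path(out_dir, paste0("family_", AA_ONE_TO_THREE[[aa]], ".nwk"))
    write_newick(bs$tree, nwk)
    out[[paste0("tree_", aa)]] <- nwk
    if (nrow(bs$support) > 0L) {
      bs$support$isotype <- aa
      sup_rows[[aa]] <- bs$support
    }
  }
  sup <- if (length(sup_rows) > 0L) do.call(rbind, sup_rows) else
    data.frame(node = integer(0), taxa = character(0), count = integer(0),
               support = numeric(0), isotype = character(0))
  out$support <- file.path(out_dir, "bootstrap_support.tsv")
  write_tsv_with_header(sup, out$support, "switch-scan", seed, config)
  invisible(out)
}

.stage_vcf_scan <- function(config, out_dir, seed) {
  .require_inputs(config, c("vcf", "bed", "genome"))
  genes <- read_trna_bed(config$bed, genome = config$genome)
  events <- scan_variants(config$vcf, genes,
                          min_allele_count = .cfg(config, "min_allele_count", 1L))
  out <- list(events = file.path(out_dir, "anticodon_variants.tsv"),
              table = file.path(out_dir, "switch_table.tsv"))
  write_tsv_with_header(events, out$events, "vcf-scan", seed, config)
  write_tsv_with_header(tabulate_anticodon_switches(events), out$table,
                        "vcf-scan", seed, config)
  invisible(out)
}

.stage_demand <- function(config, out_dir, seed) {
  .require_inputs(config, c("cds", "expr"))
  cds <- Biostrings::readDNAStringSet(config$cds)
  usage <- codon_usage_table(stats::setNames(as.character(cds), names(cds)))
  df <- utils::read.delim(config$expr, check.names = FALSE)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df[[1]]
  dr <- demand_ratio(expr, usage, focal_codon = .cfg(config, "codon", "ACG"),
                     top_n = .cfg(config, "top", 25L),
                     exclude_top = isTRUE(config$exclude_top))
  # per-time-point rank test of focal-codon share: top set vs the rest
  tops <- attr(dr, "top_gene_ids")
  rel <- usage$rel_freq[rownames(expr), normalize_rna(.cfg(config, "codon", "ACG"))]
  kw <- lapply(dr$timepoint, function(tp) {
    top <- tops[[tp]]
    kruskal_wallis(list(rel[top], rel[setdiff(rownames(expr), top)]))
  })
  dr$kw_H <- vapply(kw, `[[`, numeric(1), "H")
  dr$kw_p <- vapply(kw, `[[`, numeric(1), "p")
  dr$stars <- vapply(kw, `[[`, character(1), "stars")
  out <- list(demand = file.path(out_dir, "demand.tsv"))
  write_tsv_with_header(dr, out$demand, "demand", seed, config)
  invisible(out)
}

.stage_stability <- function(config, out_dir, seed) {
  if (!is.null(config$fasta)) {
    .require_inputs(config, c("fasta", "structures"))
    seqs <- Biostrings::readBStringSet(config$fasta)
    seqs <- stats::setNames(normalize_rna(as.character(seqs)), names(seqs))
    structure <- readLines(config$structures)[1]
  } else {
    fx <- trt2_isoform_fixtures()
    seqs <- fx$sequences
    structure <- fx$structure
  }
  temps <- .cfg(config, "temperatures", c(30, 35, 42))
  ref <- seqs[[1]]
  rows <- list()
  for (v in seq_along(seqs)) {
    prof <- ddg_variants(ref, seqs[[v]], structure, temperatures = temps,
                         threshold = .cfg(config, "threshold", 2.65),
                         label = names(seqs)[v])
    prof$variant <- names(seqs)[v]
    prof$rtd_flag <- attr(prof, "rtd_flag")
    rows[[v]] <- as.data.frame(prof)
  }
  out <- list(stability = file.path(out_dir, "stability.tsv"))
  write_tsv_with_header(do.call(rbind, rows), out$stability, "stability",
                        seed, config)
  invisible(out)
}

.stage_proteome <- function(config, out_dir, seed) {
  .require_inputs(config, c("table", "groups"))
  tab <- read_peptide_table(config$table, config$groups)
  control <- .cfg(config, "control", tab$groups$group[1])
  tab <- filter_valid(tab, min_valid = .cfg(config, "min_valid", 3L))
  tab <- impute_lod(tab, seed = seed)
  strains <- setdiff(unique(tab$groups$group), control)
  base_rows <- tab$features$variant_class == "base"
  base_tab <- peptide_table(tab$intensities[base_rows, , drop = FALSE],
                            tab$features[base_rows, , drop = FALSE], tab$groups)
  diff_rows <- lapply(strains, function(s) {
    r <- permutation_fdr(base_tab, s, control, s0 = .cfg(config, "s0", 1),
                         fdr = .cfg(config, "fdr", 0.05), seed = seed)
    r$strain <- s
    r
  })
  diff <- do.call(rbind, diff_rows)
  subs <- do.call(rbind, lapply(strains, function(s) {
    do.call(rbind, lapply(c("T>K", "T>M"), function(ss) data.frame(
      strain = s, substitution = ss,
      fraction = as.numeric(substitution_fraction(tab, s, ss)),
      ratio_vs_control = as.numeric(ratio_vs_control(tab, s, control, ss)),
      stringsAsFactors = FALSE)))
  }))
  out <- list(differential = file.path(out_dir, "differential.tsv"),
              substitutions = file.path(out_dir, "substitutions.tsv"),
              summary = file.path(out_dir, "summary.json"))
  write_tsv_with_header(diff, out$differential, "proteome", seed, config)
  write_tsv_with_header(subs, out$substitutions, "proteome", seed, config)
  jsonlite::write_json(list(
    n_features = nrow(tab$intensities),
    n_significant = sum(diff$significant),
    control = control, strains = strains), out$summary, auto_unbox = TRUE)
  invisible(out)
}

.stage_tetrad <- function(config, out_dir, seed) {
  loci <- if (!is.null(config$model)) {
    .require_inputs(config, "model")
    do.call(rbind, lapply(yaml::read_yaml(config$model)$loci, function(l)
      data.frame(name = l$name, role = l$role, genotype = l$genotype,
                 linked_to = if (is.null(l$linked_to)) NA_character_ else l$linked_to,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(name = "essential_del", role = "essential_deletion",
               genotype = "het", stringsAsFactors = FALSE)
  }
  model <- cross_model(loci)
  sim <- simulate_tetrads(model, n_tetrads = .cfg(config, "n", 1000L), seed = seed)
  out <- list(tetrads = file.path(out_dir, "tetrads.tsv"),
              summary = file.path(out_dir, "summary.json"))
  write_tsv_with_header(sim$outcomes, out$tetrads, "tetrad", seed, config)
  jsonlite::write_json(list(
    expected_viability = sim$expected,
    viable_fraction = sim$viable_fraction,
    marker_fraction_all = sim$marker_fraction_all,
    marker_fraction_viable = sim$marker_fraction_viable),
    out$summary, auto_unbox = TRUE)
  invisible(out)
}

#' Replay the full synthetic pipeline
#'
#' Generates every synthetic input under `out_dir` and runs every analysis
#' stage on it: a tRNA pool with the two anticodon-switch scenarios (a
#' 14-copy lysine family and a 5-copy methionine family each donating one
#' CGU-switched copy) scanned for switches; a genome/VCF with a planted
#' anticodon variant scanned and tabulated; an expression time course scored
#' for codon demand; the packaged stability fixtures profiled; a peptide
#' table pushed through filtering, imputation, substitution fractions and
#' the permutation-FDR test; and the tetrad models of an unsuppressed and a
#' suppressed essential-deletion cross. Deterministic under `seed`: running
#' twice with the same seed produces byte-identical output trees.
#'
#' @param seed integer seed for every stochastic step.
#' @param out_dir output directory.
#' @return invisible list of per-stage output paths.
#' @export
replay_all <- function(seed = 1L, out_dir = "replay") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  sim_dir <- file.path(out_dir, "simulated")
  fams <- data.frame(aa = c("T", "K", "M"), anticodon = c("CGU", "CUU", "CAU"),
                     copies = c(1L, 14L, 5L))
  sw <- data.frame(family = c(2L, 3L), copy = c(1L, 1L),
                   to_anticodon = c("CGU", "CGU"))
  gp <- gen_trna_pool(fams, planted_switches = sw, seed = seed,
                      dir = file.path(sim_dir, "pool"))
  paths$pool <- gp$files
  paths$switch_scan <- run_stage("switch-scan",
    list(pool = gp$files$fasta, structures = gp$files$structures,
         bootstrap = 100L, seed = seed),
    file.path(out_dir, "switch-scan"))

  gg <- gen_genome_with_trnas(gp$pool,
    planted_variants = data.frame(gene_id = "tRNA-Lys-CTT-2-2", offset = 2L,
                                  alt = "G", n_carriers = 2L),
    seed = seed, dir = file.path(sim_dir, "genome"))
  paths$vcf_scan <- run_stage("vcf-scan",
    list(vcf = gg$files$vcf, bed = gg$files$bed, genome = gg$files$genome,
         seed = seed),
    file.path(out_dir, "vcf-scan"))

  ge <- gen_expression_timecourse(seed = seed, dir = file.path(sim_dir, "expression"))
  paths$demand <- run_stage("demand",
    list(cds = ge$files$cds, expr = ge$files$expr, codon = "ACG", top = 25L,
         seed = seed),
    file.path(out_dir, "demand"))

  paths$stability <- run_stage("stability", list(seed = seed),
                               file.path(out_dir, "stability"))

  pt <- gen_peptide_table(seed = seed, dir = file.path(sim_dir, "peptides"))
  paths$proteome <- run_stage("proteome",
    list(table = pt$files$peptides, groups = pt$files$groups,
         control = "control", seed = seed),
    file.path(out_dir, "proteome"))

  for (mdl in c("unsuppressed", "suppressed")) {
    loci <- data.frame(
      name = c("essential_del", "natmx", "suppressor"),
      role = c("essential_deletion", "marker", "suppressor"),
      genotype = c("het", "het", if (mdl == "suppressed") "hom_alt" else "hom_ref"),
      linked_to = c(NA, "essential_del", NA), stringsAsFactors = FALSE)
    yaml::write_yaml(list(loci = lapply(seq_len(nrow(loci)), function(i)
      as.list(loci[i, ]))), file.path(out_dir, paste0("tetrad_", mdl, ".yaml")))
    paths[[paste0("tetrad_", mdl)]] <- run_stage("tetrad",
      list(model = file.path(out_dir, paste0("tetrad_", mdl, ".yaml")),
           n = 1000L, seed = seed),
      file.path(out_dir, paste0("tetrad-", mdl)))
  }
  invisible(paths)
}
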