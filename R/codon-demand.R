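#' Frame-0 codon counts of a coding sequence
#'
#' Exact triplet counts of a CDS read in frame 0, as a 64-vector over the RNA
#' codons. Ambiguity codes either raise an error or silently drop the
#' affected triplets from the 64 canonical counts.
#'
#' @param cds DNA or RNA string whose length is divisible by 3.
#' @param ambiguous `"error"` (default) or `"skip"` for IUPAC ambiguity codes.
#' @param strict require an AUG start codon and a stop codon at the end.
#' @return named integer vector of 64 codon counts (RNA alphabet).
#' @export
codon_counts <- function(cds, ambiguous = c("error", "skip"), strict = FALSE) {
  ambiguous <- match.arg(ambiguous)
  cds <- normalize_rna(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not divisible by 3 (frame error)",
         call. = FALSE)
  }
  has_ambig <- grepl("[^ACGU]", cds)
  if (has_ambig && ambiguous == "error") {
    stop("CDS contains ambiguity codes; use ambiguous = \"skip\" to drop them",
         call. = FALSE)
  }
  if (strict) {
    code <- genetic_code()
    if (substr(cds, 1, 3) != "AUG") stop("strict mode: CDS does not start with AUG", call. = FALSE)
    last <- substr(cds, nchar(cds) - 2, nchar(cds))
    if (!last %in% stop_codons(code)) stop("strict mode: CDS does not end in a stop codon", call. = FALSE)
  }
  x <- Biostrings::RNAString(cds)
  counts <- Biostrings::oligonucleotideFrequency(x, width = 3L, step = 3L)
  counts[order(names(counts))]
}

#' Codon usage table for a set of coding sequences
#'
#' Per-gene codon counts plus, for every sense codon, its *relative usage
#' frequency within its synonymous family* (the share of, e.g., ACG among the
#' four threonine codons of that gene). The relative frequency is `NA`
#' (flagged, not zero) for genes in which the amino acid does not occur.
#' An absolute per-1000-codons matrix is also provided.
#'
#' @param cds_set named character vector or list of CDS strings.
#' @param code genetic code.
#' @param ambiguous passed to [codon_counts()].
#' @return object of class `codon_usage_table`: list with `counts`
#'   (genes x 64), `rel_freq` (genes x 61 sense codons, within-family
#'   shares), `per_1000` and `code`.
#' @export
codon_usage_table <- function(cds_set, code = genetic_code(), ambiguous = "error") {
  cds_set <- unlist(cds_set)
  if (is.null(names(cds_set)) || anyDuplicated(names(cds_set))) {
    stop("cds_set must have unique gene names", call. = FALSE)
  }
  counts <- t(vapply(cds_set, codon_counts, integer(64), ambiguous = ambiguous))
  sense <- sense_codons(code)
  rel <- matrix(NA_real_, nrow(counts), length(sense),
                dimnames = list(rownames(counts), sense))
  for (aa in unique(code[sense])) {
    fam <- sense[code[sense] == aa]
    tot <- rowSums(counts[, fam, drop = FALSE])
    share <- counts[, fam, drop = FALSE] / tot
    share[tot == 0L, ] <- NA_real_
    rel[, fam] <- share
  }
  per_1000 <- counts / rowSums(counts) * 1000
  structure(list(counts = counts, rel_freq = rel, per_1000 = per_1000, code = code),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("<codon_usage_table> ", nrow(x$counts), " genes, ",
      sum(x$counts), " codons\n", sep = "")
  invisible(x)
}

#' Heat-shock codon-demand statistic
#'
#' For each time point of an induction time course, the ratio of the mean
#' relative focal-codon frequency (within its synonymous family) over the
#' top-`top_n` most-induced genes to the mean over the background gene set.
#' Induction is ranked by descending log2 fold change at that time point,
#' with ties at the boundary broken by gene id. The background defaults to
#' *all* genes (the top set included); `exclude_top` removes them. Genes in
#' which the focal amino acid does not occur are excluded from the means and
#' counted, never propagated as `NaN`.
#'
#' @param expr numeric matrix of log2 fold changes, genes x time points, with
#'   row and column names.
#' @param usage a [codon_usage_table()] covering at least the genes of `expr`.
#' @param focal_codon focal codon (RNA or DNA spelling).
#' @param top_n number of top induced genes (default 25).
#' @param exclude_top exclude the top set from the background mean.
#' @return data.frame of `DemandStatistic` rows: `timepoint`, `ratio`,
#'   `mean_top`, `mean_background`, `n_top_defined`, `n_background_defined`,
#'   `undefined` flag, plus a `top_gene_ids` list attribute.
#' @export
demand_ratio <- function(expr, usage, focal_codon = "ACG", top_n = 25L,
                         exclude_top = FALSE) {
  stopifnot(inherits(usage, "codon_usage_table"))
  focal_codon <- normalize_rna(focal_codon)
  if (!focal_codon %in% colnames(usage$rel_freq)) {
    stop("focal codon ", focal_codon, " is not a sense codon", call. = FALSE)
  }
  genes <- rownames(expr)
  if (!all(genes %in% rownames(usage$rel_freq))) {
    stop("expression matrix contains genes absent from the usage table", call. = FALSE)
  }
  if (top_n > nrow(expr)) stop("top_n exceeds the number of genes", call. = FALSE)
  rel <- usage$rel_freq[genes, focal_codon]
  tops <- list()
  rows <- lapply(colnames(expr), function(tp) {
    ord <- order(-expr[, tp], genes)
    top <- genes[ord[seq_len(top_n)]]
    tops[[tp]] <<- top
    bg <- if (exclude_top) setdiff(genes, top) else genes
    top_vals <- rel[top]; bg_vals <- rel[bg]
    mt <- mean(top_vals, na.rm = TRUE); mb <- mean(bg_vals, na.rm = TRUE)
    undef <- all(is.na(top_vals)) || all(is.na(bg_vals)) ||
      is.na(mb) || mb == 0
    data.frame(timepoint = tp,
               ratio = if (undef) NA_real_ else mt / mb,
               mean_top = mt, mean_background = mb,
               n_top_defined = sum(!is.na(top_vals)),
               n_background_defined = sum(!is.na(bg_vals)),
               undefined = undef, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "top_gene_ids") <- tops
  out
}

#' Kruskal-Wallis rank-sum comparison with significance stars
#'
#' Thin wrapper over [stats::kruskal.test()] (tie-corrected H, chi-square
#' approximation with `k - 1` degrees of freedom) that adds the conventional
#' significance stars (`ns` for p > 0.05, then `*`, `**`, `***`, `****` at
#' 0.05, 0.01, 0.001 and 0.0001). Groups whose values are all identical give
#' H = 0 and p = 1.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return list with `H`, `df`, `p` and `stars`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1)) > 0L))
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1, stars = "ns"))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, stars = significance_stars(kt$p.value))
}

#' @rdname kruskal_wallis
#' @param p p-value(s).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (pp < 1e-4) "****" else if (pp < 1e-3) "***" else if (pp < 1e-2) "**"
    else if (pp < 0.05) "*" else "ns"
  }, character(1))
}

#' Relative expression fold change by the 2^-ddCt method
#'
#' `dCt = Ct_target - mean(Ct_references)` in sample and control (reference
#' genes aggregated by the arithmetic mean of their Ct values);
#' `ddCt = dCt_sample - dCt_control`; the fold change is `2^-ddCt`.
#'
#' @param ct_target_sample,ct_target_control Ct of the target gene in the
#'   sample and control conditions.
#' @param ct_refs_sample,ct_refs_control numeric vectors of reference-gene
#'   (household-gene) Ct values in sample and control.
#' @return fold change (sample relative to control).
#' @examples
#' ddct_fold_change(19, c(20, 22), 20, c(20, 22)) # one cycle lower: 2-fold
#' @export
ddct_fold_change <- function(ct_target_sample, ct_refs_sample,
                             ct_target_control, ct_refs_control) {
  stopifnot(length(ct_refs_sample) >= 1L, length(ct_refs_control) >= 1L,
            all(is.finite(c(ct_target_sample, ct_refs_sample,
                            ct_target_control, ct_refs_control))))
  dct_sample <- ct_target_sample - mean(ct_refs_sample)
  dct_control <- ct_target_control - mean(ct_refs_control)
  2^-(dct_sample - dct_control)
}
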