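#' Global edit distance between two sequences
#'
#' Exact global alignment cost with unit substitution, insertion and deletion
#' costs (Levenshtein distance), computed by [utils::adist()]. This replaces
#' the short-read-aligner similarity search sometimes used for this purpose
#' with a deterministic, parameter-free metric.
#'
#' @param a,b character strings (empty strings allowed).
#' @return non-negative integer distance.
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' All-pairs edit distance matrix for a tRNA gene pool
#'
#' @param pool list of [trna_gene()] objects.
#' @return symmetric integer matrix with gene ids as dimnames.
#' @export
pool_distance_matrix <- function(pool) {
  seqs <- vapply(pool, `[[`, character(1), "sequence")
  ids <- vapply(pool, `[[`, character(1), "gene_id")
  d <- utils::adist(seqs)
  dimnames(d) <- list(ids, ids)
  d
}

.event_row <- function(gene_id, neighbor_id, distance, annotated_aa,
                       decoded_aa, neighbor_aa) {
  data.frame(
    gene_id = gene_id, neighbor_id = neighbor_id, distance = distance,
    annotated_aa = annotated_aa, decoded_aa = decoded_aa,
    neighbor_aa = neighbor_aa,
    switched = !is.na(decoded_aa) && !is.na(neighbor_aa) && decoded_aa != neighbor_aa,
    stringsAsFactors = FALSE
  )
}

#' Closest nonequal neighbour of a tRNA gene in a pool
#'
#' Finds the pool member with minimal edit distance to the query among members
#' whose *sequence* differs from the query's (identical duplicate gene copies
#' are excluded, so that cross-family neighbours are found). Ties are broken
#' by lexicographically smallest gene id. The returned event is flagged
#' `switched` when the query's decoded anticodon amino acid differs from the
#' neighbour's.
#'
#' @param gene a [trna_gene()] (need not be a pool member).
#' @param pool list of [trna_gene()] objects.
#' @param code genetic code.
#' @return one-row data.frame (a `SwitchEvent`): `gene_id`, `neighbor_id`,
#'   `distance`, `annotated_aa`, `decoded_aa`, `neighbor_aa`, `switched`.
#' @export
closest_nonequal_neighbor <- function(gene, pool, code = genetic_code()) {
  seqs <- vapply(pool, `[[`, character(1), "sequence")
  ids <- vapply(pool, `[[`, character(1), "gene_id")
  keep <- seqs != gene$sequence
  if (!any(keep)) {
    stop("no nonequal neighbour: every pool sequence is identical to ",
         gene$gene_id, call. = FALSE)
  }
  d <- as.integer(utils::adist(gene$sequence, seqs[keep]))
  cand <- which(d == min(d))
  pick <- cand[order(ids[keep][cand])][1]
  neighbor <- pool[keep][[pick]]
  .event_row(
    gene$gene_id, neighbor$gene_id, d[pick],
    annotated_aa = gene$annotated_isotype,
    decoded_aa = locate_anticodon(gene, code = code)$aa,
    neighbor_aa = locate_anticodon(neighbor, code = code)$aa
  )
}

#' Count anticodon-switch events in a tRNA gene pool
#'
#' For every gene in the pool, finds its closest nonequal neighbour and flags
#' the gene as switched when the two decode different amino acids. Because a
#' switched gene's parent may reciprocally have the switched gene as its own
#' nearest nonequal neighbour, both a per-gene count and a deduplicated
#' switched-pair count are reported.
#'
#' @param pool list of at least two [trna_gene()] objects.
#' @param code genetic code.
#' @return list with `events` (one SwitchEvent row per gene), `n_switched`
#'   (genes flagged) and `n_switched_pairs` (unique unordered switched pairs).
#' @export
count_switches <- function(pool, code = genetic_code()) {
  if (length(pool) < 2L) stop("pool must contain at least two genes", call. = FALSE)
  seqs <- vapply(pool, `[[`, character(1), "sequence")
  ids <- vapply(pool, `[[`, character(1), "gene_id")
  aas <- vapply(pool, function(g) locate_anticodon(g, code = code)$aa, character(1))
  d <- utils::adist(seqs)
  rows <- vector("list", length(pool))
  for (i in seq_along(pool)) {
    keep <- seqs != seqs[i]
    if (!any(keep)) {
      stop("no nonequal neighbour: every pool sequence is identical to ",
           ids[i], call. = FALSE)
    }
    di <- d[i, keep]
    cand <- which(di == min(di))
    pick <- cand[order(ids[keep][cand])][1]
    j <- which(keep)[pick]
    rows[[i]] <- .event_row(ids[i], ids[j], di[pick],
                            pool[[i]]$annotated_isotype, aas[i], aas[j])
  }
  events <- do.call(rbind, rows)
  sw <- events[events$switched, , drop = FALSE]
  pair_key <- apply(cbind(sw$gene_id, sw$neighbor_id), 1,
                    function(p) paste(sort(p), collapse = "\r"))
  list(events = events, n_switched = sum(events$switched),
       n_switched_pairs = length(unique(pair_key)))
}

#' Proportion of differing sites between two aligned sequences
#'
#' @param a,b aligned, equal-length sequences (characters compared
#'   position-wise).
#' @return fraction of differing positions in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("p_distance requires aligned sequences of equal length", call. = FALSE)
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca != cb)
}

#' Jukes-Cantor distance from a proportion of differing sites
#'
#' Evaluates `d = -(3/4) log(1 - 4 p / 3)`. Proportions at or beyond the model
#' ceiling `p >= 0.75` (substitution saturation) map to a configurable cap and
#' the result carries a `saturated` attribute.
#'
#' @param p numeric vector of site-difference proportions in `[0, 1]`.
#' @param cap distance assigned to saturated entries.
#' @return numeric vector of distances with a logical `saturated` attribute.
#' @export
jc_distance <- function(p, cap = 5) {
  stopifnot(all(p >= 0 & p <= 1))
  sat <- p >= 0.75
  d <- rep(cap, length(p))
  d[!sat] <- -0.75 * log(1 - 4 * p[!sat] / 3)
  attr(d, "saturated") <- sat
  d
}

#' Jukes-Cantor distance matrix of aligned sequences
#'
#' @param seqs named character vector of aligned, equal-length sequences.
#' @param cap saturation cap, see [jc_distance()].
#' @return symmetric numeric matrix of JC distances.
#' @export
jc_distance_matrix <- function(seqs, cap = 5) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- jc_distance(mean(m[i, ] != m[j, ]), cap = cap)
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]) with optional clamping of
#' negative branch lengths: a negative branch is set to zero and its deficit
#' transferred to the sister branch, the standard post-processing for
#' non-additive inputs.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and at
#'   least three taxa.
#' @param clamp_negative clamp negative branch lengths (default `TRUE`).
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(d, clamp_negative = TRUE) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal", call. = FALSE)
  tr <- ape::nj(d)
  if (clamp_negative && any(tr$edge.length < 0)) {
    for (pass in 1:10) {
      neg <- which(tr$edge.length < -1e-12)
      if (length(neg) == 0L) break
      for (e in neg) {
        parent <- tr$edge[e, 1]
        sibs <- setdiff(which(tr$edge[, 1] == parent), e)
        if (length(sibs) > 0L) {
          tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
        }
        tr$edge.length[e] <- 0
      }
    }
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Serialise a tree to a Newick file
#'
#' @param tree a `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Bootstrap support for neighbour-joining tree edges
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Jukes-Cantor/neighbour-joining tree for each replicate, and reports for
#' each internal edge of the full-data tree the fraction of replicate trees
#' containing the same bipartition. Reproducible under a fixed seed.
#'
#' @param seqs named character vector of aligned, equal-length sequences
#'   (at least 4 for internal edges to exist).
#' @param n_replicates number of bootstrap replicates (0 gives an empty
#'   support table).
#' @param seed optional integer seed (RNG state is restored on exit).
#' @param cap saturation cap for [jc_distance()].
#' @return list with `tree` (full-data NJ tree) and `support` (data.frame:
#'   internal `node`, clade member `taxa`, `count`, `support` fraction).
#' @export
bootstrap_support <- function(seqs, n_replicates = 100L, seed = NULL, cap = 5) {
  ref <- nj_tree(jc_distance_matrix(seqs, cap = cap))
  if (n_replicates == 0L) {
    return(list(tree = ref, support = data.frame(
      node = integer(0), taxa = character(0), count = integer(0),
      support = numeric(0), stringsAsFactors = FALSE)))
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  trees <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      mm <- m[, cols, drop = FALSE]
      reseqs <- stats::setNames(apply(mm, 1, paste, collapse = ""), rownames(m))
      nj_tree(jc_distance_matrix(reseqs, cap = cap))
    })
  })
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  internal <- ape::Ntip(ref) + seq_len(ref$Nnode)
  taxa <- vapply(internal, function(nd) {
    tips <- ape::extract.clade(ref, nd)$tip.label
    paste(sort(tips), collapse = ",")
  }, character(1))
  list(tree = ref,
       support = data.frame(node = internal, taxa = taxa, count = counts,
                            support = counts / n_replicates,
                            stringsAsFactors = FALSE))
}
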