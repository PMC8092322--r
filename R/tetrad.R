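#' Define a diploid cross for tetrad-viability analysis
#'
#' Describes the loci segregating in a diploid about to be sporulated. Each
#' locus has a role (`essential_deletion`, `suppressor`, or `marker`), a
#' genotype (`het`, `hom_alt`, `hom_ref` with respect to the non-reference
#' allele: the deletion, the suppressor mutation, or the resistance marker),
#' and optionally a linkage partner: `same_locus` loci co-segregate in
#' coupling (a resistance cassette replacing the deleted gene is the standard
#' case), all other loci assort independently. Meiosis is modelled without
#' crossover interference or gene conversion; a heterozygous locus segregates
#' 2:2 in every tetrad. A spore dies if and only if it carries an
#' essential-gene deletion allele and no functional (alt) suppressor allele.
#'
#' @param loci data.frame with columns `name`, `role`
#'   (essential_deletion / suppressor / marker), `genotype`
#'   (het / hom_alt / hom_ref) and optionally `linked_to` (name of a
#'   `same_locus` partner, `NA` for unlinked).
#' @return object of class `cross_model`.
#' @export
cross_model <- function(loci) {
  stopifnot(is.data.frame(loci), all(c("name", "role", "genotype") %in% names(loci)))
  if (!"linked_to" %in% names(loci)) loci$linked_to <- NA_character_
  stopifnot(all(loci$role %in% c("essential_deletion", "suppressor", "marker")),
            all(loci$genotype %in% c("het", "hom_alt", "hom_ref")),
            !anyDuplicated(loci$name))
  for (i in seq_len(nrow(loci))) {
    lk <- loci$linked_to[i]
    if (!is.na(lk)) {
      j <- match(lk, loci$name)
      if (is.na(j)) stop("linked_to refers to unknown locus ", lk, call. = FALSE)
      if (loci$genotype[j] != loci$genotype[i]) {
        stop("contradictory linkage: same_locus partners ", loci$name[i], " and ",
             lk, " have different genotypes", call. = FALSE)
      }
    }
  }
  # linkage groups: connected components of the same_locus relation
  group <- seq_len(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    lk <- loci$linked_to[i]
    if (!is.na(lk)) {
      j <- match(lk, loci$name)
      group[group == group[i]] <- group[j]
    }
  }
  loci$linkage_group <- match(group, unique(group))
  structure(list(loci = loci), class = "cross_model")
}

#' @export
print.cross_model <- function(x, ...) {
  cat("<cross_model> ", nrow(x$loci), " loci:\n", sep = "")
  print.data.frame(x$loci)
  invisible(x)
}

# The 6 possible 2-of-4 spore subsets receiving the alt allele of a
# heterozygous linkage group (uniform under no-interference meiosis: for two
# unlinked het loci this reproduces the 1:1:4 PD:NPD:T tetrad ratio).
.HET_PATTERNS <- utils::combn(4L, 2L, simplify = FALSE)

# spores x loci logical matrix of alt-allele carriage for one joint pattern
# assignment (one pattern index per linkage group).
.spore_alt <- function(model, pattern_idx) {
  loci <- model$loci
  alt <- matrix(FALSE, nrow = 4L, ncol = nrow(loci),
                dimnames = list(NULL, loci$name))
  for (i in seq_len(nrow(loci))) {
    alt[, i] <- switch(loci$genotype[i],
      hom_alt = rep(TRUE, 4L),
      hom_ref = rep(FALSE, 4L),
      het = seq_len(4L) %in% .HET_PATTERNS[[pattern_idx[loci$linkage_group[i]]]]
    )
  }
  alt
}

.spore_viability <- function(model, alt) {
  loci <- model$loci
  del <- loci$role == "essential_deletion"
  sup <- loci$role == "suppressor"
  dies <- rowSums(alt[, del, drop = FALSE]) > 0L &
    rowSums(alt[, sup, drop = FALSE]) == 0L
  !dies
}

.het_groups <- function(model) {
  loci <- model$loci
  unique(loci$linkage_group[loci$genotype == "het"])
}

# enumerate all joint segregation patterns; f(alt matrix) is accumulated as a
# probability-weighted mean (all patterns equally likely).
.enumerate_tetrads <- function(model, f) {
  hg <- .het_groups(model)
  if (length(hg) == 0L) {
    return(f(.spore_alt(model, integer(0))))
  }
  grids <- expand.grid(rep(list(1:6), length(hg)))
  vals <- apply(grids, 1, function(row) {
    idx <- integer(max(model$loci$linkage_group))
    idx[hg] <- as.integer(row)
    f(.spore_alt(model, idx))
  })
  mean(vals)
}

#' Expected spore viability of a cross
#'
#' Exact expectation of the viable-spore fraction, by enumeration over all
#' joint tetrad segregation patterns (2:2 per heterozygous linkage group, all
#' six spore assignments equally likely, independent assortment across
#' unlinked groups).
#'
#' @param model a [cross_model()].
#' @return expected viable fraction in `[0, 1]`.
#' @examples
#' # heterozygous essential deletion, no suppressor: 50% viability
#' m <- cross_model(data.frame(name = "trt2del", role = "essential_deletion",
#'                             genotype = "het"))
#' expected_viability(m)
#' @export
expected_viability <- function(model) {
  stopifnot(inherits(model, "cross_model"))
  .enumerate_tetrads(model, function(alt) mean(.spore_viability(model, alt)))
}

#' Simulate tetrad dissection of a cross
#'
#' Monte-Carlo tetrads under the same segregation model as
#' [expected_viability()]; per-tetrad spore genotypes, viable counts and
#' marker-carrying counts are returned. Reproducible under a fixed seed.
#'
#' @param model a [cross_model()].
#' @param n_tetrads number of tetrads (>= 1).
#' @param seed optional integer seed.
#' @return list with `outcomes` (data.frame: `tetrad`, `viable`,
#'   `marker_all`, `marker_viable` counts per tetrad), `viable_fraction`,
#'   `marker_fraction_all`, `marker_fraction_viable` and `expected` (the
#'   analytic viability).
#' @export
simulate_tetrads <- function(model, n_tetrads, seed = NULL) {
  stopifnot(inherits(model, "cross_model"), n_tetrads >= 1L)
  loci <- model$loci
  hg <- .het_groups(model)
  marker <- loci$role == "marker"
  res <- with_seed(seed, {
    t(vapply(seq_len(n_tetrads), function(tt) {
      idx <- integer(max(loci$linkage_group))
      if (length(hg) > 0L) idx[hg] <- sample.int(6L, length(hg), replace = TRUE)
      alt <- .spore_alt(model, idx)
      viable <- .spore_viability(model, alt)
      has_marker <- rowSums(alt[, marker, drop = FALSE]) > 0L
      # 2:2 segregation sanity check for every heterozygous locus
      het <- loci$genotype == "het"
      stopifnot(all(colSums(alt[, het, drop = FALSE]) == 2L))
      c(viable = sum(viable), marker_all = sum(has_marker),
        marker_viable = sum(has_marker & viable))
    }, numeric(3)))
  })
  outcomes <- data.frame(tetrad = seq_len(n_tetrads), viable = res[, "viable"],
                         marker_all = res[, "marker_all"],
                         marker_viable = res[, "marker_viable"])
  list(outcomes = outcomes,
       viable_fraction = sum(res[, "viable"]) / (4 * n_tetrads),
       marker_fraction_all = sum(res[, "marker_all"]) / (4 * n_tetrads),
       marker_fraction_viable = if (sum(res[, "viable"]) > 0)
         sum(res[, "marker_viable"]) / sum(res[, "viable"]) else NA_real_,
       expected = expected_viability(model))
}

#' Marker segregation fractions of a cross
#'
#' Exact fractions of spores carrying the (heterozygous) marker allele,
#' among all spores (always 1/2 for a het marker, by 2:2 segregation) and
#' among viable spores (0 when the marked deletion is unsuppressed, 1/2 under
#' full suppression).
#'
#' @param model a [cross_model()] containing at least one `marker` locus.
#' @return list with `among_all` and `among_viable`.
#' @export
marker_fraction <- function(model) {
  stopifnot(inherits(model, "cross_model"), any(model$loci$role == "marker"))
  marker <- model$loci$role == "marker"
  among_all <- .enumerate_tetrads(model, function(alt) {
    mean(rowSums(alt[, marker, drop = FALSE]) > 0L)
  })
  num <- .enumerate_tetrads(model, function(alt) {
    v <- .spore_viability(model, alt)
    mean((rowSums(alt[, marker, drop = FALSE]) > 0L) & v)
  })
  den <- expected_viability(model)
  list(among_all = among_all,
       among_viable = if (den > 0) num / den else NA_real_)
}
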