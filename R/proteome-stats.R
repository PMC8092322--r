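#' Construct a peptide quantification table
#'
#' Bundles a features x samples matrix of log2 intensities (NA = missing)
#' with per-feature metadata (sequence, parent protein, variant class) and a
#' sample-to-group map. Variant classes are `"base"` for unmodified peptides
#' and `"T>K"` / `"T>M"` for threonine-substitution search variants; a
#' substituted row references the base sequence context it derives from.
#'
#' @param intensities numeric matrix, features x samples, log2 scale, `NA`
#'   for missing values; finite values must be positive on the raw scale
#'   (any finite log2 value).
#' @param features data.frame with columns `sequence`, `protein`,
#'   `variant_class` (one of base, T>K, T>M), `site` (substitution site or
#'   `NA`); one row per matrix row.
#' @param groups data.frame with columns `sample`, `group` (strain) and
#'   optionally `replicate`; one row per matrix column.
#' @return object of class `peptide_table`.
#' @export
peptide_table <- function(intensities, features, groups) {
  stopifnot(is.matrix(intensities), nrow(features) == nrow(intensities),
            nrow(groups) == ncol(intensities),
            all(c("sequence", "protein", "variant_class") %in% names(features)),
            all(c("sample", "group") %in% names(groups)))
  if (!all(features$variant_class %in% c("base", "T>K", "T>M"))) {
    stop("variant_class must be one of base, T>K, T>M", call. = FALSE)
  }
  colnames(intensities) <- groups$sample
  structure(list(intensities = intensities, features = features, groups = groups),
            class = "peptide_table")
}

#' @export
print.peptide_table <- function(x, ...) {
  cat("<peptide_table> ", nrow(x$intensities), " features x ",
      ncol(x$intensities), " samples (", length(unique(x$groups$group)),
      " groups); ", round(100 * mean(is.na(x$intensities)), 1),
      "% missing\n", sep = "")
  invisible(x)
}

.group_valid_counts <- function(tab) {
  grp <- tab$groups$group
  t(rowsum(t(!is.na(tab$intensities)) * 1L, grp))
}

#' Filter features on valid values per group
#'
#' Keeps features with at least `min_valid` non-missing values in at least
#' one sample group; all other features are removed (their count is recorded
#' in the `removed` attribute). Groups with fewer than `min_valid` samples in
#' total can never satisfy the rule on their own and trigger a warning.
#'
#' @param tab a [peptide_table()].
#' @param min_valid minimum valid values per group (default 3).
#' @return filtered [peptide_table()] with attribute `removed`.
#' @export
filter_valid <- function(tab, min_valid = 3L) {
  stopifnot(inherits(tab, "peptide_table"))
  sizes <- table(tab$groups$group)
  small <- names(sizes)[sizes < min_valid]
  if (length(small) > 0L) {
    warning("group(s) ", paste(small, collapse = ", "), " have fewer than ",
            min_valid, " samples; the validity rule can never pass for them alone",
            call. = FALSE)
  }
  counts <- .group_valid_counts(tab)
  keep <- apply(counts, 1, max) >= min_valid
  out <- peptide_table(tab$intensities[keep, , drop = FALSE],
                       tab$features[keep, , drop = FALSE], tab$groups)
  attr(out, "removed") <- sum(!keep)
  out
}

#' Impute missing intensities around the detection limit
#'
#' Per-sample imputation of missing log2 intensities from a normal
#' distribution placed in the tail of that sample's observed distribution:
#' draws from `Normal(mean - downshift * sd, (width * sd)^2)` of the sample's
#' observed values. The defaults (down-shift 1.8 sd, width 0.3 sd) follow
#' common label-free-proteomics practice and are configurable. Reproducible
#' under a fixed seed; a table without missing values is returned unchanged.
#'
#' @param tab a [peptide_table()] (log2 intensities).
#' @param downshift distribution down-shift in units of the sample sd.
#' @param width distribution width in units of the sample sd.
#' @param seed optional integer seed.
#' @return imputed [peptide_table()] (no missing values) with attribute
#'   `imputed_mask` (logical matrix of imputed cells).
#' @export
impute_lod <- function(tab, downshift = 1.8, width = 0.3, seed = NULL) {
  stopifnot(inherits(tab, "peptide_table"))
  x <- tab$intensities
  mask <- is.na(x)
  if (any(mask)) {
    x <- with_seed(seed, {
      for (j in seq_len(ncol(x))) {
        obs <- x[!mask[, j], j]
        if (sum(mask[, j]) == 0L) next
        if (length(obs) < 2L) {
          stop("sample ", colnames(x)[j],
               " has fewer than 2 observed values; cannot impute", call. = FALSE)
        }
        m <- mean(obs); s <- stats::sd(obs)
        x[mask[, j], j] <- stats::rnorm(sum(mask[, j]), m - downshift * s, width * s)
      }
      x
    })
  }
  out <- peptide_table(x, tab$features, tab$groups)
  attr(out, "imputed_mask") <- mask
  out
}

#' Threonine substitution fraction of a strain
#'
#' The fraction of peptide observations (or summed raw intensity) attributed
#' to threonine-to-lysine or threonine-to-methionine substitution variants,
#' relative to all observations of substitutable (threonine-containing) base
#' peptides plus the substituted ones, within one strain's samples. An
#' observation is a non-missing intensity cell.
#'
#' @param tab a [peptide_table()].
#' @param strain group label.
#' @param substitution `"T>K"` or `"T>M"`.
#' @param mode `"count"` (default: observation counts) or `"intensity"`
#'   (summed raw-scale intensities).
#' @return fraction in `[0, 1]`, or `NA` with attribute `undefined = TRUE`
#'   when the denominator is zero.
#' @export
substitution_fraction <- function(tab, strain, substitution = c("T>K", "T>M"),
                                  mode = c("count", "intensity")) {
  substitution <- match.arg(substitution)
  mode <- match.arg(mode)
  stopifnot(strain %in% tab$groups$group)
  cols <- tab$groups$group == strain
  sub_rows <- tab$features$variant_class == substitution
  base_rows <- tab$features$variant_class == "base" &
    grepl("T", tab$features$sequence, fixed = TRUE)
  xs <- tab$intensities[sub_rows, cols, drop = FALSE]
  xb <- tab$intensities[base_rows, cols, drop = FALSE]
  if (mode == "count") {
    num <- sum(!is.na(xs)); den <- num + sum(!is.na(xb))
  } else {
    num <- sum(2^xs[!is.na(xs)]); den <- num + sum(2^xb[!is.na(xb)])
  }
  if (den == 0) {
    out <- NA_real_; attr(out, "undefined") <- TRUE
    return(out)
  }
  num / den
}

#' @rdname substitution_fraction
#' @param control control strain to divide by.
#' @return `ratio_vs_control`: ratio of the strain's substitution fraction to
#'   the control's (the null expectation without mistranslation is 1), `NA`
#'   flagged when the control fraction is zero or undefined.
#' @export
ratio_vs_control <- function(tab, strain, control, substitution = c("T>K", "T>M"),
                             mode = c("count", "intensity")) {
  fs <- substitution_fraction(tab, strain, substitution, mode)
  fc <- substitution_fraction(tab, control, substitution, mode)
  if (is.na(fs) || is.na(fc) || fc == 0) {
    out <- NA_real_; attr(out, "undefined") <- TRUE
    return(out)
  }
  fs / fc
}

#' Distribution shift of threonine-containing peptides
#'
#' Tests whether the log2-fold-change distribution of a peptide subset
#' (threonine-containing peptides) is shifted downward relative to the full
#' distribution: reports `median(subset) - median(all)`, the
#' Kolmogorov-Smirnov statistic between the subset and its complement, and a
#' two-sided permutation p-value obtained by reshuffling subset membership.
#' When the subset equals the full set the shift and KS statistic are 0.
#'
#' @param log2fc_all numeric vector of log2 fold changes for all peptides.
#' @param subset_idx indices (or logical mask) of the subset within
#'   `log2fc_all`.
#' @param n_perm number of membership permutations (default 10000).
#' @param seed optional integer seed.
#' @return list with `shift`, `ks_statistic`, `p` and `n_subset`.
#' @export
thr_shift <- function(log2fc_all, subset_idx, n_perm = 10000L, seed = NULL) {
  n <- length(log2fc_all)
  if (is.logical(subset_idx)) subset_idx <- which(subset_idx)
  stopifnot(length(subset_idx) > 0L, all(subset_idx >= 1L & subset_idx <= n))
  sub <- log2fc_all[subset_idx]
  med_all <- stats::median(log2fc_all)
  shift <- stats::median(sub) - med_all
  comp <- log2fc_all[-subset_idx]
  ks <- if (length(comp) == 0L) 0 else
    unname(suppressWarnings(stats::ks.test(sub, comp))$statistic)
  k <- length(subset_idx)
  p <- NA_real_
  if (length(comp) > 0L && n_perm > 0L) {
    perm_shift <- with_seed(seed, {
      vapply(seq_len(n_perm), function(r) {
        stats::median(log2fc_all[sample.int(n, k)]) - med_all
      }, numeric(1))
    })
    p <- (1 + sum(abs(perm_shift) >= abs(shift))) / (n_perm + 1)
  } else if (length(comp) == 0L) {
    p <- 1
  }
  list(shift = shift, ks_statistic = ks, p = p, n_subset = k)
}

#' S0-moderated two-sample t statistic
#'
#' The two-sample t statistic with a background-variance constant `s0` added
#' to the denominator: `t = (mean_A - mean_B) / (se_pooled + s0)`, where
#' `se_pooled` is the usual pooled-variance standard error. `s0 = 0` recovers
#' the ordinary two-sample t statistic but requires non-degenerate per-row
#' variance.
#'
#' @param group_a,group_b numeric matrices (rows x replicates) or vectors,
#'   at least 2 values per group per row.
#' @param s0 background variance constant (default 1).
#' @return numeric vector of moderated t statistics (one per row).
#' @export
moderated_t_s0 <- function(group_a, group_b, s0 = 1) {
  if (is.vector(group_a)) group_a <- matrix(group_a, nrow = 1)
  if (is.vector(group_b)) group_b <- matrix(group_b, nrow = 1)
  na <- ncol(group_a); nb <- ncol(group_b)
  stopifnot(na >= 2L, nb >= 2L, nrow(group_a) == nrow(group_b))
  ma <- rowMeans(group_a); mb <- rowMeans(group_b)
  va <- apply(group_a, 1, stats::var); vb <- apply(group_b, 1, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (s0 == 0 && any(se == 0)) {
    stop("degenerate variance with s0 = 0; use s0 > 0 or remove constant rows",
         call. = FALSE)
  }
  (ma - mb) / (se + s0)
}

.two_group_splits <- function(n, na, max_exhaustive = 2000L, n_perm = 1000L,
                              seed = NULL) {
  total <- choose(n, na)
  if (total <= max_exhaustive) {
    splits <- utils::combn(n, na, simplify = FALSE)
  } else {
    splits <- with_seed(seed, lapply(seq_len(n_perm), function(r) sample.int(n, na)))
  }
  splits
}

#' Permutation-FDR differential test (S0-moderated)
#'
#' Tests every feature for a group difference with the S0-moderated t
#' statistic and controls the false discovery rate by permutation of the
#' group labels: all distinct balanced label assignments are enumerated when
#' there are at most `max_exhaustive` of them, otherwise `n_perm` random
#' assignments are drawn. For each observed |t| cutoff the estimated false
#' positives are the median across permutations of the number of permuted
#' statistics exceeding the cutoff; `q = FP / observed positives`, capped at
#' 1 and monotonised so that q never decreases as |t| decreases. Features
#' with `q <= fdr` are flagged significant.
#'
#' @param tab a [peptide_table()] (complete, i.e. after [impute_lod()]), or a
#'   numeric matrix with `group_labels` supplied.
#' @param group_a,group_b the two group labels to compare.
#' @param s0 background variance constant (default 1).
#' @param fdr FDR level (default 0.05).
#' @param n_perm number of sampled permutations when exhaustive enumeration
#'   is not feasible.
#' @param max_exhaustive enumerate all distinct assignments up to this many.
#' @param seed optional integer seed.
#' @param group_labels character vector of per-column labels when `tab` is a
#'   plain matrix.
#' @return data.frame of `DifferentialResult` rows: `id`, `mean_a`, `mean_b`,
#'   `diff`, `t_mod`, `q`, `significant`, ordered as the input rows; number
#'   of permutations used in attribute `n_permutations`.
#' @export
permutation_fdr <- function(tab, group_a, group_b, s0 = 1, fdr = 0.05,
                            n_perm = 1000L, max_exhaustive = 2000L,
                            seed = NULL, group_labels = NULL) {
  if (inherits(tab, "peptide_table")) {
    x <- tab$intensities
    labels <- tab$groups$group
    ids <- if (!is.null(tab$features$sequence)) tab$features$sequence else rownames(x)
  } else {
    x <- tab
    labels <- group_labels
    ids <- rownames(x)
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  sel <- labels %in% c(group_a, group_b)
  x <- x[, sel, drop = FALSE]
  labels <- labels[sel]
  if (any(is.na(x))) {
    stop("matrix contains missing values; filter and impute first", call. = FALSE)
  }
  ia <- which(labels == group_a)
  n <- ncol(x); na <- length(ia)

  tstat <- function(cols_a) {
    moderated_t_s0(x[, cols_a, drop = FALSE],
                   x[, setdiff(seq_len(n), cols_a), drop = FALSE], s0 = s0)
  }
  t_obs <- tstat(ia)
  splits <- .two_group_splits(n, na, max_exhaustive, n_perm, seed)
  abs_obs <- abs(t_obs)
  # counts[i, p]: number of permuted |t| in permutation p exceeding |t_obs[i]|
  fp <- matrix(0L, nrow = length(t_obs), ncol = length(splits))
  for (p in seq_along(splits)) {
    tp <- sort(abs(tstat(splits[[p]])))
    fp[, p] <- length(tp) - findInterval(abs_obs, tp, left.open = TRUE)
  }
  fp_med <- apply(fp, 1, stats::median)
  pos <- rank(-abs_obs, ties.method = "max")
  q <- pmin(fp_med / pos, 1)
  # monotonise (BH-style): each row gets the smallest q achievable at or
  # below its |t|, so q never decreases as |t| decreases
  ord <- order(abs_obs, decreasing = TRUE)
  q[ord] <- rev(cummin(rev(q[ord])))
  ma <- rowMeans(x[, ia, drop = FALSE])
  mb <- rowMeans(x[, setdiff(seq_len(n), ia), drop = FALSE])
  out <- data.frame(id = ids, mean_a = ma, mean_b = mb, diff = ma - mb,
                    t_mod = t_obs, q = q, significant = q <= fdr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_permutations") <- length(splits)
  out
}
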