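test_that("valid-value filtering keeps rows with one complete group", {
  x <- rbind(c(20, 21, 22, NA, NA, NA),   # 3 valid in A, 0 in B: kept
             c(20, NA, NA, 21, NA, NA),   # 1 and 1: removed
             c(20, 21, NA, 22, 23, NA),   # 2 and 2: removed
             c(NA, NA, NA, 20, 21, 22))   # 0 and 3: kept
  tab <- toy_peptide_table(x)
  out <- filter_valid(tab, min_valid = 3)
  expect_equal(nrow(out$intensities), 2L)
  expect_equal(attr(out, "removed"), 2L)
  expect_equal(out$features$sequence, c("PEPT1", "PEPT4"))

  # oracle: direct counting on a random validity mask
  set.seed(77)
  xr <- matrix(stats::rnorm(200 * 6, 20), 200, 6)
  xr[stats::runif(length(xr)) < 0.5] <- NA
  tabr <- toy_peptide_table(xr)
  keep_oracle <- vapply(seq_len(200), function(i) {
    sum(!is.na(xr[i, 1:3])) >= 3 || sum(!is.na(xr[i, 4:6])) >= 3
  }, logical(1))
  expect_equal(filter_valid(tabr)$features$sequence,
               tabr$features$sequence[keep_oracle])

  expect_warning(filter_valid(toy_peptide_table(x[, 1:5],
                                                c(A = 3L, B = 2L))),
                 "fewer than")
})

test_that("detection-limit imputation draws from the stated distribution", {
  # one sample with known observed mean/sd and many missing values
  n <- 20000L
  obs <- c(stats::rnorm(5000, 20, 1))
  x <- matrix(c(obs, rep(NA_real_, n - 5000)), ncol = 1)
  tab <- peptide_table(x, data.frame(sequence = paste0("P", 1:n),
                                     protein = paste0("P", 1:n),
                                     variant_class = "base", site = NA),
                       data.frame(sample = "s1", group = "A"))
  imp <- impute_lod(tab, seed = 99)
  filled <- imp$intensities[attr(imp, "imputed_mask")]
  m <- mean(obs); s <- stats::sd(obs)
  expect_equal(mean(filled), m - 1.8 * s, tolerance = 0.1 / (m - 1.8 * s))
  expect_equal(stats::sd(filled), 0.3 * s, tolerance = 0.05)

  # a complete table is returned unchanged; fixed seed reproduces
  full <- toy_peptide_table(matrix(stats::rnorm(24, 20), 4, 6))
  expect_identical(impute_lod(full, seed = 1)$intensities, full$intensities)
  imp2 <- impute_lod(tab, seed = 99)
  expect_identical(imp$intensities, imp2$intensities)

  tiny <- peptide_table(matrix(c(20, NA), 2, 1),
                        data.frame(sequence = c("A", "B"), protein = c("A", "B"),
                                   variant_class = "base", site = NA),
                        data.frame(sample = "s1", group = "A"))
  expect_error(impute_lod(tiny), "fewer than 2 observed")
})

test_that("the filter-impute pipeline is deterministic under a fixed seed", {
  pt <- gen_peptide_table(seed = 12)
  run <- function() {
    tab <- filter_valid(pt$table)
    impute_lod(tab, seed = 5)$intensities
  }
  expect_identical(run(), run())
})

test_that("substitution fractions recover planted rates and modes agree", {
  pt <- gen_peptide_table(strains = c("control", "host"), n_features = 10000,
                          thr_fraction = 0.7,
                          substitution_rates = c(control = 0.001, host = 0.01),
                          seed = 13)
  frac <- substitution_fraction(pt$table, "host", "T>K")
  # planted per-observation rate 0.01 -> expected fraction 0.01/1.01, about
  # 21000 substitutable observations: 3 binomial sds of slack
  n_obs <- sum(!is.na(pt$table$intensities[
    pt$table$features$variant_class == "base" &
      grepl("T", pt$table$features$sequence, fixed = TRUE),
    pt$table$groups$group == "host"]))
  p0 <- 0.01 / 1.01
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / n_obs))

  ratio <- ratio_vs_control(pt$table, "host", "control", "T>K")
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)

  # equal planted rates: the null expectation is a ratio near 1
  pt2 <- gen_peptide_table(strains = c("control", "host"), n_features = 8000,
                           thr_fraction = 0.7, substitution_rates = 0.01,
                           seed = 14)
  expect_lt(abs(ratio_vs_control(pt2$table, "host", "control", "T>K") - 1), 0.35)

  # count mode is invariant to intensity rescaling (log2 shift)
  tabshift <- peptide_table(pt$table$intensities + 5, pt$table$features,
                            pt$table$groups)
  expect_equal(substitution_fraction(tabshift, "host", "T>K"), frac)
  # intensity mode responds to per-sample multipliers coherently
  fi <- substitution_fraction(pt$table, "host", "T>K", mode = "intensity")
  fi2 <- substitution_fraction(tabshift, "host", "T>K", mode = "intensity")
  expect_equal(fi, fi2, tolerance = 1e-9)  # uniform multiplier cancels

  none <- gen_peptide_table(strains = c("control", "host"),
                            substitution_rates = 0, seed = 15)
  expect_equal(substitution_fraction(none$table, "host", "T>K"), 0)
})

test_that("the threonine-peptide shift statistic recovers a planted shift", {
  # the subset equals the full set: zero shift, zero KS
  x <- stats::rnorm(200)
  all_eq <- thr_shift(x, seq_along(x), n_perm = 0)
  expect_equal(all_eq$shift, 0)
  expect_equal(all_eq$ks_statistic, 0)
  expect_equal(all_eq$p, 1)

  # realistic proteome scale: 3663 threonine peptides among 18059
  set.seed(44)
  n <- 18059; k <- 3663; delta <- -0.5; sigma <- 0.7
  fc <- stats::rnorm(n, 0, sigma)
  idx <- sample(n, k)
  fc[idx] <- fc[idx] + delta
  est <- thr_shift(fc, idx, n_perm = 200, seed = 3)
  # analytic oracle: the population value of median(subset) - median(all),
  # where "all" is the 80/20 normal mixture (the overall median moves too)
  w <- k / n
  med_all <- stats::uniroot(function(m)
    (1 - w) * stats::pnorm(m, 0, sigma) + w * stats::pnorm(m, delta, sigma) - 0.5,
    c(-1, 1), tol = 1e-10)$root
  true_shift <- delta - med_all
  expect_lt(abs(est$shift - true_shift), 0.05)
  expect_lt(est$p, 0.01)
  expect_gt(est$ks_statistic, 0.1)
})

test_that("the shift permutation p-value is uniform under the null", {
  n_sim <- 1000L
  pvals <- with_seed(505, {
    vapply(seq_len(n_sim), function(i) {
      x <- stats::rnorm(200)
      thr_shift(x, sample(200, 40), n_perm = 99)$p
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the moderated statistic reduces to the t statistic at s0 = 0", {
  set.seed(2)
  a <- matrix(stats::rnorm(30), 10, 3); b <- matrix(stats::rnorm(30), 10, 3)
  t0 <- moderated_t_s0(a, b, s0 = 0)
  for (i in 1:10) {
    expect_equal(t0[i], unname(stats::t.test(a[i, ], b[i, ],
                                             var.equal = TRUE)$statistic),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(moderated_t_s0(a, b, s0 = 1)) < abs(t0)))
  const <- matrix(5, 4, 3)
  expect_error(moderated_t_s0(const, const, s0 = 0), "degenerate")
})

test_that("permutation q-values equal an exhaustive-enumeration oracle", {
  set.seed(31)
  x <- matrix(stats::rnorm(60 * 6), 60, 6)
  x[1:6, 1:3] <- x[1:6, 1:3] + 3
  labels <- rep(c("A", "B"), each = 3)
  res <- permutation_fdr(x, "A", "B", group_labels = labels, seed = 1)
  expect_equal(attr(res, "n_permutations"), 20L)  # all C(6,3) splits

  # oracle: independent re-derivation with explicit loops
  tfun <- function(ca) {
    cb <- setdiff(1:6, ca)
    sapply(seq_len(nrow(x)), function(i) {
      ma <- mean(x[i, ca]); mb <- mean(x[i, cb])
      sp2 <- (2 * stats::var(x[i, ca]) + 2 * stats::var(x[i, cb])) / 4
      (ma - mb) / (sqrt(sp2 * (2 / 3)) + 1)
    })
  }
  tobs <- abs(tfun(1:3))
  perms <- utils::combn(6, 3, simplify = FALSE)
  permmat <- sapply(perms, function(p) abs(tfun(p)))
  qs <- sapply(seq_along(tobs), function(i) {
    fp <- stats::median(colSums(permmat >= tobs[i]))
    min(fp / sum(tobs >= tobs[i]), 1)
  })
  ord <- order(tobs, decreasing = TRUE)
  qs[ord] <- rev(cummin(rev(qs[ord])))
  expect_equal(res$q, qs, tolerance = 1e-12)
  expect_equal(res$t_mod, tfun(1:3), tolerance = 1e-12)
})

test_that("permutation FDR controls false positives under the null", {
  set.seed(71)
  x <- matrix(stats::rnorm(2000 * 6), 2000, 6)
  res <- permutation_fdr(x, "A", "B", group_labels = rep(c("A", "B"), each = 3),
                         seed = 4)
  expect_lte(mean(res$significant), 0.05 + 0.02)
  expect_true(all(res$q[res$significant] <= 0.05))
})

test_that("permutation FDR detects strong planted effects across seeds", {
  out <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(stats::rnorm(2000 * 6), 2000, 6)
    eff <- sample(2000, 100)          # 5% of rows, effect 4 sd
    x[eff, 1:3] <- x[eff, 1:3] + 4
    r <- permutation_fdr(x, "A", "B", group_labels = rep(c("A", "B"), each = 3),
                         seed = s)
    flagged <- which(r$significant)
    c(sens = mean(eff %in% flagged),
      fdr = if (length(flagged) > 0) mean(!flagged %in% eff) else 0)
  }, numeric(2))
  expect_gte(mean(out["sens", ]), 0.9)
  expect_lte(mean(out["fdr", ]), 0.1)
})
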