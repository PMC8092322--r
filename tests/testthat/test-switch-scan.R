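test_that("edit distance matches a brute-force oracle and is a metric", {
  expect_equal(edit_distance("ACGU", "ACGU"), 0L)
  expect_equal(edit_distance("ACGU", "ACGA"), 1L)
  expect_equal(edit_distance("ACGU", "AGU"), 1L)
  expect_equal(edit_distance("", "ACG"), 3L)

  set.seed(11)
  strs <- replicate(12, paste(sample(c("A", "C", "G", "U"),
                                     sample(3:7, 1), replace = TRUE),
                              collapse = ""))
  for (i in seq_along(strs)) {
    for (j in seq_along(strs)) {
      dij <- edit_distance(strs[i], strs[j])
      expect_equal(dij, oracle_edit_distance(strs[i], strs[j]))
      expect_equal(dij, edit_distance(strs[j], strs[i]))       # symmetry
      if (i == j) expect_equal(dij, 0L)                         # identity
      for (k in seq_along(strs)) {                              # triangle
        expect_lte(dij, edit_distance(strs[i], strs[k]) +
                        edit_distance(strs[k], strs[j]))
      }
    }
  }
})

test_that("closest nonequal neighbour excludes duplicates and breaks ties", {
  tmpl <- make_cloverleaf("CGU")
  mk <- function(id, seq) trna_gene(id, seq, structure = tmpl$structure)
  s0 <- tmpl$sequence
  s1 <- s0; substr(s1, 15, 15) <- "C"  # one substitution away (D loop)
  q <- mk("tRNA-Thr-CGT-1-1", s0)
  pool <- list(mk("tRNA-Thr-CGT-1-2", s0),   # identical duplicate: excluded
               mk("tRNA-Thr-CGT-1-3", s1))
  ev <- closest_nonequal_neighbor(q, pool)
  expect_equal(ev$neighbor_id, "tRNA-Thr-CGT-1-3")
  expect_equal(ev$distance, 1L)
  expect_false(ev$switched)

  # two equidistant neighbours: lexicographically smaller id wins
  s2 <- s0; substr(s2, 16, 16) <- "G"
  pool2 <- list(mk("tRNA-Thr-CGT-9-9", s1), mk("tRNA-Thr-CGT-2-1", s2))
  expect_equal(closest_nonequal_neighbor(q, pool2)$neighbor_id, "tRNA-Thr-CGT-2-1")

  expect_error(closest_nonequal_neighbor(q, list(mk("dup", s0))), "no nonequal")
})

test_that("a planted anticodon switch is attributed to its family parent", {
  gp <- toy_pool(planted = data.frame(family = 2, copy = 2, to_anticodon = "CGU"),
                 seed = 5)
  switched_id <- gp$ground_truth$gene_id
  g <- gp$pool[[which(vapply(gp$pool, `[[`, character(1), "gene_id") == switched_id)]]
  ev <- closest_nonequal_neighbor(g, gp$pool[vapply(gp$pool, `[[`, character(1),
                                                    "gene_id") != switched_id])
  expect_true(ev$switched)
  expect_equal(ev$decoded_aa, "T")
  expect_equal(ev$neighbor_aa, "M")
  expect_match(ev$neighbor_id, "tRNA-Met")
})

test_that("count_switches recovers exactly the planted switch set", {
  expect_equal(count_switches(toy_pool(seed = 2)$pool)$n_switched, 0L)

  for (seed in 1:6) {
    planted <- data.frame(family = c(1, 2), copy = c(1, 3),
                          to_anticodon = c("CGU", "CGU"))
    gp <- toy_pool(planted = planted, seed = seed)
    cs <- count_switches(gp$pool)
    sw <- cs$events[cs$events$switched, ]
    planted_ids <- gp$ground_truth$gene_id
    # every planted gene is flagged; every switched pair involves a planted
    # gene (the other side being a family parent that reciprocally finds the
    # switched copy); the planted genes involved are exactly the planted set
    expect_true(all(planted_ids %in% sw$gene_id), info = paste("seed", seed))
    expect_true(all(sw$gene_id %in% planted_ids | sw$neighbor_id %in% planted_ids),
                info = paste("seed", seed))
    involved <- intersect(unique(c(sw$gene_id, sw$neighbor_id)), planted_ids)
    expect_setequal(involved, planted_ids)
    expect_gte(cs$n_switched_pairs, nrow(planted))
    # oracle: the flagged events equal an exhaustive all-pairs argmin scan
    d <- pool_distance_matrix(gp$pool)
    ids <- rownames(d)
    for (r in seq_len(nrow(cs$events))) {
      i <- match(cs$events$gene_id[r], ids)
      seqs <- vapply(gp$pool, `[[`, character(1), "sequence")
      keep <- seqs != seqs[i]
      expect_equal(cs$events$distance[r], min(d[i, keep]))
    }
  }
})

test_that("a CAU-to-CGU switch in a methionine family is reported Met-to-Thr", {
  fams <- data.frame(aa = "M", anticodon = "CAU", copies = 5L)
  gp <- gen_trna_pool(fams, planted_switches = data.frame(
    family = 1, copy = 4, to_anticodon = "CGU"), seed = 24)
  cs <- count_switches(gp$pool)
  ev <- cs$events[cs$events$gene_id == gp$ground_truth$gene_id, ]
  expect_true(ev$switched)
  expect_equal(ev$decoded_aa, "T")
  expect_equal(ev$neighbor_aa, "M")
})

test_that("switches creating stop-decoding anticodons need force", {
  fams <- data.frame(aa = "K", anticodon = "CUU", copies = 3L)
  expect_error(gen_trna_pool(fams, planted_switches = data.frame(
    family = 1, copy = 1, to_anticodon = "UUA"), seed = 1), "stop")
  gp <- gen_trna_pool(fams, planted_switches = data.frame(
    family = 1, copy = 1, to_anticodon = "UUA"), seed = 1, force = TRUE)
  expect_equal(gp$ground_truth$to_aa, "*")
})

test_that("p-distance and Jukes-Cantor transform behave across the domain", {
  expect_equal(p_distance("ACGU", "ACGU"), 0)
  expect_equal(p_distance("ACGU", "ACGA"), 0.25)
  expect_error(p_distance("ACG", "ACGU"), "equal length")

  expect_equal(as.numeric(jc_distance(0)), 0)
  expect_equal(as.numeric(jc_distance(0.1)), 0.10732, tolerance = 1e-4)
  d <- jc_distance(c(0.2, 0.75, 0.9), cap = 7)
  expect_equal(as.numeric(d[2:3]), c(7, 7))
  expect_equal(attr(d, "saturated"), c(FALSE, TRUE, TRUE))
})

test_that("neighbour joining solves the three-taxon system exactly", {
  d <- matrix(c(0, 5, 9,
                5, 0, 8,
                9, 8, 0), 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  # three-point formulas: x_A = (dAB + dAC - dBC)/2 etc.
  expected <- c(A = (5 + 9 - 8) / 2, B = (5 + 8 - 9) / 2, C = (9 + 8 - 5) / 2)
  tip_edges <- tr$edge[, 2] <= 3
  got <- stats::setNames(tr$edge.length[tip_edges],
                         tr$tip.label[tr$edge[tip_edges, 2]])
  expect_equal(got[names(expected)], expected)
})

test_that("neighbour joining recovers additive trees exactly", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:12, 1)
    true <- ape::rtree(n)
    d <- ape::cophenetic.phylo(true)
    rec <- nj_tree(d[true$tip.label, true$tip.label])
    expect_lt(max(abs(ape::cophenetic.phylo(rec)[true$tip.label, true$tip.label] - d)),
              1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), rec)), 0)
  }
})

test_that("equidistant taxa give a star-like tree with zero internal branches", {
  n <- 5
  d <- matrix(2, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(d) <- 0
  tr <- nj_tree(d)
  internal <- tr$edge[, 2] > n
  expect_true(all(abs(tr$edge.length[internal]) < 1e-12))
})

test_that("neighbour joining validates its input", {
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(matrix(c(0, 1, 3, 2, 0, 1, 3, 1, 0), 3, 3)), "symmetric")
})

test_that("bootstrap support separates planted clades and is reproducible", {
  set.seed(42)
  base <- paste(sample(c("A", "C", "G", "U"), 40, replace = TRUE), collapse = "")
  mutate_at <- function(s, pos, to) { for (p in pos) substr(s, p, p) <- to; s }
  cladeA <- mutate_at(base, 1:10, "A")
  cladeB <- mutate_at(base, 1:10, "C")   # 10 diagnostic columns
  jitter1 <- function(s, p) mutate_at(s, p, "G")
  seqs <- c(a1 = cladeA, a2 = jitter1(cladeA, 15), a3 = jitter1(cladeA, 16),
            b1 = cladeB, b2 = jitter1(cladeB, 17), b3 = jitter1(cladeB, 18))
  bs <- bootstrap_support(seqs, n_replicates = 100, seed = 7)
  # the a/b split must appear with support ~1
  split_rows <- vapply(strsplit(bs$support$taxa, ","), function(tx)
    setequal(tx, c("a1", "a2", "a3")) || setequal(tx, c("b1", "b2", "b3")),
    logical(1))
  expect_true(any(split_rows))
  expect_true(all(bs$support$support[split_rows] > 0.95))

  bs2 <- bootstrap_support(seqs, n_replicates = 100, seed = 7)
  expect_identical(bs$support, bs2$support)

  empty <- bootstrap_support(seqs, n_replicates = 0)
  expect_equal(nrow(empty$support), 0L)
})
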