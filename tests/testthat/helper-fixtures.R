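# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as naive loops/recursions, independent of the package
# code paths they check.

# Independent edit-distance oracle: plain recursive Wagner-Fischer on short
# strings (exponential without memoisation; keep inputs short).
oracle_edit_distance <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  sub_cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(oracle_edit_distance(substr(a, 2, nchar(a)), b) + 1L,
      oracle_edit_distance(a, substr(b, 2, nchar(b))) + 1L,
      oracle_edit_distance(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + sub_cost)
}

# Independent bracket-matching oracle for dot-bracket strings: stack walk
# returning only the pair list.
oracle_pairs <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  stack <- integer(0)
  out <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    if (chars[i] == ")") {
      out[[length(out) + 1L]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    }
  }
  do.call(rbind, out)
}

# Gene fixtures for the three causative tRNA mutations: a lysine tRNA
# (anticodon CUU), an elongator methionine tRNA (CAU), both on the 76-nt
# template with the anticodon at 34-36, and a 72-nt threonine tRNA (CGU,
# anticodon at 33-35, anticodon stem closed by the 28-40 pair).
table1_fixture_genes <- function() {
  lys <- make_cloverleaf("CUU", ac_loop = 7L, linker = 6L)
  met <- make_cloverleaf("CAU", ac_loop = 7L, linker = 6L)
  thr <- make_cloverleaf("CGU", ac_loop = 5L, linker = 4L)
  list(
    tK = trna_gene("tK(CUU)K", lys$sequence, structure = lys$structure),
    EMT2 = trna_gene("EMT2-tRNA-Met-CAT", met$sequence, structure = met$structure),
    TRT2 = trna_gene("TRT2-tRNA-Thr-CGT", thr$sequence, structure = thr$structure)
  )
}

# Small peptide table with fully controlled validity/missingness patterns.
toy_peptide_table <- function(values, groups_of = c(A = 3L, B = 3L)) {
  samples <- unlist(lapply(names(groups_of), function(g)
    paste0(g, seq_len(groups_of[[g]]))))
  groups <- data.frame(sample = samples,
                       group = rep(names(groups_of), groups_of),
                       stringsAsFactors = FALSE)
  feats <- data.frame(sequence = paste0("PEPT", seq_len(nrow(values))),
                      protein = paste0("P", seq_len(nrow(values))),
                      variant_class = "base", site = NA_integer_,
                      stringsAsFactors = FALSE)
  peptide_table(values, feats, groups)
}

# A standard three-family pool (Lys/Met/Thr) with optional planted switches.
toy_pool <- function(planted = NULL, copies = c(6L, 5L, 4L), seed = 1L,
                     mutation_rate = 0.02) {
  fams <- data.frame(aa = c("K", "M", "T"),
                     anticodon = c("CUU", "CAU", "UGU"),
                     copies = copies)
  gen_trna_pool(fams, mutation_rate = mutation_rate,
                planted_switches = planted, seed = seed)
}
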