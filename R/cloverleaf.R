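#' Parse a dot-bracket secondary structure
#'
#' Stack-based parser for `(`, `)`, `.` dot-bracket strings. Returns the base
#' pairs (properly nested by construction), the maximal helices (runs of
#' stacked pairs) and the hairpin loops in 5'-to-3' order. Characters other
#' than `(`, `)` and `.` signal pseudoknot notation or corruption and are
#' rejected.
#'
#' All indices in the returned object are 1-based.
#'
#' @param sequence RNA sequence (only its length is used; may be `NULL`).
#' @param dotbracket dot-bracket string.
#' @return object of class `cloverleaf`: list with `pairs` (two-column integer
#'   matrix, `i < j`), `helices` (list of pair-index vectors), `hairpin_loops`
#'   (list of integer position vectors, 5'-to-3') and `length`.
#' @examples
#' parse_cloverleaf("GGGAAACCC", "(((...)))")
#' @export
parse_cloverleaf <- function(sequence = NULL, dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  n <- length(chars)
  if (!is.null(sequence) && nchar(sequence) != n) {
    stop("sequence and dot-bracket string differ in length", call. = FALSE)
  }
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad) > 0L) {
    stop("pseudoknot or invalid structure character(s): ",
         paste(sQuote(bad), collapse = ", "),
         "; only '(', ')' and '.' are supported", call. = FALSE)
  }
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  plist <- vector("list", n)
  k <- 0L
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      open <- c(open, i)
    } else if (chars[i] == ")") {
      if (length(open) == 0L) {
        stop("unbalanced brackets: unmatched ')' at position ", i, call. = FALSE)
      }
      k <- k + 1L
      plist[[k]] <- c(open[length(open)], i)
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0L) {
    stop("unbalanced brackets: unmatched '(' at position ", open[1], call. = FALSE)
  }
  pairs <- if (k > 0L) do.call(rbind, plist[seq_len(k)]) else matrix(integer(0), ncol = 2)
  if (k > 0L) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]

  partner <- integer(n)
  if (k > 0L) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }

  # helices: maximal runs of stacked pairs (i, j), (i+1, j-1)
  helices <- list()
  if (k > 0L) {
    cur <- 1L
    run <- c(1L)
    while (cur < k + 1L) {
      nxt <- if (cur < k) cur + 1L else NA_integer_
      stacked <- !is.na(nxt) &&
        pairs[nxt, 1] == pairs[cur, 1] + 1L && pairs[nxt, 2] == pairs[cur, 2] - 1L
      if (stacked) {
        run <- c(run, nxt)
      } else {
        helices[[length(helices) + 1L]] <- run
        if (!is.na(nxt)) run <- c(nxt)
      }
      cur <- cur + 1L
    }
  }

  # hairpin loops: unpaired stretch directly closed by a pair with nothing
  # paired inside
  hairpins <- list()
  if (k > 0L) {
    for (r in seq_len(k)) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (j > i + 1L && all(partner[(i + 1L):(j - 1L)] == 0L)) {
        hairpins[[length(hairpins) + 1L]] <- (i + 1L):(j - 1L)
      }
    }
    hairpins <- hairpins[order(vapply(hairpins, min, integer(1)))]
  }

  structure(
    list(pairs = pairs, helices = helices, hairpin_loops = hairpins,
         partner = partner, length = n, dotbracket = dotbracket),
    class = "cloverleaf"
  )
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat("<cloverleaf> ", x$length, " nt, ", nrow(x$pairs), " pairs, ",
      length(x$helices), " helices, ", length(x$hairpin_loops),
      " hairpin loops\n", sep = "")
  invisible(x)
}

#' Locate the anticodon of a tRNA gene
#'
#' With a secondary structure, the anticodon is the middle three bases of the
#' *second* hairpin loop in 5'-to-3' order (the anticodon loop of the
#' cloverleaf); for a 7-nt loop these are loop positions 3-5, which in a
#' canonical 76-nt tRNA correspond to positions 34-36. Without a structure the
#' anticodon is parsed from the gene identifier and located in the sequence
#' (the occurrence closest to canonical position 34 when it occurs more than
#' once). The loop rule is used rather than a fixed offset because tRNA gene
#' lengths vary (some threonine tRNA genes are only 72 bp).
#'
#' @param gene a [trna_gene()].
#' @param method `"auto"` (structure if present, else header), `"structure"`,
#'   or `"header"`.
#' @param code genetic code.
#' @return object of class `anticodon_call`: list with `gene_id`, `anticodon`,
#'   `span` (1-based index triple), `codon`, `aa`, `is_stop`.
#' @export
locate_anticodon <- function(gene, method = c("auto", "structure", "header"),
                             code = genetic_code()) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (!is.null(gene$structure)) "structure" else "header"
  }
  if (method == "structure") {
    if (is.null(gene$structure)) {
      stop("gene ", gene$gene_id, " has no structure", call. = FALSE)
    }
    cl <- parse_cloverleaf(gene$sequence, gene$structure)
    if (length(cl$hairpin_loops) < 2L) {
      stop("ambiguous anticodon: structure of ", gene$gene_id,
           " has fewer than two hairpin loops", call. = FALSE)
    }
    loop <- cl$hairpin_loops[[2]]
    if (length(loop) < 5L) {
      stop("ambiguous anticodon: second hairpin loop of ", gene$gene_id,
           " is shorter than 5 nt", call. = FALSE)
    }
    span <- loop[floor((length(loop) - 3L) / 2L) + 1L:3L]
  } else {
    ac <- gene$header_anticodon
    if (is.na(ac)) {
      stop("gene_id ", gene$gene_id, " does not encode an anticodon", call. = FALSE)
    }
    hits <- gregexpr(ac, gene$sequence, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      stop("inconsistency: anticodon ", ac, " from gene_id ", gene$gene_id,
           " is absent from the sequence", call. = FALSE)
    }
    start <- hits[which.min(abs(hits - 34L))]
    span <- start + 0:2
  }
  anticodon <- substr(gene$sequence, span[1], span[3])
  dec <- decode_anticodon(anticodon, code)
  structure(
    list(gene_id = gene$gene_id, anticodon = anticodon, span = as.integer(span),
         codon = dec$codon, aa = dec$aa, is_stop = dec$is_stop),
    class = "anticodon_call"
  )
}

#' @export
print.anticodon_call <- function(x, ...) {
  cat("<anticodon_call> ", x$gene_id, ": anticodon ", x$anticodon,
      " at ", x$span[1], "-", x$span[3], ", codon ", x$codon, ", ",
      if (x$is_stop) "STOP" else AA_ONE_TO_THREE[[x$aa]], "\n", sep = "")
  invisible(x)
}

#' Apply a point mutation to a tRNA gene
#'
#' Takes an HGVS-like change string `"c.<pos> <ref>><alt>"` (1-based position
#' within the gene; `T` in the change is treated as `U`), verifies the
#' reference base, and returns the mutated gene together with the anticodon
#' call before and after and a classification of the effect:
#' `"anticodon_change"` when the mutated position lies in the anticodon span,
#' `"stem_change"` when it lies in a base-paired (helix) position, `"other"`
#' otherwise.
#'
#' @param gene a [trna_gene()].
#' @param change change string, e.g. `"c.35 T>G"` or `"c.40C>A"`.
#' @param code genetic code.
#' @return list with `gene` (mutated), `before`, `after` (anticodon calls),
#'   `position`, `ref`, `alt` and `effect`.
#' @export
apply_point_mutation <- function(gene, change, code = genetic_code()) {
  m <- regmatches(change, regexec(
    "^c\\.?\\s*([0-9]+)\\s*([ACGTUacgtu])\\s*>\\s*([ACGTUacgtu])$", change))[[1]]
  if (length(m) == 0L) {
    stop("cannot parse change string ", sQuote(change),
         "; expected \"c.<pos> <ref>><alt>\"", call. = FALSE)
  }
  pos <- as.integer(m[2])
  ref <- normalize_rna(m[3])
  alt <- normalize_rna(m[4])
  n <- nchar(gene$sequence)
  if (pos < 1L || pos > n) {
    stop("position ", pos, " out of range 1-", n, " for ", gene$gene_id, call. = FALSE)
  }
  have <- substr(gene$sequence, pos, pos)
  if (have != ref) {
    stop("reference mismatch at c.", pos, " of ", gene$gene_id,
         ": change says ", ref, " but sequence has ", have, call. = FALSE)
  }
  before <- locate_anticodon(gene, code = code)
  mutated <- gene
  substr(mutated$sequence, pos, pos) <- alt
  if (!is.null(gene$structure)) {
    after <- locate_anticodon(mutated, code = code)
  } else {
    # a point substitution cannot move the anticodon; reuse the located span
    # (the header of the mutated gene still names the old anticodon)
    ac <- substr(mutated$sequence, before$span[1], before$span[3])
    dec <- decode_anticodon(ac, code)
    after <- structure(
      list(gene_id = mutated$gene_id, anticodon = ac, span = before$span,
           codon = dec$codon, aa = dec$aa, is_stop = dec$is_stop),
      class = "anticodon_call")
  }
  effect <- if (pos %in% before$span) {
    "anticodon_change"
  } else if (!is.null(gene$structure) &&
             parse_cloverleaf(gene$sequence, gene$structure)$partner[pos] != 0L) {
    "stem_change"
  } else {
    "other"
  }
  list(gene = mutated, before = before, after = after,
       position = pos, ref = ref, alt = alt, effect = effect)
}
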