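#' Nearest-neighbour energy model for fixed RNA secondary structures
#'
#' Loads the packaged enthalpy/entropy parameter tables: stacking terms for
#' every doublet of adjacent Watson-Crick or G-U base pairs, and loop
#' initiation penalties for hairpin, bulge, internal and multibranch loops.
#' The temperature dependence is `dG(T) = dH - T * dS` with `T` in kelvin.
#' The shipped table has Turner-style magnitudes but is deliberately small
#' and simplified (no dangling ends, no coaxial stacking, wobble stacks
#' approximated as scaled A-U stacks); the model is used for *sign and
#' ordering* statements about variant stability, not for reproducing any
#' published energy to the decimal.
#'
#' @param stack_file optional path overriding the packaged stack table
#'   (TSV: `pair1`, `pair2`, `dH`, `dS`).
#' @param loop_file optional path overriding the packaged loop table
#'   (TSV: `type`, `size`, `dG37`, `dS`).
#' @return object of class `energy_model`.
#' @export
energy_model <- function(stack_file = NULL, loop_file = NULL) {
  if (is.null(stack_file)) {
    stack_file <- system.file("extdata", "stack-params.tsv", package = "trnaswitch",
                              mustWork = TRUE)
  }
  if (is.null(loop_file)) {
    loop_file <- system.file("extdata", "loop-params.tsv", package = "trnaswitch",
                             mustWork = TRUE)
  }
  st <- utils::read.delim(stack_file, stringsAsFactors = FALSE)
  lo <- utils::read.delim(loop_file, stringsAsFactors = FALSE)
  stacks <- stats::setNames(
    lapply(seq_len(nrow(st)), function(i) c(dH = st$dH[i], dS = st$dS[i])),
    paste(st$pair1, st$pair2, sep = "/"))
  structure(list(stacks = stacks, loops = lo,
                 canonical = c("AU", "UA", "CG", "GC", "GU", "UG")),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> ", length(x$stacks), " stack doublets, ",
      nrow(x$loops), " loop entries\n", sep = "")
  invisible(x)
}

.loop_term <- function(model, type, size) {
  lo <- model$loops
  if (startsWith(type, "multiloop")) {
    row <- lo[lo$type == type, ]
  } else {
    cand <- lo[lo$type == type, ]
    row <- cand[which.min(abs(cand$size - min(size, max(cand$size)))), ]
  }
  c(dH = 0, dS = row$dS[1])
}

#' Gibbs folding energy of a fixed tRNA secondary structure
#'
#' Evaluates `dG = sum_stacks (dH - T dS) + sum_loops (dH - T dS)` for the
#' given structure at a temperature in degrees Celsius. Pairs whose bases do
#' not form a Watson-Crick or G-U pair are not scored as pairs: the pair is
#' dissolved and absorbed into the surrounding loop (this is how a stem
#' mismatch created by a destabilising mutation is represented). The
#' computation is deterministic; a structure with no pairs has `dG = 0`.
#'
#' @param sequence RNA string.
#' @param structure a [parse_cloverleaf()] object or dot-bracket string.
#' @param t_celsius temperature in degrees Celsius.
#' @param model an [energy_model()].
#' @return Gibbs energy in kcal/mol.
#' @export
dg_fold <- function(sequence, structure, t_celsius = 37,
                    model = energy_model()) {
  sequence <- normalize_rna(sequence)
  if (is.character(structure)) structure <- parse_cloverleaf(sequence, structure)
  tk <- t_celsius + 273.15
  s <- strsplit(sequence, "")[[1]]

  pairs <- structure$pairs
  if (nrow(pairs) > 0L) {
    keep <- vapply(seq_len(nrow(pairs)), function(r) {
      paste0(s[pairs[r, 1]], s[pairs[r, 2]]) %in% model$canonical
    }, logical(1))
    pairs <- pairs[keep, , drop = FALSE]
  }
  n <- length(s)
  partner <- integer(n)
  if (nrow(pairs) > 0L) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  dH <- 0; dS <- 0
  add <- function(term) { dH <<- dH + term[["dH"]]; dS <<- dS + term[["dS"]] }

  if (nrow(pairs) > 0L) for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    # children: maximal pairs directly inside (i, j)
    children <- list()
    k <- i + 1L
    while (k < j) {
      if (partner[k] > k) {
        children[[length(children) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else {
        k <- k + 1L
      }
    }
    nc <- length(children)
    if (nc == 0L) {
      add(.loop_term(model, "hairpin", j - i - 1L))
    } else if (nc == 1L) {
      k <- children[[1]][1]; l <- children[[1]][2]
      left <- k - i - 1L; right <- j - l - 1L
      if (left == 0L && right == 0L) {
        key <- paste0(s[i], s[j], "/", s[k], s[l])
        term <- model$stacks[[key]]
        if (is.null(term)) {
          stop("energy model has no entry for stack doublet ", key, call. = FALSE)
        }
        add(term)
      } else if (left == 0L || right == 0L) {
        add(.loop_term(model, "bulge", left + right))
      } else {
        add(.loop_term(model, "internal", left + right))
      }
    } else {
      unpaired <- (j - i - 1L) - sum(vapply(children, function(p) p[2] - p[1] + 1L,
                                            integer(1)))
      add(.loop_term(model, "multiloop_base", NA))
      for (b in seq_len(nc + 1L)) add(.loop_term(model, "multiloop_branch", NA))
      for (u in seq_len(max(unpaired, 0L))) add(.loop_term(model, "multiloop_unpaired", NA))
    }
  }
  dH - tk * dS
}

#' Stability profile of a tRNA variant against a reference
#'
#' Evaluates the folding energy of a reference and a variant sequence on the
#' *same* structure template across a temperature grid (default the
#' 30/35/42 degree grid used for heat-stress work) and reports
#' `ddG(T) = dG_variant(T) - dG_reference(T)`. Pairs broken by the variant are
#' dissolved into loops by [dg_fold()]. The profile carries a
#' rapid-tRNA-decay flag: destabilisations with `ddG` strictly larger than
#' 2.65 kcal/mol at any requested temperature mark tRNAs that are typically
#' degraded by the RTD pathway.
#'
#' @param ref_seq,variant_seq RNA sequences of equal length.
#' @param structure dot-bracket string or [parse_cloverleaf()] object for the
#'   shared template.
#' @param temperatures numeric vector of temperatures in degrees Celsius.
#' @param threshold RTD destabilisation threshold in kcal/mol.
#' @param label variant label for printing.
#' @param model an [energy_model()].
#' @return object of class `stability_profile`: data.frame with `temperature`,
#'   `dG_ref`, `dG_variant`, `ddG`, plus attributes `rtd_flag`, `ddg_max`,
#'   `label`.
#' @export
ddg_variants <- function(ref_seq, variant_seq, structure,
                         temperatures = c(30, 35, 42), threshold = 2.65,
                         label = "variant", model = energy_model()) {
  prof <- data.frame(
    temperature = temperatures,
    dG_ref = vapply(temperatures, function(tc) dg_fold(ref_seq, structure, tc, model),
                    numeric(1)),
    dG_variant = vapply(temperatures, function(tc) dg_fold(variant_seq, structure, tc, model),
                        numeric(1)))
  prof$ddG <- prof$dG_variant - prof$dG_ref
  attr(prof, "ddg_max") <- max(prof$ddG)
  attr(prof, "rtd_flag") <- rtd_flag(max(prof$ddG), threshold)
  attr(prof, "label") <- label
  class(prof) <- c("stability_profile", "data.frame")
  prof
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("<stability_profile> ", attr(x, "label"), "; max ddG = ",
      round(attr(x, "ddg_max"), 3), " kcal/mol; RTD flag: ",
      attr(x, "rtd_flag"), "\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

#' Rapid-tRNA-decay destabilisation flag
#'
#' Variants whose folding-energy increase is strictly larger than the
#' threshold (2.65 kcal/mol by default) are flagged as substrates for rapid
#' tRNA degradation; a change of exactly the threshold is not flagged.
#'
#' @param ddg_max maximal `ddG` across temperatures, kcal/mol.
#' @param threshold flagging threshold, kcal/mol.
#' @return logical flag.
#' @export
rtd_flag <- function(ddg_max, threshold = 2.65) {
  stopifnot(is.finite(ddg_max))
  ddg_max > threshold
}

#' Synthetic threonine-tRNA isoform fixtures
#'
#' A synthetic 72-nt cloverleaf emulating the three alleles of a singleton
#' threonine tRNA gene studied in heat-stressed yeast: the reference allele
#' with an intact G28-C40 pair closing the anticodon stem, a destabilised
#' allele in which position 28 is mutated to U leaving a U-C mismatch, and a
#' re-stabilised allele in which position 40 is additionally mutated to A,
#' restoring a (noncognate) U-A pair. These are constructed molecules, not
#' database sequences; they reproduce the pairing topology of the alleles,
#' which is all the energy model scores.
#'
#' @return list with `structure` (dot-bracket) and `sequences` (named:
#'   `reference`, `destabilized`, `restabilized`).
#' @export
trt2_isoform_fixtures <- function() {
  base <- make_cloverleaf(anticodon = "CGU", ac_loop = 5L, linker = 4L)
  ref <- base$sequence
  stopifnot(substr(ref, 28, 28) == "G", substr(ref, 40, 40) == "C")
  destab <- ref; substr(destab, 28, 28) <- "U"
  restab <- destab; substr(restab, 40, 40) <- "A"
  list(structure = base$structure,
       sequences = c(reference = ref, destabilized = destab,
                     restabilized = restab))
}
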