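#' Build a synthetic canonical cloverleaf tRNA sequence
#'
#' Constructs a synthetic tRNA gene body with the canonical cloverleaf
#' architecture: 7-bp acceptor stem, 4-bp D stem with an 8-nt D loop, 4-bp
#' anticodon stem with a 5- or 7-nt anticodon loop, and a 5-bp T stem with a
#' 7-nt T loop. With the default 7-nt anticodon loop and 6-nt variable linker
#' the molecule is 76 nt and the anticodon sits at positions 34-36; with a
#' 5-nt loop and 4-nt linker it is 72 nt (the length of the yeast
#' threonine-tRNA gene `TRT2`) with the anticodon at 33-35 and the outermost
#' anticodon-stem pair joining positions 28 and 40.
#'
#' These are synthetic fixture molecules, not database sequences; they exist
#' so that every structural rule in the package can be exercised with known
#' ground truth.
#'
#' @param anticodon RNA 3-mer placed in the middle of the anticodon loop.
#' @param ac_loop anticodon loop length, 5 or 7.
#' @param linker length of the unpaired linker before the 3' acceptor strand
#'   (2-8 nt).
#' @return list with `sequence`, `structure` (dot-bracket), `anticodon_span`
#'   (1-based triple) and `mutable` (unpaired positions outside the anticodon,
#'   safe to mutate without touching pairing or identity).
#' @export
make_cloverleaf <- function(anticodon = "CGU", ac_loop = 7L, linker = 6L) {
  anticodon <- normalize_rna(anticodon)
  .assert_rna(anticodon, "anticodon")
  stopifnot(nchar(anticodon) == 3L, ac_loop %in% c(5L, 7L),
            linker >= 2L, linker <= 8L)
  loop_seq <- if (ac_loop == 7L) {
    paste0("UU", anticodon, "AA")
  } else {
    paste0("U", anticodon, "A")
  }
  segs <- list(
    acc5  = c("GGCGCGG", "((((((("),
    sp1   = c("UA", ".."),
    d5    = c("GCGC", "(((("),
    dloop = c("AGUUCAAA", "........"),
    d3    = c("GCGC", "))))"),
    sp2   = c("AU", ".."),
    ac5   = c("GCCG", "(((("),
    acl   = c(loop_seq, strrep(".", ac_loop)),
    ac3   = c("CGGC", "))))"),
    var   = c("AGGU", "...."),
    t5    = c("GGCGC", "((((("),
    tloop = c("UUCGAAU", "......."),
    t3    = c("GCGCC", ")))))"),
    link  = c(strrep("AAUCCAAU", 2L), strrep(".", 16L)),
    acc3  = c("CCGCGCC", ")))))))")
  )
  segs$link[1] <- substr(segs$link[1], 1L, linker)
  segs$link[2] <- strrep(".", linker)
  sequence <- paste(vapply(segs, `[`, character(1), 1L), collapse = "")
  dotbracket <- paste(vapply(segs, `[`, character(1), 2L), collapse = "")
  cl <- parse_cloverleaf(sequence, dotbracket)
  loop2 <- cl$hairpin_loops[[2]]
  span <- loop2[floor((length(loop2) - 3L) / 2L) + 1L:3L]
  unpaired <- which(cl$partner == 0L)
  mutable <- setdiff(unpaired, c(span, span[1] - 1L, span[3] + 1L))
  list(sequence = sequence, structure = dotbracket,
       anticodon_span = as.integer(span), mutable = as.integer(mutable))
}
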