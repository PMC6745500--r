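#' Read sequences from FASTA into a tibble
#'
#' Thin tidy wrapper around Biostrings; sequences come back as plain
#' character strings so alignment columns can be manipulated with base
#' string tools.
#'
#' @param path FASTA file.
#' @param type `"AA"` (default) or `"DNA"`.
#' @return Tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  tibble(id = names(set), seq = unname(as.character(set)))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `seqs`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path)
  invisible(seqs)
}

#' Write a phylogenetic tree to newick
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `tree`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(tree)
}

#' Global pairwise alignment utility
#'
#' Needleman-Wunsch global alignment with match/mismatch/gap scores
#' 1/-1/-2 (linear gaps), provided as a convenience for preparing aligned
#' domain pairs in tests and examples; production analyses are expected to
#' consume pre-aligned sequences.
#'
#' @param a,b Character scalars (sequences of the same alphabet).
#' @param type `"AA"` or `"DNA"`.
#' @return Tibble with one row: aligned `a`, `b` and the alignment `score`.
#' @export
align_pair <- function(a, b, type = c("AA", "DNA")) {
  type <- match.arg(type)
  alphabet <- if (type == "AA") Biostrings::AA_ALPHABET else Biostrings::DNA_ALPHABET
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  if (type == "AA") {
    letters20 <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")
    mat <- matrix(-1, 20, 20, dimnames = list(letters20, letters20))
    diag(mat) <- 1
  }
  al <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2
  )
  tibble(
    a = as.character(Biostrings::alignedPattern(al)),
    b = as.character(Biostrings::alignedSubject(al)),
    score = Biostrings::score(al)
  )
}
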