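# a generic KRAB-A-box-like consensus used as the default ancestor of the
# synthetic domain sets (synthetic sequence, not extracted from any database)
KRAB_A_CONSENSUS <- "VTFEDVAVYFSQEEWGLLDPAQRALYRDVMLENYRNLVSLG"

#' Simulate aligned KRAB A-box domains with a divergent variant cluster
#'
#' Standard (sK) domains diverge mildly from a shared consensus; variant
#' (vK) domains diverge strongly from the same consensus, emulating the
#' heterogeneous variant cluster of a KRAB domain tree. The model is
#' substitution-only (each column mutates independently to a uniformly
#' chosen different residue), so alignment length is preserved and the
#' expected p-distance of a sequence to the consensus equals its
#' divergence parameter.
#'
#' @param n_sk,n_vk Number of standard and variant domains (defaults
#'   60 and 20).
#' @param sk_consensus Ancestor/consensus amino-acid string.
#' @param divergence_sk,divergence_vk Per-column substitution
#'   probabilities (defaults 0.08 and 0.45).
#' @param seed Mandatory RNG seed.
#' @return List with `sequences` (tibble `id`, `seq`), `truth` (tibble
#'   `id`, `class`) and `consensus`.
#' @export
gen_krab_sequences <- function(n_sk = 60, n_vk = 20,
                               sk_consensus = KRAB_A_CONSENSUS,
                               divergence_sk = 0.08, divergence_vk = 0.45,
                               seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  set.seed(seed)
  cons <- strsplit(toupper(sk_consensus), "")[[1]]
  mutate_seq <- function(d) {
    hit <- runif(length(cons)) < d
    out <- cons
    out[hit] <- vapply(which(hit), function(i) sample(setdiff(AA20, cons[i]), 1), "")
    paste(out, collapse = "")
  }
  ids <- c(sprintf("sK%03d", seq_len(n_sk)), sprintf("vK%03d", seq_len(n_vk)))
  cls <- c(rep("sK", n_sk), rep("vK", n_vk))
  seqs <- c(vapply(seq_len(n_sk), function(i) mutate_seq(divergence_sk), ""),
            vapply(seq_len(n_vk), function(i) mutate_seq(divergence_vk), ""))
  list(
    sequences = tibble(id = ids, seq = seqs),
    truth = tibble(id = ids, class = cls),
    consensus = sk_consensus
  )
}

STOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]
SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

#' Simulate codon-sequence pairs evolved under a selectable omega
#'
#' Each pair consists of a stop-free random ancestor and a derived copy
#' produced by a Poisson number of proposed single-nucleotide
#' substitutions (`branch_length` expected proposals per nucleotide site).
#' Proposals creating a stop codon are redrawn (rejection sampling);
#' synonymous proposals are always accepted and nonsynonymous proposals
#' are accepted with probability `omega`, so the realized
#' nonsynonymous/synonymous rate ratio equals `omega`.
#'
#' @param n_pairs,n_codons Number of pairs and codons per sequence
#'   (defaults 100 and 150).
#' @param omega Relative acceptance probability of nonsynonymous changes
#'   (1 = neutral, 0 = fully purifying).
#' @param branch_length Expected substitution proposals per nucleotide
#'   site (default 0.3).
#' @param seed Mandatory RNG seed.
#' @return Tibble with `pair_id`, `seq_a` (ancestor), `seq_b` (derived);
#'   the simulated `omega` is attached as attribute `"omega"`.
#' @export
gen_codon_pairs <- function(n_pairs = 100, n_codons = 150, omega = 1,
                            branch_length = 0.3, seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (omega < 0) abort("omega must be >= 0")
  set.seed(seed)
  out <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    anc <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    der <- anc
    n_events <- rpois(1, branch_length * 3 * n_codons)
    for (e in seq_len(n_events)) {
      repeat {
        site <- sample.int(3 * n_codons, 1)
        cod_i <- (site - 1) %/% 3 + 1
        pos <- (site - 1) %% 3 + 1
        chars <- strsplit(der[cod_i], "")[[1]]
        nt <- sample(setdiff(NT, chars[pos]), 1)
        chars[pos] <- nt
        cand <- paste(chars, collapse = "")
        if (!(cand %in% STOP_CODONS)) break
      }
      syn <- translate_codon(cand) == translate_codon(der[cod_i])
      if (syn || runif(1) < omega) der[cod_i] <- cand
    }
    out[[p]] <- tibble(
      pair_id = sprintf("pair%04d", p),
      seq_a = paste(anc, collapse = ""),
      seq_b = paste(der, collapse = "")
    )
  }
  res <- bind_rows(out)
  attr(res, "omega") <- omega
  res
}
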