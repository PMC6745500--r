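GENETIC_CODE_STD <- Biostrings::GENETIC_CODE
NT <- c("A", "C", "G", "T")

translate_codon <- function(codon) unname(GENETIC_CODE_STD[codon])
is_stop <- function(codon) GENETIC_CODE_STD[codon] == "*"

# split an aligned coding sequence into codon strings
codon_split <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) abort("sequence length is not a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

# NG86 synonymous site count of one codon: enumerate its 9 single-nucleotide
# mutants; mutants creating a stop are excluded from the denominator
ng86_syn_sites <- function(codon) {
  aa <- translate_codon(codon)
  chars <- strsplit(codon, "")[[1]]
  syn <- 0L; valid <- 0L
  for (p in 1:3) {
    for (nt in setdiff(NT, chars[p])) {
      mut <- chars
      mut[p] <- nt
      mut_codon <- paste(mut, collapse = "")
      if (is_stop(mut_codon)) next
      valid <- valid + 1L
      if (translate_codon(mut_codon) == aa) syn <- syn + 1L
    }
  }
  3 * syn / valid
}

# pathway-averaged (Sd, Nd) between two codons; minimal substitution
# pathways passing through a stop codon are excluded; if every pathway is
# blocked, all pathways are used as a fallback
ng86_codon_diff <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- all_permutations(pos)
  path_sd <- numeric(0); path_nd <- numeric(0)
  blocked_sd <- numeric(0); blocked_nd <- numeric(0)
  to <- strsplit(c2, "")[[1]]
  for (ord in perms) {
    cur <- strsplit(c1, "")[[1]]
    sdd <- 0; ndd <- 0; blocked <- FALSE
    for (step in seq_along(ord)) {
      nxt <- cur
      nxt[ord[step]] <- to[ord[step]]
      cod_cur <- paste(cur, collapse = "")
      cod_nxt <- paste(nxt, collapse = "")
      if (is_stop(cod_nxt) && step < length(ord)) blocked <- TRUE
      if (translate_codon(cod_cur) == translate_codon(cod_nxt)) {
        sdd <- sdd + 1
      } else {
        ndd <- ndd + 1
      }
      cur <- nxt
    }
    if (blocked) {
      blocked_sd <- c(blocked_sd, sdd); blocked_nd <- c(blocked_nd, ndd)
    } else {
      path_sd <- c(path_sd, sdd); path_nd <- c(path_nd, ndd)
    }
  }
  if (length(path_sd) == 0) { path_sd <- blocked_sd; path_nd <- blocked_nd }
  c(sd = mean(path_sd), nd = mean(path_nd))
}

all_permutations <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

#' Nei-Gojobori (1986) dN/dS for an aligned codon pair
#'
#' Expected synonymous and nonsynonymous sites are counted per codon by
#' enumerating the nine single-nucleotide mutants against the standard
#' genetic code (stop-producing mutants excluded from the denominator) and
#' averaging over the two sequences; observed differences are averaged
#' over all minimal substitution pathways between differing codons,
#' excluding pathways that traverse a stop codon. Proportions are
#' Jukes-Cantor corrected, `d = -(3/4) log(1 - 4p/3)`, and the ratio is
#' `dN/dS`, undefined (`NA`) when `dS = 0`. Codon columns containing a gap
#' in either sequence are skipped.
#'
#' @param seq_a,seq_b Aligned coding sequences (equal length, multiple of
#'   3, DNA letters and `-`), no internal stop codons.
#' @return A `dnds_result` object with fields `S_sites`, `N_sites`, `Sd`,
#'   `Nd`, `pS`, `pN`, `dS`, `dN`, `dnds`, `n_codons`.
#' @export
ng86_dnds <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) abort("sequences must be aligned (equal length)")
  ca <- codon_split(seq_a)
  cb <- codon_split(seq_b)
  has_gap <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
  ca <- ca[!has_gap]; cb <- cb[!has_gap]
  if (length(ca) == 0) abort("no gap-free codon columns")
  bad <- !grepl("^[ACGT]{3}$", ca) | !grepl("^[ACGT]{3}$", cb)
  if (any(bad)) abort(paste0("invalid codon at position ", which(bad)[1]))
  if (any(is_stop(ca)) || any(is_stop(cb))) {
    abort(paste0("internal stop codon at codon ",
                 which(is_stop(ca) | is_stop(cb))[1]))
  }
  S <- (sum(vapply(ca, ng86_syn_sites, 0)) +
          sum(vapply(cb, ng86_syn_sites, 0))) / 2
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca), function(i) ng86_codon_diff(ca[i], cb[i]),
                  c(sd = 0, nd = 0))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p, what) {
    if (p >= 0.75) {
      abort(paste0("Jukes-Cantor correction undefined: ", what,
                   " proportion ", signif(p, 4), " >= 3/4"))
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS, "synonymous"); dN <- jc(pN, "nonsynonymous")
  structure(
    list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
         dS = dS, dN = dN,
         dnds = if (dS > 0) dN / dS else NA_real_,
         n_codons = length(ca)),
    class = "dnds_result"
  )
}

#' @export
print.dnds_result <- function(x, ...) {
  cat("<dnds_result> ", x$n_codons, " codons: dN = ", signif(x$dN, 4),
      ", dS = ", signif(x$dS, 4), ", dN/dS = ",
      if (is.na(x$dnds)) "undefined (dS = 0)" else signif(x$dnds, 4),
      "\n", sep = "")
  invisible(x)
}

#' dN/dS against the evolutionarily most distant ortholog(s)
#'
#' Selects the ortholog(s) whose species divergence age is maximal,
#' computes NG86 dN/dS per pairwise alignment with the human sequence,
#' and, when several species are equally distant, averages the defined
#' ratios. Undefined ratios (dS = 0) are excluded with a warning; if all
#' selected ratios are undefined the result is `NA`.
#'
#' @param human_seq Human coding sequence; each ortholog row carries its
#'   own pairwise alignment of this sequence.
#' @param orthologs Tibble with columns `species`, `age_my`, `seq_human`
#'   (the human sequence as aligned to that ortholog; defaults to
#'   `human_seq` when absent) and `seq` (the aligned ortholog sequence).
#' @return List with `ratio` (mean dN/dS over the most distant orthologs)
#'   and `detail` (per-ortholog tibble `species`, `age_my`, `dnds`).
#' @export
most_distant_dnds <- function(human_seq, orthologs) {
  stopifnot(all(c("species", "age_my", "seq") %in% names(orthologs)))
  if (nrow(orthologs) == 0) abort("need at least one ortholog with an age")
  sel <- orthologs[orthologs$age_my == max(orthologs$age_my), , drop = FALSE]
  ratios <- vapply(seq_len(nrow(sel)), function(i) {
    h <- if ("seq_human" %in% names(sel)) sel$seq_human[i] else human_seq
    ng86_dnds(h, sel$seq[i])$dnds
  }, 0)
  detail <- tibble(species = sel$species, age_my = sel$age_my, dnds = ratios)
  if (all(is.na(ratios))) {
    warn("all dN/dS ratios undefined (dS = 0) among most distant orthologs")
    return(list(ratio = NA_real_, detail = detail))
  }
  if (anyNA(ratios)) {
    warn("undefined dN/dS ratio(s) excluded from the average")
  }
  list(ratio = mean(ratios, na.rm = TRUE), detail = detail)
}
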