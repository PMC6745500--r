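#' Tidy the parameters of a fitted interaction mixture
#'
#' @param x A `mixture_fit` from [fit_mixture()].
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(term = c("pi", "lambda_ratio"),
         estimate = c(x$pi, x$lambda_ratio))
}

#' One-row summary of a fitted interaction mixture
#'
#' @param x A `mixture_fit` from [fit_mixture()].
#' @param ... Unused.
#' @return Tibble with fit diagnostics.
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(batch = x$batch, pi = x$pi, lambda_ratio = x$lambda_ratio,
         logLik = tail(x$loglik, 1), n_iter = x$n_iter,
         converged = x$converged, n_pairs = nrow(x$pairs))
}

#' Tidy an NG86 dN/dS decomposition
#'
#' @param x A `dnds_result` from [ng86_dnds()].
#' @param ... Unused.
#' @return One-row tibble with the site/difference decomposition and the
#'   corrected rates.
#' @method tidy dnds_result
#' @export
tidy.dnds_result <- function(x, ...) {
  as_tibble(x[c("S_sites", "N_sites", "Sd", "Nd", "pS", "pN",
                "dS", "dN", "dnds", "n_codons")])
}

#' Tidy a bait-correlation matrix into long format
#'
#' @param x A `kzfp_correlation` from [interactome_correlation()].
#' @param ... Unused.
#' @return Tibble with `bait_a`, `bait_b`, `r`.
#' @method tidy kzfp_correlation
#' @export
tidy.kzfp_correlation <- function(x, ...) {
  as_tibble(x$correlation, rownames = "bait_a") |>
    pivot_longer(-"bait_a", names_to = "bait_b", values_to = "r")
}

#' Tidy a consensus logo
#'
#' @param x A `consensus_logo` from [consensus_logo()].
#' @param ... Unused.
#' @return Tibble with per-column residue probabilities and the column's
#'   information content.
#' @method tidy consensus_logo
#' @export
tidy.consensus_logo <- function(x, ...) {
  left_join(x$probabilities, x$information, by = "column")
}
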