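#' Bait-expression quality control
#'
#' A biological replicate of a bait passes QC when the bait protein itself
#' was detected with strictly more than `min_count` spectral counts in each
#' of its technical replicates, ensuring adequate bait levels before any
#' interaction is scored. Failing one biological replicate excludes only
#' that replicate; the bait is dropped only when all replicates fail.
#'
#' @param x A [count_matrix()].
#' @param bait Bait id; the bait protein must be present in the prey
#'   universe under the same id.
#' @param min_count QC threshold (default 10, strict).
#' @return Tibble with one row per biological replicate: `bait_id`,
#'   `batch`, `bio_replicate`, `pass`.
#' @export
qc_bait_expression <- function(x, bait, min_count = 10) {
  stopifnot(inherits(x, "count_matrix"))
  if (!(bait %in% x$preys)) {
    abort(paste0("bait protein '", bait, "' absent from prey universe"))
  }
  br <- runs_of(x, bait)
  if (nrow(br) == 0) abort(paste0("no runs for bait '", bait, "'"))
  br$count <- x$counts[bait, br$run_id]
  br |>
    group_by(.data$bait_id, .data$batch, .data$bio_replicate) |>
    summarise(pass = all(.data$count > min_count), .groups = "drop")
}

# run metadata of a bait restricted to QC-passing biological replicates
passing_runs <- function(x, bait, min_count = 10) {
  qc <- qc_bait_expression(x, bait, min_count = min_count)
  ok <- qc[qc$pass, c("batch", "bio_replicate")]
  br <- runs_of(x, bait)
  semi_join(br, ok, by = c("batch", "bio_replicate"))
}

#' Fold change of prey counts over batch-matched negative controls
#'
#' The CRAPome-style average fold change: mean spectral count across the
#' bait's QC-passing runs divided by the mean across the control runs of
#' the same batch(es). A control mean below `pseudocount` is replaced by
#' `pseudocount` (denominator only), so preys absent from controls get a
#' finite enrichment.
#'
#' @param x A [count_matrix()].
#' @param bait Bait id.
#' @param prey Optional character vector of prey ids; defaults to every
#'   prey except the bait itself.
#' @param pseudocount Floor for the control mean (default 0.5).
#' @param min_count Bait-expression QC threshold passed to
#'   [qc_bait_expression()]; set to `-Inf` to use all runs.
#' @return Tibble with `bait_id`, `prey_id`, `avg_fc`, `log2_fc`.
#' @export
fold_change <- function(x, bait, prey = NULL, pseudocount = 0.5,
                        min_count = 10) {
  stopifnot(inherits(x, "count_matrix"))
  br <- passing_runs(x, bait, min_count = min_count)
  if (nrow(br) == 0) {
    abort(paste0("bait '", bait, "' has no QC-passing runs"))
  }
  batches <- unique(br$batch)
  cr <- runs_of(x, "CONTROL", batch = batches)
  if (nrow(cr) == 0) abort(paste0("no control runs in batch(es) of '", bait, "'"))
  if (is.null(prey)) prey <- setdiff(x$preys, bait)
  missing_prey <- setdiff(prey, x$preys)
  if (length(missing_prey) > 0) {
    abort(paste0("unknown prey: ", missing_prey[1]))
  }
  bait_mean <- rowMeans(x$counts[prey, br$run_id, drop = FALSE])
  ctrl_mean <- rowMeans(x$counts[prey, cr$run_id, drop = FALSE])
  avg_fc <- bait_mean / pmax(ctrl_mean, pseudocount)
  tibble(
    bait_id = bait, prey_id = prey,
    avg_fc = unname(avg_fc), log2_fc = log2(unname(avg_fc))
  )
}

#' Fit the two-component Poisson interaction mixture for one MS batch
#'
#' A transparent empirical-Bayes stand-in for spectral-count interaction
#' scoring. Within a batch, a prey's counts in a bait's runs are either
#' background, `Poisson(lambda0)` with a prey-specific rate shared with
#' the batch controls, or a true interaction,
#' `Poisson(lambda_ratio * lambda0)` with a global enrichment factor. All
#' three ingredients - the prior weight `pi` of the true component, the
#' enrichment `lambda_ratio`, and every per-prey background rate - are
#' estimated jointly by EM over the batch's controls plus all (bait, prey)
#' pairs, so a prey whose few control counts happen to fluctuate low still
#' gets an accurate background rate from its counts across the other
#' baits. Control means serve as the initialization of the background
#' rates. Posterior interaction probabilities follow by Bayes rule from
#' the converged fit, which is deterministic given the data (fixed
#' initialization, no randomness).
#'
#' @param x A [count_matrix()].
#' @param batch Batch id (must contain at least 2 control runs).
#' @param pi_init,ratio_init EM initialization (defaults 0.05 and 5).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param lambda0_floor Floor on the per-prey background rates
#'   (default 0.1) avoiding degenerate zero-rate likelihoods.
#' @param min_count Bait QC threshold (runs of failing replicates are
#'   excluded from the fit).
#' @return A `mixture_fit` object: fitted `pi`, `lambda_ratio`, per-prey
#'   `lambda0`, the log-likelihood trace (bait pairs plus controls), a
#'   convergence flag and a `pairs` tibble with per-pair posterior
#'   probabilities.
#' @export
fit_mixture <- function(x, batch, pi_init = 0.05, ratio_init = 5,
                        tol = 1e-8, max_iter = 1000,
                        lambda0_floor = 0.1, min_count = 10) {
  stopifnot(inherits(x, "count_matrix"))
  runs <- x$runs[x$runs$batch == batch, , drop = FALSE]
  if (nrow(runs) == 0) abort(paste0("unknown batch: ", batch))
  ctrl <- runs$run_id[runs$bait_id == "CONTROL"]
  if (length(ctrl) < 2) abort("mixture fit requires >= 2 control runs in the batch")
  m <- length(ctrl)
  ctrl_tot <- rowSums(x$counts[, ctrl, drop = FALSE])
  ctrl_lfact <- rowSums(lgamma(x$counts[, ctrl, drop = FALSE] + 1))

  baits_all <- unique(runs$bait_id[runs$bait_id != "CONTROL"])
  baits <- character(0)
  S_cols <- list(); lf_cols <- list(); nvec <- integer(0)
  for (b in baits_all) {
    br <- passing_runs(x, b, min_count = min_count)
    br <- br[br$batch == batch, , drop = FALSE]
    if (nrow(br) == 0) next
    baits <- c(baits, b)
    k <- x$counts[, br$run_id, drop = FALSE]
    S_cols[[b]] <- rowSums(k)
    lf_cols[[b]] <- rowSums(lgamma(k + 1))
    nvec <- c(nvec, nrow(br))
  }
  if (length(baits) == 0) abort("no QC-passing bait runs in batch")
  S <- do.call(cbind, S_cols)         # prey x bait totals
  lfact <- do.call(cbind, lf_cols)
  W <- matrix(1, nrow(S), ncol(S), dimnames = dimnames(S))
  for (b in intersect(baits, x$preys)) W[b, b] <- 0   # self pairs excluded

  lambda0 <- pmax(ctrl_tot / m, lambda0_floor)
  pi_hat <- pi_init
  r_hat <- ratio_init
  trace <- numeric(0)
  converged <- FALSE
  N <- matrix(nvec, nrow(S), ncol(S), byrow = TRUE)

  for (it in seq_len(max_iter)) {
    L0 <- lambda0 * N
    ll0 <- -L0 + S * log(lambda0) - lfact
    ll1 <- -r_hat * L0 + S * log(r_hat * lambda0) - lfact
    la <- log(pi_hat) + ll1
    lb <- log1p(-pi_hat) + ll0
    mx <- pmax(la, lb)
    ll_pair <- mx + log(exp(la - mx) + exp(lb - mx))
    ll_ctrl <- -m * lambda0 + ctrl_tot * log(lambda0) - ctrl_lfact
    trace <- c(trace, sum(W * ll_pair) + sum(ll_ctrl))
    resp <- W / (1 + exp(lb - la))

    pi_new <- min(max(sum(resp) / sum(W), 1e-6), 1 - 1e-6)
    eff_n <- (resp * r_hat + (W - resp)) * N
    lambda_new <- pmax((ctrl_tot + rowSums(W * S)) / (m + rowSums(eff_n)),
                       lambda0_floor)
    denom <- sum(resp * lambda_new * N)
    r_new <- if (denom > 0) max(sum(resp * S) / denom, 1 + 1e-6) else r_hat
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    pi_hat <- pi_new
    r_hat <- r_new
    lambda0 <- lambda_new
  }

  L0 <- lambda0 * N
  la <- log(pi_hat) - r_hat * L0 + S * log(r_hat * lambda0) - lfact
  lb <- log1p(-pi_hat) - L0 + S * log(lambda0) - lfact
  post <- 1 / (1 + exp(lb - la))
  keep <- which(W == 1, arr.ind = TRUE)
  pairs <- tibble(
    bait_id = baits[keep[, 2]], prey_id = x$preys[keep[, 1]],
    n_runs = nvec[keep[, 2]], total = S[keep],
    posterior = post[keep]
  ) |> arrange(.data$bait_id, .data$prey_id)

  structure(
    list(
      batch = batch, pi = pi_hat, lambda_ratio = r_hat,
      lambda0 = lambda0, loglik = trace, converged = converged,
      n_iter = length(trace), pairs = pairs
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> batch ", x$batch, ": pi = ", signif(x$pi, 4),
      ", lambda_ratio = ", signif(x$lambda_ratio, 4),
      ", ", nrow(x$pairs), " pairs, ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iter, " iterations\n", sep = "")
  invisible(x)
}

#' Closed-form posterior of the two-component Poisson model
#'
#' Bayes-rule posterior probability that a single observed count comes
#' from the enriched component, given fixed model parameters. Exposed for
#' transparency and testing; [fit_mixture()] applies the same rule across
#' a pair's replicate runs.
#'
#' @param k Observed count(s).
#' @param lambda0 Background rate.
#' @param pi Prior weight of the enriched component.
#' @param lambda_ratio Enrichment factor of the true component (> 1).
#' @return Posterior probabilities in `[0, 1]`, same length as `k`.
#' @export
posterior_prob <- function(k, lambda0, pi, lambda_ratio) {
  l1 <- dpois(k, lambda_ratio * lambda0, log = TRUE) + log(pi)
  l0 <- dpois(k, lambda0, log = TRUE) + log1p(-pi)
  1 / (1 + exp(l0 - l1))
}

#' Bayesian false discovery rate of posterior-ranked interactions
#'
#' Pairs are ranked by decreasing posterior probability; the BFDR of the
#' accept-set down to rank k is the mean of (1 - posterior) over that set,
#' and each pair is tagged with the BFDR of the smallest accept-set that
#' contains it. Along the ranking the BFDR is automatically non-decreasing.
#'
#' @param posterior Numeric vector of posterior probabilities in `[0, 1]`.
#' @return Numeric vector of BFDR values aligned with the input.
#' @export
bfdr <- function(posterior) {
  stopifnot(all(posterior >= 0 & posterior <= 1, na.rm = TRUE))
  out <- rep(NA_real_, length(posterior))
  idx <- which(!is.na(posterior))
  if (length(idx) == 0) return(out)
  ord <- idx[order(posterior[idx], decreasing = TRUE)]
  out[ord] <- cumsum(1 - posterior[ord]) / seq_along(ord)
  out
}

#' Score every bait-prey pair of an experiment
#'
#' Runs the full scoring stage: per-batch mixture fits ([fit_mixture()]),
#' CRAPome-style average fold changes ([fold_change()]) and a global BFDR
#' over the pooled pair list (mirroring an experiment-wide probabilistic
#' model estimated from all baits and all controls). Baits whose
#' biological replicates all fail QC are reported with `qc_pass = FALSE`
#' and no posterior.
#'
#' @param x A [count_matrix()].
#' @param config A [pipeline_config()]; thresholds `qc_min_count` and
#'   `pseudocount` are used here.
#' @return Tibble with one row per scored (bait, prey) pair: `bait_id`,
#'   `prey_id`, `batch`, `avg_fc`, `log2_fc`, `posterior`, `bfdr`,
#'   `qc_pass`.
#' @export
score_interactions <- function(x, config = pipeline_config()) {
  stopifnot(inherits(x, "count_matrix"))
  baits <- unique(x$runs$bait_id[x$runs$bait_id != "CONTROL"])
  fits <- lapply(unique(x$runs$batch), function(bt) {
    fit_mixture(x, bt,
                lambda0_floor = config$lambda0_floor,
                min_count = config$qc_min_count)
  })
  post <- bind_rows(lapply(fits, function(f) {
    mutate(f$pairs, batch = f$batch)
  }))

  fcs <- bind_rows(lapply(baits, function(b) {
    qc <- qc_bait_expression(x, b, min_count = config$qc_min_count)
    if (!any(qc$pass)) {
      fc <- fold_change(x, b, pseudocount = config$pseudocount,
                        min_count = -Inf)
      fc$qc_pass <- FALSE
    } else {
      fc <- fold_change(x, b, pseudocount = config$pseudocount,
                        min_count = config$qc_min_count)
      fc$qc_pass <- TRUE
    }
    fc
  }))

  scores <- left_join(fcs,
                      post[, c("bait_id", "prey_id", "batch", "posterior")],
                      by = c("bait_id", "prey_id"))
  scores$bfdr <- bfdr(scores$posterior)
  scores[, c("bait_id", "prey_id", "batch", "avg_fc", "log2_fc",
             "posterior", "bfdr", "qc_pass")]
}

#' Keep significant interactions at the pipeline thresholds
#'
#' An interaction is retained when its bait passed expression QC, its
#' BFDR is strictly below `bfdr_max` and its average fold change over
#' controls is strictly above `fc_min`.
#'
#' @param scores Tibble from [score_interactions()].
#' @param bfdr_max BFDR threshold (default 0.01, strict `<`).
#' @param fc_min Fold-change threshold (default 2, strict `>`).
#' @return The filtered score tibble.
#' @export
call_significant <- function(scores, bfdr_max = 0.01, fc_min = 2) {
  qc <- if ("qc_pass" %in% names(scores)) scores$qc_pass else TRUE
  scores[qc & !is.na(scores$bfdr) & scores$bfdr < bfdr_max &
           scores$avg_fc > fc_min, , drop = FALSE]
}
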