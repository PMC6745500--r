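#' Configuration of the synthetic AP-MS experiment
#'
#' Defines the study conditions emulated by [gen_apms()]: baits purified in
#' `bio_reps` biological x `tech_reps` technical replicates alongside
#' batch-local negative-control runs, prey-specific Poisson background
#' rates shared between controls and bait runs, and a fixed multiplicative
#' enrichment on true interactions.
#'
#' @param n_baits,n_preys,n_controls Number of baits, generic preys, and
#'   control runs per batch (defaults 50, 400, 12).
#' @param bio_reps,tech_reps Biological and technical replicates per bait
#'   (defaults 2 and 2).
#' @param true_edge_rate Probability that a (bait, prey) pair is a true
#'   interaction (default 0.05).
#' @param enrichment_factor Multiplicative fold on the background mean for
#'   true interactions (default 8; must exceed 1).
#' @param background_shape,background_scale Gamma hyperparameters of the
#'   prey-specific background rates (defaults 2 and 1).
#' @param bait_self_count_mean Poisson mean of the bait protein's own
#'   counts in its runs (default 60, comfortably above the expression QC).
#' @param n_batches Number of MS batches; baits are assigned round-robin
#'   and each batch gets its own controls (default 1).
#' @param overdispersion Optional gamma-mixing variance inflating the
#'   Poisson noise (0 = pure Poisson, the model the scorer assumes).
#' @param seed Mandatory RNG seed.
#' @return A validated `apms_sim_config` list.
#' @export
apms_sim_config <- function(n_baits = 50, n_preys = 400, n_controls = 12,
                            bio_reps = 2, tech_reps = 2,
                            true_edge_rate = 0.05, enrichment_factor = 8,
                            background_shape = 2, background_scale = 1,
                            bait_self_count_mean = 60, n_batches = 1,
                            overdispersion = 0, seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (enrichment_factor <= 1) abort("enrichment_factor must be > 1")
  if (true_edge_rate <= 0 || true_edge_rate >= 1) {
    abort("true_edge_rate must be in (0, 1)")
  }
  structure(
    list(n_baits = n_baits, n_preys = n_preys, n_controls = n_controls,
         bio_reps = bio_reps, tech_reps = tech_reps,
         true_edge_rate = true_edge_rate,
         enrichment_factor = enrichment_factor,
         background_shape = background_shape,
         background_scale = background_scale,
         bait_self_count_mean = bait_self_count_mean,
         n_batches = n_batches, overdispersion = overdispersion,
         seed = as.integer(seed)),
    class = "apms_sim_config"
  )
}

#' Simulate an AP-MS spectral-count experiment with known truth
#'
#' Control runs draw every prey from `Poisson(lambda0_prey)`; a bait's runs
#' draw non-interacting preys from the same background and true
#' interactions from `Poisson(enrichment_factor * lambda0_prey)`; the bait
#' protein itself appears at `Poisson(bait_self_count_mean)`. Bait proteins
#' are part of the prey universe (under their own ids) so expression QC is
#' computable. The serialized truth is sufficient for exact confusion
#' matrices downstream.
#'
#' @param config An [apms_sim_config()].
#' @return List with `matrix` (a [count_matrix()]) and `truth` (list with
#'   `edges`, `lambda0`, `config`).
#' @export
gen_apms <- function(config) {
  stopifnot(inherits(config, "apms_sim_config"))
  set.seed(config$seed)
  preys <- sprintf("prey%04d", seq_len(config$n_preys))
  baits <- sprintf("bait%03d", seq_len(config$n_baits))
  universe <- c(preys, baits)
  lambda0 <- rgamma(length(universe), shape = config$background_shape,
                    scale = config$background_scale)
  names(lambda0) <- universe

  # any protein of the universe, including other baits, can be a true
  # interactor; only the bait's own protein is excluded (self-association
  # is not an interaction)
  edge_draw <- matrix(runif(length(universe) * config$n_baits) <
                        config$true_edge_rate,
                      nrow = length(universe),
                      dimnames = list(universe, baits))
  for (b in baits) edge_draw[b, b] <- FALSE
  edges <- which(edge_draw, arr.ind = TRUE)
  truth_edges <- tibble(
    bait_id = baits[edges[, 2]], prey_id = universe[edges[, 1]],
    enrichment = config$enrichment_factor
  )

  batches <- sprintf("batch%02d", seq_len(config$n_batches))
  bait_batch <- setNames(rep(batches, length.out = config$n_baits), baits)

  run_rows <- list()
  for (bt in batches) {
    run_rows[[length(run_rows) + 1]] <- tibble(
      run_id = sprintf("%s_ctrl%02d", bt, seq_len(config$n_controls)),
      bait_id = "CONTROL", batch = bt,
      bio_replicate = seq_len(config$n_controls), tech_replicate = 1L,
      control_kind = rep(c("gfp", "untransduced"),
                         length.out = config$n_controls)
    )
  }
  for (b in baits) {
    grid <- expand.grid(tech_replicate = seq_len(config$tech_reps),
                        bio_replicate = seq_len(config$bio_reps))
    run_rows[[length(run_rows) + 1]] <- tibble(
      run_id = sprintf("%s_b%dt%d", b, grid$bio_replicate,
                       grid$tech_replicate),
      bait_id = b, batch = unname(bait_batch[b]),
      bio_replicate = as.integer(grid$bio_replicate),
      tech_replicate = as.integer(grid$tech_replicate),
      control_kind = "none"
    )
  }
  runs <- bind_rows(run_rows)

  means <- matrix(lambda0, nrow = length(universe), ncol = nrow(runs),
                  dimnames = list(universe, runs$run_id))
  for (i in seq_len(nrow(runs))) {
    b <- runs$bait_id[i]
    if (b == "CONTROL") next
    hit <- truth_edges$prey_id[truth_edges$bait_id == b]
    means[hit, i] <- means[hit, i] * config$enrichment_factor
    means[b, i] <- config$bait_self_count_mean
  }
  if (config$overdispersion > 0) {
    g <- matrix(rgamma(length(means), shape = 1 / config$overdispersion,
                       scale = config$overdispersion),
                nrow = nrow(means))
    means <- means * g
  }
  counts <- matrix(rpois(length(means), means), nrow = nrow(means),
                   dimnames = dimnames(means))

  list(
    matrix = count_matrix(counts, runs),
    truth = list(
      edges = truth_edges,
      lambda0 = tibble(prey_id = universe, lambda0 = unname(lambda0)),
      config = config
    )
  )
}

#' Simulate bait localization classes and prey annotations with planted
#' nuclear/cytoplasmic conflicts
#'
#' Baits are labeled nuclear or mixed; a controlled number of preys that
#' truly interact with nuclear baits are annotated as exclusively
#' cytoplasmic, so the localization filter's recall can be measured
#' exactly. The number of marked preys is
#' `round(conflict_rate * n_distinct(preys of nuclear-bait true edges))`.
#' Non-conflict preys draw annotations that are never exclusively
#' cytoplasmic (including a share of unannotated preys), so no unplanted
#' edge can be removed.
#'
#' @param baits,preys Character vectors of bait and prey ids.
#' @param edges True edge tibble (`bait_id`, `prey_id`), e.g. from
#'   [gen_apms()] truth.
#' @param conflict_rate Fraction of eligible preys to mark (default 0.05).
#' @param nuclear_frac Fraction of baits labeled nuclear (default 0.7).
#' @param seed Mandatory RNG seed.
#' @return List with `bait_meta`, `prey_annotations` (long tibble
#'   `prey_id`, `cc_class`) and `planted` (conflict edge tibble).
#' @export
gen_localization <- function(baits, preys, edges, conflict_rate = 0.05,
                             nuclear_frac = 0.7, seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  set.seed(seed)
  bait_meta <- tibble(
    bait_id = baits,
    localization = ifelse(runif(length(baits)) < nuclear_frac,
                          "nuclear", "mixed"),
    krab_class = sample(c("sK", "vK"), length(baits), replace = TRUE,
                        prob = c(0.8, 0.2)),
    age_my = sample(c(30, 45, 105, 163, 320), length(baits), replace = TRUE),
    has_bbox = runif(length(baits)) < 0.5
  )
  nuclear <- bait_meta$bait_id[bait_meta$localization == "nuclear"]
  eligible <- intersect(unique(edges$prey_id[edges$bait_id %in% nuclear]),
                        preys)
  n_mark <- round(conflict_rate * length(eligible))
  marked <- if (n_mark > 0) sample(eligible, n_mark) else character(0)

  other <- setdiff(preys, marked)
  profile <- sample(4, length(other), replace = TRUE,
                    prob = c(0.5, 0.25, 0.15, 0.1))
  ann <- list(tibble(prey_id = marked,
                     cc_class = rep("cytoplasmic", length(marked))))
  ann <- c(ann, list(
    tibble(prey_id = other[profile == 1], cc_class = "nuclear"),
    tibble(prey_id = rep(other[profile == 2], each = 2),
           cc_class = rep(c("nuclear", "cytoplasmic"),
                          sum(profile == 2))),
    tibble(prey_id = other[profile == 3], cc_class = "other"),
    tibble(prey_id = other[profile == 4], cc_class = "unknown")
  ))
  planted <- edges[edges$bait_id %in% nuclear &
                     edges$prey_id %in% marked,
                   c("bait_id", "prey_id"), drop = FALSE]
  list(
    bait_meta = bait_meta,
    prey_annotations = bind_rows(ann),
    planted = planted
  )
}
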