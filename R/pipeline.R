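#' Pipeline configuration
#'
#' Collects every threshold of the scoring and filtering cascade with its
#' default. The configuration (plus seed) is serialized next to every
#' pipeline output for provenance.
#'
#' @param qc_min_count Bait-expression QC threshold (default 10, strict).
#' @param bfdr_max BFDR acceptance threshold (default 0.01, strict).
#' @param fc_min Fold-change acceptance threshold (default 2, strict).
#' @param pseudocount Control-mean floor for fold changes (default 0.5).
#' @param kap1fc_strong Strong/weak KAP1FC boundary (default 3, boundary
#'   strong).
#' @param kap1_id Prey id of KAP1 (default `"KAP1"`).
#' @param reciprocal_overlap Reciprocal interval-overlap threshold
#'   (default 0.10, inclusive).
#' @param macs_score_min Peak-score cut (default 80, strict).
#' @param tss_pad TSS window half-width in bases (default 2500).
#' @param coverage_min Coverage threshold of the LoF cascade (default 20).
#' @param lof_tail_frac Terminal CDS fraction where LoF calls are dropped
#'   (default 0.05).
#' @param lambda0_floor Background-rate floor of the mixture model
#'   (default 0.1).
#' @param seed Optional seed recorded for provenance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(qc_min_count = 10, bfdr_max = 0.01, fc_min = 2,
                            pseudocount = 0.5, kap1fc_strong = 3,
                            kap1_id = "KAP1", reciprocal_overlap = 0.10,
                            macs_score_min = 80, tss_pad = 2500,
                            coverage_min = 20, lof_tail_frac = 0.05,
                            lambda0_floor = 0.1, seed = NULL) {
  cfg <- list(qc_min_count = qc_min_count, bfdr_max = bfdr_max,
              fc_min = fc_min, pseudocount = pseudocount,
              kap1fc_strong = kap1fc_strong, kap1_id = kap1_id,
              reciprocal_overlap = reciprocal_overlap,
              macs_score_min = macs_score_min, tss_pad = tss_pad,
              coverage_min = coverage_min, lof_tail_frac = lof_tail_frac,
              lambda0_floor = lambda0_floor, seed = seed)
  num <- cfg[setdiff(names(cfg), c("seed", "kap1_id"))]
  if (any(unlist(num) <= 0)) abort("all thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Run the scoring-and-filtering cascade end to end
#'
#' Executes score -> significance filter -> localization filter ->
#' KAP1FC classification -> unique interactors -> network export, writing
#' TSV outputs, the GEXF network, a machine-readable attrition report and
#' the configuration used. Output is deterministic for a given input and
#' configuration.
#'
#' @param x A [count_matrix()].
#' @param bait_meta Tibble with `bait_id`, `localization` (and optionally
#'   `krab_class`).
#' @param prey_annotations Long tibble with `prey_id`, `cc_class`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `scores`, `interactome`, `kap1_calls`,
#'   `unique_interactors`, `attrition` and the written `paths`.
#' @export
run_pipeline <- function(x, bait_meta, prey_annotations,
                         config = pipeline_config(), out_dir) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  scores <- stage("score", score_interactions(x, config))
  sig <- stage("significance",
               call_significant(scores, bfdr_max = config$bfdr_max,
                                fc_min = config$fc_min))
  final <- stage("localization",
                 localization_filter(sig, bait_meta, prey_annotations))
  baits_ok <- unique(scores$bait_id[scores$qc_pass])
  kap1_calls <- NULL
  if (config$kap1_id %in% x$preys) {
    kap1_calls <- stage("kap1fc", bind_rows(lapply(baits_ok, function(b) {
      kap1_fc(x, b, kap1_id = config$kap1_id,
              strong_threshold = config$kap1fc_strong,
              pseudocount = config$pseudocount,
              min_count = config$qc_min_count)
    })))
  } else {
    inform(paste0("prey '", config$kap1_id,
                  "' not in matrix; KAP1FC stage skipped"))
  }
  uniq <- stage("unique_interactors", unique_interactors(final))
  attrition <- tibble(
    stage = c("scored_pairs", "significant", "after_localization"),
    n_edges = c(nrow(scores), nrow(sig), nrow(final))
  )
  paths <- c(
    scores = file.path(out_dir, "scores.tsv"),
    interactome = file.path(out_dir, "interactome.tsv"),
    unique_interactors = file.path(out_dir, "unique_interactors.tsv"),
    attrition = file.path(out_dir, "attrition.json"),
    config = file.path(out_dir, "config.yaml")
  )
  readr::write_tsv(scores, paths[["scores"]], progress = FALSE)
  readr::write_tsv(final, paths[["interactome"]], progress = FALSE)
  readr::write_tsv(uniq$baits, paths[["unique_interactors"]], progress = FALSE)
  jsonlite::write_json(attrition, paths[["attrition"]], auto_unbox = TRUE)
  yaml::write_yaml(unclass(config), paths[["config"]])
  if (!is.null(kap1_calls)) {
    paths[["kap1_calls"]] <- file.path(out_dir, "kap1_calls.tsv")
    readr::write_tsv(kap1_calls, paths[["kap1_calls"]], progress = FALSE)
  }
  net <- export_network(final, file.path(out_dir, "network"),
                        kap1_calls = kap1_calls, bait_meta = bait_meta)
  invisible(list(
    scores = scores, interactome = final, kap1_calls = kap1_calls,
    unique_interactors = uniq, attrition = attrition,
    paths = c(paths, net)
  ))
}
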