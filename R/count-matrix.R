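#' Spectral-count matrix with run metadata
#'
#' The primary input of the AP-MS pipeline: a prey x run matrix of unique,
#' proteotypic spectral counts together with the metadata describing each
#' LC-MS/MS run (bait, batch, biological and technical replicate, and
#' whether the run is a negative control).
#'
#' @param counts Numeric matrix of non-negative integer spectral counts.
#'   Rows are prey proteins (rownames mandatory), columns are runs
#'   (colnames mandatory, matching `runs$run_id`).
#' @param runs Data frame of run metadata with columns `run_id`, `bait_id`
#'   (`"CONTROL"` for negative-control runs), `batch`, `bio_replicate`,
#'   `tech_replicate` and `control_kind` (one of `"none"`, `"gfp"`,
#'   `"untransduced"`).
#'
#' @details Control semantics are enforced: `control_kind != "none"` exactly
#'   when `bait_id == "CONTROL"`, and every batch that contains bait runs
#'   must contain at least one control run, since fold changes and the
#'   mixture model are computed against batch-local controls.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix), `runs` (tibble) and `preys` (character).
#' @seealso [read_count_matrix()], [tidy.count_matrix()]
#' @export
count_matrix <- function(counts, runs) {
  runs <- as_tibble(runs)
  required <- c("run_id", "bait_id", "batch", "bio_replicate",
                "tech_replicate", "control_kind")
  missing_cols <- setdiff(required, names(runs))
  if (length(missing_cols) > 0) {
    abort(paste0("run metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry prey rownames and run colnames")
  }
  if (anyDuplicated(runs$run_id)) {
    abort("duplicated run_id in run metadata")
  }
  missing_meta <- setdiff(colnames(counts), runs$run_id)
  if (length(missing_meta) > 0) {
    abort(paste0("count column(s) without run metadata: ",
                 paste(missing_meta, collapse = ", ")))
  }
  runs <- runs[match(colnames(counts), runs$run_id), , drop = FALSE]
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts))
  if (length(bad) > 0) {
    abort(paste0("counts must be non-negative integers; offending value ",
                 counts[bad[1]], " at cell ", bad[1]))
  }
  storage.mode(counts) <- "integer"
  is_ctrl <- runs$bait_id == "CONTROL"
  if (any(is_ctrl != (runs$control_kind != "none"))) {
    off <- runs$run_id[which(is_ctrl != (runs$control_kind != "none"))[1]]
    abort(paste0("run ", off,
                 ": control_kind must be != 'none' iff bait_id == 'CONTROL'"))
  }
  bait_batches <- unique(runs$batch[!is_ctrl])
  ctrl_batches <- unique(runs$batch[is_ctrl])
  orphan <- setdiff(bait_batches, ctrl_batches)
  if (length(orphan) > 0) {
    abort(paste0("batch without any control run: ",
                 paste(orphan, collapse = ", ")))
  }
  structure(
    list(counts = counts, runs = runs, preys = rownames(counts)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  n_ctrl <- sum(x$runs$bait_id == "CONTROL")
  cat("<count_matrix> ", length(x$preys), " preys x ", ncol(x$counts),
      " runs (", n_ctrl, " controls, ",
      length(unique(x$runs$batch)), " batch(es), ",
      length(unique(x$runs$bait_id[x$runs$bait_id != "CONTROL"])),
      " baits)\n", sep = "")
  invisible(x)
}

#' Read a spectral-count matrix and its run metadata from TSV
#'
#' @param path TSV with a `prey_id` column followed by one column per run.
#' @param meta_path TSV with columns `run_id`, `bait_id`, `batch`,
#'   `bio_replicate`, `tech_replicate`, `control_kind`.
#' @return A validated [count_matrix()].
#' @export
read_count_matrix <- function(path, meta_path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tab)[1] != "prey_id") {
    abort("first column of a count table must be 'prey_id'")
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$prey_id
  count_matrix(counts, meta)
}

#' Write a count matrix to TSV (counts + run metadata)
#'
#' @param x A [count_matrix()].
#' @param path,meta_path Output TSV paths for counts and run metadata.
#' @return `x`, invisibly.
#' @export
write_count_matrix <- function(x, path, meta_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- bind_cols(tibble(prey_id = x$preys),
                   as_tibble(as.data.frame(x$counts)))
  readr::write_tsv(tab, path, progress = FALSE)
  readr::write_tsv(x$runs, meta_path, progress = FALSE)
  invisible(x)
}

#' Tidy a count matrix into long format
#'
#' @param x A [count_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (prey, run) cell, joined to run metadata.
#' @method tidy count_matrix
#' @export
tidy.count_matrix <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "prey_id") |>
    pivot_longer(-"prey_id", names_to = "run_id", values_to = "count")
  left_join(long, x$runs, by = "run_id")
}

# run ids of a bait's (or the controls') runs within an optional batch
runs_of <- function(x, bait, batch = NULL) {
  r <- x$runs
  if (!is.null(batch)) r <- r[r$batch %in% batch, , drop = FALSE]
  r[r$bait_id == bait, , drop = FALSE]
}
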