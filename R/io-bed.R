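#' Read a BED file into a tidy interval tibble
#'
#' Intervals are stored 0-based half-open, the native BED convention, and
#' are the only coordinate convention used inside the package (1-based
#' sources such as VCF are converted on ingest). Columns beyond the third
#' are interpreted per BED: column 4 is `name`, column 5 is `score`.
#' Intervals are returned sorted by (chrom, start, end).
#'
#' @param path Path to a BED3+ file (tab-separated, no header).
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name` and `score`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("BED line ", which(nf < 3)[1], ": fewer than 3 fields"))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    abort(paste0("BED line ", which(is.na(start) | is.na(end))[1],
                 ": non-numeric coordinates"))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    abort(paste0("BED line ", bad[1], ": invalid interval [",
                 start[bad[1]], ", ", end[bad[1]], ")"))
  }
  out <- tibble(chrom = chrom, start = as.integer(start), end = as.integer(end))
  if (max(nf) >= 4) {
    out$name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
  }
  if (max(nf) >= 5) {
    out$score <- suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, "")
    ))
  }
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write a tidy interval tibble as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optional
#'   `name`, `score` (0-based half-open).
#' @param path Output path.
#' @return `intervals`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  check_intervals(intervals)
  x <- arrange(intervals, .data$chrom, .data$start, .data$end)
  cols <- c("chrom", "start", "end")
  if ("score" %in% names(x) && !("name" %in% names(x))) x$name <- "."
  if ("name" %in% names(x)) cols <- c(cols, "name")
  if ("score" %in% names(x)) cols <- c(cols, "score")
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(intervals)
}

check_intervals <- function(x, arg = "intervals") {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort(paste0("`", arg, "` must have columns chrom, start, end"))
  }
  bad <- which(x$start >= x$end | x$start < 0)
  if (length(bad) > 0) {
    abort(paste0("`", arg, "` row ", bad[1], ": invalid interval [",
                 x$start[bad[1]], ", ", x$end[bad[1]], ")"))
  }
  invisible(x)
}

#' Convert 1-based inclusive coordinates to 0-based half-open intervals
#'
#' @param tbl Tibble with 1-based inclusive `start`, `end` columns.
#' @return The same tibble in 0-based half-open convention.
#' @export
from_one_based <- function(tbl) {
  tbl$start <- tbl$start - 1L
  check_intervals(tbl)
}

# tidy intervals -> GRanges (GRanges is 1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}
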