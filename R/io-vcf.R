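#' Read a minimal VCF subset into a tidy variant tibble
#'
#' Parses the VCF subset used by the loss-of-function constraint pipeline:
#' fixed columns CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO with the INFO tags
#' `GENE` (gene id), `CSQ` (`lof` or `other`) and `LOF_CONF`
#' (`high`/`low`/`flagged`/`na`). All other INFO content is ignored.
#' Records with more than one ALT allele are rejected by this reader:
#' multiallelic splitting is an explicit pipeline step
#' ([split_multiallelic()]) applied to raw record tibbles, not a side
#' effect of parsing.
#'
#' @param path VCF(-subset) file.
#' @return Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `filter_status`, `gene_id`, `consequence`, `lof_confidence`.
#' @export
read_variant_table <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_variants())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8)) {
    abort(paste0("VCF record ", which(nf < 8)[1], ": fewer than 8 fields"))
  }
  alt <- vapply(fields, `[[`, "", 5)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    abort(paste0("VCF record ", which(multi)[1],
                 ": multiallelic ALT; split records first (split_multiallelic)"))
  }
  info <- vapply(fields, `[[`, "", 8)
  tibble(
    chrom = vapply(fields, `[[`, "", 1),
    pos = as.integer(vapply(fields, `[[`, "", 2)),
    ref = vapply(fields, `[[`, "", 4),
    alt = alt,
    filter_status = vapply(fields, `[[`, "", 7),
    gene_id = info_tag(info, "GENE"),
    consequence = info_tag(info, "CSQ", default = "other"),
    lof_confidence = info_tag(info, "LOF_CONF", default = "na")
  )
}

info_tag <- function(info, tag, default = NA_character_) {
  pat <- paste0("(?:^|;)", tag, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else default, "")
}

empty_variants <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), filter_status = character(), gene_id = character(),
    consequence = character(), lof_confidence = character()
  )
}

#' Write a variant tibble as a minimal VCF subset
#'
#' @param variants Tibble as returned by [read_variant_table()].
#' @param path Output path.
#' @return `variants`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class: lof or other\">",
    "##INFO=<ID=LOF_CONF,Number=1,Type=String,Description=\"LoF confidence: high/low/flagged/na\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- paste(
    variants$chrom, variants$pos, ".", variants$ref, variants$alt, ".",
    variants$filter_status,
    paste0("GENE=", variants$gene_id,
           ";CSQ=", variants$consequence,
           ";LOF_CONF=", variants$lof_confidence),
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(variants)
}
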