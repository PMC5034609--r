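#' Write DMC/DMP/consistent-gene result tables
#'
#' Differentially methylated CpGs are written as BED6+ (`chrom`, 0-based
#' `start`, `end`, `name`, `score` = -log10(q) capped at 300, `strand` "."),
#' with `delta`, `p`, `q` and `direction` as extra columns. DMPs and the
#' consistent gene set are written as plain TSV. All files round-trip
#' through [read_dmc_bed()] and [readr::read_tsv()].
#'
#' @param dmcs DMC tibble from [call_dmcs()] (may be empty).
#' @param dmps DMP tibble from [call_dmps()] (may be empty).
#' @param consistent_set Consistent-gene tibble from [consistent_dmps()]
#'   (optional).
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of file paths.
#' @export
write_result_tables <- function(dmcs, dmps, consistent_set = NULL, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  paths <- c(
    dmc = file.path(out_dir, "dmc.bed"),
    dmp = file.path(out_dir, "dmp.tsv")
  )
  write_dmc_bed(dmcs, paths[["dmc"]])
  readr::write_tsv(dmps, paths[["dmp"]])
  if (!is.null(consistent_set)) {
    paths <- c(paths, consistent = file.path(out_dir, "consistent_genes.tsv"))
    readr::write_tsv(consistent_set, paths[["consistent"]])
  }
  paths
}

#' Write DMC records as BED6+
#'
#' @param dmcs DMC tibble (`chrom`, `pos`, `delta`, `p`, `q`, `direction`,
#'   `significant`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmc_bed <- function(dmcs, path) {
  hdr <- paste(c("#chrom", "start", "end", "name", "score", "strand",
                 "delta", "p", "q", "direction", "significant"),
               collapse = "\t")
  if (nrow(dmcs) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  score <- pmin(-log10(dmcs$q), 300)
  score[!is.finite(score)] <- 300
  bed <- tibble(
    chrom = dmcs$chrom,
    start = dmcs$pos - 1L,
    end = dmcs$pos,
    name = paste0(dmcs$chrom, ":", dmcs$pos),
    score = round(score, 4),
    strand = ".",
    delta = dmcs$delta, p = dmcs$p, q = dmcs$q,
    direction = dmcs$direction, significant = dmcs$significant
  )
  writeLines(hdr, path)
  readr::write_tsv(bed, path, col_names = FALSE, append = TRUE)
  invisible(path)
}

#' Read DMC records back from BED6+
#'
#' Inverse of [write_dmc_bed()]; restores 1-based cytosine positions.
#'
#' @param path BED6+ file written by [write_dmc_bed()].
#' @return A DMC tibble.
#' @export
read_dmc_bed <- function(path) {
  raw <- readr::read_tsv(
    path, comment = "#", col_names = c(
      "chrom", "start", "end", "name", "score", "strand",
      "delta", "p", "q", "direction", "significant"
    ),
    col_types = "ciicdcdddcl", progress = FALSE
  )
  tibble(
    chrom = raw$chrom, pos = raw$start + 1L,
    delta = raw$delta, p = raw$p, q = raw$q,
    direction = raw$direction, significant = raw$significant
  )
}

#' Write a CpG call table
#'
#' @param calls Call tibble from [read_cpg_calls()].
#' @param path Output path.
#' @param dialect Output dialect, as in [read_cpg_calls()].
#' @return `path`, invisibly.
#' @export
write_cpg_calls <- function(calls, path,
                            dialect = c("coverage_percent", "counts")) {
  dialect <- match.arg(dialect)
  if (dialect == "coverage_percent") {
    out <- tibble(
      chrom = calls$chrom, start = calls$pos, end = calls$pos,
      pct = 100 * calls$meth / (calls$meth + calls$unmeth),
      meth = calls$meth, unmeth = calls$unmeth
    )
  } else {
    out <- calls[, c("chrom", "pos", "meth", "unmeth")]
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write an interval set as BED3
#'
#' Converts the package's 1-based inclusive intervals back to 0-based
#' half-open BED.
#'
#' @param intervals Tibble `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_bed <- function(intervals, path) {
  out <- tibble(chrom = intervals$chrom,
                start = intervals$start - 1L,
                end = intervals$end)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
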