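#' Read a per-CpG methylation call table
#'
#' Reads bismark-coverage-style TSV files of per-CpG methylated and
#' unmethylated read counts. Two dialects are supported:
#'
#' * `"coverage_percent"`: six columns `chrom, start, end, percent, meth,
#'   unmeth` (the bismark coverage format; `start` is the 1-based cytosine
#'   position and the stated percentage is re-derived from the counts and
#'   checked to within 0.5 percentage points).
#' * `"counts"`: four columns `chrom, pos, meth, unmeth`.
#'
#' Input tables are assumed plus-strand-collapsed (one record per CpG dyad).
#' Callers that emit separate records for the two strands of a dyad can be
#' accommodated with `collapse_strands = TRUE`, which sums a record at
#' `pos + 1` into the plus-strand cytosine at `pos`.
#'
#' @param path Path to a TSV file (no header).
#' @param dialect `"coverage_percent"` or `"counts"`.
#' @param sample_id Sample identifier attached to the result (defaults to the
#'   file name without extension).
#' @param collapse_strands Sum adjacent-position records into one dyad.
#' @param assembly Optional character vector of valid chromosome names; rows
#'   on other chromosomes raise an error.
#'
#' @return A tibble with columns `chrom`, `pos` (1-based cytosine position),
#'   `meth`, `unmeth`, carrying a `sample_id` attribute.
#' @export
read_cpg_calls <- function(path,
                           dialect = c("coverage_percent", "counts"),
                           sample_id = NULL,
                           collapse_strands = FALSE,
                           assembly = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  n_col <- if (dialect == "coverage_percent") 6L else 4L
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    warn(sprintf("'%s' is empty; returning an empty call table", basename(path)))
    out <- tibble(chrom = character(), pos = integer(),
                  meth = integer(), unmeth = integer())
    attr(out, "sample_id") <- sample_id
    return(out)
  }
  if (ncol(raw) < n_col) {
    abort(sprintf("'%s': expected >= %d tab-separated columns for dialect '%s', found %d",
                  basename(path), n_col, dialect, ncol(raw)))
  }

  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort(sprintf("'%s' line %d: non-numeric %s value '%s'",
                    basename(path), bad[1], what, raw[[col]][bad[1]]))
    }
    v
  }

  if (dialect == "coverage_percent") {
    calls <- tibble(
      chrom = raw[[1]],
      pos = num(2, "position"),
      pct = num(4, "percentage"),
      meth = num(5, "methylated count"),
      unmeth = num(6, "unmethylated count")
    )
    total <- calls$meth + calls$unmeth
    recomputed <- if_else(total > 0, 100 * calls$meth / total, NA_real_)
    off <- which(total > 0 & abs(recomputed - calls$pct) > 0.5)
    if (length(off) > 0) {
      abort(sprintf(
        "'%s' line %d: stated %.2f%% disagrees with counts (%.2f%% from %d/%d)",
        basename(path), off[1], calls$pct[off[1]], recomputed[off[1]],
        calls$meth[off[1]], total[off[1]]
      ))
    }
    calls$pct <- NULL
  } else {
    calls <- tibble(
      chrom = raw[[1]],
      pos = num(2, "position"),
      meth = num(3, "methylated count"),
      unmeth = num(4, "unmethylated count")
    )
  }

  bad_pos <- which(calls$pos < 1 | calls$pos != floor(calls$pos))
  if (length(bad_pos) > 0) {
    abort(sprintf("'%s' line %d: invalid position %s",
                  basename(path), bad_pos[1], calls$pos[bad_pos[1]]))
  }
  if (any(calls$meth < 0 | calls$unmeth < 0)) {
    abort(sprintf("'%s': negative counts are not allowed", basename(path)))
  }
  if (!is.null(assembly)) {
    alien <- setdiff(unique(calls$chrom), assembly)
    if (length(alien) > 0) {
      abort(sprintf("'%s': chromosome(s) %s not in the declared assembly",
                    basename(path), paste(alien, collapse = ", ")))
    }
  }

  zero <- calls$meth + calls$unmeth == 0
  if (any(zero)) {
    warn(sprintf("'%s': dropping %d zero-depth row(s)", basename(path), sum(zero)))
    calls <- calls[!zero, , drop = FALSE]
  }

  calls <- calls %>%
    mutate(pos = as.integer(.data$pos),
           meth = as.integer(.data$meth),
           unmeth = as.integer(.data$unmeth)) %>%
    arrange(.data$chrom, .data$pos)

  if (collapse_strands) {
    calls <- collapse_dyads(calls)
  }
  dup <- calls %>% count(.data$chrom, .data$pos) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("'%s': duplicate CpG record at %s:%d",
                  basename(path), dup$chrom[1], dup$pos[1]))
  }
  attr(calls, "sample_id") <- sample_id
  calls
}

# Pair each plus-strand cytosine with a record at pos + 1 (its minus-strand
# mate) and sum the counts onto the plus-strand position.
collapse_dyads <- function(calls) {
  calls <- arrange(calls, .data$chrom, .data$pos)
  same_chrom <- c(calls$chrom[-1] == calls$chrom[-nrow(calls)], FALSE)
  gap1 <- c(diff(calls$pos) == 1L, FALSE) & same_chrom
  # greedy pairing left-to-right: a row already consumed as a mate cannot
  # start a new pair
  is_mate <- logical(nrow(calls))
  i <- 1L
  while (i < nrow(calls)) {
    if (gap1[i] && !is_mate[i]) {
      is_mate[i + 1L] <- TRUE
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  starts <- which(!is_mate)
  mate_of <- which(is_mate)
  merged <- calls[starts, , drop = FALSE]
  if (length(mate_of) > 0) {
    take <- match(mate_of - 1L, starts)
    merged$meth[take] <- merged$meth[take] + calls$meth[mate_of]
    merged$unmeth[take] <- merged$unmeth[take] + calls$unmeth[mate_of]
  }
  merged
}

#' Read gene models from refFlat or BED12
#'
#' @param path Path to the annotation file.
#' @param format `"refflat"` (UCSC refFlat column order, 0-based half-open
#'   coordinates) or `"bed12"`.
#'
#' @return A tibble with one row per transcript: `gene_id`, `symbol`,
#'   `chrom`, `strand`, `tx_start`, `tx_end` (1-based inclusive) and an
#'   `exons` list-column of `(start, end)` tibbles sorted along the
#'   chromosome.
#' @export
read_gene_models <- function(path, format = c("refflat", "bed12")) {
  format <- match.arg(format)
  raw <- readr::read_tsv(
    path, col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(tibble(gene_id = character(), symbol = character(),
                  chrom = character(), strand = character(),
                  tx_start = integer(), tx_end = integer(),
                  exons = list()))
  }

  split_ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1]])

  if (format == "refflat") {
    if (ncol(raw) < 11) abort("refFlat needs 11 columns")
    genes <- tibble(
      gene_id = raw[[1]], symbol = raw[[1]], chrom = raw[[3]],
      strand = raw[[4]],
      tx_start = as.integer(raw[[5]]) + 1L,
      tx_end = as.integer(raw[[6]]),
      exons = purrr::map2(raw[[10]], raw[[11]], function(s, e) {
        tibble(start = split_ints(s) + 1L, end = split_ints(e))
      })
    )
  } else {
    if (ncol(raw) < 12) abort("BED12 needs 12 columns")
    chrom_start <- as.integer(raw[[2]])
    genes <- tibble(
      gene_id = raw[[4]], symbol = raw[[4]], chrom = raw[[1]],
      strand = raw[[6]],
      tx_start = chrom_start + 1L,
      tx_end = as.integer(raw[[3]]),
      exons = purrr::pmap(
        list(chrom_start, raw[[11]], raw[[12]]),
        function(cs, sizes, offs) {
          sz <- split_ints(sizes); of <- split_ints(offs)
          tibble(start = cs + of + 1L, end = cs + of + sz)
        }
      )
    )
  }

  if (!all(genes$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  if (any(genes$tx_start > genes$tx_end)) {
    abort("transcript start beyond end")
  }
  for (i in seq_len(nrow(genes))) {
    ex <- arrange(genes$exons[[i]], .data$start)
    if (any(ex$start > ex$end) ||
        any(ex$start < genes$tx_start[i]) || any(ex$end > genes$tx_end[i])) {
      abort(sprintf("gene '%s': exon outside transcript bounds", genes$gene_id[i]))
    }
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      abort(sprintf("gene '%s': overlapping exons", genes$gene_id[i]))
    }
    genes$exons[[i]] <- ex
  }
  genes
}

#' Read a BED3+ interval file
#'
#' BED input is 0-based half-open; the result is 1-based inclusive, sorted
#' within each chromosome. Overlapping intervals are retained.
#'
#' @param path Path to a BED file.
#' @param name Label stored in the `name` attribute (e.g. `"CGI"`).
#' @return A tibble `chrom`, `start`, `end`.
#' @export
read_interval_bed <- function(path, name = "intervals") {
  raw <- readr::read_tsv(
    path, col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
    attr(out, "name") <- name
    return(out)
  }
  if (ncol(raw) < 3) abort("BED needs at least 3 columns")
  start0 <- as.integer(raw[[2]])
  end0 <- as.integer(raw[[3]])
  if (any(is.na(start0)) || any(is.na(end0))) abort("non-integer BED coordinates")
  bad <- which(start0 >= end0)
  if (length(bad) > 0) {
    abort(sprintf("line %d: empty or inverted BED interval [%d, %d)",
                  bad[1], start0[bad[1]], end0[bad[1]]))
  }
  out <- tibble(chrom = raw[[1]], start = start0 + 1L, end = end0) %>%
    arrange(.data$chrom, .data$start, .data$end)
  attr(out, "name") <- name
  out
}

#' Read a gene-by-sample FPKM expression table
#'
#' @param path TSV with a header row of sample identifiers and a first
#'   column of gene identifiers.
#' @return A wide tibble: `gene_id` plus one numeric FPKM column per sample.
#' @export
read_expression_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(tab) < 2) abort("expression table needs gene_id plus >= 1 sample")
  names(tab)[1] <- "gene_id"
  if (anyDuplicated(tab$gene_id)) {
    abort(sprintf("duplicated gene_id '%s'",
                  tab$gene_id[duplicated(tab$gene_id)][1]))
  }
  for (col in names(tab)[-1]) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (any(is.na(v) | is.nan(v))) {
      abort(sprintf("sample '%s': non-numeric or missing FPKM value", col))
    }
    if (any(v < 0)) {
      abort(sprintf("sample '%s': negative FPKM value", col))
    }
    tab[[col]] <- v
  }
  tab
}
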