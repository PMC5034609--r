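## Genomic context assignment.
##
## Region definitions: a promoter spans 1 kb upstream of the TSS through
## 500 bp downstream (1500 bp, TSS base included in the downstream part);
## the gene body runs from the end of the promoter to the TTS; CpG-island
## shores are the 2 kb flanks of an island and shelves the next 2 kb, with
## precedence island > shore > shelf. Internally everything is 1-based
## inclusive; IRanges/GenomicRanges do the interval arithmetic.

gr_intervals <- function(tb) {
  GenomicRanges::GRanges(
    tb$chrom, IRanges::IRanges(start = tb$start, end = tb$end)
  )
}

gr_positions <- function(tb) {
  GenomicRanges::GRanges(
    tb$chrom, IRanges::IRanges(start = tb$pos, width = 1L)
  )
}

gr_to_tibble <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
}

#' Build the promoter / gene-body / exon / CGI-band feature catalog
#'
#' Transcript models are collapsed per `gene_id` (union of exons, 5'-most
#' TSS, 3'-most TTS). For a plus-strand gene with TSS `t` the promoter is
#' `[t - promoter_up, t + promoter_down - 1]` and the gene body
#' `[t + promoter_down, TTS]`; minus-strand genes mirror this arithmetic.
#' Genes too short to extend past the promoter get an empty gene body.
#' Island/shore/shelf bands are made mutually disjoint with precedence
#' island > shore > shelf; bands from different islands are unioned.
#'
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param cgis CpG-island interval tibble from [read_interval_bed()].
#' @param cfg [analysis_config()] (promoter and band widths).
#' @return A list of class `feature_catalog` with tibbles `promoters`,
#'   `gene_bodies` (both keyed by `gene_id`), `exons` (collapsed union),
#'   `islands`, `shores`, `shelves`, plus the collapsed `genes` table.
#' @export
build_feature_catalog <- function(genes, cgis, cfg = analysis_config()) {
  cfg <- as_config(cfg)

  if (nrow(genes) == 0) {
    empty_keyed <- tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character())
    bands <- cgi_bands(cgis, cfg$shore_bp, cfg$shelf_bp)
    return(structure(
      list(genes = genes, promoters = empty_keyed, gene_bodies = empty_keyed,
           exons = tibble(chrom = character(), start = integer(),
                          end = integer()),
           islands = bands$island, shores = bands$shore,
           shelves = bands$shelf),
      class = "feature_catalog"
    ))
  }

  collapsed <- genes %>%
    group_by(.data$gene_id) %>%
    summarise(
      symbol = .data$symbol[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      n_chrom = dplyr::n_distinct(.data$chrom),
      n_strand = dplyr::n_distinct(.data$strand),
      tx_start = min(.data$tx_start),
      tx_end = max(.data$tx_end),
      exons = list(bind_rows(.data$exons)),
      .groups = "drop"
    )
  if (any(collapsed$n_chrom > 1) || any(collapsed$n_strand > 1)) {
    abort("a gene_id maps to several chromosomes or strands; cannot collapse")
  }
  collapsed <- select(collapsed, -"n_chrom", -"n_strand")

  plus <- collapsed$strand == "+"
  tss <- if_else(plus, collapsed$tx_start, collapsed$tx_end)
  tts <- if_else(plus, collapsed$tx_end, collapsed$tx_start)

  prom_start <- if_else(plus, tss - cfg$promoter_up,
                        tss - cfg$promoter_down + 1L)
  prom_end <- if_else(plus, tss + cfg$promoter_down - 1L,
                      tss + cfg$promoter_up)
  promoters <- tibble(
    gene_id = collapsed$gene_id, chrom = collapsed$chrom,
    start = pmax(prom_start, 1L), end = prom_end,
    strand = collapsed$strand
  )

  body_start <- if_else(plus, tss + cfg$promoter_down, tts)
  body_end <- if_else(plus, tts, tss - cfg$promoter_down)
  gene_bodies <- tibble(
    gene_id = collapsed$gene_id, chrom = collapsed$chrom,
    start = body_start, end = body_end, strand = collapsed$strand
  ) %>%
    filter(.data$start <= .data$end)

  exon_tb <- collapsed %>%
    select("gene_id", "chrom", "exons") %>%
    tidyr::unnest("exons")
  exon_union <- if (nrow(exon_tb) > 0) {
    gr_to_tibble(GenomicRanges::reduce(gr_intervals(exon_tb)))
  } else {
    tibble(chrom = character(), start = integer(), end = integer())
  }

  bands <- cgi_bands(cgis, cfg$shore_bp, cfg$shelf_bp)

  structure(
    list(
      genes = collapsed, promoters = promoters, gene_bodies = gene_bodies,
      exons = exon_union,
      islands = bands$island, shores = bands$shore, shelves = bands$shelf
    ),
    class = "feature_catalog"
  )
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat("<feature_catalog>\n")
  cat(sprintf("  genes: %d  promoters: %d  gene bodies: %d  exon blocks: %d\n",
              nrow(x$genes), nrow(x$promoters), nrow(x$gene_bodies),
              nrow(x$exons)))
  cat(sprintf("  CGI islands: %d  shores: %d  shelves: %d\n",
              nrow(x$islands), nrow(x$shores), nrow(x$shelves)))
  invisible(x)
}

cgi_bands <- function(cgis, shore_bp, shelf_bp) {
  empty <- tibble(chrom = character(), start = integer(), end = integer())
  if (nrow(cgis) == 0) {
    return(list(island = empty, shore = empty, shelf = empty))
  }
  isl <- GenomicRanges::reduce(gr_intervals(cgis))

  band <- function(inner_lo, inner_hi) {
    # inner_lo..inner_hi are offsets (bp) beyond the island edge
    left <- tibble(
      chrom = as.character(GenomicRanges::seqnames(isl)),
      start = GenomicRanges::start(isl) - inner_hi,
      end = GenomicRanges::start(isl) - inner_lo
    )
    right <- tibble(
      chrom = as.character(GenomicRanges::seqnames(isl)),
      start = GenomicRanges::end(isl) + inner_lo,
      end = GenomicRanges::end(isl) + inner_hi
    )
    both <- bind_rows(left, right) %>%
      mutate(start = pmax(.data$start, 1L)) %>%
      filter(.data$start <= .data$end)
    if (nrow(both) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(gr_intervals(both))
  }

  shore <- GenomicRanges::setdiff(band(1L, shore_bp), isl)
  shelf_raw <- band(shore_bp + 1L, shore_bp + shelf_bp)
  shelf <- GenomicRanges::setdiff(GenomicRanges::setdiff(shelf_raw, isl), shore)

  list(island = gr_to_tibble(isl), shore = gr_to_tibble(shore),
       shelf = gr_to_tibble(shelf))
}

# query and subject may legitimately use different chromosome sets
# (e.g. positions on chromosomes with no annotated feature), so the
# seqlevel mismatch warning is noise here
quiet_overlaps <- function(f, query, subject, ...) {
  suppressWarnings(f(query, subject, ...))
}

overlaps_any <- function(pos_gr, tb) {
  if (nrow(tb) == 0) return(logical(length(pos_gr)))
  quiet_overlaps(IRanges::overlapsAny, pos_gr, gr_intervals(tb))
}

#' Assign each CpG position its genic context
#'
#' Labels each position `promoter`, `exon`, `intron` or `intergenic`, with
#' precedence promoter > exon > intron when a position overlaps several
#' feature kinds across genes. `gene_ids` lists every gene whose promoter
#' contains the position.
#'
#' @param positions Tibble with `chrom` and `pos`.
#' @param catalog A [build_feature_catalog()] result.
#' @return `positions` with added `genic` and `gene_ids` (list) columns.
#' @export
assign_genic_context <- function(positions, catalog) {
  stopifnot(inherits(catalog, "feature_catalog"))
  pos_gr <- gr_positions(positions)

  known <- unique(c(catalog$promoters$chrom, catalog$gene_bodies$chrom,
                    catalog$exons$chrom))
  alien <- setdiff(unique(positions$chrom), known)
  if (length(alien) > 0) {
    warn(sprintf("positions on chromosome(s) %s match no annotated feature; labelled intergenic",
                 paste(alien, collapse = ", ")))
  }

  in_prom <- overlaps_any(pos_gr, catalog$promoters)
  in_exon <- overlaps_any(pos_gr, catalog$exons)
  in_body <- overlaps_any(pos_gr, catalog$gene_bodies)

  genic <- dplyr::case_when(
    in_prom ~ "promoter",
    in_exon ~ "exon",
    in_body ~ "intron",
    TRUE ~ "intergenic"
  )

  gene_ids <- rep(list(character()), nrow(positions))
  if (nrow(catalog$promoters) > 0) {
    hits <- quiet_overlaps(GenomicRanges::findOverlaps, pos_gr,
                           gr_intervals(catalog$promoters))
    if (length(hits) > 0) {
      by_pos <- split(
        catalog$promoters$gene_id[S4Vectors::subjectHits(hits)],
        S4Vectors::queryHits(hits)
      )
      gene_ids[as.integer(names(by_pos))] <- lapply(by_pos, unique)
    }
  }

  positions %>% mutate(genic = genic, gene_ids = gene_ids)
}

#' Assign each CpG position its CpG-island context
#'
#' Labels each position `island`, `shore`, `shelf` or `open_sea` with
#' precedence island > shore > shelf; bands from any island may assign a
#' position.
#'
#' @inheritParams assign_genic_context
#' @return `positions` with an added `cgi` column.
#' @export
assign_cgi_context <- function(positions, catalog) {
  stopifnot(inherits(catalog, "feature_catalog"))
  pos_gr <- gr_positions(positions)
  cgi <- dplyr::case_when(
    overlaps_any(pos_gr, catalog$islands) ~ "island",
    overlaps_any(pos_gr, catalog$shores) ~ "shore",
    overlaps_any(pos_gr, catalog$shelves) ~ "shelf",
    TRUE ~ "open_sea"
  )
  mutate(positions, cgi = cgi)
}

#' Annotate CpG positions with genic and CGI context
#'
#' Convenience wrapper running [assign_genic_context()] and
#' [assign_cgi_context()].
#'
#' @inheritParams assign_genic_context
#' @return `positions` with `genic`, `cgi` and `gene_ids` columns.
#' @export
annotate_cpgs <- function(positions, catalog) {
  positions %>%
    assign_genic_context(catalog) %>%
    assign_cgi_context(catalog)
}

#' Fraction of features covered by at least two CpGs
#'
#' @param positions Tibble with `chrom` and `pos` (distinct CpG positions).
#' @param features Interval tibble (`chrom`, `start`, `end`), one row per
#'   feature.
#' @return A one-row tibble: `n_features`, `n_covered` (features containing
#'   >= 2 distinct positions) and `fraction`.
#' @export
region_cpg_coverage <- function(positions, features) {
  if (nrow(features) == 0) abort("empty feature set")
  pos <- distinct(positions, .data$chrom, .data$pos)
  n_in <- quiet_overlaps(GenomicRanges::countOverlaps, gr_intervals(features),
                         gr_positions(pos))
  tibble(
    n_features = nrow(features),
    n_covered = sum(n_in >= 2),
    fraction = sum(n_in >= 2) / nrow(features)
  )
}
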