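#' Construct a methylome matrix
#'
#' A `methylome` holds per-CpG methylated and total read counts across
#' samples: a `sites` tibble (`chrom`, `pos`), a `samples` metadata tibble
#' (`sample_id`, `lineage`, `day`, `treatment`), and two integer matrices
#' `meth` and `depth` of dimension sites x samples.
#'
#' @param sites Tibble with `chrom` and `pos`.
#' @param samples Sample metadata tibble (see [sample_meta()]).
#' @param meth,depth Integer matrices, sites x samples, with
#'   `0 <= meth <= depth`.
#' @return An object of class `methylome`.
#' @export
methylome <- function(sites, samples, meth, depth) {
  stopifnot(
    is_tibble(sites), all(c("chrom", "pos") %in% names(sites)),
    is_tibble(samples), "sample_id" %in% names(samples),
    is.matrix(meth), is.matrix(depth),
    nrow(meth) == nrow(sites), ncol(meth) == nrow(samples),
    all(dim(meth) == dim(depth))
  )
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id")
  if (anyDuplicated(paste(sites$chrom, sites$pos))) {
    abort("duplicate (chrom, pos) site")
  }
  if (any(meth < 0) || any(depth < 0) || any(meth > depth)) {
    abort("need 0 <= meth <= depth elementwise")
  }
  colnames(meth) <- colnames(depth) <- samples$sample_id
  structure(
    list(sites = sites, samples = samples,
         meth = meth, depth = depth),
    class = "methylome"
  )
}

#' Sample metadata for the nine-sample adipogenesis design
#'
#' @param sample_id Unique sample identifier.
#' @param lineage `"BAT"`, `"WAT"` or `"BWAT"` (norepinephrine-treated WAT).
#' @param day Differentiation day, one of 0, 4 or 6 by default.
#' @param treatment `"none"` or `"NE"`.
#' @param allowed_days Integer days the design permits.
#' @return A tibble with one row per sample.
#' @export
sample_meta <- function(sample_id, lineage, day, treatment = "none",
                        allowed_days = c(0L, 4L, 6L)) {
  if (!all(lineage %in% c("BAT", "WAT", "BWAT"))) {
    abort("lineage must be BAT, WAT or BWAT")
  }
  if (!all(day %in% allowed_days)) {
    abort(sprintf("day must be one of %s", paste(allowed_days, collapse = ", ")))
  }
  if (!all(treatment %in% c("none", "NE"))) {
    abort("treatment must be 'none' or 'NE'")
  }
  tibble(sample_id = sample_id, lineage = lineage,
         day = as.integer(day), treatment = treatment)
}

#' The default nine-sample study design
#'
#' Three lineages (brown adipocytes, white adipocytes, norepinephrine-treated
#' white adipocytes) sampled at differentiation days 0, 4 and 6.
#'
#' @return A nine-row sample metadata tibble.
#' @export
study_design <- function() {
  grid <- tidyr::expand_grid(lineage = c("BAT", "WAT", "BWAT"),
                             day = c(0L, 4L, 6L))
  sample_meta(
    sample_id = paste0(grid$lineage, "_d", grid$day),
    lineage = grid$lineage, day = grid$day,
    treatment = if_else(grid$lineage == "BWAT", "NE", "none")
  )
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> %d CpG sites x %d samples\n",
              nrow(x$sites), nrow(x$samples)))
  cat("  samples:", paste(x$samples$sample_id, collapse = ", "), "\n")
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.methylome <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Tidy a methylome into long form
#'
#' @param x A `methylome`.
#' @param ... Unused.
#' @return A long tibble: `chrom`, `pos`, `sample_id`, `meth`, `depth`,
#'   `fraction` (NA where depth is 0).
#' @export
tidy.methylome <- function(x, ...) {
  long <- tidyr::expand_grid(
    site = seq_len(nrow(x$sites)), sample = seq_len(nrow(x$samples))
  )
  tibble(
    chrom = x$sites$chrom[long$site],
    pos = x$sites$pos[long$site],
    sample_id = x$samples$sample_id[long$sample],
    meth = x$meth[cbind(long$site, long$sample)],
    depth = x$depth[cbind(long$site, long$sample)]
  ) %>%
    mutate(fraction = if_else(.data$depth > 0,
                              .data$meth / .data$depth, NA_real_))
}

#' Assemble per-sample call tables into one methylome
#'
#' The site universe is the union of sites over all tables; cells absent
#' from a sample are recorded with depth 0 (the common-coverage filter
#' removes them later).
#'
#' @param tables List of call tibbles from [read_cpg_calls()], one per
#'   sample, in the same order as `metas` rows.
#' @param metas Sample metadata tibble ([sample_meta()]).
#' @return A [methylome()].
#' @export
assemble_methylome <- function(tables, metas) {
  if (length(tables) != nrow(metas)) {
    abort("need exactly one call table per sample metadata row")
  }
  if (anyDuplicated(metas$sample_id)) abort("duplicate sample_id")
  assemblies <- unique(unlist(lapply(tables, attr, "assembly")))
  if (length(assemblies) > 1) {
    abort(sprintf("call tables declare conflicting assemblies: %s",
                  paste(assemblies, collapse = ", ")))
  }

  sites <- bind_rows(lapply(tables, function(t) t[, c("chrom", "pos")])) %>%
    distinct() %>%
    arrange(.data$chrom, .data$pos)
  key <- paste(sites$chrom, sites$pos)

  n_sites <- nrow(sites)
  n_samp <- nrow(metas)
  meth <- matrix(0L, n_sites, n_samp)
  depth <- matrix(0L, n_sites, n_samp)
  for (j in seq_len(n_samp)) {
    t <- tables[[j]]
    i <- match(paste(t$chrom, t$pos), key)
    meth[i, j] <- t$meth
    depth[i, j] <- t$meth + t$unmeth
  }
  methylome(sites, metas, meth, depth)
}

#' Keep autosomal CpGs covered in every sample
#'
#' Retains exactly the sites on the configured autosomes whose sequencing
#' depth reaches `cfg$min_depth` in every sample, preserving site order.
#' Filtering is idempotent.
#'
#' @param m A [methylome()].
#' @param cfg [analysis_config()].
#' @return A filtered `methylome`.
#' @export
filter_common_autosomal <- function(m, cfg = analysis_config()) {
  cfg <- as_config(cfg)
  keep <- m$sites$chrom %in% cfg$autosomes &
    matrixStats_row_min(m$depth) >= cfg$min_depth
  if (!any(keep)) {
    abort("no CpG survives the common-coverage filter; review min_depth/autosomes")
  }
  methylome(
    m$sites[keep, , drop = FALSE], m$samples,
    m$meth[keep, , drop = FALSE], m$depth[keep, , drop = FALSE]
  )
}

# rowMins without a matrixStats dependency
matrixStats_row_min <- function(x) {
  if (ncol(x) == 1) return(x[, 1])
  do.call(pmin, lapply(seq_len(ncol(x)), function(j) x[, j]))
}

#' Per-cell methylation fractions
#'
#' @param m A [methylome()].
#' @param allow_missing Return `NaN` for depth-0 cells instead of erroring.
#' @return A numeric sites x samples matrix of `meth / depth`.
#' @export
meth_fractions <- function(m, allow_missing = FALSE) {
  if (!allow_missing && any(m$depth == 0)) {
    abort("methylation fraction undefined at depth 0; filter first or set allow_missing = TRUE")
  }
  m$meth / m$depth
}

#' Classify methylation fractions into LM / PM / HM
#'
#' Lowly methylated below `lm_cut` (default 30%), highly methylated above
#' `hm_cut` (default 70%), partially methylated in the closed interval
#' between them.
#'
#' @param fraction Numeric vector of methylation fractions in \[0, 1\].
#' @param cfg [analysis_config()].
#' @return A factor with levels `LM`, `PM`, `HM`.
#' @export
classify_meth_level <- function(fraction, cfg = analysis_config()) {
  cfg <- as_config(cfg)
  stopifnot(all(fraction >= 0 & fraction <= 1, na.rm = TRUE))
  factor(
    dplyr::case_when(
      fraction < cfg$lm_cut ~ "LM",
      fraction > cfg$hm_cut ~ "HM",
      TRUE ~ "PM"
    ),
    levels = c("LM", "PM", "HM")
  )
}

#' Methylation-class composition and pairwise shift counts
#'
#' Summarizes, per sample, how many CpGs fall in each LM/PM/HM class, and,
#' for each (later, earlier) sample pairing, how many CpGs shifted up
#' (hyper, delta >= cutoff) or down (hypo, delta <= -cutoff) at each
#' requested cutoff. A cutoff of 0 counts every nonzero shift.
#'
#' @param m A filtered [methylome()].
#' @param pairings Tibble with columns `target` (later sample) and
#'   `reference` (earlier sample); an optional `label` column is carried
#'   through.
#' @param cfg [analysis_config()].
#' @param cutoffs Numeric vector of absolute-shift cutoffs (fractions).
#' @return A list with tibbles `class_counts` (`sample_id`, `class`, `n`)
#'   and `shifts` (`label`, `target`, `reference`, `cutoff`, `n_hyper`,
#'   `n_hypo`).
#' @export
class_dynamics <- function(m, pairings, cfg = analysis_config(),
                           cutoffs = c(0.10, 0.20, 0.30)) {
  cfg <- as_config(cfg)
  frac <- meth_fractions(m)

  class_counts <- purrr::map_dfr(seq_len(nrow(m$samples)), function(j) {
    cl <- classify_meth_level(frac[, j], cfg)
    tibble(sample_id = m$samples$sample_id[j],
           class = factor(c("LM", "PM", "HM"), levels = c("LM", "PM", "HM")),
           n = as.integer(table(cl)))
  })

  if (!all(c("target", "reference") %in% names(pairings))) {
    abort("pairings needs columns 'target' and 'reference'")
  }
  if (!"label" %in% names(pairings)) {
    pairings$label <- paste(pairings$target, "-", pairings$reference)
  }
  shifts <- purrr::pmap_dfr(
    pairings[, c("label", "target", "reference")],
    function(label, target, reference) {
      jt <- match(target, m$samples$sample_id)
      jr <- match(reference, m$samples$sample_id)
      if (is.na(jt) || is.na(jr)) {
        abort(sprintf("unknown sample in pairing '%s'", label))
      }
      delta <- frac[, jt] - frac[, jr]
      purrr::map_dfr(cutoffs, function(cut) {
        tibble(
          label = label, target = target, reference = reference,
          cutoff = cut,
          n_hyper = sum(delta >= cut & delta > 0),
          n_hypo = sum(delta <= -cut & delta < 0)
        )
      })
    }
  )
  list(class_counts = class_counts, shifts = shifts)
}

#' Summarize a clone-bisulfite matrix
#'
#' Clone bisulfite sequencing reads out the methylation state of every CpG
#' in a cloned amplicon: rows are clones, columns CpG sites, entries 1
#' (methylated cytosine) or 0 (unmethylated).
#'
#' @param cm Binary matrix, clones x sites; optional column names are taken
#'   as CpG positions.
#' @return A list with `per_site` (tibble `site`, `frac_meth`) and
#'   `unmeth_fraction`, the proportion of all (clone, site) cells that are
#'   unmethylated.
#' @export
summarize_clone_matrix <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) < 1 || ncol(cm) < 1) {
    abort("clone matrix needs >= 1 clone and >= 1 site")
  }
  if (!all(cm %in% c(0, 1))) abort("clone matrix entries must be 0 or 1")
  site <- if (!is.null(colnames(cm))) colnames(cm) else as.character(seq_len(ncol(cm)))
  list(
    per_site = tibble(site = site, frac_meth = colMeans(cm)),
    unmeth_fraction = mean(cm == 0)
  )
}
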