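#' Run the full differential-methylation analysis from one config
#'
#' Orchestrates the end-to-end pipeline: read inputs, assemble and filter
#' the methylome, annotate CpGs, call DMCs and DMPs for every configured
#' comparison, intersect DMPs across timepoints into the consistent gene
#' set, test gene-family enrichment, filter expression and quantify
#' methylation-expression anti-correlation, and cluster methylome and
#' transcriptome. Every intermediate is written under `out_dir` and a
#' machine-readable JSON report summarizes the run. Rerunning with
#' identical inputs and seed reproduces an identical report.
#'
#' The config is a YAML file or equivalent list with entries:
#' \describe{
#'   \item{calls}{list of `{sample_id, path, lineage, day, treatment}`.}
#'   \item{dialect}{call-table dialect (see [read_cpg_calls()]).}
#'   \item{genes}{`{path, format}` gene models.}
#'   \item{cgi}{CpG-island BED path.}
#'   \item{expression}{optional FPKM TSV path.}
#'   \item{comparisons}{list of `{label, target, reference}`.}
#'   \item{consistency}{labels of the comparisons intersected for the
#'     consistent gene set (>= 2).}
#'   \item{correlation}{optional `{comparison, expr_target,
#'     expr_reference}` driving the methylation-expression correlation.}
#'   \item{family}{optional path to a gene-family list (one id per line)
#'     for hypergeometric enrichment of the consistent set.}
#'   \item{cluster}{optional `{k_methylome, k_transcriptome}`.}
#'   \item{config}{[analysis_config()] overrides.}
#'   \item{seed}{integer seed for permutation tests.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config Path to a YAML file, or a config list.
#' @return The run report (list), invisibly written to
#'   `out_dir/report.json`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- as_config(config$config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  validate_pipeline_config(config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  log_info <- function(...) message(sprintf(...))
  report <- list(config = config, seed = seed,
                 version = as.character(utils::packageVersion("methdyn")))

  ## -- read & assemble -------------------------------------------------
  m <- stage("assemble", {
    metas <- purrr::map_dfr(config$calls, function(cc) {
      sample_meta(cc$sample_id, cc$lineage, as.integer(cc$day),
                  cc$treatment %||% "none")
    })
    tables <- purrr::map(config$calls, function(cc) {
      read_cpg_calls(cc$path, dialect = config$dialect %||% "counts",
                     sample_id = cc$sample_id)
    })
    assemble_methylome(tables, metas)
  })
  log_info("assembled %d CpG sites x %d samples", nrow(m$sites), nrow(m$samples))

  mf <- stage("filter", filter_common_autosomal(m, cfg))
  report$n_cpgs_assembled <- nrow(m$sites)
  report$n_cpgs_retained <- nrow(mf$sites)
  log_info("retained %d common autosomal CpGs (depth >= %d)",
           nrow(mf$sites), cfg$min_depth)

  ## -- annotation ------------------------------------------------------
  catalog <- stage("annotation", {
    genes <- read_gene_models(config$genes$path,
                              format = config$genes$format %||% "refflat")
    cgis <- read_interval_bed(config$cgi, name = "CGI")
    build_feature_catalog(genes, cgis, cfg)
  })
  contexts <- stage("annotation", annotate_cpgs(mf$sites, catalog))
  readr::write_tsv(
    mutate(contexts, gene_ids = purrr::map_chr(
      .data$gene_ids, paste, collapse = ","
    )),
    file.path(out_dir, "cpg_context.tsv")
  )
  report$genic_context <- as.list(table(contexts$genic))
  report$cgi_context <- as.list(table(contexts$cgi))

  ## -- differential ----------------------------------------------------
  comparisons <- purrr::map_dfr(config$comparisons, as_tibble)
  dmc_by_label <- list()
  dmp_by_label <- list()
  for (i in seq_len(nrow(comparisons))) {
    lab <- comparisons$label[i]
    dmcs <- stage(paste0("dmc:", lab), {
      call_dmcs(mf, comparisons$target[i], comparisons$reference[i], cfg,
                label = lab)
    })
    dmps <- stage(paste0("dmp:", lab), call_dmps(dmcs, catalog, cfg))
    dmc_by_label[[lab]] <- dmcs
    dmp_by_label[[lab]] <- dmps
    cmp_dir <- file.path(out_dir, paste0("comparison_", lab))
    write_result_tables(dmcs, dmps, out_dir = cmp_dir)
    log_info("%s: %d CpGs tested, %d significant, %d DMPs",
             lab, nrow(dmcs), sum(dmcs$significant), nrow(dmps))
  }
  report$comparisons <- purrr::imap(dmc_by_label, function(dmcs, lab) {
    sig <- filter(dmcs, .data$significant)
    list(
      n_tested = nrow(dmcs), n_significant = nrow(sig),
      n_hyper = sum(sig$direction == "hyper"),
      n_hypo = sum(sig$direction == "hypo"),
      dominance_p = if (nrow(sig) > 0) {
        direction_dominance_test(sum(sig$direction == "hyper"),
                                 sum(sig$direction == "hypo"))
      } else {
        NA
      },
      n_dmps = nrow(dmp_by_label[[lab]])
    )
  })

  ## -- consistency -----------------------------------------------------
  consistent <- NULL
  if (!is.null(config$consistency)) {
    consistent <- stage("consistency", {
      consistent_dmps(dmp_by_label[unlist(config$consistency)])
    })
    readr::write_tsv(consistent, file.path(out_dir, "consistent_genes.tsv"))
    report$n_consistent_genes <- nrow(consistent)
    report$n_consistent_hyper <- sum(consistent$direction == "hyper")
    report$n_consistent_hypo <- sum(consistent$direction == "hypo")
    log_info("consistent gene set: %d genes", nrow(consistent))
  }

  ## -- enrichment ------------------------------------------------------
  if (!is.null(config$family) && !is.null(consistent)) {
    enr <- stage("enrichment", {
      family <- readLines(config$family)
      covered <- annotated_promoter_universe(mf$sites, catalog)
      hypergeometric_enrichment(
        intersect(consistent$gene_id, covered),
        intersect(family, covered), covered
      )
    })
    report$enrichment <- as.list(tidy(enr))
  }

  ## -- expression ------------------------------------------------------
  if (!is.null(config$expression)) {
    expr <- stage("expression", {
      filter_expressed(read_expression_table(config$expression), cfg,
                       genes = catalog$genes)
    })
    report$n_genes_expressed <- nrow(expr)

    if (!is.null(config$correlation) && !is.null(consistent) &&
        nrow(consistent) >= 3) {
      corr <- stage("correlation", {
        lab <- config$correlation$comparison
        deltas <- dmp_by_label[[lab]] %>%
          select("gene_id", delta = "mean_delta")
        lfc <- expression_lfc(expr, config$correlation$expr_target,
                              config$correlation$expr_reference)
        methylation_expression_correlation(deltas, lfc, seed = seed)
      })
      report$correlation <- as.list(glance(corr))
    }

    if (!is.null(config$cluster)) {
      trans_cl <- stage("cluster:transcriptome", {
        vals <- log2(as.matrix(expr[, -1, drop = FALSE]) + 1)
        hierarchical_cluster(vals, k = config$cluster$k_transcriptome %||% 3,
                             distance = "correlation")
      })
      report$transcriptome_clusters <- trans_cl$labels$cluster
      report$transcriptome_day_ari <- grouping_agreement(
        trans_cl$labels$cluster,
        mf$samples$day[match(trans_cl$labels$sample_id,
                             mf$samples$sample_id)]
      )
    }
  }

  ## -- methylome clustering -------------------------------------------
  if (!is.null(config$cluster)) {
    meth_cl <- stage("cluster:methylome", {
      regions <- merge_cpg_regions(mf, cfg)
      hierarchical_cluster(regions$values,
                           k = config$cluster$k_methylome %||% 3,
                           distance = "euclidean")
    })
    report$methylome_clusters <- meth_cl$labels$cluster
    report$methylome_lineage_ari <- grouping_agreement(
      meth_cl$labels$cluster,
      mf$samples$lineage[match(meth_cl$labels$sample_id,
                               mf$samples$sample_id)]
    )
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  log_info("report written to %s", report_path)
  invisible(report)
}

# genes whose promoter contains >= 1 analyzable CpG: the default
# enrichment universe
annotated_promoter_universe <- function(sites, catalog) {
  hits <- quiet_overlaps(GenomicRanges::findOverlaps, gr_positions(sites),
                         gr_intervals(catalog$promoters))
  sort(unique(catalog$promoters$gene_id[S4Vectors::subjectHits(hits)]))
}

validate_pipeline_config <- function(config) {
  if (is.null(config$calls) || length(config$calls) == 0) {
    abort("config needs a non-empty 'calls' list")
  }
  needed <- c(
    purrr::map_chr(config$calls, "path"),
    config$genes$path, config$cgi, config$expression, config$family
  )
  missing <- needed[!file.exists(unlist(needed))]
  if (length(missing) > 0) {
    abort(sprintf("input file(s) not found: %s",
                  paste(missing, collapse = ", ")))
  }
  if (is.null(config$comparisons) || length(config$comparisons) == 0) {
    abort("config needs >= 1 comparison")
  }
  labels <- purrr::map_chr(config$comparisons, "label")
  if (anyDuplicated(labels)) abort("comparison labels must be unique")
  if (!is.null(config$consistency)) {
    unknown <- setdiff(unlist(config$consistency), labels)
    if (length(unknown) > 0) {
      abort(sprintf("consistency references unknown comparison(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    if (length(config$consistency) < 2) {
      abort("consistency needs >= 2 comparisons")
    }
  }
  if (!is.null(config$correlation)) {
    if (is.null(config$expression)) {
      abort("correlation stage enabled but no expression table configured")
    }
    if (!config$correlation$comparison %in% labels) {
      abort("correlation references an unknown comparison")
    }
  }
  invisible(TRUE)
}

#' Default configuration for a simulated study directory
#'
#' Builds the [run_full_analysis()] config for files written by
#' [write_simulation()]: the six headline comparisons (day 4 and day 6
#' versus day 0 within each untreated lineage; WAT versus BAT at days 0, 4
#' and 6), consistency over the three WAT-vs-BAT timepoints, correlation on
#' the day-6 comparison, and k = 3 clustering for both data types.
#'
#' @param sim_dir Directory written by [write_simulation()].
#' @param out_dir Pipeline output directory.
#' @param seed Integer seed.
#' @return A config list.
#' @export
simulation_config <- function(sim_dir, out_dir = file.path(sim_dir, "results"),
                              seed = 1L) {
  metas <- readr::read_tsv(file.path(sim_dir, "samples.tsv"),
                           col_types = "ccic", progress = FALSE)
  calls <- purrr::pmap(metas, function(sample_id, lineage, day, treatment) {
    list(sample_id = sample_id, path = file.path(
      sim_dir, paste0(sample_id, ".calls.tsv")
    ), lineage = lineage, day = day, treatment = treatment)
  })
  wat_vs_bat <- lapply(c(0, 4, 6), function(d) {
    list(label = paste0("WATvsBAT_d", d),
         target = paste0("WAT_d", d), reference = paste0("BAT_d", d))
  })
  time_course <- purrr::flatten(lapply(c("BAT", "WAT"), function(l) {
    lapply(c(4, 6), function(d) {
      list(label = paste0(l, "_d", d, "vs0"),
           target = paste0(l, "_d", d), reference = paste0(l, "_d0"))
    })
  }))
  list(
    seed = seed, out_dir = out_dir,
    calls = calls, dialect = "counts",
    genes = list(path = file.path(sim_dir, "genes.refflat"),
                 format = "refflat"),
    cgi = file.path(sim_dir, "cgi.bed"),
    expression = file.path(sim_dir, "fpkm.tsv"),
    comparisons = c(wat_vs_bat, time_course),
    consistency = purrr::map_chr(wat_vs_bat, "label"),
    correlation = list(comparison = "WATvsBAT_d6",
                       expr_target = "WAT_d6", expr_reference = "BAT_d6"),
    cluster = list(k_methylome = 3, k_transcriptome = 3)
  )
}
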