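#' Analysis configuration
#'
#' Bundles every numeric threshold used by the pipeline. Defaults follow the
#' standard RRBS differential-methylation recipe for this study design:
#' CpGs require sequencing depth >= 10 in all samples; a CpG is tested only
#' when the methylation difference between the pair is at least 10%; calls
#' use a Benjamini-Hochberg FDR of 0.05; methylation classes are lowly
#' (< 30%), partially (30-70%) and highly (> 70%) methylated; promoters span
#' 1 kb upstream to 500 bp downstream of the TSS; CpG-island shores and
#' shelves are successive 2 kb bands; nearby CpGs closer than 500 bp merge
#' into one region; genes with FPKM < 1 in every sample are dropped; and a
#' differentially methylated promoter (DMP) needs at least two significant
#' same-direction CpGs.
#'
#' @param min_depth Minimum per-sample sequencing depth for a CpG to be kept.
#' @param min_diff Minimum absolute methylation difference (fraction) for a
#'   CpG to enter the Fisher test.
#' @param alpha FDR level applied to BH-adjusted p-values.
#' @param lm_cut,hm_cut Class boundaries: lowly methylated below `lm_cut`,
#'   highly methylated above `hm_cut`, partially methylated in between
#'   (boundaries inclusive to the partial class).
#' @param merge_gap CpGs closer than this many bp chain into one region
#'   (strict inequality: a gap equal to `merge_gap` splits).
#' @param min_fpkm A gene is kept when its FPKM reaches this value in at
#'   least one sample.
#' @param promoter_up,promoter_down Promoter extent upstream/downstream of
#'   the TSS in bp (downstream includes the TSS base, so the default promoter
#'   is exactly 1500 bp).
#' @param shore_bp,shelf_bp Width of the CpG-island shore and shelf bands.
#' @param min_dmcs_per_dmp Minimum number of significant same-direction CpGs
#'   inside a promoter for a DMP call.
#' @param autosomes Character vector of chromosome names retained by the
#'   common-coverage filter (default mouse chr1-chr19).
#' @param dmp_mode `"strict"` requires all significant promoter CpGs to share
#'   one direction; `"majority"` calls the majority direction when at least
#'   `min_dmcs_per_dmp` significant CpGs agree.
#'
#' @return A list of class `methdyn_config`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$min_depth
analysis_config <- function(min_depth = 10L,
                            min_diff = 0.10,
                            alpha = 0.05,
                            lm_cut = 0.30,
                            hm_cut = 0.70,
                            merge_gap = 500L,
                            min_fpkm = 1,
                            promoter_up = 1000L,
                            promoter_down = 500L,
                            shore_bp = 2000L,
                            shelf_bp = 2000L,
                            min_dmcs_per_dmp = 2L,
                            autosomes = paste0("chr", 1:19),
                            dmp_mode = c("strict", "majority")) {
  dmp_mode <- match.arg(dmp_mode)
  if (!(lm_cut > 0 && lm_cut < hm_cut && hm_cut < 1)) {
    abort("need 0 < lm_cut < hm_cut < 1")
  }
  stopifnot(
    min_depth >= 1, min_diff >= 0, alpha > 0, alpha < 1,
    merge_gap > 0, promoter_up > 0, promoter_down > 0,
    shore_bp > 0, shelf_bp > 0, min_dmcs_per_dmp >= 1,
    length(autosomes) >= 1
  )
  structure(
    list(
      min_depth = as.integer(min_depth), min_diff = min_diff, alpha = alpha,
      lm_cut = lm_cut, hm_cut = hm_cut, merge_gap = as.integer(merge_gap),
      min_fpkm = min_fpkm, promoter_up = as.integer(promoter_up),
      promoter_down = as.integer(promoter_down),
      shore_bp = as.integer(shore_bp), shelf_bp = as.integer(shelf_bp),
      min_dmcs_per_dmp = as.integer(min_dmcs_per_dmp),
      autosomes = autosomes, dmp_mode = dmp_mode
    ),
    class = "methdyn_config"
  )
}

#' @export
print.methdyn_config <- function(x, ...) {
  cat("<methdyn_config>\n")
  for (nm in setdiff(names(x), "autosomes")) {
    cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  cat(sprintf("  %-18s %s ... (%d)\n", "autosomes",
              paste(head(x$autosomes, 3), collapse = ", "),
              length(x$autosomes)))
  invisible(x)
}

as_config <- function(cfg) {
  if (inherits(cfg, "methdyn_config")) return(cfg)
  if (is.null(cfg)) return(analysis_config())
  if (is.list(cfg)) return(do.call(analysis_config, cfg))
  abort("`cfg` must be NULL, a list, or an analysis_config()")
}
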