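#' Scoring configuration
#'
#' Bundles every threshold used by the detection, filtering and scoring rules.
#' Defaults follow the established conventions for metagenomic strain tracking:
#' a species is called present from >= 3 of its 10 single-copy marker genes;
#' a gene cluster is present when its horizontal coverage exceeds 100 bp and
#' 20% of the representative gene length with mean vertical coverage above
#' 0.5x; an allele is "observed" when supported by >= 2 reads; candidate SNVs
#' need such support in >= 2 samples; conspecific scoring needs >= 100
#' informative positions. The dominance/presence thresholds used to call
#' categorical outcomes from strain fractions default to 0.8 and 0.2 and are
#' deliberately configurable: results should always be reported alongside the
#' configuration used.
#'
#' @param min_marker_genes Minimum marker genes for species detection.
#' @param min_horiz_bp Gene presence: horizontal coverage must exceed this (bp).
#' @param min_frac_len Gene presence: fraction of gene length covered must
#'   exceed this.
#' @param min_mean_depth Gene presence: mean vertical coverage must exceed this.
#' @param min_core_median_depth Confident absence requires the extended-core
#'   median vertical coverage of the sample to exceed this.
#' @param detect_reads Reads required for an allele to count as observed.
#' @param min_snv_samples Samples (with the gene confidently detected) in which
#'   an allele needs `detect_reads` support to be retained as a candidate SNV.
#' @param min_shared Minimum variant positions with shared coverage for an
#'   allele distance to be defined.
#' @param min_informative Minimum informative positions for conspecific
#'   outcome scoring.
#' @param theta_dominant Fraction above which a strain source is dominant.
#' @param theta_present Fraction above which a strain source counts as present.
#' @param core_prevalence Extended core: gene must be present in more than this
#'   fraction of genomes.
#' @param core_top_n Extended core fallback: number of most prevalent gene
#'   clusters used when the prevalence rule yields fewer than `core_top_n`.
#'
#' @return A list of class `"strainflow_config"`.
#' @export
#' @examples
#' cfg <- scoring_config(theta_dominant = 0.9)
#' cfg$theta_dominant
scoring_config <- function(min_marker_genes = 3L,
                           min_horiz_bp = 100,
                           min_frac_len = 0.2,
                           min_mean_depth = 0.5,
                           min_core_median_depth = 1,
                           detect_reads = 2L,
                           min_snv_samples = 2L,
                           min_shared = 20L,
                           min_informative = 100L,
                           theta_dominant = 0.8,
                           theta_present = 0.2,
                           core_prevalence = 0.8,
                           core_top_n = 50L) {
  stopifnot(
    min_marker_genes >= 1, detect_reads >= 1, min_snv_samples >= 1,
    min_shared >= 1, min_informative >= 1
  )
  if (!(theta_present > 0 && theta_present < theta_dominant && theta_dominant <= 1)) {
    abort("need 0 < theta_present < theta_dominant <= 1")
  }
  structure(
    list(
      min_marker_genes = as.integer(min_marker_genes),
      min_horiz_bp = min_horiz_bp,
      min_frac_len = min_frac_len,
      min_mean_depth = min_mean_depth,
      min_core_median_depth = min_core_median_depth,
      detect_reads = as.integer(detect_reads),
      min_snv_samples = as.integer(min_snv_samples),
      min_shared = as.integer(min_shared),
      min_informative = as.integer(min_informative),
      theta_dominant = theta_dominant,
      theta_present = theta_present,
      core_prevalence = core_prevalence,
      core_top_n = as.integer(core_top_n)
    ),
    class = "strainflow_config"
  )
}

#' @export
print.strainflow_config <- function(x, ...) {
  cat("<strainflow scoring configuration>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
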