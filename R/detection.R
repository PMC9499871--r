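#' Species detection from marker genes
#'
#' A species is considered present in a sample if at least
#' `config$min_marker_genes` (default 3) of its ten near-universal single-copy
#' taxonomic marker genes were confidently detected. Whether a marker counts
#' as "confidently detected" is decided upstream; this function consumes the
#' per-sample marker tally.
#'
#' @param marker_hits Tibble with columns `species_id`, `sample_id`,
#'   `n_marker_genes` (integer in 0..10).
#' @param config A [scoring_config()].
#' @return The input with a logical `detected` column.
#' @export
#' @examples
#' detect_species(tibble::tibble(
#'   species_id = "s1", sample_id = c("a", "b"), n_marker_genes = c(3L, 2L)
#' ))
detect_species <- function(marker_hits, config = scoring_config()) {
  need <- c("species_id", "sample_id", "n_marker_genes")
  miss <- setdiff(need, names(marker_hits))
  if (length(miss) > 0) abort(paste0("marker table lacks columns: ", paste(miss, collapse = ", ")))
  n <- marker_hits$n_marker_genes
  if (any(is.na(n)) || any(n < 0) || any(n > 10)) {
    abort("n_marker_genes must lie in 0..10")
  }
  marker_hits |>
    as_tibble() |>
    mutate(detected = .data$n_marker_genes >= config$min_marker_genes)
}

#' Define a species' extended core genome
#'
#' Extended core genes are the gene clusters present in more than
#' `config$core_prevalence` (default 80%, strict inequality) of the genomes in
#' a species-level cluster. When fewer than `config$core_top_n` gene clusters
#' satisfy the prevalence rule — typical for pangenomes built from many
#' incomplete genomes — the `core_top_n` (default 50) most prevalent gene
#' clusters are used instead, with prevalence ties broken by lexicographic
#' gene identifier so the result is deterministic.
#'
#' @param membership Tibble of `gene_cluster_id` x `genome_id` presence pairs
#'   for one species.
#' @param species_id Identifier recorded in the result.
#' @param config A [scoring_config()].
#' @return An `extended_core` list: `species_id`, `core_gene_ids`,
#'   `rule_used` (`"prevalence_80"` or `"top_50"`), and the per-gene
#'   `prevalence` table.
#' @export
define_extended_core <- function(membership, species_id = "species",
                                 config = scoring_config()) {
  if (nrow(membership) == 0) abort("membership table is empty")
  membership <- distinct(as_tibble(membership), .data$gene_cluster_id, .data$genome_id)
  n_genomes <- n_distinct(membership$genome_id)
  prev <- membership |>
    count(.data$gene_cluster_id, name = "n_genomes") |>
    mutate(prevalence = .data$n_genomes / .env$n_genomes) |>
    arrange(desc(.data$prevalence), .data$gene_cluster_id)
  core <- prev$gene_cluster_id[prev$prevalence > config$core_prevalence]
  if (length(core) < config$core_top_n) {
    core <- head(prev$gene_cluster_id, config$core_top_n)
    rule <- "top_50"
  } else {
    rule <- "prevalence_80"
  }
  structure(
    list(
      species_id = species_id,
      core_gene_ids = sort(core),
      rule_used = rule,
      prevalence = prev
    ),
    class = "extended_core"
  )
}

#' @export
print.extended_core <- function(x, ...) {
  cat(sprintf(
    "<extended core: %s — %d genes (%s rule)>\n",
    x$species_id, length(x$core_gene_ids), x$rule_used
  ))
  invisible(x)
}

#' Call per-sample gene-cluster presence states
#'
#' Assigns each (gene cluster, sample) pair exactly one of three states.
#' A gene is `present` if the species is detected in the sample, its
#' horizontal coverage exceeds `min_horiz_bp` (100 bp) and `min_frac_len`
#' (20% of the representative gene length), and its mean vertical coverage
#' exceeds `min_mean_depth` (0.5x). It is `confidently_absent` if it attracted
#' no mappings at all (zero horizontal coverage) in a sample where the
#' species' extended core genes are covered at a median vertical coverage
#' above `min_core_median_depth` (1x) — i.e. the species is there with high
#' confidence, but the gene is not. Everything else is `unknown`.
#'
#' Gene clusters of the pangenome with no coverage row in a sample are treated
#' as attracting zero mappings.
#'
#' @param coverage Coverage tibble (see [read_gene_coverage()]) for one species.
#' @param detection Output of [detect_species()] for the same species.
#' @param core An `extended_core` from [define_extended_core()].
#' @param config A [scoring_config()].
#' @param pangenome_genes Optional character vector of all gene clusters in
#'   the species pangenome; coverage rows for genes outside it raise an error,
#'   and missing (gene, sample) pairs are filled with zero coverage.
#' @return A `gene_profile` tibble: `species_id`, `gene_cluster_id`,
#'   `sample_id`, `horiz_bp`, `frac_len`, `mean_depth`,
#'   `state` in `{"present", "confidently_absent", "unknown"}`.
#' @export
call_gene_presence <- function(coverage, detection, core,
                               config = scoring_config(),
                               pangenome_genes = NULL) {
  coverage <- validate_gene_coverage(coverage)
  species <- unique(c(coverage$species_id, detection$species_id))
  if (length(species) > 1) abort("call_gene_presence expects a single species")
  genes <- unique(coverage$gene_cluster_id)
  if (!is.null(pangenome_genes)) {
    alien <- setdiff(genes, pangenome_genes)
    if (length(alien) > 0) {
      abort(paste0("gene cluster not in pangenome: ", paste(alien, collapse = ", ")))
    }
    genes <- unique(c(genes, pangenome_genes))
  }
  samples <- union(coverage$sample_id, detection$sample_id)
  grid <- tidyr::expand_grid(gene_cluster_id = genes, sample_id = samples) |>
    left_join(
      coverage |> select("gene_cluster_id", "sample_id", "horiz_bp", "frac_len", "mean_depth"),
      by = c("gene_cluster_id", "sample_id")
    ) |>
    mutate(across(c("horiz_bp", "frac_len", "mean_depth"), ~ tidyr::replace_na(.x, 0)))

  det <- detection |> select("sample_id", "detected")
  grid <- grid |> left_join(det, by = "sample_id") |>
    mutate(detected = tidyr::replace_na(.data$detected, FALSE))

  # per-sample median vertical coverage of the extended core (absent rows = 0)
  core_med <- grid |>
    filter(.data$gene_cluster_id %in% core$core_gene_ids) |>
    group_by(.data$sample_id) |>
    summarise(core_median_depth = median(.data$mean_depth), .groups = "drop")
  grid <- grid |> left_join(core_med, by = "sample_id") |>
    mutate(core_median_depth = tidyr::replace_na(.data$core_median_depth, 0))

  grid |>
    mutate(
      state = case_when(
        .data$detected &
          .data$horiz_bp > config$min_horiz_bp &
          .data$frac_len > config$min_frac_len &
          .data$mean_depth > config$min_mean_depth ~ "present",
        .data$horiz_bp == 0 &
          .data$core_median_depth > config$min_core_median_depth ~ "confidently_absent",
        TRUE ~ "unknown"
      ),
      species_id = species
    ) |>
    select("species_id", "gene_cluster_id", "sample_id",
           "horiz_bp", "frac_len", "mean_depth", "state")
}

#' Filter raw candidate SNVs
#'
#' An allele at a variant position is retained if it is supported by at least
#' `min_reads` reads in each of at least `min_samples` samples in which the
#' containing gene cluster is confidently detected (state `present`). Counts
#' for alleles failing the rule are zeroed, and positions at which fewer than
#' two distinct alleles survive across all samples (no variant left) are
#' dropped. The filter is idempotent.
#'
#' @param table A `variant_table`.
#' @param gene_profile Optional output of [call_gene_presence()]; when `NULL`,
#'   every sample counts as confidently detected.
#' @param min_reads Minimum supporting reads per sample.
#' @param min_samples Minimum number of supporting samples.
#' @return A filtered `variant_table` (possibly empty).
#' @export
filter_raw_snvs <- function(table, gene_profile = NULL,
                            min_reads = 2L, min_samples = 2L) {
  stopifnot(min_reads >= 1, min_samples >= 1)
  table <- validate_variant_table(table)
  if (nrow(table) == 0) return(table)

  if (is.null(gene_profile)) {
    table$.eligible <- TRUE
  } else {
    gp <- gene_profile |>
      select("gene_cluster_id", "sample_id", "state")
    table <- table |>
      left_join(gp, by = c("gene_cluster_id", "sample_id")) |>
      mutate(.eligible = !is.na(.data$state) & .data$state == "present") |>
      select(-"state")
  }

  long <- table |>
    tidyr::pivot_longer(all_of(COUNT_COLS), names_to = "allele",
                        names_prefix = "count_", values_to = "count")
  support <- long |>
    filter(.data$.eligible, .data$count >= min_reads) |>
    count(.data$species_id, .data$position_id, .data$allele, name = "n_support") |>
    filter(.data$n_support >= min_samples)
  retained <- long |>
    inner_join(support, by = c("species_id", "position_id", "allele"))

  variant_pos <- retained |>
    distinct(.data$species_id, .data$position_id, .data$allele) |>
    count(.data$species_id, .data$position_id) |>
    filter(.data$n >= 2) |>
    select(-"n")
  if (nrow(variant_pos) == 0) {
    return(validate_variant_table(table[0, setdiff(names(table), c(".eligible", "depth"))]))
  }

  out <- long |>
    semi_join(variant_pos, by = c("species_id", "position_id")) |>
    left_join(support |> mutate(keep = TRUE),
              by = c("species_id", "position_id", "allele")) |>
    mutate(count = ifelse(is.na(.data$keep), 0, .data$count)) |>
    select(-"n_support", -"keep", -".eligible", -"depth") |>
    tidyr::pivot_wider(names_from = "allele", values_from = "count",
                       names_prefix = "count_")
  validate_variant_table(out)
}
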