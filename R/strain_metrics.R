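#' Strain population diversity (SPD) from allele frequencies
#'
#' For one species in one sample, SPD is the sum over variant positions of the
#' inverse Simpson index of the four allele frequencies minus one,
#'
#' \deqn{SPD = \frac{\sum_{i=1}^{n_{var}} (p_A^2+p_C^2+p_G^2+p_T^2)^{-1} - 1}{cov_{hor}}}
#'
#' normalized by the total horizontal coverage `cov_hor` of the species'
#' extended core genome (number of covered positions), so values are
#' comparable between samples of unequal coverage. SPD can be read as the
#' average effective number of nondominant alleles: it is 0 when every
#' position is monomorphic (one dominant strain) and reaches 3 when all four
#' alleles occur at equal proportions at every covered position.
#'
#' @param freqs A numeric matrix or data frame with one row per variant
#'   position and four columns (allele frequencies A, C, G, T); each row must
#'   lie on the simplex. Zero rows are allowed (no variant positions).
#' @param cov_hor Number of covered extended-core positions; must be at least
#'   `nrow(freqs)`. `0` yields `NA` (SPD undefined without coverage).
#' @return A single SPD value.
#' @export
#' @examples
#' spd(matrix(rep(0.25, 4), 1), cov_hor = 1)   # all four alleles equal -> 3
#' spd(matrix(c(1, 0, 0, 0), 1), cov_hor = 5)  # monomorphic -> 0
spd <- function(freqs, cov_hor) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != 4 && nrow(freqs) > 0) abort("freqs needs four allele columns")
  if (length(cov_hor) != 1 || is.na(cov_hor) || cov_hor < 0) {
    abort("cov_hor must be a single non-negative number")
  }
  n_var <- nrow(freqs)
  if (cov_hor == 0) {
    if (n_var > 0) abort("cov_hor == 0 but variant positions supplied")
    return(NA_real_)
  }
  if (cov_hor < n_var) abort("cov_hor must be >= number of variant positions")
  if (n_var == 0) return(0)
  if (any(freqs < 0) || any(abs(rowSums(freqs) - 1) > 1e-8)) {
    abort("allele frequencies must lie on the simplex")
  }
  sum(1 / rowSums(freqs^2) - 1) / cov_hor
}

#' Strain population diversity per species and sample
#'
#' Applies [spd()] to every (species, sample) in a variant table, restricted
#' to the extended core when `core` is given. Positions with zero depth in a
#' sample are not observed there and do not enter the sum. `cov_hor` — the
#' horizontal coverage of the extended core — should be supplied from the
#' coverage data; when it is not, the number of variant positions covered at
#' depth >= 1 in the sample is used as a lower bound.
#'
#' @param table A `variant_table`.
#' @param cov_hor Optional tibble `species_id`, `sample_id`, `cov_hor`.
#' @param core Optional `extended_core`; positions outside its genes are
#'   ignored.
#' @return A tibble with `species_id`, `sample_id`, `spd`, `n_var`, `cov_hor`.
#' @export
strain_diversity <- function(table, cov_hor = NULL, core = NULL) {
  table <- allele_frequencies(table)
  if (!is.null(core)) {
    table <- table |> filter(.data$gene_cluster_id %in% core$core_gene_ids)
  }
  res <- table |>
    filter(.data$depth > 0) |>
    group_by(.data$species_id, .data$sample_id) |>
    group_modify(function(g, key) {
      f <- as.matrix(g[paste0("freq_", ALLELES)])
      tibble(n_var = nrow(g), .spd_num = sum(1 / rowSums(f^2) - 1))
    }) |>
    ungroup()
  if (is.null(cov_hor)) {
    res$cov_hor <- res$n_var
  } else {
    res <- res |> left_join(cov_hor, by = c("species_id", "sample_id"))
    if (any(is.na(res$cov_hor))) abort("cov_hor missing for some species/sample")
    if (any(res$cov_hor < res$n_var)) abort("cov_hor must be >= n_var")
  }
  res |>
    mutate(spd = ifelse(.data$cov_hor > 0, .data$.spd_num / .data$cov_hor, NA_real_)) |>
    select("species_id", "sample_id", "spd", "n_var", "cov_hor")
}

#' Allele distance (AD) between two strain populations
#'
#' The allele distance between the strain populations of one species in two
#' samples is the average, over variant positions of the extended core with
#' shared coverage, of the Euclidean distance between the two samples'
#' 4-dimensional allele-frequency vectors, scaled by `1/sqrt(2)` so that the
#' distance lives on `[0, 1]` (two fixed, different alleles are at the maximum
#' Euclidean distance `sqrt(2)`). A position has shared coverage when its read
#' depth reaches `shared_depth` (default 2, matching the two-read detection
#' convention) in both samples. At least `min_shared` (default 20) such
#' positions are required, otherwise the distance is missing (`NA`) and must
#' be propagated, never imputed. If the species is not observed in either
#' sample the distance is 1 by convention, continuous with the maximum
#' attainable conspecific distance.
#'
#' @param table A `variant_table` for one species (extended-core positions).
#' @param sample_x,sample_y Sample identifiers.
#' @param present_x,present_y Whether the species is detected in each sample
#'   (from [detect_species()]).
#' @param min_shared Minimum shared-coverage variant positions.
#' @param shared_depth Depth required in both samples for shared coverage.
#' @return A one-row tibble: `species_id`, `sample_x`, `sample_y`, `ad`,
#'   `n_shared_positions`.
#' @export
allele_distance <- function(table, sample_x, sample_y,
                            present_x = TRUE, present_y = TRUE,
                            min_shared = 20L, shared_depth = 2L) {
  species <- unique(table$species_id)
  if (length(species) > 1) abort("allele_distance expects a single species")
  out <- function(ad, n) {
    tibble(species_id = species[1] %||% NA_character_,
           sample_x = sample_x, sample_y = sample_y,
           ad = ad, n_shared_positions = n)
  }
  if (!present_x || !present_y) return(out(1, 0L))
  tab <- allele_frequencies(table)
  fx <- tab |> filter(.data$sample_id == sample_x, .data$depth >= shared_depth)
  fy <- tab |> filter(.data$sample_id == sample_y, .data$depth >= shared_depth)
  shared <- intersect(fx$position_id, fy$position_id)
  n <- length(shared)
  if (n < min_shared) return(out(NA_real_, n))
  fcols <- paste0("freq_", ALLELES)
  mx <- as.matrix(fx[match(shared, fx$position_id), fcols])
  my <- as.matrix(fy[match(shared, fy$position_id), fcols])
  d <- sqrt(rowSums((mx - my)^2)) / sqrt(2)
  out(mean(d), n)
}

#' All pairwise allele distances for one species
#'
#' @param table A `variant_table` for one species.
#' @param detection Output of [detect_species()] covering the samples of
#'   interest; samples listed there but carrying no variant rows are treated
#'   by the absence convention.
#' @param min_shared,shared_depth See [allele_distance()].
#' @return A long tibble of unordered sample pairs.
#' @export
pairwise_allele_distances <- function(table, detection,
                                      min_shared = 20L, shared_depth = 2L) {
  samples <- sort(unique(detection$sample_id))
  det <- setNames(detection$detected, detection$sample_id)
  pairs <- utils::combn(samples, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    allele_distance(table, p[1], p[2],
                    present_x = isTRUE(det[[p[1]]]),
                    present_y = isTRUE(det[[p[2]]]),
                    min_shared = min_shared, shared_depth = shared_depth)
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
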