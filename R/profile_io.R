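#' Read a per-species SNV allele-count table
#'
#' The table is a long-format TSV with one row per
#' (species, position, gene cluster, sample) and four allele-count columns
#' `count_A`, `count_C`, `count_G`, `count_T`. Position identifiers are
#' opaque: they carry no genome-coordinate semantics, but every position must
#' map to exactly one gene cluster. Total read depth at a position is the sum
#' of the four counts; allele frequencies are always (re)derived as
#' counts normalized by that total depth.
#'
#' @param path Path to a TSV file.
#' @return A validated `variant_table` tibble with columns `species_id`,
#'   `position_id`, `gene_cluster_id`, `sample_id`, `count_A`..`count_T` and a
#'   derived `depth` column.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cols <- readr::cols(
    species_id = readr::col_character(),
    position_id = readr::col_character(),
    gene_cluster_id = readr::col_character(),
    sample_id = readr::col_character(),
    count_A = readr::col_double(),
    count_C = readr::col_double(),
    count_G = readr::col_double(),
    count_T = readr::col_double()
  )
  x <- readr::read_tsv(path, col_types = cols, progress = FALSE)
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "malformed SNV table %s: parse failure at line %d (%s)",
      path, prob$row[1] + 1L, prob$expected[1]
    ))
  }
  validate_variant_table(x)
}

#' Validate (and canonicalize) a variant table
#'
#' Checks column presence, non-negative integer counts, and the invariant that
#' each `position_id` maps to a single `gene_cluster_id` within a species.
#' If a `depth` column is supplied it must equal the sum of the four allele
#' counts everywhere; otherwise it is derived.
#'
#' @param x A data frame of allele counts.
#' @return The input as a `variant_table` tibble with a `depth` column.
#' @export
validate_variant_table <- function(x) {
  need <- c("species_id", "position_id", "gene_cluster_id", "sample_id", COUNT_COLS)
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("variant table lacks columns: ", paste(miss, collapse = ", ")))
  }
  x <- as_tibble(x)
  cnt <- as.matrix(x[COUNT_COLS])
  if (anyNA(cnt)) abort("variant table has missing allele counts")
  if (any(cnt < 0)) abort("variant table has negative allele counts")
  if (any(cnt != round(cnt))) abort("allele counts must be integers")
  tot <- rowSums(cnt)
  if ("depth" %in% names(x) && any(is.na(x$depth) | x$depth != tot)) {
    abort("depth column does not equal the sum of allele counts")
  }
  x$depth <- tot
  bad <- x |>
    distinct(.data$species_id, .data$position_id, .data$gene_cluster_id) |>
    count(.data$species_id, .data$position_id) |>
    filter(.data$n > 1)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "position %s (species %s) maps to more than one gene cluster",
      bad$position_id[1], bad$species_id[1]
    ))
  }
  dup <- x |> count(.data$species_id, .data$position_id, .data$sample_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate rows for position %s sample %s", dup$position_id[1], dup$sample_id[1]
    ))
  }
  class(x) <- c("variant_table", class(x))
  x
}

#' Write a variant table as TSV
#'
#' @param x A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  keep <- c("species_id", "position_id", "gene_cluster_id", "sample_id", COUNT_COLS)
  out <- as_tibble(x)[keep]
  out[COUNT_COLS] <- lapply(out[COUNT_COLS], as.integer)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Allele frequencies from counts
#'
#' Adds `freq_A`..`freq_T`, each allele count normalized by the total read
#' depth at its position; rows with zero depth get `NA` frequencies.
#'
#' @param x A `variant_table`.
#' @return The table with four frequency columns; frequencies sum to 1 where
#'   depth > 0.
#' @export
allele_frequencies <- function(x) {
  x <- validate_variant_table(x)
  d <- ifelse(x$depth > 0, x$depth, NA_real_)
  for (a in ALLELES) {
    x[[paste0("freq_", a)]] <- x[[paste0("count_", a)]] / d
  }
  x
}

#' Read a gene-cluster coverage table
#'
#' Long-format TSV with columns `species_id`, `gene_cluster_id`, `sample_id`,
#' `horiz_bp` (horizontal coverage in bp), `frac_len` (fraction of the
#' representative gene length covered) and `mean_depth` (mean vertical
#' coverage). Coverage is always taken from this table, never re-derived from
#' reads.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble.
#' @export
read_gene_coverage <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    species_id = readr::col_character(),
    gene_cluster_id = readr::col_character(),
    sample_id = readr::col_character(),
    horiz_bp = readr::col_double(),
    frac_len = readr::col_double(),
    mean_depth = readr::col_double()
  ), progress = FALSE)
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed coverage table %s: line %d", path, prob$row[1] + 1L))
  }
  validate_gene_coverage(x)
}

#' @rdname read_gene_coverage
#' @param x A data frame of gene coverage rows.
#' @export
validate_gene_coverage <- function(x) {
  need <- c("species_id", "gene_cluster_id", "sample_id", "horiz_bp", "frac_len", "mean_depth")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) abort(paste0("coverage table lacks columns: ", paste(miss, collapse = ", ")))
  x <- as_tibble(x)
  if (any(x$horiz_bp < 0) || any(x$mean_depth < 0)) abort("negative coverage values")
  if (any(x$frac_len < 0 | x$frac_len > 1)) abort("frac_len must lie in [0, 1]")
  x
}

#' Write a gene-cluster coverage table as TSV
#' @param x A coverage tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_coverage <- function(x, path) {
  keep <- c("species_id", "gene_cluster_id", "sample_id", "horiz_bp", "frac_len", "mean_depth")
  readr::write_tsv(as_tibble(x)[keep], path, progress = FALSE)
  invisible(path)
}

#' Read a pangenome membership table
#'
#' Long-format TSV of `gene_cluster_id` x `genome_id` pairs; a row means the
#' gene cluster was identified in that genome.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene_cluster_id`, `genome_id`.
#' @export
read_pangenome <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_cluster_id = readr::col_character(),
    genome_id = readr::col_character()
  ), progress = FALSE)
  distinct(x)
}

#' @rdname read_pangenome
#' @param x A membership tibble.
#' @export
write_pangenome <- function(x, path) {
  readr::write_tsv(as_tibble(x)[c("gene_cluster_id", "genome_id")], path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' One row per sample with at least `sample_id`, `fmt_id`, `role` (one of
#' `donor`, `recipient_pre`, `post`), `day` (days after the intervention; NA
#' for baselines), `subject_id` and `geography`. Any further columns are kept
#' as covariates.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                       progress = FALSE)
  need <- c("sample_id", "fmt_id", "role", "day", "subject_id", "geography")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) abort(paste0("metadata lacks columns: ", paste(miss, collapse = ", ")))
  bad <- setdiff(unique(x$role), c("donor", "recipient_pre", "post"))
  if (length(bad) > 0) abort(paste0("unknown sample role: ", paste(bad, collapse = ", ")))
  as_tibble(x)
}

#' Assemble D-R-P triads from sample metadata
#'
#' Groups metadata rows by `fmt_id` into donor / recipient-baseline /
#' post-FMT sample triads. Autologous transfers (no donor sample) reuse the
#' recipient baseline in the donor slot, which by construction empties the
#' donor-determinant allele sets downstream.
#'
#' @param metadata Tibble from [read_metadata()].
#' @return A tibble with one row per FMT: `fmt_id`, `donor_sample`,
#'   `recipient_sample`, `post_samples` (list column ordered by day),
#'   `post_days` (list column), `allogenic`, `donor_subject`,
#'   `recipient_subject`, `geography`.
#' @export
build_triads <- function(metadata) {
  metadata |>
    group_by(.data$fmt_id) |>
    group_modify(function(g, key) {
      don <- g |> filter(.data$role == "donor")
      rec <- g |> filter(.data$role == "recipient_pre")
      pos <- g |> filter(.data$role == "post") |> arrange(.data$day)
      if (nrow(rec) != 1) {
        abort(sprintf("FMT %s needs exactly one recipient_pre sample", key$fmt_id))
      }
      if (nrow(pos) < 1) {
        abort(sprintf("FMT %s has no post-FMT sample", key$fmt_id))
      }
      allo <- nrow(don) == 1
      if (nrow(don) > 1) abort(sprintf("FMT %s has more than one donor sample", key$fmt_id))
      tibble(
        donor_sample = if (allo) don$sample_id else rec$sample_id,
        recipient_sample = rec$sample_id,
        post_samples = list(pos$sample_id),
        post_days = list(pos$day),
        allogenic = allo,
        donor_subject = if (allo) don$subject_id else rec$subject_id,
        recipient_subject = rec$subject_id,
        geography = rec$geography[1]
      )
    }) |>
    ungroup()
}
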