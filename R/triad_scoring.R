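# Internal: align one species' variant rows for one sample onto a fixed
# position index, returning the n_pos x 4 allele-count matrix.
.counts_matrix <- function(tab, positions, sample) {
  m <- matrix(0, nrow = length(positions), ncol = 4,
              dimnames = list(positions, ALLELES))
  rows <- tab[tab$sample_id == sample, , drop = FALSE]
  if (nrow(rows) > 0) {
    idx <- match(rows$position_id, positions)
    m[idx, ] <- as.matrix(rows[COUNT_COLS])
  }
  m
}

# Internal: per-position evaluability status of a sample.
# "covered"  — total depth >= detect_reads at the position;
# "absent"   — the containing gene is confidently absent in the sample;
# "unknown"  — anything else (excluded from the informative set).
.position_status <- function(counts, genes, gene_state) {
  depth <- rowSums(counts)
  st <- gene_state[genes]
  status <- rep("unknown", length(depth))
  status[!is.na(st) & st == "confidently_absent"] <- "absent"
  status[depth >= attr(counts, "detect_reads")] <- "covered"
  status
}

# Internal: assemble counts, observed-allele and status matrices for one
# species across the three (or more) samples of a triad.
.species_state <- function(table, gene_profile, samples, species_id, config) {
  tab <- table[table$species_id == species_id, , drop = FALSE]
  pos_map <- tab |> distinct(.data$position_id, .data$gene_cluster_id) |>
    arrange(.data$position_id)
  positions <- pos_map$position_id
  genes <- pos_map$gene_cluster_id
  gp <- gene_profile[gene_profile$species_id == species_id, , drop = FALSE]
  out <- lapply(samples, function(s) {
    cm <- .counts_matrix(tab, positions, s)
    attr(cm, "detect_reads") <- config$detect_reads
    gs <- gp[gp$sample_id == s, , drop = FALSE]
    gene_state <- setNames(gs$state, gs$gene_cluster_id)
    list(
      counts = cm,
      obs = cm >= config$detect_reads,
      status = .position_status(cm, genes, gene_state)
    )
  })
  names(out) <- samples
  list(positions = positions, genes = genes, samples = out)
}

#' Determinant alleles of a donor/recipient pair
#'
#' Donor-determinant alleles are variants unique to the donor baseline (D)
#' relative to the recipient pre-FMT baseline (R), and vice versa for
#' recipient-determinant alleles. An allele is *observed* in a sample when it
#' is supported by at least `config$detect_reads` reads (default 2). Multiple
#' observed alleles at the same position are all taken into account. A
#' position is evaluable in a sample when it is either covered by
#' `detect_reads` reads or lies in a gene cluster that is confidently absent
#' there (so differential gene content between strains also yields
#' determinants); positions with unknown state in either sample are excluded
#' from the informative set.
#'
#' @param table A `variant_table` covering the triad's samples.
#' @param gene_profile Output of [call_gene_presence()] for the same species.
#' @param donor,recipient Sample identifiers of D and R.
#' @param species_id Species to evaluate.
#' @param config A [scoring_config()].
#' @return A `determinant_sets` list: tibbles `donor` and `recipient` of
#'   (position_id, allele) pairs, the character vector
#'   `informative_positions` (evaluable in both D and R), and `n_informative`.
#' @export
determinant_alleles <- function(table, gene_profile, donor, recipient,
                                species_id, config = scoring_config()) {
  st <- .species_state(table, gene_profile, c(donor, recipient), species_id, config)
  D <- st$samples[[donor]]; R <- st$samples[[recipient]]
  informative <- D$status != "unknown" & R$status != "unknown"
  don <- D$obs & !R$obs & informative
  rec <- R$obs & !D$obs & informative
  pairs <- function(m) {
    w <- which(m, arr.ind = TRUE)
    tibble(position_id = st$positions[w[, 1]], allele = ALLELES[w[, 2]]) |>
      arrange(.data$position_id, .data$allele)
  }
  structure(
    list(
      species_id = species_id,
      donor = pairs(don),
      recipient = pairs(rec),
      informative_positions = st$positions[informative],
      n_informative = sum(informative)
    ),
    class = "determinant_sets"
  )
}

#' Post-FMT determinant alleles
#'
#' Alleles observed in the post-FMT sample (with at least
#' `config$detect_reads` supporting reads) that are unique to P relative to
#' both the donor and recipient baselines — evidence of novel or previously
#' undetected strains. Only positions evaluable (covered or confidently
#' absent) in all three samples are considered.
#'
#' @inheritParams determinant_alleles
#' @param post Sample identifier of the post-FMT sample.
#' @return A tibble of (position_id, allele) pairs.
#' @export
post_determinant_alleles <- function(table, gene_profile, post, donor, recipient,
                                     species_id, config = scoring_config()) {
  st <- .species_state(table, gene_profile, unique(c(post, donor, recipient)),
                       species_id, config)
  P <- st$samples[[post]]; D <- st$samples[[donor]]; R <- st$samples[[recipient]]
  informative <- P$status != "unknown" & D$status != "unknown" & R$status != "unknown"
  novel <- P$obs & !D$obs & !R$obs & informative
  w <- which(novel, arr.ind = TRUE)
  tibble(position_id = st$positions[w[, 1]], allele = ALLELES[w[, 2]]) |>
    arrange(.data$position_id, .data$allele)
}

#' Donor / recipient / novel strain fractions in a post-FMT sample
#'
#' Quantifies how much of the post-FMT strain population is attributable to
#' donor baseline strains, recipient baseline strains, or novel sources.
#' Informative positions are those evaluable (covered with
#' `config$detect_reads` reads or confidently absent) in all three samples of
#' the triad; conspecific scoring requires at least `config$min_informative`
#' (default 100) of them. Then
#' `f_donor` = detected / evaluable donor-determinant alleles at informative
#' positions of P (symmetrically `f_recipient`), and `f_novel` = detected
#' post-determinant alleles divided by the number of informative positions.
#' A zero denominator yields a missing fraction (e.g. `f_donor` in autologous
#' transfers, where the donor-determinant set is empty by construction).
#'
#' @inheritParams post_determinant_alleles
#' @return A one-row tibble: `f_donor`, `f_recipient`, `f_novel`,
#'   `n_informative`, `scorable` (logical).
#' @export
strain_fractions <- function(table, gene_profile, post, donor, recipient,
                             species_id, config = scoring_config()) {
  st <- .species_state(table, gene_profile, unique(c(post, donor, recipient)),
                       species_id, config)
  P <- st$samples[[post]]; D <- st$samples[[donor]]; R <- st$samples[[recipient]]
  informative <- P$status != "unknown" & D$status != "unknown" & R$status != "unknown"
  n_inf <- sum(informative)
  if (n_inf < config$min_informative) {
    return(tibble(f_donor = NA_real_, f_recipient = NA_real_, f_novel = NA_real_,
                  n_informative = n_inf, scorable = FALSE))
  }
  don_det <- D$obs & !R$obs & informative
  rec_det <- R$obs & !D$obs & informative
  novel_det <- P$obs & !D$obs & !R$obs & informative
  frac <- function(det) {
    n_eval <- sum(det)
    if (n_eval == 0) return(NA_real_)
    sum(det & P$obs) / n_eval
  }
  tibble(
    f_donor = frac(don_det),
    f_recipient = frac(rec_det),
    f_novel = sum(novel_det) / n_inf,
    n_informative = n_inf,
    scorable = TRUE
  )
}

#' Categorical FMT outcome for one species
#'
#' Presence/absence patterns are scored first: a species present in the donor
#' but not the recipient baseline that appears post FMT is a donor
#' colonization; present only in the recipient and retained, a recipient
#' persistence; appearing from neither baseline, a novel influx; present in
#' the recipient baseline but lost post FMT, a species loss; present only in
#' the donor and failing to appear, a donor rejection. When the species is
#' present in all three samples (conspecific case) the strain fractions
#' decide: coexistence when both donor and recipient fractions reach
#' `theta_present`; dominance by one source when its fraction reaches
#' `theta_dominant` while the other stays below `theta_present`; novel influx
#' when the novel fraction reaches `theta_dominant`; otherwise the largest
#' fraction wins, with the deterministic tie-break donor > recipient > novel.
#' Missing fractions are treated as zero for the decision (their reported
#' values stay missing).
#'
#' @param f_donor,f_recipient,f_novel Strain fractions (may be `NA`).
#' @param in_donor,in_recipient,in_post Species presence in D, R, P.
#' @param scorable Whether conspecific scoring had enough informative
#'   positions.
#' @param config A [scoring_config()].
#' @return A single category string.
#' @export
classify_outcome <- function(f_donor, f_recipient, f_novel,
                             in_donor, in_recipient, in_post,
                             scorable = TRUE, config = scoring_config()) {
  if (!in_post) {
    if (!any(is.na(c(f_donor, f_recipient, f_novel)))) {
      abort("fractions supplied for a species not observed post FMT")
    }
    if (in_recipient) return("species_loss")
    if (in_donor) return("donor_rejection")
    abort("species absent from all three samples is not scorable")
  }
  if (in_donor && !in_recipient) return("donor_colonization")
  if (!in_donor && in_recipient) return("recipient_persistence")
  if (!in_donor && !in_recipient) return("novel_influx")
  # conspecific: present in D, R and P
  if (!scorable) return("not_scorable")
  fd <- if (is.na(f_donor)) 0 else f_donor
  fr <- if (is.na(f_recipient)) 0 else f_recipient
  fn <- if (is.na(f_novel)) 0 else f_novel
  if (is.na(f_donor) && is.na(f_recipient)) {
    # no determinant alleles at all (e.g. autologous transfers, where donor
    # and recipient baseline are the same sample): donor/recipient
    # attribution is undefined, only novel influx remains decidable
    return(if (fn >= config$theta_dominant) "novel_influx" else "not_scorable")
  }
  if (fd >= config$theta_present && fr >= config$theta_present) return("coexistence")
  if (fd >= config$theta_dominant && fr < config$theta_present) return("donor_colonization")
  if (fr >= config$theta_dominant && fd < config$theta_present) return("recipient_persistence")
  if (fn >= config$theta_dominant) return("novel_influx")
  c("donor_colonization", "recipient_persistence", "novel_influx")[
    which.max(c(fd, fr, fn))]
}

#' Score all species of one FMT time series
#'
#' Produces one outcome record per species and post-FMT sample of a D-R-P
#' triad. Every post-FMT time point is scored independently. For autologous
#' transfers the recipient baseline stands in for the donor sample, which
#' forces empty donor-determinant sets. Species observed in none of the
#' triad's samples contribute no record. Presence-based outcomes carry
#' degenerate fractions (e.g. a donor-only species observed post FMT has
#' `f_donor = 1`) so that cohort indices average over all species observed
#' post FMT.
#'
#' @param triad One row of [build_triads()] output (or a list with fields
#'   `fmt_id`, `donor_sample`, `recipient_sample`, `post_samples`,
#'   `post_days`).
#' @param table A `variant_table` covering the triad's samples.
#' @param gene_profile Gene presence states for the same samples.
#' @param detection Output of [detect_species()].
#' @param config A [scoring_config()].
#' @return A tibble of outcome records: `fmt_id`, `species_id`,
#'   `post_sample`, `day`, `in_donor`, `in_recipient`, `in_post`,
#'   `f_donor`, `f_recipient`, `f_novel`, `n_informative`, `category`.
#' @export
score_timeseries <- function(triad, table, gene_profile, detection,
                             config = scoring_config()) {
  donor <- triad$donor_sample[[1]]
  recipient <- triad$recipient_sample[[1]]
  posts <- unlist(triad$post_samples)
  days <- unlist(triad$post_days)
  det <- detection |> select("species_id", "sample_id", "detected")
  is_in <- function(sp, s) {
    hit <- det$detected[det$species_id == sp & det$sample_id == s]
    length(hit) > 0 && isTRUE(hit[1])
  }
  species <- sort(unique(det$species_id[det$detected]))
  recs <- list()
  for (sp in species) {
    in_d <- is_in(sp, donor)
    in_r <- is_in(sp, recipient)
    for (k in seq_along(posts)) {
      p <- posts[k]
      in_p <- is_in(sp, p)
      if (!in_d && !in_r && !in_p) next
      if (in_d && in_r && in_p) {
        fr <- strain_fractions(table, gene_profile, p, donor, recipient, sp, config)
        cat_ <- classify_outcome(fr$f_donor, fr$f_recipient, fr$f_novel,
                                 in_d, in_r, in_p, fr$scorable, config)
        row <- tibble(
          f_donor = fr$f_donor, f_recipient = fr$f_recipient,
          f_novel = fr$f_novel, n_informative = fr$n_informative
        )
      } else {
        cat_ <- classify_outcome(NA, NA, NA, in_d, in_r, in_p, TRUE, config)
        row <- tibble(
          f_donor = if (in_p) as.numeric(in_d && !in_r) else NA_real_,
          f_recipient = if (in_p) as.numeric(!in_d && in_r) else NA_real_,
          f_novel = if (in_p) as.numeric(!in_d && !in_r) else NA_real_,
          n_informative = NA_integer_
        )
      }
      recs[[length(recs) + 1]] <- tibble(
        fmt_id = triad$fmt_id[[1]], species_id = sp,
        post_sample = p, day = days[k],
        in_donor = in_d, in_recipient = in_r, in_post = in_p
      ) |> bind_cols(row) |> mutate(category = cat_)
    }
  }
  bind_rows(recs)
}
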