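#' Colonization and persistence indices for one FMT
#'
#' The colonization index of an FMT is the average fraction of donor strains
#' across all species observed post FMT; the persistence index is the average
#' fraction of persistent recipient strains. Species without a defined
#' fraction (missing denominator, not scorable) are excluded from the mean;
#' with no contributing species the index is missing.
#'
#' @param records Outcome records from [score_timeseries()] for one FMT and
#'   one time point.
#' @return A single value in `[0, 1]`, or `NA`.
#' @export
#' @examples
#' colonization_index(tibble::tibble(in_post = TRUE, f_donor = c(0.5, 1)))
colonization_index <- function(records) {
  f <- records$f_donor[records$in_post]
  f <- f[!is.na(f)]
  if (length(f) == 0) return(NA_real_)
  mean(f)
}

#' @rdname colonization_index
#' @export
persistence_index <- function(records) {
  f <- records$f_recipient[records$in_post]
  f <- f[!is.na(f)]
  if (length(f) == 0) return(NA_real_)
  mean(f)
}

#' Per-category outcome fractions of one FMT
#'
#' Counts outcome categories across the species observed in the recipient
#' post FMT (species absent post FMT are excluded from the denominator) and
#' normalizes to fractions, which sum to 1.
#'
#' @param records Outcome records for one FMT at one time point.
#' @return A tibble with `fmt_id`, `category`, `n`, `fraction`.
#' @export
community_outcome_fractions <- function(records) {
  post <- records |> filter(.data$in_post)
  if (nrow(post) == 0) abort("no species observed post FMT")
  post |>
    count(.data$fmt_id, .data$category) |>
    group_by(.data$fmt_id) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
}

#' Restrict outcome records to the last available time point
#'
#' Cohort summaries conventionally use the last available post-FMT sample of
#' each time series.
#'
#' @param records Outcome records across FMTs/time points.
#' @return Records of the latest `day` per FMT.
#' @export
last_timepoint <- function(records) {
  records |>
    group_by(.data$fmt_id) |>
    filter(.data$day == max(.data$day)) |>
    ungroup()
}

#' Summarize outcome records into per-FMT indices
#'
#' @param records Outcome records (all FMTs). The last available time point
#'   per FMT is used.
#' @return A tibble with one row per FMT: `colonization_index`,
#'   `persistence_index`, and one `frac_<category>` column per category.
#' @export
summarize_cohort <- function(records) {
  last <- last_timepoint(records)
  idx <- last |>
    group_by(.data$fmt_id) |>
    summarise(
      colonization_index = colonization_index(pick(everything())),
      persistence_index = persistence_index(pick(everything())),
      .groups = "drop"
    )
  frac <- community_outcome_fractions(last |> filter(.data$in_post)) |>
    select("fmt_id", "category", "fraction") |>
    tidyr::pivot_wider(names_from = "category", values_from = "fraction",
                       names_prefix = "frac_", values_fill = 0)
  left_join(idx, frac, by = "fmt_id")
}

#' Binarized strain-level outcomes
#'
#' Maps each categorical outcome to four booleans: *resilience* (recipient
#' strains persisted, dominant or coexisting with donor strains),
#' *colonization* (donor strains colonized as dominant or coexisting
#' populations), *takeover* (donor strains became dominant) and *turnover*
#' (the recipient's baseline strains were displaced by donor and/or novel or
#' previously undetectable strains). Takeover implies both colonization and
#' turnover. Records that were not scorable yield missing values.
#'
#' @param records Outcome records with a `category` column.
#' @return The records with logical columns `resilience`, `colonization`,
#'   `takeover`, `turnover` appended.
#' @export
binarize_outcomes <- function(records) {
  known <- c("donor_colonization", "recipient_persistence", "coexistence",
             "novel_influx", "donor_rejection", "species_loss", "not_scorable")
  bad <- setdiff(unique(records$category), known)
  if (length(bad) > 0) abort(paste0("unknown category: ", paste(bad, collapse = ", ")))
  records |>
    mutate(
      resilience = case_when(
        .data$category == "not_scorable" ~ NA,
        TRUE ~ .data$category %in% c("recipient_persistence", "coexistence")
      ),
      colonization = case_when(
        .data$category == "not_scorable" ~ NA,
        TRUE ~ .data$category %in% c("donor_colonization", "coexistence")
      ),
      takeover = case_when(
        .data$category == "not_scorable" ~ NA,
        TRUE ~ .data$category == "donor_colonization"
      ),
      turnover = case_when(
        .data$category == "not_scorable" ~ NA,
        TRUE ~ .data$category %in% c("donor_colonization", "novel_influx", "species_loss")
      )
    )
}

#' Shuffled-triad null cohorts
#'
#' Simulates FMT time series by replacing, per observed D-R-P triad, (1) the
#' donor sample, (2) the recipient baseline sample, or (3) both, with samples
#' from other FMTs. Randomizations are stratified by geography and by subject:
#' a replacement is only eligible if it comes from a different subject than
#' the triad's recipient (respectively donor), so that donors used in several
#' FMTs are never paired with their own recipients. Ten simulated triads per
#' observed triad are drawn by default. Within one replicate of the cohort,
#' replacements are assigned without reuse where feasible; across replicates,
#' draws are independent. A triad whose stratum offers no eligible
#' alternative is skipped with a warning, and the true pairing is never
#' reused when an alternative exists.
#'
#' @param triads Output of [build_triads()].
#' @param mode One of `"shuffle_donor"`, `"shuffle_recipient"`,
#'   `"shuffle_both"`.
#' @param replicates Simulated triads per observed triad (default 10).
#' @param seed Integer seed; the same seed reproduces the null cohort
#'   exactly.
#' @return A tibble of simulated triads with columns of `triads` plus
#'   `replicate` and `mode`; `donor_sample` and/or `recipient_sample` carry
#'   the shuffled assignment.
#' @export
shuffle_triads <- function(triads, mode = c("shuffle_donor", "shuffle_recipient",
                                            "shuffle_both"),
                           replicates = 10L, seed = 1L) {
  mode <- match.arg(mode)
  lonely <- names(which(table(triads$geography) < 2))
  for (g in lonely) {
    warn(sprintf("stratum '%s' has a single triad; skipped in null cohort", g))
  }
  set.seed(seed)
  out <- list()
  for (rep_i in seq_len(replicates)) {
    sim <- triads
    if (mode %in% c("shuffle_donor", "shuffle_both")) {
      sim <- .shuffle_slot(sim, slot = "donor")
    }
    if (mode %in% c("shuffle_recipient", "shuffle_both")) {
      sim <- .shuffle_slot(sim, slot = "recipient")
    }
    sim$replicate <- rep_i
    sim$mode <- mode
    out[[rep_i]] <- sim
  }
  bind_rows(out) |> filter(!is.na(.data$donor_sample), !is.na(.data$recipient_sample))
}

# Internal: reassign one slot (donor or recipient baseline) within geography
# strata, avoiding same-subject pairings and the true assignment, without
# reuse within the replicate where a feasible assignment exists.
.shuffle_slot <- function(triads, slot) {
  samp_col <- if (slot == "donor") "donor_sample" else "recipient_sample"
  subj_col <- if (slot == "donor") "donor_subject" else "recipient_subject"
  # the subject the replacement must differ from:
  other_subj <- if (slot == "donor") triads$recipient_subject else triads$donor_subject
  new_samp <- rep(NA_character_, nrow(triads))
  new_subj <- rep(NA_character_, nrow(triads))
  for (g in unique(triads$geography)) {
    idx <- which(triads$geography == g)
    if (length(idx) < 2) next  # singleton stratum; warned upstream
    pool_samp <- triads[[samp_col]][idx]
    pool_subj <- triads[[subj_col]][idx]
    assigned <- .assign_without_reuse(
      pool_samp, pool_subj,
      forbid_subj = as.character(other_subj[idx]),
      forbid_samp = triads[[samp_col]][idx]
    )
    new_samp[idx] <- assigned$samp
    new_subj[idx] <- assigned$subj
  }
  triads[[samp_col]] <- new_samp
  triads[[subj_col]] <- new_subj
  triads
}

# Internal: draw a within-stratum assignment. Targets are visited in random
# order; each picks uniformly among the remaining eligible pool entries
# (different subject, not its own true sample). If the without-reuse matching
# runs dry for some target, that target falls back to an eligible draw with
# reuse; targets with no eligible entry at all keep NA (skipped upstream).
.assign_without_reuse <- function(pool_samp, pool_subj, forbid_subj, forbid_samp) {
  n <- length(pool_samp)
  res_samp <- rep(NA_character_, n)
  res_subj <- rep(NA_character_, n)
  remaining <- rep(TRUE, n)
  for (i in sample.int(n)) {
    elig_all <- which(pool_subj != forbid_subj[i] & pool_samp != forbid_samp[i])
    if (length(elig_all) == 0) next
    elig <- elig_all[remaining[elig_all]]
    if (length(elig) == 0) elig <- elig_all
    j <- elig[sample.int(length(elig), 1)]
    res_samp[i] <- pool_samp[j]
    res_subj[i] <- pool_subj[j]
    remaining[j] <- FALSE
  }
  list(samp = res_samp, subj = res_subj)
}

#' Test clinical associations of outcome metrics
#'
#' For each outcome metric, compares responders with nonresponders by a
#' Wilcoxon rank-sum test (exact by default for fewer than 50 observations
#' without ties) and, when covariates are supplied, by sequential ANOVA on a
#' linear model in which the response indicator enters after the covariates.
#' All p-values computed in one invocation form the family for
#' Benjamini-Hochberg correction.
#'
#' @param summaries Tibble with one row per FMT, containing the metric
#'   columns and a logical/binary `response` column (FMTs with missing
#'   response are dropped).
#' @param metrics Character vector of metric column names to test.
#' @param covariates Optional character vector of covariate columns for the
#'   sequential ANOVA.
#' @param exact Passed to [stats::wilcox.test()]; default chooses an exact
#'   test for small samples.
#' @return A tibble with `metric`, `test`, `statistic`, `p_value`,
#'   `q_value` (BH-adjusted across all rows).
#' @export
associate_clinical <- function(summaries, metrics, covariates = NULL,
                               exact = NULL) {
  if (!"response" %in% names(summaries)) abort("summaries needs a 'response' column")
  dat <- summaries |> filter(!is.na(.data$response))
  res <- purrr::map_dfr(metrics, function(m) {
    y <- dat[[m]]
    grp <- as.logical(dat$response)
    keep <- !is.na(y)
    w <- suppressWarnings(
      wilcox.test(y[keep & grp], y[keep & !grp], exact = exact)
    )
    rows <- tibble(metric = m, test = "wilcoxon",
                   statistic = unname(w$statistic), p_value = w$p.value)
    if (!is.null(covariates)) {
      f <- stats::reformulate(c(covariates, "response"), response = m)
      fit <- lm(f, data = dat)
      an <- anova(fit)
      p <- an["response", "Pr(>F)"]
      rows <- bind_rows(rows, tibble(
        metric = m, test = "sequential_anova",
        statistic = an["response", "F value"], p_value = p
      ))
    }
    rows
  })
  res |> mutate(q_value = p.adjust(.data$p_value, method = "BH"))
}
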