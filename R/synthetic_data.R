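# Stable sub-seed derivation so every simulated entity draws from its own
# stream; values stay below 2^31 - 1.
.derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 12345) %% 2147483647)
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate a conspecific strain haplotype panel
#'
#' Generates `n_strains` haplotypes of one species over `n_positions` variant
#' sites distributed round-robin across `n_genes` gene clusters, the first
#' `core_fraction` of which form the extended core carried by every
#' haplotype; accessory genes are carried by a random subset of haplotypes
#' (never by all or none, so gene content separates strains).
#'
#' Two allele layouts are available. `"marker"` (default) emulates
#' strain-diagnostic SNVs: each position carries a background allele shared by
#' the panel plus one strain-private alternative allele, with position
#' ownership rotating over strains — so any two strains differ at about
#' `2 n_positions / n_strains` sites and each strain has private marker
#' alleles, as conspecific gut strains resolved against a pangenome do.
#' In marker mode the last `n_divergent` strains (default 1) are instead
#' divergent haplotypes that differ from the background and from every marker
#' allele at every position — emulating phylogenetically distinct strains
#' entering from the environment, the source population of novel-influx
#' outcomes. `"disjoint"` makes every pair of haplotypes differ at every
#' position (maximally divergent populations).
#'
#' @param n_strains,n_positions,n_genes Panel dimensions.
#' @param core_fraction Fraction of genes in the extended core.
#' @param gene_length Representative gene length in bp.
#' @param mode Allele layout, `"marker"` or `"disjoint"`.
#' @param n_divergent Number of trailing divergent haplotypes in marker mode.
#' @param species_id Species identifier used in emitted tables.
#' @param seed Integer seed; identical seeds give identical panels.
#' @return A `haplotype_panel` list: `positions` tibble (position_id,
#'   gene_cluster_id), `haplotypes` (strains x positions allele matrix),
#'   `gene_content` (strains x genes logical), `genes`, `core_gene_ids`,
#'   `gene_length`, `species_id`, `mode`.
#' @export
simulate_species <- function(n_strains = 4L, n_positions = 400L, n_genes = 40L,
                             core_fraction = 0.7, gene_length = 1500L,
                             mode = c("marker", "disjoint"),
                             n_divergent = 1L,
                             species_id = "species_1", seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_strains >= 1, n_positions >= 1, n_genes >= 1)
  set.seed(seed)
  genes <- sprintf("%s_g%03d", species_id, seq_len(n_genes))
  n_core <- max(1L, ceiling(core_fraction * n_genes))
  core_genes <- genes[seq_len(n_core)]
  positions <- tibble(
    position_id = sprintf("%s_p%05d", species_id, seq_len(n_positions)),
    gene_cluster_id = rep(genes, length.out = n_positions)
  )
  hap <- matrix("", nrow = n_strains, ncol = n_positions,
                dimnames = list(paste0("strain_", seq_len(n_strains)),
                                positions$position_id))
  if (mode == "marker") {
    background <- sample(ALLELES, n_positions, replace = TRUE)
    owner <- rep(seq_len(n_strains), length.out = n_positions)
    for (i in seq_len(n_positions)) {
      hap[, i] <- background[i]
      if (n_strains > 1) {
        hap[owner[i], i] <- sample(setdiff(ALLELES, background[i]), 1)
      }
    }
    n_div <- min(n_divergent, max(n_strains - 1L, 0L))
    if (n_div > 0) {
      div_strains <- seq(n_strains - n_div + 1L, n_strains)
      for (i in seq_len(n_positions)) {
        used <- c(background[i], hap[owner[i], i])
        for (s in div_strains) {
          pick <- setdiff(ALLELES, used)
          if (length(pick) == 0) pick <- setdiff(ALLELES, background[i])
          a <- if (length(pick) == 1) pick else sample(pick, 1)
          hap[s, i] <- a
          used <- c(used, a)
        }
      }
    }
  } else {
    base <- sample.int(4, n_positions, replace = TRUE)
    for (s in seq_len(n_strains)) {
      hap[s, ] <- ALLELES[((base + s - 2L) %% 4L) + 1L]
    }
  }
  content <- matrix(TRUE, nrow = n_strains, ncol = n_genes,
                    dimnames = list(rownames(hap), genes))
  if (n_genes > n_core) {
    for (g in seq(n_core + 1L, n_genes)) {
      carry <- runif(n_strains) < 0.6
      if (n_strains >= 2) {
        if (all(carry)) carry[sample.int(n_strains, 1)] <- FALSE
        if (!any(carry)) carry[sample.int(n_strains, 1)] <- TRUE
      } else if (!any(carry)) {
        carry[1] <- TRUE
      }
      content[, g] <- carry
    }
  }
  structure(
    list(
      species_id = species_id, positions = positions, haplotypes = hap,
      gene_content = content, genes = genes, core_gene_ids = core_genes,
      gene_length = gene_length, mode = mode, n_divergent = as.integer(n_divergent)
    ),
    class = "haplotype_panel"
  )
}

#' Redraw a panel's haplotypes on a fixed scaffold
#'
#' Keeps the species' position and gene identifiers (so samples from
#' different panels remain comparable) but redraws alleles and accessory gene
#' content. Used to give every FMT of a synthetic cohort an independent
#' strain pool of the same species.
#'
#' @param panel A `haplotype_panel`.
#' @param seed Integer seed.
#' @return A new `haplotype_panel` on the same scaffold.
#' @export
respawn_haplotypes <- function(panel, seed) {
  fresh <- simulate_species(
    n_strains = nrow(panel$haplotypes),
    n_positions = nrow(panel$positions),
    n_genes = length(panel$genes),
    core_fraction = length(panel$core_gene_ids) / length(panel$genes),
    gene_length = panel$gene_length,
    mode = panel$mode,
    n_divergent = panel$n_divergent %||% 1L,
    species_id = panel$species_id,
    seed = seed
  )
  fresh$positions <- panel$positions
  fresh$genes <- panel$genes
  fresh$core_gene_ids <- panel$core_gene_ids
  colnames(fresh$haplotypes) <- panel$positions$position_id
  colnames(fresh$gene_content) <- panel$genes
  fresh
}

#' Simulate one metagenomic sample from a strain mixture
#'
#' Mixes the panel's haplotypes at the given weights and emits the
#' variant-table and gene-coverage rows the profile readers expect. Per
#' position, read depth is Poisson with mean `depth` times the summed weight
#' of strains carrying the containing gene, and allele counts are multinomial
#' over the mixture-weighted haplotype alleles, with a per-read sequencing
#' error flip at rate `error_rate`. Gene coverage follows the Poisson
#' coverage model: mean vertical depth is Poisson-sampled around `depth`
#' times the carrier weight, and the covered fraction is `1 - exp(-depth)`.
#' Genes carried by no weighted strain attract no coverage row beyond a zero
#' entry. An all-zero weight vector yields an absent species (no reads, zero
#' marker genes).
#'
#' @param panel A `haplotype_panel`.
#' @param weights Mixture weights over strains; non-negative, summing to 1
#'   (or 0 for an absent species).
#' @param depth Mean sequencing depth (> 0).
#' @param sample_id Sample identifier.
#' @param seed Integer seed.
#' @param error_rate Per-read allele flip probability.
#' @return A list of tibbles: `variants`, `coverage`, `markers`
#'   (species_id, sample_id, n_marker_genes).
#' @export
simulate_sample <- function(panel, weights, depth, sample_id = "sample",
                            seed = 1L, error_rate = 0.001) {
  if (depth <= 0) abort("depth must be positive")
  n_strains <- nrow(panel$haplotypes)
  if (length(weights) != n_strains || any(weights < 0)) {
    abort("weights must be non-negative, one per strain")
  }
  w_tot <- sum(weights)
  if (w_tot > 0 && abs(w_tot - 1) > 1e-8) abort("weights must sum to 1 (or 0)")
  set.seed(seed)
  L <- panel$gene_length
  gene_w <- as.numeric(weights %*% panel$gene_content)
  names(gene_w) <- panel$genes

  cov <- tibble(
    species_id = panel$species_id,
    gene_cluster_id = panel$genes,
    sample_id = sample_id,
    mean_depth = ifelse(gene_w > 0, rpois(length(gene_w), depth * gene_w * L) / L, 0)
  ) |>
    mutate(
      frac_len = ifelse(.data$mean_depth > 0, 1 - exp(-.data$mean_depth), 0),
      horiz_bp = round(.env$L * .data$frac_len)
    ) |>
    select("species_id", "gene_cluster_id", "sample_id",
           "horiz_bp", "frac_len", "mean_depth")

  pos_gene <- panel$positions$gene_cluster_id
  w_pos <- gene_w[pos_gene]
  d <- ifelse(w_pos > 0, rpois(length(w_pos), depth * w_pos), 0L)
  counts <- matrix(0L, nrow = length(d), ncol = 4, dimnames = list(NULL, ALLELES))
  for (i in which(d > 0)) {
    carriers <- panel$gene_content[, pos_gene[i]] & weights > 0
    p <- vapply(ALLELES, function(a) {
      sum(weights[carriers & panel$haplotypes[, i] == a])
    }, numeric(1))
    p <- p / sum(p)
    p <- p * (1 - error_rate) + (1 - p) * error_rate / 3
    counts[i, ] <- rmultinom(1, d[i], p)[, 1]
  }
  keep <- d > 0
  variants <- tibble(
    species_id = panel$species_id,
    position_id = panel$positions$position_id[keep],
    gene_cluster_id = pos_gene[keep],
    sample_id = sample_id,
    count_A = counts[keep, 1], count_C = counts[keep, 2],
    count_G = counts[keep, 3], count_T = counts[keep, 4]
  )
  markers <- tibble(
    species_id = panel$species_id, sample_id = sample_id,
    n_marker_genes = if (w_tot > 0) 10L else 0L
  )
  list(variants = variants, coverage = cov, markers = markers)
}

#' Define a planted D-R-P mixture scenario
#'
#' Builds the donor, recipient and post-FMT mixture weight vectors that plant
#' a given outcome category. The panel must have at least five strains:
#' strains 1-2 act as the donor population, 3-4 as the recipient population
#' and 5 as a novel strain absent from both baselines.
#'
#' @param category Target outcome category (one of `donor_colonization`,
#'   `recipient_persistence`, `coexistence`, `novel_influx`,
#'   `donor_rejection`, `species_loss`, or `autologous` for an autologous
#'   control whose donor slot reuses the recipient baseline).
#' @param panel A `haplotype_panel` with >= 5 strains.
#' @param depth Mean sequencing depth of each simulated sample.
#' @param fmt_id Identifier for the simulated FMT.
#' @param post_days Days after the intervention for the post sample(s).
#' @param seed Integer seed.
#' @return A `mixture_scenario` list with weight vectors, the target
#'   category, and simulation parameters.
#' @export
mixture_scenario <- function(category, panel, depth = 50, fmt_id = "fmt_1",
                             post_days = 30, seed = 1L) {
  n <- nrow(panel$haplotypes)
  if (n < 5) abort("scenario panels need at least 5 strains")
  w <- function(...) {
    v <- numeric(n)
    spec <- list(...)
    for (nm in names(spec)) v[as.integer(nm)] <- spec[[nm]]
    v
  }
  donor_w <- w(`1` = 0.6, `2` = 0.4)
  recip_w <- w(`3` = 0.6, `4` = 0.4)
  zero <- numeric(n)
  post_w <- switch(category,
    donor_colonization = donor_w,
    recipient_persistence = recip_w,
    coexistence = 0.5 * donor_w + 0.5 * recip_w,
    novel_influx = w(`5` = 1),
    donor_rejection = zero,
    species_loss = zero,
    autologous = recip_w,
    abort(paste0("unknown target category: ", category))
  )
  if (category == "donor_rejection") recip_w <- zero
  if (category == "species_loss") donor_w <- zero
  if (category == "autologous") donor_w <- recip_w
  structure(
    list(
      species_id = panel$species_id, category = category,
      donor_weights = donor_w, recipient_weights = recip_w,
      post_weights = list(post_w), post_days = post_days,
      depth = depth, fmt_id = fmt_id, seed = seed,
      autologous = identical(category, "autologous")
    ),
    class = "mixture_scenario"
  )
}

#' Simulate a D-R-P triad from a mixture scenario
#'
#' Emits the donor, recipient-baseline and post-FMT samples of one FMT for
#' one species, together with the planted ground-truth category and the
#' triad row the scoring functions consume.
#'
#' @param scenario A [mixture_scenario()].
#' @param panel The `haplotype_panel` the scenario refers to.
#' @param error_rate Per-read sequencing error rate.
#' @return A list: `variants`, `coverage`, `markers` (stacked over samples),
#'   `triad` (one-row tibble for [score_timeseries()]), and `truth` (the
#'   planted category).
#' @export
simulate_triad <- function(scenario, panel, error_rate = 0.001) {
  fid <- scenario$fmt_id
  donor_id <- paste0(fid, "_D")
  recip_id <- paste0(fid, "_R")
  post_ids <- paste0(fid, "_P", seq_along(scenario$post_weights))
  if (scenario$autologous) donor_id <- recip_id

  sims <- list()
  if (!scenario$autologous) {
    sims$D <- simulate_sample(panel, scenario$donor_weights, scenario$depth,
                              donor_id, .derive_seed(scenario$seed, donor_id),
                              error_rate)
  }
  sims$R <- simulate_sample(panel, scenario$recipient_weights, scenario$depth,
                            recip_id, .derive_seed(scenario$seed, recip_id),
                            error_rate)
  for (k in seq_along(post_ids)) {
    sims[[post_ids[k]]] <- simulate_sample(
      panel, scenario$post_weights[[k]], scenario$depth, post_ids[k],
      .derive_seed(scenario$seed, post_ids[k]), error_rate
    )
  }
  triad <- tibble(
    fmt_id = fid,
    donor_sample = donor_id,
    recipient_sample = recip_id,
    post_samples = list(post_ids),
    post_days = list(rep(scenario$post_days, length.out = length(post_ids))),
    allogenic = !scenario$autologous,
    donor_subject = paste0(fid, if (scenario$autologous) "_recipient" else "_donor"),
    recipient_subject = paste0(fid, "_recipient"),
    geography = "geo_1"
  )
  list(
    variants = validate_variant_table(bind_rows(lapply(sims, `[[`, "variants"))),
    coverage = bind_rows(lapply(sims, `[[`, "coverage")),
    markers = bind_rows(lapply(sims, `[[`, "markers")),
    triad = triad,
    truth = scenario$category
  )
}

#' Default covariate effect table for synthetic cohorts
#'
#' @param colonization Named numeric vector of linear effects (per unit of
#'   the covariate) on the per-FMT colonization propensity.
#' @param takeover Named numeric vector of logistic (log-odds) effects on
#'   per-species donor takeover.
#' @return A tibble `covariate`, `response`, `beta`.
#' @export
cohort_effects <- function(colonization = numeric(), takeover = numeric()) {
  bind_rows(
    tibble(covariate = names(colonization), response = "colonization_index",
           beta = unname(colonization)),
    tibble(covariate = names(takeover), response = "takeover",
           beta = unname(takeover))
  )
}

#' Simulate a full synthetic FMT cohort
#'
#' Generates sample metadata and triads, a covariate table with planted
#' linear effects on the per-FMT colonization propensity and logistic
#' effects on per-species donor takeover, and — either directly or via full
#' strain-mixture profiles — per-species outcome records.
#'
#' With `emit_profiles = FALSE` (default), outcome records are drawn from the
#' planted mixture model: each FMT gets a colonization propensity
#' `mu = 0.5 + X beta + noise` (clamped to `[0, 1]`); conspecific species
#' take over with probability `plogis(qlogis(0.2) + X gamma)` (then
#' `f_donor ~ U(0.85, 1)`), otherwise fractions scatter around `mu`;
#' remaining species follow presence/absence outcomes. With
#' `emit_profiles = TRUE`, every (FMT, species) pair additionally gets full
#' SNV and coverage tables: each FMT draws an independent haplotype pool on a
#' shared per-species scaffold, so unrelated donors share alleles only by
#' chance — the property the shuffled-triad nulls probe.
#'
#' @param n_fmts Number of FMTs (>= 2 with profiles, >= 20 recommended for
#'   modeling).
#' @param n_species Species per FMT.
#' @param n_extra_covariates Additional standard-normal numeric covariates
#'   (decoy predictors), named `cov_01`, ...
#' @param effects A [cohort_effects()] table (default: no planted effects).
#' @param seed Integer master seed; all entity-level randomness derives from
#'   it.
#' @param emit_profiles Whether to also simulate SNV/coverage profiles.
#' @param depth,n_positions Profile simulation parameters.
#' @param n_geographies Number of geography strata.
#' @param p_conspecific Probability a species is present in both baselines.
#' @return A list: `metadata`, `triads`, `covariates` (tibble with `fmt_id`),
#'   `tags`, `effects`, `records`, `truth` (per-FMT propensities and per
#'   species takeover draws), and `profiles` (list of `variants`, `coverage`,
#'   `markers`, or `NULL`).
#' @export
simulate_cohort <- function(n_fmts = 50L, n_species = 30L,
                            n_extra_covariates = 0L,
                            effects = cohort_effects(), seed = 1L,
                            emit_profiles = FALSE,
                            depth = 50, n_positions = 400L,
                            n_geographies = 2L, p_conspecific = 0.7) {
  stopifnot(n_fmts >= 2, n_species >= 1)
  set.seed(.derive_seed(seed, "cohort"))
  fmt_ids <- sprintf("fmt_%03d", seq_len(n_fmts))
  geo <- rep(sprintf("geo_%d", seq_len(n_geographies)), length.out = n_fmts)

  covariates <- tibble(
    fmt_id = fmt_ids,
    recipient_richness = rnorm(n_fmts),
    donor_richness = rnorm(n_fmts),
    community_dissimilarity = rnorm(n_fmts),
    butyrogenesis_recipient = rnorm(n_fmts),
    abx_pretreatment = runif(n_fmts) < 0.4,
    bowel_prep = runif(n_fmts) < 0.5,
    route = sample(c("duodenal", "colonic"), n_fmts, replace = TRUE),
    fresh_frozen = sample(c("fresh", "frozen"), n_fmts, replace = TRUE),
    indication = sample(c("rcdi", "uc", "mets"), n_fmts, replace = TRUE),
    bray_curtis_shift = rnorm(n_fmts)
  )
  if (n_extra_covariates > 0) {
    extra <- matrix(rnorm(n_fmts * n_extra_covariates), nrow = n_fmts)
    colnames(extra) <- sprintf("cov_%02d", seq_len(n_extra_covariates))
    covariates <- bind_cols(covariates, as_tibble(extra))
  }
  tags <- bind_rows(
    tibble(column = c("recipient_richness", "donor_richness",
                      "community_dissimilarity"),
           timing = "ex_ante", scope = "community_diversity"),
    tibble(column = "butyrogenesis_recipient", timing = "ex_ante", scope = "metabolic"),
    tibble(column = c("abx_pretreatment", "bowel_prep", "route",
                      "fresh_frozen", "indication"),
           timing = "ex_ante", scope = "procedural"),
    tibble(column = "bray_curtis_shift", timing = "post_hoc", scope = "community_diversity"),
    if (n_extra_covariates > 0) {
      tibble(column = sprintf("cov_%02d", seq_len(n_extra_covariates)),
             timing = "ex_ante", scope = "species_abundance")
    }
  )

  lin_pred <- function(resp) {
    eff <- effects |> filter(.data$response == resp)
    v <- numeric(n_fmts)
    for (i in seq_len(nrow(eff))) {
      col <- covariates[[eff$covariate[i]]]
      if (!is.numeric(col) && !is.logical(col)) {
        abort("planted effects only supported for numeric/logical covariates")
      }
      v <- v + eff$beta[i] * as.numeric(col)
    }
    v
  }
  mu <- .clamp01(0.5 + lin_pred("colonization_index") + rnorm(n_fmts, sd = 0.05))
  p_take <- plogis(stats::qlogis(0.2) + lin_pred("takeover"))

  metadata <- purrr::map_dfr(seq_len(n_fmts), function(i) {
    tibble(
      sample_id = paste0(fmt_ids[i], c("_D", "_R", "_P1")),
      fmt_id = fmt_ids[i],
      role = c("donor", "recipient_pre", "post"),
      day = c(NA, NA, 30),
      subject_id = c(paste0("donor_", i), paste0("recipient_", i),
                     paste0("recipient_", i)),
      geography = geo[i]
    )
  })
  triads <- build_triads(metadata)

  species_ids <- sprintf("species_%02d", seq_len(n_species))
  cfg <- scoring_config()
  per_fmt <- vector("list", n_fmts)
  for (i in seq_len(n_fmts)) {
    pat <- sample(c("conspecific", "donor_only", "recipient_only", "neither"),
                  n_species, replace = TRUE,
                  prob = c(p_conspecific, rep((1 - p_conspecific) / 3, 3)))
    fd <- fr <- fn <- rep(NA_real_, n_species)
    in_d <- pat %in% c("conspecific", "donor_only")
    in_r <- pat %in% c("conspecific", "recipient_only")
    in_p <- rep(FALSE, n_species)
    take <- rep(FALSE, n_species)
    keep <- rep(TRUE, n_species)

    cs <- pat == "conspecific"
    in_p[cs] <- TRUE
    take[cs] <- runif(sum(cs)) < p_take[i]
    tk <- cs & take
    fd[tk] <- runif(sum(tk), 0.85, 1)
    fr[tk] <- runif(sum(tk), 0, 0.1)
    nt <- cs & !take
    fd[nt] <- .clamp01(mu[i] + rnorm(sum(nt), sd = 0.15))
    fr[nt] <- .clamp01(1 - fd[nt] + rnorm(sum(nt), sd = 0.1))
    fn[cs] <- runif(sum(cs), 0, 0.1)

    dn <- pat == "donor_only"
    in_p[dn] <- runif(sum(dn)) < 0.7
    rc <- pat == "recipient_only"
    in_p[rc] <- runif(sum(rc)) < 0.8
    pres <- (dn | rc) & in_p
    fd[pres] <- as.numeric(dn[pres]); fr[pres] <- as.numeric(rc[pres]); fn[pres] <- 0

    ne <- pat == "neither"
    keep[ne] <- runif(sum(ne)) < 0.3  # species absent from the whole triad
    in_p[ne] <- keep[ne]
    fd[ne & keep] <- 0; fr[ne & keep] <- 0; fn[ne & keep] <- 1

    cat_ <- vapply(which(keep), function(s) {
      classify_outcome(fd[s], fr[s], fn[s], in_d[s], in_r[s], in_p[s], TRUE, cfg)
    }, character(1))
    per_fmt[[i]] <- list(
      records = tibble(
        fmt_id = fmt_ids[i], species_id = species_ids[keep],
        post_sample = paste0(fmt_ids[i], "_P1"), day = 30,
        in_donor = in_d[keep], in_recipient = in_r[keep], in_post = in_p[keep],
        f_donor = fd[keep], f_recipient = fr[keep], f_novel = fn[keep],
        n_informative = ifelse(pat[keep] == "conspecific", n_positions, NA_integer_),
        category = cat_
      ),
      truth = tibble(fmt_id = fmt_ids[i], species_id = species_ids[keep],
                     takeover = take[keep], pattern = pat[keep])
    )
  }
  records <- bind_rows(lapply(per_fmt, `[[`, "records"))
  truth_take <- lapply(per_fmt, `[[`, "truth")

  profiles <- NULL
  if (emit_profiles) {
    scaffolds <- lapply(species_ids, function(sp) {
      simulate_species(n_strains = 5L, n_positions = n_positions,
                       species_id = sp, seed = .derive_seed(seed, sp))
    })
    names(scaffolds) <- species_ids
    parts <- list()
    for (i in seq_len(n_fmts)) {
      for (sp in species_ids) {
        rec <- records |> filter(.data$fmt_id == fmt_ids[i], .data$species_id == sp)
        if (nrow(rec) == 0) next
        cat_i <- rec$category[1]
        if (cat_i == "not_scorable") next
        panel <- respawn_haplotypes(scaffolds[[sp]],
                                    .derive_seed(seed, paste0(fmt_ids[i], sp)))
        target <- if (cat_i %in% c("donor_colonization", "recipient_persistence",
                                   "coexistence", "novel_influx")) {
          if (rec$in_donor[1] && rec$in_recipient[1]) cat_i
          else if (cat_i == "donor_colonization") "donor_colonization"
          else cat_i
        } else cat_i
        sc <- mixture_scenario(target, panel, depth = depth,
                               fmt_id = fmt_ids[i],
                               seed = .derive_seed(seed, paste0("tri", fmt_ids[i], sp)))
        # align presence pattern for baseline-absent cases
        if (!rec$in_donor[1]) sc$donor_weights <- numeric(5)
        if (!rec$in_recipient[1]) sc$recipient_weights <- numeric(5)
        tri <- simulate_triad(sc, panel)
        parts[[length(parts) + 1]] <- tri[c("variants", "coverage", "markers")]
      }
    }
    profiles <- list(
      variants = validate_variant_table(bind_rows(lapply(parts, `[[`, "variants"))),
      coverage = bind_rows(lapply(parts, `[[`, "coverage")),
      markers = bind_rows(lapply(parts, `[[`, "markers")) |>
        distinct(.data$species_id, .data$sample_id, .keep_all = TRUE)
    )
  }

  list(
    metadata = metadata, triads = triads, covariates = covariates,
    tags = tags, effects = effects, records = records,
    truth = list(colonization_propensity = tibble(fmt_id = fmt_ids, mu = mu),
                 takeover = bind_rows(truth_take)),
    profiles = profiles
  )
}
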