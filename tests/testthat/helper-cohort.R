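# Helpers for scoring whole synthetic cohorts (observed, shuffled-null and
# fresh-unrelated background triads) through the full pipeline.

cohort_gene_profiles <- function(coverage, markers, n_core = 28) {
  det <- detect_species(markers)
  species <- unique(markers$species_id)
  dplyr::bind_rows(lapply(species, function(sp) {
    call_gene_presence(
      dplyr::filter(coverage, species_id == sp),
      dplyr::filter(det, species_id == sp),
      list(core_gene_ids = sprintf("%s_g%03d", sp, seq_len(n_core)))
    )
  }))
}

# Score every triad row (observed or shuffled) of a profile-emitting cohort.
score_cohort <- function(triads_tbl, variants, gene_profile, detection) {
  dplyr::bind_rows(lapply(seq_len(nrow(triads_tbl)), function(i) {
    r <- score_timeseries(triads_tbl[i, ], variants, gene_profile, detection)
    if ("replicate" %in% names(triads_tbl)) r$replicate <- triads_tbl$replicate[i]
    r
  }))
}

per_fmt_colonization <- function(records) {
  grp <- if ("replicate" %in% names(records)) c("replicate", "fmt_id") else "fmt_id"
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(ci = colonization_index(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
}

# Colonization index measured against freshly simulated, fully unrelated
# donor and recipient samples: the chance-level attribution background.
fresh_background_index <- function(co, cohort_seed, bg_seed, depth = 30,
                                   n_positions = 300, n_core = 28) {
  species <- unique(co$profiles$markers$species_id)
  base_vt <- dplyr::select(co$profiles$variants, -depth)
  sapply(seq_len(nrow(co$triads)), function(i) {
    tr <- co$triads[i, ]
    fv <- list(); fc <- list(); fm <- list()
    for (sp in species) {
      scaffold <- simulate_species(n_strains = 5, n_positions = n_positions,
                                   species_id = sp,
                                   seed = strainflow:::.derive_seed(cohort_seed, sp))
      for (role in c("D", "R")) {
        pan <- respawn_haplotypes(
          scaffold, strainflow:::.derive_seed(bg_seed + i, paste0(sp, role)))
        w <- if (role == "D") c(0.6, 0.4, 0, 0, 0) else c(0, 0, 0.6, 0.4, 0)
        s <- simulate_sample(pan, w, depth = depth,
                             paste0("bg_", role, "_", i),
                             seed = strainflow:::.derive_seed(bg_seed + 31 * i,
                                                             paste0(sp, role)))
        key <- paste0(sp, role)
        fv[[key]] <- s$variants; fc[[key]] <- s$coverage; fm[[key]] <- s$markers
      }
    }
    vt2 <- validate_variant_table(dplyr::bind_rows(base_vt, dplyr::bind_rows(fv)))
    mk2 <- dplyr::bind_rows(co$profiles$markers, dplyr::bind_rows(fm))
    cov2 <- dplyr::bind_rows(co$profiles$coverage, dplyr::bind_rows(fc))
    gp2 <- cohort_gene_profiles(cov2, mk2, n_core)
    det2 <- detect_species(mk2)
    tr$donor_sample <- paste0("bg_D_", i); tr$donor_subject <- "bg_donor"
    tr$recipient_sample <- paste0("bg_R_", i); tr$recipient_subject <- "bg_recipient"
    colonization_index(score_timeseries(tr, vt2, gp2, det2))
  })
}
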