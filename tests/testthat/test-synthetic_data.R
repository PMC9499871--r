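test_that("haplotype panels are seeded, reproducible and pairwise distinct", {
  p1 <- simulate_species(n_strains = 4, n_positions = 100, seed = 5)
  p2 <- simulate_species(n_strains = 4, n_positions = 100, seed = 5)
  expect_identical(p1, p2)
  p3 <- simulate_species(n_strains = 4, n_positions = 100, seed = 6)
  expect_false(identical(p1$haplotypes, p3$haplotypes))
  # all pairwise haplotype distances >= 1
  for (a in 1:3) for (b in (a + 1):4) {
    expect_gte(sum(p1$haplotypes[a, ] != p1$haplotypes[b, ]), 1)
  }
  # extended core genes carried by every haplotype; accessory content varies
  expect_true(all(p1$gene_content[, p1$core_gene_ids]))
  acc <- setdiff(p1$genes, p1$core_gene_ids)
  expect_true(all(apply(p1$gene_content[, acc, drop = FALSE], 2,
                        function(v) any(v) && !all(v))))
})

test_that("sampled allele frequencies concentrate at the mixture weights", {
  pan <- simulate_species(n_strains = 2, n_positions = 150, core_fraction = 1,
                          seed = 3)
  # single strain at very high depth: major allele frequency within 0.02 of 1
  s <- simulate_sample(pan, c(1, 0), depth = 1e4, "hi", seed = 1)
  f <- allele_frequencies(s$variants)
  major <- apply(as.matrix(f[paste0("freq_", c("A", "C", "G", "T"))]), 1, max)
  expect_true(all(major > 0.98))
  # 50/50 mixture: frequency near 0.5 at sites where the strains differ
  s2 <- simulate_sample(pan, c(0.5, 0.5), depth = 1e4, "mix", seed = 2)
  diff_pos <- pan$positions$position_id[pan$haplotypes[1, ] != pan$haplotypes[2, ]]
  f2 <- allele_frequencies(s2$variants)
  f2d <- f2[f2$position_id %in% diff_pos, ]
  major2 <- apply(as.matrix(f2d[paste0("freq_", c("A", "C", "G", "T"))]), 1, max)
  expect_lt(mean(abs(major2 - 0.5)), 0.02)
  expect_error(simulate_sample(pan, c(1, 0), depth = 0), "positive")
  expect_error(simulate_sample(pan, c(0.5, 0.2), depth = 10), "sum to 1")
})

test_that("genes private to unweighted strains attract no coverage", {
  pan <- simulate_species(n_strains = 3, n_positions = 60, n_genes = 30,
                          core_fraction = 0.5, seed = 8)
  acc <- setdiff(pan$genes, pan$core_gene_ids)
  only3 <- acc[pan$gene_content[3, acc] &
                 !pan$gene_content[1, acc] & !pan$gene_content[2, acc]]
  s <- simulate_sample(pan, c(0.6, 0.4, 0), depth = 50, "x", seed = 2)
  cov3 <- s$coverage[s$coverage$gene_cluster_id %in% only3, ]
  expect_true(all(cov3$horiz_bp == 0))
  expect_true(all(cov3$mean_depth == 0))
  pos3 <- pan$positions$position_id[pan$positions$gene_cluster_id %in% only3]
  expect_false(any(s$variants$position_id %in% pos3))
  # absent species emits no reads and no markers
  s0 <- simulate_sample(pan, c(0, 0, 0), depth = 50, "none", seed = 3)
  expect_equal(nrow(s0$variants), 0)
  expect_equal(s0$markers$n_marker_genes, 0L)
})

test_that("SPD sits at the noise floor for one strain and grows with strain count", {
  spd_of <- function(n_strains, seed) {
    pan <- simulate_species(n_strains = n_strains, n_positions = 300, seed = seed)
    w <- rep(1 / n_strains, n_strains)
    s1 <- simulate_sample(pan, w, depth = 50, "a", seed = seed + 1)
    s2 <- simulate_sample(pan, w, depth = 50, "b", seed = seed + 2)
    vt <- validate_variant_table(rbind(s1$variants, s2$variants))
    filt <- filter_raw_snvs(vt)
    if (nrow(filt) == 0) return(0)
    sd_ <- strain_diversity(filt, cov_hor = tibble::tibble(
      species_id = "species_1", sample_id = c("a", "b"), cov_hor = 300
    ))
    sd_$spd[sd_$sample_id == "a"]
  }
  vals <- sapply(1:10, function(s) {
    c(spd_of(1, s * 17), spd_of(2, s * 17 + 500), spd_of(4, s * 17 + 900))
  })
  expect_true(all(vals[1, ] <= 0.02))              # single-strain noise floor
  expect_lt(mean(vals[1, ]), mean(vals[2, ]))      # diversity grows with strains
  expect_lt(mean(vals[2, ]), mean(vals[3, ]))
})

test_that("AD separates identical mixtures from disjoint populations", {
  pan <- simulate_species(n_strains = 4, n_positions = 200, seed = 21)
  sa <- simulate_sample(pan, c(0.5, 0.5, 0, 0), depth = 100, "a", seed = 1)
  sb <- simulate_sample(pan, c(0.5, 0.5, 0, 0), depth = 100, "b", seed = 2)
  vt <- validate_variant_table(rbind(sa$variants, sb$variants))
  expect_lt(allele_distance(vt, "a", "b")$ad, 0.05)

  pd <- simulate_species(n_strains = 2, n_positions = 200, mode = "disjoint",
                         seed = 22)
  da <- simulate_sample(pd, c(1, 0), depth = 100, "a", seed = 3)
  db <- simulate_sample(pd, c(0, 1), depth = 100, "b", seed = 4)
  vtd <- validate_variant_table(rbind(da$variants, db$variants))
  expect_gt(allele_distance(vtd, "a", "b")$ad, 0.9)
})

test_that("triads plant their categories and cohorts have the right shape", {
  r <- score_scenario("donor_colonization", seed = 1, depth = 50)
  expect_equal(r$category, "donor_colonization")
  r2 <- score_scenario("novel_influx", seed = 2, depth = 50)
  expect_equal(r2$category, "novel_influx")

  co <- simulate_cohort(n_fmts = 25, n_species = 10, seed = 4)
  expect_equal(nrow(co$triads), 25)
  expect_lte(nrow(co$records), 25 * 10)
  expect_true(all(co$records$category != "not_scorable"))
  # identical seeds reproduce the cohort
  co2 <- simulate_cohort(n_fmts = 25, n_species = 10, seed = 4)
  expect_identical(co$records, co2$records)
  expect_identical(co$covariates, co2$covariates)
  # zero planted effects leave downstream models at chance
  summ <- summarize_cohort(co$records)
  dat <- dplyr::left_join(co$covariates, summ, by = "fmt_id")
  d <- build_design(dat, co$tags, "colonization_index", timing = "ex_ante")
  m <- fit_lasso_cv(d$x, d$y, "linear", repeats = 3, seed = 1)
  expect_lt(m$performance, 0.1)
})

test_that("profile-emitting cohorts are scorable end to end", {
  co <- simulate_cohort(n_fmts = 3, n_species = 2, seed = 9,
                        emit_profiles = TRUE, depth = 30, n_positions = 300)
  det <- detect_species(co$profiles$markers)
  expect_gt(nrow(co$profiles$variants), 0)
  # score one triad and compare with the planted categories
  tri <- co$triads[1, ]
  sp <- unique(co$profiles$variants$species_id)[1]
  gp <- call_gene_presence(
    co$profiles$coverage |> dplyr::filter(species_id == sp),
    det |> dplyr::filter(species_id == sp),
    list(core_gene_ids = paste0(sp, "_g", sprintf("%03d", 1:28)))
  )
  recs <- score_timeseries(tri, co$profiles$variants, gp,
                           det |> dplyr::filter(species_id == sp))
  planted <- co$records |>
    dplyr::filter(fmt_id == tri$fmt_id, species_id == sp)
  if (nrow(planted) == 1 && nrow(recs) == 1) {
    expect_equal(recs$category, planted$category)
  }
})
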