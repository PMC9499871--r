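cfg <- scoring_config()

test_that("determinant sets are the donor/recipient set differences", {
  # pos1 D={A}, R={G}; pos2 D={A,C}, R={A}
  lay <- toy_species_tables(list(
    D = list(p1 = "A", p2 = c("A", "C")),
    R = list(p1 = "G", p2 = "A")
  ))
  ds <- determinant_alleles(lay$variants, lay$gene_profile, "D", "R", "sp1")
  expect_equal(ds$donor, tibble::tibble(position_id = c("p1", "p2"),
                                        allele = c("A", "C")))
  expect_equal(ds$recipient, tibble::tibble(position_id = "p1", allele = "G"))
  expect_equal(ds$n_informative, 2)
  # identical allele layouts give empty sets
  lay2 <- toy_species_tables(list(D = list(p1 = "A"), R = list(p1 = "A")))
  ds2 <- determinant_alleles(lay2$variants, lay2$gene_profile, "D", "R", "sp1")
  expect_equal(nrow(ds2$donor), 0)
  expect_equal(nrow(ds2$recipient), 0)
})

test_that("confidently absent genes make their positions determinant", {
  # 30 positions with donor alleles in a gene confidently absent from R
  pos <- sprintf("p%02d", 1:30)
  lay <- toy_species_tables(list(D = setNames(as.list(rep("A", 30)), pos)))
  vt <- lay$variants
  gp <- tibble::tibble(
    species_id = "sp1", gene_cluster_id = "g1",
    sample_id = c("D", "R"), state = c("present", "confidently_absent")
  )
  ds <- determinant_alleles(vt, gp, "D", "R", "sp1")
  expect_equal(nrow(ds$donor), 30)          # all 30 D alleles determinant
  expect_equal(ds$n_informative, 30)        # and informative
  expect_equal(nrow(ds$recipient), 0)
  # with unknown state in R instead, nothing is informative
  gp$state[2] <- "unknown"
  ds2 <- determinant_alleles(vt, gp, "D", "R", "sp1")
  expect_equal(ds2$n_informative, 0)
})

test_that("post-FMT determinants need two reads and absence from both baselines", {
  lay <- toy_species_tables(list(
    D = list(p1 = "A", p2 = "A"),
    R = list(p1 = "A", p2 = "A"),
    P = list(p1 = c("A", "T"), p2 = "A")
  ))
  vt <- lay$variants
  pd <- post_determinant_alleles(vt, lay$gene_profile, "P", "D", "R", "sp1")
  expect_equal(pd, tibble::tibble(position_id = "p1", allele = "T"))
  # a single supporting read is not "observed"
  vt$count_T[vt$sample_id == "P" & vt$position_id == "p1"] <- 1
  vt$depth <- NULL
  vt <- validate_variant_table(vt)
  pd2 <- post_determinant_alleles(vt, lay$gene_profile, "P", "D", "R", "sp1")
  expect_equal(nrow(pd2), 0)
  # P identical to D union R allele-wise -> empty
  lay3 <- toy_species_tables(list(
    D = list(p1 = "A"), R = list(p1 = "G"), P = list(p1 = c("A", "G"))
  ))
  expect_equal(nrow(post_determinant_alleles(lay3$variants, lay3$gene_profile,
                                             "P", "D", "R", "sp1")), 0)
})

test_that("determinant sets match the brute-force oracle on random tables", {
  for (seed in 1:15) {
    vt <- random_variant_table(25, 2, seed = seed, max_count = 5)
    vt$sample_id <- ifelse(vt$sample_id == "s1", "D", "R")
    gp <- random_gene_profile(vt, seed + 7)
    got <- determinant_alleles(vt, gp, "D", "R", "sp1")
    want <- oracle_determinants(vt, gp, "D", "R")
    expect_setequal(paste(got$donor$position_id, got$donor$allele),
                    paste(want$donor$position_id, want$donor$allele))
    expect_setequal(paste(got$recipient$position_id, got$recipient$allele),
                    paste(want$recipient$position_id, want$recipient$allele))
    expect_setequal(got$informative_positions, want$informative)
  }
})

test_that("strain fractions count determinant detections over informative positions", {
  # 120 informative positions: D private allele everywhere, R private allele
  # everywhere; P carries D's allele at 60 positions and R's at the rest
  pos <- sprintf("p%03d", 1:120)
  layD <- setNames(as.list(rep("A", 120)), pos)
  layR <- setNames(as.list(rep("G", 120)), pos)
  layP <- c(setNames(as.list(rep("A", 60)), pos[1:60]),
            setNames(as.list(rep("G", 60)), pos[61:120]))
  lay <- toy_species_tables(list(D = layD, R = layR, P = layP))
  fr <- strain_fractions(lay$variants, lay$gene_profile, "P", "D", "R", "sp1")
  expect_true(fr$scorable)
  expect_equal(fr$n_informative, 120)
  expect_equal(fr$f_donor, 0.5)
  expect_equal(fr$f_recipient, 0.5)
  expect_equal(fr$f_novel, 0)
  # P identical to R: pure persistence
  lay2 <- toy_species_tables(list(D = layD, R = layR, P = layR))
  fr2 <- strain_fractions(lay2$variants, lay2$gene_profile, "P", "D", "R", "sp1")
  expect_equal(fr2$f_recipient, 1)
  expect_equal(fr2$f_donor, 0)
  expect_equal(fr2$f_novel, 0)
})

test_that("fewer than 100 informative positions is not scorable", {
  pos <- sprintf("p%03d", 1:99)
  lay <- toy_species_tables(list(
    D = setNames(as.list(rep("A", 99)), pos),
    R = setNames(as.list(rep("G", 99)), pos),
    P = setNames(as.list(rep("A", 99)), pos)
  ))
  fr <- strain_fractions(lay$variants, lay$gene_profile, "P", "D", "R", "sp1")
  expect_false(fr$scorable)
  expect_equal(fr$n_informative, 99)
  expect_true(is.na(fr$f_donor))
})

test_that("outcome classification follows presence patterns then thresholds", {
  cls <- function(...) classify_outcome(..., config = cfg)
  expect_equal(cls(NA, NA, NA, TRUE, FALSE, TRUE), "donor_colonization")
  expect_equal(cls(NA, NA, NA, FALSE, TRUE, TRUE), "recipient_persistence")
  expect_equal(cls(NA, NA, NA, FALSE, FALSE, TRUE), "novel_influx")
  expect_equal(cls(NA, NA, NA, TRUE, TRUE, FALSE), "species_loss")
  expect_equal(cls(NA, NA, NA, FALSE, TRUE, FALSE), "species_loss")
  expect_equal(cls(NA, NA, NA, TRUE, FALSE, FALSE), "donor_rejection")
  # conspecific thresholds
  expect_equal(cls(0.5, 0.5, 0, TRUE, TRUE, TRUE), "coexistence")
  expect_equal(cls(0.9, 0.1, 0, TRUE, TRUE, TRUE), "donor_colonization")
  expect_equal(cls(0.1, 0.9, 0, TRUE, TRUE, TRUE), "recipient_persistence")
  expect_equal(cls(0.1, 0.15, 0.85, TRUE, TRUE, TRUE), "novel_influx")
  # largest-fraction fallback with donor-first tie-break
  expect_equal(cls(0.4, 0.1, 0.3, TRUE, TRUE, TRUE), "donor_colonization")
  expect_equal(cls(0.1, 0.1, 0.15, TRUE, TRUE, TRUE), "novel_influx")
  expect_equal(cls(0.15, 0.15, 0.1, TRUE, TRUE, TRUE), "donor_colonization")
  # undefined attribution (no determinants at all)
  expect_equal(cls(NA, NA, 0.05, TRUE, TRUE, TRUE), "not_scorable")
  expect_equal(cls(NA, NA, 0.9, TRUE, TRUE, TRUE), "novel_influx")
  expect_error(cls(0.5, 0.5, 0, TRUE, TRUE, FALSE), "not observed post")
})

test_that("swapping donor and recipient labels swaps the fractions exactly", {
  pan <- simulate_species(n_strains = 5, seed = 71)
  sc <- mixture_scenario("coexistence", pan, depth = 30, seed = 4)
  tri <- simulate_triad(sc, pan)
  det <- detect_species(tri$markers)
  gp <- call_gene_presence(tri$coverage, det,
                           list(core_gene_ids = pan$core_gene_ids))
  fr <- strain_fractions(tri$variants, gp, "fmt_1_P1", "fmt_1_D", "fmt_1_R", "species_1")
  fr_sw <- strain_fractions(tri$variants, gp, "fmt_1_P1", "fmt_1_R", "fmt_1_D", "species_1")
  expect_identical(fr$f_donor, fr_sw$f_recipient)
  expect_identical(fr$f_recipient, fr_sw$f_donor)
  expect_identical(fr$f_novel, fr_sw$f_novel)
  expect_identical(fr$n_informative, fr_sw$n_informative)
  # and maps the dominance categories onto each other
  c1 <- classify_outcome(0.9, 0.05, 0, TRUE, TRUE, TRUE, config = cfg)
  c2 <- classify_outcome(0.05, 0.9, 0, TRUE, TRUE, TRUE, config = cfg)
  expect_equal(c(c1, c2), c("donor_colonization", "recipient_persistence"))
})

test_that("time-series scoring emits one record per species and post sample", {
  pan <- simulate_species(n_strains = 5, seed = 13)
  sc <- mixture_scenario("coexistence", pan, depth = 30, seed = 8)
  sc$post_weights <- list(sc$post_weights[[1]], sc$post_weights[[1]])
  tri <- simulate_triad(sc, pan)
  det <- detect_species(tri$markers)
  gp <- call_gene_presence(tri$coverage, det,
                           list(core_gene_ids = pan$core_gene_ids))
  recs <- score_timeseries(tri$triad, tri$variants, gp, det)
  expect_equal(nrow(recs), 2)  # one species, two post samples
  expect_equal(unique(recs$category), "coexistence")
})

test_that("autologous triads have undefined donor attribution", {
  pan <- simulate_species(n_strains = 5, seed = 23)
  sc <- mixture_scenario("autologous", pan, depth = 30, seed = 3)
  tri <- simulate_triad(sc, pan)
  det <- detect_species(tri$markers)
  gp <- call_gene_presence(tri$coverage, det,
                           list(core_gene_ids = pan$core_gene_ids))
  recs <- score_timeseries(tri$triad, tri$variants, gp, det)
  expect_true(is.na(recs$f_donor))
  expect_true(is.na(recs$f_recipient))
  expect_false(is.na(recs$f_novel))   # novel fraction still computable
  expect_lt(recs$f_novel, 0.05)
})
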