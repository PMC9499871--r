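test_that("species detection follows the three-marker-gene rule", {
  hits <- tibble::tibble(species_id = "sp1", sample_id = paste0("s", 1:4),
                         n_marker_genes = c(0L, 2L, 3L, 10L))
  det <- detect_species(hits)
  expect_equal(det$detected, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(detect_species(dplyr::mutate(hits, n_marker_genes = 11L)), "0..10")
  # threshold is configurable
  det5 <- detect_species(hits, scoring_config(min_marker_genes = 5))
  expect_equal(det5$detected, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("extended core uses strict >80% prevalence with top-50 fallback", {
  # 10 genomes; gene at 90% in, gene at exactly 80% out
  mem <- dplyr::bind_rows(
    tidyr::expand_grid(gene_cluster_id = "g_ninety", genome_id = paste0("m", 1:9)),
    tidyr::expand_grid(gene_cluster_id = "g_eighty", genome_id = paste0("m", 1:8)),
    tidyr::expand_grid(gene_cluster_id = paste0("g_common", 1:60),
                       genome_id = paste0("m", 1:10))
  )
  core <- define_extended_core(mem)
  expect_equal(core$rule_used, "prevalence_80")
  expect_true("g_ninety" %in% core$core_gene_ids)
  expect_false("g_eighty" %in% core$core_gene_ids)

  # all genes at <= 80% -> top-50 fallback, deterministic lexicographic ties
  # 5 genomes; every gene in 4 of them (exactly 80%), except g001 also in m5
  mem2 <- dplyr::bind_rows(
    tidyr::expand_grid(gene_cluster_id = sprintf("g%03d", 1:70),
                       genome_id = paste0("m", 1:4)),
    tibble::tibble(gene_cluster_id = "g001", genome_id = "m5")
  )
  core2 <- define_extended_core(mem2)
  expect_equal(core2$rule_used, "top_50")
  expect_equal(length(core2$core_gene_ids), 50)
  expect_equal(core2$core_gene_ids, sort(sprintf("g%03d", 1:50)))

  # fewer genes than the fallback size: the fallback is the floor, so the
  # whole (tiny) pangenome becomes the core
  mem3 <- tibble::tibble(gene_cluster_id = c("gA", "gB"), genome_id = "m1")
  core3 <- define_extended_core(mem3)
  expect_equal(core3$rule_used, "top_50")
  expect_equal(sort(core3$core_gene_ids), c("gA", "gB"))
})

test_that("gene presence thresholds are strict and states partition", {
  det <- tibble::tibble(species_id = "sp1", sample_id = paste0("s", 1:2),
                        n_marker_genes = c(10L, 10L)) |> detect_species()
  core <- list(core_gene_ids = "gcore")
  cov <- tibble::tibble(
    species_id = "sp1",
    gene_cluster_id = c("gcore", "g_ok", "g_short", "g_zero",
                        "gcore", "g_zero2"),
    sample_id = c("s1", "s1", "s1", "s1", "s2", "s2"),
    horiz_bp = c(1400, 150, 150, 0, 900, 0),
    frac_len = c(0.95, 0.25, 0.15, 0, 0.6, 0),
    mean_depth = c(1.5, 0.8, 0.8, 0, 0.9, 0)
  )
  gp <- call_gene_presence(cov, det, core)
  state_of <- function(g, s) gp$state[gp$gene_cluster_id == g & gp$sample_id == s]
  expect_equal(state_of("g_ok", "s1"), "present")       # 150 bp, 25%, 0.8x
  expect_equal(state_of("g_short", "s1"), "unknown")    # fails 20%-length clause
  expect_equal(state_of("g_zero", "s1"), "confidently_absent")  # core median 1.5 > 1
  expect_equal(state_of("g_zero2", "s2"), "unknown")    # core median 0.9 <= 1
  # exactly one state everywhere
  expect_true(all(gp$state %in% c("present", "confidently_absent", "unknown")))
  expect_equal(nrow(gp), nrow(dplyr::distinct(gp, gene_cluster_id, sample_id)))

  # boundary: exactly 100 bp / exactly 0.2 / exactly 0.5 are NOT present
  cov_b <- tibble::tibble(species_id = "sp1", gene_cluster_id = "gb",
                          sample_id = "s1", horiz_bp = 100, frac_len = 0.2,
                          mean_depth = 0.5)
  gpb <- call_gene_presence(dplyr::bind_rows(cov[1, ], cov_b), det, core)
  expect_equal(gpb$state[gpb$gene_cluster_id == "gb" & gpb$sample_id == "s1"],
               "unknown")

  # species not detected blocks presence
  det0 <- detect_species(tibble::tibble(species_id = "sp1", sample_id = "s1",
                                        n_marker_genes = 2L))
  gp0 <- call_gene_presence(cov[cov$sample_id == "s1", ], det0, core)
  expect_false(any(gp0$state == "present"))

  expect_error(
    call_gene_presence(cov, det, core, pangenome_genes = c("gcore", "g_ok")),
    "not in pangenome"
  )
})

test_that("SNV retention implements two-reads-in-two-samples and is idempotent", {
  # allele supported by 2 reads in 2 samples stays; 5 reads in 1 sample goes
  lay <- toy_species_tables(list(
    s1 = list(p1 = c("A", "C"), p2 = "A"),
    s2 = list(p1 = c("A", "C"), p2 = "A"),
    s3 = list(p1 = "A", p2 = c("A", "G"))
  ), depth_per_allele = 2)
  vt <- lay$variants
  # give p2's G five reads but only in s3
  vt$count_G[vt$position_id == "p2" & vt$sample_id == "s3"] <- 5
  vt$depth <- NULL
  out <- filter_raw_snvs(vt)
  expect_true("p1" %in% out$position_id)             # A and C both supported twice
  expect_false("p2" %in% out$position_id)            # G supported in one sample only
  expect_equal(filter_raw_snvs(out), out)            # idempotent

  # empty input -> empty output
  empty <- vt[0, ]
  expect_equal(nrow(filter_raw_snvs(empty)), 0)

  # support only counts in samples where the gene is confidently detected
  gp <- lay$gene_profile
  gp$state[gp$sample_id == "s2"] <- "unknown"
  out2 <- filter_raw_snvs(vt, gene_profile = gp)
  expect_false("p1" %in% out2$position_id)  # C now supported in s1 only
})

test_that("SNV retention matches the brute-force rule on random tables", {
  for (seed in 1:12) {
    vt <- random_variant_table(15, 4, seed = seed, max_count = 4)
    gp <- if (seed %% 2 == 0) random_gene_profile(vt, seed + 100) else NULL
    got <- filter_raw_snvs(vt, gene_profile = gp)
    want <- oracle_filter_snvs(vt, gene_profile = gp)
    # same surviving positions
    expect_equal(sort(unique(got$position_id)), sort(unique(want$position_id)),
                 info = paste("seed", seed))
    # same retained alleles (nonzero counts in output)
    if (nrow(got) > 0) {
      long <- tidyr::pivot_longer(got, dplyr::starts_with("count_"),
                                  names_to = "allele", names_prefix = "count_",
                                  values_to = "count")
      kept <- long |> dplyr::filter(count > 0) |>
        dplyr::distinct(position_id, allele) |> dplyr::arrange(position_id, allele)
      expect_setequal(paste(kept$position_id, kept$allele),
                      paste(want$position_id, want$allele))
    }
  }
})
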