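# Independent brute-force reference implementations used to cross-check the
# package's vectorized code paths, plus small fixture builders. These
# deliberately use plain loops over positions, alleles and samples.

ALLELES4 <- c("A", "C", "G", "T")

# A toy variant table with random counts (zero-inflated), n_samples samples,
# positions spread over a handful of gene clusters.
random_variant_table <- function(n_pos, n_samples, seed, max_count = 12,
                                 species = "sp1", n_genes = 4) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  rows <- expand.grid(
    position_id = sprintf("p%03d", seq_len(n_pos)),
    sample_id = paste0("s", seq_len(n_samples)),
    stringsAsFactors = FALSE
  )
  rows$species_id <- species
  rows$gene_cluster_id <- rep(rep(genes, length.out = n_pos), times = n_samples)
  for (a in ALLELES4) {
    v <- rpois(nrow(rows), 2.5)
    v[runif(nrow(rows)) < 0.45] <- 0
    rows[[paste0("count_", a)]] <- pmin(v, max_count)
  }
  validate_variant_table(rows)
}

# A random gene-state table over the genes/samples of a variant table.
random_gene_profile <- function(vt, seed,
                                states = c("present", "confidently_absent", "unknown"),
                                probs = c(0.7, 0.15, 0.15)) {
  set.seed(seed)
  grid <- expand.grid(
    gene_cluster_id = unique(vt$gene_cluster_id),
    sample_id = unique(vt$sample_id),
    stringsAsFactors = FALSE
  )
  grid$species_id <- vt$species_id[1]
  grid$state <- sample(states, nrow(grid), replace = TRUE, prob = probs)
  tibble::as_tibble(grid)
}

# Brute-force SPD: explicit loop over positions.
oracle_spd <- function(freqs, cov_hor) {
  freqs <- as.matrix(freqs)
  acc <- 0
  for (i in seq_len(nrow(freqs))) {
    p <- freqs[i, ]
    acc <- acc + 1 / (p[1]^2 + p[2]^2 + p[3]^2 + p[4]^2) - 1
  }
  acc / cov_hor
}

# Brute-force allele distance over a variant table for two samples.
oracle_ad <- function(vt, sx, sy, min_shared = 20, shared_depth = 2) {
  f <- allele_frequencies(vt)
  fx <- f[f$sample_id == sx & f$depth >= shared_depth, ]
  fy <- f[f$sample_id == sy & f$depth >= shared_depth, ]
  shared <- intersect(fx$position_id, fy$position_id)
  if (length(shared) < min_shared) return(list(ad = NA_real_, n = length(shared)))
  total <- 0
  for (p in shared) {
    a <- unlist(fx[fx$position_id == p, paste0("freq_", ALLELES4)])
    b <- unlist(fy[fy$position_id == p, paste0("freq_", ALLELES4)])
    total <- total + sqrt(sum((a - b)^2)) / sqrt(2)
  }
  list(ad = total / length(shared), n = length(shared))
}

# Brute-force SNV retention: double loop over alleles x samples.
oracle_filter_snvs <- function(vt, gene_profile = NULL,
                               min_reads = 2, min_samples = 2) {
  samples <- unique(vt$sample_id)
  positions <- unique(vt$position_id)
  eligible <- function(g, s) {
    if (is.null(gene_profile)) return(TRUE)
    st <- gene_profile$state[gene_profile$gene_cluster_id == g &
                               gene_profile$sample_id == s]
    length(st) == 1 && st == "present"
  }
  retained <- list()
  for (p in positions) {
    sub <- vt[vt$position_id == p, ]
    g <- sub$gene_cluster_id[1]
    for (a in ALLELES4) {
      n_sup <- 0
      for (s in samples) {
        cnt <- sub[[paste0("count_", a)]][sub$sample_id == s]
        if (length(cnt) == 1 && cnt >= min_reads && eligible(g, s)) {
          n_sup <- n_sup + 1
        }
      }
      if (n_sup >= min_samples) {
        retained[[length(retained) + 1]] <- data.frame(position_id = p, allele = a)
      }
    }
  }
  ret <- if (length(retained)) do.call(rbind, retained) else
    data.frame(position_id = character(), allele = character())
  keep_pos <- names(which(table(ret$position_id) >= 2))
  ret[ret$position_id %in% keep_pos, , drop = FALSE]
}

# Brute-force determinant-allele sets: loop over positions and alleles with
# explicit evaluability rules.
oracle_determinants <- function(vt, gene_profile, donor, recipient,
                                detect_reads = 2) {
  pos <- unique(vt[, c("position_id", "gene_cluster_id")])
  cnt <- function(p, s, a) {
    v <- vt[[paste0("count_", a)]][vt$position_id == p & vt$sample_id == s]
    if (length(v) == 0) 0 else v
  }
  state <- function(g, s) {
    st <- gene_profile$state[gene_profile$gene_cluster_id == g &
                               gene_profile$sample_id == s]
    if (length(st) == 0) "unknown" else st
  }
  status <- function(p, g, s) {
    depth <- sum(sapply(ALLELES4, function(a) cnt(p, s, a)))
    if (depth >= detect_reads) return("covered")
    if (state(g, s) == "confidently_absent") return("absent")
    "unknown"
  }
  don <- list(); rec <- list(); informative <- character()
  for (i in seq_len(nrow(pos))) {
    p <- pos$position_id[i]; g <- pos$gene_cluster_id[i]
    if (status(p, g, donor) == "unknown" || status(p, g, recipient) == "unknown") next
    informative <- c(informative, p)
    for (a in ALLELES4) {
      in_d <- cnt(p, donor, a) >= detect_reads
      in_r <- cnt(p, recipient, a) >= detect_reads
      if (in_d && !in_r) don[[length(don) + 1]] <- data.frame(position_id = p, allele = a)
      if (in_r && !in_d) rec[[length(rec) + 1]] <- data.frame(position_id = p, allele = a)
    }
  }
  bindit <- function(l) if (length(l)) do.call(rbind, l) else
    data.frame(position_id = character(), allele = character())
  list(donor = bindit(don), recipient = bindit(rec),
       informative = sort(informative))
}

# Build a fully evaluable toy species: one gene, `present` everywhere, with
# explicit per-sample allele layouts given as named lists position -> alleles.
toy_species_tables <- function(layout, depth_per_allele = 10,
                               species = "sp1", gene = "g1") {
  samples <- names(layout)
  all_pos <- sort(unique(unlist(lapply(layout, names))))
  rows <- list()
  for (s in samples) {
    for (p in all_pos) {
      alleles <- layout[[s]][[p]]
      cnts <- setNames(rep(0, 4), ALLELES4)
      if (!is.null(alleles)) cnts[alleles] <- depth_per_allele
      rows[[length(rows) + 1]] <- data.frame(
        species_id = species, position_id = p, gene_cluster_id = gene,
        sample_id = s, count_A = cnts["A"], count_C = cnts["C"],
        count_G = cnts["G"], count_T = cnts["T"]
      )
    }
  }
  vt <- validate_variant_table(do.call(rbind, rows))
  gp <- expand.grid(gene_cluster_id = gene, sample_id = samples,
                    stringsAsFactors = FALSE)
  gp$species_id <- species
  gp$state <- "present"
  list(variants = vt, gene_profile = tibble::as_tibble(gp))
}

# Score one planted scenario end to end; returns the outcome record(s).
score_scenario <- function(category, seed, depth = 20, n_strains = 5,
                           n_positions = 400) {
  pan <- simulate_species(n_strains = n_strains, n_positions = n_positions,
                          seed = seed * 31 + 7)
  sc <- mixture_scenario(category, pan, depth = depth, seed = seed)
  tri <- simulate_triad(sc, pan)
  det <- detect_species(tri$markers)
  gp <- call_gene_presence(tri$coverage, det,
                           list(core_gene_ids = pan$core_gene_ids))
  score_timeseries(tri$triad, tri$variants, gp, det)
}
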