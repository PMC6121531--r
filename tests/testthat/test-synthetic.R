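test_that("generation is byte-identical under a fixed seed", {
  truth <- synthetic_truth(seed = 99L, n_genes = 40L)
  d1 <- simulate_dataset(truth)
  d2 <- simulate_dataset(truth)
  expect_identical(d1$proteins, d2$proteins)
  expect_identical(d1$cds, d2$cds)
  expect_identical(d1$probe_table, d2$probe_table)
  expect_identical(d1$hit_table, d2$hit_table)
  expect_identical(d1$locations, d2$locations)
  expect_identical(d1$genes, d2$genes)
})

test_that("truth validation rejects invalid parameters", {
  expect_error(synthetic_truth(n_genes = 1), "at least 2")
  expect_error(synthetic_truth(noise_sd = -1), "non-negative")
  expect_error(synthetic_truth(frac_flag_fail = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_truth(probes_per_gene_range = c(3, 1)),
               "increasing")
  expect_error(synthetic_truth(
    location_shares = stats::setNames(rep(0.2, 10),
                                      names(default_location_shares()))
  ), "at most 1")
})

test_that("degenerate composition model collapses onto the class means", {
  truth <- synthetic_truth(seed = 3L, n_genes = 30L, composition_sd = 0,
                           usage_conc = Inf, gc_usage_tilt = 0)
  prot <- generate_proteome(truth)
  # class weights are exactly the means; realized fractions differ only by
  # multinomial noise, whose expectation matches
  expect_lt(abs(mean(prot$features$charged_frac) - 0.24), 0.02)
  expect_lt(abs(mean(prot$features$polar_frac) - 0.30), 0.03)
})

test_that("proteome moments match the configured generating distribution", {
  truth <- synthetic_truth(seed = 5L, n_genes = 2000L)
  prot <- generate_proteome(truth)
  f <- prot$features
  # sample mean of the charged fraction within 3 standard errors of the
  # configured mean
  se <- stats::sd(f$charged_frac) / sqrt(nrow(f))
  expect_lt(abs(mean(f$charged_frac) - 0.24), 3 * se)
  # every gene has 1-3 isoforms of distinct lengths
  iso <- dplyr::count(prot$proteins, gene_id)
  expect_true(all(iso$n >= 1 & iso$n <= 3))
  dup <- prot$proteins |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(distinct = dplyr::n_distinct(length) == dplyr::n())
  expect_true(all(dup$distinct))
  # CDS length is 3 * protein length + 3 for the longest isoform
  j <- dplyr::inner_join(prot$cds, f, by = "gene_id")
  expect_equal(nchar(j$sequence), 3 * j$length + 3)
  # recorded GC equals GC recomputed from the written CDS
  expect_equal(f$gc, gc_content(prot$cds$sequence[
    match(f$gene_id, prot$cds$gene_id)
  ]), tolerance = 1e-12)
})

test_that("null expression model gives exactly zero response", {
  truth <- synthetic_truth(
    seed = 8L, n_genes = 50L, beta_charged = 0, beta_polar = 0,
    beta_hydrophobic = 0, beta_disorder = 0, gamma_gc = 0, noise_sd = 0
  )
  ds <- simulate_dataset(truth, compute_disorder = FALSE)
  expect_true(all(ds$genes$true_r == 0))
  expect_true(all(ds$genes$e24_37 == ds$genes$e24_22))
})

test_that("a pure monotone coupling yields perfect rank correlation", {
  truth <- synthetic_truth(
    seed = 9L, n_genes = 200L, beta_charged = 0.5, beta_polar = 0,
    beta_hydrophobic = 0, beta_disorder = 0, gamma_gc = 0, noise_sd = 0
  )
  ds <- simulate_dataset(truth, compute_disorder = FALSE)
  j <- dplyr::inner_join(ds$features, ds$genes, by = "gene_id")
  expect_equal(stats::cor(j$charged_frac, j$true_r, method = "spearman"), 1)
})

test_that("noisy couplings are recovered near the truth-based oracle", {
  truth <- synthetic_truth(
    seed = 10L, n_genes = 2000L, beta_charged = 0.3, beta_polar = 0,
    beta_hydrophobic = 0, beta_disorder = 0, gamma_gc = 0, noise_sd = 1
  )
  ds <- simulate_dataset(truth, compute_disorder = FALSE)
  gr <- gene_responses(ds$probe_table, ds$hit_table)
  j <- dplyr::inner_join(ds$features, gr, by = "gene_id")
  rho_pipeline <- stats::cor(j$charged_frac, j$r, method = "spearman")
  jt <- dplyr::inner_join(ds$features, ds$genes, by = "gene_id")
  rho_oracle <- stats::cor(jt$charged_frac, jt$true_r, method = "spearman")
  expect_gt(rho_pipeline, 0)
  expect_lt(abs(rho_pipeline - rho_oracle), 0.05)
})

test_that("expression generation names genes with missing features", {
  truth <- synthetic_truth(seed = 2L, n_genes = 10L)
  prot <- generate_proteome(truth)
  feats <- prot$features
  feats$disorder_frac <- 10
  feats$gc[3] <- NA
  expect_error(generate_expression(truth, feats), feats$gene_id[3])
})

test_that("probe bookkeeping matches the configured fractions", {
  truth <- synthetic_truth(seed = 12L, n_genes = 400L,
                           beta_disorder = 0,
                           frac_flag_fail = 0.1,
                           frac_multi_gene_probes = 0.05,
                           frac_control_features = 0.08)
  ds <- simulate_dataset(truth, compute_disorder = FALSE)
  pt <- ds$probe_table
  measured <- unique(pt$probe_id[!pt$is_control])
  controls <- unique(pt$probe_id[pt$is_control])
  expect_equal(length(controls), round(0.08 * length(measured)))
  # every measured probe is annotated in the hit table
  expect_true(all(measured %in% ds$hit_table$probe_id))
  # flag-failing probes are dropped by the quality filter
  kept <- filter_probes(pt)
  expect_equal(length(measured) - length(kept),
               round(0.1 * length(measured)))
  # the configured share of probes is annotated to two genes
  hit_n <- ds$hit_table |>
    dplyr::filter(e_value <= 9.9e-6, identity_pct >= 98) |>
    dplyr::distinct(probe_id, gene_id) |>
    dplyr::count(probe_id)
  expect_equal(sum(hit_n$n == 2), round(0.05 * length(measured)))
})

test_that("location generator respects shares, shifts and multi-labelling", {
  # all proteins located, one tenth multi-labelled
  shares <- stats::setNames(rep(0.1, 10), names(default_location_shares()))
  truth <- synthetic_truth(seed = 20L, n_genes = 1000L,
                           location_shares = shares,
                           location_multi_frac = 0.1,
                           location_disorder_shift = c(),
                           location_charged_shift = c())
  ds <- simulate_dataset(truth)
  multi <- ds$locations |>
    dplyr::count(protein_id) |>
    dplyr::filter(n >= 2)
  expect_gt(nrow(multi), 70)
  expect_lt(nrow(multi), 130)

  # a positive nucleus disorder shift raises the nucleus median above the
  # proteome median
  truth2 <- synthetic_truth(seed = 21L, n_genes = 2000L,
                            location_shares = shares,
                            location_disorder_shift = c(nucleus = 1.5))
  ds2 <- simulate_dataset(truth2)
  cons <- consensus_location(ds2$locations)
  j <- dplyr::inner_join(ds2$features, cons, by = "protein_id")
  med_nuc <- stats::median(j$disorder_frac[j$compartment == "nucleus"])
  expect_gt(med_nuc, stats::median(ds2$features$disorder_frac))
})

test_that("fixture writing is deterministic and complete", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_fixture(d1, seed = 31L, scale = "tiny")
  make_fixture(d2, seed = 31L, scale = "tiny")
  files <- c("proteins.fasta", "cds.fasta", "probes.tsv", "hits.tsv",
             "locations.tsv", "truth.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  # truth.json lists every gene present in the proteome FASTA
  truth <- jsonlite::read_json(file.path(d1, "truth.json"),
                               simplifyVector = TRUE)
  prot <- read_proteins_fasta(file.path(d1, "proteins.fasta"))
  expect_setequal(truth$per_gene$gene_id, unique(prot$gene_id))
})
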