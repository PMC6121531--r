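make_probe_rows <- function(probe_id, flags_by_cond,
                            intensity = 100, is_control = FALSE) {
  purrr::imap_dfr(flags_by_cond, function(flags, cond) {
    tibble::tibble(
      probe_id = probe_id, condition = cond,
      replicate = seq_along(flags), intensity = intensity,
      well_above_bg = flags, is_control = is_control
    )
  })
}

all_cond <- function(flags) {
  list(E0_22 = flags, E24_22 = flags, E24_37 = flags)
}

test_that("probe quality filter applies the 3-of-4 rule and drops controls", {
  rows <- dplyr::bind_rows(
    make_probe_rows("p_pass", all_cond(c(TRUE, TRUE, TRUE, FALSE))),
    make_probe_rows("p_fail", all_cond(c(TRUE, TRUE, FALSE, FALSE))),
    make_probe_rows("p_ctrl", all_cond(rep(TRUE, 4)), is_control = TRUE)
  )
  expect_equal(filter_probes(rows), "p_pass")

  # scope: fails the rule only at 37 C
  rows2 <- dplyr::bind_rows(
    make_probe_rows("p_mix", list(E0_22 = rep(TRUE, 4),
                                  E24_22 = rep(TRUE, 4),
                                  E24_37 = c(TRUE, TRUE, FALSE, FALSE)))
  )
  expect_equal(filter_probes(rows2, scope = "all"), character(0))
  expect_equal(filter_probes(rows2, scope = "any"), "p_mix")
})

test_that("probe filter rejects malformed replicate structure", {
  bad <- make_probe_rows("p1", list(E24_22 = rep(TRUE, 5)))
  expect_error(filter_probes(bad), "more than 4 replicates")
  odd <- make_probe_rows("p1", list(weird = rep(TRUE, 4)))
  expect_error(filter_probes(odd), "Unknown condition")
})

test_that("annotation filter is boundary-inclusive and drops multi-gene probes", {
  hits <- tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p3", "p4"),
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    e_value = c(1e-8, 1e-5, 1e-10, 1e-10, 9.9e-6),
    identity_pct = c(98, 99, 100, 100, 98),
    overlap_pct = c(75, 90, 80, 80, 75)
  )
  m <- filter_annotations(hits)
  # p1: exactly at all three boundaries -> retained
  expect_true("p1" %in% m$probe_id)
  # p2: e-value 1e-5 exceeds 9.9e-6 -> dropped
  expect_false("p2" %in% m$probe_id)
  # p3: two surviving hits to distinct genes -> dropped entirely
  expect_false("p3" %in% m$probe_id)
  expect_true("p4" %in% m$probe_id)
  expect_equal(anyDuplicated(m$probe_id), 0L)
})

test_that("duplicate hit rows collapse with a warning", {
  hits <- tibble::tibble(
    probe_id = c("p1", "p1"), gene_id = c("g1", "g1"),
    e_value = 1e-10, identity_pct = 99, overlap_pct = 90
  )
  expect_warning(m <- filter_annotations(hits), "duplicate")
  expect_equal(nrow(m), 1)
})

test_that("aggregation averages replicates then probes", {
  probes <- dplyr::bind_rows(
    tibble::tibble(probe_id = "p1", condition = "E24_22", replicate = 1:4,
                   intensity = c(2, 4, 6, 8),
                   well_above_bg = TRUE, is_control = FALSE),
    tibble::tibble(probe_id = "p2", condition = "E24_22", replicate = 1:4,
                   intensity = c(10, 10, 10, 10),
                   well_above_bg = TRUE, is_control = FALSE),
    tibble::tibble(probe_id = "p3", condition = "E24_22", replicate = 1:4,
                   intensity = c(20, 20, 20, 20),
                   well_above_bg = TRUE, is_control = FALSE)
  )
  pm <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                       gene_id = c("g1", "g2", "g2"))
  agg <- suppressWarnings(aggregate_expression(probes, pm))
  expect_equal(agg$intensity[agg$gene_id == "g1"], 5)   # (2+4+6+8)/4
  expect_equal(agg$intensity[agg$gene_id == "g2"], 15)  # (10+20)/2
  empty <- aggregate_expression(probes, pm[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("aggregation is invariant to row order", {
  ds <- tiny_dataset()
  pm <- filter_annotations(ds$hit_table)
  ret <- filter_probes(ds$probe_table)
  a1 <- aggregate_expression(ds$probe_table, pm, retained = ret)
  shuffled <- ds$probe_table[sample(nrow(ds$probe_table)), ]
  a2 <- aggregate_expression(shuffled, pm, retained = ret)
  expect_equal(a1, a2)
})

test_that("response statistic is the log2 ratio with antisymmetry", {
  expect_equal(compute_response(8, 2), 2)
  expect_equal(compute_response(4, 4), 0)
  expect_equal(compute_response(2, 8), -2)
  set.seed(6)
  a <- rlnorm(50); b <- rlnorm(50)
  expect_equal(compute_response(a, b), -compute_response(b, a))
  expect_error(compute_response(-1, 2, gene_id = "gX"), "gX")
  expect_error(compute_response(1, 0), "Non-positive")
})

test_that("gene categories use overlapping threshold sets", {
  cl <- classify_genes(c(0.5, 2.5, -2.5, 0, 1))
  expect_equal(cl$induced, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(cl$strong_induced, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(cl$strong_induced_2, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(cl$repressed, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(cl$strong_repressed_2, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(cl$zero, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  # counts partition the genes
  r <- rnorm(200)
  cl2 <- classify_genes(r)
  expect_equal(sum(cl2$induced) + sum(cl2$repressed) + sum(cl2$zero), 200)
})

test_that("noise-free synthetic data recovers true R exactly", {
  ds <- noiseless_dataset()
  gr <- gene_responses(ds$probe_table, ds$hit_table)
  j <- dplyr::inner_join(gr, ds$genes, by = "gene_id")
  expect_gt(nrow(j), 40)
  expect_true(all(abs(j$r - j$true_r) < 1e-10))
  # E0 tracks E24,22 exactly when the QC noise is off
  expect_true(all(abs(log2(j$e0_22.x / j$e24_22.x)) < 1e-10))
})

test_that("log2-scale averaging returns the geometric mean", {
  probes <- tibble::tibble(
    probe_id = "p1", condition = "E24_22", replicate = 1:2,
    intensity = c(4, 16), well_above_bg = TRUE, is_control = FALSE
  )
  pm <- tibble::tibble(probe_id = "p1", gene_id = "g1")
  lin <- suppressWarnings(aggregate_expression(probes, pm))
  log2s <- suppressWarnings(aggregate_expression(probes, pm, scale = "log2"))
  expect_equal(lin$intensity, 10)
  expect_equal(log2s$intensity, 8)
})
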