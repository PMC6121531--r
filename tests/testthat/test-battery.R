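# analysis-ready features + responses derived once from the shared dataset
battery_inputs <- function() {
  cached("battery_inputs", {
    ds <- tiny_dataset()
    gr <- gene_responses(ds$probe_table, ds$hit_table)
    cp <- composition_profiles(ds$proteins, cds = ds$cds)
    dis <- disorder_profiles(
      dplyr::inner_join(ds$features[, c("gene_id", "protein_id")],
                        ds$proteins, by = c("gene_id", "protein_id"))
    )
    cp <- dplyr::left_join(
      cp,
      dplyr::select(dis, protein_id, disorder_frac = disordered_fraction),
      by = "protein_id"
    )
    list(features = cp, responses = gr, ds = ds)
  })
}

test_that("association battery has the Table-1 shape", {
  inp <- battery_inputs()
  ab <- association_battery(inp$features, inp$responses)
  # 20 amino acids + 3 class totals + disorder, per regime
  expect_equal(nrow(ab), 24 * 4)
  expect_setequal(unique(ab$control), c("none", "gc", "e24_22", "e24_37"))
  # q only within the 20-amino-acid family
  expect_true(all(is.na(ab$q[ab$type != "amino_acid"])))
  expect_true(all(!is.na(ab$q[ab$type == "amino_acid"])))
  # BH within each regime
  for (ctl in unique(ab$control)) {
    aa <- ab[ab$type == "amino_acid" & ab$control == ctl, ]
    expect_equal(aa$q, bh_adjust(aa$p))
  }
  expect_true(all(abs(ab$rho) <= 1))
})

test_that("association battery recovers an injected charged effect", {
  inp <- battery_inputs()
  ab <- association_battery(inp$features, inp$responses,
                            controls = "none")
  charged <- ab[ab$feature %in% c("R", "D", "E", "K"), ]
  expect_true(all(charged$rho > 0))
  expect_gt(ab$rho[ab$feature == "charged"], 0)
  expect_lt(ab$p[ab$feature == "charged"], 0.05)
  # disorder was also injected
  expect_gt(ab$rho[ab$feature == "disorder"], 0)
})

test_that("association battery validates inputs", {
  inp <- battery_inputs()
  no_gc <- dplyr::select(inp$features, -gc)
  expect_error(association_battery(no_gc, inp$responses, controls = "gc"),
               "control column")
  expect_error(association_battery(inp$features[1:3, ], inp$responses[1:3, ]),
               "At least 4")
})

test_that("group comparison reports medians in percent with BH on amino acids", {
  inp <- battery_inputs()
  gcmp <- group_comparison(inp$features, inp$responses, cutoffs = c(0, 0))
  expect_equal(nrow(gcmp), 24)
  charged <- gcmp[gcmp$feature == "charged", ]
  expect_gt(charged$median_induced, charged$median_repressed)
  expect_lt(charged$p, 0.05)
  expect_true(all(gcmp$median_induced[gcmp$type != "disorder"] <= 100))
  aa <- gcmp[gcmp$type == "amino_acid", ]
  expect_equal(aa$q, bh_adjust(aa$p))
})

test_that("a constant feature gives equal medians and p = 1", {
  feats <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40),
    !!!stats::setNames(
      as.list(rep(0.05, 20)),
      paste0("freq_", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
    ),
    charged_frac = 0.2, polar_frac = 0.4, hydrophobic_frac = 0.4
  )
  resp <- tibble::tibble(gene_id = feats$gene_id,
                         r = rep(c(-1, 1), 20))
  gcmp <- group_comparison(feats, resp)
  expect_true(all(gcmp$median_induced == gcmp$median_repressed))
  expect_true(all(gcmp$p == 1))
})

test_that("strict cutoffs on a weak-response dataset raise an informative error", {
  feats <- battery_inputs()$features
  resp <- tibble::tibble(gene_id = feats$gene_id,
                         r = stats::runif(nrow(feats), -0.5, 0.5))
  expect_error(group_comparison(feats, resp, cutoffs = c(2, -2)),
               "less stringent")
})

test_that("compartment battery counts signs and applies the binomial test", {
  # engineered data: charged-R correlation positive in 9 of 10
  # compartments, negative in 1
  comps <- names(default_location_shares())
  n_per <- 30
  rows <- purrr::imap_dfr(comps, function(cp, i) {
    x <- seq_len(n_per) / n_per
    tibble::tibble(
      gene_id = sprintf("%s_g%02d", cp, seq_len(n_per)),
      protein_id = sprintf("%s_g%02d.1", cp, seq_len(n_per)),
      charged_frac = x,
      polar_frac = (1 - x) / 2,
      hydrophobic_frac = (1 - x) / 2,
      r = if (i == 1) -x else x,
      compartment = cp
    )
  })
  feats <- rows[, c("gene_id", "protein_id", "charged_frac", "polar_frac",
                    "hydrophobic_frac")]
  resp <- rows[, c("gene_id", "r")]
  locs <- rows[, c("protein_id", "compartment")]
  cb <- compartment_battery(feats, resp, locs)
  expect_equal(nrow(cb$by_compartment), 30)  # 10 compartments x 3 classes
  st <- cb$sign_tests
  charged <- st[st$feature == "charged", ]
  expect_equal(charged$n_positive, 9)
  expect_equal(charged$majority_sign, "positive")
  expect_equal(round(charged$binomial_p, 3), 0.011)
  # polar/hydrophobic are perfectly anticorrelated with r in 9 of 10
  polar <- st[st$feature == "polar", ]
  expect_equal(polar$n_negative, 9)
  expect_equal(polar$majority_sign, "negative")
})

test_that("undersized compartments are reported as NA with a warning", {
  feats <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    protein_id = paste0(c("g1", "g2", "g3", "g4", "g5"), ".1"),
    charged_frac = c(0.1, 0.2, 0.3, 0.25, 0.15),
    polar_frac = 0.3, hydrophobic_frac = 0.4
  )
  resp <- tibble::tibble(gene_id = feats$gene_id, r = c(1, 2, 3, -1, 0.5))
  locs <- tibble::tibble(
    protein_id = feats$protein_id,
    compartment = c("nucleus", "nucleus", "nucleus", "nucleus", "cytosol")
  )
  expect_warning(cb <- compartment_battery(feats, resp, locs),
                 "fewer than")
  cyt <- cb$by_compartment[cb$by_compartment$compartment == "cytosol", ]
  expect_true(all(is.na(cyt$rho)))
  # NA rows are excluded from the sign summary
  expect_true(all(cb$sign_tests$n_compartments == 1))
})

test_that("tidy and autoplot methods work on battery results", {
  inp <- battery_inputs()
  ab <- association_battery(inp$features, inp$responses, controls = "none")
  expect_s3_class(autoplot(ab), "ggplot")
  gcmp <- group_comparison(inp$features, inp$responses)
  expect_s3_class(autoplot(gcmp), "ggplot")
})
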