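test_that("energy profile follows the windowing rule", {
  m <- default_energy_matrix()
  # homopolymer: every pair is identical
  e <- estimate_energy_profile(strrep("K", 61), m)
  expect_equal(e, rep(m["K", "K"], 61))
  # all-zero matrix
  zero <- m * 0
  expect_equal(estimate_energy_profile("ACDEFG", zero), rep(0, 6))
  # two residues, truncated windows with a single partner each
  e2 <- estimate_energy_profile("KE", m)
  expect_equal(e2, c(m["K", "E"], m["E", "K"]))
  expect_error(estimate_energy_profile("KE", m, window = 2), "at least 3")
  # asymmetric matrix is rejected
  bad <- m; bad[1, 2] <- bad[1, 2] + 1
  expect_error(estimate_energy_profile("KE", bad), "symmetric")
})

test_that("window truncation keeps scores within [0, 1]", {
  set.seed(13)
  aa <- rownames(default_energy_matrix())
  for (i in 1:10) {
    s <- paste(sample(aa, sample(3:100, 1), replace = TRUE), collapse = "")
    sc <- energy_to_score(estimate_energy_profile(s))
    expect_true(all(sc >= 0 & sc <= 1))
  }
})

test_that("scores depend only on window composition", {
  set.seed(14)
  aa <- rownames(default_energy_matrix())
  s <- sample(aa, 120, replace = TRUE)
  e <- estimate_energy_profile(paste(s, collapse = ""), window = 30)
  # shuffle residues entirely outside position 60's window (+-15)
  out_idx <- c(1:40, 80:120)
  s2 <- s
  s2[out_idx] <- s[sample(out_idx)]
  e2 <- estimate_energy_profile(paste(s2, collapse = ""), window = 30)
  expect_equal(e2[60], e[60])
})

test_that("logistic scoring is monotone with the stated midpoint", {
  expect_equal(energy_to_score(0.2, midpoint = 0.2), 0.5)
  expect_gt(energy_to_score(100), 1 - 1e-10)
  e <- sort(rnorm(50))
  expect_true(all(diff(energy_to_score(e)) > 0))
  expect_error(energy_to_score(1, scale = 0), "positive")
  expect_error(energy_to_score(1, scale = -1), "positive")
})

test_that("smoothing is a truncated centered moving average", {
  expect_equal(smooth_scores(c(0.2, 0.8, 0.5), 1), c(0.2, 0.8, 0.5))
  expect_equal(smooth_scores(rep(0.3, 10), 5), rep(0.3, 10))
  expect_equal(smooth_scores(c(0, 0, 1, 0, 0), 3),
               c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  expect_error(smooth_scores(1:5 / 10, 4), "odd")
})

test_that("disordered fraction uses a strict threshold", {
  expect_equal(disorder_fraction(c(0.5, 0.5, 0.3, 0.3)), 50)
  expect_equal(disorder_fraction(rep(0.4, 10)), 0)
  expect_equal(disorder_fraction(rep(0.41, 10)), 100)
  expect_error(disorder_fraction(numeric(0)), "non-empty")
  expect_error(disorder_fraction(c(0.5, 1.2)), "\\[0, 1\\]")
  # non-increasing in the threshold
  set.seed(15)
  sc <- runif(200)
  fr <- vapply(seq(0, 1, 0.1), function(t) disorder_fraction(sc, t),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("charged sequences score as more disordered than hydrophobic ones", {
  ke <- strrep("KE", 100)
  ilvf <- strrep("ILVF", 50)
  dp <- disorder_profiles(tibble::tibble(
    protein_id = c("ke", "ilvf"), sequence = c(ke, ilvf)
  ))
  expect_gt(dp$disordered_fraction[dp$protein_id == "ke"],
            dp$disordered_fraction[dp$protein_id == "ilvf"])
  expect_equal(dp$disordered_fraction[dp$protein_id == "ilvf"], 0)
})

test_that("batch scoring equals single-sequence scoring", {
  ds <- tiny_dataset()
  prot <- ds$proteins[1:20, ]
  dp <- disorder_profiles(prot, keep_scores = TRUE)
  for (i in c(1, 7, 20)) {
    e <- estimate_energy_profile(prot$sequence[i])
    expect_equal(dp$scores[[i]], energy_to_score(e))
  }
  expect_equal(dp$length, nchar(prot$sequence))
})

test_that("midpoint calibration recovers a separating cutoff", {
  # perfectly separated labels
  res <- calibrate_midpoint(c(1:10, 21:30) / 10, rep(c(FALSE, TRUE),
                                                     each = 10))
  expect_equal(res$balanced_accuracy, 1)
  expect_true(res$cutoff > 1 && res$cutoff < 2.1)

  # no signal: balanced accuracy near one half
  set.seed(16)
  e <- rnorm(2000)
  lab <- rep(c(TRUE, FALSE), 1000)
  res2 <- calibrate_midpoint(e, lab)
  expect_lt(res2$balanced_accuracy, 0.56)

  # two Gaussians two standard deviations apart: the optimal cutoff is the
  # midpoint of the means
  mu0 <- 0; mu1 <- 2
  e3 <- c(rnorm(4000, mu0), rnorm(4000, mu1))
  lab3 <- rep(c(FALSE, TRUE), each = 4000)
  res3 <- calibrate_midpoint(e3, lab3)
  expect_lt(abs(res3$cutoff - (mu0 + mu1) / 2), 0.2)
  expect_error(calibrate_midpoint(e3, rep(TRUE, 8000)), "both")
})

test_that("energy matrix round-trips through TSV", {
  m <- default_energy_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_energy_matrix(m, path)
  m2 <- read_energy_matrix(path)
  expect_equal(m2, m, tolerance = 1e-12)
})

test_that("non-canonical residues follow the ambiguity policy", {
  m <- default_energy_matrix()
  e <- estimate_energy_profile("KXK", m)
  expect_length(e, 3)
  # the X position is scored with the average-residue row
  expect_equal(e[2], mean(m[, "K"]))
  # canonical positions exclude X as a partner
  expect_equal(e[1], m["K", "K"])
})
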