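#' Default pairwise interaction energy matrix
#'
#' A 20 x 20 symmetric matrix of pseudo-energies approximating the tendency
#' of residue pairs to form stabilizing contacts. It is built additively
#' from the Kyte-Doolittle hydropathy index,
#' `M[a, b] = -(h_a + h_b) / 10`, so that pairs of hydrophobic residues
#' (which drive the folded core) get the most negative (most stabilizing)
#' energies while pairs of charged residues get the highest. Any symmetric
#' matrix with the 20 canonical letters as dimnames can be supplied in its
#' place, e.g. via [read_energy_matrix()].
#'
#' @return A 20 x 20 named symmetric matrix.
#' @export
default_energy_matrix <- function() {
  h <- KD_HYDROPATHY[AA_LETTERS]
  m <- -outer(h, h, `+`) / 10
  dimnames(m) <- list(AA_LETTERS, AA_LETTERS)
  m
}

check_energy_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !all(AA_LETTERS %in% rownames(matrix)) ||
      !all(AA_LETTERS %in% colnames(matrix))) {
    abort("Energy matrix must carry all 20 canonical amino-acid letters.")
  }
  m <- matrix[AA_LETTERS, AA_LETTERS]
  if (max(abs(m - t(m))) > 1e-9) abort("Energy matrix must be symmetric.")
  m
}

#' Per-residue interaction energy profile
#'
#' For residue `i`, the energy is the mean of `matrix[a_i, a_j]` over all
#' other residues `j` in a centered window of half-width `floor(window / 2)`
#' (truncated at the sequence ends). Lower (more negative) energy means more
#' stabilizing contacts, i.e. a more ordered context. Non-canonical residues
#' are excluded as partners; a non-canonical residue itself is scored with
#' the matrix's column means (an "average residue" row), and a residue with
#' no canonical partner in its window is given the matrix grand mean.
#'
#' @param sequence A single amino-acid string.
#' @param matrix Symmetric 20 x 20 energy matrix; default
#'   [default_energy_matrix()].
#' @param window Window size in residues (>= 3); default 30, matching the
#'   30-residue composition window of the underlying predictor.
#' @return Numeric vector of per-residue energies, one per residue of
#'   `sequence` (including non-canonical positions).
#' @export
estimate_energy_profile <- function(sequence, matrix = default_energy_matrix(),
                                    window = 30L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (window < 3) abort("`window` must be at least 3 residues.")
  m <- check_energy_matrix(matrix)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  if (n < 1) abort("Sequence must contain at least one residue.")
  codes <- match(chars, AA_LETTERS)  # NA for non-canonical
  energy_profile_codes(codes, m, window)
}

# Vectorized core: cumulative per-letter counts give window compositions in
# O(n * 20); works on integer codes (NA = non-canonical).
energy_profile_codes <- function(codes, m, window) {
  n <- length(codes)
  half <- window %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  energy_profile_core(codes, m, lo, hi)
}

# Shared engine over arbitrary per-position window bounds [lo, hi]; lets
# several concatenated sequences be scored in one pass with windows clamped
# at each sequence's boundaries.
energy_profile_core <- function(codes, m, lo, hi) {
  n <- length(codes)
  ind <- matrix(0L, n, 20L)
  ok <- !is.na(codes)
  ind[cbind(which(ok), codes[ok])] <- 1L
  cum <- apply(ind, 2L, cumsum)
  cum <- rbind(0L, cum)
  counts <- cum[hi + 1L, , drop = FALSE] - cum[lo, , drop = FALSE]
  # remove the residue itself as a partner
  counts[cbind(which(ok), codes[ok])] <-
    counts[cbind(which(ok), codes[ok])] - 1L
  rows <- matrix(NA_real_, n, 20L)
  rows[ok, ] <- m[codes[ok], , drop = FALSE]
  if (any(!ok)) {
    rows[!ok, ] <- matrix(colMeans(m), sum(!ok), 20L, byrow = TRUE)
  }
  npart <- rowSums(counts)
  e <- rowSums(counts * rows)
  e[npart > 0] <- e[npart > 0] / npart[npart > 0]
  e[npart == 0] <- mean(m)
  e
}

#' Logistic mapping from energy to disorder score
#'
#' `score = 1 / (1 + exp(-(e - midpoint) / scale))`: strictly increasing in
#' the energy (weaker stabilizing contacts mean more disorder), equal to 0.5
#' at the midpoint, saturating at 0 and 1. The default midpoint and scale
#' were fixed once against the package's synthetic proteome model so that a
#' typical proteome shows a median disordered fraction in the high teens of
#' percent; [calibrate_midpoint()] re-estimates them from labelled data.
#'
#' @param e Numeric vector of per-residue energies.
#' @param midpoint Energy at which the score is 0.5.
#' @param scale Logistic scale, must be positive.
#' @return Scores in \[0, 1\], same length as `e`.
#' @export
energy_to_score <- function(e, midpoint = 0.45, scale = 0.10) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    abort("`scale` must be a single positive number.")
  }
  1 / (1 + exp(-(e - midpoint) / scale))
}

#' Centered moving-average smoothing of score profiles
#'
#' Optional smoothing pass emphasising long disordered regions. The window
#' must be odd; ends are truncated (the average runs over the in-sequence
#' part of the window). Window 1 is the identity.
#'
#' @param scores Numeric vector.
#' @param window Odd positive integer.
#' @return Smoothed vector, same length.
#' @export
smooth_scores <- function(scores, window = 1L) {
  stopifnot(is.numeric(scores))
  if (window < 1 || window %% 2 == 0) {
    abort("Smoothing `window` must be an odd positive integer.")
  }
  if (window == 1L || length(scores) == 0L) return(scores)
  n <- length(scores)
  half <- (window - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cum <- c(0, cumsum(scores))
  (cum[hi + 1L] - cum[lo]) / (hi - lo + 1L)
}

#' Disordered fraction of a score profile
#'
#' Percentage of residues whose disorder score strictly exceeds the
#' threshold (default 0.4): scores exactly at the threshold do not count.
#'
#' @param scores Numeric vector of per-residue scores in \[0, 1\].
#' @param threshold Strict cutoff, default 0.4.
#' @return Percent in \[0, 100\].
#' @export
#' @examples
#' disorder_fraction(c(0.5, 0.5, 0.3, 0.3))  # 50
disorder_fraction <- function(scores, threshold = 0.4) {
  if (length(scores) == 0) abort("`scores` must be non-empty.")
  if (any(scores < 0 | scores > 1)) abort("Scores must lie in [0, 1].")
  100 * mean(scores > threshold)
}

#' Per-protein disorder profiles
#'
#' Runs the disorder stage over a protein table: energy profile with the
#' 30-residue window, logistic scoring, optional smoothing, and the
#' disordered fraction at the strict threshold.
#'
#' @param proteins Data frame with `protein_id` and `sequence` columns
#'   (a `gene_id` column, if present, is carried through).
#' @param matrix Energy matrix, default [default_energy_matrix()].
#' @param window Estimation window, default 30 residues.
#' @param threshold Disorder-call threshold, default 0.4 (strict).
#' @param midpoint,scale Logistic parameters of [energy_to_score()].
#' @param smoothing Odd smoothing window for [smooth_scores()]; default 1
#'   (none).
#' @param keep_scores If `TRUE`, attach a list-column `scores` with the
#'   per-residue score vectors.
#' @return A tibble `protein_id` (`gene_id` if supplied), `length`,
#'   `disordered_fraction`, `threshold`, `window`.
#' @export
disorder_profiles <- function(proteins, matrix = default_energy_matrix(),
                              window = 30L, threshold = 0.4,
                              midpoint = 0.45, scale = 0.10,
                              smoothing = 1L, keep_scores = FALSE) {
  proteins <- as_tibble(proteins)
  require_columns(proteins, c("protein_id", "sequence"))
  m <- check_energy_matrix(matrix)
  if (smoothing < 1 || smoothing %% 2 == 0) {
    abort("Smoothing `window` must be an odd positive integer.")
  }
  seqs <- toupper(proteins$sequence)
  half <- as.integer(window) %/% 2L
  chars <- strsplit(seqs, "")
  lens <- lengths(chars)
  if (any(lens == 0)) abort("Empty protein sequence supplied.")
  # score proteins in concatenated chunks, clamping each window at its own
  # protein's boundaries
  chunks <- split(seq_along(seqs),
                  cumsum(lens) %/% 200000L)
  score_list <- vector("list", length(seqs))
  for (idx in chunks) {
    codes <- match(unlist(chars[idx], use.names = FALSE), AA_LETTERS)
    l <- lens[idx]
    offset <- cumsum(l) - l
    pidx <- rep.int(seq_along(idx), l)
    glo <- seq_along(codes)
    lo <- pmax(glo - half, offset[pidx] + 1L)
    hi <- pmin(glo + half, offset[pidx] + l[pidx])
    e <- energy_profile_core(codes, m, lo, hi)
    sc <- energy_to_score(e, midpoint, scale)
    sc_split <- split(sc, pidx)
    if (smoothing > 1L) {
      sc_split <- lapply(sc_split, smooth_scores, window = smoothing)
    }
    score_list[idx] <- sc_split
  }
  out <- tibble(
    protein_id = proteins$protein_id,
    length = lengths(score_list),
    disordered_fraction = vapply(score_list, disorder_fraction,
                                 numeric(1), threshold = threshold),
    threshold = threshold,
    window = as.integer(window)
  )
  if ("gene_id" %in% names(proteins)) {
    out <- bind_cols(tibble(gene_id = proteins$gene_id), out)
  }
  if (keep_scores) out$scores <- score_list
  out
}

#' Calibrate the logistic midpoint from labelled residues
#'
#' Given per-residue energies with known order/disorder labels (for example
#' from a synthetic benchmark), finds the energy cutoff that maximizes
#' balanced accuracy of the strict `score > 0.4` call, and converts it to a
#' logistic midpoint for the given scale: since
#' `score > 0.4  <=>  e > midpoint + scale * log(0.4 / 0.6)`, the fitted
#' midpoint is `cutoff - scale * log(0.4 / 0.6)`.
#'
#' @param energy Numeric vector of per-residue energies.
#' @param disordered Logical vector of the same length: `TRUE` for residues
#'   labelled disordered.
#' @param scale Logistic scale to pair with the fitted midpoint.
#' @param threshold Score threshold the calibration targets, default 0.4.
#' @return A one-row tibble `midpoint`, `scale`, `cutoff`,
#'   `balanced_accuracy`, `n`.
#' @export
calibrate_midpoint <- function(energy, disordered, scale = 0.10,
                               threshold = 0.4) {
  stopifnot(is.numeric(energy), is.logical(disordered),
            length(energy) == length(disordered))
  if (anyNA(energy) || anyNA(disordered)) abort("Missing values not allowed.")
  if (all(disordered) || all(!disordered)) {
    abort("Calibration requires both ordered and disordered labels.")
  }
  if (scale <= 0) abort("`scale` must be positive.")
  e_sorted <- sort(unique(energy))
  cand <- c(e_sorted[1] - 1,
            (e_sorted[-1] + e_sorted[-length(e_sorted)]) / 2,
            e_sorted[length(e_sorted)] + 1)
  n_dis <- sum(disordered)
  n_ord <- sum(!disordered)
  # balanced accuracy of "disordered iff e > cutoff" at each candidate
  bacc <- vapply(cand, function(cut) {
    tpr <- sum(energy[disordered] > cut) / n_dis
    tnr <- sum(energy[!disordered] <= cut) / n_ord
    (tpr + tnr) / 2
  }, numeric(1))
  best <- which.max(bacc)
  cutoff <- cand[best]
  tibble(
    midpoint = cutoff - scale * log(threshold / (1 - threshold)),
    scale = scale,
    cutoff = cutoff,
    balanced_accuracy = bacc[best],
    n = length(energy)
  )
}

#' Read an energy matrix from a TSV file
#'
#' Expects a 21 x 21 layout: a header row and first column of amino-acid
#' letters framing the 20 x 20 numeric body.
#'
#' @param path Path to the TSV file.
#' @return A validated 20 x 20 symmetric matrix.
#' @export
read_energy_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl[[1]]
  storage.mode(m) <- "double"
  check_energy_matrix(m)
}

#' Write an energy matrix to a TSV file
#'
#' @param matrix A 20 x 20 symmetric matrix with amino-acid dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_matrix <- function(matrix, path) {
  m <- check_energy_matrix(matrix)
  tbl <- bind_cols(tibble(aa = rownames(m)), as_tibble(m))
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
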