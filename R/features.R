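#' Select the longest protein isoform per gene
#'
#' For genes encoding several splicing isoforms, the longest protein is the
#' one analysed. Length is the number of canonical residues (non-canonical
#' symbols such as `X`, `B`, `Z`, `U`, `*` and gaps are not counted). Ties
#' are broken by the lexicographically smallest protein identifier, so the
#' choice is deterministic.
#'
#' @param proteins Data frame with columns `gene_id`, `protein_id` and
#'   `sequence` (amino-acid strings).
#' @return A tibble with one row per gene: `gene_id`, `protein_id`,
#'   `sequence`, `length`.
#' @export
select_longest_isoform <- function(proteins) {
  proteins <- as_tibble(proteins)
  require_columns(proteins, c("gene_id", "protein_id", "sequence"))
  if (nrow(proteins) == 0) abort("No protein records supplied.")
  proteins |>
    mutate(length = canonical_length(.data$sequence)) |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$length), .data$protein_id, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$gene_id)
}

canonical_length <- function(sequences) {
  counts <- aa_count_matrix(sequences)
  as.integer(rowSums(counts))
}

# 20-column count matrix over the canonical alphabet, one row per sequence.
aa_count_matrix <- function(sequences) {
  aas <- Biostrings::AAStringSet(toupper(sequences))
  counts <- Biostrings::letterFrequency(aas, letters = AA_LETTERS)
  colnames(counts) <- AA_LETTERS
  counts
}

#' Amino-acid frequencies of a protein sequence
#'
#' Frequency of each canonical amino acid: occurrences divided by the number
#' of canonical residues. Non-canonical symbols (`X`, `B`, `Z`, `U`, `*`,
#' gaps) are excluded from both numerator and denominator.
#'
#' @param sequence A single amino-acid string.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
#' @examples
#' aa_frequencies("ACDEFGHIKLMNPQRSTVWY")["A"]
aa_frequencies <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  counts <- aa_count_matrix(sequence)[1L, ]
  total <- sum(counts)
  if (total == 0) {
    abort("Sequence contains no canonical amino-acid residues.")
  }
  counts / total
}

#' Charged/polar/hydrophobic class fractions from a frequency profile
#'
#' Sums the member frequencies of the three physico-chemical classes:
#' charged (R, D, E, K), polar (N, C, Q, H, S, T, W, Y) and hydrophobic
#' (A, G, I, L, M, F, P, V). The three fractions sum to 1.
#'
#' @param freq Named numeric frequency profile over the 20 canonical amino
#'   acids, as returned by [aa_frequencies()].
#' @return Named numeric vector `c(charged, polar, hydrophobic)`.
#' @export
class_fractions <- function(freq) {
  if (!all(AA_LETTERS %in% names(freq))) {
    abort("`freq` must be named by the 20 canonical amino-acid letters.")
  }
  vapply(AA_CLASSES, function(members) sum(freq[members]), numeric(1))
}

#' GC content of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`, case-insensitive; other letters (N and IUPAC
#' ambiguity codes) are excluded from both counts.
#'
#' @param sequence Character vector of nucleotide strings (vectorized).
#' @return Numeric vector of GC fractions in \[0, 1\].
#' @export
#' @examples
#' gc_content("ATGC")
gc_content <- function(sequence) {
  stopifnot(is.character(sequence))
  dna <- Biostrings::DNAStringSet(toupper(sequence))
  counts <- Biostrings::letterFrequency(dna, letters = c("A", "C", "G", "T"))
  total <- rowSums(counts)
  if (any(total == 0)) {
    abort("Sequence contains no unambiguous A/C/G/T letters.")
  }
  unname((counts[, "G"] + counts[, "C"]) / total)
}

#' Consensus single-compartment assignment
#'
#' Keeps proteins annotated to exactly one subcellular compartment; proteins
#' carrying two or more distinct labels are excluded from compartment-
#' stratified analyses.
#'
#' @param locations Data frame with columns `protein_id` and `compartment`.
#' @param compartments Character vector of valid compartment names; defaults
#'   to the ten compartments used throughout the package.
#' @return A tibble `protein_id`, `compartment` with one row per single-
#'   compartment protein.
#' @export
consensus_location <- function(locations, compartments = COMPARTMENTS) {
  locations <- as_tibble(locations)
  require_columns(locations, c("protein_id", "compartment"))
  if (nrow(locations) == 0) {
    return(tibble(protein_id = character(), compartment = character()))
  }
  unknown <- setdiff(unique(locations$compartment), compartments)
  if (length(unknown) > 0) {
    abort(sprintf(
      "Unknown compartment name(s): %s. Valid names: %s.",
      paste(unknown, collapse = ", "), paste(compartments, collapse = ", ")
    ))
  }
  locations |>
    distinct(.data$protein_id, .data$compartment) |>
    group_by(.data$protein_id) |>
    filter(n() == 1L) |>
    ungroup() |>
    arrange(.data$protein_id)
}

#' Per-gene protein composition profiles
#'
#' Runs the full feature-extraction stage: selects the longest isoform per
#' gene, computes amino-acid frequencies and class fractions, and attaches
#' GC content computed from coding sequences (or taken from a precomputed
#' table) and, optionally, the consensus subcellular compartment.
#'
#' @param proteins Data frame `gene_id`, `protein_id`, `sequence`.
#' @param cds Optional data frame `gene_id`, `sequence` of coding sequences
#'   from which GC content is computed.
#' @param gc Optional precomputed data frame `gene_id`, `gc` (fractions in
#'   \[0, 1\]); used when `cds` is `NULL`.
#' @param locations Optional data frame `protein_id`, `compartment`; reduced
#'   to single-compartment proteins via [consensus_location()].
#' @return A tibble with one row per gene: `gene_id`, `protein_id`,
#'   `length`, the 20 frequency columns `freq_A` ... `freq_Y`,
#'   `charged_frac`, `polar_frac`, `hydrophobic_frac`, `gc` (NA when no GC
#'   source given) and `compartment` (NA when unlocated or multi-located).
#' @export
composition_profiles <- function(proteins, cds = NULL, gc = NULL,
                                 locations = NULL) {
  longest <- select_longest_isoform(proteins)
  counts <- aa_count_matrix(longest$sequence)
  total <- rowSums(counts)
  if (any(total == 0)) {
    abort(sprintf(
      "Protein(s) without canonical residues: %s",
      paste(head(longest$gene_id[total == 0], 5), collapse = ", ")
    ))
  }
  freqs <- counts / total
  colnames(freqs) <- paste0("freq_", AA_LETTERS)
  out <- bind_cols(
    longest |> select("gene_id", "protein_id", "length"),
    as_tibble(freqs)
  ) |>
    mutate(
      charged_frac = rowSums(freqs[, paste0("freq_", AA_CLASSES$charged), drop = FALSE]),
      polar_frac = rowSums(freqs[, paste0("freq_", AA_CLASSES$polar), drop = FALSE]),
      hydrophobic_frac = rowSums(freqs[, paste0("freq_", AA_CLASSES$hydrophobic), drop = FALSE])
    )
  if (!is.null(cds)) {
    cds <- as_tibble(cds)
    require_columns(cds, c("gene_id", "sequence"))
    gc_tbl <- tibble(gene_id = cds$gene_id, gc = gc_content(cds$sequence))
    out <- left_join(out, gc_tbl, by = "gene_id")
  } else if (!is.null(gc)) {
    gc <- as_tibble(gc)
    require_columns(gc, c("gene_id", "gc"))
    out <- left_join(out, gc |> select("gene_id", "gc"), by = "gene_id")
  } else {
    out$gc <- NA_real_
  }
  if (!is.null(locations)) {
    consensus <- consensus_location(locations)
    out <- left_join(out, consensus, by = "protein_id")
  } else {
    out$compartment <- NA_character_
  }
  out
}

require_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
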