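#' Probe-level quality filtering
#'
#' Drops control features, then keeps a probe when its well-above-background
#' flag is `TRUE` in at least 3 of the 4 biological replicates. The rule's
#' scope is configurable: `"all"` (default) requires the rule in every
#' condition; `"any"` requires it in at least one condition.
#'
#' @param probes Data frame of probe measurements with columns `probe_id`,
#'   `condition` (one of `E0_22`, `E24_22`, `E24_37`), `replicate` (1-4),
#'   `intensity`, `well_above_bg` (logical), `is_control` (logical).
#' @param scope `"all"` or `"any"`: whether the >= 3/4 rule must hold in
#'   every condition or in at least one.
#' @param min_pass Minimum number of passing replicates per condition,
#'   default 3.
#' @return Character vector of retained probe identifiers.
#' @export
filter_probes <- function(probes, scope = c("all", "any"), min_pass = 3L) {
  scope <- match.arg(scope)
  probes <- as_tibble(probes)
  require_columns(probes, c("probe_id", "condition", "replicate",
                            "well_above_bg", "is_control"))
  bad_cond <- setdiff(unique(probes$condition), CONDITIONS)
  if (length(bad_cond) > 0) {
    abort(sprintf("Unknown condition(s): %s", paste(bad_cond, collapse = ", ")))
  }
  measured <- probes |> filter(!.data$is_control)
  counts <- measured |>
    group_by(.data$probe_id, .data$condition) |>
    summarise(
      n_rep = n(),
      n_pass = sum(.data$well_above_bg),
      .groups = "drop"
    )
  over <- counts |> filter(.data$n_rep > 4)
  if (nrow(over) > 0) {
    abort(sprintf(
      "Malformed input: probe %s has more than 4 replicates in condition %s.",
      over$probe_id[1], over$condition[1]
    ))
  }
  verdict <- counts |>
    group_by(.data$probe_id) |>
    summarise(
      keep = if (scope == "all") all(.data$n_pass >= min_pass)
             else any(.data$n_pass >= min_pass),
      .groups = "drop"
    )
  sort(verdict$probe_id[verdict$keep])
}

#' Annotation filtering of probe-to-gene hits
#'
#' Keeps hits with E-value at most `max_e_value`, sequence identity at least
#' `min_identity` percent and probe-length overlap at least `min_overlap`
#' percent (all boundary-inclusive). Probes that still match more than one
#' distinct gene after filtering are removed entirely, so the result maps
#' each surviving probe to exactly one gene. Duplicate (probe, gene) rows
#' are collapsed with a warning.
#'
#' @param hits Data frame with columns `probe_id`, `gene_id`, `e_value`,
#'   `identity_pct`, `overlap_pct`.
#' @param max_e_value,min_identity,min_overlap Filter thresholds; defaults
#'   9.9e-6, 98 and 75.
#' @return A tibble `probe_id`, `gene_id` with one row per retained probe.
#' @export
filter_annotations <- function(hits, max_e_value = 9.9e-6,
                               min_identity = 98, min_overlap = 75) {
  hits <- as_tibble(hits)
  require_columns(hits, c("probe_id", "gene_id", "e_value",
                          "identity_pct", "overlap_pct"))
  kept <- hits |>
    filter(
      .data$e_value <= max_e_value,
      .data$identity_pct >= min_identity,
      .data$overlap_pct >= min_overlap
    )
  n_dup <- nrow(kept) - nrow(distinct(kept, .data$probe_id, .data$gene_id))
  if (n_dup > 0) {
    warn(sprintf("Collapsed %d duplicate (probe, gene) hit row(s).", n_dup))
    kept <- kept |> distinct(.data$probe_id, .data$gene_id, .keep_all = TRUE)
  }
  kept |>
    group_by(.data$probe_id) |>
    filter(n_distinct(.data$gene_id) == 1L) |>
    ungroup() |>
    distinct(.data$probe_id, .data$gene_id) |>
    arrange(.data$probe_id)
}

#' Aggregate probe intensities to gene-level condition means
#'
#' Two-step averaging: replicate intensities are averaged per probe and
#' condition, then probe means are averaged per gene and condition. By
#' default the arithmetic mean is taken on the linear intensity scale; with
#' `scale = "log2"` averaging happens on the log2 scale (the geometric
#' mean), and the result is returned back on the linear scale.
#'
#' @param probes Probe measurement data frame (see [filter_probes()]).
#' @param probe_map Data frame `probe_id`, `gene_id` as returned by
#'   [filter_annotations()]; only probes present here are used.
#' @param retained Optional character vector of quality-passing probe ids
#'   (from [filter_probes()]); when given, the mapping is restricted to it.
#' @param scale `"linear"` (default) or `"log2"` averaging scale.
#' @return A tibble `gene_id`, `condition`, `intensity` with one row per
#'   gene and measured condition.
#' @export
aggregate_expression <- function(probes, probe_map, retained = NULL,
                                 scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  probes <- as_tibble(probes)
  probe_map <- as_tibble(probe_map)
  require_columns(probes, c("probe_id", "condition", "replicate", "intensity"))
  require_columns(probe_map, c("probe_id", "gene_id"))
  if (!is.null(retained)) {
    probe_map <- probe_map |> filter(.data$probe_id %in% retained)
  }
  if (nrow(probe_map) == 0) {
    return(tibble(gene_id = character(), condition = character(),
                  intensity = double()))
  }
  rows <- probes |>
    filter(if ("is_control" %in% names(probes)) !.data$is_control else TRUE) |>
    inner_join(probe_map, by = "probe_id")
  probe_means <- rows |>
    group_by(.data$gene_id, .data$probe_id, .data$condition) |>
    summarise(
      intensity = if (scale == "linear") mean(.data$intensity)
                  else 2^mean(log2(.data$intensity)),
      .groups = "drop"
    )
  # probes missing a condition simply do not contribute to that condition
  n_cond <- probe_means |> count(.data$probe_id) |> filter(.data$n < 3)
  if (nrow(n_cond) > 0) {
    warn(sprintf(
      "%d probe(s) lack replicates in some condition and were excluded there.",
      nrow(n_cond)
    ))
  }
  probe_means |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(
      intensity = if (scale == "linear") mean(.data$intensity)
                  else 2^mean(log2(.data$intensity)),
      .groups = "drop"
    ) |>
    arrange(.data$gene_id, .data$condition)
}

#' Heat-stress response statistic
#'
#' `R = log2(e24_37 / e24_22)`: positive for genes overexpressed at 37
#' degrees, negative for repressed genes. Vectorized.
#'
#' @param e24_37,e24_22 Positive mean intensities at 24 h, 37 C and 22 C.
#' @param gene_id Optional identifiers used in error messages.
#' @return Numeric vector of log2 ratios.
#' @export
#' @examples
#' compute_response(8, 2)  # 2
compute_response <- function(e24_37, e24_22, gene_id = NULL) {
  stopifnot(is.numeric(e24_37), is.numeric(e24_22))
  bad <- !is.finite(e24_37) | !is.finite(e24_22) | e24_37 <= 0 | e24_22 <= 0
  if (any(bad)) {
    who <- if (!is.null(gene_id)) paste(head(gene_id[bad], 5), collapse = ", ")
           else paste(head(which(bad), 5), collapse = ", ")
    abort(sprintf(
      "Non-positive expression mean(s) for: %s. R is undefined.", who
    ))
  }
  log2(e24_37 / e24_22)
}

#' Categorize genes by their heat response
#'
#' Assigns the overlapping label sets used in the analyses: `induced`
#' (R > 0), `repressed` (R < 0), `strong_induced` (R > 1),
#' `strong_induced_2` (R > 2), `strong_repressed_2` (R < -2), and `zero`
#' (R exactly 0, excluded from the induced/repressed comparisons).
#'
#' @param r Numeric vector of response values.
#' @param thresholds Named numeric vector with elements `induced` (0),
#'   `strong` (1), `strong2` (2), `strong_rep2` (-2).
#' @return A tibble of logical columns, one row per element of `r`.
#' @export
classify_genes <- function(r, thresholds = c(induced = 0, strong = 1,
                                             strong2 = 2, strong_rep2 = -2)) {
  stopifnot(is.numeric(r))
  need <- c("induced", "strong", "strong2", "strong_rep2")
  if (!all(need %in% names(thresholds)) || any(!is.finite(thresholds[need]))) {
    abort("`thresholds` must contain finite induced/strong/strong2/strong_rep2.")
  }
  tibble(
    induced = r > thresholds[["induced"]],
    repressed = r < thresholds[["induced"]],
    strong_induced = r > thresholds[["strong"]],
    strong_induced_2 = r > thresholds[["strong2"]],
    strong_repressed_2 = r < thresholds[["strong_rep2"]],
    zero = r == thresholds[["induced"]]
  )
}

#' Full expression-processing stage
#'
#' Applies probe quality filtering, annotation filtering, gene-level
#' aggregation, the response statistic and categorization in one call.
#'
#' @inheritParams filter_probes
#' @inheritParams aggregate_expression
#' @param hits Probe-to-gene hit table (see [filter_annotations()]).
#' @param thresholds Category thresholds for [classify_genes()].
#' @return A tibble with one row per gene: `gene_id`, `e0_22`, `e24_22`,
#'   `e24_37`, `r` and the six logical category columns. Genes lacking a
#'   positive mean in either 24 h condition are dropped.
#' @export
gene_responses <- function(probes, hits, scope = c("all", "any"),
                           scale = c("linear", "log2"),
                           thresholds = c(induced = 0, strong = 1,
                                          strong2 = 2, strong_rep2 = -2)) {
  scope <- match.arg(scope)
  scale <- match.arg(scale)
  retained <- filter_probes(probes, scope = scope)
  probe_map <- filter_annotations(hits)
  agg <- aggregate_expression(probes, probe_map, retained = retained,
                              scale = scale)
  if (nrow(agg) == 0) {
    return(bind_cols(
      tibble(gene_id = character(), e0_22 = double(), e24_22 = double(),
             e24_37 = double(), r = double()),
      classify_genes(double(), thresholds)
    ))
  }
  wide <- agg |>
    mutate(condition = tolower(.data$condition)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "intensity")
  for (col in c("e0_22", "e24_22", "e24_37")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide <- wide |>
    filter(!is.na(.data$e24_22), !is.na(.data$e24_37)) |>
    mutate(r = compute_response(.data$e24_37, .data$e24_22, .data$gene_id)) |>
    select("gene_id", "e0_22", "e24_22", "e24_37", "r")
  bind_cols(wide, classify_genes(wide$r, thresholds)) |>
    arrange(.data$gene_id)
}
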