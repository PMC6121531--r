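#' Feature-response association battery with confound control
#'
#' For each of the 20 amino-acid frequencies and the three class totals
#' (plus, when available, the disordered fraction), computes the Spearman
#' correlation with the response R under up to four control regimes: no
#' control, and partial correlations controlling for GC content, baseline
#' expression (`e24_22`) or heat expression (`e24_37`). Benjamini-Hochberg
#' correction is applied within each regime across the 20 amino acids only;
#' class totals and disorder are reported unadjusted, matching the
#' presentation of the study tables.
#'
#' @param features Feature table with `gene_id`, the `freq_*` columns and
#'   class fractions (see [composition_profiles()]); a `disorder_frac`
#'   column is included in the battery when present. GC control requires a
#'   `gc` column.
#' @param responses Gene response table with `gene_id`, `r` and (for the
#'   expression controls) `e24_22`, `e24_37` (see [gene_responses()]).
#' @param controls Character subset of `c("none", "gc", "e24_22",
#'   "e24_37")`.
#' @return A tibble of class `heataa_associations`: `feature`, `type`
#'   (`amino_acid`, `class_total` or `disorder`), `control`, `rho`, `p`,
#'   `q` (NA outside the amino-acid family), `n`, `significant`
#'   (q < 0.05 for amino acids, p < 0.05 otherwise).
#' @export
association_battery <- function(features, responses,
                                controls = c("none", "gc", "e24_22",
                                             "e24_37")) {
  controls <- match.arg(controls, several.ok = TRUE)
  features <- as_tibble(features)
  responses <- as_tibble(responses)
  require_columns(features, c("gene_id", paste0("freq_", AA_LETTERS),
                              "charged_frac", "polar_frac",
                              "hydrophobic_frac"))
  require_columns(responses, c("gene_id", "r"))
  joined <- inner_join(features, responses, by = "gene_id")
  if (nrow(joined) < 4) abort("At least 4 genes are required.")
  control_col <- c(none = NA, gc = "gc", e24_22 = "e24_22",
                   e24_37 = "e24_37")
  for (ctl in controls) {
    col <- control_col[[ctl]]
    if (!is.na(col) && !col %in% names(joined)) {
      abort(sprintf("Missing control column `%s` for regime \"%s\".",
                    col, ctl))
    }
  }
  feats <- c(
    setNames(paste0("freq_", AA_LETTERS), AA_LETTERS),
    charged = "charged_frac", polar = "polar_frac",
    hydrophobic = "hydrophobic_frac"
  )
  types <- c(rep("amino_acid", 20), rep("class_total", 3))
  if ("disorder_frac" %in% names(joined)) {
    feats <- c(feats, disorder = "disorder_frac")
    types <- c(types, "disorder")
  }
  rows <- purrr::map(controls, function(ctl) {
    col <- control_col[[ctl]]
    res <- purrr::map2(feats, types, function(fc, ty) {
      x <- joined[[fc]]
      if (is.na(col)) {
        rp <- spearman_rho_p(x, joined$r)
      } else {
        rp <- partial_spearman_rho_p(x, joined$r, joined[[col]])
      }
      tibble(feature = NA_character_, type = ty, control = ctl,
             rho = rp[["rho"]], p = rp[["p"]], n = nrow(joined))
    })
    out <- bind_rows(res)
    out$feature <- names(feats)
    aa <- out$type == "amino_acid"
    out$q <- NA_real_
    out$q[aa] <- bh_adjust(out$p[aa])
    out
  })
  out <- bind_rows(rows) |>
    mutate(significant = ifelse(.data$type == "amino_acid",
                                .data$q < 0.05, .data$p < 0.05)) |>
    select("feature", "type", "control", "rho", "p", "q", "n",
           "significant")
  class(out) <- c("heataa_associations", class(out))
  out
}

#' Composition comparison between induced and repressed genes
#'
#' Splits genes into an induced group (`r > cutoff_hi`) and a repressed
#' group (`r < cutoff_lo`) and compares each feature between the groups:
#' group medians on the percent scale and a two-sided Mann-Whitney test,
#' with Benjamini-Hochberg correction across the 20 amino acids.
#'
#' @inheritParams association_battery
#' @param cutoffs Numeric pair `c(hi, lo)`: the default `c(0, 0)` compares
#'   R > 0 vs R < 0; `c(2, -2)` gives the strong-response comparison.
#' @return A tibble of class `heataa_groups`: `feature`, `type`,
#'   `median_induced`, `median_repressed` (percent), `p`, `q`,
#'   `n_induced`, `n_repressed`, `cutoff_hi`, `cutoff_lo`, `significant`.
#' @export
group_comparison <- function(features, responses, cutoffs = c(0, 0)) {
  features <- as_tibble(features)
  responses <- as_tibble(responses)
  require_columns(features, c("gene_id", paste0("freq_", AA_LETTERS),
                              "charged_frac", "polar_frac",
                              "hydrophobic_frac"))
  require_columns(responses, c("gene_id", "r"))
  stopifnot(length(cutoffs) == 2, is.numeric(cutoffs))
  joined <- inner_join(features, responses, by = "gene_id")
  induced <- joined |> filter(.data$r > cutoffs[1])
  repressed <- joined |> filter(.data$r < cutoffs[2])
  if (nrow(induced) == 0 || nrow(repressed) == 0) {
    abort(paste(
      "Empty induced or repressed group under the supplied cutoffs;",
      "use less stringent thresholds."
    ))
  }
  feats <- c(
    setNames(paste0("freq_", AA_LETTERS), AA_LETTERS),
    charged = "charged_frac", polar = "polar_frac",
    hydrophobic = "hydrophobic_frac"
  )
  types <- c(rep("amino_acid", 20), rep("class_total", 3))
  if ("disorder_frac" %in% names(joined)) {
    feats <- c(feats, disorder = "disorder_frac")
    types <- c(types, "disorder")
  }
  out <- purrr::map2(feats, types, function(fc, ty) {
    a <- induced[[fc]]
    b <- repressed[[fc]]
    # disorder is already a percent; frequencies are fractions
    fac <- if (ty == "disorder") 1 else 100
    mw <- mann_whitney(a, b)
    tibble(
      type = ty,
      median_induced = median(a) * fac,
      median_repressed = median(b) * fac,
      p = mw$p
    )
  }) |> bind_rows()
  out$feature <- names(feats)
  aa <- out$type == "amino_acid"
  out$q <- NA_real_
  out$q[aa] <- bh_adjust(out$p[aa])
  out <- out |>
    mutate(
      n_induced = nrow(induced), n_repressed = nrow(repressed),
      cutoff_hi = cutoffs[1], cutoff_lo = cutoffs[2],
      significant = ifelse(aa, .data$q < 0.05, .data$p < 0.05)
    ) |>
    select("feature", "type", "median_induced", "median_repressed",
           "p", "q", "n_induced", "n_repressed", "cutoff_hi", "cutoff_lo",
           "significant")
  class(out) <- c("heataa_groups", class(out))
  out
}

#' Compartment-stratified correlations and sign tests
#'
#' Within each subcellular compartment (proteins with a single consensus
#' location), computes the Spearman correlation between R and each feature
#' class (charged, polar, hydrophobic and, when available, disorder).
#' Across compartments, each feature's correlation signs are summarised by
#' a one-tailed binomial test against the 50% expected at random, the tail
#' following the observed majority sign.
#'
#' @inheritParams association_battery
#' @param locations Data frame `protein_id`, `compartment`; reduced to
#'   single-compartment proteins via [consensus_location()]. The feature
#'   table must carry `protein_id` to join on.
#' @param min_n Minimum compartment size analysed; smaller compartments are
#'   reported as NA rows with a warning. Default 3.
#' @return A list of class `heataa_compartments` with tibbles
#'   `by_compartment` (`compartment`, `n`, `feature`, `rho`, `p`,
#'   `significant`) and `sign_tests` (`feature`, `n_compartments`,
#'   `n_positive`, `n_negative`, `majority_sign`, `binomial_p`).
#' @export
compartment_battery <- function(features, responses, locations, min_n = 3L) {
  features <- as_tibble(features)
  responses <- as_tibble(responses)
  require_columns(features, c("gene_id", "protein_id", "charged_frac",
                              "polar_frac", "hydrophobic_frac"))
  require_columns(responses, c("gene_id", "r"))
  consensus <- consensus_location(locations)
  joined <- features |>
    inner_join(consensus, by = "protein_id",
               suffix = c(".drop", "")) |>
    inner_join(responses |> select("gene_id", "r"), by = "gene_id")
  feats <- c(charged = "charged_frac", polar = "polar_frac",
             hydrophobic = "hydrophobic_frac")
  if ("disorder_frac" %in% names(joined)) {
    feats <- c(feats, disorder = "disorder_frac")
  }
  comps <- intersect(COMPARTMENTS, unique(joined$compartment))
  by_comp <- purrr::map(comps, function(cp) {
    sub <- joined |> filter(.data$compartment == cp)
    if (nrow(sub) < min_n) {
      warn(sprintf("Compartment %s has fewer than %d proteins; reported as NA.",
                   cp, min_n))
      return(tibble(compartment = cp, n = nrow(sub),
                    feature = names(feats), rho = NA_real_, p = NA_real_))
    }
    # a feature that is constant within a compartment has no defined
    # correlation there; report NA for that cell
    cells <- lapply(feats, function(fc) {
      tryCatch(spearman_rho_p(sub[[fc]], sub$r),
               error = function(e) c(rho = NA_real_, p = NA_real_))
    })
    tibble(
      compartment = cp,
      n = nrow(sub),
      feature = names(feats),
      rho = vapply(cells, `[[`, numeric(1), "rho"),
      p = vapply(cells, `[[`, numeric(1), "p")
    )
  }) |> bind_rows() |>
    mutate(significant = !is.na(.data$p) & .data$p < 0.05)
  sign_tests <- by_comp |>
    filter(!is.na(.data$rho)) |>
    group_by(.data$feature) |>
    summarise(
      n_compartments = n(),
      n_positive = sum(.data$rho > 0),
      n_negative = sum(.data$rho < 0),
      .groups = "drop"
    ) |>
    mutate(
      majority_sign = ifelse(.data$n_positive >= .data$n_negative,
                             "positive", "negative"),
      binomial_p = binomial_one_tailed(
        pmax(.data$n_positive, .data$n_negative), .data$n_compartments
      )
    )
  structure(list(by_compartment = by_comp, sign_tests = sign_tests),
            class = "heataa_compartments")
}

#' @export
print.heataa_compartments <- function(x, ...) {
  cat("Compartment-stratified correlation battery\n\n")
  print(x$by_compartment, n = 10)
  cat("\nSign tests across compartments:\n")
  print(x$sign_tests)
  invisible(x)
}
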