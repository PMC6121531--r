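#' Read a probe measurement table
#'
#' Tab-separated with header: `probe_id`, `condition`, `replicate`,
#' `intensity`, `well_above_bg`, `is_control`. Column names can be remapped
#' via `col_map` (new name = file name).
#'
#' @param path Path to the TSV file.
#' @param col_map Optional named character vector mapping package column
#'   names to the file's column names.
#' @return A tibble of probe measurements.
#' @export
read_probes <- function(path, col_map = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         comment = "#")
  tbl <- remap_columns(tbl, col_map)
  require_columns(tbl, c("probe_id", "condition", "replicate", "intensity",
                         "well_above_bg", "is_control"))
  tbl |> mutate(
    well_above_bg = as.logical(.data$well_above_bg),
    is_control = as.logical(.data$is_control)
  )
}

#' Read a probe-to-gene hit table
#'
#' Tab-separated with header: `probe_id`, `gene_id`, `e_value`,
#' `identity_pct`, `overlap_pct`.
#'
#' @inheritParams read_probes
#' @return A tibble of hits.
#' @export
read_hits <- function(path, col_map = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         comment = "#")
  tbl <- remap_columns(tbl, col_map)
  require_columns(tbl, c("probe_id", "gene_id", "e_value", "identity_pct",
                         "overlap_pct"))
  tbl
}

#' Read a subcellular location table
#'
#' Tab-separated with header: `protein_id`, `compartment`.
#'
#' @inheritParams read_probes
#' @return A tibble of location labels.
#' @export
read_locations <- function(path, col_map = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         comment = "#")
  tbl <- remap_columns(tbl, col_map)
  require_columns(tbl, c("protein_id", "compartment"))
  tbl
}

remap_columns <- function(tbl, col_map) {
  if (is.null(col_map)) return(tbl)
  for (new in names(col_map)) {
    old <- col_map[[new]]
    if (!old %in% names(tbl)) {
      abort(sprintf("Column `%s` not found in file.", old))
    }
    names(tbl)[names(tbl) == old] <- new
  }
  tbl
}

#' Read a protein FASTA into a gene/protein table
#'
#' The gene identifier is derived from the record name by stripping the
#' isoform suffix with `gene_pattern` (default: a trailing dot and digits,
#' which fits both TAIR-style `AT1G01010.1` and the synthetic `G00001.2`
#' identifiers).
#'
#' @param path Path to a FASTA file of protein sequences.
#' @param gene_pattern Regular expression removed from the record name to
#'   obtain the gene id.
#' @return A tibble `gene_id`, `protein_id`, `sequence`.
#' @export
read_proteins_fasta <- function(path, gene_pattern = "\\.\\d+$") {
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  tibble(
    gene_id = sub(gene_pattern, "", ids),
    protein_id = ids,
    sequence = as.character(aas)
  )
}

#' Read a CDS FASTA into a gene table
#'
#' @param path Path to a FASTA file of coding sequences named by gene.
#' @return A tibble `gene_id`, `sequence`.
#' @export
read_cds_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  tibble(
    gene_id = sub("\\s.*$", "", names(dna)),
    sequence = as.character(dna)
  )
}

#' Write a synthetic dataset to disk
#'
#' Writes `proteins.fasta`, `cds.fasta`, `probes.tsv`, `hits.tsv`,
#' `locations.tsv` and `truth.json` (generator parameters plus the
#' realized per-gene true response) into a directory.
#'
#' @param dataset A dataset from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "heataa_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prot <- Biostrings::AAStringSet(setNames(dataset$proteins$sequence,
                                           dataset$proteins$protein_id))
  Biostrings::writeXStringSet(prot, file.path(dir, "proteins.fasta"))
  cds <- Biostrings::DNAStringSet(setNames(dataset$cds$sequence,
                                           dataset$cds$gene_id))
  Biostrings::writeXStringSet(cds, file.path(dir, "cds.fasta"))
  readr::write_tsv(dataset$probe_table, file.path(dir, "probes.tsv"),
                   progress = FALSE)
  readr::write_tsv(dataset$hit_table, file.path(dir, "hits.tsv"),
                   progress = FALSE)
  readr::write_tsv(dataset$locations, file.path(dir, "locations.tsv"),
                   progress = FALSE)
  truth <- unclass(dataset$truth)
  truth$per_gene <- dataset$genes
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Build a small packaged synthetic dataset
#'
#' Convenience wrapper producing a complete on-disk dataset at one of three
#' scales: `tiny` (50 genes), `small` (500) or `default` (5000).
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param scale One of `"tiny"`, `"small"`, `"default"`.
#' @param ... Further overrides passed to [synthetic_truth()].
#' @return The dataset (invisibly), after writing it to `dir`.
#' @export
make_fixture <- function(dir, seed = 1L, scale = c("tiny", "small",
                                                   "default"), ...) {
  scale <- match.arg(scale)
  n_genes <- c(tiny = 50L, small = 500L, default = 5000L)[[scale]]
  dataset <- simulate_dataset(synthetic_truth(seed = seed,
                                              n_genes = n_genes, ...))
  write_dataset(dataset, dir)
  invisible(dataset)
}

#' Pipeline configuration
#'
#' Collects the input sources and analysis parameters of a full run. Input
#' entries may be file paths or in-memory data frames.
#'
#' @param probes,hits,proteins Required inputs: probe table, hit table and
#'   protein FASTA (paths or data frames).
#' @param cds,gc,locations,matrix Optional inputs: coding sequences for GC,
#'   a precomputed GC table, subcellular locations, and an energy-matrix
#'   TSV.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param r_thresholds Category thresholds for [classify_genes()].
#' @param disorder_threshold,disorder_window Disorder-call parameters
#'   (strict threshold 0.4; 30-residue window).
#' @param quality_scope `"all"` or `"any"`, see [filter_probes()].
#' @param averaging_scale `"linear"` or `"log2"`, see
#'   [aggregate_expression()].
#' @param gene_pattern Isoform-suffix pattern, see [read_proteins_fasta()].
#' @param seed Integer recorded into every output.
#' @return A list of class `heataa_config`.
#' @export
pipeline_config <- function(probes, hits, proteins, cds = NULL, gc = NULL,
                            locations = NULL, matrix = NULL, out_dir = NULL,
                            r_thresholds = c(induced = 0, strong = 1,
                                             strong2 = 2, strong_rep2 = -2),
                            disorder_threshold = 0.4,
                            disorder_window = 30L,
                            quality_scope = c("all", "any"),
                            averaging_scale = c("linear", "log2"),
                            gene_pattern = "\\.\\d+$",
                            seed = 1L) {
  config <- list(
    probes = probes, hits = hits, proteins = proteins, cds = cds, gc = gc,
    locations = locations, matrix = matrix, out_dir = out_dir,
    r_thresholds = r_thresholds,
    disorder_threshold = disorder_threshold,
    disorder_window = as.integer(disorder_window),
    quality_scope = match.arg(quality_scope),
    averaging_scale = match.arg(averaging_scale),
    gene_pattern = gene_pattern,
    seed = as.integer(seed)
  )
  for (nm in c("probes", "hits", "proteins", "cds", "gc", "locations",
               "matrix")) {
    x <- config[[nm]]
    if (is.character(x) && length(x) == 1 && !file.exists(x)) {
      abort(sprintf("Input file for `%s` does not exist: %s", nm, x))
    }
  }
  structure(config, class = "heataa_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' Only path-based (not in-memory) inputs can be serialized. `load_config`
#' restores a configuration such that `load_config(save_config(c)) = c`.
#'
#' @param config A [pipeline_config()] object.
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns
#'   the configuration.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "heataa_config"))
  plain <- unclass(config)
  if (any(vapply(plain, is.data.frame, logical(1)))) {
    abort("In-memory data-frame inputs cannot be saved to YAML.")
  }
  # yaml serializes named atomic vectors as plain sequences; keep the names
  plain$r_thresholds <- as.list(plain$r_thresholds)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  plain <- yaml::read_yaml(path)
  plain <- plain[!vapply(plain, is.null, logical(1))]
  if (!is.null(plain$r_thresholds)) {
    plain$r_thresholds <- unlist(plain$r_thresholds)
  }
  do.call(pipeline_config, plain)
}

resolve_input <- function(x, reader, ...) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(as_tibble(x))
  reader(x, ...)
}

#' Run the full analysis pipeline
#'
#' Executes expression processing, sequence feature extraction, disorder
#' prediction and the statistical battery end to end, optionally writing
#' every result table (stamped with the configuration hash and seed) into
#' the configured output directory. Without a location input, the
#' compartment-stratified battery is skipped with a warning; everything
#' else still runs.
#'
#' @param config A [pipeline_config()] object.
#' @return A list of class `heataa_run` with elements `gene_response`,
#'   `features`, `disorder`, `associations`, `groups_lenient`,
#'   `groups_strict` (NULL when a strict group is empty), `compartments`
#'   (NULL without locations), `summary` and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "heataa_config"))
  probes <- resolve_input(config$probes, read_probes)
  hits <- resolve_input(config$hits, read_hits)
  proteins <- resolve_input(config$proteins, read_proteins_fasta,
                            gene_pattern = config$gene_pattern)
  cds <- resolve_input(config$cds, read_cds_fasta)
  gc <- resolve_input(config$gc, function(p) {
    readr::read_tsv(p, col_types = readr::cols(), progress = FALSE)
  })
  locations <- resolve_input(config$locations, read_locations)
  matrix <- if (is.null(config$matrix)) default_energy_matrix()
            else if (is.matrix(config$matrix)) check_energy_matrix(config$matrix)
            else read_energy_matrix(config$matrix)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage [%s] failed: %s", name, conditionMessage(e)))
    })
  }

  gene_response <- stage("expression_processing", {
    n_in <- length(unique(probes$probe_id[!probes$is_control]))
    gr <- gene_responses(probes, hits, scope = config$quality_scope,
                         scale = config$averaging_scale,
                         thresholds = config$r_thresholds)
    message(sprintf(
      "expression_processing: %d measured probes -> %d genes with R",
      n_in, nrow(gr)
    ))
    gr
  })
  features <- stage("sequence_features", {
    ft <- composition_profiles(proteins, cds = cds, gc = gc,
                               locations = locations)
    message(sprintf("sequence_features: %d genes profiled", nrow(ft)))
    ft
  })
  disorder <- stage("disorder_prediction", {
    longest <- features |> select("gene_id", "protein_id")
    seqs <- select_longest_isoform(proteins) |>
      inner_join(longest, by = c("gene_id", "protein_id"))
    dp <- disorder_profiles(seqs, matrix = matrix,
                            window = config$disorder_window,
                            threshold = config$disorder_threshold)
    message(sprintf("disorder_prediction: %d proteins scored", nrow(dp)))
    dp
  })
  features <- features |>
    left_join(disorder |>
                select("protein_id", disorder_frac = "disordered_fraction"),
              by = "protein_id")

  associations <- stage("association_stats", {
    controls <- c("none",
                  if (!all(is.na(features$gc))) "gc",
                  "e24_22", "e24_37")
    association_battery(features, gene_response, controls = controls)
  })
  groups_lenient <- stage("association_stats", {
    group_comparison(features, gene_response, cutoffs = c(0, 0))
  })
  groups_strict <- tryCatch(
    group_comparison(features, gene_response, cutoffs = c(2, -2)),
    error = function(e) {
      warn(sprintf("Strict group comparison skipped: %s",
                   conditionMessage(e)))
      NULL
    }
  )
  compartments <- if (is.null(locations)) {
    warn("No location input: compartment-stratified battery skipped.")
    NULL
  } else {
    stage("association_stats", {
      compartment_battery(features, gene_response, locations)
    })
  }

  cls <- classify_genes(gene_response$r, config$r_thresholds)
  summary <- list(
    n_genes = nrow(gene_response),
    n_induced = sum(cls$induced),
    n_repressed = sum(cls$repressed),
    n_zero = sum(cls$zero),
    n_strong_induced = sum(cls$strong_induced),
    n_strong_induced_2 = sum(cls$strong_induced_2),
    n_strong_repressed_2 = sum(cls$strong_repressed_2),
    n_features = nrow(features),
    n_association_rows = nrow(associations),
    n_group_rows_lenient = nrow(groups_lenient),
    n_group_rows_strict = if (is.null(groups_strict)) 0L
                          else nrow(groups_strict),
    n_compartment_rows = if (is.null(compartments)) 0L
                         else nrow(compartments$by_compartment),
    seed = config$seed,
    config_hash = config_hash(config)
  )

  run <- structure(list(
    gene_response = gene_response, features = features, disorder = disorder,
    associations = associations, groups_lenient = groups_lenient,
    groups_strict = groups_strict, compartments = compartments,
    summary = summary, config = config
  ), class = "heataa_run")

  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

config_hash <- function(config) {
  plain <- unclass(config)
  plain$out_dir <- NULL
  rlang::hash(plain)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config_hash=%s seed=%d",
                   run$summary$config_hash, run$summary$seed)
  emit <- function(tbl, file) {
    path <- file.path(dir, file)
    writeLines(stamp, path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  emit(run$gene_response, "gene_response.tsv")
  emit(run$features |> select(-any_of("sequence")), "features.tsv")
  emit(run$disorder, "disorder.tsv")
  emit(run$associations, "table1.tsv")
  emit(run$groups_lenient, "table2.tsv")
  if (!is.null(run$groups_strict)) emit(run$groups_strict, "table3.tsv")
  if (!is.null(run$compartments)) {
    emit(run$compartments$by_compartment, "table5.tsv")
    emit(run$compartments$sign_tests, "table5_signs.tsv")
  }
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.heataa_run <- function(x, ...) {
  s <- x$summary
  cat("Heat-response analysis run\n")
  cat(sprintf("  genes with R: %d (induced %d, repressed %d, zero %d)\n",
              s$n_genes, s$n_induced, s$n_repressed, s$n_zero))
  cat(sprintf("  strong: R>1 %d, R>2 %d, R<-2 %d\n", s$n_strong_induced,
              s$n_strong_induced_2, s$n_strong_repressed_2))
  cat(sprintf("  features: %d genes; association rows: %d\n",
              s$n_features, s$n_association_rows))
  cat(sprintf("  seed %d, config %s\n", s$seed, s$config_hash))
  invisible(x)
}
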