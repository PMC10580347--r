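#' Assemble a screening-pipeline configuration
#'
#' Collects input paths and the analysis constants into a validated config
#' for [run_screen_pipeline()]. Thresholds default to the screen's fixed
#' constants: selection by negative distance, expression gates at
#' `alpha = 0.05` and `|d| > 0.8`, landscape temperature 310 K.
#'
#' @param network Path to the PPI edge-list TSV.
#' @param disease_genes Path to the disease gene list (one symbol per line).
#' @param drug_targets Path to the drug-target TSV (`drug_id<TAB>target`).
#' @param energy Optional path to an MM-PBSA component TSV keyed by
#'   `complex_id` (matched to `drug_id`).
#' @param descriptors Optional path to a compound-descriptor TSV keyed by
#'   `compound_id` (matched to `drug_id`).
#' @param expression,sample_sheet Optional paths to an expression TSV and
#'   its sample sheet; when given, each drug is annotated with how many of
#'   its targets pass the differential-expression gate.
#' @param n_samples Reference draws per mapped-target count (0 = skip the
#'   reference distribution).
#' @param seed Integer seed, recorded in the run manifest.
#' @param alpha,d_threshold Expression-screen gates.
#' @param fel_bins,temperature_K Free-energy-landscape grid and temperature.
#' @param out_dir Output directory (created if needed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(network, disease_genes, drug_targets,
                            energy = NULL, descriptors = NULL,
                            expression = NULL, sample_sheet = NULL,
                            n_samples = 1000L, seed = 1L,
                            alpha = 0.05, d_threshold = 0.8,
                            fel_bins = 50L, temperature_K = 310,
                            out_dir = tempfile("proxidyn_run_")) {
  cfg <- list(network = network, disease_genes = disease_genes,
              drug_targets = drug_targets, energy = energy,
              descriptors = descriptors, expression = expression,
              sample_sheet = sample_sheet,
              n_samples = as.integer(n_samples), seed = as.integer(seed),
              alpha = alpha, d_threshold = d_threshold,
              fel_bins = as.integer(fel_bins), temperature_K = temperature_K,
              out_dir = out_dir)
  stopifnot(is.finite(cfg$alpha), is.finite(cfg$d_threshold),
            cfg$n_samples >= 0L, cfg$fel_bins >= 2L)
  for (p in c("network", "disease_genes", "drug_targets")) {
    if (!file.exists(cfg[[p]])) stop("input not found: ", cfg[[p]],
                                     call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the screen-rank-annotate-report pipeline
#'
#' Executes the network-proximity screen, joins optional binding-energy,
#' drug-likeness and differential-expression annotations by drug id, and
#' writes a ranked candidate table (`candidates.tsv`) plus a machine-readable
#' run manifest (`manifest.json`, with seed, thresholds, input digests and
#' per-stage row counts) to the output directory. The output is a pure
#' function of inputs, config and seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return The ranked candidate tibble, invisibly; the paths written are in
#'   `attr(, "paths")`.
#' @export
run_screen_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  net <- read_network_tsv(config$network, quiet = quiet)
  disease <- read_gene_set(config$disease_genes)
  dt <- utils::read.delim(config$drug_targets, header = TRUE,
                          check.names = FALSE)
  say("screen: %d drug-target pairs, %d disease genes",
      nrow(dt), length(disease))

  scr <- proximity_screen(net, disease, dt, n_samples = config$n_samples,
                          seed = config$seed)
  report <- tidy(scr)
  counts <- list(drugs_scored = nrow(report),
                 drugs_unscored = nrow(scr$unscored),
                 drugs_selected = sum(report$selected))
  if (config$n_samples == 0L) {
    report <- dplyr::select(report, -dplyr::all_of(c("ref_mean", "ref_sd",
                                                     "z")))
  }

  if (!is.null(config$energy)) {
    en <- aggregate_binding_energy(read_energy_tsv(config$energy))
    en <- dplyr::rename(en, drug_id = "complex_id")
    n_match <- sum(report$drug_id %in% en$drug_id)
    if (n_match < nrow(en)) {
      warning(sprintf("%d energy row(s) had no matching drug_id",
                      nrow(en) - n_match), call. = FALSE)
    }
    report <- dplyr::left_join(report, en, by = "drug_id")
    counts$energy_rows_joined <- n_match
    say("energy: %d of %d complexes joined", n_match, nrow(en))
  }
  if (!is.null(config$descriptors)) {
    desc <- lipinski_ro5(tibble::as_tibble(
      utils::read.delim(config$descriptors, check.names = FALSE)))
    desc <- dplyr::rename(desc, drug_id = "compound_id")
    n_match <- sum(report$drug_id %in% desc$drug_id)
    if (n_match < nrow(desc)) {
      warning(sprintf("%d descriptor row(s) had no matching drug_id",
                      nrow(desc) - n_match), call. = FALSE)
    }
    report <- dplyr::left_join(report, desc, by = "drug_id")
    counts$descriptor_rows_joined <- n_match
    say("descriptors: %d of %d compounds joined", n_match, nrow(desc))
  }
  if (!is.null(config$expression)) {
    mat <- read_expression_tsv(config$expression, config$sample_sheet)
    ex <- expression_screen(mat, alpha = config$alpha,
                            d_threshold = config$d_threshold)
    de_genes <- tidy(ex)$gene[tidy(ex)$selected]
    by_drug <- split(dt[[2]], dt[[1]])
    report$n_targets_de <- vapply(report$drug_id, function(d) {
      sum(unique(by_drug[[d]]) %in% de_genes)
    }, integer(1), USE.NAMES = FALSE)
    counts$expression_genes_selected <- length(de_genes)
    say("expression: %d gene(s) pass p < %g and |d| > %g",
        length(de_genes), config$alpha, config$d_threshold)
  }

  if (nrow(report) == 0L) stop("empty final candidate table", call. = FALSE)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(config$out_dir, "candidates.tsv")
  man <- file.path(config$out_dir, "manifest.json")
  utils::write.table(as.data.frame(report), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  inputs <- purrr::compact(config[c("network", "disease_genes",
                                    "drug_targets", "energy", "descriptors",
                                    "expression", "sample_sheet")])
  jsonlite::write_json(
    list(seed = config$seed, n_samples = config$n_samples,
         alpha = config$alpha, d_threshold = config$d_threshold,
         inputs = lapply(inputs, function(p)
           list(path = p, md5 = unname(tools::md5sum(p)))),
         row_counts = counts),
    man, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote %s and %s", tsv, man)
  attr(report, "paths") <- c(candidates = tsv, manifest = man)
  invisible(report)
}
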