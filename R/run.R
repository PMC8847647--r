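# End-to-end orchestration used by both the R interface and the `lta`
# command-line script: one call runs load -> binarise -> classify -> overlap
# stats -> tables + figures, with a manifest recording the configuration.

#' Run a full switch analysis
#'
#' Loads (or accepts) the abundance table and tissue network, binarises
#' presence at `threshold`, classifies U/A/B per group, computes
#' Jaccard-Tanimoto overlap statistics for every scope, and writes
#' classification CSVs, an overlap CSV, the network pie-map SVG, a wiring
#' diagram of the A-type union, and a JSON run manifest into `output_dir`.
#' Outputs are deterministic for a fixed seed.
#'
#' @param dataset a [lipidomics_dataset()] or a file path readable by
#'   [load_lipidomics_table()].
#' @param network a [tissue_network()] or a YAML config path; `NULL` uses
#'   [default_tissue_network()].
#' @param output_dir directory for result files, created if needed.
#' @param threshold presence threshold (default 0.66).
#' @param control_group which group label is the control; defaults to the
#'   alphabetically first label. Sets the fold-change sign convention and
#'   figure colour order (control first).
#' @param parts which switch categories to tabulate (any of "U", "A", "B");
#'   overlap statistics and figures always cover the computed parts only.
#' @param lipid_class optional lipid class filter for the overlap table and
#'   figures (classification tables always cover all variables).
#' @param method,n_resamples,seed forwarded to [jaccard_pvalue()].
#' @param schema forwarded to [load_lipidomics_table()] when `dataset` is a
#'   path.
#' @return invisibly, a list with `classification`, `overlaps`, `enfc`,
#'   and `files` (paths written).
#' @export
run_switch <- function(dataset, network = NULL, output_dir = "lta_results",
                       threshold = 0.66, control_group = NULL,
                       parts = c("U", "A", "B"), lipid_class = NULL,
                       method = "auto", n_resamples = 10000L, seed = 1L,
                       schema = c(sample_id = "sample_id",
                                  compartment = "compartment",
                                  group = "group")) {
  if (is.character(network)) network <- load_network_config(network)
  if (is.null(network)) network <- default_tissue_network()
  if (is.character(dataset)) {
    dataset <- load_lipidomics_table(dataset, schema = schema)
  }
  stopifnot(inherits(dataset, "lipidomics_dataset"))
  groups <- check_two_groups(dataset)
  if (is.null(control_group)) control_group <- groups[1L]
  if (!control_group %in% groups) {
    stop("control group ", sQuote(control_group), " not among: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  parts <- match.arg(parts, several.ok = TRUE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  profile <- binarize(dataset, threshold = threshold)
  classification <- classify_switch(profile, network)
  overlaps <- overlap_table(classification, lipid_class = lipid_class,
                            method = method, n_resamples = n_resamples,
                            seed = seed)
  overlaps <- overlaps[overlaps$category %in% parts, , drop = FALSE]
  enfc_res <- enfc_table(dataset, control_group = control_group)

  files <- write_switch_tables(classification, output_dir, parts = parts)
  f_overlap <- file.path(output_dir, "overlap_stats.csv")
  utils::write.csv(overlaps, f_overlap, row.names = FALSE, quote = TRUE,
                   eol = "\r\n")
  f_enfc <- file.path(output_dir, "enfc.csv")
  utils::write.csv(enfc_res, f_enfc, row.names = FALSE, quote = TRUE,
                   eol = "\r\n")

  colour_order <- if (control_group == groups[1L]) c(1L, 2L) else c(2L, 1L)
  fig <- build_switch_figure(classification, overlaps,
                             lipid_class = lipid_class,
                             colours = .default_colours[colour_order])
  f_map <- file.path(output_dir, "switch_map.svg")
  render_switch_figure(fig, f_map)
  a_union <- union(classification$groups[[1L]]$A_list,
                   classification$groups[[2L]]$A_list)
  f_wiring <- NULL
  if (length(a_union) > 0L) {
    wd <- build_wiring_diagram(classification, a_union,
                               colours = .default_colours[colour_order])
    f_wiring <- file.path(output_dir, "wiring_A.svg")
    render_wiring_diagram(wd, f_wiring)
  }

  f_manifest <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(
    list(tool = "lipidtraffic",
         version = as.character(utils::packageVersion("lipidtraffic")),
         threshold = threshold, control_group = control_group,
         groups = groups, parts = parts,
         lipid_class = lipid_class, method = method,
         n_resamples = n_resamples, seed = seed,
         compartments = network$compartments,
         n_samples = nrow(dataset$abundance),
         n_variables = ncol(dataset$abundance)),
    f_manifest, auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(classification = classification, overlaps = overlaps,
                 enfc = enfc_res,
                 files = c(files, f_overlap, f_enfc, f_map, f_wiring,
                           f_manifest)))
}

#' Generate a synthetic study, analyse it and score the recovery
#'
#' Runs [generate_study()], writes the dataset and its planted truth as
#' CSVs, classifies the study at `threshold`, and reports planted-vs-
#' recovered confusion through [truth_recovery_report()].
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @param output_dir directory for dataset/truth/report files; `NULL` skips
#'   writing.
#' @param threshold presence threshold for the recovery classification.
#' @return invisibly, a list with `dataset`, `truth`, `classification` and
#'   `report`.
#' @export
run_simulate <- function(config = synthetic_config(), seed,
                         output_dir = NULL, threshold = 0.66) {
  study <- generate_study(config, seed = seed)
  profile <- binarize(study$dataset, threshold = threshold)
  classification <- classify_switch(profile, config$network)
  report <- truth_recovery_report(study$truth, classification)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_lipidomics_table(study$dataset,
                           file.path(output_dir, "synthetic_dataset.csv"))
    write_truth_table(study$truth,
                      file.path(output_dir, "synthetic_truth.csv"))
    utils::write.csv(as.data.frame(report$confusion),
                     file.path(output_dir, "recovery_confusion.csv"),
                     row.names = FALSE, quote = TRUE, eol = "\r\n")
    jsonlite::write_json(
      list(seed = as.integer(seed), threshold = threshold,
           recovery_rate = report$recovery_rate,
           presence_call_accuracy = report$presence_call_accuracy),
      file.path(output_dir, "recovery_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(list(dataset = study$dataset, truth = study$truth,
                 classification = classification, report = report))
}
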