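# Tabular study data: samples x lipid variables with compartment and group
# annotation. Wide CSV/TSV (samples in rows) is the canonical layout.

#' Construct a lipidomics dataset
#'
#' @param samples data frame with columns `sample_id`, `compartment`, `group`.
#' @param abundance numeric matrix, samples x variables, non-negative; row
#'   order must match `samples`, column names are shorthand lipid names.
#' @param mode optional character vector (one per variable) of ionisation-mode
#'   tags, e.g. "positive"/"negative".
#' @return An object of class `lipidomics_dataset`: a list with elements
#'   `samples`, `variables` (parsed [lipid_species][parse_lipid_name]),
#'   `abundance` and `mode`.
#' @export
lipidomics_dataset <- function(samples, abundance, mode = NULL) {
  problems <- character()
  need <- c("sample_id", "compartment", "group")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    stop("'samples' must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  samples <- samples[need]
  for (col in need) samples[[col]] <- as.character(samples[[col]])
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (anyDuplicated(samples$sample_id)) {
    problems <- c(problems, paste("duplicate sample ids:",
      paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
            collapse = ", ")))
  }
  if (anyNA(samples)) {
    problems <- c(problems, "missing sample annotation (NA) in samples table")
  }
  if (nrow(abundance) != nrow(samples)) {
    problems <- c(problems, "abundance rows do not match sample table")
  }
  if (is.null(colnames(abundance)) || any(!nzchar(colnames(abundance)))) {
    problems <- c(problems, "abundance matrix must have lipid-name columns")
  } else if (anyDuplicated(colnames(abundance))) {
    problems <- c(problems, paste("duplicate variable columns:",
      paste(unique(colnames(abundance)[duplicated(colnames(abundance))]),
            collapse = ", ")))
  }
  n_na <- sum(is.na(abundance))
  if (n_na > 0L) {
    warning(n_na, " missing abundance value(s) coerced to 0 (not detected)",
            call. = FALSE)
    abundance[is.na(abundance)] <- 0
  }
  if (any(abundance < 0)) {
    problems <- c(problems,
                  paste(sum(abundance < 0), "negative abundance value(s)"))
  }
  if (length(unique(samples$compartment)) < 2L) {
    problems <- c(problems, "at least 2 compartments are required")
  }
  if (length(problems) > 0L) {
    stop("invalid lipidomics dataset:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  rownames(abundance) <- samples$sample_id
  if (!is.null(mode) && length(mode) != ncol(abundance)) {
    stop("'mode' must have one entry per variable", call. = FALSE)
  }
  structure(
    list(samples = samples,
         variables = parse_lipid_name(colnames(abundance)),
         abundance = abundance,
         mode = mode),
    class = "lipidomics_dataset"
  )
}

#' @export
print.lipidomics_dataset <- function(x, ...) {
  cat("Lipidomics dataset:", nrow(x$abundance), "samples x",
      ncol(x$abundance), "lipid variables\n")
  cat("  compartments:", paste(sort(unique(x$samples$compartment)),
                               collapse = ", "), "\n")
  cat("  groups:      ", paste(sort(unique(x$samples$group)),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Read a lipidomics abundance table
#'
#' Reads a delimiter-separated table with one header row. Three columns hold
#' the sample annotation (named through `schema`); every remaining column is
#' taken to be a lipid variable in shorthand nomenclature. Missing cells and
#' explicit `NA` are coerced to 0 (not detected) with a warning counting the
#' coercions, because downstream presence calls are defined on signal > 0.
#'
#' @param path file path (CSV by default; `sep = "\t"` for TSV).
#' @param schema named character vector mapping the roles `sample_id`,
#'   `compartment` and `group` to column names in the file.
#' @param sep field delimiter.
#' @param transposed if `TRUE` the file stores variables in rows and samples
#'   in columns; the annotation columns then refer to the transposed table.
#' @return a validated [lipidomics_dataset()].
#' @export
load_lipidomics_table <- function(path,
                                  schema = c(sample_id = "sample_id",
                                             compartment = "compartment",
                                             group = "group"),
                                  sep = ",", transposed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  need <- c("sample_id", "compartment", "group")
  if (!all(need %in% names(schema))) {
    stop("'schema' must name the columns for: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (transposed) {
    ids <- raw[[1L]]
    raw <- as.data.frame(t(raw[-1L]), stringsAsFactors = FALSE)
    names(raw) <- ids
    raw <- cbind(data.frame(..row = rownames(raw), stringsAsFactors = FALSE),
                 raw)
    names(raw)[1L] <- schema[["sample_id"]]
    rownames(raw) <- NULL
    for (v in setdiff(names(raw), unname(schema))) {
      raw[[v]] <- as.numeric(raw[[v]])
    }
  }
  missing_cols <- setdiff(unname(schema[need]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing schema column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ann <- data.frame(sample_id = raw[[schema[["sample_id"]]]],
                    compartment = raw[[schema[["compartment"]]]],
                    group = raw[[schema[["group"]]]],
                    stringsAsFactors = FALSE)
  value_cols <- setdiff(names(raw), unname(schema[need]))
  if (length(value_cols) == 0L) {
    stop("no lipid variable columns found in ", path, call. = FALSE)
  }
  abundance <- as.matrix(raw[value_cols])
  lipidomics_dataset(ann, abundance)
}

#' Write a lipidomics dataset as CSV
#'
#' Emits the wide layout [load_lipidomics_table()] reads: annotation columns
#' `sample_id`, `compartment`, `group` followed by one column per variable.
#' Output is RFC-4180 CSV; a write/load round trip reproduces the abundance
#' matrix bit for bit.
#'
#' @param dataset a [lipidomics_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lipidomics_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "lipidomics_dataset"))
  # 17 significant digits guarantee an exact double round trip
  num <- as.data.frame(apply(dataset$abundance, 2, sprintf,
                             fmt = "%.17g", simplify = FALSE),
                       check.names = FALSE, optional = TRUE)
  df <- cbind(dataset$samples, num)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\r\n")
  invisible(path)
}

# Two-group contract shared by the switch pipeline and the CLI.
check_two_groups <- function(dataset) {
  groups <- sort(unique(dataset$samples$group))
  if (length(groups) != 2L) {
    stop("a switch analysis run requires exactly 2 groups; found ",
         length(groups), " (", paste(groups, collapse = ", "), ")",
         call. = FALSE)
  }
  groups
}
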