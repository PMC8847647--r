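# Switch analysis: binarise presence per group x compartment, then classify
# every lipid variable on the tissue network as U-type (unique to one
# compartment), A-type (present in every compartment) or B-type (present in
# both endpoints of an edge), independently per phenotype group.

#' Fraction of samples with detectable signal
#'
#' @param values numeric vector of non-negative signal intensities; 0 means
#'   not detected.
#' @return proportion of entries strictly greater than 0.
#' @examples
#' presence_fraction(c(1.2, 0, 3.4, 5.0))  # 0.75
#' @export
presence_fraction <- function(values) {
  if (length(values) == 0L) stop("empty signal sequence", call. = FALSE)
  if (anyNA(values) || any(values < 0)) {
    stop("signals must be non-negative and non-missing", call. = FALSE)
  }
  sum(values > 0) / length(values)
}

# Presence call robust to the binary representation of thresholds such as
# 0.66: a fraction within 1e-9 of the threshold counts as reaching it.
.present_at <- function(fraction, threshold) {
  fraction >= threshold | abs(fraction - threshold) < 1e-9
}

#' Binarise a dataset into per-group presence calls
#'
#' For every (group, compartment, variable) cell the presence fraction *B* is
#' the proportion of that group's samples in that compartment with signal
#' > 0. A variable is called present when *B* >= `threshold` (closed bound:
#' *B* exactly at the threshold is present). The default threshold of 0.66
#' means "signal in at least 66% of samples per group".
#'
#' @param dataset a [lipidomics_dataset()].
#' @param threshold presence threshold in (0, 1]; a threshold of 0 degenerates
#'   to "any nonzero sample" and is accepted.
#' @return object of class `presence_profile`: a list with `fractions`
#'   (long data frame: group, compartment, variable, B_fraction, present),
#'   `present` (per group, a logical compartments x variables matrix),
#'   `groups`, `compartments`, `variables` and `threshold`.
#' @export
binarize <- function(dataset, threshold = 0.66) {
  stopifnot(inherits(dataset, "lipidomics_dataset"))
  if (threshold < 0 || threshold > 1) {
    stop("'threshold' must lie in [0, 1]", call. = FALSE)
  }
  groups <- sort(unique(dataset$samples$group))
  compartments <- sort(unique(dataset$samples$compartment))
  vars <- colnames(dataset$abundance)

  cells <- expand.grid(compartment = compartments, group = groups,
                       stringsAsFactors = FALSE)
  counts <- table(dataset$samples$group, dataset$samples$compartment)
  empty <- counts[cbind(cells$group, cells$compartment)] == 0L
  if (any(empty)) {
    stop("no samples for group x compartment cell(s): ",
         paste(cells$group[empty], cells$compartment[empty], sep = "/",
               collapse = ", "), call. = FALSE)
  }

  present <- list()
  rows <- vector("list", length(groups) * length(compartments))
  i <- 0L
  for (g in groups) {
    mat <- matrix(FALSE, nrow = length(compartments), ncol = length(vars),
                  dimnames = list(compartments, vars))
    for (cmp in compartments) {
      sel <- dataset$samples$group == g & dataset$samples$compartment == cmp
      frac <- colSums(dataset$abundance[sel, , drop = FALSE] > 0) / sum(sel)
      mat[cmp, ] <- .present_at(frac, threshold)
      i <- i + 1L
      rows[[i]] <- data.frame(group = g, compartment = cmp, variable = vars,
                              B_fraction = unname(frac),
                              present = unname(mat[cmp, ]),
                              stringsAsFactors = FALSE)
    }
    present[[g]] <- mat
  }
  structure(list(fractions = do.call(rbind, rows), present = present,
                 groups = groups, compartments = compartments,
                 variables = dataset$variables, threshold = threshold),
            class = "presence_profile")
}

# Primary category label of one presence pattern on the network:
# "absent", "U@<compartment>", "A", "B@<edge>" (present in exactly the two
# endpoints of an edge) or "multi" (any other multi-compartment pattern,
# including non-adjacent pairs). Used for traceability and truth recovery.
category_label <- function(present_in, network) {
  k <- length(present_in)
  if (k == 0L) return("absent")
  if (k == 1L) return(paste0("U@", present_in))
  if (k == length(network$compartments)) return("A")
  if (k == 2L) {
    key <- edge_key(present_in[1L], present_in[2L])
    if (key %in% edge_key(network$edges$from, network$edges$to)) {
      return(paste0("B@", key))
    }
  }
  "multi"
}

#' Classify lipid variables as U-, A- or B-type on the network
#'
#' Computed independently for each group from its presence calls:
#' * **U-lists** (one per compartment): variables present in that compartment
#'   and in no other;
#' * **A-list**: variables present in every compartment of the network;
#' * **B-lists** (one per network edge): variables present in both endpoint
#'   compartments, irrespective of presence elsewhere — so the A-list is a
#'   subset of every B-list, matching how edge counts are read on network
#'   pie maps.
#'
#' Variables present nowhere are reported in `not_detected`, never silently
#' dropped. A per-variable `record` table keeps the full presence pattern and
#' a primary category label for traceability (variables spread over a
#' non-adjacent set of compartments are labelled `multi` there).
#'
#' @param profile a [binarize()] result.
#' @param network a [tissue_network()] whose compartments match the profile.
#' @return object of class `switch_classification`: per group a list with
#'   `U_lists`, `A_list`, `B_lists`, `not_detected` and `record`; plus the
#'   shared `network`, `variables` and `threshold`.
#' @export
classify_switch <- function(profile, network) {
  stopifnot(inherits(profile, "presence_profile"),
            inherits(network, "tissue_network"))
  if (!setequal(profile$compartments, network$compartments)) {
    stop("profile compartments do not match the network: profile has {",
         paste(profile$compartments, collapse = ", "), "}, network has {",
         paste(network$compartments, collapse = ", "), "}", call. = FALSE)
  }
  ekeys <- edge_key(network$edges$from, network$edges$to)
  per_group <- lapply(profile$groups, function(g) {
    mat <- profile$present[[g]][network$compartments, , drop = FALSE]
    n_present <- colSums(mat)
    vars <- colnames(mat)
    U_lists <- lapply(network$compartments, function(cmp) {
      vars[mat[cmp, ] & n_present == 1L]
    })
    names(U_lists) <- network$compartments
    A_list <- vars[n_present == length(network$compartments)]
    B_lists <- lapply(seq_len(nrow(network$edges)), function(i) {
      vars[mat[network$edges$from[i], ] & mat[network$edges$to[i], ]]
    })
    names(B_lists) <- ekeys
    record <- data.frame(
      group = g, variable = vars, n_compartments = unname(n_present),
      compartments = vapply(seq_along(vars), function(j) {
        paste(network$compartments[mat[, j]], collapse = ";")
      }, character(1)),
      category = vapply(seq_along(vars), function(j) {
        category_label(network$compartments[mat[, j]], network)
      }, character(1)),
      stringsAsFactors = FALSE
    )
    list(U_lists = U_lists, A_list = A_list, B_lists = B_lists,
         not_detected = vars[n_present == 0L], record = record)
  })
  names(per_group) <- profile$groups
  structure(list(groups = per_group, network = network,
                 variables = profile$variables,
                 threshold = profile$threshold),
            class = "switch_classification")
}

#' @export
print.switch_classification <- function(x, ...) {
  cat("Switch classification on", length(x$network$compartments),
      "compartments,", nrow(x$variables), "variables\n")
  for (g in names(x$groups)) {
    gg <- x$groups[[g]]
    cat(sprintf("  %s: A = %d, U = %s, not detected = %d\n", g,
                length(gg$A_list),
                paste(vapply(gg$U_lists, length, integer(1)),
                      collapse = "/"),
                length(gg$not_detected)))
  }
  invisible(x)
}

# Pull one scope (category + location, optionally restricted to a lipid
# class) out of one group's classification.
scope_members <- function(classification, group, category,
                          location = NULL, lipid_class = NULL) {
  gg <- classification$groups[[group]]
  if (is.null(gg)) stop("unknown group: ", group, call. = FALSE)
  members <- switch(category,
    U = {
      if (is.null(location)) stop("U scope needs a compartment",
                                  call. = FALSE)
      if (!location %in% names(gg$U_lists)) {
        stop("unknown compartment: ", location, call. = FALSE)
      }
      gg$U_lists[[location]]
    },
    A = gg$A_list,
    B = {
      if (is.null(location)) stop("B scope needs an edge", call. = FALSE)
      if (!location %in% names(gg$B_lists)) {
        stop("unknown edge: ", location, " (known: ",
             paste(names(gg$B_lists), collapse = ", "), ")", call. = FALSE)
      }
      gg$B_lists[[location]]
    },
    stop("category must be one of U, A, B", call. = FALSE)
  )
  if (!is.null(lipid_class)) {
    keep <- classification$variables$raw_name[
      classification$variables$lipid_class %in% lipid_class]
    members <- intersect(members, keep)
  }
  members
}

#' Align the variable lists of the two groups as binary vectors
#'
#' Selects one scope — a category (`"U"`, `"A"` or `"B"`), its location (a
#' compartment for U, an edge key such as `"liver--serum"` for B) and
#' optionally a lipid class — from both groups' classifications, takes the
#' union of the scoped variables, sorts it canonically (lipid class, total
#' carbons, double bonds, raw name) and returns one 0/1 membership vector per
#' group. These aligned vectors are the input to [jaccard_coefficient()] and
#' [jaccard_pvalue()].
#'
#' @param classification a [classify_switch()] result (both groups).
#' @param category `"U"`, `"A"` or `"B"`.
#' @param location compartment (U) or edge key (B); ignored for A.
#' @param lipid_class optional lipid class filter, e.g. `"TG"`.
#' @return list with `variables` (the sorted union), `x` and `y` (binary
#'   integer vectors for the first and second group in sorted group order),
#'   and `groups`.
#' @export
align_binary_lists <- function(classification, category, location = NULL,
                               lipid_class = NULL) {
  stopifnot(inherits(classification, "switch_classification"))
  groups <- names(classification$groups)
  if (length(groups) != 2L) {
    stop("aligned lists require a two-group classification", call. = FALSE)
  }
  lists <- lapply(groups, function(g) {
    scope_members(classification, g, category, location, lipid_class)
  })
  union_vars <- union(lists[[1L]], lists[[2L]])
  if (length(union_vars) == 0L) {
    stop("nothing to compare: scope is empty in both groups", call. = FALSE)
  }
  sp <- classification$variables
  sp <- sp[match(union_vars, sp$raw_name), , drop = FALSE]
  union_vars <- union_vars[lipid_order(sp)]
  list(variables = union_vars,
       x = as.integer(union_vars %in% lists[[1L]]),
       y = as.integer(union_vars %in% lists[[2L]]),
       groups = groups)
}

#' Write switch classification tables as CSV
#'
#' Emits one CSV per category and group (U per compartment, A, B per edge)
#' plus `classification_long.csv`, a combined long-format table of every
#' per-variable record including not-detected variables.
#'
#' @param classification a [classify_switch()] result.
#' @param dir output directory, created if needed.
#' @param parts which categories to write (any of "U", "A", "B").
#' @return character vector of files written, invisibly.
#' @export
write_switch_tables <- function(classification, dir,
                                parts = c("U", "A", "B")) {
  stopifnot(inherits(classification, "switch_classification"))
  parts <- match.arg(parts, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(vars, file) {
    df <- data.frame(variable = vars, stringsAsFactors = FALSE)
    utils::write.csv(df, file, row.names = FALSE, quote = TRUE, eol = "\r\n")
    written <<- c(written, file)
  }
  for (g in names(classification$groups)) {
    gg <- classification$groups[[g]]
    safe_g <- gsub("[^A-Za-z0-9._-]", "_", g)
    if ("U" %in% parts) {
      for (cmp in names(gg$U_lists)) {
        emit(gg$U_lists[[cmp]],
             file.path(dir, sprintf("U_%s_%s.csv", safe_g, cmp)))
      }
    }
    if ("A" %in% parts) {
      emit(gg$A_list, file.path(dir, sprintf("A_%s.csv", safe_g)))
    }
    if ("B" %in% parts) {
      for (e in names(gg$B_lists)) {
        emit(gg$B_lists[[e]],
             file.path(dir, sprintf("B_%s_%s.csv", safe_g, e)))
      }
    }
  }
  long <- do.call(rbind, lapply(classification$groups, `[[`, "record"))
  rownames(long) <- NULL
  f <- file.path(dir, "classification_long.csv")
  utils::write.csv(long, f, row.names = FALSE, quote = TRUE, eol = "\r\n")
  invisible(c(written, f))
}
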