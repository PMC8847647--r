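# Tissue network: compartments (tissues/fluids) as nodes, metabolic adjacency
# as undirected edges, optional terminus annotations (what the compartment
# does with lipid traffic: synthesis, storage, oxidation, structural use).

#' Construct a tissue network
#'
#' @param compartments character vector of compartment labels.
#' @param edges two-column matrix or data frame of adjacent compartment pairs
#'   (undirected; self loops and duplicates are rejected).
#' @param termini optional named character vector annotating the metabolic
#'   role of (some) compartments.
#' @return object of class `tissue_network` with elements `compartments`,
#'   `edges` (data frame `from`/`to`, endpoints sorted within a pair) and
#'   `termini`.
#' @export
tissue_network <- function(compartments, edges, termini = NULL) {
  compartments <- as.character(compartments)
  if (length(compartments) < 2L || anyDuplicated(compartments)) {
    stop("need >= 2 distinct compartments", call. = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) != 2L || nrow(edges) == 0L) {
    stop("'edges' must be a two-column edge list with >= 1 edge",
         call. = FALSE)
  }
  names(edges) <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  unknown <- setdiff(unique(c(edges$from, edges$to)), compartments)
  if (length(unknown) > 0L) {
    stop("edge list references undeclared compartment(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(edges$from == edges$to)) {
    stop("self loops are not allowed", call. = FALSE)
  }
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- unique(edges[order(edges$from, edges$to), , drop = FALSE])
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = compartments)
  if (!igraph::is_connected(g)) {
    stop("tissue network must be connected", call. = FALSE)
  }
  if (!is.null(termini)) {
    termini <- unlist(termini)
    bad <- setdiff(names(termini), compartments)
    if (length(bad) > 0L) {
      stop("termini reference undeclared compartment(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(compartments = compartments, edges = edges,
                 termini = termini),
            class = "tissue_network")
}

#' @export
print.tissue_network <- function(x, ...) {
  cat("Tissue network:", length(x$compartments), "compartments,",
      nrow(x$edges), "edges\n")
  cat(paste0("  ", x$edges$from, " -- ", x$edges$to, collapse = "\n"), "\n")
  invisible(x)
}

# Stable string key for an undirected edge.
edge_key <- function(from, to) {
  paste(pmin(from, to), pmax(from, to), sep = "--")
}

#' Default six-compartment tissue network
#'
#' Serum as the central hub adjacent to liver, heart, vastus (skeletal
#' muscle), adipose and CNS — the compartments through which diet-driven
#' metabolic disease plays out. Termini annotate the dominant traffic role:
#' synthesis (liver), storage (adipose), fatty-acid oxidation (heart, vastus,
#' liver) and structural use (CNS).
#'
#' @return a [tissue_network()].
#' @export
default_tissue_network <- function() {
  hub <- "serum"
  leaves <- c("liver", "heart", "vastus", "adipose", "CNS")
  tissue_network(
    compartments = c(hub, leaves),
    edges = data.frame(from = hub, to = leaves),
    termini = c(liver = "synthesis; fatty acid oxidation",
                CNS = "structural",
                heart = "fatty acid oxidation",
                vastus = "fatty acid oxidation",
                adipose = "storage")
  )
}

#' Read a tissue-network configuration file
#'
#' YAML with a `compartments` sequence, an `edges` sequence of two-element
#' pairs, and an optional `termini` mapping. See
#' `system.file("extdata", "default_network.yaml", package = "lipidtraffic")`
#' for the packaged default.
#'
#' @param path YAML file path.
#' @return a validated [tissue_network()].
#' @export
load_network_config <- function(path) {
  if (!file.exists(path)) stop("network config not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$compartments) || is.null(cfg$edges)) {
    stop("network config needs 'compartments' and 'edges' entries",
         call. = FALSE)
  }
  edges <- do.call(rbind, lapply(cfg$edges, function(e) {
    if (length(e) != 2L) stop("each edge must name exactly 2 compartments",
                              call. = FALSE)
    data.frame(from = e[[1L]], to = e[[2L]], stringsAsFactors = FALSE)
  }))
  tissue_network(unlist(cfg$compartments), edges, termini = cfg$termini)
}

#' Write a tissue network as a YAML configuration
#'
#' @param network a [tissue_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_config <- function(network, path) {
  stopifnot(inherits(network, "tissue_network"))
  cfg <- list(
    compartments = network$compartments,
    edges = lapply(seq_len(nrow(network$edges)), function(i) {
      c(network$edges$from[i], network$edges$to[i])
    })
  )
  if (!is.null(network$termini)) cfg$termini <- as.list(network$termini)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
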