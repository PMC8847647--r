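# Jaccard-Tanimoto coefficient and its significance value for a pair of
# aligned binary lists. The null model holds each group's list size fixed
# and treats positions as exchangeable, under which the intersection size is
# hypergeometric; resampling alternatives are provided.

#' Jaccard-Tanimoto coefficient of two binary vectors
#'
#' `J = |x AND y| / |x OR y|`: 1 for identical lists, 0 for disjoint ones.
#' `J = 0.65` means about two thirds of the pooled variables are shared by
#' both phenotypes.
#'
#' @param x,y equal-length 0/1 (or logical) vectors.
#' @return the coefficient, in `[0, 1]`.
#' @export
jaccard_coefficient <- function(x, y) {
  xy <- check_binary_pair(x, y)
  n_int <- sum(xy$x & xy$y)
  n_uni <- sum(xy$x | xy$y)
  n_int / n_uni
}

check_binary_pair <- function(x, y) {
  x <- as.integer(as.logical(x))
  y <- as.integer(as.logical(y))
  if (length(x) != length(y)) {
    stop("binary vectors must have equal length", call. = FALSE)
  }
  if (length(x) == 0L) stop("empty binary vectors", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("binary vectors must not contain NA",
                                 call. = FALSE)
  if (sum(x) + sum(y) == 0L) {
    stop("J is undefined when both vectors are all zero", call. = FALSE)
  }
  list(x = x, y = y)
}

#' Significance of a Jaccard-Tanimoto coefficient
#'
#' Tests the observed `J` against a null in which each vector keeps its
#' number of ones but the positions are exchangeable (both lists drawn at
#' random from the same pool of variables, with each group's list size held
#' fixed). Under this null the intersection size is hypergeometric, and since
#' `J` is monotone in the intersection, the one-sided significance toward
#' dissimilarity is `P(J_null <= J_obs)` — small values mean the two lists
#' share fewer variables than chance placement would produce. Identical lists
#' give `p = 1`. A two-sided alternative (summing all intersection sizes
#' whose null probability does not exceed that of the observed one) is
#' available.
#'
#' Methods:
#' * `exact` — closed-form hypergeometric enumeration ([stats::phyper()]).
#' * `permutation` — positions of `y` are permuted uniformly; the estimate
#'   includes the observed arrangement (`(1 + hits) / (n_resamples + 1)`).
#' * `bootstrap` — both vectors are redrawn with independent Bernoulli
#'   entries at each vector's observed marginal rate, so list sizes vary
#'   around their observed values; replicates with an empty union are
#'   discarded.
#' * `auto` (default) — exact for vectors up to length 170, else permutation.
#'
#' @param x,y equal-length 0/1 vectors (see [align_binary_lists()]).
#' @param method one of `"auto"`, `"exact"`, `"permutation"`, `"bootstrap"`.
#' @param n_resamples number of resamples for the resampling methods
#'   (minimum 999).
#' @param seed integer seed; mandatory for the resampling methods so results
#'   are reproducible.
#' @param alternative `"less"` (one-sided toward dissimilarity, default) or
#'   `"two.sided"`.
#' @return object of class `overlap_result`: a list with `J`, `p`, `n_union`,
#'   `n_intersection`, `method`, `alternative`, `n_resamples` and `seed`.
#' @examples
#' jaccard_pvalue(c(1, 1, 0, 0), c(0, 0, 1, 1))  # exact: p = 1/6
#' @export
jaccard_pvalue <- function(x, y,
                           method = c("auto", "exact", "permutation",
                                      "bootstrap"),
                           n_resamples = 10000L, seed = NULL,
                           alternative = c("less", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  xy <- check_binary_pair(x, y)
  x <- xy$x; y <- xy$y
  n <- length(x)
  m1 <- sum(x); m2 <- sum(y)
  k_obs <- sum(x & y)
  j_obs <- k_obs / sum(x | y)
  if (method == "auto") method <- if (n <= 170L) "exact" else "permutation"

  if (method == "exact") {
    if (alternative == "less") {
      p <- stats::phyper(k_obs, m1, n - m1, m2)
    } else {
      dens <- stats::dhyper(0:min(m1, m2), m1, n - m1, m2)
      p <- min(1, sum(dens[dens <= dens[k_obs + 1L] * (1 + 1e-9)]))
    }
    n_resamples <- NA_integer_
    seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  } else {
    if (n_resamples < 999L) {
      stop("resampling methods need n_resamples >= 999", call. = FALSE)
    }
    if (is.null(seed)) {
      stop("a seed is mandatory for resampling methods", call. = FALSE)
    }
    seed <- as.integer(seed)
    j_null <- local({
      set.seed(seed)
      if (method == "permutation") {
        vapply(seq_len(n_resamples), function(i) {
          yp <- sample(y)
          k <- sum(x & yp)
          k / (m1 + m2 - k)
        }, numeric(1))
      } else {
        vapply(seq_len(n_resamples), function(i) {
          xb <- stats::rbinom(n, 1L, m1 / n)
          yb <- stats::rbinom(n, 1L, m2 / n)
          u <- sum(xb | yb)
          if (u == 0L) NA_real_ else sum(xb & yb) / u
        }, numeric(1))
      }
    })
    j_null <- j_null[!is.na(j_null)]
    tol <- 1e-12
    if (alternative == "less") {
      p <- (1 + sum(j_null <= j_obs + tol)) / (length(j_null) + 1)
    } else {
      med <- stats::median(j_null)
      dev <- abs(j_null - med)
      p <- (1 + sum(dev >= abs(j_obs - med) - tol)) / (length(j_null) + 1)
    }
  }
  structure(list(J = j_obs, p = min(p, 1), n_union = sum(x | y),
                 n_intersection = k_obs, method = method,
                 alternative = alternative,
                 n_resamples = n_resamples, seed = seed),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  # figures report J and p to 2 decimals; full precision is kept in the object
  cat(sprintf("J %.2f, p %.2f  (intersection %d / union %d, %s%s)\n",
              x$J, x$p, x$n_intersection, x$n_union, x$method,
              if (x$alternative == "two.sided") ", two-sided" else ""))
  invisible(x)
}

#' Overlap statistics for every switch-analysis scope
#'
#' Runs [align_binary_lists()] + [jaccard_pvalue()] over the standard scopes
#' of a two-group classification: each compartment's U-lists, the A-lists,
#' and each edge's B-lists, optionally within one lipid class. Scopes empty
#' in both groups are skipped.
#'
#' @param classification a two-group [classify_switch()] result.
#' @param lipid_class optional lipid class filter.
#' @inheritParams jaccard_pvalue
#' @return data frame with one row per scope: category, location, per-group
#'   list sizes, n_intersection, n_union, J, p, method, seed.
#' @export
overlap_table <- function(classification, lipid_class = NULL,
                          method = "auto", n_resamples = 10000L,
                          seed = NULL) {
  stopifnot(inherits(classification, "switch_classification"))
  network <- classification$network
  scopes <- rbind(
    data.frame(category = "U", location = network$compartments,
               stringsAsFactors = FALSE),
    data.frame(category = "A", location = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(category = "B",
               location = edge_key(network$edges$from, network$edges$to),
               stringsAsFactors = FALSE)
  )
  groups <- names(classification$groups)
  rows <- lapply(seq_len(nrow(scopes)), function(i) {
    loc <- scopes$location[i]
    sizes <- vapply(groups, function(g) {
      length(scope_members(classification, g, scopes$category[i],
                           if (is.na(loc)) NULL else loc, lipid_class))
    }, integer(1))
    if (sum(sizes) == 0L) return(NULL)
    al <- align_binary_lists(classification, scopes$category[i],
                             if (is.na(loc)) NULL else loc, lipid_class)
    res <- jaccard_pvalue(al$x, al$y, method = method,
                          n_resamples = n_resamples, seed = seed)
    data.frame(category = scopes$category[i], location = loc,
               n_group1 = sizes[1L], n_group2 = sizes[2L],
               n_intersection = res$n_intersection, n_union = res$n_union,
               J = res$J, p = res$p, method = res$method,
               seed = res$seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  out
}
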