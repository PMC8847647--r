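# Fixtures are built in code; oracles here are deliberately naive
# re-derivations (plain loops and full enumeration) independent of the
# package's implementation paths.

# A small deterministic dataset with hand-chosen presence patterns on a
# 3-compartment path network (liver -- serum -- heart), 2 groups x 3 samples.
toy_dataset <- function() {
  samples <- expand.grid(rep = 1:3,
                         compartment = c("liver", "serum", "heart"),
                         group = c("g1", "g2"), stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_%s_%d", samples$group, samples$compartment,
                        samples$rep),
    compartment = samples$compartment, group = samples$group,
    stringsAsFactors = FALSE)
  vars <- c("TG(52:3)", "PC(36:4)", "SM(39:1)", "PE(34:2)")
  abundance <- matrix(0, nrow(samples), length(vars),
                      dimnames = list(samples$sample_id, vars))
  fill <- function(group, compartment, var, value = 10) {
    sel <- samples$group == group & samples$compartment == compartment
    abundance[sel, var] <<- value
  }
  # TG(52:3): everywhere in both groups (A-type)
  for (g in c("g1", "g2")) for (cm in c("liver", "serum", "heart")) {
    fill(g, cm, "TG(52:3)")
  }
  # PC(36:4): liver + serum in g1 (B on liver--serum), liver only in g2 (U)
  fill("g1", "liver", "PC(36:4)"); fill("g1", "serum", "PC(36:4)")
  fill("g2", "liver", "PC(36:4)")
  # SM(39:1): heart only in g2 (U); absent in g1
  fill("g2", "heart", "SM(39:1)")
  # PE(34:2): liver + heart in g1 (non-adjacent pair -> multi); absent in g2
  fill("g1", "liver", "PE(34:2)"); fill("g1", "heart", "PE(34:2)")
  lipidomics_dataset(samples, abundance)
}

toy_network <- function() {
  tissue_network(c("liver", "serum", "heart"),
                 data.frame(from = c("liver", "serum"),
                            to = c("serum", "heart")))
}

# Random small study for property tests: n_comp compartments on a random
# connected network, two groups, n_rep samples per cell.
random_dataset <- function(n_comp = 4, n_var = 20, n_rep = 4,
                           p_signal = 0.5) {
  comps <- paste0("c", seq_len(n_comp))
  edges <- data.frame(from = comps[-n_comp], to = comps[-1])  # path: connected
  extra <- which(stats::runif(n_comp - 2) < 0.3)
  if (length(extra) > 0) {
    edges <- rbind(edges, data.frame(from = comps[extra],
                                     to = comps[extra + 2L]))
  }
  network <- tissue_network(comps, edges)
  classes <- c("TG", "PC", "PE", "SM")
  vars <- unique(sprintf("%s(%d:%d)",
                         sample(classes, 3 * n_var, TRUE),
                         sample(30:58, 3 * n_var, TRUE),
                         sample(0:8, 3 * n_var, TRUE)))[seq_len(n_var)]
  samples <- expand.grid(rep = seq_len(n_rep), compartment = comps,
                         group = c("g1", "g2"), stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(nrow(samples))),
    compartment = samples$compartment, group = samples$group,
    stringsAsFactors = FALSE)
  abundance <- matrix(stats::rbinom(nrow(samples) * n_var, 1, p_signal) *
                        stats::rlnorm(nrow(samples) * n_var, 5, 1),
                      nrow(samples), n_var,
                      dimnames = list(samples$sample_id, vars))
  list(dataset = lipidomics_dataset(samples, abundance), network = network)
}

# Brute-force switch classification straight from the raw abundance matrix:
# nested loops, no shared code with binarize()/classify_switch().
brute_classify <- function(dataset, network, threshold = 0.66) {
  comps <- network$compartments
  vars <- colnames(dataset$abundance)
  out <- list()
  for (g in unique(dataset$samples$group)) {
    present <- matrix(FALSE, length(comps), length(vars),
                      dimnames = list(comps, vars))
    for (cm in comps) {
      for (v in vars) {
        sel <- dataset$samples$group == g & dataset$samples$compartment == cm
        frac <- mean(dataset$abundance[sel, v] > 0)
        present[cm, v] <- frac > threshold || abs(frac - threshold) < 1e-9
      }
    }
    U <- lapply(comps, function(cm) {
      keep <- character(0)
      for (v in vars) {
        if (present[cm, v] && sum(present[, v]) == 1) keep <- c(keep, v)
      }
      keep
    })
    names(U) <- comps
    A <- vars[apply(present, 2, all)]
    B <- list()
    for (i in seq_len(nrow(network$edges))) {
      e1 <- network$edges$from[i]; e2 <- network$edges$to[i]
      B[[paste(sort(c(e1, e2)), collapse = "--")]] <-
        vars[present[e1, ] & present[e2, ]]
    }
    out[[g]] <- list(U_lists = U, A_list = A, B_lists = B,
                     not_detected = vars[colSums(present) == 0])
  }
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of all assignments of
# the pooled (tie-free) values to the two groups.
enumerate_wilcox_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(g1, g2)
  mu <- n1 * length(g2) / 2
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Random 0/1 vector pair with at least one 1 overall.
random_binary_pair <- function(n) {
  repeat {
    x <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
    y <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
    if (sum(x) + sum(y) > 0) return(list(x = x, y = y))
  }
}
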