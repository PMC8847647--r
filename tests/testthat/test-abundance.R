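test_that("relative abundance normalises to proportions", {
  expect_equal(relative_abundance(c(2, 2, 4)), c(0.25, 0.25, 0.5))
  expect_equal(relative_abundance(c(0, 7, 0)), c(0, 1, 0))
  set.seed(51)
  for (i in 1:10) {
    x <- stats::rlnorm(sample(3:30, 1))
    expect_equal(sum(relative_abundance(x)), 1, tolerance = 1e-12)
    k <- stats::runif(1, 0.1, 100)
    expect_equal(relative_abundance(k * x), relative_abundance(x))
  }
  expect_error(relative_abundance(c(0, 0)), "all-zero")
  expect_error(relative_abundance(c(1, -2)), "non-negative")
})

test_that("rank-sum comparison: exact small-sample p and symmetry", {
  # fully separated n = 3 vs 3: the smallest attainable two-sided p is 0.1
  res <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$p_raw, 0.1)
  expect_true(res$exact)
  expect_equal(res$statistic, 0)

  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_raw, 1)
  expect_equal(compare_groups(c(5, 5, 5), c(5, 5, 5))$p_raw, 1)

  set.seed(52)
  for (i in 1:10) {
    a <- stats::rlnorm(sample(3:9, 1)); b <- stats::rlnorm(sample(3:9, 1))
    expect_equal(compare_groups(a, b)$p_raw, compare_groups(b, a)$p_raw)
  }
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("exact-mode p matches full enumeration for n1 = n2 = 4", {
  set.seed(53)
  for (i in 1:10) {
    a <- stats::rlnorm(4); b <- stats::rlnorm(4)
    expect_equal(compare_groups(a, b)$p_raw, enumerate_wilcox_p(a, b))
  }
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(signif(bonferroni_threshold(0.05, 33), 3), 0.00152)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(0.05, 0), "positive count")
  expect_error(bonferroni_threshold(1.2, 5), "alpha")
})

test_that("the comparison table flags significance against alpha / m", {
  set.seed(54)
  inst <- random_dataset(n_comp = 2, n_var = 6, n_rep = 6, p_signal = 1)
  ds <- inst$dataset
  tab <- group_comparison_table(ds, alpha = 0.05)
  expect_equal(nrow(tab), 6L)
  expect_equal(unique(tab$p_threshold_bonferroni),
               signif(0.05 / 6, 3))
  expect_identical(tab$significant,
                   tab$p_raw < tab$p_threshold_bonferroni)
})

test_that("fatty-acid ratios average per-sample ratios and exclude zero denominators", {
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:16),
    compartment = rep(c("heart", "adipose"), each = 8),
    group = rep(rep(c("lean", "obese"), each = 4), 2))
  m <- cbind("FA(15:0)" = rep(3, 16), "FA(17:0)" = rep(1, 16))
  rownames(m) <- samples$sample_id
  ds <- lipidomics_dataset(samples, m)
  fr <- fa_ratio(ds, "FA(15:0)", "FA(17:0)", compartment = "heart")
  expect_equal(unname(fr$mean_ratio), c(3, 3))

  # identical numerator and denominator gives ratio 1 everywhere
  fr1 <- fa_ratio(ds, "FA(17:0)", "FA(17:0)", compartment = "heart")
  expect_equal(unname(fr1$mean_ratio), c(1, 1))

  m2 <- m; m2[1, "FA(17:0)"] <- 0
  ds2 <- lipidomics_dataset(samples, m2)
  expect_warning(fr2 <- fa_ratio(ds2, "FA(15:0)", "FA(17:0)", "heart"),
                 "excluded")
  expect_length(fr2$ratios$lean, 3L)

  m3 <- m; m3[samples$compartment == "heart", "FA(17:0)"] <- 0
  ds3 <- lipidomics_dataset(samples, m3)
  expect_error(fa_ratio(ds3, "FA(15:0)", "FA(17:0)", "heart"),
               "zero in every sample")
  expect_error(fa_ratio(ds, "FA(19:0)", "FA(17:0)", "heart"),
               "not measured")
})

test_that("planted FA ratios of 3.7 and 2.4 are recovered from noisy data", {
  set.seed(55)
  n <- 8
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:(2 * n)),
    compartment = "heart",
    group = rep(c("lean", "obese"), each = n))
  # second compartment to satisfy the dataset contract
  samples <- rbind(samples,
                   transform(samples, sample_id = paste0(samples$sample_id, "b"),
                             compartment = "serum"))
  den <- stats::rnorm(nrow(samples), 100, 10)              # CV 10%
  ratio_true <- ifelse(samples$group == "obese", 3.7, 2.4)
  num <- ratio_true * den * stats::rnorm(nrow(samples), 1, 0.1)
  m <- cbind("FA(15:0)" = num, "FA(17:0)" = den)
  rownames(m) <- samples$sample_id
  ds <- lipidomics_dataset(samples, m)
  fr <- fa_ratio(ds, "FA(15:0)", "FA(17:0)", compartment = "heart")
  expect_equal(unname(fr$mean_ratio["lean"]), 2.4, tolerance = 0.15)
  expect_equal(unname(fr$mean_ratio["obese"]), 3.7, tolerance = 0.15)
  expect_lt(fr$p_raw, 0.05)
})

test_that("ENFC is zero at equality, antisymmetric, and sign-consistent", {
  x <- c(3, 4, 5, 6)
  res <- enfc(x, x)
  expect_equal(res$fold_change, 1)
  expect_equal(res$enfc, 0)

  set.seed(56)
  for (i in 1:15) {
    a <- stats::rlnorm(sample(3:12, 1), 2, 0.6)
    b <- stats::rlnorm(sample(3:12, 1), 2.5, 0.4)
    f <- enfc(a, b); r <- enfc(b, a)
    expect_identical(f$enfc, -r$enfc)                 # exact antisymmetry
    expect_equal(sign(f$enfc), sign(log(f$fold_change)))
  }

  # doubling every case value doubles the fold change and grows |ENFC|
  a <- c(2, 3, 4, 5); b <- c(2, 3, 4, 6)
  f1 <- enfc(a, b); f2 <- enfc(2 * a, b)
  expect_equal(f2$fold_change, 2 * f1$fold_change)
  expect_gt(abs(f2$enfc), abs(f1$enfc))

  expect_error(enfc(c(1, 2), c(1, 2, 3)), "at least 3")
  expect_error(enfc(c(0, 0, 0), c(1, 2, 3)), "non-positive")
})

test_that("a simulated two-fold effect yields a positive ENFC near 2", {
  set.seed(57)
  control <- stats::rlnorm(10, meanlog = 5, sdlog = 0.3)
  case <- stats::rlnorm(10, meanlog = 5 + log(2), sdlog = 0.3)
  res <- enfc(case, control)
  expect_gt(res$enfc, 0)
  expect_equal(res$fold_change, 2, tolerance = 0.2)
})

test_that("the ENFC table respects the nominated control group", {
  set.seed(58)
  inst <- random_dataset(n_comp = 2, n_var = 5, n_rep = 5, p_signal = 1)
  tab1 <- enfc_table(inst$dataset, control_group = "g1")
  tab2 <- enfc_table(inst$dataset, control_group = "g2")
  expect_equal(tab1$fold_change, 1 / tab2$fold_change, tolerance = 1e-12)
  expect_equal(tab1$enfc, -tab2$enfc, tolerance = 1e-12)
  expect_error(enfc_table(inst$dataset, control_group = "nope"), "control")
})
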