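small_config <- function(...) {
  synthetic_config(network = toy_network(), groups = c("g1", "g2"),
                   n_samples = 4L, n_variables = 60L, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  a <- generate_study(small_config(), seed = 101)
  b <- generate_study(small_config(), seed = 101)
  expect_identical(a$dataset$abundance, b$dataset$abundance)
  expect_identical(a$truth$planted_category, b$truth$planted_category)
  c <- generate_study(small_config(), seed = 102)
  expect_false(identical(a$dataset$abundance, c$dataset$abundance))
})

test_that("generator refuses configurations that defeat the presence rule", {
  expect_error(synthetic_config(dropout = 0.34), "presence rule")
  expect_error(synthetic_config(dropout = -0.1), "dropout")
  expect_error(synthetic_config(n_samples = 2), "n_samples")
  expect_error(synthetic_config(groups = c("a", "a")), "distinct")
})

test_that("generated names are valid shorthand spanning several classes", {
  study <- generate_study(small_config(), seed = 103)
  sp <- study$dataset$variables
  expect_setequal(unique(sp$lipid_class), c("TG", "PC", "PE", "SM"))
  expect_true(any(sp$odd_chain))
  expect_false(anyDuplicated(sp$raw_name) > 0)
})

test_that("with zero dropout the planted patterns are realised exactly", {
  study <- generate_study(small_config(), seed = 104)
  cls <- classify_switch(binarize(study$dataset), toy_network())
  rep <- truth_recovery_report(study$truth, cls)
  expect_identical(rep$recovery_rate, 1)
  expect_identical(rep$presence_call_accuracy, 1)
  expect_equal(nrow(rep$mismatches), 0L)

  # targeted check: every planted A / U@x label appears in the right list
  truth <- study$truth$planted_category
  for (i in which(truth$category == "A")) {
    expect_true(truth$variable[i] %in%
                  cls$groups[[truth$group[i]]]$A_list)
  }
  u_idx <- grep("^U@", truth$category)
  for (i in u_idx[seq_len(min(10, length(u_idx)))]) {
    cmp <- sub("^U@", "", truth$category[i])
    expect_true(truth$variable[i] %in%
                  cls$groups[[truth$group[i]]]$U_lists[[cmp]])
  }
})

test_that("a variable planted unique in one group only surfaces only there", {
  study <- generate_study(
    synthetic_config(network = toy_network(), groups = c("g1", "g2"),
                     n_samples = 4L, n_variables = 120L, p_discordant = 1,
                     category_weights = c(A = 0.1, U = 0.45, B = 0.1,
                                          absent = 0.35)),
    seed = 105)
  truth <- study$truth$planted_category
  wide <- merge(truth[truth$group == "g1", c("variable", "category")],
                truth[truth$group == "g2", c("variable", "category")],
                by = "variable", suffixes = c("_g1", "_g2"))
  pick <- wide[startsWith(wide$category_g2, "U@") &
                 wide$category_g1 == "absent", ]
  expect_gt(nrow(pick), 0)
  cls <- classify_switch(binarize(study$dataset), toy_network())
  for (i in seq_len(nrow(pick))) {
    cmp <- sub("^U@", "", pick$category_g2[i])
    expect_true(pick$variable[i] %in% cls$groups$g2$U_lists[[cmp]])
    expect_true(pick$variable[i] %in% cls$groups$g1$not_detected)
  }
})

test_that("pipeline J on the A-lists equals J computed from the truth records", {
  study <- generate_study(small_config(), seed = 106)
  cls <- classify_switch(binarize(study$dataset), toy_network())
  al <- align_binary_lists(cls, "A")
  j_pipeline <- jaccard_coefficient(al$x, al$y)
  truth <- study$truth$planted_category
  a1 <- truth$variable[truth$group == "g1" & truth$category == "A"]
  a2 <- truth$variable[truth$group == "g2" & truth$category == "A"]
  j_truth <- length(intersect(a1, a2)) / length(union(a1, a2))
  expect_equal(j_pipeline, j_truth)
})

test_that("dropout erodes recovery in the expected direction", {
  clean <- run_simulate(small_config(), seed = 107)
  noisy <- run_simulate(small_config(dropout = 0.3), seed = 107)
  expect_identical(clean$report$recovery_rate, 1)
  expect_lt(noisy$report$recovery_rate, 1)
  expect_lt(noisy$report$presence_call_accuracy, 1)
  expect_gt(noisy$report$presence_call_accuracy, 0.5)
  expect_gt(nrow(noisy$report$mismatches), 0)
})

test_that("recovery report validates its inputs", {
  study <- generate_study(small_config(), seed = 108)
  cls <- classify_switch(binarize(study$dataset), toy_network())
  truth_bad <- study$truth
  truth_bad$planted_category <- truth_bad$planted_category[-1, ]
  expect_error(truth_recovery_report(truth_bad, cls), "different")
  truth_empty <- study$truth
  truth_empty$planted_category <- truth_empty$planted_category[0, ]
  expect_error(truth_recovery_report(truth_empty, cls), "empty")
})

test_that("simulation outputs round-trip through the dataset reader", {
  dir <- withr::local_tempdir()
  res <- run_simulate(small_config(), seed = 109, output_dir = dir)
  ds <- load_lipidomics_table(file.path(dir, "synthetic_dataset.csv"))
  expect_identical(ds$abundance, res$dataset$abundance)
  truth_csv <- utils::read.csv(file.path(dir, "synthetic_truth.csv"))
  expect_equal(nrow(truth_csv), nrow(res$truth$planted_category))
  expect_true(file.exists(file.path(dir, "recovery_report.json")))
})
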