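test_that("presence fraction counts strictly positive signals", {
  expect_equal(presence_fraction(c(1.2, 0, 3.4, 5.0)), 0.75)
  expect_equal(presence_fraction(c(0, 0, 0)), 0)
  expect_equal(presence_fraction(rep(c(1, 0), c(6, 2))), 0.75)
  expect_error(presence_fraction(numeric(0)), "empty")
  expect_error(presence_fraction(c(1, -1)), "non-negative")
})

test_that("presence calls use a closed >= 0.66 bound", {
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:16),
    compartment = "liver",
    group = rep(c("g1", "g2"), each = 8))
  # g1: 5/8 detected (0.625, below threshold); g2: 6/8 detected (0.75)
  m <- matrix(c(rep(1, 5), 0, 0, 0, rep(1, 6), 0, 0), ncol = 1,
              dimnames = list(NULL, "TG(52:3)"))
  # binarize needs >= 2 compartments; add a fully detected one
  samples2 <- rbind(samples, transform(samples, sample_id = paste0(samples$sample_id, "b"),
                                       compartment = "serum"))
  m2 <- rbind(m, matrix(1, 16, 1))
  ds <- lipidomics_dataset(samples2, m2)
  prof <- binarize(ds, threshold = 0.66)
  fr <- prof$fractions
  expect_false(fr$present[fr$group == "g1" & fr$compartment == "liver"])
  expect_equal(fr$B_fraction[fr$group == "g1" & fr$compartment == "liver"],
               0.625)
  expect_true(fr$present[fr$group == "g2" & fr$compartment == "liver"])

  # a fraction exactly at the threshold is present (33/50 = 0.66)
  expect_true(lipidtraffic:::.present_at(33 / 50, 0.66))
  expect_false(lipidtraffic:::.present_at(32 / 50, 0.66))

  # threshold 0 degenerates to "any nonzero sample"
  prof0 <- binarize(ds, threshold = 0)
  expect_true(all(prof0$fractions$present))
})

test_that("binarize names empty group x compartment cells", {
  ds <- toy_dataset()
  ds$samples$compartment[ds$samples$sample_id == "g1_liver_1"] <- "serum"
  ds$samples$compartment[ds$samples$sample_id == "g1_liver_2"] <- "serum"
  ds$samples$compartment[ds$samples$sample_id == "g1_liver_3"] <- "serum"
  expect_error(binarize(ds), "g1/liver")
})

test_that("hand-built patterns classify as expected U/A/B types", {
  cls <- classify_switch(binarize(toy_dataset()), toy_network())
  g1 <- cls$groups$g1; g2 <- cls$groups$g2

  # TG(52:3) everywhere: A-type and member of every edge B-list, both groups
  expect_true("TG(52:3)" %in% g1$A_list)
  expect_true(all(vapply(g1$B_lists, function(b) "TG(52:3)" %in% b,
                         logical(1))))
  expect_true("TG(52:3)" %in% g2$A_list)

  # PC(36:4): B-type on liver--serum in g1 (not U, not A); U@liver in g2
  expect_true("PC(36:4)" %in% g1$B_lists[["liver--serum"]])
  expect_false("PC(36:4)" %in% unlist(g1$U_lists))
  expect_false("PC(36:4)" %in% g1$A_list)
  expect_true("PC(36:4)" %in% g2$U_lists$liver)

  # SM(39:1): U@heart in g2, not detected in g1
  expect_true("SM(39:1)" %in% g2$U_lists$heart)
  expect_true("SM(39:1)" %in% g1$not_detected)

  # PE(34:2): non-adjacent liver+heart pair in g1 -> traceability only
  rec <- g1$record[g1$record$variable == "PE(34:2)", ]
  expect_equal(rec$category, "multi")
  expect_false("PE(34:2)" %in% unlist(g1$B_lists))
})

test_that("classification matches a brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:20) {
    inst <- random_dataset(n_comp = sample(3:5, 1),
                           n_var = sample(10:50, 1),
                           n_rep = sample(3:6, 1))
    cls <- classify_switch(binarize(inst$dataset), inst$network)
    oracle <- brute_classify(inst$dataset, inst$network)
    for (g in names(oracle)) {
      expect_identical(cls$groups[[g]]$A_list, oracle[[g]]$A_list)
      expect_identical(cls$groups[[g]]$not_detected,
                       oracle[[g]]$not_detected)
      for (cm in inst$network$compartments) {
        expect_identical(cls$groups[[g]]$U_lists[[cm]],
                         oracle[[g]]$U_lists[[cm]])
      }
      for (e in names(oracle[[g]]$B_lists)) {
        expect_identical(cls$groups[[g]]$B_lists[[e]],
                         oracle[[g]]$B_lists[[e]])
      }
    }
  }
})

test_that("switch invariants hold: partition, A within B, U disjoint from B", {
  set.seed(32)
  for (i in 1:10) {
    inst <- random_dataset(n_comp = 4, n_var = 30, n_rep = 4)
    cls <- classify_switch(binarize(inst$dataset), inst$network)
    for (g in names(cls$groups)) {
      gg <- cls$groups[[g]]
      for (b in gg$B_lists) {
        expect_true(all(gg$A_list %in% b))
        expect_length(intersect(unlist(gg$U_lists), b), 0)
      }
      rec <- gg$record
      expect_true(all(rec$n_compartments[rec$variable %in%
                                           unlist(gg$U_lists)] == 1L))
      # every variable is accounted for exactly once in the record
      expect_setequal(rec$variable, colnames(inst$dataset$abundance))
      n_u <- sum(rec$category %in% paste0("U@", inst$network$compartments))
      expect_equal(n_u, length(unlist(gg$U_lists)))
      expect_equal(sum(startsWith(rec$category, "U@")) +
                     sum(rec$category == "A") +
                     sum(rec$category == "absent") +
                     sum(startsWith(rec$category, "B@")) +
                     sum(rec$category == "multi"),
                   nrow(rec))
    }
  }
})

test_that("raising the threshold never adds presence calls", {
  set.seed(33)
  for (i in 1:10) {
    inst <- random_dataset(n_comp = 4, n_var = 25, n_rep = 5, p_signal = 0.7)
    lo <- binarize(inst$dataset, threshold = 0.5)
    hi <- binarize(inst$dataset, threshold = 0.8)
    for (g in names(lo$present)) {
      expect_true(all(lo$present[[g]] >= hi$present[[g]]))
    }
  }
})

test_that("aligned binary lists cover the union in canonical order", {
  cls <- classify_switch(binarize(toy_dataset()), toy_network())
  al <- align_binary_lists(cls, "B", "liver--serum")
  # g1 B(liver--serum) = {TG, PC}; g2 = {TG}
  expect_equal(al$variables, c("PC(36:4)", "TG(52:3)"))  # class-sorted
  expect_equal(al$x, c(1L, 1L))
  expect_equal(al$y, c(0L, 1L))
  expect_equal(sum(al$x), 2L)

  al_a <- align_binary_lists(cls, "A")
  expect_identical(al_a$x, al_a$y)  # identical lists -> identical vectors

  # group-1-only scope: g2 vector all zeros
  al_u <- align_binary_lists(cls, "U", "heart")
  expect_true(all(al_u$x == 0L))
  expect_true(all(al_u$y == 1L))

  expect_error(align_binary_lists(cls, "U", "serum"), "empty")
  expect_error(align_binary_lists(cls, "B", "liver--heart"), "unknown edge")
})

test_that("classification tables are written per category plus a long table", {
  dir <- withr::local_tempdir()
  cls <- classify_switch(binarize(toy_dataset()), toy_network())
  files <- write_switch_tables(cls, dir)
  expect_true(file.exists(file.path(dir, "A_g1.csv")))
  expect_true(file.exists(file.path(dir, "U_g2_heart.csv")))
  expect_true(file.exists(file.path(dir, "B_g1_liver--serum.csv")))
  long <- utils::read.csv(file.path(dir, "classification_long.csv"))
  expect_equal(nrow(long), 2L * 4L)  # 2 groups x 4 variables
  expect_equal(utils::read.csv(file.path(dir, "U_g2_heart.csv"))$variable,
               "SM(39:1)")
})
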