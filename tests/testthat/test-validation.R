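# Independent largest-remainder oracle: enumerate remainder seats one at a
# time, each going to the set with the largest fractional remainder (ties:
# smaller quota, then position).
lr_oracle <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  add <- integer(length(ratios))
  for (seat in seq_len(n - sum(base))) {
    frac <- exact - base - add
    best <- which(frac == max(frac))
    if (length(best) > 1) best <- best[order(exact[best])]
    add[best[1]] <- add[best[1]] + 1L
  }
  as.integer(base + add)
}

hier_ds <- function(seed = 10L, spectra_per_map = 4L) {
  generate_dataset(generator_config(n_mice_per_arm = 5,
                                    spectra_per_map = spectra_per_map,
                                    seed = seed))
}

test_that("random splits follow largest-remainder sizes exactly", {
  expect_identical(radspectra:::largest_remainder_sizes(1000,
                                                        c(0.7, 0.2, 0.1)),
                   c(700L, 200L, 100L))
  expect_identical(radspectra:::largest_remainder_sizes(4705,
                                                        c(0.7, 0.2, 0.1)),
                   lr_oracle(4705, c(0.7, 0.2, 0.1)))
  expect_identical(lr_oracle(4705, c(0.7, 0.2, 0.1)),
                   c(3293L, 941L, 471L))
  set.seed(3)
  for (i in 1:25) {
    n <- sample(10:5000, 1)
    r <- runif(3)
    r <- r / sum(r)
    expect_identical(radspectra:::largest_remainder_sizes(n, r),
                     lr_oracle(n, r))
  }
})

test_that("random_split partitions the dataset deterministically", {
  ds <- hier_ds()
  sp <- random_split(ds, c(0.7, 0.2, 0.1), 5)
  idx <- c(sp$train, sp$validation, sp$test)
  expect_identical(sort(idx), seq_len(nrow(ds$intensities)))
  expect_identical(length(sp$train), 168L)   # 240 * 0.7
  sp2 <- random_split(ds, c(0.7, 0.2, 0.1), 5)
  expect_identical(sp, sp2)
  expect_error(random_split(subset_spectra(ds, 1:5), c(0.9, 0.05, 0.05),
                            1),
               "split error")
})

test_that("subject-wise splits hold out whole units without leakage", {
  ds <- hier_ds()
  expect_identical(length(unique(unit_ids(ds, "mouse")[
    ds$meta$label == "irradiated"])), 5L)

  sp_mouse <- subject_wise_splits(ds, "mouse")
  expect_length(sp_mouse, 5L)
  sp_map <- subject_wise_splits(ds, "map")
  expect_length(sp_map, 30L)
  sp_section <- subject_wise_splits(ds, "section")
  expect_length(sp_section, 15L)

  for (sp in c(sp_mouse, sp_section, sp_map)) {
    level <- sub("loo_", "", sp$scheme)
    uid <- unit_ids(ds, level)
    expect_length(intersect(uid[sp$test],
                            uid[c(sp$train, sp$validation)]), 0L)
    expect_identical(sort(c(sp$train, sp$validation, sp$test)),
                     seq_len(nrow(ds$intensities)))
    expect_true(all(uid[sp$test] == sp$held_out_unit))
  }

  # all-train variant for the RF
  sp_rf <- subject_wise_splits(ds, "mouse", train_val_ratio = c(1, 0))
  expect_length(sp_rf[[1]]$validation, 0L)

  expect_error(subject_wise_splits(ds, "mouse", units = "m99"),
               "lookup error")
})

test_that("the leakage guard rejects corrupted assignments", {
  ds <- hier_ds()
  sp <- subject_wise_splits(ds, "mouse")[[1]]
  expect_true(assert_no_leakage(ds, sp, "mouse"))
  bad <- sp
  bad$train <- c(bad$train, bad$test[1])     # duplicate a held-out spectrum
  expect_error(assert_no_leakage(ds, bad, "mouse"),
               class = "radspectra_leakage_error")
})

test_that("confusion metrics match hand computation and edge policy", {
  m <- compute_metrics(list(TP = 90, FN = 10, TN = 80, FP = 20))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  prec <- 90 / 110
  expect_equal(m$f1, 2 * prec * 0.9 / (prec + 0.9))

  perfect <- compute_metrics(list(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_true(all(unlist(perfect) == 1))

  nd <- compute_metrics(list(TP = 0, FN = 0, TN = 4, FP = 1))
  expect_true(is.na(nd$sensitivity))         # undefined, not zero
  expect_error(compute_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "empty")
})

test_that("accuracy decomposes into sensitivity/specificity/prevalence", {
  set.seed(5)
  for (i in 1:30) {
    cc <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                  c("TP", "FP", "TN", "FN")))
    total <- sum(unlist(cc))
    if (total == 0) next
    m <- compute_metrics(cc)
    prev <- (cc$TP + cc$FN) / total
    if (is.na(m$sensitivity) || is.na(m$specificity)) next
    expect_equal(m$accuracy,
                 m$sensitivity * prev + m$specificity * (1 - prev))
  }
})

test_that("Wilcoxon comparison matches the exact enumeration oracle", {
  a <- (1:10) / 20
  b <- (11:20) / 20                          # complete separation
  res <- wilcoxon_compare(a, b)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(res$significant)

  # rank-based: invariant under strictly increasing transforms
  res2 <- wilcoxon_compare(exp(3 * a), exp(3 * b))
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)

  same <- c(0.9, 0.8, 0.85, 0.95)
  expect_equal(wilcoxon_compare(same, same)$p_value, 1)

  deg <- wilcoxon_compare(rep(0.9, 3), rep(0.9, 4))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  expect_error(wilcoxon_compare(1, c(1, 2)), "at least two")
})

test_that("single-run summaries flag the degenerate SD convention", {
  ds <- generate_dataset(separable_config(spectra_per_map = 6,
                                          n_mice_per_arm = 2))
  lib <- small_library(5, seed = 3)
  res <- run_random_split_experiment(
    ds, "gbr_nmf_rf", n_runs = 1, base_seed = 2,
    nmf_cfg = nmf_config(lib, 0, solver = "nnls"),
    rf_cfg = rf_config(n_trees = 150, vars_per_split = 2, seed = 1))
  expect_true(res$degenerate_sd)
  expect_identical(res$sd$accuracy, 0)
  expect_identical(nrow(res$runs), 1L)
})

test_that("the CLI round-trips generate/preprocess/decompose/compare", {
  td <- withr::local_tempdir()
  p <- function(...) file.path(td, ...)
  writeLines(c("seed = 4", "n_mice_per_arm = 1", "spectra_per_map = 2",
               "sections_per_mouse = 2",
               paste0("out_spectra = ", p("sp.tsv")),
               paste0("out_meta = ", p("meta.tsv")),
               paste0("out_basis = ", p("basis.tsv")),
               "n_constrained = 5",
               paste0("log = ", p("gen.log"))),
             p("gen.cfg"))
  expect_identical(cli_main(c("generate", p("gen.cfg"))), 0L)
  expect_true(file.exists(p("sp.tsv")))
  expect_true(file.exists(p("gen.log")))

  writeLines(c(paste0("in_spectra = ", p("sp.tsv")),
               paste0("in_meta = ", p("meta.tsv")),
               "steps = despike,smooth,baseline,normalize",
               paste0("out_spectra = ", p("pp.tsv")),
               paste0("out_meta = ", p("ppmeta.tsv"))),
             p("pp.cfg"))
  expect_identical(cli_main(c("preprocess", p("pp.cfg"))), 0L)

  writeLines(c(paste0("in_spectra = ", p("pp.tsv")),
               paste0("in_meta = ", p("ppmeta.tsv")),
               paste0("basis = ", p("basis.tsv")),
               "n_free_factors = 0", "solver = nnls",
               paste0("out_scores = ", p("scores.tsv"))),
             p("dec.cfg"))
  expect_identical(cli_main(c("decompose", p("dec.cfg"))), 0L)
  sc <- read.delim(p("scores.tsv"))
  expect_identical(nrow(sc), 16L)  # 1 mouse x 2 sections x 2 maps x 2, both arms
  expect_true(all(c("label", "compound_01") %in% names(sc)))

  for (f in c("a", "b")) {
    write.table(data.frame(accuracy = c(0.9, 0.92, 0.88) +
                             (f == "b") * 0.01),
                p(paste0(f, ".tsv")), sep = "\t", row.names = FALSE)
  }
  writeLines(c(paste0("in_a = ", p("a.tsv")),
               paste0("in_b = ", p("b.tsv")),
               paste0("out = ", p("cmp.tsv"))),
             p("cmp.cfg"))
  expect_identical(cli_main(c("compare", p("cmp.cfg"))), 0L)
  expect_true(file.exists(p("cmp.tsv")))

  # configuration errors exit with status 2
  writeLines("steps = normalize", p("bad.cfg"))
  expect_identical(cli_main(c("preprocess", p("bad.cfg"))), 2L)
  expect_identical(cli_main(c("nonsense")), 2L)
})
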