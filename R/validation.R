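# Split construction, confusion metrics, multi-run experiment drivers and
# the Wilcoxon model comparison.

# Largest-remainder apportionment of n items to ratios, so set sizes
# preserve the requested proportions exactly. Remainder ties go to the
# smaller quota (largest relative remainder), then to ratio position.
largest_remainder_sizes <- function(n, ratios) {
  if (any(ratios <= 0)) stop("split error: ratios must be positive",
                             call. = FALSE)
  if (abs(sum(ratios) - 1) > 1e-9) {
    stop("split error: ratios must sum to 1", call. = FALSE)
  }
  exact <- n * ratios
  sizes <- floor(exact)
  short <- n - sum(sizes)
  if (short > 0) {
    frac <- exact - sizes
    top <- order(-frac, exact, seq_along(ratios))[seq_len(short)]
    sizes[top] <- sizes[top] + 1L
  }
  as.integer(sizes)
}

#' Random spectrum-level split
#'
#' Uniform random assignment of spectra to train/validation/test (three
#' ratios) or train/test (two ratios); set sizes follow largest-remainder
#' rounding of `N * ratios`. Deterministic per seed.
#'
#' @param ds a [spectral_dataset()].
#' @param ratios positive proportions summing to 1 (length 2 or 3).
#' @param seed integer seed.
#' @return a `split_assignment`: index vectors `train`, `validation`
#'   (possibly empty), `test`, plus `scheme`, `held_out_unit` (`NA`) and
#'   `seed`.
#' @export
random_split <- function(ds, ratios = c(0.70, 0.20, 0.10), seed = 1L) {
  n <- nrow(ds$intensities)
  if (!length(ratios) %in% 2:3) {
    stop("split error: need 2 or 3 ratios", call. = FALSE)
  }
  sizes <- largest_remainder_sizes(n, ratios)
  if (any(sizes == 0)) {
    stop("split error: a split set would be empty", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(n))
  cuts <- cumsum(sizes)
  if (length(ratios) == 3L) {
    assignment <- list(train = sort(idx[seq_len(cuts[1])]),
                       validation = sort(idx[(cuts[1] + 1L):cuts[2]]),
                       test = sort(idx[(cuts[2] + 1L):cuts[3]]))
    scheme <- sprintf("random_%d_%d_%d", round(100 * ratios[1]),
                      round(100 * ratios[2]), round(100 * ratios[3]))
  } else {
    assignment <- list(train = sort(idx[seq_len(cuts[1])]),
                       validation = integer(0),
                       test = sort(idx[(cuts[1] + 1L):cuts[2]]))
    scheme <- sprintf("random_%d_%d", round(100 * ratios[1]),
                      round(100 * ratios[2]))
  }
  structure(c(assignment,
              list(scheme = scheme, held_out_unit = NA_character_,
                   seed = as.integer(seed))),
            class = "split_assignment")
}

#' Leave-one-unit-out split assignments
#'
#' One assignment per hierarchy unit (mouse, tumour section or Raman map):
#' the unit's spectra form the test set and the remaining spectra are split
#' `train_val_ratio` into train/validation (use `c(1, 0)` for all-train, as
#' for the random forest). By default only irradiated units are held out;
#' control spectra always stay in training.
#'
#' @param ds a [spectral_dataset()].
#' @param level `"mouse"`, `"section"` or `"map"`.
#' @param units unit identifiers to hold out (default: all irradiated
#'   units, see [unit_ids()]).
#' @param train_val_ratio proportions for the remaining spectra.
#' @param seed integer seed for the train/validation assignment.
#' @return list of `split_assignment` objects.
#' @export
subject_wise_splits <- function(ds, level = c("mouse", "section", "map"),
                                units = NULL,
                                train_val_ratio = c(0.85, 0.15),
                                seed = 1L) {
  level <- match.arg(level)
  uid <- unit_ids(ds, level)
  if (is.null(units)) {
    units <- unique(uid[ds$meta$label == "irradiated"])
  }
  unknown <- setdiff(units, uid)
  if (length(unknown)) {
    stop("lookup error: unknown unit(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  all_train <- length(train_val_ratio) == 2 &&
    train_val_ratio[2] == 0
  lapply(seq_along(units), function(k) {
    u <- units[k]
    test <- which(uid == u)
    rest <- which(uid != u)
    if (all_train) {
      train <- rest
      validation <- integer(0)
    } else {
      sizes <- largest_remainder_sizes(length(rest), train_val_ratio)
      shuffled <- with_seed(seed + k, sample(rest))
      train <- sort(shuffled[seq_len(sizes[1])])
      validation <- sort(shuffled[(sizes[1] + 1L):length(rest)])
    }
    structure(list(train = train, validation = validation, test = test,
                   scheme = paste0("loo_", level), held_out_unit = u,
                   seed = as.integer(seed)),
              class = "split_assignment")
  })
}

#' Assert a subject-wise split leaks no held-out unit
#'
#' Verifies that no unit identifier present in the test set occurs in the
#' train or validation sets; raises a `radspectra_leakage_error` otherwise.
#'
#' @param ds a [spectral_dataset()].
#' @param split a `split_assignment`.
#' @param level hierarchy level of the unit identifiers.
#' @return `invisible(TRUE)` on success.
#' @export
assert_no_leakage <- function(ds, split, level) {
  uid <- unit_ids(ds, level)
  test_units <- unique(uid[split$test])
  seen <- unique(uid[c(split$train, split$validation)])
  leaked <- intersect(test_units, seen)
  if (length(leaked)) {
    stop(errorCondition(
      paste0("data-integrity error: held-out unit(s) present in training: ",
             paste(leaked, collapse = ", ")),
      class = c("radspectra_leakage_error", "error", "condition")))
  }
  invisible(TRUE)
}

#' Confusion counts (irradiated = positive class)
#'
#' @param truth,predicted label vectors/factors using
#'   `"nonirradiated"`/`"irradiated"`.
#' @return named list `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  list(TP = sum(truth == "irradiated" & predicted == "irradiated"),
       FP = sum(truth == "nonirradiated" & predicted == "irradiated"),
       TN = sum(truth == "nonirradiated" & predicted == "nonirradiated"),
       FN = sum(truth == "irradiated" & predicted == "nonirradiated"))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and F1 `2*precision*sensitivity/(precision+sensitivity)`.
#' A metric with a zero denominator is reported as `NA` (undefined), not 0.
#'
#' @param counts list or named vector with `TP`, `FP`, `TN`, `FN`.
#' @return list `accuracy`, `sensitivity`, `specificity`, `f1`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  TN <- counts[["TN"]]; FN <- counts[["FN"]]
  total <- TP + FP + TN + FN
  if (total <= 0) stop("metrics error: empty confusion table",
                       call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(TP, TP + FN)
  prec <- ratio(TP, TP + FP)
  f1 <- if (!is.na(sens) && !is.na(prec) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    NA_real_
  }
  list(accuracy = (TP + TN) / total,
       sensitivity = sens,
       specificity = ratio(TN, TN + FP),
       f1 = f1)
}

# Train the requested model on a split and return predicted labels for the
# test indices. `cnn_cfg`/`nmf_cfg`/`rf_cfg` seeds are replaced by `seed` so
# each run re-draws weights, scores and bootstraps.
fit_and_predict <- function(ds, split, model_spec, seed,
                            cnn_cfg, nmf_cfg, rf_cfg) {
  train_ds <- subset_spectra(ds, split$train)
  test_ds <- subset_spectra(ds, split$test)
  if (model_spec == "cnn") {
    cfg <- cnn_cfg
    cfg$seed <- as.integer(seed)
    val_ds <- if (length(split$validation)) {
      subset_spectra(ds, split$validation)
    } else {
      train_ds # degenerate: monitor on train when no validation set exists
    }
    model <- build_model(cfg)
    model <- train_cnn(model, train_ds, val_ds, cfg)
    classify(model, test_ds)
  } else {
    nmf_cfg$seed <- as.integer(seed)
    rf_cfg2 <- rf_cfg
    rf_cfg2$seed <- as.integer(seed)
    dec <- gbr_nmf_fit(train_ds, nmf_cfg)
    rf <- train_rf(dec$scores, class_labels(train_ds), rf_cfg2)
    test_scores <- gbr_nmf_transform(dec, test_ds)
    predict(rf, test_scores)
  }
}

#' Random-split experiment with multi-run aggregation
#'
#' For each run `r`, reseeds with `base_seed + r`, re-splits the dataset
#' (70/20/10 for the CNN; 75/25 train/test for GBR-NMF + RF), retrains and
#' evaluates on the test set. Results are aggregated as mean and sample
#' (n-1) SD over runs.
#'
#' @param ds a [spectral_dataset()] containing both classes.
#' @param model_spec `"cnn"` or `"gbr_nmf_rf"`.
#' @param n_runs number of repetitions (default 10).
#' @param base_seed per-run seeds are `base_seed + run`.
#' @param cnn_cfg a [cnn_config()] (CNN runs).
#' @param nmf_cfg an [nmf_config()] (GBR-NMF runs; required for
#'   `"gbr_nmf_rf"`).
#' @param rf_cfg an [rf_config()].
#' @param ratios optional split-ratio override.
#' @return a `run_summary`: data.frame `runs` (per-run seed, confusion
#'   counts and metrics), `mean`, `sd`, `n_runs`; with one run the SD is 0
#'   by convention and `degenerate_sd` is set.
#' @export
run_random_split_experiment <- function(ds,
                                        model_spec = c("cnn", "gbr_nmf_rf"),
                                        n_runs = 10L, base_seed = 1L,
                                        cnn_cfg = cnn_config(),
                                        nmf_cfg = NULL,
                                        rf_cfg = rf_config(),
                                        ratios = NULL) {
  model_spec <- match.arg(model_spec)
  if (n_runs < 1L) stop_config("n_runs", "must be >= 1")
  if (model_spec == "gbr_nmf_rf" && is.null(nmf_cfg)) {
    stop_config("nmf_cfg", "is required for the gbr_nmf_rf model")
  }
  if (is.null(ratios)) {
    ratios <- if (model_spec == "cnn") c(0.70, 0.20, 0.10) else
      c(rf_cfg$train_fraction, 1 - rf_cfg$train_fraction)
  }
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    seed <- base_seed + r
    rows[[r]] <- tryCatch({
      split <- random_split(ds, ratios, seed)
      pred <- fit_and_predict(ds, split, model_spec, seed,
                              cnn_cfg, nmf_cfg, rf_cfg)
      truth <- class_labels(subset_spectra(ds, split$test))
      cc <- confusion_counts(truth, pred)
      m <- compute_metrics(cc)
      data.frame(run = r, seed = seed, TP = cc$TP, FP = cc$FP, TN = cc$TN,
                 FN = cc$FN, accuracy = m$accuracy,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 f1 = m$f1)
    }, error = function(e) {
      stop(sprintf("run %d failed: %s", r, conditionMessage(e)),
           call. = FALSE)
    })
  }
  runs <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "f1")
  means <- vapply(runs[metric_cols], mean, numeric(1), na.rm = TRUE)
  sds <- if (n_runs > 1) {
    vapply(runs[metric_cols], sd, numeric(1), na.rm = TRUE)
  } else {
    stats::setNames(rep(0, length(metric_cols)), metric_cols)
  }
  structure(list(runs = runs, mean = as.list(means), sd = as.list(sds),
                 n_runs = n_runs, model = model_spec,
                 degenerate_sd = n_runs == 1L),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> %s, %d run(s)\n", x$model, x$n_runs))
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.1f%% +/- %.1f%%\n", m, 100 * x$mean[[m]],
                100 * x$sd[[m]]))
  }
  if (x$degenerate_sd) cat("  (single run: SD = 0 by convention)\n")
  invisible(x)
}

#' Subject-wise (leave-one-unit-out) experiment
#'
#' For each held-out mouse / tumour section / Raman map: train on all
#' remaining spectra (85/15 train/validation for the CNN; all-train for the
#' RF), verify zero unit leakage, and report the fraction of the held-out
#' unit's spectra assigned their true label.
#'
#' @inheritParams run_random_split_experiment
#' @param level `"mouse"`, `"section"` or `"map"`.
#' @param units unit identifiers to hold out (default: irradiated units).
#' @param base_seed seed; per-unit training seeds are `base_seed + k`.
#' @return a `subject_wise_summary`: data.frame `units` (unit, n_test,
#'   fraction_correct), plus `mean` and `sd` across units.
#' @export
run_subject_wise_experiment <- function(ds,
                                        model_spec = c("cnn", "gbr_nmf_rf"),
                                        level = c("mouse", "section",
                                                  "map"),
                                        units = NULL, base_seed = 1L,
                                        cnn_cfg = cnn_config(),
                                        nmf_cfg = NULL,
                                        rf_cfg = rf_config()) {
  model_spec <- match.arg(model_spec)
  level <- match.arg(level)
  if (model_spec == "gbr_nmf_rf" && is.null(nmf_cfg)) {
    stop_config("nmf_cfg", "is required for the gbr_nmf_rf model")
  }
  ratio <- if (model_spec == "cnn") c(0.85, 0.15) else c(1, 0)
  splits <- subject_wise_splits(ds, level, units, ratio, base_seed)
  rows <- vector("list", length(splits))
  for (k in seq_along(splits)) {
    split <- splits[[k]]
    rows[[k]] <- tryCatch({
      assert_no_leakage(ds, split, level)
      pred <- fit_and_predict(ds, split, model_spec, base_seed + k,
                              cnn_cfg, nmf_cfg, rf_cfg)
      truth <- class_labels(subset_spectra(ds, split$test))
      data.frame(unit = split$held_out_unit, n_test = length(split$test),
                 fraction_correct = mean(as.character(pred) ==
                                           as.character(truth)),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      if (inherits(e, "radspectra_leakage_error")) stop(e)
      stop(sprintf("unit '%s' failed: %s", split$held_out_unit,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  units_df <- do.call(rbind, rows)
  structure(list(units = units_df,
                 mean = mean(units_df$fraction_correct),
                 sd = if (nrow(units_df) > 1) sd(units_df$fraction_correct)
                      else 0,
                 level = level, model = model_spec),
            class = "subject_wise_summary")
}

#' @export
print.subject_wise_summary <- function(x, ...) {
  cat(sprintf(
    "<subject_wise_summary> %s, leave-one-%s-out over %d units: %.1f%% +/- %.1f%%\n",
    x$model, x$level, nrow(x$units), 100 * x$mean, 100 * x$sd))
  invisible(x)
}

#' Wilcoxon comparison of two accuracy sequences
#'
#' Two-sided Wilcoxon rank-sum test (unpaired by default; Fig.-4-style
#' unpaired comparison), exact when the combined sample size is at most 25
#' and there are no ties, normal approximation with continuity and tie
#' correction otherwise. A signed-rank (paired) variant is available by
#' flag.
#'
#' @param a,b numeric accuracy sequences (length >= 2).
#' @param paired use the paired signed-rank test.
#' @param alpha significance level (default 0.05).
#' @return a `comparison_result`: `p_value`, `significant`, `statistic`,
#'   `degenerate` (all values identical across both samples, p = 1).
#' @export
wilcoxon_compare <- function(a, b, paired = FALSE, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least two values per sample", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1L) {
    return(structure(list(p_value = 1, significant = FALSE,
                          statistic = NA_real_, degenerate = TRUE,
                          model_a_accuracies = a, model_b_accuracies = b),
                     class = "comparison_result"))
  }
  wt <- if (paired) {
    suppressWarnings(wilcox.test(a, b, paired = TRUE))
  } else {
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- !ties && (length(a) + length(b)) <= 25
    suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  }
  structure(list(p_value = wt$p.value,
                 significant = wt$p.value < alpha,
                 statistic = unname(wt$statistic), degenerate = FALSE,
                 model_a_accuracies = a, model_b_accuracies = b),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> p = %.4g (%ssignificant at 0.05)%s\n",
              x$p_value, if (x$significant) "" else "not ",
              if (x$degenerate) " [degenerate: identical samples]" else ""))
  invisible(x)
}
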