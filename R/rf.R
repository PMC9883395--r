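#' Random-forest configuration
#'
#' Defaults follow the published setup: 2000 trees, 5 candidate variables
#' per split, a 75/25 train/test split when used in random-split runs, and
#' permutation importance averaged over 10 permutations per feature.
#'
#' @param n_trees number of trees.
#' @param vars_per_split candidate features per split (`mtry`).
#' @param train_fraction training proportion for random-split experiments.
#' @param n_permutations permutations per feature for [mda_importance()].
#' @param seed integer seed.
#' @return an `rf_config` list.
#' @export
rf_config <- function(n_trees = 2000L, vars_per_split = 5L,
                      train_fraction = 0.75, n_permutations = 10L,
                      seed = 1L) {
  cfg <- list(n_trees = as.integer(n_trees),
              vars_per_split = as.integer(vars_per_split),
              train_fraction = train_fraction,
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed))
  if (cfg$n_trees < 1L) stop_config("n_trees", "must be >= 1")
  if (cfg$vars_per_split < 1L) stop_config("vars_per_split", "must be >= 1")
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    stop_config("train_fraction", "must be in (0, 1)")
  }
  class(cfg) <- "rf_config"
  cfg
}

#' Train a random forest on NMF scores
#'
#' CART trees grown to purity on bootstrap samples with Gini splits and
#' `vars_per_split` candidate features per split. Deterministic for a fixed
#' `cfg$seed`.
#'
#' @param scores numeric feature matrix (`n x p`), e.g. GBR-NMF scores.
#' @param labels factor or character labels with both classes present
#'   (positive class `"irradiated"`).
#' @param cfg an [rf_config()].
#' @return an `rf_model`.
#' @export
train_rf <- function(scores, labels, cfg = rf_config()) {
  scores <- as.matrix(scores)
  labels <- factor(as.character(labels),
                   levels = c("nonirradiated", "irradiated"))
  if (anyNA(labels)) {
    stop("training error: labels must be nonirradiated/irradiated",
         call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("training error: single-class labels", call. = FALSE)
  }
  if (ncol(scores) < cfg$vars_per_split) {
    stop_config("vars_per_split", "exceeds the number of features")
  }
  y <- as.integer(labels == "irradiated")
  forest <- with_seed(cfg$seed,
                      rf_fit_cpp(scores, y, cfg$n_trees,
                                 cfg$vars_per_split, 1L))
  structure(list(forest = forest, n_features = ncol(scores),
                 class_order = c("nonirradiated", "irradiated"),
                 config = cfg),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, %d features, mtry %d\n",
              length(x$forest), x$n_features, x$config$vars_per_split))
  invisible(x)
}

#' Predict with a trained random forest
#'
#' @param object an `rf_model`.
#' @param newdata feature matrix with the training feature count.
#' @param type `"class"` (majority vote; ties to `"nonirradiated"`) or
#'   `"prob"` (vote fractions).
#' @param ... unused.
#' @return factor of labels, or an `n x 2` vote-fraction matrix.
#' @export
predict.rf_model <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop(sprintf("shape error: %d features supplied, %d expected",
                 ncol(newdata), object$n_features), call. = FALSE)
  }
  votes1 <- rf_vote_cpp(object$forest, newdata)
  if (type == "prob") {
    out <- cbind(nonirradiated = 1 - votes1, irradiated = votes1)
    return(out)
  }
  factor(ifelse(votes1 > 0.5, "irradiated", "nonirradiated"),
         levels = object$class_order)
}

#' Permutation (Mean Decrease Accuracy) importance
#'
#' For each feature, permutes its column in the evaluation set
#' `n_permutations` times and averages the resulting accuracy drop. This is
#' explicit test-set permutation importance (not the out-of-bag variant).
#'
#' @param forest a trained `rf_model`.
#' @param scores evaluation feature matrix.
#' @param labels evaluation labels.
#' @param cfg an [rf_config()] (`n_permutations >= 1`; permutations are
#'   seeded from `cfg$seed`).
#' @return an `importance_ranking` data.frame with columns `feature`, `mda`,
#'   `se` and `rank` (1 = most important; ties broken by feature order).
#' @export
mda_importance <- function(forest, scores, labels, cfg = forest$config) {
  if (cfg$n_permutations < 1L) {
    stop_config("n_permutations", "must be >= 1")
  }
  scores <- as.matrix(scores)
  if (nrow(scores) == 0) stop("empty evaluation set", call. = FALSE)
  truth <- factor(as.character(labels),
                  levels = c("nonirradiated", "irradiated"))
  base_acc <- mean(predict(forest, scores) == truth)
  p <- ncol(scores)
  mda <- se <- numeric(p)
  with_seed(cfg$seed, {
    for (j in seq_len(p)) {
      drops <- numeric(cfg$n_permutations)
      for (k in seq_len(cfg$n_permutations)) {
        perm <- scores
        perm[, j] <- perm[sample.int(nrow(perm)), j]
        drops[k] <- base_acc - mean(predict(forest, perm) == truth)
      }
      mda[j] <- mean(drops)
      se[j] <- if (cfg$n_permutations > 1) {
        sd(drops) / sqrt(cfg$n_permutations)
      } else {
        NA_real_
      }
    }
  })
  ord <- order(-mda, seq_len(p))
  rank <- integer(p)
  rank[ord] <- seq_len(p)
  structure(data.frame(feature = seq_len(p), mda = mda, se = se,
                       rank = rank),
            class = c("importance_ranking", "data.frame"))
}
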