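test_that("conv output length follows (I - K + 2P)/S + 1 with no flooring", {
  expect_identical(conv_output_length(582, 20, 0, 1), 563L)
  expect_identical(conv_output_length(563, 20, 0, 1), 544L)
  for (I in c(1L, 5L, 17L)) {
    expect_identical(conv_output_length(I, 1, 0, 1), I)
  }

  # brute-force count of valid sliding-window positions
  count_positions <- function(I, K, P, S) {
    starts <- seq(1 - P, I + P - K + 1)      # window start, padded axis
    sum((starts - (1 - P)) %% S == 0)
  }
  expect_identical(conv_output_length(10, 3, 0, 1),
                   count_positions(10, 3, 0, 1))
  set.seed(17)
  for (i in 1:20) {
    K <- sample(2:8, 1)
    S <- sample(1:3, 1)
    P <- sample(0:3, 1)
    O <- sample(3:20, 1)
    I <- (O - 1) * S + K - 2 * P             # valid by construction
    if (I < 1) next
    expect_identical(conv_output_length(I, K, P, S),
                     count_positions(I, K, P, S))
  }

  expect_error(conv_output_length(10, 3, 0, 2), "shape error")
  expect_error(conv_output_length(5, 9, 0, 1), "shape error")
})

test_that("the default architecture builds with the published shapes", {
  m <- build_model(cnn_config())
  expect_identical(m$shapes$conv_lengths, c(563L, 544L))
  expect_identical(m$shapes$conv_channels, c(32L, 64L))
  expect_identical(m$shapes$flatten_dim, 544L * 64L)
  expect_identical(unname(m$shapes$fc_dims[length(m$shapes$fc_dims)]), 2L)

  obs <- layer_output_shapes(m)
  expect_identical(obs$conv1, c(563L, 32L))
  expect_identical(obs$conv2, c(544L, 64L))
  expect_identical(obs$output, 2L)

  m2 <- build_model(cnn_config())
  expect_identical(m$params, m2$params)    # same seed, same init

  bad <- cnn_config(input_length = 30L)
  expect_error(build_model(bad), "conv block 2")
})

test_that("one Adam step decreases the minibatch loss", {
  ds <- generate_dataset(separable_config(spectra_per_map = 4,
                                          n_mice_per_arm = 2))
  cfg <- tiny_cnn_config(seed = 3)
  model <- build_model(cfg)
  X <- ds$intensities[1:32, ]
  y <- as.integer(ds$meta$label[1:32] == "irradiated")
  set.seed(1)
  fg1 <- radspectra:::cnn_loss_grad(model, X, y)
  opt <- radspectra:::adam_init(model$params)
  st <- radspectra:::adam_step(model$params, fg1$grads, opt, cfg)
  model$params <- st$params
  set.seed(1)                                # same dropout mask
  fg2 <- radspectra:::cnn_loss_grad(model, X, y)
  expect_lt(fg2$loss, fg1$loss)
})

test_that("training separates a strong-effect fixture and tracks history", {
  ds <- generate_dataset(separable_config())
  sp <- random_split(ds, c(0.7, 0.2, 0.1), 1)
  cfg <- tiny_cnn_config(seed = 5, max_epochs = 30L, patience = 10L)
  m <- train_cnn(build_model(cfg), subset_spectra(ds, sp$train),
                 subset_spectra(ds, sp$validation), cfg)

  h <- m$history
  expect_gte(max(h$train_accuracy), 0.99)
  expect_identical(h$best_epoch, which.max(h$validation_accuracy))
  expect_identical(length(h$train_accuracy), length(h$validation_accuracy))
  expect_identical(length(h$train_accuracy), length(h$train_loss))

  # best-epoch contract: reloaded weights reproduce the recorded accuracy
  val <- subset_spectra(ds, sp$validation)
  pred <- classify(m, val)
  acc <- mean(as.character(pred) == as.character(class_labels(val)))
  expect_identical(acc, h$validation_accuracy[h$best_epoch])

  test <- subset_spectra(ds, sp$test)
  acc_test <- mean(as.character(classify(m, test)) ==
                     as.character(class_labels(test)))
  expect_gte(acc_test, 0.99)

  expect_error(train_cnn(build_model(cfg),
                         subset_spectra(ds, which(ds$meta$dose_gy == 0)),
                         val, cfg),
               "single class")
})

test_that("inference is deterministic with normalized probabilities", {
  ds <- generate_dataset(separable_config(spectra_per_map = 2,
                                          n_mice_per_arm = 1))
  cfg <- tiny_cnn_config(seed = 2, max_epochs = 2L)
  sp <- random_split(ds, c(0.6, 0.2, 0.2), 3)
  m <- train_cnn(build_model(cfg), subset_spectra(ds, sp$train),
                 subset_spectra(ds, sp$validation), cfg)

  p1 <- predict_proba(m, ds)
  p2 <- predict_proba(m, ds)
  expect_identical(p1, p2)
  expect_true(all(abs(rowSums(p1) - 1) < 1e-6))
  expect_true(all(p1 >= 0 & p1 <= 1))

  pd <- predict_proba(m, ds$intensities[c(1, 1), ])
  expect_identical(pd[1, ], pd[2, ])

  expect_error(predict_proba(m, matrix(0, 2, 100)), "shape error")
})

test_that("softmax symmetry and the tie-break both favour nonirradiated", {
  expect_equal(radspectra:::softmax_rows(matrix(0, 1, 2)),
               matrix(0.5, 1, 2))

  # zeroed output layer forces logits (0, 0) for any input
  cfg <- tiny_cnn_config(seed = 1)
  m <- build_model(cfg)
  last <- length(m$params$fc)
  m$params$fc[[last]]$W[] <- 0
  m$params$fc[[last]]$b[] <- 0
  X <- matrix(runif(3 * 582), 3, 582)
  probs <- predict_proba(m, X)
  expect_true(all(abs(probs - 0.5) < 1e-12))
  expect_true(all(classify(m, X) == "nonirradiated"))
})
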