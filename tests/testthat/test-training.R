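test_that("split_dataset is disjoint, exhaustive, stratified and seeded", {
  ds <- toy_dataset(8, 8, seed = 2)
  ex <- ds$train
  parts <- split_dataset(ex, 0.2, seed = 5)
  expect_equal(nrow(parts$train), 13) # 16 examples, stratified 80:20
  expect_equal(nrow(parts$validation), 3)
  expect_equal(sort(c(parts$train$id, parts$validation$id)), sort(ex$id))
  expect_length(intersect(parts$train$id, parts$validation$id), 0)
  # both classes present on both sides
  is_pos <- function(tbl) vapply(tbl$labels, function(l) any(l == 1), logical(1))
  expect_true(any(is_pos(parts$train)) && any(!is_pos(parts$train)))
  expect_true(any(is_pos(parts$validation)) && any(!is_pos(parts$validation)))

  again <- split_dataset(ex, 0.2, seed = 5)
  expect_identical(parts, again)

  two <- ex[1:2, ]
  halves <- suppressWarnings(split_dataset(two, 0.5, seed = 1))
  expect_equal(nrow(halves$train), 1)
  expect_equal(nrow(halves$validation), 1)
})

test_that("stratification falls back with a warning on tiny classes", {
  ds <- toy_dataset(8, 8, seed = 3)
  ex <- ds$train[c(1, 9:12), ] # one positive, four negatives
  expect_warning(split_dataset(ex, 0.4, seed = 1), "unstratified")
})

test_that("masked loss matches closed forms and ignores masked logits", {
  L <- 8
  labels <- c(1, 1, 0, 0, 1, 0, 0, 0)
  mask <- c(1, 1, 1, 1, 1, 0, 0, 0)
  # uniform logits: every unmasked position contributes ln 2
  expect_equal(masked_loss(matrix(0, L, 2), labels, mask), log(2))
  # strongly correct logits drive the loss toward zero
  strong <- cbind(ifelse(labels == 0, 50, -50), ifelse(labels == 1, 50, -50))
  expect_lt(masked_loss(strong, labels, mask), 1e-10)
  # perturbing masked positions changes nothing, bit for bit
  set.seed(51)
  logits <- matrix(rnorm(2 * L), L, 2)
  ref <- masked_loss(logits, labels, mask)
  perturbed <- logits
  perturbed[mask == 0, ] <- rnorm(sum(mask == 0) * 2) * 100
  expect_identical(masked_loss(perturbed, labels, mask), ref)
  # all-zero mask is a data bug, not a zero loss
  expect_error(masked_loss(logits, labels, rep(0, L)), "mask")
})

test_that("masked loss equals a scalar brute-force recomputation", {
  set.seed(52)
  for (rep in 1:20) {
    L <- sample(4:24, 1)
    logits <- matrix(rnorm(2 * L, sd = 3), L, 2)
    labels <- sample(0:1, L, replace = TRUE)
    mask <- sample(0:1, L, replace = TRUE)
    if (sum(mask) == 0) mask[1] <- 1
    brute <- 0
    for (i in seq_len(L)) {
      if (mask[i] == 1) {
        p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
        brute <- brute - log(p[labels[i] + 1])
      }
    }
    brute <- brute / sum(mask)
    expect_equal(masked_loss(logits, labels, mask), brute, tolerance = 1e-6)
  }
})

test_that("the early-stopping rule follows the strict-improvement contract", {
  esp <- rclseg:::early_stop_point(
    c(0.50, 0.60, 0.60, 0.60, 0.60, 0.60, 0.60),
    patience = 5
  )
  expect_true(esp$stopped_early)
  expect_equal(esp$stop_epoch, 7) # five consecutive non-improvements
  expect_equal(esp$best_epoch, 2)

  mono <- rclseg:::early_stop_point(seq(0.1, 0.9, by = 0.1), patience = 5)
  expect_false(mono$stopped_early)
  expect_equal(mono$best_epoch, 9)

  # a late improvement resets the patience counter
  late <- rclseg:::early_stop_point(c(0.5, 0.4, 0.4, 0.4, 0.6, 0.6), patience = 4)
  expect_false(late$stopped_early)
  expect_equal(late$best_epoch, 5)
})

test_that("training reduces the loss and is bit-reproducible under a seed", {
  # 64-residue scaffolds keep the toy run fast while still hosting a loop
  cfg <- sim_config(
    n_positive = 10, n_negative = 10, length_mean = 64, length_sd = 0,
    loop_len_min = 20, loop_len_max = 24, seed = 4
  )
  enc <- make_encoder("onehot")
  tc <- train_config(
    max_epochs = 6, patience = 5, batch_size = 8, seed = 9
  )
  run <- function(arch) {
    ds <- generate_dataset(cfg, l_fixed = 64)
    parts <- split_dataset(ds$train, 0.2, seed = 3)
    model <- build_model(small_model_config(arch), seed = 31)
    train_model(model, parts$train, parts$validation, enc, tc, l_fixed = 64)
  }
  for (arch in c("cnn", "unet", "bilstm")) {
    fit <- run(arch)
    expect_lt(
      fit$history$train_loss[nrow(fit$history)],
      fit$history$train_loss[1]
    )
    expect_equal(fit$best_epoch, which.max(fit$history$val_f1))
    expect_true(all(is.finite(fit$history$val_loss)))
  }
  # identical seed, identical everything
  f1 <- run("cnn")
  f2 <- run("cnn")
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("tidy, glance and autoplot expose the training history", {
  cfg <- sim_config(
    n_positive = 6, n_negative = 6, length_mean = 64, length_sd = 0,
    loop_len_min = 20, loop_len_max = 24, seed = 7
  )
  ds <- generate_dataset(cfg, l_fixed = 64)
  parts <- split_dataset(ds$train, 0.25, seed = 1)
  enc <- make_encoder("onehot")
  fit <- train_model(
    build_model(small_model_config("cnn"), seed = 1),
    parts$train, parts$validation, enc,
    train_config(max_epochs = 3, patience = 2, batch_size = 4, seed = 1),
    l_fixed = 64
  )
  td <- tidy(fit)
  expect_equal(names(td), c("epoch", "train_loss", "val_loss", "val_f1"))
  gl <- glance(fit)
  expect_equal(gl$architecture, "cnn")
  expect_equal(gl$epochs, nrow(td))
  expect_equal(gl$n_parameters, n_parameters(fit$model))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("a mismatched encoder dimension is rejected up front", {
  ds <- toy_dataset(4, 4, l_fixed = 128, seed = 8)
  parts <- split_dataset(ds$train, 0.25, seed = 1)
  model <- build_model(model_config("cnn", input_dim = 7), seed = 1)
  expect_error(
    train_model(
      model, parts$train, parts$validation, make_encoder("onehot"),
      train_config(max_epochs = 2, patience = 1, seed = 1)
    ),
    "input_dim"
  )
})
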