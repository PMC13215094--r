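rand_features <- function(B, L, D, seed = 1) {
  set.seed(seed)
  array(rnorm(B * L * D), dim = c(B, L, D))
}

test_that("all architectures preserve length and emit two logits per residue", {
  D <- 6
  for (arch in c("cnn", "unet", "bilstm")) {
    cfg <- model_config(arch,
      input_dim = D, base_channels = 4, depth = 2, lstm_hidden = 8
    )
    model <- build_model(cfg, seed = 2)
    for (L in c(16L, 32L, 64L)) {
      out <- predict_logits(model, rand_features(2, L, D)[1, , ])
      expect_equal(dim(out), c(L, 2L))
      expect_true(all(is.finite(out)))
      batched <- predict_logits(model, rand_features(3, L, D))
      expect_equal(dim(batched), c(3L, L, 2L))
    }
  }
})

test_that("the U-Net rejects lengths not divisible by 2^depth, by name", {
  cfg <- model_config("unet", input_dim = 5, base_channels = 4, depth = 4)
  model <- build_model(cfg, seed = 1)
  expect_error(
    predict_logits(model, matrix(rnorm(100 * 5), 100, 5)),
    "divisible by 2\\^depth"
  )
  # depth 2 toy: 256 -> bottleneck 64 -> 256 restored
  cfg2 <- model_config("unet", input_dim = 5, base_channels = 4, depth = 2)
  m2 <- build_model(cfg2, seed = 1)
  expect_equal(dim(predict_logits(m2, matrix(rnorm(256 * 5), 256, 5))), c(256L, 2L))
})

test_that("builds are deterministic under a fixed seed", {
  for (arch in c("cnn", "unet", "bilstm")) {
    cfg <- small_model_config(arch, input_dim = 5)
    m1 <- build_model(cfg, seed = 99)
    m2 <- build_model(cfg, seed = 99)
    expect_identical(m1$params, m2$params)
  }
})

test_that("evaluation-mode forward is deterministic and batch-independent", {
  D <- 5
  X <- rand_features(2, 32, D, seed = 8)
  for (arch in c("cnn", "bilstm")) {
    model <- build_model(small_model_config(arch, D), seed = 3)
    out1 <- predict_logits(model, X)
    out2 <- predict_logits(model, X)
    expect_identical(out1, out2)
    single <- predict_logits(model, X[1, , ])
    expect_equal(out1[1, , ], single, tolerance = 1e-12)
  }
})

test_that("zero input still yields finite bias-driven logits", {
  for (arch in c("cnn", "unet", "bilstm")) {
    model <- build_model(small_model_config(arch, 5), seed = 4)
    out <- predict_logits(model, matrix(0, 16, 5))
    expect_true(all(is.finite(out)))
  }
})

test_that("the CNN receptive field is local; U-Net and BiLSTM reach far", {
  D <- 5
  L <- 64L
  set.seed(17)
  base <- matrix(rnorm(L * D), L, D)
  pert <- base
  j <- 30L
  pert[j, ] <- pert[j, ] + 5

  cnn <- build_model(
    model_config("cnn", input_dim = D, base_channels = 4, depth = 2),
    seed = 5
  )
  delta <- rowSums(abs(predict_logits(cnn, pert) - predict_logits(cnn, base)))
  radius <- 2 * (3 - 1) / 2 # depth * (kernel - 1) / 2
  expect_true(all(delta[abs(seq_len(L) - j) > radius] == 0))
  expect_gt(delta[j], 0)

  for (arch in c("unet", "bilstm")) {
    model <- build_model(
      model_config(arch,
        input_dim = D, base_channels = 4, depth = 4, lstm_hidden = 8
      ),
      seed = 6
    )
    d <- rowSums(abs(predict_logits(model, pert) - predict_logits(model, base)))
    expect_true(any(d[abs(seq_len(L) - j) > 16] > 0))
  }
})

test_that("a BiLSTM position responds to distant context", {
  D <- 4
  model <- build_model(
    model_config("bilstm", input_dim = D, lstm_hidden = 6),
    seed = 7
  )
  set.seed(23)
  base <- matrix(rnorm(16 * D), 16, D)
  pert <- base
  pert[16, ] <- pert[16, ] + 3
  out_b <- predict_logits(model, base)
  out_p <- predict_logits(model, pert)
  expect_gt(sum(abs(out_p[1, ] - out_b[1, ])), 0)
  # degenerate single real position still yields finite logits
  one <- matrix(0, 16, D)
  one[1, ] <- rnorm(D)
  expect_true(all(is.finite(predict_logits(model, one))))
})

test_that("parameter counts match hand-computed formulas", {
  D <- 5L
  k <- 3L
  # CNN: depth 2, base 4 -> widths 4, 8
  cnn <- build_model(
    model_config("cnn", input_dim = D, base_channels = 4, depth = 2), seed = 1
  )
  conv_n <- function(cin, cout) k * cin * cout + cout
  bn_n <- function(c) 2 * c
  cnn_expected <- conv_n(D, 4) + bn_n(4) + conv_n(4, 8) + bn_n(8) + (8 * 2 + 2)
  expect_equal(n_parameters(cnn), cnn_expected)

  # BiLSTM: hidden 6 per direction
  h <- 6L
  bil <- build_model(
    model_config("bilstm", input_dim = D, lstm_hidden = h), seed = 1
  )
  lstm_n <- D * 4 * h + h * 4 * h + 4 * h
  expect_equal(n_parameters(bil), 2 * lstm_n + (2 * h * 2 + 2))

  # U-Net: depth 2, base 4 -> widths 4, 8; bottleneck 16
  un <- build_model(
    model_config("unet", input_dim = D, base_channels = 4, depth = 2), seed = 1
  )
  dc_n <- function(cin, cout) {
    conv_n(cin, cout) + bn_n(cout) + conv_n(cout, cout) + bn_n(cout)
  }
  up_n <- function(cin, cout) 2 * cin * cout + cout
  att_n <- function(c) {
    ci <- max(1, c %/% 2)
    2 * c * ci + ci + ci + 1
  }
  unet_expected <- dc_n(D, 4) + dc_n(4, 8) + # encoder
    dc_n(8, 16) + # bottleneck
    up_n(16, 8) + att_n(8) + dc_n(16, 8) + # decoder stage 1
    up_n(8, 4) + att_n(4) + dc_n(8, 4) + # decoder stage 2
    (4 * 2 + 2) # head
  expect_equal(n_parameters(un), unet_expected)
})

test_that("the attention gate bounds its output by the skip features", {
  set.seed(33)
  skip <- matrix(rnorm(24 * 6), 24, 6)
  gate <- matrix(rnorm(24 * 6), 24, 6)
  res <- attention_gate(skip, gate)
  expect_true(all(res$alpha > 0 & res$alpha < 1))
  expect_true(all(abs(res$out) <= abs(skip) + 1e-12))

  # saturated gate passes the skip through; suppressed gate annihilates it
  p <- rclseg:::nn_att_init(6)
  p$bpsi <- 50
  expect_equal(attention_gate(skip, gate, p)$out, skip, tolerance = 1e-8)
  p$bpsi <- -50
  expect_equal(max(abs(attention_gate(skip, gate, p)$out)), 0, tolerance = 1e-8)

  expect_error(attention_gate(skip[1:10, ], gate), "length")
})

test_that("checkpoints round-trip weights and are self-describing", {
  model <- build_model(small_model_config("cnn", 20), seed = 12)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path, encoding = "onehot", l_fixed = 64L)
  ck <- load_checkpoint(path)
  expect_identical(ck$model$params, model$params)
  expect_equal(ck$encoding, "onehot")
  expect_equal(ck$l_fixed, 64L)
  expect_equal(ck$channel_order, paste(AA20, collapse = ""))
  X <- matrix(rnorm(64 * 20), 64, 20)
  expect_identical(predict_logits(ck$model, X), predict_logits(model, X))
})

test_that("model gradients match finite differences on every architecture", {
  ns <- asNamespace("rclseg")
  eps <- 1e-5
  for (arch in c("cnn", "unet", "bilstm")) {
    cfg <- model_config(arch,
      input_dim = 4, base_channels = 4, depth = 2,
      dropout = 0, lstm_hidden = 5
    )
    model <- build_model(cfg, seed = 13)
    B <- 2L
    L <- 16L
    set.seed(14)
    X <- matrix(rnorm(B * L * 4), B * L, 4)
    labels <- sample(0:1, B * L, replace = TRUE)
    mask <- c(rep(1, B * L - 6), rep(0, 6))
    fwd <- ns$model_fwd(model, X, B, L, training = TRUE)
    ce <- ns$ce_masked(fwd$out, labels, mask, want_grad = TRUE)
    grads <- ns$model_bwd(model, fwd$cache, ce$dlogits)
    loss_of <- function(params) {
      m2 <- model
      m2$params <- params
      ns$ce_masked(
        ns$model_fwd(m2, X, B, L, training = TRUE)$out, labels, mask
      )$loss
    }
    # probe the first weight of the first leaf matrix in each top branch
    for (branch in names(model$params)) {
      leaf_path <- list(branch)
      leaf <- model$params[[branch]]
      g <- grads[[branch]]
      while (is.list(leaf)) {
        leaf_path <- c(leaf_path, 1L)
        leaf <- leaf[[1]]
        g <- g[[1]]
      }
      p1 <- model$params
      p2 <- model$params
      modify <- function(p, path, delta) {
        if (length(path) == 1) {
          p[[path[[1]]]][1] <- p[[path[[1]]]][1] + delta
          return(p)
        }
        p[[path[[1]]]] <- modify(p[[path[[1]]]], path[-1], delta)
        p
      }
      num <- (loss_of(modify(p1, leaf_path, eps)) -
        loss_of(modify(p2, leaf_path, -eps))) / (2 * eps)
      expect_equal(g[1], num, tolerance = 1e-4)
    }
  }
})
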