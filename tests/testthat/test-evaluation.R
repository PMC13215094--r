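test_that("predict_labels converts logits with the documented tie-break", {
  logits <- rbind(c(0, 3), c(0, 0), c(5, -5))
  out <- predict_labels(logits)
  expect_equal(out$prob[1], 1 / (1 + exp(-3)), tolerance = 1e-12)
  expect_equal(out$labels, c(1L, 1L, 0L)) # 0.5 ties go to the positive class
  expect_equal(out$prob[2], 0.5)

  masked <- predict_labels(rbind(c(0, 10), c(0, 10)), mask = c(1, 0))
  expect_equal(masked$labels, c(1L, 0L))
  expect_equal(masked$prob[2], 0)
})

test_that("residue metrics reproduce hand-checked confusion cases", {
  m <- residue_metrics(list(tp = 2, fp = 1, fn = 1, tn = 6))
  expect_equal(m$f1, 2 / 3, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.8)

  perfect <- residue_metrics(list(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(
    unlist(perfect[, c("precision", "recall", "f1", "mcc", "accuracy")]),
    c(precision = 1, recall = 1, f1 = 1, mcc = 1, accuracy = 1)
  )

  coin <- residue_metrics(list(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(coin$mcc, 0)
  expect_equal(coin$accuracy, 0.5)

  # degenerate denominators map to zero instead of NaN
  allneg <- residue_metrics(list(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_equal(allneg$f1, 0)
  expect_equal(allneg$mcc, 0)
})

brute_metrics <- function(tp, fp, fn, tn) {
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- ifelse(den == 0, 0, num / den)
  acc <- (tp + tn) / (tp + fp + fn + tn)
  list(precision = prec, recall = rec, f1 = f1, mcc = mcc, accuracy = acc)
}

test_that("residue metrics agree with an independent recomputation", {
  set.seed(61)
  for (i in 1:300) {
    v <- as.list(rpois(4, lambda = sample(c(1, 10, 100), 1)))
    names(v) <- c("tp", "fp", "fn", "tn")
    if (Reduce(`+`, v) == 0) v$tn <- 1
    got <- residue_metrics(v)
    ref <- brute_metrics(v$tp, v$fp, v$fn, v$tn)
    for (k in names(ref)) {
      expect_equal(got[[k]], ref[[k]], tolerance = 1e-9)
    }
  }
})

test_that("MCC is invariant under jointly swapping classes", {
  set.seed(62)
  for (i in 1:50) {
    v <- rpois(4, 20) + 1
    a <- residue_metrics(list(tp = v[1], fp = v[2], fn = v[3], tn = v[4]))$mcc
    b <- residue_metrics(list(tp = v[4], fp = v[3], fn = v[2], tn = v[1]))$mcc
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("span extraction finds maximal runs with mean probabilities", {
  sp <- extract_spans(c(0, 0, 1, 1, 1, 0), c(0.1, 0.2, 0.9, 0.8, 0.7, 0.3))
  expect_equal(sp$start, 3L)
  expect_equal(sp$end, 5L)
  expect_equal(sp$prob, 0.8)

  two <- extract_spans(c(1, 0, 1))
  expect_equal(two$start, c(1L, 3L))
  expect_equal(two$end, c(1L, 3L))

  expect_equal(nrow(extract_spans(c(0, 0, 0))), 0)
  expect_equal(nrow(extract_spans(integer(0))), 0)
})

test_that("primary_span keeps the longest span, earliest on ties", {
  spans <- tibble::tibble(start = c(3L, 10L), end = c(5L, 20L), prob = c(1, 1))
  expect_equal(primary_span(spans)$start, 10L)
  ties <- tibble::tibble(start = c(3L, 10L), end = c(7L, 14L), prob = c(1, 1))
  expect_equal(primary_span(ties)$start, 3L)
  expect_equal(nrow(primary_span(ties[0, ])), 0)
})

test_that("exact match demands per-residue identity over unmasked positions", {
  truth <- replicate(100, c(0, 1, 1, 0), simplify = FALSE)
  masks <- replicate(100, c(1, 1, 1, 1), simplify = FALSE)
  pred <- truth
  for (i in 1:3) pred[[i]] <- c(0, 1, 0, 0) # off by one boundary residue
  expect_equal(exact_match_rate(pred, truth, masks), 0.97)

  # masked disagreement does not count against the match
  pred2 <- list(c(0, 1, 9))
  truth2 <- list(c(0, 1, 0))
  mask2 <- list(c(1, 1, 0))
  expect_equal(exact_match_rate(pred2, truth2, mask2), 1)

  expect_error(exact_match_rate(list(), list(), list()), "Empty")
  expect_error(
    exact_match_rate(list(c(1, 0)), list(c(1)), list(c(1))),
    "mismatch"
  )
})

test_that("evaluate_model agrees with a scalar per-position reimplementation", {
  ds <- toy_dataset(10, 10, l_fixed = 128, seed = 71)
  enc <- make_encoder("onehot")
  model <- build_model(
    model_config("cnn", input_dim = 20, base_channels = 4, depth = 2),
    seed = 72
  )
  got <- evaluate_model(model, ds$train, enc)

  tp <- fp <- fn <- tn <- 0
  matched <- logical(nrow(ds$train))
  for (i in seq_len(nrow(ds$train))) {
    e <- encode_onehot(ds$train$residues[i], 128)
    logits <- predict_logits(model, e$features)
    for_labels <- integer(128)
    for (j in 1:128) {
      if (e$mask[j] == 1) {
        p1 <- exp(logits[j, 2]) / (exp(logits[j, 1]) + exp(logits[j, 2]))
        for_labels[j] <- as.integer(p1 >= 0.5)
        t <- ds$train$labels[[i]][j]
        if (for_labels[j] == 1 && t == 1) tp <- tp + 1
        if (for_labels[j] == 1 && t == 0) fp <- fp + 1
        if (for_labels[j] == 0 && t == 1) fn <- fn + 1
        if (for_labels[j] == 0 && t == 0) tn <- tn + 1
      }
    }
    on <- ds$train$mask[[i]] == 1
    matched[i] <- all(for_labels[on] == ds$train$labels[[i]][on])
  }
  expect_equal(got$tp, tp)
  expect_equal(got$fp, fp)
  expect_equal(got$fn, fn)
  expect_equal(got$tn, tn)
  expect_equal(got$exact_match_rate, mean(matched), tolerance = 1e-9)
  ref <- brute_metrics(tp, fp, fn, tn)
  expect_equal(got$f1, ref$f1, tolerance = 1e-9)
  expect_equal(got$mcc, ref$mcc, tolerance = 1e-9)
  expect_equal(got$accuracy, ref$accuracy, tolerance = 1e-9)

  # exact match of 1 coincides with zero residue errors
  expect_equal(got$exact_match_rate == 1, got$fp + got$fn == 0)

  tbl <- by_sequence(got)
  expect_equal(nrow(tbl), 20)
  expect_equal(tbl$matched, matched)
  p <- autoplot(got)
  expect_s3_class(p, "ggplot")
})
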