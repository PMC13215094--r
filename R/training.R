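# Masked-loss optimisation with early stopping on validation F1.

#' Configure a training run
#'
#' Defaults follow the protocol the segmenter was designed around: Adam
#' with learning rate 0.001, up to 50 epochs, early stopping when the
#' validation F1 fails to improve for 5 consecutive epochs, batch size 32
#' (use 4 for wide external embeddings), and an 0.8:0.2 train/validation
#' split.
#'
#' @param learning_rate Adam learning rate.
#' @param max_epochs Maximum number of epochs.
#' @param patience Consecutive non-improving epochs tolerated before
#'   stopping; must be smaller than `max_epochs`.
#' @param batch_size Sequences per optimisation step.
#' @param val_fraction Fraction held out for validation by
#'   [split_dataset()].
#' @param seed Integer seed controlling shuffling and dropout.
#' @return An object of class `rcl_train_config`.
#' @export
train_config <- function(learning_rate = 0.001,
                         max_epochs = 50L,
                         patience = 5L,
                         batch_size = 32L,
                         val_fraction = 0.2,
                         seed = 1L) {
  stopifnot(
    learning_rate > 0, max_epochs >= 1, patience >= 1,
    batch_size >= 1, val_fraction > 0, val_fraction < 1
  )
  if (patience >= max_epochs) {
    stop("`patience` must be smaller than `max_epochs`", call. = FALSE)
  }
  structure(
    list(
      learning_rate = learning_rate,
      max_epochs = as.integer(max_epochs),
      patience = as.integer(patience),
      batch_size = as.integer(batch_size),
      val_fraction = val_fraction,
      seed = as.integer(seed)
    ),
    class = "rcl_train_config"
  )
}

#' Split labelled examples into training and validation sets
#'
#' Shuffled, disjoint, exhaustive split, stratified by class
#' (positive = any positive residue label) so both partitions contain both
#' classes whenever possible. A class with fewer than 2 members cannot be
#' stratified; a warning is emitted and the split falls back to
#' unstratified.
#'
#' @param examples A labelled-example tibble from [make_labels()].
#' @param val_fraction Fraction assigned to validation.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return A list with `train` and `validation` tibbles.
#' @export
split_dataset <- function(examples, val_fraction, seed) {
  stopifnot(nrow(examples) >= 2, val_fraction > 0, val_fraction < 1)
  set.seed(seed)
  positive <- vapply(examples$labels, function(l) any(l == 1L), logical(1))
  n_val <- max(1L, round(nrow(examples) * val_fraction))
  strata <- list(which(positive), which(!positive))
  strata <- strata[lengths(strata) > 0]
  if (any(lengths(strata) < 2) && length(strata) > 1) {
    warning("A class has fewer than 2 members; falling back to an ",
      "unstratified split",
      call. = FALSE
    )
    strata <- list(seq_len(nrow(examples)))
  }
  val_idx <- integer(0)
  if (length(strata) == 1) {
    val_idx <- sample(strata[[1]], n_val)
  } else {
    for (s in strata) {
      k <- round(length(s) * val_fraction)
      k <- min(max(k, 1L), length(s) - 1L)
      val_idx <- c(val_idx, sample(s, k))
    }
    # keep the overall validation count at n_val where rounding allows
    if (length(val_idx) > n_val) {
      val_idx <- val_idx[seq_len(n_val)]
    }
  }
  val_idx <- sort(val_idx)
  list(
    train = examples[-val_idx, , drop = FALSE],
    validation = examples[val_idx, , drop = FALSE]
  )
}

# Early stopping on the validation-F1 trace: improvement means a strict
# increase over the running best (ties count toward patience); training
# stops once `patience` consecutive epochs fail to improve.
early_stop_point <- function(f1_trace, patience) {
  best <- -Inf
  best_epoch <- 0L
  stale <- 0L
  for (e in seq_along(f1_trace)) {
    if (f1_trace[e] > best) {
      best <- f1_trace[e]
      best_epoch <- e
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) {
        return(list(best_epoch = best_epoch, stop_epoch = e, stopped_early = TRUE))
      }
    }
  }
  list(
    best_epoch = best_epoch, stop_epoch = length(f1_trace),
    stopped_early = FALSE
  )
}

# ---- masked cross-entropy ------------------------------------------------

ce_masked <- function(logits, labels, mask, want_grad = FALSE) {
  nm <- sum(mask)
  if (nm == 0) {
    stop("All-zero mask: the masked loss is undefined (no real residues)",
      call. = FALSE
    )
  }
  m <- pmax(logits[, 1], logits[, 2])
  z1 <- logits[, 1] - m
  z2 <- logits[, 2] - m
  lse <- log(exp(z1) + exp(z2))
  logp <- cbind(z1 - lse, z2 - lse)
  true_col <- labels + 1L
  picked <- logp[cbind(seq_along(labels), true_col)]
  loss <- -sum(picked * mask) / nm
  if (!want_grad) {
    return(list(loss = loss))
  }
  p <- exp(logp)
  p[cbind(seq_along(labels), true_col)] <-
    p[cbind(seq_along(labels), true_col)] - 1
  list(loss = loss, dlogits = p * (mask / nm))
}

#' Masked cross-entropy loss over padded sequences
#'
#' Softmax cross-entropy of the two per-residue logits against the 0/1
#' labels, averaged over unmasked positions only. Logits at masked
#' (padding) positions contribute exactly nothing: perturbing them leaves
#' the loss bit-identical. With two complementary classes this equals the
#' binary cross-entropy of the positive-class probability.
#'
#' @param logits `L x 2` matrix (or `B x L x 2` array) of class logits,
#'   columns ordered (non-RCL, RCL).
#' @param labels 0/1 vector of length L (or `B x L` matrix).
#' @param mask 0/1 validity vector (or matrix) of the same shape as
#'   `labels`; must contain at least one 1.
#' @return The scalar mean loss over unmasked positions.
#' @export
masked_loss <- function(logits, labels, mask) {
  flat <- flatten_logit_batch(logits, labels, mask)
  ce_masked(flat$logits, flat$labels, flat$mask)$loss
}

flatten_logit_batch <- function(logits, labels, mask) {
  if (is.matrix(logits)) {
    stopifnot(ncol(logits) == 2, length(labels) == nrow(logits))
    return(list(
      logits = logits, labels = as.integer(labels),
      mask = as.numeric(mask)
    ))
  }
  stopifnot(length(dim(logits)) == 3, dim(logits)[3] == 2)
  B <- dim(logits)[1]
  L <- dim(logits)[2]
  stopifnot(all(dim(labels) == c(B, L)), all(dim(mask) == c(B, L)))
  out_logits <- matrix(0, B * L, 2)
  out_labels <- integer(B * L)
  out_mask <- numeric(B * L)
  for (s in seq_len(B)) {
    rows <- ((s - 1L) * L + 1L):(s * L)
    out_logits[rows, ] <- logits[s, , ]
    out_labels[rows] <- labels[s, ]
    out_mask[rows] <- mask[s, ]
  }
  list(logits = out_logits, labels = out_labels, mask = out_mask)
}

# ---- dataset encoding ----------------------------------------------------

encode_examples <- function(examples, encoder, l_fixed) {
  stopifnot(inherits(encoder, "rcl_encoder"))
  n <- nrow(examples)
  stopifnot(n >= 1)
  X <- matrix(0, n * l_fixed, encoder$dim)
  labels <- integer(n * l_fixed)
  mask <- numeric(n * l_fixed)
  for (i in seq_len(n)) {
    enc <- encoder$encode(examples$id[i], examples$residues[i], l_fixed)
    rows <- ((i - 1L) * l_fixed + 1L):(i * l_fixed)
    X[rows, ] <- enc$features
    labels[rows] <- examples$labels[[i]]
    mask[rows] <- examples$mask[[i]]
    if (!identical(as.integer(enc$mask), as.integer(examples$mask[[i]]))) {
      # external embeddings may disagree with the residue count; trust the
      # narrower of the two so padding is never scored
      mask[rows] <- pmin(as.numeric(enc$mask), as.numeric(examples$mask[[i]]))
    }
  }
  list(X = X, labels = labels, mask = mask, n = n, L = as.integer(l_fixed))
}

batch_rows <- function(sel, L) {
  as.vector(vapply(sel, function(s) ((s - 1L) * L + 1L):(s * L), integer(L)))
}

# Precise batch-norm recalibration: dropout perturbs the activation
# variance seen by downstream batch-norm layers during training, so the
# EMA statistics systematically mismatch the dropout-free evaluation
# distribution ("variance shift"). Before each validation pass the running
# statistics are therefore re-estimated as an exact average of batch
# statistics over training batches with dropout disabled.
bn_recalibrate <- function(model, enc, batch_size, max_batches = 16L) {
  if (length(model$bn_state) == 0) {
    return(model$bn_state)
  }
  calib <- model
  calib$config$dropout <- 0
  starts <- seq.int(1L, enc$n, by = batch_size)
  starts <- utils::head(starts, max_batches)
  old_mom <- .nn_opts$bn_momentum
  on.exit(.nn_opts$bn_momentum <- old_mom)
  for (i in seq_along(starts)) {
    sel <- starts[i]:min(starts[i] + batch_size - 1L, enc$n)
    rows <- batch_rows(sel, enc$L)
    .nn_opts$bn_momentum <- 1 / i
    res <- model_fwd(calib, enc$X[rows, , drop = FALSE],
      B = length(sel), L = enc$L, training = TRUE
    )
    calib$bn_state <- res$bn_state
  }
  calib$bn_state
}

pooled_f1 <- function(model, enc, batch_size) {
  tp <- fp <- fn <- 0
  loss_sum <- 0
  loss_n <- 0
  starts <- seq.int(1L, enc$n, by = batch_size)
  for (st in starts) {
    sel <- st:min(st + batch_size - 1L, enc$n)
    rows <- batch_rows(sel, enc$L)
    res <- model_fwd(model, enc$X[rows, , drop = FALSE],
      B = length(sel), L = enc$L, training = FALSE
    )
    lab <- enc$labels[rows]
    msk <- enc$mask[rows]
    ce <- ce_masked(res$out, lab, msk)
    nm <- sum(msk)
    loss_sum <- loss_sum + ce$loss * nm
    loss_n <- loss_n + nm
    pred <- as.integer(res$out[, 2] >= res$out[, 1]) # ties -> positive
    pred[msk == 0] <- 0L
    on <- msk == 1
    tp <- tp + sum(pred[on] == 1L & lab[on] == 1L)
    fp <- fp + sum(pred[on] == 1L & lab[on] == 0L)
    fn <- fn + sum(pred[on] == 0L & lab[on] == 1L)
  }
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(f1 = f1, loss = loss_sum / loss_n)
}

#' Train a segmentation model
#'
#' Mini-batch Adam on the masked cross-entropy, with residue-pooled
#' validation F1 computed after every epoch and early stopping when F1 has
#' not strictly improved for `config$patience` consecutive epochs. The
#' returned model carries the weights of the best epoch (highest validation
#' F1), not the last one. Fully deterministic for a fixed
#' `config$seed` under single-threaded execution.
#'
#' @param model An `rcl_model` (freshly built or warm).
#' @param train Labelled-example tibble (columns `id`, `residues`,
#'   `labels`, `mask`) used for optimisation.
#' @param validation Labelled-example tibble monitored for early stopping.
#' @param encoder An [make_encoder()] object matching `model$config$input_dim`.
#' @param config An [train_config()].
#' @param l_fixed Fixed model length; defaults to the label length of the
#'   first training example.
#' @param verbose Print one line per epoch.
#' @return An object of class `rcl_fit`: list with `model`, `history`
#'   (per-epoch tibble), `best_epoch`, `stopped_early`, `encoding`,
#'   `l_fixed`, and the configs.
#' @export
train_model <- function(model, train, validation, encoder, config,
                        l_fixed = NULL, verbose = FALSE) {
  stopifnot(
    inherits(model, "rcl_model"),
    inherits(config, "rcl_train_config"),
    nrow(train) >= 1, nrow(validation) >= 1
  )
  if (encoder$dim != model$config$input_dim) {
    stop(
      "Encoder dimension ", encoder$dim, " does not match model input_dim ",
      model$config$input_dim,
      call. = FALSE
    )
  }
  if (is.null(l_fixed)) l_fixed <- length(train$labels[[1]])
  set.seed(config$seed)
  tr <- encode_examples(train, encoder, l_fixed)
  va <- encode_examples(validation, encoder, l_fixed)
  # Prior initialisation of the classifier head: with loop residues at a
  # few percent of all positions, a zero-bias head spends its first epochs
  # predicting everything negative. Seeding the head bias with the class
  # log-odds removes that dead phase. Applied only to a fresh (all-zero)
  # head bias so warm starts are never overwritten.
  if (all(model$params$head$b == 0)) {
    prior <- mean(tr$labels[tr$mask == 1])
    prior <- min(max(prior, 1e-4), 1 - 1e-4)
    model$params$head$b <- c(log(1 - prior), log(prior))
  }
  opt <- nn_adam_init(model$params)
  best <- list(
    f1 = -Inf, epoch = 0L,
    params = model$params, bn_state = model$bn_state
  )
  f1_trace <- numeric(0)
  stopped_early <- FALSE
  history <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- sample.int(tr$n)
    loss_sum <- 0
    loss_n <- 0
    for (st in seq.int(1L, tr$n, by = config$batch_size)) {
      sel <- order_idx[st:min(st + config$batch_size - 1L, tr$n)]
      rows <- batch_rows(sel, tr$L)
      res <- model_fwd(model, tr$X[rows, , drop = FALSE],
        B = length(sel), L = tr$L, training = TRUE
      )
      model$bn_state <- res$bn_state
      ce <- ce_masked(res$out, tr$labels[rows], tr$mask[rows],
        want_grad = TRUE
      )
      if (!is.finite(ce$loss)) {
        stop("Non-finite training loss at epoch ", epoch,
          "; check inputs and learning rate",
          call. = FALSE
        )
      }
      nm <- sum(tr$mask[rows])
      loss_sum <- loss_sum + ce$loss * nm
      loss_n <- loss_n + nm
      grads <- model_bwd(model, res$cache, ce$dlogits)
      stepped <- nn_adam_step(model$params, grads, opt, config$learning_rate)
      model$params <- stepped$params
      opt <- stepped$opt
    }
    model$bn_state <- bn_recalibrate(model, tr, config$batch_size)
    val <- pooled_f1(model, va, config$batch_size)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_loss = loss_sum / loss_n,
      val_loss = val$loss,
      val_f1 = val$f1
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d  train loss %.5f  val loss %.5f  val F1 %.4f",
        epoch, loss_sum / loss_n, val$loss, val$f1
      ))
    }
    f1_trace <- c(f1_trace, val$f1)
    esp <- early_stop_point(f1_trace, config$patience)
    if (esp$best_epoch == epoch) {
      best <- list(
        f1 = val$f1, epoch = epoch,
        params = model$params, bn_state = model$bn_state
      )
    }
    if (esp$stopped_early) {
      stopped_early <- TRUE
      break
    }
  }
  model$params <- best$params
  model$bn_state <- best$bn_state
  structure(
    list(
      model = model,
      history = dplyr::bind_rows(history),
      best_epoch = best$epoch,
      best_val_f1 = best$f1,
      stopped_early = stopped_early,
      encoding = encoder$name,
      l_fixed = as.integer(l_fixed),
      train_config = config,
      model_config = model$config
    ),
    class = "rcl_fit"
  )
}

#' @export
print.rcl_fit <- function(x, ...) {
  cat(
    "<rcl_fit> ", x$model_config$architecture, " + ", x$encoding,
    " | epochs run: ", nrow(x$history),
    " | best epoch: ", x$best_epoch,
    sprintf(" (val F1 %.4f)", x$best_val_f1),
    if (x$stopped_early) " | early-stopped" else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a fitted segmentation run into its per-epoch history
#'
#' @param x An `rcl_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`, `val_f1`.
#' @export
tidy.rcl_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted segmentation run
#'
#' @param x An `rcl_fit`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, encoding, epochs run, best
#'   epoch, best validation F1, early-stopping flag, parameter count.
#' @export
glance.rcl_fit <- function(x, ...) {
  tibble::tibble(
    architecture = x$model_config$architecture,
    encoding = x$encoding,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_f1 = x$best_val_f1,
    stopped_early = x$stopped_early,
    n_parameters = n_parameters(x$model)
  )
}

#' Plot training and validation curves of a fit
#'
#' @param object An `rcl_fit`.
#' @param ... Unused.
#' @return A ggplot object: loss curves (left axis scale) and validation
#'   F1 per epoch, with the best epoch marked.
#' @export
autoplot.rcl_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history,
    cols = c("train_loss", "val_loss", "val_f1"),
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(
      xintercept = object$best_epoch, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::facet_wrap(
      ggplot2::vars(.data$series == "val_f1"),
      scales = "free_y",
      labeller = ggplot2::as_labeller(
        c(`TRUE` = "validation F1", `FALSE` = "masked cross-entropy")
      )
    ) +
    ggplot2::labs(
      x = "epoch", y = NULL, colour = NULL,
      title = "Training history",
      subtitle = sprintf(
        "%s + %s; best epoch %d",
        object$model_config$architecture, object$encoding, object$best_epoch
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
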