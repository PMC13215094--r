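# Residue-level and per-sequence metrics, and span extraction from
# per-residue predictions. Metrics are micro-averaged: confusion counts are
# pooled over all unmasked positions of all sequences before any ratio is
# taken.

#' Turn per-residue logits into labels and probabilities
#'
#' The positive-class probability is the softmax component of the RCL
#' logit; the label is the argmax of the two logits, with the tie at
#' probability 0.5 assigned to the positive class (documented, arbitrary,
#' fixed). Masked positions are labelled 0 with probability reported as 0.
#'
#' @param logits `L x 2` matrix, columns ordered (non-RCL, RCL).
#' @param mask 0/1 validity vector of length L (defaults to all valid).
#' @return A list with integer `labels` and numeric `prob`, both length L.
#' @export
predict_labels <- function(logits, mask = rep(1L, nrow(logits))) {
  stopifnot(is.matrix(logits), ncol(logits) == 2, length(mask) == nrow(logits))
  d <- logits[, 2] - logits[, 1]
  prob <- 1 / (1 + exp(-d))
  labels <- as.integer(prob >= 0.5)
  off <- mask == 0
  labels[off] <- 0L
  prob[off] <- 0
  list(labels = labels, prob = prob)
}

#' Pool confusion counts over unmasked positions
#'
#' @param predicted Integer 0/1 vector (or list of vectors) of predicted
#'   labels.
#' @param truth Matching 0/1 vector or list of true labels.
#' @param mask Matching 0/1 validity vector or list.
#' @return A list with `tp`, `fp`, `fn`, `tn` (positive class = RCL).
#' @export
confusion_counts <- function(predicted, truth, mask) {
  if (is.list(predicted)) predicted <- unlist(predicted)
  if (is.list(truth)) truth <- unlist(truth)
  if (is.list(mask)) mask <- unlist(mask)
  stopifnot(length(predicted) == length(truth), length(truth) == length(mask))
  on <- mask == 1
  p <- predicted[on]
  t <- truth[on]
  list(
    tp = sum(p == 1L & t == 1L),
    fp = sum(p == 1L & t == 0L),
    fn = sum(p == 0L & t == 1L),
    tn = sum(p == 0L & t == 0L)
  )
}

#' Residue-level metrics from pooled confusion counts
#'
#' Standard definitions; degenerate denominators are mapped to 0 (any zero
#' factor in the MCC denominator gives MCC 0, an undefined F1 gives 0).
#'
#' @param counts A list with `tp`, `fp`, `fn`, `tn`.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `f1`, `mcc`, `accuracy`.
#' @export
residue_metrics <- function(counts) {
  tp <- as.numeric(counts$tp)
  fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn)
  tn <- as.numeric(counts$tn)
  total <- tp + fp + fn + tn
  stopifnot(total > 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall,
    f1 = f1, mcc = mcc, accuracy = (tp + tn) / total
  )
}

#' Extract loop spans from a per-residue label vector
#'
#' Maximal runs of consecutive 1s become spans (1-based inclusive), in
#' position order, each carrying the mean positive-class probability over
#' its residues.
#'
#' @param labels 0/1 integer vector.
#' @param prob Positive-class probabilities (defaults to the labels
#'   themselves).
#' @return A tibble with columns `start`, `end`, `prob`.
#' @export
extract_spans <- function(labels, prob = as.numeric(labels)) {
  stopifnot(length(prob) == length(labels))
  if (length(labels) == 0 || !any(labels == 1L)) {
    return(tibble::tibble(
      start = integer(), end = integer(), prob = numeric()
    ))
  }
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values == 1L
  starts <- starts[on]
  ends <- ends[on]
  tibble::tibble(
    start = starts,
    end = ends,
    prob = mapply(function(s, e) mean(prob[s:e]), starts, ends)
  )
}

#' Select the primary loop span
#'
#' Serpins carry a single reactive center loop, so prediction keeps the
#' longest extracted span, breaking ties by the earliest start.
#'
#' @param spans A tibble from [extract_spans()].
#' @return A one-row tibble, or a zero-row tibble if `spans` is empty.
#' @export
primary_span <- function(spans) {
  if (nrow(spans) == 0) {
    return(spans)
  }
  len <- spans$end - spans$start + 1L
  spans[order(-len, spans$start)[1], , drop = FALSE]
}

#' Per-sequence exact match rate
#'
#' A sequence counts as matched only if the predicted labels equal the true
#' labels at every unmasked position; for negatives this means an all-zero
#' prediction. A single boundary residue off means no match.
#'
#' @param predicted List of 0/1 predicted label vectors, one per sequence.
#' @param truth List of true label vectors.
#' @param masks List of 0/1 validity vectors.
#' @return Fraction of matched sequences.
#' @export
exact_match_rate <- function(predicted, truth, masks) {
  n <- length(predicted)
  if (n == 0) {
    stop("Empty test set: exact match rate is undefined", call. = FALSE)
  }
  stopifnot(length(truth) == n, length(masks) == n)
  matched <- vapply(seq_len(n), function(i) {
    p <- predicted[[i]]
    t <- truth[[i]]
    m <- masks[[i]]
    if (length(p) != length(t) || length(t) != length(m)) {
      stop("Label/mask length mismatch at sequence ", i, call. = FALSE)
    }
    on <- m == 1
    all(p[on] == t[on])
  }, logical(1))
  mean(matched)
}

#' Evaluate a model on labelled examples
#'
#' Encodes the examples, runs the model in evaluation mode, pools
#' confusion counts over all unmasked positions, and computes residue
#' metrics plus the per-sequence exact match rate. Deterministic across
#' repeated calls.
#'
#' @param model An `rcl_model`.
#' @param examples Labelled-example tibble (columns `id`, `residues`,
#'   `labels`, `mask`).
#' @param encoder An [make_encoder()] matching the model.
#' @param batch_size Sequences per forward pass.
#' @return An object of class `rcl_metrics`: a one-row tibble with the
#'   counts, `precision`, `recall`, `f1`, `mcc`, `accuracy`,
#'   `exact_match_rate` and `n_sequences`, with the per-sequence outcome
#'   table in attribute `"by_sequence"`.
#' @export
evaluate_model <- function(model, examples, encoder, batch_size = 32L) {
  l_fixed <- length(examples$labels[[1]])
  enc <- encode_examples(examples, encoder, l_fixed)
  n <- enc$n
  pred_list <- vector("list", n)
  prob_list <- vector("list", n)
  for (st in seq.int(1L, n, by = batch_size)) {
    sel <- st:min(st + batch_size - 1L, n)
    rows <- batch_rows(sel, enc$L)
    res <- model_fwd(model, enc$X[rows, , drop = FALSE],
      B = length(sel), L = enc$L, training = FALSE
    )
    for (k in seq_along(sel)) {
      i <- sel[k]
      local_rows <- ((k - 1L) * enc$L + 1L):(k * enc$L)
      pl <- predict_labels(
        res$out[local_rows, , drop = FALSE],
        enc$mask[rows[local_rows]]
      )
      pred_list[[i]] <- pl$labels
      prob_list[[i]] <- pl$prob
    }
  }
  truth <- examples$labels
  masks <- examples$mask
  counts <- confusion_counts(pred_list, truth, masks)
  metrics <- residue_metrics(counts)
  metrics$exact_match_rate <- exact_match_rate(pred_list, truth, masks)
  metrics$n_sequences <- n
  by_seq <- tibble::tibble(
    id = examples$id,
    matched = vapply(
      seq_len(n),
      function(i) all((pred_list[[i]] == truth[[i]])[masks[[i]] == 1]),
      logical(1)
    ),
    predicted_span = vapply(seq_len(n), function(i) {
      ps <- primary_span(extract_spans(pred_list[[i]], prob_list[[i]]))
      if (nrow(ps) == 0) NA_character_ else sprintf("%d-%d", ps$start, ps$end)
    }, character(1)),
    true_span = vapply(seq_len(n), function(i) {
      ts <- extract_spans(truth[[i]])
      if (nrow(ts) == 0) NA_character_ else sprintf("%d-%d", ts$start[1], ts$end[1])
    }, character(1))
  )
  structure(metrics,
    class = c("rcl_metrics", class(metrics)),
    by_sequence = by_seq,
    predictions = list(labels = pred_list, prob = prob_list)
  )
}

#' Per-sequence outcome table of an evaluation
#'
#' @param metrics An `rcl_metrics` object from [evaluate_model()].
#' @return A tibble with one row per sequence: `id`, `matched`,
#'   `predicted_span`, `true_span`.
#' @export
by_sequence <- function(metrics) {
  attr(metrics, "by_sequence")
}

#' Write a metrics report as a flat key-value TSV
#'
#' @param metrics An `rcl_metrics` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  keys <- c(
    "precision", "recall", "f1", "mcc", "accuracy",
    "exact_match_rate", "n_sequences", "tp", "fp", "fn", "tn"
  )
  vals <- vapply(keys, function(k) format(metrics[[k]], digits = 10), character(1))
  writeLines(paste(keys, vals, sep = "\t"), path)
  invisible(path)
}

#' Plot residue-level metrics
#'
#' @param object An `rcl_metrics` object.
#' @param ... Unused.
#' @return A ggplot bar chart of precision, recall, F1, MCC, accuracy and
#'   exact match rate.
#' @export
autoplot.rcl_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c(
      "precision", "recall", "f1", "mcc", "accuracy", "exact_match_rate"
    )],
    cols = dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$metric, .data$value), y = .data$value
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.3f", .data$value)),
      hjust = -0.1, size = 3
    ) +
    ggplot2::coord_flip(ylim = c(0, 1.08)) +
    ggplot2::labs(
      x = NULL, y = NULL, title = "Segmentation performance",
      subtitle = sprintf("%d sequences, micro-averaged", object$n_sequences)
    ) +
    ggplot2::theme_minimal()
}
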