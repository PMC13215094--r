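# Segmentation architectures. All three share one forward contract:
# (batch x L x D) features -> (batch x L x 2) class logits, length-preserving,
# with the two logits scoring the RCL and non-RCL classes per residue.

#' Configure a segmentation model
#'
#' @param architecture `"cnn"`, `"unet"` or `"bilstm"`.
#' @param input_dim Feature dimension D of the residue encoding.
#' @param base_channels Channel width of the first level; widths double per
#'   level/block.
#' @param depth Number of convolutional blocks (CNN) or encoder levels
#'   (U-Net). A U-Net of depth `d` requires input lengths divisible by
#'   `2^d`.
#' @param dropout Dropout probability. Defaults to 0.3 for the CNN and
#'   BiLSTM and 0.25 for the U-Net.
#' @param kernel_size Odd convolution kernel width.
#' @param lstm_hidden Hidden width per direction for the BiLSTM.
#' @return An object of class `rcl_model_config`.
#' @export
model_config <- function(architecture = c("cnn", "unet", "bilstm"),
                         input_dim,
                         base_channels = 32L,
                         depth = 4L,
                         dropout = NULL,
                         kernel_size = 3L,
                         lstm_hidden = 64L) {
  architecture <- match.arg(architecture)
  if (is.null(dropout)) {
    dropout <- if (architecture == "unet") 0.25 else 0.3
  }
  stopifnot(
    length(input_dim) == 1, input_dim >= 1,
    length(base_channels) == 1, base_channels >= 1,
    length(depth) == 1, depth >= 1,
    length(dropout) == 1, dropout >= 0, dropout < 1,
    length(kernel_size) == 1, kernel_size >= 1,
    length(lstm_hidden) == 1, lstm_hidden >= 1
  )
  if (kernel_size %% 2 == 0) {
    stop("`kernel_size` must be odd (same-length padding)", call. = FALSE)
  }
  structure(
    list(
      architecture = architecture,
      input_dim = as.integer(input_dim),
      base_channels = as.integer(base_channels),
      depth = as.integer(depth),
      dropout = dropout,
      kernel_size = as.integer(kernel_size),
      lstm_hidden = as.integer(lstm_hidden)
    ),
    class = "rcl_model_config"
  )
}

new_model <- function(config, params, bn_state) {
  structure(
    list(config = config, params = params, bn_state = bn_state),
    class = "rcl_model"
  )
}

#' @export
print.rcl_model <- function(x, ...) {
  cat(
    "<rcl_model> ", x$config$architecture,
    " | D=", x$config$input_dim,
    " | parameters: ", n_parameters(x), "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of learnable parameters in a model
#'
#' @param model An `rcl_model`.
#' @return Integer parameter count (batch-norm running statistics excluded).
#' @export
n_parameters <- function(model) {
  nn_param_count(model$params)
}

#' Build a segmentation model
#'
#' Dispatches to [build_cnn()], [build_unet()] or [build_bilstm()] according
#' to `config$architecture`. Initial weights are drawn from R's RNG, so two
#' builds under the same seed are identical.
#'
#' @param config An [model_config()] object.
#' @param seed Optional integer; if given, `set.seed(seed)` is called before
#'   initialisation.
#' @return An `rcl_model`.
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "rcl_model_config"))
  if (!is.null(seed)) set.seed(seed)
  switch(config$architecture,
    cnn = build_cnn(config),
    unet = build_unet(config),
    bilstm = build_bilstm(config)
  )
}

#' Build the 1D convolutional baseline
#'
#' `depth` blocks of convolution -> batch normalisation -> ReLU -> dropout,
#' with channel widths doubling per block, followed by a pointwise
#' projection to two per-residue logits. Sequence length is preserved
#' throughout; the receptive field is local
#' (`depth * (kernel_size - 1) / 2` residues each side).
#'
#' @param config An [model_config()] with `architecture = "cnn"`.
#' @return An `rcl_model`.
#' @export
build_cnn <- function(config) {
  stopifnot(config$architecture == "cnn")
  widths <- config$base_channels * 2^(seq_len(config$depth) - 1L)
  cin <- config$input_dim
  blocks <- vector("list", config$depth)
  states <- vector("list", config$depth)
  for (b in seq_len(config$depth)) {
    blocks[[b]] <- list(
      conv = nn_conv_init(cin, widths[b], config$kernel_size),
      bn = nn_bn_init(widths[b])
    )
    states[[b]] <- nn_bn_state(widths[b])
    cin <- widths[b]
  }
  new_model(
    config,
    params = list(blocks = blocks, head = nn_linear_init(cin, 2L)),
    bn_state = list(blocks = states)
  )
}

dc_init <- function(cin, cout, k) {
  list(
    c1 = nn_conv_init(cin, cout, k),
    b1 = nn_bn_init(cout),
    c2 = nn_conv_init(cout, cout, k),
    b2 = nn_bn_init(cout)
  )
}

dc_state <- function(cout) {
  list(b1 = nn_bn_state(cout), b2 = nn_bn_state(cout))
}

dc_fwd <- function(X, p, s, B, L, training, dropout_p) {
  cv1 <- nn_conv_fwd(X, p$c1, B, L)
  bn1 <- nn_bn_fwd(cv1$out, p$b1, s$b1, training)
  rl1 <- nn_relu_fwd(bn1$out)
  cv2 <- nn_conv_fwd(rl1$out, p$c2, B, L)
  bn2 <- nn_bn_fwd(cv2$out, p$b2, s$b2, training)
  rl2 <- nn_relu_fwd(bn2$out)
  dp <- nn_dropout_fwd(rl2$out, dropout_p, training)
  list(
    out = dp$out,
    state = list(b1 = bn1$state, b2 = bn2$state),
    cache = list(
      cv1 = cv1$cache, bn1 = bn1$cache, rl1 = rl1$cache,
      cv2 = cv2$cache, bn2 = bn2$cache, rl2 = rl2$cache, dp = dp$cache
    )
  )
}

dc_bwd <- function(dY, p, cache) {
  dY <- nn_dropout_bwd(dY, cache$dp)
  dY <- nn_relu_bwd(dY, cache$rl2)
  bn2 <- nn_bn_bwd(dY, cache$bn2)
  cv2 <- nn_conv_bwd(bn2$dX, p$c2, cache$cv2)
  dY <- nn_relu_bwd(cv2$dX, cache$rl1)
  bn1 <- nn_bn_bwd(dY, cache$bn1)
  cv1 <- nn_conv_bwd(bn1$dX, p$c1, cache$cv1)
  list(
    dX = cv1$dX,
    grads = list(c1 = cv1$grads, b1 = bn1$grads, c2 = cv2$grads, b2 = bn2$grads)
  )
}

#' Build the attention-gated 1D U-Net
#'
#' Encoder: `depth` DoubleConv blocks (twice convolution -> batch norm ->
#' ReLU, dropout after the second activation), each followed by max-pooling
#' that halves the sequence length. Bottleneck: one further DoubleConv.
#' Decoder: `depth` stages of transposed-convolution upsampling (x2),
#' additive attention gating of the encoder skip features, concatenation
#' and DoubleConv. A final pointwise projection yields two logits per
#' residue. Input lengths must be divisible by `2^depth`.
#'
#' @param config An [model_config()] with `architecture = "unet"`.
#' @return An `rcl_model`.
#' @export
build_unet <- function(config) {
  stopifnot(config$architecture == "unet")
  d <- config$depth
  k <- config$kernel_size
  widths <- config$base_channels * 2^(seq_len(d) - 1L)
  bott <- config$base_channels * 2^d
  enc <- vector("list", d)
  enc_s <- vector("list", d)
  cin <- config$input_dim
  for (l in seq_len(d)) {
    enc[[l]] <- dc_init(cin, widths[l], k)
    enc_s[[l]] <- dc_state(widths[l])
    cin <- widths[l]
  }
  dec <- vector("list", d)
  dec_s <- vector("list", d)
  cin <- bott
  for (i in seq_len(d)) {
    l <- d - i + 1L # decoder stage i restores level l
    dec[[i]] <- list(
      up = nn_up_init(cin, widths[l]),
      att = nn_att_init(widths[l]),
      dc = dc_init(2L * widths[l], widths[l], k)
    )
    dec_s[[i]] <- dc_state(widths[l])
    cin <- widths[l]
  }
  new_model(
    config,
    params = list(
      enc = enc,
      bottleneck = dc_init(widths[d], bott, k),
      dec = dec,
      head = nn_linear_init(widths[1], 2L)
    ),
    bn_state = list(enc = enc_s, bottleneck = dc_state(bott), dec = dec_s)
  )
}

#' Build the bidirectional LSTM
#'
#' The encoded sequence is processed left-to-right and right-to-left by two
#' LSTMs; their per-position hidden states are concatenated
#' (width `2 * lstm_hidden`), passed through dropout and a linear
#' classification layer producing two logits per residue.
#'
#' @param config An [model_config()] with `architecture = "bilstm"`.
#' @return An `rcl_model`.
#' @export
build_bilstm <- function(config) {
  stopifnot(config$architecture == "bilstm")
  h <- config$lstm_hidden
  new_model(
    config,
    params = list(
      fwd = nn_lstm_init(config$input_dim, h),
      bwd = nn_lstm_init(config$input_dim, h),
      head = nn_linear_init(2L * h, 2L)
    ),
    bn_state = list()
  )
}

# ---- forward / backward dispatch ----------------------------------------

model_fwd <- function(model, X, B, L, training = FALSE) {
  if (ncol(X) != model$config$input_dim) {
    stop(
      "Feature dimension ", ncol(X), " does not match model input_dim ",
      model$config$input_dim,
      call. = FALSE
    )
  }
  switch(model$config$architecture,
    cnn = fwd_cnn(model, X, B, L, training),
    unet = fwd_unet(model, X, B, L, training),
    bilstm = fwd_bilstm(model, X, B, L, training)
  )
}

model_bwd <- function(model, cache, dY) {
  switch(model$config$architecture,
    cnn = bwd_cnn(model, cache, dY),
    unet = bwd_unet(model, cache, dY),
    bilstm = bwd_bilstm(model, cache, dY)
  )
}

fwd_cnn <- function(model, X, B, L, training) {
  cfg <- model$config
  P <- model$params
  S <- model$bn_state
  caches <- vector("list", cfg$depth)
  for (b in seq_len(cfg$depth)) {
    cv <- nn_conv_fwd(X, P$blocks[[b]]$conv, B, L)
    bn <- nn_bn_fwd(cv$out, P$blocks[[b]]$bn, S$blocks[[b]], training)
    S$blocks[[b]] <- bn$state
    rl <- nn_relu_fwd(bn$out)
    dp <- nn_dropout_fwd(rl$out, cfg$dropout, training)
    caches[[b]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache, drop = dp$cache)
    X <- dp$out
  }
  hd <- nn_linear_fwd(X, P$head)
  list(out = hd$out, cache = list(blocks = caches, head = hd$cache), bn_state = S)
}

bwd_cnn <- function(model, cache, dY) {
  cfg <- model$config
  P <- model$params
  hd <- nn_linear_bwd(dY, P$head, cache$head)
  grads <- list(blocks = vector("list", cfg$depth), head = hd$grads)
  dX <- hd$dX
  for (b in rev(seq_len(cfg$depth))) {
    cb <- cache$blocks[[b]]
    dX <- nn_dropout_bwd(dX, cb$drop)
    dX <- nn_relu_bwd(dX, cb$relu)
    bn <- nn_bn_bwd(dX, cb$bn)
    cv <- nn_conv_bwd(bn$dX, P$blocks[[b]]$conv, cb$conv)
    grads$blocks[[b]] <- list(conv = cv$grads, bn = bn$grads)
    dX <- cv$dX
  }
  grads
}

unet_check_length <- function(L, depth) {
  if (L %% 2^depth != 0) {
    stop(
      "U-Net input length ", L, " is not divisible by 2^depth = ", 2^depth,
      "; pad or truncate the input to a multiple of ", 2^depth,
      call. = FALSE
    )
  }
}

fwd_unet <- function(model, X, B, L, training) {
  cfg <- model$config
  P <- model$params
  S <- model$bn_state
  d <- cfg$depth
  unet_check_length(L, d)
  skips <- vector("list", d)
  enc_cache <- vector("list", d)
  pool_cache <- vector("list", d)
  Lcur <- L
  for (l in seq_len(d)) {
    dc <- dc_fwd(X, P$enc[[l]], S$enc[[l]], B, Lcur, training, cfg$dropout)
    S$enc[[l]] <- dc$state
    skips[[l]] <- dc$out
    enc_cache[[l]] <- dc$cache
    mp <- nn_maxpool_fwd(dc$out, B, Lcur)
    pool_cache[[l]] <- mp$cache
    X <- mp$out
    Lcur <- Lcur %/% 2L
  }
  bt <- dc_fwd(X, P$bottleneck, S$bottleneck, B, Lcur, training, cfg$dropout)
  S$bottleneck <- bt$state
  X <- bt$out
  dec_cache <- vector("list", d)
  for (i in seq_len(d)) {
    l <- d - i + 1L
    up <- nn_up_fwd(X, P$dec[[i]]$up)
    Lcur <- Lcur * 2L
    at <- nn_att_fwd(skips[[l]], up$out, P$dec[[i]]$att)
    cat_in <- cbind(up$out, at$out)
    dc <- dc_fwd(cat_in, P$dec[[i]]$dc, S$dec[[i]], B, Lcur, training, cfg$dropout)
    S$dec[[i]] <- dc$state
    dec_cache[[i]] <- list(up = up$cache, att = at$cache, dc = dc$cache)
    X <- dc$out
  }
  hd <- nn_linear_fwd(X, P$head)
  list(
    out = hd$out,
    cache = list(
      enc = enc_cache, pool = pool_cache, bottleneck = bt$cache,
      dec = dec_cache, head = hd$cache
    ),
    bn_state = S
  )
}

bwd_unet <- function(model, cache, dY) {
  cfg <- model$config
  P <- model$params
  d <- cfg$depth
  widths <- cfg$base_channels * 2^(seq_len(d) - 1L)
  hd <- nn_linear_bwd(dY, P$head, cache$head)
  grads <- list(
    enc = vector("list", d), bottleneck = NULL,
    dec = vector("list", d), head = hd$grads
  )
  dskip <- vector("list", d)
  dX <- hd$dX
  for (i in rev(seq_len(d))) {
    l <- d - i + 1L
    st <- cache$dec[[i]]
    dc <- dc_bwd(dX, P$dec[[i]]$dc, st$dc)
    w <- widths[l]
    dup <- dc$dX[, seq_len(w), drop = FALSE]
    datt <- dc$dX[, w + seq_len(w), drop = FALSE]
    at <- nn_att_bwd(datt, P$dec[[i]]$att, st$att)
    dskip[[l]] <- at$dskip
    up <- nn_up_bwd(dup + at$dgate, P$dec[[i]]$up, st$up)
    grads$dec[[i]] <- list(up = up$grads, att = at$grads, dc = dc$grads)
    dX <- up$dX
  }
  bt <- dc_bwd(dX, P$bottleneck, cache$bottleneck)
  grads$bottleneck <- bt$grads
  dX <- bt$dX
  for (l in rev(seq_len(d))) {
    dpool <- nn_maxpool_bwd(dX, cache$pool[[l]])
    dc <- dc_bwd(dpool + dskip[[l]], P$enc[[l]], cache$enc[[l]])
    grads$enc[[l]] <- dc$grads
    dX <- dc$dX
  }
  grads
}

fwd_bilstm <- function(model, X, B, L, training) {
  cfg <- model$config
  P <- model$params
  lf <- nn_lstm_fwd(X, P$fwd, B, L, reverse = FALSE)
  lb <- nn_lstm_fwd(X, P$bwd, B, L, reverse = TRUE)
  H <- cbind(lf$out, lb$out)
  dp <- nn_dropout_fwd(H, cfg$dropout, training)
  hd <- nn_linear_fwd(dp$out, P$head)
  list(
    out = hd$out,
    cache = list(X = X, fwd = lf$cache, bwd = lb$cache, drop = dp$cache, head = hd$cache),
    bn_state = model$bn_state
  )
}

bwd_bilstm <- function(model, cache, dY) {
  P <- model$params
  h <- model$config$lstm_hidden
  hd <- nn_linear_bwd(dY, P$head, cache$head)
  dH <- nn_dropout_bwd(hd$dX, cache$drop)
  lf <- nn_lstm_bwd(dH[, seq_len(h), drop = FALSE], cache$X, P$fwd, cache$fwd)
  lb <- nn_lstm_bwd(dH[, h + seq_len(h), drop = FALSE], cache$X, P$bwd, cache$bwd)
  list(fwd = lf$grads, bwd = lb$grads, head = hd$grads)
}

# ---- public forward ------------------------------------------------------

batch_to_rows <- function(features) {
  # (B x L x D) array -> (B*L) x D matrix, sequence-major
  B <- dim(features)[1]
  L <- dim(features)[2]
  D <- dim(features)[3]
  X <- matrix(0, B * L, D)
  for (s in seq_len(B)) {
    X[((s - 1L) * L + 1L):(s * L), ] <- features[s, , ]
  }
  X
}

rows_to_batch <- function(X, B, L) {
  D <- ncol(X)
  out <- array(0, dim = c(B, L, D))
  for (s in seq_len(B)) {
    out[s, , ] <- X[((s - 1L) * L + 1L):(s * L), , drop = FALSE]
  }
  out
}

#' Compute per-residue class logits
#'
#' Runs a model forward in evaluation mode (dropout off, batch
#' normalisation using running statistics), so repeated calls on the same
#' input are identical. Logits are produced for every position, including
#' padding; masking is the responsibility of the loss and the metrics, not
#' the model.
#'
#' @param model An `rcl_model`.
#' @param features Either an `L x D` matrix (one sequence) or a
#'   `B x L x D` array (a batch).
#' @return An `L x 2` matrix, or a `B x L x 2` array for batched input,
#'   with columns/slices ordered (non-RCL, RCL).
#' @export
predict_logits <- function(model, features) {
  if (is.matrix(features)) {
    res <- model_fwd(model, features, B = 1L, L = nrow(features), training = FALSE)
    return(res$out)
  }
  stopifnot(length(dim(features)) == 3)
  B <- dim(features)[1]
  L <- dim(features)[2]
  X <- batch_to_rows(features)
  res <- model_fwd(model, X, B = B, L = L, training = FALSE)
  rows_to_batch(res$out, B, L)
}

#' Apply the additive attention gate used by the U-Net decoder
#'
#' Exposed mainly for inspection and testing: gates `skip` features by a
#' per-position coefficient `alpha = sigmoid(psi(relu(Wg g + Wx s + b)))`
#' in (0, 1), so the gated output never exceeds the skip features in
#' magnitude.
#'
#' @param skip `L x C` matrix of encoder skip features.
#' @param gate `L x C` matrix of decoder gating features (same length).
#' @param params Gate parameters as produced inside [build_unet()]; if
#'   `NULL`, a fresh random initialisation for `C` channels is drawn.
#' @return A list with `out` (gated skip features) and `alpha`
#'   (per-position gate coefficients).
#' @export
attention_gate <- function(skip, gate, params = NULL) {
  if (!is.matrix(skip) || !is.matrix(gate) || ncol(skip) != ncol(gate)) {
    stop("`skip` and `gate` must be matrices with matching channels",
      call. = FALSE
    )
  }
  if (is.null(params)) params <- nn_att_init(ncol(skip))
  res <- nn_att_fwd(skip, gate, params)
  list(out = res$out, alpha = as.vector(res$cache$alpha))
}

# ---- checkpoints ---------------------------------------------------------

#' Save a self-describing model checkpoint
#'
#' A checkpoint carries the architecture, full model configuration, the
#' residue channel order, the fixed input length and the encoding name
#' alongside the weights, so inference never needs the original training
#' configuration and cannot silently mix encodings.
#'
#' @param model An `rcl_model`.
#' @param path Output path (RDS).
#' @param encoding Encoding name the model was trained with.
#' @param l_fixed Fixed input length used in training.
#' @param embedding_path Optional path to the external embedding container
#'   (recorded for provenance when `encoding = "external_embedding"`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, encoding, l_fixed,
                            embedding_path = NULL) {
  stopifnot(inherits(model, "rcl_model"))
  saveRDS(
    list(
      format = "rclseg-checkpoint-1",
      architecture = model$config$architecture,
      config = unclass(model$config),
      channel_order = paste(AA_CHANNELS, collapse = ""),
      l_fixed = as.integer(l_fixed),
      encoding = encoding,
      embedding_path = embedding_path,
      params = model$params,
      bn_state = model$bn_state
    ),
    path
  )
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return A list with `model` (`rcl_model`), `encoding`, `l_fixed` and
#'   `channel_order`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "rclseg-checkpoint-1")) {
    stop("Not an rclseg checkpoint: ", path, call. = FALSE)
  }
  cfg <- do.call(
    model_config,
    ck$config[c(
      "architecture", "input_dim", "base_channels", "depth",
      "dropout", "kernel_size", "lstm_hidden"
    )]
  )
  model <- new_model(cfg, ck$params, ck$bn_state)
  list(
    model = model,
    encoding = ck$encoding,
    l_fixed = ck$l_fixed,
    channel_order = ck$channel_order,
    embedding_path = ck$embedding_path
  )
}
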