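# Fixed channel order for all residue encodings. Mismatched channel order
# between training and inference is the classic silent failure for this kind
# of model, so the order is a single constant, stored in every checkpoint,
# and asserted in the test suite.
AA_CHANNELS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Ambiguity letters are kept in sequences but carry no feature signal.
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O")

blosum62_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix over the 20 standard residues
#'
#' The published BLOSUM62 matrix (as distributed with Biostrings),
#' restricted to the standard residues and reordered to the package channel
#' order `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @return A 20 x 20 integer matrix with residue dimnames.
#' @export
blosum62_matrix <- function() {
  if (is.null(blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$m <- e$BLOSUM62[AA_CHANNELS, AA_CHANNELS]
  }
  blosum62_env$m
}

encode_rows <- function(residues, l_fixed, row_lookup) {
  stopifnot(length(l_fixed) == 1, l_fixed >= 1)
  l_fixed <- as.integer(l_fixed)
  chars <- if (nzchar(residues)) strsplit(residues, "")[[1]] else character(0)
  if (length(chars) > 0 && any(!grepl("^[A-Z]$", chars))) {
    stop("Residues must be uppercase letters", call. = FALSE)
  }
  len <- min(length(chars), l_fixed)
  feats <- matrix(0, nrow = l_fixed, ncol = ncol(row_lookup))
  if (len > 0) {
    idx <- match(chars[seq_len(len)], rownames(row_lookup))
    known <- which(!is.na(idx))
    feats[known, ] <- row_lookup[idx[known], , drop = FALSE]
  }
  mask <- c(rep(1L, len), rep(0L, l_fixed - len))
  list(features = feats, mask = mask)
}

#' One-hot encode a residue string
#'
#' Each position carries a single 1 in the channel of its residue (channel
#' order `ACDEFGHIKLMNPQRSTVWY`). Ambiguity letters (X, B, Z, U, O) become
#' all-zero rows with mask 1; padding rows are zero with mask 0. Sequences
#' longer than `l_fixed` are truncated to their first `l_fixed` residues.
#'
#' @param residues Uppercase residue string.
#' @param l_fixed Fixed model length.
#' @return A list with `features` (`l_fixed` x 20 matrix), `mask`
#'   (0/1 integer vector) and `encoding` (`"onehot"`).
#' @export
encode_onehot <- function(residues, l_fixed) {
  eye <- diag(20)
  rownames(eye) <- AA_CHANNELS
  out <- encode_rows(residues, l_fixed, eye)
  out$encoding <- "onehot"
  out
}

#' BLOSUM62-encode a residue string
#'
#' Each standard residue is represented by its row of the BLOSUM62
#' substitution matrix restricted to the 20 standard residues (raw integer
#' scores, same channel order as [encode_onehot()]). Ambiguity letters and
#' padding give zero rows.
#'
#' @inheritParams encode_onehot
#' @return A list with `features`, `mask` and `encoding` (`"blosum"`).
#' @export
encode_blosum <- function(residues, l_fixed) {
  out <- encode_rows(residues, l_fixed, blosum62_matrix())
  out$encoding <- "blosum"
  out
}

#' Decode a one-hot feature matrix back to residues
#'
#' Channel argmax over unmasked rows; all-zero rows (ambiguity letters)
#' decode to `"X"`.
#'
#' @param features An L x 20 one-hot matrix.
#' @param mask 0/1 validity vector.
#' @return A residue string.
#' @export
decode_onehot <- function(features, mask = rep(1L, nrow(features))) {
  rows <- which(mask == 1L)
  if (length(rows) == 0) {
    return("")
  }
  chars <- vapply(rows, function(i) {
    r <- features[i, ]
    if (all(r == 0)) "X" else AA_CHANNELS[which.max(r)]
  }, character(1))
  paste(chars, collapse = "")
}

#' Read a per-residue embedding matrix from an embedding container file
#'
#' Adapter for externally pre-computed per-residue embeddings (for example
#' from a protein language model). The container is a plain-text file
#' holding one matrix per sequence: a `>id` line followed by one
#' whitespace-separated numeric row per residue. The matrix is truncated or
#' zero-padded to `l_fixed` rows exactly as the residue encoders do, with
#' the mask built from the stored row count; the feature dimension is taken
#' from the file.
#'
#' @param path Path to the embedding container file.
#' @param id Sequence id to extract.
#' @param l_fixed Fixed model length.
#' @return A list with `features` (`l_fixed` x D), `mask` and `encoding`
#'   (`"external_embedding"`).
#' @export
load_external_embedding <- function(path, id, l_fixed) {
  stopifnot(length(l_fixed) == 1, l_fixed >= 1)
  l_fixed <- as.integer(l_fixed)
  store <- read_embedding_container(path)
  if (!id %in% names(store)) {
    stop("No embedding stored for id '", id, "' in ", path, call. = FALSE)
  }
  m <- store[[id]]
  if (nrow(m) == 0) {
    stop("Embedding for id '", id, "' has zero rows", call. = FALSE)
  }
  len <- min(nrow(m), l_fixed)
  feats <- matrix(0, nrow = l_fixed, ncol = ncol(m))
  feats[seq_len(len), ] <- m[seq_len(len), , drop = FALSE]
  list(
    features = feats,
    mask = c(rep(1L, len), rep(0L, l_fixed - len)),
    encoding = "external_embedding"
  )
}

read_embedding_container <- function(path) {
  if (!file.exists(path)) {
    stop("Embedding container not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  headers <- which(startsWith(lines, ">"))
  if (length(headers) == 0) {
    stop("Embedding container has no '>id' headers: ", path, call. = FALSE)
  }
  bounds <- c(headers, length(lines) + 1L)
  store <- list()
  for (k in seq_along(headers)) {
    id <- trimws(sub("^>", "", lines[headers[k]]))
    body <- lines[seq2(headers[k] + 1L, bounds[k + 1L] - 1L)]
    rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
    if (length(rows) > 0) {
      d <- unique(lengths(rows))
      if (length(d) != 1 || any(vapply(rows, anyNA, logical(1)))) {
        stop("Ragged or non-numeric embedding rows for id '", id, "'",
          call. = FALSE
        )
      }
      store[[id]] <- do.call(rbind, rows)
    } else {
      store[[id]] <- matrix(numeric(0), nrow = 0, ncol = 0)
    }
  }
  store
}

#' Write a per-residue embedding container
#'
#' Inverse of [load_external_embedding()]'s reader; mainly used to build
#' small fixtures and examples.
#'
#' @param matrices Named list of numeric matrices (rows = residues).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding_container <- function(matrices, path) {
  stopifnot(is.list(matrices), !is.null(names(matrices)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(matrices)) {
    writeLines(paste0(">", id), con)
    m <- matrices[[id]]
    if (nrow(m) > 0) {
      writeLines(apply(m, 1, function(r) paste(format(r, digits = 10), collapse = "\t")), con)
    }
  }
  invisible(path)
}

seq2 <- function(from, to) {
  if (to < from) integer(0) else seq.int(from, to)
}

#' Construct a residue encoder
#'
#' An encoder bundles an encoding function with its name and feature
#' dimension so that models, checkpoints and the command-line workflows can
#' treat all encodings uniformly.
#'
#' @param name `"onehot"`, `"blosum"`, or `"external_embedding"`.
#' @param path For `"external_embedding"`, the embedding container file.
#' @return An object of class `rcl_encoder` with fields `name`, `dim` and
#'   `encode(id, residues, l_fixed)`.
#' @export
make_encoder <- function(name = c("onehot", "blosum", "external_embedding"),
                         path = NULL) {
  name <- match.arg(name)
  if (name == "onehot") {
    enc <- list(
      name = name, dim = 20L,
      encode = function(id, residues, l_fixed) encode_onehot(residues, l_fixed)
    )
  } else if (name == "blosum") {
    enc <- list(
      name = name, dim = 20L,
      encode = function(id, residues, l_fixed) encode_blosum(residues, l_fixed)
    )
  } else {
    if (is.null(path)) {
      stop("external_embedding encoder needs `path`", call. = FALSE)
    }
    store <- read_embedding_container(path)
    dims <- unique(vapply(store, ncol, integer(1)))
    dims <- dims[dims > 0]
    if (length(dims) != 1) {
      stop("Embedding container has inconsistent feature dimensions",
        call. = FALSE
      )
    }
    enc <- list(
      name = name, dim = as.integer(dims),
      encode = function(id, residues, l_fixed) {
        load_external_embedding(path, id, l_fixed)
      }
    )
  }
  structure(enc, class = "rcl_encoder")
}
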