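# Synthetic planted-loop data generator.
#
# Emulates the structure of the curated serpin dataset: positive sequences
# carry exactly one annotated loop of 20-28 residues embedded near the
# C-terminal ~85% position of a conserved-scaffold background, negatives
# have a matched length distribution and no loop. The loop signal is a
# composition bias (loops enriched in small/polar residues A, G, S, T plus
# P; the scaffold depleted of them), so that replacing the loop composition
# with the scaffold background makes loops statistically invisible -- the
# generator's own negative control.

#' Amino-acid composition presets used by the generator
#'
#' `"scaffold"`: background of positive sequences, depleted of the loop
#' alphabet (A/G/S/T/P). `"negative"`: proteome-like frequencies used for
#' non-serpin sequences (a distinct composition, so the serpin/non-serpin
#' distinction is learnable). `"loop"`: the default loop bias, concentrated
#' on A/G/S/T/P.
#'
#' @param type One of `"scaffold"`, `"negative"`, `"loop"`.
#' @return A named numeric vector of frequencies over the 20 standard
#'   residues (channel order), summing to 1.
#' @export
aa_composition <- function(type = c("scaffold", "negative", "loop")) {
  type <- match.arg(type)
  # proteome-like base frequencies (percent scale)
  base <- c(
    A = 8.3, C = 1.4, D = 5.5, E = 6.7, F = 3.9, G = 7.1, H = 2.3, I = 5.9,
    K = 5.8, L = 9.7, M = 2.4, N = 4.0, P = 4.7, Q = 3.9, R = 5.5, S = 6.6,
    T = 5.4, V = 6.9, W = 1.1, Y = 2.9
  )[AA_CHANNELS]
  out <- switch(type,
    negative = base,
    scaffold = {
      b <- base
      b[c("A", "G", "S", "T", "P")] <- b[c("A", "G", "S", "T", "P")] * 0.12
      b
    },
    loop = {
      b <- base * 0 + 0.08 / 15
      b[c("A", "G", "S", "T", "P")] <- c(0.28, 0.22, 0.18, 0.15, 0.09)
      b
    }
  )
  out / sum(out)
}

default_scaffold_motifs <- function() {
  # conserved-fold mimics planted at fixed relative positions; letters
  # deliberately avoid the loop alphabet
  c(
    WNEQFVKDLM = 0.10,
    DKHLYVRELF = 0.35,
    YIEKQLNRVD = 0.60
  )
}

#' Configure the synthetic planted-loop generator
#'
#' @param n_positive,n_negative Sequence counts.
#' @param length_mean,length_sd Gaussian length model for positives
#'   (residues).
#' @param loop_len_min,loop_len_max Loop length range (inclusive).
#' @param scaffold_motifs Named numeric vector: names are motif strings
#'   planted into every positive, values their relative positions in
#'   (0, 1). Negatives never carry motifs.
#' @param loop_alphabet_bias Named frequency vector over the 20 standard
#'   residues from which loop residues are drawn. The default
#'   (`aa_composition("loop")`) is strongly concentrated on A/G/S/T/P;
#'   passing `aa_composition("scaffold")` removes the loop signal
#'   entirely (negative control).
#' @param n_decoys Number of unlabeled loop-composition decoy segments
#'   planted away from the true loop (and into negatives). With decoys,
#'   local composition alone cannot distinguish the annotated loop; the
#'   scaffold motifs and position become the discriminating long-range
#'   cues.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `rcl_sim_config`.
#' @export
sim_config <- function(n_positive = 400L,
                       n_negative = 400L,
                       length_mean = 400,
                       length_sd = 40,
                       loop_len_min = 20L,
                       loop_len_max = 28L,
                       scaffold_motifs = default_scaffold_motifs(),
                       loop_alphabet_bias = aa_composition("loop"),
                       n_decoys = 0L,
                       seed = 1L) {
  stopifnot(
    n_positive >= 0, n_negative >= 0,
    length_mean > 0, length_sd >= 0,
    loop_len_min >= 1, loop_len_min <= loop_len_max,
    n_decoys >= 0
  )
  if (!setequal(names(loop_alphabet_bias), AA_CHANNELS)) {
    stop("`loop_alphabet_bias` must be named over the 20 standard residues",
      call. = FALSE
    )
  }
  structure(
    list(
      n_positive = as.integer(n_positive),
      n_negative = as.integer(n_negative),
      length_mean = length_mean,
      length_sd = length_sd,
      loop_len_min = as.integer(loop_len_min),
      loop_len_max = as.integer(loop_len_max),
      scaffold_motifs = scaffold_motifs,
      loop_alphabet_bias = loop_alphabet_bias[AA_CHANNELS] /
        sum(loop_alphabet_bias),
      n_decoys = as.integer(n_decoys),
      seed = as.integer(seed)
    ),
    class = "rcl_sim_config"
  )
}

draw_residues <- function(n, comp) {
  paste(
    sample(AA_CHANNELS, n, replace = TRUE, prob = comp),
    collapse = ""
  )
}

splice <- function(chars, at, insert_chars) {
  chars[at:(at + length(insert_chars) - 1L)] <- insert_chars
  chars
}

make_positive_sequence <- function(config, id) {
  len <- as.integer(round(rnorm(1, config$length_mean, config$length_sd)))
  loop_len <- sample.int(
    config$loop_len_max - config$loop_len_min + 1L, 1L
  ) + config$loop_len_min - 1L
  # loop must sit strictly inside the scaffold, >= 20 residues from each end
  if (len < loop_len + 40L) {
    stop(
      "Sequence of length ", len, " cannot host a loop of length ", loop_len,
      " at least 20 residues from each terminus; increase `length_mean`",
      call. = FALSE
    )
  }
  chars <- strsplit(draw_residues(len, aa_composition("scaffold")), "")[[1]]
  loop_ranges <- NULL
  # C-terminal-proximal placement with +-5% jitter so absolute position
  # alone does not identify the loop
  center <- round(len * (0.85 + runif(1, -0.05, 0.05)))
  start <- center - loop_len %/% 2L
  start <- max(21L, min(start, len - 20L - loop_len + 1L))
  end <- start + loop_len - 1L
  for (k in seq_along(config$scaffold_motifs)) {
    motif <- strsplit(names(config$scaffold_motifs)[k], "")[[1]]
    pos <- round(config$scaffold_motifs[k] * (len - length(motif))) + 1L
    if (pos + length(motif) - 1L >= start - 2L && pos <= end + 2L) next
    chars <- splice(chars, pos, motif)
  }
  if (config$n_decoys > 0) {
    motif_iv <- lapply(seq_along(config$scaffold_motifs), function(k) {
      w <- nchar(names(config$scaffold_motifs)[k])
      p <- round(config$scaffold_motifs[k] * (len - w)) + 1L
      c(p, p + w - 1L)
    })
    lo <- 21L
    hi <- start - 40L
    for (d in seq_len(config$n_decoys)) {
      dlen <- sample.int(
        config$loop_len_max - config$loop_len_min + 1L, 1L
      ) + config$loop_len_min - 1L
      if (hi - dlen <= lo) break
      for (try in 1:20) {
        dstart <- sample(lo:(hi - dlen), 1L)
        clear <- !any(vapply(motif_iv, function(iv) {
          dstart <= iv[2] + 2L && dstart + dlen - 1L >= iv[1] - 2L
        }, logical(1)))
        if (clear) {
          chars <- splice(
            chars, dstart,
            strsplit(draw_residues(dlen, config$loop_alphabet_bias), "")[[1]]
          )
          break
        }
      }
    }
  }
  loop <- strsplit(draw_residues(loop_len, config$loop_alphabet_bias), "")[[1]]
  chars <- splice(chars, start, loop)
  tibble::tibble(
    id = id,
    residues = paste(chars, collapse = ""),
    start = start,
    end = end,
    class = "positive"
  )
}

#' Generate positive (loop-carrying) synthetic sequences
#'
#' Each record has a scaffold background with the configured conserved
#' motifs planted at fixed relative positions, and exactly one loop of
#' length uniform in `[loop_len_min, loop_len_max]` drawn from the loop
#' composition and inserted near the 85% relative position, annotated
#' exactly.
#'
#' @param config An [sim_config()].
#' @param id_prefix Prefix for generated sequence ids.
#' @return A sequence tibble with `class = "positive"` and exact spans.
#' @export
generate_positive <- function(config, id_prefix = "pos") {
  stopifnot(inherits(config, "rcl_sim_config"))
  set.seed(config$seed)
  if (config$n_positive == 0) {
    out <- empty_sequence_tbl()
    out$class <- character(0)
    return(out)
  }
  dplyr::bind_rows(lapply(seq_len(config$n_positive), function(i) {
    make_positive_sequence(config, sprintf("%s_%04d", id_prefix, i))
  }))
}

#' Generate negative (loop-free) synthetic sequences
#'
#' Residues are i.i.d. from the proteome-like negative composition, with no
#' planted motifs and no loop (decoy segments are added when
#' `config$n_decoys > 0`). Lengths are a permutation of `length_targets`
#' when supplied (length-distribution matching), otherwise drawn from the
#' positives' Gaussian length model.
#'
#' @param config An [sim_config()].
#' @param length_targets Optional integer vector of target lengths.
#' @param id_prefix Prefix for generated ids.
#' @return A sequence tibble with `class = "negative"` and `NA` spans.
#' @export
generate_negative <- function(config, length_targets = NULL,
                              id_prefix = "neg") {
  stopifnot(inherits(config, "rcl_sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_negative
  if (n == 0) {
    out <- empty_sequence_tbl()
    out$class <- character(0)
    return(out)
  }
  lens <- if (!is.null(length_targets)) {
    if (length(length_targets) >= n) {
      sample(length_targets, n)
    } else {
      sample(length_targets, n, replace = TRUE)
    }
  } else {
    pmax(60L, as.integer(round(rnorm(n, config$length_mean, config$length_sd))))
  }
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    chars <- strsplit(draw_residues(lens[i], aa_composition("negative")), "")[[1]]
    if (config$n_decoys > 0) {
      for (d in seq_len(config$n_decoys)) {
        dlen <- sample.int(
          config$loop_len_max - config$loop_len_min + 1L, 1L
        ) + config$loop_len_min - 1L
        if (lens[i] < dlen + 42L) break
        dstart <- sample(21L:(lens[i] - 20L - dlen), 1L)
        chars <- splice(
          chars, dstart,
          strsplit(draw_residues(dlen, config$loop_alphabet_bias), "")[[1]]
        )
      }
    }
    tibble::tibble(
      id = sprintf("%s_%04d", id_prefix, i),
      residues = paste(chars, collapse = ""),
      start = NA_integer_,
      end = NA_integer_,
      class = "negative"
    )
  }))
}

#' Generate a full labelled dataset with a held-out test partition
#'
#' The train/validation pool uses `config` as given; the test partition is
#' generated from a distinct seed stream (so no sequence is shared) with
#' its own positives and length-matched negatives, and distinct id
#' prefixes.
#'
#' @param config An [sim_config()] describing the train/validation pool.
#' @param l_fixed Fixed model length used by [make_labels()].
#' @param n_test_positive,n_test_negative Test partition sizes (defaults:
#'   one quarter of the training counts).
#' @return A list with `train` and `test` labelled-example tibbles (columns
#'   `id`, `residues`, `length`, `labels`, `mask`, `class`) and the raw
#'   sequence tibbles `train_sequences`, `test_sequences`.
#' @export
generate_dataset <- function(config, l_fixed = 512L,
                             n_test_positive = NULL,
                             n_test_negative = NULL) {
  stopifnot(inherits(config, "rcl_sim_config"))
  if (is.null(n_test_positive)) {
    n_test_positive <- max(1L, config$n_positive %/% 4L)
  }
  if (is.null(n_test_negative)) {
    n_test_negative <- max(1L, config$n_negative %/% 4L)
  }
  pos <- generate_positive(config, id_prefix = "tr_pos")
  neg <- generate_negative(config,
    length_targets = nchar(pos$residues), id_prefix = "tr_neg"
  )
  test_cfg <- config
  test_cfg$seed <- config$seed + 499979L # independent stream for the test set
  test_cfg$n_positive <- as.integer(n_test_positive)
  test_cfg$n_negative <- as.integer(n_test_negative)
  tpos <- generate_positive(test_cfg, id_prefix = "te_pos")
  tneg <- generate_negative(test_cfg,
    length_targets = nchar(tpos$residues), id_prefix = "te_neg"
  )
  train_seqs <- dplyr::bind_rows(pos, neg)
  test_seqs <- dplyr::bind_rows(tpos, tneg)
  list(
    train = make_labels(train_seqs, l_fixed),
    test = make_labels(test_seqs, l_fixed),
    train_sequences = train_seqs,
    test_sequences = test_seqs
  )
}
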