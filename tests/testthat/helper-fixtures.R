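# Shared fixtures, generated in code at test time.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_residues <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

rand_sequence_tbl <- function(n, len_range = c(30, 80), with_span = TRUE,
                              seed = 1) {
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  starts <- ends <- rep(NA_integer_, n)
  if (with_span) {
    for (i in seq_len(n)) {
      w <- sample(3:10, 1)
      starts[i] <- sample(seq_len(lens[i] - w), 1)
      ends[i] <- starts[i] + w - 1L
    }
  }
  tibble::tibble(
    id = sprintf("s%03d", seq_len(n)),
    residues = vapply(lens, rand_residues, character(1)),
    start = starts,
    end = ends
  )
}

# A small planted-loop task whose sequences fit in l_fixed = 128
# (loops 20-28 residues around the 85% position of ~100-residue scaffolds).
toy_sim_config <- function(n_pos = 8, n_neg = 8, seed = 1, ...) {
  sim_config(
    n_positive = n_pos, n_negative = n_neg,
    length_mean = 100, length_sd = 6,
    seed = seed, ...
  )
}

toy_dataset <- function(n_pos = 8, n_neg = 8, l_fixed = 128, seed = 1, ...) {
  generate_dataset(toy_sim_config(n_pos, n_neg, seed = seed, ...),
    l_fixed = l_fixed,
    n_test_positive = max(2, n_pos %/% 4),
    n_test_negative = max(2, n_neg %/% 4)
  )
}

small_model_config <- function(arch, input_dim = 20) {
  model_config(arch,
    input_dim = input_dim, base_channels = 4L, depth = 2L,
    lstm_hidden = 8L
  )
}
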