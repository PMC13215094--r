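#' Read protein sequences from a FASTA file
#'
#' Sequences are returned as a tibble, one row per record, with the first
#' whitespace-delimited token of each header used as the sequence id.
#' Residues are uppercased and wrapped lines are joined. The `start`/`end`
#' columns (1-based inclusive loop coordinates) are initialised to `NA`;
#' attach annotations with [read_annotations()] + a join, or
#' [attach_spans()].
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `residues`, `start`, `end`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 alpha-1 antitrypsin-like", "MKTA", "VLSP"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(!grepl("^\\s*$", lines) & !startsWith(lines, ";"))
  if (length(meaningful) == 0) {
    return(empty_sequence_tbl())
  }
  first <- meaningful[1]
  if (!startsWith(lines[first], ">")) {
    stop("Malformed FASTA: sequence data before any header at line ", first,
      call. = FALSE
    )
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(empty_sequence_tbl())
  }
  ids <- vapply(
    strsplit(names(set), "\\s+"),
    function(x) x[1], character(1)
  )
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("Duplicate sequence id(s) in FASTA: ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    id = ids,
    residues = unname(toupper(as.character(set))),
    start = NA_integer_,
    end = NA_integer_
  )
}

empty_sequence_tbl <- function() {
  tibble::tibble(
    id = character(), residues = character(),
    start = integer(), end = integer()
  )
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs A sequence tibble (columns `id`, `residues`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  check_sequence_tbl(seqs)
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

check_sequence_tbl <- function(seqs) {
  stopifnot(is.data.frame(seqs))
  if (!all(c("id", "residues") %in% names(seqs))) {
    stop("A sequence tibble needs at least `id` and `residues` columns",
      call. = FALSE
    )
  }
  if (nrow(seqs) > 0) {
    if (any(!nzchar(seqs$residues))) {
      stop("Empty residue string in sequence table", call. = FALSE)
    }
    if (any(grepl("[^A-Z]", seqs$residues))) {
      stop("Residues must be uppercase letters", call. = FALSE)
    }
  }
  invisible(seqs)
}

#' Read loop span annotations from a TSV file
#'
#' Expects columns `id`, `start`, `end` with 1-based inclusive residue
#' coordinates, one row per sequence.
#'
#' @param path Path to a tab-separated annotation file with a header row.
#' @return A tibble with columns `id`, `start`, `end`.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path,
    col_types = readr::cols(
      id = readr::col_character(),
      start = readr::col_character(),
      end = readr::col_character()
    ),
    progress = FALSE
  )
  if (!all(c("id", "start", "end") %in% names(ann))) {
    stop("Annotation file must have columns id, start, end", call. = FALSE)
  }
  for (col in c("start", "end")) {
    raw <- ann[[col]]
    num <- suppressWarnings(as.numeric(raw))
    if (any(is.na(num)) || any(num != as.integer(num))) {
      bad <- raw[is.na(num) | num != suppressWarnings(as.integer(num))][1]
      stop("Non-integer coordinate in column `", col, "`: ", bad, call. = FALSE)
    }
    ann[[col]] <- as.integer(num)
  }
  if (anyDuplicated(ann$id)) {
    dup <- unique(ann$id[duplicated(ann$id)])
    stop("Duplicate annotation id(s): ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- ann$start > ann$end | ann$start < 1L
  if (any(bad)) {
    stop(
      "Invalid span for id(s): ",
      paste(ann$id[bad], collapse = ", "),
      " (need 1 <= start <= end)",
      call. = FALSE
    )
  }
  tibble::as_tibble(ann[, c("id", "start", "end")])
}

#' Attach loop spans to a sequence tibble
#'
#' Left-joins annotations onto sequences by `id` and validates that every
#' span fits inside its sequence.
#'
#' @param seqs A sequence tibble.
#' @param annotations A tibble from [read_annotations()].
#' @return `seqs` with `start`/`end` filled in where annotated.
#' @export
attach_spans <- function(seqs, annotations) {
  check_sequence_tbl(seqs)
  out <- dplyr::left_join(
    dplyr::select(seqs, -dplyr::any_of(c("start", "end"))),
    annotations,
    by = "id"
  )
  len <- nchar(out$residues)
  bad <- !is.na(out$end) & out$end > len
  if (any(bad)) {
    stop(
      "Span exceeds sequence length for id(s): ",
      paste(out$id[bad], collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Build fixed-length per-residue labels and masks
#'
#' Each sequence becomes a label vector of length `l_fixed` (1 inside the
#' annotated loop, 0 elsewhere) and a validity mask (1 for real residues, 0
#' for padding). Sequences longer than `l_fixed` keep their N-terminal
#' `l_fixed` residues; a record whose entire annotated span lies beyond the
#' truncation point is dropped with a warning rather than silently losing
#' its loop.
#'
#' @param seqs A sequence tibble (optionally with `start`/`end` spans).
#' @param l_fixed Fixed model length (positive integer), e.g. 1024.
#' @return A tibble with columns `id`, `length` (original residue count),
#'   `labels` and `mask` (integer list-columns of length `l_fixed`).
#' @export
make_labels <- function(seqs, l_fixed) {
  check_sequence_tbl(seqs)
  stopifnot(length(l_fixed) == 1, l_fixed >= 1)
  l_fixed <- as.integer(l_fixed)
  n <- nrow(seqs)
  keep <- rep(TRUE, n)
  labels <- vector("list", n)
  mask <- vector("list", n)
  lens <- nchar(seqs$residues)
  has_span <- !is.na(seqs$start) & !is.na(seqs$end)
  for (i in seq_len(n)) {
    len <- min(lens[i], l_fixed)
    m <- c(rep(1L, len), rep(0L, l_fixed - len))
    lab <- integer(l_fixed)
    if (has_span[i]) {
      s <- seqs$start[i]
      e <- seqs$end[i]
      if (s < 1L || e < s || e > lens[i]) {
        stop("Invalid span for id ", seqs$id[i], call. = FALSE)
      }
      if (s > l_fixed) {
        keep[i] <- FALSE
      } else {
        lab[s:min(e, l_fixed)] <- 1L
      }
    }
    labels[[i]] <- lab
    mask[[i]] <- m
  }
  if (any(!keep)) {
    warning(
      "Excluded ", sum(!keep), " record(s) whose loop span lies entirely ",
      "beyond the truncation length ", l_fixed, ": ",
      paste(seqs$id[!keep], collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    id = seqs$id[keep],
    residues = seqs$residues[keep],
    length = lens[keep],
    labels = labels[keep],
    mask = mask[keep]
  )
  if ("class" %in% names(seqs)) out$class <- seqs$class[keep]
  out
}

#' Write predicted loop spans to TSV, GFF3 or BED
#'
#' TSV and GFF3 use 1-based inclusive coordinates (the UniProt feature
#' convention used internally); BED is converted to 0-based half-open on
#' write. GFF3 rows carry feature type `reactive_center_loop` with the mean
#' positive-class probability in the score column.
#'
#' @param spans A tibble with columns `id`, `start`, `end`, `prob`
#'   (mean positive-class probability per span).
#' @param path Output path.
#' @param format One of `"tsv"`, `"gff3"`, `"bed"`.
#' @return `path`, invisibly.
#' @export
write_spans <- function(spans, path, format = c("tsv", "gff3", "bed")) {
  if (!is.character(format) || length(format) < 1 ||
    !format[1] %in% c("tsv", "gff3", "bed")) {
    stop("Unknown span output format: ", paste(format[1], collapse = ""),
      call. = FALSE
    )
  }
  format <- format[1]
  stopifnot(is.data.frame(spans))
  if (nrow(spans) > 0) {
    stopifnot(all(spans$start >= 1), all(spans$end >= spans$start))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines("id\tstart\tend\tprob", con)
    if (nrow(spans) > 0) {
      writeLines(sprintf(
        "%s\t%d\t%d\t%.4g",
        spans$id, spans$start, spans$end, spans$prob
      ), con)
    }
  } else if (format == "gff3") {
    writeLines("##gff-version 3", con)
    if (nrow(spans) > 0) {
      writeLines(sprintf(
        "%s\trclseg\treactive_center_loop\t%d\t%d\t%.4g\t.\t.\tID=%s_rcl",
        spans$id, spans$start, spans$end, spans$prob, spans$id
      ), con)
    }
  } else {
    writeLines('track name="rclseg" description="predicted reactive center loops"', con)
    if (nrow(spans) > 0) {
      writeLines(sprintf(
        "%s\t%d\t%d\trcl\t%.4g",
        spans$id, spans$start - 1L, spans$end, spans$prob
      ), con)
    }
  }
  invisible(path)
}

#' Greedy sequence-identity filtering
#'
#' Reduces redundancy the way training sets are thresholded to a maximum
#' pairwise identity: records are visited in input order and a record is
#' kept only if its global-alignment identity to every previously kept
#' record is below `threshold`. Identity is matches divided by alignment
#' length under a global alignment with BLOSUM62 scoring (gap opening 11,
#' extension 1). Deterministic given input order.
#'
#' @param seqs A sequence tibble.
#' @param threshold Maximum allowed pairwise identity, a fraction in (0, 1].
#' @return The filtered sequence tibble (a subset of the input rows).
#' @export
filter_by_identity <- function(seqs, threshold) {
  check_sequence_tbl(seqs)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
    threshold <= 0 || threshold > 1) {
    stop("`threshold` must be a fraction in (0, 1]", call. = FALSE)
  }
  n <- nrow(seqs)
  if (n <= 1) {
    return(seqs)
  }
  # U/O are absent from the BLOSUM62 score matrix; align them as X
  alnseq <- gsub("[UO]", "X", seqs$residues)
  kept <- integer(0)
  for (i in seq_len(n)) {
    redundant <- FALSE
    for (j in kept) {
      if (pairwise_identity(alnseq[i], alnseq[j]) >= threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  seqs[kept, , drop = FALSE]
}

pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Read a dataset manifest
#'
#' A manifest is a TSV with columns `id`, `residues`, `class`
#' (`positive`/`negative`) and optional `start`, `end` span columns. It is
#' the single entry point through which both synthetic and real datasets
#' flow into training and evaluation.
#'
#' @param path Path to a manifest TSV.
#' @return A sequence tibble with an extra `class` column.
#' @export
read_manifest <- function(path) {
  tbl <- readr::read_tsv(path,
    col_types = readr::cols(
      id = readr::col_character(),
      residues = readr::col_character(),
      class = readr::col_character(),
      .default = readr::col_integer()
    ),
    progress = FALSE
  )
  if (!all(c("id", "residues", "class") %in% names(tbl))) {
    stop("Manifest must have columns id, residues, class", call. = FALSE)
  }
  if (!all(tbl$class %in% c("positive", "negative"))) {
    stop("Manifest class column must be 'positive' or 'negative'",
      call. = FALSE
    )
  }
  if (!"start" %in% names(tbl)) tbl$start <- NA_integer_
  if (!"end" %in% names(tbl)) tbl$end <- NA_integer_
  check_sequence_tbl(tbl)
  tibble::as_tibble(tbl[, c("id", "residues", "start", "end", "class")])
}

#' Write a dataset manifest
#'
#' @param seqs A sequence tibble with a `class` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(seqs, path) {
  check_sequence_tbl(seqs)
  stopifnot("class" %in% names(seqs))
  readr::write_tsv(
    seqs[, c("id", "residues", "start", "end", "class")],
    path, progress = FALSE
  )
  invisible(path)
}
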