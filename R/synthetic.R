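# Synthetic fixture generators. All tests and the reproduction script run
# on data built by these functions: random sequences over a chosen
# alphabet (optionally with injected faults) and random toy property
# tables. Randomness comes from R's RNG, so set.seed() makes every
# fixture reproducible.

#' Generate random sequence records
#'
#' Sequence letters are drawn uniformly from the type's alphabet, with
#' lengths uniform in \code{length_range}. Fault injection emulates the
#' problems real public-database datasets show: \code{n_invalid} records
#' get one letter replaced by a symbol outside the alphabet, and
#' \code{n_short} records are truncated to \code{short_length} (too short
#' for most configured descriptors).
#'
#' @param n number of records.
#' @param seqtype sequence type or name (default PROT).
#' @param length_range min and max sequence length.
#' @param n_invalid records to corrupt with a non-standard letter.
#' @param n_short records to truncate to \code{short_length}.
#' @param short_length length of truncated records (default 2).
#' @param invalid_letter the out-of-alphabet symbol used (default "Z" for
#'   DNA/RNA, "B" for other types).
#' @param prefix identifier prefix; ids are \code{prefix1..prefixN}.
#' @return list of \code{\link{sequence_record}} objects.
#' @export
random_records <- function(n, seqtype = "PROT", length_range = c(50L, 200L),
                           n_invalid = 0L, n_short = 0L, short_length = 2L,
                           invalid_letter = NULL, prefix = "seq") {
  st <- get_seqtype(seqtype)
  if (is.null(invalid_letter))
    invalid_letter <- if ("B" %in% st$alphabet) "z" else "B"
  stopifnot(n_invalid + n_short <= n)
  lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
  recs <- lapply(seq_len(n), function(i) {
    letters <- paste(sample(st$alphabet, lens[i], replace = TRUE),
                     collapse = "")
    sequence_record(paste0(prefix, i), letters)
  })
  bad <- sample.int(n, n_invalid + n_short)
  for (i in seq_len(n_invalid)) {
    r <- recs[[bad[i]]]
    pos <- sample.int(nchar(r$letters), 1L)
    substring(r$letters, pos, pos) <- invalid_letter
    recs[[bad[i]]] <- r
  }
  for (i in seq_len(n_short)) {
    r <- recs[[bad[n_invalid + i]]]
    r$letters <- substring(r$letters, 1L, short_length)
    recs[[bad[n_invalid + i]]] <- r
  }
  recs
}

#' Write random records to a FASTA file
#'
#' Convenience wrapper: generates records with \code{\link{random_records}}
#' and serializes them multi-line (wrapped at \code{width} columns) to
#' exercise the multi-line parser.
#'
#' @inheritParams random_records
#' @param file destination path.
#' @param width line width for sequence wrapping.
#' @param ... passed to \code{\link{random_records}}.
#' @return (invisibly) the records written.
#' @export
random_fasta <- function(file, n, seqtype = "PROT", width = 60L, ...) {
  recs <- random_records(n, seqtype = seqtype, ...)
  lines <- unlist(lapply(recs, function(r) {
    s <- r$letters
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", r$id), substring(s, starts,
                                   pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, file)
  invisible(recs)
}

#' Generate a random toy property table
#'
#' Raw values are standard-normal draws over all |A|^n tuples; the table
#' is normalized on construction. Toy tables decouple kernel correctness
#' from any literature property values.
#'
#' @param seqtype sequence type or name.
#' @param tuple_size n (1 = residue/nucleotide, 2 = dinucleotide, ...).
#' @param name property name (default: a unique auto-generated one).
#' @param register register the table for lookup by name.
#' @return a normalized \code{"seqvec_property"}.
#' @export
random_property_table <- function(seqtype, tuple_size = 1L, name = NULL,
                                  register = FALSE) {
  st <- get_seqtype(seqtype)
  tuples <- enumerate_tuples(st, tuple_size)
  if (is.null(name))
    name <- paste0("toy.", st$name, ".", tuple_size, ".",
                   paste(sample(letters, 8L, replace = TRUE), collapse = ""))
  raw <- stats::setNames(stats::rnorm(length(tuples)), tuples)
  tab <- normalize_table(new_property_table(name, st$name, tuple_size, raw))
  if (register) register_property_table(tab, overwrite = TRUE)
  tab
}
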