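#' Recognize a FASTA header dialect
#'
#' Extracts the database tag and accession from a FASTA header line.
#' Dialects are tried in a fixed order, first match wins:
#' \enumerate{
#'   \item UniProt: \code{sp|ACC|ENTRY} or \code{tr|ACC|ENTRY}
#'   \item NCBI legacy: \code{gi|N|db|ACC|} with embedded tag gb/ref/emb/dbj
#'   \item ENA: \code{ENA|ACC|ACC.V} (EMBL)
#'   \item RefSeq modern: first token like \code{NM_000546.6}
#'     (two capitals, underscore, digits, optional version)
#'   \item GenBank/DDBJ modern: first token of 1-2 letters + 5-6 digits
#'     (+ optional version); DDBJ and GenBank accessions share a namespace,
#'     so both are tagged GENBANK (documented limitation)
#' }
#' Anything else falls back to db UNKNOWN with the full header text (minus
#' \code{>}) as identifier.
#'
#' @param header_line a header line starting with \code{>}.
#' @return a list with fields \code{db}, \code{identifier}, \code{comment}.
#' @examples
#' recognize_header(">sp|P12345|NAME_HUMAN some protein")
#' recognize_header(">NM_000546.6 Homo sapiens TP53")
#' @export
recognize_header <- function(header_line) {
  stopifnot(is.character(header_line), length(header_line) == 1L)
  if (!startsWith(header_line, ">"))
    stop("header line must start with '>'", call. = FALSE)
  text <- sub("\r$", "", substring(header_line, 2L))
  text <- trimws(text)

  hit <- function(db, identifier, comment)
    list(db = db, identifier = identifier, comment = trimws(comment))

  # UniProt
  m <- regexec("^(sp|tr)\\|([^| ]+)\\|(.*)$", text)[[1L]]
  if (m[1L] != -1L) {
    g <- regmatches(text, list(m))[[1L]]
    return(hit("UNIPROT", g[3L], g[4L]))
  }
  # NCBI legacy gi
  m <- regexec("^gi\\|[0-9]+\\|(gb|ref|emb|dbj)\\|([^| ]+)\\|?(.*)$", text)[[1L]]
  if (m[1L] != -1L) {
    g <- regmatches(text, list(m))[[1L]]
    db <- c(gb = "GENBANK", ref = "REFSEQ", emb = "EMBL", dbj = "DDBJ")[g[2L]]
    return(hit(unname(db), g[3L], sub("^\\|", "", g[4L])))
  }
  # ENA
  m <- regexec("^ENA\\|([^| ]+)\\|(\\S*)(.*)$", text)[[1L]]
  if (m[1L] != -1L) {
    g <- regmatches(text, list(m))[[1L]]
    return(hit("EMBL", g[2L], paste0(g[3L], g[4L])))
  }
  tok <- sub("\\s.*$", "", text)
  rest <- sub("^\\S+\\s*", "", text)
  # RefSeq modern accession
  if (grepl("^[A-Z]{2}_[0-9]+(\\.[0-9]+)?$", tok))
    return(hit("REFSEQ", tok, rest))
  # GenBank / DDBJ modern accession
  if (grepl("^[A-Za-z]{1,2}[0-9]{5,6}(\\.[0-9]+)?$", tok))
    return(hit("GENBANK", tok, rest))
  hit("UNKNOWN", text, "")
}

#' Parse a multi-line FASTA file
#'
#' Reads a standard multi-line FASTA stream: each record's sequence is the
#' concatenation of all lines between its header and the next. Header
#' dialects are recognized per \code{\link{recognize_header}}; identifiers
#' must be unique in the file. If accession extraction yields the same
#' identifier for two records with distinct header lines, both fall back to
#' their full-line identifiers; a duplicate surviving that fallback is a
#' parse error. LF and CRLF endings and a missing trailing newline are
#' accepted.
#'
#' A record whose sequence is empty is a data fault; with the skip policy
#' it is excluded and reported, with abort it stops the parse. If
#' \code{seqtype} is supplied, letters are validated eagerly and
#' non-standard letters take the same fault path (otherwise validation
#' happens at encoding time).
#'
#' @param input a file path, a connection, or a character vector of lines.
#' @param seqtype optional sequence type (or name) for eager letter
#'   validation.
#' @param policy a \code{\link{fault_policy}} (default skip).
#' @return a list of \code{\link{sequence_record}} objects, in file order,
#'   with attribute \code{"report"}: a data frame of skipped records
#'   (seq_id, reason).
#' @export
parse_fasta <- function(input, seqtype = NULL, policy = fault_policy()) {
  lines <- if (is.character(input) && length(input) == 1L &&
               !grepl("\n", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else if (inherits(input, "connection")) {
    readLines(input, warn = FALSE)
  } else {
    unlist(strsplit(as.character(input), "\n", fixed = TRUE))
  }
  lines <- sub("\r$", "", lines)
  # leading blank lines tolerated
  first <- which(nzchar(trimws(lines)))[1L]
  if (is.na(first)) stop("empty FASTA input", call. = FALSE)
  if (!startsWith(trimws(lines[first]), ">"))
    stop("FASTA input must begin with a '>' header line", call. = FALSE)

  is_header <- startsWith(lines, ">")
  hidx <- which(is_header)
  bounds <- c(hidx, length(lines) + 1L)

  headers <- character(length(hidx))
  seqs <- character(length(hidx))
  for (i in seq_along(hidx)) {
    headers[i] <- lines[hidx[i]]
    body <- lines[(hidx[i] + 1L):(bounds[i + 1L] - 1L)]
    if (hidx[i] + 1L > bounds[i + 1L] - 1L) body <- character()
    seqs[i] <- paste(trimws(body), collapse = "")
  }

  parsed <- lapply(headers, recognize_header)
  ids <- vapply(parsed, `[[`, "", "identifier")

  # duplicate-id fallback: distinct header lines that extracted the same id
  # revert to their full-line identifiers
  dup <- ids %in% ids[duplicated(ids)]
  if (any(dup)) {
    for (i in which(dup)) {
      full <- trimws(substring(headers[i], 2L))
      if (full != ids[i]) {
        ids[i] <- full
        parsed[[i]] <- list(db = "UNKNOWN", identifier = full, comment = "")
      }
    }
    if (anyDuplicated(ids))
      stop("duplicate identifier '", ids[duplicated(ids)][1L],
           "' in FASTA input; identifiers must be unique", call. = FALSE)
  }

  records <- vector("list", length(hidx))
  report <- empty_report()
  keep <- logical(length(hidx))
  for (i in seq_along(hidx)) {
    res <- with_fault_policy({
      if (!nzchar(clean_letters(seqs[i])))
        signal_fault(ids[i], "empty sequence")
      rec <- sequence_record(ids[i], seqs[i], db = parsed[[i]]$db,
                             comment = parsed[[i]]$comment)
      if (!is.null(seqtype)) encode_sequence(rec, seqtype)
      rec
    }, policy)
    if (is.null(res$fault)) {
      records[[i]] <- res$value
      keep[i] <- TRUE
    } else {
      report <- rbind(report, res$fault)
    }
  }
  structure(records[keep], report = report)
}

#' Serialize records to single-line FASTA
#'
#' Writes \code{>id comment} followed by the sequence on one line, so that
#' parsing the output recovers every record's id and letters.
#'
#' @param records list of \code{\link{sequence_record}} objects.
#' @param file path or connection; omit to return the lines invisibly.
#' @return (invisibly) the character vector of lines.
#' @export
write_fasta <- function(records, file = NULL) {
  lines <- unlist(lapply(records, function(r) {
    hdr <- if (nzchar(r$comment)) paste0(">", r$id, " ", r$comment)
           else paste0(">", r$id)
    c(hdr, clean_letters(r$letters))
  }))
  if (is.null(lines)) lines <- character()
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
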