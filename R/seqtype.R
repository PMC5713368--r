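#' Define a sequence type (alphabet)
#'
#' A sequence type is a named, ordered alphabet of distinct single-letter
#' symbols, optionally with a complement map (required by reverse-complement
#' modes). The letter at position \code{u} of \code{alphabet} has internal
#' index \code{u - 1}: indices are 0-based internally, while formula
#' subscripts in the descriptor definitions are 1-based.
#'
#' Built-in types \code{DNA} (A,C,G,T with Watson-Crick complements),
#' \code{RNA} (A,C,G,U) and \code{PROT} (the 20 standard amino-acid letters
#' in alphabetical order) are pre-registered when the package loads. DNA and
#' RNA are distinct: a U under the DNA type is a data fault, never silently
#' translated.
#'
#' @param name short unique identifier for the type.
#' @param alphabet character vector of distinct single-letter symbols, in
#'   index order.
#' @param complement optional named character vector mapping each letter to
#'   its complement; must be total on the alphabet but need not be an
#'   involution or injective (a methylated cytosine may complement to G
#'   alongside plain C).
#' @param case_fold fold input letters to upper case before lookup (default
#'   \code{TRUE}; disable for alphabets where case is semantic).
#' @param register register the type in the package registry so modes and
#'   the CLI can refer to it by name (default \code{TRUE}).
#' @return an object of class \code{"seqvec_seqtype"}.
#' @examples
#' mdna <- define_seqtype("DNA5", c("A", "C", "G", "T", "M"),
#'                        complement = c(A = "T", T = "A", C = "G",
#'                                       G = "C", M = "G"),
#'                        register = FALSE)
#' alphabet_size(mdna)  # 5
#' @export
define_seqtype <- function(name, alphabet, complement = NULL,
                           case_fold = TRUE, register = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  alphabet <- as.character(alphabet)
  if (length(alphabet) == 0L)
    stop("seqtype '", name, "': alphabet must be non-empty", call. = FALSE)
  if (any(nchar(alphabet) != 1L))
    stop("seqtype '", name, "': alphabet symbols must be single letters",
         call. = FALSE)
  if (anyDuplicated(alphabet))
    stop("seqtype '", name, "': duplicate letter '",
         alphabet[duplicated(alphabet)][1L], "' in alphabet", call. = FALSE)
  if (!is.null(complement)) {
    complement <- unlist(complement)
    if (is.null(names(complement)) || !all(nzchar(names(complement))))
      stop("complement map must be a named character vector", call. = FALSE)
    bad <- setdiff(c(names(complement), unname(complement)), alphabet)
    if (length(bad))
      stop("complement map refers to letters outside the alphabet: ",
           paste(bad, collapse = ", "), call. = FALSE)
    uncovered <- setdiff(alphabet, names(complement))
    if (length(uncovered))
      stop("complement map must cover every alphabet letter; missing: ",
           paste(uncovered, collapse = ", "), call. = FALSE)
    complement <- complement[alphabet]
  }
  st <- structure(
    list(name = name, alphabet = alphabet, complement = complement,
         case_fold = isTRUE(case_fold)),
    class = "seqvec_seqtype")
  if (register) {
    if (name %in% names(.seqvec$seqtypes))
      stop("sequence type '", name, "' is already registered", call. = FALSE)
    .seqvec$seqtypes[[name]] <- st
  }
  st
}

#' Look up a registered sequence type by name
#'
#' @param x a \code{"seqvec_seqtype"} object (returned unchanged) or the
#'   name of a registered type.
#' @return the \code{"seqvec_seqtype"} object.
#' @export
get_seqtype <- function(x) {
  if (inherits(x, "seqvec_seqtype")) return(x)
  st <- .seqvec$seqtypes[[x]]
  if (is.null(st))
    stop("unknown sequence type '", x, "' (registered: ",
         paste(names(.seqvec$seqtypes), collapse = ", "), ")", call. = FALSE)
  st
}

#' @export
print.seqvec_seqtype <- function(x, ...) {
  cat("Sequence type '", x$name, "': alphabet {",
      paste(x$alphabet, collapse = ","), "}",
      if (!is.null(x$complement)) " with complement map", "\n", sep = "")
  invisible(x)
}

#' Alphabet size of a sequence type
#' @param seqtype a sequence type or its registered name.
#' @return integer |A|.
#' @export
alphabet_size <- function(seqtype) length(get_seqtype(seqtype)$alphabet)

#' Create a FASTA sequence record
#'
#' @param id unique identifier (non-empty).
#' @param letters raw sequence string; whitespace and digits are tolerated
#'   and stripped at encoding time.
#' @param db source-database tag, one of UNIPROT, GENBANK, EMBL, DDBJ,
#'   REFSEQ, UNKNOWN.
#' @param comment free-text remainder of the header line.
#' @return an object of class \code{"seqvec_record"}.
#' @export
sequence_record <- function(id, letters, db = "UNKNOWN", comment = "") {
  stopifnot(is.character(id), length(id) == 1L)
  if (!nzchar(id)) stop("record identifier must be non-empty", call. = FALSE)
  db <- match.arg(db, c("UNKNOWN", "UNIPROT", "GENBANK", "EMBL",
                        "DDBJ", "REFSEQ"))
  structure(list(id = id, db = db, comment = comment,
                 letters = as.character(letters)),
            class = "seqvec_record")
}

#' @export
print.seqvec_record <- function(x, ...) {
  n <- nchar(clean_letters(x$letters))
  cat(">", x$id, if (nzchar(x$comment)) paste0(" ", x$comment),
      "  [", x$db, ", ", n, " letters]\n", sep = "")
  invisible(x)
}

# strip whitespace and digits inside sequence lines (column-formatted FASTA)
clean_letters <- function(letters) gsub("[[:space:][:digit:]]", "", letters)

#' Encode a sequence into internal alphabet indices
#'
#' Converts the raw letters of a record into an integer vector of 0-based
#' alphabet indices (an index array), after stripping whitespace/digits and
#' applying the type's case folding. A letter outside the alphabet raises a
#' non-standard-letter data fault; an empty sequence raises an
#' empty-sequence fault. Faults are classed conditions handled by the
#' dataset-level skip/abort policy (see \code{\link{fault_policy}}).
#'
#' @param record a \code{"seqvec_record"} or a plain character string.
#' @param seqtype sequence type or registered name.
#' @return integer vector of indices in \code{[0, |A| - 1]} with attributes
#'   \code{seq_id} and \code{seqtype}.
#' @examples
#' encode_sequence("ACGT", "DNA")   # 0 1 2 3
#' @export
encode_sequence <- function(record, seqtype) {
  seqtype <- get_seqtype(seqtype)
  if (inherits(record, "seqvec_record")) {
    id <- record$id
    letters <- record$letters
  } else {
    id <- "<anonymous>"
    letters <- as.character(record)
  }
  letters <- clean_letters(letters)
  if (seqtype$case_fold) letters <- toupper(letters)
  if (!nzchar(letters))
    signal_fault(id, "empty sequence")
  chars <- strsplit(letters, "", fixed = TRUE)[[1L]]
  idx <- match(chars, seqtype$alphabet)
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1L]
    signal_fault(id, sprintf("non-standard letter %s at position %d",
                             chars[pos], pos))
  }
  structure(as.integer(idx - 1L), seq_id = id, seqtype = seqtype$name)
}

#' Decode an index array back to letters
#' @param indices integer vector of 0-based indices.
#' @param seqtype sequence type or name.
#' @return the sequence string.
#' @export
decode_indices <- function(indices, seqtype) {
  seqtype <- get_seqtype(seqtype)
  paste(seqtype$alphabet[indices + 1L], collapse = "")
}

#' Load sequence type definitions from a plain-text file
#'
#' The file holds one or more keyed entries:
#' \preformatted{
#' name=DNA5
#' alphabet=ACGTM
#' complement=A:T,T:A,C:G,G:C,M:G
#' case_fold=yes
#' }
#' A new \code{name=} line starts the next definition; \code{complement}
#' and \code{case_fold} are optional (\code{case_fold} defaults to yes).
#' '#' comment lines and blank lines are ignored.
#'
#' @param file path to the definition file.
#' @param register register the parsed types (default \code{TRUE}).
#' @return (invisibly) a list of the defined sequence types.
#' @export
load_seqtype_file <- function(file, register = TRUE) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defs <- list(); cur <- NULL
  flush <- function(cur, defs) { if (!is.null(cur)) defs[[length(defs) + 1L]] <- cur; defs }
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L)
      stop("malformed sequence-type definition line: ", ln, call. = FALSE)
    key <- kv[2L]; val <- kv[3L]
    if (key == "name") { defs <- flush(cur, defs); cur <- list(name = val) }
    else if (is.null(cur))
      stop("'", key, "' before any name= line", call. = FALSE)
    else cur[[key]] <- val
  }
  defs <- flush(cur, defs)
  out <- lapply(defs, function(d) {
    if (is.null(d$alphabet))
      stop("sequence type '", d$name, "': missing alphabet=", call. = FALSE)
    comp <- NULL
    if (!is.null(d$complement)) {
      pairs <- strsplit(strsplit(d$complement, ",", fixed = TRUE)[[1L]],
                        ":", fixed = TRUE)
      comp <- stats::setNames(vapply(pairs, `[`, "", 2L),
                              vapply(pairs, `[`, "", 1L))
    }
    define_seqtype(d$name, strsplit(d$alphabet, "")[[1L]], complement = comp,
                   case_fold = is.null(d$case_fold) ||
                     tolower(d$case_fold) %in% c("yes", "true", "1"),
                   register = register)
  })
  invisible(out)
}

# Built-ins registered at load time and by reset_registry().
register_builtin_seqtypes <- function() {
  define_seqtype("DNA", c("A", "C", "G", "T"),
                 complement = c(A = "T", C = "G", G = "C", T = "A"))
  define_seqtype("RNA", c("A", "C", "G", "U"),
                 complement = c(A = "U", C = "G", G = "C", U = "A"))
  define_seqtype("PROT",
                 c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  invisible(NULL)
}
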