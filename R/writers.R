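# Result writers. All three formats print identical numeric values: the
# shortest decimal representation with `precision` significant digits and
# no scientific notation below 1e6, so results round-trip to the printed
# precision and are byte-stable across formats.

fmt_num <- function(x, precision = 6L) {
  vapply(as.numeric(x), function(v) {
    if (!is.finite(v)) return(as.character(v))
    out <- format(signif(v, precision), scientific = FALSE, trim = TRUE,
                  digits = 15L)
    if (grepl(".", out, fixed = TRUE)) out <- sub("\\.?0+$", "", out)
    if (out == "-0") out <- "0"
    out
  }, "")
}

result_parts <- function(x) {
  if (inherits(x, "seqvec_result"))
    return(list(vectors = x$vectors, labels = x$labels,
                mode_ids = x$mode_ids, mode_dims = x$mode_dims))
  if (is.matrix(x)) {
    v <- lapply(seq_len(nrow(x)), function(i) x[i, ])
    names(v) <- rownames(x) %||% paste0("seq", seq_len(nrow(x)))
    return(list(vectors = v,
                labels = stats::setNames(numeric(length(v)), names(v)),
                mode_ids = NULL, mode_dims = NULL))
  }
  stopifnot(is.list(x))
  list(vectors = x, labels = stats::setNames(numeric(length(x)), names(x)),
       mode_ids = NULL, mode_dims = NULL)
}

#' Write descriptor vectors in libSVM (svmlight) format
#'
#' One line per record: \code{<label> 1:v1 2:v2 ... D:vD}. Feature indices
#' are 1-based and strictly increasing. Zero components are emitted by
#' default so every line has the full, fixed column count;
#' \code{sparse = TRUE} drops them.
#'
#' @param x a \code{"seqvec_result"}, a numeric matrix, or a named list of
#'   numeric vectors.
#' @param file path or connection; omit to return lines invisibly.
#' @param labels optional numeric vector overriding per-record labels
#'   (recycled; default: labels carried by the result, else 0).
#' @param sparse drop zero-valued components.
#' @param precision significant digits (default 6).
#' @return (invisibly) the character vector of lines.
#' @export
write_svm <- function(x, file = NULL, labels = NULL, sparse = FALSE,
                      precision = 6L) {
  p <- result_parts(x)
  if (!is.null(labels)) p$labels <- rep_len(labels, length(p$vectors))
  lines <- vapply(seq_along(p$vectors), function(i) {
    v <- p$vectors[[i]]
    keep <- if (sparse) which(v != 0) else seq_along(v)
    paste(c(fmt_num(p$labels[[i]], precision),
            paste0(keep, ":", fmt_num(v[keep], precision))),
          collapse = " ")
  }, "")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

component_names <- function(mode_ids, mode_dims, total) {
  if (is.null(mode_ids) || is.null(mode_dims))
    return(paste0("v_", seq_len(total)))
  unlist(Map(function(id, d) paste0(id, "_", seq_len(d)),
             mode_ids, mode_dims), use.names = FALSE)
}

#' Write descriptor vectors as TSV or CSV
#'
#' One line per record: the identifier, then the vector components. An
#' identifier containing the delimiter is quoted (CSV, RFC-4180 style) or
#' has the delimiter replaced by '_' (TSV), with a logged note.
#'
#' @inheritParams write_svm
#' @param format \code{"tsv"} or \code{"csv"}.
#' @param header emit a header row naming components
#'   \code{<mode_id>_<index>} (default \code{FALSE}).
#' @return (invisibly) the character vector of lines.
#' @export
write_tabular <- function(x, file = NULL, format = c("tsv", "csv"),
                          header = FALSE, precision = 6L) {
  format <- match.arg(format)
  delim <- if (format == "tsv") "\t" else ","
  p <- result_parts(x)
  ids <- names(p$vectors)
  fix_id <- function(id) {
    if (!grepl(delim, id, fixed = TRUE)) return(id)
    message("identifier '", id, "' contains the ", format,
            " delimiter; adjusted in output")
    if (format == "csv") paste0('"', gsub('"', '""', id), '"')
    else gsub(delim, "_", id, fixed = TRUE)
  }
  lines <- vapply(seq_along(p$vectors), function(i)
    paste(c(fix_id(ids[[i]]), fmt_num(p$vectors[[i]], precision)),
          collapse = delim), "")
  if (header) {
    total <- if (length(p$vectors)) length(p$vectors[[1L]]) else 0L
    hdr <- paste(c("id", component_names(p$mode_ids, p$mode_dims, total)),
                 collapse = delim)
    lines <- c(hdr, lines)
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
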