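#' Enumerate the n-tuples of an alphabet in index order
#'
#' Tuple order is lexicographic by alphabet index, row-major over positions:
#' for DNA dinucleotides the tuple index is \code{4*idx(first) +
#' idx(second)}. This is the axis ordering of every pre-computed matrix and
#' composition vector in the package.
#'
#' @param seqtype sequence type or name.
#' @param n tuple size.
#' @return character vector of |A|^n tuples.
#' @export
enumerate_tuples <- function(seqtype, n) {
  st <- get_seqtype(seqtype)
  stopifnot(n >= 1L)
  grid <- do.call(expand.grid,
                  c(rev(replicate(n, st$alphabet, simplify = FALSE)),
                    list(stringsAsFactors = FALSE)))
  # expand.grid varies the first factor fastest; reversed columns give
  # row-major (last position fastest) ordering
  apply(grid[, rev(seq_len(n)), drop = FALSE], 1L, paste, collapse = "")
}

new_property_table <- function(name, seqtype, tuple_size, raw,
                               normalized = NULL) {
  structure(list(name = name, seqtype = seqtype,
                 tuple_size = as.integer(tuple_size),
                 raw = raw, normalized = normalized),
            class = "seqvec_property")
}

#' @export
print.seqvec_property <- function(x, ...) {
  cat("Property '", x$name, "' over ", x$seqtype, " ", x$tuple_size,
      "-tuples (", length(x$raw), " values",
      if (!is.null(x$normalized)) ", normalized", ")\n", sep = "")
  invisible(x)
}

#' Load a physicochemical property table
#'
#' Property files are plain text: header lines \code{#name:},
#' \code{#seqtype:}, \code{#tuple:}, then one \code{TUPLE value} line per
#' n-tuple. Other \code{#} lines are comments. The table must cover all
#' |A|^n tuples exactly once; values are decimal reals.
#'
#' @param file path to the property file.
#' @param seqtype sequence type the table must match; default: the
#'   \code{#seqtype:} header.
#' @param normalize also fill the normalized values (default \code{TRUE}).
#' @return a \code{"seqvec_property"} object, raw values stored in tuple
#'   index order.
#' @export
load_property_table <- function(file, seqtype = NULL, normalize = TRUE) {
  lines <- sub("\r$", "", readLines(file, warn = FALSE))
  hdr <- function(key) {
    pat <- paste0("^#", key, ":\\s*")
    ln <- grep(pat, lines, value = TRUE)
    if (!length(ln))
      stop("property file ", file, ": missing #", key, ": header",
           call. = FALSE)
    trimws(sub(pat, "", ln[1L]))
  }
  name <- hdr("name")
  declared <- hdr("seqtype")
  n <- as.integer(hdr("tuple"))
  if (is.na(n) || n < 1L)
    stop("property file ", file, ": bad #tuple: header", call. = FALSE)
  st <- get_seqtype(if (is.null(seqtype)) declared else seqtype)
  if (!is.null(seqtype) && st$name != declared)
    stop("property '", name, "' declares seqtype ", declared,
         " but ", st$name, " was requested", call. = FALSE)

  body <- trimws(lines[!startsWith(lines, "#")])
  body <- body[nzchar(body)]
  parts <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)$", body))
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("property file ", file, ": malformed line: ", body[bad[1L]],
         call. = FALSE)
  tuples <- vapply(parts, `[`, "", 2L)
  values <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  if (anyNA(values))
    stop("property file ", file, ": non-numeric value for tuple ",
         tuples[which(is.na(values))[1L]], call. = FALSE)
  if (anyDuplicated(tuples))
    stop("property '", name, "': duplicate tuple ",
         tuples[duplicated(tuples)][1L], call. = FALSE)
  expected <- enumerate_tuples(st, n)
  alien <- setdiff(tuples, expected)
  if (length(alien))
    stop("property '", name, "': tuple '", alien[1L],
         "' uses letters outside the ", st$name, " alphabet (or wrong size)",
         call. = FALSE)
  missing <- setdiff(expected, tuples)
  if (length(missing))
    stop("property '", name, "': missing ",
         paste(missing, collapse = ", "), call. = FALSE)
  raw <- stats::setNames(values[match(expected, tuples)], expected)
  tab <- new_property_table(name, st$name, n, raw)
  if (normalize) tab <- normalize_table(tab) else tab
}

#' Zero-mean unit-variance normalization of a property table
#'
#' The classic pseudo-composition conversion: \code{H(a) = (H0(a) - mean) /
#' sd}, where mean and sd are taken over all |A|^n tuples and sd is the
#' \emph{population} standard deviation (divide by N, not N-1). Idempotent
#' on its own output to within 1e-9.
#'
#' @param table a \code{"seqvec_property"}.
#' @return the table with its \code{normalized} field filled.
#' @export
normalize_table <- function(table) {
  stopifnot(inherits(table, "seqvec_property"))
  raw <- table$raw
  m <- mean(raw)
  v <- mean((raw - m)^2)
  if (v <= 0)
    stop("property '", table$name,
         "': constant raw values cannot be normalized (zero variance)",
         call. = FALSE)
  table$normalized <- (raw - m) / sqrt(v)
  table
}

#' Pre-compute pairwise correlation matrices for a property set
#'
#' For descriptor kernels the quantities consumed per position pair are the
#' averaged squared property difference
#' \deqn{\Theta(a,b) = \frac{1}{\Gamma}\sum_{k=1}^{\Gamma} [H_k(a)-H_k(b)]^2}
#' and the per-property products \eqn{\Pi_v(a,b) = P_v(a) P_v(b)}. Both are
#' pre-computed here over all |A|^n x |A|^n tuple pairs, once per mode
#' configuration, so sequence processing is pure table lookup.
#'
#' @param properties list of normalized \code{"seqvec_property"} tables
#'   sharing seqtype and tuple size.
#' @param average divide the squared-difference sum by the number of
#'   properties (default, the classic formulation); \code{FALSE} sums.
#' @return an object of class \code{"seqvec_pairtable"} with fields
#'   \code{theta} (matrix), \code{products} (list of matrices),
#'   \code{tuple_size}, \code{seqtype}, \code{property_set}.
#' @export
build_pair_tables <- function(properties, average = TRUE) {
  if (inherits(properties, "seqvec_property")) properties <- list(properties)
  stopifnot(length(properties) >= 1L)
  for (p in properties) {
    stopifnot(inherits(p, "seqvec_property"))
    if (is.null(p$normalized))
      stop("property '", p$name, "' is not normalized", call. = FALSE)
  }
  n <- unique(vapply(properties, `[[`, 1L, "tuple_size"))
  sts <- unique(vapply(properties, `[[`, "", "seqtype"))
  if (length(n) != 1L)
    stop("properties mix tuple sizes: ", paste(n, collapse = ", "),
         call. = FALSE)
  if (length(sts) != 1L)
    stop("properties mix sequence types: ", paste(sts, collapse = ", "),
         call. = FALSE)
  gamma <- length(properties)
  theta <- 0
  products <- vector("list", gamma)
  for (k in seq_len(gamma)) {
    h <- unname(properties[[k]]$normalized)
    theta <- theta + outer(h, h, function(a, b) (a - b)^2)
    products[[k]] <- outer(h, h)
  }
  if (average) theta <- theta / gamma
  names(products) <- vapply(properties, `[[`, "", "name")
  structure(list(theta = theta, products = products,
                 tuple_size = n, seqtype = sts,
                 property_set = names(products),
                 gamma = gamma),
            class = "seqvec_pairtable")
}

#' @export
print.seqvec_pairtable <- function(x, ...) {
  cat("Pair-correlation tables over ", x$seqtype, " ", x$tuple_size,
      "-tuples; properties: ", paste(x$property_set, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Register a property table under its name
#'
#' Registered tables can be referenced by name in mode configurations and
#' via the CLI \code{--props} flag.
#'
#' @param table a \code{"seqvec_property"} (normalized or not; it is
#'   normalized on registration).
#' @param overwrite replace an existing registration (default FALSE).
#' @return the registered table, invisibly.
#' @export
register_property_table <- function(table, overwrite = FALSE) {
  stopifnot(inherits(table, "seqvec_property"))
  if (!overwrite && table$name %in% names(.seqvec$properties))
    stop("property '", table$name, "' is already registered", call. = FALSE)
  if (is.null(table$normalized)) table <- normalize_table(table)
  .seqvec$properties[[table$name]] <- table
  invisible(table)
}

#' Fetch a registered property table by name
#' @param name registered property name.
#' @return a normalized \code{"seqvec_property"}.
#' @export
get_property_table <- function(name) {
  if (inherits(name, "seqvec_property")) return(name)
  p <- .seqvec$properties[[name]]
  if (is.null(p)) {
    register_builtin_properties()  # lazy load when .onLoad preceded install
    p <- .seqvec$properties[[name]]
  }
  if (is.null(p))
    stop("unknown property table '", name, "' (registered: ",
         paste(names(.seqvec$properties), collapse = ", "), ")",
         call. = FALSE)
  p
}

# Built-in tables shipped as plain-text files under inst/extdata. PROT:
# the classic hydrophobicity / hydrophilicity / side-chain-mass trio used
# by the classic pseudo-composition modes. DNA and RNA: six dinucleotide
# step parameters each. Representative published-lineage values; every
# correctness test uses toy tables instead.
register_builtin_properties <- function() {
  dir <- system.file("extdata", package = "seqvec")
  if (!nzchar(dir) || !dir.exists(dir)) return(invisible(NULL))
  for (f in list.files(dir, pattern = "\\.prop$", full.names = TRUE)) {
    tab <- load_property_table(f)
    if (!tab$name %in% names(.seqvec$properties))
      register_property_table(tab)
  }
  invisible(NULL)
}

# Property-set names used by built-in modes.
builtin_property_set <- function(seqtype, which = c("default", "classic")) {
  switch(seqtype,
    PROT = if (match.arg(which) == "classic")
      c("prot.hydrophobicity", "prot.hydrophilicity", "prot.sidechainmass")
    else c("prot.hydrophobicity", "prot.hydrophilicity"),
    DNA = c("dna.twist", "dna.tilt", "dna.roll",
            "dna.shift", "dna.slide", "dna.rise"),
    RNA = c("rna.twist", "rna.tilt", "rna.roll",
            "rna.shift", "rna.slide", "rna.rise"),
    stop("no built-in property set for sequence type ", seqtype,
         call. = FALSE))
}
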