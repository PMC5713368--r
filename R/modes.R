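# Representation-mode registry and the computing engine.
#
# A mode is a named, parameterized procedure mapping an index array to a
# fixed-length numeric vector. Modes carry a parameter schema with
# defaults, a dimension rule (constant for fixed parameters — the
# fixed-length guarantee), an optional prepare step run once per
# configuration (this is where pair-correlation tables are built, never
# per sequence), and the compute rule itself.

#' Register a representation mode
#'
#' @param mode_id short unique identifier (unique across built-ins and
#'   extensions).
#' @param seqtype name of the sequence type the mode applies to.
#' @param params named list of parameter defaults; a default of \code{NA}
#'   marks a mandatory parameter (e.g. the one-hot target length).
#' @param dimension function(params, A, gamma) -> positive integer, the
#'   output dimension; A is the alphabet size, gamma the size of the
#'   resolved property set (NA if the mode uses none).
#' @param compute function(seq, params, ctx) -> numeric vector, where
#'   \code{ctx} is the prepare result.
#' @param prepare optional function(params) -> context, run once per
#'   configured mode before any sequence is processed.
#' @param description one-line human-readable summary.
#' @param builtin internal flag marking catalogue modes.
#' @return the mode definition, invisibly.
#' @export
register_mode <- function(mode_id, seqtype, params = list(),
                          dimension, compute, prepare = NULL,
                          description = "", builtin = FALSE) {
  stopifnot(is.character(mode_id), length(mode_id) == 1L, nzchar(mode_id))
  if (mode_id %in% names(.seqvec$modes))
    stop("mode id '", mode_id, "' is already registered", call. = FALSE)
  get_seqtype(seqtype)  # must exist
  def <- structure(
    list(mode_id = mode_id, seqtype = seqtype, params = params,
         dimension = dimension, compute = compute, prepare = prepare,
         description = description, builtin = isTRUE(builtin)),
    class = "seqvec_mode")
  .seqvec$modes[[mode_id]] <- def
  invisible(def)
}

#' @export
print.seqvec_mode <- function(x, ...) {
  cat("Mode '", x$mode_id, "' (", x$seqtype, "): ", x$description, "\n",
      sep = "")
  invisible(x)
}

#' Configure a mode: merge user parameters into the schema
#'
#' Validation is dataset-independent: unknown parameters, missing mandatory
#' parameters and type problems are configuration errors raised before any
#' sequence is processed. Length-dependent problems are per-sequence data
#' faults, so one short sequence cannot abort a skip-policy run.
#'
#' @param mode_id registered mode id.
#' @param params named list of overrides.
#' @return a configured mode: the definition plus resolved \code{params}.
#' @export
configure_mode <- function(mode_id, params = list()) {
  def <- .seqvec$modes[[mode_id]]
  if (is.null(def))
    stop("unknown mode id '", mode_id, "'; valid ids: ",
         paste(sort(names(.seqvec$modes)), collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(params), names(def$params))
  if (length(unknown))
    stop("mode '", mode_id, "': unknown parameter(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  resolved <- utils::modifyList(def$params, params)
  mandatory <- names(def$params)[vapply(def$params, function(p)
    length(p) == 1L && is.na(p), TRUE)]
  still <- mandatory[vapply(resolved[mandatory], function(p)
    length(p) == 1L && is.na(p), TRUE)]
  if (length(still))
    stop("mode '", mode_id, "': missing mandatory parameter(s) ",
         paste(still, collapse = ", "), call. = FALSE)
  for (nm in c("k", "lambda", "d_max", "target_length"))
    if (nm %in% names(resolved)) {
      v <- resolved[[nm]]
      if (!is.numeric(v) || length(v) != 1L || v != round(v) ||
          v < if (nm == "lambda") 0 else 1)
        stop("mode '", mode_id, "': parameter ", nm,
             " must be a non-negative integer", call. = FALSE)
      resolved[[nm]] <- as.integer(v)
    }
  if ("omega" %in% names(resolved) &&
      (!is.numeric(resolved$omega) || resolved$omega <= 0))
    stop("mode '", mode_id, "': omega must be > 0", call. = FALSE)
  def$params <- resolved
  def
}

mode_gamma <- function(def) {
  if ("props" %in% names(def$params)) length(def$params$props) else NA_integer_
}

#' Output dimension of a configured mode
#' @param def a configured mode from \code{\link{configure_mode}}.
#' @return positive integer.
#' @export
mode_dimension <- function(def) {
  A <- alphabet_size(def$seqtype)
  as.integer(def$dimension(def$params, A, mode_gamma(def)))
}

#' List the registered representation modes
#'
#' A fresh registry holds the 35 built-in modes: 12 DNA, 8 RNA and 15
#' protein. Extensions append to the catalogue. Output is stable, sorted
#' by (seqtype, mode_id).
#'
#' @param seqtype optional filter by sequence type name.
#' @return data frame with columns mode_id, seqtype, params (schema
#'   summary), description.
#' @export
list_modes <- function(seqtype = NULL) {
  defs <- .seqvec$modes
  if (!is.null(seqtype))
    defs <- Filter(function(d) d$seqtype == seqtype, defs)
  fmt_params <- function(p) {
    if (!length(p)) return("")
    paste(vapply(names(p), function(nm) {
      v <- p[[nm]]
      v <- if (length(v) == 1L && is.na(v)) "<required>"
           else paste(v, collapse = "+")
      paste0(nm, "=", v)
    }, ""), collapse = " ")
  }
  out <- data.frame(
    mode_id = vapply(defs, `[[`, "", "mode_id"),
    seqtype = vapply(defs, `[[`, "", "seqtype"),
    params = vapply(defs, function(d) fmt_params(d$params), ""),
    description = vapply(defs, `[[`, "", "description"),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$seqtype, out$mode_id), , drop = FALSE]
}

# Pair tables are cached per (property set, average) configuration so
# repeated mode configurations share the pre-computation.
cached_pair_tables <- function(props, average = TRUE) {
  key <- paste(c(props, if (average) "avg" else "sum"), collapse = "\r")
  hit <- .seqvec$pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  pair <- build_pair_tables(lapply(props, get_property_table),
                            average = average)
  .seqvec$pair_cache[[key]] <- pair
  pair
}

#' Run the computing engine over a dataset
#'
#' Validates every mode configuration up front, runs each mode's prepare
#' step once (building pair tables per configuration, never per sequence),
#' then converts each record to the concatenation of the requested modes'
#' vectors, in request order. Per-record data faults (non-standard letter,
#' insufficient length, degenerate denominator) follow the skip/abort
#' policy.
#'
#' @param records list of \code{\link{sequence_record}} objects (or the
#'   result of \code{\link{parse_fasta}}).
#' @param seqtype sequence type or name; all modes must match it.
#' @param modes character vector of mode ids, or a list whose elements are
#'   mode ids or \code{list(mode_id, params)} pairs, or configured modes.
#' @param policy a \code{\link{fault_policy}}.
#' @param params named list of parameter overrides applied to every mode
#'   that accepts them (CLI convenience); per-mode params win.
#' @return an object of class \code{"seqvec_result"}: list with
#'   \code{vectors} (named list, seq_id -> numeric vector), \code{labels}
#'   (named numeric), \code{dim}, \code{mode_ids}, \code{report} (skip
#'   reports, also carried over from parsing).
#' @export
run_engine <- function(records, seqtype, modes, policy = fault_policy(),
                       params = list()) {
  st <- get_seqtype(seqtype)
  configured <- lapply(modes, function(m) {
    if (inherits(m, "seqvec_mode")) return(m)
    if (is.character(m)) {
      def <- .seqvec$modes[[m]]
      if (is.null(def))
        stop("unknown mode id '", m, "'; valid ids: ",
             paste(sort(names(.seqvec$modes)), collapse = ", "),
             call. = FALSE)
      shared <- params[intersect(names(params), names(def$params))]
      return(configure_mode(m, shared))
    }
    stopifnot(is.list(m), !is.null(m$mode_id))
    def <- configure_mode(m$mode_id, c(
      m$params %||% list(),
      params[setdiff(intersect(names(params),
                               names(.seqvec$modes[[m$mode_id]]$params)),
                     names(m$params %||% list()))]))
    def
  })
  for (def in configured)
    if (def$seqtype != st$name)
      stop("mode '", def$mode_id, "' is defined for seqtype ", def$seqtype,
           ", not ", st$name, call. = FALSE)

  ctxs <- lapply(configured, function(def)
    if (is.null(def$prepare)) NULL else def$prepare(def$params))
  dims <- vapply(seq_along(configured), function(i)
    mode_dimension(configured[[i]]), 0L)
  total_dim <- sum(dims)

  report <- attr(records, "report")
  if (is.null(report)) report <- empty_report()
  vectors <- list()
  labels <- numeric()
  for (rec in records) {
    res <- with_fault_policy({
      idx <- encode_sequence(rec, st)
      push_context(rec, idx, st)
      parts <- lapply(seq_along(configured), function(i) {
        v <- as.numeric(configured[[i]]$compute(idx, configured[[i]]$params,
                                                ctxs[[i]]))
        if (length(v) != dims[i])
          signal_fault(rec$id, sprintf(
            "mode '%s' emitted a vector of length %d, expected %d",
            configured[[i]]$mode_id, length(v), dims[i]))
        v
      })
      list(values = unlist(parts), label = current_context()$label)
    }, policy)
    pop_context()
    if (is.null(res$fault)) {
      vectors[[rec$id]] <- res$value$values
      labels[rec$id] <- res$value$label %||% 0
    } else {
      report <- rbind(report, res$fault)
    }
  }
  structure(list(vectors = vectors, labels = labels, dim = total_dim,
                 mode_ids = vapply(configured, `[[`, "", "mode_id"),
                 mode_dims = dims,
                 seqtype = st$name, report = report),
            class = "seqvec_result")
}

#' @export
print.seqvec_result <- function(x, ...) {
  cat("seqvec result: ", length(x$vectors), " descriptor vector(s) of ",
      "dimension ", x$dim, " (modes: ",
      paste(x$mode_ids, collapse = ", "), ")\n", sep = "")
  if (nrow(x$report))
    cat("  skipped ", nrow(x$report), " record(s); see $report\n", sep = "")
  invisible(x)
}

#' Convert an engine result to a numeric matrix
#' @param x a \code{"seqvec_result"}.
#' @param ... unused.
#' @return matrix, one row per surviving record.
#' @export
as.matrix.seqvec_result <- function(x, ...) {
  if (!length(x$vectors))
    return(matrix(numeric(), nrow = 0L, ncol = x$dim))
  do.call(rbind, x$vectors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- per-sequence context (shared with the extension API) ----------------

push_context <- function(record, indices, seqtype) {
  .seqvec$context <- list(record = record, indices = indices,
                          seqtype = seqtype, label = NULL)
  invisible(NULL)
}
pop_context <- function() { .seqvec$context <- NULL; invisible(NULL) }
current_context <- function(required = FALSE) {
  ctx <- .seqvec$context
  if (required && is.null(ctx))
    stop("this function is only available inside a mode compute rule",
         call. = FALSE)
  ctx
}

# --- built-in catalogue ---------------------------------------------------

# helpers shared by catalogue entries
prep_pair <- function(props_param = "props", average = TRUE)
  function(params) cached_pair_tables(params[[props_param]], average = average)
prep_tables <- function(params)
  lapply(params$props, get_property_table)

reg_kmer <- function(id, st, k = 1L, collapse = FALSE, desc) {
  register_mode(id, st, params = list(k = k),
    dimension = if (collapse)
      function(params, A, gamma) {
        rc <- revcomp_tuple_map(st, params$k)
        length(unique(pmin(seq_along(rc) - 1L, rc)))
      }
    else function(params, A, gamma) A^params$k,
    compute = if (collapse)
      function(seq, params, ctx)
        kmer_composition(seq, st, params$k, collapse_revcomp = TRUE)
    else function(seq, params, ctx) kmer_composition(seq, st, params$k),
    description = desc, builtin = TRUE)
}

reg_onehot <- function(id, st) {
  register_mode(id, st, params = list(target_length = NA),
    dimension = function(params, A, gamma) params$target_length * A,
    compute = function(seq, params, ctx)
      one_hot(seq, st, params$target_length),
    description = paste0("one-hot encoding (", st,
                         "), zero-padded to target_length positions"),
    builtin = TRUE)
}

reg_autocorr <- function(id, st, method, props, desc) {
  register_mode(id, st, params = list(d_max = 1L, props = props),
    dimension = function(params, A, gamma) {
      g <- length(params$props)
      switch(method, CC = params$d_max * g * (g - 1L),
             ACC = params$d_max * g * g, params$d_max * g)
    },
    prepare = prep_tables,
    compute = function(seq, params, ctx)
      autocorrelation(seq, method, params$d_max, ctx),
    description = desc, builtin = TRUE)
}

reg_pse <- function(id, st, type, k, props, desc, fixed_k = FALSE) {
  register_mode(id, st,
    params = list(k = k, lambda = 1L, omega = 0.05, props = props),
    dimension = function(params, A, gamma)
      A^params$k + params$lambda * if (type == 1L) 1L else gamma,
    prepare = prep_pair(),
    compute = if (type == 1L)
      function(seq, params, ctx)
        pse_type1(seq, st, params$k, params$lambda, params$omega, ctx)
    else
      function(seq, params, ctx)
        pse_type2(seq, st, params$k, params$lambda, params$omega, ctx),
    description = desc, builtin = TRUE)
}

register_builtin_modes <- function() {
  dna_din <- builtin_property_set("DNA")
  dna_tri <- c("dna3.syntha", "dna3.synthb")
  rna_din <- builtin_property_set("RNA")
  prot_classic <- builtin_property_set("PROT", "classic")
  prot_hh <- builtin_property_set("PROT", "default")

  # --- DNA (12) ---
  reg_kmer("kmer-dna", "DNA", 1L, FALSE, "k-mer composition over A,C,G,T")
  reg_kmer("revkmer-dna", "DNA", 1L, TRUE,
           "canonical (reverse-complement-collapsed) k-mer composition")
  reg_onehot("onehot-dna", "DNA")
  reg_autocorr("dac", "DNA", "AC", dna_din,
               "dinucleotide-property autocorrelation")
  reg_autocorr("dcc", "DNA", "CC", dna_din,
               "dinucleotide-property cross-covariance")
  reg_autocorr("dacc", "DNA", "ACC", dna_din,
               "dinucleotide-property auto-cross covariance")
  reg_autocorr("tac", "DNA", "AC", dna_tri,
               "trinucleotide-property autocorrelation")
  reg_autocorr("tcc", "DNA", "CC", dna_tri,
               "trinucleotide-property cross-covariance")
  reg_autocorr("tacc", "DNA", "ACC", dna_tri,
               "trinucleotide-property auto-cross covariance")
  reg_pse("psednc", "DNA", 1L, 2L, dna_din,
          "pseudo-dinucleotide composition (Type-1, k=2)")
  reg_pse("pseknc1", "DNA", 1L, 3L, dna_din,
          "Type-1 pseudo k-tuple nucleotide composition")
  reg_pse("pseknc2", "DNA", 2L, 3L, dna_din,
          "Type-2 (series) pseudo k-tuple nucleotide composition")

  # --- RNA (8) ---
  reg_kmer("kmer-rna", "RNA", 1L, FALSE, "k-mer composition over A,C,G,U")
  reg_onehot("onehot-rna", "RNA")
  reg_autocorr("dac-rna", "RNA", "AC", rna_din,
               "RNA dinucleotide-property autocorrelation")
  reg_autocorr("dcc-rna", "RNA", "CC", rna_din,
               "RNA dinucleotide-property cross-covariance")
  reg_autocorr("dacc-rna", "RNA", "ACC", rna_din,
               "RNA dinucleotide-property auto-cross covariance")
  reg_pse("psednc-rna", "RNA", 1L, 2L, rna_din,
          "RNA pseudo-dinucleotide composition (Type-1, k=2)")
  reg_pse("sc-psednc-rna", "RNA", 2L, 2L, rna_din,
          "RNA series-correlation pseudo-dinucleotide composition (Type-2)")
  reg_pse("pseknc-rna", "RNA", 1L, 3L, rna_din,
          "RNA Type-1 pseudo k-tuple nucleotide composition")

  # --- PROT (15) ---
  reg_kmer("aac", "PROT", 1L, FALSE, "amino-acid composition")
  reg_kmer("dpc", "PROT", 2L, FALSE, "dipeptide composition")
  reg_kmer("tpc", "PROT", 3L, FALSE, "tripeptide composition")
  reg_onehot("onehot-prot", "PROT")
  reg_pse("pseaac1", "PROT", 1L, 1L, prot_classic,
          paste0("classic Type-1 pseudo-amino-acid composition ",
                 "(hydrophobicity/hydrophilicity/side-chain mass)"))
  reg_pse("pseaac2", "PROT", 2L, 1L, prot_hh,
          paste0("classic Type-2 (amphiphilic) pseudo-amino-acid ",
                 "composition (hydrophobicity + hydrophilicity)"))
  reg_pse("pc-pseaac-g", "PROT", 1L, 1L, prot_classic,
          "general Type-1 pseudo composition over a user property set")
  reg_pse("sc-pseaac-g", "PROT", 2L, 1L, prot_hh,
          "general Type-2 pseudo composition over a user property set")
  reg_autocorr("ac-prot", "PROT", "AC", prot_classic,
               "amino-acid-property autocorrelation")
  reg_autocorr("cc-prot", "PROT", "CC", prot_classic,
               "amino-acid-property cross-covariance")
  reg_autocorr("acc-prot", "PROT", "ACC", prot_classic,
               "amino-acid-property auto-cross covariance")
  register_mode("dr", "PROT", params = list(d_max = 1L),
    dimension = function(params, A, gamma) params$d_max * A^2,
    compute = function(seq, params, ctx)
      distance_pair(seq, "PROT", params$d_max),
    description = "distance-pair (DR) residue-pair frequencies",
    builtin = TRUE)
  reg_autocorr("moran", "PROT", "MORAN", prot_classic,
               "Moran autocorrelation of amino-acid properties")
  reg_autocorr("geary", "PROT", "GEARY", prot_classic,
               "Geary autocorrelation of amino-acid properties")
  reg_autocorr("nmbroto", "PROT", "NMBROTO", prot_classic,
               "normalized Moreau-Broto autocorrelation")
  invisible(NULL)
}

#' Reset the registries to the built-in state
#'
#' Restores the 35-mode built-in catalogue, the three built-in sequence
#' types and the bundled property tables, discarding everything loaded by
#' extensions (the equivalent of a process restart).
#'
#' @return invisibly, NULL.
#' @export
reset_registry <- function() {
  .seqvec$seqtypes <- list()
  .seqvec$properties <- list()
  .seqvec$modes <- list()
  .seqvec$pair_cache <- list()
  .seqvec$options <- list()
  .seqvec$output_format <- NULL
  .seqvec$extra_cli <- list()
  .seqvec$context <- NULL
  register_builtin_seqtypes()
  register_builtin_properties()
  register_builtin_modes()
  invisible(NULL)
}
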