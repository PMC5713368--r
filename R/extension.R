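# Runtime extension system. An extension is an R source file evaluated
# against a fixed 23-function API through which it can register sequence
# types, property tables and representation modes, declare or re-bind CLI
# options, and (inside a compute rule) inspect the current sequence.
# Loading an extension executes its code with the privileges of the
# calling process; load only extensions you trust. No sandboxing is
# attempted.

api_function_names <- c(
  "register_seqtype", "register_property", "register_mode",
  "declare_option", "get_option", "set_output_format",
  "current_seq_id", "current_sequence", "current_indices", "seq_length",
  "alphabet", "alphabet_size",
  "get_property_raw", "get_property_normalized", "property_value",
  "kmer_counts", "theta_parallel", "tau_series", "build_pair_tables",
  "emit_vector", "set_label", "skip_sequence", "log_message")

#' The extension API surface
#'
#' Names of the functions available inside extension files: registration
#' (sequence types, properties, modes, CLI options), per-sequence
#' accessors usable only inside a compute rule, kernel helpers, and
#' output/label/skip controls.
#'
#' @return character vector of the 23 API function names.
#' @export
extension_api <- function() api_function_names

# call a user function tolerating shorter formal lists
call_flex <- function(f, args) {
  fo <- formals(f)
  if (!is.null(fo) && "..." %in% names(fo)) return(do.call(f, args))
  do.call(f, args[seq_len(min(length(args), length(fo)))])
}

# wrap an extension compute rule: runs with the per-sequence context
# available and honors emit_vector() as an alternative to returning the
# vector.
wrap_ext_compute <- function(compute) {
  force(compute)
  function(seq, params, ctx) {
    .seqvec$context$emitted <- NULL
    out <- call_flex(compute, list(seq, params, ctx))
    emitted <- .seqvec$context$emitted
    if (!is.null(emitted)) emitted else out
  }
}

build_api_env <- function() {
  env <- new.env(parent = getNamespace("seqvec"))

  env$register_seqtype <- function(name, alphabet, complement = NULL,
                                   case_fold = TRUE)
    define_seqtype(name, alphabet, complement, case_fold, register = TRUE)

  env$register_property <- function(x, name = NULL, seqtype = NULL,
                                    tuple_size = 1L, values = NULL) {
    tab <- if (inherits(x, "seqvec_property")) x
    else if (is.character(x) && length(x) == 1L && file.exists(x))
      load_property_table(x)
    else {
      # x is the name, values a named tuple->value vector
      nm <- if (is.null(name)) x else name
      st <- get_seqtype(seqtype)
      expected <- enumerate_tuples(st, tuple_size)
      if (!setequal(names(values), expected))
        stop("property '", nm, "': values must cover all ",
             length(expected), " tuples", call. = FALSE)
      new_property_table(nm, st$name, tuple_size,
                         stats::setNames(as.numeric(values[expected]),
                                         expected))
    }
    register_property_table(tab)
  }

  env$register_mode <- function(mode_id, seqtype, params = list(),
                                dimension, compute, prepare = NULL,
                                description = "") {
    if (is.numeric(dimension)) {
      d <- as.integer(dimension)
      dimension <- function(params, A, gamma) d
    }
    register_mode(mode_id, seqtype, params = params,
                  dimension = dimension,
                  compute = wrap_ext_compute(compute),
                  prepare = prepare, description = description)
  }

  env$declare_option <- function(flag, type = c("character", "integer",
                                                "numeric", "flag"),
                                 default = NULL, help = "") {
    type <- match.arg(type)
    flag <- sub("^--?", "", flag)
    if (flag %in% names(.seqvec$extra_cli) ||
        flag %in% vapply(default_cli_schema(), `[[`, "", "name"))
      message("extension re-binds option -", flag,
              " (last-loaded definition wins)")
    .seqvec$extra_cli[[flag]] <- list(name = flag, type = type,
                                      default = default, help = help)
    if (!flag %in% names(.seqvec$options))
      .seqvec$options[[flag]] <- default
    invisible(flag)
  }

  env$get_option <- function(name) .seqvec$options[[sub("^--?", "", name)]]

  env$set_output_format <- function(format) {
    .seqvec$output_format <- match.arg(tolower(format),
                                       c("svm", "tsv", "csv"))
    invisible(.seqvec$output_format)
  }

  env$current_seq_id <- function()
    current_context(required = TRUE)$record$id
  env$current_sequence <- function() {
    ctx <- current_context(required = TRUE)
    decode_indices(ctx$indices, ctx$seqtype)
  }
  env$current_indices <- function()
    as.integer(current_context(required = TRUE)$indices)
  env$seq_length <- function()
    length(current_context(required = TRUE)$indices)
  env$alphabet <- function(seqtype = NULL) {
    st <- if (is.null(seqtype)) current_context(required = TRUE)$seqtype
          else seqtype
    get_seqtype(st)$alphabet
  }
  env$alphabet_size <- function(seqtype = NULL)
    length(env$alphabet(seqtype))

  env$get_property_raw <- function(name) get_property_table(name)$raw
  env$get_property_normalized <- function(name)
    get_property_table(name)$normalized
  env$property_value <- function(name, tuple, normalized = TRUE) {
    tab <- get_property_table(name)
    src <- if (normalized) tab$normalized else tab$raw
    v <- src[[tuple]]
    if (is.null(v))
      stop("tuple '", tuple, "' not in property '", tab$name, "'",
           call. = FALSE)
    v
  }

  env$kmer_counts <- function(k = 1L) {
    ctx <- current_context(required = TRUE)
    st <- get_seqtype(ctx$seqtype)
    A <- length(st$alphabet)
    if (length(ctx$indices) < k)
      signal_fault(ctx$record$id,
                   sprintf("insufficient length for k=%d", k))
    t <- tuple_index_array(ctx$indices, as.integer(k), A)
    stats::setNames(tabulate(t + 1L, nbins = A^k),
                    enumerate_tuples(st, as.integer(k)))
  }
  env$theta_parallel <- function(lambda, pair)
    theta_parallel(current_context(required = TRUE)$indices, lambda, pair)
  env$tau_series <- function(lambda, pair)
    tau_series(current_context(required = TRUE)$indices, lambda, pair)
  env$build_pair_tables <- function(properties, average = TRUE) {
    if (is.character(properties))
      return(cached_pair_tables(properties, average = average))
    build_pair_tables(properties, average = average)
  }

  env$emit_vector <- function(values) {
    current_context(required = TRUE)
    .seqvec$context$emitted <- as.numeric(values)
    invisible(NULL)
  }
  env$set_label <- function(label) {
    current_context(required = TRUE)
    .seqvec$context$label <- as.numeric(label)
    invisible(NULL)
  }
  env$skip_sequence <- function(reason = "skipped by extension")
    signal_fault(current_context(required = TRUE)$record$id, reason)
  env$log_message <- function(...) message("[extension] ", ...)

  stopifnot(setequal(ls(env), api_function_names))
  env
}

#' Load an extension file
#'
#' Evaluates an R source file in an environment exposing the 23-function
#' extension API (\code{\link{extension_api}}). Loading is transactional:
#' if evaluation fails, no registration survives. Extension mode ids must
#' not collide with built-ins or earlier extensions. Extensions may
#' re-declare a CLI flag's meaning; the last-loaded declaration wins, with
#' a logged note.
#'
#' \strong{Security}: loading an extension executes arbitrary code.
#'
#' @param file path to the extension file.
#' @return an object of class \code{"seqvec_extension"}: source path plus
#'   the names of the sequence types, properties, modes and options it
#'   registered.
#' @export
load_extension <- function(file) {
  if (!file.exists(file))
    stop("extension file not found: ", file, call. = FALSE)
  snapshot <- list(seqtypes = .seqvec$seqtypes,
                   properties = .seqvec$properties,
                   modes = .seqvec$modes,
                   extra_cli = .seqvec$extra_cli,
                   options = .seqvec$options,
                   output_format = .seqvec$output_format)
  env <- build_api_env()
  ok <- FALSE
  tryCatch({
    sys.source(file, envir = env, keep.source = FALSE)
    ok <- TRUE
  }, error = function(e) {
    stop("failed to load extension '", file, "': ", conditionMessage(e),
         call. = FALSE)
  }, finally = {
    if (!ok) {
      .seqvec$seqtypes <- snapshot$seqtypes
      .seqvec$properties <- snapshot$properties
      .seqvec$modes <- snapshot$modes
      .seqvec$extra_cli <- snapshot$extra_cli
      .seqvec$options <- snapshot$options
      .seqvec$output_format <- snapshot$output_format
    }
  })
  structure(list(
    source_path = file,
    registered = list(
      seqtypes = setdiff(names(.seqvec$seqtypes), names(snapshot$seqtypes)),
      properties = setdiff(names(.seqvec$properties),
                           names(snapshot$properties)),
      modes = setdiff(names(.seqvec$modes), names(snapshot$modes))),
    declared_options = setdiff(names(.seqvec$extra_cli),
                               names(snapshot$extra_cli))),
    class = "seqvec_extension")
}

#' @export
print.seqvec_extension <- function(x, ...) {
  cat("Extension ", x$source_path, ":\n", sep = "")
  for (nm in names(x$registered))
    if (length(x$registered[[nm]]))
      cat("  ", nm, ": ", paste(x$registered[[nm]], collapse = ", "),
          "\n", sep = "")
  if (length(x$declared_options))
    cat("  options: -", paste(x$declared_options, collapse = ", -"),
        "\n", sep = "")
  invisible(x)
}
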