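#' Data-fault policy
#'
#' Per-record problems — a non-standard letter, an empty sequence, a
#' sequence too short for the requested descriptor — are \emph{data faults}.
#' Dataset-level operations handle them according to a user-chosen policy:
#' \code{"skip"} excludes the record and emits exactly one report entry
#' (id + reason), \code{"abort"} stops all further processing.
#'
#' @param on_fault \code{"skip"} (default) or \code{"abort"}.
#' @return an object of class \code{"seqvec_policy"}.
#' @export
fault_policy <- function(on_fault = c("skip", "abort")) {
  structure(list(on_fault = match.arg(on_fault)), class = "seqvec_policy")
}

# Signal a per-record data fault as a classed condition. Dataset loops
# catch "seqvec_fault"; anywhere else it propagates as an ordinary error.
signal_fault <- function(seq_id, reason) {
  stop(structure(
    class = c("seqvec_fault", "error", "condition"),
    list(message = sprintf("data fault [%s]: %s", seq_id, reason),
         call = NULL, seq_id = seq_id, reason = reason)))
}

# Run `expr` under a fault policy. Returns list(value=, fault=NULL) on
# success; under skip returns list(value=NULL, fault=report row); under
# abort rethrows.
with_fault_policy <- function(expr, policy) {
  tryCatch(
    list(value = expr, fault = NULL),
    seqvec_fault = function(cond) {
      if (policy$on_fault == "abort") stop(cond)
      list(value = NULL,
           fault = data.frame(seq_id = cond$seq_id, reason = cond$reason,
                              stringsAsFactors = FALSE))
    })
}

# Empty skip-report table (schema anchor for rbind).
empty_report <- function() {
  data.frame(seq_id = character(), reason = character(),
             stringsAsFactors = FALSE)
}
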