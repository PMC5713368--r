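# Numeric kernels. All kernels consume a 0-based integer index array (see
# encode_sequence) and return a bare numeric vector of fixed, parameter-
# determined length. Formula subscripts are 1-based (mathematical
# convention); internal indices are 0-based.

seq_id_of <- function(seq) {
  id <- attr(seq, "seq_id")
  if (is.null(id)) "<anonymous>" else id
}

# 0-based index of each overlapping n-tuple (row-major over positions):
# tuple starting at i has index sum_j idx[i+j-1] * A^(n-j).
tuple_index_array <- function(seq, n, A) {
  L <- length(seq)
  N <- L - n + 1L
  if (N < 1L) return(integer(0))
  out <- as.integer(seq[seq_len(N)])
  if (n > 1L) for (j in 2:n)
    out <- out * A + as.integer(seq[j:(N + j - 1L)])
  out
}

# 0-based reverse-complement tuple index for every tuple of size k.
revcomp_tuple_map <- function(seqtype, k) {
  st <- get_seqtype(seqtype)
  if (is.null(st$complement))
    stop("sequence type '", st$name,
         "' has no complement map; reverse-complement collapse unavailable",
         call. = FALSE)
  A <- length(st$alphabet)
  comp_idx <- match(st$complement, st$alphabet) - 1L  # complement of index i
  M <- A^k
  t <- 0:(M - 1L)
  # digits of t, most-significant first
  digits <- matrix(0L, nrow = M, ncol = k)
  rem <- t
  for (j in k:1) { digits[, j] <- rem %% A; rem <- rem %/% A }
  rc <- integer(M)
  for (j in 1:k) rc <- rc * A + comp_idx[digits[, k + 1L - j] + 1L]
  as.integer(rc)
}

#' k-mer composition
#'
#' Frequencies of overlapping k-tuples: \code{f_u = count(u) / (L - k + 1)},
#' one component per tuple in index order; components sum to 1. With
#' \code{collapse_revcomp}, counts of a k-mer and its reverse complement are
#' pooled onto the lexicographically smaller of the pair (canonical k-mer),
#' reducing the dimension to the number of canonical classes.
#'
#' @param seq index array from \code{\link{encode_sequence}}.
#' @param seqtype sequence type or name.
#' @param k tuple size (L >= k required; shorter sequences are data faults).
#' @param collapse_revcomp pool strand-symmetric counts (requires a
#'   complement map on the type).
#' @return named numeric vector of length |A|^k (or the number of canonical
#'   classes).
#' @export
kmer_composition <- function(seq, seqtype, k = 1L, collapse_revcomp = FALSE) {
  st <- get_seqtype(seqtype)
  A <- length(st$alphabet)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  L <- length(seq)
  if (L < k)
    signal_fault(seq_id_of(seq),
                 sprintf("insufficient length for k-mer composition (L=%d < k=%d)",
                         L, k))
  t <- tuple_index_array(seq, k, A)
  counts <- tabulate(t + 1L, nbins = A^k)
  freqs <- counts / length(t)
  tuples <- enumerate_tuples(st, k)
  if (!collapse_revcomp) return(stats::setNames(freqs, tuples))
  rc <- revcomp_tuple_map(st, k)
  canon <- pmin(0:(A^k - 1L), rc)
  classes <- sort(unique(canon))
  pooled <- vapply(classes, function(cl) sum(freqs[canon == cl]), 0)
  stats::setNames(pooled, tuples[classes + 1L])
}

#' Parallel-correlation sequence-order factors (theta tiers)
#'
#' For tuples \eqn{D_i} of size n (the pair table's tuple size) and lag
#' \eqn{j = 1..\lambda}:
#' \deqn{\theta_j = \frac{1}{L-n+1-j} \sum_{i=1}^{L-n+1-j} \Theta(D_i, D_{i+j})}
#' where \eqn{\Theta} is the pre-computed averaged squared property
#' difference. All tiers are >= 0; a homopolymer yields all-zero tiers.
#'
#' @param seq index array.
#' @param lambda number of lags (0 gives an empty vector; at least one term
#'   per tier is required, i.e. lambda <= L - n).
#' @param pair a \code{\link{build_pair_tables}} result.
#' @return numeric vector \eqn{\theta_1..\theta_\lambda}.
#' @export
theta_parallel <- function(seq, lambda, pair) {
  stopifnot(inherits(pair, "seqvec_pairtable"))
  lambda <- as.integer(lambda)
  if (lambda == 0L) return(numeric())
  n <- pair$tuple_size
  A <- as.integer(round(nrow(pair$theta)^(1 / n)))
  t <- tuple_index_array(seq, n, A) + 1L
  N <- length(t)
  if (lambda < 0L || lambda > N - 1L)
    signal_fault(seq_id_of(seq),
                 sprintf("insufficient length for lambda=%d (need L >= %d)",
                         lambda, lambda + n))
  vapply(seq_len(lambda), function(j) {
    i <- seq_len(N - j)
    mean(pair$theta[cbind(t[i], t[i + j])])
  }, 0)
}

#' Series-correlation sequence-order factors (tau tiers)
#'
#' Per-property product correlations, lag-major then property-minor:
#' \deqn{\tau_{(j-1)\Gamma+v} = \frac{1}{L-n+1-j} \sum_{i=1}^{L-n+1-j}
#'   \Pi_v(D_i, D_{i+j})}
#' where \eqn{\Pi_v(a,b) = P_v(a) P_v(b)}. For proteins with two properties
#' this reproduces the classic \eqn{\tau_{2j-1}, \tau_{2j}} interleaving.
#' Entries may be negative; series correlation does not vanish on
#' homopolymers.
#'
#' @inheritParams theta_parallel
#' @return numeric vector of length \code{lambda * gamma}.
#' @export
tau_series <- function(seq, lambda, pair) {
  stopifnot(inherits(pair, "seqvec_pairtable"))
  lambda <- as.integer(lambda)
  if (lambda == 0L) return(numeric())
  n <- pair$tuple_size
  A <- as.integer(round(nrow(pair$theta)^(1 / n)))
  t <- tuple_index_array(seq, n, A) + 1L
  N <- length(t)
  if (lambda < 0L || lambda > N - 1L)
    signal_fault(seq_id_of(seq),
                 sprintf("insufficient length for lambda=%d (need L >= %d)",
                         lambda, lambda + n))
  out <- numeric(lambda * pair$gamma)
  for (j in seq_len(lambda)) {
    i <- seq_len(N - j)
    ij <- cbind(t[i], t[i + j])
    for (v in seq_len(pair$gamma))
      out[(j - 1L) * pair$gamma + v] <- mean(pair$products[[v]][ij])
  }
  out
}

#' Type-1 (parallel-correlation) pseudo composition
#'
#' The classic Type-I pseudo-amino-acid / pseudo-k-tuple-nucleotide
#' composition: k-tuple frequencies \eqn{f_u} plus \eqn{\lambda} theta
#' tiers, jointly normalized:
#' \deqn{Z = 1 + \omega \sum_j \theta_j, \quad
#'   x_u = f_u / Z \ (u \le |A|^k), \quad
#'   x_{|A|^k + j} = \omega \theta_j / Z.}
#' All components are >= 0 and sum to 1. With \eqn{\lambda = 0} the result
#' reduces exactly to \code{\link{kmer_composition}}.
#'
#' @param seq index array.
#' @param seqtype sequence type or name.
#' @param k composition tuple size.
#' @param lambda number of correlation tiers.
#' @param omega weight factor (> 0) scaling the pseudo block.
#' @param pair pair-correlation tables whose tuple size sets n for the
#'   theta tiers (may differ from k, as in PseDNC where k = 2 = n).
#' @return numeric vector of length \code{|A|^k + lambda}.
#' @export
pse_type1 <- function(seq, seqtype, k = 1L, lambda = 1L, omega = 0.05,
                      pair = NULL) {
  stopifnot(omega > 0)
  f <- kmer_composition(seq, seqtype, k)
  th <- if (lambda > 0) theta_parallel(seq, lambda, pair) else numeric()
  Z <- 1 + omega * sum(th)
  unname(c(f, omega * th)) / Z
}

#' Type-2 (series-correlation / amphiphilic) pseudo composition
#'
#' As \code{\link{pse_type1}} with tau tiers replacing theta:
#' \deqn{Z = 1 + \omega \sum_m \tau_m, \quad x_u = f_u / Z, \quad
#'   x_{|A|^k + m} = \omega \tau_m / Z.}
#' Components sum to 1 but pseudo components may be negative. A vanishing
#' denominator (|Z| < 1e-12) is a degenerate-denominator data fault.
#'
#' @inheritParams pse_type1
#' @return numeric vector of length \code{|A|^k + lambda * gamma}.
#' @export
pse_type2 <- function(seq, seqtype, k = 1L, lambda = 1L, omega = 0.05,
                      pair = NULL) {
  stopifnot(omega > 0)
  f <- kmer_composition(seq, seqtype, k)
  ta <- if (lambda > 0) tau_series(seq, lambda, pair) else numeric()
  Z <- 1 + omega * sum(ta)
  if (abs(Z) < 1e-12)
    signal_fault(seq_id_of(seq),
                 "degenerate denominator in Type-2 pseudo composition")
  unname(c(f, omega * ta)) / Z
}

#' One-hot encoding
#'
#' Position-wise indicator representation padded to a fixed target length:
#' letter a at position i sets component \code{(i-1)*|A| + idx(a) + 1}.
#' Shorter sequences are zero-padded; longer sequences are data faults.
#'
#' @param seq index array.
#' @param seqtype sequence type or name.
#' @param target_length number of positions encoded (mandatory, no
#'   default).
#' @return numeric 0/1 vector of length \code{target_length * |A|}.
#' @export
one_hot <- function(seq, seqtype, target_length) {
  st <- get_seqtype(seqtype)
  A <- length(st$alphabet)
  target_length <- as.integer(target_length)
  stopifnot(target_length >= 1L)
  L <- length(seq)
  if (L > target_length)
    signal_fault(seq_id_of(seq),
                 sprintf("sequence length %d exceeds one-hot target length %d",
                         L, target_length))
  out <- numeric(target_length * A)
  out[(seq_len(L) - 1L) * A + as.integer(seq) + 1L] <- 1
  out
}

#' Autocorrelation descriptor family
#'
#' Property-based covariance descriptors over tuple positions. With
#' \eqn{P_v(D_i)} the normalized property value of the i-th tuple, N the
#' number of tuples and \eqn{\bar P_v} the within-sequence mean:
#' \describe{
#'   \item{AC}{\eqn{(1/(N-d)) \sum (P_v(D_i)-\bar P_v)(P_v(D_{i+d})-\bar P_v)}}
#'   \item{CC}{same with two distinct properties v, w}
#'   \item{ACC}{all AC entries then all CC entries}
#'   \item{MORAN}{AC divided by the within-sequence variance (divide by N)}
#'   \item{GEARY}{\eqn{[(1/(2(N-d))) \sum (P_v(D_i)-P_v(D_{i+d}))^2] /
#'     [(1/(N-1)) \sum (P_v(D_i)-\bar P_v)^2]}}
#'   \item{NMBROTO}{normalized Moreau-Broto,
#'     \eqn{(1/(N-d)) \sum P_v(D_i) P_v(D_{i+d})}}
#' }
#' Ordering is lag-major, then property (pair) index. On a zero-variance
#' sequence, MORAN and GEARY components are defined as 0 (homopolymers are
#' legitimate input; faults are reserved for structural problems).
#'
#' @param seq index array.
#' @param method one of AC, CC, ACC, MORAN, GEARY, NMBROTO.
#' @param d_max maximum lag (d_max <= N - 1 required).
#' @param tables list of normalized property tables sharing tuple size.
#' @return numeric vector; dimension \code{d_max * gamma} (AC, MORAN,
#'   GEARY, NMBROTO), \code{d_max * gamma * (gamma - 1)} (CC) or
#'   \code{d_max * gamma^2} (ACC).
#' @export
autocorrelation <- function(seq,
                            method = c("AC", "CC", "ACC", "MORAN",
                                       "GEARY", "NMBROTO"),
                            d_max = 1L, tables = list()) {
  method <- match.arg(method)
  if (inherits(tables, "seqvec_property")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  for (p in tables)
    if (is.null(p$normalized))
      stop("property '", p$name, "' is not normalized", call. = FALSE)
  n <- unique(vapply(tables, `[[`, 1L, "tuple_size"))
  stopifnot(length(n) == 1L)
  st <- get_seqtype(tables[[1L]]$seqtype)
  A <- length(st$alphabet)
  d_max <- as.integer(d_max)
  stopifnot(d_max >= 1L)
  t <- tuple_index_array(seq, n, A) + 1L
  N <- length(t)
  if (N < 1L || d_max > N - 1L || (method == "GEARY" && N < 2L))
    signal_fault(seq_id_of(seq),
                 sprintf("insufficient length for %s with d_max=%d", method,
                         d_max))
  gamma <- length(tables)
  pv <- lapply(tables, function(p) unname(p$normalized)[t])
  pbar <- vapply(pv, mean, 0)
  cent <- Map(function(p, m) p - m, pv, pbar)

  ac_one <- function(v, d) {
    i <- seq_len(N - d)
    mean(cent[[v]][i] * cent[[v]][i + d])
  }
  cc_one <- function(v, w, d) {
    i <- seq_len(N - d)
    mean(cent[[v]][i] * cent[[w]][i + d])
  }

  ac_block <- function() {
    out <- numeric(d_max * gamma)
    for (d in seq_len(d_max)) for (v in seq_len(gamma))
      out[(d - 1L) * gamma + v] <- ac_one(v, d)
    out
  }
  cc_block <- function() {
    pairs <- which(outer(seq_len(gamma), seq_len(gamma), `!=`), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    np <- nrow(pairs)
    out <- numeric(d_max * np)
    for (d in seq_len(d_max)) for (p in seq_len(np))
      out[(d - 1L) * np + p] <- cc_one(pairs[p, 1L], pairs[p, 2L], d)
    out
  }

  switch(method,
    AC = ac_block(),
    CC = {
      if (gamma < 2L)
        stop("CC requires at least two properties", call. = FALSE)
      cc_block()
    },
    ACC = {
      if (gamma < 2L)
        stop("ACC requires at least two properties", call. = FALSE)
      c(ac_block(), cc_block())
    },
    MORAN = {
      out <- numeric(d_max * gamma)
      for (v in seq_len(gamma)) {
        varv <- mean(cent[[v]]^2)
        for (d in seq_len(d_max))
          out[(d - 1L) * gamma + v] <- if (varv > 0) ac_one(v, d) / varv else 0
      }
      out
    },
    GEARY = {
      out <- numeric(d_max * gamma)
      for (v in seq_len(gamma)) {
        varv <- sum(cent[[v]]^2) / (N - 1L)
        for (d in seq_len(d_max)) {
          i <- seq_len(N - d)
          num <- sum((pv[[v]][i] - pv[[v]][i + d])^2) / (2 * (N - d))
          out[(d - 1L) * gamma + v] <- if (varv > 0) num / varv else 0
        }
      }
      out
    },
    NMBROTO = {
      out <- numeric(d_max * gamma)
      for (d in seq_len(d_max)) for (v in seq_len(gamma)) {
        i <- seq_len(N - d)
        out[(d - 1L) * gamma + v] <- mean(pv[[v]][i] * pv[[v]][i + d])
      }
      out
    })
}

#' Distance-pair (DR) descriptor
#'
#' For each distance d = 1..d_max and ordered letter pair (a, b), the
#' frequency of positions i with \eqn{R_i = a} and \eqn{R_{i+d} = b},
#' divided by L - d. Ordering is distance-major, then pair index
#' \code{idx(a) * |A| + idx(b)}; each distance block sums to 1.
#'
#' @param seq index array.
#' @param seqtype sequence type or name.
#' @param d_max maximum distance (d_max <= L - 1 required).
#' @return numeric vector of length \code{d_max * |A|^2}.
#' @export
distance_pair <- function(seq, seqtype, d_max = 1L) {
  st <- get_seqtype(seqtype)
  A <- length(st$alphabet)
  d_max <- as.integer(d_max)
  stopifnot(d_max >= 1L)
  L <- length(seq)
  if (d_max > L - 1L)
    signal_fault(seq_id_of(seq),
                 sprintf("insufficient length for distance-pair d_max=%d (L=%d)",
                         d_max, L))
  out <- numeric(d_max * A^2)
  for (d in seq_len(d_max)) {
    i <- seq_len(L - d)
    pidx <- as.integer(seq[i]) * A + as.integer(seq[i + d])
    out[(d - 1L) * A^2 + seq_len(A^2)] <-
      tabulate(pidx + 1L, nbins = A^2) / (L - d)
  }
  out
}
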