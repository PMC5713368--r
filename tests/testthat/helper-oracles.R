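# Independent naive re-implementations of every kernel, working directly
# on letter strings and raw property values with explicit double loops.
# They never touch the package's pre-computed pair tables or index arrays,
# so agreement certifies the fast path end to end.

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# all n-tuples of `alphabet` in lexicographic-by-index order
oracle_tuples <- function(alphabet, n) {
  out <- ""
  for (i in seq_len(n)) out <- as.vector(t(outer(out, alphabet, paste0)))
  out
}

# zero-mean unit-population-variance normalization of a raw named vector
oracle_normalize <- function(raw) {
  m <- sum(raw) / length(raw)
  s <- sqrt(sum((raw - m)^2) / length(raw))
  (raw - m) / s
}

# overlapping n-tuple strings of a sequence
oracle_seq_tuples <- function(letters, n) {
  L <- nchar(letters)
  vapply(seq_len(L - n + 1L), function(i) substr(letters, i, i + n - 1L), "")
}

oracle_kmer <- function(letters, alphabet, k, complement = NULL,
                        collapse = FALSE) {
  tups <- oracle_seq_tuples(letters, k)
  all_t <- oracle_tuples(alphabet, k)
  f <- vapply(all_t, function(t) sum(tups == t), 0) / length(tups)
  if (!collapse) return(f)
  rc <- vapply(all_t, function(t) {
    ch <- rev(split_chars(t))
    paste(complement[ch], collapse = "")
  }, "")
  canon_of <- ifelse(match(all_t, all_t) <= match(rc, all_t), all_t, rc)
  classes <- all_t[sort(unique(match(canon_of, all_t)))]
  vapply(classes, function(cl) sum(f[canon_of == cl]), 0)
}

# theta tiers from raw property values (normalizes internally)
oracle_theta <- function(letters, lambda, raw_list, n, average = TRUE) {
  H <- lapply(raw_list, oracle_normalize)
  tups <- oracle_seq_tuples(letters, n)
  N <- length(tups)
  vapply(seq_len(lambda), function(j) {
    acc <- 0
    for (i in seq_len(N - j)) {
      corr <- 0
      for (h in H) corr <- corr + (h[[tups[i]]] - h[[tups[i + j]]])^2
      if (average) corr <- corr / length(H)
      acc <- acc + corr
    }
    acc / (N - j)
  }, 0)
}

oracle_tau <- function(letters, lambda, raw_list, n) {
  H <- lapply(raw_list, oracle_normalize)
  tups <- oracle_seq_tuples(letters, n)
  N <- length(tups)
  out <- numeric(0)
  for (j in seq_len(lambda)) for (v in seq_along(H)) {
    acc <- 0
    for (i in seq_len(N - j))
      acc <- acc + H[[v]][[tups[i]]] * H[[v]][[tups[i + j]]]
    out <- c(out, acc / (N - j))
  }
  out
}

oracle_pse1 <- function(letters, alphabet, k, lambda, omega, raw_list, n) {
  f <- oracle_kmer(letters, alphabet, k)
  th <- if (lambda > 0) oracle_theta(letters, lambda, raw_list, n)
        else numeric()
  Z <- 1 + omega * sum(th)
  unname(c(f, omega * th)) / Z
}

oracle_pse2 <- function(letters, alphabet, k, lambda, omega, raw_list, n) {
  f <- oracle_kmer(letters, alphabet, k)
  ta <- if (lambda > 0) oracle_tau(letters, lambda, raw_list, n)
        else numeric()
  Z <- 1 + omega * sum(ta)
  unname(c(f, omega * ta)) / Z
}

oracle_autocorr <- function(letters, method, d_max, raw_list, n) {
  H <- lapply(raw_list, oracle_normalize)
  tups <- oracle_seq_tuples(letters, n)
  N <- length(tups)
  g <- length(H)
  pv <- lapply(H, function(h) vapply(tups, function(t) h[[t]], 0))
  pbar <- vapply(pv, mean, 0)
  ac <- function(v, d)
    mean((pv[[v]][1:(N - d)] - pbar[v]) * (pv[[v]][(1 + d):N] - pbar[v]))
  cc <- function(v, w, d)
    mean((pv[[v]][1:(N - d)] - pbar[v]) * (pv[[w]][(1 + d):N] - pbar[w]))
  ac_all <- function() {
    out <- numeric(0)
    for (d in 1:d_max) for (v in 1:g) out <- c(out, ac(v, d))
    out
  }
  cc_all <- function() {
    out <- numeric(0)
    for (d in 1:d_max) for (v in 1:g) for (w in 1:g)
      if (v != w) out <- c(out, cc(v, w, d))
    out
  }
  switch(method,
    AC = ac_all(),
    CC = cc_all(),
    ACC = c(ac_all(), cc_all()),
    MORAN = {
      out <- numeric(0)
      for (d in 1:d_max) for (v in 1:g) {
        varv <- mean((pv[[v]] - pbar[v])^2)
        out <- c(out, if (varv > 0) ac(v, d) / varv else 0)
      }
      out
    },
    GEARY = {
      out <- numeric(0)
      for (d in 1:d_max) for (v in 1:g) {
        varv <- sum((pv[[v]] - pbar[v])^2) / (N - 1)
        num <- sum((pv[[v]][1:(N - d)] - pv[[v]][(1 + d):N])^2) /
          (2 * (N - d))
        out <- c(out, if (varv > 0) num / varv else 0)
      }
      out
    },
    NMBROTO = {
      out <- numeric(0)
      for (d in 1:d_max) for (v in 1:g)
        out <- c(out, mean(pv[[v]][1:(N - d)] * pv[[v]][(1 + d):N]))
      out
    })
}

oracle_distance_pair <- function(letters, alphabet, d_max) {
  ch <- split_chars(letters)
  L <- length(ch)
  out <- numeric(0)
  for (d in 1:d_max) {
    block <- numeric(0)
    for (a in alphabet) for (b in alphabet)
      block <- c(block,
                 sum(ch[1:(L - d)] == a & ch[(1 + d):L] == b) / (L - d))
    out <- c(out, block)
  }
  out
}

# --- shared fixtures ------------------------------------------------------

# the {A,B} toy alphabet, registered once per session
ensure_ab_seqtype <- function() {
  tryCatch(get_seqtype("AB"),
           error = function(e)
             define_seqtype("AB", c("A", "B"),
                            complement = c(A = "B", B = "A")))
}

toy_property <- function(values, seqtype = "AB", n = 1L,
                         name = "toy") {
  tuples <- enumerate_tuples(seqtype, n)
  stopifnot(length(values) == length(tuples))
  if (is.null(names(values))) names(values) <- tuples
  normalize_table(seqvec:::new_property_table(name,
                                              get_seqtype(seqtype)$name,
                                              n, values[tuples]))
}

random_letters <- function(len, alphabet)
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
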