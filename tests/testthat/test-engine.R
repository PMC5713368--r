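ensure_ab_seqtype()
p_ab <- toy_property(c(A = 1, B = 3), name = "hA")        # -1, +1
p_ab2 <- toy_property(c(A = 3, B = 1), name = "hB")       # +1, -1
pair_ab <- build_pair_tables(list(p_ab))
pair_ab2 <- build_pair_tables(list(p_ab, p_ab2))

test_that("k-mer composition matches its closed-form examples", {
  aaaa <- encode_sequence("AAAA", "PROT")
  f <- kmer_composition(aaaa, "PROT", 1L)
  expect_equal(unname(f[1L]), 1)
  expect_equal(sum(f), 1)
  expect_equal(sum(f != 0), 1L)

  acgt <- encode_sequence("ACGT", "DNA")
  f2 <- kmer_composition(acgt, "DNA", 2L)
  expect_equal(unname(f2[c("AC", "CG", "GT")]), rep(1 / 3, 3L))
  expect_equal(sum(f2), 1)

  fc <- kmer_composition(acgt, "DNA", 1L, collapse_revcomp = TRUE)
  expect_equal(unname(fc), c(0.5, 0.5))
  expect_equal(names(fc), c("A", "C"))

  expect_error(kmer_composition(encode_sequence("AC", "DNA"), "DNA", 3L),
               class = "seqvec_fault")
})

test_that("theta tiers match direct evaluation and vanish on homopolymers", {
  hom <- encode_sequence("AAAAA", "AB")
  expect_equal(theta_parallel(hom, 2L, pair_ab), c(0, 0))
  expect_equal(theta_parallel(encode_sequence("AB", "AB"), 1L, pair_ab), 4)
  expect_equal(theta_parallel(encode_sequence("ABAB", "AB"), 2L, pair_ab),
               c(4, 0))
  expect_error(theta_parallel(encode_sequence("AB", "AB"), 2L, pair_ab),
               class = "seqvec_fault")
})

test_that("tau tiers interleave properties lag-major and keep sign", {
  ab <- encode_sequence("AB", "AB")
  expect_equal(tau_series(ab, 1L, pair_ab2), c(-1, -1))
  # series correlation does not vanish on homopolymers
  expect_equal(tau_series(encode_sequence("AAAA", "AB"), 1L, pair_ab), 1)
  expect_equal(tau_series(ab, 0L, pair_ab2), numeric())
})

test_that("Type-1 pseudo composition reproduces the worked example", {
  ab <- encode_sequence("AB", "AB")
  expect_equal(pse_type1(ab, "AB", 1L, 1L, 0.5, pair_ab),
               c(1 / 6, 1 / 6, 2 / 3))
  # homopolymer: all theta zero, Z = 1
  hom <- encode_sequence("AAAAAA", "PROT")
  pair_p <- build_pair_tables(lapply(
    c("prot.hydrophobicity", "prot.hydrophilicity", "prot.sidechainmass"),
    get_property_table))
  v <- pse_type1(hom, "PROT", 1L, 3L, 0.05, pair_p)
  expect_length(v, 23L)
  expect_equal(v[1L], 1)
  expect_equal(sum(v != 0), 1L)
})

test_that("Type-2 pseudo composition handles negatives and degenerate Z", {
  ab <- encode_sequence("AB", "AB")
  expect_equal(pse_type2(ab, "AB", 1L, 1L, 0.1, pair_ab2),
               c(0.625, 0.625, -0.125, -0.125))
  expect_error(pse_type2(ab, "AB", 1L, 1L, 0.5, pair_ab2),
               class = "seqvec_fault")
  # Fig-style classic protein configuration: 20 + 2*10 dimensions
  set.seed(41)
  s <- encode_sequence(random_letters(80, get_seqtype("PROT")$alphabet),
                       "PROT")
  pair_hh <- build_pair_tables(lapply(
    c("prot.hydrophobicity", "prot.hydrophilicity"), get_property_table))
  v <- pse_type2(s, "PROT", 1L, 10L, 0.05, pair_hh)
  expect_length(v, 40L)
  expect_equal(sum(v), 1, tolerance = 1e-9)
})

test_that("lambda = 0 reduces both pseudo compositions to the composition", {
  set.seed(42)
  for (rep in 1:10) {
    s <- encode_sequence(random_letters(sample(5:40, 1L), c("A", "B")), "AB")
    f <- unname(kmer_composition(s, "AB", 1L))
    expect_identical(pse_type1(s, "AB", 1L, 0L, 0.05, pair_ab), f)
    expect_identical(pse_type2(s, "AB", 1L, 0L, 0.05, pair_ab2), f)
  }
})

test_that("one-hot encodes positions, pads, and faults on overflow", {
  expect_equal(one_hot(encode_sequence("AC", "DNA"), "DNA", 2L),
               c(1, 0, 0, 0, 0, 1, 0, 0))
  expect_equal(one_hot(encode_sequence("A", "DNA"), "DNA", 2L),
               c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_error(one_hot(encode_sequence("ACG", "DNA"), "DNA", 2L),
               class = "seqvec_fault")
})

test_that("autocorrelation family matches its two-letter closed forms", {
  ab <- encode_sequence("AB", "AB")
  expect_equal(autocorrelation(ab, "AC", 1L, list(p_ab)), -1)
  expect_equal(autocorrelation(ab, "MORAN", 1L, list(p_ab)), -1)
  expect_equal(autocorrelation(ab, "GEARY", 1L, list(p_ab)), 1)
  expect_equal(autocorrelation(ab, "NMBROTO", 1L, list(p_ab)), -1)
  # zero-variance sequence: MORAN/GEARY components defined as 0
  hom <- encode_sequence("AAAA", "AB")
  expect_equal(autocorrelation(hom, "AC", 2L, list(p_ab)), c(0, 0))
  expect_equal(autocorrelation(hom, "MORAN", 2L, list(p_ab)), c(0, 0))
  expect_equal(autocorrelation(hom, "GEARY", 1L, list(p_ab)), 0)
  # dimensions: CC gamma(gamma-1), ACC gamma^2 per lag
  s <- encode_sequence("ABABAB", "AB")
  expect_length(autocorrelation(s, "CC", 1L, list(p_ab, p_ab2)), 2L)
  expect_length(autocorrelation(s, "ACC", 2L, list(p_ab, p_ab2)), 8L)
  expect_error(autocorrelation(ab, "AC", 5L, list(p_ab)),
               class = "seqvec_fault")
})

test_that("distance-pair frequencies count ordered pairs per distance", {
  expect_equal(distance_pair(encode_sequence("AB", "AB"), "AB", 1L),
               c(0, 1, 0, 0))
  expect_equal(distance_pair(encode_sequence("AAA", "AB"), "AB", 2L),
               c(1, 0, 0, 0, 1, 0, 0, 0))
  expect_equal(distance_pair(encode_sequence("ABAB", "AB"), "AB", 1L),
               c(0, 2 / 3, 1 / 3, 0))
  expect_error(distance_pair(encode_sequence("AB", "AB"), "AB", 2L),
               class = "seqvec_fault")
})

test_that("every kernel matches the naive oracle on random inputs", {
  set.seed(43)
  ab_alpha <- c("A", "B")
  for (rep in 1:60) {
    len <- sample(5:50, 1L)
    s_chr <- random_letters(len, ab_alpha)
    s <- encode_sequence(s_chr, "AB")
    n <- sample(1:2, 1L)
    gamma <- sample(1:3, 1L)
    tabs <- lapply(seq_len(gamma), function(i)
      random_property_table("AB", n))
    raws <- lapply(tabs, `[[`, "raw")
    pair <- build_pair_tables(tabs)
    lambda <- sample(0:min(3L, len - n - 1L), 1L)
    k <- sample(1:2, 1L)
    d_max <- sample(1:min(3L, len - n), 1L)
    omega <- stats::runif(1L, 0.01, 1)

    expect_equal(unname(kmer_composition(s, "AB", k)),
                 unname(oracle_kmer(s_chr, ab_alpha, k)), tolerance = 1e-12)
    if (lambda > 0) {
      expect_equal(theta_parallel(s, lambda, pair),
                   unname(oracle_theta(s_chr, lambda, raws, n)),
                   tolerance = 1e-12)
      expect_equal(tau_series(s, lambda, pair),
                   unname(oracle_tau(s_chr, lambda, raws, n)),
                   tolerance = 1e-12)
    }
    expect_equal(pse_type1(s, "AB", k, lambda, omega, pair),
                 oracle_pse1(s_chr, ab_alpha, k, lambda, omega, raws, n),
                 tolerance = 1e-12)
    tau_sum <- if (lambda > 0) sum(oracle_tau(s_chr, lambda, raws, n)) else 0
    if (abs(1 + omega * tau_sum) > 1e-6)
      expect_equal(pse_type2(s, "AB", k, lambda, omega, pair),
                   oracle_pse2(s_chr, ab_alpha, k, lambda, omega, raws, n),
                   tolerance = 1e-12)
    for (meth in c("AC", "MORAN", "GEARY", "NMBROTO"))
      expect_equal(autocorrelation(s, meth, d_max, tabs),
                   unname(oracle_autocorr(s_chr, meth, d_max, raws, n)),
                   tolerance = 1e-12)
    if (gamma >= 2L)
      for (meth in c("CC", "ACC"))
        expect_equal(autocorrelation(s, meth, d_max, tabs),
                     unname(oracle_autocorr(s_chr, meth, d_max, raws, n)),
                     tolerance = 1e-12)
    expect_equal(distance_pair(s, "AB", d_max),
                 oracle_distance_pair(s_chr, ab_alpha, d_max),
                 tolerance = 1e-12)
  }
})

test_that("sum-to-one, nonnegativity and reversal invariances hold", {
  set.seed(44)
  for (rep in 1:50) {
    len <- sample(6:50, 1L)
    s_chr <- random_letters(len, c("A", "B"))
    s <- encode_sequence(s_chr, "AB")
    rev_s <- encode_sequence(paste(rev(split_chars(s_chr)), collapse = ""),
                             "AB")
    lambda <- sample(1:3, 1L)
    v1 <- pse_type1(s, "AB", 1L, lambda, 0.2, pair_ab)
    expect_equal(sum(v1), 1, tolerance = 1e-9)
    expect_true(all(v1 >= 0))
    v2 <- pse_type2(s, "AB", 1L, lambda, 0.05, pair_ab2)
    expect_equal(sum(v2), 1, tolerance = 1e-9)
    f <- kmer_composition(s, "AB", 2L)
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_true(all(f >= 0))
    expect_true(all(distance_pair(s, "AB", 2L) >= 0))
    # theta/tau tiers are reversal-invariant for n = 1
    expect_equal(theta_parallel(s, lambda, pair_ab),
                 theta_parallel(rev_s, lambda, pair_ab), tolerance = 1e-12)
    expect_equal(tau_series(s, lambda, pair_ab2),
                 tau_series(rev_s, lambda, pair_ab2), tolerance = 1e-12)
    # composition is invariant under any permutation
    perm <- encode_sequence(
      paste(sample(split_chars(s_chr)), collapse = ""), "AB")
    expect_equal(kmer_composition(perm, "AB", 1L),
                 kmer_composition(s, "AB", 1L), tolerance = 1e-12)
  }
})

test_that("the built-in catalogue holds 35 modes partitioned 12/8/15", {
  m <- list_modes()
  expect_equal(nrow(m), 35L)
  expect_equal(sum(m$seqtype == "DNA"), 12L)
  expect_equal(sum(m$seqtype == "RNA"), 8L)
  expect_equal(sum(m$seqtype == "PROT"), 15L)
  expect_equal(nrow(list_modes("PROT")), 15L)
  expect_false(is.unsorted(order(m$seqtype, m$mode_id)))
  # output dimension is independent of L for fixed parameters
  set.seed(45)
  for (id in c("aac", "dpc", "psednc", "pseaac1", "pseaac2", "dac", "dr")) {
    def <- configure_mode(id)
    st <- get_seqtype(def$seqtype)
    dims <- vapply(c(30L, 60L, 120L), function(L) {
      s <- encode_sequence(random_letters(L, st$alphabet), st)
      ctx <- if (is.null(def$prepare)) NULL else def$prepare(def$params)
      length(def$compute(s, def$params, ctx))
    }, 0L)
    expect_equal(unique(dims), mode_dimension(def), info = id)
  }
})

test_that("the engine concatenates modes and honors the fault policy", {
  set.seed(46)
  recs <- random_records(3, "PROT", c(30L, 60L))
  res <- run_engine(recs, "PROT", "aac")
  expect_length(res$vectors, 3L)
  expect_equal(res$dim, 20L)

  res2 <- run_engine(recs, "PROT",
                     list("aac", list(mode_id = "pseaac1",
                                      params = list(lambda = 2L))))
  expect_equal(res2$dim, 42L)
  expect_equal(unique(lengths(res2$vectors)), 42L)

  # one record too short for lambda: skipped with a report
  recs3 <- c(recs[1:2], list(sequence_record("short", "AC")))
  res3 <- run_engine(recs3, "PROT", list(list(mode_id = "pseaac1",
                                              params = list(lambda = 5L))))
  expect_length(res3$vectors, 2L)
  expect_equal(res3$report$seq_id, "short")
  expect_error(run_engine(recs3, "PROT",
                          list(list(mode_id = "pseaac1",
                                    params = list(lambda = 5L))),
                          policy = fault_policy("abort")),
               class = "seqvec_fault")

  # configuration errors precede any processing
  expect_error(run_engine(recs, "PROT", "nosuchmode"), "unknown mode id")
  expect_error(run_engine(recs, "DNA", "aac"), "not DNA")
  expect_error(run_engine(recs, "PROT",
                          list(list(mode_id = "aac",
                                    params = list(bogus = 1)))),
               "unknown parameter")
  expect_error(run_engine(recs, "PROT", "onehot-prot"),
               "missing mandatory parameter")
})
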