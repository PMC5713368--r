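write_ext <- function(lines) {
  f <- tempfile(fileext = ".R")
  writeLines(lines, f)
  f
}

test_that("the documented API surface has exactly the 23 named callables", {
  api <- extension_api()
  expect_length(api, 23L)
  expect_true(length(api) >= 20L)
  expect_true(all(c("register_seqtype", "register_property", "register_mode",
                    "declare_option", "get_option", "set_output_format",
                    "current_seq_id", "current_sequence", "current_indices",
                    "seq_length", "alphabet", "alphabet_size",
                    "get_property_raw", "get_property_normalized",
                    "property_value", "kmer_counts", "theta_parallel",
                    "tau_series", "build_pair_tables", "emit_vector",
                    "set_label", "skip_sequence", "log_message") %in% api))
})

test_that("an extension registers a mode and the catalogue grows by one", {
  reset_registry()
  f <- write_ext(c(
    'register_mode("myaac", "PROT",',
    '  dimension = 20,',
    '  compute = function() {',
    '    counts <- kmer_counts(1)',
    '    emit_vector(counts / sum(counts))',
    '  },',
    '  description = "extension AAC")'))
  manifest <- load_extension(f)
  expect_equal(manifest$registered$modes, "myaac")
  expect_equal(nrow(list_modes()), 36L)
  expect_true("myaac" %in% list_modes()$mode_id)

  set.seed(51)
  recs <- random_records(5, "PROT", c(20L, 50L))
  expect_equal(as.matrix(run_engine(recs, "PROT", "myaac")),
               as.matrix(run_engine(recs, "PROT", "aac")))
  # id collisions with built-ins are load failures
  g <- write_ext('register_mode("aac", "PROT", dimension = 20,
                  compute = function() emit_vector(numeric(20)))')
  expect_error(load_extension(g), "already registered")
  reset_registry()
  expect_equal(nrow(list_modes()), 35L)
})

test_that("loading is transactional: a failing extension registers nothing", {
  reset_registry()
  f <- write_ext(c(
    'register_mode("good-mode", "PROT", dimension = 1,',
    '  compute = function() emit_vector(1))',
    'stop("deliberate failure")'))
  expect_error(load_extension(f), "deliberate failure")
  expect_equal(nrow(list_modes()), 35L)
  expect_false("good-mode" %in% list_modes()$mode_id)
  # syntax errors too
  g <- write_ext("this is not ( valid R")
  expect_error(load_extension(g), "failed to load")
  expect_equal(nrow(list_modes()), 35L)
})

test_that("extensions declare CLI options that modes can read", {
  reset_registry()
  f <- write_ext(c(
    'declare_option("l", type = "integer", default = 1,',
    '               help = "lambda tiers")',
    'register_mode("lambda-echo", "PROT",',
    '  dimension = function(params, A, gamma) 1L,',
    '  compute = function() emit_vector(get_option("l")))'))
  load_extension(f)
  reg <- seqvec:::.seqvec
  reg$options[["l"]] <- 10L   # as the CLI parse would set it
  recs <- list(sequence_record("s1", "ACDEF"))
  res <- run_engine(recs, "PROT", "lambda-echo")
  expect_equal(unname(res$vectors[["s1"]]), 10)
  reset_registry()
})

test_that("a Type-2 pseudo composition written as an extension is bit-identical to the built-in", {
  reset_registry()
  f <- write_ext(c(
    'pair <- build_pair_tables(c("prot.hydrophobicity",',
    '                            "prot.hydrophilicity"))',
    'register_mode("pseaac2-ext", "PROT",',
    '  params = list(lambda = 1L, omega = 0.05),',
    '  dimension = function(params, A, gamma) A + 2L * params$lambda,',
    '  compute = function(seq, params) {',
    '    counts <- kmer_counts(1)',
    '    f <- counts / sum(counts)',
    '    tau <- tau_series(params$lambda, pair)',
    '    Z <- 1 + params$omega * sum(tau)',
    '    emit_vector(c(f, params$omega * tau) / Z)',
    '  })'))
  load_extension(f)
  set.seed(52)
  recs <- random_records(100, "PROT", c(25L, 80L))
  for (lambda in c(1L, 10L)) {
    ext <- run_engine(recs, "PROT",
                      list(list(mode_id = "pseaac2-ext",
                                params = list(lambda = lambda))))
    ref <- run_engine(recs, "PROT",
                      list(list(mode_id = "pseaac2",
                                params = list(lambda = lambda))))
    expect_identical(as.matrix(ext), as.matrix(ref))
  }
  reset_registry()
})

test_that("per-sequence API calls fail outside a compute rule, and skip_sequence reports", {
  reset_registry()
  api <- seqvec:::build_api_env()
  expect_error(api$current_seq_id(), "inside a mode compute rule")
  expect_error(api$current_indices(), "inside a mode compute rule")
  f <- write_ext(c(
    'register_mode("skipper", "PROT", dimension = 1,',
    '  compute = function() {',
    '    if (seq_length() < 10) skip_sequence("too short for skipper")',
    '    set_label(1)',
    '    emit_vector(seq_length())',
    '  })'))
  load_extension(f)
  recs <- list(sequence_record("long1", strrep("ACDEF", 4L)),
               sequence_record("tiny", "ACD"))
  res <- run_engine(recs, "PROT", "skipper")
  expect_length(res$vectors, 1L)
  expect_equal(res$report$seq_id, "tiny")
  expect_match(res$report$reason, "too short for skipper")
  expect_equal(unname(res$labels["long1"]), 1)
  reset_registry()
})

test_that("wrong-dimension extension vectors are runtime data faults", {
  reset_registry()
  f <- write_ext('register_mode("badsize", "PROT", dimension = 5,
    compute = function() emit_vector(c(1, 2)))')
  load_extension(f)
  recs <- list(sequence_record("s1", "ACDEF"))
  res <- run_engine(recs, "PROT", "badsize")
  expect_length(res$vectors, 0L)
  expect_match(res$report$reason, "expected 5")
  reset_registry()
})
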