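# The simulator: configuration validation, determinism, error model,
# depth conservation.

test_that("configuration errors name the offending field", {
  expect_match(conditionMessage(expect_error(
    sim_config(gc_content = 1.5), class = "dgetag_config_error")),
    "gc_content")
  expect_match(conditionMessage(expect_error(
    sim_config(transcript_length_range = c(10, 40)),
    class = "dgetag_config_error")), "transcript_length_range")
  expect_match(conditionMessage(expect_error(
    sim_config(substitution_rate = 0.6, n_rate = 0.5),
    class = "dgetag_config_error")), "substitution_rate")
  expect_match(conditionMessage(expect_error(
    sim_config(n_transcripts = -1), class = "dgetag_config_error")),
    "n_transcripts")
})

test_that("empty reference, determinism, and taggable-by-construction", {
  expect_equal(length(simulate_reference(sim_config(n_transcripts = 0))$sequences),
               0L)

  cfg <- sim_config(n_transcripts = 50, seed = 1)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_reference_fasta(simulate_reference(cfg), f1)
  write_reference_fasta(simulate_reference(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  ref <- simulate_reference(sim_config(n_transcripts = 300,
                                       transcript_length_range = c(200, 400),
                                       seed = 7))
  # brute-force scan confirms the taggable flags
  scans <- vapply(ref$sequences,
                  function(s) length(oracle_scan_tags(s)$tags) > 0,
                  logical(1))
  expect_identical(unname(ref$taggable), unname(scans))
  expect_gte(mean(ref$taggable), 0.90)
})

test_that("library simulation is deterministic and conserves depth", {
  cfg <- sim_config(n_transcripts = 30, depth_per_library = 1500, seed = 12)
  ref <- simulate_reference(cfg)
  s1 <- simulate_libraries(ref, cfg)
  s2 <- simulate_libraries(ref, cfg)
  for (lib in names(s1$libraries)) {
    expect_identical(s1$libraries[[lib]]$raw_counts,
                     s2$libraries[[lib]]$raw_counts)
    expect_equal(sum(s1$libraries[[lib]]$raw_counts), 1500)
  }
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_tag_counts(s1$libraries[[3]]$raw_counts, t1)
  write_tag_counts(s2$libraries[[3]]$raw_counts, t2)
  expect_identical(readLines(t1), readLines(t2))
  # ground-truth expected counts never exceed the library depth
  per_lib <- tapply(s1$truth$expected_counts$expected_count,
                    paste(s1$truth$expected_counts$species,
                          s1$truth$expected_counts$stage),
                    sum)
  expect_true(all(per_lib <= 1500 + 1e-9))
})

test_that("error-free degenerate case gives a single tag at full depth", {
  cfg <- sim_config(n_transcripts = 1, depth_per_library = 500,
                    n_species = 1, n_stages = 1, substitution_rate = 0,
                    n_rate = 0, adaptor_read_fraction = 0, seed = 2)
  sim <- simulate_libraries(simulate_reference(cfg), cfg)
  counts <- sim$libraries[[1]]$raw_counts
  expect_equal(length(counts), 1L)
  expect_equal(unname(counts), 500L)
  expect_equal(names(counts), unname(sim$truth$transcript_tags))
})

test_that("N-call rate matches the closed-form binomial expectation", {
  cfg <- sim_config(n_transcripts = 5, depth_per_library = 10000,
                    n_species = 1, n_stages = 1, substitution_rate = 0,
                    n_rate = 0.01, adaptor_read_fraction = 0, seed = 3)
  sim <- simulate_libraries(simulate_reference(cfg), cfg)
  counts <- sim$libraries[[1]]$raw_counts
  n_reads <- sum(counts[grepl("N", names(counts))])
  p <- 1 - (1 - 0.01)^17
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(n_reads / 10000 - p), 3 * se)
})

test_that("adaptor contamination is emitted and later removed by the filter", {
  cfg <- sim_config(n_transcripts = 10, depth_per_library = 2000,
                    n_species = 1, n_stages = 1,
                    adaptor_read_fraction = 0.05, seed = 4)
  sim <- simulate_libraries(simulate_reference(cfg), cfg)
  counts <- sim$libraries[[1]]$raw_counts
  adaptor_tag <- substr(dge_default_adaptor(), 1, 17)
  expect_gte(counts[[adaptor_tag]], 100)
  expect_equal(unname(sim$truth$contaminant_reads[1]), 100)
  cleaned <- filter_tags(counts, filter_config())
  expect_false(adaptor_tag %in% names(cleaned$clean))
  expect_gte(cleaned$report$adaptor_removed, 1L)
})

test_that("a reference without any taggable transcript is a simulation error", {
  cfg <- sim_config(n_transcripts = 2, seed = 5)
  expect_error(simulate_libraries(setNames(c("AAAAAT", "CCCCCC"),
                                           c("t1", "t2")), cfg),
               class = "dgetag_simulation_error")
})
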