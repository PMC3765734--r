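# Tag-to-gene assignment with at most one mismatch.

make_index <- function(tags, ids = sprintf("g%03d", seq_along(tags))) {
  build_tag_index(ref_from_tags(tags, ids))
}

test_that("map_tag resolves exact, one-mismatch, unmapped and ambiguous cases", {
  set.seed(41)
  base <- "ACGTACGTACGTACGTA"
  idx <- make_index(c(base, "TTTTTTTTTTTTTTTTT"), c("g1", "g2"))

  exact <- map_tag(base, idx)
  expect_equal(exact$match_class, "exact")
  expect_equal(exact$transcript_ids, "g1")
  expect_true(is.na(exact$mismatch_position))

  mm <- base
  substr(mm, 9, 9) <- "G"                     # position 9: C -> G
  got <- map_tag(mm, idx)
  expect_equal(got$match_class, "one_mismatch")
  expect_equal(got$transcript_ids, "g1")
  expect_equal(got$mismatch_position, 9L)

  far <- base
  substr(far, 1, 2) <- "TT"                   # distance 2 from g1, 15 from g2
  expect_equal(map_tag(far, idx)$match_class, "unmapped")

  # shared-suffix reference: exact hit on a tag carried by two transcripts
  shared <- make_index(c(base, base), c("a", "b"))
  amb <- map_tag(base, shared)
  expect_equal(amb$match_class, "ambiguous")
  expect_setequal(amb$transcript_ids, c("a", "b"))

  expect_error(map_tag("ACGT", idx), class = "dgetag_input_error")
  expect_error(map_tag("ACGTNCGTACGTACGTA", idx),
               class = "dgetag_input_error")
})

test_that("an exact hit beats any one-mismatch hit (two-tier resolution)", {
  t1 <- "AAAAAAAAAAAAAAAAA"
  t2 <- "CAAAAAAAAAAAAAAAA"                   # Hamming 1 from t1
  idx <- make_index(c(t1, t2), c("g1", "g2"))
  got <- map_tag(t1, idx)
  expect_equal(got$match_class, "exact")
  expect_equal(got$transcript_ids, "g1")
})

test_that("map_library matches the brute-force Hamming scan on random instances", {
  set.seed(42)
  for (i in 1:25) {
    ref_tags <- random_tags(sample(10:60, 1))
    ids <- sprintf("g%03d", seq_along(ref_tags))
    idx <- make_index(ref_tags, ids)
    # queries biased toward the reference: exact copies, 1- and 2-mutants
    q <- c(sample(ref_tags, 5, replace = TRUE),
           vapply(sample(ref_tags, 5, replace = TRUE), function(t) {
             p <- sample(17, 1)
             substr(t, p, p) <- sample(setdiff(c("A","C","G","T"),
                                               substr(t, p, p)), 1)
             t
           }, character(1)),
           random_tags(10))
    q <- unique(q)
    clean <- setNames(rep(2L, length(q)), q)
    got <- map_library(clean, idx)
    for (j in seq_along(q)) {
      oracle <- oracle_map_tag(q[j], ref_tags, ids)
      expect_equal(got$assignments$match_class[j], oracle$class)
      got_tx <- strsplit(got$assignments$transcript_ids[j], ",")[[1]]
      expect_setequal(got_tx, oracle$tx)
      single <- map_tag(q[j], idx)
      expect_equal(single$match_class, oracle$class)
      expect_setequal(single$transcript_ids, oracle$tx)
    }
    # classes are disjoint and partition the distinct clean tags
    expect_equal(sum(got$class_counts), got$distinct_clean)
  }
})

test_that("perfect-recovery limit: every canonical tag maps exactly, ratio 1", {
  cfg <- sim_config(n_transcripts = 40, depth_per_library = 2000,
                    n_species = 1, n_stages = 1, substitution_rate = 0,
                    n_rate = 0, adaptor_read_fraction = 0, seed = 8)
  ref <- simulate_reference(cfg)
  sim <- simulate_libraries(ref, cfg)
  idx <- build_tag_index(ref$sequences)
  lib <- tag_library("s", "st", sim$libraries[[1]]$raw_counts)
  got <- map_library(lib$clean_counts, idx)
  expect_equal(got$mapping_ratio, 1.0)
  expect_true(all(got$assignments$match_class %in% c("exact", "ambiguous")))
  expect_equal(sum(got$transcript_counts) +
                 sum(got$assignments$count[got$assignments$match_class ==
                                             "ambiguous"]),
               lib$clean_tag_total)
})

test_that("ambiguous policies shift the mapped statistic and per-transcript counts", {
  base <- "ACGTACGTACGTACGTA"
  idx <- make_index(c(base, base, "TTTTTTTTTTTTTTTTT"), c("a", "b", "c"))
  clean <- setNames(c(6L, 4L), c(base, "TTTTTTTTTTTTTTTTT"))
  count <- map_library(clean, idx, ambiguous = "count")
  drop <- map_library(clean, idx, ambiguous = "drop")
  dist <- map_library(clean, idx, ambiguous = "distribute")
  expect_equal(count$mapped_unique_tags, 2L)
  expect_equal(drop$mapped_unique_tags, 1L)
  expect_equal(count$transcript_counts, c(c = 4))
  expect_equal(dist$transcript_counts[c("a", "b", "c")],
               c(a = 3, b = 3, c = 4))
})

test_that("adding a transcript never shrinks any tag's Hamming<=1 candidate set", {
  candidates <- function(tag, idx) {
    nb <- c(tag, hamming1_neighbors(tag)$neighbor)
    hit <- match(nb, idx$tags)
    sort(unique(unlist(idx$transcripts[hit[!is.na(hit)]])))
  }
  set.seed(43)
  for (i in 1:10) {
    ref_tags <- random_tags(20)
    ids <- sprintf("g%03d", seq_along(ref_tags))
    q <- unique(c(sample(ref_tags, 3), random_tags(5)))
    idx_small <- make_index(ref_tags, ids)
    idx_big <- make_index(c(ref_tags, random_tags(1)), c(ids, "extra"))
    for (tag in q) {
      expect_true(all(candidates(tag, idx_small) %in%
                        candidates(tag, idx_big)))
    }
  }
})

test_that("empty index maps everything unmapped with a warning", {
  idx <- build_tag_index(setNames(character(0), character(0)))
  expect_warning(got <- map_library(c(ACGTACGTACGTACGTA = 3L), idx))
  expect_equal(got$assignments$match_class, "unmapped")
  expect_equal(got$mapped_unique_tags, 0L)
})
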