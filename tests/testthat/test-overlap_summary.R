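# Venn partitions, coexpression fractions, library summary tables.

test_that("venn_partition matches hand-enumerated regions", {
  A <- expressed_set("A", c("a", "b", "c"))
  B <- expressed_set("B", c("b", "c", "d"))
  C <- expressed_set("C", "c")
  got <- venn_partition(list(A, B, C))
  expect_equal(got[["A"]], 1L)          # {a}
  expect_equal(got[["A&B"]], 1L)        # {b}
  expect_equal(got[["A&B&C"]], 1L)      # {c}
  expect_equal(got[["B"]], 1L)          # {d}
  expect_equal(sum(got), 4L)            # |union|
  expect_equal(sum(got != 0), 4L)

  same <- venn_partition(list(expressed_set("X", c("p", "q")),
                              expressed_set("Y", c("p", "q"))))
  expect_equal(same[["X&Y"]], 2L)
  expect_equal(same[["X"]], 0L)
  expect_equal(same[["Y"]], 0L)
})

test_that("venn regions: permutation invariance, union sum, per-set recovery", {
  set.seed(61)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    pool <- sprintf("t%03d", 1:60)
    sets <- lapply(seq_len(k), function(j) {
      expressed_set(paste0("L", j), sample(pool, sample(5:40, 1)))
    })
    got <- venn_partition(sets)
    perm <- venn_partition(sample(sets))
    expect_identical(got[sort(names(got))], perm[sort(names(perm))])
    union_size <- length(unique(unlist(lapply(sets, `[[`, "members"))))
    expect_equal(sum(got), union_size)
    # each set's size equals the sum over regions containing it
    for (s in sets) {
      in_region <- vapply(strsplit(names(got), "&", fixed = TRUE),
                          function(r) s$library_id %in% r, logical(1))
      expect_equal(sum(got[in_region]), length(s$members))
    }
    # oracle: classify every element of the union directly
    for (el in sample(unique(unlist(lapply(sets, `[[`, "members"))), 5)) {
      label <- paste(sort(vapply(sets[vapply(sets, function(s)
        el %in% s$members, logical(1))], `[[`, character(1), "library_id")),
        collapse = "&")
      expect_gte(got[[label]], 1L)
    }
  }
})

test_that("mixed universes and degenerate set counts are rejected", {
  A <- expressed_set("A", c("x"), universe = "tags")
  B <- expressed_set("B", c("x"), universe = "genes")
  expect_error(venn_partition(list(A, B)), class = "dgetag_input_error")
  expect_error(coexpression_fraction(A, B), class = "dgetag_input_error")
  expect_error(venn_partition(list(A)), class = "dgetag_input_error")
})

test_that("coexpression fractions follow direct arithmetic", {
  d1 <- expressed_set("A", sprintf("a%d", 1:10))
  d2 <- expressed_set("B", sprintf("b%d", 1:10))
  expect_equal(coexpression_fraction(d1, d2),
               list(intersection = 0L, fraction_of_a = 0, fraction_of_b = 0))

  a <- expressed_set("A", sprintf("t%03d", 1:100))
  b <- expressed_set("B", sprintf("t%03d", 71:130))
  got <- coexpression_fraction(a, b)
  expect_equal(got$intersection, 30L)
  expect_equal(got$fraction_of_a, 0.30)
  expect_equal(got$fraction_of_b, 0.50)

  ident <- coexpression_fraction(a, a)
  expect_equal(ident$fraction_of_a, 1.0)
  expect_equal(ident$fraction_of_b, 1.0)

  # membership thresholding on clean counts
  thr <- expressed_set("T", c(x = 5, y = 1, z = 3), threshold = 2)
  expect_setequal(thr$members, c("x", "z"))
})

test_that("library summary reproduces the published per-stage table arithmetic", {
  s <- summarize_libraries(helicoverpa_library_stats())
  arm <- s$totals[s$totals$species == "armigera", ]
  ass <- s$totals[s$totals$species == "assulta", ]
  expect_equal(arm$unique_clean_tags, 356842)
  expect_equal(arm$mapped_unique_tags, 268145)
  expect_equal(arm$mapping_tag_ratio, 75.14)
  expect_equal(ass$mapping_tag_ratio, 64.52)
  embryo <- s$per_stage[s$per_stage$species == "armigera" &
                          s$per_stage$stage == "embryo", ]
  expect_equal(embryo$mapping_tag_ratio, 73.35)
  # totals equal stage sums for every count column
  for (col in c("raw_reads", "clean_tags", "unique_clean_tags",
                "mapped_unique_tags", "genes_hit")) {
    for (sp in c("armigera", "assulta")) {
      expect_equal(s$totals[s$totals$species == sp, col],
                   sum(s$per_stage[s$per_stage$species == sp, col]))
    }
  }
})

test_that("summary edge cases: zero-mapped ratio, missing stage warning", {
  zero <- data.frame(species = "s", stage = c("embryo", "larva", "pupa",
                                              "adult"),
                     raw_reads = 10L, clean_tags = 8L,
                     unique_clean_tags = 4L, mapped_unique_tags = 0L,
                     genes_hit = 0L)
  sz <- summarize_libraries(zero)
  expect_true(all(sz$per_stage$mapping_tag_ratio == 0))

  expect_warning(summarize_libraries(zero[1:3, ]), "missing stage")
  expect_error(summarize_libraries(zero[, -3]), class = "dgetag_input_error")
})

test_that("round-half-up decides boundary ratio cells", {
  # 68.375 must round up to 68.38, not to even
  df <- data.frame(species = "s", stage = "embryo", raw_reads = 0L,
                   clean_tags = 0L, unique_clean_tags = 88171L,
                   mapped_unique_tags = 60287L, genes_hit = 0L)
  s <- suppressWarnings(summarize_libraries(df))  # single-stage input
  expect_equal(s$per_stage$mapping_tag_ratio, 68.38)
})
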