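test_that("tip cover isolates dead-end vertices", {
  fx <- fixture_graphs()$tip_chain
  cov <- tip_path_cover(fx$g)
  expect_length(cov$paths, 3L) # two tips + the middle vertex
  expect_true(all(lengths(lapply(cov$paths, `[[`, "v")) == 1L))

  iso <- fixture_graphs()$isolated$g
  expect_length(tip_path_cover(iso)$paths, 3L) # isolated vertices are not tips

  # no dead-ends: identical to the greedy cover
  cyc <- fixture_graphs()$cycle_component$g
  expect_identical(tip_path_cover(cyc), greedy_path_cover(cyc))
})

test_that("tip forest absorbs back-attached tips and skips the rest", {
  fx <- fixture_graphs()$tip_chain
  cov <- tip_path_cover(fx$g)
  f <- tip_forest(fx$g, cov)
  expect_lte(max(f$depth), 2L)
  # the middle vertex can prepend-absorb exactly one of its two tips: the
  # one attached at the back of its (canonical) occurrence
  expect_equal(sum(f$parent != 0L), 1L)
  expect_equal(length(f$roots), 2L)

  # two adjacent dead-ends only: nothing absorbable, both stay roots
  g2 <- esskit:::.graph_from_labels(c("GGCAT", "GCATT"), 5L)
  expect_equal(length(esskit:::.dead_end_vertices(g2)), 2L)
  cov2 <- tip_path_cover(g2)
  f2 <- tip_forest(g2, cov2)
  expect_equal(sum(f2$parent != 0L), 0L)

  # no dead-ends: every path is a root and the output equals the SPSS
  cyc <- fixture_graphs()$cycle_component$g
  cov3 <- tip_path_cover(cyc)
  f3 <- tip_forest(cyc, cov3)
  expect_equal(length(f3$roots), length(cov3$paths))
})

test_that("tip compression is lossless, marker-free and never nested", {
  set.seed(61)
  for (i in 1:10) {
    k <- sample(c(5L, 9L, 15L, 21L), 1)
    genome <- random_genome(sample(150:400, 1), seed = 600 + i)
    reads <- simulate_reads(genome, sim_config(nchar(genome), 50L, 6, 0.02, seed = i))
    K <- extract_kmers(reads, k)
    if (length(K$kmers) == 0) next
    res <- ess_tip_compress(K)
    expect_identical(decode_kmers(res), K$kmers)
    all_chars <- paste(res$strings, collapse = "")
    expect_false(grepl("[+-]", all_chars))
    for (x in res$strings) {
      ch <- strsplit(x, "")[[1]]
      depth <- cumsum((ch == "[") - (ch == "]"))
      expect_lte(max(depth), 1L)
    }
    # each absorption trades k-1 characters for 2 brackets
    n_abs <- res$num_paths - res$n_sc
    expect_equal(res$weight, res$spss_weight - (k - 3L) * n_abs)
    if (n_abs > 0 && k > 3) expect_lt(res$weight, res$spss_weight)
  }
})

test_that("graphs with zero dead-ends emit the SPSS itself", {
  cyc <- fixture_graphs()$cycle_component$g
  K <- kmer_set(cyc$labels, cyc$k)
  res <- ess_tip_compress(K)
  cov <- tip_path_cover(compact(build_dbg(K)))
  spss <- spell_cover(cov, compact(build_dbg(K)))
  expect_setequal(res$strings, spss$strings)
  expect_equal(res$weight, res$spss_weight)
})

test_that("dec_tip implements the implicit-prefix rule", {
  expect_setequal(dec_tip("AACC[G]", 3), c("AACC", "CCG"))
  expect_equal(dec_tip("AACC", 3), "AACC")
  expect_error(dec_tip("AA[C]", 3), "shorter than k|k-1 outer")
  expect_error(dec_tip("AACC[+G]", 3), "marker")
  expect_error(dec_tip("AACC[G[T]]", 3), "nested")
})

test_that("error-bearing reads give tip-heavy graphs where tip mode beats its SPSS", {
  genome <- random_genome(3000, seed = 77)
  reads <- simulate_reads(genome, sim_config(3000, 80L, 8, 0.01, seed = 77))
  K <- extract_kmers(reads, 15L)
  res <- ess_tip_compress(K)
  expect_gt(res$num_paths - res$n_sc, 0L) # some tips absorbed
  expect_lt(res$weight, res$spss_weight)
  expect_identical(decode_kmers(res), K$kmers)
})
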