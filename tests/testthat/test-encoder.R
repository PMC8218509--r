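with_fixture_result <- function(fx, mode = "ess") {
  cover <- if (is.null(fx$cover)) greedy_path_cover(fx$g) else fx$cover
  ae <- find_absorption_edges(fx$g, cover)
  da <- build_absorption_digraph(ae, cover)
  forest <- max_edge_spanning_out_forest(da)
  enc <- esskit:::.enrich_all(cover, forest, fx$g, mode = mode)
  list(cover = cover, forest = forest, strings = enc$strings, n_psi = enc$n_psi)
}

test_that("fixture encodings match the hand-derived enriched strings", {
  fx <- fixture_graphs()
  expect_equal(with_fixture_result(fx$toy_absorb)$strings, "TCGT[+AA]T")
  expect_equal(with_fixture_result(fx$multi_child)$strings, "AAACC[-A]T[+G][+A]T")
  expect_equal(with_fixture_result(fx$recursive3)$strings, "AAACCT[+GA[+T]A]T")
  expect_equal(with_fixture_result(fx$mutual_cycle)$strings, "AACCAA[+CCG]G")
})

test_that("spell_path_enrich exposes per-path enriched strings", {
  fx <- fixture_graphs()$toy_absorb
  r <- with_fixture_result(fx)
  expect_equal(spell_path_enrich(1L, r$forest, r$cover, fx$g), "TCGT[+AA]T")
  expect_equal(spell_path_enrich(2L, r$forest, r$cover, fx$g), "+AA")
})

test_that("predicted_weight evaluates the weight identity", {
  expect_equal(predicted_weight(5, 2, 1, 3), 10L) # chars of TCGT[+AA]T
  expect_equal(predicted_weight(2, 1, 1, 3), 4L) # |AACC|
  # n_sc = |cover| reduces to the SPSS weight (no-absorption limit)
  for (np in 1:5) {
    expect_equal(predicted_weight(20, np, np, 11), 20L + np * 10L)
  }
})

test_that("ess_compress on tiny sets", {
  res <- ess_compress(kmer_set(c("AAC", "ACC"), 3))
  expect_equal(res$strings, "AACC")
  expect_equal(res$num_paths, 1L)
  expect_equal(res$n_sc, 1L)
  expect_equal(res$weight, 4L)
  expect_equal(res$weight, predicted_weight(2, 1, 1, 3))
})

test_that("the weight identity holds exactly across random instances", {
  set.seed(41)
  for (i in 1:25) {
    k <- sample(c(5L, 7L, 9L, 11L, 15L, 21L, 31L), 1)
    K <- random_kmer_set(k, sample(80:300, 1), seed = 200 + i)
    if (length(K$kmers) == 0) next
    res <- ess_compress(K)
    expect_equal(res$weight, predicted_weight(res$num_kmers, res$num_paths, res$n_sc, k))
    expect_equal(sum(res$n_psi), res$weight) # per-string accounting
    expect_gte(res$weight, res$lower_bound)
    # markers in the output: one per absorbed path
    nmark <- sum(lengths(regmatches(res$strings, gregexpr("[+-]", res$strings))))
    expect_equal(nmark, res$num_paths - res$n_sc)
    # absorption saves exactly k-4 per absorbed path relative to the SPSS
    expect_equal(res$spss_weight - res$weight, (k - 4L) * (res$num_paths - res$n_sc))
    if (res$num_paths == res$n_sc) expect_equal(res$weight, res$spss_weight)
  }
})

test_that("enriched output is well-formed", {
  set.seed(42)
  for (i in 1:10) {
    K <- random_kmer_set(7, 250, seed = 300 + i)
    res <- ess_compress(K)
    for (x in res$strings) {
      ch <- strsplit(x, "")[[1]]
      depth <- cumsum((ch == "[") - (ch == "]"))
      expect_true(all(depth >= 0) && depth[length(depth)] == 0)
      # no outer marker in a root string
      expect_false(any(ch %in% c("+", "-") & depth == 0))
      # each bracket group starts with exactly one marker at its own level
      opens <- which(ch == "[")
      expect_true(all(ch[opens + 1L] %in% c("+", "-")))
    }
  }
})

test_that("compression round trips losslessly through the decoder", {
  set.seed(43)
  for (i in 1:12) {
    k <- sample(c(5L, 9L, 15L, 21L), 1)
    K <- random_kmer_set(k, sample(100:400, 1), seed = 400 + i)
    res <- ess_compress(K)
    expect_identical(decode_kmers(res), K$kmers)
  }
})
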