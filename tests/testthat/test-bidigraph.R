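test_that("orient and oriented overlaps match the side conventions", {
  expect_equal(orient("ACG", 0), "ACG")
  expect_equal(orient("ACG", 1), "CGT")
  expect_equal(orient("AAC", 1), "GTT")

  expect_true(oriented_overlap("AAC", 0, "TTG", 0, k = 3))
  expect_true(oriented_overlap("ACG", 1, "CGA", 0, k = 3))
  expect_false(oriented_overlap("AAC", 0, "TTG", 1, k = 3))

  # symmetry under swapping the two (string, side) pairs
  set.seed(21)
  for (i in 1:30) {
    x0 <- random_genome(5, seed = i)
    x1 <- random_genome(5, seed = 1000 + i)
    s0 <- sample(0:1, 1)
    s1 <- sample(0:1, 1)
    expect_equal(
      oriented_overlap(x0, s0, x1, s1, 5),
      oriented_overlap(x1, s1, x0, s0, 5)
    )
  }
})

test_that("glue concatenates minus the shared overlap", {
  expect_equal(glue("ACG", "CGT", 3), "ACGT")
  expect_equal(glue("TCGT", "GTT", 3), "TCGTT")
  expect_equal(glue("AAA", "AAA", 3), "AAAA")
  expect_error(glue("ACG", "GGT", 3), "mismatch")
})

test_that("build_dbg is overlap-closed with deduplicated pair-set edges", {
  g <- build_dbg(kmer_set(c("AAC", "ACC"), 3))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(unlist(g$edges), c(u = 1L, su = 1L, v = 2L, sv = 0L)) # {(AAC,1),(ACC,0)}

  g2 <- build_dbg(kmer_set("AAA", 3))
  expect_equal(nrow(g2$edges), 1L)
  expect_true(g2$edges$u == 1L && g2$edges$v == 1L) # loop

  g3 <- build_dbg(kmer_set(c("ACG", "GGG"), 3))
  expect_true(all(g3$edges$u == g3$edges$v)) # loops only, no edge between them

  expect_error(build_dbg(kmer_set(character(0), 3)), "empty")
})

test_that("edge sets agree with the brute-force oriented-overlap oracle", {
  for (seed in 1:8) {
    K <- random_kmer_set(5, 80, seed = seed)
    g <- build_dbg(K)
    oracle <- oracle_overlap_edges(g$labels, g$k)
    got <- g$edges
    rownames(got) <- NULL
    expect_equal(got, oracle, info = paste("seed", seed))
  }
})

test_that("dead_end_sides reports edge-free sides", {
  g <- build_dbg(kmer_set(c("AAC", "ACC"), 3))
  expect_equal(dead_end_sides(g, "AAC"), 0L)
  expect_error(dead_end_sides(g, "GGG"), "unknown vertex")

  fx <- fixture_graphs()$isolated
  for (lab in fx$g$labels) expect_equal(dead_end_sides(fx$g, lab), c(0L, 1L))

  # chain: both ends have one dead side, the middle vertex none
  tc <- fixture_graphs()$tip_chain
  n_dead_sides <- vapply(seq_along(tc$g$labels), function(v) length(dead_end_sides(tc$g, v)), 0L)
  expect_equal(sort(n_dead_sides), c(0L, 1L, 1L))
})

test_that("maximal unitigs partition the k-mers exactly once", {
  g <- build_dbg(kmer_set(c("AAC", "ACC"), 3))
  u <- maximal_unitigs(g)
  expect_length(u, 1L)
  expect_equal(spell_path(u[[1]], g), "AACC")

  # spelling a flipped path reverse-complements it
  expect_equal(spell_path(structure(list(v = rev(u[[1]]$v), o = 1L - rev(u[[1]]$o)),
    class = "oriented_path"
  ), g), "GGTT")

  for (seed in 1:10) {
    K <- random_kmer_set(7, 200, seed = 40 + seed)
    g <- build_dbg(K)
    us <- maximal_unitigs(g)
    # all vertices exactly once
    expect_equal(sort(unlist(lapply(us, `[[`, "v"))), seq_along(g$labels))
    # the canonical k-mers of the spellings are exactly the labels, no dups
    sp <- vapply(us, spell_path, "", g = g)
    km <- spss_to_kmers(sp, k = 7)
    expect_identical(km$kmers, g$labels)
  }
})

test_that("spell_path computes glued spellings with offsets", {
  fx <- fixture_graphs()$toy_absorb
  p <- fx$cover$paths[[1]]
  res <- spell_path(p, fx$g, with_offsets = TRUE)
  expect_equal(res$spell, "TCGTT")
  expect_equal(res$starts, c(1L, 2L, 3L))
  single <- oriented_path(1L, 0L)
  expect_equal(spell_path(single, fx$g), fx$g$labels[1])
})

test_that("compact produces the overlap-closed unitig graph, idempotently", {
  g <- build_dbg(kmer_set(c("AAC", "ACC"), 3))
  cg <- compact(g)
  expect_equal(cg$labels, "AACC")
  expect_true(all(cg$edges$u == cg$edges$v)) # at most loops

  # compaction of an all-isolated graph is the identity
  iso <- fixture_graphs()$isolated$g
  expect_equal(compact(iso)$labels, iso$labels)

  for (seed in 1:6) {
    K <- random_kmer_set(7, 150, seed = 60 + seed)
    cg <- compact(build_dbg(K))
    # overlap-closure oracle on the compacted labels
    expect_equal(cg$edges, oracle_overlap_edges(cg$labels, cg$k))
    # idempotence up to relabelling
    cg2 <- compact(cg)
    expect_equal(cg2$labels, sort(canonicalize(vapply(
      maximal_unitigs(cg), spell_path, "",
      g = cg
    ))))
    # k-mer content preserved
    expect_identical(spss_to_kmers(cg$labels, 7)$kmers, K$kmers)
  }
})

test_that("perfect cycle components are broken deterministically", {
  fx <- fixture_graphs()$cycle_component
  g <- fx$g
  deg <- matrix(0L, length(g$labels), 2)
  us <- maximal_unitigs(g)
  expect_length(us, 1L)
  # starts at the smallest label
  expect_equal(us[[1]]$v[1], 1L)
  expect_identical(
    spss_to_kmers(spell_path(us[[1]], g), 3)$kmers,
    g$labels
  )
  # repeated runs identical
  expect_identical(us, maximal_unitigs(g))
})
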