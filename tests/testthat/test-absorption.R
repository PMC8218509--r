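test_that("absorption edges require internal parent and outer-side child endpoint", {
  fx <- fixture_graphs()$toy_absorb
  ae <- find_absorption_edges(fx$g, fx$cover)
  expect_equal(nrow(ae), 1L)
  expect_equal(fx$g$labels[ae$parent_vertex], "ACG") # canonical of CGT
  expect_equal(fx$g$labels[ae$child_vertex], "GTA")
  expect_equal(ae$parent_path, 1L)
  expect_equal(ae$child_path, 2L)

  # every returned edge satisfies the three conditions, on random covers
  for (seed in 1:6) {
    cg <- compact(build_dbg(random_kmer_set(7, 200, seed = 130 + seed)))
    cov <- greedy_path_cover(cg)
    ci <- esskit:::.cover_index(cov, length(cg$labels))
    ae <- find_absorption_edges(cg, cov)
    if (nrow(ae) == 0) next
    expect_true(all(ae$parent_path != ae$child_path))
    pos <- ci$pos_of[ae$parent_vertex]
    expect_true(all(pos > 1L & pos < ci$len_of[ae$parent_vertex]))
    cpos <- ci$pos_of[ae$child_vertex]
    clen <- ci$len_of[ae$child_vertex]
    expect_true(all(cpos == 1L | cpos == clen))
  }
})

test_that("the absorption digraph is simple with deterministic representatives", {
  fx <- fixture_graphs()$multi_child
  ae <- find_absorption_edges(fx$g, fx$cover)
  da <- build_absorption_digraph(ae, fx$cover)
  expect_equal(nrow(da$arcs), 3L) # one arc per child
  expect_equal(da$arcs$parent_path, c(1L, 1L, 1L))
  expect_equal(sort(da$arcs$child_path), 2:4)

  # parallel absorption edges collapse to the lexicographically smallest
  fake <- data.frame(
    parent_path = c(1L, 1L), child_path = c(2L, 2L),
    parent_vertex = c(5L, 3L), child_vertex = c(7L, 7L),
    parent_side = c(0L, 1L), child_side = c(0L, 0L)
  )
  cov2 <- structure(list(paths = vector("list", 2L)), class = "path_cover")
  da2 <- build_absorption_digraph(fake, cov2)
  expect_equal(nrow(da2$arcs), 1L)
  expect_equal(da2$arcs$parent_vertex, 3L)

  # a mutual absorption pair yields a 2-cycle in the digraph
  mc <- fixture_graphs()$mutual_cycle
  dam <- build_absorption_digraph(find_absorption_edges(mc$g, mc$cover), mc$cover)
  expect_equal(nrow(dam$arcs), 2L)
  expect_setequal(paste(dam$arcs$parent_path, dam$arcs$child_path), c("1 2", "2 1"))
})

test_that("condensation counts source components", {
  d <- as_absorption_digraph(3L, rbind(c(1, 2), c(2, 1), c(1, 3)))
  cond <- condensation(d)
  expect_equal(cond$n_sc, 1L)
  expect_equal(length(unique(cond$membership)), 2L)

  expect_equal(condensation(as_absorption_digraph(3L, NULL))$n_sc, 3L)

  d3 <- as_absorption_digraph(3L, rbind(c(1, 2), c(2, 3), c(3, 1)))
  expect_equal(condensation(d3)$n_sc, 1L)
})

test_that("the selected out-forest is edge-maximal (brute-force oracle)", {
  # worked examples
  d <- as_absorption_digraph(3L, rbind(c(1, 2), c(2, 1), c(1, 3)))
  f <- max_edge_spanning_out_forest(d)
  expect_equal(length(f$roots), 1L)
  expect_equal(sum(f$parent != 0L), 2L)

  f0 <- max_edge_spanning_out_forest(as_absorption_digraph(3L, NULL))
  expect_equal(length(f0$roots), 3L)
  expect_equal(sum(f0$parent != 0L), 0L)

  f3 <- max_edge_spanning_out_forest(as_absorption_digraph(
    3L, rbind(c(1, 2), c(2, 3), c(3, 1))
  ))
  expect_equal(length(f3$roots), 1L)
  expect_equal(sum(f3$parent != 0L), 2L)

  # exhaustive over all 64 digraphs on 3 nodes
  pairs <- which(!diag(TRUE, 3), arr.ind = TRUE)
  for (mask in 0:63) {
    arcs <- pairs[bitwAnd(mask, bitwShiftL(1L, 0:5)) != 0L, , drop = FALSE]
    d <- as_absorption_digraph(3L, arcs)
    f <- max_edge_spanning_out_forest(d)
    oracle <- oracle_max_out_forest(3L, arcs)
    expect_equal(sum(f$parent != 0L), oracle$max_arcs)
    expect_equal(length(f$roots), oracle$min_roots)
    expect_equal(length(f$roots), condensation(d)$n_sc)
  }

  # random digraphs up to 8 nodes
  set.seed(31)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    dg <- random_digraph(n, p = stats::runif(1, 0.1, 0.5))
    d <- as_absorption_digraph(dg$n, dg$arcs)
    f <- max_edge_spanning_out_forest(d)
    oracle <- oracle_max_out_forest(dg$n, dg$arcs)
    expect_equal(sum(f$parent != 0L), oracle$max_arcs, info = paste("iter", i))
    expect_equal(length(f$roots), condensation(d)$n_sc)
    # structural invariants: in-degree <= 1, acyclic, arcs from D
    expect_true(all(tabulate(f$parent[f$parent != 0L], n) <= n)) # parent map
    for (v in seq_len(n)) {
      seen <- integer(0)
      u <- v
      while (f$parent[u] != 0L) {
        expect_false(u %in% seen)
        seen <- c(seen, u)
        u <- f$parent[u]
      }
    }
    if (nrow(d$arcs) > 0) {
      have <- paste(d$arcs$parent_path, d$arcs$child_path)
      used <- paste(f$parent[f$parent != 0L], which(f$parent != 0L))
      expect_true(all(used %in% have))
    }
  }
})

test_that("n_sc is at least the component count of the compacted graph", {
  for (seed in 1:8) {
    K <- random_kmer_set(7, 150, seed = 150 + seed)
    cg <- compact(build_dbg(K))
    cov <- greedy_path_cover(cg)
    da <- build_absorption_digraph(find_absorption_edges(cg, cov), cov)
    f <- max_edge_spanning_out_forest(da)
    expect_gte(f$n_sc, cover_lower_bound(cg)$C)
  }
})
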