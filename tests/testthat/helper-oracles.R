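# Independent brute-force oracles used across the test files. These stay
# deliberately naive: exhaustive enumeration over all pairs / subsets /
# parent assignments, so they share no code path with the implementation
# they check.

# All edges of the overlap-closed bidirected graph over `labels`, found by
# testing every ordered pair of vertices and every side combination with
# oriented_overlap(), then normalizing to unordered pair-sets.
oracle_overlap_edges <- function(labels, k) {
  n <- length(labels)
  rows <- list()
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      for (su in 0:1) {
        for (sv in 0:1) {
          if (oriented_overlap(labels[u], su, labels[v], sv, k)) {
            if (u > v || (u == v && su > sv)) {
              rows[[length(rows) + 1L]] <- c(v, sv, u, su)
            } else {
              rows[[length(rows) + 1L]] <- c(u, su, v, sv)
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(u = integer(0), su = integer(0), v = integer(0), sv = integer(0)))
  }
  m <- unique(do.call(rbind, rows))
  out <- data.frame(u = m[, 1], su = m[, 2], v = m[, 3], sv = m[, 4])
  out <- out[order(out$u, out$v, out$su, out$sv), ]
  rownames(out) <- NULL
  out
}

# Maximum number of arcs over all spanning out-forests of a digraph given
# as an n and a two-column matrix of arcs (from, to). Enumerates every
# assignment of (parent | none) per node from its in-neighbours and keeps
# the acyclic ones. Also returns the minimum number of roots.
oracle_max_out_forest <- function(n, arcs) {
  in_nbrs <- lapply(seq_len(n), function(v) {
    if (length(arcs) == 0L) integer(0) else unique(arcs[arcs[, 2] == v, 1])
  })
  choices <- lapply(in_nbrs, function(x) c(0L, x)) # 0 = root
  best <- -1L
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    parent <- as.integer(grid[r, ])
    # acyclicity: follow parents from each node
    ok <- TRUE
    for (v in seq_len(n)) {
      seen <- integer(0)
      u <- v
      while (parent[u] != 0L) {
        if (u %in% seen) {
          ok <- FALSE
          break
        }
        seen <- c(seen, u)
        u <- parent[u]
      }
      if (!ok) break
    }
    if (ok) best <- max(best, sum(parent != 0L))
  }
  list(max_arcs = best, min_roots = n - best)
}

# Minimum number of paths over all vertex-disjoint path covers of a
# bidigraph: a cover corresponds to a set of non-loop edges with at most
# one selected edge per (vertex, side) slot and no cycles; the number of
# paths is then n - |selection|. Exhaustive over edge subsets.
oracle_min_path_cover <- function(g) {
  n <- length(g$labels)
  e <- g$edges
  e <- e[e$u != e$v, , drop = FALSE]
  m <- nrow(e)
  stopifnot(m <= 16L)
  best <- 0L
  for (mask in 0:(2^m - 1L)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    if (length(sel) <= best) next
    slots <- c(
      paste(e$u[sel], e$su[sel]),
      paste(e$v[sel], e$sv[sel])
    )
    if (anyDuplicated(slots)) next
    # acyclic: selected edges form simple chains over vertices
    uf <- seq_len(n)
    find <- function(x) {
      while (uf[x] != x) x <- uf[x]
      x
    }
    ok <- TRUE
    for (i in sel) {
      ru <- find(e$u[i])
      rv <- find(e$v[i])
      if (ru == rv) {
        ok <- FALSE
        break
      }
      uf[ru] <- rv
    }
    if (ok) best <- max(best, length(sel))
  }
  n - best
}

# Random small canonical k-mer set drawn from a short random genome, so
# the graphs have branches, tips and repeats.
random_kmer_set <- function(k, genome_len = 120L, seed = 1L) {
  extract_kmers(random_genome(genome_len, seed = seed), k = k)
}

# Random small digraph without self-arcs, as (n, arcs matrix).
random_digraph <- function(n, p = 0.3) {
  arcs <- which(matrix(stats::runif(n * n) < p, n, n) &
    !diag(TRUE, n), arr.ind = TRUE)
  list(n = n, arcs = unname(arcs))
}

# Wrap (n, arcs) as a minimal absorption_digraph for the forest functions.
as_absorption_digraph <- function(n, arcs) {
  if (length(arcs) == 0L || nrow(arcs) == 0L) {
    arcs_df <- data.frame(
      parent_path = integer(0), child_path = integer(0),
      parent_vertex = integer(0), child_vertex = integer(0),
      parent_side = integer(0), child_side = integer(0)
    )
  } else {
    arcs_df <- data.frame(
      parent_path = arcs[, 1], child_path = arcs[, 2],
      parent_vertex = 0L, child_vertex = 0L,
      parent_side = 0L, child_side = 0L
    )
    arcs_df <- unique(arcs_df)
    arcs_df <- arcs_df[order(arcs_df$parent_path, arcs_df$child_path), ]
  }
  structure(list(n = n, arcs = arcs_df), class = "absorption_digraph")
}

# Round trip helper: compress result -> decode -> canonical k-mer vector.
decode_kmers <- function(res) {
  spss <- decompress(list(strings = res$strings, k = res$k, mode = res$mode))
  spss_to_kmers(spss)$kmers
}
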