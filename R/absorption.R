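# Absorption edges, the absorption digraph D over cover paths, its
# strongly-connected-component condensation, and the edge-maximizing
# spanning out-forest that guides the recursive encoder.

# Per-cover lookup tables: path id, position within path, path length,
# orientation, for every vertex.
.cover_index <- function(cover, n_vertices) {
  path_of <- integer(n_vertices)
  pos_of <- integer(n_vertices)
  o_of <- integer(n_vertices)
  len_of <- integer(n_vertices)
  for (i in seq_along(cover$paths)) {
    p <- cover$paths[[i]]
    path_of[p$v] <- i
    pos_of[p$v] <- seq_along(p$v)
    o_of[p$v] <- p$o
    len_of[p$v] <- length(p$v)
  }
  if (any(path_of == 0L)) stop("cover does not cover every vertex", call. = FALSE)
  list(path_of = path_of, pos_of = pos_of, o_of = o_of, len_of = len_of)
}

#' Find absorption edges of a path cover
#'
#' An edge of the compacted graph is an absorption edge when (1) its
#' endpoints lie on two distinct cover paths, (2) the parent endpoint is
#' an internal vertex of its path, and (3) the child endpoint is an
#' endpoint vertex of its path reachable as the path's first vertex after
#' an allowed flip, with the edge attached at the child occurrence's outer
#' (free) side. Edges attaching at a child endpoint's inner side are
#' excluded: the shared (k-1)-mer would lie interior to the child
#' spelling and could not be removed.
#'
#' @param cdbg A `bidigraph`.
#' @param cover A `path_cover` of `cdbg`.
#' @return Data frame with one row per absorption edge (both directions of
#'   an edge may qualify independently): columns `parent_path`,
#'   `child_path`, `parent_vertex`, `child_vertex`, `parent_side`,
#'   `child_side`, in deterministic order.
#' @export
find_absorption_edges <- function(cdbg, cover) {
  ci <- .cover_index(cover, length(cdbg$labels))
  e <- cdbg$edges
  empty <- data.frame(
    parent_path = integer(0), child_path = integer(0),
    parent_vertex = integer(0), child_vertex = integer(0),
    parent_side = integer(0), child_side = integer(0)
  )
  if (nrow(e) == 0L) return(empty)
  e <- e[e$u != e$v, , drop = FALSE] # loops never absorb
  if (nrow(e) == 0L) return(empty)
  # both ordered directions of every edge are candidates
  cand <- rbind(
    data.frame(pv = e$u, sp = e$su, cv = e$v, sc = e$sv),
    data.frame(pv = e$v, sp = e$sv, cv = e$u, sc = e$su)
  )
  pp <- ci$path_of[cand$pv]
  cp <- ci$path_of[cand$cv]
  parent_internal <- ci$pos_of[cand$pv] > 1L & ci$pos_of[cand$pv] < ci$len_of[cand$pv]
  cpos <- ci$pos_of[cand$cv]
  clen <- ci$len_of[cand$cv]
  child_outer <- (clen == 1L) |
    (cpos == 1L & cand$sc == ci$o_of[cand$cv]) |
    (cpos == clen & cand$sc == 1L - ci$o_of[cand$cv])
  keep <- pp != cp & parent_internal & child_outer
  out <- data.frame(
    parent_path = pp[keep], child_path = cp[keep],
    parent_vertex = cand$pv[keep], child_vertex = cand$cv[keep],
    parent_side = cand$sp[keep], child_side = cand$sc[keep]
  )
  out <- out[order(
    out$parent_path, out$child_path,
    out$parent_vertex, out$child_vertex, out$parent_side, out$child_side
  ), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the absorption digraph
#'
#' Nodes are the cover's path ids; there is one arc parent -> child per
#' ordered pair of paths joined by at least one absorption edge. When
#' several absorption edges join the same pair, the representative with
#' the lexicographically smallest (parent_vertex, child_vertex, sides) is
#' kept, making the digraph simple and deterministic.
#'
#' @param edges Data frame from [find_absorption_edges()].
#' @param cover The `path_cover` the edges refer to.
#' @return An `absorption_digraph`: list with `n` (number of paths) and
#'   `arcs` (data frame with the same columns as `edges`).
#' @export
build_absorption_digraph <- function(edges, cover) {
  n <- length(cover$paths)
  if (nrow(edges) > 0L) {
    ord <- order(
      edges$parent_path, edges$child_path,
      edges$parent_vertex, edges$child_vertex, edges$parent_side, edges$child_side
    )
    edges <- edges[ord, , drop = FALSE]
    first <- !duplicated(edges[, c("parent_path", "child_path")])
    edges <- edges[first, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(n = n, arcs = edges), class = "absorption_digraph")
}

#' @export
print.absorption_digraph <- function(x, ...) {
  cat("Absorption digraph: ", x$n, " paths, ", nrow(x$arcs), " arcs\n", sep = "")
  invisible(x)
}

#' Strongly connected components and source count
#'
#' Condenses a digraph into its strongly connected components and counts
#' the components with in-degree zero in the condensation (the sources).
#'
#' @param d An `absorption_digraph`, or a list with `n` and an `arcs` data
#'   frame having `parent_path`/`child_path` (or `from`/`to`) columns.
#' @return List with `membership` (integer vector, components numbered by
#'   their smallest member) and `n_sc` (number of source components).
#' @export
condensation <- function(d) {
  arcs <- d$arcs
  from <- if ("parent_path" %in% names(arcs)) arcs$parent_path else arcs$from
  to <- if ("child_path" %in% names(arcs)) arcs$child_path else arcs$to
  ig <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = TRUE,
    vertices = data.frame(name = seq_len(d$n))
  )
  mem <- igraph::components(ig, mode = "strong")$membership[as.character(seq_len(d$n))]
  # renumber components by smallest member for determinism
  smallest <- tapply(seq_len(d$n), mem, min)
  new_id <- rank(smallest) # old comp id -> rank of its smallest member
  mem <- as.integer(new_id[as.character(mem)])
  ncomp <- max(mem)
  has_in <- rep(FALSE, ncomp)
  if (length(from) > 0L) {
    cross <- mem[from] != mem[to]
    has_in[unique(mem[to][cross])] <- TRUE
  }
  list(membership = mem, n_sc = as.integer(sum(!has_in)))
}

#' Edge-maximizing spanning out-forest
#'
#' Selects a spanning out-forest of the absorption digraph with the
#' maximum possible number of arcs: one representative node ("starter",
#' the smallest id) is taken from each source component of the SCC
#' condensation, and a depth-first search is grown from the starters (in
#' ascending order, neighbours visited in ascending child id). The
#' resulting forest has exactly `n_sc` roots and `n - n_sc` arcs, the
#' maximum for any spanning out-forest.
#'
#' @param d An `absorption_digraph`.
#' @return An `out_forest`: list with `parent` (integer vector, 0 for
#'   roots), `arc` (list indexed by child node: the representative
#'   absorption-edge row, or `NULL`), `roots`, `n_sc`, and `depth`
#'   (1 for roots).
#' @export
max_edge_spanning_out_forest <- function(d) {
  n <- d$n
  cond <- condensation(d)
  mem <- cond$membership
  has_in <- rep(FALSE, max(mem))
  if (nrow(d$arcs) > 0L) {
    cross <- mem[d$arcs$parent_path] != mem[d$arcs$child_path]
    has_in[unique(mem[d$arcs$child_path][cross])] <- TRUE
  }
  # starter: smallest node of each source component
  starters <- sort(vapply(
    which(!has_in),
    function(cmp) min(which(mem == cmp)), 0L
  ))

  adj <- vector("list", n)
  arc_row <- vector("list", n) # by child: row index of incoming forest arc
  if (nrow(d$arcs) > 0L) {
    sp <- split(seq_len(nrow(d$arcs)), d$arcs$parent_path)
    for (nm in names(sp)) {
      rows <- sp[[nm]]
      adj[[as.integer(nm)]] <- rows[order(d$arcs$child_path[rows])]
    }
  }

  parent <- integer(n)
  depth <- integer(n)
  visited <- logical(n)
  for (s in starters) {
    if (visited[s]) next
    visited[s] <- TRUE
    depth[s] <- 1L
    # iterative depth-first search, neighbours in ascending child id
    frame_node <- integer(n)
    frame_ptr <- integer(n)
    top <- 1L
    frame_node[1L] <- s
    frame_ptr[1L] <- 1L
    while (top > 0L) {
      u <- frame_node[top]
      rows <- adj[[u]]
      advanced <- FALSE
      while (frame_ptr[top] <= length(rows)) {
        r <- rows[frame_ptr[top]]
        frame_ptr[top] <- frame_ptr[top] + 1L
        ch <- d$arcs$child_path[r]
        if (!visited[ch]) {
          visited[ch] <- TRUE
          parent[ch] <- u
          arc_row[[ch]] <- r
          depth[ch] <- depth[u] + 1L
          top <- top + 1L
          frame_node[top] <- ch
          frame_ptr[top] <- 1L
          advanced <- TRUE
          break
        }
      }
      if (!advanced) top <- top - 1L
    }
  }
  if (!all(visited)) {
    stop("internal error: starter set does not reach every path", call. = FALSE)
  }
  roots <- which(parent == 0L)
  structure(
    list(
      parent = parent,
      arc = lapply(arc_row, function(r) if (is.null(r)) NULL else d$arcs[r, , drop = FALSE]),
      roots = roots,
      n_sc = cond$n_sc,
      depth = depth
    ),
    class = "out_forest"
  )
}

#' @export
print.out_forest <- function(x, ...) {
  cat("Out-forest: ", length(x$parent), " nodes, ", length(x$roots),
    " roots, max depth ", max(x$depth), "\n",
    sep = ""
  )
  invisible(x)
}

#' Dump the absorption digraph and a forest as DOT
#'
#' @param d An `absorption_digraph`.
#' @param forest Optional `out_forest`; its arcs are drawn bold.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(d, forest = NULL, path) {
  lines <- c("digraph absorption {", sprintf("  p%d;", seq_len(d$n)))
  if (nrow(d$arcs) > 0L) {
    in_forest <- rep(FALSE, nrow(d$arcs))
    if (!is.null(forest)) {
      for (ch in seq_along(forest$parent)) {
        if (forest$parent[ch] != 0L) {
          hit <- d$arcs$parent_path == forest$parent[ch] & d$arcs$child_path == ch
          in_forest[hit] <- TRUE
        }
      }
    }
    lines <- c(lines, sprintf(
      "  p%d -> p%d%s;",
      d$arcs$parent_path, d$arcs$child_path,
      ifelse(in_forest, " [style=bold]", "")
    ))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
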