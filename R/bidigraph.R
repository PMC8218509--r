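# Bidirected DNA graphs.
#
# A vertex is a DNA string (its label) with two attachment sides. Side
# convention used throughout: side 0 is the *front* of the forward label
# (its prefix end), side 1 is the *back* (its suffix end); under reverse
# complement the mapping flips. An edge is an unordered set of two
# (vertex, side) pairs {(u,su),(v,sv)} and exists when the labels have an
# (su,sv)-oriented overlap of length k-1. In an oriented occurrence
# orient(lab(u), o) of a vertex along a path, the incoming side is o and
# the outgoing side is 1-o, so consecutive path steps (u,ou) -> (v,ov) use
# the edge {(u, 1-ou), (v, ov)}.

#' Orient a DNA string
#'
#' Identity for `s = 0`, reverse complement for `s = 1`.
#'
#' @param x Character vector of DNA strings.
#' @param s Orientation flag, 0 or 1 (recycled).
#' @return Character vector of oriented strings.
#' @export
orient <- function(x, s) {
  .check_dna(x)
  if (!all(s %in% c(0L, 1L))) stop("orientation flag must be 0 or 1", call. = FALSE)
  out <- x
  flip <- rep_len(as.integer(s), length(x)) == 1L
  if (any(flip)) out[flip] <- .rc(x[flip])
  out
}

# Exit (k-1)-mer of a label through side s: the last k-1 characters of
# orient(x, 1-s). Its reverse complement is the entry mer pre(orient(x, s)).
.side_mer <- function(x, s, k) {
  n <- nchar(x)
  ifelse(rep_len(s, length(x)) == 1L,
    substring(x, n - k + 2L, n),
    .rc(substring(x, 1L, k - 1L))
  )
}

#' Test for an oriented overlap between two strings
#'
#' `x0` and `x1` have an (s0,s1)-oriented overlap when the last k-1
#' characters of `orient(x0, 1-s0)` equal the first k-1 characters of
#' `orient(x1, s1)`, i.e. the two strings can be oriented to be glueable.
#' Symmetric under swapping the two (string, side) pairs.
#'
#' @param x0,x1 DNA strings of length >= k-1.
#' @param s0,s1 Side flags in \{0, 1\}.
#' @param k K-mer length (overlap length is k-1).
#' @return Logical.
#' @examples
#' oriented_overlap("AAC", 0, "TTG", 0, k = 3) # TRUE
#' @export
oriented_overlap <- function(x0, s0, x1, s1, k) {
  suf <- substring(orient(x0, 1L - as.integer(s0)), nchar(x0) - k + 2L, nchar(x0))
  pre <- substring(orient(x1, as.integer(s1)), 1L, k - 1L)
  suf == pre
}

#' Glue two overlapping strings
#'
#' Concatenates `x` and `y` after dropping `y`'s first k-1 characters;
#' requires the last k-1 characters of `x` to equal the first k-1 of `y`.
#'
#' @param x,y DNA strings.
#' @param k K-mer length.
#' @return The glued string of length `nchar(x) + nchar(y) - (k-1)`.
#' @examples
#' glue("ACG", "CGT", 3) # "ACGT"
#' @export
glue <- function(x, y, k) {
  if (substring(x, nchar(x) - k + 2L, nchar(x)) != substring(y, 1L, k - 1L)) {
    stop("glue: overlap mismatch between '", x, "' and '", y, "'", call. = FALSE)
  }
  paste0(x, substring(y, k))
}

# Overlap-closed edge set for a label vector: every (su,sv)-oriented
# overlap of length k-1 between two labels (including a label with itself)
# yields exactly one edge, stored as a canonically ordered unordered pair.
.build_edges <- function(labels, k) {
  n <- length(labels)
  vid <- rep(seq_len(n), 2L)
  side <- rep(c(0L, 1L), each = n)
  m <- c(.side_mer(labels, 0L, k), .side_mer(labels, 1L, k))
  rcm <- .rc(m)
  cm <- ifelse(m <= rcm, m, rcm)
  is_pal <- m == rcm
  fwd <- m == cm & !is_pal
  rev <- m != cm

  ef <- data.frame(cm = cm[fwd], u = vid[fwd], su = side[fwd], stringsAsFactors = FALSE)
  er <- data.frame(cm = cm[rev], v = vid[rev], sv = side[rev], stringsAsFactors = FALSE)
  cross <- merge(ef, er, by = "cm")
  edges <- cross[, c("u", "su", "v", "sv")]

  if (any(is_pal)) {
    idx <- which(is_pal)
    ep <- data.frame(cm = cm[idx], id = idx, stringsAsFactors = FALSE)
    pp <- merge(ep, ep, by = "cm")
    pp <- pp[pp$id.x <= pp$id.y, , drop = FALSE]
    pal_edges <- data.frame(
      u = vid[pp$id.x], su = side[pp$id.x],
      v = vid[pp$id.y], sv = side[pp$id.y]
    )
    edges <- rbind(edges, pal_edges)
  }

  if (nrow(edges) > 0L) {
    swap <- edges$u > edges$v | (edges$u == edges$v & edges$su > edges$sv)
    edges[swap, c("u", "su", "v", "sv")] <- edges[swap, c("v", "sv", "u", "su")]
    edges <- unique(edges)
    edges <- edges[order(edges$u, edges$v, edges$su, edges$sv), , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges
}

.new_bidigraph <- function(labels, edges, k) {
  structure(
    list(labels = labels, labels_rc = .rc(labels), edges = edges, k = k),
    class = "bidigraph"
  )
}

#' Build the bidirected de Bruijn graph of a k-mer set
#'
#' One two-sided vertex per canonical k-mer, with an edge for every
#' oriented overlap of length k-1 between labels (overlap-closed), loops
#' included. Vertex identifiers are the canonical labels themselves, held
#' in sorted order, so the construction is fully deterministic.
#'
#' @param K A [kmer_set].
#' @return A `bidigraph` object with elements `labels` (sorted character
#'   vector), `edges` (data frame with columns `u`, `su`, `v`, `sv`;
#'   `u`/`v` index into `labels`), and `k`.
#' @export
build_dbg <- function(K) {
  stopifnot(inherits(K, "kmer_set"))
  if (length(K$kmers) == 0L) stop("cannot build a graph from an empty k-mer set", call. = FALSE)
  labels <- sort(K$kmers)
  .new_bidigraph(labels, .build_edges(labels, K$k), K$k)
}

#' @export
print.bidigraph <- function(x, ...) {
  cat("Bidirected DNA graph: ", length(x$labels), " vertices, ",
    nrow(x$edges), " edges, k = ", x$k, "\n",
    sep = ""
  )
  invisible(x)
}

# number of distinct edges incident to each (vertex, side); n x 2 matrix
.side_degree <- function(g) {
  n <- length(g$labels)
  deg <- matrix(0L, nrow = n, ncol = 2L)
  e <- g$edges
  if (nrow(e) > 0L) {
    # a loop {(u,s),(u,s)} is one edge, incident once to its side
    self_loop <- e$u == e$v & e$su == e$sv
    idx <- c(
      2L * (e$u - 1L) + e$su + 1L,
      2L * (e$v[!self_loop] - 1L) + e$sv[!self_loop] + 1L
    )
    deg <- matrix(tabulate(idx, nbins = 2L * n), ncol = 2L, byrow = TRUE)
  }
  deg
}

.vertex_index <- function(g, v) {
  if (is.character(v)) {
    i <- match(v, g$labels)
    if (anyNA(i)) stop("unknown vertex label: ", v[which(is.na(i))[1L]], call. = FALSE)
    i
  } else {
    i <- as.integer(v)
    if (any(i < 1L | i > length(g$labels))) stop("vertex index out of range", call. = FALSE)
    i
  }
}

#' Sides of a vertex with no incident edges
#'
#' A vertex is a dead-end (a tip) when exactly one side is returned;
#' isolated vertices return both sides.
#'
#' @param g A `bidigraph`.
#' @param v Vertex label (character) or index.
#' @return Integer vector (subset of `c(0, 1)`) of edge-free sides.
#' @export
dead_end_sides <- function(g, v) {
  i <- .vertex_index(g, v)
  deg <- .side_degree(g)
  c(0L, 1L)[deg[i, ] == 0L]
}

#' Construct an oriented path
#'
#' @param v Integer vector of vertex indices (or character labels resolved
#'   against `g` when given).
#' @param o Integer vector of orientation flags (0 forward, 1 reverse
#'   complement), same length as `v`.
#' @param g Optional `bidigraph` used to resolve labels and validate.
#' @return An `oriented_path` object: list with integer vectors `v`, `o`.
#' @export
oriented_path <- function(v, o, g = NULL) {
  if (!is.null(g)) v <- .vertex_index(g, v)
  p <- structure(list(v = as.integer(v), o = as.integer(o)), class = "oriented_path")
  if (length(p$v) != length(p$o) || length(p$v) == 0L) {
    stop("path needs equal-length, non-empty v and o", call. = FALSE)
  }
  if (anyDuplicated(p$v)) stop("path revisits a vertex", call. = FALSE)
  if (!all(p$o %in% c(0L, 1L))) stop("orientations must be 0/1", call. = FALSE)
  if (!is.null(g)) .validate_path(p, g)
  p
}

.edge_key <- function(u, su, v, sv) {
  swap <- u > v | (u == v & su > sv)
  paste(ifelse(swap, v, u), ifelse(swap, sv, su), ifelse(swap, u, v), ifelse(swap, su, sv))
}

.validate_path <- function(p, g) {
  n <- length(p$v)
  if (n == 1L) return(invisible(TRUE))
  have <- .edge_key(g$edges$u, g$edges$su, g$edges$v, g$edges$sv)
  need <- .edge_key(p$v[-n], 1L - p$o[-n], p$v[-1L], p$o[-1L])
  if (!all(need %in% have)) stop("path uses a non-existent edge", call. = FALSE)
  invisible(TRUE)
}

# flip an oriented path end-to-end (spelling becomes its reverse complement)
.flip_path <- function(p) {
  structure(list(v = rev(p$v), o = 1L - rev(p$o)), class = "oriented_path")
}

#' Spell an oriented path
#'
#' Glues the oriented occurrences `orient(lab(v_i), o_i)` left to right;
#' consecutive occurrences overlap by exactly k-1 characters. Flipping a
#' path reverse-complements its spelling.
#'
#' @param p An `oriented_path`.
#' @param g The `bidigraph` it lives in.
#' @param with_offsets If `TRUE`, also return the 1-based start position of
#'   each step's occurrence within the spelling.
#' @return The spelled string, or (with offsets) a list `(spell, starts)`.
#' @export
spell_path <- function(p, g, with_offsets = FALSE) {
  rc <- if (is.null(g$labels_rc)) .rc(g$labels) else g$labels_rc
  occ <- ifelse(p$o == 1L, rc[p$v], g$labels[p$v])
  k <- g$k
  n <- length(occ)
  if (n > 1L) {
    suf <- substring(occ[-n], nchar(occ[-n]) - k + 2L, nchar(occ[-n]))
    pre <- substring(occ[-1L], 1L, k - 1L)
    if (!all(suf == pre)) stop("invalid path: consecutive occurrences do not overlap", call. = FALSE)
  }
  s <- if (n == 1L) occ else paste0(occ[1L], paste(substring(occ[-1L], k), collapse = ""))
  if (!with_offsets) return(s)
  starts <- cumsum(c(1L, nchar(occ)[-n] - (k - 1L)))
  list(spell = s, starts = starts)
}

#' Maximal unitigs of a bidirected DNA graph
#'
#' Decomposes the vertex set into the unique set of maximal non-branching
#' oriented paths. Extension through a side requires that side (and the
#' partner side it connects to) carry exactly one edge; loops never
#' participate. A connected component that is a perfect cycle is broken at
#' its vertex with the lexicographically smallest label. Paths are
#' flip-normalized so the smaller of (first label, last label) comes first.
#'
#' @param g An overlap-closed `bidigraph`.
#' @return List of `oriented_path` objects covering every vertex exactly once.
#' @export
maximal_unitigs <- function(g) {
  n <- length(g$labels)
  deg <- .side_degree(g)
  # link arrays indexed by slot 2*(v-1)+s+1: the unique continuation, if any
  link_v <- integer(2L * n)
  link_s <- integer(2L * n)
  e <- g$edges
  if (nrow(e) > 0L) {
    ok <- e$u != e$v &
      deg[cbind(e$u, e$su + 1L)] == 1L &
      deg[cbind(e$v, e$sv + 1L)] == 1L
    eo <- e[ok, , drop = FALSE]
    link_v[2L * (eo$u - 1L) + eo$su + 1L] <- eo$v
    link_s[2L * (eo$u - 1L) + eo$su + 1L] <- eo$sv
    link_v[2L * (eo$v - 1L) + eo$sv + 1L] <- eo$u
    link_s[2L * (eo$v - 1L) + eo$sv + 1L] <- eo$su
  }

  visited <- logical(n)
  paths <- vector("list", n)
  np <- 0L

  # follow links from (start, o_start) until the chain ends (chains) or
  # wraps around to the start (perfect cycles); marks visited in bulk
  walk <- function(start, o_start) {
    vs <- integer(64L)
    os <- integer(64L)
    len <- 0L
    u <- start
    o <- o_start
    repeat {
      len <- len + 1L
      if (len > length(vs)) {
        vs <- c(vs, integer(length(vs)))
        os <- c(os, integer(length(os)))
      }
      vs[len] <- u
      os[len] <- o
      slot <- 2L * (u - 1L) + (1L - o) + 1L # exit through back side 1-o
      nxt <- link_v[slot]
      if (nxt == 0L || nxt == start) break
      u <- nxt
      o <- link_s[slot] # entry side of nxt becomes the front of its occurrence
    }
    list(v = vs[seq_len(len)], o = os[seq_len(len)])
  }

  # chain starts: vertices with at least one unlinked side
  starts <- which(link_v[2L * (seq_len(n) - 1L) + 1L] == 0L |
    link_v[2L * (seq_len(n) - 1L) + 2L] == 0L)
  for (u in starts) {
    if (visited[u]) next
    s0_linked <- link_v[2L * (u - 1L) + 1L] != 0L
    # free side becomes the front of the first occurrence
    o <- if (s0_linked) 1L else 0L
    p <- walk(u, o)
    visited[p$v] <- TRUE
    np <- np + 1L
    paths[[np]] <- structure(p, class = "oriented_path")
  }
  # remaining vertices lie on perfect cycles; break at smallest label
  remaining <- which(!visited)
  for (u in remaining) {
    if (visited[u]) next # labels are sorted: first unvisited = smallest label
    p <- walk(u, 0L)
    visited[p$v] <- TRUE
    np <- np + 1L
    paths[[np]] <- structure(p, class = "oriented_path")
  }
  paths <- paths[seq_len(np)]
  # flip-normalize
  lapply(paths, function(p) {
    if (g$labels[p$v[length(p$v)]] < g$labels[p$v[1L]]) .flip_path(p) else p
  })
}

#' Compact a bidirected de Bruijn graph
#'
#' Builds the compacted graph whose vertices are the maximal unitigs of
#' `g`, labelled by the canonical form of their spellings, overlap-closed
#' over the new labels. Idempotent up to relabelling.
#'
#' @param g An overlap-closed `bidigraph`.
#' @return A `bidigraph` over the unitig spellings (same `k`).
#' @export
compact <- function(g) {
  unitigs <- maximal_unitigs(g)
  spells <- vapply(unitigs, spell_path, "", g = g)
  labels <- sort(canonicalize(spells))
  if (anyDuplicated(labels)) stop("internal error: duplicate unitig spellings", call. = FALSE)
  .new_bidigraph(labels, .build_edges(labels, g$k), g$k)
}

#' Export a bidirected graph as GFA1
#'
#' Debug-oriented export: segments are the vertex labels, links carry
#' +/- orientations with a `(k-1)M` overlap.
#'
#' @param g A `bidigraph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(g, path) {
  lines <- c(
    "H\tVN:Z:1.0",
    sprintf("S\t%d\t%s", seq_along(g$labels), g$labels)
  )
  e <- g$edges
  if (nrow(e) > 0L) {
    # edge {(u,su),(v,sv)}: traverse u oriented 1-su, then v oriented sv
    from_o <- ifelse(1L - e$su == 0L, "+", "-")
    to_o <- ifelse(e$sv == 0L, "+", "-")
    lines <- c(lines, sprintf(
      "L\t%d\t%s\t%d\t%s\t%dM",
      e$u, from_o, e$v, to_o, g$k - 1L
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
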