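# Vertex-disjoint normalized path covers of the compacted graph, their
# induced string sets, and instance-specific lower bounds.

#' Total character count of a string set
#'
#' @param strings Character vector.
#' @return Sum of string lengths (0 for an empty set).
#' @examples
#' weight(c("ACGT", "CGA")) # 7
#' @export
weight <- function(strings) {
  if (length(strings) == 0L) return(0L)
  sum(nchar(strings))
}

.new_path_cover <- function(paths) {
  structure(list(paths = paths), class = "path_cover")
}

#' @export
print.path_cover <- function(x, ...) {
  cat("Path cover: ", length(x$paths), " paths over ",
    sum(vapply(x$paths, function(p) length(p$v), 0L)), " vertices\n",
    sep = ""
  )
  invisible(x)
}

# Free outer sides of a path's two endpoints: the front side of the first
# occurrence and the back side of the last. A singleton exposes both sides.
.endpoint_sides <- function(p) {
  n <- length(p$v)
  list(
    first = c(v = p$v[1L], s = p$o[1L]),
    last = c(v = p$v[n], s = 1L - p$o[n])
  )
}

# normalize so the smaller of (first label, last label) comes first
.normalize_path <- function(p, g) {
  n <- length(p$v)
  if (g$labels[p$v[n]] < g$labels[p$v[1L]]) .flip_path(p) else p
}

#' Greedy vertex-disjoint path cover
#'
#' Starts from singleton paths and iterates the graph's edges in
#' lexicographic order of (smaller endpoint label, larger endpoint label,
#' side pair), merging the two paths at an edge whenever the edge joins
#' currently-free outer endpoint sides of two distinct paths, flipping one
#' path as needed. Loops are skipped and a union-find on path membership
#' prevents cycles. The result is deterministic for a given graph.
#'
#' @param cdbg An overlap-closed `bidigraph` (typically from [compact()]).
#' @return A `path_cover`: list of `oriented_path`s, flip-normalized, in
#'   which every vertex appears exactly once.
#' @export
greedy_path_cover <- function(cdbg) {
  n <- length(cdbg$labels)
  e <- cdbg$edges
  # sort edges by label pair then side pair (u,v are label-sorted indices)
  if (nrow(e) > 0L) {
    e <- e[order(e$u, e$v, e$su, e$sv), , drop = FALSE]
  }
  path_of <- seq_len(n) # vertex -> path id (paths named by a representative)
  paths <- lapply(seq_len(n), function(i) {
    structure(list(v = i, o = 0L), class = "oriented_path")
  })
  # free[v, s+1]: is side s of vertex v a free outer endpoint side?
  free <- matrix(TRUE, nrow = n, ncol = 2L)

  for (i in seq_len(nrow(e))) {
    u <- e$u[i]; su <- e$su[i]; v <- e$v[i]; sv <- e$sv[i]
    if (u == v) next # loops cannot extend a path
    pu <- path_of[u]; pv <- path_of[v]
    if (pu == pv) next
    if (!free[u, su + 1L] || !free[v, sv + 1L]) next
    a <- paths[[pu]]; b <- paths[[pv]]
    na <- length(a$v); nb <- length(b$v)
    # arrange a so that u is last and its back side is su (=> o_last = 1-su)
    if (a$v[na] != u || (1L - a$o[na]) != su) a <- .flip_path(a)
    na <- length(a$v)
    if (a$v[na] != u || (1L - a$o[na]) != su) next # edge side not an outer side
    # arrange b so that v is first and its front side is sv (=> o_first = sv)
    if (b$v[1L] != v || b$o[1L] != sv) b <- .flip_path(b)
    if (b$v[1L] != v || b$o[1L] != sv) next
    merged <- structure(list(v = c(a$v, b$v), o = c(a$o, b$o)), class = "oriented_path")
    paths[[pu]] <- merged
    paths[pv] <- list(NULL)
    path_of[b$v] <- pu
    free[u, su + 1L] <- FALSE
    free[v, sv + 1L] <- FALSE
  }

  keep <- !vapply(paths, is.null, TRUE)
  out <- lapply(paths[keep], .normalize_path, g = cdbg)
  # deterministic path order: by first-vertex label
  ord <- order(vapply(out, function(p) p$v[1L], 0L))
  .new_path_cover(out[ord])
}

#' Spell a path cover into a string set
#'
#' Returns the spellings of the cover's paths: a spectrum-preserving
#' string set (SPSS) of the k-mer set the graph was built from. Its weight
#' obeys `weight = |K| + |cover| * (k-1)` exactly, which is asserted, and
#' the k-mer content is verified to be duplicate-free.
#'
#' @param cover A `path_cover`.
#' @param cdbg The `bidigraph` the cover lives on.
#' @return An object of class `spss`: list with `strings` and `k`.
#' @export
spell_cover <- function(cover, cdbg) {
  strings <- vapply(cover$paths, spell_path, "", g = cdbg)
  s <- structure(list(strings = strings, k = cdbg$k), class = "spss")
  km <- spss_to_kmers(s) # errors on duplicate k-mers
  expected <- length(km$kmers) + length(strings) * (cdbg$k - 1L)
  if (weight(strings) != expected) {
    stop(
      "internal error: cover spelling weight ", weight(strings),
      " != |K| + |cover|(k-1) = ", expected,
      call. = FALSE
    )
  }
  s
}

#' @export
print.spss <- function(x, ...) {
  cat("SPSS: ", length(x$strings), " strings, weight ", weight(x$strings),
    ", k = ", x$k, "\n",
    sep = ""
  )
  invisible(x)
}

#' Lower bounds on path covers
#'
#' Computes `C`, the number of connected components of the undirected graph
#' underlying `cdbg`, and `beta`, a lower bound on the number of paths in
#' any vertex-disjoint path cover: summed over components,
#' `max(1, ceiling(d/2))` where `d` counts dead-end (edge-free) sides in
#' the component. Every dead-end side must be an exposed endpoint side of
#' some path, each path exposes two, and each component needs at least one
#' path.
#'
#' @param cdbg A `bidigraph`.
#' @return List with integer elements `beta` and `C`.
#' @export
cover_lower_bound <- function(cdbg) {
  n <- length(cdbg$labels)
  e <- cdbg$edges
  ig <- igraph::graph_from_data_frame(
    data.frame(from = e$u, to = e$v),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  comp <- igraph::components(ig)$membership[as.character(seq_len(n))]
  dead <- 2L - rowSums(.side_degree(cdbg) > 0L) # dead-end sides per vertex
  d_c <- tapply(dead, comp, sum)
  beta <- sum(pmax(1L, ceiling(d_c / 2)))
  list(beta = as.integer(beta), C = as.integer(max(comp)))
}

#' Weight lower bound for enriched-string representations
#'
#' `|K| + 3*beta + C*(k-4)`: no enriched-string representation built from
#' any vertex-disjoint path cover and any admissible absorption scheme can
#' weigh less.
#'
#' @param num_kmers Size of the k-mer set.
#' @param bound List with `beta` and `C` (see [cover_lower_bound()]).
#' @param k K-mer length (>= 3).
#' @return Integer lower bound.
#' @export
ess_weight_lower_bound <- function(num_kmers, bound, k) {
  stopifnot(k >= 3L)
  as.integer(num_kmers + 3L * bound$beta + bound$C * (k - 4L))
}
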