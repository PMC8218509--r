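# Recursive enrichment encoder: turns a path cover plus an absorption
# out-forest into the enriched string set, with exact per-string
# character accounting.
#
# Geometry. Each absorbed path is arranged (flipped if necessary) so that
# the vertex receiving the absorption edge comes first and the shared
# (k-1)-mer is the spelling's prefix; that prefix is replaced by a single
# marker. Each child's bracket group is spliced into its parent
# immediately after the last character of the shared (k-1)-mer occurrence
# at the parent-side of the absorption edge:
#   * edge on the back side of the parent occurrence (side == 1 - o):
#     the occurrence's last k-1 characters equal the child prefix -> "+";
#   * edge on the front side (side == o): the occurrence's first k-1
#     characters are its reverse complement -> "-".
# The decoder's marker-replacement rule (rightmost k-1 outer characters
# left of "[") inverts both cases; sibling groups spliced at one point do
# not disturb each other because bracketed characters are not outer.

# Arrange every cover path for encoding: a path absorbed via forest arc
# (child_vertex cv, child_side sc) is flipped so cv is its first vertex
# with front side sc; roots keep their stored arrangement.
.arrange_paths <- function(cover, forest) {
  lapply(seq_along(cover$paths), function(i) {
    p <- cover$paths[[i]]
    a <- forest$arc[[i]]
    if (is.null(a)) return(p)
    cv <- a$child_vertex
    sc <- a$child_side
    if (length(p$v) == 1L) {
      return(structure(list(v = p$v, o = sc), class = "oriented_path"))
    }
    if (p$v[1L] != cv || p$o[1L] != sc) p <- .flip_path(p)
    if (p$v[1L] != cv || p$o[1L] != sc) {
      stop("internal error: absorption edge does not attach at the child's outer side",
        call. = FALSE
      )
    }
    p
  })
}

# Insertion point (index of the last character of the shared (k-1)-mer
# occurrence) and the preceding k-1 characters, for one forest arc, in the
# parent's arranged spelling coordinates.
.insertion_point <- function(arc, parent_path, parent_spell, cdbg) {
  k <- cdbg$k
  j <- match(arc$parent_vertex, parent_path$v)
  o_u <- parent_path$o[j]
  start <- parent_spell$starts[j]
  occ_len <- nchar(cdbg$labels[arc$parent_vertex])
  ins <- if (arc$parent_side == 1L - o_u) {
    start + occ_len - 1L # back of the occurrence
  } else {
    start + k - 2L # front of the occurrence
  }
  if (ins < k) {
    stop("internal error: insertion point inside the removable prefix", call. = FALSE)
  }
  list(ins = ins, preceding = substring(parent_spell$spell, ins - k + 2L, ins))
}

# Core shared by both modes. Returns strings (one per forest root, in
# ascending root path id), per-path character counts n_psi, and the total
# marker count.
.enrich_all <- function(cover, forest, cdbg, mode = c("ess", "tip"), keep_all = FALSE) {
  mode <- match.arg(mode)
  k <- cdbg$k
  npaths <- length(cover$paths)
  arranged <- .arrange_paths(cover, forest)
  spells <- lapply(arranged, spell_path, g = cdbg, with_offsets = TRUE)

  # splice plan per parent: positions, child ids; marker per child
  splice <- vector("list", npaths)
  marker <- character(npaths)
  for (ch in seq_len(npaths)) {
    a <- forest$arc[[ch]]
    if (is.null(a)) next
    pp <- a$parent_path
    ip <- .insertion_point(a, arranged[[pp]], spells[[pp]], cdbg)
    child_prefix <- substring(spells[[ch]]$spell, 1L, k - 1L)
    if (child_prefix == ip$preceding) {
      marker[ch] <- "+"
    } else if (child_prefix == .rc(ip$preceding)) {
      marker[ch] <- "-"
    } else {
      stop("internal error: shared (k-1)-mer mismatch at absorption edge", call. = FALSE)
    }
    if (mode == "tip" && marker[ch] != "+") {
      stop("internal error: tip-mode absorption requires an implicit '+' marker",
        call. = FALSE
      )
    }
    splice[[pp]] <- rbind(splice[[pp]], data.frame(ins = ip$ins, child = ch))
  }

  # bottom-up assembly (children before parents)
  enriched <- character(npaths)
  n_psi <- integer(npaths)
  for (i in order(forest$depth, decreasing = TRUE)) {
    x <- spells[[i]]$spell
    n_psi[i] <- nchar(x)
    sp <- splice[[i]]
    if (!is.null(sp)) {
      sp <- sp[order(sp$ins, sp$child, decreasing = TRUE), , drop = FALSE]
      for (r in seq_len(nrow(sp))) {
        x <- paste0(
          substring(x, 1L, sp$ins[r]),
          "[", enriched[sp$child[r]], "]",
          substring(x, sp$ins[r] + 1L)
        )
      }
    }
    if (forest$parent[i] != 0L) {
      cut <- substring(x, k) # spliced groups all sit at positions >= k
      x <- if (mode == "tip") cut else paste0(marker[i], cut)
      n_psi[i] <- n_psi[i] - (k - 1L) + (if (mode == "tip") 2L else 3L)
    }
    enriched[i] <- x
  }
  roots <- sort(forest$roots)
  out <- list(
    strings = enriched[roots],
    n_psi = n_psi,
    num_markers = if (mode == "ess") sum(forest$parent != 0L) else 0L
  )
  if (keep_all) out$all_strings <- enriched
  out
}

#' Enriched string of one cover path
#'
#' Computes the enriched representation of a single path under a given
#' absorption forest: children's enriched strings are computed recursively
#' and spliced in as bracket groups; if the path is itself absorbed, its
#' leading k-1 characters are replaced by the appropriate marker.
#' Primarily a window into the encoder for testing and inspection; the
#' full pipeline is [ess_compress()].
#'
#' @param path_id Path id (index into `cover$paths`).
#' @param forest An `out_forest` over the cover.
#' @param cover A `path_cover`.
#' @param cdbg The `bidigraph` the cover lives on.
#' @return A single enriched string.
#' @export
spell_path_enrich <- function(path_id, forest, cover, cdbg) {
  .enrich_all(cover, forest, cdbg, mode = "ess", keep_all = TRUE)$all_strings[path_id]
}

#' Predicted weight of the enriched representation
#'
#' The encoder's output weight satisfies the exact identity
#' `|K| + 3*|cover| + n_sc*(k-4)`: every path contributes its spelling,
#' each of the `|cover| - n_sc` absorbed paths trades k-1 nucleotides for
#' two brackets and one marker, and Eq. `weight(SPSS) = |K| + |cover|(k-1)`
#' closes the algebra.
#'
#' @param num_kmers `|K|`.
#' @param num_paths Number of cover paths.
#' @param n_sc Number of source components of the absorption digraph
#'   (= number of output strings).
#' @param k K-mer length.
#' @return Integer predicted weight.
#' @export
predicted_weight <- function(num_kmers, num_paths, n_sc, k) {
  stopifnot(n_sc <= num_paths)
  as.integer(num_kmers + 3L * num_paths + n_sc * (k - 4L))
}

.new_compression_result <- function(strings, mode, k, num_kmers, num_paths, n_sc,
                                    lower_bound, n_psi, num_markers, spss_weight) {
  w <- weight(strings)
  pred <- if (mode == "ess") predicted_weight(num_kmers, num_paths, n_sc, k) else NA_integer_
  structure(
    list(
      strings = strings, mode = mode, k = k,
      num_kmers = num_kmers, num_paths = num_paths, n_sc = n_sc,
      weight = as.integer(w), predicted_weight = pred,
      lower_bound = as.integer(lower_bound),
      spss_weight = as.integer(spss_weight),
      n_psi = n_psi, num_markers = as.integer(num_markers)
    ),
    class = "compression_result"
  )
}

#' @export
print.compression_result <- function(x, ...) {
  cat("Enriched string set (mode=", x$mode, "): ", length(x$strings), " strings\n",
    "  |K| = ", x$num_kmers, ", k = ", x$k,
    ", |cover| = ", x$num_paths, ", n_sc = ", x$n_sc, "\n",
    "  weight = ", x$weight,
    if (!is.na(x$predicted_weight)) paste0(" (predicted ", x$predicted_weight, ")") else "",
    ", SPSS weight = ", x$spss_weight,
    ", lower bound = ", x$lower_bound, "\n",
    "  chars/k-mer = ", sprintf("%.4f", x$weight / x$num_kmers), "\n",
    sep = ""
  )
  invisible(x)
}

# shared pipeline driver
.compress_pipeline <- function(K, mode, cover_fun, forest_fun) {
  g <- build_dbg(K)
  cdbg <- compact(g)
  cover <- cover_fun(cdbg)
  forest <- forest_fun(cdbg, cover)
  enc <- .enrich_all(cover, forest, cdbg, mode = mode)
  bound <- cover_lower_bound(cdbg)
  lb <- ess_weight_lower_bound(length(K$kmers), bound, K$k)
  spss_w <- length(K$kmers) + length(cover$paths) * (K$k - 1L)
  res <- .new_compression_result(
    enc$strings, mode, K$k,
    num_kmers = length(K$kmers), num_paths = length(cover$paths),
    n_sc = length(forest$roots), lower_bound = lb,
    n_psi = enc$n_psi, num_markers = enc$num_markers, spss_weight = spss_w
  )
  if (mode == "ess") {
    if (res$weight != res$predicted_weight) {
      stop(
        "internal error: output weight ", res$weight,
        " differs from the predicted ", res$predicted_weight,
        call. = FALSE
      )
    }
    if (res$weight < res$lower_bound) {
      stop("internal error: output weight below the lower bound", call. = FALSE)
    }
  }
  res
}

#' Compress a k-mer set into an enriched string set
#'
#' Full pipeline: de Bruijn graph, compaction, greedy path cover,
#' absorption digraph, edge-maximizing spanning out-forest, recursive
#' enrichment. The output satisfies, and the function asserts, the exact
#' identity `weight = |K| + 3|cover| + n_sc(k-4)` and the lower bound
#' `weight >= |K| + 3*beta + C(k-4)`; the number of output strings equals
#' `n_sc`, and the number of marker characters equals `|cover| - n_sc`.
#'
#' @param K A [kmer_set].
#' @return A `compression_result` (see [predicted_weight()] for the weight
#'   identity and [ess_tip_compress()] for the tip-restricted variant).
#' @examples
#' ess_compress(kmer_set(c("AAC", "ACC"), 3))
#' @export
ess_compress <- function(K) {
  stopifnot(inherits(K, "kmer_set"))
  if (length(K$kmers) == 0L) stop("cannot compress an empty k-mer set", call. = FALSE)
  .compress_pipeline(
    K, "ess",
    cover_fun = greedy_path_cover,
    forest_fun = function(cdbg, cover) {
      ae <- find_absorption_edges(cdbg, cover)
      da <- build_absorption_digraph(ae, cover)
      max_edge_spanning_out_forest(da)
    }
  )
}
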