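# Tip-restricted compression: only dead-end vertices (tips, typically
# sequencing-error artifacts or coverage gaps) are absorbed, each into an
# adjacent non-dead-end vertex. The absorption forest has depth <= 2, so
# brackets never nest, and the encoding drops the marker character: a
# bracket group implicitly stands for [the k-1 outer characters to its
# left] + content, 2 extra characters per absorption instead of 3.

.dead_end_vertices <- function(cdbg) {
  deg <- .side_degree(cdbg)
  which(rowSums(deg == 0L) == 1L)
}

#' Dead-end-centric path cover
#'
#' Puts every dead-end vertex in its own dedicated singleton path and runs
#' the greedy cover on the subgraph obtained by removing all dead-end
#' vertices. Graphs without dead-ends give the same cover as
#' [greedy_path_cover()].
#'
#' @param cdbg An overlap-closed `bidigraph`.
#' @return A `path_cover`.
#' @export
tip_path_cover <- function(cdbg) {
  dead <- .dead_end_vertices(cdbg)
  if (length(dead) == 0L) return(greedy_path_cover(cdbg))
  keep <- setdiff(seq_along(cdbg$labels), dead)
  paths <- lapply(dead, function(v) {
    structure(list(v = v, o = 0L), class = "oriented_path")
  })
  if (length(keep) > 0L) {
    e <- cdbg$edges
    esub <- e[e$u %in% keep & e$v %in% keep, , drop = FALSE]
    esub$u <- match(esub$u, keep) # keep is ascending, so edge ordering survives

    esub$v <- match(esub$v, keep)
    sub <- .new_bidigraph(cdbg$labels[keep], esub, cdbg$k)
    subcover <- greedy_path_cover(sub)
    paths <- c(paths, lapply(subcover$paths, function(p) {
      structure(list(v = keep[p$v], o = p$o), class = "oriented_path")
    }))
  }
  ord <- order(vapply(paths, function(p) p$v[1L], 0L))
  .new_path_cover(paths[ord])
}

#' Depth-2 absorption forest over a tip cover
#'
#' For each dead-end vertex, selects the deterministic smallest eligible
#' absorption: an edge to a non-dead-end vertex whose shared (k-1)-mer
#' sits at the back of that vertex's occurrence in its own path, so that
#' the implicit marker of the 2-character encoding is always "+". Tips
#' with no eligible neighbour (for example a tip adjacent only to other
#' tips, or attached only at the front of the neighbouring occurrence)
#' stay roots of their own trees, as do all non-dead-end paths.
#'
#' @param cdbg A `bidigraph`.
#' @param cover A `path_cover` from [tip_path_cover()].
#' @return An `out_forest` of depth at most 2.
#' @export
tip_forest <- function(cdbg, cover) {
  n <- length(cover$paths)
  ci <- .cover_index(cover, length(cdbg$labels))
  dead <- .dead_end_vertices(cdbg)
  is_dead <- logical(length(cdbg$labels))
  is_dead[dead] <- TRUE

  parent <- integer(n)
  arc <- vector("list", n)
  depth <- rep(1L, n)
  e <- cdbg$edges
  if (nrow(e) > 0L && length(dead) > 0L) {
    cand <- rbind(
      data.frame(pv = e$u, sp = e$su, cv = e$v, sc = e$sv),
      data.frame(pv = e$v, sp = e$sv, cv = e$u, sc = e$su)
    )
    cand <- cand[is_dead[cand$cv] & !is_dead[cand$pv] & cand$pv != cand$cv, , drop = FALSE]
    # eligibility: shared (k-1)-mer at the back of the parent occurrence
    cand <- cand[cand$sp == 1L - ci$o_of[cand$pv], , drop = FALSE]
    if (nrow(cand) > 0L) {
      cand <- cand[order(cand$cv, cdbg$labels[cand$pv], cand$sp, cand$sc), , drop = FALSE]
      cand <- cand[!duplicated(cand$cv), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        child_path <- ci$path_of[cand$cv[r]]
        parent_path <- ci$path_of[cand$pv[r]]
        parent[child_path] <- parent_path
        depth[child_path] <- 2L
        arc[[child_path]] <- data.frame(
          parent_path = parent_path, child_path = child_path,
          parent_vertex = cand$pv[r], child_vertex = cand$cv[r],
          parent_side = cand$sp[r], child_side = cand$sc[r]
        )
      }
    }
  }
  roots <- which(parent == 0L)
  structure(
    list(parent = parent, arc = arc, roots = roots,
         n_sc = length(roots), depth = depth),
    class = "out_forest"
  )
}

#' Tip-restricted compression of a k-mer set
#'
#' Same pipeline as [ess_compress()] but with the dead-end-centric cover
#' and depth-2 forest: faster and simpler, no recursion, marker-free
#' 2-character absorption encoding (`mode = "tip"`). The output weight is
#' verified by direct accounting:
#' `|K| + |cover|(k-1) - (k-3) * n_absorbed`.
#'
#' @param K A [kmer_set].
#' @return A `compression_result` with `mode = "tip"`.
#' @export
ess_tip_compress <- function(K) {
  stopifnot(inherits(K, "kmer_set"))
  if (length(K$kmers) == 0L) stop("cannot compress an empty k-mer set", call. = FALSE)
  res <- .compress_pipeline(K, "tip", cover_fun = tip_path_cover, forest_fun = tip_forest)
  n_absorbed <- res$num_paths - res$n_sc
  expected <- res$spss_weight - (K$k - 3L) * n_absorbed
  if (res$weight != expected) {
    stop(
      "internal error: tip-mode weight ", res$weight,
      " differs from direct accounting ", expected,
      call. = FALSE
    )
  }
  res
}

#' Decode a tip-mode enriched string
#'
#' Tip-mode strings contain no marker characters and no nested brackets;
#' each bracket group's content decodes to the rightmost k-1 outer
#' characters to the left of its `[` followed by the content.
#'
#' @param x A single tip-mode enriched string.
#' @param k K-mer length.
#' @return Character vector of decoded DNA strings: the outer string
#'   first, then one string per bracket group, left to right.
#' @export
dec_tip <- function(x, k) {
  stopifnot(length(x) == 1L)
  sc <- .ess_scan(x)
  if (any(sc$ch %in% c("+", "-"))) {
    stop("marker character in tip-mode string", call. = FALSE)
  }
  if (any(sc$depth > 1L)) {
    stop("nested brackets in tip-mode string", call. = FALSE)
  }
  lv <- .dec_level(x, NULL, k)
  if (nchar(lv$outer) < k) {
    stop("decoded string shorter than k: '", lv$outer, "'", call. = FALSE)
  }
  out <- lv$outer
  if (!is.null(lv$groups)) {
    kids <- paste0(lv$groups$mr, lv$groups$content)
    if (!all(grepl("^[ACGT]+$", kids))) {
      stop("invalid characters inside tip-mode bracket group", call. = FALSE)
    }
    if (any(nchar(kids) < k)) {
      stop("decoded string shorter than k", call. = FALSE)
    }
    out <- c(out, kids)
  }
  out
}
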