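# Decompression: enriched strings -> SPSS -> canonical k-mer set.
#
# The decoder is a pure string algorithm: it never inspects the graph, so
# it can be exercised on hand-written enriched strings independently of
# the encoder.

# Split an enriched string into characters and compute bracket depth.
# depth[i] is the nesting depth AT character i ("[" already counted,
# "]" already uncounted), so outer characters are those at depth 0 that
# are not brackets.
.ess_scan <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  opens <- ch == "["
  closes <- ch == "]"
  depth <- cumsum(as.integer(opens) - as.integer(closes))
  if (any(depth < 0L) || (length(depth) > 0L && depth[length(depth)] != 0L)) {
    stop("unbalanced brackets in enriched string", call. = FALSE)
  }
  list(ch = ch, depth = depth, opens = opens, closes = closes)
}

# Decode one level: substitute outer markers, return the outer string, the
# outer character vector, and (start, end) of each top-level bracket's
# content together with the index each "[" holds among outer+bracket
# positions.
.dec_level <- function(x, marker_replacement, k) {
  sc <- .ess_scan(x)
  ch <- sc$ch
  outer_mask <- sc$depth == 0L & !sc$opens & !sc$closes
  marker_pos <- which(outer_mask & (ch == "+" | ch == "-"))
  if (length(marker_pos) > 0L) {
    if (is.null(marker_replacement)) {
      stop("outer marker found in a root enriched string", call. = FALSE)
    }
    rc_mr <- .rc(marker_replacement)
    repl <- ifelse(ch[marker_pos] == "+", marker_replacement, rc_mr)
    ch[marker_pos] <- repl
  }
  # outer string after substitution (markers expand to k-1 characters)
  outer_chars <- ch[outer_mask]
  outer <- paste(outer_chars, collapse = "")
  # top-level bracket groups
  top_open <- which(sc$opens & sc$depth == 1L)
  top_close <- which(sc$closes & sc$depth == 0L)
  if (length(top_open) != length(top_close)) {
    stop("unbalanced brackets in enriched string", call. = FALSE)
  }
  groups <- NULL
  if (length(top_open) > 0L) {
    # for each "[", the marker replacement passed down is the rightmost
    # k-1 outer characters (post-substitution) to its left
    cum_outer <- cumsum(ifelse(outer_mask, nchar(ch), 0L))
    left_len <- cum_outer[top_open] # outer chars strictly left of "["
    if (any(left_len < k - 1L)) {
      stop("fewer than k-1 outer characters before '['", call. = FALSE)
    }
    child_mr <- substring(outer, left_len - (k - 1L) + 1L, left_len)
    content <- substring(x, top_open + 1L, top_close - 1L)
    groups <- list(content = content, mr = child_mr)
  }
  list(outer = outer, groups = groups)
}

#' Decode an enriched string
#'
#' Recursive decompressor for enriched strings over
#' \{A,C,G,T,[,],+,-\}. Every outer `+` is replaced by
#' `marker_replacement` and every outer `-` by its reverse complement; the
#' outer characters are emitted as one string; each top-level bracket
#' group is then decoded with the rightmost k-1 outer characters
#' (post-substitution) to the left of its `[` as the new replacement.
#' Emission order is deterministic: a string's outer part precedes its
#' children, depth-first in bracket order.
#'
#' @param x A single enriched string.
#' @param marker_replacement A DNA string of length k-1, or `NULL` for a
#'   root string (which must then contain no outer marker).
#' @param k K-mer length.
#' @return Character vector of decoded DNA strings, each of length >= k.
#' @examples
#' dec("ACG[+A]T", NULL, 3) # c("ACGT", "CGA")
#' @export
dec <- function(x, marker_replacement = NULL, k) {
  stopifnot(length(x) == 1L)
  out <- character(0)
  stack <- list(list(x = x, mr = marker_replacement))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lv <- .dec_level(top$x, top$mr, k)
    if (nchar(lv$outer) < k) {
      stop("decoded string shorter than k: '", lv$outer, "'", call. = FALSE)
    }
    if (!grepl("^[ACGT]+$", lv$outer)) {
      stop("decoded string contains non-ACGT characters: '", lv$outer, "'", call. = FALSE)
    }
    out <- c(out, lv$outer)
    if (!is.null(lv$groups)) {
      ng <- length(lv$groups$content)
      for (j in rev(seq_len(ng))) { # reversed push => left-to-right pop
        stack[[length(stack) + 1L]] <- list(
          x = lv$groups$content[j],
          mr = lv$groups$mr[j]
        )
      }
    }
  }
  out
}

#' Decompress an ESS file into a string set
#'
#' Calls the mode-appropriate decoder ([dec()] or [dec_tip()]) on every
#' record of an ESS file and returns the union as an SPSS.
#'
#' @param path Path to an ESS file (optionally gzip/xz compressed), or a
#'   list as returned by [read_ess()].
#' @return An `spss` object (list with `strings` and `k`).
#' @export
decompress <- function(path) {
  rec <- if (is.list(path)) path else read_ess(path)
  strings <- if (rec$mode == "tip") {
    unlist(lapply(rec$strings, dec_tip, k = rec$k), use.names = FALSE)
  } else {
    unlist(lapply(rec$strings, dec, marker_replacement = NULL, k = rec$k), use.names = FALSE)
  }
  structure(list(strings = strings, k = rec$k), class = "spss")
}

#' K-mer set of an SPSS
#'
#' Extracts the canonical k-mers of all windows of all strings and errors
#' if any k-mer occurs more than once (within or across strings), which
#' would violate the SPSS conditions.
#'
#' @param s An `spss` object, or a character vector of strings.
#' @param k K-mer length (taken from `s` when it is an `spss`).
#' @return A [kmer_set].
#' @export
spss_to_kmers <- function(s, k = NULL) {
  if (inherits(s, "spss")) {
    k <- s$k
    strings <- s$strings
  } else {
    strings <- s
  }
  ordered <- kmers_in_spss_order(structure(list(strings = strings, k = k), class = "spss"))
  structure(list(kmers = sort(ordered), k = as.integer(k)), class = "kmer_set")
}

#' Canonical k-mers in string-set order
#'
#' Enumerates the canonical k-mers string by string, left to right, in the
#' record order of the (decompressed) SPSS. This deterministic order pairs
#' with a per-k-mer value file for count co-compression: counts written in
#' this order can be recovered after decompression without storing keys.
#'
#' @param s An `spss` object.
#' @return Character vector of canonical k-mers, a permutation of the
#'   represented set; errors on any duplicate.
#' @export
kmers_in_spss_order <- function(s) {
  stopifnot(inherits(s, "spss"))
  k <- s$k
  if (any(nchar(s$strings) < k)) stop("SPSS string shorter than k", call. = FALSE)
  .check_dna(s$strings, "SPSS string")
  windows <- unlist(lapply(s$strings, function(x) {
    n <- nchar(x)
    substring(x, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  canon <- canonicalize(windows)
  if (anyDuplicated(canon)) {
    stop("duplicate k-mer in string set: ", canon[duplicated(canon)][1L], call. = FALSE)
  }
  canon
}
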