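.check_dna <- function(x, what = "sequence") {
  if (length(x) == 0L) stop(what, " must be non-empty", call. = FALSE)
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad)) {
    stop(
      what, " contains characters outside {A,C,G,T}: ",
      paste(utils::head(x[bad], 3L), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(x)
}

.check_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k)) {
    stop("k must be a single integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 3L) stop("k must be >= 3", call. = FALSE)
  if (k %% 2L == 0L) {
    stop("k must be odd (even k admits k-mers equal to their own reverse complement)",
      call. = FALSE
    )
  }
  k
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the strict {A,C,G,T} alphabet.
#' Applying it twice is the identity.
#'
#' @param x Character vector of DNA strings (uppercase ACGT only).
#' @return Character vector of the same length with each string reversed
#'   and complemented.
#' @examples
#' reverse_complement(c("ACG", "AAA", "ACGT"))
#' @export
reverse_complement <- function(x) {
  .check_dna(x, "k-mer")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Internal: RC without validation (hot path; inputs already checked
# upstream). Scalar calls avoid the XStringSet construction overhead.
.rc1 <- function(x) intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", x))))

.rc <- function(x) {
  n <- length(x)
  if (n == 0L) return(character(0))
  if (n > 64L) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  } else {
    vapply(x, .rc1, "", USE.NAMES = FALSE)
  }
}

#' Canonical form of DNA strings
#'
#' The canonical form of a string is the lexicographically smaller of the
#' string and its reverse complement. Idempotent, and invariant under
#' reverse complement of the input.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of canonical forms.
#' @examples
#' canonicalize("CGT") # "ACG"
#' @export
canonicalize <- function(x) {
  .check_dna(x, "k-mer")
  r <- .rc(x)
  ifelse(x <= r, x, r)
}

#' Canonical k-mer set
#'
#' Container for a finite set of canonical k-mers of a fixed odd length k.
#' Members are stored sorted and unique; every member equals its canonical
#' form.
#'
#' @param kmers Character vector of k-mers (canonicalized and deduplicated
#'   on construction).
#' @param k Odd integer >= 3, the k-mer length.
#' @return An object of class `kmer_set` with elements `kmers` (sorted
#'   character vector) and `k`.
#' @examples
#' kmer_set(c("CGT", "ACG", "TAA"), k = 3)
#' @export
kmer_set <- function(kmers, k) {
  k <- .check_k(k)
  kmers <- as.character(kmers)
  if (length(kmers) > 0L) {
    .check_dna(kmers, "k-mer")
    if (any(nchar(kmers) != k)) stop("all k-mers must have length k = ", k, call. = FALSE)
    kmers <- sort(unique(canonicalize(kmers)))
  }
  structure(list(kmers = kmers, k = k), class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("Canonical k-mer set: ", length(x$kmers), " k-mers, k = ", x$k, "\n", sep = "")
  if (length(x$kmers) > 0L) {
    show <- utils::head(x$kmers, 6L)
    cat("  ", paste(show, collapse = " "), if (length(x$kmers) > 6L) " ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.kmer_set <- function(x) length(x$kmers)

#' Extract and count canonical k-mers from sequences
#'
#' Slides a window of length k over every input sequence, canonicalizes each
#' ACGT-only window, counts occurrences, and keeps the k-mers seen at least
#' `min_count` times. Windows containing an ambiguous base (N or any other
#' non-ACGT symbol) are skipped, i.e. ambiguous bases split a sequence into
#' independent ACGT-only runs, following k-mer-counter convention.
#'
#' @param sequences Character vector of sequences (may contain non-ACGT
#'   symbols; case-insensitive).
#' @param k Odd integer >= 3.
#' @param min_count Minimum number of occurrences (abundance filter), >= 1.
#' @return A [kmer_set].
#' @examples
#' extract_kmers(c("TCGTT", "GTAA"), k = 3)
#' @export
extract_kmers <- function(sequences, k, min_count = 1L) {
  k <- .check_k(k)
  if (length(min_count) != 1L || is.na(min_count) || min_count < 1L) {
    stop("min_count must be a single integer >= 1", call. = FALSE)
  }
  sequences <- toupper(as.character(sequences))
  # split at ambiguous bases into ACGT-only runs
  runs <- unlist(strsplit(sequences, "[^ACGT]+"), use.names = FALSE)
  runs <- runs[nchar(runs) >= k]
  if (length(runs) == 0L) {
    return(structure(list(kmers = character(0), k = k), class = "kmer_set"))
  }
  windows <- unlist(lapply(runs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  canon <- canonicalize(windows)
  counts <- table(canon)
  keep <- counts[counts >= min_count]
  keep <- keep[order(names(keep))]
  cnt <- stats::setNames(as.integer(keep), names(keep))
  structure(list(kmers = names(keep), k = k, counts = cnt), class = "kmer_set")
}

#' Read / write plain-text k-mer list files
#'
#' The k-mer list format is one uppercase k-mer per line with LF line
#' endings. `write_kmer_file()` emits the canonical k-mers sorted
#' lexicographically so output is deterministic and diffable;
#' `read_kmer_file()` canonicalizes and deduplicates, inferring k from the
#' (uniform) line length. Files ending in `.gz` are (de)compressed
#' transparently.
#'
#' @param path File path; `.gz` suffix enables gzip.
#' @param x A [kmer_set].
#' @return `read_kmer_file()` returns a [kmer_set]; `write_kmer_file()`
#'   returns `path` invisibly.
#' @export
read_kmer_file <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- toupper(trimws(lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("k-mer file is empty: ", path, call. = FALSE)
  lens <- unique(nchar(lines))
  if (length(lens) != 1L) {
    stop("ragged k-mer file: line lengths ", paste(sort(lens), collapse = ", "), call. = FALSE)
  }
  kmer_set(lines, k = lens)
}

#' @rdname read_kmer_file
#' @export
write_kmer_file <- function(x, path) {
  stopifnot(inherits(x, "kmer_set"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(sort(x$kmers), con, sep = "\n")
  invisible(path)
}
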