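# Sequence input and the ESS container format.

#' Read sequences from FASTA or FASTQ
#'
#' Reads a FASTA or FASTQ file (plain or gzip) into a plain character
#' vector. The format is auto-detected from the file extension and, failing
#' that, from the first byte of the (decompressed) content ('>' for FASTA,
#' '@' for FASTQ). Quality scores are ignored.
#'
#' @param path Path to a `.fa/.fasta/.fna/.fq/.fastq` file, optionally
#'   `.gz`-compressed.
#' @return Character vector of uppercase sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  base <- sub("\\.gz$", "", path)
  fmt <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) {
    "fastq"
  } else if (grepl("\\.(fa|fasta|fna)$", base, ignore.case = TRUE)) {
    "fasta"
  } else {
    con <- gzfile(path, "rt") # gzfile reads plain files too
    first <- readLines(con, n = 1L)
    close(con)
    if (length(first) == 0L) stop("empty sequence file: ", path, call. = FALSE)
    if (startsWith(first, ">")) "fasta" else if (startsWith(first, "@")) "fastq" else {
      stop("cannot detect FASTA/FASTQ format of ", path, call. = FALSE)
    }
  }
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  toupper(as.character(seqs))
}

#' Write a set of DNA strings as FASTA
#'
#' Records are named `path_0001`, `path_0002`, ... in input order, the
#' record naming used for decompressed string sets.
#'
#' @param strings Character vector of DNA strings.
#' @param path Output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_spss_fasta <- function(strings, path) {
  .check_dna(strings, "string set")
  x <- Biostrings::DNAStringSet(strings)
  names(x) <- sprintf("path_%04d", seq_along(strings))
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

.ess_alphabet_ok <- function(x) grepl("^[][ACGT+-]*$", x)

#' Read / write the ESS container format
#'
#' The ESS format is line-oriented text: a header line
#' `#ESS<TAB>v1<TAB>k=<k><TAB>mode=<ess|tip><TAB>n=<count>` followed by one
#' enriched string per line, LF endings. `compress_with = "gzip"` or
#' `"xz"` wraps the whole file in a generic compressor.
#'
#' @param strings Character vector of enriched strings.
#' @param k K-mer length recorded in the header.
#' @param mode `"ess"` (full recursive absorption) or `"tip"` (dead-end
#'   absorption only, marker-free).
#' @param path File path.
#' @param compress_with One of `"none"`, `"gzip"`, `"xz"`.
#' @return `write_ess()` returns `path` invisibly; `read_ess()` returns a
#'   list with elements `strings`, `k`, `mode`.
#' @export
write_ess <- function(strings, k, mode = c("ess", "tip"), path,
                      compress_with = c("none", "gzip", "xz")) {
  mode <- match.arg(mode)
  compress_with <- match.arg(compress_with)
  if (!all(.ess_alphabet_ok(strings))) {
    stop("enriched strings restricted to {A,C,G,T,[,],+,-}", call. = FALSE)
  }
  con <- switch(compress_with,
    none = file(path, "wb"),
    gzip = gzfile(path, "wb"),
    xz = xzfile(path, "wb")
  )
  on.exit(close(con))
  header <- sprintf("#ESS\tv1\tk=%d\tmode=%s\tn=%d", as.integer(k), mode, length(strings))
  writeLines(c(header, strings), con, sep = "\n")
  invisible(path)
}

#' @rdname write_ess
#' @export
read_ess <- function(path) {
  # gzfile() autodetects gzip; xz needs an explicit probe of the magic bytes
  magic <- readBin(path, "raw", n = 6L)
  con <- if (length(magic) >= 6L &&
    identical(magic, as.raw(c(0xFD, 0x37, 0x7A, 0x58, 0x5A, 0x00)))) {
    xzfile(path, "rt")
  } else {
    gzfile(path, "rt")
  }
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L || !startsWith(lines[1L], "#ESS\t")) {
    stop("not an ESS file (missing '#ESS' header): ", path, call. = FALSE)
  }
  fields <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  kv <- fields[grepl("=", fields, fixed = TRUE)]
  kvs <- strsplit(kv, "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kvs, `[`, "", 2L),
    vapply(kvs, `[`, "", 1L)
  )
  if (!all(c("k", "mode", "n") %in% names(vals))) {
    stop("garbled ESS header: ", lines[1L], call. = FALSE)
  }
  k <- as.integer(vals[["k"]])
  mode <- vals[["mode"]]
  if (!mode %in% c("ess", "tip")) stop("unknown ESS mode: ", mode, call. = FALSE)
  strings <- lines[-1L]
  strings <- strings[nzchar(strings)]
  if (length(strings) != as.integer(vals[["n"]])) {
    stop("ESS record count mismatch: header n=", vals[["n"]],
      " but found ", length(strings),
      call. = FALSE
    )
  }
  if (!all(.ess_alphabet_ok(strings))) stop("invalid characters in ESS records", call. = FALSE)
  list(strings = strings, k = k, mode = mode)
}

#' Write / read a per-k-mer value file
#'
#' One integer per line, in a caller-supplied k-mer order (see
#' [kmers_in_spss_order()]); used to co-compress k-mer counts alongside the
#' enriched string set.
#'
#' @param values Integer vector.
#' @param path File path (`.gz` for gzip).
#' @return `write_value_file()` returns `path` invisibly;
#'   `read_value_file()` returns an integer vector.
#' @export
write_value_file <- function(values, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(format(as.integer(values), scientific = FALSE, trim = TRUE), con, sep = "\n")
  invisible(path)
}

#' @rdname write_value_file
#' @export
read_value_file <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  as.integer(readLines(con))
}
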