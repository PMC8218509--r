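# Synthetic genomes, error-bearing reads, and hand-built graph/cover
# fixtures, so every pipeline stage is testable without external data.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    })
  }
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' @param genome_length Genome length in bp.
#' @param read_length Read length in bp (<= genome_length).
#' @param coverage Mean per-base coverage (> 0).
#' @param error_rate Per-base substitution probability in [0, 1).
#' @param seed Integer seed; all randomness flows through it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 100000L, read_length = 100L,
                       coverage = 10, error_rate = 0.01, seed = 1L) {
  stopifnot(
    genome_length >= 1L, read_length >= 1L, read_length <= genome_length,
    coverage > 0, error_rate >= 0, error_rate < 1
  )
  structure(
    list(
      genome_length = as.integer(genome_length),
      read_length = as.integer(read_length),
      coverage = coverage, error_rate = error_rate, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Random genome sequence
#'
#' Uniform i.i.d. ACGT string, reproducible per seed.
#'
#' @param length Genome length (>= 1).
#' @param seed Integer seed.
#' @return A single DNA string.
#' @export
random_genome <- function(length, seed = 1L) {
  stopifnot(length >= 1L)
  .with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
}

#' Simulate shotgun reads with substitution errors
#'
#' Draws `ceiling(coverage * genome_length / read_length)` reads from
#' uniform random start positions, each strand with probability 1/2, and
#' applies i.i.d. substitution errors at `error_rate` per base. A positive
#' error rate produces de Bruijn graphs rich in tips (dead-end unitigs),
#' the structure the tip-restricted compressor exploits. No indels, no
#' quality strings, single-end only.
#'
#' @param genome A DNA string.
#' @param cfg A [sim_config] (its `genome_length` is ignored in favour of
#'   `nchar(genome)`).
#' @return Character vector of reads.
#' @export
simulate_reads <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  glen <- nchar(genome)
  rl <- cfg$read_length
  stopifnot(rl <= glen)
  nreads <- as.integer(ceiling(cfg$coverage * glen / rl))
  .with_seed(cfg$seed + 1L, {
    starts <- sample.int(glen - rl + 1L, nreads, replace = TRUE)
    reads <- substring(genome, starts, starts + rl - 1L)
    flip <- stats::runif(nreads) < 0.5
    reads[flip] <- .rc(reads[flip])
    if (cfg$error_rate > 0) {
      mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
        nrow = rl
      )
      hit <- which(matrix(stats::runif(length(mat)) < cfg$error_rate, nrow = rl))
      if (length(hit) > 0L) {
        # substitute with one of the three other bases, uniformly
        cur <- mat[hit]
        alt <- vapply(cur, function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, "")
        mat[hit] <- alt
      }
      reads <- apply(mat, 2L, paste, collapse = "")
    }
    reads
  })
}

# Build a bidigraph directly from vertex labels (overlap-closed), used by
# the fixtures below.
.graph_from_labels <- function(labels, k) {
  labels <- sort(canonicalize(labels))
  .new_bidigraph(labels, .build_edges(labels, k), k)
}

# Turn a list of spelled paths (character vectors of oriented occurrence
# strings, overlapping by k-1) into an injected cover on g.
.cover_from_occurrences <- function(g, occ_paths) {
  paths <- lapply(occ_paths, function(occs) {
    canon <- canonicalize(occs)
    v <- match(canon, g$labels)
    if (anyNA(v)) stop("fixture occurrence not a vertex: ", occs[is.na(v)][1L], call. = FALSE)
    o <- as.integer(occs != g$labels[v])
    oriented_path(v, o, g)
  })
  .new_path_cover(paths)
}

#' Hand-built graph and cover fixtures
#'
#' A named collection of small graph fixtures, most with injected (forced)
#' path covers that bypass the greedy cover so encoder behaviour is
#' testable independently of cover heuristics. Included structures:
#'
#' * `toy_absorb`: a 3-vertex parent path with an internal vertex adjacent
#'   to the head of a 2-vertex child path; exactly one absorption edge.
#'   Encodes to `TCGT[+AA]T`.
#' * `multi_child`: one parent path absorbing three singleton children at
#'   its internal vertex, two of them at the same insertion point
#'   (consecutive bracket groups) and one at the occurrence's front (a
#'   `-` marker). Encodes to `AAACC[-A]T[+G][+A]T`.
#' * `recursive3`: a 3-level absorption chain (a path that is both child
#'   and parent), nesting depth 2: `AAACCT[+GA[+T]A]T`.
#' * `mutual_cycle`: two 3-vertex paths whose internal vertices each
#'   absorb the other's head: a 2-cycle in the absorption digraph,
#'   resolved by the out-forest into `AACCAA[+CCG]G`.
#' * `tip_chain`: a 3-vertex chain whose two end vertices are dead-ends.
#' * `isolated`: three isolated vertices.
#' * `cycle_component`: a perfect-cycle component (compaction corner
#'   case, broken at the smallest label).
#'
#' @return Named list; each element holds `g` (a `bidigraph`), `cover`
#'   (a `path_cover`, or `NULL` where the greedy cover should be used),
#'   `k`, and, where meaningful, the expected encoding under the injected
#'   cover.
#' @export
fixture_graphs <- function() {
  out <- list()

  # parent TCG-CGT-GTT (spell TCGTT), child GTA-TAA (GTAA); the internal
  # vertex CGT is adjacent to the child head GTA via the shared 2-mer GT
  k <- 3L
  g <- .graph_from_labels(c("TCG", "CGT", "GTT", "GTA", "TAA"), k)
  cover <- .cover_from_occurrences(g, list(c("TCG", "CGT", "GTT"), c("GTA", "TAA")))
  out$toy_absorb <- list(
    g = g, cover = cover, k = k,
    expected_strings = "TCGT[+AA]T", expected_spss = c("TCGTT", "GTAA")
  )

  # parent AAACC-AACCT-ACCTT (spell AAACCTT, internal AACCT); children:
  # ACCTG and ACCTA share ACCT with the back of the internal occurrence
  # (same insertion point, "+"), GGTTA shares the reverse complement of
  # its front mer AACC ("-")
  k <- 5L
  parent_occ <- c("AAACC", "AACCT", "ACCTT")
  g <- .graph_from_labels(c(parent_occ, "ACCTG", "ACCTA", "GGTTA"), k)
  cover <- .cover_from_occurrences(g, list(parent_occ, "ACCTG", "ACCTA", "GGTTA"))
  out$multi_child <- list(
    g = g, cover = cover, k = k,
    expected_strings = "AAACC[-A]T[+G][+A]T"
  )

  # psi1 absorbs psi2 (ACCT), psi2 absorbs psi3 (CTGA): 3-level recursion
  k <- 5L
  p1 <- c("AAACC", "AACCT", "ACCTT")
  p2 <- c("ACCTG", "CCTGA", "CTGAA")
  p3 <- "CTGAT"
  g <- .graph_from_labels(c(p1, p2, p3), k)
  cover <- .cover_from_occurrences(g, list(p1, p2, p3))
  out$recursive3 <- list(
    g = g, cover = cover, k = k,
    expected_strings = "AAACCT[+GA[+T]A]T"
  )

  # two chains: suf4 of internal ACCAA = CCAA = pre4 of head CCAAC, and
  # suf4 of internal CAACC = AACC = pre4 of head AACCA, giving arcs both
  # ways between the two paths
  k <- 5L
  q1 <- c("AACCA", "ACCAA", "CCAAG")
  q2 <- c("CCAAC", "CAACC", "AACCG")
  g <- .graph_from_labels(c(q1, q2), k)
  cover <- .cover_from_occurrences(g, list(q1, q2))
  out$mutual_cycle <- list(
    g = g, cover = cover, k = k,
    expected_strings = "AACCAA[+CCG]G"
  )

  # 3-vertex chain; both end vertices are dead-ends (tips)
  k <- 5L
  g <- .graph_from_labels(c("GGCAT", "GCATT", "CATTC"), k)
  out$tip_chain <- list(g = g, cover = NULL, k = k)

  # three isolated vertices
  k <- 5L
  g <- .graph_from_labels(c("AAACG", "CCCGA", "GGGTA"), k)
  out$isolated <- list(g = g, cover = NULL, k = k)

  # perfect cycle: 3-mers of the circular sequence CTGTTC
  k <- 3L
  g <- build_dbg(extract_kmers("CTGTTCCT", k))
  out$cycle_component <- list(g = g, cover = NULL, k = k)

  out
}
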