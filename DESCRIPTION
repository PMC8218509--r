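Package: esskit
Title: Disk Compression of K-mer Sets via Enriched String Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless disk compression of canonical k-mer sets. A k-mer set is
    represented as a small set of "enriched" strings over the alphabet
    {A,C,G,T,[,],+,-} by building the bidirected de Bruijn graph, compacting it
    into unitigs, covering the compacted graph with vertex-disjoint oriented
    paths, and recursively absorbing whole paths into other paths along a
    maximum spanning out-forest of the absorption digraph. Includes the exact
    weight identity for the encoded output, instance-specific lower bounds, a
    faster tip-restricted variant that only absorbs dead-end unitigs, a
    recursive decompressor that recovers the exact k-mer set, FASTA/FASTQ and
    plain k-mer-list input, and a synthetic read simulator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
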