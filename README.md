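# esskit

Lossless disk compression of k-mer sets for R.

K-mer based tools (assembly, metagenomics, database search) routinely
reduce sequence data to a set *K* of canonical k-mers, and storing those
sets dominates disk budgets at scale. A *spectrum-preserving string set*
(SPSS) stores *K* as a set of longer strings whose k-mers are exactly *K*
with no duplicates: gluing two k-mers along a (k−1)-overlap saves k−1
characters. `esskit` goes one step further: it emits **enriched strings**
over the alphabet `{A,C,G,T,[,],+,-}` in which whole strings are absorbed
into other strings. A bracket group `[...]` embeds an absorbed child; its
leading marker `+` stands for the k−1 characters immediately left of the
`[`, and `-` for their reverse complement. Absorbing a child therefore
trades k−1 nucleotides for 3 characters, a saving of k−4 per absorption.

## Method

The pipeline, for a canonical k-mer set *K* with odd k:

1. **Bidirected de Bruijn graph** `dBG(K)`: one two-sided vertex per
   canonical k-mer, an edge for every (k−1)-length oriented overlap
   (`build_dbg()`).
2. **Compaction** to unitigs: `cdBG(K)` (`compact()`).
3. **Greedy vertex-disjoint path cover** Ψ of `cdBG(K)`
   (`greedy_path_cover()`). Spelling Ψ gives an SPSS of weight
   `|K| + |Ψ|(k−1)`.
4. **Absorption**: a cdBG edge whose one endpoint is *internal* to a path
   and whose other endpoint is a flippable *endpoint* of another path lets
   the second path be absorbed into the first. These edges form the
   absorption digraph D over paths; an edge-maximizing spanning out-forest
   of D (found optimally via the SCC condensation and a starter-set DFS,
   `max_edge_spanning_out_forest()`) selects which absorptions happen.
5. **Encoding** (`ess_compress()`): one enriched string per forest root.
   The output weight satisfies, exactly,

   ```
   weight = |K| + 3|Ψ| + n_sc (k − 4)
   ```

   where `n_sc` is the number of source components of D's condensation,
   and is bounded below by `|K| + 3β + C(k−4)` with β a path-cover lower
   bound and C the number of connected components. Both are asserted at
   run time.
6. **Decompression** (`decompress()`, `dec()`): a pure string algorithm —
   substitute outer markers, emit outer characters, recurse into bracket
   groups with the rightmost k−1 outer characters as the next marker
   replacement. It recovers *K* exactly.

`ess_tip_compress()` is a faster variant that only absorbs *dead-end*
unitigs (tips, typically sequencing-error artifacts) into adjacent
vertices: its forest has depth ≤ 2, brackets never nest, the marker is
implicit, and each absorption costs 2 characters instead of 3.

## Worked example

```r
library(esskit)

K <- kmer_set(c("TCG", "CGT", "GTT", "GTA", "TAA"), k = 3)  # 5 canonical 3-mers
res <- ess_compress(K)
res
#> Enriched string set (mode=ess): 1 strings
#>   |K| = 5, k = 3, |cover| = 1, n_sc = 1
#>   weight = 7 (predicted 7), SPSS weight = 7, lower bound = 7
#>   chars/k-mer = 1.4000
res$strings
#> [1] "TCGTAAC"

dec("TCGT[+AA]T", NULL, k = 3)
#> [1] "TCGTT" "GTAA"

spss_to_kmers(decompress(list(strings = res$strings, k = 3, mode = "ess")))
#> Canonical k-mer set: 5 k-mers, k = 3
#>   AAC ACG CGA GTA TAA
```

Here the greedy cover finds a single path spelling all five 3-mers in one
7-character string, so no absorption is needed and the weight identity
reads `5 + 3·1 + 1·(3−4) = 7`. The `dec` call shows the decoder on a
hand-written enriched string: `+` is replaced by the two characters left
of the bracket (`GT`), giving `TCGT[GTAA]T`, and the bracketed string is
cleaved out: `{TCGTT, GTAA}`. Note that at k = 3 an absorption saves
k−4 = −1 characters, i.e. it costs one; the savings are real for k > 4
and grow linearly in k.

On simulated reads (100 kb genome, coverage 10, 1% errors, k = 21) the
package reports about 1.18 characters per k-mer for the full encoder,
1.51 for the tip-restricted variant, and 2.64 for plain unitigs, with the
instance lower bound around 1.02 (numbers printed by
`scripts/acceptance.R`, seed 1).

## File formats

* **k-mer list**: one uppercase k-mer per line, LF endings; written
  sorted for bit-exact diffing.
* **ESS container**: header `#ESS<TAB>v1<TAB>k=<k><TAB>mode=<ess|tip><TAB>n=<count>`
  followed by one enriched string per line; optional whole-file gzip/xz.
* **SPSS FASTA**: decompressed strings as records `path_0001`, ...
* **value file**: one integer per line, aligned with
  `kmers_in_spss_order()` for count co-compression.
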