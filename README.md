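# helitronr

Discovery and structural characterization of **helitrons** — rolling-circle
DNA transposons — from genomic sequence in FASTA.

Helitrons lack terminal inverted repeats and create no target-site
duplication, so they are found by their structural hallmarks instead: a
TC-motif 5'-terminus, a CTRR-motif 3'-terminus ending in the conserved
CTAG, a 16–20 bp sub-terminal palindrome that can form a hairpin, and a
preference for inserting between an adenine and a thymidine. `helitronr`
implements the full motif-based workflow for the two maize families helA
and helB, plus the downstream structural analyses:

* **Motif scanning** — nine built-in terminal motifs (loose + strict pass
  per family per end, and the decayed pseudo 3'-consensus
  `CCGT[ATCG]GCA[AT]CGCACG[AG]{2}[ATCG]{6,8}CTAT`), scanned on both strands
  with every match length reported; N never matches.
* **Element calling** — a 5'-hit pairs with the farthest same-family,
  same-strand 3'-hit ending < 20 kb downstream; AT-flank, hairpin and
  putative-autonomy (> 10 kb, no long-transposon overlap) annotations.
* **Termini analysis** — pseudo 3'-termini (CTAT vs intact CTAG),
  multiple-termini profiling, and prediction of nested-transposition
  products: reading a three-level nested stack out from the innermost
  5'-terminus yields a product with **three 3'-termini** and a remnant with
  **two 5'-termini**.
* **Homology engine** — seed-and-extend local search (a transparent BLASTN
  stand-in), seed-based discovery (5'-probe > 25 bp/> 70% id, 3'-probe
  > 25 bp/> 80% id, pairing < 20 kb), multicopy boundary validation, and
  tiered copy-number counting (coverage/identity > 95/95, > 90/90, > 85/85,
  length > 200 bp at > 80%).
* **Capture analysis** — decomposition of related elements into shared
  segment blocks (> 85% identity) and inference of stepwise gene-fragment
  `capture`, internal `loss` and `nested_insertion` events, with exact
  replay of every inferred edge and parsimony orientation from a third
  element.
* **Synthetic genomes** — a generator that plants elements with
  strict-pattern termini, A…T flanks, hairpins, captured fragments, pseudo
  termini and nested insertions, emitting full ground truth (FASTA + BED +
  JSON) so every module is testable offline.

## Worked example

Simulate a genome with planted elements, call helitrons, and compare with
truth:

```r
library(helitronr)

cfg <- simulation_config(genome_length = 200000, n_helA = 3, n_helB = 1,
                         element_length_range = c(500, 3000),
                         p_nested = 0, seed = 7)
sim <- generate_genome(cfg)
sim
#> <synthetic_genome> 205700 bp, 4 planted elements

calls <- call_helitrons(sim$genome, pass = "strict")
as.data.frame(calls)[, c("call_id", "start", "end", "strand", "family",
                         "length", "at_insertion", "stem_length",
                         "multi_termini_5", "multi_termini_3")]
#>          call_id  start    end strand family length at_insertion stem_length
#> 1 chr1_helA_0001  48346  49666      +   helA   1320         TRUE           8
#> 2 chr1_helA_0002  72155  73415      +   helA   1260         TRUE          10
#> 3 chr1_helA_0003  73138  73415      +   helA    277        FALSE          10
#> 4 chr1_helB_0004  98217 100119      -   helB   1902         TRUE           8
#> 5 chr1_helA_0005 123709 124927      -   helA   1218         TRUE          10
#>   multi_termini_5 multi_termini_3
#> 1               1               1
#> 2               2               1
#> 3               1               1
#> 4               1               1
#> 5               1               1
```

All four planted elements are recovered with exact boundaries on both
strands, each flanked by the host A…T dinucleotide, with the planted
sub-terminal hairpin annotated (stem length in bp). The second helA carries
a planted internal 5'-terminus (`multi_termini_5 = 2`); the pairing rule
deliberately also emits the short overlapping call starting at that
internal terminus (row 3), mirroring how multiple-termini elements present
in real screens.

Nested-transposition read-out (the origin proposed for multiple-termini
elements):

```r
cfgn <- nested_config(c("outer", "mid", "inner"),
                      five_pos = c(0, 300, 600),
                      three_pos = c(2600, 2000, 1400))
predict_nested_products(cfgn, "inner")
#> $product
#> n_termini_5 n_termini_3
#>           1           3
#> $remnant
#> n_termini_5 n_termini_3
#>           2           0
```

A transposition launched from the innermost element's 5'-terminus produces
an element with one 5'- and three 3'-termini, leaving a remnant with two
5'-termini.

## Command line

```sh
Rscript -e 'helitronr::hel_cli()' simulate --out-prefix sim --seed 7 \
    --genome-length 200000 --n-hela 3 --n-helb 1
Rscript -e 'helitronr::hel_cli()' call --fasta sim.fasta --out-prefix calls
```

Subcommands: `simulate`, `call`, `termini`, `nested`, `discover`,
`copynum`, `capture-graph`. Every output directory receives a
`manifest.json` (command, parameters, input checksums, version, seed); all
randomness flows from `--seed`.

## Scope

Protein-level annotation of autonomous machinery (Rep/helicase/RPA ORFs),
phylogenies, and searches against external protein databases are out of
scope, as is reproducing genome-wide counts from real maize assemblies.
See `vignettes/helitron-discovery.Rmd` for the models, parameter choices,
synthetic-world assumptions and limitations.
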