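# pgmap — proteogenomic mapping of peptides onto genomes

`pgmap` maps experimentally observed peptides **exactly** onto a nucleotide
database translated in all six reading frames under a user-selected NCBI
genetic code, and extends each match into an **expressed Protein Sequence
Tag (ePST)**: a nucleotide tag bounded by plausible translation signals
that serves as evidence of an expressed region for structural genome
annotation.

It is written for proteogenomics practitioners: you have MS/MS-identified
peptides that the predicted proteome does not explain, and you want to know
where they sit on the genome and what coding unit surrounds them. Spectral
matching and peptide validation happen upstream; `pgmap` starts from a
peptide FASTA and ends at browser-ready evidence tracks.

## Method

* **Matching.** The peptide set is compiled into an Aho–Corasick keyword
  automaton (built from scratch in this package): construction is
  *O(Σ|peptide|)*, and one scan of each frame translation finds **all**
  occurrences — overlapping and nested included — in *O(text)*, one state
  transition per residue. Matching is exact: no mismatches, no I/L folding;
  stop (`*`) and ambiguity (`X`) characters reset the scan and can never lie
  inside a hit.
* **Translation.** All six frames (`+1..+3` = forward offsets 0–2,
  `−1..−3` = reverse-complement offsets 0–2) under any genetic code given in
  the NCBI toolkit table layout (`ncbieaa`/`sncbieaa`); codes 1, 2, 4 and 11
  are bundled. Coordinates are 1-based inclusive on the forward strand.
* **ePST extension.** Three modes:
  * *prokaryote* — 3' to the first in-frame stop (included); 5' to the
    first start codon after the nearest upstream in-frame stop, falling
    back to the peptide start;
  * *eukaryote_signal* — additionally bounded by splice signals
    (canonical `GT`/`AG` dinucleotides, or GeneSplicer predictions, or
    none), nearest-wins;
  * *fixed* — ± *n* nucleotides, clamped at record ends.
* **Outputs.** `<prefix>.fasta` (ePST sequences), `<prefix>.tsv`
  (14-column per-ePST report), `<prefix>.gff3` (`protein_match` features) —
  mutually consistent row for row, byte-identical across reruns.

## Worked example

The package bundles the channel catfish virus (CCV) proteogenomic dataset:
17 peptides that map to novel reading frames of the viral genome, plus
their published ePST nucleotide sequences. Mapping the peptides against the
ePSTs themselves is a self-contained regression — every peptide must be
found:

```r
library(pgmap)
peps  <- system.file("extdata", "ccv_peptides.fasta", package = "pgmap")
epsts <- system.file("extdata", "ccv_epsts.fasta",    package = "pgmap")
run <- run_pipeline(pipeline_config(peps, epsts, code_id = 1,
                                    out_prefix = "ccv", log_level = "warning"))
run
#> <pgmap_run>
#>   mode: prokaryote | genetic code 1 (Standard)
#>   peptides: 17 in, 0 skipped, 17 with >=1 match
#>   records: 17 | exact matches: 17 | ePSTs: 17

tidy(run)[1, c("peptide_id", "peptide_seq", "map_start", "map_end",
               "strand", "frame", "epst_start", "epst_end", "epst_length")]
#>     peptide_id peptide_seq map_start map_end strand frame epst_start epst_end epst_length
#> 1 Proteinase-1  NLDLLDNSTG        30      59      +    +3         24      101          78
```

Reading: the 10-residue peptide `NLDLLDNSTG` reverse-maps to nucleotides
30–59 of its ePST record (30 nt = 10 codons), on the `+` strand in frame
`+3`, and the prokaryotic rule extends it to a 78-nt ORF-like tag at
24–101 ending in a stop codon. The GFF3 view of the same row:

```
Proteinase-1  pgmap  protein_match  24  101  .  +  0  ID=epst00001;Name=Proteinase-1;Target=Proteinase-1 1 10
```

`glance(run)` gives the one-row count summary; `autoplot(run)` draws the
ePSTs along their records with the anchoring peptides overlaid.

A shell front-end with the same options lives at
`inst/scripts/pgmap.R` (`--peptides`, `--genome`, `--code-table`,
`--code-id`, `--mode`, `--splice`, `--genesplicer-file`, `--extend-nt`,
`--out-prefix`, `--log-level`, plus a `fixture` subcommand wrapping
`generate_fixture()`).

To run the genome-level CCV check as well, place the viral genome FASTA
(RefSeq NC_001493.1) at `inst/extdata/NC_001493.1.fasta` before installing,
or set `options(pgmap.ccv_genome = "<path>")`; the corresponding test fails
with a pointer here when the file is absent.

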