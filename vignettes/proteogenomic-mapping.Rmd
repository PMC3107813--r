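---
title: "Proteogenomic mapping with pgmap: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic mapping with pgmap: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgmap)
```

## The problem

Tandem mass spectrometry identifies peptides that were actually translated
in a cell. When such a peptide cannot be found in the predicted proteome but
can be found in the genome, it is direct evidence for an unannotated coding
region or a wrong gene model. Proteogenomic mapping therefore asks two
questions: *where exactly* does an observed peptide sit on the genome, and
*what is the plausible coding unit around it*? `pgmap` answers both: it maps
peptide sequences exactly onto a nucleotide database translated in all six
reading frames under a selectable NCBI genetic code, and extends each match
into an expressed Protein Sequence Tag (ePST) — a nucleotide tag bounded by
translation signals that can be loaded into a genome browser next to the
existing annotation.

The peptide list is expected to be pre-filtered upstream: spectral matching,
peptide validation, and removal of peptides already explained by the
predicted proteome are the user's responsibility. `pgmap` starts from a
peptide FASTA and ends at evidence tracks.

## Exact matching: the keyword automaton

Matching is exact by design — a single amino-acid substitution makes a
peptide a different molecule, so no mismatch tolerance, and no I/L
equivalence folding, is applied. The matcher is an Aho–Corasick automaton
built over the peptide set: a keyword trie whose failure links redirect the
scan to the longest suffix that is still a pattern prefix. Construction is
linear in the total length of the peptides; scanning is linear in the text,
with every character consumed exactly once. After the breadth-first
failure-link pass the implementation materialises the dense transition
table, so the scan is a single table lookup per character. The automaton is
built once per run and reused across all records and frames.

Characters that can never occur in a peptide (`*` for stop, `X` for
ambiguous codons) occupy a catch-all column that resets the automaton to its
root: stops and ambiguity therefore act as hard match separators, which is
exactly the behaviour exact matching requires. The test suite checks the
automaton against an independent naive per-keyword substring scan on
hundreds of randomized instances, and asserts the state-count bound
(`states <= 1 + total pattern length`) and the one-step-per-character scan
property via an instrumented counter.

## Six-frame translation and coordinates

Frame labels follow the conventional reading: `+k` translates the forward
sequence from 0-based offset `k−1`; `−k` translates the reverse complement
from offset `k−1`. Trailing 1–2 nucleotides of a frame are dropped. All
emitted coordinates are 1-based, inclusive, on the forward strand (the GFF3
convention); a span `[s, e]` on the reverse complement of a record of
length `L` maps back to `[L−e+1, L−s+1]`. These conventions are load-bearing
— the reported reading frame of a match depends on them — so they are
asserted by mirror-symmetry property tests: mapping against a record and
against its reverse complement must give coordinate sets related by exactly
that transformation with strands flipped.

Genetic codes are read from a table file in the NCBI toolkit layout
(64-character `ncbieaa` amino-acid string plus `sncbieaa` initiation-codon
flags, TCAG codon nesting). The bundled table carries codes 1 (standard),
2, 4 and 11; any other table file in the same layout can be supplied, and a
simplified two-line key/value dialect is also accepted. Codons containing
any character outside `A/C/G/T` translate to `X`. The original tool's
behaviour on ambiguous nucleotides is not documented anywhere we could
check, so `X`-on-ambiguity is this package's own choice; since `X` can never
equal a peptide residue, it is the conservative one for an exact-match tool.

## ePST extension rules

All extension runs in coding-strand space: minus-strand matches are
processed on the reverse complement and mapped back afterwards, which makes
the rules strand-invariant by construction (and tested as such).

**Prokaryotic rule.** The match is extended 3' to the first in-frame stop
codon, which is *included* in the ePST — the tag then represents a complete
ORF-like unit, and the containment property (the peptide is always found in
the six-frame translation of its own ePST) is insensitive to this choice.
On the 5' side the first in-frame stop upstream is located, then the scan
returns downstream looking for the first start codon at or before the
peptide start; if none exists the peptide start opens the ePST. A contig
end before a stop truncates at the last complete codon and is flagged
`sequence_end` rather than raising an error — contigs legitimately end
mid-ORF.

**Eukaryotic signal-bounded rule.** Splicing means a stop-to-stop walk can
run far past a real exon boundary, so the scan also stops at splice
signals: 3' at the last complete codon before the first downstream donor,
5' at the nearest upstream acceptor, with in-frame stop codons (excluded)
and start codons (included) also terminating the 5' scan. Precedence among
the three 5' terminators is nearest-wins, scanning codon-by-codon outward;
when a splice position and a codon signal fall inside the same codon, the
splice signal wins (the codon is only accepted if it lies entirely before
the signal). Unlike the prokaryotic rule, the 5' scan examines codons
strictly upstream of the peptide, so a peptide whose first codon is itself
a start codon does not terminate the eukaryotic scan at the peptide start.
Canonical signals are every `GT` (donor, position of its first base) and
`AG` (acceptor, position of its second base) on the coding strand, scanned
without frame restriction — the dinucleotides, not a motif model, are the
default signal set. Alternatively, GeneSplicer predictions can be supplied;
the standard five-column prediction rows are parsed (the donor position is
`min(end5, end3)`, the acceptor `max(end5, end3)`), and forward-strand
positions are mirrored into coding space for minus-strand matches (donor
`p → L−p`, acceptor `a → L−a+2`, i.e. the corresponding base of the
mirrored dinucleotide span). Splice handling can also be disabled
(`sites = "none"`), which reduces the rule to start/stop bounded scanning.

**Fixed-length rule.** The span simply grows by `n` nucleotides each side,
clamped at the record ends. No codon-boundary guarantee is made; the
translation column is computed from the first complete codon of the
peptide's frame inside the span. A codon count is `3 × n` sugar.

In the codon-aware modes every ePST starts and ends on an in-frame codon
boundary, its length is divisible by three, and its translation contains
the peptide and at most one `*`, terminal, exactly when the 3' boundary is
a stop codon. These invariants are asserted in the test suite.

## Outputs

Three files per run, all derived from the same ePST table and checked
row-for-row consistent: a FASTA of ePST nucleotide sequences (headers
`epst|<peptide>|<record>|<start>-<end>|<strand>|<frame>`, wrapped at 60
columns); a 14-column TSV (peptide id and sequence, record header, match
coordinates, strand, frame, reverse-translated peptide, the longer
stop-to-stop context, ePST sequence, coordinates, length and translation —
the column names are this package's, chosen snake_case, since the
enumeration they follow never named them); and a GFF3 track of
`protein_match` features (source `pgmap`, phase `0` in codon-aware modes,
`.` in fixed mode, attributes `ID`/`Name`/`Target`). The GFF3 lines are
emitted directly by the package so that identical inputs produce
byte-identical files; tests validate the output by round-tripping it
through an independent GFF3 importer.

## The synthetic fixture generator

`generate_fixture()` builds the package's ground-truth test data: a genome
in which each peptide's reverse translation is embedded in a cassette with
known boundaries, on a random strand and frame. Prokaryote cassettes plant
a 5' stop, fillers free of starts and stops, a start codon, the peptide,
and a 3' stop; eukaryote cassettes bound the peptide with `AG`/`GT`
signals, using fillers drawn only from `C/T` codons so that no spurious
stop, start, or splice dinucleotide can arise anywhere in the cassette,
junctions included. The background is rejection-sampled until every peptide
occurs exactly once across all six frames, so the truth table (match
coordinates, frame, ePST boundaries) is exact by construction.

What the generator emulates: planted coding signals, both strands, all six
frames, contig truncation (via fixed-length clamping tests). What it does
not emulate: real codon-usage bias, repeat structure, overlapping genes,
multi-exon genes (multi-exon ePST assembly is out of scope for the
extension rules themselves), and sequencing ambiguity codes. Passing the
fixture tests therefore demonstrates the correctness of the matching and
boundary logic, not performance on any particular real genome — for that,
the packaged channel catfish virus dataset provides a real regression
anchor.

Default fixture scales in the tests (6–10 peptides of 7–15 residues,
genomes of a few kilobases) are chosen so each property runs in seconds
while still exercising both strands and all frames; the CCV dataset (17
peptides, ePSTs totalling ~5 kb) is the package's fixed real-data scale.

## The packaged CCV dataset

The package bundles the channel catfish virus proteogenomic dataset: 17
peptides that map to novel reading frames of the viral genome, together
with their published ePST nucleotide sequences and reading frames. Because
each ePST contains its source peptide by construction, mapping the 17
peptides against a FASTA of the 17 ePSTs must find every peptide — this
self-contained containment regression is the package's headline acceptance
check (`scripts/acceptance.R`). The published ePST sequences appear to
include context beyond a strict signal-to-signal span for some entries, so
the regression asserts peptide containment rather than sequence identity of
recomputed ePSTs.

The genome-level check (all 17 peptides on NC_001493.1, with
`NLDLLDNSTG` in frame `+1`) needs the viral genome FASTA, which is not
redistributed with the package; the corresponding test states how to supply
it and fails informatively when it is absent.

## Numerical and degenerate-input choices

* Records shorter than a codon translate to empty frames and yield no
  matches — logged, never an error; zero matches is a result.
* Peptides with letters outside the 20 standard amino acids are skipped
  with a warning and recorded in a skipped list (and written to
  `<prefix>.skipped.txt`), not fatal.
* Duplicate FASTA ids are uniquified with a numeric suffix; duplicate
  peptide *sequences* under different ids each get their own match rows.
* Hit ordering is fixed (end offset, then keyword id; match tables by
  record, frame `+1..+3,−1..−3`, then position) so outputs are
  deterministic and diffable.
* All randomness in the fixture generator is governed by a single seed and
  restored afterwards.

## Known limitations

Spliced (gapped) peptide matches across exon boundaries are out of scope:
a peptide spanning two exons will simply not match. Only exact residue
identity is supported. The eukaryotic rule produces single-segment ePSTs
bounded by the nearest signals; it does not assemble multi-exon models or
rank alternative boundaries. Runtime scales linearly with genome length for
a fixed peptide set; the implementation is single-threaded.
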