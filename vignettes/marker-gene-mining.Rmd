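---
title: "Marker-gene mining with BLAST score ratios: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gene mining with BLAST score ratios: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerMiner)
```

# The problem

Functional marker genes — *mcrA*, the alpha subunit of methyl-coenzyme M
reductase and the diagnostic gene of archaeal methane metabolism, is the
motivating example — can be surveyed directly in raw metagenomic reads,
without whole-metagenome assembly or binning. The workflow has five stages:

1. **Database curation.** Candidate proteins are compared against a seed
   family. For each candidate with any positive alignment, the BLAST score
   ratio (BSR) is the best family raw score divided by the candidate's
   maximum possible score, its self-hit. Candidates with BSR at or above a
   cutoff and near-full length are kept, then collapsed into a
   non-redundant centroid set by greedy 90%-identity clustering.
2. **Read screening.** Each read is translated in all six frames and locally
   aligned against the marker database; the best hit above a raw-score
   floor is kept.
3. **False-positive removal.** Every hit read is re-scored against an
   outgroup database (in production use, a comprehensive protein
   collection). The outgroup BSR is marker score / best outgroup score;
   reads are retained when the ratio is at least theta or when they have no
   outgroup hit at all — absence of a better non-marker homolog is the
   rationale of the ratio, and divergent true positives must survive.
4. **Gene reconstruction.** Datasets with strictly more than 20 retained
   reads (about two-fold coverage of a 1.5 kb gene at 150 nt reads) are
   assembled per dataset by a greedy overlap-consensus assembler; contigs
   longer than 1,000 nt are carried forward, reading frames (allowing
   edge-open predictions) are called, and proteins longer than 300 residues
   are selected.
5. **Profiling.** Reconstructed and database sequences recruit reads at a
   90% amino-acid identity floor; the below-floor fraction measures unseen
   diversity, and clade membership is assigned when the clade-vs-full-db
   BSR exceeds 0.75.

A small stoichiometry/energetics module accompanies the sequence tools: it
checks element and charge balance of proposed catabolic reactions and
normalizes whole-reaction standard free energies per mole of substrate
(e.g. methanol disproportionation to formate + methane at -203.4 kJ/mol
reaction is -67.8 kJ/mol methanol; to CO2 + methane at -319.4 kJ/mol is
-79.85 kJ/mol methanol).

# Alignment model

All scoring uses Smith-Waterman (local) or Needleman-Wunsch (global, end
gaps penalized) dynamic programming with BLOSUM62 and affine gaps. A gap of
length $L$ costs $g_o + (L-1)\,g_e$ with defaults $g_o = 11$, $g_e = 1$.
Bit scores are $(\lambda S - \ln K)/\ln 2$ with $\lambda = 0.267$,
$K = 0.041$; they are reported for human comparison only. **BSR is always a
ratio of raw scores**, so a self-hit is exactly 1 by construction — a ratio
of bit scores would not be.

The matrix is extended with `X` (scores 0 against everything, so masked
residues neither help nor hurt), `O` (pyrrolysine readthrough, scored like
X) and the stop character `*` (BLOSUM62's -4 penalty). Percent identity is
identical residue pairs divided by alignment columns *including gap
columns*, over the optimal global alignment; "MKVMKV" vs "MKV" is 0.5 by
definition. Traceback ties resolve diagonal > up > left, so outputs are
reproducible.

Translated search enumerates all six frames (table 11, the
bacterial/archaeal code; trailing partial codons dropped, ambiguous codons
rendered X, stops rendered `*`) and keeps the single best hit, ties broken
by lower database index then lower frame. The default per-read raw-score
floor is 40; it is deliberately permissive — random 150 nt reads searched
against ~20 centroids clear it a few percent of the time as a best-of-126
order statistic — because the outgroup BSR stage, not the score floor, is
the false-positive filter.

**The k-mer prefilter.** `screenReads(prefilter = TRUE)` skips the dynamic
program for frame/target pairs sharing no exact amino-acid 4-mer. For
high-identity hits (the reads the pipeline ultimately retains; at 0.5%
nucleotide error a 50-residue translation virtually always contains exact
4-mers) the prefilter is lossless, and the retained set after outgroup-BSR
filtering is identical with the prefilter on or off — both facts are
enforced by the test suite. What it drops are marginal noise hits at
25-45% identity hovering at the score floor, which the BSR stage removes
anyway. All protein-protein operations (curation, clustering, clade
assignment) run without the prefilter.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `bsrCutoff` | 0.5 | ratio | curation retention; a diagnostic scatter of the two scores is the intended companion |
| `minLenFraction` | 0.8 | fraction of median seed length | operationalizes "full-length" |
| identity threshold | 0.90 | global identity | greedy clustering |
| `minScore` | 40 | raw score | per-read hit floor |
| `theta` | 0.8 | BSR | read-level outgroup filter |
| `minHits` | 20 | reads | dataset gate, strict (> 20) |
| `minOverlap` / `minOverlapIdentity` | 30 / 0.95 | nt / identity | assembler merge thresholds |
| `minContigLen` | 1,000 | nt | strict contig gate |
| `minAa` | 300 | residues | strict protein-length gate |
| clade `cutoff` | 0.75 | BSR | strict clade assignment |

The three gates are strict inequalities ("over 20 hits", "over 300 amino
acids", ">1,000 bp"): 20 retained reads fail the gate, a 300-residue
protein fails the selection. The recruitment boundary is the one place the
two natural phrasings ("over 90%" recruited vs "lower than 90%" novel)
must partition the queries; identity **at or above** the floor counts as
recruited, so the two sets are complementary, and the convention is
recorded in the profile object (`boundary = ">="`).

# The greedy assembler

Reads from a single gene family at a few-fold coverage do not need a de
Bruijn assembler. The package uses a deterministic overlap-layout-consensus
scheme: all pairwise ungapped overlaps (either orientation) of at least 30
nt and 95% identity are computed; the longest overlap (then fewest
mismatches, then lexicographically smallest contig-id pair) is merged
first; placements accumulate; and the final consensus is the per-column
majority with ties resolved in favour of the earliest-placed read. Ungapped
overlaps match the substitution-only error model of the read simulator
(and of the screening stage, which discards qualities). The consensus is
reported on an arbitrary strand — downstream ORF calling is
strand-symmetric, and accuracy checks align both orientations.

Consensus accuracy is measured as the identity fraction of the optimal
*local* alignment of the consensus against the reference: contig ends stop
where coverage stops, and an end-gap-penalized global identity would count
uncovered reference ends as errors (an exact 1,643 nt consensus of a
1,650 nt gene would score 0.996 despite being perfect).

Known limitation: no chimera guard joins are special-cased; the assembler
is intended for a bag of reads already restricted to one family by the
screening stages.

# ORF calling on reconstructed contigs

Maximal stop-free codon stretches are enumerated in all six frames.
Stretches anchored at a contig edge are reported without requiring a start
or stop (flags `open5`/`open3`), because reconstructed gene contigs
routinely truncate mid-gene; interior stretches require a prokaryotic
start (ATG/GTG/TTG) and are trimmed to the first one. With
`amberReadthrough = TRUE`, TAG codes for the readthrough residue `O` and
only TAA/TGA terminate — without it, genes using amber-encoded pyrrolysine
(the methylamine methyltransferases of several methylotrophic methanogens)
truncate at the first TAG. Readthrough can *merge* two stretches that each
already pass the length filter, so it can reduce the number of reported
ORFs while rescuing truncated genes; the guaranteed property is that with
a length filter above each TAG-separated segment, readthrough never finds
fewer ORFs.

Coordinates are 0-based half-open in R objects and 1-based inclusive in
every written report.

# What the synthetic data emulate — and what they do not

Every stage is exercised by generated data with complete truth tables:

* **Families** are produced by per-site substitution (uniform among the
  other 19 residues) from a packaged 550-residue synthetic root protein
  ("mcrA-like" in length and composition only; generated, not copied from
  any database). Two topologies are available. `star` diverges every
  member independently from the root at its nominal level — useful for
  calibration, because realized divergence concentrates within about two
  points of nominal for 300+ residues. `tree` radiates members from
  randomly chosen earlier members in 0.1 steps up to a root-divergence
  cap, which is the shape real families have: total diversity can span
  20-60% while nearest relatives stay close. The distinction matters for
  curation: the raw-score BSR of a candidate against its nearest seed
  crosses 0.5 near 40% divergence (measured: about 0.47 at 40%, 0.24 at
  60%), so a star family at 60% against a root-only seed is *designed* to
  fail curation, while a radiating family with a curated core is the
  situation the method addresses. The standing curation benchmark
  therefore uses a 40-member tree family whose 10 lowest-divergence
  members form the seed database.
* **Genes** are reverse-translated with uniform synonymous codon choice
  (no codon-bias claims are tested); translation in frame +1 reproduces
  the protein exactly.
* **Reads** (150 nt, uniform start and strand, i.i.d. substitution errors
  at 0.5% by default) carry truth rows with source, interval, strand and
  nominal divergence. There are no indels and no quality-score model by
  default — the screening pipeline is quality-agnostic and the planted
  frame stays exact; an indel mode is intentionally absent rather than
  half-tested.
* **The spike-in screen** mixes 200 target reads, 200 reads from a paralog
  family diverged 50% from the marker root, and 10,000 background reads
  drawn from 40 unrelated genes. The outgroup database holds the decoy and
  background *proteins* — the role a comprehensive collection plays in
  production, where the true source of any spurious marker hit is present
  and drags its BSR down. Background reads with no outgroup homolog would
  be retained by design, so an outgroup that cannot see the background's
  sources would make precision meaningless rather than hard.

Passing tests on these data show the machinery is correct under the stated
error model and geometry; they do not show robustness to indels,
platform-specific error profiles, codon bias, chimeric reads or abundance
skew across datasets.

Problem sizes used by the test suite and the acceptance script — 500
oracle alignment pairs, 40-member curation families, 10 assembly
replicates at 10x coverage of a 1.5 kb gene, a 10,400-read spike-in — were
chosen as the smallest sets at which the measured rates stabilize, and run
in a few minutes end to end.

# Thermodynamics bookkeeping

Species carry elemental composition, charge and optionally a standard
formation energy (kJ/mol). `balanceCheck()` reports per-element and charge
residuals (products minus reactants); `reactionDg()` combines formation
energies linearly; `perSubstrate()` divides a whole-reaction value by the
substrate's stoichiometric coefficient. Formation energies are supplied by
the user's table — none are hard-coded as authoritative — and
whole-reaction values may be given directly, as in the packaged methanol
disproportionation examples, whose source compilation is not reprinted
here. Sign convention: negative is exergonic.

```{r thermo}
rx <- readReactions(system.file("extdata", "reactions_methanol.json",
                                package = "markerMiner"))
thermoReport(rx)
```

# Numerical and degenerate-input choices

* Empty local alignment (no positive-scoring pair): raw score 0, zero
  columns, identity 0 — not an error.
* Sequences shorter than a frame's offset translate to the empty string;
  contigs shorter than k get a zero k-mer vector and a `short` flag; GC is
  computed over unambiguous bases only.
* Greedy clustering visits sequences in length-descending order with input
  order breaking ties; each sequence joins the *first* centroid at or
  above the threshold. Idempotence on the centroid set follows.
* All simulators require an explicit seed; byte-identical outputs per
  seed.
* `evaluateAgainstTruth()` reports NA precision when nothing is retained
  (0/0), rather than inventing a value.

# Design choices that were genuinely open

* **Raw-score BSR** (not bit score): the self-hit is then exactly 1 and
  cutoffs are scale-free.
* **Curation scores candidates against the best single seed**, not a
  pooled profile — simpler, and the ratio already normalizes for length.
* **`bsrCutoff = 0.5` and `minLenFraction = 0.8`** are exposed
  configuration, not claims; the curation diagnostics table supports
  choosing them per family.
* **Reads with zero outgroup hits are retained**: the divergent true
  positives the method exists to find are exactly the reads a
  comprehensive outgroup may not contain.
* **Strictness of the three gates** follows the "over N" phrasing
  wherever one exists; each has a configuration override.
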