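---
title: "Consensus calling from molecule-tagged amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus calling from molecule-tagged amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conseqr)
library(dplyr)
```

## The model

Molecule tagging attaches a random oligonucleotide (the molecule tag, MT —
a UMI) to each template DNA molecule before exponential PCR. Every read
descending from one template then carries that template's tag, so
discrepancies among reads sharing a tag must be technical: sequencing
miscalls or polymerase substitutions. Collapsing each tag category into a
consensus sequence (ConSeq) cancels independent errors, and because each
ConSeq stands for one original template, relative ConSeq counts are robust
to preferential amplification.

`conseqr` operates on a per-read table: reads are parsed into
tag/primer/amplicon regions, binned by tag key, stacked into a depth × L
alignment matrix per category, and reduced column-wise to a consensus base
and quality. Qualities travel as Phred+33 strings (the FASTQ on-disk form)
and are decoded only where arithmetic happens.

### Region matching

The matcher is an anchored regular expression built from the declared
structure: a fixed-length tag, an optional linker, the primer (IUPAC
degeneracies expand to character classes), the amplicon capture, and — for
whole-fragment reads — the reverse-complemented 3' structure. Matching is
exact: no mismatches are tolerated in tag or primer regions. A read with an
error inside structure simply fails to categorize, which costs a small,
quality-dependent fraction of reads but never mis-assigns a tag. Tag
comparison is exact string equality; categories are not merged across
near-identical tags, and tag-collision handling is delegated entirely to
the c-score filter downstream. Coordinates are 0-based half-open
internally; only whole-region slices are exposed, and region qualities are
exact slices of the read's qualities.

### Read stacking and length clustering

Reads in one category almost always share one length: Illumina amplicon
reads have tightly clustered lengths and rarely contain indels. The
alignment matrix is therefore built by stacking reads row-wise, with no
gaps and no MSA. When lengths do differ, reads are binned by exact length
and only the largest bin is stacked (`n_used` of the resulting ConSeq
records how many). A tie between largest bins is broken deterministically
toward the greatest length; any fixed rule is equally defensible here, and
a deterministic one makes runs reproducible. The matrix builder is
pluggable, so an MSA-based builder can be slotted in, but stacking is the
default and the only built-in.

### Column consensus

For one column with bases $b_1..b_d$ and qualities $q_1..q_d$:

* the **mode base** wins; its quality is the mean of the qualities of the
  reads carrying it, rounded half-up and capped at 93;
* a **count tie** goes to the tied base with the highest mean quality —
  this is what makes depth-2 categories usable: two disagreeing reads are
  resolved by quality rather than discarded;
* an **exact quality tie** yields the IUPAC code covering the tied bases,
  with quality the rounded mean over all their observations. Downstream,
  an ambiguity call counts as correct iff the true base is in its
  expansion.
* `N` observations carry no base information: they are excluded from
  counting and from quality averaging (an all-`N` column yields `N`).

Rounding is half-up rather than R's round-half-even so that results do not
depend on the parity of neighbouring means.

### The c-score

Each ConSeq is scored
$c = \frac{1}{L}\sum_j f_j \, \bar q_j$, where $f_j$ is the fraction of
rows literally equal to the consensus base at column $j$ and $\bar q_j$
the mean quality of those agreeing observations. Under perfect agreement
$c$ equals the mean consensus quality; disagreement pulls it down, and
columns whose consensus is an ambiguity code contribute zero. The score is
Phred-scaled so the conventional removal bound of 35 (inclusive: `c ≤ 35`
is removed) is meaningful for high-quality runs: a clean Q40 category
scores ≈ 40, while a tag accidentally shared by two templates (a
"birthday paradox" collision) splits its columns wherever the templates
differ and scores far lower. This formula is this package's own
construction, designed for that threshold-scale compatibility; it is not a
transcription of any external definition, and c-scores from other
implementations are not numerically comparable.

### Filtering

`filter_params()` defaults: minimum depth 2, minimum mean consensus
quality 20, c-score bound 35, SRCs excluded. Each record is removed for at
most one reason, checked in the order depth → mean quality → c-score, so
the removal table partitions the input. SRCs have no c-score (depth 1) and
are filtered on mean quality alone when included. Note the c-score default
assumes a high-quality library: on a library whose mean quality is itself
near 35, the bound removes clean ConSeqs too and should be lowered
explicitly.

### Digital normalization

`subsample_category()` caps a category at `max_depth` reads by a seeded
uniform subsample. Accuracy gains saturate quickly with depth, so a cap
(e.g. 20–50) bounds runtime on heavily amplified tags at negligible cost;
the hypergeometric retention of the majority base is exercised in the test
suite.

## Paired-end input

Overlapping mates are merged before parsing. The reverse mate is
reverse-complemented and slid along the forward read; among overlaps of at
least `min_overlap` (default 10 nt) the smallest mismatch ratio wins, ties
going to the longer overlap, and pairs whose best ratio exceeds 0.25 are
routed to the non-overlap path. Within the overlap, agreeing bases take
`max(q_f, q_r)`; disagreeing positions take the higher-quality base with
quality `|q_f − q_r|` floored at 2, and an exact tie keeps the forward
base at quality 2 — conflicting evidence is deliberately left low-quality
so the consensus stage can out-vote it. These combination rules are this
package's own; read-through ("outie") geometries where the mates extend
past each other are not handled and return no-merge. Non-overlapping pairs
are processed as two linked consensus problems: mates are joined by read
id, keyed by `fwd_tag + "+" + rev_tag`, and the forward and reverse
amplicon regions are consensused independently per key.

## The simulator

`simulate_mt_reads()` emulates the protocol the method addresses, stage by
stage, with a truth table mapping every read to its tag, template and true
amplicon:

* **Tagging before PCR** — each of `n_molecules` template molecules draws
  a distinct random tag; with `collision_rate > 0` a matching fraction of
  keys is deliberately reused by a second molecule with a different
  template, planting birthday-paradox collisions.
* **PCR** — a per-molecule "founder" substitution is drawn with
  probability $1-(1-e)^L$ (one substitution somewhere in the fragment at
  cycle 1) and inherited by the roughly half of the molecule's reads that
  descend from the mutant first-cycle copy; later-cycle errors are
  independent per read at $1-(1-e)^{C-1}$ per base. This two-level
  approximation reproduces the key qualitative behaviour — a depth-
  independent error floor from early-cycle misincorporation — without
  simulating the full branching lineage.
* **Amplification bias** — each molecule's depth draw is scaled by a
  lognormal efficiency weight (σ = 0.3 by default), so realized depth
  correlates with efficiency.
* **Sequencing** — position-wise substitutions at a uniform rate or along
  a linear quality ramp (default Q38→Q28 across the read, a MiSeq-like
  profile); emitted qualities are computed as $-10\log_{10}p$ from the
  error probability actually used, so qualities are calibrated by
  construction.
* **Depth distribution** — lognormal (meanlog 1.0, sdlog 0.7, truncated
  to ≥ 1) by default, a right-skewed shape resembling real tagged
  libraries; it is a stand-in chosen for realism, not a fit to any
  dataset.

The default structure is 8-nt tags on both ends of the 515F/806R 16S V4
amplicon. What the simulator does **not** model: indel errors (rare on
Illumina), chimeras, quality-profile idiosyncrasies of particular
instruments, and true branching PCR genealogies. Tests passing on
simulated data therefore demonstrate the algorithmic properties —
error cancellation, depth monotonicity, collision discrimination — not
instrument-specific performance.

## Evaluation

`evaluate_epb()` computes errors per base against the truth: per record,
mismatches to the true amplicon divided by its length, with an IUPAC
ambiguity call counted correct iff the truth is in its expansion; records
are grouped by depth with mean and standard error, mirroring how
depth/accuracy trade-offs are usually displayed. For a key that maps to
two templates (a planted collision) the majority template is used; records
with unknown keys are excluded and counted.

## Problem sizes and numerical choices

The test suite and the acceptance script run simulations of 400–2000
molecules with 100–120 nt amplicons — large enough that binomial noise on
EPB estimates is far below the effects being checked, and small enough to
run in minutes on one core. Quality means are compared with a 1e-9
tolerance when breaking ties (they are means of small integer sets);
consensus qualities are capped at the Phred+33 ceiling of 93; merging
floors conflict qualities at 2 rather than 0 to keep the encoded character
printable and the evidence distinguishable from "no information".

## Known limitations

* Tag errors are not corrected: a sequencing error inside a tag creates a
  spurious (usually depth-1) category rather than rejoining its parent.
  This loses a little depth but never contaminates a category.
* Gapped consensus is out of scope; an indel-bearing read lands in a
  minority length cluster and is dropped from stacking.
* The c-score threshold of 35 presumes Q35+ base calls; see above.
* Variable-length tags are representable only by running multiple
  structure specs over the same input.
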