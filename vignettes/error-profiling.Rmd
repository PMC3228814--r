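---
title: "Profiling and correcting pyrosequencing errors in antibody amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling and correcting pyrosequencing errors in antibody amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ab454)
```

## The problem

454 pyrosequencing reads flow-space signals, so its characteristic failure
mode is miscounting the length of homopolymer runs: a GG in the template
becomes GGG in the read, a GGGG becomes GGG. For antibody variable-domain
(FV) amplicons this matters more than for most targets. Antibody libraries
contain very large numbers of closely related sequences, and a single
spurious indel shifts the reading frame of everything downstream,
destroying the conserved framework cysteines and tryptophan and turning a
productive rearrangement into an apparently unproductive one — or, worse,
creating the illusion of novel sequence diversity.

When each sample's true sequence is known (control antibodies verified by
Sanger sequencing), every read can be compared against its reference and
each difference called exactly. `ab454` implements that comparison as a
pipeline: simulate reads with a realistic error mixture, align each read to
its reference, extract and normalize error events, classify reads, profile
errors by type, region, homopolymer context and recurrence, and finally
correct frameshift-causing indels and re-call functionality.

## Read categories and the error model

Each read is assigned exactly one category from the event list of its
alignment:

* **accurate** — no events;
* **single_insertion** — exactly one 1-nt insertion;
* **multi_insertion** — only insertions, totalling 2 or more nucleotides
  (a 2-nt run extension counts here, as do two separate single
  insertions);
* **single_deletion**, **single_substitution** — one 1-nt event of that
  type and nothing else;
* **mixed** — anything else: two or more distinct event types, or a
  multi-base deletion or substitution.

The simulator's default mixture encodes the error structure reported for
replicate pyrosequencing runs of Sanger-verified control antibodies:
60% accurate reads, 12% single insertions, 8% additional multi-insertion
reads (insertion classes 20% combined), 5% + 5% single deletions and
substitutions, and 10% mixed multi-nucleotide variants. Treating pure
multi-insertions as their own class rather than "mixed" keeps the 12%
versus 20% insertion distinction computable; mixed is reserved for reads
combining distinct event types or multi-base non-insertion changes.

Indel placement is homopolymer-biased. With probability
`homopolymer_bias` (default 0.8) an insertion extends a run of length >= 2
of a base drawn from `insertion_base_probs`, and a deletion shrinks a
run; otherwise the event lands at a uniformly random interior site. The
default inserted-base distribution is G 0.55, A 0.20, C 0.20, T 0.05 —
chosen so that G accounts for just over half of inserted nucleotides, with
C and A well represented and T rare, the qualitative ordering observed in
the source data; the exact values are unpublished, so they are exposed as
a parameter rather than asserted. The 0.8 homopolymer bias is likewise a
modelling choice, not a measured quantity: published tables report indels
both at runs of 2-4 nt and at "random" sites without quantifying the
split, so the bias is a tunable default. Optional hotspots let specific
runs (e.g. a CDR1 polyG) attract extra weight, emulating the recurrent
codon-27/29 insertion errors seen in real runs.

Reference sequences are generated codon-wise (stop codons rejected), with
conserved Cys codons closing FR1 and FR3 and a Trp codon opening FR2, and
with codon-aligned GGG runs planted — always at least one inside CDR1.
Region lengths default to FR1 78, CDR1 24, FR2 51, CDR2 30, FR3 114,
CDR3 33 nt (330 nt total), a typical heavy-chain variable domain with all
boundaries on codon boundaries.

### What the simulator does not model

Simulated reads are error-free outside the planted events: there is no
flow-space signal model, no quality scores, no chimeras, no primer or
adapter sequence, and events within a read are kept at least 6 nt apart so
every planted event is unambiguously recoverable. Events are also confined
to the interior of the reference (3 nt margins), reflecting amplicons
whose termini are anchored by primers. Passing tests therefore demonstrate
that the aligner, classifier and corrector recover a known error structure
exactly — not that real 454 data is this clean. On real reads, closely
spaced events can merge into ambiguous alignments and terminal errors can
be absorbed into unaligned flanks.

## Alignment

Reads are aligned by an exact dynamic-programming aligner (C++ core) with
match +2, mismatch -1 and a linear gap cost of -1 per base. This scoring
follows the BLAST parameter set `-r2 -q-1 -G-1`; since no gap-extension
cost accompanies it, the simplest reading is a linear gap model, which is
what the package uses. End gaps are free on both sequences (overlap
alignment), and full coverage of the reference is then enforced by the
full-length filter rather than inside the recursion: a truncated read
leaves part of the reference unaligned and is dropped, exactly as only
reads covering the entire FV domain are retained before any error
statistics. For reads that do span the reference this is equivalent to a
glocal alignment, and it sidesteps the question of how local HSPs would be
stitched.

Traceback ties are broken deterministically (diagonal, then deletion,
then insertion); the canonical event list does not depend on this order
because indels are subsequently **left-normalized**: each indel is shifted
to the leftmost reference position producing an identical edited string,
and same-type events that normalize into the same homopolymer run are
merged into one multi-base event (so a read with two extra G's in one run
reports a single 2-nt insertion — "4G in place of 2"). The simulator logs
planted events in the same canonical form, which is what makes truth logs
and alignment output directly comparable. `N` aligns as a mismatch
against every base, so it can never manufacture a spurious match.

Coordinates follow one convention everywhere: 0-based reference positions,
insertions before `ref_pos`, deletions and substitutions over the
half-open interval `[ref_pos, ref_interval_end)`.

Homopolymer context is attached per event: the length of the maximal
reference run at the event site (for insertions, the run of the inserted
base adjacent to the insertion point; length 1 when it matches neither
neighbour). An event is "homopolymeric" when that run has length >= 2.

## Functionality and correction

Functionality is called from the alignment: a read is **productive** when
its net indel length is a multiple of 3 and its translation (started at
the read position aligned to the reference frame offset) contains no stop
codon; **stop_codon** when a premature stop is present, whatever the
frame; **unproductive** when it is frameshifted without a stop; and
**no_alignment** when alignment identity falls below a configurable floor
(default 0.6), the operational stand-in for unalignable "no rearrangement"
artifacts. Whether the conserved Cys/Trp residues survive is reported but
does not enter the verdict. Note that under this rule table most
frameshifted reads land in `stop_codon` rather than `unproductive`,
because a shifted frame almost always encounters a stop within ~100
codons.

Correction is the two-pass procedure used by reference-numbering tools: a
first alignment locates indels; insertions are excised from the read and
deletions are padded, restoring the reference numbering; the padded
sequence is re-aligned and functionality re-called. The pad symbol is a
lowercase `n`; a codon containing a pad translates to `X`, never to a
stop, so restored deletions cannot fabricate stop codons, but a padded
conserved codon does count as breaking the conserved residue.
Substitutions are never touched — they are invisible to frame
restoration, which is exactly why in-frame, stop-free substitution errors
survive correction and form the residual error mass that only repeated
sequencing could remove. The package compares reads against the supplied
Sanger-verified reference rather than a germline allele database: the
algorithmic skeleton (two alignment passes, excise/pad, re-identify) is
the same, but the reference covers CDR3, so CDR3 indels are corrected like
any others.

Recovery — a non-productive read becoming productive through correction —
is reported against two denominators, all reads and erroneous reads,
since published recovery percentages are ambiguous about which is meant.

## Numerical and design choices

* Probabilities in configurations must sum to 1 within 1e-9; category
  percentages are reported to 0.1%.
* Recurrent signatures group erroneous reads by their composition
  difference vector (dA, dG, dT, dC) plus canonical event positions by
  default (distinguishing, say, two different polyG hotspots with the
  same composition change); composition-only grouping is available as an
  option. The reporting threshold defaults to 0.5% of erroneous reads.
* The simulator, reference generator and pipeline each use a private RNG
  stream seeded explicitly, so fixtures are byte-reproducible and never
  disturb the caller's random state.
* Degenerate inputs: empty sequences and non-IUPAC characters are errors;
  an all-accurate mixture, an empty FASTA and an event-free read are all
  well-defined (100% accurate profile, empty collection with a warning,
  `accurate` classification).

## Problem sizes

The packaged analyses use a 330-nt reference throughout. Mixture-recovery
checks run at n = 5000 reads (3 binomial standard errors of the
configured mixture — at p = 0.6 that is about +/- 2 percentage points),
parameter-recovery and correction properties at a few hundred reads, and
the alignment oracle comparisons at up to 12 nt (exhaustive recursion)
plus longer random pairs against an independent overlap aligner. These
sizes give stable statistics while keeping a full run in minutes on one
core.

## A complete run

```{r, eval = FALSE}
res <- run_pipeline(replica_config(n_reads = 5000, seed = 7))
res$profile$categories     # category counts and percentages
res$profile$homopolymer_table  # "4G in place of 3"-style rows
res$functionality          # productive / unproductive / stop codon table
res$recovery               # recovered fraction, both denominators
```

## Known limitations

Substitution errors are out of correction's reach by design; reads whose
substitutions stay in frame and stop-free are indistinguishable from real
variants without repeated sequencing or clonal context. The classifier's
category for a read with coincidentally adjacent events reflects the
parsimonious alignment, not necessarily the generating process. And the
simulator's clean error model means measured recovery rates on synthetic
data are upper bounds for real reads.
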