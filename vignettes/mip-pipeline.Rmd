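---
title: "MIP panel analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MIP panel analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mipseqr analyzes targeted sequencing data captured with molecular
inversion probes (MIPs). This vignette explains the models each stage
implements, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the design decisions made
where the design was genuinely open.

## The capture model and coordinates

A MIP probe is described by its extension and ligation arm sequences and a
*scan target*, the genomic interval between the arms that the probe
actually interrogates. On the plus strand the extension arm ends at
`scan_start` and the ligation arm begins at `scan_end`; minus-strand
probes mirror the arm order. The contiguous interval covered by arms plus
scan — the *window* — is the reference footprint of a captured fragment.
All internal coordinates are 0-based half-open; 1-based coordinates exist
only at the MIPgen, VCF and report boundaries. A single conversion point
eliminates whole classes of off-by-one errors; MIPgen's 1-based inclusive
scan coordinates are converted on read, so a MIPgen row with scan
positions 101..211 becomes `[100, 211)`, 111 bp — the typical MIP target
size.

MIPgen design files carry no probe classes, so inversion and SRY probes
are declared in a small companion table (`mip_id`, `probe_class`,
`event_id`). Validation enforces arm lengths of 15–40 bp, positive scan
length, arm/scan adjacency when the design file carries arm coordinates,
and that every mutant junction probe shares an `event_id` with a
reference junction probe.

## Demultiplexing

An observed index is assigned to the unique sample whose barcode(s) lie
within `max_mismatch` (default 1) Hamming distance per index; ties at the
minimum distance and out-of-tolerance reads are left unassigned rather
than guessed. With barcode sets of pairwise distance ≥ 2·max_mismatch+1
this rule cannot cross-assign. Both separate index reads and inline 5'
barcodes (trimmed from read 1 before merging) are supported, since both
MIP protocols exist in practice.

## Overlap consensus merging

Mate 2 is reverse-complemented and every ungapped suffix/prefix overlap of
length ≥ `min_overlap` (default 11) is scored as the quality-weighted sum
of matches minus mismatches (weight = min of the two base qualities). The
best-scoring overlap with mismatch fraction ≤ `max_mismatch_frac`
(default 0.05) is consensus-called: agreeing bases get quality
`min(q1+q2, qual_cap)` (cap 60), disagreements keep the higher-quality
base at `|q1−q2|`; equal-quality disagreements deterministically keep the
mate-1 base at quality 0. Score ties break toward the longer overlap, so
the procedure is deterministic and order-independent. Pairs without an
acceptable overlap pass through unmerged and are aligned as individual
mates — non-merging is a valid outcome, not an error.

## Alignment

The built-in aligner is written for panel-sized references: exact 24-mer
anchors sampled across the read propose diagonals, candidates are
verified ungapped by mismatch counting, and when anchors disagree on the
diagonal (an indel) or no ungapped placement is acceptable the candidate
window is refined with a pattern-global `pairwiseAlignment`, which
supplies the gapped CIGAR. Placements with mismatch+gap bases above 10%
of the read length are rejected; a uniquely best placement gets MAPQ 60,
ties MAPQ 0. The aligner's sensitivity limit — a read with errors in
every sampled anchor goes unmapped — is negligible at panel error rates.
For genome-scale references an external `bwa mem` adapter is provided.

## Probe assignment and arm trimming

Captured fragments start and end at the probe window by construction, so
a merged read is assigned to the probe whose window endpoints match its
alignment endpoints within `tol` (default 5 bp — tolerant of small indels
and endpoint jitter, far below the tiling offset so cross-probe
misassignment is not a concern). Unmerged mates are matched on their
5'-side endpoint only. Among qualifying probes the smallest total
endpoint deviation wins, with ties broken toward the lexicographically
smallest probe id.

Arm bases are probe oligo sequence, not sample sequence: a variant under
an arm is invisible there, and leaving arm bases in the pileup dilutes or
erases true variant evidence. Trimming therefore removes every aligned
base whose reference position falls outside the assigned probe's scan
target, rewrites the CIGAR and advances the alignment start; insertions
at a trim boundary are removed with the trimmed side, and a trim side is
only active when the read actually reaches into that arm. Removal is a
hard trim, not soft clipping, so no downstream step can accidentally
re-include arm bases. Reads left without aligned bases are dropped and
counted. The module's core guarantee — no emitted read retains an aligned
position inside its probe's arms — is enforced by an exhaustive per-read
test.

## Coverage and downsampling

Coverage profiles (mean depth, fraction of bases at callable depth,
maximal sub-threshold and zero-coverage intervals per sample and target
region) are computed on full depth. For calling, reads are capped at
`cap = 500` per sample and probe by a uniform random subset; per-group
seeds are derived deterministically from the run seed and the group key,
so downsampling is reproducible regardless of processing order. The cap
granularity is a package choice — the capture literature states no
standard — and per-probe is the natural unit: over-capture in MIP data is
a per-probe phenomenon, while a coarser (per-locus) cap would thin
legitimately covered neighbouring probes instead of the offender.

## The genotyper

The internal caller is a deliberately simple diallelic pileup model, not
a reassembly caller — the external VCF/gVCF ingestion path exists for
that. At a site the alternative allele is the most frequent non-reference
observation; per-read error probability is
`ε = min(max(10^(−Q/10), error_floor), 0.75)` with `error_floor = 1e-4`
(base qualities above Q40 are not taken at face value, and a Q0 base —
which the consensus rule emits on an equal-quality disagreement — is
treated as uninformative rather than impossible); likelihoods are
`L(g) = Π P(obs|g)` with `P(obs|allele) = 1−ε` on match, `ε/3` otherwise,
and the heterozygote an even mixture. The prior over genotypes is
uniform, so GQ — the Phred-scaled gap between best and second-best
posterior, i.e. −10·log10 of the odds of an incorrect call — equals the
likelihood gap, and is capped at 99. Sites with fewer than
`min_call_depth = 8` observations are no-calls (`./.`). Candidate sites
require ≥ 3 supporting reads and ≥ 20% of a sample's depth; every sample
is then genotyped at every candidate site, which keeps the multi-sample
VCF rectangular.

Indels are represented as left-aligned, parsimony-trimmed alleles keyed
at the anchor base. Left normalization happens at pileup time, so
equivalent gap placements from the aligner collapse onto one canonical
site. Hemizygous calling (ploidy 1 for X-linked targets in inferred
males) is available but off by default, matching the common default of
diploid joint calling.

## Inversions and sex

Recurrent inversions are genotyped from a second alignment pass of all
reads against a contig-only reference holding each event's reference and
mutant junction sequences. Reads at MAPQ ≥ 20 are counted per contig;
per event, totals below `min_event_reads = 10` are FAILED, a mutant
fraction ≥ 0.8 is INVERTED, ≤ 0.2 is REF, anything between AMBIGUOUS.
The 0.8 default reflects hemizygous male patients (near-pure mutant
signal); heterozygous carrier screening would lower it to ~0.3. The
numeric rule is this package's explicit interpretation — count-based
inversion reporting is standard, a published threshold is not.

Sex is called from reads assigned to Y-unique (SRY) probes: male when the
SRY count clears both an absolute floor (10) and a fraction (5×10⁻⁴) of
the sample's assigned reads, female at ≤ 2 SRY reads (tolerating index
hopping), ambiguous between.

## QC flags and reports

A probe fails for a sample when its count is below `min_reads = 10` or
its relative abundance falls below `min_rel_frac = 0.05` of that probe's
cross-sample median; overperformance beyond 20× the median is flagged
symmetrically. Only target-class probes are judged — SRY probes are
legitimately empty in female samples. Sample flags have strict priority:
`Failed Sample` (no usable results) > `Failed Inversions` (any FAILED
event) > `Check MIPs` (≥ 5 failed probes or < 95% of target bases at
callable depth) > `OK`. `Failed Sample` is the totalizing case the flag
set needs to be a function of arbitrary inputs.

Five CSV tables (`ind_status`, `variant_calls`, `variant_calls_benign`,
`variant_annotation`, `inversion_calls`) join on `sample_id` or the
`chrom:pos:ref:alt` variant key; the benign table is a row-wise subset of
the calls table driven by a user-supplied benign list (no clinical
database is bundled). HTML reports (`summary.html`, `report.html`, one
`ind_<sample>.html` each) are generated from templates with stable
element ids, so consumers and tests address parsed structure rather than
bytes; benign variants render gray, others highlighted. Exon/intron-style
annotation is ingested from a user-supplied table; the package never
computes effect predictions itself.

## The synthetic data generator

`simulate_run()` emulates a desk-scale run end to end: two random
reference loci (GC ≈ 0.5, no real genomic sequence shipped) tiled by 40
target probes with 20 bp arms and 111 bp scans at a 56 bp offset (~50%
overlap, so arm-hidden variants are always rescued by a neighbouring
probe); an SRY contig with 5 probes; 2 inversion events as independent
ref/mut junction contigs; 8 samples with length-8 barcodes generated at
pairwise Hamming distance ≥ 3; per-sample planted SNVs and 1–3 bp indels
(3 per sample, 20% indels, 30% homozygous) on phased haplotypes;
log-normal per-MIP capture factors (σ = 0.5, mean 1) shared across
samples — the "highly imbalanced" property MIP panels are known for;
Poisson read counts at ~50 pairs per probe and sample; 100 bp reads with
Q30-consistent substitution errors (rate 0.001). Arm bases in simulated
fragments are reference (probe) sequence while the scan is
haplotype-derived, which is exactly the property that makes arm trimming
necessary. Every read records its true sample and probe, so
demultiplexing, assignment, genotyping, sex and inversion calls can be
scored exactly.

Planted variants are private to one sample and spaced ≥ 10 bp apart
run-wide, with indels pre-normalized; this keeps every call site clean to
score. Deliberately not modelled: PCR duplicates and polymerase bias,
quality-score degradation along the read, chimeric fragments, barcode
cross-talk, and shared (population) variants. Passing tests on this
generator therefore demonstrate the pipeline's logic — coordinate
handling, trimming safety, likelihood arithmetic, count-based calls,
report integrity — not robustness to those artifacts on real instruments.

Default problem sizes (8 samples × ~47 probes × ~50 pairs ≈ 18k read
pairs; a smaller 4 × 12 configuration in module tests) keep a full
pipeline run around a minute on one CPU, which is the scale the test
suite and the acceptance script use.

## Numerical and degenerate-input choices

Quality arithmetic is integer Phred+33 throughout; consensus qualities
cap at 60 and GQ at 99. Empty samples get relative abundance 0 rather
than NaN. Zero-coverage intervals are reported as deletion candidates
only when the sample's mean target coverage elsewhere is ≥ 20
(`adequate_mean`), since a failed sample has no coverage anywhere. A
probe tie in assignment (identical total deviation) breaks to the
lexicographically smallest id; an alignment tie to the lexicographically
first placement at MAPQ 0. The flag function is total: any combination of
upstream results maps to exactly one of the four flags.

## Known limitations

The internal genotyper has no local reassembly, so complex or clustered
indels near each other can be mis-spelled; the external VCF path is the
remedy. The built-in aligner is not a general-purpose mapper: it assumes
panel-sized references and high base quality. Inversion calling is
restricted to events represented by designed junction contigs —
breakpoint discovery is out of scope. Variant annotation (HGVS, effect
prediction) is ingested, never computed.
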