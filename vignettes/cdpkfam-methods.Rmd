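---
title: "Methods: a genome-wide CDPK family survey pipeline"
author: "cdpkfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a genome-wide CDPK family survey pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Calcium-dependent protein kinases (CDPKs) are plant calcium sensors that
combine an N-terminal serine/threonine kinase domain with a C-terminal
calmodulin-like region built from EF-hand motifs. A genome-wide family
survey asks, for one target genome (here the allotetraploid white clover,
*Trifolium repens*, with its "O" and "P" homoeologous subgenomes): which
genes belong to the family, how do they partition into the canonical
groups I-IV, what conserved motifs do they share, how did the family
expand by duplication, which functional partners do they interact with,
and how do they respond to cold stress over time?

`cdpkfam` implements that survey as a set of composable stages plus a
seeded synthetic-data generator whose planted truth drives the test
suite. The stages are:

1. **Identification** — reference proteins query the target proteome by
   exact Smith-Waterman local alignment (BLOSUM62, affine gaps 11/1); a
   target is a candidate when some reference covers at least 80% of the
   longer sequence at an e-value proxy of at most 1e-5, and a candidate
   is confirmed when it carries both a kinase-domain hit and at least one
   EF-hand hit.
2. **Phylogeny** — MAFFT alignment, uncorrected p-distances, Saitou-Nei
   neighbor joining, nonparametric column bootstrap, and clade-based
   assignment of members to the groups of labelled reference leaves.
3. **Motifs** — EM (MEME-style) discovery of up to ten motifs of width
   6-50, any number of occurrences per sequence, with sequential masking.
4. **Duplications** — pairs above 80% identity and 80%
   coverage-of-the-longer-gene, collapsed over tightly linked copies and
   classified tandem versus segmental.
5. **Network projection** — reciprocal best hits map target genes onto a
   reference co-functional network; edges transfer when both endpoints
   are mapped (interolog projection).
6. **GO enrichment** — one-sided hypergeometric tests with the elim
   hierarchy correction at alpha 0.05, per namespace.
7. **Expression and qPCR** — FPKM, the strict FPKM > 1 expressed filter,
   log2(x+1) plus per-gene centring/scaling, average-linkage clustering
   on 1-Pearson distances, fold-change response calls against the 0H
   control, and 2^-ddCt quantification of Ct tables.

`run_survey()` chains all stages from one input bundle and writes a
report bundle; two runs with the same seed are byte-identical.

# Scoring and identification choices

**E-value proxy.** BLAST itself is not invoked; significance of a local
alignment of score $S$ between sequences of lengths $m,n$ is summarised
by the Karlin-Altschul form $E = K\,m\,n\,e^{-\lambda S}$ with the
gapped BLOSUM62/11/1 constants $\lambda = 0.267$, $K = 0.041$. This
keeps the familiar 1e-5 cutoff semantics with an exact aligner. Scores
come from dynamic programming (via Biostrings), where a gap of length
$L$ costs $11 + L$.

**Coverage denominator.** Coverage is alignment length over the *longer*
sequence, for both identification and duplication calling, so one
convention serves both stages.

**Domain filter.** Profile HMMs are deliberately not re-implemented.
Each domain is a fixed consensus block (kinase-like, 60 aa, carrying the
VAIK/HRD/DFG-style catalytic anchors; EF-hand-like, 29 aa, with the
DxDxDG calcium-binding loop); a window is a hit when its ungapped
BLOSUM62 similarity to the block reaches 60% of the block's self-score.
At the generator's 10% domain substitution rate the expected window
score is about 88% of the self-score with a standard deviation of a few
percent, so the 60% threshold separates planted domains from background
by several standard deviations in both directions. Membership requires
both domain labels; `require_both = FALSE` relaxes this, since the
original protocol's text does not state whether one or both Pfam models
were mandatory.

# Phylogeny

The aligner is MAFFT (default parameters, deterministic), which is what
a practitioner would run where the original protocol used MUSCLE; any
pre-computed alignment can be passed instead, so the aligner is not a
hard dependency of the downstream statistics. Distances are uncorrected
p-distances with pairwise deletion of gap columns (the protocol names no
substitution model). Neighbor joining is the classic Saitou-Nei
agglomeration; negative branch-length estimates are clamped to zero with
the deficit moved to the sister edge, preserving the path length of the
joined pair. On tree-additive matrices the generating topology and
branch lengths are recovered exactly (this is a property test). "Rapid
bootstrap" is read as a plain nonparametric column bootstrap: resample
columns with replacement, rebuild, and score each internal bipartition
of the full-data tree by its replicate frequency. The default of 1000
replicates matches the study; tests and the pipeline's scaled runs use
30-200 replicates, a package choice that keeps suites fast while the
support estimator is unchanged.

Group assignment roots nowhere: for each member leaf, the smallest
bipartition side containing the member and at least one labelled
reference leaf is found over all edges; the member inherits the group
when all reference leaves in that side agree, and is `ungrouped`
otherwise. This reproduces the study's behaviour of leaving a few
members outside groups I-IV when they fall between reference clades.

# Motif discovery

Each motif is a finite mixture over fixed-width windows: PWM versus a
0-order background estimated from the input. EM updates posterior site
probabilities, the PWM (pseudocount 0.1), and the site abundance
(clipped to [1/windows, 0.3]); convergence is a PWM sup-change below
1e-4 or 200 iterations. Site calling is ANR: any window at posterior
odds of at least 10 against background, greedily non-overlapping. After
each motif its sites are masked, so site sets are disjoint across
motifs.

Three design choices matter and were tuned on principle, not on any
specific dataset:

* **Seeding.** EM from random substrings rarely lands on a planted
  block. Seeds are therefore drawn from (a) windows dense in 4-mers that
  recur across sequences — conserved blocks light up even at 10-20%
  divergence — (b) windows with the lowest background likelihood, and
  (c) random windows. Short 5-iteration EMs rank the seeds and the two
  best are run to convergence.
* **Width selection.** EM runs at widths {6, 8, 10, 15, 20, 29, 50}
  intersected with the requested bounds, and the width maximising a
  BIC-penalised log-likelihood ratio, $\mathrm{LLR} - \tfrac{19\,w}{2}
  \log(\text{sites})$, wins. The per-column penalty scales with the
  realised site count, which stops wide windows from absorbing flanking
  noise columns.
* **Phase refinement.** A converged EM can sit a few columns off the
  true site. The called site set is shifted by -3..3 columns, the PWM
  re-estimated per shift, and the maximum-LLR phase kept before sites
  are re-called.

# Duplications

A reported pair must exceed both 80% thresholds strictly. "Tightly
linked" copies — the same chromosome with at most one intervening gene
in coordinate order over the full annotation — merge transitively into a
cluster, and each cluster pair contributes one event, so a three-copy
tandem array counts once. An event is tandem when its partners share a
chromosome and are within the tight-linkage window or 100 kb; otherwise
segmental. Both knobs (`max_intervening`, `max_span_bp`) are exposed
because the original protocol quantifies neither. Collinearity blocks
(MCScanX-style synteny) are out of scope; segmental simply means
"duplicated but not tandem", matching the binary reporting of the
survey this package re-implements.

# Network projection and enrichment

Reciprocal best hits use the same aligner and e-value proxy as
identification (one scoring contract across the artifact). Strict
reciprocity is the default; the one-way maps are available from
`best_hit_map()` directly for the looser reading. Projection transfers
an edge when both endpoints map, drops self-loops and merges duplicate
edges; family-centred subnetworks are 1-hop ego graphs by default, with
per-seed interactor counts taken in the full projected network.

Enrichment is the hypergeometric upper tail with the elim correction:
terms are processed deepest-first, and a term significant at alpha 0.05
has its annotated genes removed from its ancestors before they are
tested. Only the elim variant is implemented (the protocol names topGO
without a variant); the classic Fisher p-value is reported alongside as
`p_raw`, both unadjusted, which is the topGO reporting convention. The
background gene universe is a required explicit argument, because the
original protocol does not state whether the whole proteome or the
projected network served as background.

# Expression and qPCR

FPKM is $10^9 c / (N L)$ with $N$ the per-sample total of mapped reads.
The generator emits $N$ explicitly: a family panel of ~50 genes is a
negligible slice of a transcriptome, and summing the panel's counts
would let a strong planted induction inflate the denominator and bias
every fold change (a real RNA-seq quantifier takes $N$ from the whole
library). When no totals are supplied, column sums are used.

The zero-handling of "log2" is a +1 pseudocount; centring/scaling is
per gene, with zero-variance genes set to all-zero rows under a
warning. Response calls compare replicate-mean FPKM per timepoint with
the control via $\log_2((\bar x_t + 1)/(\bar x_{0H} + 1))$ at a
threshold of 1 log2 unit — the study reports "up-regulated" without a
stated criterion, so the threshold is a package default and exposed.
2^-ddCt averages replicate dCt values per timepoint and normalises to
the control, whose fold change is exactly 1.

# The synthetic study system

The generator emulates the study's conditions as defaults: 16
chromosomes in O/P pairs, 50 members in groups I = 17, II = 15,
III = 13, IV = 5 (the published table's partition), single-domain
decoys, two tandem clusters and five segmental pairs, 10% domain
divergence, 80% orthology coverage, a 200-edge reference network, the
eight cold timepoints 0H-72H with three replicates, a 15-gene planted
early induction of eight-fold, five silent genes, negative-binomial
counts with dispersion 0.1, and a 32-fold qPCR peak gene quantified at
0.2 cycles of Ct noise.

Group structure comes from group-specific random core sequences; each
duplication unit diverges 20% from its group core, copies within a unit
2% from the unit ancestor, and reference orthologs 5% from their target
gene. These rates place within-unit identity (~92-96%) safely above the
80% duplication thresholds and cross-unit identity (~65-70%) safely
below, with the margins large relative to sampling noise at typical
protein lengths. The reference proteome consists of the planted
orthologs themselves, with member orthologs carrying group labels; this
makes reciprocal-best-hit truth structurally clean, since every
reference protein has a designated 95%-identity partner and spurious
reciprocal pairs cannot form.

Mutations are substitutions only. That keeps planted domains at known
coordinates and full-length alignments at coverage ~1, which is what
the coverage-threshold tests need; it also means the generator does not
exercise indel handling in the aligner (the alignment oracle tests do).
Other deliberate non-realisms: no codon or intron sequence content
(the GFF3 carries coordinates and exon counts only), uniform residue
usage instead of real amino-acid composition, no read-level simulation,
and protein lengths that are constant within a group. Passing recovery
tests therefore demonstrate the algorithms' contracts under controlled
truth, not performance on real proteomes.

# Problem sizes and determinism

The test suite runs the full-size synthetic study (50 members, 30
decoys) for recovery-rate checks and a reduced one (24 members, 10
decoys, 30-replicate bootstrap, 2 motifs) for end-to-end and
byte-reproducibility checks; the acceptance script runs the full-size
study plus a 50-sequence motif experiment. These sizes are package
choices balancing coverage against suite runtime. Every stochastic
component (generators, bootstrap, motif seeding) derives its stream
from an explicit integer seed, and each generator stage seeds
independently with a fixed offset, so partial reruns reproduce the
same data.

# Known limitations

* The e-value proxy uses fixed Karlin-Altschul constants; it is a
  cutoff device, not a calibrated significance estimate.
* Consensus-block domain scanning is not a profile HMM; sensitivity to
  strongly diverged real domains will be lower than HMMER's.
* Segmental classification is purely positional; without synteny
  blocks, ancient tandem copies separated by later rearrangements would
  be misclassified.
* The motif model is 0-order background with a per-motif PWM; it does
  not model gapped motifs or higher-order composition.
* Expression response calls are threshold rules on replicate means, not
  a dispersion-modelling differential test; they match the descriptive
  analysis they re-implement, not a DESeq2-style inference.
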