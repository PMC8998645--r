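---
title: "Methods and design notes for rlrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for rlrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlrkit)
```

# Scope

rlrkit implements a molecular-evolution analysis pipeline for RIG-I-like
receptor (RLR) gene families — cytoplasmic viral-RNA sensors built from a
DEXDc + HELICc helicase core and a C-terminal regulatory domain (RD), with
highly variable N-terminal signalling domains, especially across
lophotrochozoans. The pipeline covers five analyses: domain-architecture
typing, tandem-array detection from scaffold gene orders, exon–intron
structural-divergence mechanism classification between sibling homologs,
FPKM-based expression profiling with differential-expression calling, and
codon-model tests for positive selection. A synthetic-data module
generates every input format with planted ground truth, so each stage is
validated end-to-end without external downloads.

Upstream steps that produce these inputs — homology search and gene-model
correction (HMMER/TBLASTN/GeneWise), multiple sequence alignment and tree
building (MAFFT/IQ-TREE), and read mapping/quantification — are out of
scope; the package consumes their standard outputs (GFF3 + FASTA, domain
tables, newick trees, count matrices, codon alignments).

# Gene models and coordinates

Internally all genomic intervals are 0-based half-open; GFF3 I/O converts
at the boundary (GFF3 is 1-based inclusive). Only CDS features define a
gene model's exons, because the structures being compared are
protein-coding exon diagrams; UTR exons are ignored. A terminal stop codon
is trimmed from the translation; an internal stop sets a flag but does not
reject the model — pseudoexonization and recent exonization can
legitimately put stops in an annotated frame. Records whose spliced CDS
length is not divisible by 3 are rejected (with the gene id reported),
since no consistent reading frame exists.

# Pairwise alignment

Global (Needleman–Wunsch) and local (Smith–Waterman) affine-gap alignment
are computed by `Biostrings::pairwiseAlignment`; a gap of length $L$ costs
$o + Le$ (open $o$, extend $e$). Defaults: BLOSUM62 with $o=10$, $e=0.5$
for protein; match $+2$ / mismatch $-3$ with $o=5$, $e=2$ for DNA.
Identity is matches over aligned columns excluding double-gap columns;
"similarity" (positively scoring substitutions) is reported separately,
since percent-similarity claims in the literature are ambiguous between
the two. The test suite validates the engine against an independently
written exhaustive three-state (Gotoh) dynamic program on hundreds of
short random pairs.

Exon-to-alignment mapping converts an exon covering CDS nucleotides
$[s, e)$ to protein positions $[\lfloor s/3 \rfloor, \lceil e/3 \rceil)$;
a residue whose codon is split by an exon boundary is assigned to the 5'
exon and the boundary is flagged.

# Architecture typing

A gene passes the RLR screen when DEXDc, HELICc and RD all occur, in that
order, along the protein. The N-terminal architecture (domains preceding
the helicase core) is collapsed — runs of a repeated domain count once,
except CARD whose copy number is kept up to two, because one versus two
CARDs separates the cnidarian-like type (C) from the vertebrate-like
two-CARD type (V1) — and looked up in a taxonomy table mapping patterns to
the 11 labels A1, V1, V2, C, L1–L6 and X.

Only some labels are firmly anchored in the field's usage: V1
(CARD–CARD), V2 (no N-terminal domain), C (single CARD), A1
(death-domain, sponges), L2 (DED) and L4 (IG). The remaining L types are
shipped as editable defaults (L1 = lophotrochozoan CARD–CARD, L3 = CASc,
L5 = SAM, L6 = lophotrochozoan death-domain) rather than hard-coded:
clade-specific rows take precedence over generic ones, the taxonomy can be
replaced from a TSV, and every output records the `taxonomy_version`.
Unmatched architectures classify as X with the observed pattern kept as
evidence, which makes classification total: every architecture maps to
exactly one label.

# Tandem arrays

A tandem array is a maximal run of RLR genes on one scaffold in which
consecutive RLRs are separated by at most `max_intervening` non-RLR genes.
The default of 3 reflects that local duplicates in real assemblies are
usually interleaved with a few unrelated genes; the parameter is exposed
because the field has no fixed convention. Raising `max_intervening` can
only add genes to arrays (a property the tests check).

# Structural-divergence classification

This is the core algorithm. For a sibling pair (a cherry in the gene
tree — the two most similar homologs), the two gene structures are
compared on the global protein alignment:

1. **Exon homology.** Each exon's residues are mapped to alignment
   columns. Two exons are homology candidates when their reciprocal
   overlap reaches `tau_overlap` (default 0.5) under *either* of two
   definitions: aligned residue pairs (robust when the aligner scatters
   gaps inside an exon's interval) or column intervals (robust when a
   large intraexonic indel leaves few aligned pairs). Candidates are
   matched greedily by descending aligned-pair count, 1:1, with crossing
   matches forbidden. Two guards absorb alignment ambiguity around large
   insertions, which a single optimal global alignment cannot avoid (the
   optimal path sometimes scatters a long gap into spurious
   junk-sequence matches for a handful of points): a match is demoted if
   it rests on fewer than 5 aligned pairs or shows identity below
   `min_match_identity` (0.2 — midway on the scale between random
   protein identity, about 0.07, and the most diverged homologs
   considered), and two leftover orphans are rescued into a match when
   their exon sequences align directly at identity at least
   `rescue_identity` (0.3).

2. **Divergence test.** A pair is structurally divergent iff the exon
   counts differ or at least one matched exon pair has unequal
   nucleotide lengths.

3. **Mechanisms** (not mutually exclusive):
   - *Intraexonic insertion/deletion*: a gap run of at least
     `min_indel_aa` (2) columns strictly inside a matched exon pair,
     flanked by at least 5 aligned columns, **and** a matched-exon
     length difference of at least `min_indel_aa` codons. The length
     condition is definitional — an indel changes the exon's length —
     and suppresses compensating gap pairs that affine alignment
     introduces between diverged but indel-free exons.
   - *Exonization/pseudoexonization*: an orphan exon of at least
     `min_orphan_aa` (10) residues whose nucleotide sequence locally
     aligns to the partner's non-exonic sequence (introns plus `flank`,
     default 5 kb) at identity ≥ 0.40 over ≥ 0.60 of the orphan — the
     quantification of "aligned with confidence". This search uses a
     sensitive DNA scoring (match +1 / mismatch −1, gap open 6 /
     extend 1): the default +2/−3 scoring reaches its break-even exactly
     at 60% identity, the expected identity of a pair whose branches
     each carry 20% substitutions, and would truncate true hits; gaps
     stay expensive because a true non-coding homolog diverges by
     substitution, so meandering gapped alignments are evidence of
     nothing.
   - *Gain/loss of exon/intron*: orphans with no such non-exonic hit
     (novel sequence), and split-pattern orphans — an orphan whose
     residues mostly align, at homolog-level identity, into one matched
     partner exon, the signature of one exon corresponding to two after
     an intron gain/loss.

   Because assigning polarity (exonization vs pseudoexonization; gain vs
   loss) needs an outgroup, the labels bundle both directions.
   Classification is symmetric in the pair order.

# Expression

FPKM is $c \cdot 10^9 / (N \cdot \ell)$ with $c$ the fragment count, $N$
the library size and $\ell$ the gene length in nt; gene length is the
spliced CDS length (the choice is stated because conventions differ).
Differential expression uses a conditional negative-binomial exact test
with a single common dispersion as a documented stand-in for an edgeR
analysis — equivalence to edgeR is not claimed. The common dispersion is
estimated by conditional maximum likelihood given the per-gene group sums
(the qCML idea), which, unlike the method of moments at 3 replicates, is
nearly unbiased; a moment estimator shifted the null p-value distribution
visibly liberal in calibration runs. The two-sided p-value sums the
probabilities of all splits of the pooled count no more probable than the
observed one; dispersion 0 reduces to the exact binomial (Poisson) test.
Fold changes are $\log_2((\bar F_b + c)/(\bar F_a + c))$ on mean FPKM with
pseudocount $c = 0.01$. A gene is significantly differentially expressed
when $|\log_2 FC| \ge 1.5$ and BH-FDR $\le 0.05$; "upregulated"
additionally requires the fold change to be positive. A fold-change-only
mode (`fc_only = TRUE`) reproduces the laxer upregulation rule used for
infection contrasts, where both conditions cannot always be required.

# Codon models

The GY94 rate matrix over the 61 sense codons has off-diagonal rates
proportional to the target codon's frequency $\pi_j$, times $\kappa$ for
transitions and $\omega$ for nonsynonymous changes; multi-nucleotide
changes are forbidden. Codon frequencies default to F3x4 (positional
nucleotide frequencies, stops removed, lightly smoothed so no sense codon
has frequency zero). For site mixtures (M1a: $\omega_0 < 1$ plus neutral;
M2a: adds $\omega_2 > 1$; M7: beta-distributed $\omega$ in 10
equal-probability categories; M8: beta plus a selected class) the class
matrices share a single scaling so the *mixture-average* substitution
rate is one per unit branch length; the two-ratio branch model scales
each matrix to rate one separately, matching the usual convention that
branch lengths are expected substitutions per codon.

Likelihoods use Felsenstein pruning with per-class eigendecomposition of
the symmetrised reversible generator; the inner loop is in compiled code
(RcppArmadillo), as is usual for phylogenetic likelihood packages. Gaps
are missing data (partial likelihood one for every state). Fits maximise
over $\kappa$, the $\omega$-parameters and all branch lengths by L-BFGS-B
on log/logit-transformed parameters, from three start points by default
(one standard, two jittered under seeds derived from the user's seed).
An alternative model can be warm-started from its nested null
(`init =` the null fit): the extra positively selected class enters with
near-zero weight, so the start point is likelihood-equivalent to the null
optimum and the nesting inequality
$\ln L_{\text{alt}} \ge \ln L_{\text{null}}$ holds up to optimizer
tolerance (the tests allow $10^{-2}$). Likelihood-ratio tests use
$\chi^2$ with 2 df for M1a–M2a and M7–M8 and 1 df for M0 versus the
two-ratio model; these tests are conservative on boundary nulls, which
the type-I calibration below confirms.

Positively selected sites are reported by naive empirical Bayes (NEB) at
the MLEs, flagging sites whose posterior probability of an $\omega > 1$
class exceeds 0.9. This is a deliberate simplification relative to BEB
(which integrates over parameter uncertainty); NEB is known to be less
reliable at small sample sizes, and the function documentation says so.

The simulator draws each site's class once, evolves root-to-tips from the
stationary distribution with the same scaled matrices the likelihood
uses, and returns the true class per site, so simulate-then-fit
round-trips are exact tests of the machinery.

# Synthetic data: what it emulates, and what it does not

The generators emit every input the pipeline reads, each with a truth
record. Design choices:

- Background divergence between siblings is i.i.d. nucleotide
  substitution at a per-branch rate with a 2:1 transition bias and *no
  indels outside the planted event*, keeping truth labels unambiguous. A
  pair whose branches each carry rate $d$ is about $2d$ diverged.
- Structural events are planted in exactly one randomly chosen
  descendant: exon gain inserts novel sense codons into an intron;
  exonization overwrites a stretch of the shared ancestral intron with
  sense codons and raises it to an exon in one descendant only (so the
  partner retains the homologous sequence as intron — the defining
  signal); intraexonic indels insert or delete whole codons inside an
  exon with 8-codon margins; splits insert an intron mid-exon. Default
  event sizes are 100–300 aa, the size range of the large exon-gain
  events reported in real RLR sibling pairs; validation runs use
  30–300 aa to include harder, smaller events.
- Count matrices are negative binomial with log-normal baseline means
  (median ≈ 100), equal library sizes and a common dispersion; planted
  genes multiply the second group's mean by $2^{\log_2 FC}$.
- Repertoire generation writes domain tables consistent with each planted
  type and scaffold orders with decoy genes; scattered (non-array) RLRs
  are separated by 8 decoys so they stay out of arrays at any sensible
  `max_intervening`.

What the generators do *not* emulate: splice-site motifs, repeats, GC
heterogeneity, background indels, unequal library sizes, annotation
error, and alignment error from upstream tools. Passing validation
therefore demonstrates correctness of the algorithms under their stated
assumptions, not robustness to every artifact of real assemblies.

# Validation design and problem sizes

The validation suite (and `scripts/acceptance.R`, which recomputes the
same quantities) uses these study conditions, chosen once:

- **Mechanism recovery**: 200 pairs per mechanism, per-branch divergence
  uniform on [0.02, 0.2], events 30–300 aa, default thresholds;
  per-mechanism precision and recall must reach 0.95.
- **Alignment**: 500 random pairs of length ≤ 12 against the exhaustive
  Gotoh oracle, exact agreement.
- **Codon models**: two-taxon closed-form agreement to $10^{-8}$
  (against a series-based matrix exponential written independently of
  the eigendecomposition path); M0 $\omega$ recovery at 500 codons / 6
  taxa over 20 replicates, asserting the *mean* estimate within ±20% of
  the truth (single-replicate sampling error at this information content
  is itself near 15%, so a per-replicate bound would test noise, not
  bias); M1a-vs-M2a type-I rate ≤ 0.07 at $\alpha = 0.05$ over 200 null
  simulations of 60 codons on 4 taxa, single-start fits with the
  alternative warm-started from the null (the observed rate is far below
  nominal, as expected for a boundary null).
- **Expression**: 2000-gene 3v3 null at dispersion 0.1 flags ≤ 7% at
  FDR ≤ 0.05; 100 planted $|\log_2 FC| = 3$ genes are recovered ≥ 90%.
- **Typing/trees**: exhaustive enumeration of all 43 architectures with
  ≤ 2 N-terminal domains maps into the 11 labels; cherry extraction
  matches brute-force MRCA enumeration on 100 random 10-leaf trees.

Simulation sizes were set so the whole suite runs comfortably on a
single CPU; `scripts/acceptance.R` uses somewhat smaller replicate
counts (60 pairs per mechanism, 60 null LRT simulations, 8 recovery
fits) and reports the measured values rather than pass/fail.

# Known limitations

- Polarity of structural events (gain vs loss, exonization vs
  pseudoexonization) is not inferred; it requires outgroup information.
- The divergence classifier depends on one global protein alignment;
  although the matching layer absorbs its common failure modes, deeply
  diverged pairs (protein identity below ~40%) approach the regime where
  exon correspondence is genuinely ambiguous.
- The NB exact test assumes near-equal library sizes within groups and a
  single common dispersion; it is a stand-in, not an edgeR
  re-implementation.
- NEB site identification understates uncertainty relative to BEB.
- The branch model is the two-ratio model only; branch-site models are
  out of scope.
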