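---
title: "Methods: micro-synteny networks, domain scanning and the genome simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micro-synteny networks, domain scanning and the genome simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Specialized-metabolism gene families often descend from a
primary-metabolism ancestor through repeated duplication. The MAM/IPMS
family is the canonical plant example: IPMS (isopropylmalate synthase,
leucine pathway) carries two domains — an HMGL-like condensation domain
and a LeuA allosteric domain — while MAM (methylthioalkylmalate
synthase, glucosinolate chain elongation) retains only the HMGL-like
domain. The family's history mixes polyploidy, tandem duplication,
transposition, domain loss and gene fusion, and the informative signal
is as much *where* a gene sits (its conserved genomic context, or
micro-synteny) as what its sequence says.

`syntegraph` implements the full analysis chain — all-vs-all protein
search, collinear-block detection, synteny-network communities, domain
architecture calls, distance-based gene trees, and the family-specific
fusion/dosage/duplication-type analyses — together with a forward
simulator that generates inputs with a known event history. Every
algorithmic stage is validated against an independent oracle or
simulated truth in the test suite.

# The simulator: a stated world

`sim_config()` describes a small crucifer-like clade:

* **Species tree** — 4 leaves, `((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05)`
  with a 0.02 stem edge; branch lengths are expected substitutions per
  site. Total leaf-to-leaf divergence (~25–30% of sites) is typical of
  within-family comparisons among crucifer genomes.
* **Genome** — 3 chromosomes × 40 background genes (50–85 aa), an
  IPMS-like gene on chr1 and a MAM-like gene on chr2, representing the
  post-polyploidy state in which the family was born. Family segment
  lengths: 25 + 110 (HMGL-like) + 10 + 90 (LeuA) + 15 aa. Desk-scale
  proteins are shorter than real ones (~450 aa); all scores and
  e-values adapt through the length terms.
* **Events per branch** — a scheduled whole-genome duplication on the
  stem (multiplier 2, per-copy retention 0.6, per the common fate of
  polyploid duplicates), then Poisson numbers of tandem duplications
  (rate 4 per family gene per unit branch length), transpositions
  (2.5), and losses (0.5). The MAM locus is famously
  tandem-duplication-hot, which these rates reflect; they are stated
  once and not revisited. New family duplicates lose their LeuA domain
  with probability 0.5. Fusions (rate 0 by default) splice two paralogs
  at the HMGL boundaries, replacing the acceptor — chimera scenarios
  are planted explicitly by `simulate_fusion_scenario()`.
* **Substitutions** — i.i.d. per-site replacement with probability
  `1 − exp(−t)`, uniform over the 19 alternatives. This is the simplest
  model that supports identity-based recovery; it has no rate
  heterogeneity, so bootstrap supports on simulated data are
  optimistic relative to real alignments.

Randomness is organised as labelled substreams
(`substream_seed(seed, purpose, branch)`), so the event draws and the
substitution draws are decoupled; an independent replay of the event
log plus the substitution substream reconstructs every leaf genome
byte-for-byte (tested).

`simulate_default()` re-draws under derived sub-seeds until the history
contains at least 5 tandem duplications, 3 transpositions, a retained
polyploid family duplicate, and 2 family genes per leaf. This
conditions the Poisson realisation on the scenario the validation
criteria describe without changing any rate.

**What a green test does not establish:** the simulator has no
rearrangements, no background gene turnover, no rate heterogeneity, no
pseudogenes, and uniform intergenic spacing. Success on simulated data
shows the pipeline's logic is correct, not that real genomes at real
divergences will be as clean.

# Numerical and parameter choices

* **Alignment** — Gotoh affine gaps with the d/e convention (first gap
  residue costs `gap_open`, each further residue `gap_extend`), BLOSUM62
  11/1 for searches. The local DP's tie-breaks (diagonal, then up, then
  left; first maximum endpoint) make tracebacks deterministic.
* **E-values** — `E = K·m·n·exp(−λS)`. The shipped constants
  (λ = 0.22, K = 0.025) were fitted once by the package's own shuffle
  calibration (`calibrate_evalue()`, Gumbel moments, 500 random
  200-aa pairs) because published gapped-BLOSUM62 constants assume a
  different first-gap-residue charge and overstate significance under
  this convention. E-values here rank and filter; they are not meant
  to be cross-comparable with BLAST reports.
* **Chaining** — MCScanX-shipped defaults (min block 5 anchors, max gap
  25 genes, −1 per skipped gene, anchor scores capped at 50 bits),
  gene-rank coordinates, strand ignored. Best-first extraction with
  removal; ties resolved by anchor count then lexicographic member
  order, so anchor input order cannot matter.
* **Domain scan** — ungapped PSSM window over the profile length; no
  insert/delete states. The empirical e-value is the fraction of 200
  seeded shuffles of the *same* protein scoring at least as high, times
  a database-size factor. The threshold 0.007 is inclusive ("inclusion
  threshold"). A best window with non-positive log-odds skips the null
  (its empirical P would be ~0.5, far above any sane threshold).
* **Occupancy filter** — a column survives iff its non-gap fraction is
  ≥ the threshold; exactly 50% survives the default. Same boundary
  convention (≥) for the 80% conservation rule.
* **Distances and trees** — p-distance over shared non-gap columns,
  Kimura correction `−ln(1 − p − 0.2p²)`, saturation capped at d = 5
  for p ≥ 0.85. Canonical Saitou–Nei NJ with Studier–Keppler updates;
  Q-ties broken by the lexicographically smallest pair of cluster
  representatives; negative branch lengths clamped to 0. This
  distance+NJ+bootstrap stack deliberately replaces ML inference
  (GTRCAT-style): the downstream analyses consume clades and supports,
  not likelihoods, and distance methods are fast, deterministic, and
  provably consistent on additive inputs (tested on 50 random
  topologies).
* **Clade assignment** — a label's clade is the *maximal* bipartition
  side containing all of its exemplars, none of any other label's, with
  support ≥ 70 by default; leaves claimed by two labels become
  `unresolved`. This is one concrete operationalization of assigning
  named clades from exemplar genes; with single exemplars it extends to
  the largest compatible group rather than the bare MRCA.
* **Fusion test** — per segment (before/domain/after), all pairwise
  focal×donor global identities (gaps count as mismatches, since the
  segments are homologous end-to-end by construction), compared with a
  two-sided Mann–Whitney test at α = 0.05 (identity samples are small
  and non-normal; the normal approximation handles ties). A fusion is
  flagged when segments disagree about the winning donor.
* **Duplicate classifier cascade** — tandem (family gene within 5
  ranks) → syntenic_wgd (intra-genome subnetwork edge to a distal
  paralog, or a distal same-genome paralog sharing a community) →
  transposed (homologs but no community) → dispersed → singleton. The
  order mirrors MCScanX's classifier precedence. The community clause
  is this package's reading of an ambiguous rule; the alternative
  (paralog in a *different* community) mislabels genomes whose two
  ancestral loci are unrelated contexts.

# The context window at desk scale

The reference analysis queries candidates against the network with a
25-gene window on chromosomes carrying thousands of genes — a context
radius of well under 1%. On simulated 40-gene chromosomes a 25-gene
radius covers essentially every position, so transposition (whose
defining signature is *lost* context) becomes undetectable by
construction. `extract_family_subnetwork()` therefore keeps 25 as its
default (the reference parameter), while the default simulation bundles
its own proportional analysis settings (`sim$analysis$window = 3`).
The subnetwork is provably monotone in the window (tested), so
sensitivity in either direction is easy to explore.

# Degenerate inputs and edge behaviour

* Proteins shorter than a profile yield no windows and no hits (not an
  error); non-amino-acid characters are errors naming the position.
* Alignment columns that vanish entirely under cleaning raise an error
  advising a lower occupancy.
* Pairs with zero shared non-gap columns make the distance undefined:
  error naming the pair.
* `k` larger than the biggest clique yields zero communities, not an
  error; nodes in no k-clique stay unassigned; overlapping membership
  is preserved and reported (dual cluster identity is a finding, not a
  conflict).
* Single-row conservation summaries return 1.0 with a degenerate flag.
* One-replicate bootstraps give supports in {0, 100}.

# Known limitations

* The PSSM scan has no gap states; domains with indels relative to the
  profile lose score linearly. Fine for the simulator's
  length-conserved blocks, marginal for deeply diverged real domains.
* The center-star MSA is O(n²) in sequence count and merges pairwise
  alignments greedily ("once a gap, always a gap"); column quality is
  below that of modern aligners for > ~100 sequences.
* E-value calibration is tuned to the shipped scoring; changing the
  matrix or penalties calls for `calibrate_evalue()`.
* Dosage "power-of-multiplier" flags presume the planted polyploidy
  history is known; on real data they are descriptive, never inferential.
* The duplicate classifier can be fooled by a transposition that lands
  inside another family locus's context window — which is also true of
  the field's standard tools, because the evidence is genuinely
  ambiguous there.
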