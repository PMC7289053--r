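# syntegraph

Micro-synteny networks and phylogenetics for tracing the origin and
diversification of a two-domain gene family across related plant
genomes — the MAM/IPMS situation: an ancestral primary-metabolism gene
(IPMS, carrying an HMGL-like condensation domain plus a LeuA allosteric
domain) gives rise, through polyploidy, tandem and transposed
duplication, loss of the LeuA domain, and occasional gene fusion, to a
specialized-metabolism family (MAM, HMGL-like only) whose members sit at
distinct conserved genomic contexts (loci).

The package is aimed at comparative genomicists who want the whole chain
of analyses as one tested, deterministic, desk-scale pipeline — plus a
forward simulator that generates genomes with a *known* event history, so
every stage can be validated against ground truth.

## What it computes

Given per-genome protein FASTA + BED/GFF3 gene coordinates:

1. **Homology** — exact Smith–Waterman/Gotoh all-vs-all protein search
   (affine gaps, BLOSUM62 11/1), Karlin–Altschul e-values
   `E = K·m·n·e^(−λS)`, blast-tabular output.
2. **Collinearity** — anchors chained per chromosome pair by dynamic
   programming over gene-rank coordinates
   (`chain(i) = s_i + max_j chain(j) − (gap_a + gap_b)`), both
   orientations, best-score-first extraction; MCScanX-style defaults
   (min 5 anchors, max gap 25).
3. **Domains** — PSSM profiles built from seed alignments, ungapped
   best-window scanning, empirical shuffle-null e-values with the
   inclusive 0.007 threshold; architecture calls
   (HMGL+LeuA → IPMS-like, HMGL only → MAM-like) and a relative-
   divergence pre-filter against known family members.
4. **Network** — synteny graph from block anchors; family subnetwork
   extracted with an ordinal context window (default 25 genes), which
   recovers tandem-array members whose own anchor signal is masked;
   communities by k-clique percolation (CFinder semantics,
   Bron–Kerbosch maximal cliques, k = 3), with overlapping membership
   preserved.
5. **Phylogeny** — center-star progressive MSA, 50%-occupancy column
   cleaning, Kimura-corrected distances `d = −ln(1 − p − 0.2p²)`,
   neighbor joining with column-bootstrap supports, exemplar-anchored
   clade assignment; the domain-only tree is a pure input change
   (sequences sliced at domain-hit coordinates).
6. **Family analyses** — before/domain/after segment fusion test
   (pairwise global identities compared across candidate donors with a
   two-sided rank-sum test), 80 %-modal-residue conservation summary,
   duplication-type classification
   (tandem → syntenic_wgd → transposed → dispersed → singleton cascade),
   and per-locus dosage profiles with compensatory-change flags.

The simulator (`simulate_default()`, `evolve()`, `sim_config()`) evolves
an ancestral genome along a species tree with whole-genome
duplication/triplication, Poisson tandem/transposed duplications and
losses, LeuA domain loss, and chimeric fusion, and writes FASTA + BED +
a replayable ground-truth event log.

## Worked example

```r
library(syntegraph)

sim <- simulate_default(1)           # 4 genomes + ground-truth event log
print(sim$log)
#> EventLog: 101 events (domain_loss=1, speciation=6, tandem_dup=11,
#>                       transposed_dup=5, wgd=78)

cfg <- sim$log$cfg
profiles <- list(
  build_profile(simulate_seed_alignment(cfg, "hmgl"), name = "HMGL-like"),
  build_profile(simulate_seed_alignment(cfg, "leua"), name = "LeuA"))

res <- run_pipeline(sim$genomes, profiles, outdir = "out", seed = 1,
                    window = sim$analysis$window, n_boot = 50)

table(res$architectures[res$candidates])
#> IPMS-like  MAM-like
#>         5        25

res$membership
#>       clade community  n percent
#> 1 IPMS-like       C01  5     100
#> 2  MAM-like       C01  1       4
#> 3  MAM-like       C02 16      64
#> 4  MAM-like       C03  7      28
#> 5  MAM-like      none  1       4

table(res$calls$type)
#>    dispersed syntenic_wgd       tandem   transposed
#>            4            3           22            1
```

Reading the output: 30 family genes were recovered purely from domain
scans (5 with both domains, 25 HMGL-only). Community `C01` is the
IPMS-architecture locus — all five IPMS-like genes share one conserved
context, including one HMGL-only gene with dual cluster identity.  The
MAM-like genes split between two further contexts (the ancestral locus
and its polyploidy duplicate), with one transposed copy in no community
("none"): exactly the pattern by which conserved, transposed, and
dosage-changed loci are told apart.  Checked against the simulator's
hidden event log, the duplication-type calls agree with truth for 90%
of family genes on this seed (mean 0.96 over 20 seeds in the acceptance
suite).

A command-line front end mirroring the R API ships in
`inst/cli/syntegraph` (`simulate`, `search`, `network`, `pipeline`
subcommands).

## Reproducibility

Everything is seed-deterministic: a fixed seed gives byte-identical
FASTA/BED/TSV/Newick outputs (acceptance criterion; verified with
md5 sums).  Randomness is organised as labelled substreams derived from
one top-level seed (`substream_seed`), so simulation events, shuffle
nulls, and bootstrap resampling never interact.

See `vignettes/syntegraph-methods.Rmd` for the model assumptions,
parameter choices, desk-scale calibrations, and known limitations.
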