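---
title: "Methods: comparative analysis of importin alpha paralog families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of importin alpha paralog families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyofam)
```

# Scope and model

`karyofam` implements the comparative battery used to place a new paralog
inside a small protein family such as the importin α (KPNA) family: identity
matrices, distance-based phylogenies with outgroup rooting, domain-partitioned
divergence, contact-residue conservation mapping from a receptor–peptide
crystal structure, molecular weight prediction, and a seeded simulator that
provides ground truth for all of it. This vignette records the models, the
tunable parameters, and the design decisions that were genuinely open.

# Alignment and percent identity

Pairwise alignment is global Needleman–Wunsch with Gotoh's three-state affine
recursion. The scoring scheme defaults to BLOSUM62 with gap opening 10 and
gap extension 0.5 (substitution-matrix units); a gap run of length $k$ costs
$g_o + g_e k$, i.e. the opening charge is paid once and extension is paid for
every gap character. These are ClustalW-like protein defaults: the original
analyses of this kind used ClustalW, but exact ClustalW behaviour (the Gonnet
series, position-specific penalties, sequence weighting) is deliberately not
reproduced. Reproduction of a published identity matrix through the built-in
aligner is therefore expected only within about ±1.5 percentage points; the
exact path is to ingest the original Clustal `.aln` file, which the package
reads directly.

Traceback ties are broken deterministically — match/mismatch over gap-in-the-
first-sequence over gap-in-the-second — so identical inputs always produce
byte-identical alignments.

The multiple aligner is progressive: all pairwise alignments give
p-distances, a neighbor-joining guide tree is built from them and
midpoint-rooted, and profile–profile affine alignment merges sub-alignments
in post-order. Profiles are residue-frequency vectors (gaps carry no weight)
and the column score is the frequency-weighted average substitution score.
No iterative refinement is attempted.

Percent identity needs a denominator convention, and published matrices
rarely state one. Three are provided: `aligned_columns` (default; gap versus
residue counts against identity), `shorter_seq`, and `ungapped_columns`.
When reproducing someone else's matrix the convention is a free parameter
worth scanning — `identity_matrix()` takes it as an argument.

# Evolutionary distances

Distances are maximum-likelihood under a time-reversible rate matrix $Q$
scaled so that $-\sum_i \pi_i Q_{ii} = 1$, i.e. branch lengths are expected
substitutions per site. Models: Poisson (uniform), Dayhoff, and JTT
(default — the conventional modern default for protein distance programs in
the PHYLIP tradition, which is the tool family these analyses historically
used). The empirical exchangeabilities and frequencies are taken from
phangorn's model tables at run time rather than re-transcribed, and the
package validates the resulting $Q$ (zero row sums, detailed balance,
unit rate) in its test suite. Gamma rate heterogeneity across sites is not
implemented.

For a pair of aligned rows the likelihood uses pairwise deletion (columns
where both rows carry a canonical residue) and is maximised over
$d \in [10^{-6}, 10]$ by Brent optimisation (tolerance $10^{-10}$); an
optimum pinned at the upper bracket is reported as saturation, an error
rather than an infinite entry. The Poisson model returns the classical
Poisson correction $d = -\ln(1-p)$ in closed form; identical rows return
exactly 0.

# Trees

Neighbor joining follows Saitou–Nei with the Studier–Keppler
$Q_{ij} = (n-2)d_{ij} - r_i - r_j$ criterion. Ties (which occur in
degenerate and simulated data) are broken by the lexicographically smallest
label pair, a merged node inheriting the smaller of its children's labels,
so inference is deterministic. Negative branch lengths are kept by default
(PHYLIP behaviour, and required for NJ to invert additive matrices exactly);
pipelines that interpret lengths as divergences clamp them at zero
(`clamp_negative = TRUE`), which is the default inside `domain_divergence()`.

Outgroup rooting places the root at the midpoint of the outgroup's pendant
edge. That choice keeps every leaf-to-leaf path length unchanged and makes
re-rooting idempotent; where the exact root position along that edge is
unknowable from a published figure, any position on the pendant edge gives
the same outgroup-to-taxon path lengths, which is the quantity the
divergence analysis uses.

"Divergence" of a taxon (or of one of its domains) is defined operationally
as the branch-length path from the outgroup to that taxon on the (domain)
tree — a literal reading of how such figures are captioned.

Subfamily classification assigns each leaf the label of the reference taxon
with which it shares the smallest clade, excluding the root; leaves whose
smallest reference-containing clade is the root, or that tie between
differently-labelled references, are `unassigned` rather than guessed.

# Domains

Domain boundaries are supplied as 1-based inclusive intervals on an ungapped
reference sequence (TSV), because published figures usually show them only
graphically. The packaged KPNA2 annotation (IBB 1–95, ten ~42-residue ARM
repeats tiling 100–521) is an estimate from the canonical architecture and
is labelled as such; per-domain results on real families should be read as
qualitative orderings, not calibrated values. A domain's columns are the
span from its first to its last reference residue, so reference-gap columns
inside the interval belong to the domain. The "ARM repeats" analysis treats
the union of ARM1–10 as one block.

# Structure mapping

Contacts default to the common interface convention: a receptor residue is
in contact when any heavy-atom pair with the ligand is within 4.0 Å.
Published contact lists (when available) can be supplied directly as a
residue-number table, which both reproduces printed contact sets exactly
and serves to validate the cutoff-derived set. Receptor and ligand chains
are auto-detected as the longest and shortest protein chains of the
co-crystal, overridable. Water-mediated contacts are not considered.

Conservation classes follow the figure conventions of such papers:
`identical` (one residue type across all rows, gaps ignored), `conserved`
(all residues within one ClustalW strong similarity group — STA, NEQK,
NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW — chosen because "conserved" is
otherwise undefined in prose), `different`, with `gapped` recorded for
columns that contain a gap and are not identical. Summary counts fold
`gapped` into `n_different` so that identical + conserved + different =
total, matching how published counts are reported over contact columns.

# Molecular weight

Average (not monoisotopic) Expasy residue masses plus one water, because
the downstream comparison is to SDS-PAGE-scale kDa. Ambiguous residues are
an error unless explicitly allowed, in which case they contribute the mean
residue mass.

# The simulator and what a green test establishes

`simulate_family()` evolves a root sequence drawn from the model's
equilibrium frequencies along a known tree; site $s$ on a branch of length
$t$ evolves by $\exp(Q\,t\,m(s))$ with $m(s)$ the site's domain rate
multiplier. Sites are independent and there are no indels: the acceptance
surface (distances, trees, conservation counts) does not require gaps, and
a gap-free truth makes column bookkeeping exact. The generator uses a
private seeded stream and restores the caller's RNG state.

The stated world used by tests and the acceptance script is a KPNA-like
family: seven paralogs in three subfamilies (one divergent long-branch
member paired with the prototypical one, mirroring the α2 situation), three
subfamily reference leaves, and a deep outgroup, with outgroup-to-paralog
paths of order 1 substitution/site — consistent with a yeast-to-human span
and branch-length figure scales of ~0.1 per bar. The fast domain is the
N-terminal ~18 % of the sequence at 3× rate, mirroring an IBB of ~95
residues on a ~530-residue receptor. These values were fixed once, before
the corresponding tests were finalised.

A green recovery test establishes that the pipeline inverts its own
generative model (correct topology, unbiased distances, multiplier recovery
within 20 % at realistic lengths). It does not establish ClustalW
equivalence, robustness to indels or alignment error, or model adequacy for
real proteins — which is why reproduction of published identity values is
tested through an ingested `.aln` fixture separately.

# Numerical choices and degenerate inputs

- Transition matrices come from a symmetrised spectral decomposition of $Q$
  (computed once per model); tiny negative eigen-round-off entries are
  clipped and rows renormalised.
- `exp(Q·0)` short-circuits to the identity inside the simulator so
  zero-length branches copy states exactly.
- Saturated pairs, all-gap slices, empty column sets, unknown leaves or
  chains, and non-amino-acid characters are errors with the offending
  name/pair in the message, never silent NA/Inf.
- All tie-breaks (alignment traceback, NJ pair selection) are fixed, so the
  whole pipeline is deterministic given its inputs; `run_pipeline()` writes
  md5 checksums into its manifest and two runs on identical inputs are
  byte-identical.

# Known limitations

- The progressive aligner is intentionally simple; on deeply diverged real
  families it will differ from ClustalW by a few percentage points of
  identity and should not be used when the original alignment is available.
- No bootstrap or likelihood-based tree inference; NJ only.
- GenBank parsing extracts only the first forward-strand CDS feature.
- PDB parsing reads `ATOM` records of standard residues only (no mmCIF, no
  waters, no hetero-compounds).
- Structure-to-family mapping assumes consecutive author numbering within
  the receptor chain when converting contact residue numbers to sequence
  positions.
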