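---
title: "Methods: profile-HMM gene-family discovery in draft assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-HMM gene-family discovery in draft assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Multi-subfamily receptor gene families — the GnRH receptors are the motivating
case — are hard to survey in draft genome assemblies. Contigs are short, genes
are split into small exons, and any one contig typically carries less than 60
residues of coding sequence, far too little for a reliable gene-tree placement.
`famscan` implements the alternative: build profile hidden Markov models from
short, landmark-anchored *fragments* of a curated family alignment, restrict
each profile's training rows to a single subfamily, scan six-frame translations
of the assembly with every (subfamily, region) profile, and classify each
matching segment by the best E-value across subfamilies, with reciprocal
validation and exon-level evidence aggregation. Presence/absence of each
subfamily across species is then summarized on a species tree by parsimony,
and explicit phylogenetic hypotheses about subfamily relationships can be
examined with SH and AU constrained-topology tests computed from per-site
log-likelihoods.

# The profile HMM and its scoring model

Profiles are built from subfamily-restricted, region-trimmed alignments.
Columns with at least `symfrac` (default 0.5) non-gap residues become match
states. Match emissions are background-smoothed weighted counts,

$$ e_k(a) = \frac{c_k(a) + \tau\, q(a)}{C_k + \tau}, $$

with position-based (Henikoff) sequence weights on match columns (switchable
to uniform) and pseudocount mass $\tau = 5$ by default. A fixed canonical
amino-acid background $q$ ships with the package for reproducibility across
inputs; training-derived frequencies are a switch. Insert states emit the
background. Transition probabilities are add-one-smoothed counts of each
row's implied match/insert/delete path. Dirichlet-mixture priors, entropy
weighting, and the multihit model of production HMM search tools are
deliberately out of scope: the scheme above is simple enough to verify
exhaustively, and the package defines correctness by an in-repository
path-enumeration oracle rather than by equivalence with any external tool.

Scoring uses a unihit local-alignment architecture. The begin state enters
match state $k$ of an $M$-state profile with probability
$2(M-k+1)/(M(M+1))$; match state $k$ exits to the end state with probability
$1/(M-k+1)$ carved out of its outgoing mass (so entry/exit pairs $(i, j)$,
$i \le j$, are uniform for a pure-match pass); a trailing delete chain may
exit through $D_M$. Flanking sequence is emitted by N/C states whose
self-loop probability equals the geometric null's continuation probability
$p = L/(L+2)$ for a length-$L$ target, so flank residues contribute zero
log-odds and placement multiplicity cancels against the $(1-p)$ exit terms
(a background-emitting single-state profile scores exactly 1 bit at any
target length; appending ten background flank residues moves a realistic
score by well under half a bit). The forward score in bits is
$\log_2 P(\text{seq}\mid\text{hmm}) / P(\text{seq}\mid q)$ summed over all
such paths; Viterbi gives the best path and the matched span used for hit
coordinates. Both are computed in natural-log space with max-factored
log-sum-exp, in C++ for speed, and both are checked against brute-force path
enumeration on all profiles with $M \le 3$ and targets up to six residues
(tolerance $10^{-9}$ in natural log).

E-values come from a Gumbel fit to forward scores of `n_cal = 200` background
sequences of length $2M$, by the method of moments
($\hat\lambda = \pi/(\hat\sigma\sqrt6)$,
$\hat\mu = \bar S - \gamma_E/\hat\lambda$), seeded and recorded on the
profile. For a search of $n$ targets,
$E(S) = n\,(1 - \exp(-\exp(-\lambda (S - \mu))))$. Calibration is validated
two ways: parameter recovery on synthetic Gumbel draws, and the operational
property that a search of 1000 background segments yields on average about
$e$ hits with $E \le e$.

# Classification rules

Every translated segment of at least `min_len = 20` residues (shorter
matches carry too little information; the motivating surveys saw informative
matches down to roughly 60 residues) is scored against every calibrated
profile; hits with $E \le$ `e_max` (default $10^{-5}$; the threshold is not
stated in the motivating analyses, so it is configurable and logged) are kept.
Because all subfamily profiles are homologous, a true gene matches several
subfamilies; the *classification* of a segment is the subfamily with the
minimum E-value in its column, with ties broken by higher bit score and then
lexicographically (and flagged). Reciprocal validation re-scores the segment
against the whole library *including decoy profiles from unrelated families*
(the stand-in for searching a comprehensive profile database) and requires
the best-scoring profile to belong to the assigned subfamily.

Ortholog calls aggregate classified, validated hits by (species, subfamily):
a call is accepted when hits cover at least `exon_evidence_min = 2` distinct
fragment regions — two nearly adjacent region matches, typically on different
contigs, indicate distinct exons of a real gene — and every grouped hit
validated reciprocally. Single-region groups are reported as ambiguous rather
than discarded. Same-contig linkage is deliberately not required: in draft
assemblies exons of one gene routinely land on different contigs.

Presence/absence of each subfamily across species is reconstructed on a
rooted species tree by Fitch parsimony (equal gain/loss costs), with
ambiguous edges annotated `?`; a Dollo mode (single gain, losses only) is
available because lineage-specific gene loss is the dominant signal in this
kind of family history. An initial gain at the root is reported with
`edge = NA`.

# Likelihoods and topology tests

Per-site log-likelihoods use JTT exchangeabilities (the standard published
constants, embedded; verified in the test suite against an independent
implementation), equilibrium or alignment-derived ("empirical", add-one
smoothed) frequencies, discrete-gamma rate variation (4 equal-probability
categories represented by their means — the conventional default where the
category count is unstated), and an invariant-sites proportion. Under $+I$
the variable-category rates are rescaled by $1/(1-p_{inv})$ so branch lengths
stay comparable. Gaps and `X` are missing data. Transition matrices come from
the symmetric eigendecomposition of the rate matrix, scaled to one expected
substitution per unit branch length.

Branch lengths (and optionally $\alpha$ and $p_{inv}$) are fitted by
coordinate ascent: Brent optimization per branch on cached pre/post-order
partials, interleaved with scalar fits of the rate parameters, stopping when
a sweep improves the log-likelihood by less than $10^{-6}$ or after 20
sweeps. The likelihood is non-decreasing by construction, matches the
two-taxon closed form to $10^{-10}$, is invariant to re-rooting
($10^{-8}$), and reaches the same optima as an independent implementation on
simulated data.

Topology tests consume a sites-by-topologies log-likelihood table, with
branch lengths re-optimized once per topology on the original alignment
(replicates are never refitted — the RELL approximation). The SH test centers
each topology's resampled totals at its replicate mean and compares the
max-minus-self statistic to the observed $\delta_i$; it is conservative by
construction and its type-I error is checked by simulation (data generated
under the best topology; rejection of that topology at $\alpha = 0.05$ must
stay at or below 0.07). The AU test computes bootstrap proportions
$BP_i(r)$ at ten scales $r \in \{0.5, \dots, 1.4\}$ (ties for the replicate
maximum split equally to avoid order bias), clamps them to
$[1/2B,\ 1 - 1/2B]$, and fits
$\Phi^{-1}(1 - BP_i(r)) = d\sqrt r + c/\sqrt r$ by weighted least squares
with binomial delta-method weights (the closed-form fit; maximum likelihood
differs negligibly at the default $B = 1000$ per scale), giving
$p = 1 - \Phi(d - c)$. Curves that are 0 or 1 at every scale are flagged
degenerate and assigned the clamp-limit p-value. The fit inverts noise-free
curves exactly and matches the analytic half-space geometry of a Gaussian toy
model within Monte-Carlo error.

# What the synthetic generator emulates — and what it does not

The generator (`sim_config()`, `simulate_family()`, `emit_genome()`) defines
the study conditions for every end-to-end check:

* a five-subfamily, 350-residue GPCR-like family diverging from a common root
  over a subfamily branch of 1.2 substitutions/site, then evolving under
  JTT+gamma ($\alpha = 1$) along a fixed 12-species ultrametric tree of
  height 0.3 — deep enough that within-subfamily identity exceeds
  between-subfamily identity in essentially all pairs;
* 15 diagnostic motif columns per subfamily (disjoint across subfamilies)
  evolving at 5% of the family rate — the slow, subfamily-specific positions
  that make short fragments classifiable;
* one subfamily lacking the C-terminal 45 residues (the tail-less,
  mammalian-pituitary-like type), implemented as alignment-level truncation;
* per-branch Poisson gene duplication ($\lambda_{dup} = 0.05$) and loss
  ($\lambda_{loss} = 0.3$ per unit branch length), giving a handful of
  lineage-specific losses per run, logged as ground truth;
* genes reverse-translated with uniform synonymous codon choice (codon bias
  is irrelevant downstream because scanning operates on translations), split
  into two exons at codon boundaries, GT..AG introns when exons share a
  contig, and a 90% chance that a gene's exons are emitted on separate
  small contigs on random strands — the draft-assembly regime;
* two decoy families simulated from independent roots, used to build decoy
  profiles for reciprocal validation, plus gene-free background contigs.

Real data differ in ways the generator does not model: indels (simulation is
substitution-only, so the family alignment is exact and trivially known),
exon phase other than 0, pseudogene decay, assembly and sequencing error
beyond fragmentation, codon usage, and any physical realism of transmembrane
helices. Passing end-to-end tests therefore demonstrates the pipeline's
internal correctness under its own assumptions — coordinate bookkeeping,
scoring, calibration, classification logic, evidence aggregation, parsimony
reconstruction — not field performance on real assemblies, where alignment
quality and landmark placement dominate.

# Numerical and design choices

* Coordinates are 0-based, half-open, always on the forward strand with an
  explicit strand field; codons containing `N` translate to `X`, which scores
  at background odds.
* Default fragment regions for the synthetic family span roughly the
  alignment's TM1–4, TM4–5, TM6 and TM6–7-like blocks; for real data the
  region coordinates must be supplied, as they are landmark choices, not
  derivable constants. The pipeline's default last region stops short of the
  cytoplasmic tail so the tail-less subfamily is fully covered; the
  tail-robustness control re-runs classification with regions extending to
  the full width and with every tailed training sequence truncated at the
  last pre-tail column, and requires identical classifications of the
  tail-less genes.
* `min_residues` for region trimming defaults to half the region's columns,
  echoing a full-length-sequences-only training policy; (subfamily, region)
  cells with no surviving rows are recorded as gaps and simply never produce
  hits.
* Missing-profile cells, tie-breaks, seeds, thresholds and parameters are all
  recorded in the library manifest and run manifest; every random step takes
  an explicit seed and reruns are byte-identical.
* Simulation sizes in the test suite (12 species, ~60 genes, ~280 kb of
  contigs; 20 replicates of 500 sites for branch recovery; 200 replicates of
  300 sites at $B = 500$ for SH calibration) were chosen as the smallest
  designs that exercise every code path with stable statistics.

# Known limitations

Scores and E-values are not comparable to HMMER's (different priors, length
model, and multihit architecture); the AU implementation uses WLS rather than
the original maximum-likelihood fit; the gene-duplication model attaches
duplicates mid-branch rather than simulating a full birth-death gene tree;
Bayesian topology tests (Bayes factors via stepping-stone) are out of scope;
and ML tree *search* is not provided — candidate topologies are inputs,
optionally screened with `filter_topologies()` under positive or negative
monophyly constraints.
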