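---
title: "Models and decision rules in paleoamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and decision rules in paleoamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoamp)
```

`paleoamp` authenticates mitochondrial and nuclear gene sequences recovered
from degraded DNA as tilings of short cloned PCR amplicons. This vignette
documents the models behind each stage, the tunable parameters with their
defaults and why, the design choices made where the design was genuinely
open, and what a passing test suite does and does not establish. Everything
quantitative stated here is computed by the test suite or the acceptance
script; nothing is asserted beyond that.

## The simulated world

The simulator is a stated world, not a tuning dial: its defaults encode the
conditions the authentication procedure is designed for, and the test suite
evaluates the procedure against exactly this world.

**Design.** Three bone samples, each amplified over a 19-fragment panel: 15
overlapping cytochrome-*b* fragments of 97–219 bp (including primers) tiling
positions 1–1031 of a 1140-bp mitochondrial gene, plus 4 fragments (123–167
bp) of a nuclear gene. Coordinates are 1-based inclusive; `fragment_table()`
holds the panel. Fragment identifiers with prime marks are encoded in ASCII
(`C3p` for C3′, `C6pp` for C6″).

**Template survival.** Degraded templates are short, so amplification
success decays with fragment length:

$$P(\text{amplify} \mid L) = \exp\!\left(-\frac{\max(0, L - 97)}{\lambda}\right)$$

with `mt_survival_halflife` λ = 180 bp for mitochondrial templates and
`nuc_survival_halflife` λ = 90 bp for nuclear ones (including numts, which
reside in the nuclear genome). The 97-bp offset is the shortest designed
amplicon: the model says nothing about lengths no primer pair ever targets.
Only the qualitative facts are empirical — short fragments amplify, long
nuclear fragments do not, mitochondrial DNA survives amplification at
lengths where single-copy nuclear DNA fails (it is present in far more
copies per cell). Two parameters reproduce that asymmetry; the specific
length scales are this package's choice of a realistic poorly-preserved
(warm-climate) specimen.

**Template identity.** For a mitochondrial fragment, each PCR session first
draws its template by relative abundance — numt with probability
$w/(1+w)$, `numt_weight` w = 0.1 by default — then survives or not under
that template's length scale. Conditional on success this gives the numt
probability $w\,s_{nuc}(L) / (w\,s_{nuc}(L) + s_{mt}(L))$: numts enter
mostly through short fragments, at low frequency, exactly the observed
pattern. The numt reference is derived from the mitochondrial gene by
substituting a fixed number of sites, `round(divergence * L)`, uniformly at
random (Jukes–Cantor-style, uniform over the three alternative bases), so
the realised gene-wide divergence equals the configured value. By default
substitutions that would create an in-frame stop codon are resampled
(`numt_stop_free = TRUE`): the real co-amplified paralog was stop-free, and
the flag can be turned off to generate easy, ORF-broken numts for
classifier testing.

**Damage chemistry.** Each clone independently receives deamination events:
every template C becomes T with probability `deamination_rate` (0.02), and
symmetrically every G becomes A (deamination on the complementary strand,
read on the reported strand). Polymerase misincorporations hit every site
with probability `polymerase_error_rate` (0.001), uniform over the three
non-template bases. Damage is position-independent: the clone-level tables
this package reproduces record substitution *types*, not positional
profiles, so fragment-end enrichment is deliberately not modelled (see
Limitations). The 0.02 rate puts the dominant deamination signature
(%C\* around 85–90) in the range clone-based studies of subfossil material
report; 8 clones per positive PCR and 2 sessions per fragment sit inside
the observed 6–37 clones per fragment. The observed dispersion of clone
counts across PCRs is not documented anywhere usable, so `clones_per_pcr`
is a constant rather than a fitted distribution — an explicitly exposed
simplification.

**Reference sequences.** The mitochondrial reference is sampled codon by
codon, rejecting vertebrate-mitochondrial stop codons (TAA, TAG, AGA, AGG),
with third-codon positions drawn from the typical mammalian cytochrome-*b*
composition (A 39%, C 36%, G 3%, T 21%) so that composition-based evidence
behaves as it would on real data. The nuclear reference uses the standard
code (stops TAA, TAG, TGA). Two fields extend the minimal configuration
because the pipeline's own demonstration requires them: `samples` (the
study shape is three samples) and `nuc_gene_length` (the nuclear fragment
coordinates run to 1204, so the default nuclear reference is 1206 bp).

**Determinism.** One root seed; every sample × fragment stream and the
reference generator derive their own sub-seed from it deterministically
(kept below $2^{31}$). Fixed seed means bit-identical libraries and
byte-identical files.

## Consensus calling

Per-column strict plurality over the clones of one amplicon; a tied column
becomes the IUPAC code of the tied bases. Ties, replicate conflicts and
inter-sample conflicts are never resolved by picking a base: an A/G
conflict between two independent PCRs is coded R and listed, because a
deamination artefact in one replicate must stay visible rather than be
silently voted away. Per-column clone counts are stored as `support`, so
every call is auditable.

Clones are assumed pre-aligned and indel-free; a clone containing a gap is
rejected rather than realigned (alignment is not this procedure's job, and
the clone data this mirrors contained no insertions).

Replication evidence is ranked by `validate_replication()`:
two or more amplicons from distinct PCR sessions are independent
replicates; amplicons from a single session replicate only within-session
(polymerase artefacts shared); exactly two amplicons with *different*
coordinate spans overlapping by at least half the shorter span count as
valid overlapping replicates (two largely overlapping primer systems are
independent evidence even when each ran once — checked before the
session rule, which would otherwise shadow it); a single amplicon whose
consensus is IUPAC-*compatible* over the shared span with another sample's
validated consensus is cross-validated (compatibility, not string equality:
an R must match an A, otherwise damage-derived ambiguity would block
validation); anything else is unvalidated.

Assembly intersects IUPAC sets in overlap columns (R against A yields A —
the replicate that resolved the position wins) and hard-errors on an empty
intersection, naming the fragment pair and position: an incompatible
overlap between fragments of one sample means a numt or contaminant slipped
through and must not be papered over. Across samples the same intersection
rule applies, but an incompatibility degrades to the union code with a
warning instead of an error — between-individual conflict can be real
polymorphism, so the conservative union keeps every observed base.

## Damage spectra

Clone-versus-consensus differences are classified into the 12 directed
substitution types. The counting rule deduplicates: one distinct
(position, consensus base → clone base) event per sample and fragment,
however many clones show it — a PCR happening early in cycling propagates
one lesion into many clones, and counting it once measures lesions, not
clone counts. Two *different* changes at one position each count once.
Changes are scored against the amplicon-level consensus (the damage tables
this mirrors are per sample × fragment); columns where the consensus itself
is ambiguous are excluded from counting and reported, since no directed
change can be read off an unresolved base.

Summary statistics: TS = T→C + C→T + A→G + G→A; C\* = C→T + G→A (the
deamination signature, G→A being the complementary strand read on the
reported one); TV = the other eight types. Percentages are integers rounded
half away from zero — the only convention consistent with all the half
cases in the published table this format reproduces (93.75 → 94,
87.5 → 88, 62.5 → 63, 12.5 → 13).

## Numt screening

Amplicon consensuses of each fragment (samples pooled) are partitioned into
sequence classes by single-linkage clustering on p-distance, with
IUPAC-compatible positions counted as matches and damage-compatible
ambiguity skipped. The partition threshold 0.03 sits in the empirical gap
between the damage scale (consensus-level differences well under 1%) and
realistic numt divergence (observed 5.4–20.9%); it is configurable.

**The majority reference.** Evidence is measured against a gene-wide,
clone-weighted majority assembly of all class representatives, not against
each fragment's own top class: the genuine mitochondrial copy is the one
that is *consistent across overlapping fragments* genome-wide. The assembly
is built in two passes — a first vote, then a rebuild using only classes
within the partition threshold of that first vote. The second pass matters
in one specific failure mode: when a fragment's numt amplicons happen to
outnumber its mitochondrial ones and part of its span has no overlapping
coverage, a single-pass majority would be locally chimeric, and the genuine
class would look divergent from "the majority". A class with no overlap
against the consistent reference is AMBIGUOUS, not guessed.

**Preservation anchors.** If nuclear fragments longer than L\* bp never
amplify in a sample, a numt template of such length cannot have been
preserved there, so mitochondrial amplicons longer than L\* are genuine and
anchor everything else by identity over the shared span (≥ 0.98 genuine,
≤ 0.97 numt, between the two or no shared span ambiguous). L\* is
per-sample — preservation is a property of the specimen. Because L\* is an
inference of *non*-preservation, it is only declared when at least 10
failed attempts back it (pooled over the candidate length and everything
longer; 0/10 bounds the per-attempt success probability below ~0.26 at the
95% level, and the real thresholds this rule mirrors rested on 18 and 22
failed attempts). Declaring L\* from one or two failed PCRs would let
chance anchors dominate every verdict, which early benchmark runs of this
package demonstrated vividly.

**Decision list** (`classify_class()`):

1. Anchor evidence dominates when available: anchor-genuine length, or the
   identity verdict against an anchor.
2. Otherwise divergence and frequency decide: divergence to the majority
   ≥ 0.05 is a numt; a *minority* class separated at the partition scale
   (≥ 0.03) is also a numt — low frequency plus a distinct sequence class
   is the decisive signature, and the 5.4% lower end of the observed
   divergence range is an observation, not a rule; a majority class in the
   weak-divergence band stays ambiguous.
3. Reading-frame integrity, third-position composition and codon-position
   rate ordering are recorded as corroborating evidence only and can never
   overturn (1)–(2) — demoted deliberately, because the real co-amplified
   numts passed all three (stop-free, typical composition, coding-like
   rate pattern). A screen that leaned on them would have called those
   numts genuine.

A single class with no anchor is genuine with an explicit
unreplicated-class caveat. Note the published third-position reference
composition sums to 0.99 as printed; it is stored as printed, which bounds
the total-variation distance away from exactly zero by 0.005.

## Topology confidence

The likelihood layer evaluates *fixed* trees: branch lengths and model
parameters are inputs, never optimised (parameter estimation belongs to the
external ML/Bayesian programs whose output these tests consume). Site
log-likelihoods (natural log throughout) come from Felsenstein pruning
under per-partition GTR+I+Γ: rate matrix normalised to mean rate 1,
Γ heterogeneity as `n_gamma_cat = 4` equiprobable categories at their
conditional means (the convention of the standard ML programs), an
invariant class of weight `p_inv` implemented as a zero-rate category, and
the Γ rates scaled by $1/(1-p_{inv})$ so the mixture's mean rate is 1.
IUPAC codes enter as partial likelihoods over their base sets; gaps and
missing data as all-ones vectors. `restrict_to_covered()` implements the
"only sites covered by the focal taxon" re-analysis. The pruning path is
verified against exhaustive enumeration over internal-node states (≤ 5
taxa, |Δ| < 1e-8) and against an independent implementation (phangorn) —
both cross-checks, with the implementation authored here.

RELL resampling draws site columns with replacement (as a multinomial
weight vector, identical columns for all trees) and sums site
log-likelihoods. The SH test centres each tree's replicate totals on its
own replicate mean and compares the observed
$T_i = \max_j L_j - L_i$ to that null; with `B` below 100 a warning flags
unstable p-values. The AU test fits
$z(r) = d\sqrt{r} + c/\sqrt{r}$ to $z(r) = \Phi^{-1}(1 - BP(r))$ across
scales $r \in \{0.5, \dots, 1.4\}$ (10 scales, `B = 10000` per scale by
default — the published algorithm's defaults, reducible in tests) by
weighted least squares with binomial-variance weights, giving
$p_{AU} = 1 - \Phi(d - c)$. Bootstrap proportions of exactly 0 or 1 at a
scale get a $1/(2B)$ continuity correction; a tree at 0 (or 1) at *every*
scale is reported p = 0 (p = 1) directly, because a constant z-curve makes
the signed-distance fit degenerate (d ≈ c, p ≈ 0.5 — visibly wrong for a
tree that never wins a single replicate).

Marginal likelihoods for Bayes factors use the harmonic-mean estimator on
pooled post-burn-in posterior log-likelihood traces, stabilised as
$\ln \hat m = -(\mathrm{logsumexp}(-\ell) - \ln n)$. The scale is
Kass–Raftery on $2\ln BF$: above 10 very strong, above 6 strong, above 2
positive, else weak; positive values favour the first model. The harmonic
mean is a rough estimator with infinite-variance pathologies — it is
provided because it is the procedure being reproduced, not because it is
recommended today.

## What a green suite establishes — and what it does not

The simulator provides what real excavations cannot: ground truth. Against
it, the tests establish that the consensus rules never invent a base, that
the damage statistics implement the deduplicated counting rule and
reproduce the published table's integer percents exactly, that damage
recovery matches the configured chemistry within binomial error, and that
numt screening attains ≥ 0.95 precision and recall across divergence
0.05–0.21 and numt weight ≤ 0.3, with zero false numt calls when no numt
exists (100 seeded libraries each).

The simulated world omits, by design: positional damage profiles
(fragment-end C→T enrichment), indels and sequencing artefacts, primer
sequences and mispriming, contamination from exogenous sources,
heteroplasmy, and clone-count dispersion. A green suite therefore says the
*procedure* is implemented correctly and behaves well in the stated world;
it does not certify performance on data whose failure modes live in the
omitted dimensions. The real study's headline phylogenetic results (the
placement supports, dates, and the published Bayes-factor values) depend on
a 68-taxon alignment and external MCMC runs and are out of this package's
scope; only the arithmetic and threshold layer of those procedures is
implemented and tested here.

## Numerical and degenerate-input choices

* Rounding: integer percents half away from zero (pinned by the published
  half cases).
* p-distance: gap columns skipped; compatible-ambiguous columns skipped;
  incompatible-ambiguous columns count as differences; `NaN` when nothing
  is comparable.
* Ties in consensus columns: IUPAC code of the tied set, position listed.
* Three-way replicate conflicts: three-fold IUPAC code plus a warning.
* Empty clone library: legal; empty FASTA and header-only tables.
* Zero-length branches: transition matrix is the identity (a two-taxon
  zero-branch tree returns exactly ln of the base frequency).
* Per-node likelihood rescaling guards against underflow on larger trees.
* An AU tree with all-zero (all-one) bootstrap proportions: p = 0 (p = 1)
  directly.
* Harmonic mean: exact for constant traces; permutation-invariant; pooling
  runs equals concatenating their post-burn-in traces.

## Known limitations

* The survival model is a two-parameter caricature of preservation;
  `preservation_threshold()` inference on top of it is deliberately
  conservative (`min_attempts = 10`).
* `clones_per_pcr` is constant; real clone counts over-disperse.
* The screen assumes one numt lineage per library; multiple divergent
  paralogs would each form classes, but anchors and the majority reference
  have only been exercised against one.
* The pruning implementation is plain R: fine for the alignment sizes this
  workflow meets (hundreds of sites, tens of taxa), not a phylogenomics
  engine.
* `numt_screen()` treats fragments whose identifier starts with `I` as
  nuclear; user-supplied panels with other naming need a `gene` column in
  their fragment table.
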