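---
title: "Detecting persistent DNA lesions in somatic phylogenies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting persistent DNA lesions in somatic phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionphylo)
```

## The problem

Most somatic mutations are fixed within one or two cell cycles of the damage
that caused them. Some DNA lesions, however, evade repair and persist across
many cell divisions. Each time a replication fork crosses such a lesion,
translesion synthesis may insert a wrong base into the newly synthesized
strand, so a single persistent lesion can seed *different* mutations in
*different* descendants of the damaged cell. In a high-resolution somatic
phylogeny built from single-cell-derived colonies (each tip a colony grown
from one stem cell, whole-genome sequenced at roughly 30x), this leaves two
recognizable footprints:

* **Multi-allelic variants (MAVs)** — the same genomic position carries two
  different alternate alleles in one individual, each allele confined to its
  own subclade.
* **Phylogeny-violating variants (PVVs)** — one alternate allele is present
  in two or more subclades that do *not* form a clade, separated by a
  wild-type subclade, a pattern a single heritable mutation cannot produce.

Because the lesion segregates with one parental DNA strand while mutant
alleles appear only in the strand's replication partners, the footprint is
anchored to a contiguous chain of tree nodes: the **lesion node** (latest
point the lesion must have existed) down to the **lesion repair node**
(earliest point it must have resolved). Branch lengths are mutation counts,
so the distance between those nodes is a lower bound on the lesion's
lifetime in **molecular time** — the *minimum molecular lesion duration*
(MMLD) — convertible to chronological time through the somatic clock.

## Data model and conventions

Trees are `ape::phylo` objects with named tips and branch lengths in
mutations; coordinates are 1-based and VCF-like; read counts live in
variant x sample MTR (variant reads) and DEP (depth) matrices. All
thresholds sit in a single `pipeline_config()`:

| parameter | default | role |
|---|---|---|
| `het_vaf` | 0.5 | expected VAF of a true heterozygous variant (diploid autosome) |
| `error_rate` | 1e-6 | per-read error used for non-carriers |
| `rho_threshold` | 0.1 | beta-binomial overdispersion cut for the PVV screen |
| `positive_subclade_min_vaf` / `min_reads` | 0.25 / 3 | confident positive subclade |
| `negative_subclade_min_depth` | 13 | confident negative subclade (zero variant reads) |
| `development_cutoff` | 50 mutations | nodes earlier than this are developmental (in utero) |
| `mutation_rate_per_year` | 15 | somatic clock for molecular-to-chronological conversion |

The 13x negative-depth threshold follows the primary definition; a later
restatement of 12x in the source material is treated as a discrepancy and
both are configurable.

## Branch assignment

`assign_branch()` scores every branch (identified by its child node; the
root stands for the stem) with a binomial likelihood: tips inside the
candidate clade at `het_vaf`, tips outside at `error_rate`. This is a
simplification of the treemut model, which also carries base-quality terms;
ties break toward the smallest clade, then lexicographically, so toy trees
are reproducible. The test suite checks the assignment against an
exhaustive per-branch likelihood scan on every fixture tree.

## MAV classification

Overlapping variant pairs (same SNV position with different alternates; any
reference-interval overlap for deletions/MNVs) are classified
hierarchically from their branch assignments:

1. **simple** — the two branches share a parent; the parent is the lesion
   node, MMLD 0 (both alleles fixed at one division).
2. **separated** — one branch lies within the clade of the other's parent;
   the encompassing parent is the lesion node. The lesion path is then
   traced stepwise: descend into the unique child whose subtree carries at
   least two distinct alleles (*the reference allele counts*, resolving an
   ambiguity in the source description in favour of the geometry of the
   published examples); the last such node is the repair node.
3. **unrelated** — everything else, including two corner cases decided
   here: ancestor-nested assignments (a lesion on one strand cannot place
   both alternates on a single lineage) and separated pairs whose path
   sheds two or more reference-only subclades between the mutant subclades
   (more probably two independent mutations).

Genotypes for path tracing reuse the positive/negative subclade thresholds,
so MAV and PVV calling can never drift apart.

## PVV detection

Internal-branch mutations are screened for excess variance of their
variant-read fractions: a beta-binomial with mean `p` and overdispersion
`rho` (alpha = p(1-rho)/rho, beta = (1-p)(1-rho)/rho) is fitted by maximum
likelihood separately to samples inside and outside the assigned clade.
`rho` is profiled on a log-spaced grid over [1e-6, 0.89] with local
refinement; likelihood ties resolve to the boundary `rho = 1e-6` so
dispersion is never over-stated. A mutation proceeds when `rho >= 0.1` on
one side *and* the corresponding subclade evidence exists (a confidently
negative subclade inside, or a confidently positive subclade outside).
Whether the original fit profiled `p` or fixed it is not documented; we
profile, and flag this for sensitivity testing.

Subclade genotypes pool reads across tips: positive at pooled VAF >= 0.25
with >= 3 variant reads and no confidently negative tip inside; negative at
zero variant reads with pooled depth >= 13; mixed when both confident
states occur; indeterminate otherwise. Pooling is our choice (the source
does not state it) and maximizes power at 30x.

The lesion node is the minimal ancestor covering all positive subclades.
The walk then descends through the unique mixed child, recording each
uniform sibling subclade in path order, and stops when every child is
uniform (the repair-or-loss node). Two mixed children at any step mean the
configuration is inconsistent with a single lesion: **fail**. A call
**passes** when the recorded uniform sequence contains
positive-negative-positive. One convention deserves honesty: at the final
node the two uniform daughters are recorded in tree (Newick) child order,
and configurations whose sandwich exists only through that order are
inherently convention-dependent — the positive-positive-negative and
positive-negative-positive patterns at a single terminal step differ only
in which sibling carries the mutation, and both admit the same
mutation-plus-loss alternative. The synthetic generator therefore implants
lesions across three distinct path nodes, where the verdict is
order-independent. An indeterminate subclade at a decision point flags the
call and excludes it downstream.

MMLD is the branch-length sum from lesion node to repair node, identical
for MAVs and PVVs (`time_lesion()` asserts the difference identity).

## Phasing and LOH

Read pairs spanning a variant and a germline heterozygous SNP within 1 kb
phase each allele to a parental haplotype. In clonal colonies an allele may
phase directly (variant base + SNP base) or via the reference base to the
complementary SNP allele; in laser-capture microdissection material only
direct evidence counts. Matching phasing of both MAV alleles (or of two
positive PVV subclades) supports a single two-strike lesion; conflicting
phasing indicates independent mutations. Concordance is tested with an
exact two-sided binomial test against 0.5, doubling the smaller tail — this
reproduces the published P = 7e-20 (78/81) and P = 0.10 (128/230) exactly,
while the published 0.0009 for 21/24 is not reproducible by the exact test
(it gives ~3e-4) and is documented rather than asserted. A read-based LOH
check interrogates negative-subclade colonies for the SNP allele of the
mutation-bearing chromosome; its absence at adequate depth suggests the
"negative" subclade actually lost the locus.

## Null simulations

Two artefact generators are simulated with the *same* classification code
as the real pipeline:

* **Independent co-occurring mutations** (MAV null): unordered pairs of
  distinct branches drawn with probability proportional to branch length
  (sampled i.i.d.-by-length with equal pairs rejected, which is exactly
  proportional to the length product), classified with `classify_mav()`.
  On the four-tip fixture the simple fraction is 300/1500 = 0.2 by
  enumeration, and 50,000 draws agree within total variation 0.01.
* **Independent-mutation and somatic-reversion PVV nulls**: per replicate
  the carrier set is constructed (union of two clades, or a mutation clade
  minus a reversion clade drawn by the length-times-descendant-length
  product), depths are Poisson at the cohort mean with binomial variant
  reads (0.5 carriers, 1e-6 otherwise), and the full
  assign-screen-walk pipeline records terminal / not-detected / fail /
  pass. Pair self-draws are excluded (a lesion needs two events).

`weighted_contamination()` pools per-phylogeny simulated proportions with
the observed call counts as weights.

## Expected mutational signatures

Spectra use the standard 96-channel pyrimidine-strand convention. Dividing
a spectrum by genome trinucleotide frequencies gives a per-site *likelihood
signature*; from it the package derives the spectra that each mechanism
*should* produce:

* **true MAVs** — pairs of distinct alternates at one context, weight
  proportional to L(alt1) x L(alt2) x freq(context), on a 96-channel pair
  profile (6 alternate-pair combinations x 16 flank combinations);
* **independent-mutation PVVs** — the same mutation twice, weight
  L(alt)^2 x freq(context) (dominated by C>T at CpG on a blood-like
  clock signature);
* **reversion PVVs** — a mutation followed by its exact back-mutation,
  weight L(forward|context) x L(reverse|mutated context) x
  freq(reversion-site context), mass on the reversion channel. The
  frequency convention is ours to fix (the source omits it); weighting by
  the reversion-site context reproduces the published qualitative output
  (a dominant T>C-at-ATG peak over CpG-depleted genome frequencies),
  whereas the original-site convention would not.

Genome trinucleotide frequencies are a user-supplied table (synthetic
uniform frequencies in tests; no genome download). Cosine similarity,
an exact conditional strand-bias test, and non-negative least-squares
exposure fitting complete the module.

## Lesion timing

The lesion node's molecular time is the latest acquisition, the repair
node's the earliest resolution; nodes before 50 mutations of molecular time
are developmental (in utero). Molecular time converts to years by the
clock rate: 21 mutations at 14-16 mutations/year spans 1.3-1.5 years,
which is why the default rate is 15 and `time_lesion()` reports the
conversion at rate +/- 1. The alternate-base incorporation probability is
estimated from pre-filtered counts of unbiased subclades (lesion paths
crossing more than two nodes; the first two detection-constrained
subclades excluded — the filter is documented rather than re-derived
because only the resulting counts are available) with an exact
Clopper-Pearson interval.

## Lesion duration by rejection ABC

The generative model is a stem-cell population genealogy: exponential
growth to `N` cells over `growth_years`, then neutral Moran-type turnover
at `turnover_rate` symmetric divisions per cell per year. The complete
genealogy of extant cells is simulated backward (pairwise coalescence at
rate beta k(k-1)/N in the constant phase; birth-by-birth coalescence
through the growth phase), which is exact for the neutral model and cheap
enough to vectorize lesion implantation over millions of lesions.
Defaults: N = 100,000 and age 75 at full scale; turnover 1/year and
growth over 5 years, consistent with the posterior ranges of published
haematopoiesis models — these two are explicit configuration here rather
than posterior draws. The tree roots at the first division (the short
pre-division stem is not represented).

Lesions are implanted uniformly over total edge time with
Gamma(shape = 1, mean mu) durations; at each spanned division the lesion
follows one daughter uniformly and the other daughter's founding
replication is mutant with probability 0.5 (the measured 0.54 is an
output, not an input). A lesion is *theoretically detectable* when its
shed-outcome sequence contains mutant, wild-type, mutant — the same
subsequence rule before and after down-sampling, a single code path.
Down-sampling keeps a uniform tip subset; a shed subclade is visible only
if it retains a sampled cell; the time between the first and last visible
mutant divisions converts to molecular time by a Poisson draw at the clock
rate, and MMLDs above 200 are discarded exactly as for observed data.
Summary statistics are the intercept-only gamma-GLM mean and moment
dispersion of the pooled MMLD set. Rejection ABC standardizes both
summaries by their table-wide standard deviation and accepts the tolerance
quantile; no regression adjustment. The per-cell lesion prevalence of an
accepted run is lesions-introduced per day of lineage time times the mean
duration in days.

### Desk scale

The published setting (46-value grid over 0.5-5.0 years, four phylogenies
of 328-922 tips from 100,000 cells, tolerance 0.05 against a large
reference table) is far beyond a test budget. `desk_abc_config()` fixes
the reduced stated world once: populations of 2,000 cells aged 75, two
60-tip phylogenies per run targeting 10 detected PVVs each, a 12-value
grid from 1.0 to 4.3 years, 8 runs per grid value, tolerance 0.2 (about 19
accepted runs, mirroring the published acceptance count against a table
two orders of magnitude smaller). Durations below about a year are
excluded from the desk grid because a 60-of-2,000-cell sample yields
almost no detectable PVVs there within any desk-scale lesion budget — the
same sparsity the published analysis met with up to 3e7 implanted lesions
per setting. At this scale the acceptance suite demands 95% posterior
intervals covering the true duration in at least 90% of 20 seeded
repetitions (observed: 100%), and the reference-table mean MMLD rising
monotonically in mu (Spearman > 0.9). What a green desk-scale test does
*not* establish: the full-scale 45/46 coverage, the <1e-5 end-to-end
detectability fraction, or a calibrated per-cell prevalence — the
desk-scale prevalence is inflated by the much lower detection sensitivity
of a 60-tip sample and is only order-of-magnitude bookkeeping.

## Lesion segregation

Chromosome-scale strand asymmetry (many lesions from one insult
segregating with parental strands) is tested per branch: each SNV's strand
state is the reference strand carrying the mutated pyrimidine; branches
with at least 20 SNVs get a two-sided binomial test of state counts, a
Wald-Wolfowitz runs test (normal approximation, runs never spanning
chromosome boundaries), and rl20 — defined here as the length of the
shortest run among the longest runs that together cover at least 20% of
the branch's mutations, a definition consistent with the >= 6 positivity
threshold but flagged as open because the original defers to an external
package. A branch is positive when rl20 >= 6 and either
Benjamini-Hochberg-adjusted p-value (adjustment per test family across
branches) is below 0.05. Acceptance requires type-I error at most 5% on
1,000 strand-independent branches and at least 90% power on
chromosome-blocked branches of 300 mutations.

## Synthetic data

The generator emulates aged haematopoiesis: a coalescent genealogy with
most coalescences near the root, clock-like Poisson mutations at 15/year
with contexts drawn from a supplied signature on a synthetic two-chromosome
genome (contexts are real channel labels, no reference download), implanted
MAV/PVV lesions whose expected category, lesion/repair nodes and carriers
are recorded as machine-readable truth, Poisson-30x depths with binomial
allele sampling at error 1e-6, and het-SNP read-pair phasing evidence
consistent with the truth haplotypes. PVV implants span three distinct
path nodes and carry at least three mutant tips, the minimal geometry that
is detectable by the read-count pipeline irrespective of child-order
conventions; features of real data it does not emulate include copy-number
change, mixed colonies, and sequencing artefact modes beyond the stated
binomial error model. Everything is deterministic under (configuration,
seed).

## Known limitations

* The binomial assignment model ignores base quality and copy number.
* Subclade pooling, the profiled beta-binomial mean and the rl20
  definition are declared choices where the source is silent; each is
  configurable or flagged above.
* The pass/fail verdict for sandwiches that exist only through final-node
  sibling order is convention-dependent (documented above).
* Desk-scale ABC numbers are not the full-scale published numbers; see
  the desk-scale section for exactly what is and is not established.
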