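---
title: "Quantifying social structure in a bachelor group: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying social structure in a bachelor group: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdnet)
```

herdnet analyses the social organisation of small, fully identifiable
groups of equids observed by two classic field protocols: instantaneous
scan sampling at a fixed interval (here 10 min), recording every
individual's activity, enclosure zone and spatial neighbours, and
all-occurrence sampling of social interactions with actor, recipient and
behaviour type. The package grew around a worked example — a captive
bachelor group of nine Przewalski's horse stallions observed for 65
contact hours — whose published dyadic matrices ship with the package
(`load_fixture()`), and every method is additionally validated against a
synthetic generator that plants known structure.

## Association: the gambit of the group

Two animals are associated at a scan when they stand within one horse
body length (about 1.5 m). The field rule is transitive: if more than
two horses are chained through a common neighbour, all of them count as
one spatial group. `scan_groups()` therefore takes the connected
components of the per-scan proximity-pair graph, and the association
index of a dyad is

$$AI_{ij} = \frac{\#\{\text{scans with } i,j \text{ in the same group}\}}
                {\#\{\text{scans with both } i,j \text{ recorded}\}}.$$

The joint-visibility denominator matters only under partial visibility;
when everyone is seen at every scan (the protocol of the worked
example) it equals the total scan count, so the two conventions
coincide. Dyads never jointly observed are flagged rather than
silently zeroed. Directed interaction-rate matrices divide event counts
per ordered dyad by total contact hours, so a dyad with 70 grooming
bouts over 65 h has rate 1.077 events/h.

## The data-stream permutation null

Observed association indices are compared with a null that preserves
the sampling structure: a cumulative Bejder-style swap chain over the
group stream. Each step picks an observation day, two groups recorded
on that day, and exchanges one member between them; the test statistic
(by default `cv_statistic()`, the coefficient of variation of the
dyadic indices — social preference inflates the spread of AI) is
recorded after every `thin` accepted swaps, with no burn-in discard,
and the empirical p-value is the one-tailed proportion of chain values
at or beyond the observed one.

Three details decide whether this chain is actually a valid null, and
each is worth stating because a naive implementation fails calibration:

* **Legality is defined at the scan level.** A swap may not place an
  individual in a scan sample where it is already present. Without
  this, individuals accumulate double memberships, joint-visibility
  denominators drift downward and the permuted indices inflate — we
  measured a 42% false-positive rate on exchangeable data with the
  group-level-only rule. Under full visibility the constraint reduces
  legal swaps to pairs of groups from the same scan; under partial
  visibility observations can also move between scans of the same day.
  Either way the chain conserves per-scan group sizes and each
  individual's number of observations per day — the margins the
  method is supposed to hold fixed.
* **The proposal must be symmetric.** Members are drawn uniformly from
  the two selected groups and illegal proposals are rejected. Sampling
  only among currently legal candidates looks equivalent but biases
  the stationary distribution, because legal-candidate counts differ
  between the pre- and post-swap states.
* **One swap barely changes the matrix.** A single exchange perturbs
  one scan, so consecutive recorded statistics are strongly
  autocorrelated and a short unthinned chain under-samples the null.
  The `thin` argument (default 1, mirroring the classic
  record-every-swap usage) lets validation runs record every 10–20
  swaps instead.

With these in place, on synthetic data with exchangeable individuals
the CV-test p-values are Kolmogorov–Smirnov-uniform and dyad
classification (`classify_dyads()`: `preferred` when the proportion of
permuted indices at or above the observed is ≤ 0.05, `avoided` when it
is ≥ 0.95 — the same one-tailed distribution read at both ends) flags
about 5% of dyads. The calibration suite uses 200 replicates of 9
individuals over 5 days × 20 scans with 200 recorded samples thinned
by 20; these sizes were chosen as the smallest at which the chain is
well mixed while the whole experiment stays inside a few minutes.

## Subgroups, sociability and assortment

Community detection is greedy multilevel (Louvain) modularity
optimisation on the weighted association matrix (directed matrices are
first symmetrized by summing the two directions), restarted over 100
random node orders with the best weighted Newman–Girvan score

$$Q = \frac{1}{2W}\sum_{ij}\Big(w_{ij} - \frac{s_i s_j}{2W}\Big)
      \,\delta(c_i, c_j)$$

kept. A map-equation optimiser is deliberately not included: on the
worked example the published analysis reports that both algorithms
find the same three subgroups, and the modularity route is the one
whose score (0.593) is reproducible from the printed matrix. The
significance of a partition is assessed against matrices whose
off-diagonal weights are randomly permuted among dyads — the weight
multiset is preserved while the structure is destroyed. (Relabelling
nodes instead would leave the best achievable modularity unchanged and
test nothing.)

Per-individual sociability uses node strength $S$ (summed incident
weights; out + in for directed matrices) and the tuned weighted degree
$WD = k^{1-\alpha} S^{\alpha}$ with $k$ the number of (outgoing)
nonzero ties. $\alpha = 0.5$ — the geometric mean of tie count and
strength — is the package default because it reproduces the published
node-measure table exactly (e.g. an individual with a single tie of
weight 0.665 has $WD = \sqrt{0.665} = 0.815$, and a stallion with
incoming interactions only has $WD_{affil} = 0$, pinning the directed
convention to outgoing ties). Continuous-trait assortment is the
weighted Pearson correlation of trait values across edge endpoints,
each undirected edge entering in both orientations, with node-label
permutations for significance.

## Dominance

Agonistic encounters yield a directed win matrix: the initiator of an
offensive act wins; defensive (submissive) acts are reversed so the
animal the submission is directed to wins. David's scores use raw win
proportions $P_{ij}$ (a dyad with no encounters contributes zero to
both sides, which keeps the scores summing to exactly zero — the
published dominance-index column does too), and hierarchy linearity is
de Vries' randomized Landau h′: undecided dyads are filled at random
over `n_rand` replicates, h is computed from dominance out-degrees,
and the p-value is the right tail of h under fully random
tournaments. With the sparse agonistic data typical of stable bachelor
groups, h′ is expected to be low and non-significant; the package's
synthetic generator, which plants a strict order with 0.9 win
probability, recovers h′ = 1 at high event counts.

## Behavioural synchrony

The synchronization index of a dyad is the share of its joint scans
with the same behaviour label, at category or fine-activity level.
Per-activity synchrony uses a Jaccard-style denominator — scans where
at least one member shows the behaviour — which keeps values in [0, 1]
and returns 0 for behaviours a dyad never shows; the published
per-activity table does not disambiguate its denominator, so this
choice is recorded here and in every report.

The null shuffles one randomly chosen individual's behaviour sequence
across 100 randomly selected scan samples per permutation, preserving
its marginal behaviour distribution while breaking temporal alignment.
Two p-value conventions coexist deliberately:

* the **group mean** BSI is compared against the permuted means as a
  plain one-tailed proportion (every permutation moves the mean);
* **per-dyad** p-values are computed only over the permutations that
  shuffled one of the dyad's two members — a permutation that touched
  neither member cannot change that dyad's index, and counting those
  tied replicates would push every dyad's p towards 1 and zero the
  test's power — with the add-one small-sample correction
  $(k+1)/(n+1)$. This makes the per-dyad test slightly conservative
  (measured 2–3% positives at the 5% level on exchangeable data)
  rather than badly anticonservative or degenerate.

`cluster_synchrony()` contrasts mean synchrony within versus between
detected subgroups, with significance from membership shuffles.

## Space and time use

Time budgets are proportions of each individual's scans per behaviour
category, overall and within the protocol's three time-of-day bins
(morning 05:00–10:00, afternoon 10:10–15:00, evening 15:10–20:30,
stored as inclusive minute ranges). Zone preference uses Ivlev's
electivity $EI_z = (o_z - e_z)/(o_z + e_z)$ with the expected share
$e_z$ proportional to zone area over the zones available in the
period — for the default map, 22 equal 30 × 70 m quadrats of which
four (enclosure II) drop out after the cutover day, handled by
`availability_split()`. $EI = -1$ for an unused zone and 0 for use
exactly at availability. Evenness of space use is Dickens' spread of
participation index, 0 for uniform use and 1 for single-zone use.
These ratio-based forms were chosen because they are the classical
indices with exactly the stated endpoints; the source analysis cites
appendix formulas that are not printed, so the forms are fixed here as
a design decision. Group-level models of behaviour on cluster, time of
day and enclosure availability are out of scope; `scan_model_table()`
exports the tidy per-scan table such models need.

## Kinship

Pedigree kinship uses the tabular method (parents before offspring,
$a_{ii} = 1 + a_{sd}/2$, $a_{ij} = (a_{s_i j} + a_{d_i j})/2$,
$\varphi = A/2$), with founders pairwise unrelated. The packaged
one-generation pedigree treats the studbook parents as founders, which
is sufficient for the full-sib/half-sib structure of the worked
example (e.g. the two full brothers share $\varphi = 0.25$) but not
for deeper studbook relatedness — the published kinship–association
correlation used the full studbook and is therefore not reproducible
here. `kinship_gene_drop()` provides an independent Monte Carlo check
by dropping uniquely labelled founder alleles through the pedigree.

## The synthetic generator

`synth_generate()` emulates the study design: per scan, each planted
cluster draws a latent behaviour state from the base rates and each
member copies it with probability `sync_coupling` (else draws
independently); proximity pairs are independent Bernoulli draws per
dyad (`p_within` = 0.6 inside clusters, `p_between` = 0.05 across,
chaining left to the association stage exactly as in the field rule);
zones follow cluster-specific preference distributions; affiliative
events are Poisson per directed dyad per hour; agonistic bouts follow
a strict linear order with win probability 0.9. Defaults mirror the
study conditions — 9 individuals in clusters of 3/4/2, 25 days × 36
ten-minute scans, behaviour base rates set to the published time
budget (foraging 0.565, rest 0.199, locomotion 0.090, social 0.025,
vigilance 0.105, other 0.016). `sync_coupling = 0.6` and the
affiliative rates (0.30/0.01 events·dyad⁻¹·h⁻¹ within/between) were
chosen once as values that produce the qualitative contrast the study
reports (clearly elevated within-cluster synchrony and interaction
rates against a sparse background) at realistic magnitudes.

What the generator does **not** emulate: temporal autocorrelation of
behaviour within a day (states are drawn independently per scan),
movement and therefore spatially coherent zone occupancy, observation
gaps, khulan heterospecifics, weather. Passing tests on synthetic data
therefore demonstrate correctness of the estimators under the stated
generative model, not robustness to field messiness such as serially
correlated activity bouts.

`synth_null_dataset()` flattens every source of structure (equal pair
probability, no coupling, shared zone preference, symmetric win odds)
so that individuals are exchangeable; all permutation-test calibration
rests on it.

## Numerical conventions and degenerate inputs

Ties in one-tailed empirical p-values count against rejection
(`>=`). Matrices must carry matching row/column ids; undirected
containers enforce symmetry at 1e-8. A zero-mean dyadic matrix has no
CV; a constant matrix has no Mantel correlation or assortment; a
single available zone has no SPI; a single cluster has no
between-cluster synchrony — all are errors, not silent NAs. The Mantel
test enumerates all $n!$ relabellings exactly for up to 8 individuals
(`exhaustive = TRUE`); beyond that it samples. Louvain restarts are
driven by one seed, so detection is deterministic given (matrix,
seed). Every stochastic routine takes an explicit seed and stores it
in its result; `run_pipeline()` derives per-stage substreams from one
master seed.

## Validation scale

The test suite exercises the full study scale where it matters
(cluster recovery over 20 seeds at 25 days × 36 scans; 1000-swap
chains) and reduced scales elsewhere (calibration at 5 days × 20
scans × 200 recorded samples; gene-dropping at 10⁵ replicates), sizes
chosen so the complete suite runs in a few minutes on one core while
keeping Monte Carlo error well inside the asserted tolerances.
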