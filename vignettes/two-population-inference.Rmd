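---
title: "Methods: two-population demographic inference and coding diversity from genotype calls"
author: "twopopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-population demographic inference and coding diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`twopopgen` implements a population-genomic inference chain for a pair of
populations descended from a split, of the kind used for bottlenecked alpine
mammals with a handful of resequenced genomes: variant QC from VCF genotype
calls; per-individual heterozygosity, runs of homozygosity (RoH), kinship and
inbreeding; folded one- and two-dimensional site frequency spectra (SFS) and
the standard diversity statistics; composite-likelihood fitting of four
two-population demographic models; estimation of a gamma distribution of
fitness effects (DFE); and a comparative life-history layer. A structured
coalescent simulator generates data with the statistical structure the
analysis assumes, so every stage is testable without external data.

## The demographic model family

An ancestral population of diploid effective size $N_a$ splits into two
daughters of relative sizes $\nu_1, \nu_2$ at scaled time $T_s$ (units of
$2N_a$ generations, measured backward from the present). The four members of
the family differ only in when gene flow is active:

* **SI** (strict isolation): no migration. Free parameters $(\theta, \nu_1,
  \nu_2, T_s)$.
* **IM** (isolation with migration): continuous bidirectional flow at scaled
  rates $m_{12}, m_{21}$ ($2N_a$ times the per-generation fractions;
  $m_{12}$ is flow into population 1). Adds $(m_{12}, m_{21})$.
* **AM** (ancient migration): flow from the split until $T_a$ ago, none
  since. Adds $T_a$.
* **SC** (secondary contact): isolation from the split until $T_{sc}$ ago,
  flow since. Adds $T_{sc}$.

$\theta = 4 N_a \mu L$ scales the expected spectrum and is always profiled
analytically. Nesting: SI $\subset$ IM ($m = 0$); IM $\subset$ AM
($T_a = 0$) and IM $\subset$ SC ($T_{sc} = T_s$). Physical units use
$N_a = \hat\theta / (4 \mu L)$ and $t_{\mathrm{years}} = t \cdot 2 N_a g$,
with defaults $\mu = 10^{-8}$ per generation (a per-year rate of
$2\times10^{-9}$ at a generation time of $g = 5$ years, itself derivable
from synonymous divergence by `mutation_rate_from_divergence()`).

## The coalescent engine

Both the simulator and the expected-SFS engine run the same continuous-time,
event-driven structured coalescent (C++): exponential waiting times compete
among within-deme coalescence (rate $\binom{j_d}{2}/\nu_d$) and per-lineage
backward migration (rate $m_{d\cdot}$), with epoch boundaries at the
migration switch time and the split. This is exact for the sample sizes used
(tens of chromosomes) and fast (about $10^6$ genealogies per second for
$4+4$ diploids).

Two implementation details matter for testing:

* The engine uses a private counter-based RNG stream, so results never
  perturb R's RNG and are exactly reproducible from an integer seed.
* Waiting budgets are spent against the integrated total rate across epoch
  boundaries, and events are selected by a single uniform against cumulative
  rates, so **zero-rate event types consume no randomness**. Models whose
  rate functions coincide produce *identical* event streams from the same
  seed; the nesting limits AM($T_a{=}0$) = IM, SC($T_{sc}{=}T_s$) = IM and
  IM($m{=}0$) = SI therefore hold exactly at matched seeds, and the test
  suite asserts them at $10^{-2}$ relative tolerance (they pass at 0).

Mutations are infinite-sites: Poisson on branches with rate $\theta/2$,
positions drawn uniformly without replacement from the $1..L$ grid.
Genotypes pair consecutive sampled chromosomes within a population. The
genome can be split into independently segregating loci (free recombination
between, none within); no within-locus recombination is modelled, which
matters only for variance between replicates, not for any expectation the
tests assert.

## Sequencing noise and artifact injection

The noise layer attaches DP (negative binomial around `mean_depth`;
deterministic when `depth_dispersion = 0`), AD (heterozygote reads split
binomially, distorted with probability `balance_noise`; split exactly in
half when `balance_noise = 0`) and GQ (Phred margin between the called and
the best competing genotype under a 1% error model, clamped to
`[gq_floor, gq_ceiling]`). Per-site QC annotations (QUAL, QD, SOR, MQ,
MQRankSum, ReadPosRankSum) are drawn from passing ranges, or from failing
ranges with probability `info_fail_fraction`. With all noise parameters
zero the layer is fully deterministic, so the two replicate callsets of the
reference individual are bit-identical — the property the replicate-based
false-positive filter is tested against.

Clustered artifacts emulate mapping errors in duplicated regions: in each
of `fp_window_count` designated 5-kb windows, `fp_per_window` new positions
are injected at which the two replicate callsets carry discordant
homozygous genotypes. The truth record lists the injected positions and
windows, so the FP-window detector's confusion matrix is exact.

## Variant QC

Genotype level: a genotype is kept iff DP $\ge 6$, GQ $\ge 10$, and — if
heterozygous — the reference-allele ratio lies in $[0.23, 0.76]$. Site
level, two stages: the *heterozygosity* stage requires QUAL $\ge 20$ and
site coverage within 20%–200% of the callset mean; the *demography* stage
requires QUAL $\ge 30$ and mean DP in $[10, 50]$. Both require RMS mapping
quality $\ge 20$ and the hard filters QD $> 2$, SOR $< 3$, MQ $> 50$,
MQRankSum $\in [-2.4, 0.6]$, ReadPosRankSum $\in [-2.2, 2.4]$ — the rank-sum
thresholds are interpretable only as exclusion boundaries, and missing
annotations pass, as in standard hard filtering. All rules are pure
per-site/per-genotype predicates, so filters are idempotent and
order-independent (asserted as properties).

A position where the two replicate callsets disagree with *homozygous*
genotypes is a false-positive SNP; any 5-kb window (grid anchored at
coordinate 1, half-open) holding more than one FP-SNP is blacklisted
genome-wide. Thinning keeps the first SNP per 20-kb window. Anchoring and
the first-by-coordinate rule are fixed conventions so counts are
deterministic.

## Per-individual statistics

* Heterozygosity: $1000 \cdot \mathrm{hets} / \mathrm{callable\ bp}$; the
  callable length excludes blacklisted windows and failed sites.
* RoH: a two-state HMM; heterozygote emission $10^{-3}$ inside RoH
  (genotyping error), the individual's genome-wide heterozygous fraction
  outside; switch probability $(1 - e^{-2\rho d})/2$ between sites at
  distance $d$ with $\rho = 10^{-7}$/bp. Viterbi decoding, forward–backward
  posterior per segment, segments $> 2$ Mb reported by default (long runs
  indicate recent inbreeding). Sex chromosomes are excluded via an autosome
  allow-list.
* Kinship: the KING-robust estimator
  $\phi = (N_{\mathrm{HetHet}} - 2 N_{\mathrm{OppHom}}) /
  (N_{\mathrm{Het},i} + N_{\mathrm{Het},j})$, with the symmetric
  denominator so $\phi(i,j) = \phi(j,i)$; 0.5 for self, $\approx 0.25$ for
  parent–offspring, $\le 0$ between long-isolated populations.
* Inbreeding: $F = (O - E)/(N - E)$ with the small-sample-corrected
  $E = \sum_s (1 - 2p_s(1-p_s) \cdot n/(n-1))$.
* PCA: variant-centered dosages decomposed by SVD, singletons included by
  default.

## Spectra

Folded spectra index sites by minor-allele count. Sites with missing
genotypes are hypergeometric down-projected from their observed allele
number to the target $n$ (sites with fewer called chromosomes are dropped
and counted). The joint SFS projects each population to $n_\mathrm{eff} = 4$
chromosomes (axes 0..4, the convention for published 4-diploid samples) and
folds on the *combined* minor allele; cells with total count exactly half
the pooled sample are split evenly with the complementary cell and flagged.
Projection of a folded spectrum is exact because the minor count determines
the hypergeometric kernel, and folding commutes with projection (a tested
property).

Diversity: $\theta_W = S/(a_1 L)$;
$\pi = \sum_i \xi_i \, 2 i (n-i) / (n(n-1)) / L$ (identical to the mean
pairwise difference, an exact identity the suite asserts); Tajima's $D$
via the standard $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$ constants,
undefined (NA with a warning) when $S = 0$. $\pi_N/\pi_S$ uses per-site
rates with the class-specific surveyed lengths.

## Demographic fitting

The expected folded joint SFS is the Monte-Carlo mean over engine
genealogies of branch lengths classified by joint descendant configuration,
scaled by $\theta/2$ and folded with exactly the conventions above, so
observed and expected spectra are commensurable. The composite likelihood
treats unmasked cells as independent Poisson counts; the $\theta$ scale has
the analytic optimum $\sum \mathrm{obs} / \sum \mathrm{exp}$. Zero expected
cells under positive observations are floored (documented option).

Optimization is multi-start Nelder-Mead in log-parameter space with bounds
$\nu \in [10^{-3}, 10^3]$, $T \in [10^{-4}, 10]$, $m \in [10^{-3}, 50]$;
the epoch-change time is parameterized as a fraction of $T_s$ so the
constraint is built in. The search proved to be the hard part, and three
empirical findings shaped it (all reproducible with the development
scripts):

1. **Candidate quality is not predicted by a random point's likelihood.**
   The coarse stage therefore adds structured candidates from an internal
   strict-isolation warm fit: under gene flow the apparent isolation time
   underestimates the true split, so split-time multipliers
   $\{1, 2, 4\}$ crossed with a migration grid seed the migration models.
2. **Descending at reduced Monte-Carlo precision strands the simplex.**
   The composite-likelihood valleys are curved; partial descents at low
   engine precision end at points where the full-precision surface shows a
   spurious local optimum. The leading candidates therefore get
   double-round full-precision descents directly.
3. **The surface is multimodal even when smooth.** Distinct local optima
   10–30 log-likelihood units apart persist at $10^6$ engine replicates.
   This is what the replicate protocol is for: `n_replicates` (default 50,
   the standard protocol for this analysis) perturbed restarts (factor
   $\le 4$; the first replicate unperturbed) around the refined optimum,
   with the best endpoint re-polished at full precision.

Model choice: likelihood-ratio tests for the nested pairs (SI–IM, IM–AM,
IM–SC; $2\Delta\ell$ against $\chi^2$ with df = parameter difference), AIC
for AM vs SC, and a full ranking table.

**Calibration caveat.** The engine's Monte-Carlo error deforms the
log-likelihood proportionally to the total SNP count; naive LRTs computed
across engine precisions are anti-conservative. The calibration test
generates null data from a point *of the fixed-precision engine family
itself* and fits both models on that same surface, which removes the
misspecification term; users comparing models on real data should use
`mc_reps` large enough that $S \cdot \varepsilon^2$ is small against the
$\chi^2$ scale ($\varepsilon \approx$ relative cell error
$\propto 1/\sqrt{\texttt{mc\_reps}}$).

### The parameter-recovery world

The ancient-migration recovery test uses $\nu_1 = 1$, $\nu_2 = 0.5$,
$T_s = 1.5$, $T_a = 0.4$, $m_{12} = 0.5$, $m_{21} = 0.25$, with a
$4\times4$ folded joint SFS Poisson-scaled to $2\times10^5$ SNPs. The
regime was chosen on expected-information grounds *before* fixing the
test: under strong migration ($m \gtrsim 2$) the family has a flat ridge —
we measured a parameter vector with $T_s$ 40% low and $\nu$ 60% low whose
spectrum sits within $\mathrm{KL} \times 2\times10^5 \approx 7$
log-likelihood units of the truth (cells differ by under 1%), so no
estimator could meet a 20% criterion there. Under weak migration every
20% single-coordinate perturbation costs 78–1500 units and recovery is
achievable. A green recovery test therefore establishes that the estimator
works *in an identifiable regime*; it does not establish that every AM
history is recoverable from 24 folded cells.

## DFE estimation

Synonymous sites are the neutral reference. Stage 1 fits a two-epoch
nuisance (relative size $\nu$, change time $\tau$) to the synonymous folded
SFS by Poisson ML; the expected neutral spectrum is exact, from lineage-
count occupancy times (block matrix exponential for the bounded epoch,
closed form for the unbounded one) and the classical subtending-probability
formula — it reduces to $\theta/i$ at $\nu = 1$ to $10^{-8}$.

Stage 2 fits a deleterious-only gamma over $N_e s$ to the nonsynonymous
SFS. The selected expectation under constant size is the diffusion sojourn
integral $\xi_i \propto \int_0^1 \binom{n}{i} x^{i-1} (1-x)^{n-i-1}
H(x;\gamma)\,dx$ with $H(x;\gamma) = (1 - e^{-\gamma(1-x)})/(1 -
e^{-\gamma})$ and $\gamma = -4 N_e s$, evaluated stably in log space on
cached 400-node Gauss–Legendre grids; the demographic nuisance is carried
over by multiplying per-frequency-class distortion factors
$r_i = \xi_i^{\mathrm{2epoch}} / \xi_i^{\mathrm{const}}$ (so $N_e s = 0$
reduces exactly to the neutral two-epoch spectrum). The gamma mixture is
discretized at 64 equal-mass quantile nodes — equal-mass nodes track the
distribution for any (shape, mean) without range tuning, which a fixed
log-spaced grid does not.

**Identifiability and the anchored rate.** Mutations with $N_e s \gg 100$
never segregate; with a freely scaled nonsynonymous rate the fitted mean
drifts arbitrarily (we observed $6\times10^5$ for a true mean of 200 with
bin proportions 0.25 off) because only the *deficit* of nonsynonymous
variants relative to the mutational input identifies the strong tail.
When both spectra carry surveyed lengths, the nonsynonymous input is
therefore anchored to the synonymous per-site estimate via
$L_{\mathrm{nonsyn}}/L_{\mathrm{syn}}$ — the standard practice of DFE
estimators. Reported bins are $N_e s \in [0,1)$ (effectively neutral),
$[1,10)$ (slightly deleterious), $[10,100)$, $[100,\infty)$.

## Comparative layer

Life-history records (adult mass plus six variables) are log-transformed;
each variable is regressed on log mass by OLS and the residuals are
combined into "reproductive output" and "reproductive timing" scores by
configurable loadings. Published Eutherian loadings are not redistributed:
the bundled `loadings_synthetic.tsv` is an equal-weight placeholder
(clearly labelled synthetic) that the tests use; users supply the
literature values. Scores are invariant to mass units and species order.
The diversity regression is OLS of $\log_{10} \pi_S$ on $\log_{10}$
propagule size (base-10 for the regression, natural logs for life-history
variables — declared conventions, the sources are silent), refitted with
and without an exclusion set. `rescale_ancestral_diversity()` applies the
equilibrium proportionality $\pi \propto N_e$.

## What the synthetic generator does and does not establish

The generator reproduces: the two-population split-with-migration-epochs
genealogy structure, infinite-sites biallelic SNPs, coding site classes
with per-gene grouping, depth/balance/GQ noise around configurable filter
boundaries, and clustered homozygous-discordant artifacts in designated
5-kb windows with exact truth records. It does not reproduce: read-level
errors, mapping bias, indels, linked selection, within-locus recombination,
or realistic gene structure. Green tests therefore establish the
correctness and calibration of the *inference machinery* under the stated
models — not robustness to upstream artifacts the simulator does not
emulate.

## Numerical choices

* Engine precision: `mc_reps` genealogies per expected spectrum; relative
  cell error $\sim 1/\sqrt{\texttt{mc\_reps}}$. Defaults: $10^5$ for
  fitting, $2\times10^4$ for coarse ranking.
* Composite-likelihood zero floor: `zero_floor` ($10^{-6}$ relative to the
  smallest positive expected cell), warned when applied.
* Ambiguous fold cells (total count exactly half the pooled sample) are
  split evenly and flagged rather than dropped.
* Degenerate inputs: empty spectra warn and return empty objects; $S = 0$
  makes Tajima's $D$ NA; a constant genotype matrix gives zero PCA scores
  with a warning; chromosomes with fewer than two informative sites warn
  and contribute no RoH segments.
* All randomness flows from one integer seed through named substreams
  (`substream_seed`), so each stage is independently reproducible and the
  pipeline summary is byte-identical across runs at a fixed seed.

## Known limitations

* The Monte-Carlo expected-SFS engine makes model comparison sensitive to
  `mc_reps` (see the calibration caveat); a deterministic moment-based
  engine would remove this and could be swapped in behind the same
  contract.
* Composite (linkage-ignoring) likelihoods understate uncertainty; no
  parameter confidence intervals are reported.
* Two populations only; the DFE excludes beneficial mutations; unfolded
  (polarized) spectra are not produced.
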