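---
title: "Models and methods behind wormscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wormscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormscreen)
```

This vignette explains the genetic models, statistics and design decisions
in `wormscreen`, in the spirit of a methods section: what each component
assumes, where its defaults come from, and what the validation suite does
and does not establish.

## The biological setting

*C. elegans* grows as self-fertilizing XX hermaphrodites; X/O males arise
from crosses and are hemizygous for the X. A forward suppressor screen
starts from a mutant that fails under some condition — here an *eat-5*-type
strain whose newly hatched larvae arrest on a restrictive food — and asks
which second-site mutations restore growth. Mutagenized hermaphrodites
(P0) transmit independently mutagenized haploid genomes to their F1
self-progeny; recessive suppressors surface as homozygotes in the F2. The
package models this pipeline end to end: transmission genetics, the two
screen designs, the statistics estimated from their yields, two-point
mapping of recovered mutations, and the phenotype comparisons used to
order genes into pathways.

## Mendelian engine

Genotypes are ordered allele pairs per locus (maternal, paternal) on a
genetic map over chromosomes I–V and X; males carry a single X allele with
the paternal slot holding the absent-X marker `"O"`. Meiosis is modelled
per chromosome as a Markov chain over the loci in map order: the first
locus takes either parental haplotype with probability 1/2, and phase
switches between adjacent loci with the interval's recombination fraction.
There is no crossover interference beyond what this chain implies. Exact
enumeration (`enumerate_offspring_distribution()`) marginalizes the same
chain — switch probabilities across skipped homozygous loci compose as
$\theta_{12} = \theta_1 + \theta_2 - 2\theta_1\theta_2$ — so simulation
and enumeration are provably one model; the test suite exploits this by
checking every simulated genotype class against its exact probability.

Map distances convert to recombination fractions linearly
($\theta = d/100$, capped at 1/2), matching the small-distance convention
in which "less than 20 cM" means a recombinant fraction below 0.2.
Haldane's map function $\theta = (1 - e^{-2d/100})/2$ is available via
`map_function = "haldane"` wherever distances enter.

Deliberate simplifications: exactly two allelic states per locus (wild
type plus tagged mutant alleles; allele ids keep mutational events
distinguishable); selfing yields hermaphrodites only (spontaneous X
nondisjunction males, ~0.1–0.2% in reality, are ignored because every
scheme modelled supplies males by crossing); no viability or fecundity
differences between genotypes except through explicit phenotype rules;
enumeration is guarded at 12 segregating loci ($2^{12}$ gamete classes per
parent), ample for any bench-realistic cross.

## Mutagenesis and screen designs

EMS mutagenesis hits each suppressor gene in each transmitted haploid
genome with probability $f$ (`mutagenesis_model()`). The hit process is
Bernoulli, at most one hit per gene per genome: at realistic frequencies
($f \sim 5\times10^{-4}$) the Poisson/Bernoulli difference is of order
$f^2$ and the single-hit bookkeeping keeps every allele identifiable.
Neutral background mutations arrive as Poisson(`background_rate`) per
genome at uniform map positions (0–50 cM per chromosome, roughly the
*C. elegans* genetic map length); they matter only for backcross studies.

Each F1 carries two independently mutagenized genomes, so the F1 carrier
frequency for one gene is $1-(1-f)^2 \approx 2f$. In the **F1 clonal
screen**, one gravid F1 is plated per dish and a plate is called suppressed
iff the F1 carries a suppressor allele — a recessive suppressor segregates
homozygous F2s on the plate, so both dominance classes are detectable, and
effective genomes are $G = 2\,F_1$. Only one isolate is kept per F1 even
when a plate carries two mutations, exactly as at the bench. Detection is
perfect by default (the frequency estimator implicitly assumes this); a
`detection < 1` knob exists for power studies. In the **F2 selection**,
`F2` viable F2s descend from a pool of selfing F1s; a recessive suppressor
is recovered only as a homozygote, at frequency
$2f(1-f)\cdot\tfrac14 + f^2 \approx f/2$, a dominant one at $\approx 3f/2$
(the heterozygote and homozygote expression probabilities, 1/4 and 3/4,
are obtained from the enumeration engine, not hard-coded). Rare
non-suppressed escapers default to zero, with a configurable
false-positive rate.

## Backcrossing and dilution

One backcross round is two crosses: strain hermaphrodite × clean male,
then a suppressor-carrying male progeny × clean hermaphrodite, keeping
suppressor-carrying hermaphrodites. The dilution of a background mutation
is defined as the drop in its expected allele frequency in the strain
*recovered after the round*, i.e. measured on suppressor-bearing gametes
of the selected heterozygous hermaphrodite (equivalently, in the
re-homozygosed strain). Under this definition — the only one consistent
with all three bench facts at once — an unlinked autosomal mutation
dilutes exactly fourfold per round, an X-linked one exactly twofold (the
male's single X passes intact to all his hermaphrodite progeny), and a
mutation completely linked in cis to the suppressor is never diluted.
`backcross_dilution()` derives these factors by chaining exact
enumerations through both crosses (phase-preserving, so linkage survives);
`simulate_backcross_round()` is the Monte Carlo counterpart, vectorized
across pedigrees with rejection sampling for the selection steps.

## Frequency estimators

With $n$ isolates of one gene across both designs,

$$\hat f = \frac{n}{2 F_1 + F_2/2},$$

the denominator being the summed effective genomes of the two designs for
a recessive suppressor. The selection's $G = F_2/2$ (and $3F_2/2$ for
dominants) is reconstructed from the expected suppressed-F2 frequency; it
is the correct exposure for *isolate* counting. When sequencing collapses
isolates into independent mutational events ($n_i$, via identical
linked-variant signatures, `count_independent_events()`), the estimator
$\hat f = n_i / G$ needs an *event-level* exposure: for the clonal screen
this is again $2F_1$, but for a selection it is at most twice the F1 pool
feeding the F2s, discounted for events whose homozygous descendants were
never sampled. The acceptance analysis therefore validates the
independent-event estimator on designs where the F2 sampling is deep
enough (F2 ≫ F1 pool) that every event is detected and the exposure is
exactly twice the pool size. Uncertainty is an exact Poisson interval for
the event count at the stated exposure — the source analysis reports the
point estimate only, and isolates are rare events over many genomes, so a
Poisson model is the natural one.

## The transgene rescue statistic

Extrachromosomal arrays transmit to a fraction $t$ of progeny, measured on
permissive food ($t = k_H/N_H$, binomial SE). On restrictive food only
escapers from arrest are counted, and the fraction transgenic among them
is $f = k_D/N_D$. The rescue statistic is the odds ratio

$$r = \frac{f(1-t)}{t(1-f)}, \qquad
  \mathrm{SEM}_r = r\sqrt{\frac{1}{N_D f(1-f)} + \frac{1}{N_H t(1-t)}},$$

the SEM being the delta-method propagation of the two independent binomial
fractions on the log-odds scale. Orientation: $r$ near 1 means transgenic
animals escape as well as their non-transgenic siblings; $r \ll 1$ means
the transgene restores arrest (rescue). The printed source formula is
typographically ambiguous about numerator and denominator; this
orientation is the one under which "values much less than 1 indicate
rescue", and the reciprocal is available via
`orientation = "transmission_odds"`. Under the generating model used for
validation, $\mathrm{odds}(f) = \mathrm{odds}(t)\cdot e_t/e_n$, so $r$
estimates the escape-probability ratio transgenic : non-transgenic
exactly. Boundary counts (0 or 100% transgenic) are refused by default; a
Haldane–Anscombe +0.5 correction is available by flag. Significance comes
from the Pearson χ² test of independence on the food × transgenic 2×2
table, without Yates correction by default (a flag enables it), Bonferroni
corrected across the lines of an experiment.

## Two-point mapping

In the mapping cross, an F1 male heterozygous for one visible marker per
chromosome — with the focal mutation in repulsion to the same-chromosome
marker — is crossed to a clean hermaphrodite. Lines that inherited the
focal mutation ("informative") throw an unlinked marker with probability
1/2 and a linked repulsion marker with probability θ; these expectations
are derived by enumerating the male's gametes conditional on the line
being informative and hermaphrodite, which also exposes the X-marker
subtlety (every hermaphrodite line receives the paternal X, so X markers
are uninformative for autosomal mutations and are flagged as such).

Per marker, `linkage_calls()` runs a two-sided exact binomial test against
the unlinked expectation, Bonferroni corrected across markers; markers
significantly below expectation are "linked" and receive a one-sided
Clopper–Pearson upper bound on θ, reported in cM as $100\,\theta$ (for 0
recombinants out of $n$: $1-(1-c)^{1/n}$; 0/16 at 95% gives 17.1 cM). The
*assigned chromosome*, however, is that of the marker most depressed below
expectation (minimum thrower fraction, ties by p-value), with that
marker's significance call attached as a qualifier. This separation is
deliberate: with 16 informative lines and a marker at 10 cM, the thrower
count is Binomial(16, 0.1) and exceeds the Bonferroni significance cut in
about a fifth of crosses, yet the linked marker is almost always the
minimum — argmin assignment recovers the right chromosome in ≈97–98% of
simulated crosses, which is what a geneticist reading the panel would
conclude, while the significance call honestly reports the strength of
evidence. The confidence level behind a distance bound is a parameter
(default 0.95), since bench reports rarely state one.

X-linkage detection from the backcross (`xlinkage_from_backcross()`)
compares the carrier fraction among cross hermaphrodites with the
autosomal expectation 1/2 (one-sided exact binomial — only an *excess* of
carriers is evidence against autosomal inheritance) and with the X-linked
all-carrier model, which any single non-carrier refutes exactly. Both
models surviving (tiny panels) or both rejected (e.g. 12/16) returns
"inconclusive".

## Phenotype models

Growth rate is the inverse of the time for a small founding population to
exhaust its plate. Because the population grows roughly exponentially with
brood size $B$ per generation, the exhaustion time scales as $1/\ln B$ and
the predicted rate ratio between strains is $\ln B_1/\ln B_2$: a drop in
effective brood size from 300 to 7 predicts a threefold, not fortyfold,
growth-rate drop. `compare_groups()` wraps the standard comparisons (Welch
t test; compare-vs-control with Bonferroni by default — Dunnett via
`multcomp` when requested and installed, since exact Dunnett tables are
not re-derived here; two-way ANOVA). The epistasis ("same pathway") call
for a double mutant requires a significant interaction term, a negative
interaction contrast, and a double-mutant mean not *significantly*
exceeding the larger single-mutant mean (one-sided Welch test at the same
α — a sharp sample-mean inequality would fail half the time when the true
means coincide). On additive data the call's type-I rate is well below the
nominal α because all three conditions must hold.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes with recorded
ground truth: screens (defaults: $f = 5\times10^{-4}$ per gene, 5128
clonal-screen F1s, 68,000 selected F2s — the scale of a real screening
campaign), rescue assays (default transmission rate $t = 0.5$, a
placeholder in the middle of the realistic range, as real arrays vary
widely and $t$ is always measured), and per-worm pump-rate datasets
(truncated-at-zero normal per genotype, defaults 10 vs 30 pumps/min with
SD 3 and $n = 12$ per genotype, typical of L1 terminal-bulb counts).
Everything is deterministic under a fixed seed.

What passing tests on these data do **not** show: the generators draw from
the same model families the estimators assume (binomial transmission,
normal pump rates, perfect detection), so recovery tests establish
internal correctness — unbiasedness, calibration of the delta-method SEM,
power of the mapping design — not robustness to real-data pathologies such
as array silencing, plate-to-plate environmental variance, scorer error,
or mutagenesis cold spots. The `detection` and `false_positive` knobs
exist precisely so such robustness studies can be run, but no claim about
real data is made here.

## Numerical choices and problem sizes

Exact enumerations are held to conservation within $10^{-12}$ and capped
at 12 segregating loci. Monte Carlo checks in the test suite use 4
binomial standard errors as their acceptance band (a per-class false-alarm
rate of ~$6\times10^{-5}$) at fixed seeds. The validation suite sizes —
20,000 offspring for oracle-equivalence checks, 200 replicate screens for
frequency recovery, 1000 rescue assays for SEM calibration, 10,000
pedigrees for dilution, 200 mapping crosses — keep each run in seconds on
one core while leaving the Monte Carlo bands far narrower than the effects
tested. Rejection sampling in the backcross simulator retries only failed
rows and errors out (capacity condition) rather than looping forever if a
conditioning event is effectively impossible. Boundary cases are explicit
errors with condition classes (`ws_argument_error`, `ws_structural_error`,
`ws_capacity_error`, `ws_degenerate_error`) so callers can distinguish
misuse from degeneracy.

## Known limitations

* No crossover interference; the linear map function is exact only at
  small distances (Haldane optional).
* No multi-allelic series at one locus beyond tagged mutant ids; no
  DNA-level representation of alleles.
* The selection simulator models "viable F2s plated" directly and
  abstracts egg-prep losses; no growth competition on plates.
* The event-level exposure of a selection (the Table-S1-style $G$) is
  implemented only in the saturated regime F2 ≫ F1 pool; partial-detection
  corrections are left to the user via the recorded simulation truth.
* Dunnett adjustment delegates to `multcomp`; without it the
  compare-vs-control default is Bonferroni, which is slightly
  conservative.
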