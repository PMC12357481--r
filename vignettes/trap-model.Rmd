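---
title: "Simulating TE invasions under the piRNA cluster trap model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating TE invasions under the piRNA cluster trap model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trapsim)
```

## The model

`trapsim` performs individual-based forward simulations of transposable
element (TE) invasions in a diploid population of constant size $N$ with
discrete, non-overlapping generations. The host defense follows the trap
model: piRNA clusters are fixed genomic intervals, and an individual
carrying at least one TE insertion inside a cluster is *regulated* — its
germline produces no new insertions of the TE. Silencing acts in trans on
all copies, and (in multi-TE simulations) on all TE types: we assume the
biases of co-invading TEs diverged recently, so host piRNAs still match
both.

Each insertion is a `(position, bias)` pair. Positions are 0-based
integers in the half-open genome interval $[0, g)$; chromosomes tile this
interval contiguously, and each chromosome may carry one cluster interval.
A haplotype holds at most one insertion per position; a diploid individual
is two haplotypes, and its copy number $n$ counts both (homologous double
occupancy counts twice).

The insertion bias $b \in [-100, 100]$ maps to the probability $p_c$ that
a new insertion lands in a cluster:

$$a = \frac{b/100 + 1}{2}, \qquad s = a f + (1-a)(1-f), \qquad
p_c = \frac{a f}{s},$$

with $f$ the genomic cluster fraction. $p_c(0) = f$ exactly, $p_c$ is
strictly increasing in $b$, and the extremes give complete avoidance
($b=-100$, $p_c=0$) and cluster-only insertion ($b=+100$, $p_c=1$). Given
the cluster/non-cluster decision, positions are uniform within the
corresponding base pairs. $f$ is always derived from the configured
geometry, never supplied directly.

One generation proceeds as:

1. **Fitness.** $w = 1 - x\,n_\mathrm{eff} + \beta c$, floored at 0, with
   $x \ge 0$ the per-copy cost, $c$ the cluster-insertion count,
   $n_\mathrm{eff} = n$ (or $n - c$ when cluster insertions are flagged
   neutral) and $\beta$ an optional per-cluster-copy benefit (default 0,
   disabled; its functional form is an additive term, the simplest choice
   consistent with a "direct benefit per cluster insertion").
2. **Parents.** For each of the $N$ offspring, two parents are drawn
   independently with probability proportional to $w$ (fecundity
   selection; hermaphrodites, selfing allowed). If no individual has
   $w > 0$ the run terminates as `fail-w` (extinction).
3. **Gametes.** Per chromosome, a starting haplotype is chosen at random
   and a $\mathrm{Poisson}(\ell_\mathrm{Mbp} \cdot r_\mathrm{cM/Mbp}/100)$
   number of crossovers with uniform breakpoints (no interference)
   alternates copying between haplotypes. Transposition happens *after*
   recombination: a regulated parent contributes nothing; otherwise
   $k \sim \mathrm{Poisson}(u n/2)$ new insertions are added, each
   inheriting the bias of a donor copy drawn uniformly from the parent's
   $n$ copies (so every copy transposes at rate $u$, and mixed-bias
   genomes are handled naturally) and placed by the biased site sampler.
   A new insertion landing on an occupied gamete site is discarded.

Runs record, per generation, the mean copy number, mean cluster-insertion
count, mean and minimum individual fitness, the regulated fraction, and
whether some cluster insertion is *fixed* — present on at least one
haplotype of every individual at the same position.

## Phases and stopping

An invasion is *rapid* until the population's first cluster insertion,
*shotgun* until every individual is regulated, and *inactive* thereafter.
Two distinct endpoints matter and both are reported: `gen_all_regulated`
(the shotgun endpoint, used for phase coloring and for "how many cluster
insertions does silencing take") and `gen_fixation` (first fixation of a
cluster insertion, the default stopping rule for long-run accounting,
reached on the drift timescale of roughly $4N$ generations). `fail-0`
(all copies lost) and `fail-w` (no viable parent) are the terminal
failure states.

Because the base population places insertions uniformly — including
inside clusters — a default run (100 starting insertions, $f = 0.03$)
usually begins with a few segregating cluster insertions, so the rapid
phase is typically very short. This is a direct consequence of uniform
placement and the phase definition, not a numerical artifact.

## Parameters

| parameter | meaning | default |
|---|---|---|
| `N` | diploid population size | 1000 |
| `u` | transposition rate per copy per generation | 0.1 |
| `x` | fitness cost per copy | 0 (neutral) |
| `bias0` | insertion bias of starting copies | 0 |
| `n0` | starting single-copy insertions (frequency $1/2N$ each) | 100 |
| chromosomes | lengths in Mbp | 5 × 10 |
| clusters | one per chromosome, kb, left-anchored | 5 × 300 ($f=0.03$) |
| rr | recombination, cM/Mbp | 4 |
| `generations` | cap | 5000 |

The defaults are the standard Drosophila-like invasion setup; starting
from 100 copies avoids early stochastic loss. Cluster intervals are
anchored at the left end of each chromosome: under uniform insertion any
fixed placement is statistically equivalent, and left-anchoring keeps
configurations reproducible. Seeds: a replicate set derives per-replicate
seeds from the base seed once (`sample.int` after `set.seed`), every
stochastic draw flows through R's RNG, and reruns are byte-identical.

## Experiments

* `establishment_experiment()` — fraction of replicates retaining ≥ 1
  copy at generation 500, started from 10 single-copy insertions, versus
  the branching reference $1 - (1-2u)^{n_0}$.
* `invasion_summary()` — phase lengths and copy numbers at the ends of
  the rapid and shotgun phases, per bias; replicates that do not complete
  a phase within the cap are flagged censored.
* `fitness_sweep()` — grid of per-chromosome cluster size × bias under
  selection; reports `min_w` per cell.
* `competition_experiment()` — two TE types differing only in bias invade
  jointly (100 copies each); after 500 generations the scaled outcome is
  $S = 2Y/(X+Y) - 1$ with $X$ ($Y$) the mean copy number of the more
  (less) cluster-biased type. Scenarios A–D cross selection
  ($x \in \{0, 0.01\}$) with genome structure (5 recombining chromosomes
  vs. 1 non-recombining chromosome). For a symmetric pair the two types
  are indistinguishable; the tracked class is split evenly, making
  $S = 0$ by construction, which matches its expectation under
  exchangeability.

### min_w

`min_w` in sweep output and summaries is the minimum over generations of
the *population mean* fitness — the maximum fitness burden of the
invasion. This is one of two defensible readings of "minimum population
fitness" (the other being the worst single individual, which every
trajectory also reports per generation as `min_w`); we use the mean-based
one because the fitness trajectories it summarises are population
averages. Sweep cells are categorised as `dark-red` (< 0.01), `red`
(< 0.1), `yellow` (< 0.33), `green` (≥ 0.33, fitness essentially
recovered), `fail-0`, or `fail-w`; the `green` lower edge is our
convention so that the categories partition all outcomes.

Under selection ($x = 0.01$) the burden is largest for small clusters and
negative biases: silencing arrives too late to prevent massive copy
accumulation. The mean-fitness minimum crosses 0.1 at cluster fractions
around 0.02–0.1% of the genome (at bias 0), and strong cluster avoidance
pushes it near 0 even at 0.1% — populations in that corner of the sweep
cannot plausibly persist.

## Numerical and design choices

* The generation loop is compiled (Rcpp); haplotypes are sorted
  position/bias vectors, recombination is a sorted merge over crossover
  segments, cluster lookup is a binary search.
* Crossover counts are Poisson per chromosome (no interference) with
  uniform breakpoints; `rr = 0` reduces to pure assortment.
* Fitness is floored at 0 before parent sampling; $w \le 0$ individuals
  are inviable.
* The fixation test scans the cluster insertions of one individual as
  candidates and verifies presence in all others; it runs only once every
  individual is regulated (a necessary condition).
* Degenerate geometry: $f = 0$ forces $p_c = 0$ and is rejected for
  $b = +100$; $f \ge 1$ is rejected at construction.
* Config files are flat YAML `key: value`; booleans are parsed
  explicitly so single-letter keys like `N` survive YAML 1.1 implicit
  typing.

## What the tests show — and problem sizes

The suite validates the machinery against independent oracles: the bias
transformation against a weighted-bp Monte-Carlo sampler; site sampling
against the closed form across the bias grid; single-insertion
transmission as a martingale; neutral fixation against $1/(2N)$ (2000
replicates at $N = 50$); early copy-number growth against the $(1+u)$
rate; drift-only establishment against a binomial Wright–Fisher oracle;
and the trap property (regulated parents never transpose) by direct
assertion on gametes. Headline behaviours are checked at desk scale:
25 default invasions for the stopping statistic and the ~4 cluster
insertions at silencing, 10 replicates per condition for fitness
ordering, 20 per cell for competition signs, and 5000 single-copy
replicates at $N = 250$ for establishment ($N = 250$ suffices because
establishment is decided in the first tens of generations, while copy
numbers are far below $N$).

One caveat the establishment check makes explicit: the classical
$p \approx 2u$ establishment probability is a small-$u$ branching
approximation that assumes offspring variance 1. In this model the
per-copy offspring distribution (Bernoulli(1/2) transmission per gamete
plus Poisson($u/2$) transposition, with approximately Poisson(2)
offspring per parent) has variance $\approx 1.10$ at $u = 0.05$, so the
variance-corrected survival probability $2(m-1)/\sigma^2 \approx 0.091$
— and trap silencing of early cluster hits trims it slightly further.
A tight Monte-Carlo band around $2u$ therefore sits a little above what
the exact model can produce at $u = 0.05$; the approximation becomes
accurate as $u \to 0$.

## What the synthetic scenarios do not capture

All inputs are self-generated; the simulator emulates the population
genetics of the trap model, not the molecular biology around it. There is
no sequence evolution or TE family divergence, no piRNA molecule or
maternal piRNA inheritance, no conversion of euchromatic insertions into
piRNA-producing loci (paramutation), no distribution of per-insertion
selection coefficients beyond the single linear cost, and cluster
placement within chromosomes is conventional. Passing tests show the
implementation is faithful to this model; they do not show that real TE
invasions behave like it where these omissions matter.
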