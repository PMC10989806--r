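---
title: "Reporter-score enrichment: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporter-score enrichment: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koreporter)
```

## The model

`koreporter` scores KEGG pathways (or modules) against per-KO evidence of
differential abundance. Given a two-sided P value $P_i$ for each KO $i$,
the per-KO score is the inverse-normal transform

$$Z_i = \Phi^{-1}(1 - P_i),$$

a pathway with $k$ members in the scored universe is aggregated as

$$Z_{\mathrm{pathway}} = \frac{1}{\sqrt{k}} \sum_{i \in \mathrm{pathway}} Z_i,$$

and the reporter score is the background-corrected

$$Z_{\mathrm{corrected}} = \frac{Z_{\mathrm{pathway}} - \mu_k}{\sigma_k},$$

where $\mu_k, \sigma_k$ are the mean and standard deviation of
$Z_{\mathrm{pathway}}$ over random KO sets of size $k$ drawn from the same
universe. A pathway is called enriched when $Z_{\mathrm{corrected}}$
exceeds a cutoff, 1.64 by default ($\Phi^{-1}(0.95)$, the one-sided 5%
point).

**The score is undirected.** $Z_i$ is a monotone function of the P value
alone. $Z_i > 0$ means $P_i < 0.5$; $Z_i < 0$ means $P_i > 0.5$, i.e. a KO
*without* evidence of change — whatever the direction of its fold change.
A strongly negative reporter score therefore identifies a pathway of
conspicuously *unremarkable* KOs, never a down-regulated one, and the
significance flag in this package compares the signed score with the
cutoff, deliberately not its absolute value. Every result printer and the
CLI `--help` restate this, because misreading the sign is the error the
package is designed to prevent.

### Why $1/\sqrt{k}$ and not $1/k$

Common renderings of the aggregation formula are typographically ambiguous
between $\frac{1}{k}\sum Z_i$ and $\frac{1}{\sqrt{k}}\sum Z_i$. We adopt
$1/\sqrt{k}$: for independent standard-normal $Z_i$ the sum has standard
deviation $\sqrt{k}$, so only the $1/\sqrt{k}$ scaling leaves the aggregate
on the standard-normal scale irrespective of $k$ — this is what
"size-independent" means, and it is the scaling of the original reporter
method. The background correction would absorb either choice (both are
affine in the sum), so the downstream ranking is unaffected; the aggregate
column `z_pathway` is what changes meaning.

### Background estimation

`background_stats()` enumerates all $\binom{n}{k}$ subsets exhaustively
when there are at most `exhaustive_cap = 1e5` of them, and otherwise draws
`n_background = 1000` Monte-Carlo subsets — uniformly from the whole scored
universe, without replacement within a subset, with replacement across
subsets. $\sigma_k$ uses the population (divide-by-$n$) form; at 1,000
subsets the sample/population distinction is negligible, but fixing it
makes runs bit-reproducible. Subsets are drawn from one shared seeded RNG
stream in ascending order of $k$ (up-mode before down-mode within each $k$
in directed fits), so results are invariant to pathway input order.

Degenerate cases are reported, not patched: if every $Z_i$ in the universe
is equal, $\sigma_k = 0$ and the affected pathways get `NA` scores with a
warning. Pathways retaining fewer than `min_k = 3` members after
intersection with the universe are dropped with a notice — a singleton
"pathway" has an essentially degenerate background and its score is mostly
noise. P values are clipped to $[10^{-15}, 1 - 10^{-15}]$ before the
inverse-normal step so that $P = 0$ or $1$ yields a large finite $Z$
(about $\pm 8$) rather than $\pm\infty$; clipping happens only there, never
in the differential-test output.

### The directed complement

When directionality is genuinely of interest, `mode = "directed"` splits
each two-sided P value by the sign $s_i$ of the KO's test statistic:

$$p^{up}_i = \begin{cases} p_i/2 & s_i > 0 \\ 1 - p_i/2 & s_i < 0 \\ 0.5 & s_i = 0,\end{cases} \qquad p^{down}_i = 1 - p^{up}_i,$$

the one-tailed P values a two-sided test implies. Up- and down-scores are
then computed exactly like the undirected score, each against its own
background, giving two rows per pathway whose significance *and* direction
are simultaneously meaningful. The halving rule assumes the underlying
test's statistic is symmetric under the null (true for the t variants and
the rank-sum test offered here).

### Multiple testing and ordering

Each score is converted to its equivalent one-sided P value
$1 - \Phi(Z_{\mathrm{corrected}})$ and BH-adjusted across the pathways of
the same mode; the fixed-cutoff `significant` flag is kept alongside
because the 1.64 convention is entrenched in this literature. Output is
sorted by score (descending), ties broken by pathway id, so runs are
diffable.

## Per-KO differential tests

`ko_diff_test()` computes the inputs: two-sided P values and signed
statistics (positive = treatment above reference) per KO. The default is
Welch's t — unequal variances are the norm in abundance data — with
Student's t and the Wilcoxon rank-sum test (exact where `stats::wilcox.test`
supports it, normal approximation with tie correction otherwise; the
reported statistic is $W - n_1 n_2 / 2$ so its sign follows the same
convention) as alternatives. Features with zero variance in both groups are
degenerate for variance-based tests and get $p = 1$, statistic 0, with a
collected warning instead of aborting the run. Abundances are not
transformed by default; a `log` option (`log(x + offset)`, offset half the
smallest positive value when zeros are present) is available and is the
sensible choice for multiplicative data. Compositional normalisation,
covariate adjustment and paired designs are out of scope.

## What the simulators emulate

`simulate_pvalues()` generates the P-value-level demonstration dataset:
200 KOs, exactly 50 of them "significant" (P uniform on $(0, 0.05)$, the
rest uniform on $(0.05, 1)$ — stratified so the count is an assertable
contract), 10 pathways of size uniform on $[8, 30]$, each with a consistent
regulation direction, plus one designated pathway made of the KOs with the
*largest* P values, all flagged up-regulated. That pathway reliably attains
the minimum reporter score — negative and often beyond $-1.64$ — while the
hypergeometric test finds nothing in it, which is precisely the trap: read
as "significantly down-regulated", an entirely unperturbed pathway becomes
a headline finding. The size range $[8, 30]$ is our choice (the original
description leaves $k$ unspecified); it keeps every size class well
populated in a 200-KO universe. When pathways overlap, per-pathway
direction signs are applied in pathway order with the designated pathway
last, so its all-up construction always survives; the emitted truth table
records each pathway's construction so downstream checks never re-derive
ground truth.

`simulate_abundance()` supplies end-to-end material for the full
diffstats-to-reporter pipeline: log-normal abundances (per-KO mean-log from
$N(2, 1)$, shared log-scale SD 0.5 — typical orders-of-magnitude spread for
functional profiles), with effect KOs shifted by `effect_size` log-scale
standard deviations in the treatment group, 10 samples per group by
default.

Neither simulator attempts real-data features: no compositionality or
sequencing-depth variation, no KO–KO correlation (members are exchangeable
draws), no zero inflation, and pathway memberships are random rather than
curated. Passing tests therefore demonstrate the statistical machinery —
calibration, undirectedness, background correctness, rank agreement with
ORA — not robustness to those real-data complications.

## Test problem sizes

The suite checks, among others: null calibration of the default test
(1,000 features, 10 per group) and of the corrected score (200 uniform P
values, 1,000 random size-10 pathways, 1,000-subset backgrounds; expected
tail 0.05 ± 0.02); Monte-Carlo-versus-exhaustive background agreement at
20,000 draws on universes with at most 500 subsets; exactness of the
hypergeometric tail against full enumeration for every table with
$N \le 12$; and parameter recovery — a 2-SD effect concentrated in one
20-KO pathway ranks that pathway first in at least 95% of 50 seeded
replicates. These sizes were chosen to make sampling error small relative
to the asserted bands while keeping the default suite quick to run.

## Known limitations

- The background treats KOs as exchangeable; correlated members (shared
  reactions, operons) make the null narrower than the correction assumes,
  so extreme scores can be mildly anticonservative on real data.
- `p_equiv` inherits Monte-Carlo error of $\mu_k, \sigma_k$
  ($O(1/\sqrt{n_\mathrm{background}})$); raise `n_background` for
  publication-grade tails.
- The directed split presumes two-sided P values from a symmetric test;
  feeding it one-sided P values double-counts direction.
- No network topology: pathways are plain KO sets, not metabolic-graph
  neighbourhoods, and KEGG retrieval is out of scope — bring your own GMT
  or KO-to-pathway mapping.
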