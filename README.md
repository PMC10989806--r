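# koreporter

Reporter-score pathway enrichment for microbiome functional profiles, with
the statistically correct — *undirected* — interpretation built in.

## The problem

Metagenome studies routinely summarise function as a KO (KEGG orthology) ×
sample abundance table and ask which KEGG pathways or modules respond to a
condition. A popular answer is the *reporter score*: per-KO P values are
pushed through the inverse normal CDF, aggregated per pathway, and
corrected against a random-set background. It is a good enrichment
statistic — but its sign is widely misread as a regulation direction.
Because the per-KO Z score is

Z_KOi = Φ⁻¹(1 − P_KOi),

it depends on the P value only: a negative Z comes from P > 0.5, i.e. a KO
with *no evidence* of differential abundance, not a down-regulated one.
Consequently a pathway with a strongly negative reporter score is simply a
pathway full of unremarkable KOs. `koreporter` implements the method for
practising microbiome bioinformaticians and enforces that reading
everywhere (results, printing, plotting, CLI help), and provides the
directed complement for when directionality is actually wanted.

## The statistic

For a pathway with k member KOs in the scored universe:

- **Transform** — Z_KOi = Φ⁻¹(1 − P_KOi), with P clipped to
  [1e−15, 1 − 1e−15] so extreme P values stay finite.
- **Aggregate** — Z_pathway = (1/√k) Σ Z_KOi. The 1/√k normalisation keeps
  the aggregate standard-normal-scaled for independent members, which is
  what makes scores comparable across pathway sizes.
- **Correct** — Z_corrected = (Z_pathway − μ_k) / σ_k, where μ_k and σ_k
  are the mean and (population) standard deviation of the aggregate over
  random KO sets of size k from the same universe — enumerated exhaustively
  when C(n, k) ≤ 100,000, estimated from 1,000 Monte-Carlo subsets
  otherwise.
- **Call** — a pathway is enriched when Z_corrected > 1.64 (the one-sided
  5% point of the standard normal; Φ⁻¹(1 − 0.05) = 1.64). The cutoff
  applies to the signed score, never to |Z_corrected|.

The directed ("reporter feature"-style) mode splits each two-sided P value
into one-tailed halves — p_up = p/2 for up-moving KOs, 1 − p/2 for
down-moving ones, p_down = 1 − p_up — and scores up- and down-regulation as
two independently background-corrected rows per pathway. The
over-representation comparator is the exact upper-tail hypergeometric test
on the KOs with P < α.

## Worked example

The bundled simulator reproduces the classic demonstration: 200 KOs with
uniform P values (exactly 50 below 0.05), 10 pathways, and one designated
pathway assembled from the *least* significant KOs, all of them
"up-regulated":

```r
library(koreporter)
sim <- simulate_pvalues(seed = 1)
fit <- reporter_score(sim$ko_stats, sim$pathways, seed = 7)
print(fit, n = 4)
#> Reporter-score enrichment (undirected mode): 10 row(s), 200 KOs, cutoff 1.64
#>  pathway       mode  k z_pathway   mu_k sigma_k reporter_score p_equiv q_value
#>     pw04 undirected 12    3.0104 1.3628  1.1217         1.4689  0.0709  0.3625
#>     pw06 undirected 19    3.2710 1.7629  1.1065         1.3629  0.0864  0.3625
#>     pw02 undirected 15    2.9830 1.5514  1.1609         1.2333  0.1087  0.3625
#>     pw03 undirected 28    2.8380 2.1866  1.0743         0.6063  0.2721  0.6802
#> ... 6 more row(s)
#> Note: the score is undirected; a negative score means no evidence of
#> enrichment, not down-regulation.

subset(sim$truth, least_significant, select = c(pathway, k, direction))
#>      pathway  k direction
#> pw10    pw10 10         1
summary(fit)
#> Reporter-score enrichment, undirected mode
#>   KO universe: 200; pathways scored: 10; min_k: 3
#>   background: monte_carlo, 1000 subsets per size class; seed: 7
#>   [undirected] 0/10 pathway(s) with score > 1.64; score range [-5.976, 1.469]
```

Pathway `pw10` — every member nominally *up*-regulated — gets the minimum
score, −5.976, because its members carry the largest P values. Read
naïvely, "reporter score < −1.64" would call it significantly
down-regulated; in fact it is the least perturbed pathway in the data, and
the hypergeometric test agrees (`run_ora(sim$ko_stats, sim$pathways)` gives
it overlap 0, p = 1).

Everything is also reachable from a shell via the installed
`exec/reporter-score` script:

```sh
reporter-score simulate --demo --seed 1 --out demo/
reporter-score compare --stats demo/ko_stats.tsv --sets demo/pathways.gmt \
                       --seed 2 --out demo/
```

which writes `reporter_results.tsv`, `ora_results.tsv`,
`compare_results.tsv` (each with a full-precision `.json` sidecar) and a
`manifest.json` that reproduces the run bit-identically.

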