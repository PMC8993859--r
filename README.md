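# mobflow

How much can other people's movements tell you about where someone will go
next? `mobflow` measures the predictive information about an individual's
(the *ego's*) future locations contained in three sources: the ego's own
movement history, the histories of their declared *social ties*, and the
histories of *non-social colocators* — strangers who happen to visit the
same places within a common time window. It is aimed at researchers working
with check-in streams from location-based social networks (LBSN), call
detail records (CDR), or any timestamped location-visit log, and at anyone
studying the privacy implications of colocation data.

## The estimators

A trajectory is a time-ordered sequence of `N` location visits over `n`
distinct locations. The package implements the non-parametric match-length
(Lempel–Ziv) estimator of the entropy rate,

    Ŝ_A = N log2(N) / Σᵢ Λᵢ ,

where `Λᵢ` is the length of the shortest subsequence starting at position
`i` not seen earlier in the trajectory. Information flow from an alter `B`
to the ego `A` is the cross-entropy

    Ŝ_{A|B} = N_A log2(N_B) / Σᵢ Λᵢ(A|B) ,

with `Λᵢ(A|B)` the cross-parsed match length against the part of `B`'s
history that is strictly earlier than the ego's visit at `i`, and it
generalizes to a set of alters 𝓑 via the position-wise maximum match and a
match-weighted mean reference length (cumulative cross-entropy `Ŝ_{A|𝓑}`).
Any entropy `S` converts to a predictability bound `Π` — the best possible
hit rate of any next-location predictor — by inverting Fano's inequality

    S = H(Π) + (1 − Π) log2(n − 1),  Π ∈ [1/n, 1],

and to a perplexity `2^S`, the equivalent number of equally likely
locations. Location-set overlap is quantified by the overlapped distinct
location ratio `η_{A|B} = |Y_A ∩ Y_B| / |Y_A|` (ODLR) and its cumulative,
union-over-alters form (CODLR).

Around the estimators the package builds the full analysis: ingestion and
activity filtering of check-in/CDR logs, social and (time-lagged)
colocation ego networks with frequency ranking, alter-accumulation curves,
saturation extrapolation `Π_∞`, social-vs-colocator predictability ratios,
lag sweeps, and overlap–predictability regression — plus a synthetic
check-in generator with planted ground truth that makes every stage
testable without external data.

## Worked example

```r
library(mobflow)

path <- system.file("extdata", "checkins_synthetic.tsv", package = "mobflow")
ds <- read_checkins(path)
#> read_checkins: 120 rows read, 0 dropped, 6 users

tr <- ds$trajectories[["ego01"]]
tr
#> <trajectory> user ego01: N = 20 visits, n = 8 distinct locations, 3.2 days

est <- entropy_rate(tr)
est
#> <entropy_estimate> self: 2.7012 bits (user ego01, N_A = 20, reference length 20.0)
fano_predictability(est$value, tr$n)
#> <predictability_estimate> Pi = 0.3788 (S = 2.7012 bits, n = 8)
perplexity(est$value)
#> [1] 6.503449
```

Each visit by this ego carries about 2.7 bits of uncertainty — as
unpredictable as a uniform choice among 6.5 locations — so no algorithm can
guess its next location more than ~38% of the time from its own past.

The same machinery runs population-wide on generated data with known
structure (social co-visitation rate 0.5 versus 0.25 for colocators):

```r
pop <- generate_population(synthetic_config(n_egos = 4, seed = 99))
res <- run_infoflow(pop$dataset, n_boot = 500, seed = 1)
res
#> <infoflow_result> 4 eligible egos, k_max = 10
#>   mean ego self-predictability: 68.39%
#>   social: mean Pi at k = 10 is 68.23% (ego past excluded)
#>   colocation: mean Pi at k = 10 is 62.91% (ego past excluded)

saturation_extrapolate(res$social_curves[["ego01"]])
#> <saturation_fit> Pi_infinity = 0.7110, kappa = 2.620 (RSS 3.24e-05 over k = 1..10)
```

Accumulating an ego's top-10 social ties recovers almost all of the ego's
own predictability, non-social colocators somewhat less — the planted
ordering — and extrapolating the accumulation curve estimates what
infinitely many alters would yield (`Π_∞`).

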