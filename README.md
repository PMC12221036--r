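# kayakpace

Modelling how sprint-kayak pacing profiles evolve across an athlete's
career, for sport scientists and performance analysts working with 50 m
split times from K1 racing (Women's K1 500 m and Men's K1 1000 m).

## The model

A race's 50 m splits are converted to segment velocities v_i = 50/Δt_i and
normalised by the race-average velocity v̄ = distance/time, removing
environmental speed differences so only the *shape* of the effort remains.
Each normalised profile is smoothed with a cubic B-spline basis and
decomposed by functional PCA,

    f(x) = μ(x) + Σ_k β_k Φ_k(x),      β_k = ∫ Φ_k(x) (f(x) − μ(x)) dx,

with orthonormal eigenfunctions Φ_k (∫Φ_j Φ_k = δ_jk). Four scores
summarise each race; PC1 reads as "dropoff" (early-race surplus, late
decline) and PC2 as "kick" (late-race acceleration).

An athlete's ordered score vectors O_1..O_T then form one chain of a shared
hidden Markov model with n latent pacing states: initial probabilities π,
constant transition matrix A (a_ij = P(S_{t+1}=j | S_t=i)), and diagonal
Gaussian emissions whose means are linear in age-group and event-type
indicators,

    O_t | S_t = j  ~  N(m_j(z_t), diag σ²_j),
    m_{j,i}(z) = β_{ij0} + Σ_k β_{ijk} z_k,

with baseline a Domestic race in the Open age group. Fitting is EM over
all athletes with random restarts; the number of states is selected by AIC
(−2·loglik + 2k); careers are decoded with the Viterbi algorithm.
Diagnostics cover geometric sojourn times, per-component residual RMSE and
career timelines. Because no race data are deposited, a fully seeded
synthetic-data generator reproduces the statistical structure end to end —
careers, latent states, scores, and raw split-time CSVs — and the
published coefficient tables ship as a ready-made parameter set
(`published_hmm_params()`).

## Worked example

```r
library(kayakpace)

# a synthetic cohort: 40 athletes, seeded
cfg <- synthetic_config("women_k1_500", n_athletes = 40,
                        races_range = c(10, 30), seed = 42)
sim      <- simulate_races(cfg)
races    <- filter_races(sim$races)       # drop domestic heats
profiles <- pacing_profiles(races)        # normalised segment velocities
fp       <- fit_fpca(profiles, K = 4)     # smooth + decompose
fp
#> Functional PCA: 732 curves, 4 components
#> variance explained: PC1 48.3%, PC2 19.5%, PC3 13.5%, PC4 12.3% (cumulative 93.65%)

fit <- em_fit(fp$scores, n_states = 4, event = "women_k1_500",
              n_restarts = 10, seed = 1)
fit
#> HMM fit: 4 states, 732 observations, 4 covariates
#> loglik 15.342 | AIC 191.316 (k = 111) | best of 10 restarts

head(fit$posteriors[, 1:4], 3)
#> # A tibble: 3 x 4
#>   athlete_id race_index state posterior
#>   <chr>           <int> <int>     <dbl>
#> 1 ath001              2     2     0.999
#> 2 ath001              3     2     1.000
#> 3 ath001              4     2     0.566
```

The variance-explained line says how much profile variation the four
components capture; `fit$posteriors` gives each race's decoded pacing
state with its posterior probability, the raw material for career
timelines (`career_summary()`, `plot_state_timeline()`). Diagnostics come
from `hmm_diagnostics(fit, fp$scores)`.

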