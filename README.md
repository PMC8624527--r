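# pwasoft

Piecewise-affine multi-model soft sensors for batch bioprocesses.

In a batch fermentation the variables that matter — cell concentration *X*
and product concentration *P* — are assayed offline every hour or so, while
the variables that are easy to log (broth temperature *T*, dissolved oxygen
*DO*, *pH*, air flow *q*, stirring speed *v*, tank pressure *p*) stream in
every few minutes. A soft sensor estimates the slow outputs from the fast
inputs. Because a batch traverses distinct physiological phases (lag,
exponential growth, stationary), a single global model underfits; `pwasoft`
identifies a **piecewise-affine ARX (PWARX) multi-model** instead:

    y(k) = [X(k)ᵀ, 1] θᵢ + ε(k)   when X(k) ∈ Ωᵢ,   i = 1..S,

where `X(k) = [y(k−1)…y(k−n_y), u₁(k−p−1)…u_r(k−p−n_u)]ᵀ` stacks past
outputs and inputs, and the polyhedral regions Ωᵢ tile regressor space. The
package solves the four coupled identification sub-problems:

1. **Orders (n_y, n_u)** — false-nearest-neighbor analysis with Cao's E/E0
   statistics over nested L∞ embeddings (`select_orders`).
2. **Number of models S and parameters θᵢ** — a particle swarm with an
   iteration-dependent compression factor μ(G) = δ·σ^(G/(N+G−1)) optimizes
   all local models and cluster centers jointly; an outer loop grows S until
   the fit threshold is met (`identify_pwarx`, `pso_optimize`).
3. **Region boundaries** — linear-kernel least-squares SVMs between adjacent
   clusters yield the dividing hyperplanes h₍ᵢⱼ₎ = [w, v]
   (`lssvm_solve`, `extract_hyperplane`, `build_surfaces`).
4. **Prediction and evaluation** — one-step-ahead prediction with
   region-resolved local laws, MAPE (as a fraction) and RMSE against a
   global affine ARX baseline (`predict_one_step`, `evaluate_model`,
   `fit_global_arx`).

Synthetic generators (an exact PWARX system, a two-regime recovery
benchmark, a three-phase fixture, and a mechanistic logistic/Luedeking–Piret
fermentation surrogate) make the whole pipeline testable without lab data.
See the methods vignette (`vignettes/pwarx-soft-sensors.Rmd`) for the model,
the algorithmic design choices, and known limitations.

## Worked example

Identify a soft sensor on the three-phase synthetic fixture (10 batches,
96 samples each, six inputs, one output lag — so each local parameter
vector has 8 entries):

```r
library(pwasoft)

fx  <- make_three_phase_fixture(seed = 1)
res <- fit_soft_sensor(fx$batches, target = "X",
                       orders = list(n_y = 1L, n_u = 1L, p = 0L),
                       S_max = 5, seed = 1)
res$model
#> <pwarx_model> target X: S = 3 local models, n_y = 1, n_u = 1, p = 0, r = 6 (2 surfaces)
res$fit
#> <pwarx_fit> S = 3 local models, J1 = 1.47012 (Y_ts = 1.98892, threshold met)
#> cluster sizes: 205, 210, 155

evaluate_model(res$model, fx$batches, split = "test")$normalized
#> <evaluation_report test> n = 179: MAPE = 0.147374, RMSE = 0.136719 (0 excluded from MAPE)
evaluate_model(fit_global_arx(res$dataset), fx$batches, split = "test")$normalized
#> <evaluation_report test> n = 179: MAPE = 0.332853, RMSE = 0.146887 (0 excluded from MAPE)
```

Reading the output: the incremental search stopped at S = 3 local models —
matching the fixture's three phases — because their joint fit J1 = 1.47
explains more than 99% of the training output variance (threshold
Y_ts = 1.99), which S = 1 and S = 2 could not. On the held-out test split
the multi-model's mean absolute percentage error (0.147, i.e. 14.7%) is
less than half the global affine baseline's (0.333), and its RMSE is lower
too — the quantitative case for the multi-model.

## Command line

A thin Rscript CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pwasoft.R", package = "pwasoft"))')
Rscript $CLI simulate --out sim --seed 11
Rscript $CLI order    --data sim/batches.csv --out order.json
Rscript $CLI identify --data sim/batches.csv --model model.json --seed 5
Rscript $CLI predict  --model model.json --data sim/batches.csv --out pred.csv
Rscript $CLI evaluate --model model.json --data sim/batches.csv --out report.json
```

Runs are deterministic: the same seed and config produce byte-identical
model JSON and reports.

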