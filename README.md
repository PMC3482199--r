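# swayucm

Uncontrolled-manifold (UCM) analysis of multi-joint postural sway, with a
focus on the *temporal* structure of the variability components.

## The scientific problem

During quiet bipedal standing the body has more kinematic degrees of
freedom (six sagittal joints: ankle, knee, hip, lumbo-sacral, lower neck
C7, atlanto-occipital AO) than any single task variable it needs to keep
steady (e.g. the anterior-posterior position of the whole-body centre of
mass, CoM). A control scheme following the *minimal intervention
principle* corrects only deviations that matter for the task, letting
task-equivalent deviations accumulate. Two signatures follow:

1. **Amount**: joint-angle variance parallel to the task's uncontrolled
   manifold (task-equivalent variability, TEV) exceeds variance orthogonal
   to it (task-relevant variability, TRV).
2. **Persistence**: because task-equivalent deviations go uncorrected,
   TEV should stay autocorrelated over much longer time lags than TRV.

This package implements the full analysis chain for testing both
signatures on six-joint sagittal kinematics, plus a synthetic
minimal-intervention sway generator for validating the chain end to end.

## The method

For a task variable `f(θ)` with Jacobian `J = ∂f/∂θ` (6-vector, evaluated
at the per-trial mean posture), joint-angle deviations are split into the
null space of `J` (the UCM, 5-dim) and its orthogonal complement (1-dim):

- `TEV = (1/5) Σ var(null-space coordinates)`, `TRV = var(range coordinate)`
  (variance normalized to subspace dimension; divisor T);
- **UCM index** `= TEV / TRV`, tested on the log scale against 0;
- **COV index** `= var_task(decorrelated surrogates) / var_task(original)`,
  where surrogates independently permute each joint's deviations over time
  and task variance is computed through the full nonlinear forward model;
- **Persistence** `R²(τ) = cor(x(t), x(t+τ))²` at dyadic lags
  τ = 1, 2, …, 128 s, averaged over TEV dimensions (equally, or weighted by
  squared task sensitivity `J_j²/ΣJ_k²`), compared between TEV and TRV by
  paired t tests on `atanh(2R²−1)` with Holm correction across lags.

Four task variables are built in: anterior-posterior CoM position and head
position (mm), trunk orientation and head orientation (pitch, degrees), on
a planar 5-segment chain with published-style relative segmental masses.
The analytic task sensitivities have the structural pattern
`(1,1,1,1,0,0)` for trunk orientation, `(1,1,1,1,1,1)` for head
orientation, and exact zeros for the AO entry of both positional tasks
(the AO joint rotates only massless geometry distal to the head point).

## Worked example

The `analysis/` scripts run the whole study on a synthetic 14-subject
cohort (300 s at 100 Hz per subject; slow task-equivalent dynamics,
τ = 30 s, SD 1.0°/dim; fast task-relevant corrections, τ = 0.5 s, SD 0.3°):

```sh
Rscript analysis/01_simulate.R     # writes results/data/subject_*.csv
Rscript analysis/02_decompose.R    # UCM indices
Rscript analysis/03_covariation.R  # COV indices (100 surrogates each)
Rscript analysis/04_persistence.R  # R^2 profiles per component and lag
Rscript analysis/05_report.R       # group tests and summary
```

The final stage prints (abridged):

```
Log-index group tests (one-sample t vs 0, Holm across tasks):
  UCM  com_position       mean log =  2.234, t(13) =   43.08, p_adj = 8.2e-15  *
  UCM  head_position      mean log =  1.943, t(13) =   39.60, p_adj = 1.8e-14  *
  ...
  COV  com_position       mean log =  1.426, t(13) =   28.73, p_adj = 1.1e-12  *

Lags (s) with Holm-significant TEV > TRV persistence:
  com_position       (equal      ): {1,2,4,8,16,32,64,128}
  head_position      (equal      ): {1,2,4,8,16,32,64,128}
```

Mean log UCM index 2.23 for CoM position means TEV exceeded TRV roughly
nine-fold per dimension; the persistence table shows TEV still correlated
at R² ≈ 0.23 after 16 s while TRV decorrelates within about a second —
the minimal-intervention signature in both amount and time.

Programmatically the same run is one call:

```r
library(swayucm)
report <- run_study(study_config(seed = 42, out_dir = "results/run"))
print(report)
```

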