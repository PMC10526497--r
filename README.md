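# depthsim

Binocular depth estimation by hierarchical active inference, with active
vision.

## What this is

Depth is ill-posed from a single image: many targets project to the same
retinal coordinate. `depthsim` simulates an agent that estimates the 2D
position of a target — depth on the *x* axis — not by detecting disparity
bottom-up, but by **inverting a projective generative model**: a belief over
the target's absolute position \(\mu_a\) and a vergence-accommodation belief
over the eye angles \(\mu_\theta = (\theta_a, \theta_v)\) jointly predict,
through homogeneous-coordinate transforms, what each eye should see,

\[
\mu_r^{(i)} \simeq T^{(i)}(\mu_\theta)\,\mu_a, \qquad
c^{(i)} = f\,\mu^{(i)}_{r,y} / \mu^{(i)}_{r,x},
\]

and precision-weighted prediction errors flow back through the transposed
Jacobians to update every belief (predictive-coding message passing in
continuous time). An attractor on the projected beliefs expresses the
*intention* to fixate; suppressing the resulting proprioceptive prediction
error rotates the eyes. Because position inference and fixation share the
same error pathways, running them simultaneously stalls; the agent instead
alternates **action and perception phases** (100 steps each), freezing the
position belief while the eyes move and blocking action while the belief
updates.

The generative process adds fovea-like visual noise whose standard
deviation grows exponentially with the distance *d* between fixation point
and target, \(\Sigma_v = e^{d/k}\), \(k = 1.5\) (zero in the uniform
condition). Under this nonuniform resolution, fixating the target is what
makes depth estimation accurate — the package reproduces that contrast
across three model variants: `infer_parallel` (eyes fixed and parallel),
`infer_vergence` (eyes start on the target), `active_vision` (random start,
simultaneous fixation and estimation through cycles).

It is aimed at computational-neuroscience and active-inference researchers
who want a small, fully inspectable continuous-time implementation of
hierarchical projective inference with action.

## A worked example

```r
library(depthsim)

rep <- run_grid(n_trials = 50, master_seed = 1)
rep$table[, c("variant", "resolution", "accuracy", "mean_time")]
```

which prints (seed 1, 50 trials/condition, ~2.5 min):

```
         variant resolution accuracy mean_time
1 infer_parallel nonuniform     0.02   1999.84
2 infer_vergence nonuniform     0.78   1879.48
3  active_vision nonuniform     0.26   1960.80
4 infer_parallel    uniform     1.00    224.30
5 infer_vergence    uniform     1.00   1583.32
6  active_vision    uniform     0.82   1855.70
```

Reading it: with a nonuniform fovea, parallel fixed eyes almost never
estimate depth (accuracy 0.02 — the target sits in the noisy periphery),
while eyes that fixate do (0.78 pre-verged; 0.26 when fixation must be
*learned* during the trial, and with more steps). With uniform (noise-free)
resolution the ordering flips: parallel eyes are the most accurate and by
far the fastest (224 steps to criterion), because verging only adds
reference-frame inference work. `rep$verdicts` encodes these orderings as
booleans; `accuracy` is the fraction of trials with final position error
below 0.1 world units and `mean_time` the mean number of integrator steps
until the error stays below that threshold (trial length 2000).

Single conditions, per-trial CSVs and traces:

```r
res <- run_condition(condition("active_vision", "nonuniform", 20, 1),
                     out_dir = "results")
tr <- run_trial(condition("active_vision", "uniform"), 3, trace = TRUE)$trace
head(tr)   # step, phase, beliefs, image coords, free energy, error
```

Command line:

```sh
Rscript inst/cli/depthsim.R run --variant active --resolution nonuniform \
  --trials 50 --seed 1 --out results
Rscript inst/cli/depthsim.R compare --trials 50 --seed 1 --out results --plot
```

## Package layout

- `R/transforms.R` — homogeneous points, roto-translations, eye extrinsics,
  pinhole projection, analytic backprop of each map, closed-form stereo
  triangulation (the geometric oracle).
- `R/inference-core.R` — generalized-coordinate beliefs, dynamic error
  units, action update, free-energy proxy.
- `R/agent.R` — the assembled hierarchy, fixation attractor, phase
  scheduler, one-step agent update.
- `R/world.R` — generative process: true geometry, gaze-ray fixation point,
  fovea noise, observations, action integration.
- `R/experiments.R` — trial runner, the three variants, condition
  summaries, ordering verdicts, comparison figure.
- `vignettes/depth-from-active-vision.Rmd` — model, assumptions, parameter
  tuning (including why the focal length is pixel-scaled), limitations.
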