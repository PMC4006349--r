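# contourctl

Interactive level-set segmentation of 2-D images and 3-D volumes by PDE
feedback control. The package is for image-analysis researchers and tool
builders who want a segmentation boundary that a human can *steer*: an
automatic region-competition flow does the bulk of the work, and sparse
signed clicks from the user provably stabilize the boundary at the shape
the user has in mind — without the user touching any mathematical
parameter.

## The model

The segmentation is the zero set of a level-set function φ (interior where
φ > 0) evolving on the narrowband |φ| ≤ ε:

    φ_t = δ_ε(φ) [ G(φ, I) + λ κ(φ) − ξ̂ U² + λ(t) κ(δ_ε²(φ) ξ̂) ]

* `G` is the image-driven competition speed: the global mean-alignment
  (Chan–Vese) term −(I−μ_in)² + (I−μ_out)², or a localized-statistics
  variant with ball-restricted means for images whose statistics drift
  across the domain.
* `U` accumulates the user's signed clicks, spread by an image-aware
  kernel, and is regulated by the nonlinear diffusion
  `U_t = h + ∇·[H_ε((U/U_M)² − 1) ∇U]`, which leaves small inputs alone
  and smears out anything beyond the threshold `U_M = sqrt(Ḡ_M/ρ + 1)`.
* `ψ̂` is an observer-like estimate of the user's ideal boundary, driven
  by `ξ̂ − e_U (αU)²` with ξ̂ = H_ε(φ) − H_ε(ψ̂) and e_U = H_ε(ψ̂) − H_ε(U):
  it follows φ where the user is silent and follows the input where the
  user insists, pulling φ along through the −ξ̂U² coupling.
* The adaptive smoothing gain λ(t) = λ₀ + λ₁·D̂ and the threshold `U_M`
  are the sufficient conditions under which the labeling-error functional
  D = ½∫ξ² is bounded and decreasing whenever the error is large.

Everything is exercised end-to-end on synthetic phantoms with ground truth
and a scripted simulated user, including the classic failure the feedback
exists to fix: on a two-ellipse phantom joined by a bright bridge, the
open-loop flow leaks through the bridge and segments both ellipses.

## Worked example

```r
library(contourctl)

ph   <- make_phantom()                       # 128x128 two-ellipse phantom
phi0 <- circle_sdf(ph$I$grid, c(40, 64), 8)  # seed in the left ellipse

# automatic flow alone: leaks through the bridge
open <- run_open_loop(ph$I, phi0, session_config(max_steps = 400))
dice_coefficient(open$phi, ph$psi)
#> [1] 0.7084488

# closed loop with the scripted user
res <- run_session(ph$I, phi0, cfg = session_config(max_steps = 1400),
                   psi = ph$psi, user = user_policy())
dice_coefficient(res$phi, ph$psi)
#> [1] 0.9965904
effort_metrics(res, ref = ph$psi)$actuated_pct_of_boundary
#> [1] 8.653846
hausdorff_interface(res$phi, res$psi_hat)
#> [1] 1
```

Read this as: the uncontrolled flow ends at Dice 0.71 against the left
ellipse (it has swallowed both), while the controlled run reaches Dice
0.997 with the user having touched under 9% of the cells a fully manual
boundary tracing would require; the segmentation and the observer estimate
agree to one cell at the end.

A command-line interface wraps the same functions:

```sh
inst/cli/contourctl phantom --out img.png --ref psi.nrrd
inst/cli/contourctl segment --image img.png --seed-center 40,64 \
    --seed-radius 8 --clicks clicks.csv --out outdir/
inst/cli/contourctl simulate --out outdir/
```

Outputs are the label mask (PNG/NIfTI/NRRD), φ/ψ̂/U snapshots, a per-step
diagnostics CSV and a JSON manifest sufficient to reproduce the run
byte-identically (`rerun_manifest()`).

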