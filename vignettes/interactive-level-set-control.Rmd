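---
title: "Closed-loop interactive segmentation: models, gains and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop interactive segmentation: models, gains and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5)
library(contourctl)
```

## The problem and the model

Region-competition level-set segmentation evolves an implicit function
$\phi(\mathbf{x}, t)$ (interior where $\phi > 0$) by the narrowband PDE

$$\phi_t \;=\; \delta_\varepsilon(\phi)\,\big[\,G(\phi, I) + \lambda\,
\kappa(\phi)\,\big],$$

where $\delta_\varepsilon$ is a regularized Dirac function confining the
dynamics to the band $|\phi| \le \varepsilon$, $\kappa(F) = \nabla \cdot
(\nabla F / |\nabla F|)$ is mean curvature, and $G$ is an image-driven
competition term — here either the global mean-alignment (Chan–Vese) speed
$-(I - \mu_{in})^2 + (I - \mu_{out})^2$ or its localized-statistics variant
in which $\mu_{in}(\mathbf{x})$, $\mu_{out}(\mathbf{x})$ are computed inside
a ball $B_{r}(\mathbf{x})$. This *open-loop* flow descends a meaningful
energy, but the structure a human expert wants is frequently **not** the
energy minimizer: on the package's two-ellipse phantom the flow leaks
through the bright bridge and segments the union of both ellipses
("bleed-through").

The package treats this as a control problem. The user's ideal boundary is
an unknown reference labeling $\psi$. Three coupled fields run together:

* $\phi$ — the displayed segmentation, driven by
  $G - \hat\xi U^2 + \lambda(t)\,\kappa(\delta_\varepsilon^2(\phi)\hat\xi)$
  on top of the open-loop flow;
* $U$ — the accumulated control field built from discrete signed clicks,
  regulated by a nonlinear diffusion that caps its magnitude near a
  threshold $U_M$;
* $\hat\psi$ — an observer-like estimate of $\psi$, driven by
  $\hat\xi - e_U(\alpha U)^2$ with $\hat\xi = H_\varepsilon(\phi) -
  H_\varepsilon(\hat\psi)$ and $e_U = H_\varepsilon(\hat\psi) -
  H_\varepsilon(U)$.

Where the user never clicks, $U = 0$ and the estimate simply follows
$\phi$; where input accumulates, the estimate is pulled toward the sign of
$U$ and in turn pulls $\phi$ through the $-\hat\xi U^2$ coupling. The
stability analysis gives two sufficient gain rules, both implemented:
$\lambda(t) = \lambda_0 + \lambda_1 D$ with $D$ the labeling-error
functional $\tfrac12\int \xi^2$, and the input-magnitude threshold
$U_M = \sqrt{\bar G_M/\rho + 1}$ derived from a static bound
$|G| \le \bar G_M$.

## One worked run

```{r phantom, eval = FALSE}
ph   <- make_phantom()                      # 128x128, two bright ellipses
phi0 <- circle_sdf(ph$I$grid, c(40, 64), 8) # seed inside the left ellipse

open <- run_open_loop(ph$I, phi0, session_config(max_steps = 400))
dice_coefficient(open$phi, ph$psi)          # ~0.71: bled into both ellipses

res <- run_session(ph$I, phi0, cfg = session_config(max_steps = 1400),
                   psi = ph$psi, user = user_policy())
dice_coefficient(res$phi, ph$psi)           # ~0.995
effort_metrics(res, ref = ph$psi)$actuated_pct_of_boundary  # ~9%
```

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `eps` | narrowband half-width (cells) | 1.5 | $\delta_\varepsilon$ spans $\ge 3$ cells; larger widens the band without benefit |
| `lambda_smooth` | open-loop curvature weight | 0.1 | conventional for unit-range intensities; large enough to suppress noise speckle, small enough that a 3-cell bridge still leaks |
| `lambda0`, `lambda1` | adaptive feedback-smoothing gains | 0.1, 0.1 | sized against the unit-range $|G|\le 1$; see "scale normalization" below |
| `rho` | margin in $U_M = \sqrt{\bar G_M/\rho + 1}$ | 0.5 | half the bound is ceded to the image term |
| `alpha` | observer input scale | $1/U_M$ | makes $(\alpha U)^2 \le 1$ at saturation |
| `r_loc` | localized-statistics ball radius (cells) | — | must exceed the local feature scale; 8 on the 96² gradient phantom |
| `sigma_x` | click kernel spatial scale (cells) | 3 | one click covers a bridge-width neighborhood |
| `sigma_I` | click kernel intensity scale | $\sqrt{\text{range}/2}$ | similarity factor halves at an intensity gap of half the range |
| click gain | impulse per click | $U_M/5$ | about five co-located clicks reach the saturating regime |
| `redist_every` | redistancing period (steps) | 5 | frequent enough that $|\nabla\phi| \in [0.8, 1.2]$ holds on the band |

**Scale normalization.** `run_session` and `run_open_loop` rescale
intensities to unit range before the dynamics (`normalize = TRUE`). The
competition speed scales as the squared intensity range, while the observer
rates are $O(1)$ by construction; without normalization a 12-bit image makes
the observer four orders of magnitude slower than the segmentation and
forces a uselessly small time step once $U$ accumulates. Labels, Dice and
the error functionals are unaffected by the affine rescaling.

**The open-loop term in the closed loop.** The algebra of the feedback law
cancels the $\lambda\kappa(\phi)$ smoothing term. Implemented literally,
the coupled system then has *no* curvature regularization wherever
$\hat\xi \approx 0$ — exactly the no-input regime in which it is supposed
to behave like the open-loop system — and the front roughens in noise. The
session therefore assembles
$G + \lambda_{smooth}\kappa(\phi) - \hat\xi U^2 +
\lambda(t)\kappa(\delta^2\hat\xi)$, which reduces *exactly* to the
open-loop flow when no input has accumulated. The theorem-form speed
(without $\kappa(\phi)$) is kept as `closed_loop_speed()` and verified in
the known-reference setting, where the error-smoothing term does the work.

**Input regulation.** The accumulator solves $U_t = h +
\nabla\cdot[H_{\varepsilon_U}((U/U_M)^2 - 1)\nabla U]$ in conservative
divergence form (zero-flux boundaries, integral preserved to round-off).
The coefficient width $\varepsilon_U$ defaults to 0.5 — below 1, so the
coefficient is *exactly* zero for $|U| \le U_M\sqrt{1-\varepsilon_U}
\approx 0.71\,U_M$ and clicks accumulate untouched, ramping to free
diffusion by $\approx 1.22\,U_M$. (A width $\ge 1$ would make the
coefficient positive everywhere and slowly erase small inputs.)

**Localized speed normalization.** The localized competition integrand is
weighted by $\delta_\varepsilon(\phi(\mathbf{y}))$ inside the ball; the
package divides by the ball integral of that weight, making the speed a
weighted *average* of the pointwise residual. The factor is positive, so
the flow direction is unchanged everywhere, and the normalized speed obeys
the same static bound $|G| \le (\text{intensity range})^2$ as the global
model — the bound from which $U_M$ is derived must hold for *any* state,
and the un-normalized ball integral does not satisfy one.

## Numerical choices

* **Discretization.** Uniform cell-centered grids (2-D and 3-D share one
  code path), second-order central differences, replicate boundaries,
  anisotropic spacing honored in every operator. Curvature floors
  $|\nabla F|$ at `grad_floor = 1e-8` and returns 0 below it.
* **Time stepping.** Explicit Euler with a shared adaptive step:
  $dt = \min(\text{CFL}, \text{diffusion bound})$, where CFL limits the
  per-step change of $\phi$ and $\hat\psi$ to 0.45 cells and the input
  diffusion requires $dt \le h^2/(2n)$. The step is a deterministic
  function of the state, so trajectories are bit-reproducible.
* **Redistancing.** Every 5 steps both $\phi$ and $\hat\psi$ are rebuilt as
  signed distances: interface cells get a gradient-corrected sub-cell
  seed (clamped by the axis-crossing estimate), the far field is solved by
  fast sweeping of $|\nabla d| = 1$ in C++. On the band this restores
  $|\nabla\phi| \in [0.8, 1.2]$ and keeps the interface within a tenth of
  a cell across repeated applications.
* **Lyapunov bookkeeping.** The functionals $D$, $\hat D$, $F$, $V$ are
  Heaviside functionals of the *labels*; between redistancings
  $|\nabla\phi|$ drifts off 1 and the raw per-step traces carry a sawtooth
  with the redistancing period. Monotonicity statements are therefore
  evaluated on the renormalized states, one sample per redistancing cycle
  (a stricter per-5-step budget than the nominal per-step tolerance).
* **Steady state.** The functional traces never quiet to a 1e-5 relative
  tolerance: the discrete front settles into a sub-cell limit cycle that
  the observer tracks with a permanent small lag. Steady state is instead
  declared when the *labeling* stops changing — no reclassified cells
  (up to `steady_tol` times the band size) for `steady_window` consecutive
  click-free steps — which is the user-facing notion of convergence, and
  is robust across image scales.
* **Degenerate inputs.** Uniformly signed fields refuse redistancing
  (nothing to distance to); a collapsed segmentation aborts the session
  with the diagnostics attached to the condition; constant images yield a
  zero speed bound and the control defaults $U_M = 1$, $\alpha = 1$.

## The synthetic data and the scripted user

`make_phantom()` builds the two-ellipse "ventricle" image: two bright
ellipses (intensity 10) joined by a 3-px bright bridge on a background of
2, with seeded Gaussian noise of sd 0.5 on a 128×128 grid — parameters
chosen so the open-loop leak through the bridge occurs robustly while the
left ellipse alone is easily segmentable. The ground truth $\psi$ is the
signed distance of the left ellipse only. `make_gradient_phantom()` builds
the complementary failure case for global statistics: an elongated shape on
a linear intensity ramp whose interior/exterior global means nearly
coincide (the interior mean is deliberately a few percent *above* the
exterior one, so the dim end of the shape is actively misclassified by the
global model) while the local contrast is constant everywhere.

`simulated_user()` emulates the human in the loop. At every inspection it
votes at the cells of largest labeling error against its private reference,
subject to three behavioral filters, each mirroring how the interactive
narrative describes real users: clicks land only within the responsive
inner band $|\phi| \le 1$ (users correct the boundary where it is, which is
also the only place the narrowband dynamics can respond); errors that
visibly *improved* since the previous look are left to the automation
(users intervene where the system stalls or worsens, e.g. the bridge
creep); and cells whose accumulated input already reaches $U_M$ are not
re-marked. The first inspection only calibrates the improved/stalled
comparison. These filters are what make the actuated-cell count a
meaningful effort measure: without them the scripted user wastes hundreds
of clicks shadowing a healthy expanding front.

What the phantoms do *not* emulate: partial-volume effects, bias fields,
texture, anatomic shape priors, 3-D anisotropic acquisition, and human
perceptual error (the scripted user reads the true $\psi$). Passing the
suite therefore demonstrates the control-loop mechanics — boundedness,
input regulation, observer alignment, rescue at low actuation effort — not
clinical segmentation accuracy.

## Problem sizes used in the checks

The automated checks run the phantom end-to-end at its native 128×128 size
(up to 2000 explicit steps for the known-reference bound; 1400 for the
interactive rescue; a 1500-step run whose click stream ends mid-course for
the input-stops decay)
and the gradient phantom at 96×96 with 600 steps; operator analytics use up
to 256×256 grids. These sizes are where the phantom geometry is stable and
the runs complete in seconds to a couple of minutes each.

## Known limitations

* The localized model has the usual small capture range: seeds must be
  within roughly `r_loc` of the target boundary (the acceptance scenario
  seeds a deflated ellipse, not a point).
* Topology is uncontrolled: the leak and its repair change connectivity
  freely.
* The per-step Lyapunov traces are diagnostics, not certified descent
  directions, away from the theorems' hypotheses (e.g. while input is
  arriving).
* 3-D works through the same operators but the scripted-user scenarios and
  phantoms are 2-D; 3-D is exercised at the I/O and operator level.
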