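---
title: "Estimating nematode size from morphometric data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nematode size from morphometric data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemasize)
```

## The problem

Physiological rates of nematodes (respiration, excretion, transport) are
routinely normalised by surface area or volume, yet both are almost always
estimated by pretending the animal is a cylinder of its maximum diameter.
Nematodes are indeed close to circular in cross-section, but the radius
varies strongly along the body: the anterior is blunt, the posterior tapers,
and the widest point is rarely at mid-length.  The cylinder therefore
overestimates size, and the classical corrections (Andrassy's 4/5 factor,
Tsalolikhin's cone/frustum average) overshoot in the other direction.

The measurements needed to do better have been published for over a century.
Cobb's notation records, at five standard anatomical landmarks (pharynx or
buccal base, nerve ring, oesophagus end, vulva or mid-body, anus), the axial
position $l_i$ and the body diameter $d_i$, both as percentages of the total
length $L$.  The de Man indices ($a = L/D_{\max}$, $b$, $c$, $c'$) carry
less information but are more widespread; four of Cobb's ten numbers can be
recovered from them (`deman_to_partial_cobb()`).  This package turns either
record into a longitudinal radius profile and computes perimeter $p$,
projected (silhouette) area $a$, surface area $a_s$ and volume $v$ of the
implied solid of revolution.

Two conventions are a recurring source of silent factor-of-two and
factor-of-100 errors: published values are *diameters* (not radii) and
*percentages* (not fractions).  The file readers therefore refuse to guess:
`units` and `value_kind` metadata are mandatory, and everything is reduced
to one canonical form - axial position and radius as fractions of $L$ -
before any computation.  Absolute units only reappear on output.

## The piecewise frustum model

Between consecutive profile coordinates the body is a conical frustum; a
cone and a cylinder are its degenerate cases.  For coordinates
$(l_i, r_i)$, $i = 0, \dots, n$ (relative units):

$$p = 2(r_0 + r_n) + 2\sum_i \sqrt{\Delta r_i^2 + \Delta l_i^2}, \qquad
  a = \sum_i (r_i + r_{i+1})\,\Delta l_i,$$

$$a_s = \pi(r_0^2 + r_n^2) + \pi\sum_i (r_i + r_{i+1})
  \sqrt{\Delta r_i^2 + \Delta l_i^2}, \qquad
  v = \frac{\pi}{3}\sum_i (r_i^2 + r_i r_{i+1} + r_{i+1}^2)\,\Delta l_i.$$

Three bookkeeping choices deserve a note:

* the perimeter and lateral-surface sums carry a factor 2 for the two
  flanks of the mirror-symmetric silhouette - the cylinder reduction
  ($p = 2L + 2D$) pins this down;
* the terminal terms $2(r_0 + r_n)$ and $\pi(r_0^2 + r_n^2)$ are the end
  caps.  They vanish for a supplemented profile (terminal radii zero) and
  are required for the cylinder reduction;
* interface discs between adjacent frusta cancel in pairs, so the
  implementation sums lateral surfaces only and never forms them.

The classical estimators are special cases.  `cylinder_estimates()` is the
two-coordinate constant profile.  `tsalolikhin_shape_estimates()` is the
three-coordinate profile $(0, d/2L)$, $(1/2, D/2L)$, $(1, 0)$; its volume
equals the cone/frustum-average formula *exactly*, which is both a test
invariant and the reason the formula underestimates real bodies whose
greatest width is not a single mid-length point.  The position-weighted
variant `tsalolikhin_lambda_volume()` moves the apex to fraction $\lambda$,
and `midlength_error()` gives the closed-form relative volume error
$\varepsilon_T = \tfrac{1}{2}(1 - 2\lambda)\,/\,(\lambda + D^2/(d^2+dD))$
of assuming $\lambda = 1/2$.

`continuous_estimates()` implements the $n \to \infty$ limit (line
integrals along the boundary) by adaptive quadrature
(`stats::integrate`, default absolute tolerance $10^{-12}$; the integrands
are smooth and cheap, so the tight default costs little).  For kinked
interpolants the caller passes the knots as `breaks` so each panel is
smooth.

## The Bezier representation

A polygonal profile underestimates a smooth animal - it is the convex hull
of the measured points.  The second estimator fits a parametric Bezier
curve $C(t) = \sum_i P_i B_{i,n}(t)$ through the coordinates, with the
control points obtained by (optionally weighted) least squares,
$P = (B'WB)^{-1}B'WC$; when the node count equals $n + 1$ this is exact
interpolation, solved directly from the square basis matrix rather than
through the normal equations (whose conditioning is squared).

Three constructions are provided (`build_outline()`):

* **simple7** - a degree-6 curve through the seven $(l, r)$ coordinates,
  mirrored about the axis.  High-degree uniform-node interpolation rings at
  the interval ends (the Runge phenomenon) and the curve develops a pair of
  anterior loops; the package detects the self-intersection by a
  segment-pair test and warns.  Useful illustratively, not as a model.
* **extended13** - one closed degree-12 curve through the coordinates of
  both flanks, ordered clockwise from the anterior tip (tip, upper front to
  back, tail, mirrored lower back to front, tip again; 13 points, uniform
  nodes $t = i/12$).  Starting and ending at the anterior tip is the only
  ordering that matches the observed behaviour: good posterior, amplified
  Runge oscillation at the anterior, where the parameter interval begins
  and ends.
* **edited** - the usable model.  Only the lower-boundary arc of the
  extended curve, from the posterior tip ($t = 6/12$) towards the first
  morphometric coordinate ($t = 11/12$), is retained; it is reflected about
  the axis to give the upper boundary and the anterior is closed by
  straight segments through the tip.

One editing decision was genuinely open.  The anterior Runge loop begins
*before* the parameter node of the first coordinate: between $t \approx
0.894$ and $t = 11/12$ the curve overshoots the anterior tip (reaching
$x \approx -0.008$) before returning to $(0.001, -0.004)$.  Retaining the
full nominal arc therefore yields an outline that crosses its own anterior
cap - not a simple closed curve - and a perimeter inflated by the loop.
The package clips the retained arc at the first parameter where the curve
crosses the vertical line through the first coordinate ($x = l_1$) and caps
from the tip to the clip point.  For the worked example this restores the
simple-closed-curve invariant and reproduces the published Bezier perimeter
($1.208 \times 10^{-3}$ m) exactly to the printed four figures, which we
take as confirmation that the editing was intended to remove the loop.  The
clip is reported in the outline object (`$clipped`).

Sizes follow from the classical solid-of-revolution line integrals along
the retained arc,

$$P = 2\!\int\!\sqrt{x'^2 + y'^2}\,dt,\quad
  A = 2\!\int\! y\,x'\,dt,\quad
  S = 2\pi\!\int\! |y|\sqrt{x'^2 + y'^2}\,dt,\quad
  V = \pi\!\int\! y^2 x'\,dt,$$

plus the exact segment/triangle/cone contributions of the linear anterior
cap.  The integrals are signed by the traversal direction; orientation is
checked (a warning fires if the traversal reverses substantially, i.e.
loops survived inside the integration range) and absolute values are taken.
Quadrature is fixed-order Gauss-Legendre (64 nodes, doubled up to 2048
until two successive estimates agree to $10^{-10}$ relative; failure to
converge is an error, not a silent result).  Polynomial integrands of the
degrees arising here are integrated exactly at the first rung.

## Verification strategy

Every estimator is checked against an independent brute-force oracle,
`revolve_oracle()`: composite trapezoid/exact-frustum sums over a densely
sampled monotone boundary polyline.  Its error model (plain $O(n^{-2})$
composite sums) is independent of the analytic code paths.  The frustum
estimator must agree with it to $10^{-10}$ relative on random profiles
(both are exact for polylines, so this tests assembly, not quadrature);
the Bezier estimator must agree to 0.1% on a 20 000-point sampling of its
own outline; the continuous estimator must recover the cylinder, cone and
sphere closed forms.

`make_fixture()` generates the test shapes: cylinder, cone, frustum (known
closed forms), a fusiform three-coordinate body whose volume is *exactly*
the position-weighted classical formula, and seeded random slender bodies
(radii at most 0.05 of $L$, matching the aspect ratios of real nematodes;
positions and radii uniform, which makes no attempt to emulate anatomical
smoothness or landmark placement).  Passing these suites therefore
demonstrates internal correctness of the geometry and algebra on
slender axisymmetric bodies; it says nothing about measurement error,
non-circular cross-sections, or fixation artefacts in real specimens.

Problem sizes used by the default test run are small by construction -
hundreds of seven-coordinate profiles and a single degree-12 curve - and
the whole suite, including the comparisons below, completes in seconds.

## Reproduction of the published worked example

The package reproduces the classical comparison table for
*Aplectus antarcticus* ($L = 0.6$ mm).  The cylinder row
($1.229 \times 10^{-3}$ m, $8.64 \times 10^{-9}$ m$^2$,
$2.75 \times 10^{-8}$ m$^2$, $9.77 \times 10^{-14}$ m$^3$), the Andrassy
volume ($7.82 \times 10^{-14}$), the Tsalolikhin projected area and volume
($5.04 \times 10^{-9}$, $3.98 \times 10^{-14}$) and the entire frustum-model
row ($1.204 \times 10^{-3}$, $7.13 \times 10^{-9}$, $2.24 \times 10^{-8}$,
$7.15 \times 10^{-14}$) come out exactly at the printed rounding, as do the
two midlength-error cases ($-0.0036$ and $-0.063$) and the interpolated
control points of the degree-6 curve.

```{r table}
prof <- cobb_to_profile(aplectus_antarcticus())
estimate_report(prof)
```

Four published numbers are *not* reproduced, deliberately:

* the published Tsalolikhin perimeter, $1.188 \times 10^{-3}$ m, is below
  the hard lower bound $2L = 1.2 \times 10^{-3}$ m that every closed
  outline of axial extent $L$ obeys; the true perimeter of the composite
  shape is $1.205 \times 10^{-3}$ m and that is what the package returns;
* the published Tsalolikhin surface area $1.58 \times 10^{-8}$ m$^2$ omits
  the anterior cap disc.  The frustum assembly includes it (the interface
  bookkeeping leaves exactly one anterior disc), giving
  $1.585 \times 10^{-8}$, which rounds to $1.59$;
* the published Bezier surface area ($2.26 \times 10^{-8}$) and volume
  ($7.40 \times 10^{-14}$) sit about 7% below what the degree-12
  uniform-node construction actually yields ($2.41 \times 10^{-8}$ and
  $7.91 \times 10^{-14}$, robust to every defensible arc selection,
  signed-versus-unsigned integral choice and quadrature).  The published
  row is internally inconsistent: its projected area is 5.8% above the
  frustum row while its surface area is only 0.9% above, and no smooth
  boundary that gains 5.8% silhouette area can gain only 0.9% surface.
  Since the same machinery reproduces the published control points to all
  printed digits and the published Bezier perimeter and projected area to
  within 1.5%, we report our computed values rather than tuning the
  construction towards two numbers that no consistent curve produces.

## Known limitations

* Circular cross-section is assumed throughout; bursae, alae and flattened
  tails violate it.
* The Bezier model is a single global polynomial with uniform nodes.
  Chord-length or centripetal parameterisations and splines would tame the
  anterior oscillation at the cost of leaving the classical construction;
  both were deliberately excluded.
* Profiles derived from de Man indices alone carry one interior coordinate
  and degrade the frustum model to the coarse classical shapes - by
  design, but worth remembering when comparing specimens measured under
  different conventions.
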