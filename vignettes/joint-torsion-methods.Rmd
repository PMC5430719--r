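---
title: "Joint-based torsion description of TM-helix bundles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-based torsion description of TM-helix bundles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmjoint)
```

## The descriptor

A polytopic membrane protein with $n$ transmembrane helices is reduced to an
ordered skeleton of $2n$ *joint points*: the C$\alpha$ atoms of the first
and last residue of each helix, $P_1 \dots P_{2n}$. Every four consecutive
joints define a signed torsion; the $2n-3$ torsions alternate between

* $\Omega_i$ — windows starting at odd joints (Helix–Loop–Helix): the
  relative tilt of helices $H_i$ and $H_{i+1}$. $\Omega \approx 0^\circ$ is
  anti-parallel, $\pm 180^\circ$ parallel.
* $\lambda_i$ — windows starting at even joints (Loop–Helix–Loop): whether
  $H_{i+2}$ lies on the same ($\approx 0^\circ$) or opposite
  ($\approx \pm 180^\circ$) side as $H_i$ relative to $H_{i+1}$.

The skeleton deliberately ignores everything inside a helix: kinked or bent
helices are straightened into a single chord, so the descriptor is
macroscopic by construction. A strongly kinked helix can produce an extreme
$\Omega$ even when the two membrane-spanning segments are not actually
parallel; the descriptor flags such cases rather than resolving them, and
helix-axis fitting or kink quantification is out of scope.

## Torsion computation

With $b_1 = p_2-p_1$, $b_2 = p_3-p_2$, $b_3 = p_4-p_3$, normals
$n_1 = b_1 \times b_2$, $n_2 = b_2 \times b_3$:

$$\theta = \operatorname{atan2}\big((n_1 \times n_2)\cdot \hat b_2,\; n_1 \cdot n_2\big)$$

reported in degrees in $(-180, 180]$, with exact $-180$ mapped to $+180$ so
the trans configuration has a single representative. This realizes the
convention "positive = clockwise rotation of the far segment relative to the
near one, projected onto the plane perpendicular to $p_2 \to p_3$ and viewed
from $p_2$ toward $p_3$". The implementation is validated three independent
ways in the test suite: against a brute-force projection oracle (project the
outer segments onto the normal plane, measure the signed angle between the
rays), against `bio3d::torsion.xyz`, and through the invariance properties
(rigid motions leave torsions unchanged to $10^{-9\,\circ}$; mirror
reflection negates them exactly; reversing the point order leaves them
unchanged).

Degenerate inputs are rejected, never patched: coincident consecutive points
("degenerate segment") and collinear triples ("undefined normal", triggered
when a normal's magnitude falls below $10^{-10}$ times the product of the
adjacent segment lengths — a relative tolerance so the test is scale-free).

## Annotation and extraction rules

TM boundaries are an explicit input, not a prediction. A user-supplied
segment table (OPM/PDBTM-style: `protein_id chain helix_index start_residue
end_residue`) always takes precedence; PDB `HELIX` header records are the
fallback, and secondary-structure assignment (DSSP-like) is never invoked —
this keeps results exactly reproducible from the annotation file. When the
curated databases disagree about a boundary, resolving the disagreement is
the user's task; the package computes from whatever table it is given.

Coordinate handling follows the single-conformer convention: one CA per
residue, altloc `' '` or `'A'` preferred, highest occupancy breaking ties.
Residues are keyed by author number plus insertion code and never
renumbered; segment boundaries match on number with empty insertion code. A
boundary residue missing from the trace (disordered terminus) is a named
error — substituting the nearest resolved residue would silently change the
geometry. Chains are processed independently and each topology names its
chain explicitly.

Two-helix topologies are accepted with a warning (the single $\Omega$ is
well defined, $\lambda$ requires three helices); single-helix input is
rejected.

## Pattern statistics

Angles are categorized by sign ($+$ for $(0,180]$, $-$ for $(-180,0)$) or,
for $\lambda$ only, by quadrant ($A=(0,90]$, $B=(90,180]$, $-A=[-90,0)$,
$-B=(-180,-90)$). An exact $0^\circ$ — a measure-zero event under any
continuous angle distribution — goes to $+$/$A$ with a warning; the quadrant
edges are closed on the side away from zero. Any fixed rule works here; this
one is documented and tested.

Consecutive patterns are strictly adjacent windows ($k = 2$ or $3$) within
one protein's same-kind sequence; counts are pooled across proteins and the
pattern space is always zero-filled (4 sign dyads, 8 triads, 16 quadrant
dyads). Bootstrap standard deviations resample the *window-level
observations* with replacement to the original count, 500 replicates by
default, all randomness from one seed. Resampling proteins instead of
windows is a defensible alternative; window-level resampling is the default
because the tallied unit is the window. A pattern that never occurs has SD
0 by construction. The binomial sanity check (two windows, one of each of
two patterns: SD $=\sqrt{2 \cdot 0.25} \approx 0.707$) is part of the test
suite.

The $\Omega$–$\lambda$ scatter pairs $\Omega_i$ with $\lambda_i$, which
share three of their four joints; marginal histograms are computed from all
angles regardless of pairing, so they do not depend on that choice. The
histogram bin width defaults to $20^\circ$ aligned to zero (the natural
resolution for the $\pm(10$–$30)^\circ$ $\Omega$ lobes) and must divide
360. TM-size groups default to 3–6, 7–10 and 11–14 helices, overridable.

## Symmetry screen

Two proteins with the same helix count are *mirror-signature candidates*
when their ordered $\lambda$-sign vectors are exact elementwise negations.
This is the minimal falsifiable reading of "symmetric configuration of
$\lambda$ signs"; a reversed-and-negated mode (bundles mirrored end-to-end)
is available but off by default, and $\Omega$ signs are not constrained.
Candidates are a screen: confirming 3-D mirror symmetry requires structural
superposition or inspection, which the package supports only by emitting
per-pair angle tables.

## Synthetic bundles

`bundle_spec()` fixes a skeleton by internal coordinates: $2n-1$ distances,
$2n-2$ planar angles in $(0,180)$ exclusive (the open bounds keep every
downstream torsion defined), $2n-3$ torsions. `build_chain()` places
$P_1$ at the origin, $P_2$ on $+x$, $P_3$ in the $xy$-plane and extends by
the standard torsion-extension (NeRF) step, so
`compute_series(build_chain(spec))` returns exactly `spec$torsions` — the
package's core oracle, exact to $\sim 10^{-13\,\circ}$ in practice and
asserted at $10^{-6\,\circ}$.

`write_bundle_pdb()` fleshes each helix out as an ideal $\alpha$-helical CA
trace: $100^\circ$ twist per residue and 2.3 Å radius (conventional
ideal-helix constants, fixture parameters rather than fitted values), with
the rise set by the joint-to-joint span (about 1.5 Å/residue when spans are
drawn in the default 26–32 Å range for ~20-residue helices). Rather than
laying residues around the raw joint axis — which would leave the terminal
CA up to 2.3 Å off the joints — the helix axis is tilted and offset in
closed form so the first and last CA of each helix land *exactly* on the
joint points: writing then re-reading a bundle reproduces the prescribed
torsions up to the 3-decimal coordinate rounding of the PDB format
(~0.005° observed). The end-to-end contract in the tests is 5°, a deliberate
margin for shorter helices and coarser discretizations. Loop residues are
linearly interpolated at ~3.8 Å spacing; they carry no information and only
make the files realistic enough to parse.

`generate_cohort()` emulates the empirical angle structure of membrane
bundles: $\Omega$ as an equal mixture of uniform$(-40,-10)$ and
uniform$(+10,+40)$ — the slanted anti-parallel lobes with the low-frequency
gap at 0 — and $\lambda$ uniform over $(-180,180]$. Helix spans 26–32 Å,
loop spans 9–14 Å, planar angles 60–120°: values a membrane-protein
crystallographer would call unremarkable. What the generator does *not*
emulate: helix kinks and bends, correlated angles along the chain,
re-entrant or half helices, membrane-plane constraints, and experimental
noise other than coordinate rounding. Tests passing on synthetic cohorts
therefore validate the machinery — extraction, torsion algebra, counting,
bootstrap, screening — not any biological claim about real distributions.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use cohorts of 10–50 synthetic
proteins with 3–10 helices, 1000 random quadruples for the oracle
comparison, 100 random specs for the round trip, and 500 bootstrap
replicates — sizes at which every check runs in seconds while keeping the
binomial bootstrap comparison within its 10% band. Angles are kept at full
double precision internally and written at one decimal place; joint
coordinates at three decimals (PDB precision), which bounds the TSV
round-trip error at $5\times10^{-4}$ Å.

## Known limitations

* The descriptor is blind to intra-helix geometry; kinked helices can
  produce outlier $\Omega$ values that do not reflect the true inter-helix
  arrangement.
* Annotation quality is inherited entirely from the input table; no
  reconciliation between annotation sources is attempted.
* The symmetry screen is necessary, not sufficient: sign vectors are a very
  coarse fingerprint and equal-length cohorts of few helices will produce
  chance candidates.
* mmCIF input, biological-assembly construction and TM-segment prediction
  are out of scope.
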