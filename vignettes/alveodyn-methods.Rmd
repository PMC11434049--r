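---
title: "Measuring alveolar micro-dynamics: models, phantoms and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring alveolar micro-dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alveodyn)
```

## The scientific problem

During tidal ventilation a pulmonary gas-exchange unit — an alveolar duct
(AD) together with the alveoli (A) that open onto it, AAD = A + AD —
expands and contracts. How the inhaled volume is divided between duct and
alveoli determines how much new membrane surface becomes available for gas
exchange. `alveodyn` quantifies this from paired three-dimensional
acquisitions at the two extremes of the cycle (end-expiration at PEEP,
end-inspiration at the inspiratory plateau pressure).

The central quantities are dimensional. For any closed shape,
$S = k\,V^{2/3}$ with a dimensionless shape factor $k = S/V^{2/3}$; a cube
has $k = 6$, and the sphere attains the isoperimetric minimum
$k = 6^{2/3}\pi^{1/3} \approx 4.8360$, which every closed surface must
exceed. Because $k$ is scale-free, its change over the cycle isolates the
change of *shape* from the change of *size*:

$$q = \frac{k_\mathrm{insp}}{k_\mathrm{exp}}$$

$q = 1$ means geometrically similar ("balloon-like") expansion; $q > 1$
means the alveoli deepen relative to their openings (alveolus-dominant
expansion, more surface per volume); $q < 1$ means the duct widens at the
alveoli's expense. Two further families of measures complete the picture:
membrane and entrance-ring strains, with the area strain
$\Delta S = (S_\mathrm{insp} - S_\mathrm{exp})/S_\mathrm{exp}$ converted
to a linear strain by $\varepsilon = (1 + \Delta S)^{1/2} - 1$, and the
inter-alveolar angle $\theta$ whose tidal change
$\Delta\theta = \theta_\mathrm{insp} - \theta_\mathrm{exp}$ has a sign
that diagnoses the expansion regime (positive when the duct spreads its
alveoli apart, negative when deepening alveoli draw together).

## Why a synthetic phantom, and what it emulates

The live-animal tomography this pipeline is designed around cannot be
re-acquired at a desk, so the package ships a generator of synthetic
gas-exchange units with *closed-form* ground truth for every measured
quantity. The phantom emulates: a common duct lumen carrying several
cup-shaped alveolar lumina with open circular mouths; murine dimensions
(alveolar equivalent diameters of roughly 50–100 µm by default, imaged at
0.65 µm isotropic voxels); radius heterogeneity across alveoli; and a
two-state deformation with a prescribed whole-unit volume ratio
(default 1.5) in three regimes — `isotropic`, `alveolus_dominant`,
`duct_dominant` — constructed so that the true $q$ is exactly 1 in the
isotropic mode and brackets 1 in the other two.

Geometrically, the duct lumen is a right regular prism (default six
faces) described by its apothem, and each alveolus is a spherical-cap
lumen whose planar mouth disk lies flush in one prism face. This is the
one place where the design deliberately departs from a circular-cylinder
duct: a planar mouth can only be *tangent* to a curved duct, which would
seal the aperture with a tissue sliver, whereas a flat face gives a
genuinely open mouth while keeping volume, surface, ring perimeter,
centroid, inter-alveolar angle and thinnest-wall ground truth exactly
closed-form. The prism is additionally rotated 10° off the image lattice:
real septa are never lattice-aligned, and an exactly axis-aligned mouth
plane would make its sub-voxel position — and hence the rim radius —
unidentifiable from a label volume.

The deformation modes scale duct and alveoli with separate linear factors
$(s_d, s_a)$. Isotropic uses $s_d = s_a = (V_\mathrm{insp}/
V_\mathrm{exp})^{1/3}$; the anisotropic modes give the non-dominant
compartment a fixed fraction (`minor_scale`, default 0.3) of the isotropic
linear strain and solve the cubic volume balance for the dominant factor,
so the whole-unit ratio is met exactly by construction. Mouth placement is
rejection sampling on the faces (largest alveoli first, with whole-
placement restarts); an infeasible configuration raises an explicit
placement error — the generator never silently reduces the number of
alveoli. Where the source imaging literature gives no value, defaults were
fixed once on anatomical grounds: the duct carries ≈ 40% of the unit
volume (exposed as `duct_volume_fraction`), mouths span 0.4 of the
alveolar radius, radii disperse by 15% (truncated at 1.5 SD), and septa
are kept at least 2.5 µm thick.

What the phantom does **not** emulate: acinar tree topology, curved and
textured septal walls, capillary-scale roughness, surfactant mechanics,
phase-contrast imaging artifacts, or reconstruction noise beyond additive
Gaussian grayscale noise. Passing the phantom suite therefore demonstrates
that the *measurement chain* is unbiased and correctly calibrated on
geometry of the right scale and topology — not that segmentation of real
phase-contrast reconstructions is solved.

## The measurement chain

1. **Segmentation** (`segment_air`): one global Otsu threshold on the
   intensity histogram (air below, tissue above; an `invert` flag for
   inverted contrast). A separability guard rejects histograms with no
   air/tissue bimodality.
2. **Instance separation** (`split_instances`): watershed on the interior
   Euclidean distance transform with *persistence merging* — a catchment
   basin whose distance peak rises less than `persistence` (default 2 µm,
   below any plausible lumen radius and above lattice ripple) over the
   saddle to a deeper basin is merged into it. Contested voxels join the
   basin of their steepest neighbor, so boundaries follow the distance
   ridge. This repairs narrow unintended bridges between lumina while
   keeping true apertures (whose saddles sit far below the lumen peaks)
   intact. Objects below `min_volume` (default 500 µm³, far below any
   alveolus) are removed and logged. Labels are ranked by volume, label 1
   being the duct; `duct_label()` also recognizes a duct by its contact
   with both axial faces.
3. **Meshing** (`extract_mesh`): marching tetrahedra at level 0.5 on the
   label indicator after a Gaussian anti-aliasing of the *field* (never
   the mesh; default σ = 0.8 voxel). Raw binary isosurfaces carry a
   faceting bias of several percent in surface area, while heavy
   smoothing rounds corners and thin features away; σ = 0.8 balances the
   two so that polyhedral and spherical test bodies are both recovered
   within their stated bands. Volumes come from signed tetrahedra (exact
   for polyhedra), areas from summed triangles.
4. **Single-state morphometry** (`measure_structures`): per structure,
   volume, surface, equivalent diameter $D_A = (6V/\pi)^{1/3}$, centroid;
   per alveolus additionally the entrance ring, the membrane area
   (total boundary minus the aperture disk), and the thinnest septal wall
   $T_A$ from the feature distance transform (ridge pairs between the
   distance cells of two lumina; the duct aperture is not a septum and is
   excluded by default).
5. **Pairing and dynamics** (`pair_dynamics`, `pair_angles`): structures
   are matched by persistent id or nearest centroid (never silently
   dropped), and the paired records yield $k$, $q$, $\Delta S$,
   $\varepsilon_A$, $\varepsilon_{ER}$, $\Delta\theta$.
6. **Statistics** (`one_sample_t`, `welch_pairwise`, `anova_oneway`,
   `five_number`, `summarize_experiment`): two-sided one-sample tests of
   $q$ against 1 and $\Delta\theta$ against 0 (accepting raw values or
   printed mean/SEM/n), one-way ANOVA across pressure groups with Welch
   pairwise post-hocs (no multiplicity adjustment by default, Holm on
   request), SEM as sample SD over $\sqrt{n}$, and five-number summaries
   with interpolated quartiles (type 7).

### The entrance ring

The aperture is an open air–air interface, so its rim must be inferred,
not traced: just outside the rim the tissue wedge between the alveolar
wall and the duct face thins below one voxel and vanishes from the label
volume, which makes the first voxel layer above the mouth plane leak
beyond the rim. The ring estimator therefore works in the layers above
that leak zone and exploits the cap geometry: on a spherical-cap wall
$\rho^2 + h^2 = a^2 + 2ch$ is linear in the height $h$, so extrapolating
the binned outer radii to $h = 0$ recovers the rim radius $a$ without
bias from the wall flare. The ring's absolute scale is pinned by a
slab-volume fit (lumen volume between two heights is linear in the
aperture area), which averages boundary-sampling noise that per-bin
maxima would amplify; the binned polygon then contributes only the
aperture's shape. On straight-walled (box-like) apertures the cap model
reads a few percent low; on cup-shaped alveoli it is accurate to about
±2% per ring at 12-voxel rims.

### Angles

$\theta$ for a neighboring pair is measured at the midpoint of the two
mouth-plane centers, between the rays to the two lumen centroids — a
deterministic reconstruction of an otherwise operator-dependent
three-point measurement. It is invariant under rigid motion and uniform
scaling, so $\Delta\theta = 0$ exactly for isotropic deformation. An
alternative definition (angle between mouth-plane normals) can be
computed from the ring objects directly.

### Resolution matching across states

Ratio statistics such as $q$ and the strains compare two states of the
same anatomy at different physical sizes but the *same* voxel size. Any
surface estimator carries a small resolution-dependent bias, which would
not cancel between states. `run_chain` therefore extracts the
inspiration-state meshes with the smoothing scaled by the measured linear
expansion (the cube root of the air-voxel-count ratio), putting both
states at matched relative resolution; the residual bias then cancels in
the ratio. On the replicated phantom studies this brings $q$ recovery
from ~0.8% systematic error to under ~0.3%. The whole-unit record in the
chain uses the union-mask isosurface (`unit_method = "union"`), which is
indifferent to where the watershed places the internal aperture
boundaries; on generator-truth labels, whose aperture boundaries are
planar, the assembled route (`unit_method = "assembled"`; duct boundary
minus aperture disks plus membranes) is more accurate because the union
mask hides sub-voxel tissue crevices at the rims.

## Problem sizes and numerical choices

The replicated studies use a scaled-down unit — duct apothem 11 µm,
alveolar radius 9 µm, five alveoli, duct fraction 0.5 — so that a whole
two-state unit fits a ~100³-voxel grid at the canonical 0.65 µm spacing;
the shape-change regimes and the measurement physics are scale-free, so
nothing about the recovery depends on the absolute size. Strain and
absolute-accuracy checks use a mid-scale unit (apothem 22 µm, radius
20 µm). Grayscale noise of SD 10 on an air/tissue contrast of 150 mimics
a high-quality reconstruction; at that level segmentation agrees with
truth on ≳ 99.9% of voxels. Statistical calibration uses 10⁴ null
replicates. Degenerate inputs fail loudly: structures under 10 voxels,
empty masks, unimodal histograms, detached alveoli, sub-minimal sample
sizes and zero-variance tests all raise descriptive errors.

## Known limitations

* **Ring-based strain precision.** A perimeter estimate at 0.65 µm voxels
  on a 8–15 µm rim carries ≈ ±2% uncertainty per ring. The ring strain
  divides two such perimeters and its relative error is amplified by
  $(1+\varepsilon)/\varepsilon \approx 8$ at the default volume ratio, so
  phantom-mean $\varepsilon_{ER}$ lands within roughly ±0.01–0.02
  *absolute* of truth (a few percent relative, versus well under 1% for
  the area-based $\varepsilon_A$). Sub-percent relative accuracy in
  $\varepsilon_{ER}$ would require rims of hundreds of voxels or
  grayscale-level (sub-voxel) aperture localization; a label volume does
  not contain that information.
* The watershed stand-in for instance repair is classical; it makes no
  attempt to reproduce any particular trained segmentation network.
* Wall thickness is a 3D minimum over septal ridges, reported to ±1
  voxel; sub-voxel walls are unresolvable by construction.
* The phantom's deformation is a two-point (end-expiration /
  end-inspiration) comparison; intra-cycle trajectories, hysteresis and
  recruitment phenomena are out of scope.

## A minimal worked example

```{r example, eval = FALSE}
spec <- phantom_spec(deformation_mode = "alveolus_dominant",
                     placement_seed = 1)
unit <- generate_unit(spec)
res <- run_chain(unit, noise_seed = 1)
res$q          # measured shape-change statistic
res$q_true     # generator ground truth
summarize_experiment(list(peep3 = res$dynamics),
                     angles = list(peep3 = res$angles))
```
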