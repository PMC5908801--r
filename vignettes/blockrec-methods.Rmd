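---
title: "Methods: depth-of-field simulation and block-based reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-of-field simulation and block-based reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model implemented by `blockrec`, the numerical
choices behind it, and what the synthetic experiments do and do not show.
It is the package's design document; the README holds a worked example.

## The imaging model

A particle at orientation `R` (ZYZ intrinsic Euler triple; `R` maps
reference-frame coordinates to the imaging frame, beam along +z) is not a
plane projection once its thickness is comparable to the depth of field.
`simulate_image_layered()` models this by rotating the density into the
imaging frame, cutting it into slabs of `layer_thickness` (default 20 Å)
along the beam, projecting each slab, filtering it with the CTF of its own
defocus `PDF + hand · z_slab`, and summing the filtered projections. The
CTF is the standard scalar form

    CTF(s) = −sqrt(1 − A²)·sin χ(s) − A·cos χ(s)
    χ(s)   = π λ Δf s² − (π/2) Cs λ³ s⁴ + phase_shift

with underfocus positive and `CTF(0) = −A`. No astigmatism is modelled
anywhere: the simulator produces none, and the block formulas use a single
scalar defocus per (particle, block). The electron wavelength follows the
relativistic formula `λ = 12.2639/sqrt(V + 0.97845e−6 V²)` Å (V in
volts); `optics_model(wavelength =)` may override it, which the benchmark
exploits (below).

Assumptions inherited from the weak-phase, linear-CTF picture: density
adds linearly, the detector is ideal, and no amplitude decay envelope is
applied. A single slab reproduces the flat (single-defocus) simulator
exactly; slab centres are the mid-planes of the covered extent on a z-axis
symmetric about the volume mid-plane, so the layering is symmetric and the
degenerate single-slab case sits exactly at the particle defocus.

## Reconstruction

`reconstruct()` is direct Fourier inversion: each image is zero-padded
(`pad_factor` 2 by default), its FT phase-shifted so the particle centre
sits at the array origin (origin shifts from the metadata are applied as
phase ramps rather than by resampling), multiplied by the CTF, and spread
onto the central section at `g = Rᵀ(h_x, h_y, 0)` with a trilinear kernel;
weights accumulate CTF². `finalize_volume()` divides by the weights with a
Wiener floor expressed as a fraction of the maximum weight (default 0.01;
the floor regularises sparsely covered voxels — for noise-free coverage
studies a smaller value such as 1e−3 recovers the map essentially
exactly). Multiplying data by the CTF both phase-flips and
amplitude-weights, so the weighted division is CTF correction in the usual
Wiener sense.

Numerical consequences measured by the test suite: with dense angular
coverage and an idealised unit transfer the map is exact (FSC > 0.99)
through ~0.85 Nyquist and > 0.95 at 0.9 Nyquist; the residual is the
trilinear interpolation of both the projection simulator and the
insertion kernel. FSC curves use one-voxel shells, and resolutions are
read at the first downward threshold crossing with linear interpolation
between shells (Nyquist is returned if the curve never crosses).

## Defocus measurement

`fit_defocus()` measures defocus from the rotationally averaged power
spectrum: subtract and divide by a smooth envelope (moving-minimum floor
followed by a moving average, window 9 shells), then maximise the
correlation with a model CTF² over a defocus grid, refining the optimum
by parabolic interpolation. Two choices matter:

* **Whitening.** Dividing by the envelope makes ring modulation at all
  radii contribute comparably; without it the steep pseudo-atom envelope
  lets low-frequency shells dominate the correlation.
* **Annulus-matched model.** The model CTF² is averaged over exactly the
  Fourier pixels of each shell rather than point-sampled at the shell
  centre. Shell averaging blurs fast rings asymmetrically (χ is quadratic
  in s); a point-sampled model leaves a defocus-dependent bias of order
  100 Å, the matched model removes it.

The fitted band defaults to [1/30, 1/5] Å⁻¹ (clamped to the grid). Boxes
must be large enough that the ring spacing at the largest search defocus
stays resolved on the band's Fourier grid; the package's tests use 256 px
boxes at 1.5 Å/px for defoci up to 3 μm. Images without rings (pure
noise) are rejected by a ring-contrast gate (whitened modulation
SD < 0.5, against O(1) for genuine rings) plus a minimum peak correlation
of 0.3; failure is an `NA` with a classed warning, never a silent number.
On layered images the fit recovers the defocus of the layer containing
the centre of mass — the particle defocus — which is what the block
pipeline needs.

## Blocks, assembly, symmetry

A block is a sphere (`centre` in the reference frame, Å; `radius`;
`sub_box` pixels). For each (symmetry-expanded) record,
`extract_block_images()` windows the image at the projected block centre
plus particle shift at nearest-pixel precision, carrying the sub-pixel
residual in the metadata — interpolating the image would smear it before
Fourier insertion, and the residual is applied later as a phase ramp. The
record receives `LDFV = hand·(R c)_z` and `LDF = PDF + LDFV`. Blocks are
reconstructed like whole particles but with `LDF` as the defocus.

`combine_blocks()` copies each voxel within `r_keep` of its nearest block
centre from that block, and outside the kept cores cross-fades blocks
with weights linear in `(distance − r_keep)` over `r_blend`, normalised
to sum to one. The linear-in-distance blend is this package's
interpretation of distance-based interpolation between neighbouring block
centres; any smooth partition of unity would serve. A block contributes
nowhere outside its own grid (its weight is zeroed there), so truncated
blocks cannot dilute covered regions. `symmetrize()` replaces each voxel
by the mean over group-rotated positions sampled trilinearly; point
groups (Cn, Dn, T, O, I — 60 operators for I) are generated by closing a
small generator set under composition. Right-angle operators are exact
lattice maps; oblique ones re-interpolate, so idempotence holds to the
trilinear error of the map's frequency content (≲0.5% RMS for smooth
maps), not to machine precision.

`local_refine()` searches Euler offsets on a grid; per candidate
orientation the in-plane shift is resolved in bulk from the FFT
cross-correlation map between the phase-flipped sub-image and the
|CTF|-weighted projection, restricted to the allowed shift range. This is
the same search space as an exhaustive grid, evaluated the way SPA
packages do it.

## Per-particle defocus refinement

All blocks of a particle share one unknown, the particle defocus; their
local defoci differ by known geometric offsets. `refine_particle_defocus()`
scans candidates over `current ± range/2` (defaults 200 nm span, 10 nm
step) and scores each by the summed phase residual over blocks and
symmetry copies,

    PR_ij = Σ w(s)·cos δθ(s) / Σ w(s),   w = |CTF(LDF_ij)|,

with `δθ` the Fourier phase difference between the phase-flipped
sub-image and the block projection, evaluated in a band (default
[1/20, 1/6] Å⁻¹ — phase agreement is uninformative at very low frequency
and noise-dominated near Nyquist). The CTF-amplitude weight normalised
per band is this package's reading of weighting the phase agreement by
CTF amplitude; with CTF ≡ 1 it reduces to the unweighted mean cosine. The
scan maximises |PR|, which tolerates a globally contrast-inverted
reference; ties break toward the candidate nearest the current value.
Per-block residuals are summed, not averaged, over blocks and symmetry
copies — additivity is part of the definition and is tested.

## Handedness

The sign convention ties defocus growth to +z. With the wrong sign every
`LDF` is off by `2·LDFV`, which visibly degrades the block map;
`handedness_test()` reconstructs under both signs and returns the sign of
the finer map, or `NA` (with a warning) when the two resolutions fall
within one Fourier shell — which is exactly what happens for particles
too small to show a depth-of-field effect, so an indeterminate result is
informative, not an error.

## The synthetic benchmark and its scale

The acceptance suite uses a deliberately scaled-down Ewald regime: a
150 Å pseudo-atom phantom in a 96³ box at 2 Å/px, with the wavelength set
to `2·5²/150 = 1/3` Å so the closed-form limit `sqrt(tλ/2)` sits at 5 Å,
2.5× the voxel — mid-band, reachable on a desk. At this wavelength CTF
rings are only resolvable on the 96-px grid for small defoci, so particle
defoci are drawn from 300–500 Å (the full-scale default remains
1.0–3.0 μm); the depth-of-field phase error depends on the defocus
*spread* across the particle, not its mean, so the limit physics is
unchanged. 287 projection directions (12° Fibonacci cover, ψ = 0) make
the conventional map sampling-limited well below 5 Å; with known
orientations, in-plane rotations only permute the already-complete
Fourier coverage, which is why ψ is not sampled there. Seven blocks
(centre + 6 face blocks at 45 Å, radius 60 Å, 64-px sub-boxes,
`r_keep` 25 Å, `r_blend` 40 Å) cover the sphere while keeping per-block
defocus spreads small.

What the phantom emulates: blob-like density of bounded support with
power across the fitted bands. What it does not: structural noise (ice,
carbon), detector envelopes, orientation errors, radiation damage, or the
low SNR of real micrographs. Passing the benchmark shows the geometry and
defocus bookkeeping of the correction are right and that the method
recovers resolution lost to the Ewald sphere under ideal data; it says
nothing about robustness to noise or to misassigned orientations, which
real-data pipelines handle upstream. Defocus-fit fidelity is measured at
full physical scale (300 kV, 1.0–3.0 μm defoci, 256² images at
1.5 Å/px), where runtimes stay in seconds per image.

## Degenerate inputs and tie-breaks

Empty particle tables, non-cubic volumes, odd box sizes, non-increasing
defocus ranges, zero search ranges and all-zero projections raise errors;
windows crossing the image edge are mean-padded and flagged rather than
rejected. `euler_from_matrix()` resolves the gimbal lock at tilt 0/180 by
assigning the in-plane angle to ψ. Nearest-block ties in
`combine_blocks()` go to the first block in the set; `max |PR|` ties go
to the candidate nearest the current defocus.

## Known limitations

* Trilinear interpolation throughout (rotation, insertion, assembly)
  bounds map fidelity near Nyquist; a gridding kernel with apodisation
  correction would push the idealised-coverage FSC closer to 1 there.
* The defocus fitter is 1D (rotationally averaged) and cannot measure
  astigmatism by construction.
* `local_refine()` resolves shifts on the pixel lattice; sub-pixel shift
  refinement would require oversampled correlation.
* The cooperative defocus scan assumes block reference volumes good
  enough for phase comparison; with very poor references the |PR| peak
  flattens and the scan returns the current value's neighbourhood.
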