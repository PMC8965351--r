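---
title: "Reconstructing images from orientation-map samples of the SE(2) wavelet transform"
author: "se2recon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing images from orientation-map samples of the SE(2) wavelet transform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(se2recon)
```

## The model

The linear stage of a V1 simple cell is classically modelled as a Gabor
receptive field: a complex modulated Gaussian at a retinotopic position
$x$ with a preferred orientation $\theta$. Fixing the scale and spatial
frequency and letting $(x, \theta)$ range over all positions and
orientations turns this population response into a group wavelet
transform under the rigid motions SE(2) of the plane:
$$ W_\psi f(x, \theta) = (f * \psi_\theta)(x), $$
with $\psi_\theta$ a rotated copy of the mother wavelet $\psi$. On an
$N \times N$ pixel grid with $M$ uniformly spaced orientations
$\theta_j = 2\pi j / M$, $j = 0, \dots, M-1$, and circular convolution,
the transform is a complex $N \times N \times M$ stack computed by FFT
with frequency-domain filters
$$ \hat\psi_{\theta_j}(\xi) = e^{-|\xi + p\,u_j|^2 / (2 s^2)}, \qquad
   u_j = (\cos\theta_j, \sin\theta_j), $$
on the centered integer frequency lattice $\{-N/2, \dots, N/2-1\}^2$.
The continuous normalization factor is dropped, so each filter peaks at
1 where $-p\,u_j$ hits a lattice point.

Cortical orientation-preference maps retain only one orientation per
position: a feature map $\Theta$ assigns to every pixel an index in
$\{0, \dots, M-1\}$, and the recorded data are the stack values on the
graph of $\Theta$ — an $N^2$-dimensional sample of an $N^2 M$-dimensional
representation. The package implements the completion problem: recover
the full stack, hence the image, from these samples alone.

## Conditioning: the Calderón function

Invertibility of the transform on images bandlimited to the open
frequency ball $B_R$ is governed by the Calderón function
$$ C(\xi) = \sum_{j=0}^{M-1} |\hat\psi_{\theta_j}(\xi)|^2
         = \sum_{j=0}^{M-1} e^{-|\xi + p\,u_j|^2 / s^2}, $$
whose extrema $A = \min_{B_R} C$ and $B = \max_{B_R} C$ are the frame
bounds: $A \|f\|^2 \le \|W_\psi f\|^2 \le B \|f\|^2$ under the package's
fixed DFT normalization (unnormalized forward, $1/N^2$ inverse). Note
the exponent: $C$ sums the *squared* filters, so the Gaussian width in
$C$ is $s/\sqrt2$. At the reference parameter set used throughout
($N = 512$, $M = 12$, $s = 51$, $p = 170$, $R = 252$) this gives
$B/A \approx 6.2 \cdot 10^3$ and a condition number
$\sqrt{B/A} \approx 78$; the lower bound is attained at the origin,
$A = C(0) = 12\,e^{-(p/s)^2} \approx 1.79 \cdot 10^{-4}$. Because $C > 0$
everywhere on a finite lattice, any radius $R$ gives an invertible
(if possibly badly conditioned) transform; $R = 252$ keeps
$\sqrt{B/A}$ below $10^2$.

```{r diagnose, eval = FALSE}
bank <- gaborBank(512, 12, 51, 170)
frameBounds(bank, 252)
```

The dual filters $\hat\gamma_j = \chi_{B_R} \hat\psi_{\theta_j} / C$
invert the transform exactly on $B_R$-bandlimited images:
`se2Adjoint(se2Forward(f, bank), dualBank(bank, R))` returns `f` to
roundoff (about $10^{-13}$ relative; the package asserts $10^{-10}$).

## The reproducing-kernel projection and the iteration

The range of the transform on bandlimited images is a reproducing-kernel
subspace of stack space. Its orthogonal projection is diagonal in
frequency across positions and mixes orientations:
$$ \widehat{\mathbb{P}F}(\xi, j) = \frac{\chi_{B_R}(\xi)}{C(\xi)}
   \hat\psi_{\theta_j}(\xi) \sum_{\ell} \hat F(\xi, \ell)
   \overline{\hat\psi_{\theta_\ell}(\xi)}, $$
computed in $O(M N^2 \log N)$ rather than by spatial kernel convolution
(the two agree under circular convolution). With
$\mathbb{O}_\Theta$ the diagonal 0/1 selection operator of the feature
map, reconstruction from the restricted data
$F_0 = \mathbb{O}_\Theta W_\psi f$ proceeds by *project and replace*:
$$ H_n = \mathbb{P} F_{n-1}, \qquad
   F_n = (1 - \mathbb{O}_\Theta) H_n + F_0 . $$
Whenever $\mathrm{Ker}(\mathbb{O}_\Theta) \cap \mathrm{Ran}(\mathbb{P})
= \{0\}$ the restricted data determine the stack uniquely, the target is
the unique fixed point, and the error obeys the exact recursion
$\tilde F - F_n = Q^\perp P (\tilde F - F_{n-1})$, hence decays
geometrically.

### What the rate actually is

The per-step error bound is $\|Q^\perp P\|$, the largest singular value
(the cosine of the smallest principal angle between
$\mathrm{Ran}(Q^\perp)$ and $\mathrm{Ran}(P)$). The *asymptotic* rate,
however, is the spectral radius of $Q^\perp P$, and for products of
orthogonal projections the nonzero eigenvalues are the squared cosines
of the principal angles: generically
$\rho(Q^\perp P) = \|Q^\perp P\|^2$. The package therefore reports both
(`contraction` and `asymptoticRate` in the solvability report), and the
desk-scale verification asserts the fitted slope of
$\log \|\tilde F - F_n\|$ against $\log \rho(Q^\perp P)$; fitting it
against $\log\|Q^\perp P\|$ would fail by exactly a factor two in the
exponent. On the reference desk instance ($N = 8$, $M = 2$, random
$\Theta$) the fitted rate matches the spectral radius to well under 5%.

### The dense oracle

`denseOperators()` assembles $\mathbb{P}$ explicitly (column by column,
through the FFT path, guarded to $N^2 M \le 4096$) and
`checkUniqueness()` decides solvability two independent ways: the
smallest singular value of $Q$ restricted to an orthonormal eigenbasis
of $\mathrm{Ran}(P)$, and $\|Q^\perp P\| < 1$. A projector rank is
counted as eigenvalues above $1/2$ (the spectrum is numerically
$\{0, 1\}$), and equals the number of lattice frequencies strictly
inside $B_R$. Instances with $\sigma_{\min}$ within a factor $10^3$ of
the $10^{-9}$ declaration threshold are flagged `"ill-conditioned"`
instead of being forced into a binary verdict. `verifyTheorem5()` runs
the dense-matrix and FFT iterations from identical restricted data and
requires entrywise agreement to $10^{-10}$ — the two routes share no
code beyond the filters.

## Feature maps

Three kinds of maps drive the selection operator:

* **random** — i.i.d. uniform indices, the salt-and-pepper arrangement
  of rodent V1;
* **pinwheel** — the quasiperiodic maps of carnivore/primate V1,
  obtained by quantizing the phase of the complex field
  $$ \phi_\rho(x) = \frac{2\pi}{K} \sum_{k=0}^{K-1}
     e^{i(\rho(x_1\cos\alpha_k + x_2\sin\alpha_k) + \Gamma_k)}, $$
  a $K$-point angular quadrature of a superposition of unit plane waves
  of wave number $\rho$ (radians/pixel) with i.i.d. uniform phases
  $\Gamma_k$. The index is $\Theta_\rho(x) = \lfloor M \,
  \mathrm{angle}(\phi_\rho(x)) / 2\pi \rfloor$ with the phase branch
  fixed to $[0, 2\pi)$ and a `mod M` guard for the floating-point edge
  at exactly $2\pi$; the phase of a zero field value is defined as 0.
* **constant** — one global orientation; restriction then keeps a single
  convolution plane and reconstruction is a deconvolution problem.

The underlying random process on the circle is specified only as
"purely random"; the package fixes it as $K = 64$ i.i.d. uniform phases
at equispaced angles. This is a modelling choice: $K \ge 8$ is accepted,
and spacing statistics depend mildly on it. The field's spectrum
concentrates on the ring $\rho/2\pi$ cycles/pixel (measured: over 98% of
power within $\pm 20\%$ of the ring at $N = 512$, $\rho = 0.4$), and
$\rho/2\pi$ may not exceed the Nyquist limit of $0.5$.

### Pinwheel statistics

`detectPinwheels()` lists every plaquette where the phase winds by
$\pm 2\pi$ (periodic boundaries; locations are plaquette centers,
lower-left corner $+ (0.5, 0.5)$). The detected density closely follows
the random-wave law $\rho^2 / 4\pi$ per pixel (about 3,400 singularities
at $N = 512$, $\rho = 0.4$), which quadruples when $\rho$ doubles. Two
spacing summaries are reported by `pinwheelSpacing()` and they differ
systematically: the density-implied spacing
$1/\sqrt{\textrm{density}} \approx 0.56 \cdot 2\pi/\rho$ is of the order
of the map's quasiperiod $2\pi/\rho$, while the mean nearest-neighbour
distance is markedly smaller ($\approx 0.37 \cdot 2\pi/\rho$ measured at
$\rho = 0.4$) because singularities are created in close $\pm$ pairs.
A spacing expectation of the form "pinwheels sit about one column
spacing apart" is therefore a statement about density, not about
nearest neighbours; checks that compare the nearest-neighbour mean
against $[0.5, 1.5] \cdot 2\pi/\rho$ sit below the lower edge of that
band for this generator, and the package does not adjust the generator
to move them.

## Phantoms

The reference experiments need 8-bit test photographs; the package
substitutes seeded phantoms. The `powerlaw` kind draws a random-phase
field with isotropic spectral amplitude $(1 + |\xi|)^{-\beta}$ and
rescales it to the full $\{0,\dots,255\}$ range; $\beta = 1.2$ by
default, a natural-image-like $\sim 1/|\xi|$ amplitude decay (a
stand-in choice, not a measured value). The `shapes` kind places
anti-aliased disks, oriented bars and an edge; `mixed` sums the two.
All are deterministic given the seed. After bandlimiting to $R = 252$
at $N = 512$ a $\beta = 1.2$ phantom loses only $\approx 0.04\%$ of its
spectral energy — but because the error metric is normalized by the
8-bit range, even this small out-of-ball tail contributes a floor of
about $1.1\%$ to errors measured against the *unbandlimited* phantom
(see below).

## The error metric and what the experiments show

Reconstruction quality is tracked by
$$ \Delta_n = 100 \, \frac{\|f - W^*_\gamma H_n\|_2}{255\,N}, $$
the RMS pixel error as a percent of the 8-bit dynamic range. Inside the
iteration loop $W^*_\gamma H_n$ collapses algebraically to a single
inverse FFT of $\chi_{B_R} S / C$ where
$S = \sum_\ell \hat F_\ell \hat\psi_{\theta_\ell}$ — an exact identity,
not an approximation — so recording $\Delta_n$ is cheap.

At the full reference conditions (power-law phantom, uniformly random
map, 500 iterations, three seeds) the package measures
$\Delta_{500} \approx 1.8\%$ against the original 8-bit phantom and
$\approx 1.4\%$ against its bandlimited version; the curve continues to
fall and crosses $1\%$ at roughly iteration 700–900. Reference results
on natural photographs reach about $1\%$ within 500 iterations; the
$\beta = 1.2$ phantom carries relatively more energy near the bandlimit
radius, where the frame is worst conditioned, so its restricted
reconstruction converges more slowly than a typical photograph's. The
package reports the measured values as they are rather than tuning the
phantom's spectrum or contrast toward the photographic behaviour; when
assessing convergence of the *iteration* itself, compare against the
bandlimited phantom (the image actually transformed) to avoid the
$1.1\%$ bandlimiting floor.

```{r recon, eval = FALSE}
bank <- gaborBank(512, 12, 51, 170); dual <- dualBank(bank, 252)
f0 <- phantom(512, "powerlaw", seed = 1)
f  <- bandlimit(f0, 252)
th <- randomMap(512, 12, seed = 2)
F0 <- restrictStack(se2Forward(f, bank), th)
tr <- projectAndReplace(F0, th, bank, dual, nIter = 500,
                        recordStride = 100, reference = f0)
deltas(tr)
```

## Numerical choices

* **Frequency convention.** Centered integer lattice
  $\{-N/2, \dots, N/2-1\}^2$ with the standard DFT index mapping; ball
  membership is the strict inequality $|\xi|^2 < R^2$ (the open ball
  always contains the origin, so a "ball with no lattice point" cannot
  occur for $R > 0$; the guard remains for robustness).
* **DFT pair.** Unnormalized forward, $1/N^2$ inverse, fixed once; all
  stated invariants hold under this pair.
* **Angles.** $j = 0, \dots, M-1$: exactly $M$ distinct orientations.
* **Complex arithmetic** throughout; images enter as real matrices and
  are promoted. Read-out takes the real part and reports the maximum
  absolute imaginary part as a diagnostic instead of discarding it
  silently.
* **Tolerances.** "In the range" and roundtrip assertions use $10^{-10}$
  relative (double precision with FFT roundoff); the solvability
  threshold on $\sigma_{\min}$ is $10^{-9}$.
* **Rotation covariance** (for $4 \mid M$) is exact for inputs
  bandlimited inside the Nyquist square: the centered lattice's
  $-N/2$ row has no rotated counterpart, so covariance fails only
  through filter values at frequencies a bandlimited input never
  excites.
* **Hot loop.** The full-size iteration (24 FFTs of $512^2$ per step)
  runs in C++ (Armadillo); a pure-R reference loop is retained and the
  two are asserted to agree entrywise, as are whole trajectories against
  the dense-matrix oracle.
* **Problem sizes.** Operator-level identities are exercised at
  $N = 8$–$16$ where a dense $(N^2 M)^2$ oracle is exact and cheap;
  full-size checks ($N = 512$) cover frame diagnostics, perfect
  reconstruction, pinwheel statistics and the three-seed reconstruction
  experiment.

## What the synthetic data do and do not show

The phantoms match natural images in their second-order statistics
(isotropic power-law spectra) and in 8-bit quantization, but not in
phase structure: they contain no edges, occlusions or textures, and a
random-phase field is Gaussian-like rather than scale-invariantly
sparse. Consequences observed here — e.g. the slower error decay near
the bandlimit — depend on the spectral envelope, which the phantom
matches; phenomena that depend on phase coherence (visual quality of
partial reconstructions, perceptual artifacts) are outside what these
tests can certify. The pinwheel generator reproduces ring spectra,
quasiperiodicity and singularity density of measured orientation maps,
but not their anisotropies or their coupling to retinotopy.

## Known limitations

* For non-solvable instances the iteration still converges empirically,
  but possibly to a different stack consistent with the data; the
  package records the limit point and makes no uniqueness claim.
* Stack persistence through 32-bit TIFF pages is lossy at the
  $2^{-32}$-of-range level (the installed TIFF writer has no float
  sample format); round-trips are asserted at $10^{-8}$ relative, not
  bit-exact.
* The scale and frequency parameters $s, p$ are global; spatially
  varying receptive-field parameters (as measured across cortex) are out
  of scope, as are nonlinear (sigmoidal, normalization-type) response
  models.
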