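# se2recon

Image analysis and reconstruction with the discrete SE(2) group-wavelet
transform, for computational-neuroscience and applied-harmonic-analysis
work on V1-style image representations.

A grayscale image `f` is represented by its correlations with rotated
Gabor receptive fields — the classical model of orientation-selective
simple cells in the primary visual cortex:

    W_psi f(x, theta_j) = (f * psi_{theta_j})(x),
    psihat_{theta_j}(xi) = exp(-|xi + p u_j|^2 / (2 s^2)),
    u_j = (cos theta_j, sin theta_j),  theta_j = 2 pi j / M,

an `N x N x M` complex stack computed by FFT on the centered frequency
lattice. Cortical orientation-preference maps keep only one orientation
per position; the package answers the question of whether, and how, the
image can be recovered from those `N^2` retained values out of `N^2 M`:

* **Frame diagnostics** — the Calderón function
  `C(xi) = sum_j |psihat_j(xi)|^2`, its frame bounds `A`, `B` over a
  frequency ball `B_R`, and the dual filters
  `gammahat_j = chi_{B_R} psihat_j / C` that invert the transform
  exactly on bandlimited images.
* **Reproducing-kernel projection** — the orthogonal projection `P` of
  stack space onto the range of the transform, computed in the frequency
  domain.
* **Feature maps** — uniformly random, pinwheel (quantized phase of a
  random superposition of plane waves of wave number `rho`), and
  constant orientation maps; phase-singularity (pinwheel) detection and
  spacing statistics.
* **Project-and-replace reconstruction** — iterate
  `H_n = P F_{n-1}; F_n = (1 - O_Theta) H_n + F_0` from the restricted
  data `F_0`; converges to the full transform whenever
  `Ker(O_Theta) ∩ Ran(P) = {0}`, with a per-iteration percent error
  trace `Delta_n = 100 ||f - W*_gamma H_n|| / (255 N)`.
* **Solvability oracle** — dense matrices for `P` and the selection `Q`
  on desk-scale instances: uniqueness verdict, contraction factor
  `||Q_perp P||`, sharp asymptotic rate (its spectral radius), and
  entrywise cross-validation of the FFT pipeline.
* **Phantoms** — seeded 8-bit test images with natural-image-like
  power-law spectra (and geometric scenes), standing in for photographs.

## Worked example

Frame diagnostics at the reference parameter set
(`N = 512, M = 12, s = 51, p = 170, R = 252`):

```r
library(se2recon)
bank <- gaborBank(512, 12, 51, 170)
frameBounds(bank, 252)
#> $A
#> [1] 0.0001793441
#> $B
#> [1] 1.103836
#> $ratio
#> [1] 6154.849
#> $conditionNumber
#> [1] 78.45285
```

`A` is attained at the frequency origin (`12 * exp(-(170/51)^2)`); the
ratio `B/A ~ 6.2e3` means the transform on images bandlimited to
`R = 252` is invertible with condition number `sqrt(B/A) ~ 78`.

Reconstruction from a random orientation map on a small grid:

```r
bank <- gaborBank(16, 3, 3, 4)
dual <- dualBank(bank, 6)
set.seed(7)
f  <- bandlimit(imageGrid(matrix(rnorm(256), 16)), 6)
th <- randomMap(16, 3, seed = 1)
F0 <- restrictStack(se2Forward(f, bank), th)   # 256 of 768 values kept
tr <- projectAndReplace(F0, th, bank, dual, nIter = 30,
                        recordStride = 5, reference = f)
deltas(tr)
#>          5         10         15         20         25         30
#> 0.06438370 0.03594382 0.02421379 0.01755611 0.01322994 0.01020311
```

The trace is the percent RMS error (of the 8-bit range) between the
reference image and the read-out `W*_gamma H_n`; it decays geometrically
because this instance satisfies the uniqueness condition, which
`checkUniqueness(denseOperators(bank, th, 6))` certifies explicitly
together with the contraction factor that sets the rate.

At full size (`N = 512`, 500 iterations, uniformly random map,
power-law phantom) the same pipeline reaches `Delta_500 ~ 1.8%` against
the 8-bit phantom (`~ 1.4%` against its bandlimited version; about 1.1
points of the former are the phantom's bandlimiting floor, not
iteration error).

A thin command-line wrapper with `phantom`, `map`, `diagnose`,
`transform`, `reconstruct` and `solvability` subcommands is installed at
`inst/scripts/se2recon-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/se2recon-cli.R", package="se2recon"))')" \
    diagnose --N 512 --M 12 --s 51 --p 170 --R 252 --out out/
```

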