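# fixtures built in code; no binary files

solidMask <- function(nr, nc, spacing = 1, view = "unspecified") {
  PixelGrid2D(matrix(1, nr, nc), spacing, spacing, view)
}

# bladder-like view pair: perturbed elliptical sagittal base stacked with a
# superellipse lateral profile, projected back to the two standard views
randomViewPair <- function(seed, spacingMM = 1) {
  set.seed(seed)
  W <- runif(1, 60, 140)
  H <- runif(1, 50, 110)
  L <- runif(1, 60, 150)
  nTrue <- runif(1, 3, 5)
  base <- makeEllipseMask(L, H, spacingMM, perturbAmp = 0.05,
                          harmonic = sample(2:3, 1),
                          phase = runif(1, 0, 2 * pi))
  projectViews(makeModelPhantom(base, W / 2, nTrue, spacingMM))
}

# irregular multi-blob mask for preprocessing properties
randomBlobMask <- function(seed, nr = 40, nc = 40) {
  set.seed(seed)
  m <- matrix(0, nr, nc)
  for (i in 1:4) {
    r0 <- sample(seq_len(nr - 8), 1)
    c0 <- sample(seq_len(nc - 8), 1)
    m[r0:(r0 + sample(3:8, 1)), c0:(c0 + sample(3:8, 1))] <- 1
  }
  PixelGrid2D(m, 1)
}

# independent quadrature oracle for the profile integral (closed Gamma form)
gammaProfileIntegral <- function(n) 2 * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
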