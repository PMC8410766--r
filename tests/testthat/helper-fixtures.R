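# Shared fixtures: a small corpus for fast unit tests and one network
# trained at the scaled-down study settings (500 examples, 800 epochs),
# built lazily and reused across test files.

.fixtures <- new.env(parent = emptyenv())

tinyCorpus <- function() {
  if (is.null(.fixtures$tiny))
    .fixtures$tiny <- buildCorpus(generatorConfig(
      nTrain = 20, nVal = 5, pairDbSize = 40, composedPoolSize = 15,
      seed = 2))
  .fixtures$tiny
}

scaledCorpus <- function() {
  if (is.null(.fixtures$corpus))
    .fixtures$corpus <- buildCorpus(generatorConfig(
      nTrain = 500, nVal = 50, seed = 42))
  .fixtures$corpus
}

trainedNet <- function() {
  if (is.null(.fixtures$net))
    .fixtures$net <- trainNetwork(buildNetwork(seed = 7), scaledCorpus(),
                                  trainConfig(epochs = 800))
  .fixtures$net
}

# Independent single-peak fit oracle: multi-start quasi-Newton (optim /
# L-BFGS-B) minimising the sum of squares -- a different optimiser from
# the Levenberg-Marquardt implementation under test.
oracleFitSingleError <- function(profile, nStarts = 12, seed = 99) {
  n <- length(profile)
  x <- seq_len(n) - 1
  pmax <- max(profile)
  obj <- function(p) sum((pseudoVoigt(x, p[1], p[2], p[3], p[4]) - profile)^2)
  best <- Inf
  bestPar <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (s in seq_len(nStarts)) {
    p0 <- c(which.max(profile) - 1 + runif(1, -3, 3), pmax * runif(1, 0.6, 1.4),
            runif(1, 2, n / 2), runif(1))
    p0[1] <- min(max(p0[1], 0), n - 1)
    fit <- tryCatch(optim(p0, obj, method = "L-BFGS-B",
                          lower = c(0, 1e-8, 0.8, 0),
                          upper = c(n - 1, 3 * pmax, 2 * n, 1),
                          control = list(maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$value < best) { best <- fit$value; bestPar <- fit$par }
  }
  mod <- pseudoVoigt(x, bestPar[1], bestPar[2], bestPar[3], bestPar[4])
  max(abs(mod - profile)) / pmax
}

# random 1D recovery fixture: peaks separated by >= 1 FWHH, away from
# edges, with additive noise at the requested minimum signal-to-noise
simulateRecovery1D <- function(seed, nPoints = 300, snr = 25) {
  set.seed(seed)
  nP <- sample(2:6, 1)
  repeat {
    f <- runif(nP, 6, 18)
    ctr <- sort(runif(nP, 20, nPoints - 21))
    if (nP == 1 || all(diff(ctr) >= (f[-nP] + f[-1]) / 2)) break
  }
  amp <- runif(nP, 0.4, 1)
  pk <- voigtPeaks(ctr, amp, f, runif(nP))
  sigma <- min(amp) / snr
  list(peaks = pk,
       spectrum = synthSpectrum1D(pk, nPoints, noiseSigma = sigma,
                                  seed = seed + 1))
}

# random 2D recovery fixture: 1-8 separable cross-peaks on a 128 x 128
# grid, pairwise separated by >= 1 FWHH in at least one dimension
simulateRecovery2D <- function(seed, shape = c(128, 128), snr = 25) {
  set.seed(seed)
  nP <- sample(1:8, 1)
  rows <- cols <- fr <- fc <- numeric(0)
  guard <- 0
  while (length(rows) < nP && guard < 500) {
    guard <- guard + 1
    r <- runif(1, 16, shape[1] - 17)
    c <- runif(1, 16, shape[2] - 17)
    f1 <- runif(1, 6, 12)
    f2 <- runif(1, 6, 12)
    ok <- TRUE
    for (j in seq_along(rows)) {
      sepR <- abs(r - rows[j]) / max(f1, fr[j])
      sepC <- abs(c - cols[j]) / max(f2, fc[j])
      if (max(sepR, sepC) < 1.0) { ok <- FALSE; break }
    }
    if (ok) { rows <- c(rows, r); cols <- c(cols, c)
              fr <- c(fr, f1); fc <- c(fc, f2) }
  }
  nP <- length(rows)
  amp <- runif(nP, 0.4, 1)
  pk <- crossPeaks(rows, cols, amp, fr, fc, runif(nP), runif(nP))
  sigma <- min(amp) / snr
  list(peaks = pk,
       spectrum = synthSpectrum2D(pk, shape, noiseSigma = sigma,
                                  seed = seed + 1))
}
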