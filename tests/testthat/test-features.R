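# Normalization, binned sd, spectral entropy, DTW.

test_that("min-max normalization maps to [0,1], preserves order, idempotent", {
  expect_equal(normalizeTrace(c(200, 450, 700)), c(0, 0.5, 1))
  set.seed(1)
  x <- rnorm(500, 450, 40)
  nx <- normalizeTrace(x)
  expect_equal(min(nx), 0)
  expect_equal(max(nx), 1)
  expect_identical(order(x), order(nx))
  expect_equal(normalizeTrace(nx), nx)
  expect_error(normalizeTrace(rep(5, 100)), "constant")
})

test_that("binned sd profile matches the brute-force oracle", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(150:3000, 1)
    nBins <- sample(2:100, 1)
    x <- normalizeTrace(rnorm(n, 450, sample(5:40, 1)))
    prof <- msdProfile(x, nBins)
    expect_equal(sigmaBins(prof), oracleBinSds(x, nBins), tolerance = 1e-12)
    expect_length(sigmaBins(prof), nBins)
    b <- binBounds(prof)
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nBins], n)
    expect_true(all(b$start[-1] == b$end[-nBins]))  # exact partition
  }
})

test_that("binned sd handles constant segments and worked example", {
  x <- c(rep(0.5, 50), 0.1, 0.2, 0.3)
  prof <- msdProfile(x, 2)
  expect_equal(sigmaBins(prof)[1], 0)
  # hand computation, N-1 denominator: sd(0.1, 0.2, 0.3) = 0.1
  prof2 <- msdProfile(c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3), 2)
  expect_equal(sigmaBins(prof2), c(0.1, 0.1), tolerance = 1e-12)
  expect_error(msdProfile(x, 100), "shorter")
})

test_that("spectral entropy hits its analytic extremes", {
  # equal-power spectrum constructed by inverse FFT -> SE exactly 1
  n <- 256L
  N <- n %/% 2L
  spec <- complex(real = rep(0, n))
  set.seed(7)
  ph <- runif(N - 1, 0, 2 * pi)
  spec[2:N] <- complex(modulus = 1, argument = ph)
  spec[N + 1L] <- 1  # Nyquist (real)
  spec[n:(N + 2L)] <- Conj(spec[2:N])
  x <- Re(fft(spec, inverse = TRUE)) / n
  expect_equal(spectralEntropy(x), 1, tolerance = 1e-10)

  # pure tone at a bin frequency -> SE ~ 0
  tone <- sin(2 * pi * 16 * (0:(n - 1)) / n)
  expect_lt(spectralEntropy(tone), 0.01)

  # white noise lands in the upper band
  ses <- vapply(1:100, function(s) {
    set.seed(s)
    spectralEntropy(rnorm(4096))
  }, numeric(1))
  expect_true(all(ses >= 0.9 & ses <= 1.0))
  expect_error(spectralEntropy(rep(3, 64)), "entropy|variation")
  expect_error(spectralEntropy(c(1, 2)), "short")
})

test_that("spectral entropy is invariant to amplitude scaling", {
  set.seed(11)
  x <- rnorm(1024, 0, 3) + sin(2 * pi * 40 * (0:1023) / 1024)
  expect_equal(spectralEntropy(x), spectralEntropy(17.3 * x),
               tolerance = 1e-12)
  se <- instantaneousSE(x * 5)
  se2 <- instantaneousSE(x)
  expect_equal(seValues(se), seValues(se2), tolerance = 1e-12)
})

test_that("instantaneous SE framing arithmetic and bounds hold", {
  set.seed(3)
  for (len in c(128, 300, 1000, 2831)) {
    x <- rnorm(len, 450, 12)
    se <- instantaneousSE(x)
    expect_length(seValues(se), (len - 128) %/% 64 + 1)
    expect_true(all(seValues(se) >= 0 & seValues(se) <= 1))
    expect_true(all(frameFracs(se) >= 0 & frameFracs(se) <= 1))
  }
  expect_error(instantaneousSE(rnorm(100)), "shorter")
})

test_that("plateau frames score lower SE than stepped noisy frames", {
  # constructed two-regime trace: stepped broadband first half, quiet
  # slowly wandering plateau second half
  set.seed(21)
  levels <- rep(450 + rnorm(8, 0, 30), each = 200)
  noisy <- levels + rnorm(1600, 0, 12)
  plateau <- 450 + poreDelay:::.smoothWander(1600, 1)
  se <- instantaneousSE(c(noisy, plateau))
  fr <- frameFracs(se)
  inPlateau <- fr > 0.55 & fr < 0.95   # frames fully inside the plateau
  inNoise <- fr > 0.05 & fr < 0.45
  expect_gt(min(seValues(se)[inNoise]), max(seValues(se)[inPlateau]))
})

test_that("stationary noise has no systematic SE trend across frames", {
  slopes <- vapply(1:50, function(s) {
    set.seed(s)
    se <- instantaneousSE(rnorm(3000, 450, 12))
    coef(lm(seValues(se) ~ frameFracs(se)))[2]
  }, numeric(1))
  ci <- mean(slopes) + c(-1, 1) * qt(0.975, 49) * sd(slopes) / sqrt(50)
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("DTW distance matches exhaustive path enumeration", {
  expect_equal(dtwDistance(c(0, 0, 1), c(0, 1)), 0)
  set.seed(9)
  for (i in 1:200) {
    a <- round(runif(sample(1:5, 1), -2, 2), 2)
    b <- round(runif(sample(1:5, 1), -2, 2), 2)
    expect_equal(dtwDistance(a, b), oracleDtw(a, b), tolerance = 1e-12)
    expect_equal(dtwDistance(a, b), dtwDistance(b, a), tolerance = 1e-12)
  }
  x <- rnorm(50)
  expect_equal(dtwDistance(x, x), 0)
  expect_error(dtwDistance(numeric(0), 1), "empty")
})
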