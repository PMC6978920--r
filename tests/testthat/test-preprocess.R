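test_that("ROI extraction averages voxels within each atlas label", {
  atlas <- array(0L, c(3, 3, 2))
  atlas[1, 1, 1] <- 7L; atlas[2, 1, 1] <- 7L   # two voxels, label 7
  atlas[3, 3, 2] <- 2L                         # one voxel, label 2
  vol <- array(0, c(3, 3, 2, 4))
  vol[1, 1, 1, ] <- 1; vol[2, 1, 1, ] <- 3     # mean 2 at every t
  vol[3, 3, 2, ] <- 3
  x <- extractRoiSeries(vol, atlas, dt = 2)
  expect_equal(unname(signals(x)["ROI2", ]), rep(3, 4))
  expect_equal(unname(signals(x)["ROI7", ]), rep(2, 4))
  expect_error(extractRoiSeries(vol, atlas, labels = 99), "absent")
})

test_that("detrending removes quadratic trends and normalizes variance", {
  tn <- 50; tt <- seq_len(tn) / tn
  quad <- 3 + 2 * tt - 5 * tt^2
  sig <- rbind(quad, quad + sin(20 * tt))
  x <- RoiTimeSeriesSet(sig, roiLabels = c("A", "B"), dt = 2)
  expect_warning(d <- detrendNormalize(x), "zero-variance")
  expect_equal(unname(signals(d)[1, ]), rep(0, tn))  # pure trend -> zeros
  expect_equal(sd(signals(d)[2, ]), 1, tolerance = 1e-12)
  # cubic component survives as its least-squares residual
  cub <- tt^3
  X <- cbind(1, tt, tt^2)
  expected <- as.numeric(cub - X %*% solve(crossprod(X), crossprod(X, cub)))
  x3 <- RoiTimeSeriesSet(rbind(cub, cub), roiLabels = c("A", "B"), dt = 2)
  d3 <- detrendNormalize(x3, rescale = FALSE)
  expect_equal(unname(signals(d3)[1, ]), expected, tolerance = 1e-10)
})

test_that("nuisance regression is an orthogonal projection", {
  set.seed(4)
  tn <- 100
  conf <- matrix(rnorm(3 * tn), 3, tn)
  sig <- rbind(conf[1, ], rnorm(tn))
  x <- RoiTimeSeriesSet(sig, roiLabels = c("A", "B"), dt = 2)
  r <- regressNuisance(x, conf)
  # a series equal to a confound is annihilated
  expect_lt(sqrt(sum(signals(r)[1, ]^2)) / sqrt(sum(sig[1, ]^2)), 1e-10)
  # residuals orthogonal to every confound
  dots <- abs(signals(r) %*% t(conf) /
                (sqrt(rowSums(signals(r)^2)) %o% sqrt(rowSums(conf^2))))
  expect_lt(max(dots), 1e-8)
  # a signal orthogonal to intercept + confound passes through unchanged
  c2 <- conf[2, ] - mean(conf[2, ])
  v <- rnorm(tn); v <- v - mean(v)
  s2 <- v - c2 * sum(v * c2) / sum(c2^2)
  x2 <- RoiTimeSeriesSet(rbind(s2), roiLabels = "A", dt = 2)
  r2 <- regressNuisance(x2, rbind(c2))
  expect_equal(unname(signals(r2)[1, ]), s2, tolerance = 1e-8)
  # duplicated confound row: warning, same residual as single copy
  expect_warning(rd <- regressNuisance(x, conf[c(1, 1, 2, 3), ]),
                 "rank-deficient")
  expect_equal(signals(rd), signals(r), tolerance = 1e-8)
})

test_that("band-pass filter honours its gain contract", {
  tn <- 600; dt <- 2
  tsec <- (seq_len(tn) - 1) * dt
  mk <- function(f) RoiTimeSeriesSet(rbind(sin(2 * pi * f * tsec)), dt = dt)
  amp <- function(x, f) {
    sp <- Mod(fft(signals(x)[1, ]))
    sp[round(f * tn * dt) + 1]
  }
  pass <- bandpassFilter(mk(0.05))
  expect_gt(amp(pass, 0.05) / amp(mk(0.05), 0.05), 0.9)
  expect_lt(amp(pass, 0.05) / amp(mk(0.05), 0.05), 1.1)
  stopb <- bandpassFilter(mk(0.2))
  expect_lt(amp(stopb, 0.2) / amp(mk(0.2), 0.2), 0.1)
  # DC offset attenuated to below 1% of its input level
  dc <- bandpassFilter(RoiTimeSeriesSet(rbind(rep(5, tn)), dt = dt))
  expect_lt(abs(mean(signals(dc)[1, ])) / 5, 0.01)
  # invalid band
  expect_error(bandpassFilter(mk(0.05), low = 0.01, high = 0.3), "Nyquist")
})

test_that("the conditioning chain is near-idempotent in the passband", {
  tn <- 600; dt <- 2
  tsec <- (seq_len(tn) - 1) * dt
  x <- RoiTimeSeriesSet(rbind(sin(2 * pi * 0.05 * tsec)), dt = dt)
  once <- bandpassFilter(x)
  twice <- bandpassFilter(once)
  mid <- 100:500  # ignore filter edge effects
  a1 <- sd(signals(once)[1, mid]); a2 <- sd(signals(twice)[1, mid])
  expect_lt(abs(a2 - a1) / a1, 0.05)
})
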