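test_that("within-group z-scoring removes between-group offsets", {
  set.seed(5)
  g <- rep(c("young", "aged"), each = 10)
  pattern <- rnorm(10)
  x <- c(pattern + 100, pattern - 50)     # same shape, huge offsets
  z <- withinGroupZscore(x, g)
  for (gg in unique(g)) {
    expect_equal(mean(z[g == gg]), 0, tolerance = 1e-12)
    expect_equal(sd(z[g == gg]), 1, tolerance = 1e-12)
  }
  expect_equal(z[g == "young"], z[g == "aged"])  # location invariance
  # Simpson's-paradox construction: between-group offsets only
  y <- c(rnorm(10, 100), rnorm(10, -50))
  x2 <- c(rnorm(10, 80), rnorm(10, -40))
  rawR <- cor(x2, y)
  zR <- cor(withinGroupZscore(x2, g), withinGroupZscore(y, g))
  expect_gt(abs(rawR), 0.9)
  expect_lt(abs(zR), 0.7)  # no within-group relation left to find
  expect_warning(withinGroupZscore(1:3, c("a", "a", "b")), "<2 members")
})

test_that("pooled correlation matches the covariance-formula oracle", {
  x <- c(0.2, 1.4, -0.7, 2.2, 0.9, -1.1, 0.3, 1.8, -0.2, 0.5)
  y <- c(0.7, 1.1, -0.9, 1.9, 0.2, -1.4, 0.8, 1.2, 0.1, 0.4)
  n <- 10
  Rhand <- (sum(x * y) / n - mean(x) * mean(y)) /
    sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  got <- pooledCorrelation(x, y)
  expect_equal(got$R, Rhand, tolerance = 1e-12)
  expect_equal(got$F, Rhand^2 * 8 / (1 - Rhand^2), tolerance = 1e-12)
  expect_equal(got$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_equal(pooledCorrelation(x, x)$R, 1)
  # independent pairs rarely exceed |R| = 0.1 at n = 1000
  set.seed(8)
  hits <- replicate(50, abs(pooledCorrelation(rnorm(1000), rnorm(1000))$R))
  expect_lt(mean(hits > 0.1), 0.1)
})

test_that("mixed ANOVA reproduces a hand-computed SS decomposition", {
  # balanced 2-group x 3-session design, 4 subjects per group
  set.seed(12)
  d <- expand.grid(subject = paste0("s", 1:8), session = paste0("t", 1:3))
  d$group <- rep(rep(c("young", "aged"), each = 4), 3)
  d$value <- rnorm(24) + 2 * (d$group == "aged") +
    0.8 * (d$session == "t3") * (d$group == "aged")
  got <- mixedAnova(d)

  # explicit classical decomposition
  a <- 2; s <- 3; n <- 4
  mu <- mean(d$value)
  mG <- tapply(d$value, d$group, mean)
  mS <- tapply(d$value, d$session, mean)
  mGS <- tapply(d$value, list(d$group, d$session), mean)
  mSub <- tapply(d$value, d$subject, mean)
  subGroup <- tapply(as.character(d$group), d$subject, `[`, 1)
  ssGroup <- s * n * sum((mG - mu)^2)
  ssSubj <- s * sum((mSub - mG[subGroup])^2)
  ssSess <- a * n * sum((mS - mu)^2)
  ssInt <- n * sum((t(mGS) - outer(mS, mG, `+`) + mu)^2)
  ssTot <- sum((d$value - mu)^2)
  ssErr <- ssTot - ssGroup - ssSubj - ssSess - ssInt
  Fgroup <- (ssGroup / (a - 1)) / (ssSubj / (a * (n - 1)))
  Fsess <- (ssSess / (s - 1)) / (ssErr / (a * (n - 1) * (s - 1)))
  Fint <- (ssInt / ((a - 1) * (s - 1))) / (ssErr / (a * (n - 1) * (s - 1)))
  expect_equal(got$F, c(Fgroup, Fsess, Fint), tolerance = 1e-10)
  expect_equal(got$df1, c(1, 2, 2))
  expect_equal(got$df2, c(6, 12, 12))

  # identical cell means (centered within group x session) -> all F = 0
  d0 <- d; d0$value <- d$value - ave(d$value, d$group, d$session)
  g0 <- mixedAnova(d0)
  expect_equal(g0$F, c(0, 0, 0), tolerance = 1e-10)

  # affine rescaling leaves F untouched
  d2 <- d; d2$value <- 3.7 * d2$value - 11
  expect_equal(mixedAnova(d2)$F, got$F, tolerance = 1e-8)

  # unbalanced designs are an explicit error
  expect_error(mixedAnova(d[-1, ]), "unbalanced")
})

test_that("permutation p values track parametric ones under normality", {
  set.seed(3)
  d <- expand.grid(subject = paste0("s", 1:10), session = paste0("t", 1:3))
  d$group <- rep(rep(c("young", "aged"), each = 5), 3)
  d$value <- rnorm(30) + 1.2 * (d$session == "t3")
  got <- mixedAnova(d, nPerm = 400, seed = 99)
  expect_true(all(abs(got$pPerm - got$p) < 0.12))
})

test_that("per-k comparison finds planted high-k bands and only those", {
  mkCurves <- function(eff) {
    grid <- expand.grid(subject = paste0("s", 1:10),
                        session = 1:3, k = 5:30)
    grid$group <- ifelse(grid$subject %in% paste0("s", 1:5),
                         "young", "aged")
    set.seed(17)
    base <- 0.8 - grid$k / 50
    bump <- eff * (grid$k > 20) * (grid$group == "aged") *
      (grid$session - 1) / 2
    grid$phi <- base + bump + rnorm(nrow(grid), sd = 0.03)
    grid$defined <- TRUE
    grid
  }
  res <- richclubGroupComparison(mkCurves(0.3))
  int <- res$perK[res$perK$effect == "group:session", ]
  expect_true(all(int$significant[int$k > 21]))
  # at most chance-level detections below the planted band
  expect_lt(mean(int$significant[int$k <= 15]), 0.2)
  band <- res$bands[["group:session"]]
  expect_true(any(band$kFrom >= 21))
  # identical curves across groups/sessions -> empty significant set
  flat <- mkCurves(0)
  flat$phi <- 0.5
  resFlat <- richclubGroupComparison(flat)
  expect_equal(sum(resFlat$perK$significant), 0L)
  # per-k F equals mixedAnova applied manually at that k
  d22 <- mkCurves(0.3); d22 <- d22[d22$k == 22, ]
  d22$value <- d22$phi
  manual <- mixedAnova(d22)
  expect_equal(res$perK$F[res$perK$k == 22], manual$F, tolerance = 1e-10)
  # undefined cells flag the whole k
  holey <- mkCurves(0.3)
  holey$defined[holey$k == 25 & holey$subject == "s1"] <- FALSE
  resH <- richclubGroupComparison(holey)
  expect_true(all(is.na(resH$perK$F[resH$perK$k == 25])))
})

test_that("per-k type-I rate is near alpha under the null", {
  # reduced calibration: fewer replicates than the acceptance run, same
  # machinery
  set.seed(41)
  nRep <- 200
  hits <- 0
  for (b in seq_len(nRep)) {
    grid <- expand.grid(subject = paste0("s", 1:8), session = 1:3, k = 10)
    grid$group <- ifelse(grid$subject %in% paste0("s", 1:4),
                         "young", "aged")
    subjEff <- rnorm(8, sd = 0.05)
    grid$phi <- 0.5 + subjEff[match(grid$subject, paste0("s", 1:8))] +
      rnorm(nrow(grid), sd = 0.05)
    grid$defined <- TRUE
    res <- richclubGroupComparison(grid)
    hits <- hits + res$perK$significant[res$perK$effect == "group:session"]
  }
  expect_gt(hits / nRep, 0.02)
  expect_lt(hits / nRep, 0.09)
})
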