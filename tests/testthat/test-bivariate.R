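## small bivariate simulation used by several tests
smallBivFixture <- function(seed = 7, rg = 0.5, overlap = 0.5, nDams = 250,
                            off = 400) {
  ped <- simulatePedigree(nSires = 15, nDams = nDams, nGenerations = 3,
                          offspringPerGeneration = off, seed = seed)
  G <- matrix(c(4, rg * sqrt(12), rg * sqrt(12), 3), 2)
  HY <- matrix(c(2, 0.5, 0.5, 1.5), 2)
  R <- matrix(c(10, 2, 2, 12), 2)
  truth <- simTruth(G = G, HY = HY, R = R, nHY = 20)
  sim <- simulateBivariate(ped, truth, trait = "FSTCx", mu = c(20, 60),
                           overlapFraction = overlap, seed = seed + 1)
  spec <- new("ModelSpec", trait = "FSTCx", stage = "heifer",
              fixedEffects = "mu", randomEffects = c("HY", "a"))
  list(ped = ped, ainv = aInverse(ped), sim = sim, spec = spec, truth = truth)
}

test_that("stacking pairs double-recorded animals and flags disconnection", {
  fx <- smallBivFixture()
  bd <- stackBivariate(fx$sim$heifer, fx$sim$cow, fx$ped)
  expect_equal(nrow(bd@pairs),
               length(intersect(fx$sim$heifer@animalId, fx$sim$cow@animalId)))
  expect_equal(length(bd@ds1@y) + length(bd@ds2@y),
               length(fx$sim$heifer@y) + length(fx$sim$cow@y))

  # genetically disconnected record sets are rejected
  pedU <- pedigree(c("U1", "U2", "V1", "V2"), rep("0", 4), rep("0", 4))
  mk <- function(ids, y) new("TraitDataset", trait = "T", stage = "heifer",
                             animalId = ids, y = y,
                             fixed = data.frame(mu = rep("1", length(y))),
                             hy = rep("h1", length(y)), ss = character(0))
  expect_error(stackBivariate(mk(c("U1", "U2"), c(1, 2)),
                              mk(c("V1", "V2"), c(3, 4)), pedU),
               "disconnected")
})

test_that("the stacked restricted likelihood matches a dense two-trait oracle", {
  fx <- smallBivFixture(seed = 17, nDams = 40, off = 50)
  bd <- stackBivariate(fx$sim$heifer, fx$sim$cow, fx$ped)
  ctx <- fertREML:::.bivContext(bd, fx$spec, fx$spec, fx$ainv, minOverlap = 3)
  th <- fertREML:::.bivPack(fx$truth$G * 0.9, fx$truth$HY * 1.2, NULL,
                            fx$truth$R * 1.1, ctx$estimR12)
  ev <- fertREML:::.bivEval(ctx, th)

  B <- fertREML:::.bivUnpack(th, FALSE, ctx$estimR12)
  A <- aMatrix(fx$ped)@values
  ids <- rownames(A)
  n1 <- ctx$n1; n2 <- ctx$n2; n <- n1 + n2
  ZaT <- function(aid) 1 * outer(aid, ids, "==")
  Za <- rbind(cbind(ZaT(bd@ds1@animalId), matrix(0, n1, length(ids))),
              cbind(matrix(0, n2, length(ids)), ZaT(bd@ds2@animalId)))
  hyLev <- sort(unique(c(bd@ds1@hy, bd@ds2@hy)))
  ZhT <- function(h) 1 * outer(h, hyLev, "==")
  Zh <- rbind(cbind(ZhT(bd@ds1@hy), matrix(0, n1, length(hyLev))),
              cbind(matrix(0, n2, length(hyLev)), ZhT(bd@ds2@hy)))
  Rm <- matrix(0, n, n)
  diag(Rm) <- c(rep(B$R[1, 1], n1), rep(B$R[2, 2], n2))
  for (r in seq_len(nrow(ctx$pairs))) {
    i <- ctx$pairs[r, 1]; j <- n1 + ctx$pairs[r, 2]
    Rm[i, j] <- Rm[j, i] <- B$R[1, 2]
  }
  V <- Za %*% kronecker(B$G, A) %*% t(Za) +
    Zh %*% kronecker(B$HY, diag(length(hyLev))) %*% t(Zh) + Rm
  X <- as.matrix(ctx$X)
  Vi <- solve(V); XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  dense <- as.numeric(determinant(V)$modulus + determinant(XVX)$modulus +
                        t(ctx$y) %*% P %*% ctx$y) +
    (n - ncol(X)) * log(2 * pi)
  expect_equal(ev$n2ll, dense, tolerance = 1e-9)
})

test_that("identical records at both stages drive the genetic correlation to one", {
  fx <- smallBivFixture(seed = 27)
  h <- fx$sim$heifer
  both <- h@animalId %in% fx$sim$cow@animalId
  dsH <- subsetTraitDataset(h, both)
  dsC <- dsH; dsC@stage <- "cow"
  bd <- stackBivariate(dsH, dsC, fx$ped)
  fit <- estimateBivariateReml(bd, fx$spec, fx$spec, fx$ainv,
                               opts = remlOptions(maxIter = 40))
  expect_gt(fit@rg, 0.95)
})

test_that("bivariate REML recovers a moderate genetic correlation", {
  fx <- smallBivFixture(seed = 37, rg = 0.5, nDams = 300, off = 500)
  bd <- stackBivariate(fx$sim$heifer, fx$sim$cow, fx$ped)
  fit <- estimateBivariateReml(bd, fx$spec, fx$spec, fx$ainv)
  expect_true(abs(fit@rg - 0.5) < max(3 * fit@rgSe, 0.35))
  # blocks stay PSD along the whole iteration trace
  for (r in seq_len(nrow(fit@trace))) {
    G <- matrix(c(fit@trace[r, "G_11"], fit@trace[r, "G_12"],
                  fit@trace[r, "G_12"], fit@trace[r, "G_22"]), 2)
    expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  # monotone likelihood
  expect_true(all(diff(fit@trace[, "neg2logLik"]) <= 1e-9))
})

test_that("swapping trait order transposes the estimates but keeps rg", {
  fx <- smallBivFixture(seed = 47, nDams = 120, off = 200)
  bd12 <- stackBivariate(fx$sim$heifer, fx$sim$cow, fx$ped)
  bd21 <- stackBivariate(fx$sim$cow, fx$sim$heifer, fx$ped)
  st <- list(G = fx$truth$G, HY = fx$truth$HY, R = fx$truth$R)
  stT <- lapply(st, function(M) M[2:1, 2:1])
  f12 <- estimateBivariateReml(bd12, fx$spec, fx$spec, fx$ainv, start = st)
  f21 <- estimateBivariateReml(bd21, fx$spec, fx$spec, fx$ainv, start = stT)
  expect_equal(f12@rg, f21@rg, tolerance = 0.02)
  # the two fits walk different paths over a flat surface; estimates agree
  # to optimization precision, not machine precision
  expect_equal(f12@G[1, 1], f21@G[2, 2], tolerance = 0.3)
  expect_equal(f12@G[1, 2], f21@G[1, 2], tolerance = 0.3)
  # the attained restricted likelihoods must agree closely
  expect_lt(abs(f12@logLik - f21@logLik), 1)
})

test_that("too little stage overlap fixes the residual covariance at zero", {
  fx <- smallBivFixture(seed = 57, overlap = 0.05, nDams = 120, off = 200)
  bd <- stackBivariate(fx$sim$heifer, fx$sim$cow, fx$ped)
  fit <- estimateBivariateReml(bd, fx$spec, fx$spec, fx$ainv,
                               minOverlap = nrow(bd@pairs) + 1,
                               opts = remlOptions(maxIter = 15))
  expect_true("residual-cov-fixed-at-0" %in% fit@flags)
  expect_equal(fit@R[1, 2], 0)
})

test_that("merging stages yields one pooled trait with stage as fixed effect", {
  fx <- smallBivFixture(seed = 67)
  m <- mergeTraits(fx$sim$heifer, fx$sim$cow)
  expect_equal(length(m@y), length(fx$sim$heifer@y) + length(fx$sim$cow@y))
  expect_true("stage" %in% colnames(m@fixed))
  expect_identical(m@stage, "all")
  spec <- new("ModelSpec", trait = "FSTCx", stage = "all",
              fixedEffects = c("mu", "stage"), randomEffects = c("HY", "a"))
  fit <- estimateReml(m, spec, fx$ainv)
  expect_true(is(fit, "VarianceComponents"))
  expect_gt(fit@h2, 0)
})
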