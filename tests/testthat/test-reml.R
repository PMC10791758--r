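## dense-matrix restricted likelihood: the independent oracle used throughout
denseRestrictedLoglik <- function(theta, ds, spec, ped) {
  A <- aMatrix(ped)@values
  ids <- rownames(A)
  n <- length(ds@y)
  V <- theta[["e"]] * diag(n)
  if ("a" %in% spec@randomEffects) {
    Za <- 1 * outer(ds@animalId, ids, "==")
    V <- V + theta[["a"]] * Za %*% A %*% t(Za)
  }
  if ("HY" %in% spec@randomEffects) {
    lev <- sort(unique(ds@hy))
    Zh <- 1 * outer(ds@hy, lev, "==")
    V <- V + theta[["hy"]] * Zh %*% t(Zh)
  }
  X <- matrix(1, n, 1)
  for (eff in colnames(ds@fixed)) {
    lev <- sort(unique(ds@fixed[[eff]]))
    if (length(lev) > 1)
      X <- cbind(X, 1 * outer(ds@fixed[[eff]], lev[-1], "=="))
  }
  p <- ncol(X)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  -0.5 * (as.numeric(determinant(V)$modulus + determinant(XVX)$modulus +
                       t(ds@y) %*% P %*% ds@y) + (n - p) * log(2 * pi))
}

test_that("sparse restricted likelihood equals the dense-matrix evaluation", {
  set.seed(91)
  ped <- simulatePedigree(nSires = 4, nDams = 8, nGenerations = 3,
                          offspringPerGeneration = 10, seed = 92)
  truth <- simTruth(mu = 50, sigma2 = c(a = 4, hy = 2, e = 10), nHY = 3,
                    nFixedLevels = 2, fixedSd = 2)
  sim <- simulateTraitDataset(ped, truth, phenotyped = pedigreeIds(ped),
                              seed = 93)
  spec <- sim$dataset; spec <- new("ModelSpec", trait = "AFC", stage = "heifer",
                                   fixedEffects = "RYM",
                                   randomEffects = c("HY", "a"))
  ainv <- aInverse(ped)
  for (theta in list(c(hy = 1, a = 2, e = 8), c(hy = 3, a = 5, e = 12))) {
    expect_equal(remlLoglik(theta, sim$dataset, spec, ainv),
                 denseRestrictedLoglik(theta, sim$dataset, spec, ped),
                 tolerance = 1e-9)
  }
  # likelihood ordering of two points agrees with the dense computation
  l1 <- remlLoglik(c(hy = 1, a = 2, e = 8), sim$dataset, spec, ainv)
  l2 <- remlLoglik(c(hy = 3, a = 5, e = 12), sim$dataset, spec, ainv)
  d1 <- denseRestrictedLoglik(c(hy = 1, a = 2, e = 8), sim$dataset, spec, ped)
  d2 <- denseRestrictedLoglik(c(hy = 3, a = 5, e = 12), sim$dataset, spec, ped)
  expect_equal(l1 > l2, d1 > d2)
})

test_that("restricted likelihood of the mean-only model matches the closed form", {
  set.seed(94)
  y <- rnorm(30, 10, 2)
  ds <- new("TraitDataset", trait = "GL", stage = "cow",
            animalId = sprintf("C%02d", 1:30), y = y,
            fixed = data.frame(row.names = seq_len(30)),
            hy = character(0), ss = character(0))
  spec <- new("ModelSpec", trait = "GL", stage = "cow",
              fixedEffects = character(0), randomEffects = character(0))
  ped <- pedigree(sprintf("C%02d", 1:30), rep("0", 30), rep("0", 30))
  s2 <- 3.7
  closed <- -0.5 * (30 * log(s2) + log(30 / s2) +
                      sum((y - mean(y))^2) / s2 + 29 * log(2 * pi))
  expect_equal(remlLoglik(c(e = s2), ds, spec, aInverse(ped)), closed,
               tolerance = 1e-10)
})

test_that("REML is invariant to fixed-effect relabelling and record order", {
  fx <- smallRemlFixture(seed = 95, n = 150)
  ds <- fx$sim$dataset
  theta <- c(hy = 1.5, a = 3, e = 9)
  base <- remlLoglik(theta, ds, fx$spec, fx$ainv)

  # relabel the fixed-effect levels (reparameterization)
  ds2 <- ds
  ds2@fixed$RYM <- paste0("zz", ds2@fixed$RYM)
  expect_equal(remlLoglik(theta, ds2, fx$spec, fx$ainv), base, tolerance = 1e-9)

  # permute the records
  o <- sample(length(ds@y))
  ds3 <- subsetTraitDataset(ds, o)
  expect_equal(remlLoglik(theta, ds3, fx$spec, fx$ainv), base, tolerance = 1e-9)

  sol1 <- solveBlup(buildMME(ds, fx$spec, fx$ainv, theta = theta))
  sol3 <- solveBlup(buildMME(ds3, fx$spec, fx$ainv, theta = theta))
  expect_equal(sol1$ebv, sol3$ebv, tolerance = 1e-8)
})

test_that("mixed-model equations shrink and reduce correctly", {
  # three unrelated animals, one record each, mean + animal only:
  # MME equals OLS augmented by I * lambda
  ped <- pedigree(c("X", "Y", "Z"), rep("0", 3), rep("0", 3))
  ds <- new("TraitDataset", trait = "GL", stage = "cow",
            animalId = c("X", "Y", "Z"), y = c(1, 2, 6),
            fixed = data.frame(row.names = 1:3), hy = character(0),
            ss = character(0))
  spec <- new("ModelSpec", trait = "GL", stage = "cow",
              fixedEffects = character(0), randomEffects = "a")
  ainv <- aInverse(ped)
  lam <- 2.5
  mme <- buildMME(ds, spec, ainv, theta = c(a = 1, e = lam))
  C <- as.matrix(mme$C)
  expect_equal(C, rbind(c(3, 1, 1, 1),
                        c(1, 1 + lam, 0, 0),
                        c(1, 0, 1 + lam, 0),
                        c(1, 0, 0, 1 + lam)), ignore_attr = TRUE)
  expect_equal(mme$rhs, c(9, 1, 2, 6), ignore_attr = TRUE)

  # shrinkage limit: lambda -> infinity drives all EBVs to zero
  huge <- solveBlup(buildMME(ds, spec, ainv, theta = c(a = 1, e = 1e10)))
  expect_lt(max(abs(huge$ebv)), 1e-6)

  # solution matches a dense solve of the same system
  sol <- solveBlup(mme)
  dense <- solve(C, mme$rhs)
  expect_equal(unname(sol$solution), unname(dense), tolerance = 1e-10)
  expect_lt(sol$orthogonality, 1e-8)
})

test_that("balanced fixed one-way design with huge shrinkage returns group means", {
  set.seed(96)
  grp <- rep(c("g1", "g2", "g3"), each = 10)
  y <- rnorm(30, c(rep(5, 10), rep(8, 10), rep(11, 10)))
  ids <- sprintf("A%02d", 1:30)
  ped <- pedigree(ids, rep("0", 30), rep("0", 30))
  ds <- new("TraitDataset", trait = "GL", stage = "cow", animalId = ids,
            y = y, fixed = data.frame(grp = grp, stringsAsFactors = FALSE),
            hy = character(0), ss = character(0))
  spec <- new("ModelSpec", trait = "GL", stage = "cow", fixedEffects = "grp",
              randomEffects = "a")
  sol <- solveBlup(buildMME(ds, spec, aInverse(ped), theta = c(a = 1, e = 1e9)))
  fitted <- sol$fixed[1] + c(0, sol$fixed[2], sol$fixed[3])
  expect_equal(unname(fitted), as.numeric(tapply(y, grp, mean)),
               tolerance = 1e-5)
})

test_that("a parent with many high-phenotype offspring gets a positive EBV", {
  set.seed(97)
  n <- 40
  kids <- sprintf("K%02d", 1:n)
  ped <- pedigree(c("SIRE", "OTHER", kids),
                  c("0", "0", rep(c("SIRE", "OTHER"), each = n / 2)),
                  rep("0", n + 2))
  y <- c(rnorm(n / 2, 12), rnorm(n / 2, 8))  # SIRE kids higher
  ds <- new("TraitDataset", trait = "GL", stage = "cow", animalId = kids,
            y = y, fixed = data.frame(row.names = seq_len(n)),
            hy = character(0), ss = character(0))
  spec <- new("ModelSpec", trait = "GL", stage = "cow",
              fixedEffects = character(0), randomEffects = "a")
  sol <- solveBlup(buildMME(ds, spec, aInverse(ped), theta = c(a = 2, e = 2)))
  expect_gt(sol$ebv[["SIRE"]], 0)
  expect_gt(sol$ebv[["SIRE"]], sol$ebv[["OTHER"]])
})

test_that("balanced one-way random design reproduces the ANOVA estimators", {
  set.seed(98)
  ngrp <- 20; m <- 8
  hy <- rep(sprintf("H%02d", 1:ngrp), each = m)
  y <- rep(rnorm(ngrp, sd = 2), each = m) + rnorm(ngrp * m, sd = 3)
  ids <- sprintf("A%03d", seq_along(y))
  ped <- pedigree(ids, rep("0", length(y)), rep("0", length(y)))
  ds <- new("TraitDataset", trait = "SIM", stage = "cow", animalId = ids, y = y,
            fixed = data.frame(row.names = seq_along(y)), hy = hy,
            ss = character(0))
  spec <- new("ModelSpec", trait = "SIM", stage = "cow",
              fixedEffects = character(0), randomEffects = "HY")
  fit <- estimateReml(ds, spec, aInverse(ped))
  aov <- anova(lm(y ~ hy))
  msb <- aov$`Mean Sq`[1]; msw <- aov$`Mean Sq`[2]
  expect_equal(fit@components[["e"]], msw, tolerance = 1e-3)
  expect_equal(fit@components[["hy"]], (msb - msw) / m, tolerance = 1e-3)
})

test_that("the AI iteration is monotone and beats a likelihood grid on tiny data", {
  fx <- smallRemlFixture(seed = 101, n = 80)
  ds <- subsetTraitDataset(fx$sim$dataset, seq_len(min(25, length(fx$sim$dataset@y))))
  spec <- new("ModelSpec", trait = "AFC", stage = "heifer",
              fixedEffects = character(0), randomEffects = "a")
  ds@fixed <- data.frame(row.names = seq_along(ds@y))
  fit <- estimateReml(ds, spec, fx$ainv)
  expect_true(all(diff(fit@trace[, "neg2logLik"]) <= 1e-9))
  varP <- var(ds@y)
  grid <- expand.grid(a = seq(0.05, 2, length.out = 10) * varP,
                      e = seq(0.05, 2, length.out = 10) * varP)
  gl <- apply(grid, 1, function(g)
    remlLoglik(c(a = g[["a"]], e = g[["e"]]), ds, spec, fx$ainv))
  expect_gte(fit@logLik, max(gl) - 1e-6)
})

test_that("data simulated without additive variance estimates near zero", {
  set.seed(103)
  ped <- simulatePedigree(nSires = 25, nDams = 600, nGenerations = 2,
                          offspringPerGeneration = 1200, seed = 104)
  truth <- simTruth(mu = 2, sigma2 = c(a = 0, hy = 0.12, e = 2.14), nHY = 12,
                    nFixedLevels = 2, fixedSd = 0.1)
  sim <- simulateTraitDataset(ped, truth, seed = 105)
  fit <- estimateReml(sim$dataset,
                      new("ModelSpec", trait = "SIM", stage = "cow",
                          fixedEffects = "RYM", randomEffects = c("HY", "a")),
                      aInverse(ped))
  expect_lt(fit@h2, 0.05)
  # the floor flag fires exactly when the component sits at its floor
  floorVal <- 1e-8 * var(sim$dataset@y)
  expect_equal(any(grepl("floored:a", fit@flags)),
               fit@components[["a"]] <= floorVal * (1 + 1e-6))
})

test_that("heritability ratios and delta-method errors behave", {
  expect_equal(unname(heritability(c(a = 109.14, hy = 446.55, e = 8690.96))["h2"]),
               109.14 / (109.14 + 446.55 + 8690.96))
  expect_equal(unname(heritability(c(a = 5, e = 0))["h2"]), 1)
  expect_error(heritability(c(a = 0, e = 0)), "undefined")
  # delta-method SE shrinks with shrinking component uncertainty
  V1 <- diag(c(4, 4, 4)); dimnames(V1) <- list(c("a", "hy", "e"), c("a", "hy", "e"))
  V2 <- V1 / 100
  th <- c(a = 10, hy = 20, e = 70)
  expect_gt(heritability(th, V1)[["se"]], heritability(th, V2)[["se"]])
})
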