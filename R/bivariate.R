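## ---- two-trait (heifer/cow) REML -------------------------------------------

#' Stacked data for a bivariate heifer/cow analysis
#'
#' @slot ds1,ds2 the stage-specific \linkS4class{TraitDataset}s (trait 1 =
#'   heifer, trait 2 = cow by convention).
#' @slot pairs integer matrix (2 columns) pairing record indices of animals
#'   measured at both stages; residual covariance is identified only through
#'   these.
#' @export
setClass("BivariateData",
  representation(ds1 = "TraitDataset", ds2 = "TraitDataset", pairs = "matrix"))

setMethod("show", "BivariateData", function(object) {
  cat(sprintf("BivariateData %s: %d heifer + %d cow records, %d animals with both\n",
              object@ds1@trait, length(object@ds1@y), length(object@ds2@y),
              nrow(object@pairs)))
})

#' Stack two stage datasets for bivariate REML
#'
#' Builds the block design (fixed effects and random-effect incidence per
#' trait) and pairs the records of animals measured at both stages. Errors
#' when the two record sets are genetically disconnected (no shared animals
#' and no shared ancestors), since the genetic correlation is then
#' unidentifiable.
#'
#' @param ds1,ds2 \linkS4class{TraitDataset}s sharing one pedigree
#'   (conventionally heifer and cow stages of one trait).
#' @param ped the shared \linkS4class{Pedigree}.
#' @return a \linkS4class{BivariateData}.
#' @export
stackBivariate <- function(ds1, ds2, ped) {
  stopifnot(is(ds1, "TraitDataset"), is(ds2, "TraitDataset"), is(ped, "Pedigree"))
  if (!all(c(ds1@animalId, ds2@animalId) %in% pedigreeIds(ped)))
    stop("all recorded animals must be in the pedigree")
  common <- intersect(ds1@animalId, ds2@animalId)
  if (!length(common)) {
    c1 <- .ancestorClosure(ped, match(unique(ds1@animalId), ped@id))
    c2 <- .ancestorClosure(ped, match(unique(ds2@animalId), ped@id))
    if (!length(intersect(c1, c2)))
      stop("traits genetically disconnected: no shared animals or ancestors")
  }
  i1 <- match(common, ds1@animalId)   # first record per animal and stage
  i2 <- match(common, ds2@animalId)
  new("BivariateData", ds1 = ds1, ds2 = ds2,
      pairs = cbind(i1, i2, deparse.level = 0))
}

## pack/unpack the parameter vector: per block the unique elements 11, 12, 22
.bivPack <- function(G, HY, SS, R, estimR12) {
  th <- c(G_11 = G[1, 1], G_12 = G[1, 2], G_22 = G[2, 2],
          HY_11 = HY[1, 1], HY_12 = HY[1, 2], HY_22 = HY[2, 2])
  if (!is.null(SS))
    th <- c(th, SS_11 = SS[1, 1], SS_12 = SS[1, 2], SS_22 = SS[2, 2])
  th <- c(th, R_11 = R[1, 1])
  if (estimR12) th <- c(th, R_12 = R[1, 2])
  c(th, R_22 = R[2, 2])
}

.bivUnpack <- function(theta, hasSS, estimR12) {
  m <- function(a, b, c) matrix(c(a, b, b, c), 2, 2)
  out <- list(G = m(theta[["G_11"]], theta[["G_12"]], theta[["G_22"]]),
              HY = m(theta[["HY_11"]], theta[["HY_12"]], theta[["HY_22"]]),
              SS = if (hasSS) m(theta[["SS_11"]], theta[["SS_12"]], theta[["SS_22"]]),
              R = m(theta[["R_11"]], if (estimR12) theta[["R_12"]] else 0,
                    theta[["R_22"]]))
  out
}

## eigenvalue-clipping PSD projection of a 2x2 block, floor relative to the
## geometric mean of its diagonal
.clipPSD <- function(M, eps = 1e-8, floorDiag = NULL) {
  if (!is.null(floorDiag)) diag(M) <- pmax(diag(M), floorDiag)
  e <- eigen(M, symmetric = TRUE)
  lo <- eps * sqrt(prod(pmax(diag(M), 1e-300)))
  if (all(e$values >= lo)) return(M)
  e$vectors %*% diag(pmax(e$values, lo)) %*% t(e$vectors)
}

.bivContext <- function(bd, spec1, spec2, ainv, assInv = NULL, minOverlap = 30) {
  ds1 <- bd@ds1; ds2 <- bd@ds2
  n1 <- length(ds1@y); n2 <- length(ds2@y); n <- n1 + n2
  X1 <- .fixedDesign(ds1@fixed, n1); X2 <- .fixedDesign(ds2@fixed, n2)
  X <- bdiag(X1, X2)
  p <- ncol(X)
  hasHY <- "HY" %in% spec1@randomEffects && "HY" %in% spec2@randomEffects
  hasSS <- "SS" %in% spec1@randomEffects && "SS" %in% spec2@randomEffects
  if (!hasHY) stop("bivariate engine expects HY in both trait models")
  Zblock <- function(lab1, lab2, lev) {
    q <- length(lev)
    rbind(cbind(.indicator(lab1, lev), sparseMatrix(i = integer(0), j = integer(0),
                                                    dims = c(n1, q))),
          cbind(sparseMatrix(i = integer(0), j = integer(0), dims = c(n2, q)),
                .indicator(lab2, lev)))
  }
  hyLev <- sort(unique(c(ds1@hy, ds2@hy)))
  Zhy <- Zblock(ds1@hy, ds2@hy, hyLev)
  Zss <- NULL; ssLev <- character(0); AssInv <- NULL; ldAss <- 0
  if (hasSS) {
    if (is.null(assInv)) stop("SS in model but no A_SS inverse supplied")
    ssLev <- rownames(assInv)
    if (!all(c(ds1@ss, ds2@ss) %in% ssLev))
      stop("service sires missing from A_SS inverse")
    Zss <- Zblock(ds1@ss, ds2@ss, ssLev)
    AssInv <- forceSymmetric(Matrix::Matrix(assInv, sparse = TRUE))
    ldAss <- -as.numeric(determinant(AssInv, logarithm = TRUE)$modulus)
  }
  aids <- rownames(ainv)
  Za <- Zblock(ds1@animalId, ds2@animalId, aids)
  Ainv <- forceSymmetric(ainv)
  ldA <- -as.numeric(determinant(Ainv, logarithm = TRUE)$modulus)
  W <- cbind(X, Zhy, if (hasSS) Zss, Za)
  qhy <- length(hyLev); qss <- length(ssLev); qa <- length(aids)
  pairs <- bd@pairs
  estimR12 <- nrow(pairs) >= minOverlap
  single1 <- setdiff(seq_len(n1), pairs[, 1])
  single2 <- setdiff(seq_len(n2), pairs[, 2])
  list(y = c(ds1@y, ds2@y), W = W, X = X, n = n, n1 = n1, n2 = n2, p = p,
       qhy = qhy, qss = qss, qa = qa, hasSS = hasSS, estimR12 = estimR12,
       Ainv = Ainv, AssInv = AssInv, ldA = ldA, ldAss = ldAss,
       pairs = pairs, single1 = single1, single2 = single2,
       idx = list(hy = p + seq_len(2 * qhy),
                  ss = if (hasSS) p + 2 * qhy + seq_len(2 * qss),
                  a = p + 2 * qhy + 2 * qss + seq_len(2 * qa)),
       cache = new.env(parent = emptyenv()))
}

## sparse R-inverse and log|R| for residual matrix R2 (2x2)
.bivRinv <- function(ctx, R2) {
  n1 <- ctx$n1; n <- ctx$n
  d <- numeric(n)
  d[ctx$single1] <- 1 / R2[1, 1]
  d[n1 + ctx$single2] <- 1 / R2[2, 2]
  i <- c(ctx$single1, n1 + ctx$single2)
  x <- c(rep(1 / R2[1, 1], length(ctx$single1)),
         rep(1 / R2[2, 2], length(ctx$single2)))
  j <- i
  logdet <- length(ctx$single1) * log(R2[1, 1]) +
    length(ctx$single2) * log(R2[2, 2])
  if (nrow(ctx$pairs)) {
    det2 <- R2[1, 1] * R2[2, 2] - R2[1, 2]^2
    if (det2 <= 0) return(NULL)
    i1 <- ctx$pairs[, 1]; i2 <- n1 + ctx$pairs[, 2]
    m <- nrow(ctx$pairs)
    i <- c(i, i1, i2, i1, i2)
    j <- c(j, i1, i2, i2, i1)
    x <- c(x, rep(R2[2, 2] / det2, m), rep(R2[1, 1] / det2, m),
           rep(-R2[1, 2] / det2, m), rep(-R2[1, 2] / det2, m))
    logdet <- logdet + m * log(det2)
  }
  list(Rinv = sparseMatrix(i = i, j = j, x = x, dims = c(n, n)),
       logdet = logdet)
}

## closed-form 2x2 inverse; NULL when not PD or too close to singular for the
## downstream sparse factorization (relative determinant floor)
.inv2 <- function(M, relDetFloor = 1e-9) {
  d <- M[1, 1] * M[2, 2] - M[1, 2]^2
  if (!is.finite(d) || any(diag(M) <= 0) ||
      d < relDetFloor * M[1, 1] * M[2, 2]) return(NULL)
  matrix(c(M[2, 2], -M[1, 2], -M[1, 2], M[1, 1]), 2) / d
}

.bivEval <- function(ctx, theta) {
  B <- .bivUnpack(theta, ctx$hasSS, ctx$estimR12)
  Gi <- .inv2(B$G); HYi <- .inv2(B$HY)
  SSi <- if (ctx$hasSS) .inv2(B$SS) else NULL
  if (is.null(Gi) || is.null(HYi) || (ctx$hasSS && is.null(SSi)) ||
      is.null(.inv2(B$R)))
    return(list(n2ll = Inf))
  ri <- .bivRinv(ctx, B$R)
  if (is.null(ri)) return(list(n2ll = Inf))
  RiW <- ri$Rinv %*% ctx$W
  WtRiW <- forceSymmetric(crossprod(ctx$W, RiW))
  WtRiy <- as.numeric(crossprod(RiW, ctx$y))
  yRiy <- as.numeric(crossprod(ctx$y, ri$Rinv %*% ctx$y))
  blocks <- list(
    sparseMatrix(i = integer(0), j = integer(0), dims = c(ctx$p, ctx$p)),
    kronecker(HYi, Diagonal(ctx$qhy)))
  if (ctx$hasSS) blocks <- c(blocks, list(kronecker(SSi, ctx$AssInv)))
  blocks <- c(blocks, list(kronecker(Gi, ctx$Ainv)))
  prec <- do.call(bdiag, blocks)
  M <- forceSymmetric(WtRiW + prec)
  # any CHOLMOD complaint (numerically non-PD near a boundary) => reject point
  asFail <- function(expr) tryCatch(withCallingHandlers(expr,
    warning = function(w) stop(conditionMessage(w))), error = function(e) NULL)
  if (is.null(ctx$cache$fac0)) {
    fac <- asFail(Cholesky(M, LDL = FALSE, super = TRUE))
    if (is.null(fac)) return(list(n2ll = Inf, err = "coefficient matrix not PD"))
    ctx$cache$fac0 <- fac
  } else {
    # a failed numeric update already proves the point unusable; no retry
    fac <- asFail(Matrix::update(ctx$cache$fac0, M))
    if (is.null(fac)) return(list(n2ll = Inf, err = "coefficient matrix not PD"))
  }
  sol <- as.numeric(solve(fac, WtRiy, system = "A"))
  logdetM <- 2 * as.numeric(determinant(fac, sqrt = TRUE)$modulus)
  if (!all(is.finite(sol)) || !is.finite(logdetM)) return(list(n2ll = Inf))
  ld2 <- function(M2) log(M2[1, 1] * M2[2, 2] - M2[1, 2]^2)
  logdetG <- ctx$qa * ld2(B$G) + 2 * ctx$ldA + ctx$qhy * ld2(B$HY) +
    (if (ctx$hasSS) ctx$qss * ld2(B$SS) + 2 * ctx$ldAss else 0)
  yPy <- yRiy - sum(sol * WtRiy)
  n2ll <- ri$logdet + logdetG + logdetM + yPy + (ctx$n - ctx$p) * log(2 * pi)
  list(n2ll = n2ll, sol = sol, fac = fac, Rinv = ri$Rinv, B = B,
       WtRiy = WtRiy)
}

## AI matrix via working vectors f_theta = (dV/dtheta) P y
.bivAI <- function(ctx, theta, ev) {
  B <- ev$B
  resid <- ctx$y - as.numeric(ctx$W %*% ev$sol)
  Rie <- as.numeric(ev$Rinv %*% resid)     # P y
  nms <- names(theta)
  Fmat <- matrix(0, ctx$n, length(theta))
  Epat <- function(k, l) {
    E <- matrix(0, 2, 2)
    if (k == l) E[k, k] <- 1 else { E[k, l] <- 1; E[l, k] <- 1 }
    E
  }
  getU <- function(name, q) {
    u <- ev$sol[ctx$idx[[name]]]
    matrix(u, q, 2)
  }
  col <- 0
  for (nm in nms) {
    col <- col + 1
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    blk <- parts[1]; k <- as.integer(substr(parts[2], 1, 1))
    l <- as.integer(substr(parts[2], 2, 2))
    if (blk == "G") {
      mix <- Epat(k, l) %*% .inv2(B$G)
      v <- getU("a", ctx$qa) %*% t(mix)
      Fmat[, col] <- as.numeric(ctx$W[, ctx$idx$a, drop = FALSE] %*% as.numeric(v))
    } else if (blk == "HY") {
      mix <- Epat(k, l) %*% .inv2(B$HY)
      v <- getU("hy", ctx$qhy) %*% t(mix)
      Fmat[, col] <- as.numeric(ctx$W[, ctx$idx$hy, drop = FALSE] %*% as.numeric(v))
    } else if (blk == "SS") {
      mix <- Epat(k, l) %*% .inv2(B$SS)
      v <- getU("ss", ctx$qss) %*% t(mix)
      Fmat[, col] <- as.numeric(ctx$W[, ctx$idx$ss, drop = FALSE] %*% as.numeric(v))
    } else {  # R block: f = (dR) R^-1 ehat, elementwise over record blocks
      f <- numeric(ctx$n)
      if (k == 1 && l == 1) {
        f[ctx$single1] <- Rie[ctx$single1]
        f[ctx$pairs[, 1]] <- Rie[ctx$pairs[, 1]]
      } else if (k == 2 && l == 2) {
        f[ctx$n1 + ctx$single2] <- Rie[ctx$n1 + ctx$single2]
        f[ctx$n1 + ctx$pairs[, 2]] <- Rie[ctx$n1 + ctx$pairs[, 2]]
      } else {
        f[ctx$pairs[, 1]] <- Rie[ctx$n1 + ctx$pairs[, 2]]
        f[ctx$n1 + ctx$pairs[, 2]] <- Rie[ctx$pairs[, 1]]
      }
      Fmat[, col] <- f
    }
  }
  RiF <- as.matrix(ev$Rinv %*% Fmat)
  WtRiF <- crossprod(ctx$W, RiF)
  S <- solve(ev$fac, WtRiF, system = "A")
  PF <- RiF - as.matrix(ev$Rinv %*% (ctx$W %*% S))
  AI <- crossprod(Fmat, PF) / 2
  AI <- (AI + t(AI)) / 2
  dimnames(AI) <- list(nms, nms)
  as.matrix(AI)
}

#' Bivariate AI-REML for heifer/cow covariance matrices
#'
#' Estimates the 2x2 additive-genetic (G), herd-year (HY), optional
#' service-sire (SS) and residual (R) covariance matrices of a two-trait
#' animal model by the same safeguarded average-information Newton iteration
#' as \code{\link{estimateReml}}, with every block projected back to
#' positive semi-definiteness (eigenvalue clipping) after each update. The
#' residual covariance is estimated only when at least \code{minOverlap}
#' animals carry records at both stages; otherwise it is fixed at zero and
#' flagged. Starting values default to the single-trait fits of the two
#' stages. The genetic correlation and its delta-method standard error are
#' reported; a near-unit correlation with a large SE indicates a boundary
#' solution and is flagged.
#'
#' @param bd a \linkS4class{BivariateData} from \code{\link{stackBivariate}}.
#' @param spec1,spec2 \linkS4class{ModelSpec}s of the two stages.
#' @param ainv sparse A-inverse of the shared pedigree.
#' @param assInv inverse service-sire relationship matrix (when SS is
#'   fitted).
#' @param opts options from \code{\link{remlOptions}}.
#' @param start optional list with matrices \code{G}, \code{HY}, \code{SS},
#'   \code{R}.
#' @param minOverlap minimum double-recorded animals for estimating the
#'   residual covariance (default 30).
#' @return a \linkS4class{CovarianceSet}.
#' @export
estimateBivariateReml <- function(bd, spec1, spec2, ainv, assInv = NULL,
                                  opts = remlOptions(), start = NULL,
                                  minOverlap = 30) {
  ctx <- .bivContext(bd, spec1, spec2, ainv, assInv, minOverlap)
  flags <- character(0)
  if (!ctx$estimR12) flags <- c(flags, "residual-cov-fixed-at-0")
  varP <- c(var(bd@ds1@y), var(bd@ds2@y))
  floorD <- opts$floorFrac * varP
  if (is.null(start)) {
    f1 <- estimateReml(bd@ds1, spec1, ainv, assInv, opts = remlOptions())
    f2 <- estimateReml(bd@ds2, spec2, ainv, assInv, opts = remlOptions())
    # keep starts away from the floor so early AI steps are well scaled
    pick <- function(cmp) c(max(f1@components[cmp], 1e-3 * varP[1], na.rm = TRUE),
                            max(f2@components[cmp], 1e-3 * varP[2], na.rm = TRUE))
    mk <- function(d, r) matrix(c(d[1], r * sqrt(prod(d)), r * sqrt(prod(d)), d[2]), 2)
    start <- list(G = mk(pick("a"), 0.3), HY = mk(pick("hy"), 0.3),
                  SS = if (ctx$hasSS) mk(pick("ss"), 0.3),
                  R = mk(pick("e"), if (ctx$estimR12) 0.1 else 0))
  }
  theta <- .bivPack(start$G, start$HY, if (ctx$hasSS) start$SS, start$R,
                    ctx$estimR12)
  project <- function(th) {
    B <- .bivUnpack(th, ctx$hasSS, ctx$estimR12)
    B$G <- .clipPSD(B$G, floorDiag = floorD)
    B$HY <- .clipPSD(B$HY, floorDiag = floorD)
    if (ctx$hasSS) B$SS <- .clipPSD(B$SS, floorDiag = floorD)
    B$R <- .clipPSD(B$R, floorDiag = pmax(floorD, 1e-6 * varP))
    if (!ctx$estimR12) B$R[1, 2] <- B$R[2, 1] <- 0
    .bivPack(B$G, B$HY, if (ctx$hasSS) B$SS, B$R, ctx$estimR12)
  }
  theta <- project(theta)
  ev <- .bivEval(ctx, theta)
  if (!is.finite(ev$n2ll)) stop("restricted likelihood not finite at start")
  trace <- matrix(NA_real_, opts$maxIter + 1, length(theta) + 1,
                  dimnames = list(NULL, c("neg2logLik", names(theta))))
  trace[1, ] <- c(ev$n2ll, theta)
  converged <- FALSE
  scale <- mean(varP)
  for (iter in seq_len(opts$maxIter)) {
    g <- setNames(numeric(length(theta)), names(theta))
    for (k in seq_along(theta)) {
      h <- max(1e-5 * abs(theta[k]), 1e-7 * scale)
      th2 <- theta; th2[k] <- th2[k] + h
      v <- .bivEval(ctx, th2)$n2ll
      if (!is.finite(v)) { th2[k] <- theta[k] - h; v <- .bivEval(ctx, th2)$n2ll
                           g[k] <- (ev$n2ll - v) / h }
      else g[k] <- (v - ev$n2ll) / h
    }
    AI <- .bivAI(ctx, theta, ev)
    ridge <- 1e-8 * mean(diag(AI))
    step <- tryCatch(-0.5 * solve(AI + diag(ridge, nrow(AI)), g),
                     error = function(e) -g / sqrt(sum(g^2) + 1e-300) * 0.01 * scale)
    # trust-region damping: no parameter moves more than ~3x its own scale
    relStep <- max(abs(step) / pmax(abs(theta), 1e-4 * scale))
    if (relStep > 3) step <- step * (3 / relStep)
    lineSearch <- function(dir) {
      size <- 1
      for (half in 0:30) {
        cand <- project(theta + size * dir)
        evc <- .bivEval(ctx, cand)
        if (is.finite(evc$n2ll) && evc$n2ll <= ev$n2ll + 1e-12)
          return(list(cand = cand, ev = evc))
        size <- size / 2
      }
      NULL
    }
    hit <- lineSearch(step)
    if (is.null(hit))  # AI direction failed: fall back on scaled steepest descent
      hit <- lineSearch(-g / sqrt(sum(g^2) + 1e-300) *
                          pmax(abs(theta), 1e-4 * scale))
    if (is.null(hit)) { converged <- TRUE; break }
    cand <- hit$cand; evc <- hit$ev
    dlik <- ev$n2ll - evc$n2ll
    rel <- max(abs(cand - theta) / pmax(abs(theta), 1e-8 * scale))
    theta <- cand; ev <- evc
    trace[iter + 1, ] <- c(ev$n2ll, theta)
    if (opts$verbose)
      message(sprintf("it %d  -2lR %.6f  rel %.2e", iter, ev$n2ll, rel))
    if (rel < opts$tol || dlik < opts$tolLik) { converged <- TRUE; break }
  }
  if (!converged) flags <- c(flags, "max-iterations")
  B <- .bivUnpack(theta, ctx$hasSS, ctx$estimR12)
  AI <- .bivAI(ctx, theta, ev)
  Vcov <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, nrow(AI), ncol(AI), dimnames = dimnames(AI)))
  se <- setNames(sqrt(pmax(diag(Vcov), 0)), names(theta))
  rg <- B$G[1, 2] / sqrt(B$G[1, 1] * B$G[2, 2])
  gr <- c(G_11 = -rg / (2 * B$G[1, 1]), G_12 = 1 / sqrt(B$G[1, 1] * B$G[2, 2]),
          G_22 = -rg / (2 * B$G[2, 2]))
  rgSe <- if (all(is.finite(Vcov))) {
    v <- Vcov[names(gr), names(gr)]
    sqrt(max(as.numeric(t(gr) %*% v %*% gr), 0))
  } else NA_real_
  Tm <- B$G + B$HY + (if (ctx$hasSS) B$SS else 0) + B$R
  rp <- Tm[1, 2] / sqrt(Tm[1, 1] * Tm[2, 2])
  h2 <- diag(B$G) / diag(Tm)
  if (abs(rg) > 0.98 || (is.finite(rgSe) && rgSe > 1))
    flags <- c(flags, "near-boundary-rg")
  trace <- trace[!is.na(trace[, 1]), , drop = FALSE]
  new("CovarianceSet", G = B$G, HY = B$HY, SS = B$SS, R = B$R, se = se,
      rg = rg, rgSe = rgSe, rp = rp, h2 = as.numeric(h2),
      converged = converged, flags = flags, trace = trace,
      logLik = -0.5 * ev$n2ll)
}

#' Merge heifer and cow records of one trait into a single trait
#'
#' Concatenates the two stage datasets, adding stage as an extra fixed-effect
#' component, so that the single-trait REML machinery applies to the pooled
#' trait — the treatment appropriate when the stage-stage genetic correlation
#' is near one.
#'
#' @param ds1,ds2 stage-specific \linkS4class{TraitDataset}s of one trait.
#' @return a pooled \linkS4class{TraitDataset} with stage "all".
#' @export
mergeTraits <- function(ds1, ds2) {
  stopifnot(identical(ds1@trait, ds2@trait))
  shared <- intersect(colnames(ds1@fixed), colnames(ds2@fixed))
  n <- length(ds1@y) + length(ds2@y)
  fixed <- if (length(shared))
    rbind(ds1@fixed[, shared, drop = FALSE], ds2@fixed[, shared, drop = FALSE])
  else data.frame(row.names = seq_len(n))
  fixed$stage <- rep(c(ds1@stage, ds2@stage), c(length(ds1@y), length(ds2@y)))
  new("TraitDataset", trait = ds1@trait, stage = "all",
      animalId = c(ds1@animalId, ds2@animalId), y = c(ds1@y, ds2@y),
      fixed = fixed,
      hy = c(ds1@hy, ds2@hy),
      ss = if (length(ds1@ss) && length(ds2@ss)) c(ds1@ss, ds2@ss) else character(0))
}
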