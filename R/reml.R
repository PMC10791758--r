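## ---- mixed-model equations and restricted likelihood -----------------------

#' @importFrom Matrix sparseMatrix Diagonal bdiag crossprod t solve Cholesky
#'   forceSymmetric determinant
NULL

## sparse indicator matrix records -> levels
.indicator <- function(labels, levels) {
  sparseMatrix(i = seq_along(labels), j = match(labels, levels), x = 1,
               dims = c(length(labels), length(levels)))
}

## full-rank fixed-effect design: intercept + treatment contrasts per effect;
## columns aliased across composite effects are dropped by a pivoted QR
.fixedDesign <- function(fixed, n) {
  X <- Matrix::Matrix(1, n, 1, sparse = TRUE)
  cols <- "(Intercept)"
  for (eff in colnames(fixed)) {
    lev <- sort(unique(as.character(fixed[[eff]])))
    if (length(lev) > 1) {
      Z <- .indicator(fixed[[eff]], lev)[, -1, drop = FALSE]
      X <- cbind(X, Z)
      cols <- c(cols, paste0(eff, lev[-1]))
    }
  }
  colnames(X) <- cols
  if (ncol(X) > 1 && ncol(X) <= 2000) {
    qd <- qr(as.matrix(X))
    if (qd$rank < ncol(X))
      X <- X[, sort(qd$pivot[seq_len(qd$rank)]), drop = FALSE]
  }
  X
}

## precompute everything theta-independent for a single-trait fit
.remlContext <- function(ds, spec, ainv, assInv = NULL) {
  stopifnot(is(ds, "TraitDataset"), is(spec, "ModelSpec"))
  n <- length(ds@y)
  if (n == 0) stop("empty dataset")
  X <- .fixedDesign(ds@fixed, n)
  p <- ncol(X)
  comps <- character(0); Zs <- list(); Ginv <- list(); qs <- integer(0)
  ldG <- 0
  if ("HY" %in% spec@randomEffects) {
    if (!length(ds@hy)) stop("model asks for HY but dataset has no herd-year labels")
    lev <- sort(unique(ds@hy))
    comps <- c(comps, "hy"); Zs$hy <- .indicator(ds@hy, lev)
    Ginv$hy <- Diagonal(length(lev)); qs["hy"] <- length(lev)
  }
  if ("SS" %in% spec@randomEffects) {
    if (!length(ds@ss)) stop("model asks for SS but dataset has no service-sire ids")
    if (is.null(assInv)) stop("model asks for SS but no A_SS inverse supplied")
    lev <- rownames(assInv)
    if (is.null(lev) || !all(ds@ss %in% lev))
      stop("service sires missing from A_SS inverse: ",
           paste(head(setdiff(ds@ss, lev)), collapse = ", "))
    comps <- c(comps, "ss"); Zs$ss <- .indicator(ds@ss, lev)
    Ginv$ss <- forceSymmetric(Matrix::Matrix(assInv, sparse = TRUE))
    qs["ss"] <- length(lev)
    ldG <- ldG - as.numeric(determinant(Ginv$ss, logarithm = TRUE)$modulus)
  }
  if ("a" %in% spec@randomEffects) {
    aids <- rownames(ainv)
    if (is.null(aids)) stop("ainv must carry animal ids as dimnames")
    if (!all(ds@animalId %in% aids))
      stop("animals missing from pedigree/A-inverse: ",
           paste(head(setdiff(ds@animalId, aids)), collapse = ", "))
    comps <- c(comps, "a")
    Zs$a <- .indicator(ds@animalId, aids)
    Ginv$a <- forceSymmetric(ainv)
    qs["a"] <- length(aids)
    ldG <- ldG - as.numeric(determinant(Ginv$a, logarithm = TRUE)$modulus)
  }
  W <- do.call(cbind, c(list(X), unname(Zs)))
  list(y = ds@y, X = X, W = W, Zs = Zs, Ginv = Ginv, comps = comps, qs = qs,
       n = n, p = p, WtW = forceSymmetric(crossprod(W)),
       Wty = as.numeric(crossprod(W, ds@y)), yty = sum(ds@y^2),
       logdetGconst = ldG, cache = new.env(parent = emptyenv()))
}

## start index of each random-effect block inside the solution vector
.blockIndex <- function(ctx) {
  starts <- ctx$p + c(0, cumsum(ctx$qs))[seq_along(ctx$qs)] + 1
  setNames(lapply(seq_along(ctx$qs),
                  function(k) starts[k]:(starts[k] + ctx$qs[k] - 1)),
           ctx$comps)
}

## lambda-form coefficient matrix for components theta (named, incl "e")
.coefMatrix <- function(ctx, theta) {
  C <- ctx$WtW
  for (comp in ctx$comps)
    C <- C + .ginvPadded(ctx, comp, theta[["e"]] / theta[[comp]])
  forceSymmetric(C)
}

.ginvPadded <- function(ctx, comp, lam) {
  idx <- .blockIndex(ctx)[[comp]]
  dim <- ctx$p + sum(ctx$qs)
  G <- as(as(ctx$Ginv[[comp]], "generalMatrix"), "TsparseMatrix")
  sparseMatrix(i = G@i + idx[1], j = G@j + idx[1], x = lam * G@x,
               dims = c(dim, dim))
}

## factorize + solve; returns list(fac, sol, n2ll, ehat)
.remlEval <- function(ctx, theta) {
  if (any(theta <= 0)) return(list(n2ll = Inf))
  C <- .coefMatrix(ctx, theta)
  # reuse the symbolic factorization (theta-independent pattern); any CHOLMOD
  # complaint means the point is numerically unusable -> reject it
  asFail <- function(expr) tryCatch(withCallingHandlers(expr,
    warning = function(w) stop(conditionMessage(w))), error = function(e) NULL)
  fac <- if (!is.null(ctx$cache$fac0))
    asFail(Matrix::update(ctx$cache$fac0, C)) else NULL
  if (is.null(fac)) {
    fac <- asFail(Cholesky(C, LDL = FALSE, super = TRUE))
    if (is.null(fac))
      return(list(n2ll = Inf,
                  err = "coefficient matrix not positive definite (singular fixed block?)"))
    ctx$cache$fac0 <- fac
  }
  sol <- as.numeric(solve(fac, ctx$Wty, system = "A"))
  logdetC <- 2 * as.numeric(determinant(fac, sqrt = TRUE)$modulus)
  if (!all(is.finite(sol)) || !is.finite(logdetC)) return(list(n2ll = Inf))
  yPy <- (ctx$yty - sum(sol * ctx$Wty)) / theta[["e"]]
  q <- sum(ctx$qs)
  n2ll <- (ctx$n - ctx$p - q) * log(theta[["e"]]) +
    sum(ctx$qs * log(theta[ctx$comps])) + ctx$logdetGconst +
    logdetC + yPy + (ctx$n - ctx$p) * log(2 * pi)
  list(fac = fac, sol = sol, n2ll = n2ll, yPy = yPy)
}

#' Restricted log-likelihood of a single-trait animal model
#'
#' Evaluates the REML log-likelihood at given variance components through the
#' sparse mixed-model-equation factorization (log-determinant identities),
#' never forming the dense phenotypic covariance matrix. Includes the
#' \eqn{-(n-p)\log(2\pi)/2} constant, so values are directly comparable with
#' a dense-matrix evaluation.
#'
#' @param theta named numeric variance components: \code{a}, optionally
#'   \code{hy} and \code{ss}, and \code{e}; all > 0.
#' @param ds a \linkS4class{TraitDataset}.
#' @param spec a \linkS4class{ModelSpec}.
#' @param ainv sparse A-inverse from \code{\link{aInverse}} (dimnames = ids).
#' @param assInv inverse of the service-sire relationship matrix (matrix with
#'   dimnames), required when SS is in the model.
#' @return scalar restricted log-likelihood.
#' @export
remlLoglik <- function(theta, ds, spec, ainv, assInv = NULL) {
  ctx <- .remlContext(ds, spec, ainv, assInv)
  ev <- .remlEval(ctx, theta)
  if (!is.finite(ev$n2ll)) stop(ev$err %||% "non-finite restricted likelihood")
  -0.5 * ev$n2ll
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build Henderson's mixed-model equations
#'
#' Assembles the lambda-form coefficient matrix
#' \deqn{[X'X, X'Z; Z'X, Z'Z + blockdiag(I\lambda_{hy}, A_{SS}^{-1}\lambda_{ss},
#' A^{-1}\lambda_a)]}
#' with \eqn{\lambda = \sigma^2_e/\sigma^2_{component}}, and the right-hand
#' side \eqn{[X'y; Z'y]}. Fixed effects are made full rank by intercept +
#' drop-first-level coding per effect.
#'
#' @inheritParams remlLoglik
#' @return list with \code{C} (sparse symmetric coefficient matrix),
#'   \code{rhs}, and \code{index}: a data.frame naming every equation
#'   (effect, level), ordered fixed effects, then HY, then SS, then animals
#'   in pedigree order.
#' @export
buildMME <- function(ds, spec, ainv, assInv = NULL, theta) {
  ctx <- .remlContext(ds, spec, ainv, assInv)
  C <- .coefMatrix(ctx, theta)
  lev <- c(colnames(ctx$X),
           unlist(lapply(ctx$comps, function(cc) colnames(ctx$Zs[[cc]]) %||%
                           as.character(seq_len(ctx$qs[[cc]])))))
  labels <- character(0)
  for (cc in ctx$comps) {
    nm <- switch(cc, hy = sort(unique(ds@hy)), ss = rownames(ctx$Ginv$ss) %||%
                   as.character(seq_len(ctx$qs[[cc]])), a = rownames(ainv))
    labels <- c(labels, nm)
  }
  index <- data.frame(
    effect = c(rep("fixed", ctx$p), rep(ctx$comps, ctx$qs)),
    level = c(colnames(ctx$X), labels), stringsAsFactors = FALSE)
  list(C = C, rhs = ctx$Wty, index = index, ctx = ctx, theta = theta)
}

#' Solve the mixed-model equations (BLUE + BLUP)
#'
#' Sparse Cholesky solve of the system from \code{\link{buildMME}}. At the
#' solution the residual is orthogonal to the fixed-effect columns
#' (\eqn{X'(y - Xb - Zu) = 0}), which is verified and reported.
#'
#' @param mme list from \code{\link{buildMME}}.
#' @return list with \code{solution} (named by effect level: fixed estimates,
#'   then EBVs per random level), \code{fixed}, \code{ebv} (additive animal
#'   effects), and \code{orthogonality} (max abs of the fixed-residual
#'   product).
#' @export
solveBlup <- function(mme) {
  ev <- .remlEval(mme$ctx, mme$theta)
  if (!is.finite(ev$n2ll)) stop(ev$err)
  sol <- ev$sol
  names(sol) <- mme$index$level
  ctx <- mme$ctx
  resid <- ctx$y - as.numeric(ctx$W %*% sol)
  orth <- max(abs(as.numeric(crossprod(ctx$X, resid))))
  idx <- .blockIndex(ctx)
  list(solution = sol, fixed = sol[seq_len(ctx$p)],
       ebv = sol[idx$a], residuals = resid, orthogonality = orth)
}

## average-information matrix at a fitted point, via working vectors:
## f_k = Z_k u_k / theta_k (f_e = residual/theta_e), AI_kl = f_k' P f_l / 2
.aiMatrix <- function(ctx, theta, ev) {
  idx <- .blockIndex(ctx)
  Fmat <- matrix(0, ctx$n, length(ctx$comps) + 1)
  for (k in seq_along(ctx$comps)) {
    comp <- ctx$comps[k]
    u <- ev$sol[idx[[comp]]]
    Fmat[, k] <- as.numeric(ctx$Zs[[comp]] %*% u) / theta[[comp]]
  }
  resid <- ctx$y - as.numeric(ctx$W %*% ev$sol)
  Fmat[, length(ctx$comps) + 1] <- resid / theta[["e"]]
  WtF <- crossprod(ctx$W, Fmat)
  S <- solve(ev$fac, WtF, system = "A")
  PF <- (Fmat - as.matrix(ctx$W %*% S)) / theta[["e"]]
  AI <- crossprod(Fmat, PF) / 2
  AI <- (AI + Matrix::t(AI)) / 2
  dimnames(AI) <- list(c(ctx$comps, "e"), c(ctx$comps, "e"))
  as.matrix(AI)
}

#' Options for the REML optimizer
#'
#' @param maxIter maximum AI iterations (default 100).
#' @param tol relative parameter-change convergence threshold (default 1e-8).
#' @param tolLik absolute change in -2 logLik treated as converged
#'   (default 1e-10).
#' @param floorFrac variance floor as a fraction of the phenotypic variance
#'   (default 1e-8); components pinned there are flagged.
#' @param start optional named start values (otherwise 10\% of the
#'   phenotypic variance per random component, remainder residual).
#' @param verbose print the iteration trace.
#' @return list of options.
#' @export
remlOptions <- function(maxIter = 100L, tol = 1e-8, tolLik = 1e-10,
                        floorFrac = 1e-8, start = NULL, verbose = FALSE) {
  list(maxIter = maxIter, tol = tol, tolLik = tolLik, floorFrac = floorFrac,
       start = start, verbose = verbose)
}

## forward-difference gradient of -2 logLik over components
.numGrad <- function(ctx, theta, base, floor) {
  g <- setNames(numeric(length(theta)), names(theta))
  for (k in names(theta)) {
    h <- max(1e-5 * theta[[k]], 1e-4 * floor)
    th2 <- theta; th2[[k]] <- th2[[k]] + h
    g[[k]] <- (.remlEval(ctx, th2)$n2ll - base) / h
  }
  g
}

#' Estimate variance components by average-information REML
#'
#' Maximizes the restricted likelihood of the single-trait animal model with
#' a safeguarded Newton iteration on the average-information (AI) matrix:
#' the AI matrix is computed exactly through the working-vector identity,
#' gradients by finite differences of the sparse-factorization likelihood,
#' and each step is halved until the restricted likelihood does not
#' decrease, so the iteration is monotone. Components that drift to the
#' floor (\code{floorFrac} x phenotypic variance) are pinned and flagged.
#' Standard errors come from the inverse AI matrix at the optimum;
#' heritability and its standard error by the delta method.
#'
#' @inheritParams remlLoglik
#' @param opts options from \code{\link{remlOptions}}.
#' @return a \linkS4class{VarianceComponents}.
#' @export
estimateReml <- function(ds, spec, ainv, assInv = NULL, opts = remlOptions()) {
  ctx <- .remlContext(ds, spec, ainv, assInv)
  varP <- var(ctx$y)
  if (!is.finite(varP) || varP <= 0) stop("response has no variance")
  floor <- opts$floorFrac * varP
  comps <- c(ctx$comps, "e")
  theta <- opts$start
  if (is.null(theta)) {
    theta <- setNames(rep(0.1 * varP, length(comps)), comps)
    theta[["e"]] <- varP * (1 - 0.1 * (length(comps) - 1))
  } else {
    stopifnot(all(comps %in% names(theta)))
    theta <- theta[comps]
  }
  ev <- .remlEval(ctx, theta)
  if (!is.finite(ev$n2ll)) stop(ev$err)
  trace <- matrix(NA_real_, opts$maxIter + 1, length(comps) + 1,
                  dimnames = list(NULL, c("neg2logLik", comps)))
  trace[1, ] <- c(ev$n2ll, theta)
  converged <- FALSE; flags <- character(0); iter <- 0L
  for (iter in seq_len(opts$maxIter)) {
    g <- .numGrad(ctx, theta, ev$n2ll, floor)
    AI <- .aiMatrix(ctx, theta, ev)
    ridge <- 1e-8 * mean(diag(AI))
    step <- tryCatch(-0.5 * solve(AI + diag(ridge, nrow(AI)), g),
                     error = function(e) -g / sqrt(sum(g^2) + 1e-300) * 0.1 * varP)
    pinned <- theta <= floor * (1 + 1e-12) & step < 0
    step[pinned] <- 0
    size <- 1; accepted <- FALSE
    for (half in 0:30) {
      cand <- pmax(theta + size * step, floor)
      evc <- .remlEval(ctx, cand)
      if (is.finite(evc$n2ll) && evc$n2ll <= ev$n2ll + 1e-12) {
        accepted <- TRUE; break
      }
      size <- size / 2
    }
    if (!accepted) { converged <- TRUE; break }
    dlik <- ev$n2ll - evc$n2ll
    rel <- max(abs(cand - theta) / pmax(abs(theta), floor))
    theta <- cand; ev <- evc
    trace[iter + 1, ] <- c(ev$n2ll, theta)
    if (opts$verbose)
      message(sprintf("it %d  -2lR %.8f  rel %.2e", iter, ev$n2ll, rel))
    if (rel < opts$tol || dlik < opts$tolLik) { converged <- TRUE; break }
  }
  if (!converged) flags <- c(flags, "max-iterations")
  floored <- names(theta)[theta <= floor * (1 + 1e-9)]
  if (length(floored)) flags <- c(flags, paste0("floored:", floored))
  AI <- .aiMatrix(ctx, theta, ev)
  Vcov <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, nrow(AI), ncol(AI), dimnames = dimnames(AI)))
  se <- sqrt(pmax(diag(Vcov), 0))
  names(se) <- comps
  h <- .h2Delta(theta, Vcov)
  trace <- trace[!is.na(trace[, 1]), , drop = FALSE]
  new("VarianceComponents", components = theta, se = se, h2 = h$h2,
      h2Se = h$se, converged = converged, flags = flags, trace = trace,
      logLik = -0.5 * ev$n2ll)
}

## delta-method h2 and SE from components + their covariance matrix
.h2Delta <- function(theta, Vcov) {
  if (!"a" %in% names(theta))
    return(list(h2 = NA_real_, se = NA_real_))  # no additive term fitted
  S <- sum(theta)
  h2 <- theta[["a"]] / S
  grad <- setNames(rep(-theta[["a"]] / S^2, length(theta)), names(theta))
  grad[["a"]] <- grad[["a"]] + 1 / S
  se <- if (all(is.finite(Vcov))) {
    g <- grad[rownames(Vcov)]
    sqrt(max(as.numeric(t(g) %*% Vcov %*% g), 0))
  } else NA_real_
  list(h2 = as.numeric(h2), se = se)
}

#' @export
setGeneric("heritability", function(x, covariance = NULL)
  standardGeneric("heritability"))

#' Heritability from variance components
#'
#' \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{hy} + \sigma^2_{ss} +
#' \sigma^2_e)} — the additive variance over the sum of all fitted random
#' components plus residual (service-sire term only when fitted). The
#' standard error is by the delta method when a covariance matrix of the
#' component estimates is available.
#'
#' @param x named numeric variance components (must contain \code{a}; all
#'   entries enter the denominator), or a \linkS4class{VarianceComponents}.
#' @param covariance optional covariance matrix of the estimates (dimnames
#'   matching \code{names(x)}).
#' @return named numeric: \code{h2} and \code{se} (NA when no covariance).
#' @examples
#' heritability(c(a = 109.14, hy = 446.55, e = 8690.96))  # ~0.0118
#' @export
setMethod("heritability", "numeric", function(x, covariance = NULL) {
  if (!"a" %in% names(x)) stop("components must be named and contain 'a'")
  if (all(x == 0)) stop("heritability undefined: all components are zero")
  V <- if (is.null(covariance))
    matrix(NA_real_, length(x), length(x), dimnames = list(names(x), names(x)))
  else covariance
  h <- .h2Delta(x, V)
  c(h2 = h$h2, se = h$se)
})

#' @export
setMethod("heritability", "VarianceComponents", function(x, covariance = NULL) {
  c(h2 = x@h2, se = x@h2Se)
})
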