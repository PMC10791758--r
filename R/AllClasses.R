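#' @import methods
#' @importFrom stats var sd pnorm qnorm rnorm runif rbinom optim setNames
#'   model.matrix aggregate
#' @importFrom utils read.table write.table head tail
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Pedigree of animals with sire and dam links
#'
#' A validated, topologically sorted pedigree. Animals are stored so that
#' every known parent precedes its offspring; \code{sire} and \code{dam} are
#' integer indices into \code{id} (\code{NA} for an unknown parent).
#'
#' @slot id character vector of unique animal identifiers, in sorted order.
#' @slot sire integer index of each animal's sire within \code{id}, or
#'   \code{NA} if unknown.
#' @slot dam integer index of each animal's dam, or \code{NA}.
#'
#' @details Validity enforces uniqueness of identifiers, parents-before-
#'   offspring ordering (which excludes cycles), and sex consistency: no
#'   identifier may be used both as a sire and as a dam.
#' @export
setClass("Pedigree",
  representation(id = "character", sire = "integer", dam = "integer"),
  validity = function(object) {
    n <- length(object@id)
    if (length(object@sire) != n || length(object@dam) != n)
      return("id, sire and dam must have equal length")
    if (anyDuplicated(object@id))
      return(paste("duplicate animal identifiers:",
                   paste(unique(object@id[duplicated(object@id)]), collapse = ", ")))
    ok <- function(p) all(is.na(p) | (p >= 1 & p < seq_len(n)))
    if (!ok(object@sire) || !ok(object@dam))
      return("every known parent must precede its offspring (pedigree not sorted or cyclic)")
    both <- intersect(object@id[object@sire[!is.na(object@sire)]],
                      object@id[object@dam[!is.na(object@dam)]])
    if (length(both))
      return(paste("sex inconsistency, used as both sire and dam:",
                   paste(both, collapse = ", ")))
    TRUE
  })

#' Additive (numerator) relationship matrix
#'
#' Dense symmetric matrix of additive genetic relationships among a set of
#' animals, with the inbreeding coefficients underlying its diagonal
#' (\eqn{a_{ii} = 1 + F_i}).
#'
#' @slot ids character identifiers labelling rows/columns.
#' @slot values symmetric numeric matrix of relationships.
#' @slot inbreeding numeric vector of inbreeding coefficients \eqn{F_i}.
#' @export
setClass("RelationshipMatrix",
  representation(ids = "character", values = "matrix", inbreeding = "numeric"),
  validity = function(object) {
    n <- length(object@ids)
    if (!all(dim(object@values) == c(n, n)))
      return("values must be n x n")
    if (length(object@inbreeding) != n)
      return("inbreeding must have one entry per id")
    if (max(abs(object@values - t(object@values))) > 1e-10)
      return("values must be symmetric")
    TRUE
  })

#' One trait's phenotypes with effect labels
#'
#' Response vector for a single fertility trait at one stage (heifer, cow or
#' pooled), together with the fixed-effect class labels and random-effect
#' (herd-year, service-sire) labels each record carries.
#'
#' @slot trait trait code, one of CI, DO, AFS, AFC, CTFS, FSTC, GL, NRR, NS.
#' @slot stage "heifer", "cow" or "all".
#' @slot animalId character identifier per record.
#' @slot y numeric response (days for intervals, count for NS, 0/1 for NRR).
#' @slot fixed data.frame of fixed-effect class labels, one column per effect.
#' @slot hy character herd-year label per record ("" when HY is not fitted).
#' @slot ss character service-sire identifier per record ("" when not fitted).
#' @export
setClass("TraitDataset",
  representation(trait = "character", stage = "character",
                 animalId = "character", y = "numeric",
                 fixed = "data.frame", hy = "character", ss = "character"),
  validity = function(object) {
    n <- length(object@y)
    if (length(object@animalId) != n) return("animalId length != y length")
    if (nrow(object@fixed) && nrow(object@fixed) != n)
      return("fixed labels must have one row per record")
    if (length(object@hy) && length(object@hy) != n) return("hy length != y length")
    if (length(object@ss) && length(object@ss) != n) return("ss length != y length")
    if (!all(is.finite(object@y))) return("y must be finite")
    if (identical(object@trait, "NRR") && !all(object@y %in% c(0, 1)))
      return("NRR responses must be 0/1")
    if (identical(object@trait, "NS") &&
        (!all(object@y >= 1) || any(object@y != round(object@y))))
      return("NS responses must be integers >= 1")
    if (object@trait %in% c("CI", "DO", "AFS", "AFC", "CTFS", "GL") &&
        any(object@y <= 0))
      return("interval trait responses must be > 0")
    TRUE
  })

#' Model specification for one trait x stage
#'
#' Machine form of the fixed/random effect layout: which composite fixed
#' effects and which random effects (herd-year HY, service sire SS, additive
#' animal a) enter the model for a given trait and stage.
#'
#' @slot trait trait code.
#' @slot stage "heifer", "cow" or "all".
#' @slot fixedEffects ordered subset of RYM, Mf, MfX, AcMcX, ApMf, ApMp,
#'   ApMpX (plus "stage" for pooled fits).
#' @slot randomEffects subset of HY, SS, a; every standard trait model
#'   (\code{\link{defaultModelSpec}}) carries the additive animal effect
#'   "a"; omitting it is allowed only for degenerate diagnostic models.
#' @export
setClass("ModelSpec",
  representation(trait = "character", stage = "character",
                 fixedEffects = "character", randomEffects = "character"),
  validity = function(object) {
    bad <- setdiff(object@randomEffects, c("HY", "SS", "a"))
    if (length(bad)) return(paste("unknown random effects:", paste(bad, collapse = ", ")))
    TRUE
  })

#' Estimated variance components of a single-trait animal model
#'
#' @slot components named numeric: additive \code{a}, herd-year \code{hy}
#'   (if fitted), service-sire \code{ss} (if fitted), residual \code{e};
#'   units are squared trait units.
#' @slot se asymptotic standard errors (inverse average-information matrix).
#' @slot h2 heritability \eqn{\sigma^2_a / \sum_k \sigma^2_k}.
#' @slot h2Se delta-method standard error of \code{h2}.
#' @slot converged logical.
#' @slot flags character: e.g. "floored:a" when a component was pinned at
#'   its lower floor.
#' @slot trace iteration trace (iteration, -2 restricted logLik, components).
#' @slot logLik restricted log-likelihood at the estimate.
#' @export
setClass("VarianceComponents",
  representation(components = "numeric", se = "numeric", h2 = "numeric",
                 h2Se = "numeric", converged = "logical", flags = "character",
                 trace = "matrix", logLik = "numeric"),
  validity = function(object) {
    if (any(object@components < 0)) return("variance components must be >= 0")
    TRUE
  })

#' Estimated covariance matrices of a bivariate animal model
#'
#' @slot G 2x2 additive genetic covariance matrix.
#' @slot HY 2x2 herd-year covariance matrix.
#' @slot SS 2x2 service-sire covariance matrix, or NULL when not fitted.
#' @slot R 2x2 residual covariance matrix (off-diagonal fixed at 0 and
#'   flagged when too few animals carry records at both stages).
#' @slot se named numeric standard errors per estimated element.
#' @slot rg genetic correlation \eqn{G_{12}/\sqrt{G_{11}G_{22}}}.
#' @slot rgSe delta-method standard error of \code{rg}.
#' @slot rp phenotypic correlation from the summed covariance matrices.
#' @slot h2 per-trait heritabilities from the bivariate fit.
#' @slot converged logical.
#' @slot flags character diagnostics (near-boundary, fixed residual
#'   covariance, identifiability warnings).
#' @slot trace iteration trace.
#' @slot logLik restricted log-likelihood at the estimate.
#' @export
setClass("CovarianceSet",
  representation(G = "matrix", HY = "matrix", SS = "matrixOrNULL",
                 R = "matrix", se = "numeric", rg = "numeric", rgSe = "numeric",
                 rp = "numeric", h2 = "numeric", converged = "logical",
                 flags = "character", trace = "matrix", logLik = "numeric"))

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  founders <- sum(is.na(object@sire) & is.na(object@dam))
  cat("Pedigree with", n, "animals (", founders, "founders )\n")
  k <- min(n, 6L)
  sid <- ifelse(is.na(object@sire), "-", object@id[object@sire])
  did <- ifelse(is.na(object@dam), "-", object@id[object@dam])
  print(data.frame(animal = head(object@id, k), sire = head(sid, k),
                   dam = head(did, k)))
  if (n > k) cat("...", n - k, "more\n")
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix for", length(object@ids), "animals; mean F =",
      signif(mean(object@inbreeding), 4), "\n")
})

setMethod("show", "TraitDataset", function(object) {
  cat(sprintf("TraitDataset %s (%s): %d records", object@trait, object@stage,
              length(object@y)))
  if (length(object@y))
    cat(sprintf("; mean %.3f sd %.3f", mean(object@y), sd(object@y)))
  cat("\n")
  if (ncol(object@fixed))
    cat("  fixed effects:", paste(colnames(object@fixed), collapse = ", "), "\n")
  re <- c(if (any(nzchar(object@hy))) "HY", if (any(nzchar(object@ss))) "SS", "a")
  cat("  random effects:", paste(re, collapse = ", "), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec %s (%s)\n  fixed: %s\n  random: %s\n",
              object@trait, object@stage,
              paste(object@fixedEffects, collapse = ", "),
              paste(object@randomEffects, collapse = ", ")))
})

setMethod("show", "VarianceComponents", function(object) {
  cat("Variance components (REML", if (!object@converged) ", NOT converged", ")\n",
      sep = "")
  tab <- data.frame(estimate = object@components,
                    se = object@se[names(object@components)])
  print(signif(as.matrix(tab), 5))
  cat(sprintf("h2 = %.4f (SE %.4f)\n", object@h2, object@h2Se))
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "CovarianceSet", function(object) {
  cat("Bivariate (co)variance estimates",
      if (!object@converged) " (NOT converged)", "\n", sep = "")
  cat("G:\n"); print(signif(object@G, 5))
  cat(sprintf("rg = %.4f (SE %.4g); h2 = %.4f / %.4f\n",
              object@rg, object@rgSe, object@h2[1], object@h2[2]))
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = "; "), "\n")
})
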