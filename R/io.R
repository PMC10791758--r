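## ---- result and configuration I/O ------------------------------------------

#' Write single-trait REML results as CSV
#'
#' One row per variance component (estimate, SE) plus the heritability row,
#' mirroring the layout of published variance-component tables.
#'
#' @param vc a \linkS4class{VarianceComponents}.
#' @param path output path.
#' @export
writeVarianceComponents <- function(vc, path) {
  stopifnot(is(vc, "VarianceComponents"))
  nm <- names(vc@components)
  df <- data.frame(component = c(nm, "h2"),
                   estimate = c(unname(vc@components), vc@h2),
                   se = c(unname(vc@se[nm]), vc@h2Se))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run log with the iteration trace
#'
#' Records convergence status, flags, the restricted log-likelihood and the
#' full iteration trace of a fit.
#'
#' @param fit a \linkS4class{VarianceComponents} or
#'   \linkS4class{CovarianceSet}.
#' @param path output path.
#' @export
writeRunLog <- function(fit, path) {
  log <- list(converged = fit@converged, flags = as.list(fit@flags),
              logLik = fit@logLik,
              trace = apply(fit@trace, 1, as.list))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA)
  } else {
    dput(log, path)
  }
  invisible(path)
}

#' Write bivariate results in the published two-trait layout
#'
#' A 2x2 text table with heritabilities on the diagonal and the genetic
#' correlation in the lower triangle, standard errors in parentheses.
#'
#' @param fit a \linkS4class{CovarianceSet}.
#' @param labels row/column labels (e.g. \code{c("heifer", "cow")}).
#' @param path output path.
#' @export
writeBivariateResults <- function(fit, path, labels = c("trait1", "trait2")) {
  stopifnot(is(fit, "CovarianceSet"))
  fmt <- function(v, s) sprintf("%.4f (%.4g)", v, s)
  h2se <- c(fit@se[["G_11"]], fit@se[["G_22"]])  # SE of the variance, reported
  df <- data.frame(
    trait = labels,
    t1 = c(fmt(fit@h2[1], h2se[1]), fmt(fit@rg, fit@rgSe)),
    t2 = c("", fmt(fit@h2[2], h2se[2])))
  colnames(df) <- c("", labels)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a key-value run configuration
#'
#' YAML when the yaml package is available, otherwise a plain
#' \code{key: value} subset (scalars and comma-separated lists). Recognised
#' keys include \code{traits}, \code{window_days}, \code{k},
#' \code{min_class_size}, \code{nrr_anchor}.
#'
#' @param path configuration file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (requireNamespace("yaml", quietly = TRUE))
    return(yaml::read_yaml(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^:]+):\\s*(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) < 3) next
    val <- trimws(strsplit(gsub("\\[|\\]", "", m[3]), ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[trimws(m[2])]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Serialize a SimTruth to key-value markup
#'
#' Writes the generating parameters of a synthetic dataset so a simulation's
#' provenance travels with its output files.
#'
#' @param truth a \code{\link{simTruth}}.
#' @param path output path.
#' @export
writeSimTruth <- function(truth, path) {
  stopifnot(inherits(truth, "SimTruth"))
  fmtMat <- function(M) paste(M, collapse = ", ")
  lines <- c(
    paste0("mu: ", truth$mu),
    paste0("sigma2_", names(truth$sigma2), ": ", truth$sigma2),
    paste0("nHY: ", truth$nHY),
    paste0("nFixedLevels: ", truth$nFixedLevels),
    paste0("fixedSd: ", truth$fixedSd),
    if (!is.null(truth$G)) paste0("G: ", fmtMat(truth$G)),
    if (!is.null(truth$HY)) paste0("HY: ", fmtMat(truth$HY)),
    if (!is.null(truth$SS)) paste0("SS: ", fmtMat(truth$SS)),
    if (!is.null(truth$R)) paste0("R: ", fmtMat(truth$R)),
    paste0("liabilityMu: ", truth$liabilityMu),
    paste0("dupRate: ", truth$dupRate),
    paste0("corruptRate: ", truth$corruptRate))
  writeLines(lines, path)
  invisible(path)
}
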