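#' Construct a Pedigree from identifier triples
#'
#' Builds a validated, topologically sorted \linkS4class{Pedigree} from
#' character vectors of animal, sire and dam identifiers. Parents that appear
#' only in the sire or dam columns are added as founders with unknown
#' parents. Ties in the topological order are broken by input order, so the
#' sorted result is deterministic.
#'
#' @param animal character vector of animal identifiers.
#' @param sire,dam character vectors of parent identifiers; \code{NA} or
#'   \code{unknownToken} marks an unknown parent.
#' @param unknownToken string coding an unknown parent (default \code{"0"}).
#' @return A \linkS4class{Pedigree}.
#' @examples
#' ped <- pedigree(c("C", "A", "B"), c("A", "0", "0"), c("B", "0", "0"))
#' pedigreeIds(ped)
#' @export
pedigree <- function(animal, sire, dam, unknownToken = "0") {
  animal <- as.character(animal); sire <- as.character(sire); dam <- as.character(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have equal length")
  unk <- function(x) is.na(x) | x == unknownToken | x == ""
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_
  if (any(i <- (!is.na(sire) & sire == animal) | (!is.na(dam) & dam == animal)))
    stop("cycle: animal is its own parent: ", paste(animal[i], collapse = ", "))
  dup <- duplicated(animal)
  if (any(dup)) {
    # exact duplicate rows are collapsed; conflicting ones are an error
    key <- paste(animal, sire, dam, sep = "\r")
    keep <- !duplicated(key)
    animal2 <- animal[keep]
    if (anyDuplicated(animal2))
      stop("duplicate animal rows with conflicting parents: ",
           paste(unique(animal2[duplicated(animal2)]), collapse = ", "))
    animal <- animal2; sire <- sire[keep]; dam <- dam[keep]
  }
  # implicit founders: ids seen only as parents
  parents <- unique(c(sire[!is.na(sire)], dam[!is.na(dam)]))
  extra <- setdiff(parents, animal)
  if (length(extra)) {
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
  }
  n <- length(animal)
  si <- match(sire, animal); di <- match(dam, animal)
  # generation-wise Kahn sort, ties broken by input order
  placed <- logical(n); order_out <- integer(n); filled <- 0L
  repeat {
    ready <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    if (!any(ready)) break
    r <- which(ready)
    order_out[filled + seq_along(r)] <- r
    filled <- filled + length(r)
    placed[r] <- TRUE
  }
  if (filled < n) {
    # walk parent links among the unplaced to show one offending chain
    start <- which(!placed)[1]
    chain <- start; cur <- start
    repeat {
      nxt <- if (!is.na(si[cur]) && !placed[si[cur]]) si[cur] else di[cur]
      if (nxt %in% chain) { chain <- c(chain, nxt); break }
      chain <- c(chain, nxt); cur <- nxt
    }
    stop("cycle detected in pedigree: ", paste(animal[chain], collapse = " -> "))
  }
  animal <- animal[order_out]
  si <- match(sire[order_out], animal); di <- match(dam[order_out], animal)
  new("Pedigree", id = animal, sire = as.integer(si), dam = as.integer(di))
}

#' Read a pedigree file
#'
#' Reads delimited text with at least three columns (animal, sire, dam);
#' extra columns are ignored. Parents appearing only as sire or dam are added
#' as founders, and the result is topologically sorted and validated.
#'
#' @param path file path.
#' @param unknownToken string coding an unknown parent (default \code{"0"}).
#' @param header logical; does the file carry a header row?
#' @param sep field separator; \code{""} = any whitespace.
#' @return A \linkS4class{Pedigree}.
#' @export
readPedigree <- function(path, unknownToken = "0", header = FALSE, sep = "") {
  df <- read.table(path, header = header, sep = sep, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("pedigree file needs >= 3 columns (animal, sire, dam)")
  pedigree(df[[1]], df[[2]], df[[3]], unknownToken = unknownToken)
}

#' @export
setGeneric("pedigreeIds", function(ped) standardGeneric("pedigreeIds"))
#' Animal identifiers in pedigree (sorted) order
#' @param ped a \linkS4class{Pedigree}.
#' @return character vector.
#' @export
setMethod("pedigreeIds", "Pedigree", function(ped) ped@id)

#' @export
setGeneric("nAnimals", function(ped) standardGeneric("nAnimals"))
#' Number of animals in a pedigree
#' @param ped a \linkS4class{Pedigree}.
#' @export
setMethod("nAnimals", "Pedigree", function(ped) length(ped@id))

#' Pedigree as a data.frame
#'
#' @param x a \linkS4class{Pedigree}.
#' @param row.names,optional,... ignored.
#' @return data.frame with columns animal, sire, dam (NA = unknown).
#' @export
as.data.frame.Pedigree <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(animal = x@id,
             sire = ifelse(is.na(x@sire), NA_character_, x@id[x@sire]),
             dam = ifelse(is.na(x@dam), NA_character_, x@id[x@dam]),
             stringsAsFactors = FALSE)
}

## ancestor closure of a set of (index) animals, including the set itself
.ancestorClosure <- function(ped, idx) {
  keep <- logical(nAnimals(ped))
  keep[idx] <- TRUE
  frontier <- idx
  while (length(frontier)) {
    p <- c(ped@sire[frontier], ped@dam[frontier])
    p <- p[!is.na(p)]
    p <- p[!keep[p]]
    keep[p] <- TRUE
    frontier <- unique(p)
  }
  which(keep)
}

#' @export
setGeneric("inbreeding", function(ped) standardGeneric("inbreeding"))

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes \eqn{F_i} for every animal without forming the dense relationship
#' matrix: for each animal the diagonal \eqn{a_{ii} = \sum_j L_{ij}^2 d_j} is
#' accumulated over its ancestor closure, where \eqn{d_j} is the Mendelian
#' sampling variance coefficient, and \eqn{F_i = a_{ii} - 1}. Founders and
#' animals with an unknown parent have \eqn{F = 0}.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @return named numeric vector of inbreeding coefficients in pedigree order.
#' @references Meuwissen & Luo (1992) Computing inbreeding coefficients in
#'   large populations. Genet Sel Evol 24:305-313.
#' @export
setMethod("inbreeding", "Pedigree", function(ped) {
  n <- nAnimals(ped); s <- ped@sire; d <- ped@dam
  F <- numeric(n); D <- numeric(n); L <- numeric(n)
  for (i in seq_len(n)) {
    ks <- !is.na(s[i]); kd <- !is.na(d[i])
    D[i] <- if (ks && kd) 0.5 - 0.25 * (F[s[i]] + F[d[i]])
            else if (ks) 0.75 - 0.25 * F[s[i]]
            else if (kd) 0.75 - 0.25 * F[d[i]]
            else 1
    if (!(ks && kd)) next  # F stays 0
    anc <- .ancestorClosure(ped, i)
    anc <- sort(anc, decreasing = TRUE)  # descendants first
    L[i] <- 1; aii <- 0
    for (j in anc) {
      lj <- L[j]
      if (lj == 0) next
      aii <- aii + lj * lj * D[j]
      if (!is.na(s[j])) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (!is.na(d[j])) L[d[j]] <- L[d[j]] + 0.5 * lj
    }
    L[anc] <- 0
    F[i] <- aii - 1
  }
  names(F) <- ped@id
  F
})

#' Dense numerator relationship matrix (tabular method)
#'
#' Builds A by the tabular recursion: for \eqn{j < i},
#' \eqn{a_{ij} = 0.5 (a_{j,s(i)} + a_{j,d(i)})} with an unknown parent
#' contributing 0, and \eqn{a_{ii} = 1 + 0.5 a_{s(i),d(i)}}.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param maxAnimals guard against accidental dense construction for large
#'   pedigrees (default 5000); use \code{\link{aInverse}} beyond it.
#' @return A \linkS4class{RelationshipMatrix}.
#' @export
aMatrix <- function(ped, maxAnimals = 5000L) {
  stopifnot(is(ped, "Pedigree"))
  n <- nAnimals(ped)
  if (n > maxAnimals)
    stop("pedigree has ", n, " animals (> maxAnimals = ", maxAnimals,
         "); use the sparse inverse path (aInverse) for estimation")
  A <- matrix(0, n, n)
  s <- ped@sire; d <- ped@dam
  for (i in seq_len(n)) {
    above <- seq_len(i - 1L)
    rel <- numeric(i - 1L)
    if (!is.na(s[i])) rel <- rel + 0.5 * A[above, s[i]]
    if (!is.na(d[i])) rel <- rel + 0.5 * A[above, d[i]]
    A[above, i] <- rel; A[i, above] <- rel
    A[i, i] <- 1 + if (!is.na(s[i]) && !is.na(d[i])) 0.5 * A[s[i], d[i]] else 0
  }
  dimnames(A) <- list(ped@id, ped@id)
  new("RelationshipMatrix", ids = ped@id, values = A, inbreeding = diag(A) - 1)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with the inbreeding adjustment: animal \eqn{i}
#' contributes \eqn{\alpha_i = 1/d_i} to cell \eqn{(i,i)},
#' \eqn{-\alpha_i/2} to the animal-parent cells and \eqn{\alpha_i/4} to the
#' parent-parent cells, where
#' \eqn{d_i = 0.5 - 0.25 (F_s + F_d)} with both parents known,
#' \eqn{0.75 - 0.25 F_p} with one, and 1 with none.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @return symmetric sparse matrix (\code{Matrix::dsCMatrix}) with
#'   dimnames = animal ids in pedigree order.
#' @export
aInverse <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- nAnimals(ped)
  F <- inbreeding(ped)
  s <- ped@sire; d <- ped@dam
  ks <- !is.na(s); kd <- !is.na(d)
  dvec <- ifelse(ks & kd, 0.5 - 0.25 * (F[ifelse(ks, s, 1L)] + F[ifelse(kd, d, 1L)]),
          ifelse(ks, 0.75 - 0.25 * F[ifelse(ks, s, 1L)],
          ifelse(kd, 0.75 - 0.25 * F[ifelse(kd, d, 1L)], 1)))
  if (any(dvec <= 0))
    stop("numerical pedigree inconsistency: Mendelian variance d_i <= 0 for ",
         paste(ped@id[dvec <= 0], collapse = ", "))
  alpha <- 1 / dvec
  ws <- which(ks); wd <- which(kd); wsd <- which(ks & kd)
  # accumulate the full (both-triangle) pattern; sparseMatrix sums duplicates
  trip_i <- c(seq_len(n),                    # (i,i): alpha
              ws, s[ws],                     # (i,s) and (s,i): -alpha/2
              wd, d[wd],                     # (i,d) and (d,i): -alpha/2
              s[ws], d[wd],                  # (s,s), (d,d): alpha/4
              s[wsd], d[wsd])                # (s,d) and (d,s): alpha/4
  trip_j <- c(seq_len(n),
              s[ws], ws,
              d[wd], wd,
              s[ws], d[wd],
              d[wsd], s[wsd])
  trip_x <- c(alpha,
              -0.5 * alpha[ws], -0.5 * alpha[ws],
              -0.5 * alpha[wd], -0.5 * alpha[wd],
              0.25 * alpha[ws], 0.25 * alpha[wd],
              0.25 * alpha[wsd], 0.25 * alpha[wsd])
  M <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x, dims = c(n, n))
  M <- Matrix::forceSymmetric(M, uplo = "U")
  dimnames(M) <- list(ped@id, ped@id)
  M
}

#' Relationship submatrix through the full pedigree
#'
#' Relationships among \code{ids} computed through the complete pedigree and
#' then restricted — e.g. the service-sire relationship matrix
#' \eqn{A_{SS}}. Columns of A are obtained by sparse solves against
#' \code{aInverse(ped)}, so no dense full-pedigree A is formed.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param ids identifiers to keep (must all be in the pedigree).
#' @return A \linkS4class{RelationshipMatrix} over \code{ids} (in pedigree
#'   order).
#' @export
subsetRelationship <- function(ped, ids) {
  stopifnot(is(ped, "Pedigree"))
  ids <- as.character(ids)
  missing <- setdiff(ids, ped@id)
  if (length(missing))
    stop("ids not in pedigree: ", paste(missing, collapse = ", "))
  idx <- sort(match(unique(ids), ped@id))
  Ainv <- aInverse(ped)
  n <- nAnimals(ped)
  E <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                            dims = c(n, length(idx)))
  cols <- as.matrix(Matrix::solve(Ainv, E))
  V <- cols[idx, , drop = FALSE]
  V <- (V + t(V)) / 2
  dimnames(V) <- list(ped@id[idx], ped@id[idx])
  new("RelationshipMatrix", ids = ped@id[idx], values = V,
      inbreeding = diag(V) - 1)
}

#' Prune a pedigree to phenotyped animals and their ancestors
#'
#' Keeps the given animals (phenotyped cows and/or service sires) plus every
#' ancestor reachable through sire/dam links; all other animals are dropped.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param phenotyped identifiers to keep (with their ancestors).
#' @return the pruned, still-sorted \linkS4class{Pedigree}.
#' @export
pruneToAncestors <- function(ped, phenotyped) {
  stopifnot(is(ped, "Pedigree"))
  phenotyped <- intersect(as.character(phenotyped), ped@id)
  if (!length(phenotyped)) stop("no phenotyped animals found in pedigree")
  keep <- .ancestorClosure(ped, match(phenotyped, ped@id))
  keep <- sort(keep)
  map <- rep(NA_integer_, nAnimals(ped)); map[keep] <- seq_along(keep)
  new("Pedigree", id = ped@id[keep],
      sire = ifelse(is.na(ped@sire[keep]), NA_integer_, map[ped@sire[keep]]),
      dam = ifelse(is.na(ped@dam[keep]), NA_integer_, map[ped@dam[keep]]))
}

#' Export a sparse A-inverse as coordinate text
#'
#' Writes the upper triangle as three columns (i, j, value) with 1-based
#' indices referring to the sorted pedigree order.
#'
#' @param ainv sparse symmetric matrix from \code{\link{aInverse}}.
#' @param path output file path.
#' @export
writeAinvCoordinates <- function(ainv, path) {
  T <- as(as(ainv, "generalMatrix"), "TsparseMatrix")
  keep <- T@i <= T@j
  df <- data.frame(i = T@i[keep] + 1L, j = T@j[keep] + 1L, value = T@x[keep])
  df <- df[order(df$i, df$j), ]
  write.table(df, path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
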