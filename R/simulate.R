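#' True generating parameters for a synthetic fertility dataset
#'
#' Bundles the parameters the simulator draws from, so recovery tests can
#' compare estimates against known truth. All variances are in squared trait
#' units (days^2 for intervals); the liability threshold drives the binary
#' 56-day non-return outcome.
#'
#' @param mu trait mean (days / count / liability units).
#' @param sigma2 named numeric of true variance components: \code{a}
#'   (additive), optionally \code{hy} (herd-year), \code{ss} (service sire),
#'   and \code{e} (residual).
#' @param nHY number of herd-year classes.
#' @param nFixedLevels levels of the single composite fixed effect the
#'   model-based generator uses (region x birth year-month stand-in).
#' @param fixedSd spread (SD) of the fixed-level means.
#' @param G,HY,SS,R optional 2x2 covariance matrices for bivariate
#'   (heifer/cow) generation.
#' @param liabilityMu mean of the conception liability (events generator);
#'   services succeed when liability exceeds 0, so the per-service conception
#'   probability is \eqn{\Phi(liabilityMu/\sigma_l)}.
#' @param dupRate,corruptRate fractions of records duplicated exactly /
#'   duplicated with a corrupted birth date, to exercise the editing rules.
#' @return an object of class \code{SimTruth} (a validated list).
#' @export
simTruth <- function(mu = 780, sigma2 = c(a = 1137, hy = 1300, e = 3462),
                     nHY = 200, nFixedLevels = 12, fixedSd = 10,
                     G = NULL, HY = NULL, SS = NULL, R = NULL,
                     liabilityMu = 0.1, dupRate = 0, corruptRate = 0) {
  stopifnot(all(sigma2 >= 0), "a" %in% names(sigma2), "e" %in% names(sigma2))
  for (M in list(G, HY, SS, R))
    if (!is.null(M)) {
      stopifnot(is.matrix(M), all(dim(M) == 2), abs(M[1, 2] - M[2, 1]) < 1e-12)
      if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
        stop("covariance matrices must be positive semi-definite")
    }
  structure(list(mu = mu, sigma2 = sigma2, nHY = nHY,
                 nFixedLevels = nFixedLevels, fixedSd = fixedSd,
                 G = G, HY = HY, SS = SS, R = R, liabilityMu = liabilityMu,
                 dupRate = dupRate, corruptRate = corruptRate),
            class = "SimTruth")
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations: founders (generation 1) are unrelated; every animal
#' of a later generation gets a sire and dam sampled from the previous
#' generation, with few sires heavily reused so that large paternal half-sib
#' families (the service-sire structure of dairy data) arise. The population
#' is closed, so inbreeding accumulates over generations.
#'
#' @param nSires founder (and per-generation) number of breeding males.
#' @param nDams founder number of females.
#' @param nGenerations total number of generations (1 = founders only).
#' @param offspringPerGeneration females + males born per later generation.
#' @param maleFraction fraction of offspring that are male (candidate sires).
#' @param nSiresUsed number of males of a generation that actually breed
#'   (default: all); small values give the large paternal half-sib families
#'   typical of AI dairy populations.
#' @param seed optional integer seed (\code{set.seed}) for reproducibility.
#' @return a \linkS4class{Pedigree}; male ids start with "M", female with "F",
#'   followed by generation number.
#' @export
simulatePedigree <- function(nSires = 20, nDams = 200, nGenerations = 3,
                             offspringPerGeneration = nDams,
                             maleFraction = 0.1, nSiresUsed = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nSires >= 1, nDams >= 1, nGenerations >= 1)
  fmt <- function(sex, gen, k) sprintf("%s%d_%05d", sex, gen, seq_len(k))
  id <- c(fmt("M", 1, nSires), fmt("F", 1, nDams))
  sire <- dam <- rep(NA_character_, length(id))
  males <- id[seq_len(nSires)]
  females <- id[nSires + seq_len(nDams)]
  if (nGenerations > 1) for (g in 2:nGenerations) {
    k <- offspringPerGeneration
    nm <- max(1L, round(k * maleFraction))
    nf <- k - nm
    kid <- c(fmt("M", g, nm), fmt("F", g, nf))
    breeding <- if (is.null(nSiresUsed)) males
                else males[seq_len(min(nSiresUsed, length(males)))]
    ks <- sample(breeding, k, replace = TRUE,
                 prob = stats::rgamma(length(breeding), 1.5))  # unequal sire use
    kd <- sample(females, k, replace = TRUE)
    id <- c(id, kid); sire <- c(sire, ks); dam <- c(dam, kd)
    males <- kid[seq_len(nm)]; females <- kid[nm + seq_len(nf)]
  }
  pedigree(id, sire, dam, unknownToken = NA)
}

#' Simulate additive genetic values by Mendelian sampling
#'
#' Walks the sorted pedigree: founders draw from \eqn{N(0, \sigma^2_a)} (or
#' \eqn{N_2(0, G)}), non-founders get the parent average plus a Mendelian
#' deviation with variance \eqn{\sigma^2_a (0.5 - 0.25 (F_s + F_d))}
#' (\eqn{0.75 - 0.25 F_p} with one known parent). This reproduces
#' \eqn{a \sim N(0, A \sigma^2_a)} exactly, in linear time, without forming A.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param sigma2a additive variance (scalar), or a 2x2 genetic covariance
#'   matrix \code{G} for a correlated pair of traits.
#' @return numeric vector (or n x 2 matrix) of breeding values, named by
#'   animal id.
#' @export
simulateBreedingValues <- function(ped, sigma2a) {
  stopifnot(is(ped, "Pedigree"))
  n <- nAnimals(ped)
  F <- inbreeding(ped)
  s <- ped@sire; d <- ped@dam
  ks <- !is.na(s); kd <- !is.na(d)
  coef <- ifelse(ks & kd, 0.5 - 0.25 * (F[ifelse(ks, s, 1L)] + F[ifelse(kd, d, 1L)]),
          ifelse(ks, 0.75 - 0.25 * F[ifelse(ks, s, 1L)],
          ifelse(kd, 0.75 - 0.25 * F[ifelse(kd, d, 1L)], 1)))
  if (is.matrix(sigma2a)) {
    G <- sigma2a
    L <- if (all(G == 0)) matrix(0, 2, 2) else t(chol(G + diag(1e-12 * max(diag(G), 1), 2)))
    Zm <- matrix(rnorm(2 * n), n, 2)
    a <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      pa <- numeric(2)
      if (ks[i]) pa <- pa + 0.5 * a[s[i], ]
      if (kd[i]) pa <- pa + 0.5 * a[d[i], ]
      a[i, ] <- pa + sqrt(coef[i]) * as.numeric(L %*% Zm[i, ])
    }
    rownames(a) <- ped@id
    return(a)
  }
  z <- rnorm(n, sd = sqrt(pmax(coef * sigma2a, 0)))
  a <- numeric(n)
  for (i in seq_len(n)) {
    pa <- 0
    if (ks[i]) pa <- pa + 0.5 * a[s[i]]
    if (kd[i]) pa <- pa + 0.5 * a[d[i]]
    a[i] <- pa + z[i]
  }
  names(a) <- ped@id
  a
}

## assign service sires to records: reuse pedigree males heavily
.sampleServiceSires <- function(ped, n, nSS = NULL) {
  males <- ped@id[startsWith(ped@id, "M")]
  if (!length(males)) males <- ped@id[seq_len(min(10, nAnimals(ped)))]
  if (!is.null(nSS)) males <- males[seq_len(min(nSS, length(males)))]
  sample(males, n, replace = TRUE)
}

#' Simulate phenotypes directly from the animal model
#'
#' Draws \eqn{y = \mu + fixed + a + hy (+ ss) + e} for the phenotyped females
#' of a pedigree, with the additive values from
#' \code{\link{simulateBreedingValues}}, herd-year and service-sire effects
#' from their model distributions, and iid residuals. This is the generator
#' used for REML parameter-recovery checks; event-level records come from
#' \code{\link{simulateEvents}}.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param truth a \code{\link{simTruth}} object; components of
#'   \code{truth$sigma2} decide which random effects exist.
#' @param trait,stage labels stored on the resulting dataset; the default
#'   "SIM" marks an unconstrained Gaussian phenotype (trait-specific range
#'   validity applies only to the real trait codes).
#' @param phenotyped ids of animals with records (default: all females of the
#'   last generation present, i.e. ids starting "F" with the maximal
#'   generation tag; falls back to all animals).
#' @param nSS number of distinct service sires to use (males of the pedigree).
#' @param seed optional integer seed.
#' @return list with \code{dataset} (a \linkS4class{TraitDataset}),
#'   \code{bv} (all true breeding values) and \code{truth}.
#' @export
simulateTraitDataset <- function(ped, truth = simTruth(), trait = "SIM",
                                 stage = "heifer", phenotyped = NULL,
                                 nSS = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is(ped, "Pedigree"), inherits(truth, "SimTruth"))
  if (is.null(phenotyped)) {
    f <- ped@id[startsWith(ped@id, "F")]
    if (length(f)) {
      gen <- sub("^F(\\d+)_.*$", "\\1", f)
      phenotyped <- f[gen == max(gen)]
    } else phenotyped <- ped@id
  }
  n <- length(phenotyped)
  s2 <- truth$sigma2
  a <- simulateBreedingValues(ped, s2[["a"]])
  y <- truth$mu + a[phenotyped] + rnorm(n, sd = sqrt(s2[["e"]]))
  fixedLev <- sprintf("L%02d", sample.int(truth$nFixedLevels, n, replace = TRUE))
  fixedEff <- rnorm(truth$nFixedLevels, sd = truth$fixedSd)
  names(fixedEff) <- sprintf("L%02d", seq_len(truth$nFixedLevels))
  y <- y + fixedEff[fixedLev]
  hy <- character(0); ss <- character(0)
  if ("hy" %in% names(s2)) {
    hy <- sprintf("HY%03d", sample.int(truth$nHY, n, replace = TRUE))
    hyEff <- rnorm(truth$nHY, sd = sqrt(s2[["hy"]]))
    y <- y + hyEff[as.integer(substring(hy, 3))]
  }
  if ("ss" %in% names(s2)) {
    ss <- .sampleServiceSires(ped, n, nSS)
    ssBv <- simulateBreedingValues(ped, s2[["ss"]])  # independent genetic draw
    y <- y + ssBv[ss]
  }
  ds <- new("TraitDataset", trait = trait, stage = stage,
            animalId = phenotyped, y = as.numeric(y),
            fixed = data.frame(RYM = fixedLev, stringsAsFactors = FALSE),
            hy = hy, ss = ss)
  list(dataset = ds, bv = a, truth = truth)
}

#' Simulate correlated heifer/cow phenotypes from the bivariate model
#'
#' Generates two stage-specific datasets for the same trait with additive
#' covariance \eqn{G \otimes A}, herd-year covariance \eqn{HY \otimes I},
#' optional service-sire covariance \eqn{SS \otimes A}, and residual
#' covariance linking the records of animals measured at both stages.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param truth a \code{\link{simTruth}} with 2x2 \code{G}, \code{HY},
#'   \code{R} (and optionally \code{SS}) matrices.
#' @param trait trait label; the default "NRRliab" marks a continuous
#'   liability-scale stand-in for the binary non-return outcome (binary
#'   validity rules apply only to the "NRR" label itself).
#' @param overlapFraction fraction of phenotyped females recorded at both
#'   stages (heifer record and cow record).
#' @param mu length-2 stage means.
#' @param nSS number of distinct service sires.
#' @param seed optional integer seed.
#' @return list with \code{heifer} and \code{cow}
#'   \linkS4class{TraitDataset}s, \code{bv} (n x 2 true breeding values) and
#'   \code{truth}.
#' @export
simulateBivariate <- function(ped, truth, trait = "NRRliab",
                              overlapFraction = 0.6, mu = c(0.3, 0.46),
                              nSS = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(truth, "SimTruth"), !is.null(truth$G), !is.null(truth$HY),
            !is.null(truth$R))
  f <- ped@id[startsWith(ped@id, "F")]
  if (!length(f)) f <- ped@id
  gen <- sub("^[MF](\\d+)_.*$", "\\1", f)
  females <- f[gen == max(gen)]
  n <- length(females)
  both <- sort(sample.int(n, round(overlapFraction * n)))
  hasH <- seq_len(n)                       # all get a heifer record
  hasC <- both                             # a subset also a cow record
  bv <- simulateBreedingValues(ped, truth$G)
  rch <- function(M) t(chol(M + diag(1e-12 * max(diag(M), 1e-12), 2)))
  hyLab <- sprintf("HY%03d", sample.int(truth$nHY, n, replace = TRUE))
  hyEff <- matrix(rnorm(2 * truth$nHY), truth$nHY, 2) %*% t(rch(truth$HY))
  ssLab <- .sampleServiceSires(ped, n, nSS)
  ssEff <- if (!is.null(truth$SS)) simulateBreedingValues(ped, truth$SS)
           else matrix(0, nAnimals(ped), 2, dimnames = list(ped@id, NULL))
  resid <- matrix(rnorm(2 * n), n, 2)
  # correlated residuals only for double-recorded animals
  residBoth <- resid %*% t(rch(truth$R))
  residSolo <- cbind(resid[, 1] * sqrt(truth$R[1, 1]), resid[, 2] * sqrt(truth$R[2, 2]))
  e <- residSolo; e[both, ] <- residBoth[both, ]
  hyi <- as.integer(substring(hyLab, 3))
  yH <- mu[1] + bv[females, 1] + hyEff[hyi, 1] + ssEff[ssLab, 1] + e[, 1]
  yC <- mu[2] + bv[females, 2] + hyEff[hyi, 2] + ssEff[ssLab, 2] + e[, 2]
  mk <- function(idx, y, stg) {
    hasSS <- !is.null(truth$SS)
    new("TraitDataset", trait = trait, stage = stg, animalId = females[idx],
        y = as.numeric(y[idx]),
        fixed = data.frame(mu = rep("1", length(idx)), stringsAsFactors = FALSE),
        hy = hyLab[idx], ss = if (hasSS) ssLab[idx] else character(0))
  }
  list(heifer = mk(hasH, yH, "heifer"), cow = mk(hasC, yC, "cow"),
       bv = bv, truth = truth)
}

.DAY_ORIGIN <- as.Date("2005-01-01")

#' Simulate fertility event records
#'
#' Generates one row per cow x parity: birth date, the insemination sequence
#' of each conception episode, service sires, conception and calving dates,
#' calf sex, farm and region. Interval traits arise from integer-day
#' placements \code{y = round(mu + a + hy (+ ss) + e)}, so
#' \code{\link{deriveTraits}} reconstructs the placed values exactly (they
#' are returned in \code{$placed}). The number of services per episode comes
#' from a per-service conception liability (success when liability > 0), the
#' 56-day non-return outcome is then deterministic from the simulated
#' insemination dates, and failed services are followed by a new insemination
#' one 21-day oestrous cycle later. Exact-duplicate and corrupted-duplicate
#' rows are injected at the rates in \code{truth} to exercise
#' \code{\link{mergeDedup}}.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param truth a \code{\link{simTruth}}; \code{sigma2} scales the gestation-
#'   length components, \code{liabilityMu} the conception liability.
#' @param females ids of cows to generate records for (default: all "F" ids).
#' @param nParities calvings simulated per cow after the first.
#' @param nFarms number of farms (regions = farms grouped in threes).
#' @param seed optional integer seed.
#' @return list with \code{records} (data.frame, one row per cow x parity,
#'   list-columns \code{insem_dates} and \code{service_sires}) and
#'   \code{placed} (data.frame of the exact integer trait values used to
#'   place the dates).
#' @export
simulateEvents <- function(ped, truth = simTruth(), females = NULL,
                           nParities = 2, nFarms = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is(ped, "Pedigree"))
  if (is.null(females)) females <- ped@id[startsWith(ped@id, "F")]
  if (!length(females)) females <- ped@id
  n <- length(females)
  aGL <- simulateBreedingValues(ped, 8.5)       # gestation-length genetics
  aLia <- simulateBreedingValues(ped, 0.05)     # conception liability genetics
  farm <- sprintf("FARM%02d", sample.int(nFarms, n, replace = TRUE))
  region <- paste0("R", (as.integer(substring(farm, 5)) - 1) %/% 3 + 1)
  birthYearSpread <- 3 * 365
  birth <- sample.int(birthYearSpread, n, replace = TRUE)
  hyLab <- paste0(farm, ":", 2005 + birth %/% 365)
  hyEff <- rnorm(length(unique(hyLab)), sd = 1.0)
  names(hyEff) <- unique(hyLab)
  rows <- vector("list", n * (nParities + 1))
  placed <- vector("list", n * (nParities + 1))
  k <- 0L
  for (i in seq_len(n)) {
    cow <- females[i]
    afs <- round(420 + 3 * aLia[cow] * 10 + rnorm(1, sd = 45))  # age at first service
    afs <- max(afs, 300)
    prevCalv <- NA_integer_
    cursor <- birth[i] + afs
    for (p in 0:nParities) {
      if (p > 0) {
        ctfs <- round(75 + 5 * aLia[cow] + hyEff[hyLab[i]] + rnorm(1, sd = 25))
        ctfs <- max(ctfs, 20)
        cursor <- prevCalv + ctfs
      }
      nServMax <- 9L
      insem <- cursor
      sires <- .sampleServiceSires(ped, 1)
      conceived <- FALSE
      for (srv in seq_len(nServMax)) {
        lia <- truth$liabilityMu + aLia[cow] + 0.1 * hyEff[hyLab[i]] + rnorm(1, sd = 0.3)
        if (lia > 0) { conceived <- TRUE; break }
        if (srv < nServMax) {
          insem <- c(insem, insem[length(insem)] + 21L)
          sires <- c(sires, .sampleServiceSires(ped, 1))
        }
      }
      concDate <- if (conceived) insem[length(insem)] else NA_integer_
      gl <- if (conceived)
        max(round(277 + aGL[cow] + rnorm(1, sd = sqrt(57))), 230) else NA_integer_
      calv <- if (conceived) concDate + gl else NA_integer_
      k <- k + 1L
      rows[[k]] <- data.frame(
        cow_id = cow, parity = p,
        birth_date = .DAY_ORIGIN + birth[i],
        previous_calving_date = .DAY_ORIGIN +
          ifelse(is.na(prevCalv), NA_integer_, prevCalv),
        conception_date = .DAY_ORIGIN + ifelse(conceived, concDate, NA_integer_),
        calving_date = .DAY_ORIGIN + ifelse(conceived, calv, NA_integer_),
        calf_sex = if (conceived) sample(c("M", "F"), 1) else NA_character_,
        farm_id = farm[i], region = region[i], stringsAsFactors = FALSE)
      rows[[k]]$insem_dates <- list(.DAY_ORIGIN + insem)
      rows[[k]]$service_sires <- list(sires)
      placed[[k]] <- data.frame(
        cow_id = cow, parity = p,
        AFS = if (p == 0) insem[1] - birth[i] else NA_integer_,
        CTFS = if (p > 0) insem[1] - prevCalv else NA_integer_,
        FSTC = if (conceived) concDate - insem[1] else NA_integer_,
        GL = gl,
        NS = length(insem),
        CI = if (p > 0 && conceived) calv - prevCalv else NA_integer_,
        DO = if (p > 0 && conceived) concDate - prevCalv else NA_integer_,
        AFC = if (p == 0 && conceived) calv - birth[i] else NA_integer_)
      if (!conceived) break
      prevCalv <- calv
    }
  }
  records <- do.call(rbind, rows[seq_len(k)])
  placed <- do.call(rbind, placed[seq_len(k)])
  # duplicate / corrupted-duplicate injection
  if (truth$dupRate > 0) {
    nd <- round(truth$dupRate * nrow(records))
    if (nd > 0) records <- rbind(records, records[sample.int(nrow(records), nd), ])
  }
  if (truth$corruptRate > 0) {
    nc <- round(truth$corruptRate * nrow(records))
    if (nc > 0) {
      bad <- records[sample.int(nrow(records), nc), ]
      bad$birth_date <- bad$birth_date + sample(30:300, nc, replace = TRUE)
      records <- rbind(records, bad)
    }
  }
  rownames(records) <- NULL
  list(records = records, placed = placed)
}

#' Deterministic miniature dataset
#'
#' A fixed-seed pedigree of at most 50 animals with event records, used in
#' documentation examples and exact regression tests. Identical on every
#' call.
#'
#' @return list with \code{pedigree}, \code{records}, \code{placed},
#'   \code{truth}.
#' @export
fixtureSmall <- function() {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  ped <- simulatePedigree(nSires = 4, nDams = 16, nGenerations = 3,
                          offspringPerGeneration = 15, seed = 4242)
  truth <- simTruth(dupRate = 0.05, corruptRate = 0.05)
  ev <- simulateEvents(ped, truth, nParities = 1, nFarms = 2, seed = 4242)
  list(pedigree = ped, records = ev$records, placed = ev$placed, truth = truth)
}
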