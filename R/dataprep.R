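## ---- record editing and trait derivation -----------------------------------

.TRAITS <- c("CI", "DO", "AFS", "AFC", "CTFS", "FSTC", "GL", "NRR", "NS")

## canonical string for one record row (list columns flattened) -- used to
## detect exact duplicates
.recordKey <- function(records, cols = names(records)) {
  flat <- lapply(records[cols], function(col) {
    if (is.list(col)) vapply(col, function(x) paste(format(x), collapse = ";"), "")
    else as.character(col)
  })
  do.call(paste, c(flat, sep = "\r"))
}

#' Merge and deduplicate event records
#'
#' One record per cow x parity: byte-identical duplicate rows are collapsed
#' to one; rows sharing a cow x parity key but disagreeing in any other field
#' (e.g. conflicting birth dates from different farm uploads) are dropped
#' entirely, since which of them is correct cannot be decided.
#'
#' @param records event-record data.frame (see \code{\link{simulateEvents}}
#'   for the column layout).
#' @return the cleaned records; attributes \code{nExactDup} and
#'   \code{nConflict} log how many rows each rule removed.
#' @export
mergeDedup <- function(records) {
  full <- .recordKey(records)
  keep1 <- !duplicated(full)
  nExact <- sum(!keep1)
  rec <- records[keep1, , drop = FALSE]
  key <- paste(rec$cow_id, rec$parity, sep = "\r")
  conflicted <- key %in% key[duplicated(key)]
  out <- rec[!conflicted, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nExactDup") <- nExact
  attr(out, "nConflict") <- sum(conflicted)
  out
}

.days <- function(a, b) as.integer(as.Date(a)) - as.integer(as.Date(b))
.monthOf <- function(d) format(as.Date(d), "%m")
.yearOf <- function(d) format(as.Date(d), "%Y")
.ageMonths <- function(d, birth) {
  ifelse(is.na(d) | is.na(birth), NA_integer_,
         as.integer(.days(d, birth) %/% 30.4375))
}
.firstInsem <- function(records) {
  as.Date(vapply(records$insem_dates, function(x)
    if (length(x)) as.integer(min(as.Date(x))) else NA_integer_, 1L), origin = "1970-01-01")
}

#' Default fixed/random effect layout per trait and stage
#'
#' The machine form of the effect table used throughout: which composite
#' fixed effects (RYM, Mf, MfX, AcMcX, ApMf, ApMp, ApMpX) and which random
#' effects (HY, SS, additive animal a) are fitted for each trait x stage.
#'
#' @param trait trait code (CI, DO, AFS, AFC, CTFS, FSTC, GL, NRR, NS).
#' @param stage "heifer", "cow" or "all".
#' @return a \linkS4class{ModelSpec}.
#' @export
defaultModelSpec <- function(trait, stage) {
  trait <- match.arg(trait, .TRAITS)
  stage <- match.arg(stage, c("heifer", "cow", "all"))
  h <- stage %in% c("heifer", "all")
  fx <- switch(trait,
    AFS = , AFC = "RYM",
    NRR = , NS = , FSTC = c("RYM", if (h) "Mf" else "ApMf"),
    GL = c("RYM", if (h) "MfX" else "ApMpX"),
    DO = c("RYM", "AcMcX"),
    CTFS = , CI = c("RYM", "ApMp"))
  if (stage == "all") fx <- c(fx, "stage")
  rnd <- c("HY", if (trait %in% c("NRR", "GL")) "SS", "a")
  new("ModelSpec", trait = trait, stage = stage, fixedEffects = fx,
      randomEffects = rnd)
}

#' Build fixed- and random-effect class labels for a set of records
#'
#' Composite labels are string-joins of their components: e.g. RYM = region
#' x year of birth x month of birth; AcMcX = age at current calving (whole
#' months) x month of current calving x calf sex x parity; ApMf / ApMp /
#' ApMpX use the age at the previous calving. HY is herd (farm) x year of
#' birth. The service sire is the bull of the first insemination for the
#' non-return outcome and the conceiving bull otherwise. Fixed-effect
#' classes with fewer than \code{minClassSize} records are merged into a
#' per-effect "OTHER" level to keep the mixed-model equations full rank.
#'
#' @param records event-record data.frame.
#' @param spec a \linkS4class{ModelSpec}.
#' @param minClassSize minimum records per fixed-effect class (default 3).
#' @return list with \code{fixed} (data.frame, one column per effect),
#'   \code{hy} and \code{ss} character vectors ("" columns when not fitted).
#' @export
buildEffectClasses <- function(records, spec, minClassSize = 3) {
  n <- nrow(records)
  need <- function(field, effect) {
    if (!field %in% names(records) || all(is.na(records[[field]])))
      stop("effect ", effect, " needs field '", field, "' which is missing")
    records[[field]]
  }
  fi <- .firstInsem(records)
  join <- function(...) paste(..., sep = ":")
  mkEffect <- function(eff) {
    switch(eff,
      RYM = join(need("region", "RYM"), .yearOf(need("birth_date", "RYM")),
                 .monthOf(records$birth_date)),
      Mf = .monthOf(fi),
      MfX = join(.monthOf(fi), need("calf_sex", "MfX")),
      AcMcX = join(.ageMonths(need("calving_date", "AcMcX"), records$birth_date),
                   .monthOf(records$calving_date), need("calf_sex", "AcMcX"),
                   records$parity),
      ApMf = join(.ageMonths(need("previous_calving_date", "ApMf"),
                             records$birth_date), .monthOf(fi), records$parity),
      ApMp = join(.ageMonths(need("previous_calving_date", "ApMp"),
                             records$birth_date),
                  .monthOf(records$previous_calving_date), records$parity),
      ApMpX = join(.ageMonths(need("previous_calving_date", "ApMpX"),
                              records$birth_date),
                   .monthOf(records$previous_calving_date), records$parity,
                   need("calf_sex", "ApMpX")),
      stage = ifelse(records$parity == 0, "heifer", "cow"),
      stop("unknown fixed effect: ", eff))
  }
  fixed <- as.data.frame(lapply(setNames(spec@fixedEffects, spec@fixedEffects),
                                mkEffect), optional = TRUE,
                         stringsAsFactors = FALSE)
  colnames(fixed) <- spec@fixedEffects
  for (j in seq_along(fixed)) {
    tab <- table(fixed[[j]])
    rare <- names(tab)[tab < minClassSize]
    if (length(rare) && length(rare) < length(tab))
      fixed[[j]][fixed[[j]] %in% rare] <- "OTHER"
  }
  hy <- if ("HY" %in% spec@randomEffects)
    join(need("farm_id", "HY"), .yearOf(need("birth_date", "HY"))) else character(0)
  ss <- character(0)
  if ("SS" %in% spec@randomEffects) {
    pickFirst <- identical(spec@trait, "NRR")
    ss <- vapply(records$service_sires, function(x) {
      if (!length(x)) NA_character_
      else if (pickFirst) as.character(x[[1]])
      else as.character(x[[length(x)]])
    }, "")
  }
  list(fixed = fixed, hy = hy, ss = ss)
}

## subset every per-record element of an effect-class list
.subsetClasses <- function(cls, keep) {
  list(fixed = cls$fixed[keep, , drop = FALSE],
       hy = if (length(cls$hy)) cls$hy[keep] else cls$hy,
       ss = if (length(cls$ss)) cls$ss[keep] else cls$ss)
}

.newTraitDataset <- function(trait, stage, records, y, keep, minClassSize) {
  keep <- keep & !is.na(y)
  spec <- defaultModelSpec(trait, stage)
  cls <- buildEffectClasses(records[keep, , drop = FALSE], spec, minClassSize)
  ds <- new("TraitDataset", trait = trait, stage = stage,
            animalId = as.character(records$cow_id[keep]),
            y = as.numeric(y[keep]), fixed = cls$fixed, hy = cls$hy, ss = cls$ss)
  attr(ds, "nSkipped") <- sum(!keep)
  ds
}

#' Derive fertility traits from event records
#'
#' Computes, in integer days (count for NS, 0/1 for the 56-day non-return
#' outcome), per cow x parity episode:
#' \itemize{
#' \item CI: calving interval, this calving minus the previous calving (cows);
#' \item DO: days open, conception minus the previous calving (cows);
#' \item CTFS: previous calving to first insemination (cows);
#' \item FSTC: first insemination to conception (0 when the first service
#'   conceives);
#' \item GL: gestation length, calving minus conception;
#' \item AFS: age at first-ever insemination (heifers);
#' \item AFC: age at first calving (heifers);
#' \item NS: number of services in the conception episode;
#' \item NRR: see \code{\link{codeNRR}}.
#' }
#' Records missing a required date are skipped for that trait (counted in
#' attribute \code{nSkipped}). The heifer stage is the parity-0 episode.
#'
#' @param records merged event records (see \code{\link{mergeDedup}}).
#' @param traits which traits to derive (default: all).
#' @param minClassSize passed to \code{\link{buildEffectClasses}}.
#' @param nrrWindow,nrrAnchor passed to \code{\link{codeNRR}}.
#' @return named list of \linkS4class{TraitDataset}s, keys like
#'   \code{"FSTC.cow"}; stage-specific only where the trait exists for the
#'   stage (CI/DO/CTFS cows, AFS/AFC heifers).
#' @export
deriveTraits <- function(records, traits = .TRAITS, minClassSize = 3,
                         nrrWindow = 56, nrrAnchor = "insemination") {
  traits <- match.arg(traits, .TRAITS, several.ok = TRUE)
  fi <- .firstInsem(records)
  heifer <- records$parity == 0
  cow <- !heifer
  out <- list()
  addBoth <- function(trait, y, ok) {
    out[[paste0(trait, ".heifer")]] <<-
      .newTraitDataset(trait, "heifer", records, y, ok & heifer, minClassSize)
    out[[paste0(trait, ".cow")]] <<-
      .newTraitDataset(trait, "cow", records, y, ok & cow, minClassSize)
  }
  for (tr in traits) switch(tr,
    CI = {
      y <- .days(records$calving_date, records$previous_calving_date)
      out[["CI.cow"]] <- .newTraitDataset("CI", "cow", records, y,
                                          cow & !is.na(y) & y > 0, minClassSize)
    },
    DO = {
      y <- .days(records$conception_date, records$previous_calving_date)
      out[["DO.cow"]] <- .newTraitDataset("DO", "cow", records, y,
                                          cow & !is.na(y) & y > 0, minClassSize)
    },
    CTFS = {
      y <- .days(fi, records$previous_calving_date)
      out[["CTFS.cow"]] <- .newTraitDataset("CTFS", "cow", records, y,
                                            cow & !is.na(y) & y > 0, minClassSize)
    },
    FSTC = {
      y <- .days(records$conception_date, fi)
      addBoth("FSTC", y, !is.na(y) & y >= 0)
    },
    GL = {
      y <- .days(records$calving_date, records$conception_date)
      addBoth("GL", y, !is.na(y) & y > 0)
    },
    AFS = {
      y <- .days(fi, records$birth_date)
      out[["AFS.heifer"]] <- .newTraitDataset("AFS", "heifer", records, y,
                                              heifer & !is.na(y) & y > 0,
                                              minClassSize)
    },
    AFC = {
      y <- .days(records$calving_date, records$birth_date)
      out[["AFC.heifer"]] <- .newTraitDataset("AFC", "heifer", records, y,
                                              heifer & !is.na(y) & y > 0,
                                              minClassSize)
    },
    NS = {
      y <- vapply(seq_len(nrow(records)), function(i) {
        ins <- as.Date(records$insem_dates[[i]])
        cd <- records$conception_date[i]
        if (!length(ins)) return(NA_integer_)
        if (is.na(cd)) length(ins) else sum(ins <= as.Date(cd))
      }, 1L)
      addBoth("NS", y, !is.na(y) & y >= 1)
    },
    NRR = {
      nr <- codeNRR(records, windowDays = nrrWindow, anchor = nrrAnchor,
                    minClassSize = minClassSize, split = TRUE)
      out[["NRR.heifer"]] <- nr$heifer
      out[["NRR.cow"]] <- nr$cow
    })
  out
}

#' Code the 56-day non-return outcome
#'
#' A record is coded 1 (no return) when no further insemination occurs
#' within \code{windowDays} after the anchor date, else 0. The anchor is the
#' first insemination by default — the definition the trait's name carries —
#' with the previous calving available as an alternative anchoring.
#'
#' @param records merged event records with known first insemination.
#' @param windowDays length of the non-return window (default 56).
#' @param anchor "insemination" (default) or "calving" (previous calving).
#' @param minClassSize passed to \code{\link{buildEffectClasses}}.
#' @param split return per-stage datasets (list heifer/cow) instead of one.
#' @return a \linkS4class{TraitDataset} (stage "all"), or a list of two when
#'   \code{split = TRUE}.
#' @export
codeNRR <- function(records, windowDays = 56, anchor = c("insemination", "calving"),
                    minClassSize = 3, split = FALSE) {
  anchor <- match.arg(anchor)
  fi <- .firstInsem(records)
  anchorDate <- if (anchor == "insemination") fi else
    as.Date(records$previous_calving_date)
  y <- vapply(seq_len(nrow(records)), function(i) {
    ins <- sort(as.Date(records$insem_dates[[i]]))
    if (!length(ins) || is.na(anchorDate[i])) return(NA_integer_)
    later <- ins[ins > fi[i]]
    as.integer(!any(later - anchorDate[i] <= windowDays))
  }, 1L)
  ok <- !is.na(y)
  if (split) {
    heifer <- records$parity == 0
    list(heifer = .newTraitDataset("NRR", "heifer", records, y, ok & heifer,
                                   minClassSize),
         cow = .newTraitDataset("NRR", "cow", records, y, ok & !heifer,
                                minClassSize))
  } else .newTraitDataset("NRR", "all", records, y, ok, minClassSize)
}

#' Outlier mask by the k-standard-deviation rule
#'
#' Single pass, two-sided: record i is kept iff
#' \eqn{|y_i - \bar y| \le k \, s}, with \eqn{s} the n-1 sample standard
#' deviation of the full vector. A zero-variance vector keeps everything.
#'
#' @param y numeric vector (length >= 2).
#' @param k multiplier (default 4).
#' @param twoSided drop only the upper tail when \code{FALSE}.
#' @return logical keep mask.
#' @export
filterOutliers <- function(y, k = 4, twoSided = TRUE) {
  stopifnot(length(y) >= 2, k > 0)
  s <- sd(y)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(y)))
  dev <- y - mean(y)
  if (twoSided) abs(dev) <= k * s else dev <= k * s
}

#' Apply the outlier rule to a trait dataset
#'
#' @param ds a \linkS4class{TraitDataset}.
#' @param k SD multiplier (default 4); the rule is skipped for the binary
#'   non-return outcome.
#' @return the filtered dataset; attribute \code{nOutliers} logs removals.
#' @export
filterTraitOutliers <- function(ds, k = 4) {
  if (identical(ds@trait, "NRR") || length(ds@y) < 2) return(ds)
  keep <- filterOutliers(ds@y, k = k)
  out <- subsetTraitDataset(ds, keep)
  attr(out, "nOutliers") <- sum(!keep)
  out
}

#' Subset a trait dataset by a record mask or index
#' @param ds a \linkS4class{TraitDataset}.
#' @param keep logical mask or integer index over records.
#' @export
subsetTraitDataset <- function(ds, keep) {
  new("TraitDataset", trait = ds@trait, stage = ds@stage,
      animalId = ds@animalId[keep], y = ds@y[keep],
      fixed = ds@fixed[keep, , drop = FALSE],
      hy = if (length(ds@hy)) ds@hy[keep] else ds@hy,
      ss = if (length(ds@ss)) ds@ss[keep] else ds@ss)
}

#' Drop records of animals absent from the pedigree
#'
#' @param ds a \linkS4class{TraitDataset}.
#' @param ped a \linkS4class{Pedigree}.
#' @return the matched dataset; attribute \code{nUnmatched} logs removals.
#' @export
matchPedigree <- function(ds, ped) {
  keep <- ds@animalId %in% pedigreeIds(ped)
  out <- subsetTraitDataset(ds, keep)
  attr(out, "nUnmatched") <- sum(!keep)
  out
}

#' @export
setGeneric("descriptiveStats", function(ds) standardGeneric("descriptiveStats"))

#' Descriptive statistics of a trait dataset
#'
#' @param ds a \linkS4class{TraitDataset} or a list of them.
#' @return data.frame with trait, stage, N, mean, SD (n-1), min, max.
#' @export
setMethod("descriptiveStats", "TraitDataset", function(ds) {
  data.frame(trait = ds@trait, stage = ds@stage, N = length(ds@y),
             mean = mean(ds@y), SD = sd(ds@y),
             min = min(ds@y), max = max(ds@y), stringsAsFactors = FALSE)
})

#' @export
setMethod("descriptiveStats", "list", function(ds)
  do.call(rbind, lapply(ds, descriptiveStats)))

## ---- events file I/O --------------------------------------------------------

#' Write event records as delimited text
#'
#' List columns (insemination dates, service sires) are ";"-joined; dates are
#' ISO-8601.
#' @param records event-record data.frame.
#' @param path output path.
#' @export
writeEvents <- function(records, path) {
  out <- records
  out$insem_dates <- vapply(records$insem_dates,
                            function(x) paste(format(as.Date(x)), collapse = ";"), "")
  out$service_sires <- vapply(records$service_sires,
                              function(x) paste(x, collapse = ";"), "")
  write.table(out, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read event records written by \code{\link{writeEvents}}
#' @param path input path.
#' @return event-record data.frame with parsed dates and list columns.
#' @export
readEvents <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  for (col in intersect(c("birth_date", "previous_calving_date",
                          "conception_date", "calving_date"), names(df)))
    df[[col]] <- as.Date(df[[col]])
  df$parity <- as.integer(df$parity)
  df$insem_dates <- lapply(strsplit(df$insem_dates, ";", fixed = TRUE), as.Date)
  df$service_sires <- strsplit(df$service_sires, ";", fixed = TRUE)
  df
}
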