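## shared fixture builders; everything is generated in code at test time

# random valid pedigree (as raw triples, unsorted) for property-style tests
randomPedigreeTriples <- function(nFounders = 20, nOffspring = 80) {
  nm <- max(2L, round(nFounders * 0.3))
  males <- sprintf("SIR%03d", seq_len(nm))
  females <- sprintf("DAM%03d", seq_len(nFounders - nm))
  animal <- c(males, females)
  sire <- dam <- rep("0", length(animal))
  for (i in seq_len(nOffspring)) {
    id <- sprintf("OFF%03d", i)
    s <- sample(males, 1)
    d <- sample(females, 1)
    animal <- c(animal, id); sire <- c(sire, s); dam <- c(dam, d)
    if (runif(1) < 0.15) males <- c(males, id) else females <- c(females, id)
  }
  o <- sample(length(animal))  # shuffle row order
  data.frame(animal = animal[o], sire = sire[o], dam = dam[o],
             stringsAsFactors = FALSE)
}

# hand-written five-animal pedigree with a full-sib mating (X inbred, F=1/4)
fullSibMatingPedigree <- function() {
  pedigree(c("A", "B", "C", "D", "X"),
           c("0", "0", "A", "A", "C"),
           c("0", "0", "B", "B", "D"))
}

# small single-trait simulation bundle used across REML tests
smallRemlFixture <- function(seed = 99, n = 400, sigma2 = c(a = 4, hy = 2, e = 10),
                             nHY = 10) {
  ped <- simulatePedigree(nSires = 8, nDams = round(n / 2), nGenerations = 3,
                          offspringPerGeneration = round(n * 0.55), seed = seed)
  truth <- simTruth(mu = 100, sigma2 = sigma2, nHY = nHY, nFixedLevels = 4,
                    fixedSd = 3)
  sim <- simulateTraitDataset(ped, truth, seed = seed + 1)
  spec <- new("ModelSpec", trait = "AFC", stage = "heifer",
              fixedEffects = "RYM", randomEffects = c("HY", "a"))
  list(ped = ped, ainv = aInverse(ped), sim = sim, spec = spec, truth = truth)
}

# tiny handcrafted event records: two cows, one parity each plus heifer stage
handEventRecords <- function() {
  mk <- function(cow, parity, birth, prevCalv, insems, conc, calv, sex, farm) {
    df <- data.frame(cow_id = cow, parity = parity,
                     birth_date = as.Date(birth),
                     previous_calving_date = as.Date(prevCalv),
                     conception_date = as.Date(conc),
                     calving_date = as.Date(calv),
                     calf_sex = sex, farm_id = farm, region = "R1",
                     stringsAsFactors = FALSE)
    df$insem_dates <- list(as.Date(insems))
    df$service_sires <- list(sprintf("BULL%02d", seq_along(insems)))
    df
  }
  rbind(
    # heifer episode: conceives at first service
    mk("COW1", 0, "2010-01-01", NA, "2011-04-01", "2011-04-01", "2012-01-05",
       "F", "FARM01"),
    # cow episode: three services, 21 d apart
    mk("COW1", 1, "2010-01-01", "2012-01-05", c("2012-03-20", "2012-04-10",
       "2012-05-01"), "2012-05-01", "2013-02-01", "M", "FARM01"),
    # second cow, heifer episode with two services
    mk("COW2", 0, "2010-02-01", NA, c("2011-05-01", "2011-05-22"),
       "2011-05-22", "2012-02-20", "F", "FARM02"))
}
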