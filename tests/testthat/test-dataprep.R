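test_that("mergeDedup collapses exact and drops conflicting duplicates", {
  rec <- handEventRecords()
  # exact duplicate -> one row survives
  out <- mergeDedup(rbind(rec, rec[1, ]))
  expect_equal(nrow(out), nrow(rec))
  expect_equal(attr(out, "nExactDup"), 1L)

  # same cow x parity, different birth date -> both rows dropped
  bad <- rec[1, ]; bad$birth_date <- bad$birth_date + 100
  out2 <- mergeDedup(rbind(rec, bad))
  expect_equal(nrow(out2), nrow(rec) - 1L)
  expect_equal(attr(out2, "nConflict"), 2L)
  expect_false(any(out2$cow_id == "COW1" & out2$parity == 0))

  # distinct parities of one cow both kept
  expect_equal(sum(mergeDedup(rec)$cow_id == "COW1"), 2L)
})

test_that("deriveTraits computes interval, count and age traits by date arithmetic", {
  rec <- handEventRecords()
  ds <- deriveTraits(rec, minClassSize = 1)

  # COW1 heifer: conceives at first service -> FSTC 0, NS 1
  fh <- ds[["FSTC.heifer"]]
  expect_equal(fh@y[fh@animalId == "COW1"], 0)
  nh <- ds[["NS.heifer"]]
  expect_equal(nh@y[nh@animalId == "COW1"], 1)
  expect_equal(nh@y[nh@animalId == "COW2"], 2)

  # COW1 cow episode, hand arithmetic
  expect_equal(ds[["CTFS.cow"]]@y,
               as.numeric(as.Date("2012-03-20") - as.Date("2012-01-05")))
  expect_equal(ds[["DO.cow"]]@y,
               as.numeric(as.Date("2012-05-01") - as.Date("2012-01-05")))
  expect_equal(ds[["CI.cow"]]@y,
               as.numeric(as.Date("2013-02-01") - as.Date("2012-01-05")))
  expect_equal(ds[["GL.cow"]]@y,
               as.numeric(as.Date("2013-02-01") - as.Date("2012-05-01")))
  expect_equal(ds[["FSTC.cow"]]@y,
               as.numeric(as.Date("2012-05-01") - as.Date("2012-03-20")))
  # ages
  expect_equal(sort(ds[["AFS.heifer"]]@y),
               sort(c(as.numeric(as.Date("2011-04-01") - as.Date("2010-01-01")),
                      as.numeric(as.Date("2011-05-01") - as.Date("2010-02-01")))))
  expect_equal(sort(ds[["AFC.heifer"]]@y),
               sort(c(as.numeric(as.Date("2012-01-05") - as.Date("2010-01-01")),
                      as.numeric(as.Date("2012-02-20") - as.Date("2010-02-01")))))
  # NS counts only services up to conception
  expect_equal(ds[["NS.cow"]]@y, 3)
})

test_that("codeNRR applies the window from the chosen anchor", {
  rec <- handEventRecords()
  nr <- codeNRR(rec, minClassSize = 1)
  # single insemination, none after -> 1 (no return)
  expect_equal(nr@y[nr@animalId == "COW1" & rec$parity[match(nr@animalId, rec$cow_id)] == 0][1], 1)
  # COW2: second insemination 21 d after the first -> returned -> 0
  expect_equal(nr@y[nr@animalId == "COW2"], 0)
  # COW1 cow episode: second service 21 d later -> 0
  h <- codeNRR(rec, split = TRUE, minClassSize = 1)
  expect_equal(h$cow@y, 0)

  # boundary: second insemination exactly window + 1 days after -> 1
  b <- handEventRecords()[1, ]
  b$insem_dates <- list(as.Date(c("2011-04-01", "2011-05-28")))  # +57 d
  b$service_sires <- list(c("BULL01", "BULL02"))
  expect_equal(codeNRR(b, windowDays = 56, minClassSize = 1)@y, 1)
  b$insem_dates <- list(as.Date(c("2011-04-01", "2011-05-27")))  # +56 d
  expect_equal(codeNRR(b, windowDays = 56, minClassSize = 1)@y, 0)
})

test_that("filterOutliers is a single-pass two-sided k-SD rule", {
  expect_true(all(filterOutliers(rep(5, 10))))          # zero variance
  y <- c(rep(0, 9), 100)
  # |100 - 10| = 90 < 4 * sd(y) ~ 126 -> kept
  expect_true(all(filterOutliers(y, k = 4)))
  expect_false(all(filterOutliers(y, k = 2)))

  # removal fraction ~ 2*pnorm(-4) on a large normal sample
  set.seed(81)
  z <- rnorm(1e5)
  frac <- mean(!filterOutliers(z, k = 4))
  expect_lt(frac, 4 * 2 * pnorm(-4))
  # non-increasing in k; k -> Inf removes nothing
  removed <- vapply(c(1, 2, 3, 4, 8), function(k) sum(!filterOutliers(z, k)), 1)
  expect_true(all(diff(removed) <= 0))
  expect_equal(removed[length(removed)], 0)
})

test_that("matchPedigree drops exactly the animals absent from the pedigree", {
  rec <- handEventRecords()
  ds <- deriveTraits(rec, traits = "GL", minClassSize = 1)[["GL.heifer"]]
  pedAll <- pedigree(c("COW1", "COW2"), c("0", "0"), c("0", "0"))
  expect_equal(length(matchPedigree(ds, pedAll)@y), length(ds@y))
  pedNone <- pedigree("ZZ", "0", "0")
  expect_equal(length(matchPedigree(ds, pedNone)@y), 0L)
  pedHalf <- pedigree("COW1", "0", "0")
  m <- matchPedigree(ds, pedHalf)
  expect_true(all(m@animalId == "COW1"))
  expect_equal(attr(m, "nUnmatched"), sum(ds@animalId != "COW1"))
})

test_that("composite effect labels join their components and pool rare classes", {
  rec <- handEventRecords()
  spec <- defaultModelSpec("GL", "cow")
  expect_identical(spec@fixedEffects, c("RYM", "ApMpX"))
  expect_identical(spec@randomEffects, c("HY", "SS", "a"))

  cls <- buildEffectClasses(rec, defaultModelSpec("AFS", "heifer"),
                            minClassSize = 1)
  # same region, different birth months -> different RYM labels
  expect_equal(cls$fixed$RYM, c("R1:2010:01", "R1:2010:01", "R1:2010:02"))
  expect_equal(cls$hy, c("FARM01:2010", "FARM01:2010", "FARM02:2010"))

  clsGL <- buildEffectClasses(rec, defaultModelSpec("GL", "heifer"),
                              minClassSize = 1)
  # calf sex enters MfX
  expect_match(clsGL$fixed$MfX[1], ":F$")
  # conceiving (last) service sire for GL
  expect_equal(clsGL$ss, c("BULL01", "BULL03", "BULL02"))
  # first service sire for the non-return outcome
  clsNRR <- buildEffectClasses(rec, defaultModelSpec("NRR", "heifer"),
                               minClassSize = 1)
  expect_equal(clsNRR$ss, rep("BULL01", 3))

  # rare-class pooling: with min 2, singleton classes become OTHER
  cls2 <- buildEffectClasses(rec, defaultModelSpec("AFS", "heifer"),
                             minClassSize = 2)
  expect_true("OTHER" %in% cls2$fixed$RYM)

  # a missing component field is an informative error
  rec2 <- rec; rec2$calf_sex <- NULL
  expect_error(buildEffectClasses(rec2, defaultModelSpec("GL", "heifer"),
                                  minClassSize = 1), "MfX.*calf_sex")
})

test_that("descriptiveStats pools Ns additively over stages", {
  rec <- handEventRecords()
  ds <- deriveTraits(rec, traits = "GL", minClassSize = 1)
  tab <- descriptiveStats(ds)
  expect_equal(sum(tab$N), 3)
  # constant vector -> SD exactly 0
  const <- new("TraitDataset", trait = "GL", stage = "cow",
               animalId = c("a", "b", "c"), y = c(280, 280, 280),
               fixed = data.frame(row.names = 1:3), hy = character(0),
               ss = character(0))
  expect_equal(descriptiveStats(const)$SD, 0)
  # pooled mean equals the weighted combination of stage means
  m <- mergeTraits(ds[["GL.heifer"]], ds[["GL.cow"]])
  pooled <- descriptiveStats(m)
  expect_equal(pooled$N, sum(tab$N))
  expect_equal(pooled$mean,
               sum(tab$N * tab$mean) / sum(tab$N))
})

test_that("derive -> filter -> match is idempotent on its own output", {
  fx <- fixtureSmall()
  rec <- mergeDedup(fx$records)
  ds <- deriveTraits(rec, traits = "FSTC", minClassSize = 1)[["FSTC.heifer"]]
  ped <- fx$pedigree
  once <- matchPedigree(filterTraitOutliers(ds), ped)
  twice <- matchPedigree(filterTraitOutliers(once), ped)
  expect_equal(once@y, twice@y)
  expect_equal(once@animalId, twice@animalId)
})

test_that("events survive a CSV round trip", {
  fx <- fixtureSmall()
  f <- tempfile(fileext = ".csv")
  writeEvents(fx$records, f)
  back <- readEvents(f)
  expect_equal(nrow(back), nrow(fx$records))
  expect_equal(back$cow_id, fx$records$cow_id)
  expect_equal(back$insem_dates[[5]], as.Date(fx$records$insem_dates[[5]]))
  ds1 <- deriveTraits(mergeDedup(fx$records), traits = "GL", minClassSize = 1)
  ds2 <- deriveTraits(mergeDedup(back), traits = "GL", minClassSize = 1)
  expect_equal(ds1[["GL.cow"]]@y, ds2[["GL.cow"]]@y)
})
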