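test_that("observation filters apply coverage, chromosome and GERP rules", {
  obs <- rbind(
    obsFrame(1, coverage = 10),                       # low coverage
    obsFrame(1, chrom = "X"),                         # sex chromosome
    obsFrame(1, pass = FALSE),                        # failed QC
    obsFrame(1, gerp = 3.0, region = "intergenic_intronic"),
    obsFrame(1, gerp = 0.0, region = "intergenic_intronic"))
  kept <- filterObservations(obs, "maps_eval")
  expect_equal(nrow(kept), 2L)  # GERP plays no role in maps_eval
  keptT <- filterObservations(obs, "table_build")
  expect_equal(nrow(keptT), 1L)
  expect_equal(keptT$gerp, 0.0)
  expect_warning(filterObservations(obsFrame(1, coverage = 5), "maps_eval"),
                 "no observations")
})

test_that("mutability table scaling and proportionality are exact", {
  # uniform observed/possible => every scaled rate is exactly the target
  possible <- data.frame(context = c("AAA>ACA", "CCC>CTC", "GGG>GAG"),
                         methylation_bin = 0L, n_possible = c(100L, 200L, 400L))
  neutral <- data.frame(context = rep(possible$context, possible$n_possible / 100),
                        methylation_bin = 0L)
  tab <- buildMutabilityTable(neutral, possible)
  expect_equal(tab@rates$rate, rep(1.2e-8, 3))
  # doubled observed proportion => doubled rate
  tab2 <- twoContextTable()
  r <- tab2@rates
  expect_equal(r$rate[r$context == "ACG>ATG"] / r$rate[r$context == "ACA>AGA"], 2)
  wm <- with(tab2@rates, sum(rate * n_possible) / sum(n_possible))
  expect_equal(wm, 1.2e-8, tolerance = 1e-12)
  # zero observed gets the pseudocount floor, zero possible is excluded
  possible0 <- rbind(possible, data.frame(context = "TTT>TAT",
                                          methylation_bin = 0L, n_possible = 0L))
  expect_warning(tab0 <- buildMutabilityTable(neutral, possible0),
                 "zero possible")
  expect_false("TTT>TAT" %in% tab0@rates$context)
  possibleZ <- data.frame(context = c("AAA>ACA", "CCC>CTC"),
                          methylation_bin = 0L, n_possible = c(100L, 100L))
  neutralZ <- data.frame(context = "AAA>ACA", methylation_bin = 0L)[rep(1, 5), ]
  tabZ <- buildMutabilityTable(neutralZ, possibleZ)
  expect_true(all(tabZ@rates$rate > 0))
})

test_that("calibration recovers an exactly linear singleton model", {
  # groups constructed to lie exactly on a known line p = a + b * rate
  possible <- data.frame(context = c("C1>A", "C2>A", "C3>A", "C4>A"),
                         methylation_bin = 0L, n_possible = 1000L)
  neutral <- data.frame(context = rep(possible$context, c(5L, 10L, 20L, 40L)),
                        methylation_bin = 0L)
  tab <- buildMutabilityTable(neutral, possible)
  rate <- tab@rates$rate[match(possible$context, tab@rates$context)]
  # rates are exactly 1.2e-8 * (4, 8, 16, 32) / 15; pick b so that
  # b * rate = -0.01 * (1, 2, 4, 8) and group proportions are exact /100
  b <- -0.01 / rate[1]
  a <- 0.58
  kPer <- c(57L, 56L, 54L, 50L)
  expect_equal(a + b * rate, kPer / 100)
  syn <- do.call(rbind, lapply(seq_along(rate), function(i) {
    obsFrame(100L, context = possible$context[i],
             allele_count = rep(c(1L, 5L), c(kPer[i], 100L - kPer[i])))
  }))
  model <- calibrateSingletonModel(syn, tab)
  expect_equal(model@intercept, a, tolerance = 1e-9)
  expect_equal(model@slope, b, tolerance = 1e-9)
  # constant proportion across rates => slope 0, intercept = proportion
  syn2 <- do.call(rbind, lapply(possible$context, function(cx) {
    obsFrame(10L, context = cx, allele_count = rep(c(1L, 9L), each = 5L))
  }))
  m2 <- calibrateSingletonModel(syn2, tab)
  expect_equal(m2@slope, 0, tolerance = 1e-10)
  expect_equal(m2@intercept, 0.5, tolerance = 1e-10)
  # degenerate single-rate input errors
  one <- obsFrame(10, context = "C1>A")
  expect_error(calibrateSingletonModel(one, tab), "degenerate")
})

test_that("MAPS arithmetic matches its definition", {
  tab <- twoContextTable()
  model <- constantModel(0.25)
  obs <- obsFrame(4, context = "ACA>AGA", allele_count = c(1L, 1L, 5L, 9L))
  res <- computeMaps(obs, model, tab)
  expect_equal(maps(res), (2 - 1) / 4)
  expect_equal(res@expectedSingletons, 1)
  # singletons exactly matching expectation => MAPS 0
  obs0 <- obsFrame(4, context = "ACA>AGA", allele_count = c(1L, 5L, 5L, 5L))
  expect_equal(maps(computeMaps(obs0, constantModel(0.25), tab)), 0)
  # unknown context errors with the offender named
  bad <- obsFrame(1, context = "NNN>NAN")
  expect_error(computeMaps(bad, model, tab), "NNN>NAN")
  expect_error(computeMaps(obs[0, ], model, tab), "at least one")
})

test_that("bootstrap CI is degenerate for identical observations and
           deterministic under a fixed seed", {
  tab <- twoContextTable()
  model <- constantModel(0.3)
  same <- obsFrame(50, context = "ACA>AGA", allele_count = 1L)
  ci <- bootstrapCi(same, model, tab, nBoot = 100, seed = 1)
  expect_equal(ci[1], ci[2])
  expect_equal(ci[1], maps(computeMaps(same, model, tab)))
  mixed <- obsFrame(200, context = "ACA>AGA",
                    allele_count = rep(c(1L, 4L), 100))
  r1 <- computeMaps(mixed, model, tab, nBoot = 500, seed = 7)
  r2 <- computeMaps(mixed, model, tab, nBoot = 500, seed = 7)
  expect_identical(r1, r2)
  expect_true(r1@ci90[1] <= maps(r1) && maps(r1) <= r1@ci90[2])
})

test_that("permutation p-value is ~0.5 for identical sets and < 1/nPerm
           for strict ordering", {
  tab <- twoContextTable()
  model <- constantModel(0.5)
  set.seed(99)
  a <- obsFrame(300, context = "ACA>AGA",
                allele_count = sample(c(1L, 5L), 300, replace = TRUE))
  pv <- permutationPvalue(a, a, model, tab, nPerm = 2000, seed = 3)
  expect_gt(pv$p, 0.40)
  expect_lt(pv$p, 0.60)
  allS <- obsFrame(100, context = "ACA>AGA", allele_count = 1L)
  noneS <- obsFrame(100, context = "ACA>AGA", allele_count = 5L)
  pv2 <- permutationPvalue(noneS, allS, model, tab, nPerm = 500, seed = 3)
  expect_equal(pv2$p, 0)
  expect_match(pv2$label, "^< ")
  expect_error(permutationPvalue(a[0, ], a, model, tab), "non-empty")
})

test_that("MAPS is invariant to a constant factor in the raw rates", {
  possible <- data.frame(context = c("C1>A", "C2>A"), methylation_bin = 0L,
                         n_possible = 1000L)
  neutral1 <- data.frame(context = rep(c("C1>A", "C2>A"), c(10L, 20L)),
                         methylation_bin = 0L)
  neutral3 <- data.frame(context = rep(c("C1>A", "C2>A"), 3 * c(10L, 20L)),
                         methylation_bin = 0L)
  tabA <- buildMutabilityTable(neutral1, possible)
  tabB <- buildMutabilityTable(neutral3, possible)  # raw rates tripled
  expect_equal(tabA@rates$rate, tabB@rates$rate)
  syn <- rbind(obsFrame(40, context = "C1>A",
                        allele_count = rep(c(1L, 2L), 20)),
               obsFrame(40, context = "C2>A",
                        allele_count = rep(c(1L, 1L, 1L, 2L), 10)))
  mA <- calibrateSingletonModel(syn, tabA)
  mB <- calibrateSingletonModel(syn, tabB)
  test <- obsFrame(60, context = "C2>A", allele_count = rep(c(1L, 3L), 30))
  expect_equal(maps(computeMaps(test, mA, tabA)),
               maps(computeMaps(test, mB, tabB)))
})

test_that("in-sample MAPS of the calibration class is ~0 and the model
           removes the mutability confounder", {
  cfg <- simulationConfig(seed = 17, nObservedPerClass = 5000,
                          nNeutralPossible = 400000,
                          nSynonymousObserved = 15000)
  pop <- simulatePopulation(cfg)
  neutralTab <- filterObservations(
    pop$observations[pop$observations$region == "intergenic_intronic", ],
    "table_build")
  tab <- buildMutabilityTable(neutralTab, pop$possibleSites)
  syn <- filterObservations(
    pop$observations[pop$observations$region == "synonymous", ], "maps_eval")
  model <- calibrateSingletonModel(syn, tab)
  expect_lt(abs(maps(computeMaps(syn, model, tab))), 0.005)
})
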