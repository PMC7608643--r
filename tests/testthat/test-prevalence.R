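test_that("carrier counts derive het/hom/mutated alleles per group", {
  panel <- smallPanel()
  v <- makeVariants(counts = list(g1 = c(ac = 3, nhom = 1, ac_male = 2,
                                         nhom_male = 1)))
  tbl <- carrierCounts(v, panel)
  g1 <- tbl[tbl$group == "g1", ]
  expect_equal(g1$het_carriers, 1L)
  expect_equal(g1$hom_carriers, 1L)
  expect_equal(g1$mutated_alleles, 3L)
  expect_equal(g1$het_male, 0L)   # ac_male 2 = 2*hom_male
  expect_equal(g1$het_female, 1L)
  # empty pathogenic set -> all-zero table
  z <- carrierCounts(v[0, ], panel)
  expect_true(all(z$mutated_alleles == 0) && all(z$het_carriers == 0))
})

test_that("sex attribution without nhomalt sex columns is greedy to males", {
  panel <- smallPanel()
  v <- makeVariants(counts = list(g1 = c(ac = 3, nhom = 1, ac_male = 2)))
  v$nhomalt_g1_male <- NULL; v$nhomalt_g1_female <- NULL
  v$nhomalt_g2_male <- NULL; v$nhomalt_g2_female <- NULL
  v$nhomalt_oth_male <- NULL; v$nhomalt_oth_female <- NULL
  tbl <- carrierCounts(v, panel)
  g1 <- tbl[tbl$group == "g1", ]
  expect_equal(g1$hom_male, 1L)
  expect_equal(g1$het_male, 0L)
  expect_equal(g1$het_female, 1L)
})

test_that("carrier table obeys the published-table identities", {
  # allele-count identity: het + 2*hom = mutated alleles in every row,
  # global row = sum of group rows
  panel <- defaultPanel()
  sim <- simulateCohort(cohortSimConfig(seed = 2L))
  calls <- classifyVariants(sim$variants, panel)
  path <- sim$variants[calls$status == "pathogenic", ]
  tbl <- carrierFrequencies(carrierCounts(path, panel))
  expect_equal(tbl$mutated_alleles,
               tbl$het_carriers + 2L * tbl$hom_carriers)
  expect_equal(tbl$het_male + tbl$het_female, tbl$het_carriers)
  glob <- tbl[tbl$group == "global", ]
  grp <- tbl[tbl$group != "global", ]
  for (col in c("mutated_alleles", "het_carriers", "hom_carriers",
                "total_alleles", "ethnic_specific_mutated_alleles"))
    expect_equal(glob[[col]], sum(grp[[col]]))
  expect_equal(tbl$allele_frequency,
               tbl$mutated_alleles / tbl$total_alleles)
  expect_equal(tbl$het_frequency, tbl$het_carriers / tbl$n_individuals)
})

test_that("group-specific and overlap sets partition pathogenic variants", {
  panel <- smallPanel()
  v <- rbind(makeVariants(counts = list(g1 = c(ac = 2))),
             makeVariants(counts = list(g1 = c(ac = 1), g2 = c(ac = 1))),
             makeVariants(counts = list()))
  v$pos <- 21000000L + 1:3
  part <- ethnicSpecificPartition(v, panel)
  expect_equal(part$specific$g1, variantId(v)[1])
  expect_equal(part$overlap, variantId(v)[2])
  expect_equal(part$unobserved, variantId(v)[3])
  all_ids <- c(unlist(part$specific), part$overlap, part$unobserved)
  expect_setequal(all_ids, variantId(v))
  expect_equal(length(all_ids), nrow(v))
})

test_that("fold difference uses display-rounded percentages, >= 1 always", {
  panel <- npc1Panel()
  cc <- npc1CarrierCounts()
  tbl <- carrierTableFromCounts(panel,
                                het = setNames(cc$het, cc$group),
                                hom = setNames(cc$hom, cc$group))
  fd <- foldDifference(tbl, "het_frequency")
  expect_equal(fd$rounded, 5.8)
  expect_equal(fd$unrounded, (265 / 8128) / (28 / 5040))
  expect_equal(fd$max_group, "afr")
  expect_equal(fd$min_group, "asj")
  expect_gte(fd$rounded, 1)
  # equal frequencies in all groups -> exactly 1
  eq <- carrierTableFromCounts(smallPanel(),
                               het = c(g1 = 50, g2 = 80),
                               hom = c(g1 = 0, g2 = 0))
  expect_equal(foldDifference(eq, "het_frequency")$rounded, 1)
  # zero minimum -> undefined
  z <- carrierTableFromCounts(smallPanel(), het = c(g1 = 0, g2 = 80),
                              hom = c(g1 = 0, g2 = 0))
  expect_true(is.na(foldDifference(z, "het_frequency")$rounded))
})

test_that("chi-square matches hand and library oracles", {
  res <- chiSquareTest(matrix(c(10, 90, 30, 70), 2, byrow = TRUE))
  expect_equal(res$statistic, 12.5)
  expect_equal(res$df, 1L)
  # identical row proportions -> statistic 0, p 1
  flat <- chiSquareTest(matrix(c(10, 20, 30, 60), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # agreement with stats::chisq.test, with and without Yates correction
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(rpois(4, 30) + 1, 2)
    a <- chiSquareTest(m, correct = TRUE)
    b <- suppressWarnings(chisq.test(m, correct = TRUE))
    expect_equal(a$statistic, unname(b$statistic), tolerance = 1e-12)
    expect_equal(a$p_value, unname(b$p.value), tolerance = 1e-12)
  }
  # degenerate marginals rejected; small expected cells flagged
  expect_error(chiSquareTest(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_true(chiSquareTest(matrix(c(1, 9, 2, 8), 2))$low_expected)
  # p underflow is labelled, never a bare zero
  big <- chiSquareTest(matrix(c(1e6, 10, 10, 1e6), 2))
  expect_identical(big$p_label, "< 2.2e-308")
})

test_that("sex comparison tests carriers vs non-carriers by sex", {
  panel <- npc1Panel()
  cc <- npc1CarrierCounts()
  tbl <- carrierTableFromCounts(panel,
                                het = setNames(cc$het, cc$group),
                                hom = setNames(cc$hom, cc$group),
                                hetMale = setNames(cc$het_male, cc$group),
                                homMale = setNames(cc$hom_male, cc$group))
  # published global totals: the global M/F carrier split is 816/754
  sx <- sexComparison(tbl, panel)
  glob <- sx[sx$scope == "global", ]
  expect_false(glob$skipped)
  carM <- 813 + 3; carF <- (1566 - 813) + 1
  m <- matrix(c(carM, 66355 - carM, carF, 56323 - carF), 2)
  expect_equal(glob$statistic, chiSquareTest(m)$statistic)
  expect_equal(nrow(sx), 7L)   # global + six groups
  # identical carrier proportions by sex -> statistic 0
  p2 <- populationPanel(c("a", "b"), n = c(1000, 1000),
                        nMale = c(500, 600), nFemale = c(500, 400))
  eq <- carrierTableFromCounts(p2, het = c(a = 100, b = 0),
                               hom = c(a = 0, b = 0),
                               hetMale = c(a = 50, b = 0),
                               homMale = c(a = 0, b = 0))
  sxe <- sexComparison(eq, p2)
  expect_equal(sxe$statistic[sxe$scope == "a"], 0)
})

test_that("heterogeneity test holds its size under the null", {
  panel <- npc1Panel()
  an <- nAlleles(panel)
  set.seed(314)
  rej <- replicate(500, {
    mut <- rbinom(length(an), an, 0.005)
    chiSquareTest(rbind(mut, an - mut))$p_value < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})
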