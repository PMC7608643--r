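test_that("per-group allele frequencies are AC/AN with zero-AN flagged", {
  panel <- smallPanel()
  v <- makeVariants(n = 2, counts = list(g1 = c(ac = 2)))
  v$AC_g1[2] <- 0L; v$AC_g1_male[2] <- 0L; v$AC_g1_female[2] <- 0L
  af <- groupAF(v, panel)
  expect_equal(unname(af[1, "g1"]), 2 / 10000)
  expect_equal(unname(af[2, "g1"]), 0)
  v$AN_g2 <- 0L
  af <- groupAF(v, panel)
  expect_equal(unname(af[, "g2"]), c(0, 0))
  expect_true(all(attr(af, "zero_an")[, "g2"]))
  v2 <- v[, -match("AC_g2", names(v))]
  expect_error(groupAF(v2, panel), "absent from variant counts")
})

test_that("rarity requires AF strictly below threshold in every group", {
  panel <- smallPanel()
  pol <- classificationPolicy()
  rare <- makeVariants(counts = list(g1 = c(ac = 5), g2 = c(ac = 5)))
  expect_true(isRare(rare, panel, pol))
  oneCommon <- makeVariants(counts = list(g1 = c(ac = 200),
                                          g2 = c(ac = 5)))
  expect_false(isRare(oneCommon, panel, pol))   # 2% in g1 disqualifies
  atThreshold <- makeVariants(counts = list(g1 = c(ac = 100)))
  expect_false(isRare(atThreshold, panel, pol)) # exactly 1%: not rare
})

test_that("the classification cascade applies rules in fixed order", {
  panel <- smallPanel()
  case <- function(v) {
    calls <- classifyVariants(v, panel)
    c(calls$status, calls$reasons)
  }
  lof <- makeVariants(consequence = "stop_gained",
                      counts = list(g1 = c(ac = 1)))
  expect_equal(case(lof), c("pathogenic", "lof_class"))
  rescued <- makeVariants(sift = "tolerated", polyphen = "benign",
                          clinvar = "pathogenic",
                          counts = list(g1 = c(ac = 1)))
  expect_equal(case(rescued), c("pathogenic", "clinvar_pathogenic"))
  damaging <- makeVariants(sift = "deleterious",
                           polyphen = "possibly_damaging",
                           counts = list(g1 = c(ac = 1)))
  expect_equal(case(damaging), c("pathogenic", "insilico_damaging"))
  discordant <- makeVariants(sift = "deleterious", polyphen = "benign",
                             counts = list(g1 = c(ac = 1)))
  expect_equal(case(discordant), c("non_pathogenic", "insilico_benign"))
  syn <- makeVariants(consequence = "synonymous",
                      protein_change = "A100A",
                      counts = list(g1 = c(ac = 1)))
  expect_equal(case(syn), c("non_pathogenic", "synonymous"))
  indel <- makeVariants(consequence = "inframe_indel",
                        counts = list(g1 = c(ac = 1)))
  expect_equal(case(indel), c("excluded", "inframe_indel"))
  flagged <- makeVariants(consequence = "stop_gained", qc_flag = TRUE,
                          counts = list(g1 = c(ac = 1)))
  expect_equal(case(flagged), c("excluded", "qc_flagged"))
  common <- makeVariants(consequence = "stop_gained",
                         counts = list(g1 = c(ac = 300)))
  expect_equal(case(common), c("excluded", "common_allele"))
  isoform2 <- makeVariants(isoform = "2", sift = "deleterious",
                           polyphen = "probably_damaging",
                           counts = list(g1 = c(ac = 1)))
  expect_equal(case(isoform2), c("excluded", "noncanonical_isoform"))
  otherOnly <- makeVariants(consequence = "stop_gained",
                            counts = list(oth = c(ac = 2)))
  expect_equal(case(otherOnly), c("excluded", "other_group_only"))
  unscorable <- makeVariants(counts = list(g1 = c(ac = 1)))
  expect_equal(case(unscorable), c("non_pathogenic", "unscorable"))
  stopLost <- makeVariants(consequence = "stop_lost",
                           protein_change = NA,
                           counts = list(g1 = c(ac = 1)))
  expect_equal(case(stopLost), c("excluded", "excluded_class"))
})

test_that("classification partitions the input and is order-independent", {
  panel <- defaultPanel()
  sim <- simulateCohort(cohortSimConfig(seed = 5L))
  calls <- classifyVariants(sim$variants, panel)
  expect_equal(nrow(calls), nrow(sim$variants))
  expect_setequal(unique(calls$status),
                  intersect(c("pathogenic", "non_pathogenic", "excluded"),
                            calls$status))
  expect_equal(sum(table(calls$status)), nrow(sim$variants))
  perm <- sample(nrow(sim$variants))
  calls2 <- classifyVariants(sim$variants[perm, ], panel)
  expect_equal(calls2$status, calls$status[perm])
  # idempotent: same input, same result
  expect_identical(classifyVariants(sim$variants, panel), calls)
})

test_that("tightening the MAF threshold never adds pathogenic calls", {
  panel <- defaultPanel()
  sim <- simulateCohort(cohortSimConfig(seed = 9L, commonFraction = 0.3))
  loose <- classifyVariants(sim$variants, panel,
                            classificationPolicy(mafThreshold = 0.02))
  tight <- classifyVariants(sim$variants, panel,
                            classificationPolicy(mafThreshold = 0.002))
  pLoose <- loose$variant_id[loose$status == "pathogenic"]
  pTight <- tight$variant_id[tight$status == "pathogenic"]
  expect_true(all(pTight %in% pLoose))
})

test_that("the census counts distinct pathogenic variants per class", {
  panel <- smallPanel()
  v <- rbind(makeVariants(n = 3, sift = "deleterious",
                          polyphen = "probably_damaging",
                          counts = list(g1 = c(ac = 5))),
             makeVariants(consequence = "frameshift",
                          counts = list(g1 = c(ac = 1))))
  v$pos <- 21000000L + 1:4
  calls <- classifyVariants(v, panel)
  cen <- mutationCensus(calls, v)
  expect_equal(sum(cen$percent), 100)
  expect_equal(cen$n[cen$consequence == "missense"], 3L)
  expect_equal(cen$percent[cen$consequence == "frameshift"], 25)
  # single pathogenic variant -> 100%
  one <- makeVariants(consequence = "stop_gained",
                      counts = list(g1 = c(ac = 1)))
  cen1 <- mutationCensus(classifyVariants(one, panel), one)
  expect_equal(cen1$percent, 100)
})
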