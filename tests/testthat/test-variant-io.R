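test_that("TSV rows map directly onto variant records", {
  panel <- npc1Panel()
  v <- makeVariants(panel = panel,
                    counts = list(afr = c(ac = 3, nhom = 1, ac_male = 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeVariantTable(v, path, panel, "tsv")
  r <- readVariantTable(path, panel, "tsv")
  expect_equal(r$AC_afr, 3L)
  expect_equal(r$AN_afr, 16256L)
  expect_equal(r$nhomalt_afr, 1L)
  expect_equal(r$AC_afr_male, 2L)
  expect_equal(r$consequence, "missense")
})

test_that("validation rejects invariant violations, naming the variant", {
  panel <- smallPanel()
  v <- makeVariants(counts = list(g1 = c(ac = 3, nhom = 2)))
  expect_error(validateVariants(v, panel), "2\\*nhomalt")
  expect_error(validateVariants(v, panel), variantId(v), fixed = TRUE)
  v2 <- makeVariants(counts = list(g1 = c(ac = 10001)))
  expect_error(validateVariants(v2, panel), "AC_g1 > AN_g1")
  v3 <- makeVariants(counts = list(g1 = c(ac = 4, ac_male = 1)))
  v3$AC_g1_female <- 1L
  expect_error(validateVariants(v3, panel), "male")
  expect_error(validateVariants(v3[, -match("AC_g2", names(v3))], panel),
               "missing required column.*AC_g2")
})

test_that("VCF and TSV dialects of one cohort load identically", {
  panel <- defaultPanel()
  sim <- simulateCohort(cohortSimConfig(
    seed = 11L, nVariants = c(missense = 25, frameshift = 4,
                              synonymous = 6)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeVariantTable(sim$variants, tsv, panel, "tsv")
  writeVariantTable(sim$variants, vcf, panel, "vcf")
  a <- readVariantTable(tsv, panel, "tsv")
  b <- readVariantTable(vcf, panel, "vcf")
  expect_identical(a, b)
  expect_equal(nrow(a), nrow(sim$variants))     # no silent drops
  expect_equal(variantId(a), variantId(sim$variants))  # order preserved
})

test_that("multi-allelic VCF sites decompose one record per alt allele", {
  panel <- smallPanel()
  v <- makeVariants(panel = panel, counts = list(g1 = c(ac = 2)))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeVariantTable(v, vcf, panel, "vcf")
  lines <- readLines(vcf)
  i <- which(!grepl("^#", lines))
  f <- strsplit(lines[i], "\t")[[1]]
  f[5] <- paste0(f[5], ",T")
  f[8] <- paste(vapply(strsplit(f[8], ";")[[1]], function(kv) {
    p <- strsplit(kv, "=")[[1]]
    if (grepl("^AN_", p[1])) kv else paste0(p[1], "=", p[2], ",", p[2])
  }, ""), collapse = ";")
  lines[i] <- paste(f, collapse = "\t")
  writeLines(lines, vcf)
  r <- readVariantTable(vcf, panel, "vcf")
  expect_equal(nrow(r), 2L)
  expect_equal(r$chrom[1], r$chrom[2])
  expect_equal(r$pos[1], r$pos[2])
  expect_equal(r$ref[1], r$ref[2])
  expect_equal(r$alt, c("G", "T"))
  expect_equal(r$AN_g1[1], r$AN_g1[2])  # site-level AN duplicated per alt
})

test_that("domain model loading enforces interval invariants", {
  dm <- npc1DomainModel()
  expect_equal(proteinLength(dm), 1278L)
  expect_equal(nrow(domainTable(dm)), 27L)
  expect_true(!is.unsorted(domainTable(dm)$start))
  expect_equal(domainTable(dm)$name[domainTable(dm)$in_ssd],
               paste0("TD", 3:7))
  # inclusive upper bound at protein end is accepted
  ok <- domainModel(data.frame(name = "CT", category = "cytoplasmic",
                               start = 90, end = 100, in_ssd = FALSE),
                    proteinLength = 100)
  expect_s4_class(ok, "DomainModel")
  expect_error(domainModel(data.frame(name = c("A", "B"),
                                      category = "luminal",
                                      start = c(1, 10), end = c(12, 20),
                                      in_ssd = FALSE), 100),
               "overlapping domains: A and B")
  expect_error(domainModel(data.frame(name = "A", category = "luminal",
                                      start = 10, end = 5, in_ssd = FALSE),
                           100),
               "end < start")
})

test_that("result tables round-trip with bit-equal floats", {
  tbl <- data.frame(group = c("a", "b"), count = c(3L, 7L),
                    freq = c(1 / 3, sqrt(2) * 1e-7))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  writeResultTable(tbl, tsv, "tsv")
  writeResultTable(tbl, json, "json")
  rt <- readResultTable(tsv, "tsv")
  rj <- readResultTable(json, "json")
  expect_identical(rt$freq, tbl$freq)   # bit-equal doubles via %.17g
  expect_identical(rj$freq, tbl$freq)
  expect_equal(rt$count, tbl$count)
  # empty result set -> header-only file
  writeResultTable(tbl[0, ], tsv, "tsv")
  expect_equal(nrow(readResultTable(tsv, "tsv")), 0L)
  expect_equal(names(readResultTable(tsv, "tsv")), names(tbl))
})

test_that("population panel files load with catch-all exclusion", {
  p <- npc1Panel()
  expect_equal(sum(nIndividuals(p)), 122678)
  expect_equal(otherLabel(p), "oth")
  expect_false("oth" %in% analysedGroups(p))
  expect_equal(unname(nAlleles(p)["sas"]), 30616)
  expect_error(populationPanel("g1", 10, 4, 5), "n_male \\+ n_female")
})
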