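test_that("residues map to domains with inclusive bounds", {
  dm <- domainModel(data.frame(name = c("D1", "D2"),
                               category = c("luminal", "transmembrane"),
                               start = c(10, 30), end = c(20, 40),
                               in_ssd = c(FALSE, TRUE)), 100)
  expect_equal(assignDomain(10, dm), "D1")   # inclusive lower bound
  expect_equal(assignDomain(20, dm), "D1")   # inclusive upper bound
  expect_equal(assignDomain(25, dm), NA_character_)  # linker
  expect_equal(assignDomain(c(15, 35, 99), dm), c("D1", "D2", NA))
  expect_error(assignDomain(101, dm), "out of protein range")
  expect_error(assignDomain(0, dm), "out of protein range")
})

test_that("domain burden equals a brute-force per-residue tally", {
  panel <- smallPanel()
  dm <- domainModel(data.frame(name = c("D1", "D2", "D3"),
                               category = c("luminal", "transmembrane",
                                            "cytoplasmic"),
                               start = c(1, 41, 71), end = c(30, 60, 100),
                               in_ssd = c(FALSE, TRUE, FALSE)), 120)
  set.seed(17)
  n <- 40
  resd <- sample.int(120, n, replace = TRUE)
  v <- makeVariants(n = n, sift = "deleterious",
                    polyphen = "probably_damaging")
  v$pos <- 21000000L + seq_len(n)
  v$protein_change <- paste0("A", resd, "V")
  ac <- sample.int(5, n, replace = TRUE)
  nhom <- ifelse(ac >= 2, rbinom(n, 1, 0.2), 0L)
  v$AC_g1 <- as.integer(ac); v$nhomalt_g1 <- as.integer(nhom)
  v$AC_g1_male <- as.integer(ac); v$AC_g1_female <- 0L
  v$nhomalt_g1_male <- as.integer(nhom); v$nhomalt_g1_female <- 0L
  ds <- domainStats(v, panel, dm)

  # brute force: iterate variants, accumulate per-domain tallies directly
  bins <- c("D1", "D2", "D3", "linker")
  whichBin <- function(r) {
    if (r <= 30) "D1" else if (r >= 41 && r <= 60) "D2"
    else if (r >= 71 && r <= 100) "D3" else "linker"
  }
  for (b in bins) {
    idx <- vapply(resd, whichBin, "") == b
    row <- ds[ds$domain == b, ]
    expect_equal(row$n_mutations, sum(idx))
    expect_equal(row$n_positions, length(unique(resd[idx])))
    expect_equal(row$n_individuals, sum((ac - nhom)[idx]))
    len <- c(D1 = 30, D2 = 20, D3 = 30, linker = 40)[[b]]
    expect_equal(row$pct_mutant_aa, 100 * length(unique(resd[idx])) / len)
    expect_equal(row$pct_individuals, 100 * sum((ac - nhom)[idx]) / len)
  }
  # partition: domains + linker account for every missense mutation
  core <- ds[ds$domain != "SSD", ]
  expect_equal(sum(core$n_mutations), n)
  # SSD aggregate equals its one member here
  expect_equal(ds[ds$domain == "SSD", ]$n_individuals,
               ds[ds$domain == "D2", ]$n_individuals)
})

test_that("duplicate hits at one residue change mutations, not positions", {
  panel <- smallPanel()
  dm <- domainModel(data.frame(name = "D1", category = "luminal",
                               start = 1, end = 10, in_ssd = FALSE), 50)
  v <- makeVariants(n = 2, sift = "deleterious",
                    polyphen = "probably_damaging",
                    counts = list(g1 = c(ac = 1)))
  v$pos <- 21000000L + 1:2
  v$protein_change <- c("A5V", "A5G")   # two alleles, one residue
  ds <- domainStats(v, panel, dm)
  d1 <- ds[ds$domain == "D1", ]
  expect_equal(d1$n_mutations, 2L)
  expect_equal(d1$n_positions, 1L)
  expect_equal(d1$pct_mutant_aa, 10)
  # non-missense records never enter domain statistics
  fs <- makeVariants(consequence = "frameshift",
                     counts = list(g1 = c(ac = 1)))
  ds2 <- domainStats(rbind(v, fs), panel, dm)
  expect_equal(sum(ds2$n_mutations[ds2$domain != "SSD"]), 2L)
})

test_that("a fully mutated domain reports 100% mutant amino acids", {
  panel <- smallPanel()
  dm <- domainModel(data.frame(name = "D1", category = "cytoplasmic",
                               start = 11, end = 15, in_ssd = FALSE), 20)
  v <- makeVariants(n = 5, sift = "deleterious",
                    polyphen = "probably_damaging",
                    counts = list(g1 = c(ac = 1)))
  v$pos <- 21000000L + 1:5
  v$protein_change <- paste0("A", 11:15, "V")
  ds <- domainStats(v, panel, dm)
  expect_equal(ds$pct_mutant_aa[ds$domain == "D1"], 100)
  # empty domain -> all zeros
  none <- domainStats(v[0, ], panel, dm)
  expect_true(all(none$n_mutations == 0) && all(none$pct_individuals == 0))
})
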