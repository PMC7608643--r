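# Small fixtures built in code: a three-group panel (one catch-all) and a
# variant-row builder over it.

smallPanel <- function() {
  populationPanel(c("g1", "g2", "oth"), n = c(5000, 8000, 500),
                  nMale = c(2400, 4100, 250), nFemale = c(2600, 3900, 250),
                  otherLabel = "oth")
}

# One-call builder: an empty table over `panel` with selected fields and
# per-group counts patched in. counts is a named list like
# list(g1 = c(ac = 3, nhom = 1, ac_male = 2)).
makeVariants <- function(n = 1, panel = smallPanel(), consequence = "missense",
                         protein_change = "A100V", sift = "missing",
                         polyphen = "missing", clinvar = "absent",
                         isoform = "1", qc_flag = FALSE, counts = list()) {
  v <- emptyVariantTable(n, panel)
  v$consequence <- consequence
  v$protein_change <- ifelse(v$consequence %in% c("missense", "synonymous"),
                             protein_change, NA_character_)
  v$sift <- sift; v$polyphen <- polyphen; v$clinvar <- clinvar
  v$isoform <- isoform; v$qc_flag <- qc_flag
  for (g in names(counts)) {
    cc <- counts[[g]]
    ac <- as.integer(cc[["ac"]])
    nhom <- as.integer(if ("nhom" %in% names(cc)) cc[["nhom"]] else 0)
    acm <- as.integer(if ("ac_male" %in% names(cc)) cc[["ac_male"]] else ac)
    nhm <- as.integer(if ("nhom_male" %in% names(cc)) cc[["nhom_male"]]
                      else min(nhom, acm %/% 2L))
    v[[sprintf("AC_%s", g)]] <- ac
    v[[sprintf("nhomalt_%s", g)]] <- nhom
    v[[sprintf("AC_%s_male", g)]] <- acm
    v[[sprintf("AC_%s_female", g)]] <- ac - acm
    v[[sprintf("nhomalt_%s_male", g)]] <- nhm
    v[[sprintf("nhomalt_%s_female", g)]] <- nhom - nhm
  }
  v
}
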