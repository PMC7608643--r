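## Packaged inputs of the NPC1 reanalysis: the six-group exome panel, a
## synthetic 27-domain protein model, the published gene-constraint counts,
## and the published per-group carrier counts -- all as plain-text fixtures
## under extdata with accessor functions.

rcFile <- function(name)
  system.file("extdata", name, package = "RareCarrier", mustWork = TRUE)

#' Packaged NPC1 study inputs
#'
#' Accessors for the plain-text fixtures shipped with the package:
#' \code{npc1Panel()} the six analysed ancestry groups plus the excluded
#' catch-all; \code{npc1DomainModel()} a \emph{synthetic} 27-domain model
#' of the 1278-residue NPC1 protein (boundaries approximate; the lengths
#' that published burden percentages pin down are honoured exactly);
#' \code{npc1GeneCounts()} the published observed/expected variant counts
#' per mutation class; \code{npc1CarrierCounts()} the published per-group
#' heterozygous/homozygous carrier counts with sex splits and the
#' ethnic-specific breakdown.
#'
#' @return \code{npc1Panel()}: a \linkS4class{PopulationPanel};
#'   \code{npc1DomainModel()}: a \linkS4class{DomainModel};
#'   \code{npc1GeneCounts()}: a one-row gene-constraint data.frame;
#'   \code{npc1CarrierCounts()}: a data.frame of per-group counts.
#' @name npc1-data
NULL

#' @rdname npc1-data
#' @export
npc1Panel <- function() readPopulationPanel(rcFile("npc1_panel.tsv"))

#' @rdname npc1-data
#' @export
npc1DomainModel <- function()
  readDomainModel(rcFile("npc1_domains_synthetic.tsv"))

#' @rdname npc1-data
#' @export
npc1GeneCounts <- function()
  utils::read.delim(rcFile("npc1_gene_constraint.tsv"))

#' @rdname npc1-data
#' @export
npc1CarrierCounts <- function()
  utils::read.delim(rcFile("npc1_carrier_counts.tsv"))

#' An empty variant table over a panel
#'
#' Builds an n-row variant table with all per-group counts zero (AN at the
#' panel's full 2n call rate), canonical isoform, no annotations and no QC
#' flags -- a scaffold for constructing explicit cohorts in examples and
#' reanalyses.
#'
#' @param n number of records.
#' @param panel a \linkS4class{PopulationPanel}.
#' @return variant data.frame (not yet meaningful for analysis until
#'   counts/annotations are filled in).
#' @export
emptyVariantTable <- function(n, panel) {
  v <- data.frame(chrom = rep("18", n), pos = 21000000L + seq_len(n),
                  ref = "A", alt = "G", gene = "NPC1",
                  consequence = "missense",
                  protein_change = NA_character_, isoform = "1",
                  sift = "missing", polyphen = "missing",
                  clinvar = "absent", qc_flag = FALSE,
                  stringsAsFactors = FALSE)
  nind <- nIndividuals(panel, groupLabels(panel))
  for (g in groupLabels(panel)) {
    v[[sprintf("AC_%s", g)]] <- 0L
    v[[sprintf("AN_%s", g)]] <- 2L * nind[[g]]
    v[[sprintf("nhomalt_%s", g)]] <- 0L
    v[[sprintf("AC_%s_male", g)]] <- 0L
    v[[sprintf("AC_%s_female", g)]] <- 0L
    v[[sprintf("nhomalt_%s_male", g)]] <- 0L
    v[[sprintf("nhomalt_%s_female", g)]] <- 0L
  }
  v
}

#' Reconstruct the published census cohort composition
#'
#' Builds a variant table whose classification reproduces the published
#' distinct-mutation census: 414 pathogenic mutations (34 frameshift, 6
#' splice acceptor, 6 splice donor, 13 stop gained, 355 missense of which
#' 2 carry a pathogenic ClinVar assertion over benign in silico verdicts)
#' plus 292 non-pathogenic missense mutations. Group placement follows the
#' published ethnic-specific breakdown: 340 pathogenic mutations are
#' confined to a single group (afr 32, asj 5, eas 36, eur 167, lat 43,
#' sas 57) and 74 are observed in two groups. Every record is a singleton
#' allele per group (rare by construction); carrier totals are not part of
#' this reconstruction.
#'
#' @param panel a \linkS4class{PopulationPanel} (the packaged NPC1 panel by
#'   default).
#' @return variant data.frame of 706 records.
#' @export
npc1CensusCohort <- function(panel = npc1Panel()) {
  specific <- c(afr = 32, asj = 5, eas = 36, eur = 167, lat = 43, sas = 57)
  nOverlap <- 74
  classes <- rep(c("frameshift", "splice_acceptor", "splice_donor",
                   "stop_gained", "missense"),
                 times = c(34, 6, 6, 13, 355))
  nPath <- length(classes)
  nBenign <- 292
  v <- emptyVariantTable(nPath + nBenign, panel)
  v$consequence <- c(classes, rep("missense", nBenign))
  mis <- v$consequence %in% c("missense", "synonymous")
  resd <- ((seq_len(nPath + nBenign) - 1L) %% 1278L) + 1L
  v$protein_change[mis] <- paste0("A", resd[mis], "V")
  ## annotations: damaging concordant for pathogenic missense except the
  ## two ClinVar-rescued records; benign concordant for the rest
  isPathMis <- seq_len(nPath + nBenign) <= nPath & v$consequence == "missense"
  v$sift[isPathMis] <- "deleterious"
  v$polyphen[isPathMis] <- "probably_damaging"
  rescued <- which(isPathMis)[1:2]
  v$sift[rescued] <- "tolerated"
  v$polyphen[rescued] <- "benign"
  v$clinvar[rescued] <- "pathogenic"
  benign <- seq_len(nPath + nBenign) > nPath
  v$sift[benign] <- "tolerated"
  v$polyphen[benign] <- "benign"
  ## group placement: specific singletons, then two-group records;
  ## benign records all placed in eur
  assignOne <- function(v, i, g) {
    v[[sprintf("AC_%s", g)]][i] <- 1L
    v[[sprintf("AC_%s_male", g)]][i] <- 1L
    v
  }
  grpSeq <- rep(names(specific), times = specific)
  for (i in seq_along(grpSeq)) v <- assignOne(v, i, grpSeq[i])
  for (i in seq_len(nOverlap)) {
    v <- assignOne(v, length(grpSeq) + i, "eur")
    v <- assignOne(v, length(grpSeq) + i, "sas")
  }
  for (i in which(benign)) v <- assignOne(v, i, "eur")
  validateVariants(v, panel)
  v
}
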