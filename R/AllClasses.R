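#' @import methods
NULL

## Controlled vocabularies shared across modules. Variant consequence levels
## follow the VEP/SO terms the classifier distinguishes; everything else the
## annotation source may emit collapses to "other".
CONSEQUENCE_LEVELS <- c("missense", "stop_gained", "splice_acceptor",
                        "splice_donor", "frameshift", "start_lost",
                        "stop_lost", "synonymous", "inframe_indel", "other")
SIFT_LEVELS     <- c("deleterious", "tolerated", "missing")
POLYPHEN_LEVELS <- c("probably_damaging", "possibly_damaging", "benign",
                     "missing")
CLINVAR_LEVELS  <- c("pathogenic", "likely_pathogenic", "benign",
                     "likely_benign", "vus", "conflicting", "absent")

#' PopulationPanel: ancestry groups of an aggregate exome cohort
#'
#' Holds the ancestry-group composition of the cohort the variant table was
#' aggregated over: one row per group with the number of sequenced
#' individuals and its male/female split. A designated catch-all group (for
#' cohorts that bin unassigned ancestries into an "other" category) is kept
#' in the object but excluded from every analysis; all per-group operations
#' in the package iterate over \code{analysedGroups()}.
#'
#' Total allele count per group is \code{2 * n} (autosomal diploid).
#'
#' @slot groups data.frame with columns \code{label}, \code{n},
#'   \code{n_male}, \code{n_female}.
#' @slot otherLabel character(1) label of the excluded catch-all group, or
#'   \code{NA_character_} if the panel has none.
#' @exportClass PopulationPanel
setClass("PopulationPanel",
         representation(groups = "data.frame", otherLabel = "character"))

setValidity("PopulationPanel", function(object) {
  g <- object@groups
  need <- c("label", "n", "n_male", "n_female")
  if (!all(need %in% names(g)))
    return(paste("groups must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(g$label))
    return("group labels must be unique")
  if (any(g$n <= 0))
    return("every group must have n > 0 individuals")
  bad <- g$label[g$n_male + g$n_female != g$n]
  if (length(bad))
    return(paste("n_male + n_female != n for group(s):",
                 paste(bad, collapse = ", ")))
  if (length(object@otherLabel) != 1)
    return("otherLabel must be length 1 (possibly NA)")
  if (!is.na(object@otherLabel) && !object@otherLabel %in% g$label)
    return(paste0("otherLabel '", object@otherLabel,
                  "' is not a declared group"))
  TRUE
})

#' Construct a PopulationPanel
#'
#' @param labels character vector of group labels.
#' @param n integer vector of individuals per group.
#' @param nMale,nFemale integer vectors; must sum to \code{n} per group.
#' @param otherLabel optional label of the catch-all group that is retained
#'   in the data model but excluded from all analyses.
#' @return A \linkS4class{PopulationPanel}.
#' @examples
#' populationPanel(c("afr", "eur"), n = c(100, 200),
#'                 nMale = c(40, 120), nFemale = c(60, 80))
#' @export
populationPanel <- function(labels, n, nMale, nFemale,
                            otherLabel = NA_character_) {
  new("PopulationPanel",
      groups = data.frame(label = as.character(labels),
                          n = as.integer(n),
                          n_male = as.integer(nMale),
                          n_female = as.integer(nFemale),
                          stringsAsFactors = FALSE),
      otherLabel = as.character(otherLabel))
}

#' @describeIn populationPanel all group labels, including the catch-all.
#' @param panel a \linkS4class{PopulationPanel}.
#' @export
groupLabels <- function(panel) panel@groups$label

#' @describeIn populationPanel labels entering the analyses (catch-all
#'   excluded).
#' @export
analysedGroups <- function(panel) {
  setdiff(panel@groups$label, panel@otherLabel)
}

#' @describeIn populationPanel the label of the excluded catch-all group
#'   (\code{NA} if none).
#' @export
otherLabel <- function(panel) panel@otherLabel

#' @describeIn populationPanel named vector of individuals per group.
#' @param groups which groups to return (default: the analysed ones).
#' @export
nIndividuals <- function(panel, groups = analysedGroups(panel)) {
  g <- panel@groups
  stats::setNames(g$n, g$label)[groups]
}

#' @describeIn populationPanel named vector of males per group.
#' @export
nMale <- function(panel, groups = analysedGroups(panel)) {
  g <- panel@groups
  stats::setNames(g$n_male, g$label)[groups]
}

#' @describeIn populationPanel named vector of females per group.
#' @export
nFemale <- function(panel, groups = analysedGroups(panel)) {
  g <- panel@groups
  stats::setNames(g$n_female, g$label)[groups]
}

#' @describeIn populationPanel named vector of total alleles (2n) per group.
#' @export
nAlleles <- function(panel, groups = analysedGroups(panel)) {
  2L * nIndividuals(panel, groups)
}

setMethod("show", "PopulationPanel", function(object) {
  g <- object@groups
  cat("PopulationPanel with", nrow(g), "group(s),",
      sum(g$n), "individuals\n")
  if (!is.na(object@otherLabel))
    cat("  excluded catch-all group:", object@otherLabel, "\n")
  print(g, row.names = FALSE)
})

#' DomainModel: protein-domain intervals of the target gene product
#'
#' Inclusive 1-based residue intervals of the annotated domains of a protein,
#' each labelled luminal, cytoplasmic or transmembrane, with a flag marking
#' membership of the sterol-sensing domain (SSD) block. Domains may not
#' overlap; residues covered by no domain form the inter-domain "linker" bin.
#'
#' @slot proteinLength integer(1) total residues.
#' @slot domains data.frame with columns \code{name}, \code{category},
#'   \code{start}, \code{end}, \code{in_ssd}, sorted by \code{start}.
#' @exportClass DomainModel
setClass("DomainModel",
         representation(proteinLength = "integer", domains = "data.frame"))

setValidity("DomainModel", function(object) {
  d <- object@domains
  need <- c("name", "category", "start", "end", "in_ssd")
  if (!all(need %in% names(d)))
    return(paste("domains must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(d$name)) return("domain names must be unique")
  if (!all(d$category %in% c("luminal", "cytoplasmic", "transmembrane")))
    return("category must be luminal, cytoplasmic or transmembrane")
  if (any(d$end < d$start)) {
    bad <- d$name[d$end < d$start]
    return(paste("end < start for domain(s):", paste(bad, collapse = ", ")))
  }
  if (any(d$start < 1) || any(d$end > object@proteinLength))
    return("domain intervals must lie within [1, proteinLength]")
  if (nrow(d) > 1) {
    o <- order(d$start)
    ovl <- which(d$start[o][-1] <= d$end[o][-nrow(d)])
    if (length(ovl))
      return(paste0("overlapping domains: ", d$name[o][ovl[1]], " and ",
                    d$name[o][ovl[1] + 1]))
  }
  TRUE
})

#' Construct a DomainModel
#'
#' @param domains data.frame with columns \code{name}, \code{category},
#'   \code{start}, \code{end}, \code{in_ssd} (1-based inclusive residue
#'   intervals).
#' @param proteinLength integer(1) protein length in residues.
#' @return A \linkS4class{DomainModel} with domains sorted by start.
#' @export
domainModel <- function(domains, proteinLength) {
  domains <- as.data.frame(domains)
  domains$start <- as.integer(domains$start)
  domains$end <- as.integer(domains$end)
  domains$in_ssd <- as.logical(domains$in_ssd)
  domains <- domains[order(domains$start), , drop = FALSE]
  rownames(domains) <- NULL
  new("DomainModel", proteinLength = as.integer(proteinLength),
      domains = domains)
}

#' @describeIn domainModel protein length in residues.
#' @param model a \linkS4class{DomainModel}.
#' @export
proteinLength <- function(model) model@proteinLength

#' @describeIn domainModel the domain table (sorted by start).
#' @export
domainTable <- function(model) model@domains

setMethod("show", "DomainModel", function(object) {
  cat("DomainModel:", nrow(object@domains), "domains over",
      object@proteinLength, "residues;",
      sum(object@domains$in_ssd), "in the SSD block\n")
})

#' ClassificationPolicy: the pathogenicity rule set
#'
#' Parameters of the deterministic classification cascade applied to every
#' variant: the rarity threshold (alt-allele frequency strictly below
#' \code{mafThreshold} in every analysed ancestry group), the consequence
#' classes treated as loss-of-function, the in silico concordance rule for
#' missense variants, the ClinVar rescue switch, the canonical isoform, and
#' the consequence classes excluded from study.
#'
#' Defaults mirror the conventional filtering of a rare-disease carrier
#' screen on aggregate exome data: MAF < 1\% in all groups; nonsense,
#' essential splice and frameshift alleles are LOF; a missense allele is
#' damaging when SIFT and PolyPhen-2 concur (\code{both_damaging}), with
#' PolyPhen "possibly damaging" counted as damaging; a pathogenic or likely
#' pathogenic ClinVar assertion overrides benign in silico verdicts;
#' synonymous, in-frame indel, start/stop-loss and unclassified consequences
#' are not scored.
#'
#' @slot mafThreshold numeric(1) in (0, 0.5].
#' @slot lofClasses character, consequence classes called pathogenic as LOF.
#' @slot inSilicoRule one of \code{"both_damaging"}, \code{"either_damaging"},
#'   \code{"sift_only"}, \code{"polyphen_only"}.
#' @slot polyphenDamaging character, PolyPhen verdicts counted as damaging.
#' @slot clinvarOverride logical(1).
#' @slot canonicalIsoform character(1).
#' @slot excludedClasses character, consequence classes never scored.
#' @exportClass ClassificationPolicy
setClass("ClassificationPolicy",
         representation(mafThreshold = "numeric", lofClasses = "character",
                        inSilicoRule = "character",
                        polyphenDamaging = "character",
                        clinvarOverride = "logical",
                        canonicalIsoform = "character",
                        excludedClasses = "character"))

setValidity("ClassificationPolicy", function(object) {
  if (object@mafThreshold <= 0 || object@mafThreshold > 0.5)
    return("mafThreshold must be in (0, 0.5]")
  if (length(intersect(object@lofClasses, object@excludedClasses)))
    return("lofClasses and excludedClasses must be disjoint")
  if (!object@inSilicoRule %in% c("both_damaging", "either_damaging",
                                  "sift_only", "polyphen_only"))
    return("unknown inSilicoRule")
  if (!all(object@lofClasses %in% CONSEQUENCE_LEVELS))
    return("unknown consequence in lofClasses")
  if (!all(object@excludedClasses %in% CONSEQUENCE_LEVELS))
    return("unknown consequence in excludedClasses")
  TRUE
})

#' Construct a ClassificationPolicy
#'
#' @param mafThreshold rarity threshold on the per-group alt-allele
#'   frequency; a variant is rare iff strictly below it in every analysed
#'   group. Default 0.01.
#' @param lofClasses consequence classes called pathogenic loss-of-function.
#' @param inSilicoRule how SIFT and PolyPhen-2 verdicts combine for missense.
#' @param polyphenDamaging PolyPhen-2 verdicts counted as damaging.
#' @param clinvarOverride if TRUE, a ClinVar pathogenic/likely pathogenic
#'   assertion makes a missense variant pathogenic regardless of the in
#'   silico verdicts.
#' @param canonicalIsoform isoform identifier variants must be annotated
#'   against; others are excluded.
#' @param excludedClasses consequence classes removed from study (synonymous
#'   additionally maps to a non-pathogenic call rather than an exclusion).
#' @return A \linkS4class{ClassificationPolicy}.
#' @export
classificationPolicy <- function(mafThreshold = 0.01,
                                 lofClasses = c("stop_gained",
                                                "splice_acceptor",
                                                "splice_donor", "frameshift"),
                                 inSilicoRule = "both_damaging",
                                 polyphenDamaging = c("probably_damaging",
                                                      "possibly_damaging"),
                                 clinvarOverride = TRUE,
                                 canonicalIsoform = "1",
                                 excludedClasses = c("synonymous",
                                                     "inframe_indel", "other",
                                                     "stop_lost",
                                                     "start_lost")) {
  new("ClassificationPolicy", mafThreshold = mafThreshold,
      lofClasses = lofClasses, inSilicoRule = inSilicoRule,
      polyphenDamaging = polyphenDamaging,
      clinvarOverride = clinvarOverride,
      canonicalIsoform = as.character(canonicalIsoform),
      excludedClasses = excludedClasses)
}

setMethod("show", "ClassificationPolicy", function(object) {
  cat("ClassificationPolicy\n")
  cat("  MAF threshold (strict, every group):", object@mafThreshold, "\n")
  cat("  LOF classes:", paste(object@lofClasses, collapse = ", "), "\n")
  cat("  in silico rule:", object@inSilicoRule,
      "| ClinVar override:", object@clinvarOverride, "\n")
  cat("  canonical isoform:", object@canonicalIsoform, "\n")
  cat("  excluded classes:",
      paste(object@excludedClasses, collapse = ", "), "\n")
})

#' EMConfig: settings of the three-class Poisson mixture behind pLI
#'
#' The constraint model assigns each gene to one of three selection classes
#' -- null (LOF fully tolerated), recessive, and haploinsufficient -- whose
#' expected LOF counts are the neutral expectation scaled by a fixed
#' depletion factor (1, 0.463, 0.089; the ExAC calibration). pLI is the
#' posterior probability of the haploinsufficient class. With
#' \code{estimatePriors = TRUE} the mixture weights are fitted by EM across
#' genes; otherwise the posteriors are a single Bayes update under
#' \code{priors}.
#'
#' @slot factors numeric(3) strictly decreasing depletion factors.
#' @slot priors numeric(3) mixture weights, sum 1.
#' @slot estimatePriors logical(1).
#' @slot tol numeric(1) absolute log-likelihood increment declaring
#'   convergence.
#' @slot maxIter integer(1).
#' @exportClass EMConfig
setClass("EMConfig",
         representation(factors = "numeric", priors = "numeric",
                        estimatePriors = "logical", tol = "numeric",
                        maxIter = "integer"))

setValidity("EMConfig", function(object) {
  if (length(object@factors) != 3 || any(diff(object@factors) >= 0))
    return("factors must be 3 strictly decreasing values")
  if (length(object@priors) != 3 || any(object@priors < 0) ||
      abs(sum(object@priors) - 1) > 1e-9)
    return("priors must be 3 non-negative values summing to 1")
  if (object@tol <= 0) return("tol must be positive")
  if (object@maxIter < 1) return("maxIter must be >= 1")
  TRUE
})

#' Construct an EMConfig
#'
#' @param factors depletion factors of the null / recessive /
#'   haploinsufficient classes.
#' @param priors initial (or, with \code{estimatePriors = FALSE}, fixed)
#'   mixture weights.
#' @param estimatePriors fit the weights by EM across genes (needs >= 2
#'   genes to be informative).
#' @param tol convergence threshold on the log-likelihood increment.
#' @param maxIter iteration cap; non-convergence is flagged, best iterate
#'   returned.
#' @return An \linkS4class{EMConfig}.
#' @export
emConfig <- function(factors = c(null = 1.0, recessive = 0.463,
                                 haploinsufficient = 0.089),
                     priors = rep(1 / 3, 3), estimatePriors = TRUE,
                     tol = 1e-8, maxIter = 1000L) {
  new("EMConfig", factors = unname(factors), priors = priors,
      estimatePriors = estimatePriors, tol = tol,
      maxIter = as.integer(maxIter))
}

setMethod("show", "EMConfig", function(object) {
  cat("EMConfig: factors", paste(object@factors, collapse = "/"),
      "| priors", paste(signif(object@priors, 3), collapse = "/"),
      if (object@estimatePriors) "(EM-fitted)" else "(fixed)", "\n")
})
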