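## Synthetic cohort and gene-table generators with known truth, emulating
## the per-population aggregate allele-count structure of a large exome
## database. Every stochastic draw for variant i flows from a sub-stream
## seeded deterministically from (seed, i), so adding variants to a config
## never perturbs earlier records.

#' The default six-group ancestry panel
#'
#' Mirrors a large exome-database panel: African/African American (8,128),
#' Ashkenazi Jewish (5,040), East Asian (9,197), European (67,709), Latino
#' (17,296) and South Asian (15,308) individuals, 122,678 analysed in
#' total, plus a catch-all "oth" group (3,070) that is retained in the data
#' model but excluded from analyses. Sex splits follow the same source.
#'
#' @return A \linkS4class{PopulationPanel}.
#' @export
defaultPanel <- function() {
  populationPanel(
    labels  = c("afr", "asj", "eas", "eur", "lat", "sas", "oth"),
    n       = c(8128, 5040, 9197, 67709, 17296, 15308, 3070),
    nMale   = c(3093, 2590, 4533, 37442, 7161, 11536, 1577),
    nFemale = c(5035, 2450, 4664, 30267, 10135, 3772, 1493),
    otherLabel = "oth")
}

#' CohortSimConfig: settings of the synthetic cohort generator
#'
#' @slot panel the \linkS4class{PopulationPanel} to simulate over.
#' @slot nVariants named integer: variants per consequence class.
#' @slot pathFraction fraction of missense variants that are
#'   truth-pathogenic.
#' @slot commonFraction fraction of truth-negative variants made common
#'   (AF above the rarity threshold in one group) to exercise the MAF
#'   filter.
#' @slot specificFraction fraction of variants confined to a single
#'   analysed group.
#' @slot zipfExponent,maxCopies the total alt-copy count of a rare variant
#'   is drawn from P(k) proportional to k^-zipfExponent on 1..maxCopies
#'   (a heavy-tailed rare-variant frequency spectrum).
#' @slot homRule \code{"hwe"} (homozygotes drawn binomially with
#'   probability q^2 per group, capped by the allele count) or
#'   \code{"explicit"} (none).
#' @slot annotationNoise probability that a missense variant's SIFT and
#'   PolyPhen verdicts contradict its truth label.
#' @slot clinvarRescue fraction of truth-pathogenic missense labelled
#'   benign in silico but pathogenic in ClinVar.
#' @slot seed integer master seed.
#' @exportClass CohortSimConfig
setClass("CohortSimConfig",
         representation(panel = "PopulationPanel", nVariants = "integer",
                        pathFraction = "numeric", commonFraction = "numeric",
                        specificFraction = "numeric",
                        zipfExponent = "numeric", maxCopies = "integer",
                        homRule = "character", annotationNoise = "numeric",
                        clinvarRescue = "numeric", seed = "integer"))

setValidity("CohortSimConfig", function(object) {
  fr <- c(object@pathFraction, object@commonFraction,
          object@specificFraction, object@annotationNoise,
          object@clinvarRescue)
  if (any(fr < 0 | fr > 1)) return("all fractions must be in [0, 1]")
  if (!object@homRule %in% c("hwe", "explicit"))
    return("homRule must be 'hwe' or 'explicit'")
  if (is.null(names(object@nVariants)) ||
      !all(names(object@nVariants) %in% CONSEQUENCE_LEVELS))
    return("nVariants must be named by consequence class")
  if (object@maxCopies < 1) return("maxCopies must be >= 1")
  TRUE
})

#' Construct a CohortSimConfig
#'
#' Defaults give a small cohort over the default panel with noiseless
#' annotations (so the classifier recovers truth exactly), a heavy-tailed
#' allele-count spectrum capped at 30 copies (always rare against panel
#' groups of thousands of individuals), Hardy-Weinberg homozygotes, and an
#' 82\% group-specific fraction.
#'
#' @param panel a \linkS4class{PopulationPanel}.
#' @param nVariants named integer vector of variants per consequence class.
#' @param pathFraction fraction of missense variants that are
#'   truth-pathogenic.
#' @param commonFraction fraction of truth-negative missense made common.
#' @param specificFraction fraction of variants confined to one group.
#' @param zipfExponent,maxCopies alt-copy spectrum parameters.
#' @param homRule \code{"hwe"} or \code{"explicit"}.
#' @param annotationNoise verdict-flip probability.
#' @param clinvarRescue ClinVar-rescue fraction among truth-pathogenic
#'   missense.
#' @param seed integer master seed.
#' @return A \linkS4class{CohortSimConfig}.
#' @export
cohortSimConfig <- function(panel = defaultPanel(),
                            nVariants = c(missense = 200, stop_gained = 10,
                                          splice_acceptor = 5,
                                          splice_donor = 5, frameshift = 20,
                                          synonymous = 50,
                                          inframe_indel = 5),
                            pathFraction = 0.55, commonFraction = 0.1,
                            specificFraction = 0.82, zipfExponent = 1.5,
                            maxCopies = 30L, homRule = "hwe",
                            annotationNoise = 0, clinvarRescue = 0,
                            seed = 1L) {
  new("CohortSimConfig", panel = panel,
      nVariants = stats::setNames(as.integer(nVariants), names(nVariants)),
      pathFraction = pathFraction, commonFraction = commonFraction,
      specificFraction = specificFraction, zipfExponent = zipfExponent,
      maxCopies = as.integer(maxCopies), homRule = homRule,
      annotationNoise = annotationNoise, clinvarRescue = clinvarRescue,
      seed = as.integer(seed))
}

setMethod("show", "CohortSimConfig", function(object) {
  cat("CohortSimConfig:", sum(object@nVariants), "variants over",
      length(groupLabels(object@panel)), "groups; seed", object@seed, "\n")
})

## Deterministic sub-stream seed for variant i under master seed s.
subSeed <- function(s, i) {
  ((as.numeric(s) %% 97651) * 20011 + i * 7919) %% 2147483629 + 1
}

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BASES <- c("A", "C", "G", "T")

#' Simulate a gnomAD-like variant cohort with truth labels
#'
#' Generates one variant record per configured slot, with per-group AC/AN/
#' nhomalt and sex-split counts, annotations consistent with the truth
#' label (subject to the configured noise and ClinVar rescue), and a truth
#' table recording each variant's intended classification and
#' group-specificity. Deterministic under a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param config a \linkS4class{CohortSimConfig}.
#' @return list with \code{variants} (validated variant data.frame) and
#'   \code{truth} (data.frame: \code{variant_id}, \code{consequence},
#'   \code{truth_status}, \code{specific_group} or NA).
#' @export
simulateCohort <- function(config) {
  if (exists(".Random.seed", .GlobalEnv)) {
    old <- get(".Random.seed", .GlobalEnv)
    on.exit(assign(".Random.seed", old, .GlobalEnv))
  } else on.exit(if (exists(".Random.seed", .GlobalEnv))
    rm(".Random.seed", envir = .GlobalEnv))
  panel <- config@panel
  groups <- analysedGroups(panel)
  nind <- nIndividuals(panel, groupLabels(panel))
  nm <- nMale(panel, groupLabels(panel))
  classes <- rep(names(config@nVariants), config@nVariants)
  nTot <- length(classes)
  zipfP <- (1:config@maxCopies)^(-config@zipfExponent)
  zipfP <- zipfP / sum(zipfP)

  rows <- vector("list", nTot)
  truth <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    set.seed(subSeed(config@seed, i))
    cls <- classes[i]
    isMis <- cls == "missense"
    truthPath <- if (isMis) stats::runif(1) < config@pathFraction
                 else cls %in% c("stop_gained", "splice_acceptor",
                                 "splice_donor", "frameshift")
    makeCommon <- isMis && !truthPath &&
      stats::runif(1) < config@commonFraction
    specific <- stats::runif(1) < config@specificFraction
    gsel <- if (specific) sample(groups, 1,
                                 prob = nind[groups] / sum(nind[groups]))
            else sample(groups, sample(2:3, 1))

    ## per-group counts
    ac <- stats::setNames(integer(length(nind)), names(nind))
    an <- 2L * nind
    if (makeCommon) {
      g <- gsel[1]
      ac[g] <- as.integer(ceiling(an[g] * stats::runif(1, 0.012, 0.05)))
    } else {
      k <- sample.int(config@maxCopies, 1, prob = zipfP)
      k <- max(k, length(gsel))
      if (length(gsel) == 1) ac[gsel] <- k
      else {
        split <- as.integer(stats::rmultinom(1, k - length(gsel),
                                             rep(1, length(gsel))))
        ac[gsel] <- 1L + split
      }
    }
    nh <- stats::setNames(integer(length(nind)), names(nind))
    if (config@homRule == "hwe") {
      for (g in names(ac)[ac > 0]) {
        q <- ac[g] / an[g]
        nh[g] <- min(stats::rbinom(1, nind[[g]], q^2), ac[g] %/% 2L)
      }
    }
    het <- ac - 2L * nh
    pMale <- nm / nind
    hetM <- stats::setNames(stats::rbinom(length(het), het, pMale),
                            names(het))
    nhM <- stats::setNames(stats::rbinom(length(nh), nh, pMale), names(nh))
    acM <- hetM + 2L * nhM

    ## annotations
    sift <- "missing"; pp <- "missing"; cv <- "absent"
    protChange <- NA_character_
    if (isMis || cls == "synonymous") {
      resd <- sample.int(1278L, 1)
      aaRef <- sample(AA1, 1)
      aaAlt <- if (cls == "synonymous") aaRef
               else sample(setdiff(AA1, aaRef), 1)
      protChange <- paste0(aaRef, resd, aaAlt)
    }
    if (isMis) {
      rescued <- truthPath && stats::runif(1) < config@clinvarRescue
      damaging <- truthPath && !rescued
      if (stats::runif(1) < config@annotationNoise) damaging <- !damaging
      sift <- if (damaging) "deleterious" else "tolerated"
      pp <- if (damaging) "probably_damaging" else "benign"
      if (rescued) cv <- "pathogenic"
    }
    ref <- sample(BASES, 1)
    alt <- if (cls == "frameshift") paste0(ref, sample(BASES, 1)) else
      sample(setdiff(BASES, ref), 1)

    row <- data.frame(chrom = "18", pos = 21100000L + i * 13L, ref = ref,
                      alt = alt, gene = "NPC1", consequence = cls,
                      protein_change = protChange, isoform = "1",
                      sift = sift, polyphen = pp, clinvar = cv,
                      qc_flag = FALSE, stringsAsFactors = FALSE)
    for (g in groupLabels(panel)) {
      row[[sprintf("AC_%s", g)]] <- ac[[g]]
      row[[sprintf("AN_%s", g)]] <- an[[g]]
      row[[sprintf("nhomalt_%s", g)]] <- nh[[g]]
      row[[sprintf("AC_%s_male", g)]] <- acM[[g]]
      row[[sprintf("AC_%s_female", g)]] <- ac[[g]] - acM[[g]]
      row[[sprintf("nhomalt_%s_male", g)]] <- nhM[[g]]
      row[[sprintf("nhomalt_%s_female", g)]] <- nh[[g]] - nhM[[g]]
    }
    rows[[i]] <- row
    truthStatus <- if (makeCommon) "excluded"
                   else if (cls %in% c("synonymous", "inframe_indel"))
                     if (cls == "synonymous") "non_pathogenic" else "excluded"
                   else if (truthPath) "pathogenic" else "non_pathogenic"
    truth[[i]] <- data.frame(
      variant_id = variantId(row), consequence = cls,
      truth_status = truthStatus,
      specific_group = if (specific) gsel[1] else NA_character_,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  validateVariants(variants, panel)
  list(variants = variants, truth = do.call(rbind, truth))
}

#' Simulate gene-constraint tables with known mixture classes
#'
#' Draws each gene's selection class from \code{priors}, its expected LOF
#' count from a lognormal, and its observed count as Poisson with mean
#' \code{factor_class * expected} -- the generating model of the pLI
#' mixture, for parameter-recovery testing.
#'
#' @param nGenes number of genes.
#' @param priors length-3 class probabilities (null, recessive,
#'   haploinsufficient), summing to 1.
#' @param meanlog,sdlog lognormal parameters of the expected counts
#'   (defaults: median 30 expected LOF per gene, sdlog 1).
#' @param factors length-3 depletion factors.
#' @param seed integer seed.
#' @return data.frame with columns \code{gene}, \code{obs}, \code{exp},
#'   \code{true_class} (1 = null, 2 = recessive, 3 = haploinsufficient).
#' @export
simulateConstraintGenes <- function(nGenes, priors = c(0.5, 0.3, 0.2),
                                    meanlog = log(30), sdlog = 1,
                                    factors = c(1, 0.463, 0.089),
                                    seed = 1L) {
  stopifnot(abs(sum(priors) - 1) < 1e-9)
  if (exists(".Random.seed", .GlobalEnv)) {
    old <- get(".Random.seed", .GlobalEnv)
    on.exit(assign(".Random.seed", old, .GlobalEnv))
  }
  set.seed(as.integer(seed))
  cl <- sample.int(3, nGenes, replace = TRUE, prob = priors)
  exp <- stats::rlnorm(nGenes, meanlog, sdlog)
  obs <- stats::rpois(nGenes, factors[cl] * exp)
  data.frame(gene = sprintf("gene%05d", seq_len(nGenes)), obs = obs,
             exp = exp, true_class = cl, stringsAsFactors = FALSE)
}
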