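## Pathogenicity classification: a deterministic rule cascade over validated
## variant records, mirroring the filtering of a rare-variant carrier screen
## on aggregate exome data.

#' Per-group alternate-allele frequencies
#'
#' AF = AC/AN within each analysed ancestry group (the catch-all group, if
#' any, is excluded). Groups with AN = 0 report AF = 0 and are flagged in
#' the \code{"zero_an"} attribute.
#'
#' @param variants variant data.frame.
#' @param panel a \linkS4class{PopulationPanel}.
#' @return numeric matrix, one row per variant, one column per analysed
#'   group; attribute \code{"zero_an"} is a logical matrix marking
#'   zero-denominator cells.
#' @export
groupAF <- function(variants, panel) {
  groups <- analysedGroups(panel)
  miss <- setdiff(sprintf("AC_%s", groups), names(variants))
  if (length(miss))
    stop("panel group(s) absent from variant counts: ",
         paste(sub("^AC_", "", miss), collapse = ", "))
  ac <- as.matrix(variants[sprintf("AC_%s", groups)])
  an <- as.matrix(variants[sprintf("AN_%s", groups)])
  af <- ifelse(an == 0, 0, ac / an)
  dimnames(af) <- list(variantId(variants), groups)
  zero <- an == 0
  dimnames(zero) <- dimnames(af)
  attr(af, "zero_an") <- zero
  af
}

#' Is a variant rare in every analysed group?
#'
#' TRUE iff the alternate-allele frequency is strictly below the policy's
#' MAF threshold in \emph{every} analysed ancestry group (a frequency of
#' exactly the threshold in any one group disqualifies).
#'
#' @inheritParams groupAF
#' @param policy a \linkS4class{ClassificationPolicy}.
#' @return logical vector, one element per variant.
#' @export
isRare <- function(variants, panel, policy = classificationPolicy()) {
  af <- groupAF(variants, panel)
  unname(apply(af < policy@mafThreshold, 1, all))
}

## Reason codes (machine-readable) used by the cascade.
REASON_CODES <- c("lof_class", "insilico_damaging", "clinvar_pathogenic",
                  "common_allele", "synonymous", "inframe_indel",
                  "qc_flagged", "other_group_only", "noncanonical_isoform",
                  "insilico_benign", "excluded_class", "unscorable")

#' Classify variants as pathogenic / non-pathogenic / excluded
#'
#' Applies the rule cascade in fixed order: (1) a QC flag excludes the
#' variant; (2) an alt-allele frequency at or above the MAF threshold in any
#' analysed group excludes it as a common allele; (3) a non-canonical
#' isoform annotation excludes it; (4) carriers confined to the catch-all
#' group exclude it; (5) consequence classes in the policy's excluded set
#' yield non-pathogenic (synonymous) or excluded (in-frame indel and other
#' unscored classes) calls; (6) loss-of-function classes are pathogenic;
#' (7) missense variants are pathogenic on a pathogenic/likely-pathogenic
#' ClinVar assertion (if the override is on), otherwise on a satisfied in
#' silico rule, otherwise non-pathogenic (with a distinct \code{unscorable}
#' code when no in silico or ClinVar evidence exists at all).
#'
#' Classification is per-variant (order-independent) and idempotent.
#'
#' @inheritParams isRare
#' @return data.frame with columns \code{variant_id}, \code{status}
#'   (\code{pathogenic}/\code{non_pathogenic}/\code{excluded}) and
#'   \code{reasons} (semicolon-joined reason codes).
#' @export
classifyVariants <- function(variants, panel,
                             policy = classificationPolicy()) {
  validateVariants(variants, panel)
  ids <- variantId(variants)
  rare <- isRare(variants, panel, policy)
  groups <- analysedGroups(panel)
  acAnalysed <- as.matrix(variants[sprintf("AC_%s", groups)])
  anyAnalysed <- rowSums(acAnalysed > 0) > 0
  other <- otherLabel(panel)
  inOther <- if (!is.na(other) &&
                 sprintf("AC_%s", other) %in% names(variants))
    variants[[sprintf("AC_%s", other)]] > 0 else rep(FALSE, nrow(variants))

  status <- character(nrow(variants))
  reasons <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    cls <- variants$consequence[i]
    if (isTRUE(variants$qc_flag[i])) {
      status[i] <- "excluded"; reasons[i] <- "qc_flagged"
    } else if (!rare[i]) {
      status[i] <- "excluded"; reasons[i] <- "common_allele"
    } else if (!is.na(variants$isoform[i]) &&
               variants$isoform[i] != policy@canonicalIsoform) {
      status[i] <- "excluded"; reasons[i] <- "noncanonical_isoform"
    } else if (inOther[i] && !anyAnalysed[i]) {
      status[i] <- "excluded"; reasons[i] <- "other_group_only"
    } else if (cls %in% policy@excludedClasses) {
      if (cls == "synonymous") {
        status[i] <- "non_pathogenic"; reasons[i] <- "synonymous"
      } else if (cls == "inframe_indel") {
        status[i] <- "excluded"; reasons[i] <- "inframe_indel"
      } else {
        status[i] <- "excluded"; reasons[i] <- "excluded_class"
      }
    } else if (cls %in% policy@lofClasses) {
      status[i] <- "pathogenic"; reasons[i] <- "lof_class"
    } else {
      ## missense (or any scorable non-LOF class)
      sift <- variants$sift[i]; pp <- variants$polyphen[i]
      cv <- variants$clinvar[i]
      siftDmg <- sift == "deleterious"
      ppDmg <- pp %in% policy@polyphenDamaging
      insilico <- switch(policy@inSilicoRule,
        both_damaging   = siftDmg && ppDmg,
        either_damaging = siftDmg || ppDmg,
        sift_only       = siftDmg,
        polyphen_only   = ppDmg)
      if (policy@clinvarOverride &&
          cv %in% c("pathogenic", "likely_pathogenic")) {
        status[i] <- "pathogenic"; reasons[i] <- "clinvar_pathogenic"
      } else if (sift == "missing" && pp == "missing" && cv == "absent") {
        status[i] <- "non_pathogenic"; reasons[i] <- "unscorable"
      } else if (insilico) {
        status[i] <- "pathogenic"; reasons[i] <- "insilico_damaging"
      } else {
        status[i] <- "non_pathogenic"; reasons[i] <- "insilico_benign"
      }
    }
  }
  data.frame(variant_id = ids, status = status, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Census of pathogenic calls by consequence class
#'
#' Counts distinct pathogenic variants per consequence class and their
#' percentage of the pathogenic total (full precision; round at display).
#'
#' @param calls data.frame from \code{\link{classifyVariants}}.
#' @param variants the matching variant data.frame (aligned by
#'   \code{variant_id}).
#' @return data.frame with columns \code{consequence}, \code{n},
#'   \code{percent}, ordered by the consequence vocabulary.
#' @export
mutationCensus <- function(calls, variants) {
  ids <- variantId(variants)
  m <- match(calls$variant_id, ids)
  if (anyNA(m)) stop("calls and variants are not aligned by variant_id")
  path <- calls$status == "pathogenic"
  cls <- factor(variants$consequence[m][path], levels = CONSEQUENCE_LEVELS)
  n <- as.integer(table(cls))
  keep <- n > 0
  total <- sum(n)
  data.frame(consequence = levels(cls)[keep], n = n[keep],
             percent = 100 * n[keep] / total, stringsAsFactors = FALSE)
}
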