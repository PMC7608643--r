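## Carrier prevalence: per-group mutated-allele and carrier counts, carrier
## frequencies, ethnic-specific partition, fold differences and chi-square
## heterogeneity tests.
##
## Counts are allele-derived: with only aggregate data, an individual
## carrying two different pathogenic variants is counted once per variant as
## a heterozygous carrier (compound heterozygotes cannot be identified from
## aggregate allele counts). Per variant and group: heterozygous carriers =
## AC - 2*nhomalt, homozygous carriers = nhomalt, mutated alleles = AC.

#' Per-group carrier counts for a set of pathogenic variants
#'
#' Aggregates per-variant allele counts into a carrier table: one row per
#' analysed group plus a \code{"global"} row summing them. Sex splits use
#' \code{AC_<g>_male/_female}; homozygote sexes come from
#' \code{nhomalt_<g>_male/_female} when those columns are present, otherwise
#' homozygote alleles are attributed greedily to males first
#' (\code{min(nhomalt, AC_male \%/\% 2)}) with the remainder to females.
#'
#' @param variants pathogenic variant data.frame (pre-filtered by the
#'   classifier).
#' @param panel a \linkS4class{PopulationPanel}.
#' @return data.frame with columns \code{group}, \code{n_individuals},
#'   \code{total_alleles}, \code{mutated_alleles}, \code{het_carriers},
#'   \code{hom_carriers}, \code{het_male}, \code{het_female},
#'   \code{hom_male}, \code{hom_female}, \code{ethnic_specific_mutations},
#'   \code{ethnic_specific_mutated_alleles}.
#' @export
carrierCounts <- function(variants, panel) {
  groups <- analysedGroups(panel)
  nind <- nIndividuals(panel)
  part <- ethnicSpecificPartition(variants, panel)
  rows <- lapply(groups, function(g) {
    ac <- variants[[sprintf("AC_%s", g)]]
    nh <- variants[[sprintf("nhomalt_%s", g)]]
    acm <- variants[[sprintf("AC_%s_male", g)]]
    acf <- variants[[sprintf("AC_%s_female", g)]]
    if (is.null(ac)) ac <- nh <- acm <- acf <- integer(0)
    nhmCol <- sprintf("nhomalt_%s_male", g)
    if (nhmCol %in% names(variants)) {
      nhm <- variants[[nhmCol]]
      nhf <- variants[[sprintf("nhomalt_%s_female", g)]]
    } else {
      nhm <- pmin(nh, acm %/% 2L)
      nhf <- nh - nhm
      infeasible <- 2L * nhf > acf
      if (any(infeasible))
        warning("sex attribution of homozygotes infeasible for ",
                sum(infeasible), " variant(s) in group ", g,
                "; attributed to males")
      nhm[infeasible] <- nh[infeasible] - (acf[infeasible] %/% 2L)
      nhf[infeasible] <- acf[infeasible] %/% 2L
    }
    specIds <- part$specific[[g]]
    spec <- variantId(variants) %in% specIds
    data.frame(group = g, n_individuals = nind[[g]],
               total_alleles = 2L * nind[[g]],
               mutated_alleles = sum(ac),
               het_carriers = sum(ac - 2L * nh),
               hom_carriers = sum(nh),
               het_male = sum(acm - 2L * nhm),
               het_female = sum(acf - 2L * nhf),
               hom_male = sum(nhm), hom_female = sum(nhf),
               ethnic_specific_mutations = length(specIds),
               ethnic_specific_mutated_alleles = sum(ac[spec]),
               stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  glob <- tbl[1, , drop = FALSE]
  glob$group <- "global"
  for (col in setdiff(names(tbl), "group")) glob[[col]] <- sum(tbl[[col]])
  out <- rbind(glob, tbl)
  rownames(out) <- NULL
  out
}

#' Populate carrier and allele frequencies on a carrier table
#'
#' Adds \code{allele_frequency} (mutated alleles / total alleles),
#' \code{het_frequency} and \code{hom_frequency} (carriers / individuals),
#' all as fractions at full precision. Groups with zero individuals report
#' 0 and are flagged in \code{zero_denominator}.
#'
#' @param table carrier-count data.frame from \code{\link{carrierCounts}}
#'   (or \code{\link{carrierTableFromCounts}}).
#' @return the table with frequency columns appended.
#' @export
carrierFrequencies <- function(table) {
  zero <- table$n_individuals == 0
  div <- function(a, b) ifelse(b == 0, 0, a / b)
  table$allele_frequency <- div(table$mutated_alleles, table$total_alleles)
  table$het_frequency <- div(table$het_carriers, table$n_individuals)
  table$hom_frequency <- div(table$hom_carriers, table$n_individuals)
  table$zero_denominator <- zero
  table
}

#' Build a carrier table from published per-group counts
#'
#' For reanalysis of printed summary tables: takes per-group heterozygous
#' and homozygous carrier counts, reconstructs mutated alleles as
#' \code{het + 2*hom}, sums a global row, and computes frequencies.
#'
#' @param panel a \linkS4class{PopulationPanel}.
#' @param het,hom named integer vectors of carrier counts (names = analysed
#'   group labels).
#' @param hetMale,homMale optional named vectors of male carrier counts
#'   (females are the remainder).
#' @return carrier table data.frame with frequencies populated.
#' @export
carrierTableFromCounts <- function(panel, het, hom, hetMale = NULL,
                                   homMale = NULL) {
  groups <- analysedGroups(panel)
  stopifnot(all(groups %in% names(het)), all(groups %in% names(hom)))
  nind <- nIndividuals(panel)
  tbl <- data.frame(group = groups, n_individuals = unname(nind[groups]),
                    total_alleles = unname(2L * nind[groups]),
                    het_carriers = unname(as.integer(het[groups])),
                    hom_carriers = unname(as.integer(hom[groups])),
                    stringsAsFactors = FALSE)
  tbl$mutated_alleles <- tbl$het_carriers + 2L * tbl$hom_carriers
  tbl$het_male <- if (is.null(hetMale)) NA_integer_
                  else as.integer(hetMale[groups])
  tbl$het_female <- tbl$het_carriers - tbl$het_male
  tbl$hom_male <- if (is.null(homMale)) NA_integer_
                  else as.integer(homMale[groups])
  tbl$hom_female <- tbl$hom_carriers - tbl$hom_male
  glob <- tbl[1, , drop = FALSE]
  glob$group <- "global"
  for (col in setdiff(names(tbl), "group")) glob[[col]] <- sum(tbl[[col]])
  out <- rbind(glob, tbl)
  rownames(out) <- NULL
  carrierFrequencies(out)
}

#' Partition pathogenic variants into group-specific and overlapping sets
#'
#' A variant is specific to an analysed group iff its alternate allele is
#' observed (AC > 0) in exactly that one group; variants observed in two or
#' more groups form the overlap set; variants with AC = 0 in every analysed
#' group go to a separate \code{unobserved} bin (never silently dropped).
#'
#' @inheritParams carrierCounts
#' @return list with \code{specific} (named list of variant-id vectors, one
#'   per group), \code{overlap} and \code{unobserved} (variant-id vectors).
#' @export
ethnicSpecificPartition <- function(variants, panel) {
  groups <- analysedGroups(panel)
  ids <- variantId(variants)
  if (nrow(variants) == 0) {
    spec <- stats::setNames(rep(list(character(0)), length(groups)), groups)
    return(list(specific = spec, overlap = character(0),
                unobserved = character(0)))
  }
  present <- sapply(groups, function(g)
    variants[[sprintf("AC_%s", g)]] > 0)
  present <- matrix(present, nrow = nrow(variants),
                    dimnames = list(ids, groups))
  k <- rowSums(present)
  spec <- lapply(groups, function(g) ids[k == 1 & present[, g]])
  names(spec) <- groups
  list(specific = spec, overlap = ids[k >= 2], unobserved = ids[k == 0])
}

#' Fold difference between the highest and lowest group frequency
#'
#' Ratio max/min over analysed groups of the chosen frequency. Following
#' the display convention of prevalence reports, the headline ratio is
#' computed on percentages rounded to 2 decimals and itself rounded to 1
#' decimal; the unrounded ratio is returned alongside.
#'
#' @param table carrier table with frequencies populated.
#' @param field \code{"het_frequency"} or \code{"allele_frequency"}.
#' @return list with \code{rounded} (1-dp ratio of 2-dp percentages),
#'   \code{unrounded}, \code{max_group}, \code{min_group}. A minimum of 0
#'   yields \code{NA} ratios (undefined).
#' @export
foldDifference <- function(table, field = c("het_frequency",
                                            "allele_frequency")) {
  field <- match.arg(field)
  rows <- table$group != "global"
  if (sum(rows) < 2) stop("need at least two groups")
  f <- table[[field]][rows]
  grp <- table$group[rows]
  if (min(f) == 0)
    return(list(rounded = NA_real_, unrounded = NA_real_,
                max_group = grp[which.max(f)], min_group = grp[which.min(f)]))
  pct <- round(100 * f, 2)
  list(rounded = round(max(pct) / min(pct), 1),
       unrounded = max(f) / min(f),
       max_group = grp[which.max(f)], min_group = grp[which.min(f)])
}

#' Chi-square heterogeneity test on a contingency table of counts
#'
#' Pearson chi-square with expected cells from the row/column marginals,
#' df = (r-1)(k-1), and a two-sided p-value from the upper tail of the
#' chi-square distribution. No continuity correction by default (matching
#' the plain test on r x k tables); Yates' correction is available for 2x2
#' tables via \code{correct = TRUE}. A p-value underflowing double
#' precision is labelled \code{"< 2.2e-308"}, never reported as 0 alone.
#'
#' @param x matrix of non-negative counts with positive marginals.
#' @param correct apply Yates' continuity correction (2x2 only).
#' @param tableKind label carried in the result (\code{allele_frequency},
#'   \code{ethnic_specific}, \code{sex}).
#' @return one-row data.frame: \code{statistic}, \code{df}, \code{p_value},
#'   \code{p_label}, \code{low_expected} (any expected cell < 5),
#'   \code{table_kind}.
#' @export
chiSquareTest <- function(x, correct = FALSE,
                          tableKind = "allele_frequency") {
  x <- as.matrix(x)
  if (any(x < 0) || anyNA(x)) stop("counts must be non-negative")
  rs <- rowSums(x); cs <- colSums(x); n <- sum(x)
  if (any(rs == 0) || any(cs == 0))
    stop("all row and column marginals must be positive")
  E <- outer(rs, cs) / n
  if (any(E == 0)) stop("expected cell count of zero")
  stat <- if (correct && all(dim(x) == 2))
    sum((pmax(abs(x - E) - 0.5, 0))^2 / E)
  else
    sum((x - E)^2 / E)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  data.frame(statistic = stat, df = df, p_value = p,
             p_label = if (p == 0) "< 2.2e-308" else
               format(p, digits = 6),
             low_expected = any(E < 5), table_kind = tableKind,
             stringsAsFactors = FALSE)
}

#' Allele-frequency heterogeneity across groups
#'
#' 2 x k test of (mutated alleles, non-mutated alleles) x analysed groups.
#'
#' @param table carrier table from \code{\link{carrierCounts}}.
#' @return one-row data.frame as \code{\link{chiSquareTest}}.
#' @export
alleleHeterogeneityTest <- function(table) {
  rows <- table$group != "global"
  m <- rbind(mutated = table$mutated_alleles[rows],
             other = table$total_alleles[rows] - table$mutated_alleles[rows])
  colnames(m) <- table$group[rows]
  chiSquareTest(m, tableKind = "allele_frequency")
}

#' Ethnic-specific carrier heterogeneity across groups
#'
#' 2 x k test of (ethnic-specific mutated alleles, other alleles) x groups.
#'
#' @param table carrier table with ethnic-specific columns populated.
#' @return one-row data.frame as \code{\link{chiSquareTest}}.
#' @export
ethnicSpecificTest <- function(table) {
  rows <- table$group != "global"
  m <- rbind(specific = table$ethnic_specific_mutated_alleles[rows],
             other = table$total_alleles[rows] -
               table$ethnic_specific_mutated_alleles[rows])
  colnames(m) <- table$group[rows]
  chiSquareTest(m, tableKind = "ethnic_specific")
}

#' Sex comparison of carrier prevalence
#'
#' One 2x2 test (carrier vs non-carrier x male/female) for the global row
#' and for every analysed group; carriers per sex are het + hom. Groups
#' with zero individuals of one sex are skipped with a flag.
#'
#' @param table carrier table with sex-split counts populated.
#' @param panel a \linkS4class{PopulationPanel}.
#' @param alpha significance level annotated on the result (default 0.05).
#' @return data.frame, one row per tested scope, with the chi-square
#'   columns plus \code{scope}, \code{significant} and \code{skipped}.
#' @export
sexComparison <- function(table, panel, alpha = 0.05) {
  groups <- analysedGroups(panel)
  nm <- nMale(panel); nf <- nFemale(panel)
  nmAll <- c(global = sum(nm), nm)
  nfAll <- c(global = sum(nf), nf)
  out <- lapply(c("global", groups), function(g) {
    row <- table[table$group == g, , drop = FALSE]
    carM <- row$het_male + row$hom_male
    carF <- row$het_female + row$hom_female
    if (nmAll[[g]] == 0 || nfAll[[g]] == 0 || anyNA(c(carM, carF))) {
      return(data.frame(scope = g, statistic = NA_real_, df = NA_integer_,
                        p_value = NA_real_, p_label = NA_character_,
                        low_expected = NA, table_kind = "sex",
                        significant = NA, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    m <- matrix(c(carM, nmAll[[g]] - carM, carF, nfAll[[g]] - carF), 2,
                dimnames = list(c("carrier", "non_carrier"),
                                c("male", "female")))
    res <- tryCatch(chiSquareTest(m, tableKind = "sex"),
                    error = function(e) NULL)
    if (is.null(res))   # degenerate marginal (e.g. no carriers at all)
      return(data.frame(scope = g, statistic = NA_real_, df = NA_integer_,
                        p_value = NA_real_, p_label = NA_character_,
                        low_expected = NA, table_kind = "sex",
                        significant = NA, skipped = TRUE,
                        stringsAsFactors = FALSE))
    cbind(scope = g, res, significant = res$p_value < alpha,
          skipped = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cumulative pathogenic allele frequencies, group-specific vs overlapping
#'
#' The per-group breakdown of the cumulative pathogenic allele frequency
#' into the contribution of group-specific mutations and of mutations
#' shared with other groups (the stacked-bar analogue of a cumulative
#' frequency figure), as fractions of the group's total alleles.
#'
#' @param table carrier table with frequencies and ethnic-specific columns.
#' @return data.frame with columns \code{group}, \code{specific_af},
#'   \code{overlapping_af}, \code{total_af}.
#' @export
cumulativeFrequencyTable <- function(table) {
  spec <- ifelse(table$total_alleles == 0, 0,
                 table$ethnic_specific_mutated_alleles / table$total_alleles)
  data.frame(group = table$group, specific_af = spec,
             overlapping_af = table$allele_frequency - spec,
             total_af = table$allele_frequency, stringsAsFactors = FALSE)
}
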