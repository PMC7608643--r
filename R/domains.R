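## Protein-domain burden of pathogenic missense mutations.
##
## Only missense mutations are placed (a truncating allele affects every
## downstream domain and is reported as a count, not positioned). The two
## headline statistics are normalised by domain length in residues:
## percentage of mutant amino acids = 100 * distinct mutated residues /
## length, and percentage of individuals = 100 * carrier-individuals /
## length (which may exceed 100 for short, heavily hit domains).

#' Assign residues to protein domains
#'
#' @param residue integer vector of 1-based residue positions.
#' @param model a \linkS4class{DomainModel}.
#' @return character vector of domain names, \code{NA} for residues in no
#'   domain (inter-domain linker).
#' @export
assignDomain <- function(residue, model) {
  if (any(residue < 1 | residue > proteinLength(model)))
    stop("residue out of protein range [1, ", proteinLength(model), "]")
  d <- domainTable(model)
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(residue, residue),
    IRanges::IRanges(d$start, d$end))
  out <- rep(NA_character_, length(residue))
  out[S4Vectors::queryHits(hits)] <- d$name[S4Vectors::subjectHits(hits)]
  out
}

#' Allele-derived carrier-individual count per variant
#'
#' Heterozygous plus homozygous carriers summed over analysed groups:
#' sum over groups of (AC - 2*nhomalt) + nhomalt = AC - nhomalt.
#'
#' @param variants variant data.frame.
#' @param panel a \linkS4class{PopulationPanel}.
#' @return integer vector, one element per variant.
#' @export
carriersPerVariant <- function(variants, panel) {
  groups <- analysedGroups(panel)
  ac <- as.matrix(variants[sprintf("AC_%s", groups)])
  nh <- as.matrix(variants[sprintf("nhomalt_%s", groups)])
  as.integer(rowSums(ac - nh))
}

#' Per-domain burden of pathogenic missense mutations
#'
#' One row per domain, plus a \code{linker} row for residues covered by no
#' domain and an \code{SSD} aggregate row summing the sterol-sensing-domain
#' block. Variants lacking a parseable protein change are skipped and
#' counted in the \code{"n_skipped"} attribute.
#'
#' @param variants pathogenic missense variant data.frame.
#' @param panel a \linkS4class{PopulationPanel} (for carrier counts).
#' @param model a \linkS4class{DomainModel}.
#' @return data.frame with columns \code{domain}, \code{category},
#'   \code{length}, \code{n_mutations}, \code{n_positions},
#'   \code{n_individuals}, \code{pct_mutant_aa}, \code{pct_individuals};
#'   attribute \code{"n_skipped"} counts unplaceable variants.
#' @export
domainStats <- function(variants, panel, model) {
  keep <- variants$consequence == "missense"
  variants <- variants[keep, , drop = FALSE]
  pc <- parseProteinChange(variants$protein_change)
  skip <- is.na(pc$residue)
  if (any(skip))
    warning(sum(skip), " missense variant(s) lack a protein change; skipped")
  variants <- variants[!skip, , drop = FALSE]
  res <- pc$residue[!skip]
  carriers <- carriersPerVariant(variants, panel)
  dom <- assignDomain(res, model)
  d <- domainTable(model)

  tally <- function(sel, name, category, len) {
    data.frame(domain = name, category = category, length = len,
               n_mutations = sum(sel),
               n_positions = length(unique(res[sel])),
               n_individuals = sum(carriers[sel]),
               pct_mutant_aa = 100 * length(unique(res[sel])) / len,
               pct_individuals = 100 * sum(carriers[sel]) / len,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(d)), function(i)
    tally(!is.na(dom) & dom == d$name[i], d$name[i], d$category[i],
          d$end[i] - d$start[i] + 1L))
  linkerLen <- proteinLength(model) - sum(d$end - d$start + 1L)
  rows <- c(rows, list(tally(is.na(dom), "linker", "linker",
                             max(linkerLen, 1L))))
  ssdSel <- !is.na(dom) & dom %in% d$name[d$in_ssd]
  ssdLen <- sum((d$end - d$start + 1L)[d$in_ssd])
  if (ssdLen > 0)
    rows <- c(rows, list(tally(ssdSel, "SSD", "aggregate", ssdLen)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(skip)
  out
}
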