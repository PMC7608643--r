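## Variant-table, domain-model and panel I/O.
##
## The variant table is a flat data.frame, one row per (site, alt allele),
## with per-group aggregate counts named after the gnomAD v2 convention:
## AC_<group>, AN_<group>, nhomalt_<group>, AC_<group>_male/_female and
## (optionally) nhomalt_<group>_male/_female. Annotation columns are
## consequence, protein_change, isoform, sift, polyphen, clinvar, qc_flag.
## Both dialects -- VCF 4.2 with those INFO keys plus a pipe-joined ANN
## field, and a TSV with the same names as columns ('.' for missing) --
## load to the identical data model.

ANNOTATION_COLS <- c("consequence", "protein_change", "isoform", "sift",
                     "polyphen", "clinvar", "qc_flag")
SITE_COLS <- c("chrom", "pos", "ref", "alt", "gene")

#' Stable variant identifier
#'
#' @param variants variant data.frame.
#' @return character vector \code{"chrom:pos:ref:alt"}.
#' @export
variantId <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

## Per-group count column names required for a panel.
countColumns <- function(panel, optional = FALSE) {
  g <- groupLabels(panel)
  if (optional)
    as.vector(t(outer(g, c("nhomalt_%s_male", "nhomalt_%s_female"),
                      function(a, b) sprintf(b, a))))
  else
    as.vector(t(outer(g, c("AC_%s", "AN_%s", "nhomalt_%s", "AC_%s_male",
                           "AC_%s_female"),
                      function(a, b) sprintf(b, a))))
}

#' Parse compact protein-change notation
#'
#' Accepts \code{"G149R"}-style strings (ancestral residue, 1-based position,
#' derived residue), with \code{"fs"} or \code{"*"} markers allowed on the
#' derived side.
#'
#' @param x character vector; \code{NA} propagates.
#' @return data.frame with columns \code{aa_ref}, \code{residue},
#'   \code{aa_alt}.
#' @export
parseProteinChange <- function(x) {
  m <- regmatches(x, regexec("^([A-Z*])([0-9]+)([A-Za-z*]+)$", x))
  bad <- !is.na(x) & lengths(m) != 4
  if (any(bad))
    stop("unparseable protein_change: ", paste(x[bad], collapse = ", "))
  data.frame(
    aa_ref = vapply(m, function(p) if (length(p)) p[2] else NA_character_,
                    ""),
    residue = vapply(m, function(p)
      if (length(p)) as.integer(p[3]) else NA_integer_, 1L),
    aa_alt = vapply(m, function(p) if (length(p)) p[4] else NA_character_,
                    ""),
    stringsAsFactors = FALSE)
}

#' Validate a variant table against its population panel
#'
#' Enforces the data-model invariants: all required site, annotation and
#' per-group count columns present; for every group
#' \code{0 <= 2*nhomalt <= AC <= AN <= 2n}; \code{AC_male + AC_female = AC};
#' \code{protein_change} present for missense and synonymous records.
#' Violations raise an error listing the offending variant ids; nothing is
#' ever silently dropped.
#'
#' @param variants variant data.frame.
#' @param panel a \linkS4class{PopulationPanel}.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validateVariants <- function(variants, panel) {
  need <- c(SITE_COLS, ANNOTATION_COLS, countColumns(panel))
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table is missing required column(s): ",
         paste(miss, collapse = ", "))
  ids <- variantId(variants)
  fail <- function(idx, what) {
    if (any(idx))
      stop("invalid variant record(s) [", what, "]: ",
           paste(ids[idx], collapse = ", "))
  }
  fail(!variants$consequence %in% CONSEQUENCE_LEVELS, "unknown consequence")
  fail(!variants$sift %in% SIFT_LEVELS, "unknown sift verdict")
  fail(!variants$polyphen %in% POLYPHEN_LEVELS, "unknown polyphen verdict")
  fail(!variants$clinvar %in% CLINVAR_LEVELS, "unknown clinvar assertion")
  nind <- nIndividuals(panel, groupLabels(panel))
  for (g in groupLabels(panel)) {
    ac <- variants[[sprintf("AC_%s", g)]]
    an <- variants[[sprintf("AN_%s", g)]]
    nh <- variants[[sprintf("nhomalt_%s", g)]]
    acm <- variants[[sprintf("AC_%s_male", g)]]
    acf <- variants[[sprintf("AC_%s_female", g)]]
    if (any(is.na(c(ac, an, nh, acm, acf))))
      stop("missing count value in group '", g, "' (line ",
           paste(which(is.na(ac + an + nh + acm + acf)), collapse = ", "),
           ")")
    fail(nh < 0 | 2L * nh > ac, sprintf("2*nhomalt_%s > AC_%s", g, g))
    fail(ac > an, sprintf("AC_%s > AN_%s", g, g))
    fail(an > 2L * nind[[g]], sprintf("AN_%s > 2n for group %s", g, g))
    fail(acm + acf != ac, sprintf("AC_%s_male + AC_%s_female != AC_%s",
                                  g, g, g))
  }
  fail(variants$consequence %in% c("missense", "synonymous") &
         is.na(variants$protein_change),
       "protein_change required for missense/synonymous")
  invisible(variants)
}

## '.' <-> NA conversions for the TSV dialect.
dotToNA <- function(x) ifelse(x == ".", NA_character_, x)
naToDot <- function(x) ifelse(is.na(x), ".", as.character(x))

#' Read a variant table
#'
#' Loads a per-variant allele-count table in either dialect into the
#' package's data model and validates it. Multi-allelic VCF sites are
#' decomposed into one record per alternate allele (site-level AN is
#' duplicated per alt). Record order is preserved; both dialects of the
#' same cohort yield identical tables.
#'
#' @param path file path.
#' @param panel the \linkS4class{PopulationPanel} declaring the expected
#'   per-group count fields.
#' @param dialect \code{"tsv"} or \code{"vcf"}.
#' @return validated variant data.frame.
#' @export
readVariantTable <- function(path, panel, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  v <- if (dialect == "tsv") readVariantTSV(path, panel)
       else readVariantVCF(path, panel)
  ## canonical column order so both dialects yield identical tables
  cols <- c(SITE_COLS, ANNOTATION_COLS, countColumns(panel),
            intersect(countColumns(panel, optional = TRUE), names(v)))
  v <- v[, cols, drop = FALSE]
  validateVariants(v, panel)
  v
}

readVariantTSV <- function(path, panel) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  need <- c(SITE_COLS, ANNOTATION_COLS, countColumns(panel))
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("TSV is missing required column(s): ", paste(miss, collapse = ", "))
  v <- raw
  v$pos <- as.integer(v$pos)
  v$protein_change <- dotToNA(v$protein_change)
  for (col in c("sift", "polyphen", "clinvar", "isoform", "consequence"))
    v[[col]] <- dotToNA(v[[col]])
  v$sift[is.na(v$sift)] <- "missing"
  v$polyphen[is.na(v$polyphen)] <- "missing"
  v$clinvar[is.na(v$clinvar)] <- "absent"
  v$qc_flag <- as.logical(as.integer(v$qc_flag))
  for (col in c(countColumns(panel),
                intersect(countColumns(panel, optional = TRUE), names(v)))) {
    val <- suppressWarnings(as.integer(dotToNA(v[[col]])))
    if (anyNA(val) && any(!is.na(dotToNA(raw[[col]])) & is.na(val)))
      stop("non-integer value in column ", col)
    v[[col]] <- val
  }
  rownames(v) <- NULL
  v
}

readVariantVCF <- function(path, panel) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)  # multi-allelic decomposition
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  ann <- strsplit(as.character(info$ANN), "|", fixed = TRUE)
  if (any(lengths(ann) != 8))
    stop("malformed ANN field (need ",
         "gene|consequence|protein_change|isoform|sift|polyphen|clinvar|flag)")
  annf <- function(i) dotToNA(vapply(ann, `[`, "", i))
  v <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    gene = annf(1), consequence = annf(2), protein_change = annf(3),
    isoform = annf(4), sift = annf(5), polyphen = annf(6),
    clinvar = annf(7),
    qc_flag = as.logical(as.integer(annf(8))),
    stringsAsFactors = FALSE)
  v$sift[is.na(v$sift)] <- "missing"
  v$polyphen[is.na(v$polyphen)] <- "missing"
  v$clinvar[is.na(v$clinvar)] <- "absent"
  for (col in countColumns(panel)) {
    if (is.null(info[[col]]))
      stop("VCF INFO is missing required key: ", col)
    v[[col]] <- as.integer(info[[col]])
  }
  for (col in countColumns(panel, optional = TRUE))
    if (!is.null(info[[col]])) v[[col]] <- as.integer(info[[col]])
  rownames(v) <- NULL
  v
}

#' Write a variant table
#'
#' @param variants variant data.frame.
#' @param path output file.
#' @param panel the \linkS4class{PopulationPanel}.
#' @param dialect \code{"tsv"} or \code{"vcf"}.
#' @return \code{path}, invisibly.
#' @export
writeVariantTable <- function(variants, path, panel,
                              dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    out <- variants
    out$protein_change <- naToDot(out$protein_change)
    out$qc_flag <- as.integer(out$qc_flag)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeVariantVCF(variants, path, panel)
  }
  invisible(path)
}

writeVariantVCF <- function(variants, path, panel) {
  groups <- groupLabels(panel)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=RareCarrier")
  for (g in groups) {
    hdr <- c(hdr,
      sprintf("##INFO=<ID=AC_%s,Number=A,Type=Integer,Description=\"Alt allele count in %s\">", g, g),
      sprintf("##INFO=<ID=AN_%s,Number=1,Type=Integer,Description=\"Total alleles in %s\">", g, g),
      sprintf("##INFO=<ID=nhomalt_%s,Number=A,Type=Integer,Description=\"Homozygous-alt individuals in %s\">", g, g),
      sprintf("##INFO=<ID=AC_%s_male,Number=A,Type=Integer,Description=\"Alt allele count in %s males\">", g, g),
      sprintf("##INFO=<ID=AC_%s_female,Number=A,Type=Integer,Description=\"Alt allele count in %s females\">", g, g),
      sprintf("##INFO=<ID=nhomalt_%s_male,Number=A,Type=Integer,Description=\"Homozygous-alt males in %s\">", g, g),
      sprintf("##INFO=<ID=nhomalt_%s_female,Number=A,Type=Integer,Description=\"Homozygous-alt females in %s\">", g, g))
  }
  hdr <- c(hdr,
    "##INFO=<ID=ANN,Number=A,Type=String,Description=\"gene|consequence|protein_change|isoform|sift|polyphen|clinvar|flag\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
  optCols <- intersect(countColumns(panel, optional = TRUE),
                       names(variants))
  infoStr <- vapply(seq_len(nrow(variants)), function(i) {
    kv <- character(0)
    for (col in c(countColumns(panel), optCols))
      kv <- c(kv, sprintf("%s=%d", col, variants[[col]][i]))
    ann <- paste(naToDot(c(variants$gene[i], variants$consequence[i],
                           variants$protein_change[i], variants$isoform[i],
                           variants$sift[i], variants$polyphen[i],
                           variants$clinvar[i],
                           as.integer(variants$qc_flag[i]))),
                 collapse = "|")
    paste(c(kv, sprintf("ANN=%s", ann)), collapse = ";")
  }, "")
  body <- paste(variants$chrom, variants$pos, variantId(variants),
                variants$ref, variants$alt, ".", "PASS", infoStr,
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a population-panel file
#'
#' TSV with columns \code{label}, \code{n}, \code{n_male}, \code{n_female}
#' and an optional \code{other} column (1 flags the catch-all group
#' excluded from analyses).
#'
#' @param path file path.
#' @return A \linkS4class{PopulationPanel}.
#' @export
readPopulationPanel <- function(path) {
  d <- utils::read.delim(path)
  other <- NA_character_
  if ("other" %in% names(d)) {
    idx <- which(as.integer(d$other) == 1L)
    if (length(idx) > 1) stop("at most one catch-all group allowed")
    if (length(idx) == 1) other <- d$label[idx]
  }
  populationPanel(d$label, d$n, d$n_male, d$n_female, otherLabel = other)
}

#' Read a protein-domain model
#'
#' TSV with header \code{name}, \code{category}, \code{start}, \code{end},
#' \code{in_ssd} and one optional comment line starting with \code{#}
#' carrying the protein length as \code{# protein_length=<n>}; alternatively
#' pass \code{proteinLength} explicitly.
#'
#' @param path file path.
#' @param proteinLength protein length in residues; if \code{NULL}, taken
#'   from the \code{# protein_length=} comment line.
#' @return A \linkS4class{DomainModel}.
#' @export
readDomainModel <- function(path, proteinLength = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(proteinLength)) {
    m <- regmatches(first, regexec("#\\s*protein_length=([0-9]+)", first))[[1]]
    if (length(m) != 2)
      stop("protein length not given and no '# protein_length=' header line")
    proteinLength <- as.integer(m[2])
  }
  d <- utils::read.delim(path, comment.char = "#")
  domainModel(d, proteinLength)
}

#' Write a domain model
#'
#' @param model a \linkS4class{DomainModel}.
#' @param path output file.
#' @export
writeDomainModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# protein_length=%d", proteinLength(model)), con)
  utils::write.table(domainTable(model), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a result table with full numeric precision
#'
#' TSV serializes doubles with \code{\%.17g} so that re-reading reproduces
#' them bit-for-bit; JSON keeps full precision natively. Display rounding is
#' left entirely to the report layer.
#'
#' @param x data.frame (or, for JSON, any list-like result).
#' @param path output file.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is.null(x)) stop("nothing to write")
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "rows", na = "null")
  } else {
    out <- as.data.frame(x)
    for (col in names(out))
      if (is.double(out[[col]]))
        out[[col]] <- sprintf("%.17g", out[[col]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    utils::read.delim(path, check.names = FALSE)
}
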