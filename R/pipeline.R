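## End-to-end orchestration: (simulate | ingest) -> classify -> prevalence
## -> domain burden -> constraint, writing every result table plus a
## machine-readable run manifest. Logs go to standard error; data only to
## files. A failure in any stage aborts with a stage-named error and
## removes partial outputs.

logMsg <- function(...) message("[RareCarrier] ", ...)

displayRound <- function(x, digits = 2) round(x, digits)

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the variant table; classify every
#' variant; compute the carrier-prevalence table, heterogeneity and sex
#' tests and the cumulative-frequency breakdown; map pathogenic missense
#' mutations onto the domain model; compute gene-constraint metrics.
#' Each stage's table is written to \code{outDir} as TSV (full precision);
#' the manifest (seed, input digests, per-stage row counts, output digests)
#' is written as JSON. Reruns with identical inputs and seed are
#' byte-identical.
#'
#' @param outDir output directory (created if needed).
#' @param panel a \linkS4class{PopulationPanel}.
#' @param variants variant data.frame, or \code{NULL} to simulate.
#' @param simConfig a \linkS4class{CohortSimConfig} used when
#'   \code{variants} is \code{NULL}.
#' @param policy a \linkS4class{ClassificationPolicy}.
#' @param domainModel a \linkS4class{DomainModel}, or \code{NULL} to skip
#'   the domain stage.
#' @param geneCounts constraint gene table (see \code{\link{geneConstraint}})
#'   or \code{NULL} to skip the constraint stage.
#' @param emSettings an \linkS4class{EMConfig}.
#' @param seed integer seed recorded in the manifest and forwarded to the
#'   simulator when one is used.
#' @return the run manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(outDir, panel = defaultPanel(), variants = NULL,
                        simConfig = NULL, policy = classificationPolicy(),
                        domainModel = NULL, geneCounts = NULL,
                        emSettings = emConfig(), seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  emit <- function(x, name) {
    path <- file.path(outDir, name)
    writeResultTable(x, path, "tsv")
    written <<- c(written, path)
    path
  }
  manifest <- list(tool = "RareCarrier",
                   version = as.character(utils::packageVersion("RareCarrier")),
                   seed = as.integer(seed),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list(), outputs = list())
  tryCatch({
    stage <- "ingest"
    if (is.null(variants)) {
      if (is.null(simConfig))
        simConfig <- cohortSimConfig(panel = panel, seed = seed)
      logMsg("simulating cohort (seed ", simConfig@seed, ")")
      sim <- simulateCohort(simConfig)
      variants <- sim$variants
      emit(sim$truth, "truth.tsv")
    } else {
      validateVariants(variants, panel)
    }
    emit(variants, "variants.tsv")
    manifest$stages$ingest <- nrow(variants)

    stage <- "classify"
    calls <- classifyVariants(variants, panel, policy)
    emit(calls, "calls.tsv")
    census <- mutationCensus(calls, variants)
    emit(census, "census.tsv")
    manifest$stages$classify <- nrow(calls)
    pathIds <- calls$variant_id[calls$status == "pathogenic"]
    pathVariants <- variants[variantId(variants) %in% pathIds, ,
                             drop = FALSE]
    logMsg(length(pathIds), " pathogenic of ", nrow(variants), " variants")

    stage <- "prevalence"
    tbl <- carrierFrequencies(carrierCounts(pathVariants, panel))
    emit(tbl, "carrier_table.tsv")
    ## degenerate tables (no mutated alleles at all) skip the tests
    safe <- function(expr) tryCatch(expr, error = function(e) NULL)
    tests <- do.call(rbind, Filter(Negate(is.null),
      list(safe(alleleHeterogeneityTest(tbl)),
           safe(ethnicSpecificTest(tbl)))))
    if (is.null(tests))
      tests <- data.frame(statistic = numeric(0), df = integer(0),
                          p_value = numeric(0), p_label = character(0),
                          low_expected = logical(0),
                          table_kind = character(0))
    sx <- sexComparison(tbl, panel)
    emit(tests, "heterogeneity_tests.tsv")
    emit(sx, "sex_tests.tsv")
    emit(cumulativeFrequencyTable(tbl), "cumulative_frequency.tsv")
    manifest$stages$prevalence <- nrow(tbl)

    if (!is.null(domainModel)) {
      stage <- "domains"
      ds <- domainStats(pathVariants, panel, domainModel)
      emit(ds, "domain_stats.tsv")
      manifest$stages$domains <- nrow(ds)
    }
    if (!is.null(geneCounts)) {
      stage <- "constraint"
      cr <- geneConstraint(geneCounts, emSettings)
      emit(cr, "constraint.tsv")
      manifest$stages$constraint <- nrow(cr)
    }
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$outputs <- as.list(tools::md5sum(written))
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  logMsg("wrote ", length(written), " tables + manifest to ", outDir)
  invisible(manifest)
}
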