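#' @import methods
NULL

#' PQTLCohort: a synthetic or ingested proteogenomic cohort
#'
#' Container for everything one pQTL analysis consumes: genotype dosages with
#' their variant map, aptamer-level protein measurements with target-gene
#' metadata, sample covariates, CSF biomarkers, disease GWAS summary
#' statistics, variant consequence annotations, and a gene-by-cell-type
#' expression table. When the cohort is simulated, the `truth` slot carries
#' the planted effects so that parameter-recovery tests can compare estimates
#' with ground truth.
#'
#' @slot genotypes numeric matrix, samples x variants, alt-allele dosages in
#'   [0, 2] (NA allowed for missing genotypes)
#' @slot variantMap data.frame with columns variant_id, chrom, pos, ref, alt,
#'   maf; one row per genotype column, positions strictly increasing within a
#'   chromosome
#' @slot proteins numeric matrix, samples x aptamers, positive RFU-like
#'   levels with NA for missing measurements
#' @slot aptamerInfo data.frame with columns aptamer_id, gene, tss_chrom,
#'   tss_pos; one row per protein column
#' @slot covariates data.frame keyed by sample_id (age, sex, genetic PCs,
#'   cohort dummies)
#' @slot biomarkers data.frame keyed by sample_id with positive amyloid and
#'   tau analyte levels
#' @slot gwas data.frame of per-variant disease summary statistics
#'   (variant_id, chrom, pos, effect_allele, other_allele, beta, se, p, n)
#' @slot annotations data.frame (variant_id, category)
#' @slot celltypeExpr numeric matrix, genes x cell types, non-negative mean
#'   expression
#' @slot truth list of planted ground truth (effects, hotspots,
#'   diseaseAptamers, caseStatus) or empty for ingested data
#' @slot metadata list of free-form provenance (seeds, generator arguments)
#'
#' @export
setClass("PQTLCohort",
  representation(
    genotypes = "matrix",
    variantMap = "data.frame",
    proteins = "matrix",
    aptamerInfo = "data.frame",
    covariates = "data.frame",
    biomarkers = "data.frame",
    gwas = "data.frame",
    annotations = "data.frame",
    celltypeExpr = "matrix",
    truth = "list",
    metadata = "list"
  ),
  prototype(
    genotypes = matrix(numeric(0), 0, 0),
    variantMap = data.frame(),
    proteins = matrix(numeric(0), 0, 0),
    aptamerInfo = data.frame(),
    covariates = data.frame(),
    biomarkers = data.frame(),
    gwas = data.frame(),
    annotations = data.frame(),
    celltypeExpr = matrix(numeric(0), 0, 0),
    truth = list(),
    metadata = list()
  )
)

validPQTLCohort <- function(object) {
  msg <- character(0)
  g <- object@genotypes
  vm <- object@variantMap
  if (ncol(g) && nrow(vm) != ncol(g)) {
    msg <- c(msg, "variantMap rows must match genotype columns")
  }
  if (length(g)) {
    rng <- range(g, na.rm = TRUE)
    if (rng[1] < -1e-8 || rng[2] > 2 + 1e-8) {
      msg <- c(msg, "dosages must lie in [0, 2]")
    }
  }
  if (nrow(vm)) {
    need <- c("variant_id", "chrom", "pos", "ref", "alt", "maf")
    if (!all(need %in% names(vm))) {
      msg <- c(msg, paste("variantMap needs columns:", paste(need, collapse = ", ")))
    } else {
      if (anyDuplicated(vm$variant_id)) msg <- c(msg, "duplicate variant_id")
      bad <- vapply(split(vm$pos, vm$chrom), function(p) any(diff(p) <= 0), TRUE)
      if (any(bad)) msg <- c(msg, "positions must strictly increase within chromosome")
    }
  }
  p <- object@proteins
  if (ncol(p) && nrow(object@aptamerInfo) != ncol(p)) {
    msg <- c(msg, "aptamerInfo rows must match protein columns")
  }
  if (length(p) && any(p[!is.na(p)] <= 0)) {
    msg <- c(msg, "observed protein levels must be positive")
  }
  if (nrow(g) && nrow(p) && nrow(g) != nrow(p)) {
    msg <- c(msg, "genotypes and proteins must share the sample axis")
  }
  if (length(msg)) msg else TRUE
}
setValidity("PQTLCohort", validPQTLCohort)

#' @describeIn PQTLCohort compact summary of the cohort dimensions
#' @param object a \code{PQTLCohort}
#' @export
setMethod("show", "PQTLCohort", function(object) {
  cat("PQTLCohort:", nrow(object@genotypes), "samples,",
      ncol(object@genotypes), "variants,",
      ncol(object@proteins), "aptamers\n")
  if (nrow(object@gwas)) cat("  disease GWAS:", nrow(object@gwas), "variants\n")
  if (length(object@truth)) {
    cat("  truth: ", nrow(object@truth$effects %||% data.frame()),
        " planted effects, ", length(object@truth$hotspots %||% list()),
        " hotspots\n", sep = "")
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accessors for PQTLCohort slots
#'
#' Standard read accessors; downstream code never touches slots directly.
#'
#' @param x a \code{PQTLCohort}
#' @return the corresponding table or matrix
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname cohort-accessors
#' @export
setMethod("genotypes", "PQTLCohort", function(x) x@genotypes)

#' @rdname cohort-accessors
#' @export
setGeneric("variantMap", function(x) standardGeneric("variantMap"))
#' @rdname cohort-accessors
#' @export
setMethod("variantMap", "PQTLCohort", function(x) x@variantMap)

#' @rdname cohort-accessors
#' @export
setGeneric("proteinLevels", function(x) standardGeneric("proteinLevels"))
#' @rdname cohort-accessors
#' @export
setMethod("proteinLevels", "PQTLCohort", function(x) x@proteins)

#' @rdname cohort-accessors
#' @export
setGeneric("aptamerInfo", function(x) standardGeneric("aptamerInfo"))
#' @rdname cohort-accessors
#' @export
setMethod("aptamerInfo", "PQTLCohort", function(x) x@aptamerInfo)

#' @rdname cohort-accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
#' @rdname cohort-accessors
#' @export
setMethod("covariates", "PQTLCohort", function(x) x@covariates)

#' @rdname cohort-accessors
#' @export
setGeneric("biomarkers", function(x) standardGeneric("biomarkers"))
#' @rdname cohort-accessors
#' @export
setMethod("biomarkers", "PQTLCohort", function(x) x@biomarkers)

#' @rdname cohort-accessors
#' @export
setGeneric("gwasSummary", function(x) standardGeneric("gwasSummary"))
#' @rdname cohort-accessors
#' @export
setMethod("gwasSummary", "PQTLCohort", function(x) x@gwas)

#' @rdname cohort-accessors
#' @export
setGeneric("variantAnnotations", function(x) standardGeneric("variantAnnotations"))
#' @rdname cohort-accessors
#' @export
setMethod("variantAnnotations", "PQTLCohort", function(x) x@annotations)

#' @rdname cohort-accessors
#' @export
setGeneric("celltypeExpression", function(x) standardGeneric("celltypeExpression"))
#' @rdname cohort-accessors
#' @export
setMethod("celltypeExpression", "PQTLCohort", function(x) x@celltypeExpr)

#' @rdname cohort-accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname cohort-accessors
#' @export
setMethod("truthTable", "PQTLCohort", function(x) x@truth)
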