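# Proteomic QC cascade and variant-level genotype filters.

newQCReport <- function() {
  data.frame(step = character(0), axis = character(0), removed = integer(0),
             remaining = integer(0), threshold = character(0),
             stringsAsFactors = FALSE)
}

addQCStep <- function(report, step, axis, removed, remaining, threshold) {
  rbind(report, data.frame(step = step, axis = axis,
                           removed = as.integer(removed),
                           remaining = as.integer(remaining),
                           threshold = as.character(threshold),
                           stringsAsFactors = FALSE))
}

#' Filter aptamers on plate scale-factor and CV metrics
#'
#' An aptamer is removed if the maximum absolute difference between its scale
#' factor and the per-plate median scale factor exceeds `sfMax` on any plate,
#' or if its median cross-plate coefficient of variation exceeds `cvMax`.
#' Aptamers whose metric rows are entirely missing are retained with a
#' warning (metrics unavailable) and logged in the report.
#'
#' @param scaleFactors aptamer x plate scale-factor matrix
#' @param cv aptamer x plate CV matrix
#' @param sfMax scale-factor deviation threshold (default 0.5)
#' @param cvMax median-CV threshold (default 0.15)
#' @return list(kept = character vector of aptamer ids, report = QC report)
#' @export
filterAptamersPlateMetrics <- function(scaleFactors, cv, sfMax = 0.5, cvMax = 0.15) {
  if (!ncol(scaleFactors)) stop("need at least one plate")
  stopifnot(identical(dim(scaleFactors), dim(cv)))
  apt <- rownames(scaleFactors)
  plateMedian <- apply(scaleFactors, 2L, stats::median, na.rm = TRUE)
  dev <- abs(sweep(scaleFactors, 2L, plateMedian))
  maxDev <- apply(dev, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  medCv <- apply(cv, 1L, stats::median, na.rm = TRUE)
  noMetrics <- is.na(maxDev) & is.na(medCv)
  if (any(noMetrics)) {
    warning(sum(noMetrics), " aptamer(s) retained with unavailable plate metrics")
  }
  failSf <- !is.na(maxDev) & maxDev > sfMax
  failCv <- !is.na(medCv) & medCv > cvMax
  drop <- failSf | failCv
  report <- newQCReport()
  report <- addQCStep(report, "scale_factor", "aptamer", sum(failSf),
                      length(apt) - sum(failSf), sfMax)
  report <- addQCStep(report, "median_cv", "aptamer", sum(failCv & !failSf),
                      length(apt) - sum(drop), cvMax)
  list(kept = apt[!drop], report = report,
       flaggedNoMetrics = apt[noMetrics])
}

# type-7 quartiles, fixed so the masking rule is deterministic
logQuartiles <- function(x) stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)

#' Mask outlying aptamer values by the 1.5 x IQR rule
#'
#' Quartiles are computed per aptamer on log10-transformed observed values
#' (type-7 interpolation). Entries whose log10 value falls below
#' Q1 - 1.5 IQR or above Q3 + 1.5 IQR are set to NA; everything else,
#' including already-missing entries, is untouched. Aptamers with fewer than
#' four observed values are not masked (warned).
#'
#' @param levels samples x aptamers positive matrix (NA = missing)
#' @return masked matrix on the original scale
#' @export
iqrMask <- function(levels) {
  out <- levels
  few <- 0L
  for (j in seq_len(ncol(levels))) {
    obs <- which(!is.na(levels[, j]))
    if (length(obs) < 4L) { few <- few + 1L; next }
    lx <- log10(levels[obs, j])
    q <- logQuartiles(lx)
    iqr <- q[2] - q[1]
    bad <- lx < q[1] - 1.5 * iqr | lx > q[2] + 1.5 * iqr
    out[obs[bad], j] <- NA_real_
  }
  if (few) warning(few, " aptamer(s) with < 4 observed values left unmasked")
  out
}

#' Ordered call-rate filtering cascade
#'
#' Applies (axis, threshold) steps strictly in order, recomputing call rates
#' on the surviving matrix after each removal. The default schedule is the
#' lenient 65% gate on aptamers then samples, followed by the stringent 85%
#' gate on aptamers then samples.
#'
#' @param mat samples x aptamers matrix with NA for missing
#' @param schedule list of c(axis, threshold) pairs, axis in
#'   {"aptamer", "sample"}
#' @return list(matrix = filtered matrix, report = QC report)
#' @export
callRateCascade <- function(mat,
                            schedule = list(c("aptamer", 0.65), c("sample", 0.65),
                                            c("aptamer", 0.85), c("sample", 0.85))) {
  report <- newQCReport()
  for (i in seq_along(schedule)) {
    axis <- schedule[[i]][1]
    thr <- as.numeric(schedule[[i]][2])
    if (axis == "aptamer") {
      cr <- colMeans(!is.na(mat))
      keep <- cr >= thr
      removed <- sum(!keep)
      mat <- mat[, keep, drop = FALSE]
      remaining <- ncol(mat)
    } else if (axis == "sample") {
      cr <- rowMeans(!is.na(mat))
      keep <- cr >= thr
      removed <- sum(!keep)
      mat <- mat[keep, , drop = FALSE]
      remaining <- nrow(mat)
    } else stop("axis must be 'aptamer' or 'sample'")
    report <- addQCStep(report, sprintf("call_rate_%d", i), axis,
                        removed, remaining, thr)
    if (!nrow(mat) || !ncol(mat)) {
      stop(sprintf("matrix empty after cascade step %d (%s, %.2f)", i, axis, thr))
    }
  }
  list(matrix = mat, report = report)
}

#' Z-score normalize protein levels on the log10 scale
#'
#' Per aptamer, observed values are log10-transformed then centered and
#' scaled to mean 0, sd 1. Missing entries stay missing. Zero-variance or
#' single-observation aptamers come back all-missing with a warning. The
#' output is invariant to positive rescaling of the raw input.
#'
#' @param mat samples x aptamers positive matrix
#' @return z-scored matrix
#' @export
normalizeLevels <- function(mat) {
  out <- mat
  degenerate <- 0L
  for (j in seq_len(ncol(mat))) {
    obs <- which(!is.na(mat[, j]))
    lx <- log10(mat[obs, j])
    s <- stats::sd(lx)
    if (length(obs) < 2L || is.na(s) || s < 1e-12) {
      out[, j] <- NA_real_
      degenerate <- degenerate + 1L
      next
    }
    out[obs, j] <- (lx - mean(lx)) / s
  }
  if (degenerate) warning(degenerate, " zero-variance aptamer(s) set to missing")
  out
}

#' Exact conditional Hardy-Weinberg test
#'
#' Two-sided exact p-value: the sum of probabilities of all heterozygote
#' counts (conditional on allele counts) whose probability does not exceed
#' that of the observed configuration.
#'
#' @param nAA,nAa,naa genotype counts
#' @return p-value in (0, 1]
#' @export
hweExactP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0L) return(1)
  nA <- 2L * nAA + nAa # minor-agnostic: use rarer allele count
  na <- 2L * naa + nAa
  rare <- min(nA, na)
  hetVals <- seq(rare %% 2L, rare, by = 2L)
  logProb <- function(h) {
    hom1 <- (rare - h) / 2
    hom2 <- n - h - hom1
    lgamma(n + 1) - lgamma(hom1 + 1) - lgamma(h + 1) - lgamma(hom2 + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }
  lp <- vapply(hetVals, logProb, 0)
  pr <- exp(lp - logSumExp(lp)) # renormalize to guard rounding
  obs <- pr[match(nAa, hetVals)]
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Variant-level genotype filters
#'
#' Removes variants failing minor allele frequency, exact Hardy-Weinberg,
#' call rate, or minor allele count gates, and strand-ambiguous (A/T, C/G)
#' variants. HWE is tested on dosages rounded to the nearest hard genotype.
#'
#' @param dosages samples x variants dosage matrix
#' @param variantMap matching variant map
#' @param mafMin minimum minor allele frequency (default 0.01)
#' @param hwePMin minimum exact HWE p-value (default 1e-6)
#' @param callRateMin minimum per-variant call rate (default 0.98)
#' @param macMin minimum minor allele count (default 10)
#' @param dropAmbiguous remove A/T and C/G variants (default TRUE)
#' @return list(kept = variant ids, report = QC report, details = per-variant
#'   data.frame of the computed metrics)
#' @export
genotypeFilters <- function(dosages, variantMap, mafMin = 0.01, hwePMin = 1e-6,
                            callRateMin = 0.98, macMin = 10,
                            dropAmbiguous = TRUE) {
  stopifnot(ncol(dosages) == nrow(variantMap))
  cr <- colMeans(!is.na(dosages))
  hard <- round(dosages)
  altCount <- colSums(hard, na.rm = TRUE)
  nObs <- colSums(!is.na(hard))
  af <- altCount / (2 * nObs)
  maf <- pmin(af, 1 - af)
  mac <- pmin(altCount, 2 * nObs - altCount)
  hweP <- vapply(seq_len(ncol(hard)), function(j) {
    g <- hard[!is.na(hard[, j]), j]
    hweExactP(sum(g == 0), sum(g == 1), sum(g == 2))
  }, 0)
  amb <- isAmbiguousPair(variantMap$ref, variantMap$alt)

  failCr <- cr < callRateMin
  failMaf <- maf < mafMin
  failMac <- mac < macMin
  failHwe <- hweP < hwePMin
  failAmb <- dropAmbiguous & amb
  drop <- failCr | failMaf | failMac | failHwe | failAmb

  report <- newQCReport()
  remaining <- ncol(dosages)
  for (nm in c("call_rate", "maf", "mac", "hwe", "ambiguous")) {
    f <- switch(nm, call_rate = failCr, maf = failMaf & !failCr,
                mac = failMac & !failCr & !failMaf,
                hwe = failHwe & !failCr & !failMaf & !failMac,
                ambiguous = failAmb & !failCr & !failMaf & !failMac & !failHwe)
    remaining <- remaining - sum(f)
    thr <- switch(nm, call_rate = callRateMin, maf = mafMin, mac = macMin,
                  hwe = hwePMin, ambiguous = dropAmbiguous)
    report <- addQCStep(report, nm, "variant", sum(f), remaining, thr)
  }
  list(kept = variantMap$variant_id[!drop], report = report,
       details = data.frame(variant_id = variantMap$variant_id,
                            call_rate = cr, maf = maf, mac = mac, hwe_p = hweP,
                            ambiguous = amb, stringsAsFactors = FALSE))
}
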