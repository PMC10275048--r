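# Genome-wide per-aptamer linear-model scans, the proteomic-PC trans
# threshold, fixed-effect IVW meta-analysis with genomic control, the
# four-gate significance filter, cis/trans labelling, and the stratified
# effect-difference statistic.

# covariate data.frame -> full-rank numeric design matrix with intercept;
# collinear columns dropped with a warning naming them
buildDesign <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  df <- covariates
  df$sample_id <- NULL
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    warning("dropping collinear covariate column(s): ", paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  X
}

#' Per-aptamer genome-wide additive linear-model scan
#'
#' For every (variant, aptamer) pair, fits z-scored protein ~ dosage +
#' covariates by OLS and reports the dosage coefficient, its standard error,
#' and the two-sided p-value from the t reference with residual degrees of
#' freedom. Samples with a missing protein value are dropped per aptamer.
#' Variants with minor allele count below `minMac` (or monomorphic) among
#' the used samples are skipped with a reason.
#'
#' The computation residualizes both the protein and the dosage matrix on
#' the covariate design, which is algebraically identical to the full OLS
#' fit and vectorizes across variants.
#'
#' @param dosages samples x variants dosage matrix
#' @param proteinZ samples x aptamers z-scored matrix (NA = missing)
#' @param covariates data.frame of covariates (complete for used samples)
#' @param variantMap variant map supplying allele metadata
#' @param minMac minimum minor allele count (default 10)
#' @param stage stage label stored on each record
#' @return list(records = data.frame of AssociationRecords,
#'   skipped = data.frame(variant_id, aptamer_id, reason))
#' @export
pqtlScan <- function(dosages, proteinZ, covariates = NULL, variantMap = NULL,
                     minMac = 10, stage = "discovery") {
  n <- nrow(dosages)
  stopifnot(nrow(proteinZ) == n)
  X <- buildDesign(covariates, n)
  if (anyNA(X)) stop("covariates must be complete for used samples")
  ea <- oa <- rep(NA_character_, ncol(dosages))
  if (!is.null(variantMap)) {
    m <- match(colnames(dosages), variantMap$variant_id)
    ea <- variantMap$alt[m]; oa <- variantMap$ref[m]
  }
  # aptamers sharing a missingness pattern share the residualized dosage
  # matrix, so the per-variant statistics become one cross-product per group
  patterns <- apply(!is.na(proteinZ), 2L, paste, collapse = "")
  recs <- list(); skip <- list()
  for (pat in unique(patterns)) {
    apts <- which(patterns == pat)
    use <- which(!is.na(proteinZ[, apts[1L]]))
    if (length(use) < ncol(X) + 2L) next
    Xa <- X[use, , drop = FALSE]
    Ga <- dosages[use, , drop = FALSE]
    Ya <- proteinZ[use, apts, drop = FALSE]
    mac <- pmin(colSums(round(Ga)), 2L * length(use) - colSums(round(Ga)))
    ok <- which(mac >= minMac)
    bad <- which(mac < minMac)
    if (length(bad)) {
      skip[[length(skip) + 1L]] <- data.frame(
        variant_id = rep(colnames(dosages)[bad], length(apts)),
        aptamer_id = rep(colnames(proteinZ)[apts], each = length(bad)),
        reason = ifelse(rep(mac[bad] == 0, length(apts)),
                        "monomorphic", "low_mac"),
        stringsAsFactors = FALSE)
    }
    if (!length(ok)) next
    qrX <- qr(Xa)
    Yr <- qr.resid(qrX, Ya)
    Gr <- qr.resid(qrX, Ga[, ok, drop = FALSE])
    gss <- colSums(Gr^2)
    degenerate <- gss < 1e-10
    df <- length(use) - qrX$rank - 1L
    Bnum <- crossprod(Gr, Yr)               # variants x aptamers
    beta <- Bnum / gss
    yss <- colSums(Yr^2)
    rss <- pmax(rep(yss, each = length(ok)) - beta^2 * gss, 0)
    se <- sqrt(rss / df / gss)
    p <- 2 * stats::pt(-abs(beta / se), df)
    keepV <- which(!degenerate)
    if (length(keepV)) {
      recs[[length(recs) + 1L]] <- data.frame(
        variant_id = rep(colnames(dosages)[ok[keepV]], length(apts)),
        aptamer_id = rep(colnames(proteinZ)[apts], each = length(keepV)),
        beta = as.vector(beta[keepV, ]), se = as.vector(se[keepV, ]),
        p = as.vector(p[keepV, ]), n = length(use),
        effect_allele = rep(ea[ok[keepV]], length(apts)),
        other_allele = rep(oa[ok[keepV]], length(apts)),
        stage = stage, stringsAsFactors = FALSE)
    }
    if (any(degenerate)) {
      skip[[length(skip) + 1L]] <- data.frame(
        variant_id = rep(colnames(dosages)[ok[degenerate]], length(apts)),
        aptamer_id = rep(colnames(proteinZ)[apts], each = sum(degenerate)),
        reason = "monomorphic", stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, recs) %||% data.frame(),
       skipped = do.call(rbind, skip) %||%
         data.frame(variant_id = character(0), aptamer_id = character(0),
                    reason = character(0)))
}

#' Study-wide trans threshold from proteomic principal components
#'
#' K is the smallest number of principal components of the mean-imputed,
#' per-aptamer standardized protein matrix whose cumulative explained
#' variance reaches `varianceTarget`; the trans threshold is 5e-8 / K. The
#' decomposition uses the singular values of the standardized matrix, so the
#' aptamers-exceed-samples case is handled through the dual spectrum.
#'
#' @param proteinZ samples x aptamers matrix (missing values allowed)
#' @param varianceTarget cumulative explained-variance target (default 0.95)
#' @param cisP genome-wide threshold for cis associations (default 5e-8)
#' @param discP,repP stage-level gates (defaults 0.005 and 0.05)
#' @return list(K, cis_p, trans_p, disc_p, rep_p, rank)
#' @export
transThreshold <- function(proteinZ, varianceTarget = 0.95, cisP = 5e-8,
                           discP = 0.005, repP = 0.05) {
  if (ncol(proteinZ) < 2) stop("need at least 2 aptamers")
  M <- proteinZ
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    s <- stats::sd(v)
    M[, j] <- if (is.na(s) || s < 1e-12) 0 else (v - mean(v)) / s
  }
  sv <- svd(M, nu = 0, nv = 0)$d
  ev <- sv^2
  ev <- ev[ev > 1e-12 * max(ev)]
  cum <- cumsum(ev) / sum(ev)
  K <- which(cum >= varianceTarget)[1]
  list(K = K, cis_p = cisP, trans_p = cisP / K, disc_p = discP, rep_p = repP,
       rank = length(ev))
}

#' Genomic-control inflation factor from two-sided p-values
#'
#' lambda = median(qchisq(1 - p, 1)) / 0.4549 -- computed from p-values so it
#' also works on externally supplied summary statistics without betas.
#'
#' @param p vector of two-sided p-values
#' @return lambda
#' @export
genomicControlLambda <- function(p) {
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq, na.rm = TRUE) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

# integer (variant, aptamer) pair keys against shared levels: avoids
# million-row string pastes on genome-scale record sets
pairKey <- function(d, levV, levA) {
  (match(d$aptamer_id, levA) - 1) * (length(levV) + 1) +
    match(d$variant_id, levV)
}

matchPairs <- function(from, to) {
  levV <- unique(c(from$variant_id, to$variant_id))
  levA <- unique(c(from$aptamer_id, to$aptamer_id))
  match(pairKey(from, levV, levA), pairKey(to, levV, levA))
}

# harmonize rep alleles onto disc; returns rep with sign-flipped betas where
# alleles are swapped, drops mismatches
harmonizeAlleles <- function(disc, rep) {
  m <- matchPairs(rep, disc)
  rep <- rep[!is.na(m), , drop = FALSE]
  d <- disc[m[!is.na(m)], , drop = FALSE]
  same <- rep$effect_allele == d$effect_allele & rep$other_allele == d$other_allele
  swap <- rep$effect_allele == d$other_allele & rep$other_allele == d$effect_allele
  rep$beta[swap] <- -rep$beta[swap]
  rep$effect_allele[swap] <- d$effect_allele[swap]
  rep$other_allele[swap] <- d$other_allele[swap]
  keep <- same | swap
  list(rep = rep[keep, , drop = FALSE], nMismatch = sum(!keep))
}

#' Fixed-effect inverse-variance-weighted meta-analysis with genomic control
#'
#' Records are matched on (variant, aptamer); replication alleles are
#' harmonized to discovery (sign flip on swapped alleles, mismatches dropped
#' and counted). With `gc = TRUE` each study's standard errors are inflated
#' by sqrt(lambda) when its lambda exceeds 1 before combining. The combined
#' p-value uses the normal reference.
#'
#' @param disc,rep AssociationRecord data.frames from \code{\link{pqtlScan}}
#' @param gc apply genomic control per input study (default TRUE)
#' @return list(meta = combined records, gc = per-study lambda table,
#'   nOnlyOneStage = pairs excluded for missing a stage,
#'   nAlleleMismatch = pairs dropped at harmonization)
#' @export
metaFixedIVW <- function(disc, rep, gc = TRUE) {
  h <- harmonizeAlleles(disc, rep)
  rep2 <- h$rep
  m <- matchPairs(rep2, disc)
  d <- disc[m, , drop = FALSE]
  lamD <- genomicControlLambda(disc$p)
  lamR <- genomicControlLambda(rep$p)
  seD <- d$se * if (gc && lamD > 1) sqrt(lamD) else 1
  seR <- rep2$se * if (gc && lamR > 1) sqrt(lamR) else 1
  wD <- 1 / seD^2; wR <- 1 / seR^2
  beta <- (d$beta * wD + rep2$beta * wR) / (wD + wR)
  se <- 1 / sqrt(wD + wR)
  meta <- data.frame(
    variant_id = d$variant_id, aptamer_id = d$aptamer_id,
    beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)),
    n = d$n + rep2$n, effect_allele = d$effect_allele,
    other_allele = d$other_allele, stage = "meta", stringsAsFactors = FALSE)
  list(meta = meta,
       gc = data.frame(stage = c("discovery", "replication"),
                       lambda = c(lamD, lamR),
                       applied = gc & c(lamD, lamR) > 1),
       nOnlyOneStage = (nrow(disc) - nrow(meta)) + (nrow(rep) - nrow(meta)),
       nAlleleMismatch = h$nMismatch)
}

#' Label variant-aptamer pairs cis or trans by the TSS window rule
#'
#' Cis iff the variant sits on the same chromosome as the aptamer target
#' gene's transcription start site and within `window` base pairs of it
#' (boundary inclusive); otherwise trans. Aptamers without a mapped TSS get
#' "unassigned".
#'
#' @param variantIds,aptamerIds parallel vectors defining the pairs
#' @param variantMap variant map
#' @param aptamerInfo aptamer metadata with tss_chrom/tss_pos
#' @param window half-width in bp (default 1e6)
#' @return character vector in {"cis", "trans", "unassigned"}
#' @export
classifyCisTrans <- function(variantIds, aptamerIds, variantMap, aptamerInfo,
                             window = 1e6) {
  vi <- match(variantIds, variantMap$variant_id)
  ai <- match(aptamerIds, aptamerInfo$aptamer_id)
  tssChrom <- aptamerInfo$tss_chrom[ai]
  tssPos <- aptamerInfo$tss_pos[ai]
  out <- ifelse(is.na(tssChrom) | is.na(tssPos), "unassigned",
         ifelse(variantMap$chrom[vi] == tssChrom &
                  abs(variantMap$pos[vi] - tssPos) <= window, "cis", "trans"))
  out
}

#' Four-gate significance filter on meta-analysis results
#'
#' A pair is retained iff discovery p < disc_p, replication p < rep_p, the
#' discovery and replication effects agree in sign, and the meta p-value
#' passes the study-wide threshold for its cis/trans label. Pairs missing a
#' stage record fail and are counted separately.
#'
#' @param meta,disc,rep AssociationRecord data.frames
#' @param thresholds list as returned by \code{\link{transThreshold}}
#' @param cisLabels character vector parallel to `meta` rows ("cis"/"trans")
#' @return list(significant = retained meta rows with label,
#'   rejections = per-gate counts)
#' @export
significanceFilter <- function(meta, disc, rep, thresholds, cisLabels) {
  stopifnot(nrow(meta) == length(cisLabels))
  di <- matchPairs(meta, disc)
  ri <- matchPairs(meta, rep)
  missingStage <- is.na(di) | is.na(ri)
  pd <- disc$p[di]; pr <- rep$p[ri]
  sd_ <- sign(disc$beta[di]); sr <- sign(rep$beta[ri])
  gateDisc <- !is.na(pd) & pd < thresholds$disc_p
  gateRep <- !is.na(pr) & pr < thresholds$rep_p
  gateDir <- !is.na(sd_) & !is.na(sr) & sd_ == sr & sd_ != 0
  metaThr <- ifelse(cisLabels == "cis", thresholds$cis_p,
             ifelse(cisLabels == "trans", thresholds$trans_p, NA_real_))
  gateMeta <- !is.na(metaThr) & meta$p < metaThr
  keep <- !missingStage & gateDisc & gateRep & gateDir & gateMeta
  out <- meta[keep, , drop = FALSE]
  out$label <- cisLabels[keep]
  list(significant = out,
       rejections = c(missing_stage = sum(missingStage),
                      discovery_gate = sum(!missingStage & !gateDisc),
                      replication_gate = sum(!missingStage & gateDisc & !gateRep),
                      direction = sum(!missingStage & gateDisc & gateRep & !gateDir),
                      study_wide = sum(!missingStage & gateDisc & gateRep &
                                         gateDir & !gateMeta)))
}

#' Effect-size difference between biomarker strata
#'
#' Zdiff = (beta_neg - beta_pos) / sqrt(se_neg^2 + se_pos^2), flagged when
#' |Zdiff| exceeds the two-sided normal critical value (default 1.960,
#' alpha = 0.05). Missing strata yield an undefined flag.
#'
#' @param betaNeg,seNeg estimates in the biomarker-negative stratum
#' @param betaPos,sePos estimates in the biomarker-positive stratum
#' @param cutoff critical value (default 1.960)
#' @return data.frame(zdiff, flagged)
#' @export
stratifiedZdiff <- function(betaNeg, seNeg, betaPos, sePos, cutoff = 1.960) {
  z <- (betaNeg - betaPos) / sqrt(seNeg^2 + sePos^2)
  data.frame(zdiff = z, flagged = ifelse(is.na(z), NA, abs(z) > cutoff))
}
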