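# Integration of pQTL summary statistics with a disease GWAS: single-
# causal-variant approximate-Bayes-factor colocalization, two-sample
# Mendelian randomization with instrument filters and the Steiger
# directionality test, and a summary-statistic PWAS.

# Wakefield log approximate Bayes factor per variant.
# W is the prior variance of the effect: (0.15 * sdY)^2 for a quantitative
# trait, 0.2^2 for case-control log-odds.
wakefieldLogABF <- function(beta, se, traitType = c("quant", "cc"), sdY = 1) {
  traitType <- match.arg(traitType)
  W <- if (traitType == "quant") (0.15 * sdY)^2 else 0.2^2
  V <- se^2
  z2 <- (beta / se)^2
  r <- W / (W + V)
  0.5 * (log(1 - r) + z2 * r)
}

#' Approximate-Bayes-factor colocalization of two traits
#'
#' Single-causal-variant colocalization over the shared variants of two
#' summary-statistic sets. Per-variant Wakefield log-ABFs feed the five
#' hypothesis sums (H0 no signal; H1/H2 signal in one trait; H3 two distinct
#' signals; H4 one shared signal), combined in log space with the
#' configuration priors and normalized to posterior probabilities.
#'
#' @param trait1,trait2 data.frames with variant_id, beta, se (and matching
#'   effect alleles; harmonize upstream)
#' @param priors c(p1, p2, p12) per-variant configuration priors
#'   (defaults 1e-4, 1e-4, 1e-5)
#' @param type1,type2 "quant" or "cc" per trait
#' @param sdY1,sdY2 trait sd for quantitative traits (1 for z-scored levels)
#' @return list(pp = named posteriors PP.H0..PP.H4, n_variants,
#'   underpowered flag (fewer than 10 shared variants), priors)
#' @export
colocAbf <- function(trait1, trait2, priors = c(1e-4, 1e-4, 1e-5),
                     type1 = "quant", type2 = "cc", sdY1 = 1, sdY2 = 1) {
  shared <- intersect(trait1$variant_id, trait2$variant_id)
  t1 <- trait1[match(shared, trait1$variant_id), , drop = FALSE]
  t2 <- trait2[match(shared, trait2$variant_id), , drop = FALSE]
  ok <- is.finite(t1$beta) & is.finite(t1$se) & t1$se > 0 &
    is.finite(t2$beta) & is.finite(t2$se) & t2$se > 0
  t1 <- t1[ok, ]; t2 <- t2[ok, ]
  nv <- nrow(t1)
  underpowered <- nv < 10
  if (!nv) stop("no shared variants with usable summary statistics")
  l1 <- wakefieldLogABF(t1$beta, t1$se, type1, sdY1)
  l2 <- wakefieldLogABF(t2$beta, t2$se, type2, sdY2)
  s1 <- logSumExp(l1)
  s2 <- logSumExp(l2)
  s12 <- logSumExp(l1 + l2)
  lH0 <- 0
  lH1 <- log(priors[1]) + s1
  lH2 <- log(priors[2]) + s2
  # sum over i != j of exp(l1_i + l2_j) = exp(s1 + s2 "minus diagonal")
  cross <- s1 + s2
  lH3 <- log(priors[1]) + log(priors[2]) +
    if (cross > s12) cross + log1p(-exp(s12 - cross)) else -Inf
  lH4 <- log(priors[3]) + s12
  lAll <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(lAll - logSumExp(lAll))
  names(pp) <- paste0("PP.H", 0:4)
  list(pp = pp, n_variants = nv, underpowered = underpowered, priors = priors)
}

#' Select and harmonize MR instruments for one aptamer
#'
#' Clumps the aptamer's genome-wide-significant pQTL records, then applies
#' the pleiotropy filters: trans instruments inside a pleiotropic region
#' regulating at least `regionAptamerMax` aptamers are removed, as are trans
#' instruments within `anchorKb` kilobases of the configured high-pleiotropy
#' anchor variant. Cis instruments in pleiotropic regions are retained but
#' flagged. Alleles are harmonized to the GWAS coding (sign flips on swapped
#' alleles; unmatched pairs dropped).
#'
#' @param pqtl AssociationRecords for one aptamer with a `label` column
#' @param gwas disease GWAS summary data.frame
#' @param dosages dosage matrix for clumping LD
#' @param variantMap variant map
#' @param regionAptamers optional named integer: variant_id -> number of
#'   aptamers regulated by that variant's pleiotropic region
#' @param anchorVariant optional variant id near which trans instruments are
#'   excluded
#' @param pThresh genome-wide instrument threshold (default 5e-8)
#' @param clumpR2,clumpKb clumping parameters. The defaults (0.01, 1000 kb)
#'   sit above the sampling floor of estimated r-squared at cohort-scale
#'   reference panels (about 1/n), so independent variants are not absorbed
#'   by estimation noise
#' @param regionAptamerMax region size triggering trans removal (default 5)
#' @param anchorKb exclusion half-width around the anchor in kb (default 500)
#' @return data.frame of instruments (beta_exp, se_exp, beta_out, se_out,
#'   p_exp, p_out, n_exp, n_out, label, flagged_pleiotropic) or a zero-row
#'   frame with attribute `reason` when nothing survives
#' @export
selectInstruments <- function(pqtl, gwas, dosages, variantMap,
                              regionAptamers = NULL, anchorVariant = NULL,
                              pThresh = 5e-8, clumpR2 = 0.01, clumpKb = 1000,
                              regionAptamerMax = 5, anchorKb = 500) {
  m <- match(pqtl$variant_id, variantMap$variant_id)
  pqtl$chrom <- variantMap$chrom[m]; pqtl$pos <- variantMap$pos[m]
  empty <- function(reason) {
    out <- data.frame(variant_id = character(0), beta_exp = numeric(0),
                      se_exp = numeric(0), beta_out = numeric(0),
                      se_out = numeric(0), p_exp = numeric(0),
                      p_out = numeric(0), n_exp = integer(0),
                      n_out = integer(0), label = character(0),
                      flagged_pleiotropic = logical(0))
    attr(out, "reason") <- reason
    out
  }
  sig <- pqtl[pqtl$p < pThresh, , drop = FALSE]
  if (!nrow(sig)) return(empty("no genome-wide-significant variants"))
  kept <- clumpVariants(sig, pThresh, clumpR2, clumpKb, dosages)
  ins <- sig[match(kept, sig$variant_id), , drop = FALSE]
  # pleiotropy filters (trans only)
  if (!is.null(regionAptamers)) {
    nApt <- regionAptamers[ins$variant_id]
    dropReg <- ins$label == "trans" & !is.na(nApt) & nApt >= regionAptamerMax
    ins$flagged_pleiotropic <- ins$label == "cis" & !is.na(nApt) &
      nApt >= regionAptamerMax
    ins <- ins[!dropReg, , drop = FALSE]
  } else ins$flagged_pleiotropic <- FALSE
  if (!is.null(anchorVariant) && nrow(ins)) {
    am <- match(anchorVariant, variantMap$variant_id)
    nearAnchor <- ins$chrom == variantMap$chrom[am] &
      abs(ins$pos - variantMap$pos[am]) <= anchorKb * 1000
    ins <- ins[!(ins$label == "trans" & nearAnchor), , drop = FALSE]
  }
  if (!nrow(ins)) return(empty("all instruments removed by pleiotropy filters"))
  # harmonize to the GWAS coding
  gi <- match(ins$variant_id, gwas$variant_id)
  present <- !is.na(gi)
  ins <- ins[present, , drop = FALSE]; gi <- gi[present]
  if (!nrow(ins)) return(empty("no instruments present in the GWAS"))
  same <- ins$effect_allele == gwas$effect_allele[gi] &
    ins$other_allele == gwas$other_allele[gi]
  swap <- ins$effect_allele == gwas$other_allele[gi] &
    ins$other_allele == gwas$effect_allele[gi]
  ins$beta[swap] <- -ins$beta[swap]
  keep <- same | swap
  ins <- ins[keep, , drop = FALSE]; gi <- gi[keep]
  if (!nrow(ins)) return(empty("allele harmonization removed all instruments"))
  data.frame(
    variant_id = ins$variant_id,
    beta_exp = ins$beta, se_exp = ins$se, p_exp = ins$p, n_exp = ins$n,
    beta_out = gwas$beta[gi], se_out = gwas$se[gi], p_out = gwas$p[gi],
    n_out = gwas$n[gi], label = ins$label,
    flagged_pleiotropic = ins$flagged_pleiotropic,
    stringsAsFactors = FALSE)
}

#' Two-sample MR estimate from harmonized instruments
#'
#' One instrument: Wald ratio beta_out / beta_exp with delta-method standard
#' error se_out / |beta_exp|. Two or more: fixed-effect IVW regression
#' through the origin, estimate = sum(b_exp b_out / se_out^2) /
#' sum(b_exp^2 / se_out^2), se = 1 / sqrt(sum(b_exp^2 / se_out^2)).
#'
#' @param instruments data.frame from \code{\link{selectInstruments}}
#' @return data.frame(method, estimate, se, p, n_instruments)
#' @export
mrEstimate <- function(instruments) {
  if (!nrow(instruments)) stop("need at least one instrument")
  if (nrow(instruments) == 1L) {
    if (abs(instruments$beta_exp) < .Machine$double.eps) {
      stop("lone instrument with zero exposure effect")
    }
    est <- instruments$beta_out / instruments$beta_exp
    se <- instruments$se_out / abs(instruments$beta_exp)
    method <- "Wald"
  } else {
    w <- instruments$beta_exp^2 / instruments$se_out^2
    est <- sum(instruments$beta_exp * instruments$beta_out /
                 instruments$se_out^2) / sum(w)
    se <- 1 / sqrt(sum(w))
    method <- "IVW"
  }
  data.frame(method = method, estimate = est, se = se,
             p = 2 * stats::pnorm(-abs(est / se)),
             n_instruments = nrow(instruments), stringsAsFactors = FALSE)
}

#' Steiger directionality test
#'
#' Per-trait variance explained is summed over instruments using
#' r^2 = z^2 / (z^2 + n - 2). Direction is exposure -> outcome iff the
#' exposure r^2 exceeds the outcome r^2; the p-value compares the
#' Fisher-z-transformed correlations treating the two samples as
#' independent (exact for a two-sample design).
#'
#' @param instruments harmonized instrument table
#' @param nExposure,nOutcome effective sample sizes (defaults from the table)
#' @return data.frame(r2_exposure, r2_outcome, correct_direction, p)
#' @export
steigerDirection <- function(instruments,
                             nExposure = stats::median(instruments$n_exp),
                             nOutcome = stats::median(instruments$n_out)) {
  if (nExposure <= 2 || nOutcome <= 2) stop("sample sizes must exceed 2")
  zE <- instruments$beta_exp / instruments$se_exp
  zO <- instruments$beta_out / instruments$se_out
  r2E <- sum(zE^2 / (zE^2 + nExposure - 2))
  r2O <- sum(zO^2 / (zO^2 + nOutcome - 2))
  rE <- sqrt(min(r2E, 1 - 1e-12))
  rO <- sqrt(min(r2O, 1 - 1e-12))
  zstat <- (atanh(rE) - atanh(rO)) /
    sqrt(1 / (nExposure - 3) + 1 / (nOutcome - 3))
  data.frame(r2_exposure = r2E, r2_outcome = r2O,
             correct_direction = r2E > r2O,
             p = 2 * stats::pnorm(-abs(zstat)))
}

#' MR across aptamers with FDR and Steiger confirmation
#'
#' @param instrumentList named list of instrument tables per aptamer
#' @return data.frame, one row per aptamer with an estimate, with q_fdr
#'   (Benjamini-Hochberg across tested aptamers) and Steiger columns
#' @export
mrAnalysis <- function(instrumentList) {
  rows <- lapply(names(instrumentList), function(a) {
    ins <- instrumentList[[a]]
    if (is.null(ins) || !nrow(ins)) return(NULL)
    est <- mrEstimate(ins)
    st <- steigerDirection(ins)
    cbind(data.frame(aptamer_id = a, stringsAsFactors = FALSE), est,
          steiger_direction = st$correct_direction, steiger_p = st$p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$q_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Fit PWAS weights in a signal window
#'
#' Residualizes the protein on covariates, then fits two candidate models on
#' the window's variants: "top1" (all weight on the most associated variant,
#' weight = its marginal OLS slope) and "lasso" (L1-penalized linear model
#' with the penalty chosen by inner cross-validation). The model with the
#' better out-of-fold R-squared wins; ties prefer top1. If neither model
#' predicts (cv R-squared <= 0), weights are still returned but flagged
#' non-predictive.
#'
#' @param dosages samples x variants dosage matrix for the window
#' @param proteinZ per-sample z-scored protein vector
#' @param covariates covariate data.frame
#' @param kFolds outer folds (default 5)
#' @param seed integer seed for fold assignment
#' @return list(weights = named vector over window variants, model, cv_r2,
#'   nonPredictive flag)
#' @export
pwasFitWeights <- function(dosages, proteinZ, covariates = NULL, kFolds = 5,
                           seed = 1) {
  use <- which(!is.na(proteinZ))
  y <- proteinZ[use]
  G <- dosages[use, , drop = FALSE]
  X <- buildDesign(if (is.null(covariates)) NULL else
    covariates[use, , drop = FALSE], length(use))
  y <- qr.resid(qr(X), y)
  n <- length(y)
  fitTop1 <- function(Gtr, ytr) {
    b <- crossprod(Gtr - rep(colMeans(Gtr), each = nrow(Gtr)), ytr - mean(ytr))
    v <- apply(Gtr, 2, stats::var) * (nrow(Gtr) - 1)
    slope <- drop(b) / pmax(v, 1e-12)
    tstat <- abs(slope) * sqrt(pmax(v, 1e-12))
    j <- which.max(tstat)
    w <- numeric(ncol(Gtr)); w[j] <- slope[j]
    w
  }
  fitLasso <- function(Gtr, ytr) {
    cvfit <- glmnet::cv.glmnet(Gtr, ytr, alpha = 1, nfolds = 5)
    as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1]
  }
  folds <- withSeed(seed, sample(rep_len(seq_len(kFolds), n)))
  sse <- c(top1 = 0, lasso = 0); sst <- 0
  withSeed(seed + 1L, {
    for (f in seq_len(kFolds)) {
      tr <- folds != f
      wT <- fitTop1(G[tr, , drop = FALSE], y[tr])
      wL <- fitLasso(G[tr, , drop = FALSE], y[tr])
      muT <- mean(y[tr] - G[tr, , drop = FALSE] %*% wT)
      muL <- mean(y[tr] - G[tr, , drop = FALSE] %*% wL)
      sse["top1"] <- sse["top1"] +
        sum((y[!tr] - G[!tr, , drop = FALSE] %*% wT - muT)^2)
      sse["lasso"] <- sse["lasso"] +
        sum((y[!tr] - G[!tr, , drop = FALSE] %*% wL - muL)^2)
      sst <- sst + sum((y[!tr] - mean(y[tr]))^2)
    }
  })
  cvR2 <- 1 - sse / sst
  model <- if (cvR2["top1"] >= cvR2["lasso"]) "top1" else "lasso"
  w <- withSeed(seed + 2L,
                if (model == "top1") fitTop1(G, y) else fitLasso(G, y))
  names(w) <- colnames(G)
  list(weights = w, model = model, cv_r2 = unname(max(cvR2)),
       nonPredictive = all(cvR2 <= 0))
}

#' Associate genetically predicted protein with disease from GWAS z-scores
#'
#' z_pwas = w'z / sqrt(w' (S + eps I) w), where S is the LD matrix of the
#' window variants from the dosage reference and eps a small ridge for
#' numerical stability.
#'
#' @param weights named weight vector over window variants
#' @param gwasZ named GWAS z-score vector over the same variants (alleles
#'   harmonized to the weights)
#' @param ldMat LD (correlation) matrix over the variants
#' @param ridge diagonal regularization (default 1e-3)
#' @return data.frame(z, p)
#' @export
pwasAssociate <- function(weights, gwasZ, ldMat, ridge = 1e-3) {
  v <- names(weights)
  z <- gwasZ[v]
  S <- ldMat[v, v, drop = FALSE] + diag(ridge, length(v))
  denom <- drop(t(weights) %*% S %*% weights)
  if (!is.finite(denom) || denom <= 0) {
    return(data.frame(z = NA_real_, p = NA_real_, undefined = TRUE))
  }
  zp <- drop(crossprod(weights, z)) / sqrt(denom)
  data.frame(z = zp, p = 2 * stats::pnorm(-abs(zp)), undefined = FALSE)
}
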