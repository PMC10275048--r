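# Direction-harmonized proteomic risk scores, the sparse-classifier
# refinement, the polygenic risk score comparator, and ROC comparison.

#' Harmonize aptamer directions to the disease-risk orientation
#'
#' Columns whose reported disease effect is negative are multiplied by -1 so
#' that a higher value always means higher risk. Aptamers without a sign are
#' excluded with a warning.
#'
#' @param zMat samples x aptamers z-score matrix (restricted to the
#'   disease-associated set)
#' @param signs named numeric or sign vector per aptamer (e.g. PWAS z)
#' @return flipped matrix restricted to aptamers with a sign
#' @export
harmonizeDirection <- function(zMat, signs) {
  s <- signs[colnames(zMat)]
  missing <- is.na(s)
  if (any(missing)) {
    warning("excluding ", sum(missing), " aptamer(s) without a direction sign")
  }
  out <- zMat[, !missing, drop = FALSE]
  flip <- sign(s[!missing]) < 0
  out[, flip] <- -out[, flip, drop = FALSE]
  out
}

#' Naive proteomic risk score
#'
#' Per-sample mean of the harmonized z-values over non-missing aptamers
#' (the sum divided by the number of non-missing levels). All-missing
#' samples get NA.
#'
#' @param flipped harmonized matrix from \code{\link{harmonizeDirection}}
#' @return named numeric per-sample score
#' @export
naiveProtRS <- function(flipped) {
  out <- rowMeans(flipped, na.rm = TRUE)
  out[rowSums(!is.na(flipped)) == 0] <- NA_real_
  out
}

#' Impute missing aptamer levels from within-group donors
#'
#' Each missing entry is replaced by a value drawn uniformly from the
#' observed values of the same aptamer among the other samples of the same
#' biomarker group. Empty donor pools fall back to the all-sample pool with
#' a warning. Observed entries are untouched; the completion is
#' seed-reproducible.
#'
#' @param mat samples x aptamers matrix
#' @param groups per-sample group labels (e.g. A+T+, A+T-, A-T-)
#' @param seed integer seed
#' @return complete matrix
#' @export
imputeWithinGroup <- function(mat, groups, seed = 1) {
  stopifnot(length(groups) == nrow(mat))
  out <- mat
  fellBack <- 0L
  withSeed(seed, {
    for (j in seq_len(ncol(mat))) {
      miss <- which(is.na(mat[, j]))
      if (!length(miss)) next
      for (i in miss) {
        pool <- mat[groups == groups[i], j]
        pool <- pool[!is.na(pool)]
        if (!length(pool)) {
          pool <- mat[!is.na(mat[, j]), j]
          fellBack <- fellBack + 1L
        }
        if (!length(pool)) stop("aptamer ", j, " has no observed values at all")
        out[i, j] <- pool[sample.int(length(pool), 1L)]
      }
    }
  })
  if (fellBack) warning(fellBack, " imputation(s) fell back to the all-sample pool")
  out
}

#' Fit the sparse proteomic classifier
#'
#' L1-penalized logistic regression on the complete harmonized matrix, with
#' the penalty chosen on the cross-validation path: "cv_1se" (default) keeps
#' the largest penalty within one standard error of the cross-validated
#' minimum -- the conventional parsimonious rule, which keeps false
#' selections low; "cv_min" keeps the deviance-minimizing penalty; and
#' "min_path" keeps the smallest penalty on the path (densest model). If no
#' feature survives, the model is flagged and downstream scoring falls back
#' to the naive score.
#'
#' @param train samples x aptamers complete matrix
#' @param labels binary outcome (0/1 or logical)
#' @param kFolds CV folds (default 10)
#' @param seed integer seed
#' @param lambdaRule "cv_1se", "cv_min" or "min_path"
#' @return RiskScoreModel list: kind, weights (nonzero features), intercept,
#'   features, lambda, fallback flag, trainSamples
#' @export
fitSparseClassifier <- function(train, labels, kFolds = 10, seed = 1,
                                lambdaRule = c("cv_1se", "cv_min", "min_path")) {
  lambdaRule <- match.arg(lambdaRule)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (anyNA(train)) stop("matrix must be complete; impute first")
  cvfit <- withSeed(seed,
    glmnet::cv.glmnet(train, y, family = "binomial", alpha = 1,
                      nfolds = kFolds))
  lam <- switch(lambdaRule, cv_1se = cvfit$lambda.1se,
                cv_min = cvfit$lambda.min, min_path = min(cvfit$lambda))
  cf <- as.numeric(stats::coef(cvfit, s = lam))
  w <- cf[-1]
  names(w) <- colnames(train)
  nz <- w[w != 0]
  fallback <- length(nz) == 0
  structure(list(kind = "sparse_protrs", weights = nz, intercept = cf[1],
                 features = colnames(train), lambda = lam,
                 fallback = fallback, trainSamples = rownames(train),
                 seed = seed),
            class = "RiskScoreModel")
}

#' Polygenic risk score by clumping and thresholding
#'
#' Variants are clumped on the GWAS p-values (all variants may seed, per the
#' clump-p = 1 convention); the retained variants with p below `pThresh`
#' contribute beta times effect-allele dosage to the score, which is then
#' standardized across samples. Variants inside `excludeRegion` are dropped
#' before clumping.
#'
#' @param dosages samples x variants dosage matrix (alt-allele coded)
#' @param gwas GWAS summary data.frame
#' @param variantMap variant map (alt = dosage-coded allele)
#' @param pThresh inclusion threshold (default 5e-8)
#' @param clump list(p = 1, r2 = 0.1, kb = 250)
#' @param excludeRegion optional list(chrom, start, end)
#' @return named per-sample standardized score with attributes `variants`
#'   (used variants) and `degenerate` (TRUE when nothing passed)
#' @export
prsScore <- function(dosages, gwas, variantMap, pThresh = 5e-8,
                     clump = list(p = 1, r2 = 0.1, kb = 250),
                     excludeRegion = NULL) {
  g <- gwas[!is.na(gwas$beta) & gwas$variant_id %in% colnames(dosages), , drop = FALSE]
  if (!is.null(excludeRegion)) {
    drop <- g$chrom == excludeRegion$chrom & g$pos >= excludeRegion$start &
      g$pos <= excludeRegion$end
    g <- g[!drop, , drop = FALSE]
  }
  kept <- clumpVariants(g, clump$p, clump$r2, clump$kb, dosages)
  g <- g[match(kept, g$variant_id), , drop = FALSE]
  g <- g[g$p < pThresh, , drop = FALSE]
  n <- nrow(dosages)
  if (!nrow(g)) {
    score <- stats::setNames(rep(0, n), rownames(dosages))
    attr(score, "variants") <- character(0)
    attr(score, "degenerate") <- TRUE
    warning("no variant passed the PRS threshold; degenerate score")
    return(score)
  }
  # align betas to the dosage-coded (alt) allele
  m <- match(g$variant_id, variantMap$variant_id)
  flip <- g$effect_allele == variantMap$ref[m] & g$other_allele == variantMap$alt[m]
  beta <- ifelse(flip, -g$beta, g$beta)
  raw <- drop(dosages[, g$variant_id, drop = FALSE] %*% beta)
  score <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else raw
  names(score) <- rownames(dosages)
  attr(score, "variants") <- g$variant_id
  attr(score, "degenerate") <- FALSE
  score
}

#' Score samples under a RiskScoreModel
#'
#' Zero-fills features missing from the supplied matrix (reporting the
#' fraction of absolute model weight retained) and returns the linear
#' predictor. Falls back to the naive mean score when the model carries no
#' nonzero weights.
#'
#' @param model a RiskScoreModel
#' @param zMat samples x aptamers harmonized matrix
#' @return named numeric scores with attribute `weightRetained`
#' @export
scoreModel <- function(model, zMat) {
  if (isTRUE(model$fallback)) {
    sc <- naiveProtRS(zMat)
    attr(sc, "weightRetained") <- NA_real_
    return(sc)
  }
  feats <- names(model$weights)
  have <- feats[feats %in% colnames(zMat)]
  M <- matrix(0, nrow(zMat), length(feats),
              dimnames = list(rownames(zMat), feats))
  M[, have] <- zMat[, have]
  M[is.na(M)] <- 0
  sc <- drop(M %*% model$weights) + model$intercept
  names(sc) <- rownames(zMat)
  attr(sc, "weightRetained") <- sum(abs(model$weights[have])) /
    sum(abs(model$weights))
  sc
}

#' Evaluate risk-score models by ROC on a held-out test set
#'
#' Computes per-model AUC with a 90% confidence interval (DeLong asymptotic;
#' bootstrap for fewer than 100 test samples) and paired two-sided DeLong
#' comparisons between all model pairs on the same samples. Refuses test
#' samples that overlap any model's training set.
#'
#' @param scores named list of per-sample score vectors (same sample order)
#' @param labels binary outcome for the test samples
#' @param trainSamples optional character vector (or list) of training
#'   sample ids to enforce train/test separation against `names(labels)`
#' @param ciLevel confidence level (default 0.90)
#' @param seed seed for the bootstrap interval at small n
#' @return list(summary = per-model data.frame(auc, ci_lo, ci_hi, n_cases,
#'   n_controls), comparisons = pairwise data.frame(model1, model2, p))
#' @export
evaluateModels <- function(scores, labels, trainSamples = NULL,
                           ciLevel = 0.90, seed = 1) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("test set must contain both classes")
  if (!is.null(trainSamples) && !is.null(names(labels))) {
    overlap <- intersect(unlist(trainSamples), names(labels))
    if (length(overlap)) {
      stop("train/test overlap for ", length(overlap), " sample(s)")
    }
  }
  method <- if (length(y) < 100) "bootstrap" else "delong"
  rocs <- lapply(scores, function(s) {
    pROC::roc(response = y, predictor = as.numeric(s), quiet = TRUE,
              direction = "<", levels = c(0, 1))
  })
  summary <- do.call(rbind, lapply(names(rocs), function(nm) {
    ci <- withSeed(seed, suppressWarnings(
      pROC::ci.auc(rocs[[nm]], conf.level = ciLevel, method = method,
                   boot.n = 500, progress = "none")))
    data.frame(model = nm, auc = as.numeric(pROC::auc(rocs[[nm]])),
               ci_lo = ci[1], ci_hi = ci[3],
               n_cases = sum(y == 1), n_controls = sum(y == 0),
               stringsAsFactors = FALSE)
  }))
  cmp <- NULL
  nms <- names(rocs)
  if (length(nms) > 1) {
    pairs <- utils::combn(nms, 2)
    cmp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      tt <- pROC::roc.test(rocs[[pairs[1, i]]], rocs[[pairs[2, i]]],
                           paired = TRUE, method = "delong")
      data.frame(model1 = pairs[1, i], model2 = pairs[2, i],
                 p = tt$p.value, stringsAsFactors = FALSE)
    }))
  }
  list(summary = summary, comparisons = cmp)
}
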