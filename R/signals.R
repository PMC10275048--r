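# LD computation, greedy index-signal detection, exact stepwise conditional
# analysis, and greedy LD clumping.

#' Pairwise LD as squared Pearson correlation of dosages
#'
#' @param dosages samples x variants dosage matrix
#' @param v1,v2 variant ids or column indices
#' @return r-squared in [0, 1]; NA (with a warning) when a variant is
#'   monomorphic among jointly observed samples
#' @export
ldR2 <- function(dosages, v1, v2) {
  x <- dosages[, v1]; y <- dosages[, v2]
  use <- !is.na(x) & !is.na(y)
  if (stats::var(x[use]) < .Machine$double.eps ||
      stats::var(y[use]) < .Machine$double.eps) {
    warning("monomorphic variant; LD undefined")
    return(NA_real_)
  }
  stats::cor(x[use], y[use])^2
}

# full r^2 matrix for a set of variants (complete-obs pairwise)
ldMatrix <- function(dosages, variants = colnames(dosages)) {
  stats::cor(dosages[, variants, drop = FALSE],
             use = "pairwise.complete.obs")^2
}

# deterministic record ordering: smaller p, then position, then variant_id
orderRecords <- function(records) {
  order(records$p, records$pos, records$variant_id)
}

#' Greedy index-signal detection for one aptamer
#'
#' Repeatedly takes the most significant remaining record that passes its
#' label's study-wide threshold, absorbs every significant record within
#' +/- `window` of it (inclusive) into that signal, removes them, and
#' continues until nothing significant remains. Ties on p are broken by
#' lower genomic position, then variant id. Ranks record discovery order.
#'
#' @param records AssociationRecords for one aptamer with columns variant_id,
#'   beta, se, p plus a `label` column ("cis"/"trans")
#' @param thresholds named vector c(cis = ..., trans = ...) of study-wide
#'   p-value thresholds per label
#' @param variantMap variant map for positions
#' @param window half-width of the absorption window in bp (default 1e6)
#' @return data.frame of IndexSignals (index_variant, chrom, pos,
#'   window_start, window_end, label, p, n_members, rank) with attribute
#'   `members`: list of absorbed variant ids per signal
#' @export
detectIndexSignals <- function(records, thresholds, variantMap, window = 1e6) {
  m <- match(records$variant_id, variantMap$variant_id)
  records$chrom <- variantMap$chrom[m]
  records$pos <- variantMap$pos[m]
  sig <- records[!is.na(records$label) &
                   records$p < unname(thresholds[records$label]), , drop = FALSE]
  out <- list(); members <- list(); rank <- 0L
  while (nrow(sig)) {
    sig <- sig[orderRecords(sig), , drop = FALSE]
    top <- sig[1L, ]
    rank <- rank + 1L
    inWin <- sig$chrom == top$chrom & abs(sig$pos - top$pos) <= window
    members[[rank]] <- sig$variant_id[inWin]
    out[[rank]] <- data.frame(
      index_variant = top$variant_id, chrom = top$chrom, pos = top$pos,
      window_start = max(1, top$pos - window), window_end = top$pos + window,
      label = top$label, p = top$p, beta = top$beta, se = top$se,
      n_members = sum(inWin), rank = rank, stringsAsFactors = FALSE)
    sig <- sig[!inWin, , drop = FALSE]
  }
  res <- do.call(rbind, out) %||%
    data.frame(index_variant = character(0), chrom = character(0),
               pos = integer(0), window_start = integer(0),
               window_end = integer(0), label = character(0), p = numeric(0),
               beta = numeric(0), se = numeric(0), n_members = integer(0),
               rank = integer(0))
  attr(res, "members") <- members
  res
}

#' Exact forward stepwise conditional analysis in a window
#'
#' With individual-level data, conditionally independent signals are found
#' by exact forward selection: at each step the remaining variant with the
#' smallest p-value conditional on the covariates and all previously
#' selected variants is added if it passes `threshold`; candidates in LD
#' (r-squared above `collinearityCap`) with any selected variant are
#' excluded. Ties break by position then variant id, so the selection is
#' stable under permutation of the input order.
#'
#' @param dosages samples x variants dosage matrix (the candidate window)
#' @param proteinZ numeric per-sample z-scored protein vector
#' @param covariates covariate data.frame
#' @param threshold conditional p-value threshold
#' @param collinearityCap r-squared cap for candidate exclusion (default 0.9)
#' @param variantMap variant map (positions for tie-breaks)
#' @param maxSignals safety cap on selected variants (default 20)
#' @return data.frame of selected variants with joint-model beta/se/p in
#'   selection order
#' @export
conditionalSignals <- function(dosages, proteinZ, covariates = NULL,
                               threshold = 5e-8, collinearityCap = 0.9,
                               variantMap = NULL, maxSignals = 20L) {
  use <- which(!is.na(proteinZ))
  y <- proteinZ[use]
  G <- dosages[use, , drop = FALSE]
  X <- buildDesign(if (is.null(covariates)) NULL else
    covariates[use, , drop = FALSE], length(use))
  pos <- if (!is.null(variantMap)) {
    variantMap$pos[match(colnames(G), variantMap$variant_id)]
  } else seq_len(ncol(G))
  selected <- character(0)
  repeat {
    cand <- setdiff(colnames(G), selected)
    if (length(selected)) {
      r2 <- ldMatrix(G)[cand, selected, drop = FALSE]
      cand <- cand[apply(r2, 1L, function(r) all(is.na(r) | r <= collinearityCap))]
    }
    if (!length(cand) || length(selected) >= maxSignals) break
    Xc <- cbind(X, G[, selected, drop = FALSE])
    qrX <- qr(Xc)
    if (qrX$rank < ncol(Xc)) {
      # rank-deficient joint design: drop the newest offender
      warning("rank-deficient conditional design; dropping last selected variant")
      selected <- selected[-length(selected)]
      next
    }
    yr <- qr.resid(qrX, y)
    Gr <- qr.resid(qrX, G[, cand, drop = FALSE])
    gss <- colSums(Gr^2)
    okv <- gss > 1e-10
    if (!any(okv)) break
    beta <- colSums(Gr * yr)[okv] / gss[okv]
    df <- length(y) - qrX$rank - 1L
    rss <- pmax(sum(yr^2) - beta^2 * gss[okv], 0)
    se <- sqrt(rss / df / gss[okv])
    p <- 2 * stats::pt(-abs(beta / se), df)
    candOk <- cand[okv]
    o <- order(p, pos[match(candOk, colnames(G))], candOk)
    if (p[o[1L]] >= threshold) break
    selected <- c(selected, candOk[o[1L]])
  }
  if (!length(selected)) {
    return(data.frame(variant_id = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), order = integer(0)))
  }
  # joint model statistics for the selected set
  Xj <- cbind(X, G[, selected, drop = FALSE])
  fit <- stats::lm.fit(Xj, y)
  df <- length(y) - fit$rank
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(Xj)))
  se <- sqrt(sigma2 * diag(XtXinv))
  idx <- ncol(X) + seq_along(selected)
  data.frame(variant_id = selected, beta = fit$coefficients[idx],
             se = se[idx],
             p = 2 * stats::pt(-abs(fit$coefficients[idx] / se[idx]), df),
             order = seq_along(selected), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Greedy LD clumping
#'
#' The best remaining record with p below `pThresh` seeds a clump; all
#' records within `kbWindow` kilobases and with r-squared at least
#' `r2Thresh` to the seed are absorbed. Returns the retained (seed) variants.
#'
#' @param records data.frame with variant_id, p, chrom, pos
#' @param pThresh only records with p < pThresh may seed (use 1 to clump all)
#' @param r2Thresh LD absorption threshold
#' @param kbWindow absorption window in kb
#' @param dosages dosage matrix for LD
#' @return character vector of retained variant ids
#' @export
clumpVariants <- function(records, pThresh, r2Thresh, kbWindow, dosages) {
  pool <- records[records$p < pThresh, , drop = FALSE]
  kept <- character(0)
  while (nrow(pool)) {
    pool <- pool[orderRecords(pool), , drop = FALSE]
    seed <- pool[1L, ]
    kept <- c(kept, seed$variant_id)
    near <- pool$chrom == seed$chrom &
      abs(pool$pos - seed$pos) <= kbWindow * 1000
    absorbed <- rep(FALSE, nrow(pool))
    if (any(near)) {
      r2 <- vapply(pool$variant_id[near], function(v) {
        if (v == seed$variant_id) return(1)
        suppressWarnings(ldR2(dosages, seed$variant_id, v))
      }, 0)
      absorbed[near] <- !is.na(r2) & r2 >= r2Thresh
    }
    absorbed[pool$variant_id == seed$variant_id] <- TRUE
    pool <- pool[!absorbed, , drop = FALSE]
  }
  kept
}
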