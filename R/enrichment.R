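# Annotation enrichment by permutation, LD-proxy most-severe consequence,
# cell-type specificity, and hypergeometric set enrichment.

#' Most severe consequence over a variant and its LD proxies
#'
#' Takes the minimum-rank category (most severe first in `order`) over the
#' variant plus all proxies; "unannotated" when no member has an annotation.
#'
#' @param variant variant id
#' @param proxies character vector of proxy variant ids (r-squared > 0.8
#'   companions; may be empty)
#' @param annotations data.frame(variant_id, category)
#' @param order severity-ordered category vector, most severe first
#' @return single category string
#' @export
mostSevereConsequence <- function(variant, proxies, annotations,
                                  order = defaultSeverityOrder()) {
  ids <- unique(c(variant, proxies))
  cats <- annotations$category[annotations$variant_id %in% ids]
  cats <- cats[cats %in% order]
  if (!length(cats)) return("unannotated")
  order[min(match(cats, order))]
}

# precompute the proxy set (r^2 > r2Thresh) for every variant in `universe`
proxySets <- function(dosages, universe, r2Thresh = 0.8) {
  r2 <- ldMatrix(dosages, universe)
  lapply(seq_along(universe), function(i) {
    universe[which(!is.na(r2[i, ]) & r2[i, ] > r2Thresh & seq_along(universe) != i)]
  })
}

#' Permutation enrichment of annotation categories
#'
#' Computes the most-severe-consequence category for every observed variant
#' (over its LD proxies), then compares per-category counts with those of
#' `nPerm` random draws of the same size from the universe, whose proxy sets
#' are computed under the same rule so the null is exchangeable. Empirical
#' p-values use the add-one convention: p = (1 + #{permutation count >=
#' observed}) / (1 + nPerm), so the attainable floor is 1 / (nPerm + 1).
#'
#' @param observed character vector of observed variant ids
#' @param universe character vector of all eligible variant ids (strictly
#'   larger than the observed set)
#' @param annotations data.frame(variant_id, category)
#' @param dosages dosage matrix for proxy computation (NULL = no proxies)
#' @param order severity order
#' @param r2Thresh proxy threshold (default 0.8)
#' @param nPerm permutations (default 1000; < 100 warns)
#' @param seed integer seed
#' @return data.frame(category, observed, perm_mean, fold_change, p)
#' @export
permutationEnrichment <- function(observed, universe, annotations,
                                  dosages = NULL,
                                  order = defaultSeverityOrder(),
                                  r2Thresh = 0.8, nPerm = 1000, seed = 1) {
  if (length(universe) <= length(observed)) {
    stop("universe must be strictly larger than the observed set")
  }
  if (nPerm < 100) warning("nPerm < 100 gives an unstable p-value floor")
  prox <- if (is.null(dosages)) {
    replicate(length(universe), character(0), simplify = FALSE)
  } else proxySets(dosages, universe, r2Thresh)
  severe <- vapply(seq_along(universe), function(i) {
    mostSevereConsequence(universe[i], prox[[i]], annotations, order)
  }, "")
  names(severe) <- universe
  lev <- c(order, "unannotated")
  countCats <- function(ids) {
    table(factor(severe[ids], levels = lev))
  }
  obsCount <- countCats(observed)
  k <- length(observed)
  permCounts <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      as.integer(countCats(sample(universe, k)))
    }, integer(length(lev)))
  })
  permMean <- rowMeans(permCounts)
  geq <- rowSums(permCounts >= as.integer(obsCount))
  data.frame(
    category = lev,
    observed = as.integer(obsCount),
    perm_mean = permMean,
    fold_change = ifelse(permMean > 0, as.integer(obsCount) / permMean, NA_real_),
    p = (1 + geq) / (1 + nPerm),
    stringsAsFactors = FALSE
  )
}

#' Cell-type specificity of a gene's expression profile
#'
#' Shares are each cell type's fraction of the row total; the gene is
#' labelled with the top cell type iff the top share is at least `ratio`
#' times the second share, else "non-specific". All-zero rows are
#' "unexpressed". The label is invariant to positive rescaling of the row.
#'
#' @param expr named non-negative vector over cell types, or a genes x cell
#'   types matrix
#' @param ratio dominance ratio (default 1.5)
#' @return label, or a vector of labels for a matrix input
#' @export
celltypeSpecificity <- function(expr, ratio = 1.5) {
  if (is.matrix(expr)) {
    return(vapply(seq_len(nrow(expr)), function(i) {
      celltypeSpecificity(expr[i, ], ratio)
    }, ""))
  }
  if (any(expr < 0)) stop("expression must be non-negative")
  if (sum(expr) == 0) return("unexpressed")
  share <- expr / sum(expr)
  o <- base::order(share, decreasing = TRUE)
  if (share[o[2]] == 0 || share[o[1]] / share[o[2]] >= ratio) {
    if (share[o[1]] == share[o[2]]) return("non-specific")
    names(expr)[o[1]]
  } else "non-specific"
}

#' Hypergeometric enrichment of cell-type-specific genes in a subset
#'
#' Upper-tail p-value P(X >= k) for X ~ Hypergeometric(N, K, m) and fold
#' change (k/m) / (K/N).
#'
#' @param k specific genes in the subset
#' @param m subset size (genes with expression data)
#' @param K specific genes in the universe
#' @param N universe size
#' @return list(p, fold_change)
#' @export
hypergeomEnrichment <- function(k, m, K, N) {
  if (k > min(m, K) || m > N || K > N || any(c(k, m, K, N) < 0)) {
    stop("impossible counts")
  }
  list(p = stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE),
       fold_change = (k / m) / (K / N))
}
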