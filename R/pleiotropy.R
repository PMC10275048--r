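# LD-based grouping of index variants into pleiotropic regions, per-region
# summaries, and the two-sample proportion test used for cross-dataset
# region comparisons.

#' Group index variants into pleiotropic regions by LD connectivity
#'
#' Per chromosome, index variants are nodes and pairs with r-squared at
#' least `r2Min` are edges; regions are the connected components (transitive
#' closure, not cliques -- a chain A-B, B-C is one region even if A and C are
#' unlinked). A region's span runs from the smallest to the largest member
#' position. Manual regions (e.g. an HLA-style locus) force-merge every
#' index variant inside the declared span, plus variants in LD at r2Min or
#' more with any in-span member, into a single region regardless of the
#' component structure.
#'
#' @param indexSignals data.frame with columns index_variant, chrom, pos,
#'   aptamer_id (one row per signal; a variant may index several aptamers)
#' @param dosages dosage matrix for LD (index variants absent from it become
#'   singleton regions with a warning)
#' @param r2Min LD threshold (default 0.1)
#' @param manualRegions optional data.frame(chrom, start, end, merge_ld)
#' @return data.frame(region_id, chrom, start, end, n_index_variants) with
#'   attribute `assignment`: data.frame(index_variant, region_id)
#' @export
groupRegions <- function(indexSignals, dosages, r2Min = 0.1,
                         manualRegions = NULL) {
  uv <- unique(indexSignals[, c("index_variant", "chrom", "pos")])
  missing <- !(uv$index_variant %in% colnames(dosages))
  if (any(missing)) {
    warning(sum(missing), " index variant(s) absent from dosages; made singletons")
  }
  comp <- integer(nrow(uv)); nextId <- 0L
  for (ch in unique(uv$chrom)) {
    idx <- which(uv$chrom == ch)
    have <- idx[!missing[idx]]
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (length(have) > 1) {
      r2 <- ldMatrix(dosages, uv$index_variant[have])
      pairs <- which(upper.tri(r2) & !is.na(r2) & r2 >= r2Min, arr.ind = TRUE)
      if (nrow(pairs)) {
        local <- match(have, idx)
        g <- igraph::add_edges(g, t(cbind(local[pairs[, 1]], local[pairs[, 2]])))
      }
    }
    comp[idx] <- nextId + igraph::components(g)$membership
    nextId <- max(comp[idx])
  }
  # manual force-merge
  if (!is.null(manualRegions) && nrow(manualRegions)) {
    for (i in seq_len(nrow(manualRegions))) {
      mr <- manualRegions[i, ]
      inSpan <- uv$chrom == mr$chrom & uv$pos >= mr$start & uv$pos <= mr$end
      member <- inSpan
      if (isTRUE(mr$merge_ld) && any(inSpan)) {
        outSpan <- which(uv$chrom == mr$chrom & !inSpan & !missing)
        boundary <- which(inSpan & !missing)
        if (length(outSpan) && length(boundary)) {
          r2 <- ldMatrix(dosages, uv$index_variant[c(boundary, outSpan)])
          sub <- r2[seq_along(boundary), length(boundary) + seq_along(outSpan),
                    drop = FALSE]
          hit <- apply(sub, 2L, function(r) any(!is.na(r) & r >= r2Min))
          member[outSpan[hit]] <- TRUE
        }
      }
      if (any(member)) {
        # merge every component touched by the manual region
        touched <- unique(comp[member])
        comp[comp %in% touched] <- touched[1]
      }
    }
  }
  ids <- match(comp, unique(comp))
  regions <- do.call(rbind, lapply(split(seq_len(nrow(uv)), ids), function(ix) {
    data.frame(chrom = uv$chrom[ix][1], start = min(uv$pos[ix]),
               end = max(uv$pos[ix]), n_index_variants = length(ix),
               stringsAsFactors = FALSE)
  }))
  regions$region_id <- sprintf("region%03d", seq_len(nrow(regions)))
  regions <- regions[, c("region_id", "chrom", "start", "end", "n_index_variants")]
  rownames(regions) <- NULL
  attr(regions, "assignment") <- data.frame(
    index_variant = uv$index_variant,
    region_id = regions$region_id[ids], stringsAsFactors = FALSE)
  regions
}

#' Summarize pleiotropic regions by aptamer and protein counts
#'
#' @param regions output of \code{\link{groupRegions}}
#' @param indexSignals data.frame(index_variant, aptamer_id)
#' @param aptamerGeneMap named character vector aptamer_id -> gene
#' @return regions with n_aptamers, n_proteins and hotspot tier flags
#'   (tier2 = at least 2 proteins, tier5, tier10, tier50plus = more than 50)
#' @export
regionSummary <- function(regions, indexSignals, aptamerGeneMap) {
  assign <- attr(regions, "assignment")
  reg <- assign$region_id[match(indexSignals$index_variant, assign$index_variant)]
  byRegion <- split(indexSignals$aptamer_id, reg)
  nApt <- vapply(byRegion, function(a) length(unique(a)), 0L)
  nProt <- vapply(byRegion, function(a) {
    length(unique(aptamerGeneMap[unique(a)]))
  }, 0L)
  i <- match(regions$region_id, names(byRegion))
  regions$n_aptamers <- ifelse(is.na(i), 0L, nApt[i])
  regions$n_proteins <- ifelse(is.na(i), 0L, nProt[i])
  regions$tier2 <- regions$n_proteins >= 2
  regions$tier5 <- regions$n_proteins >= 5
  regions$tier10 <- regions$n_proteins >= 10
  regions$tier50plus <- regions$n_proteins > 50
  regions
}

#' Two-sample z-test for proportions
#'
#' Pooled-variance z statistic with optional continuity correction and one-
#' or two-sided p-value.
#'
#' @param x1,n1 successes and trials in group 1
#' @param x2,n2 successes and trials in group 2
#' @param continuity apply the Yates-style continuity correction
#' @param sided 1 or 2
#' @return list(z, p, p1 = x1/n1, p2 = x2/n2)
#' @export
proportionTest <- function(x1, n1, x2, n2, continuity = FALSE, sided = 2) {
  if (n1 <= 0 || n2 <= 0) stop("n must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop("x must lie in [0, n]")
  p1 <- x1 / n1; p2 <- x2 / n2
  pPool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pPool * (1 - pPool) * (1 / n1 + 1 / n2))
  diff <- p1 - p2
  if (continuity) {
    cc <- 0.5 * (1 / n1 + 1 / n2)
    diff <- sign(diff) * max(0, abs(diff) - cc)
  }
  z <- if (se == 0) 0 else diff / se
  p <- if (sided == 2) 2 * stats::pnorm(-abs(z)) else stats::pnorm(-abs(z))
  list(z = z, p = min(1, p), p1 = p1, p2 = p2)
}
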