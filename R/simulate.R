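#' Build a variant map for simulation
#'
#' Lays variants on one or more chromosomes at fixed spacing with allele
#' frequencies drawn uniformly from a range. Ref/alt alleles are drawn from
#' non-strand-ambiguous pairs unless requested otherwise.
#'
#' @param nVariants total number of variants
#' @param nChrom number of chromosomes to spread them over
#' @param spacing base pairs between adjacent variants
#' @param mafRange range for the uniform minor-allele-frequency draw,
#'   within (0, 0.5]
#' @param allowAmbiguous also draw A/T and C/G pairs (default FALSE)
#' @param seed integer seed
#' @return data.frame with columns variant_id, chrom, pos, ref, alt, maf
#' @export
makeVariantMap <- function(nVariants, nChrom = 2, spacing = 50000L,
                           mafRange = c(0.05, 0.5), allowAmbiguous = FALSE,
                           seed = 1) {
  stopifnot(nVariants >= 1, nChrom >= 1)
  if (mafRange[1] <= 0 || mafRange[2] > 0.5) stop("mafRange must lie in (0, 0.5]")
  withSeed(seed, {
    chrom <- paste0("chr", rep(seq_len(nChrom), length.out = nVariants))
    chrom <- sort(chrom)
    pos <- unlist(lapply(split(seq_along(chrom), chrom),
                         function(i) seq_along(i) * spacing), use.names = FALSE)
    pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
    if (allowAmbiguous) pairs <- c(pairs, list(c("A", "T"), c("C", "G")))
    pick <- sample(length(pairs), nVariants, replace = TRUE)
    ref <- vapply(pairs[pick], `[`, "", 1L)
    alt <- vapply(pairs[pick], `[`, "", 2L)
    data.frame(
      variant_id = sprintf("%s_%d_%s_%s", chrom, pos, ref, alt),
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      maf = stats::runif(nVariants, mafRange[1], mafRange[2]),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate genotype dosages with block LD structure
#'
#' Each sample carries two haplotypes. For every haplotype, a latent Gaussian
#' vector with exchangeable within-block correlation rho is thresholded at the
#' allele-frequency quantile, so the empirical allele frequency matches the
#' variant map and within-block r-squared increases with rho. This is a
#' structural emulation of LD, not a population-genetic simulation.
#'
#' @param nSamples number of samples (> 0)
#' @param variantMap as from \code{\link{makeVariantMap}}
#' @param ldBlocks data.frame with columns chrom, start, end, rho describing
#'   non-overlapping spans of exchangeable correlation; variants outside any
#'   block are independent. NULL for full independence.
#' @param seed integer seed
#' @return samples x variants dosage matrix in [0, 2] with variant_id columns
#' @export
simulateGenotypes <- function(nSamples, variantMap, ldBlocks = NULL, seed = 1) {
  if (!is.numeric(nSamples) || nSamples < 1) stop("nSamples must be positive")
  if (any(variantMap$maf <= 0 | variantMap$maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  nV <- nrow(variantMap)
  block <- rep(0L, nV) # 0 = independent
  rhoOf <- numeric(0)
  if (!is.null(ldBlocks) && nrow(ldBlocks)) {
    if (any(ldBlocks$rho < 0 | ldBlocks$rho >= 1)) stop("block rho must be in [0, 1)")
    for (ch in unique(ldBlocks$chrom)) {
      b <- ldBlocks[ldBlocks$chrom == ch, , drop = FALSE]
      b <- b[order(b$start), , drop = FALSE]
      if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)])) {
        stop("overlapping LD blocks on ", ch)
      }
    }
    for (i in seq_len(nrow(ldBlocks))) {
      hit <- variantMap$chrom == ldBlocks$chrom[i] &
        variantMap$pos >= ldBlocks$start[i] & variantMap$pos <= ldBlocks$end[i]
      block[hit] <- i
    }
    rhoOf <- ldBlocks$rho
  }
  thr <- stats::qnorm(variantMap$maf)
  withSeed(seed, {
    dos <- matrix(0, nSamples, nV)
    for (hap in 1:2) {
      lat <- matrix(stats::rnorm(nSamples * nV), nSamples, nV)
      for (i in unique(block[block > 0L])) {
        idx <- which(block == i)
        rho <- rhoOf[i]
        if (rho > 0 && length(idx) > 1) {
          shared <- stats::rnorm(nSamples)
          lat[, idx] <- sqrt(rho) * shared + sqrt(1 - rho) * lat[, idx]
        }
      }
      dos <- dos + sweep(lat, 2L, thr, "<")
    }
    dimnames(dos) <- list(sprintf("S%04d", seq_len(nSamples)), variantMap$variant_id)
    dos
  })
}

#' Construct an empty truth table
#' @return list with empty effects/hotspots/diseaseAptamers components
#' @export
emptyTruth <- function() {
  list(
    effects = data.frame(variant_id = character(0), aptamer_id = character(0),
                         beta_true = numeric(0), stringsAsFactors = FALSE),
    hotspots = list(),
    diseaseAptamers = data.frame(aptamer_id = character(0),
                                 liability_effect = numeric(0),
                                 stringsAsFactors = FALSE)
  )
}

#' Simulate aptamer-level protein measurements
#'
#' Protein levels are generated on the log10 scale -- planted genetic effects
#' act on the z-scored log10 level through alt-allele dosage -- then
#' exponentiated to positive RFU-like values. Per-aptamer missingness is
#' missing-completely-at-random. Plate scale factors and cross-plate CVs are
#' attached so that the QC cascade has metrics to act on.
#'
#' @param genotypes samples x variants dosage matrix
#' @param aptamerIds character vector of aptamer identifiers
#' @param truth truth table (see \code{\link{emptyTruth}}); `effects` rows
#'   must reference existing variants and aptamers
#' @param covariateMatrix optional numeric samples x covariates matrix
#' @param covariateEffects optional numeric vector of per-covariate effects
#'   (recycled across aptamers)
#' @param residualSd residual standard deviation on the log10 scale (> 0)
#' @param missingRate scalar or per-aptamer missingness probability in [0, 1)
#' @param baselineLog10 mean log10 level
#' @param nPlates number of assay plates for the attached metrics
#' @param seed integer seed
#' @return list with elements `proteins` (samples x aptamers RFU matrix),
#'   `scaleFactors`, `cv` (aptamer x plate matrices), `plate` (per-sample)
#' @export
simulateProteome <- function(genotypes, aptamerIds, truth = emptyTruth(),
                             covariateMatrix = NULL, covariateEffects = NULL,
                             residualSd = 1, missingRate = 0,
                             baselineLog10 = 2.5, nPlates = 3, seed = 1) {
  if (residualSd <= 0) stop("residualSd must be > 0")
  if (any(missingRate < 0 | missingRate >= 1)) stop("missingRate must be in [0, 1)")
  eff <- truth$effects
  if (nrow(eff)) {
    if (!all(eff$aptamer_id %in% aptamerIds)) stop("truth references unknown aptamer")
    if (!all(eff$variant_id %in% colnames(genotypes))) {
      stop("truth references unknown variant")
    }
  }
  n <- nrow(genotypes)
  nA <- length(aptamerIds)
  withSeed(seed, {
    logy <- matrix(stats::rnorm(n * nA, 0, residualSd), n, nA,
                   dimnames = list(rownames(genotypes), aptamerIds))
    if (nrow(eff)) {
      for (i in seq_len(nrow(eff))) {
        j <- match(eff$aptamer_id[i], aptamerIds)
        logy[, j] <- logy[, j] + eff$beta_true[i] * genotypes[, eff$variant_id[i]]
      }
    }
    if (!is.null(covariateMatrix) && !is.null(covariateEffects)) {
      logy <- logy + drop(covariateMatrix %*% covariateEffects)
    }
    logy <- logy + baselineLog10
    prot <- 10^logy
    mr <- rep_len(missingRate, nA)
    if (any(mr > 0)) {
      mask <- matrix(stats::runif(n * nA), n, nA) < rep(mr, each = n)
      prot[mask] <- NA_real_
    }
    plate <- sample(paste0("P", seq_len(nPlates)), n, replace = TRUE)
    sf <- matrix(1 + stats::rnorm(nA * nPlates, 0, 0.02), nA, nPlates,
                 dimnames = list(aptamerIds, paste0("P", seq_len(nPlates))))
    cv <- matrix(stats::runif(nA * nPlates, 0.03, 0.10), nA, nPlates,
                 dimnames = dimnames(sf))
    list(proteins = prot, scaleFactors = sf, cv = cv, plate = plate)
  })
}

#' Simulate bimodal CSF biomarkers from a latent liability
#'
#' The amyloid-like analyte is lower and the tau-like analyte higher in
#' high-liability samples. Each analyte is a two-component Gaussian on the
#' log10 scale (component membership follows case status derived from
#' liability), exponentiated to a positive raw value.
#'
#' @param liability numeric per-sample latent disease liability
#' @param amyloid,tau lists with elements `means` (control, case), `sds`,
#'   `weight` (case fraction); component sds must be positive
#' @param baseLog10 named base level per analyte on log10 scale
#' @param scaleLog10 multiplier from mixture z-scale to log10 raw scale
#' @param liabilityNoise sd of noise added to liability before the case rank
#'   cut (decouples biomarker status from liability slightly)
#' @param seed integer seed
#' @return data.frame(sample_id, amyloid, tau) with attribute `case`
#'   (logical per-sample status used for component assignment)
#' @export
simulateBiomarkers <- function(liability,
                               amyloid = list(means = c(1, -1), sds = c(0.5, 0.5), weight = 0.5),
                               tau = list(means = c(-1, 1), sds = c(0.5, 0.5), weight = 0.5),
                               baseLog10 = c(amyloid = 2.8, tau = 1.7),
                               scaleLog10 = 0.15, liabilityNoise = 0.25,
                               seed = 1) {
  for (par in list(amyloid, tau)) {
    if (any(par$sds <= 0)) stop("component sds must be positive")
    if (par$weight <= 0 || par$weight >= 1) {
      warning("degenerate mixture weight; generating anyway")
    }
  }
  n <- length(liability)
  withSeed(seed, {
    u <- liability + stats::rnorm(n, 0, liabilityNoise)
    case <- rank(u, ties.method = "first") > n * (1 - amyloid$weight)
    drawZ <- function(par) {
      comp <- ifelse(case, 2L, 1L)
      stats::rnorm(n, par$means[comp], par$sds[comp])
    }
    out <- data.frame(
      sample_id = names(liability) %||% sprintf("S%04d", seq_len(n)),
      amyloid = 10^(baseLog10[["amyloid"]] + scaleLog10 * drawZ(amyloid)),
      tau = 10^(baseLog10[["tau"]] + scaleLog10 * drawZ(tau)),
      stringsAsFactors = FALSE
    )
    attr(out, "case") <- case
    out
  })
}

#' Simulate case-control GWAS summary statistics
#'
#' Draws a binary disease label from a logistic model on the supplied
#' liability, then fits a per-variant logistic regression of the label on
#' alt-allele dosage. Monomorphic variants are emitted with NA effect and a
#' flag rather than dropped.
#'
#' @param genotypes samples x variants dosage matrix
#' @param variantMap variant map matching genotype columns
#' @param liability per-sample latent liability (log-odds contributions)
#' @param prevalence target marginal case fraction
#' @param seed integer seed
#' @return data.frame(variant_id, chrom, pos, effect_allele, other_allele,
#'   beta, se, p, n, monomorphic) with attribute `case` (simulated labels)
#' @export
simulateGwasSummary <- function(genotypes, variantMap, liability,
                                prevalence = 0.5, seed = 1) {
  stopifnot(nrow(genotypes) == length(liability),
            ncol(genotypes) == nrow(variantMap))
  n <- nrow(genotypes)
  withSeed(seed, {
    alpha <- stats::qlogis(prevalence) - mean(liability)
    y <- stats::rbinom(n, 1L, stats::plogis(alpha + liability))
    # batched Newton-Raphson across variants (intercept + slope per variant)
    mono <- apply(genotypes, 2L, stats::var) < .Machine$double.eps
    a <- rep(stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6)), ncol(genotypes))
    b <- rep(0, ncol(genotypes))
    for (it in 1:25) {
      eta <- sweep(genotypes * rep(b, each = n), 2L, a, "+")
      mu <- stats::plogis(eta)
      w <- mu * (1 - mu)
      r <- y - mu
      g0 <- colSums(r); g1 <- colSums(r * genotypes)
      h00 <- colSums(w); h01 <- colSums(w * genotypes)
      h11 <- colSums(w * genotypes^2)
      det <- h00 * h11 - h01^2
      det[det < 1e-12] <- NA
      da <- (h11 * g0 - h01 * g1) / det
      db <- (h00 * g1 - h01 * g0) / det
      da[is.na(da)] <- 0; db[is.na(db)] <- 0
      # damped step for stability at near-separation
      step <- pmax(1, pmax(abs(da), abs(db)) / 5)
      a <- a + da / step; b <- b + db / step
      if (max(abs(db), abs(da)) < 1e-10) break
    }
    eta <- sweep(genotypes * rep(b, each = n), 2L, a, "+")
    w <- stats::plogis(eta) * (1 - stats::plogis(eta))
    h00 <- colSums(w); h01 <- colSums(w * genotypes)
    h11 <- colSums(w * genotypes^2)
    det <- h00 * h11 - h01^2
    se <- sqrt(h00 / pmax(det, 1e-300))
    res <- cbind(b, se, 2 * stats::pnorm(-abs(b / se)), as.numeric(mono))
    res[mono, 1:3] <- NA_real_
    out <- data.frame(
      variant_id = variantMap$variant_id,
      chrom = variantMap$chrom, pos = variantMap$pos,
      effect_allele = variantMap$alt, other_allele = variantMap$ref,
      beta = res[, 1L], se = res[, 2L], p = res[, 3L], n = n,
      monomorphic = res[, 4L] == 1,
      stringsAsFactors = FALSE
    )
    attr(out, "case") <- y
    out
  })
}

#' Default severity-ordered consequence vocabulary
#'
#' Most severe first, mirroring the conventional consequence ranking used by
#' variant-effect annotation tools. Fully overrideable wherever consumed.
#' @return character vector
#' @export
defaultSeverityOrder <- function() {
  c("stop_gained", "missense", "splice_region", "UTR", "intronic", "intergenic")
}

#' Simulate per-variant consequence annotations
#'
#' @param variantMap variant map
#' @param categoryProbs named probability vector over a severity-ordered
#'   vocabulary; must sum to 1
#' @param seed integer seed
#' @return data.frame(variant_id, category)
#' @export
simulateAnnotations <- function(variantMap,
                                categoryProbs = c(stop_gained = 0.01, missense = 0.06,
                                                  splice_region = 0.03, UTR = 0.1,
                                                  intronic = 0.5, intergenic = 0.3),
                                seed = 1) {
  if (!length(categoryProbs)) stop("empty annotation vocabulary")
  if (is.null(names(categoryProbs)) || any(!nzchar(names(categoryProbs)))) {
    stop("categoryProbs must be named")
  }
  if (abs(sum(categoryProbs) - 1) > 1e-8) stop("categoryProbs must sum to 1")
  withSeed(seed, {
    data.frame(
      variant_id = variantMap$variant_id,
      category = sample(names(categoryProbs), nrow(variantMap),
                        replace = TRUE, prob = categoryProbs),
      stringsAsFactors = FALSE
    )
  })
}

brainCellTypes <- function() {
  c("astrocyte", "neuron", "oligodendrocyte", "microglia", "endothelial")
}

#' Simulate a gene-by-cell-type mean expression table
#'
#' Five brain cell types. For genes in the specificity plan, the dominant
#' cell type's expression is set to `ratio` times the largest of the other
#' four, so the planted dominance ratio is exact by construction.
#'
#' @param genes character vector of gene symbols
#' @param specificityPlan optional data.frame(gene, cellType, ratio) with
#'   ratio >= 1
#' @param seed integer seed
#' @return genes x 5 non-negative matrix
#' @export
simulateCelltypeExpression <- function(genes, specificityPlan = NULL, seed = 1) {
  ct <- brainCellTypes()
  withSeed(seed, {
    expr <- matrix(stats::rgamma(length(genes) * 5L, shape = 2, scale = 10),
                   length(genes), 5L, dimnames = list(genes, ct))
    if (!is.null(specificityPlan) && nrow(specificityPlan)) {
      if (any(specificityPlan$ratio < 1)) stop("dominance ratio must be >= 1")
      for (i in seq_len(nrow(specificityPlan))) {
        g <- match(specificityPlan$gene[i], genes)
        j <- match(specificityPlan$cellType[i], ct)
        if (is.na(g) || is.na(j)) stop("specificityPlan references unknown gene or cell type")
        expr[g, j] <- specificityPlan$ratio[i] * max(expr[g, -j])
      }
    }
    expr
  })
}

#' Simulate a full proteogenomic cohort
#'
#' One call assembles everything the pipeline consumes: LD-structured
#' genotypes, a proteome with planted cis/trans effects and an optional
#' pleiotropic hotspot, covariates with a discovery/replication split,
#' bimodal biomarkers, a case-control GWAS whose liability can be mediated
#' through planted disease aptamers, consequence annotations and a cell-type
#' expression table. The truth slot records every planted parameter.
#'
#' @param nSamples,nVariants,nAptamers cohort dimensions
#' @param nChrom chromosomes in the variant map
#' @param blockSize,blockRho variants per LD block and within-block latent
#'   correlation (blockRho = 0 gives independent variants)
#' @param nCis number of aptamers given a planted cis effect
#' @param cisBeta planted cis effect per alt dose on the z-scored log10 level
#' @param nTrans number of planted trans effects (distant variant, random aptamer)
#' @param transBeta planted trans effect size
#' @param hotspot optional list(nAptamers, beta): one variant regulating many
#'   aptamers in trans
#' @param disease list(nAptamers, aptamerEffect, nVariants, variantLogOR,
#'   prevalence): liability built from planted causal aptamer levels
#'   (mediation) plus direct variant effects
#' @param missingRate per-entry protein missingness
#' @param residualSd protein residual sd on the log10 scale
#' @param mafRange variant MAF range
#' @param withGwas simulate the case-control GWAS (skip for cohorts whose
#'   analyses never touch disease summary statistics)
#' @param seed integer seed controlling every generator
#' @return a \code{\linkS4class{PQTLCohort}}
#' @export
simulateCohort <- function(nSamples = 1000, nVariants = 500, nAptamers = 100,
                           nChrom = 2, blockSize = 5, blockRho = 0.5,
                           nCis = 5, cisBeta = 0.5, nTrans = 0, transBeta = 0.4,
                           hotspot = NULL,
                           disease = list(nAptamers = 0, aptamerEffect = 0.5,
                                          nVariants = 0, variantLogOR = 0.3,
                                          prevalence = 0.5),
                           missingRate = 0, residualSd = 1,
                           mafRange = c(0.05, 0.5), withGwas = TRUE, seed = 1) {
  seed <- as.integer(seed)
  vm <- makeVariantMap(nVariants, nChrom = nChrom, mafRange = mafRange,
                       seed = seed)
  ldBlocks <- NULL
  if (blockRho > 0 && blockSize > 1) {
    ldBlocks <- do.call(rbind, lapply(split(vm, vm$chrom), function(v) {
      starts <- v$pos[seq(1, nrow(v), by = blockSize)]
      ends <- v$pos[pmin(seq(1, nrow(v), by = blockSize) + blockSize - 1L, nrow(v))]
      data.frame(chrom = v$chrom[1], start = starts, end = ends, rho = blockRho)
    }))
    rownames(ldBlocks) <- NULL
  }
  G <- simulateGenotypes(nSamples, vm, ldBlocks, seed = seed + 1L)
  aptIds <- sprintf("apt%04d", seq_len(nAptamers))
  genes <- sprintf("GENE%04d", seq_len(nAptamers))

  truth <- emptyTruth()
  withSeed(seed + 2L, {
    # aptamer TSS placed at random variant positions so cis windows are populated
    tssIdx <- sample(nVariants, nAptamers, replace = nAptamers > nVariants)
    aptInfo <- data.frame(aptamer_id = aptIds, gene = genes,
                          tss_chrom = vm$chrom[tssIdx], tss_pos = vm$pos[tssIdx],
                          stringsAsFactors = FALSE)
    if (nCis > 0) {
      cisApt <- sample(nAptamers, min(nCis, nAptamers))
      truth$effects <- rbind(truth$effects, data.frame(
        variant_id = vm$variant_id[tssIdx[cisApt]],
        aptamer_id = aptIds[cisApt], beta_true = cisBeta,
        stringsAsFactors = FALSE))
    }
    if (nTrans > 0) {
      for (k in seq_len(nTrans)) {
        a <- sample(nAptamers, 1L)
        far <- which(vm$chrom != aptInfo$tss_chrom[a] |
                       abs(vm$pos - aptInfo$tss_pos[a]) > 2e6)
        truth$effects <- rbind(truth$effects, data.frame(
          variant_id = vm$variant_id[sample(far, 1L)],
          aptamer_id = aptIds[a], beta_true = transBeta,
          stringsAsFactors = FALSE))
      }
    }
    if (!is.null(hotspot)) {
      hv <- sample(nVariants, 1L)
      hApt <- sample(setdiff(seq_len(nAptamers), match(truth$effects$aptamer_id, aptIds)),
                     hotspot$nAptamers)
      truth$effects <- rbind(truth$effects, data.frame(
        variant_id = vm$variant_id[hv], aptamer_id = aptIds[hApt],
        beta_true = hotspot$beta, stringsAsFactors = FALSE))
      truth$hotspots <- list(list(chrom = vm$chrom[hv],
                                  span = c(vm$pos[hv], vm$pos[hv]),
                                  variants = vm$variant_id[hv],
                                  aptamers = aptIds[hApt]))
    }
    invisible(NULL)
  })

  # covariates: age, sex, 2 genetic PCs, discovery/replication dummy
  cov <- withSeed(seed + 3L, data.frame(
    sample_id = rownames(G),
    age = round(stats::rnorm(nSamples, 70, 8)),
    sex = stats::rbinom(nSamples, 1L, 0.5),
    PC1 = stats::rnorm(nSamples), PC2 = stats::rnorm(nSamples),
    cohort = rep(c("discovery", "replication"), length.out = nSamples),
    stringsAsFactors = FALSE
  ))

  prot <- simulateProteome(G, aptIds, truth,
                           residualSd = residualSd, missingRate = missingRate,
                           seed = seed + 4L)

  # disease liability: planted causal aptamers (on their z-scored log10 level)
  # plus direct variant effects
  liability <- rep(0, nSamples)
  dz <- scale(log10(prot$proteins))
  if (disease$nAptamers > 0) {
    pool <- if (nrow(truth$effects)) unique(truth$effects$aptamer_id) else aptIds
    dApt <- withSeed(seed + 5L, sample(pool, min(disease$nAptamers, length(pool))))
    truth$diseaseAptamers <- data.frame(aptamer_id = dApt,
                                        liability_effect = disease$aptamerEffect,
                                        stringsAsFactors = FALSE)
    contrib <- dz[, dApt, drop = FALSE]
    contrib[is.na(contrib)] <- 0
    liability <- liability + disease$aptamerEffect * rowSums(contrib)
  }
  if (disease$nVariants > 0) {
    dVar <- withSeed(seed + 6L, sample(vm$variant_id, disease$nVariants))
    truth$diseaseVariants <- data.frame(variant_id = dVar,
                                        logOR = disease$variantLogOR,
                                        stringsAsFactors = FALSE)
    liability <- liability + disease$variantLogOR *
      rowSums(G[, dVar, drop = FALSE])
  }

  bio <- simulateBiomarkers(stats::setNames(liability, rownames(G)),
                            seed = seed + 7L)
  if (withGwas) {
    gwas <- simulateGwasSummary(G, vm, liability,
                                prevalence = disease$prevalence,
                                seed = seed + 8L)
    truth$caseStatus <- attr(gwas, "case")
  } else {
    gwas <- data.frame()
  }
  ann <- simulateAnnotations(vm, seed = seed + 9L)
  ctx <- simulateCelltypeExpression(genes, seed = seed + 10L)

  methods::new("PQTLCohort",
    genotypes = G, variantMap = vm,
    proteins = prot$proteins, aptamerInfo = aptInfo,
    covariates = cov, biomarkers = bio, gwas = gwas,
    annotations = ann, celltypeExpr = ctx, truth = truth,
    metadata = list(seed = seed, scaleFactors = prot$scaleFactors,
                    cv = prot$cv, plate = prot$plate)
  )
}
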