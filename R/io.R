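# Readers/writers for the on-disk formats, the pipeline configuration with
# its audited defaults, and stage orchestration.

#' Write a table as TSV with a header row
#' @param x data.frame
#' @param path output path
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV written by \code{\link{writeTsv}}
#' @param path input path
#' @return data.frame
#' @export
readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a dosage matrix plus variant map as TSV
#'
#' First five columns are the variant map (variant_id, chrom, pos, ref,
#' alt), then one column per sample. Coordinates are 1-based inclusive.
#'
#' @param dosages samples x variants matrix
#' @param variantMap matching variant map
#' @param path output path
#' @export
writeGenotypesTsv <- function(dosages, variantMap, path) {
  stopifnot(ncol(dosages) == nrow(variantMap))
  out <- cbind(variantMap[, c("variant_id", "chrom", "pos", "ref", "alt")],
               as.data.frame(t(dosages)))
  writeTsv(out, path)
}

#' Write a dosage matrix as a minimal VCF with a DS FORMAT field
#'
#' @param dosages samples x variants matrix
#' @param variantMap matching variant map
#' @param path output path (uncompressed .vcf)
#' @export
writeGenotypesVcf <- function(dosages, variantMap, path) {
  stopifnot(ncol(dosages) == nrow(variantMap))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dosages)), collapse = "\t")),
             con)
  body <- vapply(seq_len(nrow(variantMap)), function(i) {
    paste(c(variantMap$chrom[i],
            format(variantMap$pos[i], scientific = FALSE, trim = TRUE),
            variantMap$variant_id[i],
            variantMap$ref[i], variantMap$alt[i], ".", "PASS", ".", "DS",
            format(dosages[, i], scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, "")
  writeLines(body, con)
}

#' Read genotype dosages from VCF (DS field) or dosage TSV
#'
#' VCF input requires the DS FORMAT field; duplicate variant ids are an
#' error. TSV input follows the \code{\link{writeGenotypesTsv}} layout.
#' Positions stay 1-based; alleles are kept as written.
#'
#' @param path .vcf or .tsv file
#' @param keepSamples optional sample id keep-list
#' @return list(dosages = samples x variants matrix, variantMap)
#' @export
readGenotypes <- function(path, keepSamples = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    if (is.null(ds) || all(is.na(ds))) stop("DS field missing from VCF")
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(fix) # single-variant files
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    vm <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     maf = NA_real_, stringsAsFactors = FALSE)
    dosages <- t(ds)
    colnames(dosages) <- vm$variant_id
  } else {
    tab <- readTsv(path)
    vm <- tab[, c("variant_id", "chrom", "pos", "ref", "alt")]
    vm$maf <- NA_real_
    dosages <- t(as.matrix(tab[, -(1:5), drop = FALSE]))
    colnames(dosages) <- vm$variant_id
  }
  if (anyDuplicated(vm$variant_id)) {
    dup <- unique(vm$variant_id[duplicated(vm$variant_id)])
    stop("duplicate variant ids: ", paste(dup, collapse = ", "))
  }
  vm$maf <- pmin(colMeans(dosages, na.rm = TRUE) / 2,
                 1 - colMeans(dosages, na.rm = TRUE) / 2)
  if (!is.null(keepSamples)) {
    dosages <- dosages[rownames(dosages) %in% keepSamples, , drop = FALSE]
  }
  list(dosages = dosages, variantMap = vm)
}

#' Convert 1-based inclusive windows to BED (0-based half-open)
#'
#' @param chrom,start,end 1-based inclusive coordinates
#' @param name feature names
#' @return data.frame in BED column order
#' @export
toBed <- function(chrom, start, end, name) {
  data.frame(chrom = chrom, start = as.integer(start) - 1L,
             end = as.integer(end), name = name, stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' Every threshold the pipeline consumes, at its standard default: QC gates
#' (scale factor 0.5, median CV 0.15, call-rate cascade 65%/85%, MAF 0.01,
#' HWE 1e-6, genotype call rate 0.98, MAC 10), window half-width 1 Mb,
#' genome-wide 5e-8 with the PC-derived trans divisor, stage gates
#' 0.005/0.05, LD thresholds 0.1 (regions), 0.8 (proxies), 0.9
#' (collinearity), colocalization priors 1e-4/1e-4/1e-5 with the PP.H4 0.8
#' call rule, MR instrument threshold 5e-8 with the 500 kb anchor window and
#' the 5-aptamer region filter, PRS clumping (p 1, r2 0.1, 250 kb), and BH
#' FDR 0.05.
#'
#' @param seed integer pipeline seed
#' @return named list
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    qc = list(sfMax = 0.5, cvMax = 0.15,
              callRateSchedule = list(c("aptamer", 0.65), c("sample", 0.65),
                                      c("aptamer", 0.85), c("sample", 0.85)),
              mafMin = 0.01, hwePMin = 1e-6, callRateMin = 0.98, macMin = 10,
              dropAmbiguous = TRUE),
    assoc = list(cisP = 5e-8, discP = 0.005, repP = 0.05, window = 1e6,
                 varianceTarget = 0.95, minMac = 10),
    ld = list(regionR2 = 0.1, proxyR2 = 0.8, collinearityCap = 0.9),
    coloc = list(priors = c(1e-4, 1e-4, 1e-5), ppH4 = 0.8),
    mr = list(pThresh = 5e-8, anchorKb = 500, regionAptamerMax = 5),
    prs = list(clump = list(p = 1, r2 = 0.1, kb = 250), pThresh = 5e-8),
    enrich = list(nPerm = 1000, celltypeRatio = 1.5),
    fdr = 0.05,
    sim = list(nSamples = 500, nVariants = 300, nAptamers = 40,
               nCis = 6, cisBeta = 0.6,
               hotspot = list(nAptamers = 8, beta = 0.5),
               disease = list(nAptamers = 3, aptamerEffect = 0.8,
                              nVariants = 2, variantLogOR = 0.4,
                              prevalence = 0.5))
  )
}

#' Run the full pipeline on a cohort
#'
#' Executes the stages in dependency order -- QC, normalization, biomarker
#' dichotomization, discovery/replication scans, meta-analysis with genomic
#' control, the four-gate filter, index-signal detection, pleiotropic-region
#' grouping, annotation and cell-type enrichment, GWAS integration (coloc,
#' MR, PWAS), and risk scores -- writing each stage's table as TSV under
#' `outDir` together with the configuration and seed. Descriptive summaries
#' (correlation of |beta| with MAF and with TSS distance) are included in
#' the report.
#'
#' @param config list from \code{\link{defaultPipelineConfig}}
#' @param cohort a \code{PQTLCohort}; when NULL one is simulated from
#'   `config$sim` with `config$seed`
#' @param outDir output directory (created)
#' @param stages character vector of stage names to run (default all);
#'   "integration" and "riskscore" require the earlier stages
#' @return invisible list of in-memory stage results
#' @export
runPipeline <- function(config = defaultPipelineConfig(), cohort = NULL,
                        outDir = tempfile("pipeline"),
                        stages = c("qc", "biomarkers", "association",
                                   "signals", "pleiotropy", "enrichment",
                                   "integration", "riskscore")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) {
    cohort <- do.call(simulateCohort, c(config$sim, list(seed = config$seed)))
  }
  res <- list(config = config)
  writeLines(yaml::as.yaml(config), file.path(outDir, "config.yaml"))
  stageFail <- function(stage, msg) {
    stop(sprintf("[stage %s] %s", stage, msg), call. = FALSE)
  }

  # --- qc ---
  prot <- proteinLevels(cohort)
  if ("qc" %in% stages) {
    pm <- filterAptamersPlateMetrics(cohort@metadata$scaleFactors,
                                     cohort@metadata$cv,
                                     config$qc$sfMax, config$qc$cvMax)
    prot <- prot[, pm$kept, drop = FALSE]
    prot <- iqrMask(prot)
    cascade <- callRateCascade(prot, config$qc$callRateSchedule)
    prot <- cascade$matrix
    gf <- genotypeFilters(genotypes(cohort), variantMap(cohort),
                          config$qc$mafMin, config$qc$hwePMin,
                          config$qc$callRateMin, config$qc$macMin,
                          config$qc$dropAmbiguous)
    res$qc <- rbind(pm$report, cascade$report, gf$report)
    writeTsv(res$qc, file.path(outDir, "qc_report.tsv"))
    res$keptVariants <- gf$kept
  } else res$keptVariants <- variantMap(cohort)$variant_id

  G <- genotypes(cohort)[rownames(prot), res$keptVariants, drop = FALSE]
  vm <- variantMap(cohort)[match(res$keptVariants, variantMap(cohort)$variant_id), ]
  protZ <- normalizeLevels(prot)
  cov <- covariates(cohort)[match(rownames(prot), covariates(cohort)$sample_id), ]

  # --- biomarkers ---
  if ("biomarkers" %in% stages) {
    bio <- biomarkers(cohort)
    am <- dichotomize(bio$amyloid, "amyloid", seed = config$seed)
    ta <- dichotomize(bio$tau, "tau", seed = config$seed)
    res$atStatus <- atClassify(am$labels, ta$labels, bio$sample_id)
    res$cuts <- rbind(am$cut, ta$cut)
    writeTsv(res$atStatus, file.path(outDir, "at_status.tsv"))
    writeTsv(res$cuts, file.path(outDir, "biomarker_cutoffs.tsv"))
  }

  # --- association ---
  if ("association" %in% stages) {
    disc <- cov$cohort == "discovery"
    covCols <- setdiff(names(cov), c("sample_id", "cohort"))
    scanD <- pqtlScan(G[disc, , drop = FALSE], protZ[disc, , drop = FALSE],
                      cov[disc, c("sample_id", covCols)], vm,
                      config$assoc$minMac, stage = "discovery")
    scanR <- pqtlScan(G[!disc, , drop = FALSE], protZ[!disc, , drop = FALSE],
                      cov[!disc, c("sample_id", covCols)], vm,
                      config$assoc$minMac, stage = "replication")
    thr <- transThreshold(protZ, config$assoc$varianceTarget,
                          config$assoc$cisP, config$assoc$discP,
                          config$assoc$repP)
    meta <- metaFixedIVW(scanD$records, scanR$records, gc = TRUE)
    labels <- classifyCisTrans(meta$meta$variant_id, meta$meta$aptamer_id,
                               vm, aptamerInfo(cohort), config$assoc$window)
    sig <- significanceFilter(meta$meta, scanD$records, scanR$records,
                              thr, labels)
    res$scanDisc <- scanD$records; res$scanRep <- scanR$records
    res$meta <- meta$meta; res$gc <- meta$gc; res$thresholds <- thr
    res$significant <- sig$significant; res$rejections <- sig$rejections
    writeTsv(res$significant, file.path(outDir, "significant_pairs.tsv"))
    writeTsv(res$gc, file.path(outDir, "genomic_control.tsv"))
    # descriptive summaries: |beta| vs MAF and vs TSS distance
    if (nrow(res$significant)) {
      s <- res$significant
      mafs <- vm$maf[match(s$variant_id, vm$variant_id)]
      tss <- aptamerInfo(cohort)
      ai <- match(s$aptamer_id, tss$aptamer_id)
      dist <- ifelse(vm$chrom[match(s$variant_id, vm$variant_id)] ==
                       tss$tss_chrom[ai],
                     abs(vm$pos[match(s$variant_id, vm$variant_id)] -
                           tss$tss_pos[ai]), NA)
      res$descriptives <- data.frame(
        cor_absbeta_maf = if (nrow(s) > 2) stats::cor(abs(s$beta), mafs) else NA,
        cor_absbeta_tssdist = if (sum(!is.na(dist)) > 2) {
          stats::cor(abs(s$beta)[!is.na(dist)], dist[!is.na(dist)])
        } else NA)
      writeTsv(res$descriptives, file.path(outDir, "descriptives.tsv"))
    }
  }

  # --- signals ---
  if ("signals" %in% stages) {
    if (is.null(res$significant)) stageFail("signals", "association stage required")
    thrVec <- c(cis = res$thresholds$cis_p, trans = res$thresholds$trans_p)
    sigByApt <- split(seq_len(nrow(res$significant)), res$significant$aptamer_id)
    idx <- lapply(names(sigByApt), function(a) {
      recs <- res$significant[sigByApt[[a]], , drop = FALSE]
      s <- detectIndexSignals(recs, thrVec, vm, config$assoc$window)
      if (nrow(s)) cbind(aptamer_id = a, s, stringsAsFactors = FALSE) else NULL
    })
    res$indexSignals <- do.call(rbind, idx) %||% data.frame()
    writeTsv(res$indexSignals, file.path(outDir, "index_signals.tsv"))
  }

  # --- pleiotropy ---
  if ("pleiotropy" %in% stages && nrow(res$indexSignals %||% data.frame())) {
    regs <- groupRegions(res$indexSignals, G, config$ld$regionR2,
                         config$manualRegions)
    gmap <- stats::setNames(aptamerInfo(cohort)$gene,
                            aptamerInfo(cohort)$aptamer_id)
    res$regions <- regionSummary(regs, res$indexSignals, gmap)
    writeTsv(res$regions, file.path(outDir, "pleiotropic_regions.tsv"))
  }

  # --- enrichment ---
  if ("enrichment" %in% stages && nrow(res$indexSignals %||% data.frame())) {
    obs <- unique(res$indexSignals$index_variant)
    if (length(obs) && length(obs) < nrow(vm)) {
      res$enrichment <- permutationEnrichment(
        obs, vm$variant_id, variantAnnotations(cohort), G,
        nPerm = config$enrich$nPerm, seed = config$seed)
      writeTsv(res$enrichment, file.path(outDir, "annotation_enrichment.tsv"))
    }
    ctx <- celltypeExpression(cohort)
    res$celltype <- data.frame(gene = rownames(ctx),
                               label = celltypeSpecificity(ctx,
                                 config$enrich$celltypeRatio),
                               stringsAsFactors = FALSE)
    writeTsv(res$celltype, file.path(outDir, "celltype_specificity.tsv"))
  }

  # --- integration ---
  if ("integration" %in% stages) {
    if (is.null(res$indexSignals) || !nrow(res$indexSignals)) {
      stageFail("integration", "no index signals; run association+signals first")
    }
    gwas <- gwasSummary(cohort)
    regionApt <- NULL
    if (!is.null(res$regions)) {
      assign <- attr(res$regions, "assignment")
      if (!is.null(assign)) {
        nA <- res$regions$n_aptamers[match(assign$region_id, res$regions$region_id)]
        regionApt <- stats::setNames(nA, assign$index_variant)
      }
    }
    ints <- list()
    for (i in seq_len(nrow(res$indexSignals))) {
      sig <- res$indexSignals[i, ]
      win <- vm$variant_id[vm$chrom == sig$chrom &
                             abs(vm$pos - sig$pos) <= config$assoc$window]
      aptRecs <- res$meta[res$meta$aptamer_id == sig$aptamer_id &
                            res$meta$variant_id %in% win, , drop = FALSE]
      gw <- gwas[gwas$variant_id %in% win & !is.na(gwas$beta), , drop = FALSE]
      if (nrow(aptRecs) < 2 || nrow(gw) < 2) next
      cl <- colocAbf(aptRecs, gw, config$coloc$priors)
      pw <- pwasFitWeights(G[, win[win %in% colnames(G)], drop = FALSE],
                           protZ[, sig$aptamer_id],
                           cov[, setdiff(names(cov), "cohort")],
                           seed = config$seed)
      zv <- stats::setNames(gw$beta / gw$se, gw$variant_id)
      common <- intersect(names(pw$weights), names(zv))
      pa <- if (length(common)) {
        S <- stats::cor(G[, common, drop = FALSE],
                        use = "pairwise.complete.obs")
        pwasAssociate(pw$weights[common], zv, S)
      } else data.frame(z = NA, p = NA, undefined = TRUE)
      ints[[length(ints) + 1L]] <- data.frame(
        aptamer_id = sig$aptamer_id, index_variant = sig$index_variant,
        pp_h4 = cl$pp[["PP.H4"]], pp_h3 = cl$pp[["PP.H3"]],
        coloc_n = cl$n_variants, pwas_model = pw$model,
        pwas_cv_r2 = pw$cv_r2, pwas_z = pa$z, pwas_p = pa$p,
        stringsAsFactors = FALSE)
    }
    res$integration <- do.call(rbind, ints) %||% data.frame()
    if (nrow(res$integration)) {
      res$integration$pwas_q <- stats::p.adjust(res$integration$pwas_p, "BH")
    }
    # MR per aptamer
    labelsAll <- classifyCisTrans(res$significant$variant_id,
                                  res$significant$aptamer_id, vm,
                                  aptamerInfo(cohort), config$assoc$window)
    sigLab <- res$significant; sigLab$label <- labelsAll
    insts <- lapply(split(sigLab, sigLab$aptamer_id), function(recs) {
      selectInstruments(recs, gwas, G, vm, regionApt,
                        pThresh = config$mr$pThresh,
                        regionAptamerMax = config$mr$regionAptamerMax,
                        anchorKb = config$mr$anchorKb)
    })
    res$mr <- mrAnalysis(insts)
    writeTsv(res$integration, file.path(outDir, "integration.tsv"))
    if (nrow(res$mr %||% data.frame())) writeTsv(res$mr, file.path(outDir, "mr.tsv"))
  }

  # --- riskscore ---
  if ("riskscore" %in% stages) {
    if (is.null(res$integration) || !nrow(res$integration)) {
      stageFail("riskscore",
                "integration results required (PWAS signs); run integration or supply cached signs")
    }
    at <- res$atStatus
    keep <- !is.na(at$group) & at$group %in% c("A+T+", "A-T-")
    signs <- stats::setNames(res$integration$pwas_z, res$integration$aptamer_id)
    signs <- signs[!is.na(signs)]
    feats <- intersect(names(signs), colnames(protZ))
    if (length(feats) < 1 || sum(keep) < 20) {
      stageFail("riskscore", "insufficient PWAS-signed aptamers or labelled samples")
    }
    Z <- harmonizeDirection(protZ[keep, feats, drop = FALSE], signs[feats])
    y <- as.integer(at$group[keep] == "A+T+")
    names(y) <- at$sample_id[keep]
    res$naiveScore <- naiveProtRS(Z)
    isTrain <- cov$cohort[match(names(y), cov$sample_id)] == "discovery"
    if (length(unique(y[isTrain])) == 2 && length(unique(y[!isTrain])) == 2) {
      Zc <- imputeWithinGroup(Z, at$group[keep], seed = config$seed)
      model <- fitSparseClassifier(Zc[isTrain, , drop = FALSE], y[isTrain],
                                   seed = config$seed)
      prs <- prsScore(G[names(y), , drop = FALSE], gwasSummary(cohort), vm,
                      pThresh = config$prs$pThresh, clump = config$prs$clump)
      testIdx <- which(!isTrain)
      sc <- list(sparse_protrs = scoreModel(model, Zc[testIdx, , drop = FALSE]),
                 naive_protrs = res$naiveScore[testIdx],
                 prs = prs[names(y)[testIdx]])
      res$roc <- evaluateModels(sc, y[testIdx],
                                trainSamples = names(y)[isTrain])
      writeTsv(res$roc$summary, file.path(outDir, "roc_summary.tsv"))
      res$riskModel <- model
    }
  }
  invisible(res)
}
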