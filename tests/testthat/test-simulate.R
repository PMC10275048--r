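test_that("generators are bitwise-deterministic under a fixed seed", {
  vm <- makeVariantMap(40, seed = 3)
  expect_identical(simulateGenotypes(50, vm, seed = 9),
                   simulateGenotypes(50, vm, seed = 9))
  G <- simulateGenotypes(50, vm, seed = 9)
  p1 <- simulateProteome(G, paste0("a", 1:5), seed = 4)
  p2 <- simulateProteome(G, paste0("a", 1:5), seed = 4)
  expect_identical(p1, p2)
  li <- rnorm(50)
  expect_identical(simulateBiomarkers(li, seed = 2),
                   simulateBiomarkers(li, seed = 2))
  expect_identical(simulateGwasSummary(G, vm, li, seed = 2),
                   simulateGwasSummary(G, vm, li, seed = 2))
  expect_identical(simulateAnnotations(vm, seed = 2),
                   simulateAnnotations(vm, seed = 2))
  expect_identical(simulateCelltypeExpression(paste0("g", 1:8), seed = 2),
                   simulateCelltypeExpression(paste0("g", 1:8), seed = 2))
  expect_identical(simulateCohort(nSamples = 40, nVariants = 30,
                                  nAptamers = 5, seed = 6),
                   simulateCohort(nSamples = 40, nVariants = 30,
                                  nAptamers = 5, seed = 6))
})

test_that("genotypes match the requested allele frequencies and independence", {
  vm <- makeVariantMap(20, mafRange = c(0.3, 0.3), seed = 1)
  G <- simulateGenotypes(10000, vm, seed = 7)
  fhat <- colMeans(G) / 2
  bound <- 3 * sqrt(0.3 * 0.7 / (2 * 10000))
  expect_true(all(abs(fhat - 0.3) <= bound))
  # rho = 0: mean pairwise r^2 essentially zero
  r2 <- cor(G)^2
  expect_lte(mean(r2[upper.tri(r2)]), 0.01)
  # dosages live in [0, 2]
  expect_true(all(G %in% c(0, 1, 2)))
})

test_that("within-block LD matches a large-sample Monte-Carlo oracle", {
  # oracle: the same latent-threshold scheme evaluated at n = 1e6,
  # written out independently of the generator
  rho <- 0.95; maf <- 0.3
  thr <- qnorm(maf)
  withr::with_seed(42, {
    hap <- function() {
      shared <- rnorm(1e6)
      l1 <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(1e6)
      l2 <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(1e6)
      cbind(l1 < thr, l2 < thr)
    }
    d <- hap() + hap()
    oracleR2 <- cor(d[, 1], d[, 2])^2
  })
  vm <- makeVariantMap(2, nChrom = 1, mafRange = c(maf, maf), seed = 1)
  blocks <- data.frame(chrom = "chr1", start = 1, end = 2e6, rho = rho)
  G <- simulateGenotypes(50000, vm, blocks, seed = 8)
  expect_lt(abs(cor(G[, 1], G[, 2])^2 - oracleR2), 0.05)
})

test_that("LD block validation rejects bad input", {
  vm <- makeVariantMap(10, nChrom = 1, seed = 1)
  bad <- data.frame(chrom = "chr1", start = c(1, 100000), end = c(200000, 300000),
                    rho = 0.5)
  expect_error(simulateGenotypes(10, vm, bad), "overlap")
  expect_error(simulateGenotypes(0, vm), "positive")
  expect_error(simulateGenotypes(10, transform(vm, maf = 0.6)), "maf")
})

test_that("proteome nulls are null and planted effects are recoverable", {
  vm <- makeVariantMap(20, seed = 2)
  G <- simulateGenotypes(2000, vm, seed = 3)
  # no planted effects: dosage regressions non-significant at ~ nominal rate
  pr <- simulateProteome(G, paste0("a", 1:10), seed = 5)
  lp <- log10(pr$proteins)
  ps <- sapply(1:10, function(j) {
    summary(lm(lp[, j] ~ G[, j]))$coefficients[2, 4]
  })
  expect_gte(mean(ps > 0.05), 0.8)
  # one planted beta 0.5 at maf 0.3: OLS recovery within +/- 0.1
  vm2 <- makeVariantMap(5, mafRange = c(0.3, 0.3), seed = 2)
  G2 <- simulateGenotypes(1500, vm2, seed = 4)
  truth <- emptyTruth()
  truth$effects <- data.frame(variant_id = vm2$variant_id[1],
                              aptamer_id = "a1", beta_true = 0.5)
  pr2 <- simulateProteome(G2, paste0("a", 1:3), truth, seed = 6)
  fit <- lm(log10(pr2$proteins[, "a1"]) ~ G2[, 1])
  expect_lt(abs(coef(fit)[2] - 0.5), 0.1)
})

test_that("proteome missingness hits the requested call rate", {
  vm <- makeVariantMap(5, seed = 1)
  G <- simulateGenotypes(1000, vm, seed = 1)
  pr <- simulateProteome(G, paste0("a", 1:4), missingRate = c(0.4, 0, 0, 0),
                         seed = 2)
  cr <- colMeans(!is.na(pr$proteins))
  expect_lt(abs(cr[1] - 0.6), 0.06)
  expect_equal(unname(cr[2:4]), rep(1, 3))
  expect_error(
    simulateProteome(G, "a1",
                     truth = list(effects = data.frame(variant_id = vm$variant_id[1],
                                                       aptamer_id = "zzz",
                                                       beta_true = 1),
                                  hotspots = list(),
                                  diseaseAptamers = data.frame())),
    "unknown aptamer")
})

test_that("biomarkers separate by liability and recover the case fraction", {
  li <- setNames(rnorm(2000), sprintf("S%04d", 1:2000))
  bio <- simulateBiomarkers(li, amyloid = list(means = c(2, -2), sds = c(0.5, 0.5),
                                               weight = 0.45),
                            tau = list(means = c(-2, 2), sds = c(0.5, 0.5),
                                       weight = 0.45), seed = 3)
  case <- attr(bio, "case")
  expect_equal(mean(case), 0.45, tolerance = 0.001)
  # amyloid lower in cases, tau higher
  expect_lt(mean(bio$amyloid[case]), mean(bio$amyloid[!case]))
  expect_gt(mean(bio$tau[case]), mean(bio$tau[!case]))
  # planted case fraction recovered by the downstream mixture fit
  fit <- dichotomize(bio$amyloid, "amyloid", seed = 1)
  expect_true(fit$cut$separable)
  expect_lt(abs(fit$cut$weight_low - 0.45), 0.05) # low log-level = case side
})

test_that("gwas summaries are calibrated under the null and recover planted odds", {
  vm <- makeVariantMap(5000, nChrom = 4, seed = 5)
  G <- simulateGenotypes(1500, vm, seed = 6)
  gw <- simulateGwasSummary(G, vm, liability = rep(0, 1500), seed = 7)
  expect_gte(genomicControlLambda(gw$p), 0.95)
  expect_lte(genomicControlLambda(gw$p), 1.05)
  # strong planted effect attains the minimum p
  vm2 <- makeVariantMap(50, mafRange = c(0.3, 0.3), seed = 2)
  G2 <- simulateGenotypes(4000, vm2, seed = 3)
  gw2 <- simulateGwasSummary(G2, vm2, liability = 1.0 * G2[, 25], seed = 4)
  expect_equal(which.min(gw2$p), 25L)
  # planted log-OR 0.3 covered by +/- 2 SE in most replicates
  hit <- vapply(1:60, function(s) {
    Gs <- simulateGenotypes(4000, vm2[1:2, ], seed = 100 + s)
    gws <- simulateGwasSummary(Gs, vm2[1:2, ], liability = 0.3 * Gs[, 1],
                               seed = 200 + s)
    abs(gws$beta[1] - 0.3) <= 2 * gws$se[1]
  }, TRUE)
  expect_gte(mean(hit), 0.9)
})

test_that("monomorphic variants are flagged, not dropped", {
  vm <- toyVariantMap(3)
  G <- toyDosages(100, vm, seed = 1)
  G[, 2] <- 0
  gw <- simulateGwasSummary(G, vm, rep(0, 100), seed = 1)
  expect_equal(nrow(gw), 3L)
  expect_true(gw$monomorphic[2])
  expect_true(is.na(gw$beta[2]))
})

test_that("annotation draws respect the category distribution", {
  vm <- makeVariantMap(6000, nChrom = 6, seed = 1)
  expect_error(simulateAnnotations(vm, categoryProbs = numeric(0)), "empty")
  probs <- setNames(rep(1 / 6, 6), defaultSeverityOrder())
  ann <- simulateAnnotations(vm, probs, seed = 2)
  counts <- table(ann$category)
  sdMult <- sqrt(6000 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - 1000) <= 3 * sdMult))
  allIntronic <- simulateAnnotations(vm, c(intronic = 1), seed = 1)
  expect_true(all(allIntronic$category == "intronic"))
})

test_that("cell-type plans plant recoverable specificity", {
  plan <- data.frame(gene = paste0("g", 1:20), cellType = "neuron", ratio = 3)
  expr <- simulateCelltypeExpression(paste0("g", 1:100), plan, seed = 9)
  labels <- celltypeSpecificity(expr)
  expect_gte(sum(labels[1:20] == "neuron"), 19)
  # ratio 1 plants a tie, classified non-specific
  plan1 <- data.frame(gene = "g1", cellType = "astrocyte", ratio = 1)
  e1 <- simulateCelltypeExpression("g1", plan1, seed = 2)
  expect_equal(celltypeSpecificity(e1[1, ]), "non-specific")
  expect_error(simulateCelltypeExpression("g1",
    data.frame(gene = "g1", cellType = "astrocyte", ratio = 0.5)), "ratio")
})
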