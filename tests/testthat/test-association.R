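test_that("the scan recovers planted effects with calibrated significance", {
  vm <- makeVariantMap(30, mafRange = c(0.3, 0.3), seed = 1)
  hits <- vapply(1:30, function(s) {
    G <- simulateGenotypes(1500, vm, seed = s)
    truth <- emptyTruth()
    truth$effects <- data.frame(variant_id = vm$variant_id[7],
                                aptamer_id = "a1", beta_true = 0.5)
    pr <- simulateProteome(G, c("a1", "a2"), truth, seed = s + 500)
    z <- normalizeLevels(pr$proteins)
    sc <- pqtlScan(G, z, toyCovariates(1500, seed = s), vm)
    r <- sc$records[sc$records$variant_id == vm$variant_id[7] &
                      sc$records$aptamer_id == "a1", ]
    c(abs(r$beta - 0.5) <= 0.1, r$p < 5e-8)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
})

test_that("scan p-values are uniform under permuted proteins", {
  vm <- makeVariantMap(2000, nChrom = 2, seed = 3)
  G <- simulateGenotypes(400, vm, seed = 4)
  z <- withr::with_seed(5, matrix(rnorm(400), 400, 1,
                                  dimnames = list(rownames(G), "a1")))
  sc <- pqtlScan(G, z, NULL, vm)
  expect_gt(ks.test(sc$records$p, "punif")$p.value, 0.01)
})

test_that("monomorphic and low-MAC variants are skipped with reasons", {
  vm <- toyVariantMap(3)
  G <- toyDosages(300, vm, seed = 6)
  G[, 2] <- 1 # constant dosage
  z <- matrix(rnorm(300), ncol = 1, dimnames = list(rownames(G), "a1"))
  sc <- pqtlScan(G, z, NULL, vm)
  expect_true("v02" %in% sc$skipped$variant_id)
  expect_false("v02" %in% sc$records$variant_id)
  expect_true(all(sc$skipped$reason %in% c("monomorphic", "low_mac")))
})

test_that("allele recoding flips beta and leaves |beta|, se, p unchanged", {
  vm <- toyVariantMap(4)
  G <- toyDosages(500, vm, seed = 7)
  z <- withr::with_seed(8, matrix(0.3 * G[, 1] + rnorm(500), ncol = 1,
                                  dimnames = list(rownames(G), "a1")))
  sc1 <- pqtlScan(G, z, NULL, vm)
  # recode v01 onto the other allele
  G2 <- G; G2[, 1] <- 2 - G2[, 1]
  vm2 <- vm; vm2$ref[1] <- "G"; vm2$alt[1] <- "A"
  sc2 <- pqtlScan(G2, z, NULL, vm2)
  r1 <- sc1$records[sc1$records$variant_id == "v01", ]
  r2 <- sc2$records[sc2$records$variant_id == "v01", ]
  expect_equal(r2$beta, -r1$beta)
  expect_equal(r2$se, r1$se)
  expect_equal(r2$p, r1$p)
  # and the meta result follows the discovery coding after harmonization
  meta <- metaFixedIVW(sc1$records, sc2$records, gc = FALSE)
  expect_equal(nrow(meta$meta), 4L)
  expect_equal(meta$meta$beta[meta$meta$variant_id == "v01"],
               r1$beta, tolerance = 1e-12)
})

test_that("the PC count reproduces dimensionality and sets the trans threshold", {
  # identity covariance: K tracks the eigen-oracle on the same matrix
  z <- withr::with_seed(9, matrix(rnorm(500 * 100), 500, 100))
  thr <- transThreshold(z)
  ev <- eigen(cov(scale(z)), only.values = TRUE)$values
  oracleK <- which(cumsum(ev) / sum(ev) >= 0.95)[1]
  expect_lte(abs(thr$K - oracleK), 3)
  expect_equal(thr$trans_p, 5e-8 / thr$K)
  # rank-1 matrix: a single component explains everything
  base <- withr::with_seed(10, rnorm(200))
  z1 <- outer(base, seq(0.5, 2, length.out = 5))
  thr1 <- transThreshold(z1)
  expect_equal(thr1$K, 1L)
  expect_equal(thr1$trans_p, 5e-8)
  expect_error(transThreshold(z1[, 1, drop = FALSE]), "2 aptamers")
})

test_that("IVW meta-analysis matches hand arithmetic and a from-scratch oracle", {
  rec <- function(v, beta, se, stage) {
    data.frame(variant_id = v, aptamer_id = "a1", beta = beta, se = se,
               p = 2 * pnorm(-abs(beta / se)), n = 100L,
               effect_allele = "G", other_allele = "A", stage = stage,
               stringsAsFactors = FALSE)
  }
  # identical inputs: same beta, se / sqrt(2)
  m1 <- metaFixedIVW(rec("v1", 0.5, 0.1, "discovery"),
                     rec("v1", 0.5, 0.1, "replication"), gc = FALSE)
  expect_equal(m1$meta$beta, 0.5)
  expect_equal(m1$meta$se, 0.1 / sqrt(2))
  # (0.5, 0.1) with (0.3, 0.2): hand-computed IVW
  m2 <- metaFixedIVW(rec("v1", 0.5, 0.1, "discovery"),
                     rec("v1", 0.3, 0.2, "replication"), gc = FALSE)
  expect_equal(m2$meta$beta, 0.46, tolerance = 1e-10)
  expect_equal(m2$meta$se, sqrt(1 / (1 / 0.01 + 1 / 0.04)), tolerance = 1e-10)
  # 200-variant toy equals a from-scratch single-pass oracle to 1e-10
  withr::with_seed(11, {
    vs <- sprintf("v%03d", 1:200)
    d <- rec(vs, rnorm(200, 0, 0.3), runif(200, 0.05, 0.2), "discovery")
    r <- rec(vs, rnorm(200, 0, 0.3), runif(200, 0.05, 0.2), "replication")
  })
  m3 <- metaFixedIVW(d, r, gc = FALSE)
  wD <- 1 / d$se^2; wR <- 1 / r$se^2
  expect_equal(m3$meta$beta, (d$beta * wD + r$beta * wR) / (wD + wR),
               tolerance = 1e-10)
  expect_equal(m3$meta$se, sqrt(1 / (wD + wR)), tolerance = 1e-10)
})

test_that("genomic control detects inflation and restores the median chi-square", {
  withr::with_seed(12, {
    pNull <- runif(5000)
    lam <- genomicControlLambda(pNull)
    expect_gt(lam, 0.95); expect_lt(lam, 1.05)
    # doubled chi-square: lambda near 2; GC restores the median
    chi2 <- 2 * qchisq(pNull, 1, lower.tail = FALSE)
    pInfl <- pchisq(chi2, 1, lower.tail = FALSE)
    lamI <- genomicControlLambda(pInfl)
    expect_equal(lamI, 2, tolerance = 0.1)
    corrected <- pchisq(chi2 / lamI, 1, lower.tail = FALSE)
    expect_equal(median(qchisq(corrected, 1, lower.tail = FALSE)),
                 qchisq(0.5, 1), tolerance = 1e-6)
  })
})

test_that("the four-gate filter enforces every condition and is monotone", {
  mk <- function(pd, pr, pm, bd = 0.3, br = 0.3) {
    disc <- data.frame(variant_id = "v1", aptamer_id = "a1", beta = bd,
                       se = 0.1, p = pd, n = 100, effect_allele = "G",
                       other_allele = "A", stage = "discovery")
    rep <- transform(disc, beta = br, p = pr, stage = "replication")
    meta <- transform(disc, p = pm, stage = "meta")
    list(meta = meta, disc = disc, rep = rep)
  }
  thr <- list(cis_p = 5e-8, trans_p = 3.45e-11, disc_p = 0.005, rep_p = 0.05)
  pass <- mk(0.004, 0.04, 1e-9)
  expect_equal(nrow(significanceFilter(pass$meta, pass$disc, pass$rep, thr,
                                       "cis")$significant), 1L)
  flip <- mk(0.004, 0.04, 1e-9, bd = 0.3, br = -0.3)
  resFlip <- significanceFilter(flip$meta, flip$disc, flip$rep, thr, "cis")
  expect_equal(nrow(resFlip$significant), 0L)
  expect_equal(unname(resFlip$rejections["direction"]), 1L)
  # trans pair at 1e-10 misses the study-wide trans threshold
  transMiss <- mk(0.004, 0.04, 1e-10)
  expect_equal(nrow(significanceFilter(transMiss$meta, transMiss$disc,
                                       transMiss$rep, thr, "trans")$significant), 0L)
  # monotone: tightening any gate never adds pairs
  thr2 <- thr; thr2$disc_p <- 1e-4
  expect_lte(nrow(significanceFilter(pass$meta, pass$disc, pass$rep, thr2,
                                     "cis")$significant),
             nrow(significanceFilter(pass$meta, pass$disc, pass$rep, thr,
                                     "cis")$significant))
})

test_that("cis/trans labels honour the inclusive 1 Mb TSS window", {
  vm <- data.frame(variant_id = c("v1", "v2", "v3"), chrom = c("chr1", "chr1", "chr2"),
                   pos = c(3000000, 3000001, 2000000), ref = "A", alt = "G",
                   maf = 0.3)
  ai <- data.frame(aptamer_id = "a1", gene = "G1", tss_chrom = "chr1",
                   tss_pos = 2000000)
  lab <- classifyCisTrans(c("v1", "v2", "v3"), rep("a1", 3), vm, ai)
  expect_equal(lab, c("cis", "trans", "trans")) # |1e6| inclusive; +1 bp is out
  aiNA <- transform(ai, tss_pos = NA)
  expect_equal(classifyCisTrans("v1", "a1", vm, aiNA), "unassigned")
})

test_that("the stratified effect-difference statistic follows the formula", {
  expect_equal(stratifiedZdiff(0.4, 0.1, 0.4, 0.1)$zdiff, 0)
  z <- stratifiedZdiff(0.5, 0.1, 0.2, 0.1)
  expect_equal(z$zdiff, 0.3 / sqrt(0.02), tolerance = 1e-12)
  expect_true(z$flagged) # 2.121 exceeds the 1.960 two-sided cutoff
  expect_equal(qnorm(0.975), 1.960, tolerance = 5e-4)
})
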