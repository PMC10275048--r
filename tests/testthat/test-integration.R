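mkTrait <- function(ids, beta, se) {
  data.frame(variant_id = ids, beta = beta, se = se, stringsAsFactors = FALSE)
}

test_that("colocalization posteriors behave at the limits", {
  withr::with_seed(1, {
    ids <- sprintf("v%03d", 1:500)
    z <- rnorm(500); z[250] <- 8
    t1 <- mkTrait(ids, z * 0.05, 0.05)
  })
  res <- colocAbf(t1, t1, type2 = "quant")
  expect_equal(sum(res$pp), 1, tolerance = 1e-8)
  expect_gt(res$pp[["PP.H4"]], 0.99)
  # both flat: no signal anywhere
  withr::with_seed(2, {
    flat1 <- mkTrait(sprintf("v%03d", 1:300), rnorm(300, 0, 0.02), 0.05)
    flat2 <- mkTrait(sprintf("v%03d", 1:300), rnorm(300, 0, 0.02), 0.05)
  })
  resF <- colocAbf(flat1, flat2)
  expect_gt(resF$pp[["PP.H0"]], 0.9)
  # permutation invariance
  perm <- withr::with_seed(3, sample(500))
  resP <- colocAbf(t1[perm, ], t1, type2 = "quant")
  expect_equal(res$pp, resP$pp, tolerance = 1e-12)
  # underpowered flag below 10 shared variants
  expect_true(colocAbf(t1[1:5, ], t1[1:5, ], type2 = "quant")$underpowered)
})

test_that("3-variant posteriors equal the hand enumeration in log space", {
  t1 <- mkTrait(c("a", "b", "c"), c(0.5, 0.1, 0.0), c(0.1, 0.1, 0.1))
  t2 <- mkTrait(c("a", "b", "c"), c(0.3, 0.0, 0.2), c(0.08, 0.08, 0.08))
  priors <- c(1e-4, 1e-4, 1e-5)
  # oracle: enumerate all single-causal configurations explicitly
  labf <- function(b, s, W) {
    0.5 * log(s^2 / (s^2 + W)) + 0.5 * (b / s)^2 * W / (W + s^2)
  }
  l1 <- labf(t1$beta, t1$se, 0.15^2)
  l2 <- labf(t2$beta, t2$se, 0.2^2)
  h0 <- 1
  h1 <- sum(priors[1] * exp(l1))
  h2 <- sum(priors[2] * exp(l2))
  h3 <- 0
  for (i in 1:3) for (j in 1:3) {
    if (i != j) h3 <- h3 + priors[1] * priors[2] * exp(l1[i] + l2[j])
  }
  h4 <- sum(priors[3] * exp(l1 + l2))
  oracle <- c(h0, h1, h2, h3, h4) / sum(h0, h1, h2, h3, h4)
  res <- colocAbf(t1, t2, priors)
  expect_equal(unname(res$pp), oracle, tolerance = 1e-10)
})

test_that("instrument selection applies the pleiotropy and anchor filters", {
  vm <- makeVariantMap(30, nChrom = 2, spacing = 200000L, seed = 1)
  G <- toyDosages(2000, vm, seed = 2)
  rec <- toyRecords(vm$variant_id, rep(1e-10, 30), vm$pos, chrom = vm$chrom,
                    beta = 0.4, se = 0.05)
  rec$chrom <- vm$chrom
  rec$label <- c(rep("cis", 5), rep("trans", 25))
  gwas <- data.frame(variant_id = vm$variant_id, chrom = vm$chrom,
                     pos = vm$pos, effect_allele = "G", other_allele = "A",
                     beta = 0.1, se = 0.05, p = 0.05, n = 4000)
  # trans variant inside a 6-aptamer hotspot region is removed
  regionApt <- setNames(rep(1L, 30), vm$variant_id)
  regionApt[vm$variant_id[10]] <- 6L
  ins <- selectInstruments(rec, gwas, G, vm, regionApt, clumpR2 = 0.05)
  expect_false(vm$variant_id[10] %in% ins$variant_id)
  # cis variant in the same situation is retained but flagged
  regionApt2 <- setNames(rep(1L, 30), vm$variant_id)
  regionApt2[vm$variant_id[2]] <- 6L
  ins2 <- selectInstruments(rec, gwas, G, vm, regionApt2, clumpR2 = 0.05)
  expect_true(vm$variant_id[2] %in% ins2$variant_id)
  expect_true(ins2$flagged_pleiotropic[ins2$variant_id == vm$variant_id[2]])
  # anchor window: trans at 400 kb removed, 600 kb kept
  anchor <- vm$variant_id[12]
  d <- abs(vm$pos - vm$pos[12])
  in400 <- vm$variant_id[vm$chrom == vm$chrom[12] & d == 400000][1]
  in600 <- vm$variant_id[vm$chrom == vm$chrom[12] & d == 600000][1]
  ins3 <- selectInstruments(rec, gwas, G, vm, anchorVariant = anchor,
                            clumpR2 = 0.05)
  expect_false(in400 %in% ins3$variant_id)
  expect_true(in600 %in% ins3$variant_id)
  # sub-threshold aptamer is skipped with a reason
  weak <- rec; weak$p <- 1e-4
  insW <- selectInstruments(weak, gwas, G, vm)
  expect_equal(nrow(insW), 0L)
  expect_match(attr(insW, "reason"), "significant")
})

test_that("MR estimates follow Wald and IVW arithmetic", {
  one <- data.frame(variant_id = "v1", beta_exp = 0.5, se_exp = 0.05,
                    beta_out = 0.1, se_out = 0.05, p_exp = 1e-20,
                    p_out = 0.04, n_exp = 1000, n_out = 5000,
                    label = "cis", flagged_pleiotropic = FALSE)
  est <- mrEstimate(one)
  expect_equal(est$method, "Wald")
  expect_equal(est$estimate, 0.2)
  expect_equal(est$se, 0.1)
  # two identical instruments: IVW point estimate equals the Wald ratio
  two <- rbind(one, transform(one, variant_id = "v2"))
  est2 <- mrEstimate(two)
  expect_equal(est2$method, "IVW")
  expect_equal(est2$estimate, 0.2)
  # allele-flip invariance: flipping an instrument's coding changes nothing
  flipped <- two
  flipped$beta_exp[1] <- -flipped$beta_exp[1]
  flipped$beta_out[1] <- -flipped$beta_out[1]
  expect_equal(mrEstimate(flipped)$estimate, est2$estimate, tolerance = 1e-12)
  expect_error(mrEstimate(transform(one, beta_exp = 0)), "zero exposure")
})

test_that("MR recovers a planted protein-to-disease effect", {
  vm <- makeVariantMap(10, mafRange = c(0.3, 0.5), seed = 1)
  hits <- vapply(1:50, function(s) {
    G <- simulateGenotypes(2500, vm, seed = s)
    truth <- emptyTruth()
    truth$effects <- data.frame(variant_id = vm$variant_id[3],
                                aptamer_id = "a1", beta_true = 0.8)
    pr <- simulateProteome(G, "a1", truth, seed = s + 600)
    z <- normalizeLevels(pr$proteins)
    gw <- simulateGwasSummary(G, vm, liability = 0.3 * z[, 1], seed = s + 700)
    sc <- pqtlScan(G, z, NULL, vm)
    rec <- sc$records; rec$label <- "cis"
    ins <- selectInstruments(rec, gw, G, vm)
    if (!nrow(ins)) return(NA)
    est <- mrEstimate(ins)
    abs(est$estimate - 0.3) <= 2 * est$se
  }, TRUE)
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("Steiger directionality compares variance explained", {
  mk <- function(zE, zO, nE, nO) {
    data.frame(beta_exp = zE * 0.1, se_exp = 0.1, beta_out = zO * 0.1,
               se_out = 0.1, n_exp = nE, n_out = nO)
  }
  res <- steigerDirection(mk(10, 1, 1000, 1000))
  expect_true(res$correct_direction)
  expect_lt(res$p, 1e-6)
  same <- steigerDirection(mk(3, 3, 1000, 1000))
  expect_gt(same$p, 0.99)
  # oracle for the correlated-correlation p under independence
  ins <- mk(6, 2, 1000, 100000)
  res2 <- steigerDirection(ins)
  r2E <- 36 / (36 + 998); r2O <- 4 / (4 + 99998)
  zor <- (atanh(sqrt(r2E)) - atanh(sqrt(r2O))) / sqrt(1 / 997 + 1 / 99997)
  expect_equal(res2$p, 2 * pnorm(-abs(zor)), tolerance = 1e-12)
  expect_true(res2$correct_direction)
  expect_error(steigerDirection(mk(1, 1, 2, 100)), "exceed 2")
})

test_that("PWAS weights choose the right model and quantify fit", {
  vm <- makeVariantMap(30, mafRange = c(0.2, 0.5), seed = 1)
  G <- simulateGenotypes(1500, vm, seed = 2)
  # single causal variant: top1 selects it, cv R2 near the local h2
  y1 <- withr::with_seed(3, {
    g <- scale(G[, 15])[, 1]; h2 <- 0.25
    sqrt(h2) * g + sqrt(1 - h2) * rnorm(1500)
  })
  fit1 <- pwasFitWeights(G, y1, seed = 4)
  expect_equal(names(which.max(abs(fit1$weights))), vm$variant_id[15])
  expect_lt(abs(fit1$cv_r2 - 0.25), 0.05)
  expect_false(fit1$nonPredictive)
  # pure noise: flagged non-predictive
  nullFlags <- vapply(1:20, function(s) {
    yn <- withr::with_seed(50 + s, rnorm(800))
    pwasFitWeights(G[1:800, ], yn, seed = s)$nonPredictive
  }, TRUE)
  expect_gte(mean(nullFlags), 0.9)
  # two causal variants in low LD: lasso wins most of the time
  lassoWins <- vapply(1:15, function(s) {
    y2 <- withr::with_seed(100 + s,
      0.4 * scale(G[, 5])[, 1] + 0.4 * scale(G[, 25])[, 1] + rnorm(1500))
    pwasFitWeights(G, y2, seed = s)$model == "lasso"
  }, TRUE)
  expect_gte(mean(lassoWins), 0.8)
})

test_that("the PWAS association statistic matches its quadratic form", {
  # top1 weights on one variant reproduce that variant's GWAS z
  w <- c(v1 = 0.8, v2 = 0)
  z <- c(v1 = 4, v2 = 1)
  S <- diag(2); dimnames(S) <- list(names(w), names(w))
  res <- pwasAssociate(w, z, S, ridge = 0)
  expect_equal(res$z, 4)
  # 2-variant toy with known LD equals the hand evaluation
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(names(w), names(w)))
  w2 <- c(v1 = 0.6, v2 = -0.3)
  hand <- (0.6 * 4 - 0.3 * 1) /
    sqrt(drop(t(w2) %*% (S2 + diag(1e-3, 2)) %*% w2))
  expect_equal(pwasAssociate(w2, z, S2)$z, hand, tolerance = 1e-12)
  # degenerate quadratic form is flagged undefined
  S0 <- matrix(0, 2, 2, dimnames = list(names(w), names(w)))
  expect_true(pwasAssociate(c(v1 = 0, v2 = 0), z, S0, ridge = 0)$undefined)
})

test_that("PWAS z-scores are standard normal against a null GWAS", {
  # real protein weights, but disease z-scores carrying no signal: the
  # weighted statistic must stay calibrated
  vm <- makeVariantMap(20, seed = 5)
  G <- simulateGenotypes(1000, vm, seed = 6)
  S <- cor(G)
  zs <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      y <- 0.4 * scale(G[, 8])[, 1] + rnorm(1000)
      zg <- setNames(rnorm(20), vm$variant_id) # null GWAS
      fit <- pwasFitWeights(G, y, seed = s)
      pwasAssociate(fit$weights, zg, S)$z
    })
  }, 0)
  zs <- zs[is.finite(zs)]
  expect_gte(length(zs), 90)
  expect_lt(abs(mean(zs)), 0.3)
  expect_gt(sd(zs), 0.7); expect_lt(sd(zs), 1.4)
})
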