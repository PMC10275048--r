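# shared fixture builders; everything is generated in code

# tiny variant map on one chromosome with fixed MAFs
toyVariantMap <- function(n = 10, maf = 0.3, spacing = 50000L, chrom = "chr1") {
  data.frame(
    variant_id = sprintf("v%02d", seq_len(n)),
    chrom = chrom, pos = seq_len(n) * spacing,
    ref = "A", alt = "G", maf = rep_len(maf, n),
    stringsAsFactors = FALSE
  )
}

# association records with explicit positions for signal/clump tests
toyRecords <- function(variant_id, p, pos, chrom = "chr1",
                       beta = 0.1, se = 0.02, aptamer_id = "apt1") {
  data.frame(variant_id = variant_id, aptamer_id = aptamer_id,
             beta = rep_len(beta, length(p)), se = rep_len(se, length(p)),
             p = p, n = 1000L, effect_allele = "G", other_allele = "A",
             stage = "meta", chrom = chrom, pos = pos,
             stringsAsFactors = FALSE)
}

# covariates with just age and sex, complete
toyCovariates <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = round(rnorm(n, 70, 8)), sex = rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE
  ))
}

# independent dosage matrix at fixed maf (hard calls from binomial)
toyDosages <- function(n, variantMap, seed = 1) {
  withr::with_seed(seed, {
    G <- vapply(variantMap$maf, function(m) rbinom(n, 2L, m), integer(n))
    dimnames(G) <- list(sprintf("S%04d", seq_len(n)), variantMap$variant_id)
    G * 1.0
  })
}
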