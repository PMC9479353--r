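cfg_small <- sim_config(n_samples = 500, n_chrom = 1, chrom_len = 2e5,
                        block_size = 10, seed = 21)

test_that("genotype simulator is seed-deterministic with block-local LD", {
  g1 <- simulate_genotypes(cfg_small)
  g2 <- simulate_genotypes(cfg_small)
  expect_identical(g1$dosage, g2$dosage)

  # rho = 0: independent markers
  cfg0 <- sim_config(n_samples = 300, n_chrom = 1, chrom_len = 1.2e5,
                     within_block_rho = 0, seed = 8)
  g0 <- simulate_genotypes(cfg0)
  cc <- cor(g0$dosage)
  off <- cc[upper.tri(cc)]
  expect_lt(mean(off[seq_len(100)]^2), 0.05)

  # rho = 0.95: adjacent r2 near rho^2
  cfg95 <- sim_config(n_samples = 500, n_chrom = 1, chrom_len = 1e5,
                      within_block_rho = 0.95, block_size = 10, seed = 8)
  g95 <- simulate_genotypes(cfg95)
  blocks <- attr(g95$variants, "block")
  adj <- vapply(seq_len(ncol(g95$dosage) - 1), function(j) {
    if (g95$variants$block[j] != g95$variants$block[j + 1]) return(NA_real_)
    cor(g95$dosage[, j], g95$dosage[, j + 1])^2
  }, numeric(1))
  adj <- adj[!is.na(adj)]
  expect_gt(mean(adj), 0.5)
  expect_equal(mean(adj), 0.95^2, tolerance = 0.12)  # Monte-Carlo slack

  # realized MAFs stay inside the configured range (up to sampling error)
  st <- variant_stats(g1)
  expect_true(all(st$maf > cfg_small$maf_range[1] - 0.06))
})

test_that("junction counts implement the softmax-logit planted-effect model", {
  g <- simulate_genotypes(cfg_small)
  # null: regression slope of PSI on dosage centered at zero
  jc0 <- simulate_junction_counts(g, cfg_small, effects = NULL)
  cl <- cluster_junctions(jc0$junctions, jc0$counts)
  psi <- compute_psi(cl)
  slopes <- vapply(seq_len(min(30, nrow(psi$values))), function(i) {
    f <- psi$anchors[i, ]
    vi <- which(g$variants$chrom == f$chrom)[1]
    coef(lm(psi$values[i, ] ~ g$dosage[, vi]))[2]
  }, numeric(1))
  expect_lt(abs(mean(slopes, na.rm = TRUE)), 0.02)

  # beta = 1 on the first junction: PSI difference between dosage groups
  # matches the closed-form softmax prediction
  cfg2 <- sim_config(n_samples = 400, n_chrom = 1, chrom_len = 2e5,
                     n_clusters = 12, junctions_per_cluster = 2,
                     cluster_depth = 200, seed = 31)
  g2 <- simulate_genotypes(cfg2)
  eff <- data.frame(cluster = 1:12, beta = 1.0)
  jc <- simulate_junction_counts(g2, cfg2, eff)
  diffs <- preds <- c()
  for (i in seq_len(nrow(jc$truth))) {
    j1 <- jc$truth$feature[i]
    cl_id <- jc$truth$cluster[i]
    members <- jc$junctions$junction_id[jc$junctions$cluster_true == cl_id]
    dos <- g2$dosage[, match(jc$truth$variant[i], g2$variants$id)]
    tot <- colSums(jc$counts[members, , drop = FALSE])
    p1 <- jc$counts[j1, ] / tot
    if (sum(dos == 0) < 10 || sum(dos == 2) < 10) next
    diffs <- c(diffs, mean(p1[dos == 2], na.rm = TRUE) -
                      mean(p1[dos == 0], na.rm = TRUE))
    # closed form: E[softmax_1] under logit shift 2*beta vs 0, averaging
    # over the simulated base logits is approximated by the realized
    # group means of the multinomial probabilities, so predict from the
    # logistic map at the median base-logit gap
    preds <- c(preds, plogis(qlogis(mean(p1[dos == 0], na.rm = TRUE)) + 2) -
                      mean(p1[dos == 0], na.rm = TRUE))
  }
  expect_gt(length(diffs), 5)
  expect_equal(mean(diffs), mean(preds), tolerance = 0.08)
  expect_true(all(diffs > 0.1))

  jc_b <- simulate_junction_counts(g2, cfg2, eff)
  expect_identical(jc$counts, jc_b$counts)           # seed determinism
  expect_error(
    simulate_junction_counts(g2, cfg2, data.frame(cluster = 99, beta = 1)),
    "non-existent")
})

test_that("expression simulator plants recoverable additive effects", {
  cfg <- sim_config(n_samples = 300, n_chrom = 1, chrom_len = 4e5,
                    n_genes = 20, seed = 17)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg, effects = data.frame(gene = 1:6,
                                                         beta = 0.8))
  le <- cpm_log2(ex$counts)
  sl_sd <- vapply(1:6, function(i) {
    f <- ex$truth$feature[i]
    dos <- g$dosage[, match(ex$truth$variant[i], g$variants$id)]
    y <- le[f, ]
    unname(coef(lm(y ~ dos))[2] / sd(resid(lm(y ~ dos))))
  }, numeric(1))
  # slope on the residual-SD scale recovers the planted 0.8: the mean
  # within +/-0.15, individual genes within their sampling error
  expect_lt(abs(mean(sl_sd) - 0.8), 0.15)
  expect_true(all(abs(sl_sd - 0.8) < 0.25))
  # null gene slope centered at zero
  null_sl <- vapply(7:20, function(i) {
    y <- le[ex$genes$gene_id[i], ]
    vi <- which.min(abs(g$variants$pos - ex$genes$tss[i]))
    coef(lm(y ~ g$dosage[, vi]))[2]
  }, numeric(1))
  expect_lt(abs(mean(null_sl)), 0.05)

  # planted batch offset is removed by batch_adjust
  ex_b <- simulate_expression(g, cfg, batch_effect = 1.0)
  le_b <- cpm_log2(ex_b$counts)
  pm <- phenotype_matrix(le_b, data.frame(feature = rownames(le_b),
    chrom = "chr1", start = 1, end = 1), "expression")
  adj <- batch_adjust(pm, ex_b$batches)
  b2 <- as.integer(ex_b$batches) > 1
  resid_diff <- rowMeans(adj$values[, b2]) - rowMeans(adj$values[, !b2])
  expect_lt(max(abs(resid_diff)), 0.05)
})

test_that("GWAS z-scores follow the multivariate-normal LD model", {
  cfg <- sim_config(n_samples = 400, n_chrom = 1, chrom_len = 1.2e5,
                    seed = 13)
  g <- simulate_genotypes(cfg)
  ids <- g$variants$id[1:100]
  # null locus: no extreme z
  mx <- vapply(1:20, function(s)
    max(abs(simulate_gwas(g, ids, seed = s)$z)), numeric(1))
  expect_lt(mean(mx > 4), 0.15)

  # lead z over replicates ~ N(lambda_c, 1)
  lam <- 6
  zc <- vapply(1:200, function(s) {
    gw <- simulate_gwas(g, ids, causal_id = ids[50],
                        beta_gwas = lam / sqrt(5e4), n_gwas = 5e4, seed = s)
    gw$z[match(ids[50], gw$id)]
  }, numeric(1))
  expect_equal(mean(zc), lam, tolerance = 0.25)
  expect_equal(sd(zc), 1, tolerance = 0.2)

  # perfect-LD proxy inherits the causal mean through R %*% lambda
  d <- g$dosage[, 1:3]; d[, 3] <- d[, 1]
  gd <- make_g(d)
  zp <- vapply(1:100, function(s) {
    gw <- simulate_gwas(gd, c("v1", "v2", "v3"), causal_id = "v1",
                        beta_gwas = 8 / sqrt(5e4), n_gwas = 5e4, seed = s)
    gw$z[match("v3", gw$id)]
  }, numeric(1))
  expect_equal(mean(zp), 8, tolerance = 0.4)
})

test_that("simulated annotations are mutually exclusive and cover splice sites", {
  cfg <- sim_config(n_samples = 50, seed = 4)
  g <- simulate_genotypes(cfg)
  jc <- simulate_junction_counts(g, cfg)
  ex <- simulate_expression(g, cfg)
  anns <- simulate_annotations(cfg, jc$junctions, ex$genes)

  genic <- c("splice_site", "exon", "intron", "promoter", "enhancer")
  pos <- seq(1, 1e5)
  cover <- sapply(genic, function(a)
    interval_overlap(anns[[a]], rep("chr1", length(pos)), pos))
  expect_true(all(rowSums(cover) <= 1))              # mutually exclusive

  hits <- interval_overlap(anns$splice_site,
                           rep(jc$junctions$chrom, 2),
                           c(jc$junctions$intron_start,
                             jc$junctions$intron_end))
  expect_true(all(hits))

  # interval arithmetic equals per-base labeling on a 10 kb toy region
  toy <- seq_len(10000)
  for (a in genic) {
    lab <- label_bases(anns[[a]], "chr1", 10000)
    expect_equal(interval_overlap(anns[[a]], rep("chr1", 10000), toy), lab,
                 label = a)
  }
})
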