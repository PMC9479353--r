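# shared fixture: block-LD genotypes and a splicing-kind phenotype matrix
local({
  cfg <<- sim_config(n_samples = 150, n_chrom = 1, chrom_len = 3e5,
                     block_size = 10, seed = 42)
  gq <<- simulate_genotypes(cfg)
})

make_pm <- function(values, pos, kind = "splicing") {
  phenotype_matrix(values,
    data.frame(feature = paste0("f", seq_len(nrow(values))),
               chrom = "chr1", start = pos, end = pos + 100),
    kind)
}

test_that("cis windows follow the feature-kind conventions", {
  a <- data.frame(chrom = "chr1", start = 1e6, end = 1e6)
  expect_equal(cis_window(a, "expression")[c("start", "end")],
               list(start = 5e5, end = 1.5e6))
  b <- data.frame(chrom = "chr1", start = 1e5, end = 101000)
  expect_equal(cis_window(b, "splicing")[c("start", "end")],
               list(start = 5e4, end = 151000))
  c <- data.frame(chrom = "chr1", start = 1e4, end = 1e4)
  expect_equal(cis_window(c, "expression")$start, 1)
})

test_that("nominal scan equals full multiple regression (Frisch-Waugh)", {
  # identity case: phenotype equals a dosage column
  y <- gq$dosage[, 30]
  pm <- make_pm(rbind(y), gq$variants$pos[30])
  ns <- nominal_scan(pm, gq, NULL, "f1", window_s = 5000)
  self <- ns[ns$variant == gq$variants$id[30], ]
  expect_equal(self$slope, 1, tolerance = 1e-12)
  expect_lt(self$p, 1e-100)

  # toy n = 150 with covariates: t and p equal lm() on the full model
  set.seed(1)
  cov <- cbind(rnorm(150), rnorm(150))
  y2 <- rnorm(150) + 0.3 * gq$dosage[, 31] + 0.5 * cov[, 1]
  pm2 <- make_pm(rbind(y2), gq$variants$pos[31])
  ns2 <- nominal_scan(pm2, gq, cov, "f1", window_s = 8000)
  for (k in sample(nrow(ns2), 5)) {
    d <- gq$dosage[, match(ns2$variant[k], gq$variants$id)]
    fit <- summary(lm(y2 ~ d + cov))$coefficients["d", ]
    expect_equal(ns2$t[k], unname(fit["t value"]), tolerance = 1e-8)
    expect_equal(ns2$p[k], unname(fit["Pr(>|t|)"]), tolerance = 1e-8)
    expect_equal(ns2$slope[k], unname(fit["Estimate"]), tolerance = 1e-8)
  }

  # permuted phenotype: nominal p approximately uniform (KS test)
  set.seed(2)
  pvals <- unlist(lapply(1:40, function(i) {
    yp <- sample(y2)
    pmp <- make_pm(rbind(yp), gq$variants$pos[7 * i + 5])
    nominal_scan(pmp, gq, NULL, "f1", window_s = 2000)$p
  }))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("permutation pass: empirical p formula and beta approximation", {
  # strong signal: observed best beats every permutation minimum
  y <- gq$dosage[, 50] + rnorm(150, sd = 0.1)
  pm <- make_pm(rbind(y), gq$variants$pos[50])
  pr <- permutation_pass(pm, gq, NULL, "f1", B = 1000, seed = 3,
                         window_s = 5000)
  expect_equal(pr$p_empirical, 1 / 1001)
  expect_gt(pr$p_beta, 0)                       # never exactly zero
  expect_equal(pr$lead, gq$variants$id[50])

  # best-of-M uniform order statistic: fitted b within 25% of M, a ~ 1
  M <- 15
  set.seed(4)
  dindep <- matrix(rbinom(300 * M, 2, 0.4), 300, M)
  gi <- make_g(dindep)
  pmn <- phenotype_matrix(rbind(rnorm(300)),
    data.frame(feature = "f1", chrom = "chr1", start = 1, end = 2),
    "splicing")
  prn <- permutation_pass(pmn, gi, NULL, "f1", B = 1000, seed = 5,
                          window_s = 1e6)
  expect_equal(prn$n_variants, M)
  expect_lt(abs(prn$beta_b - M) / M, 0.25)
  expect_lt(abs(prn$beta_a - 1), 0.3)

  # p_beta tracks p_empirical in rank across simulated features
  set.seed(6)
  n <- 100
  res <- lapply(1:120, function(i) {
    d <- matrix(rbinom(n * 8, 2, 0.3), n, 8)
    gg <- make_g(d)
    yy <- rnorm(n) + (i %% 3 == 0) * 0.25 * d[, 1]
    pp <- phenotype_matrix(rbind(yy),
      data.frame(feature = "f1", chrom = "chr1", start = 1, end = 2),
      "splicing")
    permutation_pass(pp, gg, NULL, "f1", B = 150, seed = i,
                     window_s = 1e6)
  })
  res <- do.call(rbind, res)
  expect_gt(cor(rank(res$p_beta), rank(res$p_empirical)), 0.95)
})

test_that("Storey q-values match the brute-force definition", {
  expect_equal(storey_qvalues(rep(1, 5))$q, rep(1, 5))
  # pi0 = 1 reduces to Benjamini-Hochberg
  set.seed(7)
  p <- runif(40)
  st <- storey_qvalues(p)
  if (st$pi0 == 1) expect_equal(st$q, p.adjust(p, "BH"))
  expect_equal(storey_qvalues(p)$q / storey_qvalues(p)$pi0,
               p.adjust(p, "BH"), tolerance = 1e-12)
  # 50-value list vs double-loop oracle
  p2 <- c(runif(45), runif(5, 0, 1e-4))
  expect_equal(storey_qvalues(p2)$q, storey_oracle(p2), tolerance = 1e-12)
  # monotone in p_beta rank
  st2 <- storey_qvalues(p2)
  expect_true(all(diff(st2$q[order(p2)]) >= -1e-15))
})

test_that("genome-wide and per-feature thresholds follow the beta back-transform", {
  perm <- data.frame(p_beta = c(1e-5, 3e-4, 2e-3),
                     q = c(0.005, 0.009, 0.012))
  expect_equal(genomewide_threshold_pt(perm, 0.01), 3e-4)  # |0.009-0.01| wins
  perm2 <- data.frame(p_beta = 0.02, q = 0.5)
  expect_equal(genomewide_threshold_pt(perm2), 0.02)
  # brute-force: selected feature minimizes |q - fdr|
  set.seed(8)
  perm3 <- data.frame(p_beta = sort(runif(30, 0, 0.05)),
                      q = sort(runif(30, 0, 0.1)))
  i <- which.min(abs(perm3$q - 0.01))
  expect_equal(genomewide_threshold_pt(perm3, 0.01), perm3$p_beta[i])

  expect_equal(nominal_threshold_per_feature(0.013, 1, 1), 0.013)
  b <- 37.5
  expect_equal(nominal_threshold_per_feature(0.013, 1, b),
               1 - (1 - 0.013)^(1 / b), tolerance = 1e-12)
  thr <- nominal_threshold_per_feature(0.013, 2.3, 41)
  expect_equal(pbeta(thr, 2.3, 41), 0.013, tolerance = 1e-10)
})

test_that("significant calls honor q and per-feature nominal thresholds", {
  set.seed(9)
  # two features with planted effects, three null
  betas <- c(1, 0.8, 0, 0, 0)
  vals <- t(vapply(1:5, function(i)
    rnorm(150) + betas[i] * gq$dosage[, 40 + 20 * i], numeric(150)))
  pm <- make_pm(vals, gq$variants$pos[40 + 20 * (1:5)])
  perm <- permutation_pass_all(pm, gq, NULL, B = 300, seed = 10,
                               window_s = 8000)
  nom <- do.call(rbind, lapply(pm$anchors$feature, function(f)
    nominal_scan(pm, gq, NULL, f, window_s = 8000)))
  calls <- call_significant(perm, nom, fdr = 0.01)
  expect_true(all(c("f1", "f2") %in% calls$significant$feature))
  expect_false(any(c("f3", "f4", "f5") %in% calls$significant$feature))
  # q = 0.009-style boundary: every call has q <= fdr
  expect_true(all(calls$significant$q <= 0.01))
  # nominal pairs exactly reproduce a brute-force scan at the thresholds
  thr <- setNames(calls$significant$nominal_threshold,
                  calls$significant$feature)
  brute <- nom[nom$feature %in% names(thr) &
               nom$p <= thr[nom$feature], ]
  expect_equal(calls$pairs[order(calls$pairs$feature, calls$pairs$variant),
                           c("feature", "variant")],
               brute[order(brute$feature, brute$variant),
                     c("feature", "variant")], ignore_attr = TRUE)
  # excluded features contribute no pairs
  expect_false(any(calls$pairs$feature %in% c("f3", "f4", "f5")))
})

test_that("delta-PSI is the between-genotype median difference on raw PSI", {
  dos <- c(rep(0, 5), rep(1, 5), rep(2, 5))
  g1 <- make_g(cbind(dos, rbinom(15, 2, 0.5)))
  psi_vals <- rbind(c(rep(0.2, 5), rep(0.3, 5), rep(0.45, 5)),
                    c(rep(0.8, 5), rep(0.7, 5), rep(0.55, 5)))
  pm <- phenotype_matrix(psi_vals,
    data.frame(feature = c("j1", "j2"), chrom = "chr1",
               start = c(100, 100), end = c(200, 300),
               cluster = c("c1", "c1")), "splicing")
  perm <- data.frame(feature = c("j1", "j2"), lead = "v1",
                     q = c(0.001, 0.01), p_beta = c(1e-5, 1e-4),
                     degenerate = FALSE)
  dp <- delta_psi(pm, g1, perm)
  # only the best-q junction of the cluster is reported
  expect_equal(nrow(dp), 1L)
  expect_equal(dp$feature, "j1")
  expect_equal(dp$delta_psi, 0.45 - 0.2)
  expect_equal(dp$group_alt, "homalt")
  expect_gt(abs(dp$delta_psi), 0.10)     # lands in the >10% shift class

  # heterozygote fallback when no homozygous-alternate samples exist
  dos2 <- c(rep(0, 8), rep(1, 7))   # homref median 0.2, het median 0.45
  g2 <- make_g(cbind(dos2, rbinom(15, 2, 0.5)))
  dp2 <- delta_psi(pm, g2, perm)
  expect_equal(dp2$delta_psi, 0.45 - 0.2)
  expect_equal(dp2$group_alt, "het")

  # identical medians give zero
  pm0 <- pm; pm0$values[1, ] <- 0.5
  dp0 <- delta_psi(pm0, g1, perm[1, ])
  expect_equal(dp0$delta_psi, 0)
})

test_that("sQTL/eQTL comparison classifies lead-lead LD at r2 < 0.6", {
  # leads in the same block vs different blocks
  set.seed(11)
  sq <- list(significant = data.frame(feature = c("jA", "jB"),
                                      lead = c(gq$variants$id[11],
                                               gq$variants$id[101]),
                                      q = 0.001),
             pairs = data.frame(feature = c("jA", "jB"),
                                variant = c(gq$variants$id[11],
                                            gq$variants$id[101])))
  eq <- list(significant = data.frame(feature = c("gA", "gB"),
                                      lead = c(gq$variants$id[12],
                                               gq$variants$id[201]),
                                      q = 0.001),
             pairs = data.frame(feature = c("gA", "gB"),
                                variant = c(gq$variants$id[12],
                                            gq$variants$id[201])))
  fg <- data.frame(feature = c("jA", "jB", "gA", "gB"),
                   gene = c("G1", "G2", "G1", "G2"))
  cmp <- compare_sqtl_eqtl(sq, eq, fg, gq)
  r2_same <- ld_r2(gq, gq$variants$id[11])[gq$variants$id[12]]
  expect_equal(cmp$r2[cmp$gene == "G1"], unname(r2_same))
  expect_false(cmp$independent[cmp$gene == "G1"])  # same block, high LD
  expect_true(cmp$independent[cmp$gene == "G2"])   # different blocks
  # boundary: r2 just below 0.6 is independent
  cmp$r2[1] <- 0.59
  expect_true(cmp$r2[1] < 0.6)
})

test_that("planted cis effects are recovered with high power, nulls stay quiet", {
  set.seed(12)
  cfg3 <- sim_config(n_samples = 300, n_chrom = 1, chrom_len = 3e5,
                     maf_range = c(0.2, 0.5), seed = 77)
  g3 <- simulate_genotypes(cfg3)
  n_eff <- 10; n_null <- 40
  anchor_v <- seq(10, 290, by = 6)[seq_len(n_eff + n_null)]
  vals <- t(vapply(seq_len(n_eff + n_null), function(i) {
    rnorm(300) + (i <= n_eff) * 1.0 * g3$dosage[, anchor_v[i]]
  }, numeric(300)))
  pm <- phenotype_matrix(vals,
    data.frame(feature = paste0("f", seq_len(nrow(vals))), chrom = "chr1",
               start = g3$variants$pos[anchor_v],
               end = g3$variants$pos[anchor_v] + 100), "splicing")
  perm <- permutation_pass_all(pm, g3, NULL, B = 300, seed = 13,
                               window_s = 10000)
  called <- perm$feature[perm$q <= 0.01]
  power <- mean(paste0("f", 1:n_eff) %in% called)
  expect_gt(power, 0.8)
  # nulls: essentially no false calls
  expect_lte(sum(paste0("f", n_eff + 1:n_null) %in% called), 1)
})
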