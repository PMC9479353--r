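test_that("gene filtering applies the per-cohort read-support rule", {
  # 20 samples, two cohorts of 10; boundary: 5 reads in exactly 10%
  counts <- rbind(
    boundary = c(5, rep(0, 9), 5, rep(0, 9)),   # 5 reads in 10% of each
    low      = rep(4, 20),                      # 4 reads everywhere
    high     = rep(50, 20)
  )
  groups <- rep(c("a", "b"), each = 10)
  kept <- filter_genes(counts, groups = groups)
  expect_setequal(rownames(kept), c("boundary", "high"))
  expect_error(filter_genes(counts, groups = factor(groups,
                levels = c("a", "b", "c"))), "partition")

  # random toy matrix equals a brute-force double loop
  set.seed(2)
  m <- matrix(rpois(30 * 12, 3), 30, 12)
  rownames(m) <- paste0("g", 1:30)
  grp <- rep(c("x", "y"), each = 6)
  brute <- vapply(1:30, function(i) {
    all(vapply(c("x", "y"), function(gl)
      mean(m[i, grp == gl] >= 5) >= 0.10, logical(1)))
  }, logical(1))
  expect_identical(rownames(filter_genes(m, groups = grp)),
                   rownames(m)[brute])
})

test_that("cpm_log2 is scale-invariant and matches a hand-computed oracle", {
  counts <- matrix(c(100, 900, 0, 50, 150, 300), 3, 2)
  out <- cpm_log2(counts)
  lib <- colSums(counts)
  oracle <- log2(t(t(counts) / lib) * 1e6 + 1)
  expect_equal(out, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # count 100 at libsize 1e6 -> log2(100 + 1)
  one <- matrix(c(100, 1e6 - 100), 2, 1)
  expect_equal(cpm_log2(one)[1, 1], log2(101))
  # doubling all counts of a sample leaves CPM unchanged
  expect_equal(cpm_log2(counts * 2), out, ignore_attr = TRUE)
})

test_that("junction filtering keeps the stated support boundary", {
  n <- 20
  jm <- data.frame(chrom = "chr1", intron_start = c(100, 100, 300),
                   intron_end = c(200, 250, 400), strand = "+",
                   junction_id = c("j1", "j2", "j3"))
  cnt <- rbind(
    c(rep(5, 2), rep(0, 18)),   # 5 reads in ceil(0.1 * 20) = 2 samples
    rep(0, n),                  # all zero
    rep(10, n)
  )
  out <- filter_junctions(jm, cnt)
  expect_setequal(out$junctions$junction_id, c("j1", "j3"))

  set.seed(7)
  cnt2 <- matrix(rpois(40 * n, 2), 40, n)
  jm2 <- data.frame(chrom = "chr1", intron_start = 1:40 * 10,
                    intron_end = 1:40 * 10 + 5, strand = "+",
                    junction_id = paste0("r", 1:40))
  brute <- vapply(1:40, function(i)
    sum(cnt2[i, ] >= 5) >= ceiling(0.1 * n), logical(1))
  expect_identical(filter_junctions(jm2, cnt2)$junctions$junction_id,
                   jm2$junction_id[brute])
})

test_that("junction clustering joins shared splice sites and prunes", {
  jm <- data.frame(
    chrom = "chr1",
    intron_start = c(100, 100, 300, 300, 700, 900),
    intron_end   = c(200, 300, 500, 600, 800, 1000 + 600000),
    strand = "+",
    junction_id = paste0("j", 1:6)
  )
  cnt <- matrix(10, 6, 4)
  out <- cluster_junctions(jm, cnt)
  # j1-j2 share a donor; j3-j4 share a donor; j2 and j3 share coordinate
  # 300 but on different site types (acceptor vs donor) -> same site value
  # only joins when the roles coincide; j5 is a singleton; j6 too long
  cl <- split(out$junctions$junction_id, out$junctions$cluster)
  expect_true(any(vapply(cl, function(x) setequal(x, c("j1", "j2")),
                         logical(1))))
  expect_true(any(vapply(cl, function(x) setequal(x, c("j3", "j4")),
                         logical(1))))
  expect_false("j5" %in% unlist(cl))
  expect_false("j6" %in% unlist(cl))

  # low-coverage cluster removed by the total-read rule
  cnt2 <- cnt; cnt2[1:2, ] <- 3   # cluster total 24 < 30
  out2 <- cluster_junctions(jm, cnt2)
  expect_false(any(c("j1", "j2") %in% out2$junctions$junction_id))

  # random toy graph: components equal an independent union-find oracle
  set.seed(13)
  starts <- sample(1:6 * 100, 15, replace = TRUE)
  ends <- starts + sample(1:5 * 50, 15, replace = TRUE)
  jm3 <- data.frame(chrom = "chr1", intron_start = starts,
                    intron_end = ends, strand = "+",
                    junction_id = paste0("x", 1:15))
  jm3 <- jm3[!duplicated(jm3[, c("intron_start", "intron_end")]), ]
  n3 <- nrow(jm3)
  out3 <- cluster_junctions(jm3, matrix(10, n3, 5),
                            min_cluster_reads = 0)
  parent <- seq_len(n3)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n3 - 1)) for (j in (i + 1):n3) {
    if (jm3$intron_start[i] == jm3$intron_start[j] ||
        jm3$intron_end[i] == jm3$intron_end[j]) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n3), find, integer(1))
  oracle_sets <- split(jm3$junction_id, roots)
  oracle_sets <- Filter(function(s) length(s) >= 2, oracle_sets)
  got_sets <- split(out3$junctions$junction_id, out3$junctions$cluster)
  expect_setequal(unname(lapply(got_sets, sort)),
                  unname(lapply(oracle_sets, sort)))
})

test_that("PSI is the within-cluster read fraction with missing for empty totals", {
  jm <- data.frame(chrom = "chr1", intron_start = c(100, 100),
                   intron_end = c(200, 300), strand = "+",
                   junction_id = c("a", "b"))
  cnt <- cbind(c(30, 10), c(0, 0), c(8, 2))
  cl <- cluster_junctions(jm, cnt, min_cluster_reads = 0)
  psi <- compute_psi(cl)
  expect_equal(unname(psi$values[, 1]), c(0.75, 0.25))
  expect_true(all(is.na(psi$values[, 2])))        # total 0 -> missing
  # per-sample PSI sums to 1 within every cluster
  set.seed(4)
  cnt2 <- matrix(rpois(8 * 6, 20), 8, 6)
  jm2 <- data.frame(chrom = "chr1",
                    intron_start = rep(c(1000, 2000), each = 4),
                    intron_end = rep(c(1000, 2000), each = 4) +
                      1:4 * 100,
                    strand = "+", junction_id = paste0("j", 1:8))
  psi2 <- compute_psi(cluster_junctions(jm2, cnt2, min_cluster_reads = 0))
  sums <- rowsum(psi2$values, psi2$anchors$cluster)
  expect_true(all(abs(sums - 1) < 1e-12))
  # invariance to scaling one sample's cluster counts
  cnt3 <- cnt2; cnt3[, 3] <- cnt3[, 3] * 7
  psi3 <- compute_psi(cluster_junctions(jm2, cnt3, min_cluster_reads = 0))
  expect_equal(psi3$values[, 3], psi2$values[, 3])
})

test_that("rank-inverse-normal standardization has the closed form", {
  v <- matrix(c(3, 1, 4, 1.5, 9), 1, 5)
  pm <- phenotype_matrix(v, data.frame(feature = "f", chrom = "chr1",
                                       start = 1, end = 2), "splicing")
  out <- standardize(pm)
  oracle <- qnorm((rank(v[1, ]) - 0.5) / 5)
  expect_equal(unname(out$values[1, ]), oracle)
  expect_equal(mean(out$values), 0, tolerance = 1e-12)
  # monotone-transform invariance
  pm2 <- pm; pm2$values <- exp(pm$values)
  expect_equal(standardize(pm2)$values, out$values, ignore_attr = TRUE)
  # mean ~ 0, sd ~ 1 on random data
  set.seed(1)
  big <- phenotype_matrix(matrix(rnorm(300), 3, 100),
                          data.frame(feature = paste0("f", 1:3),
                                     chrom = "chr1", start = 1, end = 2),
                          "splicing")
  sb <- standardize(big)
  expect_true(all(abs(rowMeans(sb$values)) < 1e-10))
  expect_true(all(abs(apply(sb$values, 1, sd) - 1) < 0.05))
})

test_that("batch adjustment removes location and scale structure", {
  set.seed(6)
  batches <- rep(c("b1", "b2"), each = 40)
  x <- rnorm(80)
  x[batches == "b2"] <- x[batches == "b2"] + 1
  pm <- phenotype_matrix(rbind(x), data.frame(feature = "f",
        chrom = "chr1", start = 1, end = 2), "expression")
  adj <- batch_adjust(pm, batches)
  d <- mean(adj$values[1, batches == "b1"]) -
       mean(adj$values[1, batches == "b2"])
  expect_lt(abs(d), 1e-10)
  # single batch: identity up to centering structure (values unchanged
  # except for the restored grand mean, so sd preserved)
  one <- batch_adjust(pm, rep("b1", 80))
  expect_equal(one$values[1, ] - mean(one$values[1, ]),
               pm$values[1, ] - mean(pm$values[1, ]), tolerance = 1e-12)
  # planted batch offsets leave residual batch R^2 < 0.01 (ANOVA oracle)
  y <- rnorm(80) + 2 * (batches == "b2")
  pm2 <- phenotype_matrix(rbind(y), pm$anchors, "expression")
  adj2 <- batch_adjust(pm2, batches)
  fit <- anova(lm(adj2$values[1, ] ~ batches))
  r2 <- fit$`Sum Sq`[1] / sum(fit$`Sum Sq`)
  expect_lt(r2, 0.01)
})

test_that("phenotype PCs match an eigendecomposition oracle up to sign", {
  set.seed(8)
  n <- 30
  scores_true <- rnorm(n)
  vals <- outer(c(1, 2, 3, -1), scores_true) + rnorm(4 * n, sd = 0.01)
  pm <- phenotype_matrix(vals, data.frame(feature = paste0("f", 1:4),
        chrom = "chr1", start = 1, end = 2), "expression")
  pcs <- phenotype_pcs(pm, 2)
  # rank-1 signal: PC1 dominates
  x <- t(scale(t(vals)))
  sv <- svd(scale(t(x), scale = FALSE))
  expect_gt(sv$d[1]^2 / sum(sv$d^2), 0.999)
  expect_equal(abs(cor(pcs[, 1], sv$u[, 1] * sv$d[1])), 1,
               tolerance = 1e-6)
  expect_error(phenotype_pcs(pm, 10), "rank")
})
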