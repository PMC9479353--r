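#' Credible-set coverage under the single-causal model
#'
#' Simulates loci of `m` variants with block LD (dosage correlation
#' `rho^|i-j|`), one causal variant with lead z non-centrality `ncp`,
#' z-scores from the standard multivariate-normal summary-statistic
#' model, and measures how often the true causal variant falls inside
#' the credible set built at `level`.
#'
#' @param n_loci number of simulated loci (default 1000).
#' @param m variants per locus (default 100).
#' @param rho adjacent-variant dosage correlation (default 0.9).
#' @param ncp non-centrality of the causal z-score (default 6).
#' @param level credible level (default 0.95).
#' @param n_gwas,freq GWAS sample size and allele frequency used to
#'   back-fill beta/se from z.
#' @param W effect prior variance for the Wakefield ABF.
#' @param seed integer seed.
#' @return list: `coverage` (fraction of loci containing the causal),
#'   `mc_se` (Monte-Carlo standard error), `n_loci`, `mean_set_size`.
#' @export
credset_coverage <- function(n_loci = 1000, m = 100, rho = 0.9, ncp = 6,
                             level = 0.95, n_gwas = 50000, freq = 0.3,
                             W = 0.04, seed = 1L) {
  set.seed(sub_seed(seed, "credset_coverage"))
  R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  ch <- chol(R)
  se <- 1 / sqrt(2 * freq * (1 - freq) * n_gwas)
  hit <- logical(n_loci)
  sizes <- integer(n_loci)
  for (i in seq_len(n_loci)) {
    causal <- sample.int(m, 1)
    z <- R[, causal] * ncp + drop(crossprod(ch, stats::rnorm(m)))
    cpp <- single_causal_posteriors(z * se, rep(se, m), W)
    cs <- credible_set_95(cpp, ids = as.character(seq_len(m)),
                          pos = seq_len(m), level = level)
    hit[i] <- as.character(causal) %in% cs$id[cs$in_credible_set]
    sizes[i] <- sum(cs$in_credible_set)
  }
  cov <- mean(hit)
  list(coverage = cov, mc_se = sqrt(cov * (1 - cov) / n_loci),
       n_loci = n_loci, mean_set_size = mean(sizes))
}

#' Realized false discovery proportion of the discovery procedure
#'
#' Simulates `n_features` cis windows (one LD block of `block_size`
#' variants each) for `n_samples` samples; `n_effect` features carry a
#' planted additive effect of `beta` phenotype-SD per alt allele at a
#' variant with MAF at least `maf_min`; the rest are null. The full
#' discovery procedure is run per feature (permutation pass with `B`
#' permutations, beta-approximated empirical p-values, Storey q-values)
#' and the realized false discovery proportion among features called at
#' `q <= fdr` is returned.
#'
#' @param n_features,n_effect,n_samples,B,beta,fdr study conditions
#'   (defaults: 1000 features, 200 effects of 0.8 SD, 300 samples, 1000
#'   permutations, FDR 0.01).
#' @param block_size variants per feature window (default 10).
#' @param rho within-block haplotype correlation (default 0.9).
#' @param maf_min,maf_max MAF range of simulated variants (default
#'   0.2-0.5 so planted effects sit at MAF >= 0.2).
#' @param seed integer seed.
#' @return list: `fdp` (realized false discovery proportion), `n_called`,
#'   `n_false`, `power` (fraction of planted effects called).
#' @export
fdr_calibration <- function(n_features = 1000, n_effect = 200,
                            n_samples = 300, B = 1000, beta = 0.8,
                            fdr = 0.01, block_size = 10, rho = 0.9,
                            maf_min = 0.2, maf_max = 0.5, seed = 1L) {
  set.seed(sub_seed(seed, "fdr_calibration"))
  n <- n_samples
  is_effect <- rep(c(TRUE, FALSE), c(n_effect, n_features - n_effect))
  p_best <- p_perm_mat <- NULL
  res <- vector("list", n_features)
  for (f in seq_len(n_features)) {
    p <- stats::runif(1, maf_min, maf_max)
    hap <- matrix(0L, 2 * n, block_size)
    hap[, 1] <- stats::rbinom(2 * n, 1, p)
    for (j in seq_len(block_size)[-1]) {
      prev <- hap[, j - 1]
      pr <- ifelse(prev == 1, p + rho * (1 - p), p * (1 - rho))
      hap[, j] <- stats::rbinom(2 * n, 1, pr)
    }
    G <- hap[1:n, ] + hap[n + 1:n, ]
    causal <- sample.int(block_size, 1)
    y <- stats::rnorm(n) + if (is_effect[f]) beta * G[, causal] else 0
    # permutation pass (no covariates): best |r| observed and per perm
    yc <- y - mean(y)
    Gc <- scale(G, scale = FALSE)
    sds <- sqrt(colSums(Gc^2))
    ok <- sds > 0
    Gs <- sweep(Gc[, ok, drop = FALSE], 2, sds[ok], "/")
    sy <- sqrt(sum(yc^2))
    df <- n - 2
    r2p <- function(r) {
      r <- pmin(abs(r), 1)
      tv <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
      pmax(2 * stats::pt(-tv, df), .Machine$double.xmin)
    }
    pb <- min(r2p(drop(crossprod(Gs, yc)) / sy))
    P <- matrix(yc[replicate(B, sample.int(n))], n, B)
    pp <- r2p(apply(abs(crossprod(P, Gs)), 2, max) / sy)
    fit <- beta_mle(pp)
    res[[f]] <- c(p_beta = min(max(stats::pbeta(pb, fit$a, fit$b),
                                   .Machine$double.xmin), 1 - 1e-16))
  }
  p_beta <- vapply(res, `[[`, numeric(1), "p_beta")
  q <- storey_qvalues(p_beta)$q
  called <- q <= fdr
  n_false <- sum(called & !is_effect)
  list(
    fdp = if (any(called)) n_false / sum(called) else 0,
    n_called = sum(called), n_false = n_false,
    power = mean(called[is_effect])
  )
}
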