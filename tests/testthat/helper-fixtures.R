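# Fixtures and independent oracles shared across the suite.

# quick genotype_matrix from a dosage matrix (samples x variants)
make_g <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  genotype_matrix(
    dosage,
    data.frame(
      id = paste0("v", seq_len(m)),
      chrom = if (is.null(chrom)) rep("chr1", m) else chrom,
      pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
      ref = "A", alt = "G", stringsAsFactors = FALSE
    )
  )
}

# HWE exact-test oracle: direct log-factorial evaluation of the
# conditional probability of each heterozygote count given allele counts
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  m <- 2 * min(n0, n2) + n1                 # minor allele count
  if (m == 0) return(1)
  hets <- seq(m %% 2, min(m, 2 * n - m), by = 2)
  logp <- vapply(hets, function(h) {
    minhom <- (m - h) / 2
    majhom <- n - h - minhom
    lgamma(n + 1) - lgamma(majhom + 1) - lgamma(h + 1) -
      lgamma(minhom + 1) + h * log(2) +
      lgamma(m + 1) + lgamma(2 * n - m + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n1, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Storey q-value oracle: literal double loop over the definition
storey_oracle <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(max(sum(p > lambda) / ((1 - lambda) * m), 1 / m), 1)
  rk <- rank(p, ties.method = "max")
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) cand <- min(cand, m * p[j] / rk[j])
    }
    q[i] <- min(pi0 * cand, 1)
  }
  q
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
ranksum_exact_oracle <- function(x, y) {
  vals <- c(x, y)
  r <- rank(vals)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(vals), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# brute-force per-base annotation labeling over a toy region
label_bases <- function(iv, chrom, len) {
  lab <- logical(len)
  sel <- iv$chrom == chrom
  for (i in which(sel)) {
    b <- seq(iv$start[i] + 1L, iv$end[i])
    lab[b[b >= 1 & b <= len]] <- TRUE
  }
  lab
}
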