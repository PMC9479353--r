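#' Cis-window around a feature anchor
#'
#' Expression features are tested within TSS +/- 500 kb; splicing features
#' within the junction interval +/- 50 kb. Windows are clipped at position
#' 1 (and at `chrom_len` when supplied).
#'
#' @param anchor one-row data.frame with `chrom`, `start`, `end`.
#' @param kind "expression" or "splicing".
#' @param window_e,window_s half-widths in bp.
#' @param chrom_len optional chromosome length for right clipping.
#' @return list `(chrom, start, end)` in 1-based inclusive coordinates.
#' @export
cis_window <- function(anchor, kind, window_e = 500000, window_s = 50000,
                       chrom_len = NULL) {
  kind <- match.arg(kind, c("expression", "splicing"))
  w <- if (kind == "expression") window_e else window_s
  lo <- max(1, anchor$start - w)
  hi <- anchor$end + w
  if (!is.null(chrom_len)) hi <- min(hi, chrom_len)
  list(chrom = anchor$chrom, start = lo, end = hi)
}

## internal: orthonormal basis of [1 | covariates] for residualization
cov_basis <- function(n, cov = NULL) {
  x <- cbind(rep(1, n), cov)
  q <- qr(x)
  if (q$rank < ncol(x))
    x <- x[, q$pivot[seq_len(q$rank)], drop = FALSE]
  qr.Q(qr(x))
}

## internal: residualize columns of x on the basis Q
resid_on <- function(x, Q) x - Q %*% crossprod(Q, x)

## internal: variants of g inside a window; returns indices
window_variants <- function(g, win) {
  which(g$variants$chrom == win$chrom &
        g$variants$pos >= win$start & g$variants$pos <= win$end)
}

#' Nominal cis association scan for one feature
#'
#' The phenotype and every dosage column are residualized on the covariates
#' (plus intercept); slope, t and two-sided p come from the simple
#' regression of the residuals with `df = n - n_cov - 2`, which equals the
#' full multiple regression by the Frisch-Waugh theorem. Missing dosages
#' are mean-imputed inside the computation only.
#'
#' @param pm a [phenotype_matrix] (standardized).
#' @param g a [genotype_matrix].
#' @param cov samples x covariates matrix or `NULL`.
#' @param feature feature id.
#' @param window_e,window_s cis-window half-widths (bp).
#' @return data.frame of class `nominal_assoc`: `feature`, `variant`,
#'   `pos`, `slope`, `se`, `t`, `p`; zero-variance variants are skipped
#'   (attribute `n_skipped`).
#' @export
nominal_scan <- function(pm, g, cov = NULL, feature,
                         window_e = 500000, window_s = 50000) {
  stopifnot(inherits(pm, "phenotype_matrix"), inherits(g, "genotype_matrix"))
  fi <- match(feature, pm$anchors$feature)
  if (is.na(fi)) stop("unknown feature: ", feature)
  n <- ncol(pm$values)
  n_cov <- if (is.null(cov)) 0 else ncol(cov)
  if (n - n_cov - 2 < 10) stop("too few samples beyond covariates")
  win <- cis_window(pm$anchors[fi, ], pm$kind, window_e, window_s)
  vi <- window_variants(g, win)
  if (!length(vi)) {
    out <- data.frame(feature = character(0), variant = character(0),
                      pos = integer(0), slope = numeric(0),
                      se = numeric(0), t = numeric(0), p = numeric(0))
    attr(out, "n_skipped") <- 0L
    class(out) <- c("nominal_assoc", "data.frame")
    return(out)
  }
  y <- pm$values[fi, ]
  y[is.na(y)] <- mean(y, na.rm = TRUE)
  Q <- cov_basis(n, cov)
  yr <- drop(resid_on(matrix(y), Q))
  G <- impute_mean_cols(g$dosage[, vi, drop = FALSE])
  sds <- apply(G, 2, stats::sd)
  skip <- sds == 0
  Gr <- resid_on(G[, !skip, drop = FALSE], Q)
  df <- n - n_cov - 2
  sy <- sqrt(sum(yr^2))
  sx <- sqrt(colSums(Gr^2))
  r <- drop(crossprod(Gr, yr)) / (sx * sy)
  r <- pmin(pmax(r, -1), 1)
  tval <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  slope <- r * sy / sx
  se <- slope / tval
  se[tval == 0] <- sy / sx[tval == 0] / sqrt(df)
  out <- data.frame(
    feature = feature, variant = g$variants$id[vi][!skip],
    pos = g$variants$pos[vi][!skip],
    slope = slope, se = se, t = tval,
    p = pmax(2 * stats::pt(-abs(tval), df), .Machine$double.xmin),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(skip)
  class(out) <- c("nominal_assoc", "data.frame")
  out
}

## internal: maximum-likelihood Beta fit with method-of-moments start.
## Newton iterations on (log a, log b); falls back to moments on failure.
beta_mle <- function(x, max_iter = 100, tol = 1e-8) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x); v <- stats::var(x)
  v <- min(v, m * (1 - m) * 0.999)
  a <- m * (m * (1 - m) / v - 1)
  b <- (1 - m) * (m * (1 - m) / v - 1)
  a <- max(a, 1e-3); b <- max(b, 1e-3)
  mom <- c(a = a, b = b)
  n <- length(x)
  slx <- sum(log(x)); sl1x <- sum(log1p(-x))
  th <- log(c(a, b))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    a <- exp(th[1]); b <- exp(th[2])
    dga <- digamma(a); dgb <- digamma(b); dgab <- digamma(a + b)
    ga <- n * (dgab - dga) + slx          # d loglik / d a
    gb <- n * (dgab - dgb) + sl1x
    grad <- c(ga * a, gb * b)             # chain rule to log scale
    tga <- trigamma(a); tgb <- trigamma(b); tgab <- trigamma(a + b)
    haa <- n * (tgab - tga) * a^2 + ga * a
    hbb <- n * (tgab - tgb) * b^2 + gb * b
    hab <- n * tgab * a * b
    H <- matrix(c(haa, hab, hab, hbb), 2, 2)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    th_new <- th - step
    th_new <- pmin(pmax(th_new, -10), 15)
    if (max(abs(th_new - th)) < tol) { th <- th_new; converged <- TRUE; break }
    th <- th_new
  }
  if (!converged || any(!is.finite(exp(th))))
    return(list(a = mom[["a"]], b = mom[["b"]], converged = FALSE))
  list(a = exp(th[1]), b = exp(th[2]), converged = TRUE)
}

#' Permutation pass with beta approximation for one feature
#'
#' The covariate-residualized phenotype is permuted `B` times (genotypes
#' and covariates fixed); the best nominal p-value of each permutation is
#' recorded. The empirical p-value is `(r + 1) / (B + 1)` where `r` counts
#' permutations whose best p is at most the observed best p, and a
#' Beta(a, b) distribution fitted to the permutation minima by maximum
#' likelihood interpolates beyond the permutation resolution:
#' `p_beta = BetaCDF(p_nominal_best; a, b)`.
#'
#' @inheritParams nominal_scan
#' @param B number of permutations (>= 100; default 1000).
#' @param seed master seed; the feature's permutation stream is derived
#'   from it and the feature id, so results are stable under feature
#'   subsetting.
#' @return one-row data.frame of class `perm_result`: `feature`,
#'   `n_variants`, `lead`, `slope`, `p_nominal_best`, `p_empirical`,
#'   `beta_a`, `beta_b`, `p_beta`, `mle_converged`. Features with no
#'   testable variant return `NA` statistics (flagged `degenerate`).
#' @export
permutation_pass <- function(pm, g, cov = NULL, feature, B = 1000,
                             seed = 1L, window_e = 500000,
                             window_s = 50000) {
  stopifnot(B >= 100)
  fi <- match(feature, pm$anchors$feature)
  if (is.na(fi)) stop("unknown feature: ", feature)
  n <- ncol(pm$values)
  n_cov <- if (is.null(cov)) 0 else ncol(cov)
  df <- n - n_cov - 2
  win <- cis_window(pm$anchors[fi, ], pm$kind, window_e, window_s)
  vi <- window_variants(g, win)
  G <- impute_mean_cols(g$dosage[, vi, drop = FALSE])
  sds <- apply(G, 2, stats::sd)
  vi <- vi[sds > 0]
  G <- G[, sds > 0, drop = FALSE]
  degen <- length(vi) == 0
  if (degen) {
    out <- data.frame(feature = feature, n_variants = 0L,
                      lead = NA_character_, slope = NA_real_,
                      p_nominal_best = NA_real_, p_empirical = NA_real_,
                      beta_a = NA_real_, beta_b = NA_real_,
                      p_beta = NA_real_, mle_converged = NA,
                      degenerate = TRUE, stringsAsFactors = FALSE)
    class(out) <- c("perm_result", "data.frame")
    return(out)
  }
  y <- pm$values[fi, ]
  y[is.na(y)] <- mean(y, na.rm = TRUE)
  Q <- cov_basis(n, cov)
  yr <- drop(resid_on(matrix(y), Q))
  Gr <- resid_on(G, Q)
  Gs <- sweep(Gr, 2, sqrt(colSums(Gr^2)), "/")    # unit columns
  sy <- sqrt(sum(yr^2))
  robs <- drop(crossprod(Gs, yr)) / sy
  r2p <- function(r) {
    r <- pmin(abs(r), 1)
    tv <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    pmax(2 * stats::pt(-tv, df), .Machine$double.xmin)
  }
  p_obs <- r2p(robs)
  best_i <- order(p_obs, g$variants$pos[vi], g$variants$id[vi])[1]
  p_best <- p_obs[best_i]
  sx_lead <- sqrt(sum(Gr[, best_i]^2))
  slope <- robs[best_i] * sy / sx_lead
  set.seed(sub_seed(seed, paste0("perm::", feature)))
  P <- replicate(B, yr[sample.int(n)])            # n x B permuted residuals
  Rp <- crossprod(P, Gs) / sy                     # B x (#variants) corr
  best_r <- apply(abs(Rp), 1, max)
  p_perm <- r2p(best_r)
  r_count <- sum(p_perm <= p_best)
  p_emp <- (r_count + 1) / (B + 1)
  fit <- beta_mle(p_perm)
  p_beta <- stats::pbeta(p_best, fit$a, fit$b)
  p_beta <- min(max(p_beta, .Machine$double.xmin), 1 - 1e-16)
  out <- data.frame(
    feature = feature, n_variants = length(vi),
    lead = g$variants$id[vi][best_i], slope = slope,
    p_nominal_best = p_best, p_empirical = p_emp,
    beta_a = fit$a, beta_b = fit$b, p_beta = p_beta,
    mle_converged = fit$converged, degenerate = FALSE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("perm_result", "data.frame")
  out
}

#' Permutation pass over all features
#'
#' Runs [permutation_pass] for every feature of the phenotype matrix and
#' attaches Storey q-values and per-feature nominal thresholds (see
#' [storey_qvalues], [genomewide_threshold_pt],
#' [nominal_threshold_per_feature]). Degenerate features (no testable
#' cis variant) are reported with `q = 1`.
#'
#' @inheritParams permutation_pass
#' @param fdr FDR level for the genome-wide threshold (default 0.01).
#' @return `perm_result` data.frame, one row per feature, with `q` and
#'   `nominal_threshold` columns; `pt` and `pi0` attached as attributes.
#' @export
permutation_pass_all <- function(pm, g, cov = NULL, B = 1000, seed = 1L,
                                 window_e = 500000, window_s = 50000,
                                 fdr = 0.01) {
  rows <- lapply(pm$anchors$feature, function(f)
    permutation_pass(pm, g, cov, f, B = B, seed = seed,
                     window_e = window_e, window_s = window_s))
  res <- do.call(rbind, rows)
  ok <- !res$degenerate
  res$q <- NA_real_
  st <- storey_qvalues(res$p_beta[ok])
  res$q[ok] <- st$q
  res$q[!ok] <- 1
  pt <- genomewide_threshold_pt(res[ok, , drop = FALSE], fdr = fdr)
  res$nominal_threshold <- NA_real_
  res$nominal_threshold[ok] <- nominal_threshold_per_feature(
    pt, res$beta_a[ok], res$beta_b[ok])
  attr(res, "pt") <- pt
  attr(res, "pi0") <- st$pi0
  class(res) <- c("perm_result", "data.frame")
  res
}

#' Storey q-values with fixed lambda
#'
#' `pi0 = #\{p > lambda\} / ((1 - lambda) m)` clipped to (0, 1];
#' `q_i = pi0 * min_\{j: p_j >= p_i\} (m p_j / rank_j)`. With `pi0 = 1`
#' this reduces to Benjamini-Hochberg.
#'
#' @param p vector of p-values.
#' @param lambda tuning constant for the null-proportion estimate
#'   (default 0.5).
#' @return list `(q, pi0)`; `q` in the input order.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  m <- length(p)
  if (m == 0) return(list(q = numeric(0), pi0 = 1))
  pi0 <- sum(p > lambda) / ((1 - lambda) * m)
  pi0 <- min(max(pi0, 1 / m), 1)
  ord <- order(p)
  q_ord <- pi0 * m * p[ord] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q <- numeric(m)
  q[ord] <- pmin(q_ord, 1)
  list(q = q, pi0 = pi0)
}

#' Genome-wide empirical p-value threshold
#'
#' The beta-approximated empirical p-value of the feature whose q-value is
#' closest to the FDR level (ties broken toward the smaller p).
#'
#' @param perm `perm_result` data.frame with `p_beta` and `q`.
#' @param fdr FDR level (default 0.01).
#' @return scalar threshold `pt`.
#' @export
genomewide_threshold_pt <- function(perm, fdr = 0.01) {
  stopifnot(nrow(perm) >= 1)
  if (!("q" %in% names(perm)))
    perm$q <- storey_qvalues(perm$p_beta)$q
  d <- abs(perm$q - fdr)
  i <- order(d, perm$p_beta)[1]
  perm$p_beta[i]
}

#' Per-feature nominal p-value threshold
#'
#' Back-transforms the genome-wide empirical threshold through each
#' feature's fitted beta distribution: `BetaInverseCDF(pt; a, b)`.
#'
#' @param pt genome-wide threshold from [genomewide_threshold_pt].
#' @param beta_a,beta_b fitted shape parameters.
#' @return nominal p-value cutoffs.
#' @export
nominal_threshold_per_feature <- function(pt, beta_a, beta_b) {
  stats::qbeta(pt, beta_a, beta_b)
}

#' Call significant features and nominal variant-feature pairs
#'
#' Features with `q <= fdr` are significant; their nominally significant
#' pairs are the window variants with p at or below the feature's nominal
#' threshold. The lead is the smallest nominal p (ties: smaller position,
#' then id).
#'
#' @param perm `perm_result` table from [permutation_pass_all].
#' @param nominal list of `nominal_assoc` tables (or one rbind-ed table)
#'   covering the significant features.
#' @param fdr significance level on q (default 0.01).
#' @return list of class `qtl_callset`: `significant` (perm rows),
#'   `pairs` (nominal associations passing thresholds).
#' @export
call_significant <- function(perm, nominal, fdr = 0.01) {
  if (is.list(nominal) && !is.data.frame(nominal))
    nominal <- do.call(rbind, nominal)
  sig <- perm[!is.na(perm$q) & perm$q <= fdr & !perm$degenerate, ,
              drop = FALSE]
  thr <- stats::setNames(sig$nominal_threshold, sig$feature)
  pairs <- nominal[nominal$feature %in% sig$feature, , drop = FALSE]
  pairs <- pairs[pairs$p <= thr[pairs$feature], , drop = FALSE]
  # recompute leads from the nominal table with the documented tie-break
  if (nrow(pairs)) {
    ord <- order(pairs$feature, pairs$p, pairs$pos, pairs$variant)
    lead_rows <- pairs[ord, ][!duplicated(pairs$feature[ord]), ]
    sig$lead <- lead_rows$variant[match(sig$feature, lead_rows$feature)]
  }
  rownames(pairs) <- NULL
  structure(list(significant = sig, pairs = pairs), class = "qtl_callset")
}

#' Delta-PSI for significant splice junctions
#'
#' For each junction, the difference in median raw PSI between
#' homozygous-alternate and homozygous-reference samples at the lead
#' variant; when no homozygous-alternate samples exist, the heterozygote
#' median substitutes. Within each cluster only the junction with the best
#' q-value is reported.
#'
#' @param psi_raw [phenotype_matrix] of raw (unstandardized) PSI.
#' @param g a [genotype_matrix].
#' @param perm `perm_result` table with `q` (splicing features).
#' @param callset optional [call_significant] output restricting to
#'   significant junctions.
#' @return data.frame: `feature`, `cluster`, `lead`, `q`, `delta_psi`,
#'   `group_alt` ("homalt" or "het").
#' @export
delta_psi <- function(psi_raw, g, perm, callset = NULL) {
  stopifnot(inherits(psi_raw, "phenotype_matrix"))
  tab <- perm[!perm$degenerate, , drop = FALSE]
  if (!is.null(callset))
    tab <- tab[tab$feature %in% callset$significant$feature, , drop = FALSE]
  tab <- merge(tab, psi_raw$anchors[, c("feature", "cluster")],
               by = "feature")
  # best q per cluster
  tab <- tab[order(tab$cluster, tab$q, tab$p_beta), , drop = FALSE]
  tab <- tab[!duplicated(tab$cluster), , drop = FALSE]
  out <- lapply(seq_len(nrow(tab)), function(i) {
    f <- tab$feature[i]
    dos <- g$dosage[, match(tab$lead[i], g$variants$id)]
    psi <- psi_raw$values[match(f, psi_raw$anchors$feature), ]
    m0 <- stats::median(psi[!is.na(dos) & dos == 0], na.rm = TRUE)
    has_homalt <- any(dos == 2, na.rm = TRUE)
    m2 <- if (has_homalt) stats::median(psi[!is.na(dos) & dos == 2],
                                        na.rm = TRUE)
          else stats::median(psi[!is.na(dos) & dos == 1], na.rm = TRUE)
    data.frame(feature = f, cluster = tab$cluster[i], lead = tab$lead[i],
               q = tab$q[i], delta_psi = m2 - m0,
               group_alt = if (has_homalt) "homalt" else "het",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare sQTL and eQTL signals per gene
#'
#' For genes carrying both a significant sQTL and a significant eQTL,
#' reports the LD r-squared between the two lead variants (1 Mb window)
#' and classifies the pair as independent when r2 < `r2_indep`; also
#' reports the fraction of nominally significant variants shared.
#'
#' @param sqtl_calls,eqtl_calls [call_significant] outputs.
#' @param feature_gene data.frame `(feature, gene)` mapping splicing
#'   features (and expression features) to genes.
#' @param g a [genotype_matrix].
#' @param r2_indep independence threshold (default 0.6).
#' @return data.frame per gene: leads, `r2`, `independent`,
#'   `frac_shared_nominal`.
#' @export
compare_sqtl_eqtl <- function(sqtl_calls, eqtl_calls, feature_gene, g,
                              r2_indep = 0.6) {
  sg <- merge(sqtl_calls$significant, feature_gene, by = "feature")
  eg <- merge(eqtl_calls$significant, feature_gene, by = "feature")
  genes <- intersect(sg$gene, eg$gene)
  out <- lapply(genes, function(gn) {
    s <- sg[sg$gene == gn, ][1, ]      # best junction listed first upstream
    e <- eg[eg$gene == gn, ][1, ]
    r2 <- unname(ld_r2(g, s$lead, window_bp = 1e6)[e$lead])
    if (is.null(r2) || is.na(r2)) r2 <- 0
    sv <- sqtl_calls$pairs$variant[
      sqtl_calls$pairs$feature %in% sg$feature[sg$gene == gn]]
    ev <- eqtl_calls$pairs$variant[
      eqtl_calls$pairs$feature %in% eg$feature[eg$gene == gn]]
    shared <- if (length(sv)) mean(sv %in% ev) else NA_real_
    data.frame(gene = gn, lead_sqtl = s$lead, lead_eqtl = e$lead, r2 = r2,
               independent = r2 < r2_indep, frac_shared_nominal = shared,
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(gene = character(), lead_sqtl = character(),
                      lead_eqtl = character(), r2 = numeric(),
                      independent = logical(),
                      frac_shared_nominal = numeric()))
  do.call(rbind, out)
}
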