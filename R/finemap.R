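#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` and a N(0, W) effect
#' prior, the approximate Bayes factor against the point null is
#' `log ABF = 0.5 log(1 - r) + 0.5 r z^2` with `r = W / (W + se^2)` and
#' `z = beta / se`. `W = 0` returns 0 (prior mass at the null).
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), positive.
#' @param W prior variance of the effect (default `0.2^2`).
#' @return log ABF, vectorized.
#' @export
wakefield_abf <- function(beta, se, W = 0.04) {
  stopifnot(all(se > 0), W >= 0)
  r <- W / (W + se^2)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * r * z^2
}

#' Single-causal-variant posterior probabilities
#'
#' Under the restriction of exactly one causal variant per locus with a
#' uniform prior over variants, the posterior probability that variant j
#' is causal (its CPP) is its ABF normalized over the locus.
#'
#' @param beta,se per-variant effect estimates and standard errors.
#' @param W effect prior variance (default 0.04: effect SD 0.2 on a
#'   standardized trait).
#' @return numeric vector of CPPs summing to 1.
#' @export
single_causal_posteriors <- function(beta, se, W = 0.04) {
  labf <- wakefield_abf(beta, se, W)
  w <- exp(labf - max(labf))
  w / sum(w)
}

#' Minimal 95% credible set
#'
#' Variants sorted by descending CPP (ties broken by genomic position);
#' the credible set is the smallest prefix whose cumulative CPP reaches
#' the level, including the crossing variant.
#'
#' @param cpp per-variant posterior probabilities (should sum to 1).
#' @param ids variant ids.
#' @param pos genomic positions (tie-break).
#' @param level credible level (default 0.95).
#' @return data.frame of class `credible_set`: `id`, `pos`, `cpp`,
#'   `in_credible_set`, sorted by descending CPP; the lead (max CPP) is
#'   row 1.
#' @export
credible_set_95 <- function(cpp, ids, pos = seq_along(cpp), level = 0.95) {
  stopifnot(length(cpp) == length(ids), abs(sum(cpp) - 1) < 1e-6)
  ord <- order(-cpp, pos)
  cum <- cumsum(cpp[ord])
  k <- which(cum >= level)[1]
  if (is.na(k)) k <- length(cpp)
  out <- data.frame(id = ids[ord], pos = pos[ord], cpp = cpp[ord],
                    in_credible_set = seq_along(ord) <= k,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("credible_set", "data.frame")
  out
}

#' Fine-map a locus from summary statistics
#'
#' Convenience wrapper: Wakefield ABFs, single-causal posteriors and the
#' 95% credible set from a `gwas_summary` slice.
#'
#' @param stats `gwas_summary` rows for one locus.
#' @param W effect prior variance.
#' @param level credible level.
#' @return a `credible_set` with a `logabf` column.
#' @export
finemap_locus <- function(stats, W = 0.04, level = 0.95) {
  cpp <- single_causal_posteriors(stats$beta, stats$se, W)
  cs <- credible_set_95(cpp, stats$id, stats$pos, level)
  cs$logabf <- wakefield_abf(stats$beta, stats$se, W)[match(cs$id, stats$id)]
  cs
}

#' Conditional z-scores from summary statistics
#'
#' Conditions each variant's z-score on a set C of variants using the LD
#' correlation matrix:
#' `z_cond_j = (z_j - R_jC R_CC^{-1} z_C) / sqrt(1 - R_jC R_CC^{-1} R_Cj)`.
#' Variants whose denominator falls below `collinear_tol` (including the
#' conditioning variants themselves) are flagged collinear and get no
#' conditional z.
#'
#' @param z named z-score vector over the locus.
#' @param R LD correlation matrix (dimnames matching `z` names).
#' @param cond_ids ids of the conditioning set C.
#' @param collinear_tol denominator threshold (default 0.05).
#' @param ridge_eps ridge added to R_CC when singular (default 1e-6).
#' @return data.frame: `id`, `z`, `z_cond`, `collinear`.
#' @export
conditional_z <- function(z, R, cond_ids, collinear_tol = 0.05,
                          ridge_eps = 1e-6) {
  ids <- names(z)
  stopifnot(!is.null(ids), all(cond_ids %in% ids),
            all(ids %in% rownames(R)))
  R <- R[ids, ids]
  Rcc <- R[cond_ids, cond_ids, drop = FALSE]
  sol <- tryCatch(solve(Rcc), error = function(e) NULL)
  if (is.null(sol))
    sol <- solve(Rcc + diag(ridge_eps, nrow(Rcc)))
  Rjc <- R[, cond_ids, drop = FALSE]
  adj <- Rjc %*% sol
  num <- z - drop(adj %*% z[cond_ids])
  den2 <- 1 - rowSums(adj * Rjc)
  den <- sqrt(pmax(den2, 0))
  collinear <- den < collinear_tol | ids %in% cond_ids
  data.frame(
    id = ids, z = unname(z),
    z_cond = ifelse(collinear, NA_real_, num / den),
    collinear = collinear, stringsAsFactors = FALSE
  )
}
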