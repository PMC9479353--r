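## internal: ridge solve (X'X + lambda I)^{-1} X'y on centered data
ridge_fit <- function(X, y, lambda) {
  p <- ncol(X)
  drop(solve(crossprod(X) + diag(lambda, p), crossprod(X, y)))
}

## internal: lambda by generalized cross-validation over a grid
ridge_gcv <- function(X, y, grid = 10^seq(-3, 4, length.out = 40)) {
  sv <- svd(X)
  d2 <- sv$d^2
  uy <- drop(crossprod(sv$u, y))
  n <- length(y)
  gcv <- vapply(grid, function(l) {
    shrink <- d2 / (d2 + l)
    fit <- sv$u %*% (shrink * uy)
    edf <- sum(shrink)
    sum((y - fit)^2) / (n * (1 - edf / n)^2)
  }, numeric(1))
  grid[which.min(gcv)]
}

#' Fit cis prediction weights with cross-validated model selection
#'
#' Candidate models for predicting a (covariate-residualized) phenotype
#' from cis dosages: `top1` (all weight on the best marginal variant),
#' `ridge` (penalty chosen by generalized cross-validation) and `lasso`
#' (\pkg{glmnet} path, penalty at the CV minimum). The winner is the
#' model with the highest k-fold cross-validated R-squared; features
#' whose best cv R2 is at or below `r2_min` are reported non-heritable.
#'
#' @param y phenotype vector (one feature, all samples).
#' @param G samples x variants dosage matrix for the cis window.
#' @param cov covariate matrix or `NULL`.
#' @param k_folds number of CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param r2_min heritability gate on cv R2 (default 0.01).
#' @return object of class `twas_weights`: list with `variant`, `weight`
#'   (named nonzero weights), `model`, `cv_r2`, `n`, `heritable`; when
#'   non-heritable, `weight` is empty and `heritable` is `FALSE`.
#' @export
fit_weights_cv <- function(y, G, cov = NULL, k_folds = 5, seed = 1L,
                           r2_min = 0.01) {
  G <- impute_mean_cols(as.matrix(G))
  keep <- apply(G, 2, stats::sd) > 0
  if (!any(keep)) stop("no polymorphic variant in window")
  G <- G[, keep, drop = FALSE]
  n <- length(y)
  Q <- cov_basis(n, cov)
  yr <- drop(resid_on(matrix(y), Q))
  Gr <- resid_on(G, Q)
  set.seed(sub_seed(seed, "twas_folds"))
  foldid <- sample(rep_len(seq_len(k_folds), n))
  # separate folds for lasso penalty selection, so the scoring folds
  # stay out of the selection and the null cv R2 is not inflated
  foldid_sel <- sample(rep_len(seq_len(k_folds), n))
  vy <- stats::var(yr)

  cv_r2 <- function(predict_fold) {
    pred <- numeric(n)
    for (f in seq_len(k_folds)) {
      te <- foldid == f
      pred[te] <- predict_fold(which(!te), which(te))
    }
    1 - sum((yr - pred)^2) / ((n - 1) * vy)
  }

  top1_w <- function(X, yy) {
    r <- abs(suppressWarnings(stats::cor(X, yy)))
    r[is.na(r)] <- 0
    j <- which.max(r)
    w <- numeric(ncol(X))
    w[j] <- stats::cov(X[, j], yy) / stats::var(X[, j])
    w
  }
  r2_top1 <- cv_r2(function(tr, te) {
    w <- top1_w(Gr[tr, , drop = FALSE], yr[tr])
    drop(Gr[te, , drop = FALSE] %*% w)
  })
  lam <- ridge_gcv(Gr, yr)
  r2_ridge <- cv_r2(function(tr, te) {
    w <- ridge_fit(Gr[tr, , drop = FALSE], yr[tr], lam)
    drop(Gr[te, , drop = FALSE] %*% w)
  })
  r2_lasso <- -Inf
  lasso_w <- NULL
  if (ncol(Gr) >= 2) {
    cvl <- tryCatch(
      glmnet::cv.glmnet(Gr, yr, foldid = foldid_sel, standardize = TRUE,
                        intercept = FALSE),
      error = function(e) NULL)
    if (!is.null(cvl)) {
      lam_l <- cvl$lambda.min
      # honest out-of-fold R2: refit at the selected penalty per fold
      r2_lasso <- cv_r2(function(tr, te) {
        ft <- glmnet::glmnet(Gr[tr, , drop = FALSE], yr[tr],
                             lambda = lam_l, standardize = TRUE,
                             intercept = FALSE)
        drop(stats::predict(ft, Gr[te, , drop = FALSE]))
      })
      lasso_w <- drop(stats::coef(cvl, s = "lambda.min"))[-1]
    }
  }
  scores <- c(top1 = r2_top1, ridge = r2_ridge, lasso = r2_lasso)
  best <- names(scores)[which.max(scores)]
  if (max(scores) <= r2_min || (best == "lasso" && all(lasso_w == 0)))
    return(structure(list(variant = character(0), weight = numeric(0),
                          model = NA_character_, cv_r2 = max(scores),
                          n = n, heritable = FALSE),
                     class = "twas_weights"))
  w <- switch(best,
    top1 = top1_w(Gr, yr),
    ridge = ridge_fit(Gr, yr, lam),
    lasso = lasso_w
  )
  nz <- w != 0
  structure(list(variant = colnames(G)[nz], weight = unname(w[nz]),
                 model = best, cv_r2 = max(scores), n = n,
                 heritable = TRUE),
            class = "twas_weights")
}

#' TWAS association from summary statistics
#'
#' Combines prediction weights with GWAS z-scores through the LD matrix:
#' `z_twas = w' z / sqrt(w' R w)`, two-sided normal p-value. Invariant to
#' positive rescaling of the weights.
#'
#' @param wts a `twas_weights` object.
#' @param gwas a `gwas_summary` table covering the weight variants.
#' @param R LD correlation matrix covering the weight variants.
#' @param ridge_eps added to the diagonal if `w'Rw` is non-positive.
#' @return list: `z`, `p`, `best_gwas_variant` (largest |z| among weight
#'   variants), `n_variants`.
#' @export
twas_association <- function(wts, gwas, R, ridge_eps = 1e-6) {
  stopifnot(inherits(wts, "twas_weights"), wts$heritable)
  ids <- intersect(wts$variant, gwas$id)
  if (!length(ids)) stop("no weight variant present in GWAS")
  w <- wts$weight[match(ids, wts$variant)]
  z <- gwas$z[match(ids, gwas$id)]
  Rw <- R[ids, ids, drop = FALSE]
  denom2 <- drop(t(w) %*% Rw %*% w)
  if (denom2 <= 0) {
    denom2 <- drop(t(w) %*% (Rw + diag(ridge_eps, length(ids))) %*% w)
    if (denom2 <= 0) stop("non-positive weight variance w'Rw")
  }
  zt <- sum(w * z) / sqrt(denom2)
  list(z = zt, p = 2 * stats::pnorm(-abs(zt)),
       best_gwas_variant = ids[which.max(abs(z))],
       n_variants = length(ids))
}

#' Bonferroni significance for TWAS results
#'
#' @param results data.frame with a `p` column.
#' @param m_tests number of tested features.
#' @return `results` with `threshold` (0.05 / m) and `significant`.
#' @export
twas_significance <- function(results, m_tests) {
  stopifnot(m_tests >= 1)
  results$threshold <- 0.05 / m_tests
  results$significant <- results$p <= results$threshold
  results
}

#' Colocalization gate for TWAS results
#'
#' TWAS associations whose locus lacks a colocalization record, or whose
#' shared-variant posterior falls below `min_pp`, are flagged as failing
#' the gate (retained in the table).
#'
#' @param results data.frame with a `feature` column.
#' @param coloc data.frame with `feature` and `PP4` columns.
#' @param min_pp gate threshold (default 0.6).
#' @return `results` with `coloc_pp4`, `pass_coloc_gate`, `gate_reason`.
#' @export
coloc_gate <- function(results, coloc, min_pp = 0.6) {
  pp <- coloc$PP4[match(results$feature, coloc$feature)]
  results$coloc_pp4 <- pp
  results$pass_coloc_gate <- !is.na(pp) & pp >= min_pp
  results$gate_reason <- ifelse(is.na(pp), "no_coloc",
                                ifelse(pp >= min_pp, "pass", "low_pp"))
  results
}

#' Classify a TWAS locus as known or novel
#'
#' Known when the best GWAS variant is in LD (r2 >= `r2_min`) with any
#' known lead, or lies within `dist_bp` of one; novel otherwise.
#'
#' @param best_variant best GWAS variant id of the TWAS result.
#' @param known_leads ids of known GWAS lead variants.
#' @param g a [genotype_matrix].
#' @param r2_min LD rule threshold (default 0.1).
#' @param dist_bp distance rule threshold (default 500000).
#' @return "known" or "novel".
#' @export
classify_locus <- function(best_variant, known_leads, g, r2_min = 0.1,
                           dist_bp = 500000) {
  vi <- match(best_variant, g$variants$id)
  if (is.na(vi)) stop("unknown variant: ", best_variant)
  ki <- match(intersect(known_leads, g$variants$id), g$variants$id)
  if (!length(ki)) return("novel")
  same <- g$variants$chrom[ki] == g$variants$chrom[vi]
  if (any(same & abs(g$variants$pos[ki] - g$variants$pos[vi]) < dist_bp))
    return("known")
  r2 <- ld_r2(g, best_variant, window_bp = 1e9)
  hit <- r2[g$variants$id[ki]]
  if (any(!is.na(hit) & hit >= r2_min)) "known" else "novel"
}
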