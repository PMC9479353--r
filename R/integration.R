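#' Intersect GWAS credible sets with QTL credible sets
#'
#' At each colocalized locus (colocalization PP above `pp_min`), every
#' GWAS credible-set variant is labeled by membership in the
#' colocalizing QTL credible set: category `in_qtl_credible` or
#' `gwas_only`. A variant appearing in several QTL credible sets keeps
#' its maximum CPP.
#'
#' @param loci list; each element a list with `locus`, `coloc_pp`
#'   (shared-variant posterior), `gwas_cs` (a `credible_set`), and
#'   `qtl_cs` (a `credible_set` or list of them).
#' @param pp_min colocalization threshold (default 0.8, exclusive).
#' @return list of class `integration_records`: per-locus data.frames
#'   with `locus`, `id`, `cpp` (GWAS), `category`, plus summary columns
#'   `n_gwas_credible`, `n_intersection`.
#' @export
intersect_credible_sets <- function(loci, pp_min = 0.8) {
  out <- list()
  for (lc in loci) {
    if (is.na(lc$coloc_pp) || lc$coloc_pp <= pp_min) next
    gcs <- lc$gwas_cs[lc$gwas_cs$in_credible_set, , drop = FALSE]
    qlist <- if (is.data.frame(lc$qtl_cs)) list(lc$qtl_cs) else lc$qtl_cs
    qvars <- unique(unlist(lapply(qlist, function(q)
      q$id[q$in_credible_set])))
    # max CPP across multiple credible sets per variant
    cpp <- tapply(gcs$cpp, gcs$id, max)
    ids <- names(cpp)
    rec <- data.frame(
      locus = lc$locus, id = ids, cpp = as.numeric(cpp),
      category = ifelse(ids %in% qvars, "in_qtl_credible", "gwas_only"),
      stringsAsFactors = FALSE
    )
    rec$n_gwas_credible <- nrow(rec)
    rec$n_intersection <- sum(rec$category == "in_qtl_credible")
    stopifnot(rec$n_intersection[1] <= rec$n_gwas_credible[1])
    out[[length(out) + 1]] <- rec
  }
  structure(out, class = "integration_records")
}

#' Rank-sum comparison of GWAS causal posteriors between categories
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) comparing GWAS CPPs of variants shared with a QTL credible
#' set against GWAS-only variants, pooled across loci.
#'
#' @param records an `integration_records` object.
#' @return list: `statistic` (rank sum W of the shared category), `p`,
#'   `n1`, `n2`, `median_shared`, `median_only`.
#' @export
cpp_rank_comparison <- function(records) {
  all <- do.call(rbind, records)
  x <- all$cpp[all$category == "in_qtl_credible"]
  y <- all$cpp[all$category == "gwas_only"]
  if (!length(x) || !length(y)) stop("both categories must be non-empty")
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y),
       median_shared = stats::median(x), median_only = stats::median(y))
}

#' Fine-mapping resolution gain
#'
#' Counts loci resolved to at most `k` candidate variants before
#' (GWAS credible set alone) and after intersecting with the QTL
#' credible set.
#'
#' @param records an `integration_records` object.
#' @param k resolution bin (default 5 variants).
#' @return list: `before`, `after`, `k`, `n_loci`.
#' @export
resolution_counts <- function(records, k = 5) {
  nb <- vapply(records, function(r) r$n_gwas_credible[1], numeric(1))
  na_ <- vapply(records, function(r) r$n_intersection[1], numeric(1))
  stopifnot(all(na_ <= nb))
  before <- sum(nb <= k & nb > 0)
  after <- sum(na_ <= k & na_ > 0)
  list(before = before, after = after, k = k, n_loci = length(records))
}

#' Nominate candidate effector features per locus
#'
#' The union of colocalized QTL features and significant,
#' colocalization-gated TWAS features, with evidence flags for each
#' route.
#'
#' @param coloc data.frame from [colocalize_all] (needs `locus`,
#'   `feature`, `colocalized`).
#' @param twas data.frame with `locus`, `feature`, `significant`,
#'   `pass_coloc_gate`.
#' @return data.frame: `locus`, `feature`, `by_coloc`, `by_twas`.
#' @export
effector_table <- function(coloc, twas) {
  a <- coloc[coloc$colocalized, c("locus", "feature"), drop = FALSE]
  if (nrow(a)) a$by_coloc <- TRUE
  b <- twas[twas$significant & twas$pass_coloc_gate,
            c("locus", "feature"), drop = FALSE]
  if (nrow(b)) b$by_twas <- TRUE
  out <- merge(a, b, by = c("locus", "feature"), all = TRUE)
  if (!nrow(out))
    return(data.frame(locus = character(), feature = character(),
                      by_coloc = logical(), by_twas = logical()))
  out$by_coloc <- !is.na(out$by_coloc)
  out$by_twas <- !is.na(out$by_twas)
  out[order(out$locus, out$feature), ]
}
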