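## internal: log(sum(exp(x))) and log(exp(a) - exp(b)) (a > b), stable
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Bayesian colocalization posteriors for two traits
#'
#' Enumerates the five single-causal hypotheses over a shared variant
#' grid: no association (H0), trait-1 only (H1), trait-2 only (H2), two
#' distinct causal variants (H3), one shared causal variant (H4).
#' Per-variant Wakefield log ABFs are combined in log space with
#' per-variant prior probabilities `p1`, `p2` and `p12`.
#'
#' @param stats1,stats2 `gwas_summary`-like data.frames sharing variant
#'   ids (columns `id`, `beta`, `se`).
#' @param p1,p2,p12 prior probabilities a variant is causal for trait 1,
#'   trait 2, or both (defaults 1e-4, 1e-4, 1e-5).
#' @param W1,W2 effect prior variances for the two traits (defaults
#'   `0.15^2` quantitative; use `0.2^2` for case-control log-odds).
#' @return list of class `coloc_result`: `pp` (named PP0..PP4),
#'   `n_variants`.
#' @export
coloc_posteriors <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4,
                             p12 = 1e-5, W1 = 0.0225, W2 = 0.0225) {
  common <- intersect(stats1$id, stats2$id)
  if (length(common) < 2) stop("need at least 2 shared variants")
  if (length(common) < 25)
    warning("fewer than 25 shared variants; posteriors may be unstable")
  s1 <- stats1[match(common, stats1$id), ]
  s2 <- stats2[match(common, stats2$id), ]
  l1 <- wakefield_abf(s1$beta, s1$se, W1)
  l2 <- wakefield_abf(s2$beta, s2$se, W2)
  S1 <- logsumexp(l1)            # log sum_j ABF1_j
  S2 <- logsumexp(l2)
  S12 <- logsumexp(l1 + l2)      # log sum_j ABF1_j ABF2_j
  lh <- c(
    h0 = 0,
    h1 = log(p1) + S1,
    h2 = log(p2) + S2,
    h3 = log(p1) + log(p2) + logdiffexp(S1 + S2, S12),
    h4 = log(p12) + S12
  )
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, n_variants = length(common)),
            class = "coloc_result")
}

#' Eligibility of GWAS signals for colocalization testing
#'
#' A signal is eligible when at least one of its credible-set variants
#' with CPP >= `cpp_min` is in LD (r2 >= `r2_min`) with a lead QTL
#' variant. When the signal carries no credible set, the fallback rule
#' applies: any variant with GWAS p <= `p_fallback` in LD (r2 >= `r2_min`)
#' with the lead.
#'
#' @param signals list of GWAS signals; each a list with `locus`, `lead`,
#'   `gwas` (summary rows for the locus) and optionally `credible_set`
#'   (a `credible_set` data.frame).
#' @param qtl_leads character vector of lead QTL variant ids.
#' @param g a [genotype_matrix] for LD.
#' @param cpp_min credible-set CPP floor (default 0.01).
#' @param r2_min LD threshold (default 0.6).
#' @param p_fallback GWAS p threshold for the no-credible-set rule
#'   (default 5e-5).
#' @return logical vector, one per signal.
#' @export
eligible_signals <- function(signals, qtl_leads, g, cpp_min = 0.01,
                             r2_min = 0.6, p_fallback = 5e-5) {
  vapply(signals, function(sig) {
    cand <- if (!is.null(sig$credible_set)) {
      cs <- sig$credible_set
      cs$id[cs$in_credible_set & cs$cpp >= cpp_min]
    } else {
      sig$gwas$id[sig$gwas$p <= p_fallback]
    }
    cand <- intersect(cand, g$variants$id)
    if (!length(cand)) return(FALSE)
    for (lead in intersect(qtl_leads, g$variants$id)) {
      r2 <- ld_r2(g, lead, window_bp = 1e6)
      if (any(!is.na(r2[cand]) & r2[cand] >= r2_min, na.rm = TRUE))
        return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Colocalize all eligible GWAS signals against QTL statistics
#'
#' For each eligible signal, the region is the 1 Mb interval centered on
#' the signal lead; the region must contain at least one variant with
#' GWAS p <= `p_incl` and all region variants shared with the QTL
#' statistics enter the computation. A locus is called colocalized when
#' the shared-variant posterior PP4 >= `pp_min`.
#'
#' @param signals as in [eligible_signals].
#' @param qtl_stats list (or single data.frame) of per-feature QTL
#'   summary statistics (`id`, `beta`, `se`, `pos`); each eligible signal
#'   is tested against each entry whose variants overlap the region.
#' @param qtl_leads lead variant per QTL feature (named by feature).
#' @param g a [genotype_matrix].
#' @param window_bp region width (default 1e6).
#' @param p_incl region must contain a GWAS p at or below this
#'   (default 5e-5).
#' @param pp_min colocalization decision threshold (default 0.8).
#' @param ... passed to [coloc_posteriors].
#' @return data.frame: `locus`, `feature`, `n_variants`, `PP0..PP4`,
#'   `eligible`, `colocalized`.
#' @export
colocalize_all <- function(signals, qtl_stats, qtl_leads, g,
                           window_bp = 1e6, p_incl = 5e-5, pp_min = 0.8,
                           ...) {
  if (is.data.frame(qtl_stats)) qtl_stats <- list(qtl = qtl_stats)
  elig <- eligible_signals(signals, unlist(qtl_leads), g)
  rows <- list()
  for (i in seq_along(signals)) {
    if (!elig[i]) next
    sig <- signals[[i]]
    lead_pos <- sig$gwas$pos[match(sig$lead, sig$gwas$id)]
    lead_chr <- sig$gwas$chrom[match(sig$lead, sig$gwas$id)]
    reg <- sig$gwas[sig$gwas$chrom == lead_chr &
                    sig$gwas$pos >= lead_pos - window_bp / 2 &
                    sig$gwas$pos <= lead_pos + window_bp / 2, ]
    if (!any(reg$p <= p_incl)) next
    for (feat in names(qtl_stats)) {
      qs <- qtl_stats[[feat]]
      shared <- intersect(reg$id, qs$id)
      if (length(shared) < 2) next
      cp <- coloc_posteriors(reg[match(shared, reg$id), ],
                             qs[match(shared, qs$id), ], ...)
      rows[[length(rows) + 1]] <- data.frame(
        locus = sig$locus, feature = feat, n_variants = cp$n_variants,
        t(cp$pp), eligible = TRUE,
        colocalized = unname(cp$pp["PP4"] >= pp_min),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows))
    return(data.frame(locus = character(), feature = character(),
                      n_variants = integer(), PP0 = numeric(),
                      PP1 = numeric(), PP2 = numeric(), PP3 = numeric(),
                      PP4 = numeric(), eligible = logical(),
                      colocalized = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
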