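#' Infer approximately independent LD blocks
#'
#' Greedy left-to-right scan within each chromosome: a new block starts at
#' a variant whose maximum r-squared with the preceding `lookback`
#' variants falls below `r2_break`. Blocks tile each chromosome (breaks at
#' the midpoint between flanking variants).
#'
#' @param g a [genotype_matrix].
#' @param r2_break r-squared threshold opening a new block (default 0.1).
#' @param lookback how many preceding variants to scan (default 50).
#' @param chrom_len named vector of chromosome lengths; defaults to the
#'   last variant position plus median spacing.
#' @return an [interval_set] of blocks; the per-variant block index is
#'   attached as attribute `variant_block` (named by variant id).
#' @export
infer_ld_blocks <- function(g, r2_break = 0.1, lookback = 50,
                            chrom_len = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  Z <- impute_mean_cols(g$dosage)
  Z <- scale(Z)
  Z[, apply(is.na(Z) | !is.finite(Z), 2, any)] <- 0
  blocks <- list(); vb <- integer(nrow(v)); nb <- 0L
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    idx <- idx[order(v$pos[idx])]
    len <- if (!is.null(chrom_len)) chrom_len[[ch]] else
      max(v$pos[idx]) + stats::median(diff(sort(v$pos[idx])), na.rm = TRUE)
    starts <- 1L
    for (k in seq_along(idx)[-1]) {
      prev <- idx[max(1, k - lookback):(k - 1)]
      r <- crossprod(Z[, idx[k]], Z[, prev, drop = FALSE]) / (nrow(Z) - 1)
      if (max(r^2, na.rm = TRUE) < r2_break) starts <- c(starts, k)
    }
    bounds0 <- c(0, if (length(starts) > 1)
      floor((v$pos[idx[starts[-1]]] + v$pos[idx[starts[-1] - 1]]) / 2)
      else NULL)
    bounds1 <- c(bounds0[-1], len)
    for (b in seq_along(starts)) {
      nb <- nb + 1L
      blocks[[nb]] <- data.frame(chrom = ch, start = bounds0[b],
                                 end = bounds1[b],
                                 name = paste0("ldb", nb))
      kk <- starts[b]:(if (b < length(starts)) starts[b + 1] - 1
                       else length(idx))
      vb[idx[kk]] <- nb
    }
  }
  bl <- do.call(rbind, blocks)
  out <- interval_set(bl$chrom, bl$start, bl$end, bl$name)
  attr(out, "variant_block") <- stats::setNames(vb, v$id)
  out
}

#' Build LD-matched control variant sets
#'
#' For every LD block containing query variants, the bp span of those
#' variants is recorded; per permutation, intervals of those sizes are
#' placed uniformly at random and non-overlapping in the genome outside
#' the excluded space (all query-bearing blocks plus any supplied
#' exclusion intervals), and exactly `|query|` control variants are
#' sampled without replacement from the candidate variants falling inside
#' the placed intervals.
#'
#' @param query_ids query variant ids.
#' @param candidate_ids pool of variant ids controls may be drawn from.
#' @param g a [genotype_matrix].
#' @param blocks [infer_ld_blocks] output (with `variant_block`).
#' @param exclude optional [interval_set] of additional exclusions
#'   (blacklist, MHC analog).
#' @param B number of control sets (default 1000).
#' @param seed integer seed.
#' @param max_retry placement retries before giving up (default 100).
#' @param span_mode "query_span" (default) shuffles intervals sized by the
#'   span of query variants within each block; "block" shuffles intervals
#'   sized by the whole LD block.
#' @return list of class `control_sets`: `sets` (list of B id vectors),
#'   `B`, `seed`, `excluded` (merged exclusion intervals).
#' @export
build_control_sets <- function(query_ids, candidate_ids, g, blocks,
                               exclude = NULL, B = 1000, seed = 1L,
                               max_retry = 100,
                               span_mode = c("query_span", "block")) {
  span_mode <- match.arg(span_mode)
  stopifnot(inherits(g, "genotype_matrix"))
  set.seed(sub_seed(seed, "controls"))
  v <- g$variants
  vb <- attr(blocks, "variant_block")
  qb <- unique(vb[query_ids])
  spans <- do.call(rbind, lapply(qb, function(b) {
    if (span_mode == "block")
      return(data.frame(size = blocks$end[b] - blocks$start[b]))
    sel <- query_ids[vb[query_ids] == b]
    p <- v$pos[match(sel, v$id)]
    data.frame(size = max(max(p) - min(p), 1000L))
  }))
  qblocks <- as.data.frame(blocks)[qb, , drop = FALSE]
  excl <- merge_intervals(rbind_iv(
    interval_set(qblocks$chrom, qblocks$start, qblocks$end),
    if (!is.null(exclude)) exclude else NULL
  ))
  # allowed gaps = chromosome space minus exclusions
  chrom_span <- do.call(rbind, lapply(split(blocks, blocks$chrom),
    function(b) data.frame(chrom = b$chrom[1], start = min(b$start),
                           end = max(b$end))))
  gaps0 <- do.call(rbind, lapply(seq_len(nrow(chrom_span)), function(i) {
    ch <- chrom_span$chrom[i]
    full <- IRanges::IRanges(chrom_span$start[i] + 1L, chrom_span$end[i])
    esel <- excl$chrom == ch
    d <- if (any(esel))
      IRanges::setdiff(full, IRanges::IRanges(excl$start[esel] + 1L,
                                              excl$end[esel]))
      else full
    if (length(d) == 0) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(d) - 1L,
               end = IRanges::end(d))
  }))
  cand <- v[match(candidate_ids, v$id), c("id", "chrom", "pos")]
  cand <- cand[!interval_overlap(excl, cand$chrom, cand$pos), , drop = FALSE]
  # per-chromosome sorted candidate positions for fast interval lookups
  cand_by_chr <- lapply(split(cand, cand$chrom), function(x)
    x[order(x$pos), , drop = FALSE])
  k <- length(query_ids)
  sets <- vector("list", B)
  med_size <- stats::median(spans$size)
  for (b in seq_len(B)) {
    gc_ <- gaps0$chrom; gs <- gaps0$start; ge <- gaps0$end
    pool_idx <- character(0)
    place_one <- function(s) {
      w <- ge - gs
      el <- which(w >= s)
      if (!length(el)) return(FALSE)
      gi <- if (length(el) == 1) el else
        el[sample.int(length(el), 1, prob = (w[el] - s + 1))]
      st <- gs[gi] + sample.int(w[gi] - s + 1, 1) - 1L
      cb <- cand_by_chr[[gc_[gi]]]
      if (!is.null(cb)) {
        lo <- findInterval(st, cb$pos)          # pos > st (1-based in (st, st+s])
        hi <- findInterval(st + s, cb$pos)
        if (hi > lo)
          pool_idx <<- c(pool_idx, cb$id[(lo + 1):hi])
      }
      # split the gap around the placed interval
      gc_ <<- c(gc_[-gi], gc_[gi], gc_[gi])
      gs <<- c(gs[-gi], gs[gi], st + s)
      ge <<- c(ge[-gi], st, ge[gi])
      keep <- ge > gs
      gc_ <<- gc_[keep]; gs <<- gs[keep]; ge <<- ge[keep]
      TRUE
    }
    ok <- all(vapply(spans$size, place_one, logical(1)))
    # boundary effects can leave the matched intervals with fewer
    # candidates than the query; top up with extra median-size intervals
    extra <- 0L
    while (ok && length(pool_idx) < k && extra < max_retry) {
      ok <- place_one(med_size)
      extra <- extra + 1L
    }
    if (length(pool_idx) < k)
      stop("control pool exhausted after ", max_retry,
           " placement retries; use a larger genome")
    sets[[b]] <- sample(pool_idx, k)
  }
  structure(list(sets = sets, B = B, seed = seed, excluded = excl),
            class = "control_sets")
}

#' QQ inflation test against an LD-matched permutation null
#'
#' Observed statistics are the sorted -log10 GWAS p-values of the query
#' variants (restricted to MAF >= `maf_min`); the expected line uses the
#' uniform quantiles `-log10((i - 0.5)/n)`; the envelope is the rank-wise
#' 2.5th/97.5th percentile across the control sets. The enrichment flag is
#' raised when at least `flag_frac` of the top-decile ranks exceed the
#' upper envelope (default: the majority of those ranks, so that a
#' single pointwise exceedance, which is expected by chance, does not
#' raise the flag).
#'
#' @param query_ids query variant ids.
#' @param gwas a `gwas_summary` table.
#' @param controls a `control_sets` object.
#' @param g a [genotype_matrix] (for MAF).
#' @param maf_min MAF filter (default 0.05).
#' @param flag_frac exceedance fraction raising the flag (default 0.5).
#' @return list of class `qq_result`: `table` (rank, observed, expected,
#'   env_lo, env_hi), `enriched`, `n`.
#' @export
qq_inflation <- function(query_ids, gwas, controls, g, maf_min = 0.05,
                         flag_frac = 0.5) {
  maf <- stats::setNames(g$variants$maf, g$variants$id)
  obs_log10 <- function(ids) {
    ids <- ids[!is.na(maf[ids]) & maf[ids] >= maf_min]
    p <- gwas$p[match(ids, gwas$id)]
    p <- p[!is.na(p)]
    sort(-log10(p), decreasing = TRUE)
  }
  obs <- obs_log10(query_ids)
  n <- length(obs)
  if (n == 0) stop("no query variants left after MAF/GWAS intersection")
  expected <- -log10((seq_len(n) - 0.5) / n)
  ctl <- vapply(controls$sets, function(ids) {
    x <- obs_log10(ids)
    if (length(x) == n) x
    else if (length(x) <= 1) rep(if (length(x)) x else NA_real_, n)
    else stats::approx(seq(0, 1, length.out = length(x)), x,
                       xout = seq(0, 1, length.out = n))$y
  }, numeric(n))
  ctl <- matrix(ctl, nrow = n)
  env <- apply(ctl, 1, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  top <- seq_len(max(1, ceiling(n / 10)))
  enriched <- mean(obs[top] > env[2, top]) >= flag_frac
  structure(list(
    table = data.frame(rank = seq_len(n), observed = obs,
                       expected = expected, env_lo = env[1, ],
                       env_hi = env[2, ]),
    enriched = enriched, n = n
  ), class = "qq_result")
}

#' Annotation fold enrichment with matched controls
#'
#' A variant "hits" an annotation when it, or any variant in LD
#' (r2 >= `r2_proxy`) within `ld_window_bp`, overlaps the annotation. Fold
#' change is observed query hits over the mean control hits; the empirical
#' p-value is `(#\{controls >= observed\} + 1) / (B + 1)`.
#'
#' @param query_ids lead variant ids.
#' @param annotation an [interval_set].
#' @param g a [genotype_matrix].
#' @param controls a `control_sets` object.
#' @param r2_proxy LD proxy threshold (default 0.7).
#' @param ld_window_bp proxy search window (default 50000).
#' @return list: `fold`, `p`, `observed`, `control_mean`.
#' @export
annotation_fold_enrichment <- function(query_ids, annotation, g, controls,
                                       r2_proxy = 0.7,
                                       ld_window_bp = 50000) {
  needed <- unique(c(query_ids, unlist(controls$sets)))
  hit <- stats::setNames(logical(length(needed)), needed)
  for (id in needed) {
    r2 <- ld_r2(g, id, window_bp = ld_window_bp)
    prox <- names(r2)[!is.na(r2) & r2 >= r2_proxy]
    pp <- match(prox, g$variants$id)
    hit[id] <- any(interval_overlap(annotation, g$variants$chrom[pp],
                                    g$variants$pos[pp]))
  }
  obs <- sum(hit[query_ids])
  ctl <- vapply(controls$sets, function(s) sum(hit[s]), numeric(1))
  list(
    fold = obs / max(mean(ctl), .Machine$double.eps),
    p = (sum(ctl >= obs) + 1) / (length(ctl) + 1),
    observed = obs, control_mean = mean(ctl)
  )
}

#' Lead-variant query sets stratified by QTL p-value
#'
#' Builds enrichment query sets from a permutation-pass table at the
#' conventional significance strata, for use with
#' [annotation_fold_enrichment] or [qq_inflation]. When a variant leads
#' several features, its best p-value is kept.
#'
#' @param perm `perm_result` table with `lead` and `p_beta` columns.
#' @param thresholds p-value strata (default 5e-3, 5e-5, 5e-7).
#' @return named list of character vectors of lead variant ids, one per
#'   stratum.
#' @export
qtl_pvalue_strata <- function(perm, thresholds = c(5e-3, 5e-5, 5e-7)) {
  perm <- perm[!is.na(perm$p_beta), , drop = FALSE]
  best <- tapply(perm$p_beta, perm$lead, min)
  stats::setNames(
    lapply(thresholds, function(th) names(best)[best <= th]),
    paste0("p", format(thresholds, scientific = TRUE, trim = TRUE))
  )
}
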