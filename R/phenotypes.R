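#' Filter genes by read support within cohorts
#'
#' A gene is kept when it has at least `min_reads` reads in at least
#' `min_frac` of the samples of every group.
#'
#' @param counts genes x samples integer matrix.
#' @param min_reads minimum raw reads (default 5).
#' @param min_frac minimum fraction of samples per group (default 0.10).
#' @param groups factor partitioning samples into cohorts (default: one).
#' @return filtered counts matrix.
#' @export
filter_genes <- function(counts, min_reads = 5, min_frac = 0.10,
                         groups = NULL) {
  if (is.null(groups)) groups <- factor(rep("all", ncol(counts)))
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || length(groups) != ncol(counts))
    stop("groups must partition the samples")
  keep <- rep(TRUE, nrow(counts))
  for (gl in levels(groups)) {
    sel <- groups == gl
    frac <- rowMeans(counts[, sel, drop = FALSE] >= min_reads)
    keep <- keep & (frac >= min_frac)
  }
  counts[keep, , drop = FALSE]
}

#' Log2 counts-per-million
#'
#' CPM via [edgeR::cpm], then `log2(cpm + pseudocount)`. Doubling all
#' counts of a sample leaves its values unchanged.
#'
#' @param counts genes x samples matrix.
#' @param pseudocount added before the log (default 1).
#' @return matrix of log2 CPM values.
#' @export
cpm_log2 <- function(counts, pseudocount = 1) {
  log2(edgeR::cpm(counts) + pseudocount)
}

#' Filter splice junctions by read support
#'
#' Keeps junctions with at least `min_reads` spliced reads in at least
#' `min_frac` of samples.
#'
#' @param junctions junction metadata data.frame (`chrom`, `intron_start`,
#'   `intron_end`, `strand`, `junction_id`).
#' @param counts junctions x samples matrix (rows match `junctions`).
#' @param min_reads,min_frac thresholds (defaults 5 reads, 10% of samples).
#' @return list `(junctions, counts)` filtered.
#' @export
filter_junctions <- function(junctions, counts, min_reads = 5,
                             min_frac = 0.10) {
  stopifnot(nrow(junctions) == nrow(counts))
  keep <- rowMeans(counts >= min_reads) >= min_frac
  list(junctions = junctions[keep, , drop = FALSE],
       counts = counts[keep, , drop = FALSE])
}

#' Cluster junctions sharing splice sites
#'
#' Junctions on the same chromosome and strand that share a donor
#' (intron start) or acceptor (intron end) coordinate are joined; clusters
#' are the connected components of that graph (via \pkg{igraph}).
#' Junctions longer than `max_intron_bp` are removed first; clusters with a
#' single junction or with total reads (summed over junctions and samples)
#' below `min_cluster_reads` are dropped.
#'
#' @param junctions,counts as in [filter_junctions].
#' @param min_cluster_reads minimum cluster read support (default 30).
#' @param max_intron_bp maximum intron length (default 500000).
#' @param per_sample when `FALSE` (default) `min_cluster_reads` applies to
#'   the cluster total summed over all samples; when `TRUE` at least one
#'   sample must reach it on its own.
#' @return list with `junctions` (plus a `cluster` column), `counts`, and
#'   `clusters` (named list cluster id -> junction ids).
#' @export
cluster_junctions <- function(junctions, counts, min_cluster_reads = 30,
                              max_intron_bp = 500000,
                              per_sample = FALSE) {
  stopifnot(nrow(junctions) == nrow(counts))
  len_ok <- (junctions$intron_end - junctions$intron_start) <= max_intron_bp
  junctions <- junctions[len_ok, , drop = FALSE]
  counts <- counts[len_ok, , drop = FALSE]
  n <- nrow(junctions)
  if (n == 0) return(list(junctions = junctions, counts = counts,
                          clusters = list()))
  donor <- paste(junctions$chrom, junctions$strand, "d",
                 junctions$intron_start)
  accept <- paste(junctions$chrom, junctions$strand, "a",
                  junctions$intron_end)
  # bipartite junction--site graph; components restricted to junctions
  edges <- rbind(
    data.frame(from = paste0("j", seq_len(n)), to = donor),
    data.frame(from = paste0("j", seq_len(n)), to = accept)
  )
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(gr)$membership
  memb <- comp[paste0("j", seq_len(n))]
  memb <- match(memb, unique(memb))
  support <- if (per_sample)
    vapply(split(seq_len(nrow(counts)), memb), function(i)
      max(colSums(counts[i, , drop = FALSE])), numeric(1))
  else tapply(rowSums(counts), memb, sum)
  keep_cl <- which(tabulate(memb) >= 2 & support >= min_cluster_reads)
  keep <- memb %in% keep_cl
  junctions <- junctions[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  memb <- match(memb[keep], unique(memb[keep]))
  junctions$cluster <- paste0("clu_", memb)
  list(
    junctions = junctions, counts = counts,
    clusters = split(junctions$junction_id, junctions$cluster)
  )
}

#' Percent spliced in (intron excision ratios)
#'
#' PSI of a junction in a sample is its read count divided by the sample's
#' cluster total; samples where the cluster total is zero get `NA`.
#' Junctions missing in more than `max_missing_frac` of samples are
#' dropped.
#'
#' @param clustered output of [cluster_junctions].
#' @param max_missing_frac drop features with a higher missing fraction
#'   (default 0.5).
#' @return a `phenotype_matrix` (see [phenotype_matrix]) of kind
#'   "splicing", with raw PSI values.
#' @export
compute_psi <- function(clustered, max_missing_frac = 0.5) {
  jt <- clustered$junctions
  cnt <- clustered$counts
  if (nrow(jt) == 0) stop("no clustered junctions")
  tot <- rowsum(cnt, jt$cluster)               # clusters x samples
  tot_j <- tot[jt$cluster, , drop = FALSE]
  psi <- cnt / tot_j
  psi[tot_j == 0] <- NA_real_
  keep <- rowMeans(is.na(psi)) <= max_missing_frac
  phenotype_matrix(
    values = psi[keep, , drop = FALSE],
    anchors = data.frame(
      feature = jt$junction_id[keep], chrom = jt$chrom[keep],
      start = jt$intron_start[keep], end = jt$intron_end[keep],
      cluster = jt$cluster[keep], stringsAsFactors = FALSE
    ),
    kind = "splicing"
  )
}

#' Phenotype matrix
#'
#' Features x samples numeric phenotypes with per-feature genomic anchors:
#' TSS for expression features (`start == end`), the junction interval for
#' splicing features.
#'
#' @param values features x samples matrix (rownames = feature ids).
#' @param anchors data.frame with `feature`, `chrom`, `start`, `end` and,
#'   for splicing, `cluster`.
#' @param kind "expression" or "splicing".
#' @return object of class `phenotype_matrix`.
#' @export
phenotype_matrix <- function(values, anchors, kind) {
  values <- as.matrix(values)
  kind <- match.arg(kind, c("expression", "splicing"))
  stopifnot(nrow(values) == nrow(anchors),
            all(c("feature", "chrom", "start", "end") %in% names(anchors)))
  rownames(values) <- anchors$feature
  structure(list(values = values, anchors = anchors, kind = kind),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("phenotype_matrix (%s): %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Rank-based inverse-normal standardization
#'
#' Per feature: missing values are imputed at the feature median, values
#' are ranked (ties averaged) and mapped through
#' `qnorm((rank - 0.5) / n)`. The result is invariant to any monotone
#' transform of the input.
#'
#' @param pm a [phenotype_matrix].
#' @return a [phenotype_matrix] with standardized values.
#' @export
standardize <- function(pm) {
  stopifnot(inherits(pm, "phenotype_matrix"))
  v <- pm$values
  n <- ncol(v)
  out <- t(apply(v, 1, function(x) {
    x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
  }))
  const <- apply(out, 1, function(x) stats::sd(x) == 0)
  pm$values <- out[!const, , drop = FALSE]
  pm$anchors <- pm$anchors[!const, , drop = FALSE]
  pm
}

#' Location-scale batch adjustment
#'
#' Per feature: each batch is centered at its own mean and rescaled so its
#' standard deviation matches the pooled (residual) standard deviation;
#' the grand mean is restored. Removes additive and multiplicative batch
#' structure exactly.
#'
#' @param pm a [phenotype_matrix].
#' @param batches factor of batch labels, one per sample.
#' @return adjusted [phenotype_matrix].
#' @export
batch_adjust <- function(pm, batches) {
  stopifnot(inherits(pm, "phenotype_matrix"),
            length(batches) == ncol(pm$values))
  batches <- as.factor(batches)
  v <- pm$values
  for (f in seq_len(nrow(v))) {
    x <- v[f, ]
    grand <- mean(x, na.rm = TRUE)
    cent <- x
    for (b in levels(batches)) {
      sel <- batches == b
      cent[sel] <- x[sel] - mean(x[sel], na.rm = TRUE)
    }
    pooled_sd <- stats::sd(cent, na.rm = TRUE)
    for (b in levels(batches)) {
      sel <- batches == b
      bsd <- stats::sd(cent[sel], na.rm = TRUE)
      if (!is.na(bsd) && bsd > 0 && !is.na(pooled_sd) && pooled_sd > 0)
        cent[sel] <- cent[sel] / bsd * pooled_sd
    }
    v[f, ] <- cent + grand
  }
  pm$values <- v
  pm
}

#' Principal components of a phenotype matrix
#'
#' Top-k PCs of the feature-standardized matrix; returns per-sample scores
#' for use as covariates. Sign convention: the loading with the largest
#' absolute value in each component is positive.
#'
#' @param pm a [phenotype_matrix].
#' @param k number of components.
#' @return samples x k matrix of PC scores (columns `PC1..PCk`).
#' @export
phenotype_pcs <- function(pm, k) {
  stopifnot(inherits(pm, "phenotype_matrix"))
  v <- pm$values
  v[is.na(v)] <- 0
  x <- t(scale(t(v)))                      # standardize features
  x <- x[apply(x, 1, function(r) all(is.finite(r))), , drop = FALSE]
  r <- min(dim(x)) - 1
  if (k > r) stop("k exceeds matrix rank (", r, ")")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- colnames(pm$values)
  scores
}
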