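#' Simulation configuration
#'
#' Defaults describe the study-scale conditions the rest of the package is
#' validated under: a diploid cohort with block-structured LD, splice
#' clusters whose junction usage responds to planted cis variants,
#' log-scale expression with planted eQTLs and batch structure, and GWAS
#' summary statistics whose causal variant is shared with, linked to, or
#' independent of a planted QTL.
#'
#' @param n_samples number of diploid samples.
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp.
#' @param block_size variants per LD block.
#' @param within_block_rho haplotype allele correlation between adjacent
#'   markers in a block, in \[0, 1).
#' @param maf_range range the per-block minor allele frequency is drawn from.
#' @param variant_spacing bp between adjacent variants.
#' @param n_clusters number of splice clusters.
#' @param junctions_per_cluster junctions per cluster (recycled).
#' @param cluster_depth mean junction-spanning reads per cluster per sample.
#' @param nb_size negative-binomial size (dispersion) of cluster totals.
#' @param n_genes number of genes.
#' @param n_batches number of sequencing batches (samples split evenly).
#' @param batch_sd standard deviation of per-batch additive offsets.
#' @param seed master seed; every generator draws from it deterministically.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300, n_chrom = 2, chrom_len = 2e6,
                       block_size = 20, within_block_rho = 0.9,
                       maf_range = c(0.1, 0.5), variant_spacing = 1000,
                       n_clusters = 40, junctions_per_cluster = 3,
                       cluster_depth = 60, nb_size = 10,
                       n_genes = 60, n_batches = 2, batch_sd = 0.5,
                       seed = 1L) {
  stopifnot(n_samples >= 1, n_chrom >= 1, block_size >= 1,
            within_block_rho >= 0, within_block_rho < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(as.list(environment()), class = "sim_config")
}

## internal: deterministic sub-seed from the master seed and a stream label
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  # double arithmetic: exact below 2^53, result always a valid seed
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483562)
}

#' Simulate block-LD diploid genotypes
#'
#' Haplotype alleles within each LD block follow a first-order Markov chain
#' with stationary frequency equal to the block's allele frequency and
#' correlation `within_block_rho` between adjacent markers; blocks are
#' independent. Dosage is the sum of two independent haplotypes, so the
#' dosage correlation of adjacent markers is also `within_block_rho` (and
#' r-squared is its square).
#'
#' @param cfg a [sim_config].
#' @return a [genotype_matrix]; block assignment is stored in
#'   `$variants$block`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sub_seed(cfg$seed, "genotypes"))
  n_var_chr <- floor(cfg$chrom_len / cfg$variant_spacing)
  n_blocks_chr <- ceiling(n_var_chr / cfg$block_size)
  rho <- cfg$within_block_rho
  out <- vector("list", cfg$n_chrom)
  meta <- vector("list", cfg$n_chrom)
  for (ch in seq_len(cfg$n_chrom)) {
    sizes <- diff(floor(seq(0, n_var_chr, length.out = n_blocks_chr + 1)))
    sizes <- sizes[sizes > 0]
    cols <- vector("list", length(sizes))
    for (b in seq_along(sizes)) {
      m <- sizes[b]
      p <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
      hap <- matrix(0L, 2 * cfg$n_samples, m)
      hap[, 1] <- stats::rbinom(2 * cfg$n_samples, 1, p)
      if (m > 1) for (j in 2:m) {
        prev <- hap[, j - 1]
        pr <- ifelse(prev == 1, p + rho * (1 - p), p * (1 - rho))
        hap[, j] <- stats::rbinom(2 * cfg$n_samples, 1, pr)
      }
      cols[[b]] <- hap[seq_len(cfg$n_samples), , drop = FALSE] +
        hap[cfg$n_samples + seq_len(cfg$n_samples), , drop = FALSE]
    }
    dose <- do.call(cbind, cols)
    pos <- seq_len(ncol(dose)) * cfg$variant_spacing
    meta[[ch]] <- data.frame(
      id = sprintf("chr%d_v%d", ch, seq_len(ncol(dose))),
      chrom = paste0("chr", ch), pos = pos,
      ref = "A", alt = "G",
      block = paste0("chr", ch, "_b", rep(seq_along(sizes), sizes)),
      stringsAsFactors = FALSE
    )
    out[[ch]] <- dose
  }
  variants <- do.call(rbind, meta)
  g <- genotype_matrix(do.call(cbind, out),
                       variants[, c("id", "chrom", "pos", "ref", "alt")],
                       samples = sprintf("S%03d", seq_len(cfg$n_samples)))
  g$variants$block <- variants$block
  g
}

#' Batch labels for a simulated cohort
#' @param cfg a [sim_config].
#' @return factor of length `n_samples`.
#' @export
sim_batches <- function(cfg) {
  factor(paste0("batch", rep_len(seq_len(cfg$n_batches), cfg$n_samples)))
}

#' Simulate junction counts within splice clusters
#'
#' Each cluster occupies a genomic interval; its junctions share a donor
#' coordinate so that junction clustering recovers the planted clusters.
#' Per sample, the cluster total is negative binomial around
#' `cluster_depth` and junction counts are multinomial with proportions
#' softmax(base logits + beta * dosage at the planted variant + batch
#' offset on the affected junction).
#'
#' @param g a [genotype_matrix] from [simulate_genotypes].
#' @param cfg a [sim_config].
#' @param effects data.frame `(cluster, beta)` of planted sQTLs, one row
#'   per affected cluster (`cluster` indexes 1..n_clusters); the causal
#'   variant is chosen near the cluster midpoint. `NULL` for a null
#'   simulation. Optionally a `variant` column fixes the causal variant id.
#' @param batch_effect additive logit offset applied to the first junction
#'   of every cluster for batches after the first (default 0).
#' @return list with `junctions` (junction table: data.frame `chrom`,
#'   `intron_start`, `intron_end`, `strand`, `cluster_true`, plus a counts
#'   matrix in `$counts`), and `truth` (data.frame of planted effects).
#' @export
simulate_junction_counts <- function(g, cfg, effects = NULL,
                                     batch_effect = 0) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "sim_config"))
  set.seed(sub_seed(cfg$seed, "junctions"))
  if (!is.null(effects) && any(effects$cluster > cfg$n_clusters))
    stop("effect on non-existent cluster")
  n <- cfg$n_samples
  batches <- sim_batches(cfg)
  k <- rep_len(cfg$junctions_per_cluster, cfg$n_clusters)
  # place clusters evenly across chromosomes
  chrs <- unique(g$variants$chrom)
  meta <- vector("list", cfg$n_clusters)
  counts <- vector("list", cfg$n_clusters)
  truth <- list()
  per_chr <- ceiling(cfg$n_clusters / length(chrs))
  span <- floor(cfg$chrom_len / (per_chr + 1))
  for (cl in seq_len(cfg$n_clusters)) {
    ch <- chrs[((cl - 1) %% length(chrs)) + 1]
    slot <- ((cl - 1) %/% length(chrs)) + 1
    # shared donor coordinate (intron start), aligned to the variant grid
    # so splice-site windows can contain genotyped variants
    donor <- round(slot * span / cfg$variant_spacing) * cfg$variant_spacing
    ends <- donor + 2 * cfg$variant_spacing * seq_len(k[cl])
    meta[[cl]] <- data.frame(
      chrom = ch, intron_start = donor, intron_end = ends, strand = "+",
      cluster_true = paste0("clu", cl), stringsAsFactors = FALSE
    )
    logits <- matrix(stats::rnorm(k[cl], sd = 0.5), nrow = n, ncol = k[cl],
                     byrow = TRUE)
    eff <- if (!is.null(effects)) effects[effects$cluster == cl, , drop = FALSE]
           else NULL
    if (!is.null(eff) && nrow(eff) > 0) {
      vid <- if (!is.null(eff$variant)) eff$variant[1] else {
        cand <- g$variants[g$variants$chrom == ch, ]
        cand$id[which.min(abs(cand$pos - donor))]
      }
      dos <- g$dosage[, match(vid, g$variants$id)]
      dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
      logits[, 1] <- logits[, 1] + eff$beta[1] * dos
      truth[[length(truth) + 1]] <- data.frame(
        kind = "sqtl", feature = paste0("clu", cl, "_j1"),
        cluster = paste0("clu", cl), variant = vid, beta = eff$beta[1],
        stringsAsFactors = FALSE
      )
    }
    if (batch_effect != 0)
      logits[, 1] <- logits[, 1] +
        batch_effect * (as.integer(batches) > 1)
    pr <- exp(logits - apply(logits, 1, max))
    pr <- pr / rowSums(pr)
    tot <- stats::rnbinom(n, mu = cfg$cluster_depth, size = cfg$nb_size)
    cnt <- matrix(0L, k[cl], n)
    for (s in seq_len(n)) if (tot[s] > 0)
      cnt[, s] <- stats::rmultinom(1, tot[s], pr[s, ])
    counts[[cl]] <- cnt
  }
  jmeta <- do.call(rbind, meta)
  jmeta$junction_id <- paste0(jmeta$cluster_true, "_j",
                              unlist(lapply(k, seq_len)))
  cnt <- do.call(rbind, counts)
  dimnames(cnt) <- list(jmeta$junction_id, g$samples)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(), feature = character(),
               cluster = character(), variant = character(),
               beta = numeric())
  list(junctions = jmeta, counts = cnt, truth = truth, batches = batches)
}

#' Simulate gene expression counts with planted eQTLs
#'
#' Log2-scale expression is Gaussian around a per-gene baseline, with an
#' additive dosage effect (in residual-SD units) for planted eQTLs and an
#' additive per-batch offset; counts are Poisson around
#' `libsize * 2^logexpr` with library sizes varying two-fold.
#'
#' @param g a [genotype_matrix].
#' @param cfg a [sim_config].
#' @param effects data.frame `(gene, beta)` (gene indexes 1..n_genes;
#'   beta in residual-SD units per alt allele); optional `variant` column.
#' @param batch_effect additive log2 offset for batches after the first.
#' @return list with `genes` (data.frame `gene_id`, `chrom`, `tss`),
#'   `counts` (genes x samples), `truth`, `batches`.
#' @export
simulate_expression <- function(g, cfg, effects = NULL, batch_effect = 0) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "sim_config"))
  set.seed(sub_seed(cfg$seed, "expression"))
  if (!is.null(effects) && any(effects$gene > cfg$n_genes))
    stop("effect on non-existent gene")
  n <- cfg$n_samples
  batches <- sim_batches(cfg)
  chrs <- unique(g$variants$chrom)
  per_chr <- ceiling(cfg$n_genes / length(chrs))
  span <- floor(cfg$chrom_len / (per_chr + 1))
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
    chrom = chrs[((seq_len(cfg$n_genes) - 1) %% length(chrs)) + 1],
    tss = (((seq_len(cfg$n_genes) - 1) %/% length(chrs)) + 1) * span,
    stringsAsFactors = FALSE
  )
  libsize <- stats::runif(n, 1, 2) * 1e6
  base <- stats::runif(cfg$n_genes, 3, 8)
  logex <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n) + base
  truth <- list()
  if (!is.null(effects)) for (i in seq_len(nrow(effects))) {
    gi <- effects$gene[i]
    vid <- if (!is.null(effects$variant)) effects$variant[i] else {
      cand <- g$variants[g$variants$chrom == genes$chrom[gi], ]
      cand$id[which.min(abs(cand$pos - genes$tss[gi]))]
    }
    dos <- g$dosage[, match(vid, g$variants$id)]
    dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
    logex[gi, ] <- logex[gi, ] + effects$beta[i] * dos
    truth[[length(truth) + 1]] <- data.frame(
      kind = "eqtl", feature = genes$gene_id[gi], cluster = NA_character_,
      variant = vid, beta = effects$beta[i], stringsAsFactors = FALSE
    )
  }
  if (batch_effect != 0)
    logex <- logex + rep(batch_effect * (as.integer(batches) > 1),
                         each = cfg$n_genes)
  mu <- t(t(2^logex / 2^6) * libsize / 1e3)  # typical bulk RNA-seq depth
  counts <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  dimnames(counts) <- list(genes$gene_id, g$samples)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(), feature = character(),
               cluster = character(), variant = character(),
               beta = numeric())
  list(genes = genes, counts = counts, truth = truth, batches = batches,
       libsize = libsize)
}

#' Simulate GWAS summary statistics at a locus
#'
#' Z-scores follow the standard multivariate-normal model: z ~ N(R lambda,
#' R) where R is the locus LD correlation matrix and lambda has a single
#' nonzero entry `sqrt(n_gwas) * beta_gwas` at the causal variant. Effect
#' sizes and standard errors are back-filled from allele frequency and
#' sample size via `se = 1/sqrt(2 f (1-f) n)`.
#'
#' @param g a [genotype_matrix] supplying LD and allele frequencies.
#' @param locus_ids variant ids forming the locus.
#' @param causal_id causal variant id (`NA` for a null locus).
#' @param beta_gwas causal effect size per allele.
#' @param n_gwas GWAS sample size.
#' @param seed integer seed.
#' @param ridge_eps ridge added to R when its Cholesky fails.
#' @return `gwas_summary` data.frame for the locus.
#' @export
simulate_gwas <- function(g, locus_ids, causal_id = NA, beta_gwas = 0,
                          n_gwas = 50000, seed = 1L, ridge_eps = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.na(causal_id) && !(causal_id %in% locus_ids))
    stop("causal variant not in locus")
  set.seed(as.integer(seed) %% 2147483562L)
  R <- ld_matrix(g, locus_ids)
  m <- length(locus_ids)
  lam <- numeric(m)
  if (!is.na(causal_id))
    lam[match(causal_id, locus_ids)] <- sqrt(n_gwas) * beta_gwas
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(R + diag(ridge_eps, m))
  z <- drop(R %*% lam) + drop(crossprod(ch, stats::rnorm(m)))
  vi <- match(locus_ids, g$variants$id)
  st <- variant_stats(g)[vi, ]
  f <- pmin(pmax(st$freq, 0.01), 0.99)
  se <- 1 / sqrt(2 * f * (1 - f) * n_gwas)
  gwas_summary(data.frame(
    id = locus_ids, chrom = g$variants$chrom[vi], pos = g$variants$pos[vi],
    beta = z * se, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)), n = n_gwas, freq = f,
    stringsAsFactors = FALSE
  ))
}

#' Simulate genomic annotations
#'
#' Builds a collection of interval sets over the simulated genome:
#' splice-site windows (8 bp each side of every junction boundary), exon,
#' intron, promoter and enhancer classes that occupy mutually exclusive
#' genic space, plus one blacklist and one MHC-analog region per genome
#' (for exercising control-shuffle exclusions).
#'
#' @param cfg a [sim_config].
#' @param junctions junction table from [simulate_junction_counts].
#' @param genes gene table from [simulate_expression].
#' @return named list of [interval_set]s: `splice_site`, `exon`, `intron`,
#'   `promoter`, `enhancer`, `blacklist`, `mhc`.
#' @export
simulate_annotations <- function(cfg, junctions, genes) {
  pad <- 8L
  ss <- rbind(
    data.frame(chrom = junctions$chrom,
               start = junctions$intron_start - pad - 1L,
               end = junctions$intron_start + pad),
    data.frame(chrom = junctions$chrom,
               start = junctions$intron_end - pad - 1L,
               end = junctions$intron_end + pad)
  )
  ss <- merge_intervals(interval_set(ss$chrom, pmax(ss$start, 0L), ss$end))
  # gene bodies: TSS .. TSS + 20 kb; alternate exon/intron in 2 kb tiles
  tiles <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    s <- seq(genes$tss[i], genes$tss[i] + 18000, by = 2000)
    data.frame(chrom = genes$chrom[i], start = s, end = s + 2000,
               class = rep(c("exon", "intron"), length.out = length(s)))
  }))
  prom <- interval_set(genes$chrom, pmax(genes$tss - 2000, 0), genes$tss,
                       name = "promoter")
  enh <- interval_set(genes$chrom, genes$tss + 25000, genes$tss + 26000,
                      name = "enhancer")
  subtract <- function(iv, excl) {
    keep <- lapply(split(seq_len(nrow(iv)), iv$chrom), function(idx) {
      ch <- iv$chrom[idx[1]]
      a <- IRanges::IRanges(iv$start[idx] + 1L, iv$end[idx])
      esel <- excl$chrom == ch
      if (!any(esel)) d <- a
      else d <- IRanges::setdiff(a, IRanges::IRanges(excl$start[esel] + 1L,
                                                     excl$end[esel]))
      if (length(d) == 0) return(NULL)
      data.frame(chrom = ch, start = IRanges::start(d) - 1L,
                 end = IRanges::end(d))
    })
    keep <- do.call(rbind, keep)
    if (is.null(keep) || nrow(keep) == 0) return(NULL)
    interval_set(keep$chrom, keep$start, keep$end)
  }
  exon <- subtract(interval_set(tiles$chrom[tiles$class == "exon"],
                                tiles$start[tiles$class == "exon"],
                                tiles$end[tiles$class == "exon"]), ss)
  intron_cls <- interval_set(tiles$chrom[tiles$class == "intron"],
                             tiles$start[tiles$class == "intron"],
                             tiles$end[tiles$class == "intron"])
  intron_cls <- subtract(intron_cls, merge_intervals(rbind_iv(ss, exon)))
  prom <- subtract(prom, merge_intervals(rbind_iv(ss, exon, intron_cls)))
  enh <- subtract(enh, merge_intervals(rbind_iv(ss, exon, intron_cls, prom)))
  list(
    splice_site = ss, exon = exon, intron = intron_cls,
    promoter = prom, enhancer = enh,
    blacklist = interval_set("chr1", cfg$chrom_len - 60000,
                             cfg$chrom_len - 50000, name = "blacklist"),
    mhc = interval_set(paste0("chr", cfg$n_chrom), cfg$chrom_len - 120000,
                       cfg$chrom_len - 80000, name = "mhc_analog")
  )
}

## internal: rbind interval sets, dropping NULLs
rbind_iv <- function(...) {
  xs <- Filter(Negate(is.null), list(...))
  out <- do.call(rbind, lapply(xs, as.data.frame))
  interval_set(out$chrom, out$start, out$end)
}

#' Write planted truth to a TSV
#' @param truth data.frame of planted effects.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}
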