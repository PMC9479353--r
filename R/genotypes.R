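#' Construct a genotype matrix
#'
#' Container for biallelic SNP dosages together with per-variant metadata.
#' Dosages are counts of the alternate allele in \{0, 1, 2\} with `NA` for
#' missing genotypes. Minor allele frequency and missing rate are recomputed
#' from the dosage matrix at construction so the stored metadata can never
#' drift from the data.
#'
#' @param dosage numeric matrix, samples x variants, values in \{0, 1, 2, NA\}.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   (one row per column of `dosage`, same order).
#' @param samples character vector of sample ids (one per row of `dosage`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `variants` (with `maf` and `missing_rate` columns filled) and
#'   `samples`.
#' @export
genotype_matrix <- function(dosage, variants, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  stopifnot(
    nrow(variants) == ncol(dosage),
    length(samples) == nrow(dosage),
    all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants))
  )
  if (anyDuplicated(variants$id))
    stop("duplicate variant id: ", variants$id[duplicated(variants$id)][1])
  bad <- variants$ref == variants$alt
  if (any(bad)) stop("ref == alt for variant ", variants$id[which(bad)[1]])
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be in {0, 1, 2, NA}")
  dimnames(dosage) <- list(samples, variants$id)
  st <- dosage_stats(dosage)
  variants$maf <- st$maf
  variants$missing_rate <- st$missing_rate
  structure(
    list(dosage = dosage, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants (%d chromosome%s)\n",
    length(x$samples), nrow(x$variants),
    length(unique(x$variants$chrom)),
    if (length(unique(x$variants$chrom)) == 1) "" else "s"
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

## internal: per-column alt-allele frequency, maf, missing rate, counts
dosage_stats <- function(dosage) {
  n_nonmiss <- colSums(!is.na(dosage))
  alt <- colSums(dosage, na.rm = TRUE)
  freq <- ifelse(n_nonmiss > 0, alt / (2 * n_nonmiss), NA_real_)
  list(
    freq = freq,
    maf = pmin(freq, 1 - freq),
    missing_rate = 1 - n_nonmiss / nrow(dosage),
    n0 = colSums(dosage == 0, na.rm = TRUE),
    n1 = colSums(dosage == 1, na.rm = TRUE),
    n2 = colSums(dosage == 2, na.rm = TRUE)
  )
}

#' Per-variant summary statistics
#'
#' @param g a [genotype_matrix].
#' @return data.frame with one row per variant: `id`, alt-allele frequency
#'   `freq`, `maf`, `missing_rate` and genotype counts `n0`, `n1`, `n2`.
#'   All-missing variants get `maf = NA` and `all_missing = TRUE`.
#' @export
variant_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"), nrow(g$variants) > 0)
  st <- dosage_stats(g$dosage)
  data.frame(
    id = g$variants$id, freq = st$freq, maf = st$maf,
    missing_rate = st$missing_rate,
    n0 = st$n0, n1 = st$n1, n2 = st$n2,
    all_missing = is.na(st$maf),
    stringsAsFactors = FALSE
  )
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on genotype counts: conditioning on the observed
#' allele counts, the p-value is the total probability of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count. Probabilities are evaluated with the standard recurrence over
#' heterozygote counts, which is numerically stable for large samples.
#'
#' @param n_homref,n_het,n_homalt non-negative genotype counts.
#' @return p-value in (0, 1]. Monomorphic samples return 1.
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  stopifnot(n_homref >= 0, n_het >= 0, n_homalt >= 0)
  n <- n_homref + n_het + n_homalt
  if (n < 1) stop("empty genotype table")
  n_rare <- 2 * min(n_homref, n_homalt) + n_het
  if (n_rare == 0) return(1)

  # heterozygote counts share the parity of the minor allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  probs <- numeric(length(hets))
  # start at the mode-adjacent midpoint and recurse outward:
  # P(h+2)/P(h) = (n_rare-h)(2n-n_rare-h) / ((h+2)(h+1))
  mid_i <- which.min(abs(hets - n_rare * (2 * n - n_rare) / (2 * n)))
  probs[mid_i] <- 1
  if (mid_i < length(hets)) {
    for (i in mid_i:(length(hets) - 1)) {
      h <- hets[i]
      probs[i + 1] <- probs[i] *
        (n_rare - h) * (2 * n - n_rare - h) / ((h + 2) * (h + 1))
    }
  }
  if (mid_i > 1) {
    for (i in mid_i:2) {
      h <- hets[i]
      probs[i - 1] <- probs[i] * h * (h - 1) /
        ((n_rare - h + 2) * (2 * n - n_rare - h + 2))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

#' Variant-level quality control
#'
#' Removes variants failing, in order, the MAF, missingness and
#' Hardy-Weinberg filters; each removed variant is reported once with the
#' first failing rule.
#'
#' @param g a [genotype_matrix].
#' @param maf_min variants with MAF below this are removed (default 0.01).
#' @param miss_max variants with missing rate at or above this are removed
#'   (default 0.05).
#' @param hwe_min variants with exact HWE p-value at or below this are
#'   removed (default 1e-6).
#' @return list with `genotypes` (filtered [genotype_matrix]) and `removed`
#'   (data.frame of `id`, `reason` in \{"maf", "missing", "hwe"\}).
#' @export
qc_filter_variants <- function(g, maf_min = 0.01, miss_max = 0.05,
                               hwe_min = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"),
            maf_min >= 0, maf_min <= 1, miss_max >= 0, miss_max <= 1)
  st <- variant_stats(g)
  hwe_p <- mapply(hwe_exact_test, st$n0, st$n1, st$n2)
  reason <- rep(NA_character_, nrow(st))
  reason[is.na(reason) & (is.na(st$maf) | st$maf < maf_min)] <- "maf"
  reason[is.na(reason) & st$missing_rate >= miss_max] <- "missing"
  reason[is.na(reason) & hwe_p <= hwe_min] <- "hwe"
  keep <- is.na(reason)
  if (!any(keep)) warning("all variants removed by QC")
  removed <- data.frame(id = st$id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- genotype_matrix(
    g$dosage[, keep, drop = FALSE],
    g$variants[keep, c("id", "chrom", "pos", "ref", "alt"), drop = FALSE],
    g$samples
  )
  list(genotypes = out, removed = removed)
}

#' Drop duplicate samples
#'
#' Sample-level QC reduced to duplicate detection: samples whose dosage
#' correlation with an earlier sample exceeds `r_max` are dropped (the
#' later sample of each pair).
#'
#' @param g a [genotype_matrix].
#' @param r_max dosage correlation above which two samples are duplicates.
#' @return list with `genotypes` and `dropped` (character vector of ids).
#' @export
drop_duplicate_samples <- function(g, r_max = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- impute_mean_cols(t(g$dosage))  # variants x samples
  cc <- suppressWarnings(stats::cor(d))
  cc[upper.tri(cc, diag = TRUE)] <- 0
  dup <- apply(cc > r_max, 1, any, na.rm = TRUE)
  if (!any(dup)) return(list(genotypes = g, dropped = character(0)))
  out <- genotype_matrix(
    g$dosage[!dup, , drop = FALSE],
    g$variants[, c("id", "chrom", "pos", "ref", "alt")],
    g$samples[!dup]
  )
  list(genotypes = out, dropped = g$samples[dup])
}

## internal: mean-impute NA entries per column (used only inside LD and
## regression computations; stored dosages are never modified)
impute_mean_cols <- function(x) {
  if (!anyNA(x)) return(x)
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- mu[idx[, 2]]
  x
}

#' Linkage disequilibrium (r-squared) around a focal variant
#'
#' Squared Pearson correlation of dosages between the focal variant and all
#' variants on the same chromosome within `window_bp`, computed over samples
#' non-missing in both variants.
#'
#' @param g a [genotype_matrix].
#' @param focal variant id present in `g`.
#' @param window_bp half-width of the window in bp (default 1 Mb).
#' @return named numeric vector of r-squared values (includes the focal
#'   variant itself, r2 = 1). Zero-variance pairs yield `NA`.
#' @export
ld_r2 <- function(g, focal, window_bp = 1e6) {
  stopifnot(inherits(g, "genotype_matrix"), window_bp > 0)
  i <- match(focal, g$variants$id)
  if (is.na(i)) stop("focal variant not found: ", focal)
  v <- g$variants
  sel <- which(v$chrom == v$chrom[i] & abs(v$pos - v$pos[i]) <= window_bp)
  x <- g$dosage[, i]
  r <- suppressWarnings(drop(stats::cor(
    x, g$dosage[, sel, drop = FALSE], use = "pairwise.complete.obs")))
  stats::setNames(r^2, v$id[sel])
}

#' Signed LD correlation matrix for a set of variants
#'
#' Pearson correlation of dosage columns (missing entries mean-imputed),
#' as used by fine-mapping, conditional analysis and TWAS. Zero-variance
#' columns produce zero off-diagonal correlation and unit diagonal.
#'
#' @param g a [genotype_matrix].
#' @param ids variant ids (default: all).
#' @return correlation matrix with `ids` as dimnames.
#' @export
ld_matrix <- function(g, ids = g$variants$id) {
  stopifnot(inherits(g, "genotype_matrix"))
  j <- match(ids, g$variants$id)
  if (anyNA(j)) stop("unknown variant id(s): ", paste(ids[is.na(j)], collapse = ", "))
  d <- impute_mean_cols(g$dosage[, j, drop = FALSE])
  sds <- apply(d, 2, stats::sd)
  r <- suppressWarnings(stats::cor(d))
  r[is.na(r)] <- 0
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  attr(r, "zero_variance") <- ids[sds == 0]
  r
}
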