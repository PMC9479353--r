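#' Load genotypes from a VCF file
#'
#' Reads a VCF (v4.x) with GT or DS genotype fields into a
#' [genotype_matrix]. Only biallelic SNP records are kept; multiallelic
#' records are skipped and counted. Parsing is delegated to
#' \pkg{vcfR}.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @return a [genotype_matrix]; the number of skipped multiallelic records
#'   is attached as attribute `n_multiallelic_skipped` (with a warning when
#'   nonzero).
#' @export
load_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0)
    warning(n_multi, " multiallelic record(s) skipped")
  keep <- !multi
  real_id <- fix$ID[!is.na(fix$ID) & fix$ID != "."]
  if (anyDuplicated(real_id))
    stop("duplicate variant id: ", real_id[duplicated(real_id)][1])
  fmt <- colnames(v@gt)[1]
  fields <- strsplit(unname(v@gt[1, 1]), ":", fixed = TRUE)[[1]]
  if (fmt != "FORMAT") stop("malformed VCF: missing FORMAT column")
  if ("DS" %in% fields) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dos <- round(ds)
  } else if ("GT" %in% fields) {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gsub("|", "/", gt, fixed = TRUE)
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    dos[gt %in% c("0/0")] <- 0
    dos[gt %in% c("0/1", "1/0")] <- 1
    dos[gt %in% c("1/1")] <- 2
  } else stop("VCF has neither GT nor DS genotype fields")
  dos <- dos[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id])
  if (anyDuplicated(ids))
    stop("duplicate variant id: ", ids[duplicated(ids)][1])
  variants <- data.frame(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  g <- genotype_matrix(t(dos), variants, samples = colnames(dos))
  attr(g, "n_multiallelic_skipped") <- n_multi
  g
}

#' Write a genotype matrix as a VCF file
#'
#' Writes a minimal VCF v4.2 with GT fields, records sorted by
#' (chrom, pos). Missing dosages become `./.`.
#'
#' @param g a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  ord <- order(v$chrom, v$pos)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  )
  body <- vapply(ord, function(i) {
    d <- g$dosage[, i]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Load GWAS summary statistics
#'
#' Reads a TSV with header columns `id chrom pos ref alt beta se z p n freq`
#' (`ref`, `alt` and `z` optional; `z` is filled from `beta/se` when
#' absent).
#'
#' @param path path to the TSV.
#' @return data.frame of class `gwas_summary`, sorted by (chrom, pos).
#' @export
load_gwas_summary <- function(path) {
  x <- as.data.frame(data.table::fread(path), stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "beta", "se", "p", "n", "freq")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(x$se < 0, na.rm = TRUE)) stop("negative standard error")
  gwas_summary(x)
}

#' Construct / validate a GWAS summary-statistics table
#'
#' @param x data.frame with columns `id chrom pos beta se p n freq` and
#'   optionally `z`.
#' @return validated data.frame of class `gwas_summary` sorted by
#'   (chrom, pos).
#' @export
gwas_summary <- function(x) {
  if (!("z" %in% names(x)) || all(is.na(x$z))) x$z <- x$beta / x$se
  both <- !is.na(x$z) & !is.na(x$beta) & !is.na(x$se) & x$se > 0
  if (any(abs(x$z[both] - x$beta[both] / x$se[both]) > 1e-6))
    stop("z inconsistent with beta/se")
  if (any(x$p <= 0 | x$p > 1, na.rm = TRUE)) stop("p-values must be in (0, 1]")
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("gwas_summary", "data.frame")
  x
}

#' @rdname load_gwas_summary
#' @param gwas a `gwas_summary` data.frame.
#' @export
write_gwas_summary <- function(gwas, path) {
  data.table::fwrite(as.data.frame(gwas)[order(gwas$chrom, gwas$pos), ],
                     path, sep = "\t")
  invisible(path)
}

#' Interval sets (BED convention)
#'
#' Genomic intervals stored 0-based half-open, as in BED. `interval_set()`
#' validates and sorts; `load_intervals()` / `write_intervals()` read and
#' write BED3+ files; `interval_overlap()` tests which 1-based positions
#' fall inside a set (via \pkg{IRanges}).
#'
#' @param chrom,start,end,name interval fields; `start` 0-based inclusive,
#'   `end` 0-based exclusive.
#' @return `interval_set`: data.frame with class `interval_set`.
#' @export
interval_set <- function(chrom, start, end,
                         name = paste0("iv", seq_along(chrom))) {
  x <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), name = as.character(name),
                  stringsAsFactors = FALSE)
  if (any(x$start >= x$end)) stop("intervals must satisfy start < end")
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("interval_set", "data.frame")
  x
}

#' @rdname interval_set
#' @param path path to a BED file (3+ columns, no header).
#' @export
load_intervals <- function(path) {
  x <- as.data.frame(data.table::fread(path, header = FALSE))
  if (ncol(x) < 3) stop("BED file needs at least 3 columns")
  interval_set(x[[1]], x[[2]], x[[3]],
               name = if (ncol(x) >= 4) x[[4]] else paste0("iv", seq_len(nrow(x))))
}

#' @rdname interval_set
#' @param iv an `interval_set`.
#' @export
write_intervals <- function(iv, path) {
  data.table::fwrite(as.data.frame(iv), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname interval_set
#' @param pos_chrom,pos 1-based positions to test.
#' @return `interval_overlap`: logical vector, TRUE where the position lies
#'   inside some interval of the set.
#' @export
interval_overlap <- function(iv, pos_chrom, pos) {
  stopifnot(length(pos_chrom) == length(pos))
  out <- logical(length(pos))
  for (ch in unique(pos_chrom)) {
    sel <- iv$chrom == ch
    if (!any(sel)) next
    # BED [start, end) covers 1-based positions start+1 .. end
    ir <- IRanges::IRanges(start = iv$start[sel] + 1L, end = iv$end[sel])
    qi <- which(pos_chrom == ch)
    q <- IRanges::IRanges(start = pos[qi], width = 1L)
    out[qi] <- IRanges::overlapsAny(q, ir)
  }
  out
}

## internal: total bp of an interval set restricted to one chromosome,
## merged; and complement within [0, len)
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  out <- lapply(split(seq_len(nrow(iv)), iv$chrom), function(idx) {
    ir <- IRanges::reduce(IRanges::IRanges(iv$start[idx] + 1L, iv$end[idx]))
    data.frame(chrom = iv$chrom[idx[1]], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  })
  out <- do.call(rbind, out)
  interval_set(out$chrom, out$start, out$end)
}
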