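#' Pipeline configuration
#'
#' Validated configuration for the end-to-end demonstration pipeline.
#' Unknown keys are rejected. Analysis thresholds default to the values
#' used throughout the package: FDR 0.01, cis windows 500 kb
#' (expression) / 50 kb (splicing), colocalization decision PP 0.8, TWAS
#' gate PP 0.6, 95% credible sets, variant MAF floor 0.01, QQ MAF floor
#' 0.05.
#'
#' @param ... overrides for the defaults listed below.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sim = sim_config(),
    fdr = 0.01, perms = 300, cis_window_e = 500000, cis_window_s = 50000,
    coloc_pp = 0.8, twas_gate = 0.6, credible_level = 0.95,
    maf_min = 0.01, qq_maf = 0.05, qq_controls = 200,
    n_expr_pcs = 5, n_spl_pcs = 3,
    n_sqtl = 10, n_eqtl = 10, sqtl_beta = 1.5, eqtl_beta = 0.8,
    batch_effect = 0.5, gwas_n = 50000, gwas_z = 8,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "pipeline_config")
}

## internal: md5 of an R object (via serialization to a temp file)
obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the demonstration pipeline on synthetic data
#'
#' Stages: simulate genotypes/phenotypes/GWAS with planted truth;
#' quantify phenotypes; map cis-sQTLs and cis-eQTLs (permutation pass,
#' Storey q-values, hierarchical nominal thresholds); QQ inflation
#' against LD-matched controls; fine-map QTL and GWAS signals;
#' colocalize; TWAS with colocalization gating; integrate credible sets
#' and nominate effector features. Every stage writes a TSV into
#' `out_dir`; a JSON manifest records parameters, seeds and stage
#' hashes, and stages whose hash is unchanged on a rerun are logged as
#' cache hits (their outputs are left untouched).
#'
#' @param cfg a [pipeline_config].
#' @param out_dir output directory (created).
#' @return invisible list with the main in-memory results.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  manifest <- list(package_version = as.character(utils::packageVersion("isletqtl")),
                   seed = cfg$seed, stages = list())
  upstream_hash <- ""
  stage <- function(name, params, outputs, compute) {
    h <- obj_hash(list(params, upstream_hash))
    upstream_hash <<- h
    cached <- !is.null(old_manifest$stages[[name]]) &&
      identical(old_manifest$stages[[name]]$hash, h) &&
      all(file.exists(file.path(out_dir, outputs)))
    manifest$stages[[name]] <<- list(hash = h, cached = cached,
                                     outputs = outputs)
    message(sprintf("[isletqtl] stage %-10s %s", name,
                    if (cached) "(cache hit)" else "running"))
    compute(cached)
  }
  tsv <- function(x, f) data.table::fwrite(as.data.frame(x),
                                           file.path(out_dir, f), sep = "\t")

  ## --- simulate -------------------------------------------------------
  sim <- NULL
  stage("simulate", cfg[c("sim", "n_sqtl", "n_eqtl", "sqtl_beta",
                          "eqtl_beta", "batch_effect", "gwas_n",
                          "gwas_z", "seed")],
        c("truth.tsv"), function(cached) {
    g <- simulate_genotypes(cfg$sim)
    sq_eff <- data.frame(cluster = seq_len(cfg$n_sqtl),
                         beta = cfg$sqtl_beta)
    eq_eff <- data.frame(gene = seq_len(cfg$n_eqtl), beta = cfg$eqtl_beta)
    jc <- simulate_junction_counts(g, cfg$sim, sq_eff,
                                   batch_effect = cfg$batch_effect)
    ex <- simulate_expression(g, cfg$sim, eq_eff,
                              batch_effect = cfg$batch_effect)
    # GWAS loci: shared / linked / distinct relative to planted eQTLs
    beta_g <- cfg$gwas_z / sqrt(cfg$gwas_n)
    mk_locus <- function(i, mode) {
      causal_qtl <- ex$truth$variant[i]
      blk <- g$variants$block[match(causal_qtl, g$variants$id)]
      in_blk <- g$variants$id[g$variants$block == blk]
      ch <- g$variants$chrom[match(causal_qtl, g$variants$id)]
      pos <- g$variants$pos[match(causal_qtl, g$variants$id)]
      near <- g$variants$id[g$variants$chrom == ch &
                            abs(g$variants$pos - pos) <= 5e4]
      causal <- switch(mode,
        shared = causal_qtl,
        linked = setdiff(in_blk, causal_qtl)[1],
        distinct = {
          far <- g$variants[g$variants$chrom == ch &
                            abs(g$variants$pos - pos) > 3e4 &
                            abs(g$variants$pos - pos) <= 5e4 &
                            g$variants$block != blk, ]
          if (nrow(far)) far$id[1] else setdiff(near, in_blk)[1]
        })
      if (is.na(causal)) causal <- causal_qtl
      gw <- simulate_gwas(g, near, causal, beta_g, cfg$gwas_n,
                          seed = sub_seed(cfg$seed, paste0("gwas", i)))
      list(locus = paste0("locus_", mode, "_", i), mode = mode,
           feature = ex$truth$feature[i], causal = causal, gwas = gw,
           lead = gw$id[which.max(abs(gw$z))])
    }
    modes <- rep(c("shared", "linked", "distinct"),
                 length.out = min(6, cfg$n_eqtl))
    loci <- lapply(seq_along(modes), function(i) mk_locus(i, modes[i]))
    truth <- rbind(jc$truth, ex$truth)
    gw_truth <- do.call(rbind, lapply(loci, function(l)
      data.frame(kind = "gwas", feature = l$locus, cluster = NA,
                 variant = l$causal, beta = beta_g, mode = l$mode)))
    truth$mode <- NA_character_
    sim <<- list(g = g, jc = jc, ex = ex, loci = loci,
                 truth = rbind(truth, gw_truth))
    if (!cached) tsv(sim$truth, "truth.tsv")
  })
  g <- sim$g

  ## --- phenotypes -----------------------------------------------------
  ph <- NULL
  stage("phenotypes", cfg[c("n_expr_pcs", "n_spl_pcs")],
        c("psi.tsv", "expression.tsv"), function(cached) {
    fj <- filter_junctions(sim$jc$junctions, sim$jc$counts)
    cl <- cluster_junctions(fj$junctions, fj$counts)
    psi_raw <- compute_psi(cl)
    psi_std <- batch_adjust(standardize(psi_raw), sim$jc$batches)
    spcs <- phenotype_pcs(psi_std, cfg$n_spl_pcs)
    ec <- filter_genes(sim$ex$counts)
    le <- cpm_log2(ec)
    epm <- phenotype_matrix(
      le, data.frame(feature = rownames(le),
                     chrom = sim$ex$genes$chrom[match(rownames(le),
                                                      sim$ex$genes$gene_id)],
                     start = sim$ex$genes$tss[match(rownames(le),
                                                    sim$ex$genes$gene_id)],
                     end = sim$ex$genes$tss[match(rownames(le),
                                                  sim$ex$genes$gene_id)]),
      kind = "expression")
    epm <- batch_adjust(epm, sim$ex$batches)
    epcs <- phenotype_pcs(epm, cfg$n_expr_pcs)
    ph <<- list(psi_raw = psi_raw, psi = psi_std, spcs = spcs,
                expr = epm, epcs = epcs)
    if (!cached) {
      tsv(cbind(ph$psi$anchors, ph$psi$values), "psi.tsv")
      tsv(cbind(ph$expr$anchors, ph$expr$values), "expression.tsv")
    }
  })

  ## --- QTL mapping ----------------------------------------------------
  qtl <- NULL
  stage("qtl", cfg[c("fdr", "perms", "cis_window_e", "cis_window_s")],
        c("sqtl_perm.tsv", "eqtl_perm.tsv", "delta_psi.tsv"),
        function(cached) {
    run1 <- function(pm, cov) {
      perm <- permutation_pass_all(pm, g, cov, B = cfg$perms,
                                   seed = cfg$seed,
                                   window_e = cfg$cis_window_e,
                                   window_s = cfg$cis_window_s,
                                   fdr = cfg$fdr)
      nom <- do.call(rbind, lapply(pm$anchors$feature, function(f)
        nominal_scan(pm, g, cov, f, window_e = cfg$cis_window_e,
                     window_s = cfg$cis_window_s)))
      calls <- call_significant(perm, nom, fdr = cfg$fdr)
      list(perm = perm, nom = nom, calls = calls)
    }
    sq <- run1(ph$psi, ph$spcs)
    eq <- run1(ph$expr, ph$epcs)
    dpsi <- delta_psi(ph$psi_raw, g, sq$perm, sq$calls)
    qtl <<- list(sq = sq, eq = eq, dpsi = dpsi)
    if (!cached) {
      tsv(sq$perm, "sqtl_perm.tsv"); tsv(eq$perm, "eqtl_perm.tsv")
      tsv(dpsi, "delta_psi.tsv")
    }
  })

  ## --- QQ inflation against matched controls --------------------------
  qq <- NULL
  stage("qq", cfg[c("qq_maf", "qq_controls")], c("qq.tsv"),
        function(cached) {
    anns <- simulate_annotations(cfg$sim, sim$jc$junctions, sim$ex$genes)
    blocks <- infer_ld_blocks(g)
    gwas_all <- do.call(rbind, lapply(sim$loci, function(l) l$gwas))
    gwas_all <- gwas_all[!duplicated(gwas_all$id), ]
    # background p-values for variants outside simulated loci
    others <- setdiff(g$variants$id, gwas_all$id)
    set.seed(sub_seed(cfg$seed, "qq_bg"))
    zbg <- stats::rnorm(length(others))
    vi <- match(others, g$variants$id)
    bg <- gwas_summary(data.frame(
      id = others, chrom = g$variants$chrom[vi], pos = g$variants$pos[vi],
      beta = zbg, se = 1, z = zbg, p = 2 * stats::pnorm(-abs(zbg)),
      n = cfg$gwas_n, freq = 0.5))
    gwas_full <- gwas_summary(rbind(as.data.frame(gwas_all),
                                    as.data.frame(bg)))
    query <- unique(qtl$eq$calls$pairs$variant)
    if (length(query) < 5)
      query <- unique(qtl$eq$calls$significant$lead)
    ctl <- build_control_sets(query, g$variants$id, g, blocks,
                              exclude = rbind_iv(anns$blacklist, anns$mhc),
                              B = cfg$qq_controls, seed = cfg$seed)
    qq <<- qq_inflation(query, gwas_full, ctl, g, maf_min = cfg$qq_maf)
    qq$gwas <<- gwas_full
    if (!cached) tsv(qq$table, "qq.tsv")
  })

  ## --- fine-mapping and colocalization ---------------------------------
  cl_res <- NULL
  stage("coloc", cfg[c("coloc_pp", "credible_level")],
        c("coloc.tsv", "credible_sets.tsv"), function(cached) {
    # QTL summary stats per locus feature; GWAS credible sets per locus
    qtl_cs <- list(); rows <- list(); loci_rec <- list()
    for (l in sim$loci) {
      feat <- l$feature
      if (!(feat %in% ph$expr$anchors$feature)) next
      nom <- qtl$eq$nom[qtl$eq$nom$feature == feat, ]
      qs <- data.frame(id = nom$variant, pos = nom$pos, beta = nom$slope,
                       se = nom$se)
      gwas_cs <- finemap_locus(l$gwas, level = cfg$credible_level)
      q_cs <- finemap_locus(
        data.frame(id = qs$id, pos = qs$pos, beta = qs$beta, se = qs$se),
        level = cfg$credible_level)
      lead <- qtl$eq$perm$lead[qtl$eq$perm$feature == feat]
      sig <- list(locus = l$locus, lead = l$lead, gwas = l$gwas,
                  credible_set = gwas_cs)
      cres <- colocalize_all(list(sig), stats::setNames(list(qs), feat),
                             stats::setNames(lead, feat), g,
                             pp_min = cfg$coloc_pp)
      if (nrow(cres)) {
        rows[[length(rows) + 1]] <- cbind(cres, mode = l$mode)
        loci_rec[[length(loci_rec) + 1]] <- list(
          locus = l$locus, coloc_pp = cres$PP4[1], gwas_cs = gwas_cs,
          qtl_cs = q_cs)
      }
      qtl_cs[[feat]] <- q_cs
    }
    coloc_tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(locus = character(), feature = character(),
                 PP4 = numeric(), colocalized = logical(),
                 mode = character())
    cl_res <<- list(coloc = coloc_tab, qtl_cs = qtl_cs,
                    loci_rec = loci_rec)
    if (!cached) {
      tsv(coloc_tab, "coloc.tsv")
      cs_all <- do.call(rbind, lapply(names(qtl_cs), function(f)
        cbind(feature = f, qtl_cs[[f]])))
      tsv(cs_all, "credible_sets.tsv")
    }
  })

  ## --- TWAS -------------------------------------------------------------
  tw <- NULL
  stage("twas", cfg[c("twas_gate")], c("twas.tsv"), function(cached) {
    rows <- list()
    for (l in sim$loci) {
      feat <- l$feature
      fi <- match(feat, ph$expr$anchors$feature)
      if (is.na(fi)) next
      win <- cis_window(ph$expr$anchors[fi, ], "expression",
                        cfg$cis_window_e, cfg$cis_window_s)
      vi <- window_variants(g, win)
      wts <- fit_weights_cv(ph$expr$values[fi, ],
                            g$dosage[, vi, drop = FALSE], ph$epcs,
                            seed = cfg$seed)
      if (!wts$heritable) next
      ids <- intersect(wts$variant, l$gwas$id)
      if (length(ids) < 1) next
      R <- ld_matrix(g, union(wts$variant, ids))
      assoc <- twas_association(wts, l$gwas, R)
      rows[[length(rows) + 1]] <- data.frame(
        locus = l$locus, feature = feat, model = wts$model,
        cv_r2 = wts$cv_r2, z = assoc$z, p = assoc$p,
        best_gwas_variant = assoc$best_gwas_variant,
        stringsAsFactors = FALSE)
    }
    res <- if (length(rows)) do.call(rbind, rows) else
      data.frame(locus = character(), feature = character(),
                 model = character(), cv_r2 = numeric(), z = numeric(),
                 p = numeric(), best_gwas_variant = character())
    if (nrow(res)) {
      res <- twas_significance(res, m_tests = nrow(res))
      res <- coloc_gate(res, cl_res$coloc, min_pp = cfg$twas_gate)
      known <- vapply(sim$loci, function(l) l$lead, character(1))
      res$locus_class <- vapply(res$best_gwas_variant, classify_locus,
                                character(1), known_leads = known, g = g)
    }
    tw <<- res
    if (!cached) tsv(res, "twas.tsv")
  })

  ## --- integration -------------------------------------------------------
  integ <- NULL
  stage("integrate", list(k = 5), c("effectors.tsv", "resolution.tsv"),
        function(cached) {
    recs <- intersect_credible_sets(cl_res$loci_rec, pp_min = cfg$coloc_pp)
    resol <- if (length(recs)) resolution_counts(recs) else
      list(before = 0, after = 0, k = 5, n_loci = 0)
    eff <- effector_table(cl_res$coloc, tw)
    planted_shared <- vapply(
      Filter(function(l) l$mode == "shared", sim$loci),
      function(l) l$feature, character(1))
    eff$planted_shared <- eff$feature %in% planted_shared
    integ <<- list(records = recs, resolution = resol, effectors = eff)
    if (!cached) {
      tsv(eff, "effectors.tsv")
      tsv(data.frame(before = resol$before, after = resol$after,
                     k = resol$k, n_loci = resol$n_loci), "resolution.tsv")
    }
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(sim = sim, phenotypes = ph, qtl = qtl, qq = qq,
                 coloc = cl_res, twas = tw, integration = integ,
                 manifest = manifest, out_dir = out_dir))
}

#' Summarize a pipeline run directory
#'
#' Reads the stage TSVs of a [run_pipeline] output directory and writes
#' deterministic summary tables: significant-feature counts, the
#' delta-PSI volcano table, the QQ table and the credible-set resolution
#' table.
#'
#' @param run_dir directory produced by [run_pipeline].
#' @return invisible list of the summary tables (also written as
#'   `report_*.tsv`).
#' @export
report <- function(run_dir) {
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (!file.exists(p)) return(data.frame())
    as.data.frame(data.table::fread(p))
  }
  sq <- rd("sqtl_perm.tsv"); eq <- rd("eqtl_perm.tsv")
  summary_tab <- data.frame(
    metric = c("n_splicing_features", "n_sqtl_significant",
               "n_expression_features", "n_eqtl_significant",
               "n_colocalized", "n_twas_significant", "n_effectors"),
    value = c(nrow(sq), sum(sq$q <= 0.01, na.rm = TRUE),
              nrow(eq), sum(eq$q <= 0.01, na.rm = TRUE),
              sum(rd("coloc.tsv")$colocalized, na.rm = TRUE),
              sum(rd("twas.tsv")$significant, na.rm = TRUE),
              nrow(rd("effectors.tsv")))
  )
  volcano <- rd("delta_psi.tsv")
  if (nrow(volcano)) volcano$neglog10_q <- -log10(pmax(volcano$q, 1e-300))
  out <- list(summary = summary_tab, volcano = volcano,
              qq = rd("qq.tsv"), resolution = rd("resolution.tsv"))
  for (nm in names(out)) {
    x <- out[[nm]]
    if (ncol(x) == 0) x <- data.frame(empty = logical(0))
    data.table::fwrite(x, file.path(run_dir,
                       paste0("report_", nm, ".tsv")), sep = "\t")
  }
  invisible(out)
}
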