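#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis chain in one validated
#' object. Unknown keys are rejected (the constructor has no `...`).
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param n_genes,n_mirnas,n_lncrnas,n_peaks synthetic data sizes.
#' @param n_reads repertoire reads simulated per subset.
#' @param p_adj_core stringent signature threshold (adjusted p).
#' @param p_cancel cancellation threshold in the isotype contrast.
#' @param de_p adjusted-p threshold for the broad mRNA DE sets.
#' @param p_mirna,p_lncrna raw-p thresholds for the miRNA (0.05) and lncRNA
#'   (0.001) screens.
#' @param dar_p raw-p threshold for the DAR screen.
#' @param window_bp DAR-to-gene assignment window (bp).
#' @param md_small,md_large MD-score radii (bp).
#' @param min_site_type minimal seed-site type for target prediction.
#' @param r_max inverse-correlation cutoff for target release.
#' @param cis_window cis labeling window (bp).
#' @param r_report co-expression summary threshold.
#' @param delta_mirna,delta_lncrna delta-abundance annotation thresholds
#'   (normalized transcripts; depth-dependent, full-depth values 1000/100).
#' @param error_rate repertoire error correction constant.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_genes = 10000, n_mirnas = 500,
                            n_lncrnas = 1000, n_peaks = 10000, n_reads = 2000,
                            p_adj_core = 1e-29, p_cancel = 0.05, de_p = 0.05,
                            p_mirna = 0.05, p_lncrna = 0.001, dar_p = 0.05,
                            window_bp = 10000, md_small = 150, md_large = 1500,
                            min_site_type = "7mer-m8", r_max = -0.5,
                            cis_window = 1e6, r_report = 0.7,
                            delta_mirna = 1000, delta_lncrna = 100,
                            error_rate = 0.008) {
  stopifnot(p_adj_core > 0, p_adj_core <= 1, p_cancel > 0, p_cancel <= 1,
            de_p > 0, de_p <= 1, p_mirna > 0, p_lncrna > 0, dar_p > 0,
            window_bp >= 0, md_small > 0, md_small < md_large,
            r_max <= 0, cis_window >= 0, error_rate >= 0, error_rate <= 1)
  min_site_type <- match.arg(min_site_type,
                             c("6mer", "7mer-A1", "7mer-m8", "8mer"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic multi-omic pipeline
#'
#' Chains simulate -> repertoire -> DE -> signature -> ATAC -> ncRNA on
#' planted synthetic data, optionally writing every output (TSV/BED/FASTA)
#' plus a JSON manifest of md5 content hashes to `outdir`. Re-running with
#' an identical config reproduces identical hashes.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (NULL = nothing written).
#' @return (Invisibly) a list with the generated data, DE tables, signature,
#'   screens, repertoire summaries and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  gcfg <- generator_config(n_genes = config$n_genes,
                           n_mirnas = config$n_mirnas,
                           n_lncrnas = config$n_lncrnas,
                           n_peaks = config$n_peaks, seed = config$seed)
  sp <- signature_plan(gcfg)
  mp <- mirna_plan(gcfg, sp)
  lp <- lncrna_plan(gcfg)

  mrna <- generate_expression(gcfg, sp)
  mirna <- generate_expression(gcfg, mp)
  lnc <- generate_expression(gcfg, lp)
  ann <- generate_annotation(gcfg, sp, mp, lp, cis_window = config$cis_window)
  atac <- generate_atac(gcfg, atac_plan(window_bp = config$window_bp),
                        expr_truth = mrna$truth, gene_ranges = ann$genes)

  # --- mRNA DE + signature -------------------------------------------------
  mcm <- filter_expressed(mrna$counts, 1, unit = "RPKM")
  de_g <- nb_exact_test(mcm, "NBC", "IgG")
  de_a <- nb_exact_test(mcm, "NBC", "IgA")
  de_iso <- nb_exact_test(mcm, "IgA", "IgG")
  sig <- core_signature(de_g, de_a, de_iso, p_adj_core = config$p_adj_core,
                        p_cancel = config$p_cancel)
  shared_de <- core_signature(de_g, de_a, NULL, p_adj_core = config$de_p,
                              p_cancel = config$p_cancel)
  logrpkm <- normalize_units(mcm, "RPKM", log2 = TRUE)
  embed <- NULL
  sig_feats <- c(sig$up, sig$down)
  if (length(sig_feats) >= 2L)
    embed <- embed_subsets(logrpkm[sig_feats, , drop = FALSE],
                           mcm$samples$subset)

  # --- miRNA screen --------------------------------------------------------
  micm <- filter_expressed(mirna$counts, 5, unit = "reads")
  mde_g <- nb_exact_test(micm, "NBC", "IgG")
  mde_a <- nb_exact_test(micm, "NBC", "IgA")
  mde_iso <- nb_exact_test(micm, "IgA", "IgG")
  # shared ncRNA profiles are defined by the two vs-NBC screens; the isotype
  # contrast is reported alongside (the "cancellation" is checked, not used
  # as a filter for these raw-p screens)
  mir_sig <- core_signature(mde_g, mde_a, NULL,
                            p_adj_core = config$p_mirna,
                            p_cancel = config$p_cancel, p_col = "p")
  mir_delta <- pmax(mde_g$delta_abundance,
                    mde_a$delta_abundance)[match(c(mir_sig$up, mir_sig$down),
                                                 mde_g$feature)]

  # --- lncRNA screen -------------------------------------------------------
  lcm <- filter_expressed(lnc$counts, 1, unit = "RPKM")
  lde_g <- nb_exact_test(lcm, "NBC", "IgG")
  lde_a <- nb_exact_test(lcm, "NBC", "IgA")
  lde_iso <- nb_exact_test(lcm, "IgA", "IgG")
  lnc_sig <- core_signature(lde_g, lde_a, NULL,
                            p_adj_core = config$p_lncrna,
                            p_cancel = config$p_cancel, p_col = "p")

  # --- ATAC ----------------------------------------------------------------
  pk <- atac$peaks
  venn <- venn_peaks(pk[S4Vectors::mcols(pk)$present_nbc],
                     pk[S4Vectors::mcols(pk)$present_mbc])
  dars <- call_dars(atac$counts, "NBC", "MBC", p_threshold = config$dar_p)
  de_dir <- rbind(data.frame(feature = shared_de$up, direction = "up"),
                  data.frame(feature = shared_de$down, direction = "down"))
  conc <- integrate_de_dar(de_dir, dars[dars$significant,
                                        c("feature", "direction")],
                           ann$genes, pk, window_bp = config$window_bp)

  # --- ncRNA screens -------------------------------------------------------
  sites <- find_seed_sites(ann$utrs,
                           ann$mirna_seqs[mir_sig$down])
  rpkm <- normalize_units(mcm, "RPKM")
  rpm <- normalize_units(micm, "RPM")
  lnc_rpkm <- normalize_units(lcm, "RPKM")
  release <- target_release_screen(shared_de$up, mir_sig$down, sites,
                                   rpm, rpkm,
                                   min_site_type = config$min_site_type,
                                   r_max = config$r_max)
  sponges <- sponge_screen(lnc_sig$up, mir_sig$down, release,
                           lnc_rpkm, rpm, rpkm)
  coexpr <- lncrna_coexpression(
    lnc_rpkm[intersect(c(lnc_sig$up, lnc_sig$down), rownames(lnc_rpkm)), ,
             drop = FALSE],
    rpkm[intersect(c(shared_de$up, shared_de$down), rownames(rpkm)), ,
         drop = FALSE],
    ann$lncrnas, ann$genes, cis_window = config$cis_window,
    r_report = config$r_report)

  # --- repertoire ----------------------------------------------------------
  rplan <- repertoire_plan(error_rate = config$error_rate)
  rep_res <- lapply(stats::setNames(nm = gcfg$subsets), function(su) {
    sim <- generate_repertoire(rplan, config$n_reads, su,
                               seed = config$seed + 600L + match(su, gcfg$subsets))
    ann_r <- assign_vdj(sim$reads, rplan$db)
    list(sim = sim, ann = ann_r,
         usage = usage_profile(ann_r, rplan$db, "V", "family"),
         cdr3 = cdr3_stats(ann_r),
         mutfreq = mutation_frequency(ann_r, error_rate = config$error_rate))
  })

  res <- list(config = config, generator = gcfg,
              plans = list(mrna = sp, mirna = mp, lncrna = lp),
              data = list(mrna = mrna, mirna = mirna, lncrna = lnc,
                          annotation = ann, atac = atac),
              de = list(mrna = list(igg = de_g, iga = de_a, iso = de_iso),
                        mirna = list(igg = mde_g, iga = mde_a, iso = mde_iso),
                        lncrna = list(igg = lde_g, iga = lde_a, iso = lde_iso)),
              signature = sig, shared_de = shared_de, embedding = embed,
              mirna_signature = mir_sig, mirna_delta = mir_delta,
              lncrna_signature = lnc_sig,
              atac_results = list(venn = venn, dars = dars, concordance = conc),
              ncrna = list(sites = sites, release = release,
                           sponges = sponges, coexpression = coexpr),
              repertoire = rep_res)
  if (!is.null(outdir)) res$manifest <- write_pipeline_outputs(res, outdir)
  invisible(res)
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_counts(res$data$mrna$counts, p("mrna_counts.tsv"), p("mrna_samples.tsv"))
  write_counts(res$data$mirna$counts, p("mirna_counts.tsv"))
  write_counts(res$data$lncrna$counts, p("lncrna_counts.tsv"))
  write_counts(res$data$atac$counts, p("atac_counts.tsv"), p("atac_samples.tsv"))
  write_bed(res$data$annotation$genes, p("genes.bed"))
  write_bed(res$data$annotation$lncrnas, p("lncrnas.bed"))
  write_bed(res$data$annotation$mirnas, p("mirnas.bed"))
  write_bed(res$data$atac$peaks, p("peaks.bed"))
  write_fasta(res$data$annotation$utrs, p("utr.fa"))
  write_fasta(res$data$annotation$mirna_seqs, p("mirna.fa"), alphabet = "RNA")
  wt <- function(d, f) utils::write.table(d, p(f), sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(res$de$mrna$igg, "de_igg_vs_nbc.tsv")
  wt(res$de$mrna$iga, "de_iga_vs_nbc.tsv")
  wt(res$de$mrna$iso, "de_igg_vs_iga.tsv")
  wt(res$signature$table, "signature.tsv")
  wt(res$ncrna$release$released, "mirna_targets.tsv")
  wt(res$ncrna$sponges, "sponges.tsv")
  for (su in names(res$repertoire))
    write_fasta(res$repertoire[[su]]$sim$reads, p(paste0("reads_", su, ".fa")))
  files <- sort(list.files(outdir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, p("manifest.json"), dataframe = "rows",
                       pretty = TRUE)
  manifest
}
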