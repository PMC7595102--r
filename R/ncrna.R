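SITE_RANK <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer" = 4L)

#' Scan 3'UTRs for canonical miRNA seed sites
#'
#' Finds reverse-complement matches to miRNA positions 2-7 (the 6mer core)
#' and classifies each locus by extending it: a pair opposite position 8
#' upgrades to 7mer-m8, an A opposite position 1 to 7mer-A1, both to 8mer.
#' The maximal type per locus is reported; when the maximal type is not in
#' `allowed_types`, the best allowed contained type is reported instead
#' (containment consistency). Ambiguous bases never match.
#'
#' @param utrs named character vector or DNAStringSet of 3'UTRs (DNA or RNA
#'   alphabet).
#' @param mirnas named character vector or RNAStringSet of mature miRNAs
#'   (5'->3', length >= 8).
#' @param allowed_types site types to report.
#' @return data.frame: `mirna`, `gene`, `position` (0-based start of the
#'   reported site in the UTR), `type`.
#' @export
find_seed_sites <- function(utrs, mirnas,
                            allowed_types = c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
  if (is(utrs, "XStringSet")) utrs <- as.character(utrs)
  if (is(mirnas, "XStringSet")) mirnas <- as.character(mirnas)
  utrs <- chartr("Uu", "Tt", toupper(utrs))
  if (is.null(names(utrs))) names(utrs) <- paste0("utr", seq_along(utrs))
  if (is.null(names(mirnas))) names(mirnas) <- paste0("mir", seq_along(mirnas))
  allowed_types <- match.arg(allowed_types, several.ok = TRUE)
  if (any(nchar(mirnas) < 8L)) stop2("miRNAs must be at least 8 nt")

  out <- list()
  for (m in names(mirnas)) {
    core <- seed_site_string(mirnas[[m]], "6mer")
    m8_char <- substr(seed_site_string(mirnas[[m]], "7mer-m8"), 1L, 1L)
    hits <- gregexpr(core, utrs, fixed = TRUE)
    for (g in seq_along(utrs)) {
      h <- hits[[g]]; h <- h[h > 0]
      if (!length(h)) next
      u <- utrs[[g]]
      has_m8 <- h > 1L & substring(u, h - 1L, h - 1L) == m8_char
      has_a1 <- substring(u, h + 6L, h + 6L) == "A"
      full <- ifelse(has_m8 & has_a1, "8mer",
                     ifelse(has_m8, "7mer-m8",
                            ifelse(has_a1, "7mer-A1", "6mer")))
      rep_type <- vapply(full, function(ty) {
        contained <- switch(ty,
                            "8mer" = c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                            "7mer-m8" = c("7mer-m8", "6mer"),
                            "7mer-A1" = c("7mer-A1", "6mer"),
                            "6mer" = "6mer")
        ok <- contained[contained %in% allowed_types]
        if (length(ok)) ok[1] else NA_character_
      }, character(1))
      keep <- !is.na(rep_type)
      if (!any(keep)) next
      pos0 <- (h - 1L) - ifelse(rep_type %in% c("8mer", "7mer-m8"), 1L, 0L)
      out[[length(out) + 1L]] <-
        data.frame(mirna = m, gene = names(utrs)[g],
                   position = pos0[keep], type = unname(rep_type[keep]),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out) %||%
    data.frame(mirna = character(), gene = character(),
               position = integer(), type = character())
}

# Nearest-neighbor RNA stack energies (kcal/mol) for Watson-Crick stacks,
# keyed by the miRNA-strand dinucleotide (5'->3'); G:U-containing stacks get
# a flat -0.5, duplex initiation +4.09.
NN_STACK <- c(AA = -0.93, UU = -0.93, AU = -1.10, UA = -1.33,
              CU = -2.08, AG = -2.08, CA = -2.11, UG = -2.11,
              GU = -2.24, AC = -2.24, GA = -2.35, UC = -2.35,
              CG = -2.36, GG = -3.26, CC = -3.26, GC = -3.42)
NN_INIT <- 4.09
NN_WOBBLE <- -0.5

#' Hybridization free energy of a miRNA:target duplex
#'
#' Best gapless-core duplex between the miRNA and a target-site window:
#' over all antiparallel offsets, consecutive Watson-Crick (or G:U wobble)
#' pairs contribute nearest-neighbor stack energies and the most stable
#' contiguous run, plus a fixed initiation penalty, is reported. Interactions
#' no more stable than the initiation penalty (Delta G > 0), or with no
#' stackable pairs at all, are reported as NA. This is a deliberately
#' simplified duplex model (no intramolecular folding).
#'
#' @param mirna mature miRNA sequence (5'->3').
#' @param window target-site window sequence (5'->3'), 8-40 nt.
#' @return Delta G in kcal/mol (<= 0), or NA.
#' @export
duplex_energy <- function(mirna, window) {
  m <- strsplit(chartr("Tt", "Uu", toupper(as.character(mirna))), "")[[1]]
  w <- strsplit(chartr("Tt", "Uu", toupper(as.character(window))), "")[[1]]
  if (length(w) < 8L || length(w) > 40L) stop2("window must be 8-40 nt")
  r <- rev(w)
  Lm <- length(m); Lw <- length(r)
  wc <- function(x, y) (x == "A" & y == "U") | (x == "U" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
  gu <- function(x, y) (x == "G" & y == "U") | (x == "U" & y == "G")
  best <- Inf
  for (s in (1L - Lm):(Lw - 1L)) {
    i <- seq.int(max(1L, 1L - s), min(Lm, Lw - s))
    if (length(i) < 2L) next
    j <- i + s
    ok_wc <- wc(m[i], r[j]); ok_gu <- gu(m[i], r[j])
    ok <- ok_wc | ok_gu
    if (sum(ok) < 2L) next
    np <- length(i) - 1L
    e <- rep(Inf, np)
    both <- ok[-length(ok)] & ok[-1L]
    wcb <- ok_wc[-length(ok_wc)] & ok_wc[-1L]
    key <- paste0(m[i[-length(i)]], m[i[-1L]])
    e[both & wcb] <- NN_STACK[key[both & wcb]]
    e[both & !wcb] <- NN_WOBBLE
    # most negative contiguous run (stacks broken by unpaired positions)
    run <- 0; best_run <- Inf
    for (q in seq_len(np)) {
      if (is.infinite(e[q])) { run <- 0; next }
      run <- min(e[q], run + e[q])
      best_run <- min(best_run, run)
    }
    best <- min(best, best_run)
  }
  if (is.infinite(best)) return(NA_real_)
  dg <- best + NN_INIT
  if (dg > 0) NA_real_ else dg
}

#' miRNA target-release screen
#'
#' A gene is a released target of a miRNA iff the gene is upregulated, the
#' miRNA downregulated, the gene's 3'UTR carries at least one seed site of
#' type >= `min_site_type`, and the miRNA-gene expression correlation across
#' the sorted libraries is at most `r_max` (Spearman) with p <
#' `p_threshold`.
#'
#' @param up_genes character vector (or DE table with `feature`) of
#'   upregulated genes.
#' @param down_mirnas character vector (or DE table) of downregulated miRNAs.
#' @param sites seed-site table ([find_seed_sites()] output or generator
#'   truth): columns `mirna`, `gene`, `type`.
#' @param mirna_expr miRNA expression matrix (RPM), features x samples.
#' @param gene_expr gene expression matrix (RPKM), features x samples; the
#'   two matrices must share sample columns.
#' @param min_site_type minimal qualifying site type (default "7mer-m8").
#' @param r_max inverse-correlation cutoff (default -0.5).
#' @param p_threshold correlation significance cutoff (default 0.05).
#' @return A list: `released` (data.frame mirna, gene, site_type, r_s, p),
#'   `by_mirna` (list of gene vectors), `n_up`, `fraction` (released up
#'   genes / all up genes).
#' @export
target_release_screen <- function(up_genes, down_mirnas, sites, mirna_expr,
                                  gene_expr, min_site_type = "7mer-m8",
                                  r_max = -0.5, p_threshold = 0.05) {
  if (is.data.frame(up_genes)) up_genes <- up_genes$feature
  if (is.data.frame(down_mirnas)) down_mirnas <- down_mirnas$feature
  min_rank <- SITE_RANK[[min_site_type]]
  common <- intersect(colnames(mirna_expr), colnames(gene_expr))
  if (length(common) < 3L) stop2("expression matrices must share samples")
  mirna_expr <- mirna_expr[, common, drop = FALSE]
  gene_expr <- gene_expr[, common, drop = FALSE]

  n_up <- length(up_genes)
  drop_g <- setdiff(up_genes, rownames(gene_expr))
  drop_m <- setdiff(down_mirnas, rownames(mirna_expr))
  if (length(drop_g) || length(drop_m))
    message("excluded without expression: ", length(drop_g), " gene(s), ",
            length(drop_m), " miRNA(s)")
  up_genes <- setdiff(up_genes, drop_g)
  down_mirnas <- setdiff(down_mirnas, drop_m)

  qual <- sites[SITE_RANK[sites$type] >= min_rank &
                  sites$mirna %in% down_mirnas &
                  sites$gene %in% up_genes, , drop = FALSE]
  rel <- list()
  for (m in unique(qual$mirna)) {
    for (g in unique(qual$gene[qual$mirna == m])) {
      ct <- suppressWarnings(
        stats::cor.test(mirna_expr[m, ], gene_expr[g, ],
                        method = "spearman", exact = FALSE))
      if (is.na(ct$estimate) || ct$estimate > r_max || ct$p.value >= p_threshold)
        next
      best <- qual$type[qual$mirna == m & qual$gene == g]
      rel[[length(rel) + 1L]] <-
        data.frame(mirna = m, gene = g,
                   site_type = best[which.max(SITE_RANK[best])],
                   r_s = unname(ct$estimate), p = ct$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  released <- do.call(rbind, rel) %||%
    data.frame(mirna = character(), gene = character(),
               site_type = character(), r_s = numeric(), p = numeric())
  list(released = released,
       by_mirna = split(released$gene, released$mirna),
       n_up = n_up,
       fraction = length(unique(released$gene)) / max(1L, n_up))
}

#' lncRNA co-expression with cis/trans labeling
#'
#' Spearman correlation (Pearson on ranks; p by the t approximation) for
#' every lncRNA-partner pair across the shared libraries. A pair is `cis`
#' iff both features sit on the same chromosome with a gap of at most
#' `cis_window`, else `trans`. Constant expression vectors are excluded.
#' The summary reports, separately for cis and trans pairs, the fractions
#' with r_s > `r_report` and r_s < -`r_report`.
#'
#' @param lnc_expr,partner_expr expression matrices (features x samples)
#'   sharing sample columns.
#' @param lnc_ranges,partner_ranges named GRanges with the feature loci.
#' @param cis_window maximum cis gap in bp (default 1 Mb).
#' @param r_report threshold for the summary fractions (default 0.7).
#' @return A list: `records` (data.frame lncrna, partner, r_s, p, relation)
#'   and `summary` (data.frame per relation: n, frac_pos, frac_neg).
#' @export
lncrna_coexpression <- function(lnc_expr, partner_expr, lnc_ranges,
                                partner_ranges, cis_window = 1e6,
                                r_report = 0.7) {
  common <- intersect(colnames(lnc_expr), colnames(partner_expr))
  if (length(common) < 3L) stop2("expression matrices must share samples")
  lnc_expr <- as.matrix(lnc_expr)[, common, drop = FALSE]
  partner_expr <- as.matrix(partner_expr)[, common, drop = FALSE]

  keep_l <- apply(lnc_expr, 1L, function(x) stats::sd(x) > 0)
  keep_p <- apply(partner_expr, 1L, function(x) stats::sd(x) > 0)
  if (any(!keep_l) || any(!keep_p))
    message("excluded constant feature(s): ", sum(!keep_l), " lncRNA, ",
            sum(!keep_p), " partner")
  lnc_expr <- lnc_expr[keep_l, , drop = FALSE]
  partner_expr <- partner_expr[keep_p, , drop = FALSE]
  nl <- nrow(lnc_expr); np <- nrow(partner_expr); ns <- length(common)
  if (!nl || !np) stop2("no variable features left")

  rl <- t(apply(lnc_expr, 1L, rank))
  rp <- t(apply(partner_expr, 1L, rank))
  R <- stats::cor(t(rl), t(rp))
  tstat <- R * sqrt((ns - 2) / pmax(1e-12, 1 - R^2))
  P <- 2 * stats::pt(abs(tstat), df = ns - 2, lower.tail = FALSE)

  # cis pairs via window overlap
  lr <- lnc_ranges[rownames(lnc_expr)]
  pr <- partner_ranges[rownames(partner_expr)]
  ext <- GenomicRanges::resize(lr, GenomicRanges::width(lr) + 2 * cis_window,
                               fix = "center")
  lv <- union(GenomeInfoDb::seqlevels(ext), GenomeInfoDb::seqlevels(pr))
  GenomeInfoDb::seqlevels(ext) <- lv
  GenomeInfoDb::seqlevels(pr) <- lv
  hits <- GenomicRanges::findOverlaps(ext, pr, ignore.strand = TRUE)
  cis <- matrix(FALSE, nl, np)
  cis[cbind(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))] <- TRUE

  records <- data.frame(
    lncrna = rep(rownames(lnc_expr), np),
    partner = rep(rownames(partner_expr), each = nl),
    r_s = as.vector(R), p = as.vector(P),
    relation = ifelse(as.vector(cis), "cis", "trans"),
    stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(records, records$relation), function(d)
    data.frame(relation = d$relation[1], n = nrow(d),
               frac_pos = mean(d$r_s > r_report),
               frac_neg = mean(d$r_s < -r_report))))
  rownames(summ) <- NULL
  list(records = records, summary = summ)
}

#' Screen for miRNA-sponging lncRNAs
#'
#' A lncRNA L is a sponge candidate for miRNA M iff L is upregulated, M is
#' downregulated, their expression correlates negatively (r_s < 0 with p <
#' `p_threshold`), and the median correlation of L with M's released target
#' genes is positive. When M has no released targets the candidate is
#' evaluated on the first three conditions only and flagged `partial`.
#'
#' @param up_lncrnas,down_mirnas character vectors (or DE tables with
#'   `feature`).
#' @param release output of [target_release_screen()].
#' @param lnc_expr,mirna_expr,gene_expr expression matrices sharing sample
#'   columns.
#' @param p_threshold significance cutoff for the L-M correlation.
#' @return data.frame: `lncrna`, `mirna`, `r_s`, `p`, `median_target_r`,
#'   `partial`, `candidate`.
#' @export
sponge_screen <- function(up_lncrnas, down_mirnas, release, lnc_expr,
                          mirna_expr, gene_expr, p_threshold = 0.05) {
  if (is.data.frame(up_lncrnas)) up_lncrnas <- up_lncrnas$feature
  if (is.data.frame(down_mirnas)) down_mirnas <- down_mirnas$feature
  common <- Reduce(intersect, list(colnames(lnc_expr), colnames(mirna_expr),
                                   colnames(gene_expr)))
  if (length(common) < 3L) stop2("expression matrices must share samples")
  up_lncrnas <- intersect(up_lncrnas, rownames(lnc_expr))
  down_mirnas <- intersect(down_mirnas, rownames(mirna_expr))
  out <- list()
  for (L in up_lncrnas) {
    for (M in down_mirnas) {
      ct <- suppressWarnings(
        stats::cor.test(lnc_expr[L, common], mirna_expr[M, common],
                        method = "spearman", exact = FALSE))
      neg <- !is.na(ct$estimate) && ct$estimate < 0 && ct$p.value < p_threshold
      targets <- intersect(release$by_mirna[[M]] %||% character(),
                           rownames(gene_expr))
      partial <- length(targets) == 0L
      med <- NA_real_
      if (!partial)
        med <- stats::median(vapply(targets, function(g)
          suppressWarnings(stats::cor(lnc_expr[L, common],
                                      gene_expr[g, common],
                                      method = "spearman")), numeric(1)),
          na.rm = TRUE)
      cand <- neg && (partial || (!is.na(med) && med > 0))
      if (neg)
        out[[length(out) + 1L]] <-
          data.frame(lncrna = L, mirna = M, r_s = unname(ct$estimate),
                     p = ct$p.value, median_target_r = med,
                     partial = partial, candidate = cand,
                     stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out) %||%
    data.frame(lncrna = character(), mirna = character(), r_s = numeric(),
               p = numeric(), median_target_r = numeric(),
               partial = logical(), candidate = logical())
}
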