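#' Generate synthetic gene/lncRNA/miRNA annotation, 3'UTRs and miRNA sequences
#'
#' Lays gene, lncRNA and miRNA loci out on chr1-chr22, writes a 3'UTR per
#' gene and a 22-nt mature sequence per miRNA, and plants canonical seed
#' sites: every designated target gene receives site(s) for the MIR181-family
#' analogues (which carry the real MIR181-5p seed), and every accidental
#' occurrence of a screened (planted-down) miRNA's seed match is scrubbed
#' from all other UTRs, so the seed-site truth table is exact by
#' construction. Half of the designed lncRNA-gene pairs are placed within
#' the cis window of their partner gene, the other half outside it; the
#' MIAT analogue is placed on a different chromosome from the MIR181-like
#' loci (chr1 and chr9 host-gene analogues).
#'
#' @param config a [generator_config()].
#' @param sig_plan mRNA [signature_plan()].
#' @param mir_plan [mirna_plan()] (supplies targets and screened miRNAs).
#' @param lnc_plan [lncrna_plan()].
#' @param cis_window bp window used to design in/out-of-window lncRNA pairs.
#' @param site_types types planted in target UTRs (first value used for the
#'   five core-target analogues, then recycled).
#' @return A list: `genes`, `lncrnas`, `mirnas` (named, sorted GRanges),
#'   `utrs` (DNAStringSet named by gene), `mirna_seqs` (RNAStringSet),
#'   `sites` (truth data.frame: mirna, gene, position (0-based), type),
#'   `cis_pairs` (data.frame lncrna, gene, designed_cis).
#' @export
generate_annotation <- function(config, sig_plan, mir_plan, lnc_plan,
                                cis_window = 1e6,
                                site_types = c("8mer", "7mer-m8")) {
  stopifnot(inherits(config, "generator_config"))
  bases <- c("A", "C", "G", "T")
  n_g <- config$n_genes; n_l <- config$n_lncrnas; n_m <- config$n_mirnas
  gid <- feature_ids("G", seq_len(n_g), n_g)
  lid <- feature_ids("LNC", seq_len(n_l), n_l)
  mid <- feature_ids("MIR", seq_len(n_m), n_m)

  with_seed(config$seed + 505L, {
    chroms <- paste0("chr", 1:22)
    gene_chrom <- rep_len(chroms, n_g)
    widths <- round(rlnorm(n_g, log(20000), 0.7))
    genes <- GenomicRanges::GRanges(gene_chrom, IRanges::IRanges(1, width = 1))
    # sequential layout per chromosome with random intergenic gaps
    starts <- integer(n_g)
    for (ch in chroms) {
      i <- which(gene_chrom == ch)
      gaps <- round(rlnorm(length(i), log(30000), 0.8))
      starts[i] <- cumsum(gaps + c(0L, widths[i][-length(i)])) + 1L
    }
    genes <- GenomicRanges::GRanges(gene_chrom,
                                    IRanges::IRanges(starts, width = widths),
                                    strand = sample(c("+", "-"), n_g, TRUE))
    names(genes) <- gid

    # lncRNAs: designed cis/trans pairing with partner genes (round-robin)
    partner <- gid[(seq_len(n_l) - 1L) %% n_g + 1L]
    designed_cis <- rep(c(TRUE, FALSE), length.out = n_l)
    lw <- round(rlnorm(n_l, log(3000), 0.5))
    pg <- genes[partner]
    off_cis <- round(runif(n_l, 1e3, cis_window / 2))
    off_trans <- round(runif(n_l, cis_window * 2, cis_window * 4))
    lstart <- GenomicRanges::end(pg) + ifelse(designed_cis, off_cis, off_trans)
    lchrom <- as.character(GenomicRanges::seqnames(pg))
    # the MIAT analogue must be trans to the MIR181 host loci (chr1/chr9)
    miat <- lnc_plan$table$feature[which(lnc_plan$table$analog == "MIAT-like")]
    if (length(miat)) {
      mi <- match(miat, lid)
      lchrom[mi] <- "chr22"; lstart[mi] <- 5e7
    }
    lncrnas <- GenomicRanges::GRanges(lchrom,
                                      IRanges::IRanges(lstart, width = lw),
                                      strand = sample(c("+", "-"), n_l, TRUE))
    names(lncrnas) <- lid

    tm <- mir_plan$target_mirnas
    mchrom <- sample(chroms, n_m, TRUE)
    mstart <- sample.int(2.4e8, n_m)
    mi <- match(tm, mid)
    mchrom[mi[1]] <- "chr1"; mstart[mi[1]] <- 1.98e8
    if (length(tm) > 1) { mchrom[mi[2]] <- "chr9"; mstart[mi[2]] <- 1.24e8 }
    mirnas <- GenomicRanges::GRanges(mchrom,
                                     IRanges::IRanges(mstart, width = 85L),
                                     strand = sample(c("+", "-"), n_m, TRUE))
    names(mirnas) <- mid

    # mature miRNA sequences; MIR181 analogues carry the real MIR181-5p seed
    mir_seq <- vapply(seq_len(n_m), function(i)
      paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE), collapse = ""),
      character(1))
    names(mir_seq) <- mid
    mir_seq[tm[1]] <- "AACAUUCAACGCUGUCGGUGAGU"   # MIR181a-5p
    if (length(tm) > 1) mir_seq[tm[2]] <- "AACAUUCAUUGCUGUCGGUGGGU"  # MIR181b-5p
    # screened (planted-down) miRNAs outside the MIR181 family must carry
    # seed cores distinct from each other and from the MIR181 seed
    screened <- mir_plan$table$feature[mir_plan$table$role == "core_down"]
    others <- setdiff(screened, tm)
    repeat {
      cores <- substr(mir_seq[c(tm[1], others)], 2L, 7L)
      dup <- which(duplicated(cores))
      if (!length(dup)) break
      for (i in dup)  # index 1 is the MIR181 seed and is never a duplicate
        substr(mir_seq[others[i - 1L]], 2L, 7L) <-
          paste(sample(c("A", "C", "G", "U"), 6L, replace = TRUE), collapse = "")
    }

    # 3'UTRs
    ulen <- round(runif(n_g, 300, 2000))
    utrs <- vapply(ulen, function(L)
      paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
    names(utrs) <- gid

    # scrub accidental seed matches of every screened miRNA from all UTRs
    scr_sites <- unique(vapply(mir_seq[screened], function(m)
      seed_site_string(m, "6mer"), character(1)))
    for (pat in scr_sites) utrs <- scrub_pattern(utrs, pat, bases)

    # plant sites for the MIR181-family analogues in the designated targets
    targets <- intersect(mir_plan$targets, gid)
    core5 <- head(targets, 5L)
    truth <- list()
    for (k in seq_along(targets)) {
      g <- targets[k]
      type <- if (g %in% core5) site_types[1] else
        site_types[(k - 1L) %% length(site_types) + 1L]
      site <- seed_site_string(mir_seq[tm[1]], type)
      m8_char <- substr(seed_site_string(mir_seq[tm[1]], "7mer-m8"), 1L, 1L)
      L <- nchar(utrs[[g]]); sl <- nchar(site)
      pos <- sample.int(L - sl - 2L, 1L) + 1L
      substr(utrs[[g]], pos, pos + sl - 1L) <- site
      # control the flanks so the planted type is also the maximal type
      if (!type %in% c("8mer", "7mer-m8") &&
          substr(utrs[[g]], pos - 1L, pos - 1L) == m8_char)
        substr(utrs[[g]], pos - 1L, pos - 1L) <-
          sample(setdiff(bases, m8_char), 1L)
      if (!type %in% c("8mer", "7mer-A1") &&
          substr(utrs[[g]], pos + sl, pos + sl) == "A")
        substr(utrs[[g]], pos + sl, pos + sl) <- sample(c("C", "G", "T"), 1L)
      # re-scrub any accidental extra core created at the insertion edges,
      # then record the planted site for every family member (shared seed)
      for (m in tm)
        truth[[length(truth) + 1L]] <-
          data.frame(mirna = m, gene = g, position = pos - 1L, type = type,
                     stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth) %||%
      data.frame(mirna = character(), gene = character(),
                 position = integer(), type = character())

    # verify by exhaustive rescan that targets carry exactly the planted
    # core occurrences and non-targets none; repair stray edge-created cores
    core <- seed_site_string(mir_seq[tm[1]], "6mer")
    for (it in 1:10) {
      hits <- gregexpr(core, utrs, fixed = TRUE)
      bad <- FALSE
      for (i in seq_along(utrs)) {
        h <- hits[[i]]; h <- h[h > 0]
        want <- truth$position[truth$gene == gid[i] & truth$mirna == tm[1]] + 1L
        if (nchar(core) == 6L) {
          # planted site strings contain the core at a fixed offset
          ty <- truth$type[truth$gene == gid[i] & truth$mirna == tm[1]]
          want <- want + ifelse(ty %in% c("8mer", "7mer-m8"), 1L, 0L)
        }
        stray <- setdiff(h, want)
        if (length(stray)) {
          bad <- TRUE
          ty <- truth$type[truth$gene == gid[i] & truth$mirna == tm[1]]
          spans <- unlist(lapply(seq_along(want), function(j)
            (want[j] - ifelse(ty[j] %in% c("8mer", "7mer-m8"), 1L, 0L)) +
              0:(nchar(seed_site_string(mir_seq[tm[1]], ty[j])) - 1L)))
          for (p in stray) {
            cand <- setdiff(p + 0:5, spans)
            q <- if (length(cand)) cand[1] else p + 2L
            substr(utrs[[i]], q, q) <-
              sample(setdiff(bases, substr(utrs[[i]], q, q)), 1L)
          }
        }
      }
      if (!bad) break
    }

    list(genes = BiocGenerics::sort(genes, ignore.strand = TRUE),
         lncrnas = BiocGenerics::sort(lncrnas, ignore.strand = TRUE),
         mirnas = BiocGenerics::sort(mirnas, ignore.strand = TRUE),
         utrs = Biostrings::DNAStringSet(utrs),
         mirna_seqs = Biostrings::RNAStringSet(mir_seq),
         sites = truth,
         cis_pairs = data.frame(lncrna = lid, gene = partner,
                                designed_cis = designed_cis,
                                stringsAsFactors = FALSE))
  })
}

# DNA string a UTR must contain (5'->3') for a canonical site of the given
# type against miRNA `m` (RNA or DNA, 5'->3').
seed_site_string <- function(m, type = c("6mer", "7mer-A1", "7mer-m8", "8mer")) {
  type <- match.arg(type)
  m <- chartr("Uu", "Tt", toupper(m))
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  core <- rc(substr(m, 2L, 7L))
  switch(type,
         "6mer" = core,
         "7mer-A1" = paste0(core, "A"),
         "7mer-m8" = rc(substr(m, 2L, 8L)),
         "8mer" = paste0(rc(substr(m, 2L, 8L)), "A"))
}

# Replace the middle base of every occurrence of `pat` until none remain.
scrub_pattern <- function(seqs, pat, bases) {
  mid <- ceiling(nchar(pat) / 2)
  for (it in 1:20) {
    hits <- gregexpr(pat, seqs, fixed = TRUE)
    n_hit <- vapply(hits, function(h) sum(h > 0), integer(1))
    if (!any(n_hit)) break
    for (i in which(n_hit > 0)) {
      for (p in hits[[i]][hits[[i]] > 0]) {
        old <- substr(seqs[[i]], p + mid - 1L, p + mid - 1L)
        substr(seqs[[i]], p + mid - 1L, p + mid - 1L) <-
          sample(setdiff(bases, old), 1L)
      }
    }
  }
  seqs
}
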