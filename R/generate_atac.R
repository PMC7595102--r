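#' ATAC simulation plan
#'
#' Peak-presence Venn fractions default to the printed overlap of accessible
#' loci (43.6% MBC-only, 11.9% NBC-only, 44.5% shared), the DE-to-DAR
#' concordance to 35.4%, and the up-share of planted DARs to 51.7%.
#'
#' @param concordant_fraction fraction of planted DE genes given a
#'   same-direction DAR within the assignment window.
#' @param shared_fraction,mbc_only_fraction,nbc_only_fraction peak-presence
#'   Venn fractions; must sum to 1 (tolerance 1e-9).
#' @param n_dars number of planted differentially accessible peaks
#'   (default ~5.4% of peaks, the printed 4198 / 77388 rate).
#' @param dar_up_share fraction of DARs with increased accessibility in MBC.
#' @param dar_effect absolute log2 accessibility effect of a DAR.
#' @param peak_mean,peak_dispersion NB model of present peaks.
#' @param background_mean NB mean of a peak in samples where it is not
#'   called present (default 20: presence calling flips on a ~2.5-fold
#'   signal ratio, as for marginal peaks in real data, keeping the count
#'   matrix normalizable).
#' @param peak_width peak interval width (bp).
#' @param window_bp DAR-to-gene assignment window used when placing
#'   concordant DARs (and kept clear of non-concordant ones).
#' @param lib_size_range per-sample ATAC depth range (ratios only).
#' @return An `atac_plan`.
#' @export
atac_plan <- function(concordant_fraction = 0.354, shared_fraction = 0.445,
                      mbc_only_fraction = 0.436, nbc_only_fraction = 0.119,
                      n_dars = NULL, dar_up_share = 0.517, dar_effect = 2,
                      peak_mean = 50, peak_dispersion = 0.15,
                      background_mean = 20, peak_width = 400L,
                      window_bp = 10000L, lib_size_range = c(15000, 30000)) {
  fr <- c(mbc_only_fraction, nbc_only_fraction, shared_fraction)
  if (any(fr < 0 | fr > 1) || abs(sum(fr) - 1) > 1e-9)
    stop2("Venn fractions must lie in [0, 1] and sum to 1")
  if (concordant_fraction < 0 || concordant_fraction > 1)
    stop2("concordant_fraction must lie in [0, 1]")
  structure(list(concordant_fraction = concordant_fraction,
                 shared_fraction = shared_fraction,
                 mbc_only_fraction = mbc_only_fraction,
                 nbc_only_fraction = nbc_only_fraction,
                 n_dars = n_dars, dar_up_share = dar_up_share,
                 dar_effect = dar_effect, peak_mean = peak_mean,
                 peak_dispersion = peak_dispersion,
                 background_mean = background_mean,
                 peak_width = as.integer(peak_width),
                 window_bp = as.integer(window_bp),
                 lib_size_range = lib_size_range),
            class = "atac_plan")
}

#' Generate synthetic ATAC peaks, counts and DAR truth
#'
#' Produces a sorted peak set with per-group presence flags following the
#' plan's Venn fractions, an NB count matrix for 4 NBC vs 4 MBC libraries,
#' and planted DARs. When expression truth and gene intervals are supplied,
#' a `concordant_fraction` of the planted DE genes receive a same-direction
#' DAR inside their gene body (hence within any sensible assignment window),
#' and the remaining DARs are kept at least `window_bp` away from every
#' planted DE gene so concordance is controlled by the plan.
#'
#' @param config a [generator_config()] (supplies `n_peaks` and the seed).
#' @param plan an [atac_plan()].
#' @param expr_truth optional truth table from [generate_expression()].
#' @param gene_ranges optional named [GenomicRanges::GRanges] of gene loci
#'   (required when `expr_truth` is given).
#' @return A list: `counts` (a [count_matrix()], 8 samples), `peaks`
#'   (sorted GRanges; mcols `peak`, `class`, `present_nbc`, `present_mbc`),
#'   `dar_truth` (data.frame peak, direction, gene).
#' @export
generate_atac <- function(config, plan, expr_truth = NULL, gene_ranges = NULL) {
  stopifnot(inherits(config, "generator_config"), inherits(plan, "atac_plan"))
  if (!is.null(expr_truth) && is.null(gene_ranges))
    stop2("gene_ranges required to place concordant DARs")
  n <- config$n_peaks
  subjects <- c("A", "D", "E", "F")
  samples <- data.frame(
    sample = c(paste0("NBC_", subjects), paste0("MBC_", subjects)),
    subset = rep(c("NBC", "MBC"), each = 4L),
    subject = rep(subjects, 2L), stringsAsFactors = FALSE)

  with_seed(config$seed + 404L, {
    de <- NULL
    conc <- NULL
    if (!is.null(expr_truth)) {
      de <- expr_truth[expr_truth$role %in%
                         c("core_up", "core_down", "extra_up", "extra_down"), ]
      de <- de[de$feature %in% names(gene_ranges), ]
      n_conc <- round(plan$concordant_fraction * nrow(de))
      conc <- de[sample.int(nrow(de), n_conc), c("feature", "role")]
      conc$direction <- ifelse(grepl("up$", conc$role), "up", "down")
    }
    n_conc <- if (is.null(conc)) 0L else nrow(conc)
    if (n_conc > n) stop2("more concordant DARs than peaks")

    # Venn classes; concordant peaks are forced to "shared", and the
    # remainder is drawn so the expected overall composition matches the plan.
    target <- round(n * c(mbc = plan$mbc_only_fraction,
                          nbc = plan$nbc_only_fraction,
                          shared = plan$shared_fraction))
    target["shared"] <- max(0L, target["shared"] - n_conc)
    pool <- sample(rep.int(c("mbc", "nbc", "shared"), target))
    n_rest <- n - n_conc
    if (length(pool) > n_rest) pool <- pool[seq_len(n_rest)]
    if (length(pool) < n_rest)
      pool <- c(pool, sample(c("mbc", "nbc", "shared"), n_rest - length(pool),
                             TRUE, prob = c(plan$mbc_only_fraction,
                                            plan$nbc_only_fraction,
                                            plan$shared_fraction)))
    cls <- c(rep("shared", n_conc), pool)

    # positions
    chroms <- paste0("chr", 1:22)
    w <- plan$peak_width
    if (n_conc > 0) {
      gr_conc <- gene_ranges[conc$feature]
      starts <- GenomicRanges::start(gr_conc) +
        pmax(0L, floor((GenomicRanges::width(gr_conc) - w) / 2))
      conc_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr_conc),
                                        IRanges::IRanges(starts, width = w))
    }
    draw_rest <- function(k) {
      GenomicRanges::GRanges(sample(chroms, k, TRUE),
                             IRanges::IRanges(sample.int(2.4e8, k), width = w))
    }
    rest_gr <- draw_rest(n_rest)
    if (!is.null(de) && nrow(de)) {
      avoid <- GenomicRanges::resize(gene_ranges[de$feature],
                                     GenomicRanges::width(gene_ranges[de$feature]) +
                                       2L * (plan$window_bp + w),
                                     fix = "center")
      for (it in 1:25) {
        bad <- IRanges::overlapsAny(rest_gr, avoid)
        if (!any(bad)) break
        rest_gr[bad] <- draw_rest(sum(bad))
      }
    }
    peaks <- if (n_conc > 0) c(conc_gr, rest_gr) else rest_gr
    ids <- sprintf("P%05d", seq_len(n))
    names(peaks) <- ids
    S4Vectors::mcols(peaks)$peak <- ids
    S4Vectors::mcols(peaks)$class <- cls
    S4Vectors::mcols(peaks)$present_nbc <- cls %in% c("nbc", "shared")
    S4Vectors::mcols(peaks)$present_mbc <- cls %in% c("mbc", "shared")

    # DAR assignment
    n_dars <- plan$n_dars %||% max(n_conc, round(0.054 * n))
    n_extra <- max(0L, n_dars - n_conc)
    dir_conc <- if (n_conc > 0) conc$direction else character()
    n_up_total <- round(plan$dar_up_share * n_dars)
    n_up_extra <- min(n_extra, max(0L, n_up_total - sum(dir_conc == "up")))
    extra_pool <- which(cls == "shared" & seq_len(n) > n_conc)
    if (length(extra_pool) < n_extra) {
      n_extra <- length(extra_pool)
      warning("fewer shared peaks than requested DARs; truncating")
    }
    extra_idx <- sample(extra_pool, n_extra)
    dir_extra <- sample(rep.int(c("up", "down"),
                                c(n_up_extra, n_extra - n_up_extra)))
    dar_idx <- c(seq_len(n_conc), extra_idx)
    dar_dir <- c(dir_conc, dir_extra)
    dar_truth <- data.frame(peak = ids[dar_idx], direction = dar_dir,
                            gene = c(if (n_conc > 0) conc$feature else character(),
                                     rep(NA_character_, n_extra)),
                            stringsAsFactors = FALSE)

    # counts
    b <- plan$peak_mean * 2^rnorm(n, 0, 1)
    depths <- exp(runif(8L, log(plan$lib_size_range[1]),
                        log(plan$lib_size_range[2])))
    fct <- depths / geomean(depths)
    mu <- matrix(b, n, 8L, dimnames = list(ids, samples$sample))
    mu[!S4Vectors::mcols(peaks)$present_nbc, samples$subset == "NBC"] <-
      plan$background_mean
    mu[!S4Vectors::mcols(peaks)$present_mbc, samples$subset == "MBC"] <-
      plan$background_mean
    eff <- ifelse(dar_dir == "up", plan$dar_effect, -plan$dar_effect)
    mu[dar_idx, samples$subset == "MBC"] <-
      mu[dar_idx, samples$subset == "MBC"] * 2^eff
    mu <- sweep(mu, 2L, fct, "*")
    cnt <- matrix(rnbinom(n * 8L, mu = as.vector(mu),
                          size = 1 / plan$peak_dispersion),
                  n, 8L, dimnames = dimnames(mu))

    peaks <- BiocGenerics::sort(peaks, ignore.strand = TRUE)
    cnt <- cnt[names(peaks), , drop = FALSE]
    list(counts = count_matrix(cnt, samples), peaks = peaks,
         dar_truth = dar_truth)
  })
}
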