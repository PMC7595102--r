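#' Venn comparison of two peak sets
#'
#' Each set is first collapsed by merging overlapping or book-ended
#' intervals; the universe is the merged union of both. A universe peak is
#' "shared" iff it overlaps a peak of each set by at least `min_overlap_bp`,
#' unique to one set if it only overlaps that set's peaks. Fractions are of
#' the universe and sum to 1. The result is invariant to input order.
#'
#' @param peaks_a,peaks_b [GenomicRanges::GRanges] of accessible loci
#'   (e.g. NBC-present and MBC-present peaks).
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return A list: `counts` and `fractions`, each with entries `unique_a`,
#'   `unique_b`, `shared`; and `universe` (the merged GRanges, with a
#'   `status` metadata column).
#' @export
venn_peaks <- function(peaks_a, peaks_b, min_overlap_bp = 1L) {
  peaks_a <- as_granges_peaks(peaks_a)
  peaks_b <- as_granges_peaks(peaks_b)
  ra <- GenomicRanges::reduce(peaks_a, ignore.strand = TRUE)
  rb <- GenomicRanges::reduce(peaks_b, ignore.strand = TRUE)
  uni <- GenomicRanges::reduce(c(ra, rb), ignore.strand = TRUE)
  ina <- IRanges::overlapsAny(uni, ra, minoverlap = min_overlap_bp,
                              ignore.strand = TRUE)
  inb <- IRanges::overlapsAny(uni, rb, minoverlap = min_overlap_bp,
                              ignore.strand = TRUE)
  status <- ifelse(ina & inb, "shared", ifelse(ina, "unique_a", "unique_b"))
  S4Vectors::mcols(uni)$status <- status
  counts <- c(unique_a = sum(status == "unique_a"),
              unique_b = sum(status == "unique_b"),
              shared = sum(status == "shared"))
  list(counts = counts, fractions = counts / length(uni), universe = uni)
}

as_granges_peaks <- function(x) {
  if (is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$end <= x$start)) stop2("malformed interval(s): end <= start")
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

#' Call differentially accessible regions (DARs)
#'
#' Runs the shared exact NB machinery ([nb_exact_test()]) on a peak count
#' matrix and flags peaks significant at raw `p < p_threshold` (the DAR
#' screen of the emulated study; adjusted p-values are also reported).
#'
#' @param cm peak [count_matrix()].
#' @param group_a,group_b subset labels or sample ids (B over A, so "up"
#'   means more accessible in B).
#' @param p_threshold raw p-value threshold (default 0.05).
#' @param ... passed on to [nb_exact_test()].
#' @return The DE table with extra columns `significant` (logical) and
#'   `direction` (`"up"`/`"down"`).
#' @export
call_dars <- function(cm, group_a, group_b, p_threshold = 0.05, ...) {
  de <- nb_exact_test(cm, group_a, group_b, ...)
  de$significant <- de$p < p_threshold
  de$direction <- ifelse(de$log2fc > 0, "up", "down")
  de
}

#' Integrate differential expression with differential accessibility
#'
#' A DE gene is concordant iff at least one significant DAR with the same
#' direction lies within `window_bp` of the gene body (gene interval
#' extended by the window on both sides; strand-agnostic). Genes without an
#' interval are counted as unmatched and reported.
#'
#' @param de_genes data.frame with columns `feature` and `direction`
#'   (`"up"`/`"down"`) -- e.g. significant genes from [nb_exact_test()]
#'   with direction derived from the fold change.
#' @param dars data.frame of significant DARs with columns `feature` (peak
#'   id) and `direction`.
#' @param gene_ranges named GRanges of gene intervals.
#' @param peak_ranges named GRanges of peak intervals.
#' @param window_bp assignment window (default 10 kb).
#' @return A list: `table` (per-gene: direction, matched DAR, concordant)
#'   and `summary` (n_up, n_down, n_up_concordant, n_down_concordant,
#'   fraction_concordant), plus `unmatched` gene ids.
#' @export
integrate_de_dar <- function(de_genes, dars, gene_ranges, peak_ranges,
                             window_bp = 10000L) {
  stopifnot(all(c("feature", "direction") %in% names(de_genes)),
            all(c("feature", "direction") %in% names(dars)))
  has_iv <- de_genes$feature %in% names(gene_ranges)
  unmatched <- de_genes$feature[!has_iv]
  if (length(unmatched))
    message(length(unmatched), " DE gene(s) without intervals, unmatched")
  genes <- de_genes[has_iv, , drop = FALSE]
  dars <- dars[dars$feature %in% names(peak_ranges), , drop = FALSE]

  gr <- gene_ranges[genes$feature]
  win <- GenomicRanges::resize(gr, GenomicRanges::width(gr) + 2L * window_bp,
                               fix = "center")
  pk <- peak_ranges[dars$feature]
  hits <- GenomicRanges::findOverlaps(win, pk, ignore.strand = TRUE)
  same <- genes$direction[S4Vectors::queryHits(hits)] ==
    dars$direction[S4Vectors::subjectHits(hits)]
  conc_idx <- unique(S4Vectors::queryHits(hits)[same])

  genes$matched_dar <- NA_character_
  first <- tapply(S4Vectors::subjectHits(hits)[same],
                  S4Vectors::queryHits(hits)[same], function(i) i[1])
  genes$matched_dar[as.integer(names(first))] <- dars$feature[unlist(first)]
  genes$concordant <- seq_len(nrow(genes)) %in% conc_idx

  n_up <- sum(genes$direction == "up")
  n_down <- sum(genes$direction == "down")
  n_up_c <- sum(genes$concordant & genes$direction == "up")
  n_down_c <- sum(genes$concordant & genes$direction == "down")
  list(table = genes,
       summary = c(n_up = n_up, n_down = n_down,
                   n_up_concordant = n_up_c, n_down_concordant = n_down_c,
                   fraction_concordant = (n_up_c + n_down_c) /
                     max(1L, n_up + n_down)),
       unmatched = unmatched)
}

#' Concordance fraction from printed counts
#'
#' The bookkeeping identity behind the integration summary: fraction =
#' (up-concordant + down-concordant) / (up + down).
#'
#' @param n_up,n_down DE gene counts by direction.
#' @param n_up_concordant,n_down_concordant genes with a same-direction DAR.
#' @return The concordant fraction.
#' @export
concordance_fraction <- function(n_up, n_down, n_up_concordant,
                                 n_down_concordant) {
  (n_up_concordant + n_down_concordant) / (n_up + n_down)
}

#' Motif displacement (MD) score
#'
#' MD = (motif hits within `small_radius` of the nearest peak center) /
#' (hits within `large_radius`). Undefined (NA) when no hit falls within the
#' large radius. Positions can be numeric (single sequence) or GRanges
#' (per-chromosome nearest distances).
#'
#' @param hits motif hit positions: numeric vector or GRanges (midpoints
#'   are used).
#' @param centers peak centers: numeric vector or GRanges.
#' @param small_radius,large_radius inner/outer radii in bp (150 and 1500 by
#'   default; `small_radius` must be smaller).
#' @return The MD score in \[0, 1\], or NA.
#' @export
md_score <- function(hits, centers, small_radius = 150, large_radius = 1500) {
  if (small_radius >= large_radius) stop2("small_radius must be < large_radius")
  if (small_radius <= 0) stop2("radii must be positive")
  d <- nearest_center_distance(hits, centers)
  n_large <- sum(d <= large_radius)
  if (n_large == 0) return(NA_real_)
  sum(d <= small_radius) / n_large
}

#' @rdname md_score
#' @param hits_a,hits_b,centers_a,centers_b hit positions and peak centers
#'   in conditions A and B.
#' @return `delta_md()`: MD(B) - MD(A); antisymmetric under condition swap.
#' @export
delta_md <- function(hits_a, centers_a, hits_b, centers_b,
                     small_radius = 150, large_radius = 1500) {
  md_score(hits_b, centers_b, small_radius, large_radius) -
    md_score(hits_a, centers_a, small_radius, large_radius)
}

nearest_center_distance <- function(hits, centers) {
  if (is(hits, "GRanges") || is(centers, "GRanges")) {
    stopifnot(is(hits, "GRanges"), is(centers, "GRanges"))
    h <- GenomicRanges::resize(hits, 1L, fix = "center")
    cn <- GenomicRanges::resize(centers, 1L, fix = "center")
    nd <- GenomicRanges::distanceToNearest(h, cn, ignore.strand = TRUE)
    d <- rep(Inf, length(h))
    d[S4Vectors::queryHits(nd)] <- S4Vectors::mcols(nd)$distance
    return(d)
  }
  if (!length(centers)) return(rep(Inf, length(hits)))
  cs <- sort(centers)
  i <- findInterval(hits, cs)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(cs))
  pmin(abs(hits - cs[lo]), abs(hits - cs[hi]))
}
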