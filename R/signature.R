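#' Extract the core transcriptional signature by intersection and cancellation
#'
#' A feature enters the signature's up set iff it is significant below
#' `p_adj_core` with positive log2 fold change in BOTH vs-naive contrasts
#' AND is *not* significant (p >= `p_cancel`) in the isotype contrast --
#' the "cancellation" that marks a change shared by both switched isotypes.
#' The down set is symmetric. Features whose class is listed in
#' `exclude_classes` (e.g. IgH constant-region transcripts, which differ by
#' construction between isotypes) are reported separately and never enter
#' the up/down sets.
#'
#' The default threshold 1e-29 is the stringent screen of the emulated
#' study ("p_adj < 10 x 10^-30"); [core_signature_at()] provides the relaxed
#' 1e-14 variant used for the unswitched-memory contrast. Setting
#' `p_col = "p"` runs the same set logic on raw p-values (the miRNA/lncRNA
#' screens).
#'
#' @param de_a,de_b DE tables ([nb_exact_test()] output) for the two
#'   vs-naive contrasts (e.g. IgG-vs-NBC and IgA-vs-NBC). `de_b` may be
#'   NULL for a single-contrast screen.
#' @param de_cancel DE table for the isotype contrast (IgG-vs-IgA); NULL
#'   skips cancellation.
#' @param p_adj_core significance threshold for the vs-naive screens.
#' @param p_cancel a feature is "cancelled" (kept) when its isotype-contrast
#'   p-value is >= this threshold.
#' @param exclude_classes feature classes set aside (requires a
#'   `feature_class` column).
#' @param p_col p-value column used throughout (`"p_adj"` or `"p"`).
#' @return A `signature_set`: list with `up`, `down`, `excluded` (feature
#'   ids), `thresholds`, and `table` (per-member detail).
#' @export
core_signature <- function(de_a, de_b = NULL, de_cancel = NULL,
                           p_adj_core = 1e-29, p_cancel = 0.05,
                           exclude_classes = "IGHC", p_col = "p_adj") {
  feats <- de_a$feature
  for (tab in list(de_b, de_cancel)) {
    if (!is.null(tab) && !setequal(tab$feature, feats))
      stop2("DE tables must share one feature universe")
  }
  pa <- de_a[[p_col]]; la <- de_a$log2fc
  if (!is.null(de_b)) {
    i <- match(feats, de_b$feature)
    pb <- de_b[[p_col]][i]; lb <- de_b$log2fc[i]
  } else { pb <- pa; lb <- la }
  cancel_ok <- rep(TRUE, length(feats))
  if (!is.null(de_cancel))
    cancel_ok <- de_cancel[[p_col]][match(feats, de_cancel$feature)] >= p_cancel

  up <- pa < p_adj_core & la > 0 & pb < p_adj_core & lb > 0 & cancel_ok
  dn <- pa < p_adj_core & la < 0 & pb < p_adj_core & lb < 0 & cancel_ok

  excl <- rep(FALSE, length(feats))
  if (!is.null(exclude_classes) && !is.null(de_a$feature_class))
    excl <- de_a$feature_class %in% exclude_classes
  excluded <- feats[(up | dn) & excl]
  up_ids <- feats[up & !excl]
  dn_ids <- feats[dn & !excl]

  tab <- data.frame(feature = c(up_ids, dn_ids),
                    direction = rep(c("up", "down"),
                                    c(length(up_ids), length(dn_ids))),
                    stringsAsFactors = FALSE)
  i <- match(tab$feature, feats)
  tab$p_a <- pa[i]; tab$log2fc_a <- la[i]
  tab$p_b <- pb[i]; tab$log2fc_b <- lb[i]
  if (!is.null(de_cancel))
    tab$p_cancel <- de_cancel[[p_col]][match(tab$feature, de_cancel$feature)]
  structure(list(up = up_ids, down = dn_ids, excluded = excluded,
                 thresholds = c(p_adj_core = p_adj_core, p_cancel = p_cancel),
                 p_col = p_col, table = tab),
            class = "signature_set")
}

#' @rdname core_signature
#' @param ... passed on to [core_signature()].
#' @export
core_signature_at <- function(de_a, de_b = NULL, de_cancel = NULL,
                              p_adj_core = 1e-14, ...) {
  core_signature(de_a, de_b, de_cancel, p_adj_core = p_adj_core, ...)
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d up, %d down (%d excluded by class) at %s < %g, cancellation at %g\n",
              length(x$up), length(x$down), length(x$excluded),
              x$p_col, x$thresholds["p_adj_core"], x$thresholds["p_cancel"]))
  invisible(x)
}

#' PCA embedding of samples on a signature with cluster quality
#'
#' Rows (features) of the log-expression matrix are standardized (mean 0,
#' population SD 1; constant rows map to zero), samples are projected on the
#' first two principal components, and the subset labeling's silhouette
#' coefficient is computed on the 2-D coordinates. Per-subset 95% prediction
#' ellipses (bivariate normal, chi-square(2) quantile) are returned for
#' plotting.
#'
#' @param expr numeric matrix, features x samples (e.g. log2 RPKM),
#'   typically restricted to a signature's members.
#' @param labels subset label per sample (used for silhouette and ellipses).
#' @return A list: `coordinates` (data.frame sample, PC1, PC2, subset),
#'   `var_explained` (proportions), `silhouette` (overall mean),
#'   `silhouette_by_label`, `ellipses` (per label: center, cov, radius).
#' @export
embed_subsets <- function(expr, labels) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop2("need at least 2 signature features")
  if (ncol(expr) < 3L) stop2("need at least 3 samples")
  stopifnot(length(labels) == ncol(expr))
  z <- row_standardize(expr)
  pca <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pca$x))
  xy <- pca$x[, seq_len(k), drop = FALSE]
  if (k == 1L) xy <- cbind(xy, 0)
  colnames(xy) <- c("PC1", "PC2")
  ve <- pca$sdev^2 / sum(pca$sdev^2)

  sil <- NA_real_; sil_by <- NULL
  lf <- factor(labels)
  if (nlevels(lf) >= 2L) {
    s <- cluster::silhouette(as.integer(lf), stats::dist(xy))
    sil <- mean(s[, "sil_width"])
    sil_by <- tapply(s[, "sil_width"], labels, mean)
  }
  ell <- lapply(split(seq_len(ncol(expr)), labels), function(i) {
    if (length(i) < 2L) return(NULL)
    list(center = colMeans(xy[i, , drop = FALSE]),
         cov = stats::cov(xy[i, , drop = FALSE]),
         radius = sqrt(stats::qchisq(0.95, df = 2)))
  })
  list(coordinates = data.frame(sample = colnames(expr),
                                PC1 = xy[, 1], PC2 = xy[, 2],
                                subset = labels, stringsAsFactors = FALSE),
       var_explained = ve, silhouette = sil, silhouette_by_label = sil_by,
       ellipses = ell)
}

#' Row-standardized matrix for heatmap display
#'
#' Per-row z-scores using the population SD (denominator n), so the result
#' is bit-reproducible and bounded; constant rows map to all zeros.
#'
#' @param expr numeric matrix (features x samples).
#' @param features optional feature ids (or a `signature_set`, whose up and
#'   down members are used) to restrict and order the rows.
#' @param sample_order optional column order.
#' @return Matrix of z-scores with the selected rows/columns.
#' @export
heatmap_matrix <- function(expr, features = NULL, sample_order = NULL) {
  expr <- as.matrix(expr)
  if (inherits(features, "signature_set")) features <- c(features$up, features$down)
  if (!is.null(features)) {
    if (!all(features %in% rownames(expr))) stop2("features missing from expression")
    expr <- expr[features, , drop = FALSE]
  }
  if (!is.null(sample_order)) expr <- expr[, sample_order, drop = FALSE]
  row_standardize(expr)
}

row_standardize <- function(m) {
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))   # population SD
  z <- (m - mu) / ifelse(sdp > 0, sdp, 1)
  z[sdp == 0, ] <- 0
  z
}
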