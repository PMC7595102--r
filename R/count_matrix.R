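#' Count matrix with sample metadata
#'
#' Bundles an integer feature-by-sample count matrix with its sample sheet
#' (sample, subset, subject) and optional per-feature annotation: feature
#' lengths in bp (required for RPKM) and a feature class (used, e.g., to tag
#' IgH constant-region transcripts so the signature step can set them aside).
#'
#' @param counts integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Negative or non-finite
#'   values are rejected.
#' @param samples data.frame with columns `sample`, `subset` and optionally
#'   `subject`; must cover every column of `counts`.
#' @param lengths optional numeric vector of feature lengths (bp), named by
#'   feature or in row order; all must be positive.
#' @param feature_class optional character vector of feature classes, named
#'   by feature or in row order.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `samples`, `lengths`, `feature_class`.
#' @examples
#' m <- matrix(rpois(8, 10), 4, 2, dimnames = list(paste0("g", 1:4), c("a", "b")))
#' cm <- count_matrix(m, data.frame(sample = c("a", "b"), subset = c("NBC", "IgG")))
#' dim(cm$counts)
#' @export
count_matrix <- function(counts, samples, lengths = NULL, feature_class = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("counts must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop2("duplicated feature id(s): ",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop2("counts must be finite and non-negative")
  samples <- as.data.frame(samples)
  if (!all(c("sample", "subset") %in% names(samples)))
    stop2("sample sheet needs columns 'sample' and 'subset'")
  miss <- setdiff(colnames(counts), samples$sample)
  if (length(miss))
    stop2("samples missing from sample sheet: ", paste(miss, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(lengths)) {
    lengths <- align_feature_vector(lengths, rownames(counts), "lengths")
    if (any(!is.finite(lengths)) || any(lengths <= 0))
      stop2("feature lengths must be positive")
  }
  if (!is.null(feature_class))
    feature_class <- align_feature_vector(feature_class, rownames(counts), "feature_class")
  structure(list(counts = counts, samples = samples, lengths = lengths,
                 feature_class = feature_class),
            class = "count_matrix")
}

align_feature_vector <- function(x, features, what) {
  if (!is.null(names(x))) {
    if (!all(features %in% names(x)))
      stop2(what, " must cover every feature")
    x <- x[features]
  } else if (length(x) != length(features)) {
    stop2(what, " must have one value per feature")
  }
  names(x) <- features
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("subsets:", paste(sprintf("%s (%d)", names(table(x$samples$subset)),
                                table(x$samples$subset)), collapse = ", "), "\n")
  if (!is.null(x$lengths)) cat("feature lengths: present\n")
  if (!is.null(x$feature_class))
    cat("feature classes:", paste(unique(x$feature_class), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Subset a count_matrix by feature ids and/or sample ids (internal).
cm_subset <- function(cm, features = NULL, samp = NULL) {
  if (!is.null(features)) {
    idx <- match(features, rownames(cm$counts))
    if (anyNA(idx)) stop2("unknown feature id(s)")
    cm$counts <- cm$counts[idx, , drop = FALSE]
    if (!is.null(cm$lengths)) cm$lengths <- cm$lengths[idx]
    if (!is.null(cm$feature_class)) cm$feature_class <- cm$feature_class[idx]
  }
  if (!is.null(samp)) {
    idx <- match(samp, colnames(cm$counts))
    if (anyNA(idx)) stop2("unknown sample id(s)")
    cm$counts <- cm$counts[, idx, drop = FALSE]
    cm$samples <- cm$samples[idx, , drop = FALSE]
  }
  cm
}

# Resolve a group spec (subset label(s) or explicit sample ids) to sample ids.
resolve_group <- function(cm, group) {
  if (all(group %in% cm$samples$sample)) return(group)
  if (all(group %in% cm$samples$subset))
    return(cm$samples$sample[cm$samples$subset %in% group])
  stop2("group must be subset label(s) or sample id(s): ",
        paste(group, collapse = ", "))
}
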