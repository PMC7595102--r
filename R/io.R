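#' Read a count matrix with its sample sheet
#'
#' The matrix TSV has a `feature` id column followed by one integer column
#' per sample; the sample sheet TSV has columns `sample`, `subset` and
#' optionally `subject`. Duplicate feature ids, negative or non-integer
#' counts and samples missing from the sheet are rejected.
#'
#' @param path count matrix TSV.
#' @param sample_sheet sample sheet TSV path, or a data.frame.
#' @param lengths_col optional name of a feature-length column in the TSV.
#' @param class_col optional name of a feature-class column.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, sample_sheet, lengths_col = NULL,
                        class_col = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"feature" %in% names(d)) stop2("count TSV needs a 'feature' column")
  if (anyDuplicated(d$feature))
    stop2("duplicated feature id(s): ",
          paste(unique(d$feature[duplicated(d$feature)]), collapse = ", "))
  lens <- fclass <- NULL
  if (!is.null(lengths_col)) { lens <- d[[lengths_col]]; d[[lengths_col]] <- NULL }
  if (!is.null(class_col)) { fclass <- d[[class_col]]; d[[class_col]] <- NULL }
  m <- as.matrix(d[, setdiff(names(d), "feature"), drop = FALSE])
  rownames(m) <- d$feature
  if (!is.numeric(m)) stop2("non-numeric counts")
  if (any(m != round(m))) stop2("non-integer counts")
  if (any(m < 0)) stop2("negative counts")
  sheet <- if (is.character(sample_sheet))
    utils::read.delim(sample_sheet, stringsAsFactors = FALSE) else sample_sheet
  count_matrix(m, sheet, lengths = lens, feature_class = fclass)
}

#' @rdname read_counts
#' @param cm a [count_matrix()].
#' @param sheet_path optional path to also write the sample sheet.
#' @export
write_counts <- function(cm, path, sheet_path = NULL) {
  d <- data.frame(feature = rownames(cm$counts), cm$counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(cm$lengths)) d$length <- unname(cm$lengths)
  if (!is.null(cm$feature_class)) d$feature_class <- unname(cm$feature_class)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sheet_path))
    utils::write.table(cm$samples, sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read / write BED intervals
#'
#' Standard BED (0-based half-open on disk) via rtracklayer; intervals come
#' back as a 1-based GRanges, sorted on load (stable for ties). Interval
#' names become GRanges names.
#'
#' @param path BED file path.
#' @return `read_bed()`: a sorted GRanges.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(S4Vectors::mcols(gr)$name)) names(gr) <- S4Vectors::mcols(gr)$name
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' @rdname read_bed
#' @param gr a GRanges (names are written to the BED name column).
#' @export
write_bed <- function(gr, path) {
  if (is.null(S4Vectors::mcols(gr)$name) && !is.null(names(gr)))
    S4Vectors::mcols(gr)$name <- names(gr)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings with 60-column wrapping on write.
#'
#' @param path FASTA file path.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return `read_fasta()`: a DNAStringSet or RNAStringSet.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "DNA") Biostrings::readDNAStringSet(path)
  else Biostrings::readRNAStringSet(path)
}

#' @rdname read_fasta
#' @param seqs an XStringSet or named character vector.
#' @export
write_fasta <- function(seqs, path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (is.character(seqs))
    seqs <- if (alphabet == "DNA") Biostrings::DNAStringSet(seqs)
            else Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}
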