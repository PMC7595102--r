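#' Assign V, D and J germline segments to IgH amplicon reads
#'
#' A simplified germline aligner for amplicon-style reads that span the full
#' V segment at their 5' end and the full J segment at their 3' end. The V
#' call is the germline maximizing the anchored ungapped alignment score
#' (match +1, mismatch -1; equivalent to the local score on gap-free reads);
#' likewise for J, anchored at the 3' end. D is the best ungapped match
#' within the junction and is reported only when the best alignment contains
#' a run of at least `d_min_run` consecutive matching bases. The CDR3 is
#' translated between the conserved V-end Cys codon and the J-start Trp
#' codon (anchors excluded from the reported peptide). V mismatches are
#' classified silent/replacement by codon translation in the germline
#' reading frame and FR/CDR by the database's V boundaries.
#'
#' Reads whose best V score falls below `score_floor` are marked
#' unassignable (`v_call` NA) and are excluded from downstream profiles.
#'
#' @param reads named character vector (or DNAStringSet) of reads, each at
#'   least 60 nt.
#' @param db a [make_germline_db()] database.
#' @param score_floor minimum V alignment score (default 40).
#' @param d_min_run minimum consecutive-match run for a D call (default 5).
#' @return A list with `calls` (data.frame: read, v_call, d_call, j_call,
#'   v_score, j_score, cdr3_aa, cdr3_len, n_mismatch, aligned_bases) and
#'   `mismatches` (data.frame: read, position, germline, base, region,
#'   class).
#' @export
assign_vdj <- function(reads, db, score_floor = 40, d_min_run = 5L) {
  stopifnot(inherits(db, "germline_db"))
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  if (is.null(names(reads))) names(reads) <- sprintf("R%06d", seq_along(reads))
  if (any(nchar(reads) < 60L)) stop2("reads must be at least 60 nt")
  n <- length(reads)
  lens <- nchar(reads)

  # anchored scoring: char matrices padded with "-" (never matches)
  vmax <- max(nchar(db$V$seq))
  jmax <- max(nchar(db$J$seq))
  M5 <- char_matrix(substr(reads, 1L, vmax), vmax)
  M3 <- char_matrix(rev_str_pad(reads, jmax), jmax)

  score_class <- function(M, segs, width, anchor) {
    sc <- matrix(-Inf, n, nrow(segs))
    for (k in seq_len(nrow(segs))) {
      s <- strsplit(segs$seq[k], "")[[1]]
      L <- length(s)
      cols <- if (anchor == "5p") seq_len(L) else (width - L + 1L):width
      eq <- M[, cols, drop = FALSE] == matrix(s, n, L, byrow = TRUE)
      matches <- rowSums(eq)
      ov <- pmin(lens, L)
      sc[, k] <- 2L * matches - ov
    }
    sc
  }
  vs <- score_class(M5, db$V, vmax, "5p")
  js <- score_class(M3, db$J, jmax, "3p")
  vbest <- max.col(vs, ties.method = "first")
  jbest <- max.col(js, ties.method = "first")
  vscore <- vs[cbind(seq_len(n), vbest)]
  jscore <- js[cbind(seq_len(n), jbest)]
  assign_ok <- vscore >= score_floor

  v_id <- ifelse(assign_ok, db$V$id[vbest], NA_character_)
  j_id <- ifelse(assign_ok, db$J$id[jbest], NA_character_)

  # per-read mismatch extraction and CDR3, grouped by called V for speed
  region_of <- function(pos) {
    r <- db$v_regions
    r$region[findInterval(pos, r$start)]
  }
  cdr3 <- rep(NA_character_, n)
  dcall <- rep(NA_character_, n)
  n_mm <- integer(n)
  gc_tab <- Biostrings::GENETIC_CODE
  d_chars <- strsplit(db$D$seq, "")
  acc <- list(read = list(), position = list(), germline = list(),
              base = list(), region = list(), class = list())
  for (k in sort(unique(vbest[assign_ok]))) {
    idx <- which(assign_ok & vbest == k)
    vseq <- strsplit(db$V$seq[k], "")[[1]]
    Lv <- length(vseq)
    sub <- M5[idx, seq_len(Lv), drop = FALSE]
    neq <- sub != matrix(vseq, length(idx), Lv, byrow = TRUE)
    v_aa <- aa_of(db$V$seq[k], gc_tab)
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      pos <- which(neq[ii, ] & seq_len(Lv) <= lens[i])
      if (length(pos)) {
        codon <- (pos - 1L) %/% 3L + 1L
        rd_codon <- substring(reads[i], codon * 3L - 2L, codon * 3L)
        rd_aa <- unname(gc_tab[rd_codon])
        rd_aa[is.na(rd_aa)] <- "X"
        m <- length(acc$read) + 1L
        acc$read[[m]] <- rep.int(names(reads)[i], length(pos))
        acc$position[[m]] <- pos
        acc$germline[[m]] <- vseq[pos]
        acc$base[[m]] <- substring(reads[i], pos, pos)
        acc$region[[m]] <- region_of(pos)
        acc$class[[m]] <- ifelse(rd_aa == v_aa[codon], "silent", "replacement")
        n_mm[i] <- length(pos)
      }
      # CDR3: between the V-end Cys codon and the J-start Trp codon
      Lj <- nchar(db$J$seq[jbest[i]])
      j_start <- lens[i] - Lj + 1L
      if (j_start > Lv + 1L) {
        junc <- substr(reads[i], Lv + 1L, j_start - 1L)
        if (nchar(junc) %% 3L == 0L && nchar(junc) >= 3L)
          cdr3[i] <- paste(aa_of(junc, gc_tab), collapse = "")
        dcall[i] <- best_d(strsplit(junc, "")[[1]], d_chars, db$D$id,
                           d_min_run)
      }
    }
  }
  mism <- data.frame(read = unlist(acc$read) %||% character(),
                     position = unlist(acc$position) %||% integer(),
                     germline = unlist(acc$germline) %||% character(),
                     base = unlist(acc$base) %||% character(),
                     region = unlist(acc$region) %||% character(),
                     class = unlist(acc$class) %||% character(),
                     stringsAsFactors = FALSE)
  calls <- data.frame(
    read = names(reads),
    v_call = v_id, d_call = dcall, j_call = j_id,
    v_score = vscore, j_score = jscore,
    cdr3_aa = cdr3, cdr3_len = ifelse(is.na(cdr3), NA_integer_, nchar(cdr3)),
    n_mismatch = n_mm,
    aligned_bases = ifelse(assign_ok,
                           pmin(lens, nchar(db$V$seq)[vbest]), 0L),
    stringsAsFactors = FALSE)
  calls$n_mismatch[!assign_ok] <- NA_integer_
  n_un <- sum(!assign_ok)
  if (n_un) message(n_un, " read(s) unassignable (V score below floor)")
  list(calls = calls, mismatches = mism)
}

char_matrix <- function(x, width) {
  x <- formatC(x, width = -width)           # right-pad with spaces
  x <- substr(x, 1L, width)
  matrix(unlist(strsplit(x, ""), use.names = FALSE), length(x), width,
         byrow = TRUE)
}

# last `width` characters of each string, right-aligned and reversed-padded
rev_str_pad <- function(x, width) {
  L <- nchar(x)
  out <- substr(x, pmax(1L, L - width + 1L), L)
  formatC(out, width = width)               # left-pad with spaces
}

aa_of <- function(seq, gc_tab) {
  L <- nchar(seq) - nchar(seq) %% 3L
  if (L < 3L) return(character())
  codons <- substring(seq, seq(1L, L - 2L, 3L), seq(3L, L, 3L))
  aa <- unname(gc_tab[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# Best ungapped D alignment within a junction: for every shift, score =
# matches - mismatches over the overlap; a shift qualifies only if it
# contains a run of >= `min_run` consecutive matches. Matches per shift are
# tallied in one pass from the outer equality matrix; the run condition is
# checked lazily, best score first.
best_d <- function(a, d_chars, d_ids, min_run) {
  m <- length(a)
  if (m < min_run) return(NA_character_)
  best_score <- -Inf; best_id <- NA_character_
  for (k in seq_along(d_chars)) {
    b <- d_chars[[k]]
    nb <- length(b)
    E <- outer(b, a, "==")              # nb x m; shift s = col - row
    sft <- .col(dim(E)) - .row(dim(E))  # in -(nb-1) .. (m-1)
    mt <- tabulate(sft[E] + nb, nbins = m + nb - 1L)  # matches per shift
    s_all <- (1L - nb):(m - 1L)
    ov <- pmin(m, nb + s_all) - pmax(1L, 1L + s_all) + 1L
    score <- 2L * mt - ov
    cand <- which(mt >= min_run & score > best_score)
    for (ci in cand[order(score[cand], decreasing = TRUE)]) {
      if (score[ci] <= best_score) break
      s <- s_all[ci]
      i <- seq.int(max(1L, 1L + s), min(m, nb + s))
      eq <- a[i] == b[i - s]
      r <- rle(eq)
      if (max(c(0L, r$lengths[r$values])) >= min_run) {
        best_score <- score[ci]; best_id <- d_ids[k]
        break
      }
    }
  }
  best_id
}

#' V/D/J usage profile
#'
#' Fraction of assignable reads calling each gene (or family). Ids present
#' in the database but never called get fraction 0; fractions sum to 1.
#'
#' @param ann output of [assign_vdj()] (or its `calls` data.frame).
#' @param db the germline database (defines the id universe).
#' @param segment `"V"`, `"D"` or `"J"`.
#' @param level `"gene"` or `"family"`.
#' @return Named numeric vector of fractions.
#' @export
usage_profile <- function(ann, db, segment = c("V", "D", "J"),
                          level = c("gene", "family")) {
  segment <- match.arg(segment); level <- match.arg(level)
  calls <- if (is.data.frame(ann)) ann else ann$calls
  col <- paste0(tolower(segment), "_call")
  x <- calls[[col]][!is.na(calls$v_call)]
  x <- x[!is.na(x)]
  if (!length(x)) stop2("no assignable reads")
  seg <- db[[segment]]
  if (level == "family") {
    x <- seg$family[match(x, seg$id)]
    universe <- unique(seg$family)
  } else universe <- seg$id
  tab <- table(factor(x, levels = universe))
  as.numeric(tab) / length(x) -> fr
  stats::setNames(fr, universe)
}

#' Spearman correlation between two usage profiles
#'
#' Computed over the union of ids (an id absent from a profile contributes
#' 0), with ties handled by average ranks.
#'
#' @param a,b named fraction vectors from [usage_profile()].
#' @return Spearman's rank correlation coefficient.
#' @export
usage_correlation <- function(a, b) {
  ids <- union(names(a), names(b))
  if (length(ids) < 3L) stop2("need at least 3 ids")
  av <- ifelse(is.na(a[ids]), 0, a[ids])
  bv <- ifelse(is.na(b[ids]), 0, b[ids])
  stats::cor(av, bv, method = "spearman")
}

#' CDR3 length statistics
#'
#' @param ann output of [assign_vdj()] (or its `calls` data.frame).
#' @return A list: `histogram` (named counts per integer length, as fractions
#'   in `fraction`), `mean`, `sem`, `n`.
#' @export
cdr3_stats <- function(ann) {
  calls <- if (is.data.frame(ann)) ann else ann$calls
  len <- calls$cdr3_len[!is.na(calls$cdr3_len)]
  if (!length(len)) stop2("no annotations with a CDR3")
  h <- table(len)
  list(histogram = h, fraction = as.numeric(h) / length(len),
       mean = mean(len),
       sem = if (length(len) > 1) stats::sd(len) / sqrt(length(len)) else 0,
       n = length(len))
}

#' Error-corrected somatic mutation frequency
#'
#' Raw frequency = total V-region mismatches / total aligned V bases;
#' corrected frequency subtracts the polymerase + sequencing error rate
#' (default 0.008) and floors at 0. The silent/replacement x FR/CDR
#' breakdown partitions the same mismatches.
#'
#' @param ann output of [assign_vdj()].
#' @param error_rate per-base error rate subtracted from the raw frequency.
#' @return A list: `n_reads`, `n_aligned_bases`, `n_mismatches`, `raw_freq`,
#'   `corrected_freq`, `rs_breakdown` (class x region table).
#' @export
mutation_frequency <- function(ann, error_rate = 0.008) {
  calls <- ann$calls
  ok <- !is.na(calls$v_call)
  bases <- sum(calls$aligned_bases[ok])
  if (bases == 0) stop2("zero aligned bases")
  mm <- ann$mismatches
  raw <- nrow(mm) / bases
  list(n_reads = sum(ok), n_aligned_bases = bases, n_mismatches = nrow(mm),
       raw_freq = raw,
       corrected_freq = max(raw - error_rate, 0),
       rs_breakdown = table(factor(mm$class, c("silent", "replacement")),
                            factor(ifelse(grepl("^CDR", mm$region), "CDR", "FR"),
                                   c("FR", "CDR"))))
}
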