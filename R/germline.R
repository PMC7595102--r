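#' Synthetic IgH germline database
#'
#' Builds a V/D/J germline segment database with the structure the repertoire
#' module expects: V genes in 7 families (members of a family diverge ~8%
#' from a family consensus), each 294 nt ending in the conserved Cys codon
#' (TGT) and carrying IMGT-style FR1/CDR1/FR2/CDR2/FR3 boundaries; 7 D
#' segments of 12-31 nt; 6 J segments beginning with the conserved Trp codon
#' (TGG). Default usage weights mirror the genomic representation of the
#' human V_H families (V_H3 most used, then V_H4 and V_H1) and the J_H5/J_H6
#' preponderance.
#'
#' @param n_v_per_family V gene counts for families V1..V7.
#' @param family_weights sampling weight of each V family (sums to 1; split
#'   equally among members).
#' @param j_weights sampling weight per J segment.
#' @param seed RNG seed; the database is deterministic given it.
#' @return A `germline_db`: list with data.frames `V` (id, family, seq,
#'   weight), `D`, `J`, and `v_regions` (FR/CDR nucleotide boundaries shared
#'   by all V genes).
#' @export
make_germline_db <- function(n_v_per_family = c(4L, 2L, 6L, 3L, 2L, 1L, 1L),
                             family_weights = c(0.17, 0.02, 0.55, 0.18,
                                                0.03, 0.02, 0.03),
                             j_weights = c(0.05, 0.05, 0.08, 0.15, 0.30, 0.37),
                             seed = 42) {
  stopifnot(length(n_v_per_family) == 7L, length(family_weights) == 7L,
            length(j_weights) == 6L)
  if (abs(sum(family_weights) - 1) > 1e-9 || abs(sum(j_weights) - 1) > 1e-9)
    stop2("usage weights must sum to 1 per segment class")
  bases <- c("A", "C", "G", "T")
  v_len <- 294L
  with_seed(seed, {
    vs <- do.call(rbind, lapply(seq_len(7L), function(fam) {
      cons <- sample(bases, v_len, replace = TRUE)
      do.call(rbind, lapply(seq_len(n_v_per_family[fam]), function(g) {
        s <- cons
        mut <- runif(v_len) < 0.08
        s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1L),
                         character(1))
        s[(v_len - 2):v_len] <- c("T", "G", "T")  # conserved Cys codon
        data.frame(id = sprintf("V%d-%d", fam, g),
                   family = sprintf("V%d", fam),
                   seq = paste(s, collapse = ""),
                   weight = family_weights[fam] / n_v_per_family[fam],
                   stringsAsFactors = FALSE)
      }))
    }))
    ds <- data.frame(id = sprintf("D%d", 1:7), family = sprintf("D%d", 1:7),
                     seq = vapply(sample(12:31, 7, replace = TRUE), function(L)
                       paste(sample(bases, L, replace = TRUE), collapse = ""),
                       character(1)),
                     weight = rep(1 / 7, 7), stringsAsFactors = FALSE)
    js <- data.frame(id = sprintf("J%d", 1:6), family = sprintf("J%d", 1:6),
                     seq = vapply(1:6, function(i)
                       paste(c("T", "G", "G",
                               sample(bases, 36, replace = TRUE)), collapse = ""),
                       character(1)),
                     weight = j_weights, stringsAsFactors = FALSE)
    structure(list(
      V = vs, D = ds, J = js,
      v_regions = data.frame(
        region = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
        start = c(1L, 79L, 103L, 154L, 178L),
        end = c(78L, 102L, 153L, 177L, 294L))),
      class = "germline_db")
  })
}

#' Repertoire simulation plan
#'
#' @param germline_db a [make_germline_db()] database.
#' @param mutation_rate named per-subset per-base substitution rates
#'   (defaults: NBC 0.0020, unswMBC 0.0417, IgG 0.0314, IgA 0.0566 -- the
#'   printed change/base frequencies of the emulated subsets).
#' @param error_rate per-base polymerase + sequencing error rate (0.008).
#' @param cdr3_mean named per-subset mean CDR3 length in amino acids
#'   (defaults 16.05, 14.86, 15.53, 15.08).
#' @param cdr3_sd SD of the per-read CDR3 length (amino acids).
#' @param usage_weights optional list with elements `V`, `D`, `J` overriding
#'   the database weights.
#' @return A `repertoire_plan`.
#' @export
repertoire_plan <- function(germline_db = make_germline_db(),
                            mutation_rate = c(NBC = 0.0020, unswMBC = 0.0417,
                                              IgG = 0.0314, IgA = 0.0566),
                            error_rate = 0.008,
                            cdr3_mean = c(NBC = 16.05, unswMBC = 14.86,
                                          IgG = 15.53, IgA = 15.08),
                            cdr3_sd = 3.5, usage_weights = NULL) {
  stopifnot(inherits(germline_db, "germline_db"))
  for (cls in c("V", "D", "J"))
    if (!nrow(germline_db[[cls]])) stop2("empty germline class: ", cls)
  if (any(mutation_rate < 0 | mutation_rate > 1) ||
      error_rate < 0 || error_rate > 1)
    stop2("rates must lie in [0, 1]")
  w <- list(V = germline_db$V$weight, D = germline_db$D$weight,
            J = germline_db$J$weight)
  if (!is.null(usage_weights)) w[names(usage_weights)] <- usage_weights
  for (cls in names(w)) {
    if (abs(sum(w[[cls]]) - 1) > 1e-9)
      stop2("usage weights must sum to 1 for class ", cls)
  }
  structure(list(db = germline_db, usage_weights = w,
                 mutation_rate = mutation_rate, error_rate = error_rate,
                 cdr3_mean = cdr3_mean, cdr3_sd = cdr3_sd),
            class = "repertoire_plan")
}

#' Simulate an IgH amplicon read set with planted mutations
#'
#' Each read is a full V segment, an N1 region, a (possibly trimmed) D
#' fragment, an N2 region, and a full J segment. The junction length is
#' 3 x the drawn CDR3 length (amino acids), so the CDR3 sits in frame
#' between the V-end Cys codon and the J-start Trp codon. N-region lengths
#' are geometric(p = 0.25), which leaves D fragments short and D calls
#' noisy. Substitutions are placed i.i.d. at rate `mutation_rate[subset] +
#' error_rate`; each substituted position is labeled a true mutation with
#' probability mutation_rate / (mutation_rate + error_rate), else a
#' sequencing/polymerase error, and the truth lists the two separately.
#'
#' @param plan a [repertoire_plan()].
#' @param n_reads number of reads.
#' @param subset subset label selecting the mutation rate and CDR3 mean; any
#'   label absent from the plan vectors falls back to a rate of 0.
#' @param seed RNG seed.
#' @return A list: `reads` (named character vector of sequences), `truth`
#'   (per-read data.frame: v/d/j ids, cdr3 length, junction composition),
#'   `mutations` (data.frame read, position, ref, alt, type = mutation|error).
#' @export
generate_repertoire <- function(plan, n_reads, subset, seed = 1) {
  stopifnot(inherits(plan, "repertoire_plan"), n_reads >= 1)
  db <- plan$db
  m_rate <- unname(plan$mutation_rate[subset])
  if (is.na(m_rate)) m_rate <- 0
  e_rate <- plan$error_rate
  c_mean <- unname(plan$cdr3_mean[subset])
  if (is.na(c_mean)) c_mean <- 15
  bases <- c("A", "C", "G", "T")

  with_seed(seed, {
    vi <- sample.int(nrow(db$V), n_reads, TRUE, prob = plan$usage_weights$V)
    di <- sample.int(nrow(db$D), n_reads, TRUE, prob = plan$usage_weights$D)
    ji <- sample.int(nrow(db$J), n_reads, TRUE, prob = plan$usage_weights$J)
    cdr3_len <- pmax(5L, round(rnorm(n_reads, c_mean, plan$cdr3_sd)))
    junc <- 3L * cdr3_len
    d_full <- nchar(db$D$seq)[di]
    n1 <- pmin(rgeom(n_reads, 0.25), junc)
    d_use <- pmin(d_full, junc - n1)
    n2 <- junc - n1 - d_use

    d_start <- pmax(1L, floor((d_full - d_use) / 2) + 1L)
    d_frag <- substr(db$D$seq[di], d_start, d_start + d_use - 1L)
    rand_chunk <- function(lens) {
      tot <- sum(lens)
      ch <- sample(bases, tot, replace = TRUE)
      grp <- rep.int(seq_along(lens), lens)
      out <- rep("", length(lens))
      if (tot) {
        agg <- vapply(split(ch, factor(grp, levels = seq_along(lens))),
                      paste, character(1), collapse = "")
        out <- unname(agg)
      }
      out
    }
    n1s <- rand_chunk(n1); n2s <- rand_chunk(n2)
    reads <- paste0(db$V$seq[vi], n1s, d_frag, n2s, db$J$seq[ji])

    # plant substitutions over the concatenated read bases
    lens <- nchar(reads)
    chars <- strsplit(paste(reads, collapse = ""), "")[[1]]
    rate <- m_rate + e_rate
    hit <- which(runif(length(chars)) < rate)
    mut_tab <- NULL
    if (length(hit)) {
      old <- chars[hit]
      shift <- sample.int(3L, length(hit), replace = TRUE)
      new <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
      chars[hit] <- new
      read_of <- findInterval(hit - 1L, cumsum(lens)) + 1L
      pos_in <- hit - cumsum(c(0L, lens))[read_of]
      type <- ifelse(runif(length(hit)) < m_rate / rate, "mutation", "error")
      mut_tab <- data.frame(read = sprintf("R%06d", read_of),
                            position = pos_in, ref = old, alt = new,
                            type = type, stringsAsFactors = FALSE)
    }
    reads <- vapply(split(chars, rep.int(seq_len(n_reads), lens)),
                    paste, character(1), collapse = "")
    names(reads) <- sprintf("R%06d", seq_len(n_reads))

    truth <- data.frame(read = names(reads), v_call = db$V$id[vi],
                        d_call = db$D$id[di], j_call = db$J$id[ji],
                        cdr3_len = cdr3_len, n1 = n1, d_used = d_use, n2 = n2,
                        subset = subset, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth,
         mutations = mut_tab %||% data.frame(read = character(), position = integer(),
                                             ref = character(), alt = character(),
                                             type = character()))
  })
}
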