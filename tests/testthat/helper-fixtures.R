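# Shared fixtures and independent (brute-force) oracles for the test suite.

.fixtures <- new.env(parent = emptyenv())

# small count_matrix with two 3-sample groups
toy_cm <- function(counts, subsets = rep(c("NBC", "IgG"), each = 3)) {
  n <- ncol(counts)
  colnames(counts) <- paste0("s", seq_len(n))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  count_matrix(counts, data.frame(sample = colnames(counts), subset = subsets))
}

# NB matrix with planted fold changes in group B (last nB columns)
sim_nb_cm <- function(n_feat, mu, phi, nA = 3, nB = 3, de_idx = integer(),
                      log2fc = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_feat * (nA + nB), mu = mu, size = 1 / phi),
              n_feat, nA + nB)
  if (length(de_idx))
    m[de_idx, nA + seq_len(nB)] <-
      rnbinom(length(de_idx) * nB, mu = mu * 2^log2fc, size = 1 / phi)
  toy_cm(m, subsets = rep(c("A", "B"), c(nA, nB)))
}

# independent TMM: direct trimmed-mean computation against an explicit
# reference column (no quantile-based reference selection)
brute_tmm_pair <- function(m, j, ref, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(m)
  ok <- m[, j] > 0 & m[, ref] > 0
  M <- log2((m[ok, j] / lib[j]) / (m[ok, ref] / lib[ref]))
  A <- 0.5 * log2((m[ok, j] / lib[j]) * (m[ok, ref] / lib[ref]))
  keep <- M >= quantile(M, trim_m) & M <= quantile(M, 1 - trim_m) &
    A >= quantile(A, trim_a) & A <= quantile(A, 1 - trim_a)
  2^mean(M[keep])
}

# brute-force all-pairs interval overlap (chrom/start/end data.frames, 1-based)
brute_overlap_pairs <- function(a, b, min_bp = 1L) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1L
      if (ov >= min_bp) out <- rbind(out, c(i, j))
    }
  }
  out
}

# exhaustive seed-site search: slide every canonical site string over the UTR
brute_seed_scan <- function(utr, mirna) {
  utr <- chartr("Uu", "Tt", toupper(utr))
  hits <- NULL
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  m <- chartr("Uu", "Tt", toupper(mirna))
  core <- rc(substr(m, 2, 7)); m8 <- substr(rc(substr(m, 2, 8)), 1, 1)
  L <- nchar(utr)
  for (i in seq_len(L - 5L)) {
    if (substr(utr, i, i + 5L) != core) next
    has_m8 <- i > 1 && substr(utr, i - 1L, i - 1L) == m8
    has_a1 <- i + 6L <= L && substr(utr, i + 6L, i + 6L) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    pos0 <- (i - 1L) - if (has_m8) 1L else 0L
    hits <- rbind(hits, data.frame(position = pos0, type = type))
  }
  hits
}

# brute-force germline assignment: score every germline by a direct loop
brute_assign_v <- function(read, vtab) {
  sc <- vapply(seq_len(nrow(vtab)), function(k) {
    v <- strsplit(vtab$seq[k], "")[[1]]
    r <- strsplit(substr(read, 1, length(v)), "")[[1]]
    L <- min(length(v), length(r))
    sum(r[1:L] == v[1:L]) - sum(r[1:L] != v[1:L])
  }, numeric(1))
  vtab$id[which.max(sc)]
}

# default full-size run shared by several acceptance checks (computed once)
default_mrna_run <- function(seed = 1) {
  key <- paste0("mrna", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- generator_config(seed = seed)
    sp <- signature_plan(cfg)
    ex <- generate_expression(cfg, sp)
    cm <- filter_expressed(ex$counts, 1, unit = "RPKM")
    .fixtures[[key]] <- list(
      cfg = cfg, plan = sp, ex = ex, cm = cm,
      de_g = nb_exact_test(cm, "NBC", "IgG"),
      de_a = nb_exact_test(cm, "NBC", "IgA"),
      de_iso = nb_exact_test(cm, "IgA", "IgG"))
  }
  .fixtures[[key]]
}

default_germline <- function() {
  if (is.null(.fixtures$db)) .fixtures$db <- make_germline_db()
  .fixtures$db
}
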