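small_cfg <- function(seed = 1)
  generator_config(n_genes = 1500, n_mirnas = 120, n_lncrnas = 150,
                   n_peaks = 2000, seed = seed)

small_plan <- function(cfg)
  signature_plan(cfg, n_extra_up = 60, n_extra_down = 80)

test_that("generator validates its configuration", {
  expect_error(generator_config(dispersion = 0), "positive")
  expect_error(generator_config(n_subjects = 0), "at least one")
  expect_error(generator_config(lib_size_range = c(10, 5)), "increasing")
  cfg <- small_cfg()
  expect_error(signature_plan(generator_config(n_genes = 10)), "more features")
})

test_that("same seed gives bit-identical outputs, new seed differs", {
  cfg <- small_cfg(7)
  pl <- small_plan(cfg)
  a <- generate_expression(cfg, pl)
  b <- generate_expression(cfg, pl)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  c2 <- generate_expression(small_cfg(8), small_plan(small_cfg(8)))
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("truth and null partition the feature set; effects appear once", {
  cfg <- small_cfg()
  pl <- small_plan(cfg)
  ex <- generate_expression(cfg, pl)
  expect_false(anyDuplicated(ex$truth$feature) > 0)
  expect_true(all(ex$truth$feature %in% rownames(ex$counts$counts)))
  nulls <- setdiff(rownames(ex$counts$counts), ex$truth$feature)
  expect_equal(length(nulls) + nrow(ex$truth), cfg$n_genes)
  # null features carry no effect in the mean matrix: mu proportional to the
  # depth factors for every null feature (same column pattern)
  mu_null <- ex$mu[nulls[1:50], ]
  ratios <- sweep(mu_null, 1, mu_null[, 1], "/")
  expect_true(all(abs(sweep(ratios, 2, ratios[1, ], "-")) < 1e-12))
})

test_that("an empty plan plants nothing", {
  cfg <- small_cfg()
  pl <- small_plan(cfg)
  pl$table <- pl$table[0, , drop = FALSE]
  ex <- generate_expression(cfg, pl)
  expect_equal(nrow(ex$truth), 0)
})

test_that("null-gene sample means sit within 3 SE of the planted mean", {
  cfg <- generator_config(n_genes = 10000, seed = 2)
  pl <- signature_plan(cfg)
  ex <- generate_expression(cfg, pl)
  nulls <- setdiff(rownames(ex$counts$counts), ex$truth$feature)
  nulls <- nulls[ex$baselines[nulls] > 0.1]
  mu <- ex$mu[nulls, ]
  phi <- ex$dispersion[nulls]
  se <- sqrt(rowSums(mu + phi * mu^2)) / ncol(mu)
  dev <- abs(rowMeans(ex$counts$counts[nulls, ]) - rowMeans(mu))
  expect_gte(mean(dev <= 3 * se), 0.99)
})

test_that("null counts are consistent with the NB(mu, phi) moment model", {
  cfg <- small_cfg(4)
  pl <- small_plan(cfg)
  ex <- generate_expression(cfg, pl)
  nulls <- setdiff(rownames(ex$counts$counts), ex$truth$feature)
  nulls <- nulls[rowMeans(ex$mu[nulls, ]) >= 5]
  mu <- ex$mu[nulls, ]
  phi <- ex$dispersion[nulls]
  q <- rowSums((ex$counts$counts[nulls, ] - mu)^2 / (mu + phi * mu^2))
  reject <- q > qchisq(0.99, df = ncol(mu))
  expect_gte(mean(!reject), 0.95)
})

test_that("repertoire generator: zero rates reproduce germline exactly", {
  db <- default_germline()
  pl <- repertoire_plan(db, mutation_rate = c(NBC = 0), error_rate = 0)
  sim <- generate_repertoire(pl, 30, "NBC", seed = 5)
  expect_equal(nrow(sim$mutations), 0)
  v <- setNames(db$V$seq, db$V$id)
  j <- setNames(db$J$seq, db$J$id)
  expect_true(all(startsWith(sim$reads, v[sim$truth$v_call])))
  expect_true(all(endsWith(sim$reads, j[sim$truth$j_call])))
  expect_equal(nchar(sim$reads),
               nchar(v[sim$truth$v_call]) + 3 * sim$truth$cdr3_len +
                 nchar(j[sim$truth$j_call]), ignore_attr = TRUE)
})

test_that("observed mismatch fraction matches the binomial expectation", {
  pl <- repertoire_plan(default_germline(),
                        mutation_rate = c(IgA = 0.0566), error_rate = 0.008)
  sim <- generate_repertoire(pl, 4000, "IgA", seed = 6)
  n_bases <- sum(nchar(sim$reads))
  frac <- nrow(sim$mutations) / n_bases
  p0 <- 0.0566 + 0.008
  se <- sqrt(p0 * (1 - p0) / n_bases)
  expect_lt(abs(frac - p0), 3 * se)
  # truth labels mutations and errors separately and covers all substitutions
  expect_setequal(unique(sim$mutations$type), c("mutation", "error"))
  expect_true(all(sim$mutations$ref != sim$mutations$alt))
})

test_that("ATAC generator: Venn fractions, planted DARs and concordance", {
  cfg <- small_cfg(3)
  pl <- small_plan(cfg)
  ex <- generate_expression(cfg, pl)
  mp <- mirna_plan(cfg, pl, n_extra_targets = 10)
  lp <- lncrna_plan(cfg)
  ann <- generate_annotation(cfg, pl, mp, lp)
  apl <- atac_plan()
  at <- generate_atac(cfg, apl, expr_truth = ex$truth, gene_ranges = ann$genes)
  cls <- S4Vectors::mcols(at$peaks)$class
  frac <- table(cls)[c("mbc", "nbc", "shared")] / length(at$peaks)
  expect_lt(abs(frac[["mbc"]] - 0.436), 0.01)
  expect_lt(abs(frac[["nbc"]] - 0.119), 0.01)
  expect_lt(abs(frac[["shared"]] - 0.445), 0.01)
  # shared_fraction = 1 leaves no unique peaks
  at1 <- generate_atac(cfg, atac_plan(shared_fraction = 1,
                                      mbc_only_fraction = 0,
                                      nbc_only_fraction = 0))
  v1 <- venn_peaks(at1$peaks[S4Vectors::mcols(at1$peaks)$present_nbc],
                   at1$peaks[S4Vectors::mcols(at1$peaks)$present_mbc])
  expect_equal(unname(v1$fractions["shared"]), 1)
  # truth-level concordance close to the planned fraction
  de_dir <- ex$truth[ex$truth$role %in% c("core_up", "core_down",
                                          "extra_up", "extra_down"), ]
  de_dir <- data.frame(feature = de_dir$feature,
                       direction = ifelse(grepl("up$", de_dir$role),
                                          "up", "down"))
  conc <- integrate_de_dar(de_dir,
                           data.frame(feature = at$dar_truth$peak,
                                      direction = at$dar_truth$direction),
                           ann$genes, at$peaks)
  expect_lt(abs(conc$summary[["fraction_concordant"]] - 0.354), 0.03)
  expect_error(atac_plan(shared_fraction = 0.6, mbc_only_fraction = 0.6,
                         nbc_only_fraction = 0.1), "sum to 1")
})

test_that("annotation generator: planted seed sites are the exact truth", {
  cfg <- small_cfg(9)
  pl <- small_plan(cfg)
  mp <- mirna_plan(cfg, pl, n_extra_targets = 15)
  lp <- lncrna_plan(cfg)
  ann <- generate_annotation(cfg, pl, mp, lp)
  sc <- find_seed_sites(ann$utrs, ann$mirna_seqs[mp$target_mirnas])
  key <- function(d) paste(d$mirna, d$gene, d$position, d$type)
  expect_setequal(key(sc), key(ann$sites))
  # target analogues include the five MIR181-target core genes
  core5 <- pl$table$feature[!is.na(pl$table$analog) &
                              pl$table$analog %in%
                              paste0(c("RASSF6", "TOX", "TRERF1", "RORA",
                                       "TRPV3"), "-like")]
  expect_true(all(core5 %in% ann$sites$gene))
  # designed cis pairs fall inside the window, trans pairs outside
  cp <- ann$cis_pairs
  d <- GenomicRanges::distance(ann$lncrnas[cp$lncrna], ann$genes[cp$gene],
                               ignore.strand = TRUE)
  same_chr <- as.character(GenomicRanges::seqnames(ann$lncrnas[cp$lncrna])) ==
    as.character(GenomicRanges::seqnames(ann$genes[cp$gene]))
  is_cis <- same_chr & !is.na(d) & d <= 1e6
  expect_true(all(is_cis[cp$designed_cis & cp$lncrna != "LNC00001"]))
  expect_true(all(!is_cis[!cp$designed_cis]))
})
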