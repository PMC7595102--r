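mir181a <- c(m181a = "AACAUUCAACGCUGUCGGUGAGU")

test_that("find_seed_sites classifies constructed sites correctly", {
  # 8mer site for the MIR181a seed: revcomp(pos 2-8) + A = "TGAATGTA"
  utr8 <- c(u = paste0("CCCCCC", "TGAATGTA", "CCCCCC"))
  s <- find_seed_sites(utr8, mir181a)
  expect_equal(nrow(s), 1)
  expect_equal(s$type, "8mer")
  expect_equal(s$position, 6)  # 0-based
  # 7mer-m8 (no A at the 3' flank)
  utr7 <- c(u = paste0("CCCCCC", "TGAATGT", "CCCCCC"))
  s7 <- find_seed_sites(utr7, mir181a)
  expect_equal(s7$type, "7mer-m8")
  # zero planted sites -> empty
  expect_equal(nrow(find_seed_sites(c(u = "CCCCCCCCCCCC"), mir181a)), 0)
  expect_error(find_seed_sites(utr8, c(m = "ACGUACG")), "8 nt")
})

test_that("site-type hierarchy degrades to the best allowed contained type", {
  utr8 <- c(u = paste0("CCCCCC", "TGAATGTA", "CCCCCC"))
  s <- find_seed_sites(utr8, mir181a, allowed_types = c("7mer-m8", "6mer"))
  expect_equal(s$type, "7mer-m8")
  s6 <- find_seed_sites(utr8, mir181a, allowed_types = "6mer")
  expect_equal(s6$type, "6mer")
  expect_equal(s6$position, 7)  # the 6mer core starts one base downstream
})

test_that("classifier agrees with an exhaustive substring search", {
  set.seed(101)
  utrs <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = ""),
    character(1))
  names(utrs) <- paste0("u", 1:100)
  got <- find_seed_sites(utrs, mir181a)
  want <- do.call(rbind, lapply(names(utrs), function(g) {
    h <- brute_seed_scan(utrs[[g]], mir181a)
    if (is.null(h)) return(NULL)
    cbind(gene = g, h)
  }))
  key <- function(d) paste(d$gene, d$position, d$type)
  if (is.null(want)) {
    expect_equal(nrow(got), 0)
  } else {
    expect_setequal(key(got), key(want))
  }
})

test_that("duplex_energy matches a hand-computed stack sum and edge rules", {
  # fully complementary GC-only 8-mer: GGGGCCCC vs itself reversed-complement
  # stacks (miRNA 5'->3'): GG GG GG GC CC CC CC
  want <- 3 * -3.26 + -3.42 + 3 * -3.26 + 4.09
  expect_equal(duplex_energy("GGGGCCCC", "GGGGCCCC"), want)
  # no complementarity -> no duplex
  expect_true(is.na(duplex_energy("AAAAAAAA", "CCCCCCCC")))
  expect_error(duplex_energy("GGGGCCCC", "ACGU"), "8-40")
  # 8mer site is at least as stable as the 6mer site in the same context
  m <- unname(mir181a)
  utr8 <- paste0("CCCCCC", "TGAATGTA", "CCCCCC")
  utr6 <- paste0("CCCCCC", "CGAATGTC", "CCCCCC")
  dg8 <- duplex_energy(m, utr8)
  dg6 <- duplex_energy(m, utr6)
  expect_true(dg8 <= dg6 || is.na(dg6))
})

test_that("target_release_screen applies the four-way rule", {
  expr_m <- rbind(mir1 = c(9, 8, 7, 6, 5, 4, 3, 2, 1, 1.5, 0.5, 0.2))
  colnames(expr_m) <- paste0("s", 1:12)
  up <- c("gA", "gB", "gC")
  expr_g <- rbind(gA = rev(expr_m[1, ]),              # r_s = -1
                  gB = expr_m[1, ],                   # r_s = +1
                  gC = rev(expr_m[1, ]))              # r_s = -1, but no site
  colnames(expr_g) <- colnames(expr_m)
  sites <- data.frame(mirna = c("mir1", "mir1"), gene = c("gA", "gB"),
                      type = c("7mer-m8", "8mer"))
  out <- target_release_screen(up, "mir1", sites, expr_m, expr_g)
  expect_equal(out$released$gene, "gA")
  expect_equal(out$fraction, 1 / 3)
  # empty down-miRNA set -> nothing released
  out0 <- target_release_screen(up, character(), sites, expr_m, expr_g)
  expect_equal(nrow(out0$released), 0)
  expect_equal(out0$fraction, 0)
  # 6mer sites only qualify when the minimum type is lowered
  sites6 <- data.frame(mirna = "mir1", gene = "gA", type = "6mer")
  expect_equal(nrow(target_release_screen(up, "mir1", sites6, expr_m,
                                          expr_g)$released), 0)
  expect_equal(nrow(target_release_screen(up, "mir1", sites6, expr_m, expr_g,
                                          min_site_type = "6mer")$released), 1)
})

test_that("planted MIR181 targets are released on synthetic data", {
  # 12 subjects: the correlation screen needs more libraries than the
  # 4 x 3 default to call every planted target (see the methods vignette)
  cfg <- generator_config(n_genes = 1500, n_mirnas = 120, n_lncrnas = 150,
                          n_subjects = 12, seed = 1)
  sp <- signature_plan(cfg, n_extra_up = 60, n_extra_down = 80)
  mp <- mirna_plan(cfg, sp, n_extra_targets = 10)
  lp <- lncrna_plan(cfg)
  ex <- generate_expression(cfg, sp)
  mi <- generate_expression(cfg, mp)
  ann <- generate_annotation(cfg, sp, mp, lp)
  rpkm <- normalize_units(ex$counts, "RPKM")
  rpm <- normalize_units(mi$counts, "RPM")
  core5 <- sp$table$feature[!is.na(sp$table$analog) & sp$table$analog %in%
                              paste0(c("RASSF6", "TOX", "TRERF1", "RORA",
                                       "TRPV3"), "-like")]
  up <- sp$table$feature[sp$table$role %in% c("core_up", "extra_up")]
  down <- mp$table$feature[mp$table$role == "core_down"]
  out <- target_release_screen(up, down, ann$sites, rpm, rpkm)
  expect_true(all(core5 %in% out$released$gene))
})

test_that("lncrna_coexpression labels relations and handles degeneracies", {
  g1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, 1.01e6))
  g2 <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1e6, 1.01e6))
  names(g1) <- "L1"; names(g2) <- "G1"
  x <- matrix(c(1, 3, 2, 5, 4, 7, 6, 9, 8, 11, 10, 12), 1,
              dimnames = list("L1", paste0("s", 1:12)))
  y <- x; rownames(y) <- "G1"
  # identical vectors: r_s = 1; different chromosomes: trans
  out <- lncrna_coexpression(x, y, g1, g2)
  expect_equal(out$records$r_s, 1)
  expect_equal(out$records$relation, "trans")
  # same chromosome within the window: cis
  g2b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1.5e6, 1.51e6))
  names(g2b) <- "G1"
  expect_equal(lncrna_coexpression(x, y, g1, g2b)$records$relation, "cis")
  # constant vectors are excluded
  y2 <- rbind(y, G2 = rep(5, 12))
  g2c <- c(g2b, GenomicRanges::GRanges("chr1", IRanges::IRanges(2e6, 2.01e6)))
  names(g2c) <- c("G1", "G2")
  expect_message(out2 <- lncrna_coexpression(x, y2, g1, g2c), "constant")
  expect_equal(nrow(out2$records), 1)
  # r_s is invariant under monotone transforms
  expect_equal(lncrna_coexpression(x, exp(y / 3), g1, g2b)$records$r_s, 1)
})

test_that("latent-factor cis pairs are recovered at the planted fraction", {
  set.seed(77)
  n_pair <- 200; ns <- 12
  driven <- 1:10  # 5% of pairs share a strong latent factor
  lnc <- matrix(rnorm(n_pair * ns), n_pair, ns,
                dimnames = list(paste0("L", 1:n_pair), paste0("s", 1:ns)))
  mrna <- matrix(rnorm(n_pair * ns), n_pair, ns,
                 dimnames = list(paste0("G", 1:n_pair), colnames(lnc)))
  for (i in driven) {
    z <- rnorm(ns)
    lnc[i, ] <- sqrt(0.1) * rnorm(ns) + z   # rho ~ 0.95
    mrna[i, ] <- sqrt(0.1) * rnorm(ns) + z
  }
  pos <- (1:n_pair) * 3e6
  gl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos + 1e4))
  gm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos + 2e4, pos + 3e4))
  names(gl) <- rownames(lnc); names(gm) <- rownames(mrna)
  out <- lncrna_coexpression(lnc, mrna, gl, gm)
  rec <- out$records
  diag_rec <- rec[sub("^G", "", rec$partner) == sub("^L", "", rec$lncrna), ]
  expect_equal(nrow(diag_rec), n_pair)
  frac <- mean(diag_rec$r_s > 0.7)
  expect_lt(abs(frac - 0.05), 0.02)
  # exchange symmetry of the summary fractions
  out_sw <- lncrna_coexpression(mrna, lnc, gm, gl)
  expect_equal(sort(out$summary$frac_pos), sort(out_sw$summary$frac_pos))
})

test_that("sponge_screen applies its rule on a hand-built instance", {
  samples <- paste0("s", 1:12)
  mir <- rbind(m1 = 12:1)
  lnc <- rbind(L1 = 1:12)
  gene <- rbind(gA = 1:12 + rnorm(12, sd = 0.01))
  colnames(mir) <- colnames(lnc) <- colnames(gene) <- samples
  release <- list(by_mirna = list(m1 = "gA"))
  out <- sponge_screen("L1", "m1", release, lnc, mir, gene)
  expect_equal(nrow(out), 1)
  expect_true(out$candidate)
  expect_false(out$partial)
  expect_gt(out$median_target_r, 0)
  # no upregulated lncRNAs -> empty
  out0 <- sponge_screen(character(), "m1", release, lnc, mir, gene)
  expect_equal(nrow(out0), 0)
  # miRNA without released targets -> partial candidate
  release2 <- list(by_mirna = list())
  out2 <- sponge_screen("L1", "m1", release2, lnc, mir, gene)
  expect_true(out2$partial)
  expect_true(out2$candidate)
})

test_that("the MIAT analogue is detected as a MIR181 sponge", {
  # powered scenario: 12 subjects (48 libraries) make the correlation screen
  # informative at the default noise level (see the methods vignette)
  cfg <- generator_config(n_genes = 1500, n_mirnas = 120, n_lncrnas = 150,
                          n_subjects = 12, seed = 1)
  sp <- signature_plan(cfg, n_extra_up = 60, n_extra_down = 80)
  mp <- mirna_plan(cfg, sp, n_extra_targets = 10)
  lp <- lncrna_plan(cfg)
  ex <- generate_expression(cfg, sp)
  mi <- generate_expression(cfg, mp)
  ln <- generate_expression(cfg, lp)
  ann <- generate_annotation(cfg, sp, mp, lp)
  rpkm <- normalize_units(ex$counts, "RPKM")
  rpm <- normalize_units(mi$counts, "RPM")
  lnc_rpkm <- normalize_units(ln$counts, "RPKM")
  up_g <- sp$table$feature[sp$table$role %in% c("core_up", "extra_up")]
  down_m <- mp$table$feature[mp$table$role == "core_down"]
  up_l <- lp$table$feature[lp$table$role == "core_up"]
  release <- target_release_screen(up_g, down_m, ann$sites, rpm, rpkm)
  out <- sponge_screen(up_l, down_m, release, lnc_rpkm, rpm, rpkm)
  hit <- out[out$lncrna == "LNC00001" &
               out$mirna == mp$target_mirnas[1] & out$candidate, ]
  expect_equal(nrow(hit), 1)
  expect_false(hit$partial)
  expect_gt(hit$median_target_r, 0)
})
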