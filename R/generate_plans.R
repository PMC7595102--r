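#' Generator configuration
#'
#' Holds the study layout and noise model for the synthetic-data module.
#' Defaults mirror the emulated design: 4 B cell subsets (NBC, unswMBC,
#' IgG+ swMBC, IgA+ swMBC) x 3 subjects = 12 RNA libraries, negative-binomial
#' counts with variance mu + phi mu^2, and per-library depths drawn
#' log-uniformly from `lib_size_range` and applied as multiplicative factors
#' (the default range is the study's 12-21 million mRNA reads scaled down
#' about 1000-fold so the full pipeline runs in seconds).
#'
#' @param n_genes,n_mirnas,n_lncrnas,n_peaks feature counts per data class.
#' @param n_subjects subjects contributing one library per subset.
#' @param subsets ordered subset labels; the first is treated as the naive
#'   reference, the last two as the class-switched isotypes.
#' @param baseline_mean median NB mean of an unplanted feature at unit depth.
#' @param dispersion NB dispersion phi (> 0); scalar or per-feature vector.
#' @param lib_size_range pair of positive depths; only their ratios matter.
#' @param baseline_log2_sd spread (log2 scale) of per-feature baselines.
#' @param subject_sd optional log2-scale SD of a per-subject random effect
#'   (default 0 = none).
#' @param seed integer seed; identical configs give bit-identical outputs.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_genes = 10000, n_mirnas = 500, n_lncrnas = 1000,
                             n_peaks = 10000, n_subjects = 3,
                             subsets = c("NBC", "unswMBC", "IgG", "IgA"),
                             baseline_mean = 0.5, dispersion = 0.1,
                             lib_size_range = c(12000, 21000),
                             baseline_log2_sd = 2, subject_sd = 0, seed = 1) {
  if (any(dispersion <= 0)) stop2("dispersion must be positive")
  if (length(subsets) < 2 || n_subjects < 1)
    stop2("every subset needs at least one sample")
  if (length(lib_size_range) != 2 || any(lib_size_range <= 0) ||
      diff(lib_size_range) < 0)
    stop2("lib_size_range must be an increasing pair of positive numbers")
  structure(list(n_genes = n_genes, n_mirnas = n_mirnas,
                 n_lncrnas = n_lncrnas, n_peaks = n_peaks,
                 n_subjects = n_subjects, subsets = subsets,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 lib_size_range = lib_size_range,
                 baseline_log2_sd = baseline_log2_sd,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "generator_config")
}

# Shared constructor for the per-class DE plans. `table` rows describe every
# planted feature: role, analog label, per-subset log2 effects, abundance tier.
new_de_plan <- function(class, id_prefix, n_features, table, unsw_fraction,
                        baseline_mean, baseline_log2_sd, lib_size_range,
                        seed_offset, extra = list()) {
  if (anyDuplicated(table$feature))
    stop2("a feature may carry at most one planted effect")
  up <- table$feature[table$role %in% c("core_up", "extra_up")]
  dn <- table$feature[table$role %in% c("core_down", "extra_down")]
  if (length(intersect(up, dn))) stop2("up and down sets must be disjoint")
  if (unsw_fraction < 0 || unsw_fraction > 1)
    stop2("unsw_fraction must lie in [0, 1]")
  structure(c(list(class = class, id_prefix = id_prefix,
                   n_features = n_features, table = table,
                   unsw_fraction = unsw_fraction,
                   baseline_mean = baseline_mean,
                   baseline_log2_sd = baseline_log2_sd,
                   lib_size_range = lib_size_range,
                   seed_offset = seed_offset), extra),
            class = "de_plan")
}

#' Planted mRNA signature plan
#'
#' Default composition follows the emulated study: a core signature of 17
#' upregulated and 7 downregulated mRNAs shared by both switched-memory
#' subsets (effect `core_effect` log2 units vs NBC, attenuated by
#' `unsw_fraction` in unswMBC to model the transitional transcriptome); a
#' broader DE layer of 445 further up and 605 further down genes (totals 462
#' up / 612 down) at `extra_effect`; two unswMBC-specific genes (TFEC/ZBTB32
#' analogues); and five IgH constant-region analogues (class `IGHC`) with
#' isotype-reciprocal effects, which the signature step excludes by class.
#' The first five core-up genes are tagged as MIR181-target analogues
#' (RASSF6, TOX, TRERF1, RORA, TRPV3).
#'
#' @param config a [generator_config()].
#' @param core_effect,extra_effect,unsw_effect absolute log2 effects.
#' @param n_core_up,n_core_down,n_extra_up,n_extra_down set sizes.
#' @param unsw_fraction attenuation of sw effects in unswMBC.
#' @return A `de_plan`.
#' @export
signature_plan <- function(config, core_effect = 3, extra_effect = 2,
                           unsw_effect = 3, n_core_up = 17, n_core_down = 7,
                           n_extra_up = 445, n_extra_down = 605,
                           unsw_fraction = 0.4) {
  n <- config$n_genes
  need <- n_core_up + n_core_down + 2L + 5L + n_extra_up + n_extra_down
  if (need > n) stop2("plan needs more features than configured")
  ids <- feature_ids("G", seq_len(need), n)
  i <- 0L
  take <- function(k) { out <- ids[i + seq_len(k)]; i <<- i + k; out }
  core_up <- take(n_core_up); core_down <- take(n_core_down)
  unsw_up <- take(2L); ighc <- take(5L)
  extra_up <- take(n_extra_up); extra_down <- take(n_extra_down)

  analog <- rep(NA_character_, need)
  names(analog) <- ids[seq_len(need)]
  analog[core_up[seq_len(min(5L, length(core_up)))]] <-
    paste0(c("RASSF6", "TOX", "TRERF1", "RORA", "TRPV3"), "-like")[seq_len(min(5L, length(core_up)))]
  analog[unsw_up] <- c("TFEC-like", "ZBTB32-like")
  analog[ighc] <- c("IgCmu-like", "IgCdelta-like", "IgCgamma-like",
                    "IgCalpha-like", "IgCepsilon-like")

  tab <- rbind(
    plan_rows(core_up, "core_up", core_effect, unsw_fraction, tier = "high"),
    plan_rows(core_down, "core_down", -core_effect, unsw_fraction, tier = "high"),
    data.frame(feature = unsw_up, role = "unsw_up",
               lfc_unsw = unsw_effect, lfc_igg = extra_effect,
               lfc_iga = extra_effect, tier = "high",
               stringsAsFactors = FALSE),
    data.frame(feature = ighc, role = "ighc",
               lfc_unsw = c(0, 0, 0, 0, 0),
               lfc_igg = c(-2, -3, 3, 0, 1.5),
               lfc_iga = c(-2, -3, 0, 3, 0), tier = "high",
               stringsAsFactors = FALSE),
    plan_rows(extra_up, "extra_up", extra_effect, unsw_fraction, tier = "mid"),
    plan_rows(extra_down, "extra_down", -extra_effect, unsw_fraction, tier = "mid")
  )
  tab$analog <- unname(analog[tab$feature])
  # the five MIR181-target analogues ride the shared latent axis with a
  # small positive loading: released targets covary with the sponge and
  # against the miRNA beyond the subset means (the target-release biology)
  targ5 <- core_up[seq_len(min(5L, length(core_up)))]
  new_de_plan("mrna", "G", n, tab, unsw_fraction,
              baseline_mean = config$baseline_mean,
              baseline_log2_sd = config$baseline_log2_sd,
              lib_size_range = config$lib_size_range, seed_offset = 101L,
              extra = list(couplings = data.frame(feature = targ5,
                                                  loading = 0.4)))
}

plan_rows <- function(ids, role, effect, unsw_fraction, tier) {
  if (!length(ids)) return(NULL)
  data.frame(feature = ids, role = role, lfc_unsw = effect * unsw_fraction,
             lfc_igg = effect, lfc_iga = effect, tier = tier,
             stringsAsFactors = FALSE)
}

#' Planted miRNA profile plan
#'
#' 13 downregulated and 6 upregulated miRNAs shared by both swMBC subsets
#' (the printed miRNA-profile composition), planted on abundant miRNAs: real
#' small-RNA libraries are dominated by a handful of species, and the two
#' most downregulated analogues (MIR181a-like, MIR181b-like, which share the
#' MIR181 seed) sit at the very top of the abundance distribution. The first
#' `n_core_targets` target genes come from the mRNA plan's core analogues and
#' `n_extra_targets` further targets from its broader up set (50 of the 462
#' upregulated genes by default).
#'
#' @param config a [generator_config()].
#' @param sig_plan the mRNA [signature_plan()] the targets refer to.
#' @param effect absolute log2 effect in swMBC vs NBC.
#' @param n_up,n_down planted set sizes.
#' @param n_extra_targets targets beyond the five core analogues.
#' @param unsw_fraction attenuation in unswMBC.
#' @return A `de_plan` with extra fields `targets` (gene ids) and
#'   `target_mirnas` (the MIR181-family analogue ids).
#' @export
mirna_plan <- function(config, sig_plan, effect = 3, n_up = 6, n_down = 13,
                       n_extra_targets = 45, unsw_fraction = 0.4) {
  n <- config$n_mirnas
  ids <- feature_ids("MIR", seq_len(n_down + n_up), n)
  down <- ids[seq_len(n_down)]
  up <- ids[n_down + seq_len(n_up)]
  tab <- rbind(
    plan_rows(down, "core_down", -effect, unsw_fraction, tier = "high"),
    plan_rows(up, "core_up", effect, unsw_fraction, tier = "high")
  )
  tab$tier[tab$feature == down[1]] <- "vhigh"
  tab$analog <- NA_character_
  tab$analog[match(down[1:2], tab$feature)] <- c("MIR181a-like", "MIR181b-like")

  stab <- sig_plan$table
  core_targets <- stab$feature[!is.na(stab$analog) &
                                 stab$analog %in% paste0(c("RASSF6", "TOX", "TRERF1",
                                                           "RORA", "TRPV3"), "-like")]
  extra_up <- stab$feature[stab$role == "extra_up"]
  targets <- c(core_targets, head(extra_up, n_extra_targets))
  new_de_plan("mirna", "MIR", n, tab, unsw_fraction,
              baseline_mean = 0.4, baseline_log2_sd = 3,
              lib_size_range = c(600, 2500), seed_offset = 202L,
              extra = list(targets = targets, target_mirnas = down[1:2],
                           couplings = data.frame(feature = down[1:2],
                                                  loading = -0.8)))
}

#' Planted lncRNA profile plan
#'
#' 23 upregulated and 17 downregulated lncRNAs shared by both swMBC subsets,
#' with the first upregulated one tagged as the MIAT analogue (the MIR181
#' sponge, upregulated in unswMBC as well); 21 of the 40 sit in the abundant
#' tier (the printed delta-abundance annotation). Three isotype-differential
#' lncRNAs mirror the IgH-locus lncRNAs (AL928768.3-like 10.8-fold higher in
#' IgA, COPDA1-like 6.0-fold and RP11-731F5.1-like 4.6-fold higher in IgG).
#'
#' @param config a [generator_config()].
#' @param effect absolute log2 effect in swMBC vs NBC.
#' @param n_up,n_down planted set sizes.
#' @param unsw_fraction attenuation in unswMBC (MIAT-like keeps 0.8).
#' @return A `de_plan`.
#' @export
lncrna_plan <- function(config, effect = 3, n_up = 23, n_down = 17,
                        unsw_fraction = 0.4) {
  n <- config$n_lncrnas
  ids <- feature_ids("LNC", seq_len(n_up + n_down + 3L), n)
  up <- ids[seq_len(n_up)]
  down <- ids[n_up + seq_len(n_down)]
  iso <- ids[n_up + n_down + 1:3]
  tab <- rbind(
    plan_rows(up, "core_up", effect, unsw_fraction, tier = "high"),
    plan_rows(down, "core_down", -effect, unsw_fraction, tier = "high"),
    data.frame(feature = iso, role = "isotype", lfc_unsw = 0,
               lfc_igg = c(0, log2(6.0), log2(4.6)),
               lfc_iga = c(log2(10.8), 0, 0), tier = "high",
               stringsAsFactors = FALSE)
  )
  # 21 of the 40 shared DE lncRNAs are abundant; the rest sit lower.
  shared <- c(up, down)
  low <- shared[-seq_len(21L)]
  tab$tier[tab$feature %in% low] <- "mid"
  tab$analog <- NA_character_
  tab$analog[tab$feature == up[1]] <- "MIAT-like"
  tab$analog[match(iso, tab$feature)] <-
    c("AL928768.3-like", "COPDA1-like", "RP11-731F5.1-like")
  tab$lfc_unsw[tab$feature == up[1]] <- 0.8 * effect
  new_de_plan("lncrna", "LNC", n, tab, unsw_fraction,
              baseline_mean = 0.6, baseline_log2_sd = 2,
              lib_size_range = c(1200, 2100), seed_offset = 303L,
              extra = list(couplings = data.frame(feature = up[1],
                                                  loading = 0.8)))
}
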