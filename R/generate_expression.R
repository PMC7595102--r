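#' Generate a synthetic count matrix with planted differential expression
#'
#' Draws an NB feature-by-sample count matrix for the configured subset x
#' subject layout. Per-feature baselines are log2-normal around
#' `baseline_mean` (planted features are drawn from higher abundance tiers:
#' signature-grade features among the well-expressed, as in the emulated
#' study); per-sample depths come from `lib_size_range` and act as
#' multiplicative factors; planted log2 effects from the plan shift the NB
#' mean in the affected subsets. Counts are NB with variance mu + phi mu^2.
#'
#' @param config a [generator_config()].
#' @param plan a `de_plan` from [signature_plan()], [mirna_plan()] or
#'   [lncrna_plan()]. An empty plan table plants nothing.
#' @return A list:
#' \describe{
#'   \item{counts}{a [count_matrix()] (with feature lengths; IgH-constant
#'     analogues carry `feature_class = "IGHC"`).}
#'   \item{truth}{data.frame of every planted effect (one row per planted
#'     feature: role, analog, per-subset log2 effects, baseline).}
#'   \item{baselines, dispersion}{per-feature generative parameters.}
#'   \item{mu}{the planted NB mean matrix (for moment checks).}
#' }
#' Identical config + plan give bit-identical output.
#' @export
generate_expression <- function(config, plan) {
  stopifnot(inherits(config, "generator_config"), inherits(plan, "de_plan"))
  n <- plan$n_features
  ids <- feature_ids(plan$id_prefix, seq_len(n), n)
  if (!all(plan$table$feature %in% ids))
    stop2("plan features must be a subset of the configured features")
  if (any(config$dispersion <= 0)) stop2("dispersion must be positive")

  subsets <- config$subsets
  subjects <- paste0("S", seq_len(config$n_subjects))
  grid <- expand.grid(subject = subjects, subset = subsets,
                      stringsAsFactors = FALSE)[, 2:1]
  samples <- data.frame(sample = paste(grid$subset, grid$subject, sep = "_"),
                        subset = grid$subset, subject = grid$subject,
                        stringsAsFactors = FALSE)
  ns <- nrow(samples)

  with_seed(config$seed + plan$seed_offset, {
    u <- rnorm(n, 0, plan$baseline_log2_sd)
    tier <- stats::setNames(rep("bg", n), ids)
    tier[plan$table$feature] <- plan$table$tier
    u[tier == "mid"] <- rnorm(sum(tier == "mid"), 4.5, 1)
    u[tier == "high"] <- rnorm(sum(tier == "high"), 5, 1)
    u[tier == "vhigh"] <- rnorm(sum(tier == "vhigh"), 10, 0.3)
    baselines <- stats::setNames(plan$baseline_mean * 2^u, ids)

    depths <- exp(runif(ns, log(plan$lib_size_range[1]),
                        log(plan$lib_size_range[2])))
    fct <- depths / geomean(depths)

    lfc <- matrix(0, n, ns, dimnames = list(ids, samples$sample))
    if (nrow(plan$table)) {
      idx <- match(plan$table$feature, ids)
      for (s in seq_len(ns)) {
        sub <- samples$subset[s]
        eff <- switch(sub,
                      unswMBC = plan$table$lfc_unsw,
                      IgG = plan$table$lfc_igg,
                      IgA = plan$table$lfc_iga,
                      rep(0, nrow(plan$table)))
        lfc[idx, s] <- eff
      }
    }

    mu <- baselines * 2^lfc
    mu <- sweep(mu, 2L, fct, "*")
    if (config$subject_sd > 0) {
      for (sj in subjects) {
        cols <- samples$subject == sj
        mu[, cols] <- mu[, cols] * 2^rnorm(n, 0, config$subject_sd)
      }
    }
    # cross-class latent coupling: a per-library factor shared by every
    # data class (drawn from the master seed only), with signed loadings --
    # this plants the sponge hallmark, residual anti-covariation between
    # the MIAT and MIR181 analogues beyond the subset means
    if (!is.null(plan$couplings) && nrow(plan$couplings)) {
      z <- with_seed(config$seed + 777L, rnorm(ns))
      # orthogonal to the subset structure, unit amplitude: the latent models
      # residual library-level covariation, not additional subset effects
      z <- z - stats::ave(z, samples$subset)
      if (stats::sd(z) > 0) z <- z / stats::sd(z)
      for (r in seq_len(nrow(plan$couplings))) {
        f <- plan$couplings$feature[r]
        mu[f, ] <- mu[f, ] * 2^(plan$couplings$loading[r] * z)
      }
    }
    phi <- if (length(config$dispersion) == 1L)
      rep(config$dispersion, n) else config$dispersion
    if (length(phi) != n) stop2("per-feature dispersion has wrong length")
    cnt <- matrix(rnbinom(n * ns, mu = as.vector(mu), size = rep(1 / phi, ns)),
                  n, ns, dimnames = dimnames(mu))
    lens <- round(rlnorm(n, log(1500), 0.5))
    names(lens) <- ids

    fclass <- NULL
    if (any(plan$table$role == "ighc")) {
      fclass <- stats::setNames(rep(plan$class, n), ids)
      fclass[plan$table$feature[plan$table$role == "ighc"]] <- "IGHC"
    }

    truth <- plan$table
    truth$baseline <- unname(baselines[truth$feature])
    truth$dispersion <- phi[match(truth$feature, ids)]

    list(counts = count_matrix(cnt, samples, lengths = lens,
                               feature_class = fclass),
         truth = truth, baselines = baselines,
         dispersion = stats::setNames(phi, ids), mu = mu)
  })
}
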