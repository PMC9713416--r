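#' Simulation configuration
#'
#' One cell of the factorial design plus the structural constants of the
#' breeding scheme. Defaults reproduce the study conditions: 26 synthetic
#' founders over 21 chromosomes of 1.22 M / 1,200 SNPs, burn-in of 10
#' cycles of phenotypic selection (1 unselected cycle for biparental
#' founders), then 10 cycles of genomic selection with 400 crosses, 20
#' selected parents, and a training population growing by a net 80 DHs per
#' cycle from 400 to 1,200.
#'
#' @param founder_mode \code{"full"} (all founders, 10 burn-in cycles of
#'   phenotypic selection) or \code{"biparental"} (two most divergent
#'   founders, 1 unselected burn-in cycle).
#' @param n_qtl_per_chrom QTL per chromosome (2 oligogenic, 200 polygenic).
#' @param h2 heritability at standardization (0.2 or 0.8).
#' @param map_type \code{"WT"}, \code{"Pericentromere"} or
#'   \code{"Chromosome"}.
#' @param scale_factor map-distance fold change (1, 2 or 20; WT forces 1).
#' @param scenario effect-sign scenario 1..5.
#' @param qtl_type \code{"R"} (random) or \code{"DV"} (deleterious-variant).
#' @param predictor \code{"GW"} (SnpChip markers) or \code{"CV"} (causal
#'   variants).
#' @param match_dv_counts reduce the R-QTL count on D-group chromosomes to
#'   the DV capacity (60 at full scale) so R and DV settings are matched;
#'   applied only when \code{n_qtl_per_chrom > 2}.
#' @param d_group_n_qtl QTL per D-group chromosome under matched settings.
#' @param n_founders,n_chrom,mean_length,snp_density,coupling_target passed
#'   to \code{\link{generate_founders}} when no founder set is supplied.
#' @param markers_per_bin SnpChip sampling density per 1 cM bin.
#' @param n_burnin burn-in cycles (NULL: 10 for full, 1 for biparental).
#' @param n_gs_cycles genomic-selection cycles.
#' @param n_crosses crosses (and DH candidates) per cycle.
#' @param n_parents_burnin,n_parents_gs selected parents per cycle.
#' @param n_tp_add candidates phenotyped and appended to the TP per cycle.
#' @param tp_drop_rule \code{"net80"} drops the 80 lowest-EBV TP members
#'   per cycle (TP grows 400 to 1,200 over 10 cycles);
#'   \code{"literal20pct"} drops 20 percent of the updated TP.
#' @param interference_nu gamma interference shape for meiosis.
#' @param seed integer replicate seed.
#' @param founders optional prebuilt \code{founder_set} (reused across
#'   replicates, as with a fixed real dataset).
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(founder_mode = c("full", "biparental"),
                       n_qtl_per_chrom = 200, h2 = 0.8,
                       map_type = "WT", scale_factor = 1,
                       scenario = 1, qtl_type = c("R", "DV"),
                       predictor = c("GW", "CV"),
                       match_dv_counts = TRUE, d_group_n_qtl = 60,
                       n_founders = 26, n_chrom = 21, mean_length = 1.22,
                       snp_density = 1200, coupling_target = 0.33,
                       markers_per_bin = 5,
                       n_burnin = NULL, n_gs_cycles = 10, n_crosses = 400,
                       n_parents_burnin = 80, n_parents_gs = 20,
                       n_tp_add = 160,
                       tp_drop_rule = c("net80", "literal20pct"),
                       interference_nu = 2.63, seed = 1, founders = NULL) {
  founder_mode <- match.arg(founder_mode)
  qtl_type <- match.arg(qtl_type)
  predictor <- match.arg(predictor)
  tp_drop_rule <- match.arg(tp_drop_rule)
  if (founder_mode == "biparental" && qtl_type == "DV")
    stop("DV QTL are only evaluated in the full founder population")
  if (is.null(n_burnin))
    n_burnin <- if (founder_mode == "full") 10L else 1L
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# phenotypic-selection burn-in; returns list(tp = population, parents)
run_burn_in <- function(parents, map, arch, model, cfg) {
  for (cyc in seq_len(cfg$n_burnin)) {
    f1 <- random_crosses(parents, map, cfg$n_crosses, cfg$interference_nu)
    dh <- make_dh(f1, map, cfg$interference_nu,
                  id_prefix = sprintf("B%02d", cyc))
    if (cyc < cfg$n_burnin && cfg$founder_mode == "full") {
      y <- phenotype(dh, arch, model)
      parents <- subset_population(dh, top_k(y, cfg$n_parents_burnin))
    } else {
      parents <- dh  # final cycle: all DHs advance as the TP
    }
  }
  parents
}

#' Burn-in phase
#'
#' Runs the phenotypic-selection burn-in: each cycle makes
#' \code{n_crosses} random crosses among the current parents (the founders
#' in cycle 1), one F1 and one DH per cross, and advances the top 80 DHs by
#' phenotype; in the final cycle all 400 DHs are advanced as the training
#' population. Biparental mode runs a single unselected cycle. The trait is
#' then re-standardized to unit additive variance in the TP.
#'
#' @param founders a \code{founder_set}.
#' @param arch a \code{trait_arch} (founder-standardized).
#' @param cfg a \code{sim_config}.
#' @return list with \code{tp} (population), \code{arch} (re-standardized)
#'   and \code{model} (phenotype model re-anchored at varA = 1).
#' @export
burn_in <- function(founders, arch, cfg) {
  pop0 <- founder_population(founders)
  if (n_ind(pop0) < 2) stop("fewer than 2 parents")
  model <- phenotype_model(cfg$h2)
  tp <- run_burn_in(pop0, founders$map, arch, model, cfg)
  arch <- standardize_variance(arch, tp)
  model <- phenotype_model(cfg$h2, varA = 1)
  list(tp = tp, arch = arch, model = model)
}

dose_predictors <- function(pop, cfg_predictor, markers, qtl) {
  idx <- if (cfg_predictor == "CV") qtl else markers
  dose_matrix(pop, idx)
}

# When selection has fixed every predictor in the TP (an endpoint of the
# scheme, not a failure), fall back to a null model: zero effects, EBV =
# phenotype mean for everyone.
fit_rrblup_or_null <- function(Z, y, predictor_set) {
  tryCatch(fit_rrblup(Z, y, predictor_set = predictor_set),
           error = function(e) {
             if (!grepl("no predictor variation", conditionMessage(e)))
               stop(e)
             structure(list(intercept = mean(y),
                            effects = rep(0, ncol(Z)), lambda = Inf,
                            center = colMeans(Z),
                            predictor_set = predictor_set,
                            n_train = nrow(Z)),
                       class = "marker_effects_model")
           })
}

record_cycle <- function(cycle, cand, cand0, arch, ebv, tp_size) {
  g <- genetic_value(cand, arch)
  vA <- additive_variance(cand, arch)
  gvA <- genic_variance(cand, arch)
  fx <- qtl_fixation(cand, arch)
  daf <- allele_frequency_change(cand, cand0, arch)
  data.frame(
    cycle = cycle,
    varA = vA, genicVarA = gvA, bulmer = bulmer_effect(vA, gvA),
    mean_g = mean(g),
    accuracy = prediction_accuracy(ebv, g),
    fix_small = fx$fixed[1], fix_medium = fx$fixed[2],
    fix_large = fx$fixed[3],
    daf_small = daf$dAF[1], daf_medium = daf$dAF[2], daf_large = daf$dAF[3],
    daf_pos = attr(daf, "dAF_pos"), daf_neg = attr(daf, "dAF_neg"),
    tp_size = tp_size, n_candidates = n_ind(cand))
}

#' Run one simulation replicate end to end
#'
#' Executes the full pipeline: founder construction (or reuse), SnpChip and
#' QTL assignment, effect-sign scenario, variance standardization,
#' phenotypic burn-in, re-standardization, map treatment, and 10 cycles of
#' genomic selection with per-cycle response variables. Each GS cycle fits
#' RRBLUP on the training population, predicts the 400 DH candidates,
#' selects the top 20 as parents of the next cycle, phenotypes the top 160
#' into the TP and prunes the lowest-EBV TP members.
#'
#' @param cfg a \code{sim_config}.
#' @return a data.frame of 11 cycle records (cycle 0 = post-burn-in
#'   baseline), with the configuration attached as columns.
#' @export
run_replicate <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 1L))

  founders <- cfg$founders
  if (is.null(founders))
    founders <- generate_founders(cfg$n_founders, cfg$n_chrom,
                                  cfg$mean_length, cfg$snp_density,
                                  cfg$coupling_target,
                                  seed = derive_seed(cfg$seed, 11L))
  if (cfg$founder_mode == "biparental") founders <- derive_biparental(founders)

  set.seed(derive_seed(cfg$seed, 2L))
  markers <- if (cfg$predictor == "GW")
    sample_snpchip(founders, cfg$markers_per_bin) else integer(0)

  grp <- genome_group(nrow(founders$map$chrom))
  n_per <- rep(cfg$n_qtl_per_chrom, nrow(founders$map$chrom))
  if (cfg$match_dv_counts && cfg$n_qtl_per_chrom > 2 &&
      cfg$founder_mode == "full")
    n_per[grp == "D"] <- min(cfg$d_group_n_qtl, cfg$n_qtl_per_chrom)
  dv_pool <- if (cfg$qtl_type == "DV") sample_dv_pool(founders) else NULL
  if (cfg$qtl_type == "DV") {
    # DV capacity caps the per-chromosome count
    for (k in seq_along(n_per)) {
      on_chr <- which(founders$map$loci$chrom == founders$map$chrom$chrom[k])
      cap <- length(setdiff(intersect(dv_pool, on_chr), markers))
      if (cap == 0) stop("chromosome ", k, ": empty DV pool")
      n_per[k] <- min(n_per[k], cap)
    }
  }
  qtl <- assign_qtl(founders, cfg$qtl_type, n_per, dv_pool, markers)
  raw <- stats::rnorm(length(qtl))
  eff <- assign_effect_signs(raw, cfg$scenario)
  arch <- trait_arch(qtl, eff, cfg$qtl_type, cfg$scenario)
  arch <- standardize_variance(arch, founder_population(founders))

  bi <- burn_in(founders, arch, cfg)
  tp <- bi$tp; arch <- bi$arch; model <- bi$model

  trt <- map_treatment(cfg$map_type, cfg$scale_factor)
  gmap <- scale_map(founders$map, trt)

  tp_y <- phenotype(tp, arch, model)
  fit <- fit_rrblup_or_null(
    dose_predictors(tp, cfg$predictor, markers, arch$qtl), tp_y,
    cfg$predictor)
  ebv0 <- predict_ebv(fit, dose_predictors(tp, cfg$predictor, markers,
                                           arch$qtl))
  cand0 <- tp  # the TP is also the first candidate population
  records <- record_cycle(0L, cand0, cand0, arch, ebv0, n_ind(tp))
  parents <- subset_population(cand0, top_k(ebv0, cfg$n_parents_gs))

  for (cyc in seq_len(cfg$n_gs_cycles)) {
    f1 <- random_crosses(parents, gmap, cfg$n_crosses, cfg$interference_nu)
    cand <- make_dh(f1, gmap, cfg$interference_nu,
                    id_prefix = sprintf("G%02d", cyc))
    fit <- fit_rrblup_or_null(
      dose_predictors(tp, cfg$predictor, markers, arch$qtl), tp_y,
      cfg$predictor)
    ebv <- predict_ebv(fit, dose_predictors(cand, cfg$predictor, markers,
                                            arch$qtl))
    parents <- subset_population(cand, top_k(ebv, cfg$n_parents_gs))
    # TP update: phenotype the top candidates, append, prune by EBV
    add_idx <- top_k(ebv, cfg$n_tp_add)
    add <- subset_population(cand, add_idx)
    add_y <- phenotype(add, arch, model)
    tp <- bind_populations(tp, add)
    tp_y <- c(tp_y, add_y)
    tp_ebv <- predict_ebv(fit, dose_predictors(tp, cfg$predictor, markers,
                                               arch$qtl))
    n_drop <- if (cfg$tp_drop_rule == "net80")
      max(0L, cfg$n_tp_add - 80L) else round(0.2 * n_ind(tp))
    n_drop <- min(n_drop, n_ind(tp) - 2L)
    drop_idx <- bottom_k(tp_ebv, n_drop)
    keep <- setdiff(seq_len(n_ind(tp)), drop_idx)
    tp <- subset_population(tp, keep)
    tp_y <- tp_y[keep]
    records <- rbind(records,
                     record_cycle(cyc, cand, cand0, arch, ebv, n_ind(tp)))
  }
  records$gain <- genetic_gain(records$mean_g, records$cycle)
  for (nm in c("founder_mode", "n_qtl_per_chrom", "h2", "map_type",
               "scale_factor", "scenario", "qtl_type", "predictor", "seed"))
    records[[nm]] <- cfg[[nm]]
  rownames(records) <- NULL
  records
}
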