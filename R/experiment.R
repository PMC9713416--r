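#' Factorial design of simulation settings
#'
#' Builds the crossed design over founder mode, QTL number, heritability,
#' recombination scale, map type, QTL type, effect-sign scenario and
#' predictor set, with the study's exclusions applied: biparental founders
#' use only scenarios 3 and 4, and (by default) never DV QTL. At the
#' study's levels (full + biparental founders, 2/200 QTL, 0.2/0.8
#' heritability, 2x/20x, three map types, R/DV, scenarios 1-5, GW/CV) the
#' scenario restriction alone yields the published accounting of 672
#' settings; additionally excluding the biparental x DV cells, which were
#' never evaluated, leaves 576 runnable settings.
#'
#' @param founder_mode,n_qtl_per_chrom,h2,scale_factor,map_type,qtl_type,scenario,predictor
#'   factor levels to cross.
#' @param exclude_biparental_dv drop biparental x DV cells (default TRUE).
#' @param n_replicates replicates per setting.
#' @return data.frame with one row per setting plus a \code{setting} id.
#' @export
factorial_design <- function(founder_mode = c("full", "biparental"),
                             n_qtl_per_chrom = c(2, 200),
                             h2 = c(0.2, 0.8),
                             scale_factor = c(2, 20),
                             map_type = c("WT", "Pericentromere",
                                          "Chromosome"),
                             qtl_type = c("R", "DV"),
                             scenario = 1:5,
                             predictor = c("GW", "CV"),
                             exclude_biparental_dv = TRUE,
                             n_replicates = 100) {
  g <- expand.grid(founder_mode = founder_mode,
                   n_qtl_per_chrom = n_qtl_per_chrom, h2 = h2,
                   scale_factor = scale_factor, map_type = map_type,
                   qtl_type = qtl_type, scenario = scenario,
                   predictor = predictor,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  drop <- g$founder_mode == "biparental" & !g$scenario %in% c(3, 4)
  if (exclude_biparental_dv)
    drop <- drop | (g$founder_mode == "biparental" & g$qtl_type == "DV")
  g <- g[!drop, , drop = FALSE]
  rownames(g) <- NULL
  g$setting <- seq_len(nrow(g))
  attr(g, "n_replicates") <- n_replicates
  g
}

#' Run a factorial grid of replicated simulations
#'
#' Executes \code{\link{run_replicate}} for every setting and replicate.
#' Replicate seeds are derived deterministically from \code{base_seed},
#' the setting index, and the replicate index, so results are identical
#' whatever the worker count or completion order, and a rerun with the
#' same \code{base_seed} reproduces the table. Completed
#' (setting, replicate) pairs found in \code{previous} are skipped;
#' replicates that fail are logged with a warning and excluded.
#'
#' @param design data.frame from \code{\link{factorial_design}}.
#' @param base_seed integer.
#' @param n_replicates replicates per setting (default from the design).
#' @param workers parallel workers (forked; 1 = serial).
#' @param founders optional shared \code{founder_set} reused by every
#'   replicate, as when all runs draw from one real dataset.
#' @param config_args named list of extra arguments passed to
#'   \code{\link{sim_config}} (e.g. reduced problem sizes).
#' @param previous optional earlier result table to resume from.
#' @return long-format data.frame: one row per setting x replicate x cycle.
#' @export
run_grid <- function(design, base_seed = 1,
                     n_replicates = attr(design, "n_replicates"),
                     workers = 1L, founders = NULL, config_args = list(),
                     previous = NULL) {
  if (is.null(n_replicates)) n_replicates <- 1L
  tasks <- expand.grid(setting = design$setting,
                       replicate = seq_len(n_replicates),
                       KEEP.OUT.ATTRS = FALSE)
  if (!is.null(previous)) {
    done <- paste(previous$setting, previous$replicate)
    tasks <- tasks[!paste(tasks$setting, tasks$replicate) %in% done, ,
                   drop = FALSE]
  }
  run_one <- function(t_i) {
    s <- tasks$setting[t_i]; r <- tasks$replicate[t_i]
    row <- design[design$setting == s, ]
    args <- utils::modifyList(list(
      founder_mode = row$founder_mode,
      n_qtl_per_chrom = row$n_qtl_per_chrom, h2 = row$h2,
      map_type = row$map_type, scale_factor = row$scale_factor,
      scenario = row$scenario, qtl_type = row$qtl_type,
      predictor = row$predictor,
      seed = derive_seed(base_seed, s, r), founders = founders),
      config_args)
    res <- try(run_replicate(do.call(sim_config, args)), silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("setting ", s, " replicate ", r, " failed: ",
              attr(res, "condition")$message, call. = FALSE)
      return(NULL)
    }
    res$setting <- s
    res$replicate <- r
    res
  }
  out <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(tasks)), run_one, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(tasks)), run_one)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (!is.null(previous)) out <- rbind(previous, out)
  rownames(out) <- NULL
  out
}

grid_factors <- c("founder_mode", "n_qtl_per_chrom", "h2", "scale_factor",
                  "map_type", "qtl_type", "scenario", "predictor")

#' ANOVA proportion-of-variance decomposition
#'
#' Fits the all-main-effects plus first-order-interactions linear model to
#' one response at one cycle, e.g.
#' \code{gain ~ (n_qtl + h2 + scale + map_type + qtl_type + scenario +
#' predictor)^2}, with the replicate block removed first (the
#' between-replicate sum of squares is subtracted before the fixed-term
#' decomposition, which under a balanced design is equivalent to a random
#' replicate intercept). Each term's share of the total sum of squares is
#' reported as a percentage; imbalance is handled with Type-II sums of
#' squares.
#'
#' @param results long-format table from \code{\link{run_grid}}.
#' @param response response column name (e.g. \code{"gain"},
#'   \code{"varA"}, \code{"bulmer"}, \code{"accuracy"}).
#' @param cycle GS cycle at which to analyse (typically 6 or 10).
#' @return data.frame with columns \code{term} and \code{share} (percent),
#'   including \code{replicate} and \code{residual} rows.
#' @export
variance_decomposition <- function(results, response, cycle = 10) {
  dat <- results[results$cycle == cycle, , drop = FALSE]
  if (nrow(dat) == 0) stop("no rows at cycle ", cycle)
  y <- dat[[response]]
  if (is.null(y)) stop("unknown response: ", response)
  ok <- is.finite(y)
  dat <- dat[ok, , drop = FALSE]; y <- y[ok]
  facs <- grid_factors[vapply(grid_factors, function(f)
    length(unique(dat[[f]])) > 1, TRUE)]
  if (length(facs) == 0) stop("no varying factors at cycle ", cycle)
  ss_total <- sum((y - mean(y))^2)

  # replicate block removed before the fixed decomposition
  ss_rep <- 0
  if (!is.null(dat$replicate) && length(unique(dat$replicate)) > 1) {
    rep_means <- stats::ave(y, dat$replicate)
    ss_rep <- sum((rep_means - mean(y))^2)
    y <- y - rep_means + mean(y)
  }
  for (f in facs) dat[[f]] <- factor(dat[[f]])
  dat$.y <- y
  fml <- stats::as.formula(paste(".y ~ (", paste(facs, collapse = " + "),
                                 ")^2"))
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    al <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient model; aliased terms: ",
         paste(unique(al), collapse = ", "))
  }
  a2 <- car::Anova(fit, type = 2)
  terms_ <- setdiff(rownames(a2), "Residuals")
  share <- a2[terms_, "Sum Sq"] / ss_total * 100
  out <- data.frame(term = terms_, share = share)
  out <- rbind(out,
               data.frame(term = "replicate", share = ss_rep / ss_total * 100),
               data.frame(term = "residual",
                          share = a2["Residuals", "Sum Sq"] / ss_total * 100))
  rownames(out) <- NULL
  out
}

#' Estimated marginal means for a factor
#'
#' Level means averaged with equal weight over the crossed combinations of
#' the other design factors: cell means are computed on the full factor
#' crossing and then averaged per level of the requested factor, optionally
#' inside a conditioning subset (e.g. CV predictor, 20x, scenario 4).
#'
#' @param results long-format table from \code{\link{run_grid}}.
#' @param factor_name one of the design factors.
#' @param response response column name.
#' @param cycle GS cycle.
#' @param conditioning optional named list of factor = value filters.
#' @return data.frame with columns \code{level} and \code{mean}.
#' @export
marginal_means <- function(results, factor_name, response, cycle = 10,
                           conditioning = NULL) {
  dat <- results[results$cycle == cycle, , drop = FALSE]
  for (nm in names(conditioning))
    dat <- dat[dat[[nm]] %in% conditioning[[nm]], , drop = FALSE]
  if (nrow(dat) == 0) stop("empty subset")
  others <- setdiff(grid_factors, factor_name)
  others <- others[vapply(others, function(f)
    length(unique(dat[[f]])) > 1, TRUE)]
  y <- dat[[response]]
  cells <- if (length(others))
    interaction(dat[c(factor_name, others)], drop = TRUE)
  else factor(dat[[factor_name]])
  cell_mean <- tapply(y, cells, mean)
  cell_level <- tapply(as.character(dat[[factor_name]]), cells,
                       function(v) v[1])
  means <- tapply(cell_mean, cell_level, mean)
  data.frame(level = names(means), mean = as.numeric(means))
}

#' Percent difference relative to a reference level
#'
#' @param x value of interest.
#' @param ref reference value.
#' @return percent difference, \code{100 (x - ref) / ref}.
#' @export
percent_difference <- function(x, ref) 100 * (x - ref) / ref
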