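#' Sample a SNP-chip marker panel
#'
#' Markers are drawn by binning each chromosome's map into 1 cM bins and
#' sampling up to \code{per_bin} loci uniformly per non-empty bin; empty
#' bins contribute nothing and bins with fewer loci than \code{per_bin}
#' contribute all of theirs. With ~10 loci per cM this yields about 1,200
#' markers on a 1.22 M chromosome at the default \code{per_bin = 10}.
#' Co-located picks were already jittered apart (by 0.00001 M) at map
#' construction.
#'
#' @param founders a \code{founder_set}.
#' @param per_bin maximum markers sampled per 1 cM bin.
#' @param seed optional integer seed (uses the current RNG stream if NULL).
#' @return sorted integer vector of marker locus indices.
#' @export
sample_snpchip <- function(founders, per_bin = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- founders$map
  bin <- floor(map$loci$pos * 100)  # 1 cM bins
  key <- paste(map$loci$chrom, bin)
  picks <- unlist(lapply(split(seq_len(nrow(map$loci)), key), function(idx) {
    if (length(idx) <= per_bin) idx else resample(idx, per_bin)
  }), use.names = FALSE)
  sort(picks)
}

#' Sample the deleterious-variant candidate pool
#'
#' Draws, without replacement, 90 percent of high-impact loci and 25
#' percent of nonsynonymous-coding loci (counts rounded half up). The pool
#' is re-drawn each replicate.
#'
#' @param founders a \code{founder_set} with annotations.
#' @param frac_high,frac_nonsyn sampling fractions.
#' @param seed optional integer seed.
#' @return sorted integer vector of candidate locus indices.
#' @export
sample_dv_pool <- function(founders, frac_high = 0.9, frac_nonsyn = 0.25,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hi <- which(founders$ann$high)
  ns <- which(founders$ann$nonsyn)
  n_h <- round_half_up(frac_high * length(hi))
  n_n <- round_half_up(frac_nonsyn * length(ns))
  sort(c(if (n_h > 0) resample(hi, n_h),
         if (n_n > 0) resample(ns, n_n)))
}

#' Assign QTL loci
#'
#' Random (R) QTL are drawn uniformly per chromosome from non-marker loci;
#' deleterious-variant (DV) QTL are drawn from the candidate pool minus
#' markers. \code{n_per_chrom} may be a single count or one count per
#' chromosome (e.g. a reduced count on D-group chromosomes under matched
#' settings).
#'
#' @param founders a \code{founder_set}.
#' @param qtl_type \code{"R"} or \code{"DV"}.
#' @param n_per_chrom QTL count per chromosome (scalar or vector).
#' @param dv_pool candidate indices from \code{\link{sample_dv_pool}}
#'   (required for DV).
#' @param marker_set marker indices to exclude.
#' @param seed optional integer seed.
#' @return sorted integer vector of QTL locus indices.
#' @export
assign_qtl <- function(founders, qtl_type = c("R", "DV"), n_per_chrom,
                       dv_pool = NULL, marker_set = integer(0), seed = NULL) {
  qtl_type <- match.arg(qtl_type)
  if (!is.null(seed)) set.seed(seed)
  map <- founders$map
  n_chrom <- nrow(map$chrom)
  n_per_chrom <- rep_len(n_per_chrom, n_chrom)
  if (qtl_type == "DV") {
    if (is.null(dv_pool) || length(dv_pool) == 0)
      stop("DV QTL requested but the candidate pool is empty")
    eligible_all <- setdiff(dv_pool, marker_set)
  } else {
    eligible_all <- setdiff(seq_len(nrow(map$loci)), marker_set)
  }
  out <- integer(0)
  for (k in seq_len(n_chrom)) {
    on_chr <- which(map$loci$chrom == map$chrom$chrom[k])
    elig <- intersect(eligible_all, on_chr)
    if (length(elig) < n_per_chrom[k])
      stop(sprintf(
        "chromosome %d: %d eligible loci for %d requested QTL",
        map$chrom$chrom[k], length(elig), n_per_chrom[k]))
    out <- c(out, resample(elig, n_per_chrom[k]))
  }
  sort(out)
}

#' Apply an effect-sign scenario
#'
#' Effect magnitudes keep their absolute values; signs are overwritten
#' according to the coupling/repulsion scenario: (1) all positive, (2)
#' random 2/3 positive, (3) random 1/2 positive, (4) deterministic
#' alternation along map order with a random first sign (exactly half
#' positive for even QTL counts), (5) random 1/3 positive. Alternation in
#' scenario 4 continues across chromosome boundaries.
#'
#' @param effects numeric raw effect magnitudes, in QTL map order.
#' @param scenario integer 1..5.
#' @param seed optional integer seed.
#' @return signed numeric effects.
#' @export
assign_effect_signs <- function(effects, scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(effects)
  a <- abs(effects)
  sgn <- switch(as.character(scenario),
    "1" = rep(1, n),
    "2" = ifelse(stats::runif(n) < 2 / 3, 1, -1),
    "3" = ifelse(stats::runif(n) < 1 / 2, 1, -1),
    "4" = {
      first <- if (stats::runif(1) < 0.5) 1 else -1
      first * rep_len(c(1, -1), n)
    },
    "5" = ifelse(stats::runif(n) < 1 / 3, 1, -1),
    stop("unknown scenario: ", scenario))
  a * sgn
}

#' Trait architecture
#'
#' Bundles QTL locus indices (map order), signed additive effects and the
#' QTL class. The genetic value of an individual is
#' \eqn{g = \sum_i a_i \, dose_i} with dose the count of the allele coded 1;
#' all effects are purely additive.
#'
#' @param qtl integer QTL locus indices (map order).
#' @param eff numeric additive effects, aligned with \code{qtl}.
#' @param qtl_type \code{"R"} or \code{"DV"}.
#' @param scenario effect-sign scenario id.
#' @return a \code{trait_arch} object.
#' @export
trait_arch <- function(qtl, eff, qtl_type = "R", scenario = NA_integer_) {
  stopifnot(length(qtl) == length(eff))
  ord <- order(qtl)
  structure(list(qtl = as.integer(qtl[ord]), eff = as.numeric(eff[ord]),
                 qtl_type = qtl_type, scenario = scenario),
            class = "trait_arch")
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf("trait_arch: %d %s QTL, scenario %s, sum(a^2) = %.3f\n",
              length(x$qtl), x$qtl_type, x$scenario, sum(x$eff^2)))
  invisible(x)
}

#' True genetic values
#'
#' @param pop a \code{population}.
#' @param arch a \code{trait_arch}.
#' @return numeric vector, one genetic value per individual.
#' @export
genetic_value <- function(pop, arch) {
  drop(dose_matrix(pop, arch$qtl) %*% arch$eff)
}

#' Standardize effects to unit additive variance
#'
#' Divides every QTL effect by the square root of the population's realized
#' additive genetic variance, so the standardized architecture gives
#' varA = 1 in that population. Applied after founder setup and again after
#' burn-in; idempotent.
#'
#' @param arch a \code{trait_arch}.
#' @param pop the reference \code{population} (polymorphic at >= 1 QTL).
#' @return the rescaled \code{trait_arch}.
#' @export
standardize_variance <- function(arch, pop) {
  v <- additive_variance(pop, arch)
  if (v <= 0) stop("no genetic variance to standardize")
  arch$eff <- arch$eff / sqrt(v)
  arch
}

#' Phenotype model
#'
#' Fixes the environmental variance at trait-standardization time:
#' \eqn{\sigma^2_e = varA (1 - H^2) / H^2} with varA = 1 after
#' standardization. The value is held constant across selection cycles, so
#' realized heritability drifts as genetic variance erodes.
#'
#' @param h2 target heritability at standardization (e.g. 0.2 or 0.8).
#' @param varA additive variance at standardization (default 1).
#' @return a \code{phenotype_model} with element \code{sigma2_e}.
#' @export
phenotype_model <- function(h2, varA = 1) {
  stopifnot(h2 > 0, h2 <= 1)
  structure(list(h2 = h2, sigma2_e = varA * (1 - h2) / h2),
            class = "phenotype_model")
}

#' Simulate phenotypes
#'
#' \eqn{y = g + e}, \eqn{e \sim N(0, \sigma^2_e)} i.i.d.
#'
#' @param pop a \code{population}.
#' @param arch a \code{trait_arch}.
#' @param model a \code{phenotype_model}.
#' @param seed optional integer seed.
#' @return numeric phenotype vector.
#' @export
phenotype <- function(pop, arch, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- genetic_value(pop, arch)
  if (model$sigma2_e == 0) return(g)
  g + stats::rnorm(length(g), 0, sqrt(model$sigma2_e))
}
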