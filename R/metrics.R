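#' Additive genetic variance
#'
#' Population variance (divisor n) of true genetic values.
#'
#' @param pop a \code{population} with >= 2 individuals.
#' @param arch a \code{trait_arch}.
#' @return numeric variance in trait units squared.
#' @export
additive_variance <- function(pop, arch) {
  g <- genetic_value(pop, arch)
  mean((g - mean(g))^2)
}

#' Genic (linkage-equilibrium) additive variance
#'
#' Sum over QTL of \eqn{2 p (1-p) a^2}: the additive variance expected under
#' Hardy-Weinberg and linkage equilibrium. The HWE form is used regardless
#' of actual inbreeding, so for a fully inbred population at linkage
#' equilibrium the realized additive variance is twice this quantity.
#'
#' @param pop a \code{population}.
#' @param arch a \code{trait_arch}.
#' @return numeric variance in trait units squared.
#' @export
genic_variance <- function(pop, arch) {
  p <- allele_freq(pop, arch$qtl)
  sum(2 * p * (1 - p) * arch$eff^2)
}

#' Bulmer-effect ratio
#'
#' \code{varA / (2 genicVarA)} for fully inbred populations; the factor 2
#' converts the HWE genic variance to its inbred-population expectation.
#' Values below 1 indicate selection- or repulsion-generated negative
#' linkage disequilibrium.
#'
#' @param varA realized additive variance.
#' @param genicVarA genic variance (HWE form).
#' @return numeric ratio; \code{NA} when \code{genicVarA} is 0.
#' @export
bulmer_effect <- function(varA, genicVarA) {
  ifelse(genicVarA > 0, varA / (2 * genicVarA), NA_real_)
}

#' Genetic gain per cycle
#'
#' Difference between the population mean genetic value at each cycle and
#' the mean at cycle 1, so the gain at cycle 1 is 0 by definition.
#'
#' @param mean_g numeric vector of per-cycle mean genetic values.
#' @param cycle integer vector of cycle indices aligned with \code{mean_g};
#'   must contain cycle 1.
#' @return numeric vector of gains.
#' @export
genetic_gain <- function(mean_g, cycle = seq_along(mean_g) - 1L) {
  if (!1 %in% cycle) stop("cycle-1 record required")
  mean_g - mean_g[match(1, cycle)]
}

# tercile membership by |effect|: 1 = small, 2 = medium, 3 = large;
# remainders are assigned to the lower terciles.
effect_terciles <- function(eff) {
  n <- length(eff)
  base <- n %/% 3L; rem <- n %% 3L
  sizes <- c(base + (rem >= 1L), base + (rem >= 2L), base)
  r <- rank(abs(eff), ties.method = "first")
  tc <- integer(n)
  tc[r <= sizes[1]] <- 1L
  tc[r > sizes[1] & r <= sizes[1] + sizes[2]] <- 2L
  tc[r > sizes[1] + sizes[2]] <- 3L
  tc
}

#' QTL fixation fractions by effect tercile
#'
#' QTL are ranked by absolute effect and split into small (bottom third),
#' medium, and large (top third) terciles, remainders going to the lower
#' terciles. For each tercile the fraction of QTL with allele frequency 0 or
#' 1 is reported, along with the fraction fixed for the favorable allele.
#'
#' @param pop a \code{population}.
#' @param arch a \code{trait_arch} with >= 3 QTL.
#' @return data.frame with columns \code{tercile}, \code{n}, \code{fixed},
#'   \code{fixed_favorable}.
#' @export
qtl_fixation <- function(pop, arch) {
  if (length(arch$qtl) < 3) stop("need at least 3 QTL")
  p <- allele_freq(pop, arch$qtl)
  tc <- effect_terciles(arch$eff)
  fixed <- p == 0 | p == 1
  # favorable allele: coded-1 allele when effect > 0, else coded-0 allele
  fix_fav <- (p == 1 & arch$eff > 0) | (p == 0 & arch$eff < 0)
  out <- data.frame(tercile = c("small", "medium", "large"),
                    n = tabulate(tc, 3L))
  out$fixed <- vapply(1:3, function(t)
    if (out$n[t] > 0) mean(fixed[tc == t]) else NA_real_, 0)
  out$fixed_favorable <- vapply(1:3, function(t)
    if (out$n[t] > 0) mean(fix_fav[tc == t]) else NA_real_, 0)
  out
}

#' Favorable-allele frequency change by effect tercile
#'
#' Mean change in the frequency of the favorable allele (the allele whose
#' dose increases the genetic value) between a baseline and a later
#' population, stratified by effect tercile. Negative values for a tercile
#' mean the unfavorable allele gained frequency there (hitchhiking).
#'
#' @param pop_t later \code{population}.
#' @param pop_0 baseline \code{population} sharing the locus set.
#' @param arch a \code{trait_arch}.
#' @return data.frame with columns \code{tercile}, \code{dAF} and the
#'   overall means for positive- and negative-effect QTL as attributes
#'   \code{dAF_pos}, \code{dAF_neg}.
#' @export
allele_frequency_change <- function(pop_t, pop_0, arch) {
  if (ncol(pop_t$hap1) != ncol(pop_0$hap1)) stop("locus sets differ")
  dp <- allele_freq(pop_t, arch$qtl) - allele_freq(pop_0, arch$qtl)
  dp_fav <- ifelse(arch$eff >= 0, dp, -dp)
  tc <- effect_terciles(arch$eff)
  out <- data.frame(tercile = c("small", "medium", "large"),
                    dAF = vapply(1:3, function(t)
                      if (any(tc == t)) mean(dp_fav[tc == t]) else NA_real_,
                      0))
  attr(out, "dAF_pos") <- if (any(arch$eff > 0))
    mean(dp_fav[arch$eff > 0]) else NA_real_
  attr(out, "dAF_neg") <- if (any(arch$eff < 0))
    mean(dp_fav[arch$eff < 0]) else NA_real_
  out
}

#' Fraction of neighboring loci with minor alleles in repulsion
#'
#' Over adjacent pairs of the given loci within each chromosome, the
#' fraction whose minor-allele indicator columns are negatively correlated
#' across founders. The minor allele is the full-founder-set designation
#' carried by the founder set (so the measurement is stable under
#' biparental recoding). Pairs where either locus has zero variance are
#' excluded.
#'
#' @param founders a \code{founder_set}.
#' @param loci optional locus indices (e.g. QTL); default all loci.
#' @return numeric fraction in [0, 1].
#' @export
neighboring_repulsion_fraction <- function(founders, loci = NULL) {
  map <- founders$map
  if (is.null(loci)) loci <- seq_len(nrow(map$loci))
  loci <- sort(loci)
  g <- founders$geno[, loci, drop = FALSE]
  # minor indicator: 1 when the founder carries the full-set minor allele
  mc <- founders$minor_code[loci]
  minor <- 1L * (g == matrix(mc, nrow(g), length(mc), byrow = TRUE))
  chrom <- map$loci$chrom[loci]
  ctr <- scale(minor, center = TRUE, scale = FALSE)
  v <- colMeans(ctr^2)
  neg <- 0L; tot <- 0L
  for (c_i in unique(chrom)) {
    idx <- which(chrom == c_i)
    if (length(idx) < 2) next
    a <- idx[-length(idx)]; b <- idx[-1]
    ok <- v[a] > 0 & v[b] > 0
    cv <- colMeans(ctr[, a, drop = FALSE] * ctr[, b, drop = FALSE])
    tot <- tot + sum(ok)
    neg <- neg + sum(cv[ok] < 0)
  }
  if (tot == 0L) return(NA_real_)
  neg / tot
}
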