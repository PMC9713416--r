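#' Sample crossover positions on one chromosome
#'
#' Crossovers are generated by a stationary gamma renewal process on the
#' Morgan scale: chiasma events occur along the four-strand bundle with
#' gamma(shape = nu, rate = 2 nu) inter-event distances (mean 0.5 M, i.e.
#' intensity 2 per Morgan), and each chiasma involves the sampled chromatid
#' with probability 1/2. The thinned process has expectation one crossover
#' per Morgan, so the expected crossover count per gamete equals the
#' chromosome map length. Shape nu = 2.63 gives positive interference whose
#' two-point recombination fractions track the Kosambi map function
#' (r = tanh(2d)/2) at map distances up to ~0.5 M. Stationarity is obtained
#' by starting the renewal process a fixed burn-in distance before the
#' chromosome origin; no obligate crossover is enforced.
#'
#' @param length chromosome map length in Morgans.
#' @param nu gamma shape (interference strength); 1 recovers a Poisson
#'   (no-interference) process.
#' @return numeric vector of crossover positions in (0, length), possibly
#'   empty.
#' @export
sample_crossovers <- function(length, nu = 2.63) {
  if (length <= 0) return(numeric(0))
  burn <- 5
  span <- length + burn
  n0 <- max(8L, ceiling(span * 2 * 2.5))
  x <- -burn + cumsum(stats::rgamma(n0, shape = nu, rate = 2 * nu))
  while (x[base::length(x)] < length) {
    x <- c(x, x[base::length(x)] +
             cumsum(stats::rgamma(8L, shape = nu, rate = 2 * nu)))
  }
  x <- x[x > 0 & x < length]
  x[stats::runif(base::length(x)) < 0.5]
}

# One gamete for one chromosome: haplotype vectors plus the chromosome's
# locus positions and length. Uses the current RNG stream.
gamete_chrom <- function(h1, h2, pos, length, nu = 2.63) {
  xo <- sample_crossovers(length, nu)
  start <- if (stats::runif(1) < 0.5) 0L else 1L
  if (base::length(xo) == 0L) {
    return(if (start == 0L) h1 else h2)
  }
  phase <- (findInterval(pos, xo) + start) %% 2L
  out <- h1
  sel <- phase == 1L
  out[sel] <- h2[sel]
  out
}

# Internal: simulate one gamete per requested parent over all chromosomes.
# parents: population; rows: integer indices (one gamete per entry, repeats
# allowed). Returns a matrix n_gametes x L.
sim_gametes <- function(parents, rows, map, nu = 2.63) {
  L <- ncol(parents$hap1)
  out <- matrix(0L, nrow = base::length(rows), ncol = L)
  chrom <- map$loci$chrom
  for (k in seq_len(nrow(map$chrom))) {
    sel <- which(chrom == map$chrom$chrom[k])
    pos <- map$loci$pos[sel]
    len <- map$chrom$length[k]
    h1 <- parents$hap1[, sel, drop = FALSE]
    h2 <- parents$hap2[, sel, drop = FALSE]
    for (g in seq_along(rows)) {
      i <- rows[g]
      out[g, sel] <- gamete_chrom(h1[i, ], h2[i, ], pos, len, nu)
    }
  }
  out
}

#' Simulate a single gamete
#'
#' @param parent a \code{population}.
#' @param map a \code{genetic_map} aligned to the parent's loci.
#' @param individual row index of the parent individual.
#' @param nu gamma interference shape (see \code{\link{sample_crossovers}}).
#' @return integer haplotype vector over all loci.
#' @export
simulate_gamete <- function(parent, map, individual = 1L, nu = 2.63) {
  drop(sim_gametes(parent, individual, map, nu))
}

#' Cross two individuals
#'
#' Each cross produces one F1 progeny: one recombinant gamete from each
#' parent. Chromosomes assort independently.
#'
#' @param mother,father \code{population}s (single- or multi-individual).
#' @param map shared \code{genetic_map}.
#' @param mother_row,father_row row indices of the two parents.
#' @param nu interference shape.
#' @return a one-individual \code{population} (the F1).
#' @export
make_cross <- function(mother, father, map, mother_row = 1L, father_row = 1L,
                       nu = 2.63) {
  if (ncol(mother$hap1) != ncol(father$hap1))
    stop("parents do not share a locus set")
  gm <- sim_gametes(mother, mother_row, map, nu)
  gf <- sim_gametes(father, father_row, map, nu)
  new_population(gm, gf, id = "F1_0001")
}

#' Random crosses within a parent population
#'
#' Parent pairs are drawn uniformly with replacement across crosses, selfing
#' excluded; each cross yields one F1.
#'
#' @param parents a \code{population} with at least 2 individuals.
#' @param map a \code{genetic_map}.
#' @param n_crosses number of crosses.
#' @param nu interference shape.
#' @param id_prefix prefix for progeny identifiers.
#' @return a \code{population} of \code{n_crosses} F1 individuals.
#' @export
random_crosses <- function(parents, map, n_crosses, nu = 2.63,
                           id_prefix = "F1") {
  n <- n_ind(parents)
  if (n < 2) stop("fewer than 2 parents")
  mo <- sample.int(n, n_crosses, replace = TRUE)
  fa <- sample.int(n, n_crosses, replace = TRUE)
  while (any(bad <- fa == mo)) {
    fa[bad] <- sample.int(n, sum(bad), replace = TRUE)
  }
  gm <- sim_gametes(parents, mo, map, nu)
  gf <- sim_gametes(parents, fa, map, nu)
  new_population(gm, gf, id = sprintf("%s_%04d", id_prefix,
                                      seq_len(n_crosses)))
}

#' Doubled haploids from F1 individuals
#'
#' One recombinant gamete is sampled from each F1 and duplicated to full
#' homozygosity.
#'
#' @param f1 a \code{population} of F1 individuals.
#' @param map a \code{genetic_map}.
#' @param nu interference shape.
#' @param id_prefix prefix for DH identifiers.
#' @return a fully inbred \code{population}, one DH per F1.
#' @export
make_dh <- function(f1, map, nu = 2.63, id_prefix = "DH") {
  g <- sim_gametes(f1, seq_len(n_ind(f1)), map, nu)
  new_population(g, g, id = sprintf("%s_%04d", id_prefix, seq_len(nrow(g))))
}
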