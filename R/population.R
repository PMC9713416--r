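#' Construct a population of diploid individuals
#'
#' A population stores two haplotype matrices (individuals x loci, alleles
#' coded 0/1) aligned to a genetic map's locus order. Founders, F1s, doubled
#' haploids and training populations are all populations; fully inbred
#' individuals simply have identical haplotypes.
#'
#' @param hap1,hap2 integer matrices (n x L) of 0/1 alleles.
#' @param id character identifiers, one per individual.
#' @return an object of class \code{population}.
#' @export
new_population <- function(hap1, hap2 = hap1, id = NULL) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  stopifnot(identical(dim(hap1), dim(hap2)))
  if (is.null(id)) id <- sprintf("ind%04d", seq_len(nrow(hap1)))
  stopifnot(length(id) == nrow(hap1))
  structure(list(hap1 = hap1, hap2 = hap2, id = as.character(id)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: %d individuals x %d loci (%s)\n",
              nrow(x$hap1), ncol(x$hap1),
              if (is_inbred(x)) "fully inbred" else "heterozygous"))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a \code{population}.
#' @return integer count.
#' @export
n_ind <- function(pop) nrow(pop$hap1)

is_inbred <- function(pop) all(pop$hap1 == pop$hap2)

#' Genotype dose matrix
#'
#' @param pop a \code{population}.
#' @param loci optional locus indices (columns).
#' @return integer matrix of allele-1 dose in \{0, 1, 2\}.
#' @export
dose_matrix <- function(pop, loci = NULL) {
  if (is.null(loci)) pop$hap1 + pop$hap2
  else pop$hap1[, loci, drop = FALSE] + pop$hap2[, loci, drop = FALSE]
}

#' Allele frequency of the allele coded 1
#'
#' Computed on genotype dose / 2 over individuals, so fully inbred
#' populations give line frequencies.
#'
#' @param pop a \code{population}.
#' @param loci optional locus indices.
#' @return numeric vector of frequencies.
#' @export
allele_freq <- function(pop, loci = NULL) {
  colMeans(dose_matrix(pop, loci)) / 2
}

subset_population <- function(pop, ind = NULL, loci = NULL) {
  if (is.null(ind)) ind <- seq_len(n_ind(pop))
  if (is.null(loci)) loci <- seq_len(ncol(pop$hap1))
  new_population(pop$hap1[ind, loci, drop = FALSE],
                 pop$hap2[ind, loci, drop = FALSE],
                 id = pop$id[ind])
}

bind_populations <- function(a, b) {
  new_population(rbind(a$hap1, b$hap1), rbind(a$hap2, b$hap2),
                 id = c(a$id, b$id))
}
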