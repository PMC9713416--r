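#' Construct a genetic map
#'
#' A genetic map holds, per chromosome, an ordered set of locus positions in
#' Morgans, the chromosome length, the centromere position, and the
#' low-recombination window: a 0.2 M interval spanning the centromere on the
#' wildtype map. Co-located loci are jittered apart by 0.00001 M so that all
#' positions are strictly increasing within a chromosome.
#'
#' @param chrom integer chromosome index per locus.
#' @param id character locus identifiers (unique).
#' @param pos numeric positions in Morgans (non-decreasing within chromosome;
#'   ties jittered).
#' @param length named or ordered numeric vector of chromosome lengths in
#'   Morgans; defaults to the maximum locus position per chromosome.
#' @param centromere numeric vector of centromere positions per chromosome;
#'   defaults to the chromosome midpoint.
#' @param window_halfwidth half-width of the low-recombination window in
#'   Morgans (default 0.1, giving the 0.2 M window).
#' @return an object of class \code{genetic_map}: a list with elements
#'   \code{loci} (data.frame: chrom, id, pos) and \code{chrom} (data.frame:
#'   chrom, length, centromere, win_lo, win_hi).
#' @export
genetic_map <- function(chrom, id, pos, length = NULL, centromere = NULL,
                        window_halfwidth = 0.1) {
  stopifnot(length(chrom) == length(pos), length(id) == length(pos))
  if (anyDuplicated(id)) stop("duplicated locus identifiers")
  chrom <- as.integer(chrom)
  ord <- order(chrom, pos, seq_along(pos))
  chrom <- chrom[ord]; id <- id[ord]; pos <- as.numeric(pos[ord])
  chroms <- sort(unique(chrom))
  # jitter exact ties apart
  for (c_i in chroms) {
    sel <- which(chrom == c_i)
    p <- pos[sel]
    while (any(diff(p) <= 0)) {
      j <- which(diff(p) <= 0)
      p[j + 1L] <- p[j] + 0.00001
    }
    pos[sel] <- p
  }
  len <- vapply(chroms, function(c_i) max(pos[chrom == c_i]), 0)
  if (!is.null(length)) {
    stopifnot(base::length(length) == base::length(chroms))
    len <- pmax(as.numeric(length), len)
  }
  cent <- if (is.null(centromere)) len / 2 else as.numeric(centromere)
  stopifnot(base::length(cent) == base::length(chroms))
  ct <- data.frame(
    chrom = chroms, length = len, centromere = cent,
    win_lo = pmax(0, cent - window_halfwidth),
    win_hi = pmin(len, cent + window_halfwidth)
  )
  structure(list(
    loci = data.frame(chrom = chrom, id = id, pos = pos,
                      stringsAsFactors = FALSE),
    chrom = ct
  ), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d loci on %d chromosomes, total %.2f M\n",
              nrow(x$loci), nrow(x$chrom), sum(x$chrom$length)))
  invisible(x)
}

#' Recombination treatment
#'
#' A map treatment names the recombination landscape applied at the start of
#' genomic selection: \code{"WT"} leaves the map unchanged;
#' \code{"Chromosome"} multiplies all map distances by \code{scale_factor};
#' \code{"Pericentromere"} multiplies only distances inside the wildtype
#' low-recombination window. WT forces \code{scale_factor = 1}.
#'
#' @param map_type one of \code{"WT"}, \code{"Pericentromere"},
#'   \code{"Chromosome"}.
#' @param scale_factor numeric fold change of map distance, \eqn{\ge 1}.
#' @return a \code{map_treatment} object.
#' @export
map_treatment <- function(map_type = c("WT", "Pericentromere", "Chromosome"),
                          scale_factor = 1) {
  map_type <- match.arg(map_type)
  if (scale_factor < 1) stop("scale_factor must be >= 1")
  if (map_type == "WT") scale_factor <- 1
  structure(list(map_type = map_type, scale_factor = scale_factor),
            class = "map_treatment")
}

#' Scale a genetic map by a recombination treatment
#'
#' Applies the coordinate transform implied by the treatment. For the
#' Pericentromere type, an interval straddling the window boundary is split
#' at the boundary and scaled piecewise, so the transformed position of
#' \eqn{x} is \eqn{x + (s-1)\,|[0,x] \cap W|} with \eqn{W} the wildtype
#' window; total-length arithmetic is then exact (e.g. a 1.22 M chromosome
#' with a 0.2 M window under 20x becomes 1.22 + 19 x 0.2 = 5.02 M).
#'
#' @param map a \code{genetic_map}.
#' @param treatment a \code{map_treatment}.
#' @return the scaled \code{genetic_map}; locus order is preserved.
#' @export
scale_map <- function(map, treatment) {
  stopifnot(inherits(map, "genetic_map"), inherits(treatment, "map_treatment"))
  s <- treatment$scale_factor
  if (treatment$map_type == "WT" || s == 1) return(map)
  out <- map
  for (k in seq_len(nrow(map$chrom))) {
    ci <- map$chrom$chrom[k]
    sel <- map$loci$chrom == ci
    if (treatment$map_type == "Chromosome") {
      out$loci$pos[sel] <- map$loci$pos[sel] * s
      out$chrom$length[k] <- map$chrom$length[k] * s
      out$chrom$centromere[k] <- map$chrom$centromere[k] * s
      out$chrom$win_lo[k] <- map$chrom$win_lo[k] * s
      out$chrom$win_hi[k] <- map$chrom$win_hi[k] * s
    } else {
      lo <- map$chrom$win_lo[k]; hi <- map$chrom$win_hi[k]
      shift <- function(x) x + (s - 1) * pmax(0, pmin(x, hi) - lo)
      out$loci$pos[sel] <- shift(map$loci$pos[sel])
      out$chrom$length[k] <- shift(map$chrom$length[k])
      out$chrom$centromere[k] <- shift(map$chrom$centromere[k])
      out$chrom$win_lo[k] <- shift(lo)
      out$chrom$win_hi[k] <- shift(hi)
    }
  }
  out
}

#' Read a genetic map from delimited text
#'
#' Expects columns \code{chrom}, \code{id}, \code{pos}; positions may be in
#' Morgans or centiMorgans.
#'
#' @param path file path (tab- or comma-delimited, header required).
#' @param unit \code{"M"} or \code{"cM"}.
#' @param ... passed to \code{\link{genetic_map}}.
#' @return a \code{genetic_map}.
#' @export
read_genetic_map <- function(path, unit = c("M", "cM"), ...) {
  unit <- match.arg(unit)
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (!all(c("chrom", "id", "pos") %in% names(tab)))
    stop("map file must have columns chrom, id, pos")
  pos <- tab$pos
  if (unit == "cM") pos <- pos / 100
  genetic_map(tab$chrom, as.character(tab$id), pos, ...)
}
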