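#' @title Founder sets
#' @description A founder set bundles a fully inbred biallelic genotype
#'   matrix (founders x loci, one haplotype per founder; allele coded 1 is
#'   the major allele in the full set), a genetic map in Morgans, per-locus
#'   deleterious-variant annotations, and the bookkeeping of which code
#'   carries the full-set minor allele (needed after biparental recoding).
#' @name founder_set
NULL

new_founder_set <- function(geno, map, ann, labels, minor_code = NULL,
                            phase_rep = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(minor_code)) minor_code <- rep(0L, ncol(geno))
  stopifnot(nrow(map$loci) == ncol(geno), nrow(ann) == ncol(geno),
            length(labels) == nrow(geno), length(minor_code) == ncol(geno))
  rownames(geno) <- labels
  structure(list(geno = geno, map = map, ann = ann,
                 labels = as.character(labels),
                 minor_code = as.integer(minor_code),
                 phase_rep = phase_rep),
            class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat(sprintf(
    "founder_set: %d founders x %d loci on %d chromosomes (%d annotated)\n",
    nrow(x$geno), ncol(x$geno), nrow(x$map$chrom),
    sum(x$ann$high | x$ann$nonsyn)))
  invisible(x)
}

#' Founder set as a diploid population
#'
#' @param founders a \code{founder_set}.
#' @return a fully inbred \code{population}.
#' @export
founder_population <- function(founders) {
  new_population(founders$geno, founders$geno, id = founders$labels)
}

# genome group per chromosome: first/middle/last third are A/B/D
genome_group <- function(n_chrom) {
  g <- rep(c("A", "B", "D"), each = ceiling(n_chrom / 3))[seq_len(n_chrom)]
  if (n_chrom >= 3) {
    thirds <- floor(n_chrom / 3)
    g <- rep("B", n_chrom)
    g[seq_len(ceiling((n_chrom - thirds) / 2))] <- "A"
    g[seq.int(n_chrom - thirds + 1L, n_chrom)] <- "D"
  }
  g
}

resample <- function(x, k) x[sample.int(length(x), k)]

# One synthetic chromosome of minor-allele carrier sets. Linkage phase is
# structured the way diverse inbred panels are: a fixed minority founder
# group carries most minor alleles (coupling-type loci draw carriers from
# that pool), while repulsion-type loci place their minor alleles on the
# complementary founders. Two loci are then in repulsion exactly when
# their types differ, so the repulsion fraction is the same for adjacent
# loci and for loci far apart (distance-invariant phase), matching the
# way linkage phase is measured on sparse QTL subsets.
gen_chrom_geno <- function(n_f, n_loci, q_rep, q_rep_win, in_window,
                           noise = 0.04, perturb = 0.3) {
  kmax <- max(1L, floor((n_f - 1) / 2))
  kk <- sample.int(kmax, n_loci, replace = TRUE, prob = 1 / seq_len(kmax))
  all_f <- seq_len(n_f)
  pool <- resample(all_f, min(n_f, max(2L, ceiling(n_f / 3))))
  anti <- resample(setdiff(all_f, pool), n_f - length(pool))
  M <- matrix(0L, n_f, n_loci)
  qv <- ifelse(in_window, q_rep_win, q_rep)
  type_rep <- stats::runif(n_loci) < qv
  u_noise <- stats::runif(n_loci)
  u_pert <- stats::runif(n_loci)
  for (j in seq_len(n_loci)) {
    k <- kk[j]
    if (u_noise[j] < noise) {
      cj <- resample(all_f, k)
    } else {
      src <- if (type_rep[j]) anti else pool
      if (length(src) == 0L) src <- all_f
      if (k <= length(src)) {
        # nested carrier sets (first k of the group's rank order) keep
        # same-type pairs in coupling; a mild perturbation restores
        # haplotype diversity without flipping the phase
        cj <- src[seq_len(k)]
        # perturb only multi-carrier sets, swapping the lowest-rank
        # carrier: sets keep overlapping through their top ranks, so the
        # perturbation adds haplotype diversity without flipping phase
        if (k >= 2L && u_pert[j] < perturb && length(src) > k)
          cj[k] <- src[k + sample.int(length(src) - k, 1)]
      } else {
        cj <- c(src, resample(setdiff(all_f, src), k - length(src)))
      }
    }
    M[cj, j] <- 1L
  }
  list(geno = 1L - M,  # major allele coded 1
       rep_type = type_rep & u_noise >= noise)
}

#' Generate a synthetic founder set
#'
#' Emulates a diverse panel of fully inbred founders: \code{n_chrom}
#' chromosomes of about \code{mean_length} Morgans carrying
#' \code{snp_density} biallelic loci each, with a 0.2 M low-recombination
#' window spanning the centromere (chromosome midpoint). Linkage phase is
#' structured by a minority founder group per chromosome that carries most
#' minor alleles: coupling-type loci draw carriers as perturbed nested
#' subsets of that group, repulsion-type loci draw from its complement, so
#' the fraction of locus pairs whose minor alleles are in repulsion is
#' distance-invariant. The per-locus repulsion-type rate is tuned by an
#' empirical adjustment loop (at most 50 iterations) until the realized
#' fraction of neighboring loci in repulsion lands within 2 percentage
#' points of \code{coupling_target}. Inside the low-recombination window
#' the repulsion-type rate is reduced to 30 percent of baseline (tighter
#' historical linkage, hence more coupling), mirroring the lower repulsion
#' observed among pericentromeric deleterious variants. Deleterious-variant
#' annotations are attached via \code{\link{annotate_deleterious}}.
#'
#' @param n_founders number of inbred founders (>= 2).
#' @param n_chrom number of chromosomes.
#' @param mean_length mean chromosome length in Morgans.
#' @param snp_density loci per chromosome (>= 10).
#' @param coupling_target desired fraction of neighboring minor-allele pairs
#'   in repulsion, in [0, 1].
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   output.
#' @param annotate attach deleterious-variant annotations (default TRUE).
#' @param ... passed to \code{\link{annotate_deleterious}}.
#' @return a \code{founder_set}.
#' @export
generate_founders <- function(n_founders = 26, n_chrom = 21,
                              mean_length = 1.22, snp_density = 1200,
                              coupling_target = 0.33, seed = 1,
                              annotate = TRUE, ...) {
  if (n_founders < 2) stop("n_founders must be >= 2")
  if (snp_density < 10) stop("snp_density must be >= 10 per chromosome")
  if (coupling_target < 0 || coupling_target > 1)
    stop("coupling_target must lie in [0, 1]")
  set.seed(derive_seed(seed, 101L))
  lens <- mean_length * stats::runif(n_chrom, 0.8, 1.2)
  lens <- lens * (mean_length * n_chrom) / sum(lens)  # exact mean
  pos_list <- lapply(lens, function(L) sort(stats::runif(snp_density, 0, L)))
  map <- genetic_map(
    chrom = rep(seq_len(n_chrom), each = snp_density),
    id = sprintf("snp_%02d_%05d", rep(seq_len(n_chrom), each = snp_density),
                 rep(seq_len(snp_density), n_chrom)),
    pos = unlist(pos_list), length = lens)

  in_window <- logical(nrow(map$loci))
  for (k in seq_len(n_chrom)) {
    sel <- map$loci$chrom == k
    in_window[sel] <- map$loci$pos[sel] >= map$chrom$win_lo[k] &
      map$loci$pos[sel] <= map$chrom$win_hi[k]
  }

  # a pair is in repulsion when exactly one locus is repulsion-type, so
  # the per-locus type rate solves 2q(1-q) = target; the empirical loop
  # absorbs finite-sample bias (rare-allele indicators skew negative)
  q <- (1 - sqrt(max(0, 1 - 2 * min(coupling_target, 0.5)))) / 2
  geno <- NULL
  for (it in seq_len(50L)) {
    set.seed(derive_seed(seed, 202L, it))
    cols <- lapply(seq_len(n_chrom), function(k) {
      sel <- map$loci$chrom == k
      gen_chrom_geno(n_founders, sum(sel), q, q * 0.3, in_window[sel])
    })
    geno <- do.call(cbind, lapply(cols, `[[`, "geno"))
    phase_rep <- unlist(lapply(cols, `[[`, "rep_type"))
    fs_tmp <- new_founder_set(
      geno, map, data.frame(high = logical(ncol(geno)),
                            nonsyn = logical(ncol(geno))),
      labels = sprintf("FND_%03d", seq_len(n_founders)))
    realized <- neighboring_repulsion_fraction(fs_tmp)
    if (abs(realized - coupling_target) <= 0.02) break
    q <- min(0.5, max(0.005, q + 0.5 * (coupling_target - realized)))
  }

  ann <- data.frame(high = logical(ncol(geno)), nonsyn = logical(ncol(geno)))
  fs <- new_founder_set(geno, map, ann,
                        labels = sprintf("FND_%03d", seq_len(n_founders)),
                        phase_rep = phase_rep)
  if (annotate) fs$ann <- annotate_deleterious(fs, seed = derive_seed(seed, 303L), ...)
  fs
}

#' Annotate putative deleterious variants
#'
#' Flags loci as high-impact or nonsynonymous-coding (mutually exclusive),
#' with flag density inside the 0.2 M low-recombination window elevated by
#' \code{pericentromere_enrichment} relative to the chromosome arms, and
#' with D-genome-group chromosomes (last third) carrying
#' \code{d_genome_fraction} of the baseline annotation density. The defaults
#' give a deleterious-variant candidate pool (90 percent of high-impact plus
#' 25 percent of nonsynonymous loci) of about 0.3 x density per A/B
#' chromosome and one sixth of that on D chromosomes, i.e. roughly 360 vs 60
#' candidates at 1,200 loci per chromosome.
#'
#' @param founders a \code{founder_set}.
#' @param pericentromere_enrichment ratio (>= 1) of within-window to
#'   outside-window flag density. Feasibility requires the total flag rate
#'   times the enriched window share to stay below saturation; the defaults
#'   leave ample headroom up to about 4-fold enrichment.
#' @param d_genome_fraction multiplier on annotation density for D-group
#'   chromosomes; the default gives a DV candidate pool of about 60 loci
#'   per D chromosome at 1,200 loci per chromosome.
#' @param rate_high,rate_nonsyn baseline fraction of loci flagged
#'   high-impact / nonsynonymous on A/B chromosomes.
#' @param coupling_bias relative weight favoring coupling-phase loci when
#'   the founder set carries linkage-phase information (synthetic panels
#'   do): deleterious minor alleles ride the majority linkage phase, so
#'   neighboring deleterious-variant QTL end up in repulsion less often
#'   than random QTL. Ignored for founder sets without phase information
#'   (e.g. read from files).
#' @param seed integer seed.
#' @return a data.frame with logical columns \code{high} and \code{nonsyn},
#'   one row per locus.
#' @export
annotate_deleterious <- function(founders, pericentromere_enrichment = 3,
                                 d_genome_fraction = 0.23,
                                 rate_high = 0.18, rate_nonsyn = 0.22,
                                 coupling_bias = 4, seed = 1) {
  if (pericentromere_enrichment < 1) stop("enrichment must be >= 1")
  map <- founders$map
  if (any(!is.finite(map$chrom$win_lo)) || any(!is.finite(map$chrom$win_hi)))
    stop("low-recombination window undefined on some chromosome")
  set.seed(seed)
  e <- pericentromere_enrichment
  n_chrom <- nrow(map$chrom)
  grp <- genome_group(n_chrom)
  high <- logical(nrow(map$loci))
  nonsyn <- logical(nrow(map$loci))
  for (k in seq_len(n_chrom)) {
    sel <- which(map$loci$chrom == map$chrom$chrom[k])
    pos <- map$loci$pos[sel]
    inw <- pos >= map$chrom$win_lo[k] & pos <= map$chrom$win_hi[k]
    avail_in <- sel[inw]; avail_out <- sel[!inw]
    mult <- if (grp[k] == "D") d_genome_fraction else 1
    # stratified sampling with exact per-stratum counts, so the realized
    # inside/outside flag density ratio matches the enrichment
    share_in <- e * length(avail_in) /
      (e * length(avail_in) + length(avail_out))
    pw <- if (is.null(founders$phase_rep)) rep(1, nrow(map$loci))
          else ifelse(founders$phase_rep, 1, coupling_bias)
    wsample <- function(avail, n)
      if (n > 0) avail[sample.int(length(avail), n, prob = pw[avail])]
      else integer(0)
    for (cls in c("high", "nonsyn")) {
      rate <- if (cls == "high") rate_high else rate_nonsyn
      n_cls <- round_half_up(rate * mult * length(sel))
      n_in <- min(round_half_up(n_cls * share_in), length(avail_in))
      n_out <- min(n_cls - n_in, length(avail_out))
      pick <- c(wsample(avail_in, n_in), wsample(avail_out, n_out))
      if (cls == "high") high[pick] <- TRUE else nonsyn[pick] <- TRUE
      avail_in <- setdiff(avail_in, pick)
      avail_out <- setdiff(avail_out, pick)
    }
  }
  data.frame(high = high, nonsyn = nonsyn)
}

subset_founder_loci <- function(founders, keep) {
  map <- founders$map
  map$loci <- map$loci[keep, , drop = FALSE]
  rownames(map$loci) <- NULL
  new_founder_set(founders$geno[, keep, drop = FALSE], map,
                  founders$ann[keep, , drop = FALSE],
                  founders$labels, founders$minor_code[keep],
                  if (!is.null(founders$phase_rep))
                    founders$phase_rep[keep])
}

#' Derive a biparental founder set
#'
#' Selects the pair of founders maximizing simple allele-sharing
#' dissimilarity (mean genotype mismatch over loci; ties broken by founder
#' order), removes loci monomorphic between the pair, and recodes so that
#' allele 1 is the first parent's allele. The full-set minor-allele
#' designation is carried through for linkage-phase measurements.
#'
#' @param founders a \code{founder_set} with >= 2 founders.
#' @return a two-founder \code{founder_set}.
#' @export
derive_biparental <- function(founders) {
  n <- nrow(founders$geno)
  if (n < 2) stop("need at least 2 founders")
  g <- founders$geno
  d <- as.matrix(stats::dist(g, method = "manhattan")) / ncol(g)
  d[lower.tri(d, diag = TRUE)] <- -Inf
  best <- which(d == max(d), arr.ind = TRUE)[1, ]
  i <- best[["row"]]; j <- best[["col"]]
  keep <- which(g[i, ] != g[j, ])
  fs <- subset_founder_loci(founders, keep)
  fs$geno <- fs$geno[c(i, j), , drop = FALSE]
  fs$labels <- founders$labels[c(i, j)]
  rownames(fs$geno) <- fs$labels
  # recode: allele 1 = first parent's allele
  flip <- fs$geno[1, ] == 0L
  fs$geno[, flip] <- 1L - fs$geno[, flip, drop = FALSE]
  fs$minor_code[flip] <- 1L - fs$minor_code[flip]
  fs
}

#' Read a founder set from delimited text
#'
#' Genotype table layout: columns \code{id}, \code{chrom}, \code{pos}, then
#' one column per founder with calls in \{0, 1, NA\} or \{A, B, NA\}.
#' Filters are applied in order: loci with more than \code{max_missing}
#' missing calls or unknown chromosome are dropped; monomorphic loci are
#' dropped; the major allele is recoded as 1; remaining missing calls are
#' filled with the major allele (a documented simplification of stochastic
#' imputation, flagged in the log). Optionally, founders that are outliers
#' on the first genotype principal component can be removed.
#'
#' @param genotype_path path to the genotype table (map embedded).
#' @param annotation_path optional path to an annotation table with columns
#'   \code{id} and \code{class} in \{high, nonsynonymous, none\}.
#' @param unit map position unit, \code{"M"} or \code{"cM"}.
#' @param max_missing maximum tolerated fraction of missing calls per locus.
#' @param pc_outlier_removal drop founders whose first-PC score deviates
#'   more than \code{pc_sd_threshold} standard deviations from the mean.
#' @param pc_sd_threshold threshold in SD units.
#' @param centromere optional numeric vector of centromere positions
#'   (Morgans) per chromosome; defaults to chromosome midpoints.
#' @param verbose log filtering steps via \code{message}.
#' @return a \code{founder_set}.
#' @export
read_founders <- function(genotype_path, annotation_path = NULL,
                          unit = c("M", "cM"), max_missing = 0.6,
                          pc_outlier_removal = FALSE, pc_sd_threshold = 3,
                          centromere = NULL, verbose = TRUE) {
  unit <- match.arg(unit)
  tab <- utils::read.table(genotype_path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stop("genotype table must have columns id, chrom, pos")
  if (anyDuplicated(tab$id)) stop("duplicated locus identifiers")
  fcols <- setdiff(names(tab), c(need, "minor_code"))
  if (length(fcols) < 2) stop("need at least 2 founder columns")
  chrom <- suppressWarnings(as.integer(tab$chrom))
  pos <- as.numeric(tab$pos)
  if (unit == "cM") pos <- pos / 100
  for (c_i in unique(chrom[!is.na(chrom)])) {
    p <- pos[which(chrom == c_i)]
    if (any(diff(p) < 0)) stop("unsorted map on chromosome ", c_i)
  }
  calls <- as.matrix(tab[, fcols])
  miss <- rowMeans(is.na(calls))
  keep <- miss <= max_missing & !is.na(chrom)
  if (verbose && any(!keep))
    message(sum(!keep), " loci dropped (missingness > ", max_missing,
            " or unknown chromosome)")
  tab <- tab[keep, , drop = FALSE]; calls <- calls[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]

  # numeric or letter calls -> 0/1 with major allele coded 1 (ties keep the
  # existing 0/1 coding, or the lexicographically larger letter)
  recode_locus <- function(x) {
    obs <- x[!is.na(x)]
    alleles <- sort(unique(obs))
    if (length(alleles) < 2) return(NULL)  # monomorphic
    if (length(alleles) > 2) stop("more than 2 alleles at a locus")
    cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    major <- if (cnt[2] >= cnt[1]) alleles[2] else alleles[1]
    out <- as.integer(x == major)
    out[is.na(x)] <- 1L  # fill with major
    out
  }
  coded <- lapply(seq_len(nrow(calls)), function(r) recode_locus(calls[r, ]))
  poly <- !vapply(coded, is.null, TRUE)
  if (!any(poly)) stop("no polymorphic loci")
  if (verbose && any(!poly))
    message(sum(!poly), " monomorphic loci dropped")
  n_miss <- sum(is.na(calls[poly, ]))
  if (verbose && n_miss > 0)
    message(n_miss, " missing calls filled with the major allele ",
            "(simplified imputation)")
  geno <- do.call(cbind, coded[poly])  # founders x loci
  tab <- tab[poly, , drop = FALSE]
  chrom <- chrom[poly]; pos <- pos[poly]
  rownames(geno) <- fcols

  if (pc_outlier_removal && nrow(geno) > 3) {
    pc1 <- stats::prcomp(geno, center = TRUE, scale. = FALSE)$x[, 1]
    out_f <- abs(pc1 - mean(pc1)) > pc_sd_threshold * stats::sd(pc1)
    if (any(out_f)) {
      if (verbose)
        message("removed PC-outlier founders: ",
                paste(fcols[out_f], collapse = ", "))
      geno <- geno[!out_f, , drop = FALSE]
      poly2 <- apply(geno, 2, function(x) length(unique(x)) > 1)
      geno <- geno[, poly2, drop = FALSE]
      tab <- tab[poly2, , drop = FALSE]
      chrom <- chrom[poly2]; pos <- pos[poly2]
      if (ncol(geno) == 0) stop("no polymorphic loci")
      flip <- colMeans(geno) < 0.5
      geno[, flip] <- 1L - geno[, flip, drop = FALSE]
    }
  }

  cent <- centromere
  map <- genetic_map(chrom, as.character(tab$id), pos, centromere = cent)
  # genetic_map may reorder loci; align genotype columns
  ord <- match(map$loci$id, tab$id)
  geno <- geno[, ord, drop = FALSE]
  tab <- tab[ord, , drop = FALSE]

  ann <- data.frame(high = logical(nrow(map$loci)),
                    nonsyn = logical(nrow(map$loci)))
  if (!is.null(annotation_path)) {
    at <- utils::read.table(annotation_path, header = TRUE, sep = "",
                            stringsAsFactors = FALSE)
    if (!all(c("id", "class") %in% names(at)))
      stop("annotation table must have columns id, class")
    cls <- at$class[match(map$loci$id, at$id)]
    ann$high <- !is.na(cls) & cls == "high"
    ann$nonsyn <- !is.na(cls) & cls == "nonsynonymous"
  }
  minor_code <- if ("minor_code" %in% names(tab))
    as.integer(tab$minor_code) else rep(0L, nrow(map$loci))
  new_founder_set(geno, map, ann, labels = rownames(geno),
                  minor_code = minor_code)
}

#' Write a founder set as a plain-text archive
#'
#' Writes \code{genotypes.tsv} (id, chrom, pos, minor_code, one column per
#' founder) and \code{annotations.tsv} (id, class) into a directory; the
#' archive round-trips through \code{\link{read_founders}}.
#'
#' @param founders a \code{founder_set}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_founders <- function(founders, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gt <- data.frame(id = founders$map$loci$id,
                   chrom = founders$map$loci$chrom,
                   pos = founders$map$loci$pos,
                   minor_code = founders$minor_code,
                   t(founders$geno), check.names = FALSE)
  utils::write.table(gt, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cls <- ifelse(founders$ann$high, "high",
                ifelse(founders$ann$nonsyn, "nonsynonymous", "none"))
  utils::write.table(
    data.frame(id = founders$map$loci$id, class = cls),
    file.path(dir, "annotations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
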