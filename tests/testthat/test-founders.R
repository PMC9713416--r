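test_that("synthetic founders have the required structure", {
  fs <- small_founders()
  expect_s3_class(fs, "founder_set")
  expect_equal(nrow(fs$geno), 26)
  expect_equal(ncol(fs$geno), 3 * 200)
  # major allele coded 1 at every locus
  expect_true(all(colMeans(fs$geno) >= 0.5))
  # no monomorphic loci
  expect_true(all(colMeans(fs$geno) < 1))
  # locus order strictly increasing within chromosomes
  for (k in 1:3) {
    p <- fs$map$loci$pos[fs$map$loci$chrom == k]
    expect_true(all(diff(p) > 0))
  }
  # annotation classes mutually exclusive
  expect_false(any(fs$ann$high & fs$ann$nonsyn))
})

test_that("same seed reproduces founders bit-identically", {
  a <- generate_founders(8, 2, 1.0, 60, 0.3, seed = 9)
  b <- generate_founders(8, 2, 1.0, 60, 0.3, seed = 9)
  expect_identical(a, b)
  c <- generate_founders(8, 2, 1.0, 60, 0.3, seed = 10)
  expect_false(identical(a$geno, c$geno))
})

test_that("two inbred founders give allele frequency 1/2 everywhere", {
  fs <- generate_founders(2, 2, 1.0, 50, 0.3, seed = 5)
  expect_true(all(colMeans(fs$geno) == 0.5))
})

test_that("impossible coupling targets are rejected", {
  expect_error(generate_founders(6, 1, 1, 50, coupling_target = 1.4),
               "coupling_target")
  expect_error(generate_founders(6, 1, 1, 50, coupling_target = -0.1),
               "coupling_target")
  expect_error(generate_founders(1, 1, 1, 50, 0.3), "n_founders")
  expect_error(generate_founders(6, 1, 1, 5, 0.3), "snp_density")
})

test_that("realized repulsion tracks the coupling target monotonically", {
  realized <- vapply(c(0.1, 0.3, 0.5), function(tgt) {
    mean(vapply(1:20, function(s) {
      neighboring_repulsion_fraction(
        generate_founders(20, 2, 1.0, 120, tgt, seed = s, annotate = FALSE))
    }, 0))
  }, 0)
  expect_true(all(diff(realized) > 0))
  expect_true(all(abs(realized - c(0.1, 0.3, 0.5)) < 0.05))
})

test_that("pericentromeric annotation enrichment matches the requested ratio", {
  fs <- generate_founders(20, 4, 1.22, 800, 0.33, seed = 21,
                          annotate = FALSE)
  ann <- annotate_deleterious(fs, pericentromere_enrichment = 3,
                              d_genome_fraction = 1, seed = 3)
  flagged <- ann$high | ann$nonsyn
  ratios <- vapply(1:4, function(k) {
    sel <- fs$map$loci$chrom == k
    pos <- fs$map$loci$pos[sel]
    inw <- pos >= fs$map$chrom$win_lo[k] & pos <= fs$map$chrom$win_hi[k]
    win_len <- fs$map$chrom$win_hi[k] - fs$map$chrom$win_lo[k]
    out_len <- fs$map$chrom$length[k] - win_len
    (sum(flagged[sel][inw]) / win_len) / (sum(flagged[sel][!inw]) / out_len)
  }, 0)
  expect_true(mean(ratios) > 2.4 && mean(ratios) < 3.6)
  # enrichment 1: flags uniform, density ratio near 1
  ann1 <- annotate_deleterious(fs, pericentromere_enrichment = 1,
                               d_genome_fraction = 1, seed = 3)
  f1 <- ann1$high | ann1$nonsyn
  r1 <- vapply(1:4, function(k) {
    sel <- fs$map$loci$chrom == k
    pos <- fs$map$loci$pos[sel]
    inw <- pos >= fs$map$chrom$win_lo[k] & pos <= fs$map$chrom$win_hi[k]
    win_len <- fs$map$chrom$win_hi[k] - fs$map$chrom$win_lo[k]
    (sum(f1[sel][inw]) / win_len) /
      (sum(f1[sel][!inw]) / (fs$map$chrom$length[k] - win_len))
  }, 0)
  expect_true(abs(mean(r1) - 1) < 0.35)
  expect_error(annotate_deleterious(fs, pericentromere_enrichment = 0.5),
               "enrichment")
})

test_that("D-group chromosomes carry the reduced annotation density", {
  fs <- generate_founders(26, 21, 1.22, 400, 0.33, seed = 31)
  pool <- sample_dv_pool(fs, seed = 2)
  per_chrom <- tabulate(fs$map$loci$chrom[pool], 21)
  grp <- c(rep("A", 7), rep("B", 7), rep("D", 7))
  # D pools about one sixth of A/B pools
  expect_lt(mean(per_chrom[grp == "D"]), 0.3 * mean(per_chrom[grp != "D"]))
})

test_that("biparental derivation picks the brute-force most divergent pair", {
  fs <- small_founders()
  bp <- derive_biparental(fs)
  expect_equal(nrow(bp$geno), 2)
  expect_lt(ncol(bp$geno), ncol(fs$geno))
  # exhaustive oracle over all C(26, 2) pairs
  best <- -1; best_pair <- NULL
  for (i in 1:25) for (j in (i + 1):26) {
    d <- mean(fs$geno[i, ] != fs$geno[j, ])
    if (d > best) { best <- d; best_pair <- c(i, j) }
  }
  expect_setequal(bp$labels, fs$labels[best_pair])
  # loci monomorphic between the pair are gone; allele 1 = first parent
  expect_true(all(bp$geno[1, ] == 1L))
  expect_true(all(bp$geno[2, ] == 0L))
})

test_that("duplicate founders are never selected as the biparental pair", {
  fs <- generate_founders(6, 1, 1.0, 60, 0.3, seed = 2)
  g <- rbind(fs$geno, fs$geno[1, , drop = FALSE])
  dup <- recombgs:::new_founder_set(g, fs$map, fs$ann,
                                    labels = c(fs$labels, "FND_001b"))
  bp <- derive_biparental(dup)
  expect_false(setequal(bp$labels, c("FND_001", "FND_001b")))
})

test_that("reader applies the missingness/monomorphic/major-allele filters", {
  set.seed(7)
  # 10 loci x 10 founders: 3 loci with 70% missing, 1 monomorphic -> 6 kept
  calls <- matrix(sample(c("A", "B"), 100, replace = TRUE), nrow = 10)
  calls[1:3, 1:7] <- NA         # 70% missing
  calls[4, ] <- "B"             # monomorphic
  df <- data.frame(id = sprintf("m%02d", 1:10), chrom = 1,
                   pos = seq(0.01, 0.10, by = 0.01), calls)
  fs <- read_founders(write_toy_genotypes(df), verbose = FALSE)
  expect_equal(ncol(fs$geno), 6)
  expect_equal(fs$map$loci$id, sprintf("m%02d", 5:10))
  expect_true(all(colMeans(fs$geno) >= 0.5))
})

test_that("majority recode codes the common allele as 1 and fills missing", {
  calls <- matrix("B", nrow = 1, ncol = 26)
  calls[1, 1:4] <- "A"
  calls2 <- matrix(c(rep("A", 13), rep("B", 12), NA), nrow = 1)
  df <- data.frame(id = c("x1", "x2"), chrom = 1, pos = c(0.1, 0.2),
                   rbind(calls, calls2))
  fs <- read_founders(write_toy_genotypes(df), verbose = FALSE)
  # 4 A vs 22 B -> B coded 1
  expect_equal(sum(fs$geno[, 1]), 22)
  # 13 A vs 12 B -> A coded 1; missing filled with major (A)
  expect_equal(sum(fs$geno[, 2]), 14)
})

test_that("degenerate or malformed genotype tables are rejected", {
  df <- data.frame(id = c("a", "b"), chrom = 1, pos = c(0.1, 0.2),
                   f1 = c("A", "A"), f2 = c("A", "A"), f3 = c("A", "A"))
  expect_error(read_founders(write_toy_genotypes(df), verbose = FALSE),
               "no polymorphic loci")
  df2 <- data.frame(id = c("a", "b"), chrom = 1, pos = c(0.2, 0.1),
                    f1 = c("A", "A"), f2 = c("B", "B"), f3 = c("A", "B"))
  expect_error(read_founders(write_toy_genotypes(df2), verbose = FALSE),
               "unsorted")
  df3 <- data.frame(id = c("a", "a"), chrom = 1, pos = c(0.1, 0.2),
                    f1 = c("A", "A"), f2 = c("B", "B"), f3 = c("A", "B"))
  expect_error(read_founders(write_toy_genotypes(df3), verbose = FALSE),
               "duplicated")
})

test_that("reading a written archive is idempotent", {
  fs <- generate_founders(8, 2, 1.0, 80, 0.3, seed = 12)
  dir <- withr::local_tempdir()
  write_founders(fs, dir)
  back <- read_founders(file.path(dir, "genotypes.tsv"),
                        file.path(dir, "annotations.tsv"), verbose = FALSE)
  expect_equal(unname(back$geno), unname(fs$geno))
  expect_equal(back$map$loci$pos, fs$map$loci$pos)
  expect_equal(back$ann, fs$ann)
  # second round trip changes nothing
  dir2 <- withr::local_tempdir()
  write_founders(back, dir2)
  back2 <- read_founders(file.path(dir2, "genotypes.tsv"),
                         file.path(dir2, "annotations.tsv"), verbose = FALSE)
  expect_equal(unname(back2$geno), unname(back$geno))
})
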