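test_that("SnpChip sampling draws up to per_bin markers per cM bin", {
  fs <- small_founders()
  set.seed(11)
  mk <- sample_snpchip(fs, per_bin = 1)
  bin <- paste(fs$map$loci$chrom[mk], floor(fs$map$loci$pos[mk] * 100))
  expect_false(any(duplicated(bin)))            # at most 1 per bin
  # bins with fewer loci than per_bin contribute all of theirs
  mk_all <- sample_snpchip(fs, per_bin = 1000)
  expect_equal(sort(mk_all), seq_len(ncol(fs$geno)))
  # ~10 loci/cM at per_bin = 10 recovers nearly all loci; at scale this
  # yields the ~1200 markers per 1.22 M chromosome
  expect_gt(length(sample_snpchip(fs, per_bin = 10)) / ncol(fs$geno), 0.85)
})

test_that("DV candidate pool is 90% of high plus 25% of nonsynonymous", {
  fs <- small_founders()
  n_high <- sum(fs$ann$high); n_ns <- sum(fs$ann$nonsyn)
  rhu <- recombgs:::round_half_up
  pool <- sample_dv_pool(fs, seed = 4)
  expect_length(pool, rhu(0.9 * n_high) + rhu(0.25 * n_ns))
  expect_true(all(fs$ann$high[pool] | fs$ann$nonsyn[pool]))
  expect_equal(sum(fs$ann$high[pool]), rhu(0.9 * n_high))
  # arithmetic of the sampling rule: 500 high + 400 nonsyn -> 550
  expect_equal(round(0.9 * 500) + round(0.25 * 400), 550)
})

test_that("QTL assignment honours counts, pools and marker disjointness", {
  fs <- small_founders()
  set.seed(5)
  markers <- sample_snpchip(fs, per_bin = 1)
  qtl <- assign_qtl(fs, "R", 2, marker_set = markers, seed = 6)
  expect_length(qtl, 2 * 3)
  expect_length(intersect(qtl, markers), 0)
  pool <- sample_dv_pool(fs, seed = 7)
  qtl_dv <- assign_qtl(fs, "DV", 5, dv_pool = pool, marker_set = markers,
                       seed = 8)
  expect_true(all(qtl_dv %in% pool))
  expect_length(intersect(qtl_dv, markers), 0)
  expect_error(assign_qtl(fs, "DV", 10, dv_pool = integer(0)), "empty")
  expect_error(assign_qtl(fs, "R", 10000, seed = 9), "eligible")
})

test_that("DV QTL sit closer to centromeres than random QTL", {
  fs <- small_founders()
  pool <- sample_dv_pool(fs, seed = 1)
  dist_cent <- function(idx) {
    k <- fs$map$loci$chrom[idx]
    abs(fs$map$loci$pos[idx] - fs$map$chrom$centromere[k])
  }
  set.seed(12)
  d_dv <- d_r <- numeric(100)
  for (i in 1:100) {
    d_dv[i] <- mean(dist_cent(assign_qtl(fs, "DV", 10, dv_pool = pool)))
    d_r[i] <- mean(dist_cent(assign_qtl(fs, "R", 10)))
  }
  expect_lt(mean(d_dv), mean(d_r))
})

test_that("effect-sign scenarios give their stated sign fractions", {
  mag <- abs(rnorm(200))
  s1 <- assign_effect_signs(mag, 1, seed = 1)
  expect_true(all(s1 > 0))
  s4 <- assign_effect_signs(mag, 4, seed = 2)
  expect_equal(sum(s4 > 0), 100)
  expect_true(all(s4[-1] * s4[-200] < 0))     # alternation along map order
  expect_equal(abs(s4), mag)                  # magnitudes untouched
  big <- abs(rnorm(10000))
  for (sc in c(2, 3, 5)) {
    frac <- mean(assign_effect_signs(big, sc, seed = sc) > 0)
    expect_lt(abs(frac - c(`2` = 2/3, `3` = 1/2, `5` = 1/3)[as.character(sc)]),
              0.02)
  }
  expect_error(assign_effect_signs(mag, 9), "unknown scenario")
})

test_that("variance standardization yields unit varA and is idempotent", {
  fs <- small_founders()
  pop <- founder_population(fs)
  arch <- trait_arch(assign_qtl(fs, "R", 20, seed = 3),
                     rnorm(60), "R", 3)
  std <- standardize_variance(arch, pop)
  expect_equal(additive_variance(pop, std), 1, tolerance = 1e-9)
  # scale invariance: doubling raw effects changes nothing
  arch2 <- arch; arch2$eff <- arch$eff * 2
  expect_equal(standardize_variance(arch2, pop)$eff, std$eff)
  # idempotence
  expect_equal(standardize_variance(std, pop)$eff, std$eff)
  # single-QTL closed form: inbred, p = 1/2, a = 3 -> a / sqrt(4pq a^2) = 1
  g <- matrix(c(0L, 1L), 10, 1)
  pop1 <- new_population(g, g)
  a1 <- trait_arch(1L, 3, "R", 1)
  expect_equal(standardize_variance(a1, pop1)$eff, 1)
  zero <- new_population(matrix(1L, 5, 1), matrix(1L, 5, 1))
  expect_error(standardize_variance(a1, zero), "no genetic variance")
})

test_that("genetic values match a brute-force dose sum", {
  g1 <- matrix(c(0L, 1L, 1L, 0L, 1L,
                 1L, 1L, 0L, 0L, 0L), 2, 5, byrow = TRUE)
  g2 <- matrix(c(1L, 1L, 0L, 0L, 1L,
                 0L, 1L, 0L, 1L, 0L), 2, 5, byrow = TRUE)
  pop <- new_population(g1, g2)
  arch <- trait_arch(1:5, c(0.5, -1, 2, 0.1, -0.3))
  manual <- vapply(1:2, function(i)
    sum((g1[i, ] + g2[i, ]) * arch$eff), 0)
  expect_identical(genetic_value(pop, arch), manual)
  # all doses zero -> 0; single QTL a = 0.5, dose 2 -> 1
  z <- new_population(matrix(0L, 2, 5), matrix(0L, 2, 5))
  expect_equal(genetic_value(z, arch), c(0, 0))
  d2 <- new_population(matrix(1L, 1, 1), matrix(1L, 1, 1))
  expect_equal(genetic_value(d2, trait_arch(1L, 0.5)), 1.0)
})

test_that("phenotypes follow y = g + N(0, sigma2_e) with fixed sigma2_e", {
  expect_equal(phenotype_model(0.8)$sigma2_e, 0.25)
  expect_equal(phenotype_model(0.2)$sigma2_e, 4)
  fs <- small_founders()
  pop <- founder_population(fs)
  arch <- standardize_variance(
    trait_arch(assign_qtl(fs, "R", 20, seed = 3), rnorm(60)), pop)
  m0 <- phenotype_model(1)       # sigma2_e = 0 -> y = g exactly
  expect_identical(phenotype(pop, arch, m0), genetic_value(pop, arch))
  # realized regression of g on y ~ H2 at standardization
  set.seed(14)
  p <- allele_freq(pop, arch$qtl)
  big <- le_dh_population(10000, p)
  archb <- standardize_variance(trait_arch(seq_along(p), arch$eff), big)
  y <- phenotype(big, archb, phenotype_model(0.8))
  slope <- stats::coef(stats::lm(genetic_value(big, archb) ~ y))[2]
  expect_lt(abs(slope - 0.8), 0.03)
})
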