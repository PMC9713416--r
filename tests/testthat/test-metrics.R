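make_toy_pop <- function(g1, g2 = g1) new_population(g1, g2)

test_that("additive variance is the population variance of genetic values", {
  g <- rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(0L, 0L))
  pop <- make_toy_pop(g)
  arch <- trait_arch(1:2, c(1, -0.5))
  vals <- (g + g) %*% arch$eff
  expect_equal(additive_variance(pop, arch),
               mean((vals - mean(vals))^2))      # divisor n, not n-1
  same <- make_toy_pop(matrix(1L, 4, 2))
  expect_equal(additive_variance(same, arch), 0)
  # single inbred locus, p = 1/2, a = 1: varA = 4pq a^2 = 1
  one <- make_toy_pop(matrix(c(0L, 1L), 10, 1))
  expect_equal(additive_variance(one, trait_arch(1L, 1)), 1)
})

test_that("genic variance is the HWE sum 2pq a^2", {
  one <- make_toy_pop(matrix(c(0L, 1L), 10, 1))
  expect_equal(genic_variance(one, trait_arch(1L, 1)), 0.5)
  fixed <- make_toy_pop(matrix(1L, 4, 1))
  expect_equal(genic_variance(fixed, trait_arch(1L, 2)), 0)
  # inbred population at linkage equilibrium: varA / genicVarA -> 2
  set.seed(31)
  pop <- le_dh_population(20000, rep(0.4, 50))
  arch <- trait_arch(1:50, rnorm(50))
  expect_equal(additive_variance(pop, arch) / genic_variance(pop, arch), 2,
               tolerance = 0.05)
})

test_that("Bulmer ratio arithmetic and invariances", {
  expect_equal(bulmer_effect(0.8, 0.5), 0.8)
  expect_true(is.na(bulmer_effect(0.3, 0)))
  # invariant to rescaling all effects
  set.seed(32)
  pop <- le_dh_population(500, runif(20, 0.2, 0.8))
  a <- trait_arch(1:20, rnorm(20))
  a2 <- a; a2$eff <- a$eff * 7
  expect_equal(
    bulmer_effect(additive_variance(pop, a), genic_variance(pop, a)),
    bulmer_effect(additive_variance(pop, a2), genic_variance(pop, a2)))
})

test_that("per-locus shuffling destroys LD and restores varA = 2 genicVarA", {
  fs <- small_founders()
  pop <- founder_population(fs)
  arch <- standardize_variance(
    trait_arch(assign_qtl(fs, "R", 30, seed = 33), rnorm(90)), pop)
  set.seed(34)
  big <- recombgs:::subset_population(
    pop, sample.int(n_ind(pop), 5000, replace = TRUE))
  g <- big$hap1
  for (j in seq_len(ncol(g))) g[, j] <- sample(g[, j])
  shuf <- new_population(g, g)
  ratio <- additive_variance(shuf, arch) / (2 * genic_variance(shuf, arch))
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("genetic gain is relative to cycle 1 and shift-invariant", {
  mg <- c(1.0, 1.4, 2.1)
  expect_equal(genetic_gain(mg, cycle = 1:3), c(0, 0.4, 1.1))
  expect_equal(genetic_gain(mg + 5, cycle = 1:3), mg - 1.0)
  expect_equal(genetic_gain(c(0.9, 1.0, 1.4, 2.1), cycle = 0:3)[2], 0)
  expect_error(genetic_gain(mg, cycle = 2:4), "cycle-1")
})

test_that("fixation terciles follow the remainder rule and fixation counts", {
  expect_equal(recombgs:::effect_terciles(rnorm(200)) |> tabulate(3),
               c(67, 67, 66))
  g <- cbind(rep(0:1, 5), rep(1L, 10), rep(0L, 10), rep(c(0L, 1L), 5))
  pop <- make_toy_pop(g)
  fx <- qtl_fixation(pop, trait_arch(1:4, c(0.1, 0.2, 0.9, 0.5)))
  # terciles by |effect| with remainders to the lower terciles:
  # small = loci 1,2; medium = locus 4; large = locus 3
  expect_equal(fx$n, c(2, 1, 1))
  expect_equal(fx$fixed, c(0.5, 0, 1))
  # locus 2 fixed at p=1 with positive effect is a favorable fixation;
  # locus 3 fixed at p=0 with positive effect is not
  expect_equal(fx$fixed_favorable, c(0.5, 0, 0))
  poly <- make_toy_pop(cbind(rep(0:1, 5), rep(0:1, 5), rep(0:1, 5)))
  expect_equal(qtl_fixation(poly, trait_arch(1:3, c(1, 2, 3)))$fixed,
               rep(0, 3))
  expect_error(qtl_fixation(poly, trait_arch(1:2, c(1, 2))), "3 QTL")
})

test_that("favorable-allele frequency change detects selection and stasis", {
  g0 <- cbind(rep(0:1, 10), rep(0:1, 10), rep(0:1, 10))
  pop0 <- make_toy_pop(g0)
  arch <- trait_arch(1:3, c(0.1, -0.5, 2))
  same <- allele_frequency_change(pop0, pop0, arch)
  expect_equal(same$dAF, rep(0, 3))
  # selection raising allele 1 at the large-effect locus
  g1 <- g0; g1[, 3] <- 1L
  d <- allele_frequency_change(make_toy_pop(g1), pop0, arch)
  expect_equal(d$dAF, c(0, 0, 0.5))
  # negative-effect locus gaining allele 1 counts as unfavorable change
  g2 <- g0; g2[, 2] <- 1L
  d2 <- allele_frequency_change(make_toy_pop(g2), pop0, arch)
  expect_equal(d2$dAF[2], -0.5)
  expect_equal(attr(d2, "dAF_neg"), -0.5)
})

test_that("neighboring repulsion fraction counts negative minor-allele LD", {
  # 6 loci: columns constructed with known pairwise correlation signs
  base <- c(rep(0L, 4), rep(1L, 4))
  g <- cbind(base, base, 1L - base, 1L - base, base, base)
  map <- genetic_map(rep(1, 6), letters[1:6], seq(0.1, 0.6, by = 0.1))
  fs <- recombgs:::new_founder_set(
    g, map, data.frame(high = logical(6), nonsyn = logical(6)),
    labels = sprintf("f%d", 1:8))
  # adjacent pairs: ++, +-, -+ ... brute-force correlation signs
  signs <- vapply(1:5, function(j) sign(cor(g[, j], g[, j + 1])), 0)
  expect_equal(neighboring_repulsion_fraction(fs), mean(signs < 0))
  # identical columns -> 0; anti-correlated columns -> 1
  fs_same <- recombgs:::new_founder_set(
    cbind(base, base, base), genetic_map(rep(1, 3), letters[1:3],
                                         c(0.1, 0.2, 0.3)),
    data.frame(high = logical(3), nonsyn = logical(3)),
    labels = sprintf("f%d", 1:8))
  expect_equal(neighboring_repulsion_fraction(fs_same), 0)
  fs_anti <- recombgs:::new_founder_set(
    cbind(base, 1L - base, base), genetic_map(rep(1, 3), letters[1:3],
                                              c(0.1, 0.2, 0.3)),
    data.frame(high = logical(3), nonsyn = logical(3)),
    labels = sprintf("f%d", 1:8))
  expect_equal(neighboring_repulsion_fraction(fs_anti), 1)
})
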