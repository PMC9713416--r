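# Shared fixtures, built in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

# small synthetic founder panel used across module tests
small_founders <- function() {
  if (is.null(.fixture_env$fs))
    .fixture_env$fs <- generate_founders(
      n_founders = 26, n_chrom = 3, mean_length = 1.0, snp_density = 200,
      coupling_target = 0.33, seed = 404)
  .fixture_env$fs
}

# two-locus, one-heterozygote population for two-point recombination tests
two_locus_parent <- function(d = 0.1) {
  map <- genetic_map(c(1, 1), c("l1", "l2"), c(0.05, 0.05 + d),
                     length = d + 0.1)
  list(pop = new_population(rbind(c(0L, 0L)), rbind(c(1L, 1L))), map = map)
}

# fully inbred population at linkage equilibrium: each locus sampled
# independently with the given allele frequency
le_dh_population <- function(n, p) {
  g <- vapply(p, function(pp) as.integer(stats::runif(n) < pp),
              integer(n))
  new_population(g, g)
}

# one small full-scheme replicate, reused by scheme and acceptance tests
scheme_fixture <- function() {
  if (is.null(.fixture_env$scheme_rec)) {
    fs <- small_founders()
    cfg <- sim_config(founder_mode = "full", n_qtl_per_chrom = 20, h2 = 0.8,
                      map_type = "WT", scale_factor = 1, scenario = 3,
                      qtl_type = "R", predictor = "CV", n_chrom = 3,
                      snp_density = 200, match_dv_counts = FALSE,
                      seed = 501, founders = fs)
    .fixture_env$scheme_cfg <- cfg
    .fixture_env$scheme_rec <- run_replicate(cfg)
  }
  list(cfg = .fixture_env$scheme_cfg, rec = .fixture_env$scheme_rec)
}

# a small WT-vs-20x grid, reused by experiment and acceptance tests
grid_fixture <- function() {
  if (is.null(.fixture_env$grid_res)) {
    fs <- small_founders()
    d <- factorial_design(founder_mode = "full", n_qtl_per_chrom = 20,
                          h2 = 0.8, scale_factor = 20,
                          map_type = c("WT", "Chromosome"), qtl_type = "R",
                          scenario = c(1, 4), predictor = "CV",
                          n_replicates = 3)
    .fixture_env$grid_design <- d
    .fixture_env$grid_res <- run_grid(
      d, base_seed = 99, founders = fs,
      config_args = list(n_chrom = 3, snp_density = 200,
                         match_dv_counts = FALSE))
  }
  list(design = .fixture_env$grid_design, res = .fixture_env$grid_res)
}

# write a small founder genotype table; returns the file path
write_toy_genotypes <- function(df, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  path <- file.path(dir, "geno.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
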