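test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(scale = 2e-4, n_chunks = 30)
  sc <- restrict_samples(build_standard_tree(0.5), c("14", "5", "9", "0", "13"))
  p1 <- simulate_replicates(sc, cfg, n = 1, seed = 99, dir = tempfile())
  p2 <- simulate_replicates(sc, cfg, n = 1, seed = 99, dir = tempfile())
  expect_identical(readLines(paste0(p1, ".geno")), readLines(paste0(p2, ".geno")))
  expect_identical(readLines(paste0(p1, ".snp")), readLines(paste0(p2, ".snp")))
  p3 <- simulate_replicates(sc, cfg, n = 1, seed = 100, dir = tempfile())
  expect_false(identical(readLines(paste0(p1, ".geno")),
                         readLines(paste0(p3, ".geno"))))
})

test_that("simulated output is a valid genotype matrix with sorted positions", {
  g <- std_geno(1)
  expect_s3_class(g, "genotype_matrix")
  expect_gt(n_snps(g), 1000)
  expect_equal(n_individuals(g), 160)
  expect_setequal(populations(g), as.character(0:15))
  expect_silent(qpadmix:::validate_genotype_matrix(g))
  # genetic positions are physical positions times the recombination rate
  expect_equal(g$snp$genetic_pos, g$snp$physical_pos * 1e-8)
})

test_that("single-population diversity matches the coalescent expectation", {
  # mean pairwise diversity per bp is 4 Ne mu for a panmictic population
  ne <- 2.5e4
  pops <- tibble::tibble(name = "X", size = ne, samples = 4L, label = "X")
  sc <- demography_scenario("one_pop", pops)
  cfg <- sim_config(chromosomes = tibble::tibble(chrom = 1:40, length_bp = 5e4))
  g <- simulate_genotypes(sc, cfg, seed = 321)
  af <- allele_frequencies(g, "X")
  n <- af$count[, 1]
  pi_hat <- sum(2 * af$freq[, 1] * (1 - af$freq[, 1]) * n / (n - 1)) / 2e6
  expected <- 4 * ne * 1.5e-8
  # Monte-Carlo tolerance: 40 independent chunks give a few-percent CV
  expect_gt(pi_hat, expected * 0.7)
  expect_lt(pi_hat, expected * 1.3)
})

test_that("SNP yield scales proportionally with genome length", {
  sc <- restrict_samples(build_standard_tree(0.5), c("14", "5", "9"))
  g1 <- simulate_genotypes(sc, sim_config(scale = 2e-4, n_chunks = 40), seed = 5)
  g2 <- simulate_genotypes(sc, sim_config(scale = 4e-4, n_chunks = 40), seed = 6)
  expect_gt(n_snps(g2) / n_snps(g1), 1.6)
  expect_lt(n_snps(g2) / n_snps(g1), 2.4)
})

test_that("full-scale SNP yield extrapolates to tens of millions", {
  # measured desk-scale density, scaled to the 2.9 Gb genome
  g <- std_geno(1)
  total_bp <- sum(sim_config(scale = 8e-4, n_chunks = 128)$chromosomes$length_bp)
  projected <- n_snps(g) / total_bp * sum(human_chromosome_lengths()$length_bp)
  expect_gt(projected, 1.5e7)
  expect_lt(projected, 6e7)
})

test_that("an empty variant set warns rather than fails", {
  pops <- tibble::tibble(name = "X", size = 2.5e4, samples = 2L, label = "X")
  sc <- demography_scenario("one_pop", pops)
  cfg <- sim_config(mutation_rate = 1e-15,
                    chromosomes = tibble::tibble(chrom = 1L, length_bp = 1e4))
  expect_warning(simulate_genotypes(sc, cfg, seed = 1), "empty variant set")
})
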