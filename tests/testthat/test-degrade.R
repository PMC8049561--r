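test_that("down-sampling keeps order, exact counts and determinism", {
  g <- random_genotypes(seed = 20)
  expect_identical(downsample_sites(g, n_snps(g), seed = 1)$geno, g$geno)
  d1 <- downsample_sites(g, 500, seed = 2)
  expect_equal(n_snps(d1), 500)
  expect_false(is.unsorted(match(d1$snp$snp_id, g$snp$snp_id)))
  expect_identical(downsample_sites(g, 500, seed = 2)$snp$snp_id, d1$snp$snp_id)
  expect_error(downsample_sites(g, n_snps(g) + 1), "cannot down-sample")
})

test_that("missingness hits the nominal rate within binomial error", {
  g <- random_genotypes(n_snp = 4000, seed = 21)
  expect_identical(apply_missingness(g, 0, seed = 1)$geno, g$geno)
  d <- apply_missingness(g, 0.25, seed = 3)
  per_ind <- colMeans(is.na(d$geno))
  sd3 <- 3 * sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(per_ind - 0.25) < sd3 + 1e-9))
  # exact-count variant sets the same number in every individual
  de <- apply_missingness(g, 0.25, seed = 4, exact = TRUE)
  expect_true(all(colSums(is.na(de$geno)) == 1000))
})

test_that("pseudohaploidization keeps frequencies, inflates variance", {
  g <- random_genotypes(n_snp = 4000, seed = 22)
  hom <- g; hom$geno[hom$geno == 1L] <- 2L
  expect_identical(pseudohaploidize(hom, seed = 1)$geno, hom$geno)
  ph <- pseudohaploidize(g, seed = 5)
  expect_true(is_pseudohaploid(ph))
  expect_identical(is.na(ph$geno), is.na(g$geno))
  # heterozygote resampling preserves the expected frequency
  af0 <- allele_frequencies(g, "A")$freq[, 1]
  af1 <- allele_frequencies(ph, "A")$freq[, 1]
  expect_lt(abs(mean(af1 - af0)), 0.005)
  expect_gt(stats::var(af1 - af0), 0)
})

test_that("transition flags cover the requested fraction deterministically", {
  g <- random_genotypes(n_snp = 5000, seed = 23)
  t1 <- assign_transitions(g, 0.776, seed = 6)
  expect_equal(sum(t1$snp$is_transition), round(0.776 * 5000))
  expect_identical(assign_transitions(g, 0.776, seed = 6)$snp$is_transition,
                   t1$snp$is_transition)
  expect_equal(sum(assign_transitions(g, 0, seed = 7)$snp$is_transition), 0)
})

test_that("damage flips reference copies unidirectionally at the right rate", {
  g <- random_genotypes(n_snp = 3000, seed = 24)
  gt <- assign_transitions(g, 1, seed = 8)
  expect_error(apply_damage(g, 0.05), "transition flags")
  expect_identical(apply_damage(gt, 0, seed = 1)$geno, gt$geno)
  dmg <- apply_damage(gt, 0.05, seed = 9)
  expect_true(all(dmg$geno >= gt$geno, na.rm = TRUE))  # never decreases
  # per-copy flip expectation: monomorphic-reference sites with 10 diploids
  # gain 20 * d alt copies on average
  zero <- matrix(0L, 2000, 10)
  snp <- tibble::tibble(snp_id = paste0("z", 1:2000), chromosome = 1L,
                        genetic_pos = (1:2000) * 1e-8,
                        physical_pos = (1:2000), ref_allele = "C",
                        alt_allele = "T", is_transition = TRUE)
  ind <- tibble::tibble(sample_id = paste0("m", 1:10), population = "Z")
  gz <- genotype_matrix(zero, snp, ind)
  gz$snp$is_transition <- TRUE
  dz <- apply_damage(gz, 0.05, seed = 10)
  mean_alt <- mean(rowSums(dz$geno))
  expect_lt(abs(mean_alt - 1), 3 * sqrt(20 * 0.05 * 0.95 / 2000))
  # damage restricted to a population subset leaves others untouched
  d2 <- apply_damage(gt, 0.05, populations = "A", seed = 11)
  bc <- gt$ind$population != "A"
  expect_identical(d2$geno[, bc], gt$geno[, bc])
})

test_that("heterozygote ascertainment keeps het sites and drops the panel", {
  g <- random_genotypes(seed = 25)
  asc <- ascertain_het(g, "B", seed = 12)
  expect_equal(n_individuals(asc), n_individuals(g) - 1L)
  panel <- setdiff(g$ind$sample_id, asc$ind$sample_id)
  col <- which(g$ind$sample_id == panel)
  kept <- match(asc$snp$snp_id, g$snp$snp_id)
  expect_true(all(g$geno[kept, col] == 1L))
  expect_true(all(g$geno[-kept, col] != 1L | is.na(g$geno[-kept, col])))
  # a fully homozygous panel individual is a degenerate input
  hom <- g; hom$geno[hom$geno == 1L] <- 0L
  expect_error(ascertain_het(hom, "B", seed = 1), "no heterozygous sites")
})

test_that("sample-size reduction retains the requested individuals", {
  g <- random_genotypes(seed = 26)
  expect_equal(n_individuals(reduce_sample_size(g, "A", 10, seed = 1)), 30)
  r <- reduce_sample_size(g, "A", 1, seed = 13)
  expect_equal(sum(r$ind$population == "A"), 1)
  expect_equal(sum(r$ind$population == "B"), 10)
  expect_error(reduce_sample_size(g, "A", 0), "at least one")
  expect_error(reduce_sample_size(g, "A", 99), "only 10")
})

test_that("the degradation stack applies in aDNA order and logs provenance", {
  g <- random_genotypes(n_snp = 3000, seed = 27)
  cfg <- degrade_config(downsample_sites = 1500, missing_rate = 0.1,
                        pseudohaploid = TRUE, damage_rate = 0.05,
                        damage_populations = "A",
                        sample_sizes = c(B = 2L))
  d <- apply_degradation(g, cfg, seed = 31)
  expect_equal(n_snps(d), 1500)
  expect_true(is_pseudohaploid(d))
  expect_equal(sum(d$ind$population == "B"), 2)
  ops <- provenance(d)$op
  expect_equal(ops, c("downsample_sites", "assign_transitions", "apply_damage",
                      "pseudohaploidize", "apply_missingness",
                      "reduce_sample_size"))
  # deterministic under the same master seed
  d2 <- apply_degradation(g, cfg, seed = 31)
  expect_identical(d$geno, d2$geno)
})
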