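test_that("allele frequencies match brute-force hand counts", {
  g <- toy_genotypes()
  af <- allele_frequencies(g, c("P1", "P2"))
  # site 1: P1 has genotypes 0,1 -> 1 alt of 4; P2 has 2,NA -> 2 of 2
  expect_equal(unname(af$freq[1, "P1"]), 0.25)
  expect_equal(unname(af$freq[1, "P2"]), 1)
  expect_equal(unname(af$count[1, "P2"]), 2)
  # one diploid with genotype 1 -> frequency 0.5
  g1 <- subset_genotypes(g, individuals = 1)
  expect_equal(unname(allele_frequencies(g1, "P1")$freq[3, 1]), 0.5)

  # larger brute-force check against direct counting
  gr <- random_genotypes(n_snp = 500, seed = 7)
  af2 <- allele_frequencies(gr, "B")
  cols <- which(gr$ind$population == "B")
  manual <- apply(gr$geno[, cols], 1, function(x) sum(x) / (2 * sum(!is.na(x))))
  expect_equal(unname(af2$freq[, 1]), manual)
})

test_that("fully missing sites are flagged undefined, and counts add up", {
  g <- toy_genotypes()
  g$geno[2, 1:2] <- NA_integer_
  af <- allele_frequencies(g, c("P1", "P2"))
  expect_true(is.na(af$freq[2, "P1"]))
  expect_equal(unname(af$count[2, "P1"]), 0)
  # alt + ref = non-missing allele count at every site
  gr <- apply_missingness(random_genotypes(seed = 3), 0.3, seed = 4)
  af2 <- allele_frequencies(gr, "A")
  cols <- gr$ind$population == "A"
  alt <- rowSums(gr$geno[, cols], na.rm = TRUE)
  expect_equal(unname(af2$freq[, 1] * af2$count[, 1]), alt)
  expect_error(allele_frequencies(g, "nope"), "unknown population")
})

test_that("shared_site_mask is the all-populations intersection and monotone", {
  gr <- random_genotypes(seed = 5)
  expect_true(all(shared_site_mask(gr, c("A", "B", "C"))))
  gd <- apply_missingness(gr, 0.6, seed = 6)
  m_all <- shared_site_mask(gd, c("A", "B", "C"))
  m_sub <- shared_site_mask(gd, c("A", "B"))
  expect_true(all(m_sub[m_all]))  # monotone in the population set
  # a population fully missing at a site makes the mask false there
  gd$geno[1, gd$ind$population == "B"] <- NA_integer_
  expect_false(shared_site_mask(gd, c("A", "B"))[1])
})

test_that("Hudson FST matches manual arithmetic and behaves at the limits", {
  # two-site fixture computed by hand
  geno <- matrix(c(0L, 2L, 2L, 2L,
                   0L, 0L, 2L, 0L), nrow = 2, byrow = TRUE)
  snp <- tibble::tibble(snp_id = c("a", "b"), chromosome = 1L,
                        genetic_pos = c(0, 1e-4), physical_pos = c(1L, 2L),
                        ref_allele = "A", alt_allele = "G")
  ind <- tibble::tibble(sample_id = paste0("x", 1:4),
                        population = c("P", "P", "Q", "Q"))
  g <- genotype_matrix(geno, snp, ind)
  # site 1: p1=0.5 (n=4), p2=1 -> num=(0.5)^2-0.5*0.5/3-0 = 0.1666...,
  #          den=0.5*0+1*0.5=0.5
  # site 2: p1=0, p2=0.5 -> num=0.25-0-0.25/3=0.1666..., den=0.5
  expect_equal(pairwise_fst(g, "P", "Q"), (1 / 6 + 1 / 6) / (0.5 + 0.5))

  # identical frequencies, large samples: near zero
  gr <- random_genotypes(n_snp = 5000, inds_per_pop = 30, seed = 9)
  expect_lt(abs(pairwise_fst(gr, "A", "B")), 0.01)
  expect_error(pairwise_fst(subset_genotypes(toy_genotypes(), sites = 0),
                            "P1", "P2"), "no usable sites")
})

test_that("populations 1-5 of the benchmark tree are mutually very close", {
  g <- std_geno(1)
  within <- fst_matrix(g, as.character(1:5))$fst
  cross <- purrr::map_dbl(as.character(1:5), ~pairwise_fst(g, .x, "9"))
  # preserved structure: the 1-5 clade is far tighter than the clade-to-
  # clade differentiation (desk-scale drift inflates absolute FST above the
  # full-genome regime; see the methods vignette)
  expect_lt(mean(within), 0.03)
  expect_lt(mean(within), 0.5 * mean(cross))
})

test_that("PCA separates clusters and matches the eigendecomposition", {
  # two clusters of identical genotypes: PC1 separates them exactly
  geno <- cbind(matrix(0L, 10, 3), matrix(2L, 10, 3))
  geno[1, 1] <- 1L  # avoid degenerate identical columns overall
  snp <- tibble::tibble(snp_id = paste0("s", 1:10), chromosome = 1L,
                        genetic_pos = (1:10) * 1e-5, physical_pos = (1:10) * 10L,
                        ref_allele = "A", alt_allele = "G")
  ind <- tibble::tibble(sample_id = paste0("i", 1:6),
                        population = rep(c("L", "R"), each = 3))
  g <- genotype_matrix(geno, snp, ind)
  pc <- pca_projection(g)
  expect_true(all(sign(pc$PC1[pc$population == "L"]) !=
                    sign(pc$PC1[pc$population == "R"])))

  # toy matrix against a dense eigensolver oracle (up to sign)
  gr <- random_genotypes(n_snp = 200, pops = c("A", "B"), inds_per_pop = 4,
                         seed = 11)
  pc2 <- pca_projection(gr)
  p <- rowMeans(gr$geno) / 2
  keep <- p > 0 & p < 1
  x <- (gr$geno[keep, ] - 2 * p[keep]) / sqrt(p[keep] * (1 - p[keep]))
  ev <- eigen(crossprod(x) / sum(keep), symmetric = TRUE)
  oracle <- ev$vectors[, 1] * sqrt(ev$values[1])
  expect_lt(min(sum((pc2$PC1 - oracle)^2), sum((pc2$PC1 + oracle)^2)), 1e-20)
  expect_error(pca_projection(subset_genotypes(gr, individuals = 1:2)),
               "at least 3")
})
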