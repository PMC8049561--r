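make_freq_fixture <- function() {
  # 5-site fixture over four populations with hand-checkable frequencies
  geno <- rbind(c(0L, 0L, 2L, 2L, 1L, 1L, 0L, 2L),
                c(2L, 2L, 0L, 0L, 1L, 1L, 2L, 0L),
                c(1L, 1L, 1L, 1L, 0L, 2L, 2L, 2L),
                c(0L, 2L, 0L, 2L, 2L, 2L, 0L, 0L),
                c(2L, 0L, 1L, 1L, 0L, 0L, 1L, 1L))
  snp <- tibble::tibble(snp_id = paste0("s", 1:5), chromosome = c(1L, 1L, 1L, 2L, 2L),
                        genetic_pos = c(0, 1e-4, 2e-4, 0, 1e-4),
                        physical_pos = c(1L, 2L, 3L, 1L, 2L) * 100L,
                        ref_allele = "A", alt_allele = "G")
  ind <- tibble::tibble(sample_id = paste0("i", 1:8),
                        population = rep(c("A", "B", "C", "D"), each = 2))
  genotype_matrix(geno, snp, ind)
}

test_that("f4 matches the brute-force site-by-site oracle", {
  g <- make_freq_fixture()
  af <- allele_frequencies(g)
  oracle <- mean((af$freq[, "A"] - af$freq[, "B"]) *
                   (af$freq[, "C"] - af$freq[, "D"]))
  fv <- f4_vector_with_cov(g, tibble::tibble(A = "A", B = "B", C = "C", D = "D"),
                           block_size = 10)
  expect_equal(fv$est, oracle, tolerance = 1e-12)
})

test_that("f4 identities: self-comparison, sign flip, pair swap, linearity", {
  g <- std_geno(1)
  af <- allele_frequencies(g, c("1", "2", "3", "7", "13"))
  blocks <- make_blocks(g$snp)
  q <- tibble::tibble(A = c("1", "1", "2", "7", "1", "1", "2"),
                      B = c("1", "2", "1", "13", "3", "2", "3"),
                      C = c("7", "7", "7", "1", "7", "7", "7"),
                      D = c("13", "13", "13", "2", "13", "13", "13"))
  fv <- f4_vector_with_cov(g, q, af = af, blocks = blocks)
  expect_equal(fv$est[1], 0)                        # A = B gives exactly 0
  expect_equal(fv$est[2], -fv$est[3], tolerance = 1e-14)  # swap A,B flips sign
  expect_equal(fv$est[2], fv$est[4], tolerance = 1e-14)   # swap (A,B),(C,D)
  # linearity on identical site sets: f4(1,3) = f4(1,2) + f4(2,3)
  expect_equal(fv$est[5], fv$est[6] + fv$est[7], tolerance = 1e-14)
})

test_that("the f2 cache reproduces direct f4 computation exactly", {
  g <- std_geno(1)
  af <- allele_frequencies(g, c("14", "5", "9", "0", "7"))
  blocks <- make_blocks(g$snp)
  q <- tibble::tibble(A = "14", B = c("5", "9"), C = "0", D = "7")
  direct <- f4_vector_with_cov(g, q, af = af, blocks = blocks)
  cache <- compute_f2_cache(af, blocks)
  fast <- f4_vector_with_cov(g, q, blocks = blocks, f2_cache = cache)
  expect_equal(fast$est, direct$est, tolerance = 1e-12)
  expect_equal(fast$cov, direct$cov, tolerance = 1e-12)
})

test_that("covariance diagonal equals the per-statistic jackknife variance", {
  g <- std_geno(2)
  q <- tibble::tibble(A = "14", B = c("5", "9", "11"), C = "0", D = "13")
  fv <- f4_vector_with_cov(g, q)
  expect_equal(sqrt(diag(fv$cov)), fv$se, tolerance = 1e-12)
  ev <- eigen(fv$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-16))
  # per-component SE agrees with the scalar helper on the same sums
  jk1 <- jackknife_estimate(fv$S[, 1], fv$N[, 1])
  expect_equal(jk1$se, fv$se[1], tolerance = 1e-12)
})

test_that("site policies agree on complete data and differ under missingness", {
  g <- std_geno(2)
  q <- tibble::tibble(A = "14", B = "5", C = "0", D = "7")
  yes <- f4_vector_with_cov(g, q, policy = "allsnps_yes")
  no <- f4_vector_with_cov(g, q, policy = "allsnps_no",
                           all_pops = c("14", "5", "9", "0", "7", "12", "13"))
  expect_equal(yes$est, no$est)
  gm <- apply_missingness(g, 0.6, seed = 17)
  yes2 <- f4_vector_with_cov(gm, q, policy = "allsnps_yes")
  no2 <- f4_vector_with_cov(gm, q, policy = "allsnps_no",
                            all_pops = c("14", "5", "9", "0", "7", "12", "13"))
  expect_gt(yes2$n_snps[1], no2$n_snps[1])
})

test_that("populations 5 and 6 are symmetric with respect to outsiders", {
  # f4(5,6; X,Y) should be within 3 SE of zero for X,Y outside the clade
  zs <- purrr::map_dbl(1:3, function(i) {
    g <- std_geno(i)
    fv <- f4_vector_with_cov(g, tibble::tibble(A = "5", B = "6", C = "9", D = "13"))
    fv$est / fv$se
  })
  expect_true(all(abs(zs) < 3))
})
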