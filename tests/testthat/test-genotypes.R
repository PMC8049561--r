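test_that("EIGENSTRAT round trip is lossless including missing data", {
  g <- toy_genotypes()
  prefix <- file.path(tempdir(), "rt_test")
  write_eigenstrat(g, prefix)
  g2 <- read_eigenstrat(prefix)
  expect_identical(g2$geno, unname(g$geno))
  expect_equal(g2$snp$snp_id, g$snp$snp_id)
  expect_equal(g2$snp$genetic_pos, g$snp$genetic_pos)
  expect_equal(g2$ind$population, g$ind$population)
  # the on-disk characters follow the reference-count convention
  lines <- readLines(paste0(prefix, ".geno"))
  expect_equal(lines[1], "2109")  # alt counts 0,1,2,NA -> ref counts 2,1,0,9
})

test_that("a 9 character maps to one missing call at that cell", {
  g <- toy_genotypes()
  prefix <- file.path(tempdir(), "miss_test")
  write_eigenstrat(g, prefix)
  g2 <- read_eigenstrat(prefix)
  expect_true(is.na(g2$geno[1, 4]))
  expect_equal(sum(is.na(g2$geno)), 1L)
})

test_that("alt coding flag bypasses the reference-count flip", {
  g <- toy_genotypes()
  prefix <- file.path(tempdir(), "alt_test")
  write_eigenstrat(g, prefix, coding = "alt")
  expect_identical(read_eigenstrat(prefix, coding = "alt")$geno,
                   unname(g$geno))
  flipped <- read_eigenstrat(prefix, coding = "ref")$geno
  expect_identical(flipped[2, 1], 0L)
})

test_that("malformed .geno files raise format errors naming the problem", {
  g <- toy_genotypes()
  prefix <- file.path(tempdir(), "bad_test")
  write_eigenstrat(g, prefix)
  # row with wrong width
  lines <- readLines(paste0(prefix, ".geno"))
  writeLines(c(lines[1], "21", lines[3]), paste0(prefix, ".geno"))
  expect_error(read_eigenstrat(prefix), "line 2")
  # non-numeric genotype character
  writeLines(c(lines[1], "21x9", lines[3]), paste0(prefix, ".geno"))
  expect_error(read_eigenstrat(prefix), "invalid genotype character")
  # row count mismatch
  writeLines(lines[1:2], paste0(prefix, ".geno"))
  expect_error(read_eigenstrat(prefix), "expected 3 genotype rows")
})

test_that("pseudohaploid data round trip with only 0, 2 and 9 characters", {
  g <- pseudohaploidize(toy_genotypes(), seed = 1)
  prefix <- file.path(tempdir(), "ph_test")
  write_eigenstrat(g, prefix)
  chars <- unique(strsplit(paste(readLines(paste0(prefix, ".geno")),
                                 collapse = ""), "")[[1]])
  expect_true(all(chars %in% c("0", "2", "9")))
  expect_true(is_pseudohaploid(read_eigenstrat(prefix)))
})

test_that("an empty matrix writes and reads back as a valid empty dataset", {
  g <- toy_genotypes()
  g0 <- genotype_matrix(g$geno[integer(0), , drop = FALSE],
                        g$snp[integer(0), ], g$ind)
  prefix <- file.path(tempdir(), "empty_test")
  write_eigenstrat(g0, prefix)
  g2 <- read_eigenstrat(prefix)
  expect_equal(n_snps(g2), 0L)
  expect_equal(n_individuals(g2), 4L)
})

test_that("constructor enforces metadata invariants", {
  g <- toy_genotypes()
  expect_error(genotype_matrix(g$geno[, 1:3], g$snp, g$ind), "columns")
  expect_error(genotype_matrix(g$geno[1:2, ], g$snp, g$ind), "rows")
  bad_ind <- g$ind; bad_ind$sample_id[2] <- bad_ind$sample_id[1]
  expect_error(genotype_matrix(g$geno, g$snp, bad_ind), "unique")
  bad_snp <- g$snp; bad_snp$alt_allele <- bad_snp$ref_allele
  expect_error(genotype_matrix(g$geno, bad_snp, g$ind), "differ")
  bad_snp2 <- g$snp; bad_snp2$physical_pos <- c(300L, 200L, 100L)
  expect_error(genotype_matrix(g$geno, bad_snp2, g$ind), "increasing")
})
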