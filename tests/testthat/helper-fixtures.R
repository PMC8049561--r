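# Shared fixtures. Simulated replicates are cached across test files; all
# fixtures are generated in code at test time.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- fn()
  .fixture_env[[name]]
}

# A small batch of standard-tree replicates shared by the statistical tests.
std_reps <- function() {
  cached("std_reps", function() {
    simulate_standard_replicates(4, alpha = 0.5,
                                 config = sim_config(scale = 8e-4, n_chunks = 128),
                                 seed = 424242,
                                 dir = file.path(tempdir(), "qpadmix_std_reps"))
  })
}

std_geno <- function(i = 1) {
  cached(paste0("std_geno_", i), function() read_eigenstrat(std_reps()[i]))
}

# Hand-sized genotype fixture with explicit values.
toy_genotypes <- function() {
  geno <- matrix(c(0L, 1L, 2L, NA,
                   2L, 2L, 0L, 0L,
                   1L, 1L, 1L, 1L),
                 nrow = 3, byrow = TRUE)
  snp <- tibble::tibble(snp_id = paste0("s", 1:3), chromosome = 1L,
                        genetic_pos = c(0, 1e-4, 2e-4),
                        physical_pos = c(100L, 200L, 300L),
                        ref_allele = "A", alt_allele = "G")
  ind <- tibble::tibble(sample_id = paste0("i", 1:4),
                        population = c("P1", "P1", "P2", "P2"))
  genotype_matrix(geno, snp, ind)
}

# Random diploid matrix over several populations, complete or with given
# per-cell missingness; deterministic given seed.
random_genotypes <- function(n_snp = 2000, pops = c("A", "B", "C"),
                             inds_per_pop = 10, maf_alpha = 0.8, seed = 1) {
  set.seed(seed)
  n_ind <- length(pops) * inds_per_pop
  p <- stats::rbeta(n_snp, maf_alpha, maf_alpha)
  geno <- matrix(stats::rbinom(n_snp * n_ind, 2, rep(p, n_ind)), nrow = n_snp)
  snp <- tibble::tibble(snp_id = paste0("s", seq_len(n_snp)),
                        chromosome = rep(1:20, length.out = n_snp) |> sort(),
                        physical_pos = 0L, genetic_pos = 0)
  snp <- snp |> dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(physical_pos = dplyr::row_number() * 50L,
                  genetic_pos = .data$physical_pos * 1e-8) |>
    dplyr::ungroup()
  snp$ref_allele <- "A"; snp$alt_allele <- "G"
  ind <- tibble::tibble(sample_id = paste0("i", seq_len(n_ind)),
                        population = rep(pops, each = inds_per_pop))
  genotype_matrix(geno, snp, ind)
}
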