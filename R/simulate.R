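#' Human-like autosome lengths
#'
#' Approximate lengths in base pairs of the 22 human autosomes, used as the
#' template genome for simulations; scale them down for desk-scale runs.
#'
#' @return Tibble with columns `chrom` and `length_bp`.
#' @export
human_chromosome_lengths <- function() {
  mb <- c(248.9, 242.2, 198.3, 190.2, 181.5, 170.8, 159.3, 145.1,
          138.4, 133.8, 135.1, 133.3, 114.4, 107.0, 101.9, 90.3,
          83.3, 80.4, 58.6, 64.4, 46.7, 50.8)
  tibble::tibble(chrom = 1:22, length_bp = round(mb * 1e6))
}

#' Simulation configuration
#'
#' Bundles the mutation and recombination parameters, the chromosome
#' structure and the per-population sample size for the coalescent stage.
#' Defaults follow human-like values: mutation rate 1.5e-8 per bp per
#' generation, recombination rate 1.0e-8 per bp per generation, 22
#' chromosomes with human-proportioned lengths, and 10 diploid individuals
#' per population. `scale` multiplies every chromosome length; the package's
#' desk scale of 0.001 gives roughly 40,000 SNPs on the benchmark tree and
#' makes a replicate cheap enough to run by the hundreds (SNP yield grows
#' linearly with scale; at scale 1 the benchmark tree yields SNPs in the
#' tens of millions).
#'
#' At reduced scale the genome is split into more, shorter chromosomes
#' (equal-length linkage chunks) rather than 22 miniature ones: what matters
#' statistically at desk scale is the number of independent linkage chunks
#' feeding the block jackknife — a full-size genome offers ~700 blocks of
#' 0.05 Morgans, and collapsing a 1/1000-scale genome into 22 chunks would
#' starve the jackknife covariance and distort both P-value calibration and
#' test power. At `scale = 1` the configuration is the 22 human-length
#' autosomes.
#'
#' @param scale Multiplier applied to the total genome length, in (0, 1].
#' @param mutation_rate,recombination_rate Per bp per generation.
#' @param samples_per_population Diploid individuals sampled per population
#'   (each diploid is a combined pair of simulated haploid genomes).
#' @param n_chunks Number of independent chromosomes/linkage chunks; default
#'   22 at full scale, otherwise enough chunks of roughly 18 kb (capped at
#'   220) to keep the block count healthy.
#' @param chromosomes Tibble with `chrom`, `length_bp`; overrides `scale`
#'   and `n_chunks`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(scale = 0.001, mutation_rate = 1.5e-8,
                       recombination_rate = 1.0e-8,
                       samples_per_population = 10,
                       n_chunks = NULL, chromosomes = NULL) {
  stopifnot(scale > 0, scale <= 1, mutation_rate > 0, recombination_rate > 0)
  if (is.null(chromosomes)) {
    if (scale == 1) {
      chromosomes <- human_chromosome_lengths()
    } else {
      total <- round(sum(human_chromosome_lengths()$length_bp) * scale)
      if (is.null(n_chunks)) {
        n_chunks <- max(22, min(220, round(total / 18000)))
      }
      chromosomes <- tibble::tibble(chrom = seq_len(n_chunks),
                                    length_bp = max(round(total / n_chunks), 1000))
    }
  }
  structure(list(chromosomes = tibble::as_tibble(chromosomes),
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 samples_per_population = as.integer(samples_per_population)),
            class = "sim_config")
}

python_binary <- function() {
  py <- getOption("qpadmix.python", Sys.getenv("QPADMIX_PYTHON", ""))
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found on PATH", call. = FALSE)
  py
}

helper_script <- function() {
  path <- system.file("python", "simulate.py", package = "qpadmix")
  if (!nzchar(path)) stop("bundled simulate.py not found", call. = FALSE)
  path
}

write_sim_config <- function(config, path) {
  jsonlite::write_json(list(chromosomes = config$chromosomes,
                            mutation_rate = config$mutation_rate,
                            recombination_rate = config$recombination_rate,
                            samples_per_population = config$samples_per_population),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate replicate genotype datasets from a demography scenario
#'
#' Runs the bundled msprime driver once for a batch of replicates, writing
#' one EIGENSTRAT triplet per replicate. Each chromosome is simulated as an
#' independent coalescent-with-recombination run; derived-allele counts of
#' paired haploid genomes form the diploid genotypes. Deterministic given
#' `seed`.
#'
#' @param scenario A [demography_scenario()].
#' @param config A [sim_config()].
#' @param n Number of replicates.
#' @param seed Integer master seed for this batch.
#' @param dir Output directory (created if needed); defaults to a session
#'   temporary directory.
#' @return Character vector of `n` EIGENSTRAT path prefixes.
#' @export
simulate_replicates <- function(scenario, config = sim_config(), n = 1,
                                seed = 1, dir = tempfile("sims")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc_path <- file.path(dir, "scenario.json")
  cfg_path <- file.path(dir, "config.json")
  write_scenario(scenario, sc_path)
  write_sim_config(config, cfg_path)
  prefix <- file.path(dir, "rep")
  out <- system2(python_binary(),
                 c(helper_script(), "--scenario", sc_path, "--config", cfg_path,
                   "--replicates", n, "--seed", as.integer(seed),
                   "--out-prefix", prefix),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("simulation engine failed:\n", paste(out, collapse = "\n"), call. = FALSE)
  }
  if (n == 1) prefix else sprintf("%s_%03d", prefix, seq_len(n))
}

#' Simulate a single genotype matrix
#'
#' Convenience wrapper around [simulate_replicates()] that reads the result
#' back into memory.
#'
#' @inheritParams simulate_replicates
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(scenario, config = sim_config(), seed = 1) {
  dir <- tempfile("sim")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  prefix <- simulate_replicates(scenario, config, n = 1, seed = seed, dir = dir)
  g <- read_eigenstrat(prefix)
  if (n_snps(g) == 0) warning("simulation produced an empty variant set")
  g
}
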