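# Data-quality corruption operators. Each is independently seedable,
# preserves site order, and appends a provenance record to the matrix.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

log_op <- function(g, op, ...) {
  rec <- tibble::tibble(op = op,
                        params = paste(names(list(...)), unlist(list(...)),
                                       sep = "=", collapse = ", "))
  attr(g, "provenance") <- dplyr::bind_rows(attr(g, "provenance"), rec)
  g
}

#' Provenance log of applied degradation operators
#'
#' @param g A [genotype_matrix()].
#' @return Tibble of applied operations (possibly empty).
#' @export
provenance <- function(g) {
  p <- attr(g, "provenance")
  if (is.null(p)) tibble::tibble(op = character(), params = character()) else p
}

#' Randomly down-sample sites
#'
#' Uniform subset of `n` sites without replacement, preserving site order.
#'
#' @param g A [genotype_matrix()].
#' @param n Number of sites to retain.
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @return A [genotype_matrix()].
#' @export
downsample_sites <- function(g, n, seed = NULL) {
  if (n > n_snps(g)) stop("cannot down-sample ", n_snps(g), " sites to ", n,
                          call. = FALSE)
  keep <- with_seed(seed, sort(sample.int(n_snps(g), n)))
  log_op(subset_genotypes(g, sites = keep), "downsample_sites", n = n, seed = seed)
}

#' Apply random per-cell missingness
#'
#' Each (site, individual) genotype is independently set missing with the
#' given rate, emulating per-individual random site dropout. With
#' `exact = TRUE` each individual instead has exactly `round(rate * n)`
#' sites set missing.
#'
#' @inheritParams downsample_sites
#' @param rate Missingness probability in `[0, 1)`.
#' @param exact Use a fixed per-individual count instead of i.i.d. draws.
#' @return A [genotype_matrix()].
#' @export
apply_missingness <- function(g, rate, seed = NULL, exact = FALSE) {
  stopifnot(rate >= 0, rate < 1)
  if (rate > 0) {
    g$geno <- with_seed(seed, {
      if (exact) {
        m <- round(rate * n_snps(g))
        for (j in seq_len(ncol(g$geno))) {
          g$geno[sample.int(n_snps(g), m), j] <- NA_integer_
        }
        g$geno
      } else {
        drop_mask <- matrix(stats::runif(length(g$geno)) < rate, nrow(g$geno))
        g$geno[drop_mask] <- NA_integer_
        g$geno
      }
    })
  }
  log_op(g, "apply_missingness", rate = rate, seed = seed, exact = exact)
}

#' Pseudohaploidize genotypes
#'
#' Emulates single-allele genotype calling: heterozygotes become 0 or 2 with
#' probability 1/2 each; homozygotes and missing calls are unchanged.
#'
#' @inheritParams downsample_sites
#' @return A [genotype_matrix()] containing no heterozygous calls.
#' @export
pseudohaploidize <- function(g, seed = NULL) {
  het <- which(g$geno == 1L)
  if (length(het)) {
    g$geno[het] <- with_seed(seed, 2L * stats::rbinom(length(het), 1L, 0.5))
  }
  log_op(g, "pseudohaploidize", seed = seed)
}

#' Flag a random fraction of sites as transitions
#'
#' Marks a uniform random fraction of sites as transition (C/T or G/A-like)
#' sites, the substrate for [apply_damage()]. The default 0.776 matches the
#' transition share of widely used capture panels.
#'
#' @inheritParams downsample_sites
#' @param fraction Fraction of sites to flag, in `[0, 1]`.
#' @return A [genotype_matrix()] with `is_transition` filled in.
#' @export
assign_transitions <- function(g, fraction = 0.776, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  flags <- rep(FALSE, n_snps(g))
  n_flag <- round(fraction * n_snps(g))
  if (n_flag > 0) {
    flags[with_seed(seed, sample.int(n_snps(g), n_flag))] <- TRUE
  }
  g$snp$is_transition <- flags
  log_op(g, "assign_transitions", fraction = fraction, seed = seed)
}

#' Apply ancient-DNA damage at transition sites
#'
#' Post-mortem deamination model: at flagged transition sites, in the listed
#' populations, each reference allele copy independently flips to the
#' alternative allele with probability `d` (genotype g becomes
#' g + Binomial(2 - g, d)). The change is unidirectional, so genotype values
#' never decrease.
#'
#' @inheritParams downsample_sites
#' @param d Per-copy flip probability in `[0, 1)`.
#' @param populations Populations to damage (default: all).
#' @return A [genotype_matrix()].
#' @export
apply_damage <- function(g, d = 0.05, populations = NULL, seed = NULL) {
  stopifnot(d >= 0, d < 1)
  flags <- g$snp$is_transition
  if (all(is.na(flags)) || !any(flags, na.rm = TRUE)) {
    stop("no transition flags set; call assign_transitions() first",
         call. = FALSE)
  }
  if (is.null(populations)) populations <- populations(g)
  cols <- which(g$ind$population %in% populations)
  rows <- which(flags)
  if (d > 0 && length(rows) && length(cols)) {
    sub <- g$geno[rows, cols, drop = FALSE]
    idx <- which(!is.na(sub) & sub < 2L)
    sub[idx] <- sub[idx] + with_seed(seed, {
      stats::rbinom(length(idx), 2L - sub[idx], d)
    })
    g$geno[rows, cols] <- sub
  }
  log_op(g, "apply_damage", d = d,
         populations = paste(populations, collapse = "|"), seed = seed)
}

#' Ascertain sites heterozygous in a panel individual
#'
#' Restricts the dataset to sites at which one randomly chosen individual
#' from the panel population is heterozygous, then removes that individual
#' from the dataset (it must not be reused in analyses).
#'
#' @inheritParams downsample_sites
#' @param panel_population Population from which the panel individual is
#'   drawn.
#' @param panel_individual Optional explicit `sample_id`; default is a
#'   seeded random choice.
#' @return A [genotype_matrix()] restricted to ascertained sites, without
#'   the panel individual.
#' @export
ascertain_het <- function(g, panel_population, seed = NULL,
                          panel_individual = NULL) {
  cand <- which(g$ind$population == panel_population)
  if (!length(cand)) stop("empty panel population", call. = FALSE)
  if (is.null(panel_individual)) {
    pick <- with_seed(seed, sample(cand, 1))
  } else {
    pick <- which(g$ind$sample_id == panel_individual)
    if (!length(pick)) stop("unknown panel individual", call. = FALSE)
  }
  sites <- which(!is.na(g$geno[, pick]) & g$geno[, pick] == 1L)
  if (!length(sites)) {
    stop("panel individual has no heterozygous sites", call. = FALSE)
  }
  out <- subset_genotypes(g, sites = sites,
                          individuals = setdiff(seq_len(n_individuals(g)), pick))
  log_op(out, "ascertain_het", panel_population = panel_population,
         panel_individual = g$ind$sample_id[pick], seed = seed)
}

#' Reduce the sample size of a population
#'
#' Retains a uniform random subset of `n` individuals of the population.
#'
#' @inheritParams downsample_sites
#' @param population Population label.
#' @param n Individuals to retain (>= 1).
#' @return A [genotype_matrix()].
#' @export
reduce_sample_size <- function(g, population, n, seed = NULL) {
  if (n < 1) stop("must retain at least one individual", call. = FALSE)
  cur <- which(g$ind$population == population)
  if (n > length(cur)) {
    stop(population, " has only ", length(cur), " individuals", call. = FALSE)
  }
  drop_ <- with_seed(seed, sample(cur, length(cur) - n))
  keep <- setdiff(seq_len(n_individuals(g)), drop_)
  log_op(subset_genotypes(g, individuals = keep), "reduce_sample_size",
         population = population, n = n, seed = seed)
}

#' Degradation configuration
#'
#' Bundles the corruption operators into a single stack applied by
#' [apply_degradation()] in ancient-DNA processing order: ascertainment,
#' site down-sampling, transition assignment and damage, pseudohaploidization,
#' missingness, per-population sample-size reduction.
#'
#' @param downsample_sites Target site count or `NULL`.
#' @param missing_rate Per-cell missingness rate in `[0, 1)`.
#' @param pseudohaploid Apply pseudohaploidization?
#' @param transition_fraction Fraction of sites flagged as transitions.
#' @param damage_rate Per-copy reference-to-alternative flip probability.
#' @param damage_populations Populations to damage (`NULL` = all) — damage is
#'   applied only when `damage_rate > 0`.
#' @param ascertainment Panel population label or `NULL`.
#' @param sample_sizes Named integer vector of per-population sample-size
#'   overrides.
#' @return A list of class `degrade_config`.
#' @export
degrade_config <- function(downsample_sites = NULL, missing_rate = 0,
                           pseudohaploid = FALSE, transition_fraction = 0.776,
                           damage_rate = 0, damage_populations = NULL,
                           ascertainment = NULL, sample_sizes = NULL) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            damage_rate >= 0, damage_rate < 1,
            transition_fraction >= 0, transition_fraction <= 1)
  structure(list(downsample_sites = downsample_sites,
                 missing_rate = missing_rate, pseudohaploid = pseudohaploid,
                 transition_fraction = transition_fraction,
                 damage_rate = damage_rate,
                 damage_populations = damage_populations,
                 ascertainment = ascertainment, sample_sizes = sample_sizes),
            class = "degrade_config")
}

#' Apply a degradation stack
#'
#' @param g A [genotype_matrix()].
#' @param config A [degrade_config()].
#' @param seed Integer master seed; the individual operators draw from
#'   seeds derived by counter.
#' @return A degraded [genotype_matrix()] (see [provenance()]).
#' @export
apply_degradation <- function(g, config, seed = 1) {
  s <- function(i) if (is.null(seed)) NULL else seed + i
  if (!is.null(config$ascertainment)) {
    g <- ascertain_het(g, config$ascertainment, seed = s(1))
  }
  if (!is.null(config$downsample_sites)) {
    g <- downsample_sites(g, min(config$downsample_sites, n_snps(g)), seed = s(2))
  }
  if (config$damage_rate > 0) {
    g <- assign_transitions(g, config$transition_fraction, seed = s(3))
    g <- apply_damage(g, config$damage_rate, config$damage_populations, seed = s(4))
  }
  if (config$pseudohaploid) g <- pseudohaploidize(g, seed = s(5))
  if (config$missing_rate > 0) g <- apply_missingness(g, config$missing_rate, seed = s(6))
  if (!is.null(config$sample_sizes)) {
    for (i in seq_along(config$sample_sizes)) {
      g <- reduce_sample_size(g, names(config$sample_sizes)[i],
                              config$sample_sizes[[i]], seed = s(6 + i))
    }
  }
  g
}
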