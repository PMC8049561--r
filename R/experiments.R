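#' Constrained binomial likelihood-ratio P-value (coin-flipping analogy)
#'
#' Generalized likelihood-ratio test of the interval null
#' \eqn{H_0: p_L < p \le p_U} for a binomial proportion against the
#' unconstrained alternative, mirroring how qpAdm judges constrained
#' admixture models against the free alternative. The statistic is
#' \eqn{-2\log\Lambda} with the constrained supremum taken at the bin
#' endpoint nearest the MLE (the supremum of the binomial likelihood over
#' the interval), referred to the upper tail of chi-squared with 1 df; when
#' the MLE lies inside the bin, \eqn{\Lambda = 1} and the P-value is 1.
#'
#' @param n_flips Number of trials.
#' @param n_heads Number of successes.
#' @param lower,upper Bin limits, `0 <= lower < upper <= 1`.
#' @return A single P-value.
#' @export
binom_lrt_pvalue <- function(n_flips, n_heads, lower, upper) {
  stopifnot(n_heads >= 0, n_heads <= n_flips, lower >= 0, upper <= 1,
            lower < upper)
  mle <- n_heads / n_flips
  if (mle > lower && mle <= upper || (lower == 0 && mle == 0)) return(1)
  p_con <- if (mle <= lower) lower else upper
  loglik <- function(p) {
    stats::dbinom(n_heads, n_flips, p, log = TRUE)
  }
  stat <- 2 * (loglik(mle) - loglik(p_con))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' The full coin-flipping demonstration table
#'
#' P-values of the constrained binomial LRT over the ten width-0.1 bins for
#' two observation settings (64 heads in 100 flips; 646 in 1,000).
#'
#' @param settings Tibble with columns `n_flips`, `n_heads`.
#' @return Tibble with `n_flips`, `n_heads`, `bin_lower`, `bin_upper`,
#'   `p_value`, `plausible` (P >= 0.05).
#' @export
experiment_coin_demo <- function(settings = tibble::tibble(n_flips = c(100, 1000),
                                                           n_heads = c(64, 646))) {
  grid <- tidyr::expand_grid(settings, bin_lower = (0:9) / 10)
  grid$bin_upper <- grid$bin_lower + 0.1
  grid$p_value <- purrr::pmap_dbl(grid[, c("n_flips", "n_heads", "bin_lower",
                                           "bin_upper")],
                                  function(n_flips, n_heads, bin_lower, bin_upper)
                                    binom_lrt_pvalue(n_flips, n_heads,
                                                     bin_lower, bin_upper))
  grid$plausible <- grid$p_value >= 0.05
  grid
}

#' Expected shared-site count under per-individual missingness
#'
#' Under the strict site-intersection policy a site is analyzed only if
#' every population retains at least one individual with data there; with
#' i.i.d. per-individual missingness the expected retained count is
#' \eqn{S (1 - m^{n})^{P}} for S sites, missing rate m, n individuals per
#' population and P populations.
#'
#' @param total_sites S.
#' @param missing_rate m in `[0, 1]`.
#' @param inds_per_pop n.
#' @param n_pops P.
#' @return Expected number of retained sites.
#' @export
expected_intersection_snps <- function(total_sites, missing_rate, inds_per_pop,
                                       n_pops) {
  stopifnot(missing_rate >= 0, missing_rate <= 1, inds_per_pop >= 1, n_pops >= 1)
  total_sites * (1 - missing_rate^inds_per_pop)^n_pops
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483399) + 1L
}

#' Simulate a batch of standard-tree replicates
#'
#' @param n Replicates.
#' @param alpha Admixture proportion into population 14.
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @param dir Output directory.
#' @param keep_pops Optional label subset to sample (see
#'   [restrict_samples()]).
#' @return Character vector of EIGENSTRAT prefixes.
#' @export
simulate_standard_replicates <- function(n, alpha = 0.5, config = sim_config(),
                                         seed = 1, dir = tempfile("std"),
                                         keep_pops = NULL) {
  sc <- build_standard_tree(alpha)
  if (!is.null(keep_pops)) sc <- restrict_samples(sc, keep_pops)
  simulate_replicates(sc, config, n = n, seed = seed, dir = dir)
}

#' Admixture-proportion accuracy across the alpha grid
#'
#' Simulates the benchmark tree over a grid of admixture proportions,
#' fits the standard model to every replicate and reports the estimate,
#' its jackknife standard error and whether the true value lies within
#' 3 standard errors.
#'
#' @param alphas Grid of simulated admixture proportions.
#' @param replicates Replicates per grid point.
#' @param config A [sim_config()]; only the populations of the standard
#'   model are sampled.
#' @param seed Master seed.
#' @param degrade Optional [degrade_config()] applied to each replicate.
#' @param options A [qpadm_options()].
#' @return Tibble: `alpha`, `replicate`, `alpha_hat`, `se`, `p_value`,
#'   `n_snps`, `covered` (|alpha_hat - alpha| <= 3 se).
#' @export
experiment_alpha_accuracy <- function(alphas = seq(0, 1, by = 0.1),
                                      replicates = 20,
                                      config = sim_config(scale = 0.001),
                                      seed = 1, degrade = NULL,
                                      options = qpadm_options()) {
  model <- standard_model()
  keep <- c(model$target, model$sources, model$references)
  purrr::imap_dfr(as.list(alphas), function(a, i) {
    prefixes <- simulate_standard_replicates(replicates, alpha = a,
                                             config = config,
                                             seed = derive_seed(seed, i),
                                             keep_pops = keep)
    purrr::imap_dfr(as.list(prefixes), function(pref, r) {
      g <- read_eigenstrat(pref)
      if (!is.null(degrade)) g <- apply_degradation(g, degrade,
                                                    seed = derive_seed(seed, i * 1000 + r))
      fit <- qpadm(g, model, options)
      unlink(paste0(pref, c(".geno", ".snp", ".ind")))
      tibble::tibble(alpha = a, replicate = r,
                     alpha_hat = unname(fit$weights[1]),
                     se = unname(fit$weight_se[1]),
                     p_value = fit$p_value, n_snps = fit$n_snps_used,
                     covered = abs(fit$weights[1] - a) <= 3 * fit$weight_se[1])
    })
  })
}

#' P-value distributions for competing source pairs
#'
#' Simulates standard-tree replicates (alpha 0.5) and fits, on each, the
#' models pairing source 9 with each candidate substitute for source 5
#' under the base reference set. Summaries: KS uniformity per model and the
#' frequency with which the generative model attains the highest P-value.
#'
#' @param replicates Number of replicate simulations (ignored when `reps`
#'   is given).
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @param candidates Substitute sources paired with population 9.
#' @param references Reference set (drop population 0 to make sources 1-5
#'   exchangeable).
#' @param reps Optional pre-simulated replicate prefixes.
#' @param options A [qpadm_options()].
#' @return List with `results` (per model x replicate tibble), `uniformity`
#'   (KS per model), `top_frequency` (fraction of replicates where the
#'   5+9 model has the highest P), and `prefixes`.
#' @export
experiment_pvalue_dist <- function(replicates = 200,
                                   config = sim_config(scale = 0.0015,
                                                       n_chunks = 240),
                                   seed = 1,
                                   candidates = c("1", "2", "3", "4", "5", "11"),
                                   references = c("0", "7", "10", "12", "13"),
                                   reps = NULL,
                                   options = qpadm_options()) {
  if (is.null(reps)) {
    reps <- simulate_standard_replicates(replicates, 0.5, config, seed)
  }
  models <- lapply(candidates, function(s)
    qpadm_model("14", sort_pop_labels(c(s, "9")), references))
  results <- evaluate_models(reps, models, options)
  uniformity <- results |>
    dplyr::group_by(.data$sources) |>
    dplyr::summarise(pvalue_uniformity(.data$p_value), .groups = "drop")
  ref_label <- paste(sort_pop_labels(c("5", "9")), collapse = "+")
  top <- if (ref_label %in% results$sources) {
    pvalue_ranking_frequency(results, ref_label)
  } else NA_real_
  list(results = results, uniformity = uniformity, top_frequency = top,
       prefixes = reps)
}

#' Base versus rotating model comparison
#'
#' Enumerates all two-source models over the candidate sources and
#' evaluates them on shared replicates under both the fixed base reference
#' set and the rotating protocol.
#'
#' @inheritParams experiment_pvalue_dist
#' @param source_candidates Populations eligible as sources.
#' @param base_references The fixed base reference set.
#' @param rotating_set The full rotating candidate set.
#' @return List with `results` (tibble incl. `protocol` column) and
#'   `matrix` (plausibility proportions per protocol x source pair), plus
#'   `prefixes`.
#' @export
experiment_model_comparison <- function(replicates = 20,
                                        config = sim_config(scale = 0.004,
                                                            n_chunks = 560),
                                        seed = 1,
                                        source_candidates = c("1", "2", "3", "4", "5",
                                                              "8", "9", "11", "15"),
                                        base_references = c("0", "7", "10", "12", "13"),
                                        rotating_set = rotating_candidates("14"),
                                        reps = NULL,
                                        options = qpadm_options()) {
  if (is.null(reps)) {
    reps <- simulate_standard_replicates(replicates, 0.5, config, seed)
  }
  rot <- enumerate_models(search_protocol("rotating", rotating_set, k = 2),
                          "14", source_pool = source_candidates)
  base <- enumerate_models(search_protocol("base", source_candidates,
                                           base_references = base_references,
                                           k = 2), "14")
  models <- dplyr::bind_rows(rotating = rot, base = base, .id = "protocol")
  res <- evaluate_models(reps, models, options)
  mat <- res |>
    dplyr::group_by(.data$protocol, .data$sources) |>
    dplyr::summarise(n = dplyr::n(), prop_plausible = mean(.data$plausible),
                     mean_p = mean(.data$p_value), .groups = "drop")
  list(results = res, matrix = mat, prefixes = reps)
}

#' Single-source (clade) scan of a target under the rotating protocol
#'
#' @inheritParams experiment_pvalue_dist
#' @param target Target population.
#' @param sources Candidate single sources (default: all rotating
#'   candidates).
#' @return Tibble of [evaluate_models()] results with k = 1 models.
#' @export
experiment_clade_scan <- function(target, sources = NULL,
                                  replicates = 20,
                                  config = sim_config(scale = 0.0015,
                                                      n_chunks = 240),
                                  seed = 1, reps = NULL,
                                  options = qpadm_options()) {
  if (is.null(reps)) {
    reps <- simulate_standard_replicates(replicates, 0.5, config, seed)
  }
  cands <- rotating_candidates(target)
  if (is.null(sources)) sources <- cands
  models <- lapply(sources, function(s)
    qpadm_model(target, s, sort_pop_labels(setdiff(cands, s))))
  evaluate_models(reps, models, options)
}

#' Block jackknife size sweep
#'
#' Fits the standard model with a range of jackknife block sizes on the
#' same replicates, recording P-values and weight standard errors.
#'
#' @inheritParams experiment_pvalue_dist
#' @param block_sizes Block sizes in Morgans.
#' @return Tibble: `block_size`, `replicate`, `p_value`, `alpha_hat`, `se`,
#'   `n_blocks`.
#' @export
experiment_jackknife_sweep <- function(block_sizes = c(1e-4, 1e-3, 5e-3, 0.05, 1),
                                       replicates = 50,
                                       config = sim_config(scale = 0.0015,
                                                           n_chunks = 240),
                                       seed = 1, reps = NULL) {
  if (is.null(reps)) {
    model <- standard_model()
    reps <- simulate_standard_replicates(replicates, 0.5, config, seed,
                                         keep_pops = c(model$target, model$sources,
                                                       model$references))
  }
  purrr::map_dfr(as.list(reps), function(pref) {
    g <- read_eigenstrat(pref)
    purrr::map_dfr(as.list(block_sizes), function(bs) {
      fit <- qpadm(g, standard_model(), qpadm_options(block_size = bs))
      tibble::tibble(block_size = bs, p_value = fit$p_value,
                     alpha_hat = unname(fit$weights[1]),
                     se = unname(fit$weight_se[1]), n_blocks = fit$n_blocks)
    })
  }, .id = "replicate")
}

#' Site-intersection behavior under missing data
#'
#' Applies i.i.d. missingness at several rates and contrasts the two
#' site-handling policies on the standard model: SNPs actually used,
#' admixture estimate and its standard error.
#'
#' @inheritParams experiment_pvalue_dist
#' @param missing_rates Per-cell missingness rates.
#' @return Tibble: `missing_rate`, `policy`, `replicate`, `alpha_hat`,
#'   `se`, `p_value`, `n_snps_used`.
#' @export
experiment_allsnps <- function(missing_rates = c(0.25, 0.8, 0.85, 0.9),
                               replicates = 10,
                               config = sim_config(scale = 0.001),
                               seed = 1, reps = NULL) {
  model <- standard_model()
  if (is.null(reps)) {
    reps <- simulate_standard_replicates(replicates, 0.5, config, seed,
                                         keep_pops = c(model$target, model$sources,
                                                       model$references))
  }
  purrr::imap_dfr(as.list(reps), function(pref, r) {
    g0 <- read_eigenstrat(pref)
    purrr::map_dfr(as.list(missing_rates), function(mr) {
      g <- apply_missingness(g0, mr, seed = derive_seed(1, r * 100 + round(mr * 100)))
      purrr::map_dfr(c(TRUE, FALSE), function(all_snps) {
        fit <- tryCatch(qpadm(g, model, qpadm_options(allsnps = all_snps)),
                        error = function(e) NULL)
        if (is.null(fit)) return(tibble::tibble())
        tibble::tibble(missing_rate = mr,
                       policy = if (all_snps) "allsnps_yes" else "allsnps_no",
                       replicate = r, alpha_hat = unname(fit$weights[1]),
                       se = unname(fit$weight_se[1]), p_value = fit$p_value,
                       n_snps_used = fit$n_snps_used)
      })
    })
  })
}

#' Gene flow involving a reference population
#'
#' Simulates the benchmark tree plus a pulse of proportion gamma from
#' population 10 into source population 9 before (generation 350) or after
#' (generation 200) population 9 split from the pulse-donor lineage, and
#' fits the standard model.
#'
#' @inheritParams experiment_pvalue_dist
#' @param alphas Simulated admixture proportions.
#' @param gammas Pulse proportions.
#' @param pulse_generations Pulse times.
#' @param drop_ref10 Also fit with population 10 removed from the
#'   references.
#' @return Tibble: `alpha`, `gamma`, `pulse_generation`, `replicate`,
#'   `refs`, `alpha_hat`, `se`.
#' @export
experiment_reference_geneflow <- function(alphas = 0.5,
                                          gammas = c(0.01, 0.05, 0.1, 0.25),
                                          pulse_generations = c(200, 350),
                                          replicates = 5,
                                          config = sim_config(scale = 0.001),
                                          seed = 1, drop_ref10 = TRUE) {
  grid <- tidyr::expand_grid(alpha = alphas, gamma = gammas,
                             pulse_generation = pulse_generations)
  model_full <- standard_model()
  model_no10 <- qpadm_model("14", c("5", "9"), c("0", "7", "12", "13"))
  purrr::imap_dfr(split(grid, seq_len(nrow(grid))), function(row, i) {
    sc <- build_reference_geneflow_tree(row$alpha, row$gamma, row$pulse_generation)
    sc <- restrict_samples(sc, c("14", "5", "9", "0", "7", "10", "12", "13"))
    prefixes <- simulate_replicates(sc, config, n = replicates,
                                    seed = derive_seed(seed, as.integer(i)))
    purrr::imap_dfr(as.list(prefixes), function(pref, r) {
      g <- read_eigenstrat(pref)
      af <- allele_frequencies(g)
      blocks <- make_blocks(g$snp)
      f2c <- compute_f2_cache(af, blocks)
      fits <- list(full = qpadm(g, model_full, af = af, blocks = blocks, f2_cache = f2c))
      if (drop_ref10) {
        fits$no10 <- qpadm(g, model_no10, af = af, blocks = blocks, f2_cache = f2c)
      }
      unlink(paste0(pref, c(".geno", ".snp", ".ind")))
      purrr::imap_dfr(fits, function(fit, nm) {
        tibble::tibble(alpha = row$alpha, gamma = row$gamma,
                       pulse_generation = row$pulse_generation, replicate = r,
                       refs = nm, alpha_hat = unname(fit$weights[1]),
                       se = unname(fit$weight_se[1]), p_value = fit$p_value)
      })
    })
  })
}

#' P-value trajectories as the reference set grows
#'
#' Simulates the 118-population expansion of the benchmark tree and, for
#' each replicate, evaluates the standard model while the remaining
#' populations are appended to the reference set one at a time in a seeded
#' random order.
#'
#' @inheritParams experiment_pvalue_dist
#' @param step Record every `step`-th reference count (1 = every count).
#' @return Tibble: `replicate`, `n_references`, `n_extra`, `p_value`,
#'   `statistic`.
#' @export
experiment_many_refs <- function(replicates = 10,
                                 config = sim_config(scale = 2.5e-4, n_chunks = 60),
                                 seed = 1, step = 4) {
  sc <- build_many_pops_tree()
  prefixes <- simulate_replicates(sc, config, n = replicates,
                                  seed = derive_seed(seed, 17))
  base_refs <- c("0", "7", "10", "12", "13")
  purrr::imap_dfr(as.list(prefixes), function(pref, r) {
    g <- read_eigenstrat(pref)
    extra <- setdiff(populations(g), c("14", "5", "9", "6", base_refs))
    set.seed(derive_seed(seed, 1000 + r))
    extra <- sample(extra)
    af <- allele_frequencies(g)
    blocks <- make_blocks(g$snp)
    counts <- unique(c(seq(0, length(extra), by = step), length(extra)))
    out <- purrr::map_dfr(as.list(counts), function(nx) {
      refs <- c(base_refs, extra[seq_len(nx)])
      fit <- qpadm(g, qpadm_model("14", c("5", "9"), refs),
                   af = af, blocks = blocks, weight_se = FALSE)
      tibble::tibble(replicate = r, n_references = length(refs), n_extra = nx,
                     p_value = fit$p_value, statistic = fit$statistic)
    })
    unlink(paste0(pref, c(".geno", ".snp", ".ind")))
    out
  })
}

#' Continuous gene flow following a pulse
#'
#' @inheritParams experiment_pvalue_dist
#' @param alphas Pulse proportions (at generation 240).
#' @param ms Subsequent per-generation migration rates from populations 5
#'   and 9 into population 14.
#' @return Tibble: `alpha`, `m`, `replicate`, `alpha_hat`, `se`, `p_value`.
#' @export
experiment_continuous_after_pulse <- function(alphas = c(0, 0.5),
                                              ms = c(0, 1e-5, 1e-4, 1e-3, 1e-2),
                                              replicates = 5,
                                              config = sim_config(scale = 0.001),
                                              seed = 1) {
  grid <- tidyr::expand_grid(alpha = alphas, m = ms)
  model <- standard_model()
  keep <- c(model$target, model$sources, model$references)
  purrr::imap_dfr(split(grid, seq_len(nrow(grid))), function(row, i) {
    sc <- restrict_samples(build_continuous_after_pulse(row$alpha, row$m), keep)
    prefixes <- simulate_replicates(sc, config, n = replicates,
                                    seed = derive_seed(seed, 31 + as.integer(i)))
    purrr::imap_dfr(as.list(prefixes), function(pref, r) {
      fit <- qpadm(read_eigenstrat(pref), model)
      unlink(paste0(pref, c(".geno", ".snp", ".ind")))
      tibble::tibble(alpha = row$alpha, m = row$m, replicate = r,
                     alpha_hat = unname(fit$weights[1]),
                     se = unname(fit$weight_se[1]), p_value = fit$p_value)
    })
  })
}

#' Stepping-stone analyses
#'
#' Simulates the nine-population stepping-stone history and fits (i) deme 2
#' as a mixture of demes 1 and 3 and (ii) deme 1 as a mixture of demes 2
#' and 3 (the out-of-bounds diagnostic), with references 0, 4, 6, 7, 8.
#'
#' @inheritParams experiment_pvalue_dist
#' @param ms Neighbor migration rates.
#' @return List with `fits` (per m x replicate tibble) and `prefixes` (of
#'   the last m simulated).
#' @export
experiment_stepping_stone <- function(ms = 0.01, replicates = 20,
                                      config = sim_config(scale = 0.004,
                                                          n_chunks = 560),
                                      seed = 1) {
  refs <- c("0", "4", "6", "7", "8")
  out <- purrr::imap(as.list(ms), function(m, i) {
    prefixes <- simulate_replicates(build_stepping_stone(m), config,
                                    n = replicates,
                                    seed = derive_seed(seed, 53 + i))
    fits <- purrr::imap_dfr(as.list(prefixes), function(pref, r) {
      g <- read_eigenstrat(pref)
      af <- allele_frequencies(g)
      blocks <- make_blocks(g$snp)
      f2c <- compute_f2_cache(af, blocks)
      f2 <- qpadm(g, qpadm_model("2", c("1", "3"), refs),
                  af = af, blocks = blocks, f2_cache = f2c)
      f1 <- qpadm(g, qpadm_model("1", c("2", "3"), refs),
                  af = af, blocks = blocks, f2_cache = f2c, weight_se = FALSE)
      tibble::tibble(m = m, replicate = r,
                     target = c("2", "1"),
                     alpha_hat = c(unname(f2$weights[1]), unname(f1$weights[1])),
                     se = c(unname(f2$weight_se[1]), NA),
                     p_value = c(f2$p_value, f1$p_value),
                     plausible = c(f2$plausible, f1$plausible))
    })
    list(fits = fits, prefixes = prefixes)
  })
  list(fits = purrr::map_dfr(out, "fits"),
       prefixes = out[[length(out)]]$prefixes)
}

#' Combined data-quality degradation
#'
#' Applies stacked corruption (damage, pseudohaploidization, missingness,
#' sample-size reduction) and fits the standard model.
#'
#' @inheritParams experiment_pvalue_dist
#' @param alphas Simulated admixture proportions.
#' @param missing_rates Missingness rates.
#' @param sample_sizes Per-population sample sizes.
#' @param damage_scopes `"all"` or `"target"`.
#' @return Tibble of fits with the degradation descriptors.
#' @export
experiment_combined_degradation <- function(alphas = c(0.1, 0.5, 0.9),
                                            missing_rates = c(0.25, 0.75),
                                            sample_sizes = c(10, 2, 1),
                                            damage_scopes = c("all", "target"),
                                            replicates = 5,
                                            config = sim_config(scale = 0.001),
                                            seed = 1) {
  model <- standard_model()
  keep <- c(model$target, model$sources, model$references)
  purrr::imap_dfr(as.list(alphas), function(a, ia) {
    prefixes <- simulate_standard_replicates(replicates, a, config,
                                             seed = derive_seed(seed, 71 + ia),
                                             keep_pops = keep)
    purrr::imap_dfr(as.list(prefixes), function(pref, r) {
      g0 <- read_eigenstrat(pref)
      grid <- tidyr::expand_grid(mr = missing_rates, n = sample_sizes,
                                 scope = damage_scopes)
      out <- purrr::pmap_dfr(grid, function(mr, n, scope) {
        dc <- degrade_config(
          missing_rate = mr, pseudohaploid = TRUE, damage_rate = 0.05,
          damage_populations = if (scope == "target") "14" else NULL,
          sample_sizes = if (n < 10) {
            stats::setNames(rep(as.integer(n), length(keep)), keep)
          } else NULL)
        g <- apply_degradation(g0, dc, seed = derive_seed(seed, r * 100))
        fit <- tryCatch(qpadm(g, model), error = function(e) NULL)
        if (is.null(fit)) return(tibble::tibble())
        tibble::tibble(alpha = a, replicate = r, missing_rate = mr,
                       sample_size = n, damage_scope = scope,
                       alpha_hat = unname(fit$weights[1]),
                       se = unname(fit$weight_se[1]),
                       p_value = fit$p_value, plausible = fit$plausible)
      })
      unlink(paste0(pref, c(".geno", ".snp", ".ind")))
      out
    })
  })
}

#' Run a named experiment and write its tables
#'
#' Dispatches to the `experiment_*` drivers and, when `out_dir` is given,
#' writes each result table as TSV plus a small JSON summary. Deterministic
#' given `seed`.
#'
#' @param name One of `"coin_demo"`, `"pvalue_dist"`, `"jackknife_sweep"`,
#'   `"alpha_accuracy"`, `"model_comparison"`, `"allsnps"`,
#'   `"combined_degradation"`, `"reference_geneflow"`, `"many_refs"`,
#'   `"continuous_after_pulse"`, `"stepping_stone"`.
#' @param ... Passed to the driver.
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @return The driver's value (tables), invisibly when writing.
#' @export
run_experiment <- function(name = c("coin_demo", "pvalue_dist", "jackknife_sweep",
                                    "alpha_accuracy", "model_comparison",
                                    "allsnps", "combined_degradation",
                                    "reference_geneflow", "many_refs",
                                    "continuous_after_pulse", "stepping_stone"),
                           ..., seed = 1, out_dir = NULL) {
  name <- match.arg(name)
  fn <- switch(name,
               coin_demo = function(..., seed) experiment_coin_demo(...),
               pvalue_dist = experiment_pvalue_dist,
               jackknife_sweep = experiment_jackknife_sweep,
               alpha_accuracy = experiment_alpha_accuracy,
               model_comparison = experiment_model_comparison,
               allsnps = experiment_allsnps,
               combined_degradation = experiment_combined_degradation,
               reference_geneflow = experiment_reference_geneflow,
               many_refs = experiment_many_refs,
               continuous_after_pulse = experiment_continuous_after_pulse,
               stepping_stone = experiment_stepping_stone)
  res <- if (name == "coin_demo") fn(...) else fn(..., seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- if (is.data.frame(res)) list(results = res) else
      purrr::keep(res, is.data.frame)
    purrr::iwalk(tables, function(tab, nm) {
      utils::write.table(tab, file.path(out_dir, paste0(name, "_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    })
    jsonlite::write_json(list(experiment = name, seed = seed,
                              tables = names(tables),
                              date = as.character(Sys.Date())),
                         file.path(out_dir, paste0(name, "_summary.json")),
                         auto_unbox = TRUE)
    return(invisible(res))
  }
  res
}
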