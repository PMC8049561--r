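#' Model-comparison protocols
#'
#' A search protocol describes how candidate source pairs are turned into
#' qpAdm models. Under `"base"`, every combination of k sources is tested
#' against one fixed reference set. Under `"rotating"`, the sources are
#' drawn from a single candidate set and every candidate not serving as a
#' source acts as a reference, so the best available sources discipline
#' every competing model.
#'
#' @param kind `"rotating"` or `"base"`.
#' @param candidates Character vector of candidate populations (for
#'   `"rotating"`, the full rotating set; for `"base"`, the potential
#'   sources).
#' @param base_references Fixed reference set (`"base"` only).
#' @param k Number of sources per model (1 or 2 in practice).
#' @return A list of class `search_protocol`.
#' @export
search_protocol <- function(kind = c("rotating", "base"), candidates,
                            base_references = NULL, k = 2) {
  kind <- match.arg(kind)
  candidates <- as.character(candidates)
  if (kind == "base") {
    if (is.null(base_references)) stop("base protocol needs base_references",
                                       call. = FALSE)
    if (length(intersect(candidates, base_references))) {
      stop("base candidates must not overlap the base references", call. = FALSE)
    }
  }
  structure(list(kind = kind, candidates = candidates,
                 base_references = as.character(base_references), k = k),
            class = "search_protocol")
}

#' Enumerate candidate qpAdm models under a protocol
#'
#' @param protocol A [search_protocol()].
#' @param target Target population label.
#' @param source_pool For `"rotating"`, restrict sources to this subset of
#'   the candidates (references still rotate over the full candidate set);
#'   default: all candidates.
#' @return Tibble with columns `sources` (collapsed label), `model`
#'   (list-column of [qpadm_model()]).
#' @export
enumerate_models <- function(protocol, target, source_pool = NULL) {
  k <- protocol$k
  cands <- setdiff(protocol$candidates, target)
  pool <- if (is.null(source_pool)) cands else intersect(cands, as.character(source_pool))
  if (length(pool) < k) stop("fewer candidate sources than k", call. = FALSE)
  combos <- utils::combn(sort_pop_labels(pool), k, simplify = FALSE)
  models <- lapply(combos, function(src) {
    refs <- switch(protocol$kind,
                   base = protocol$base_references,
                   rotating = setdiff(cands, src))
    qpadm_model(target, src, sort_pop_labels(refs))
  })
  tibble::tibble(
    sources = vapply(combos, paste, character(1), collapse = "+"),
    model = models
  )
}

#' Sort population labels numerically when possible
#'
#' @param x Character vector of labels.
#' @return Sorted labels (numeric order for all-numeric labels).
#' @export
sort_pop_labels <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  if (any(is.na(n))) sort(x) else x[order(n)]
}

#' Evaluate candidate models over replicate datasets
#'
#' Runs [qpadm()] for every model on every replicate, reusing allele
#' frequencies and the block partition within a replicate.
#'
#' @param reps Replicate datasets: list of [genotype_matrix()] objects or a
#'   character vector of EIGENSTRAT prefixes.
#' @param models Tibble from [enumerate_models()], or a list of
#'   [qpadm_model()].
#' @param options A [qpadm_options()].
#' @param weight_se Also compute jackknife standard errors of the weights
#'   (off by default: plausibility needs only the point estimates).
#' @return Tibble with one row per model x replicate: `replicate`,
#'   `sources`, `p_value`, `weight_1`..., `plausible`, `statistic`, `df`.
#' @export
evaluate_models <- function(reps, models, options = qpadm_options(),
                            weight_se = FALSE) {
  if (inherits(models, "qpadm_model")) models <- list(models)
  if (!is.data.frame(models)) {
    models <- tibble::tibble(
      sources = vapply(models, function(m) paste(m$sources, collapse = "+"),
                       character(1)),
      model = models)
  }
  all_pops <- unique(unlist(lapply(models$model, function(m)
    c(m$target, m$sources, m$references))))
  extra <- models[, setdiff(names(models), "model"), drop = FALSE]
  purrr::imap_dfr(as.list(unname(reps)), function(rep_data, r) {
    g <- if (is.character(rep_data)) read_eigenstrat(rep_data) else rep_data
    af <- allele_frequencies(g, intersect(all_pops, populations(g)))
    blocks <- make_blocks(g$snp, options$block_size)
    f2c <- compute_f2_cache(af, blocks)
    purrr::imap_dfr(models$model, function(m, i) {
      fit <- qpadm(g, m, options, af = af, blocks = blocks, f2_cache = f2c,
                   weight_se = weight_se)
      w <- as.list(stats::setNames(unname(fit$weights),
                                   paste0("weight_", seq_along(fit$weights))))
      tibble::tibble(replicate = r, extra[i, , drop = FALSE],
                     p_value = fit$p_value, !!!w,
                     plausible = fit$plausible,
                     statistic = fit$statistic, df = fit$df)
    })
  })
}

#' Aggregate model evaluations into a plausibility matrix
#'
#' @param results Tibble from [evaluate_models()].
#' @return Tibble with one row per source combination: replicate counts,
#'   plausible counts and proportions, mean P-value and mean weights.
#' @export
plausibility_matrix <- function(results) {
  wcols <- grep("^weight_", names(results), value = TRUE)
  results |>
    dplyr::group_by(.data$sources) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_plausible = sum(.data$plausible),
      prop_plausible = mean(.data$plausible),
      mean_p = mean(.data$p_value),
      dplyr::across(dplyr::all_of(wcols), mean, .names = "mean_{.col}"),
      .groups = "drop")
}

#' Kolmogorov-Smirnov test of P-value uniformity
#'
#' One-sample KS test of the P-values against Uniform(0, 1).
#'
#' @param p_values Numeric vector in `[0, 1]`, length >= 20.
#' @return Tibble with `n`, `statistic`, `p_value`.
#' @export
pvalue_uniformity <- function(p_values) {
  if (length(p_values) < 20) stop("need at least 20 P-values", call. = FALSE)
  if (any(p_values < 0 | p_values > 1)) {
    stop("P-values must lie in [0, 1]", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(p_values, "punif"))
  tibble::tibble(n = length(p_values),
                 statistic = unname(ks$statistic),
                 p_value = ks$p.value)
}

#' How often a model attains the highest P-value
#'
#' Among models evaluated on the same replicates, the fraction of replicates
#' in which the given model's P-value is the maximum. P-value ranking is a
#' poor model-selection criterion precisely because this fraction is well
#' below 1 even for the generative model.
#'
#' @param results Tibble from [evaluate_models()] (columns `replicate`,
#'   `sources`, `p_value`).
#' @param reference_sources Collapsed source label (e.g. `"5+9"`).
#' @return Fraction in `[0, 1]`.
#' @export
pvalue_ranking_frequency <- function(results, reference_sources) {
  if (!reference_sources %in% results$sources) {
    stop("reference model not present in results", call. = FALSE)
  }
  counts <- table(results$sources)
  if (length(unique(counts)) != 1) {
    stop("models were not evaluated on matching replicate sets", call. = FALSE)
  }
  by_rep <- split(results, results$replicate)
  wins <- vapply(by_rep, function(d) {
    d$p_value[d$sources == reference_sources] >= max(d$p_value)
  }, logical(1))
  mean(wins)
}

#' The standard benchmark admixture model
#'
#' Target 14, sources 5 and 9, references 0, 7, 10, 12 and 13 — the correct
#' model of the benchmark tree built by [build_standard_tree()].
#'
#' @return A [qpadm_model()].
#' @export
standard_model <- function() {
  qpadm_model("14", c("5", "9"), c("0", "7", "10", "12", "13"))
}

#' Default rotating candidate set of the benchmark tree
#'
#' All sixteen populations except the target and population 6 (excluded by
#' default because it is phylogenetically a clade with source 5; set
#' `include_6 = TRUE` to keep it).
#'
#' @param target Target label (excluded).
#' @param include_6 Keep population 6 in the set.
#' @return Character vector of labels.
#' @export
rotating_candidates <- function(target = "14", include_6 = FALSE) {
  cands <- as.character(0:15)
  drop_ <- c(target, if (!include_6) "6")
  setdiff(cands, drop_)
}
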