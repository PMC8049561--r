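#' Per-population alternative-allele frequencies
#'
#' Computes, for each requested population and each site, the frequency of the
#' alternative allele among non-missing allele copies, together with the
#' number of non-missing copies observed. Sites where a population has no
#' non-missing copies are undefined (`NA` frequency, count 0).
#'
#' @param g A [genotype_matrix()].
#' @param pops Character vector of population labels; defaults to all.
#' @return A list with matrices `freq` (sites x populations, `NA` where
#'   undefined) and `count` (non-missing allele copies, haploid units).
#' @export
allele_frequencies <- function(g, pops = populations(g)) {
  unknown <- setdiff(pops, g$ind$population)
  if (length(unknown)) {
    stop("unknown population label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  nsite <- n_snps(g)
  freq <- count <- matrix(NA_real_, nsite, length(pops),
                          dimnames = list(NULL, pops))
  for (p in pops) {
    cols <- which(g$ind$population == p)
    sub <- g$geno[, cols, drop = FALSE]
    obs <- 2L * (ncol(sub) - rowSums(is.na(sub)))
    alt <- rowSums(sub, na.rm = TRUE)
    count[, p] <- obs
    freq[, p] <- ifelse(obs > 0, alt / obs, NA_real_)
  }
  list(freq = freq, count = count)
}

#' Sites shared by every listed population
#'
#' A site is retained when every listed population has at least one
#' non-missing allele copy there. This is the site-intersection rule used by
#' the `allsnps: NO` analysis policy, under which all f4-statistics of a model
#' are computed on the sites shared by every population in the model.
#'
#' @inheritParams allele_frequencies
#' @return Logical vector, one element per site.
#' @export
shared_site_mask <- function(g, pops = populations(g)) {
  af <- allele_frequencies(g, pops)
  rowSums(af$count > 0) == length(pops)
}

#' Hudson pairwise FST
#'
#' Hudson-type estimator computed as a ratio of averages: the per-site
#' numerator \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)} and
#' denominator \eqn{p_1(1-p_2) + p_2(1-p_1)} are summed over usable sites
#' before division, which is robust to rare variants. Sites where either
#' population has fewer than two non-missing allele copies are skipped.
#'
#' @inheritParams allele_frequencies
#' @param pop_a,pop_b Population labels.
#' @return A single FST value.
#' @export
pairwise_fst <- function(g, pop_a, pop_b) {
  af <- allele_frequencies(g, c(pop_a, pop_b))
  p1 <- af$freq[, 1]; p2 <- af$freq[, 2]
  n1 <- af$count[, 1]; n2 <- af$count[, 2]
  use <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  if (!any(use)) stop("no usable sites for FST", call. = FALSE)
  p1 <- p1[use]; p2 <- p2[use]; n1 <- n1[use]; n2 <- n2[use]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

#' FST matrix for a set of populations
#'
#' @inheritParams allele_frequencies
#' @return A tibble with columns `pop_a`, `pop_b`, `fst` for each unordered
#'   pair.
#' @export
fst_matrix <- function(g, pops = populations(g)) {
  pairs <- utils::combn(pops, 2)
  tibble::tibble(
    pop_a = pairs[1, ], pop_b = pairs[2, ],
    fst = purrr::map2_dbl(pairs[1, ], pairs[2, ], ~pairwise_fst(g, .x, .y))
  )
}

#' Principal-component projection of individuals
#'
#' Classical genotype PCA: sites are mean-centered and normalized by
#' \eqn{\sqrt{p(1-p)}} with `p` the overall alternative-allele frequency;
#' monomorphic sites are dropped; missing genotypes are imputed at the site
#' mean. Deterministic up to the sign of each component.
#'
#' @inheritParams allele_frequencies
#' @param n_pc Number of components to return (default 2).
#' @return A tibble with columns `sample_id`, `population` and `PC1`,
#'   `PC2`, ...
#' @export
pca_projection <- function(g, pops = populations(g), n_pc = 2) {
  keep <- g$ind$population %in% pops
  if (sum(keep) < 3) stop("need at least 3 individuals for PCA", call. = FALSE)
  geno <- g$geno[, keep, drop = FALSE]
  p <- rowMeans(geno, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2) stop("need at least 2 polymorphic sites for PCA", call. = FALSE)
  geno <- geno[poly, , drop = FALSE]
  p <- p[poly]
  x <- (geno - 2 * p) / sqrt(p * (1 - p))
  x[is.na(x)] <- 0
  # individuals x individuals covariance keeps the eigenproblem small
  cv <- crossprod(x) / nrow(x)
  eg <- eigen(cv, symmetric = TRUE)
  scores <- eg$vectors[, seq_len(n_pc), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(n_pc)], 0)), n_pc)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  dplyr::bind_cols(
    tibble::tibble(sample_id = g$ind$sample_id[keep],
                   population = g$ind$population[keep]),
    tibble::as_tibble(scores)
  )
}
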