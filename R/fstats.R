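#' f4-statistics with block-jackknife standard errors
#'
#' `f4()` computes one or more f4-statistics
#' \eqn{f_4(A,B;C,D) = \mathrm{mean}[(p_A-p_B)(p_C-p_D)]} over usable sites,
#' with weighted block-jackknife means and standard errors. Allele
#' frequencies are unbiased sample frequencies; f4 needs no small-sample
#' heterozygosity correction (unlike f2/f3).
#'
#' @param g A [genotype_matrix()].
#' @param quadruples Tibble (or data frame) with character columns `A`, `B`,
#'   `C`, `D` of population labels, one row per statistic.
#' @param policy Site-handling policy: `"allsnps_yes"` (each statistic uses
#'   the sites where its own four populations have data) or `"allsnps_no"`
#'   (every statistic is restricted to sites shared by *all* populations in
#'   `all_pops`, defaulting to all populations appearing in `quadruples`).
#' @param block_size Jackknife block size in Morgans.
#' @param all_pops Populations defining the shared-site mask under
#'   `"allsnps_no"`.
#' @return A tibble with columns `A`, `B`, `C`, `D`, `est` (jackknife mean),
#'   `se`, `z`, `n_snps`, `n_blocks`.
#' @export
f4 <- function(g, quadruples, policy = c("allsnps_yes", "allsnps_no"),
               block_size = 0.05, all_pops = NULL) {
  fv <- f4_vector_with_cov(g, quadruples, policy = policy,
                           block_size = block_size, all_pops = all_pops)
  dplyr::bind_cols(tibble::as_tibble(quadruples),
                   tibble::tibble(est = fv$est, se = fv$se,
                                  z = fv$est / fv$se,
                                  n_snps = fv$n_snps,
                                  n_blocks = fv$n_blocks))
}

#' f4 vector with jackknife covariance
#'
#' Computes a vector of f4-statistics on a common block partition, retaining
#' per-block numerator sums and site counts, and estimates the joint
#' covariance of the vector by the weighted delete-one-block jackknife.
#' Under `"allsnps_yes"` blocks empty for a given statistic carry zero
#' weight for that component; the covariance is always estimated from the
#' same block partition for all components.
#'
#' @inheritParams f4
#' @param af Optional precomputed [allele_frequencies()] result covering all
#'   needed populations (avoids recomputation in model scans).
#' @param blocks Optional precomputed [make_blocks()] partition.
#' @param f2_cache Optional [compute_f2_cache()] result (complete data only;
#'   exact shortcut for the per-block sums).
#' @return An object of class `f4_vector`: list with `quadruples`, `est`,
#'   `se`, `cov` (jackknife covariance, positive semi-definite), `S` and `N`
#'   (B x d per-block sums and counts), `n_snps`, `n_blocks`, `nu`
#'   (jackknife degrees of freedom), `policy`.
#' @export
f4_vector_with_cov <- function(g, quadruples, policy = c("allsnps_yes", "allsnps_no"),
                               block_size = 0.05, all_pops = NULL,
                               af = NULL, blocks = NULL, f2_cache = NULL) {
  policy <- match.arg(policy)
  quadruples <- tibble::as_tibble(quadruples)
  stopifnot(all(c("A", "B", "C", "D") %in% names(quadruples)))
  pops <- unique(unlist(quadruples[, c("A", "B", "C", "D")]))
  need <- unique(c(pops, all_pops))
  if (is.null(af) && is.null(f2_cache)) af <- allele_frequencies(g, need)
  if (is.null(blocks)) blocks <- make_blocks(g$snp, block_size)
  d <- nrow(quadruples)
  B <- nrow(blocks$info)

  if (!is.null(f2_cache) && all(pops %in% f2_cache$pops)) {
    S <- N <- matrix(0, B, d)
    for (m in seq_len(d)) {
      A <- quadruples$A[m]; Bq <- quadruples$B[m]
      C <- quadruples$C[m]; D <- quadruples$D[m]
      S[, m] <- 0.5 * (f2_pair_sum(f2_cache, A, D) + f2_pair_sum(f2_cache, Bq, C) -
                         f2_pair_sum(f2_cache, A, C) - f2_pair_sum(f2_cache, Bq, D))
      N[, m] <- f2_cache$N
    }
  } else {
    if (is.null(af)) af <- allele_frequencies(g, pops)
    mask <- TRUE
    if (policy == "allsnps_no") {
      if (is.null(all_pops)) all_pops <- pops
      mask <- rowSums(!is.na(af$freq[, all_pops, drop = FALSE])) == length(all_pops)
    }
    S <- N <- matrix(0, B, d)
    for (m in seq_len(d)) {
      pA <- af$freq[, quadruples$A[m]]; pB <- af$freq[, quadruples$B[m]]
      pC <- af$freq[, quadruples$C[m]]; pD <- af$freq[, quadruples$D[m]]
      x <- (pA - pB) * (pC - pD)
      use <- !is.na(x) & mask
      if (!any(use)) {
        stop("f4(", paste(quadruples[m, 1:4], collapse = ","),
             "): no usable sites", call. = FALSE)
      }
      bl <- blocks$block[use]
      S[, m] <- unname(rowsum_padded(x[use], bl, B))
      N[, m] <- tabulate(bl, nbins = B)
    }
  }

  tot_S <- colSums(S); tot_N <- colSums(N)
  est <- tot_S / tot_N
  # delete-one-block estimates
  del <- sweep(-S, 2, tot_S, `+`) / sweep(-N, 2, tot_N, `+`)
  for (m in seq_len(d)) del[N[, m] == 0, m] <- est[m]
  jk <- weighted_jackknife(est, del, N)

  structure(list(quadruples = quadruples, est = est, se = jk$se,
                 cov = jk$cov, S = S, N = N,
                 n_snps = tot_N, n_blocks = colSums(N > 0),
                 nu = jk$nu, policy = policy, block_info = blocks$info),
            class = "f4_vector")
}

rowsum_padded <- function(x, group, nbins) {
  out <- numeric(nbins)
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' Per-block f2 sums for fast f4 computation on complete data
#'
#' Every f4-statistic decomposes exactly into pairwise f2 terms,
#' \eqn{f_4(A,B;C,D) = [f_2(A,D)+f_2(B,C)-f_2(A,C)-f_2(B,D)]/2}, site by
#' site. On complete data (no undefined frequencies, so all site sets agree)
#' the per-block f4 sums of any quadruple are therefore linear combinations
#' of per-block f2 sums over population pairs, which this cache precomputes
#' once per dataset. Model scans pass it to [qpadm()] to avoid re-scanning
#' the genotype matrix for every model.
#'
#' @param af An [allele_frequencies()] result.
#' @param blocks A [make_blocks()] partition.
#' @return A cache object, or `NULL` if the data contain undefined
#'   frequencies (callers then fall back to direct computation).
#' @export
compute_f2_cache <- function(af, blocks) {
  if (anyNA(af$freq)) return(NULL)
  pops <- colnames(af$freq)
  B <- nrow(blocks$info)
  pairs <- utils::combn(length(pops), 2)
  S2 <- matrix(0, B, ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    d2 <- (af$freq[, pairs[1, m]] - af$freq[, pairs[2, m]])^2
    S2[, m] <- rowsum_padded(d2, blocks$block, B)
  }
  key <- matrix(0L, length(pops), length(pops),
                dimnames = list(pops, pops))
  for (m in seq_len(ncol(pairs))) {
    key[pairs[1, m], pairs[2, m]] <- m
    key[pairs[2, m], pairs[1, m]] <- m
  }
  list(S2 = S2, key = key, pops = pops,
       N = tabulate(blocks$block, nbins = B), B = B)
}

f2_pair_sum <- function(cache, a, b) {
  if (a == b) return(numeric(cache$B))
  cache$S2[, cache$key[a, b]]
}

#' @export
print.f4_vector <- function(x, ...) {
  cat("<f4_vector> ", length(x$est), " statistic(s), ",
      nrow(x$S), " blocks, policy ", x$policy, "\n", sep = "")
  invisible(x)
}
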