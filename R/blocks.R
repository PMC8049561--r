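#' Partition SNPs into jackknife blocks
#'
#' Greedy partition along each chromosome: a new block starts when the
#' genetic distance from the block's first SNP reaches or exceeds
#' `block_size` (a SNP exactly at the boundary starts a new block). Blocks
#' never span chromosomes. The default 0.05 Morgans matches the standard
#' qpAdm block size.
#'
#' @param snp SNP tibble (as in [genotype_matrix()]) with `chromosome` and
#'   non-decreasing `genetic_pos` within chromosome, in Morgans.
#' @param block_size Block length in Morgans.
#' @return A list with `block` (integer block id per SNP, consecutive) and
#'   `info` (tibble: `block`, `chromosome`, `n_snps`, `gen_start`,
#'   `gen_end`).
#' @export
make_blocks <- function(snp, block_size = 0.05) {
  stopifnot(block_size > 0)
  block <- integer(nrow(snp))
  next_id <- 0L
  for (chr in unique(snp$chromosome)) {
    idx <- which(snp$chromosome == chr)
    g <- snp$genetic_pos[idx]
    if (is.unsorted(g)) stop("genetic positions not sorted on chromosome ", chr,
                             call. = FALSE)
    i <- 1L
    while (i <= length(idx)) {
      next_id <- next_id + 1L
      last <- i + sum(g[i:length(g)] - g[i] < block_size) - 1L
      block[idx[i:last]] <- next_id
      i <- last + 1L
    }
  }
  info <- tibble::as_tibble(stats::aggregate(
    seq_len(nrow(snp)), by = list(block = block),
    FUN = length))
  names(info)[2] <- "n_snps"
  info$chromosome <- snp$chromosome[match(info$block, block)]
  info$gen_start <- snp$genetic_pos[match(info$block, block)]
  info$gen_end <- rev(snp$genetic_pos)[match(info$block, rev(block))]
  list(block = block, info = info[, c("block", "chromosome", "n_snps",
                                      "gen_start", "gen_end")])
}

#' Weighted delete-one-block jackknife
#'
#' Weighted jackknife estimate, standard errors and covariance from
#' delete-one-block estimates, with block weights proportional to the number
#' of sites each block contributes (Busing-style weighting). With equal
#' block weights this reduces to the classical delete-one jackknife. Blocks
#' with zero weight for a component contribute nothing to that component.
#'
#' @param theta_hat Full-data estimate (length-d vector).
#' @param theta_del B x d matrix of delete-one-block estimates.
#' @param w Block weights: length-B vector, or B x d matrix when components
#'   use different site sets.
#' @return List with `est` (bias-corrected estimate), `se`, `cov` (d x d,
#'   positive semi-definite by construction), and `nu` (effective degrees of
#'   freedom, number of contributing blocks minus one).
#' @export
weighted_jackknife <- function(theta_hat, theta_del, w) {
  theta_del <- as.matrix(theta_del)
  d <- length(theta_hat)
  B <- nrow(theta_del)
  if (B < 2) stop("need at least 2 blocks for the jackknife", call. = FALSE)
  if (is.matrix(w)) W <- w else W <- matrix(w, B, d)
  stopifnot(nrow(W) == B, ncol(W) == d)

  est <- se <- numeric(d)
  Cmat <- matrix(0, B, d)
  n_eff <- integer(d)
  for (i in seq_len(d)) {
    wi <- W[, i]
    use <- wi > 0 & !is.na(theta_del[, i])
    Bi <- sum(use)
    n_eff[i] <- Bi
    if (Bi < 2) stop("component ", i, " has fewer than 2 non-empty blocks",
                     call. = FALSE)
    n <- sum(wi[use])
    h <- n / wi[use]
    est_j <- Bi * theta_hat[i] - sum((1 - wi[use] / n) * theta_del[use, i])
    tau <- h * theta_hat[i] - (h - 1) * theta_del[use, i]
    cc <- (tau - est_j) / sqrt(h - 1)
    est[i] <- est_j
    Cmat[use, i] <- cc / sqrt(Bi)
    se[i] <- sqrt(sum(cc^2) / Bi)
  }
  cov <- crossprod(Cmat)
  list(est = est, se = se, cov = cov, nu = min(n_eff) - 1L)
}

#' Jackknife mean and standard error from per-block sums
#'
#' Convenience wrapper for a single statistic that is a ratio of summed
#' per-block numerators to per-block site counts (such as an f4-statistic):
#' computes the point estimate, the delete-one-block estimates and the
#' weighted jackknife mean and standard error.
#'
#' @param block_sums Per-block numerator sums.
#' @param block_counts Per-block site counts (jackknife weights).
#' @return List with `est` (weighted jackknife mean), `se`, `point`
#'   (plain ratio estimate) and `nu`.
#' @export
jackknife_estimate <- function(block_sums, block_counts) {
  keep <- block_counts > 0
  if (sum(keep) < 2) stop("need at least 2 non-empty blocks", call. = FALSE)
  S <- sum(block_sums)
  N <- sum(block_counts)
  point <- S / N
  del <- ifelse(keep, (S - block_sums) / (N - block_counts), point)
  jk <- weighted_jackknife(point, matrix(del, ncol = 1), block_counts)
  list(est = jk$est, se = jk$se, point = point, nu = jk$nu)
}
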