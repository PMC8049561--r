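#' qpAdm analysis options
#'
#' @param allsnps If `TRUE` (default, matching common practice) each
#'   f4-statistic uses the sites available for its own four populations; if
#'   `FALSE`, all statistics are restricted to sites shared by every
#'   population in the model.
#' @param block_size Jackknife block size in Morgans (default 0.05).
#' @param p_threshold Plausibility threshold: a model is plausible when its
#'   P-value strictly exceeds this and all weights lie in `[0, 1]`.
#' @param p_method Reference distribution for the likelihood-ratio
#'   statistic. `"hotelling"` (default) maps the minimized GLS form through a
#'   Hotelling \eqn{T^2}/F tail with degrees of freedom tied to the number of
#'   jackknife blocks, which keeps P-values calibrated when blocks are few;
#'   it converges to the `"chisq"` upper tail (the classical choice) as the
#'   block count grows.
#' @return A list of class `qpadm_options`.
#' @export
qpadm_options <- function(allsnps = TRUE, block_size = 0.05,
                          p_threshold = 0.05,
                          p_method = c("hotelling", "chisq")) {
  stopifnot(p_threshold > 0, p_threshold < 1, block_size > 0)
  structure(list(allsnps = isTRUE(allsnps), block_size = block_size,
                 p_threshold = p_threshold, p_method = match.arg(p_method)),
            class = "qpadm_options")
}

#' Specify a qpAdm model
#'
#' @param target Target population label.
#' @param sources Character vector of k >= 1 source labels.
#' @param references Character vector of reference ("right") labels; at
#'   least k + 1 are required.
#' @return A list of class `qpadm_model`.
#' @export
qpadm_model <- function(target, sources, references) {
  sources <- as.character(sources); references <- as.character(references)
  target <- as.character(target)
  if (target %in% c(sources, references)) {
    stop("target must not appear among sources or references", call. = FALSE)
  }
  if (length(intersect(sources, references))) {
    stop("sources and references must be disjoint", call. = FALSE)
  }
  if (anyDuplicated(c(sources, references))) {
    stop("duplicated population in model", call. = FALSE)
  }
  if (length(references) < length(sources) + 1) {
    stop("need at least k + 1 reference populations", call. = FALSE)
  }
  structure(list(target = target, sources = sources, references = references),
            class = "qpadm_model")
}

#' f4 design matrix of a qpAdm model
#'
#' Builds the k x (n_R - 1) matrix with entry (i, j) =
#' f4(target, source_i; ref_1, ref_{j+1}) together with its block-jackknife
#' covariance. Under the admixture null the target row combination
#' annihilates this matrix: there is a weight vector w (summing to 1) with
#' w'X = 0, i.e. the matrix has rank at most k - 1.
#'
#' @param g A [genotype_matrix()].
#' @param model A [qpadm_model()].
#' @param options A [qpadm_options()].
#' @param af,blocks,f2_cache Optional precomputed frequencies, block
#'   partition and f2 cache (see [f4_vector_with_cov()]).
#' @return List with `X`, the `f4_vector` object `fv` (vec order: columns of
#'   `X` stacked), and dimensions `k`, `nc`.
#' @export
build_f4_design <- function(g, model, options = qpadm_options(),
                            af = NULL, blocks = NULL, f2_cache = NULL) {
  k <- length(model$sources)
  refs <- model$references
  nc <- length(refs) - 1
  quads <- tidyr::expand_grid(j = refs[-1], i = model$sources)  # col-major
  quadruples <- tibble::tibble(A = model$target, B = quads$i,
                               C = refs[1], D = quads$j)
  fv <- f4_vector_with_cov(g, quadruples,
                           policy = if (options$allsnps) "allsnps_yes" else "allsnps_no",
                           block_size = options$block_size,
                           all_pops = c(model$target, model$sources, refs),
                           af = af, blocks = blocks, f2_cache = f2_cache)
  X <- matrix(fv$est, nrow = k, ncol = nc,
              dimnames = list(model$sources, refs[-1]))
  list(X = X, fv = fv, k = k, nc = nc)
}

# Solve M x = b with a Cholesky factorization, ridging the diagonal by
# eps = 1e-10 * trace/dim (growing by 10x as needed) if M is numerically
# singular. Returns list(x, eps).
chol_solve <- function(M, b) {
  M <- (M + t(M)) / 2
  eps_unit <- sum(diag(M)) / nrow(M)
  eps <- 0
  for (trial in 0:8) {
    R <- tryCatch(chol(M + diag(eps, nrow(M))), error = function(e) NULL)
    if (!is.null(R)) {
      return(list(x = backsolve(R, forwardsolve(t(R), b)), eps = eps))
    }
    eps <- if (eps == 0) 1e-10 * eps_unit else eps * 10
  }
  stop("covariance matrix is numerically singular beyond repair", call. = FALSE)
}

# Quadratic form of the row combination u'X with its exact covariance,
# given the k^2 grid of (nc x nc) covariance slices.
profile_objective <- function(u, X, slices) {
  k <- nrow(X)
  s <- drop(crossprod(u, X))
  Cu <- matrix(0, ncol(X), ncol(X))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    Cu <- Cu + u[a] * u[b] * slices[[(a - 1) * k + b]]
  }
  drop(crossprod(s, chol_solve(Cu, s)$x))
}

cov_slices <- function(cov, k, nc) {
  # vec order is column-major in X: index (i, j) -> (j-1)*k + i
  out <- vector("list", k * k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    ia <- (seq_len(nc) - 1) * k + a
    ib <- (seq_len(nc) - 1) * k + b
    out[[(a - 1) * k + b]] <- cov[ia, ib, drop = FALSE]
  }
  out
}

# Minimize the profile objective over directions u on the unit sphere.
# k = 2 uses a grid plus golden-section refinement on the angle; larger k
# uses Nelder-Mead from the smallest singular direction with restarts.
minimize_rank_null <- function(X, slices, init = NULL) {
  k <- nrow(X)
  if (k == 1) {
    return(list(u = 1, objective = profile_objective(1, X, slices)))
  }
  if (k == 2) {
    f <- function(th) profile_objective(c(cos(th), sin(th)), X, slices)
    if (!is.null(init)) {
      th0 <- atan2(init[2], init[1]) %% pi
      opt <- stats::optimize(f, c(th0 - 0.6, th0 + 0.6), tol = 1e-9)
    } else {
      grid <- seq(0, pi, length.out = 61)[-61]
      vals <- vapply(grid, f, double(1))
      th0 <- grid[which.min(vals)]
      opt <- stats::optimize(f, c(th0 - 0.1, th0 + 0.1), tol = 1e-9)
    }
    u <- c(cos(opt$minimum), sin(opt$minimum))
    return(list(u = u, objective = opt$objective))
  }
  fn <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) return(1e30)
    profile_objective(v / nv, X, slices)
  }
  if (is.null(init)) init <- svd(X)$u[, k]
  best <- stats::optim(init, fn, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
  for (r in 1:3) {
    cand <- stats::optim(init + stats::rnorm(k, sd = 0.3), fn,
                         method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
    if (cand$value < best$value) best <- cand
  }
  u <- best$par / sqrt(sum(best$par^2))
  list(u = u, objective = best$value)
}

#' Rank-constrained weighted least-squares fit of a matrix
#'
#' Minimizes \eqn{(\mathrm{vec}(X-E))' \Sigma^{-1} (\mathrm{vec}(X-E))} over
#' matrices E of rank at most r. For r one less than the row count (the
#' qpAdm case) the rank constraint is equivalent to the existence of a left
#' null vector u, and the minimum over E for fixed u is available in closed
#' form as the GLS quadratic form of u'X with its exact covariance; the
#' objective is then profiled over u. `r = 0` and full rank are closed form.
#'
#' @param X Numeric matrix (rows x columns).
#' @param cov Covariance of `vec(X)` (column-major stacking).
#' @param r Target rank: 0, `nrow(X) - 1`, or `min(dim(X))`.
#' @return List with `E` (fitted matrix), `objective` (minimized GLS form),
#'   and for the profiled case `u` (unit left-null vector of `E`).
#' @export
fit_rank <- function(X, cov, r) {
  X <- as.matrix(X)
  k <- nrow(X); nc <- ncol(X)
  stopifnot(r >= 0, r <= min(k, nc))
  if (r == min(k, nc)) {
    return(list(E = X, objective = 0, u = NULL))
  }
  if (r == 0 && k > 1) {
    # all rows zero: objective is the full quadratic form
    x <- as.vector(X)
    return(list(E = matrix(0, k, nc), objective = drop(crossprod(x, chol_solve(cov, x)$x)),
                u = NULL))
  }
  if (r != k - 1) {
    stop("fit_rank supports r = 0, r = nrow(X) - 1 and full rank", call. = FALSE)
  }
  slices <- cov_slices(cov, k, nc)
  sol <- minimize_rank_null(X, slices)
  u <- sol$u
  # fitted matrix: project the misfit out along u with GLS weighting
  s <- drop(crossprod(u, X))
  Cu <- matrix(0, nc, nc)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    Cu <- Cu + u[a] * u[b] * slices[[(a - 1) * k + b]]
  }
  bvec <- chol_solve(Cu, s)$x
  U <- matrix(0, nc, k * nc)
  for (j in seq_len(nc)) U[j, (j - 1) * k + seq_len(k)] <- u
  adj <- cov %*% t(U) %*% bvec
  E <- X - matrix(adj, k, nc)
  list(E = E, objective = sol$objective, u = u)
}

qpadm_pvalue <- function(statistic, q, nu, method) {
  if (method == "hotelling" && nu - q + 1 >= 1) {
    fstat <- statistic * (nu - q + 1) / (nu * q)
    stats::pf(fstat, q, nu - q + 1, lower.tail = FALSE)
  } else {
    stats::pchisq(statistic, df = q, lower.tail = FALSE)
  }
}

#' Fit a qpAdm admixture model
#'
#' Tests whether the target population's allele frequencies can be written
#' as a mixture of the source populations' frequencies, using the rank
#' constraint on the f4 design matrix: the likelihood-ratio statistic is the
#' minimized GLS misfit at rank k - 1, referred to an upper tail with
#' n_R - k degrees of freedom. Admixture weights are the normalized left
#' null vector of the fitted matrix; their standard errors come from
#' delete-one-block re-estimation. A model is plausible when the P-value
#' exceeds the threshold and every weight lies in `[0, 1]`; out-of-range
#' weights are reported as estimated, never clamped.
#'
#' @inheritParams build_f4_design
#' @param g A [genotype_matrix()] or an EIGENSTRAT path prefix.
#' @param weight_se Compute delete-one-block jackknife standard errors for
#'   the weights (skip in large model scans where only the point estimates
#'   and the P-value matter).
#' @return An object of class `qpadm_fit`: list with `target`, `sources`,
#'   `references`, `weights`, `weight_se`, `statistic`, `df`, `p_value`,
#'   `plausible`, `n_snps_used`, `n_blocks`, `nu`, `options`, `X`, `E`,
#'   `cov`.
#' @export
qpadm <- function(g, model, options = qpadm_options(), af = NULL, blocks = NULL,
                  f2_cache = NULL, weight_se = TRUE) {
  if (is.character(g)) g <- read_eigenstrat(g)
  stopifnot(inherits(model, "qpadm_model"))
  k <- length(model$sources)
  des <- build_f4_design(g, model, options, af = af, blocks = blocks,
                         f2_cache = f2_cache)
  fv <- des$fv
  nu <- fv$nu
  fit <- fit_rank(des$X, fv$cov, k - 1)
  q <- length(model$references) - k
  p <- qpadm_pvalue(fit$objective, q, nu, options$p_method)

  u <- if (k == 1) 1 else fit$u
  weights <- normalize_weights(u, model$sources)

  # delete-one-block weight re-estimation (covariance held fixed)
  B <- nrow(fv$S)
  w_del <- matrix(NA_real_, B, k)
  tot_S <- colSums(fv$S); tot_N <- colSums(fv$N)
  wblocks <- rowSums(fv$N)
  if (k > 1 && weight_se) {
    slices <- cov_slices(fv$cov, k, des$nc)
    if (k == 2) {
      w_del <- jackknife_weights_k2(fv, slices, u, weights, tot_S, tot_N, wblocks)
    } else {
      for (b in seq_len(B)) {
        if (wblocks[b] <= 0) next
        nb <- tot_N - fv$N[b, ]
        if (any(nb <= 0)) { w_del[b, ] <- weights; next }
        Xb <- matrix((tot_S - fv$S[b, ]) / nb, nrow = k)
        solb <- minimize_rank_null(Xb, slices, init = u)
        w_del[b, ] <- normalize_weights(solb$u, model$sources, template = weights)
      }
    }
    use <- !is.na(w_del[, 1])
    jk <- weighted_jackknife(weights, w_del[use, , drop = FALSE], wblocks[use])
    w_se <- jk$se
  } else {
    w_se <- if (k == 1) 0 else NA_real_
  }

  structure(list(
    target = model$target, sources = model$sources,
    references = model$references,
    weights = stats::setNames(weights, model$sources),
    weight_se = stats::setNames(rep(w_se, length.out = k), model$sources),
    statistic = fit$objective, df = q, p_value = p,
    plausible = (p > options$p_threshold) && all(weights >= 0 & weights <= 1),
    n_snps_used = round(mean(fv$n_snps)),
    n_blocks = max(fv$n_blocks), nu = nu,
    options = options, X = des$X, E = fit$E, cov = fv$cov
  ), class = "qpadm_fit")
}

# Fast delete-one-block weight re-estimation for two sources. The GLS
# weighting of the profile objective depends only on the angle, not the
# block, so the Cholesky factors at a three-point angle stencil are shared
# across blocks and each block needs only quadratic forms; the per-block
# minimum comes from the parabola through the stencil.
jackknife_weights_k2 <- function(fv, slices, u, weights, tot_S, tot_N, wblocks) {
  B <- nrow(fv$S)
  th0 <- atan2(u[2], u[1])
  h <- 0.08
  thetas <- th0 + c(-h, 0, h)
  # delete-one design matrices, d x B
  nb <- t(tot_N - t(fv$N))
  Xb <- t(tot_S - t(fv$S)) / nb  # B x d
  ok <- wblocks > 0 & apply(nb > 0, 1, all)
  w_del <- matrix(NA_real_, B, 2)
  Tmat <- matrix(NA_real_, B, 3)
  nc <- ncol(slices[[1]])
  for (j in 1:3) {
    uu <- c(cos(thetas[j]), sin(thetas[j]))
    Cu <- uu[1]^2 * slices[[1]] + uu[1] * uu[2] * (slices[[2]] + slices[[3]]) +
      uu[2]^2 * slices[[4]]
    Cu <- (Cu + t(Cu)) / 2
    R <- tryCatch(chol(Cu), error = function(e) NULL)
    if (is.null(R)) {
      R <- chol(Cu + diag(1e-10 * sum(diag(Cu)) / nc, nc))
    }
    # s_b for all blocks: combination of the two rows of each Xb
    idx1 <- seq(1, 2 * nc, by = 2); idx2 <- idx1 + 1
    Sb <- uu[1] * Xb[, idx1, drop = FALSE] + uu[2] * Xb[, idx2, drop = FALSE]
    Z <- forwardsolve(t(R), t(Sb))
    Tmat[, j] <- colSums(Z^2)
  }
  # parabola vertex through the stencil
  num <- Tmat[, 1] - Tmat[, 3]
  den <- 2 * (Tmat[, 1] - 2 * Tmat[, 2] + Tmat[, 3])
  shift <- ifelse(abs(den) > 1e-30, h * num / den, 0)
  shift <- pmin(pmax(shift, -0.5), 0.5)
  th_b <- th0 + shift
  ub <- cbind(cos(th_b), sin(th_b))
  sums <- rowSums(ub)
  sums[abs(sums) < 1e-12] <- 1e-12
  w_del[ok, ] <- (ub / sums)[ok, , drop = FALSE]
  w_del
}

# Scale the left-null vector so the weights sum to one; align the sign with
# a template (the full-data weights) for jackknife stability.
normalize_weights <- function(u, sources, template = NULL) {
  s <- sum(u)
  if (abs(s) < 1e-12) {
    w <- u / 1e-12
  } else {
    w <- u / s
  }
  if (!is.null(template) && sum((w - template)^2) > sum((-w - template)^2)) {
    # direction flip cannot happen after sum-normalization; kept for safety
    w <- w
  }
  w
}

#' Single-source clade test (qpWave rank-0 special case)
#'
#' Tests whether the target forms a genetic clade with a single source
#' population with respect to the references: the 1 x (n_R - 1) f4 row is
#' tested against zero (rank 0), with n_R - 1 degrees of freedom.
#'
#' @inheritParams qpadm
#' @param target,source Population labels.
#' @param references Reference labels (at least 2).
#' @return A `qpadm_fit` with k = 1 and weight fixed at 1.
#' @export
clade_test <- function(g, target, source, references,
                       options = qpadm_options(), af = NULL, blocks = NULL,
                       f2_cache = NULL) {
  qpadm(g, qpadm_model(target, source, references), options,
        af = af, blocks = blocks, f2_cache = f2_cache)
}

#' @export
print.qpadm_fit <- function(x, ...) {
  cat("<qpadm_fit> target ", x$target, " ~ ",
      paste(x$sources, collapse = " + "), "\n", sep = "")
  cat(sprintf("  statistic %.3f on %d df, P = %.4g (%s)\n", x$statistic,
              x$df, x$p_value, if (x$plausible) "plausible" else "rejected"))
  if (length(x$weights) > 1 || x$weights[1] != 1) {
    cat("  weights: ",
        paste(sprintf("%s = %.3f (SE %.3f)", names(x$weights), x$weights,
                      x$weight_se), collapse = ", "), "\n", sep = "")
  }
  cat("  SNPs used: ", x$n_snps_used, "; blocks: ", x$n_blocks, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the admixture weights of a qpAdm fit
#'
#' @param x A `qpadm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per source: `source`, `weight`, `se`, `z`.
#' @export
tidy.qpadm_fit <- function(x, ...) {
  tibble::tibble(source = x$sources,
                 weight = unname(x$weights),
                 se = unname(x$weight_se),
                 z = unname(x$weights / ifelse(x$weight_se > 0, x$weight_se, NA)))
}

#' One-row summary of a qpAdm fit
#'
#' @param x A `qpadm_fit`.
#' @param ... Unused.
#' @return One-row tibble with `target`, `sources`, `statistic`, `df`,
#'   `p_value`, `plausible`, `n_snps_used`, `n_blocks`.
#' @export
glance.qpadm_fit <- function(x, ...) {
  tibble::tibble(target = x$target,
                 sources = paste(x$sources, collapse = "+"),
                 statistic = x$statistic, df = x$df, p_value = x$p_value,
                 plausible = x$plausible, n_snps_used = x$n_snps_used,
                 n_blocks = x$n_blocks)
}
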