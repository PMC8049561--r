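test_that("model construction enforces the qpAdm constraints", {
  expect_error(qpadm_model("14", c("5", "9"), c("0", "7", "14")), "target")
  expect_error(qpadm_model("14", c("5", "9"), c("5", "0", "7")), "disjoint")
  expect_error(qpadm_model("14", c("5", "9"), c("0", "7")), "k \\+ 1")
  m <- standard_model()
  expect_equal(length(m$references), 5)
})

test_that("the f4 design matrix has the documented shape and df", {
  g <- std_geno(1)
  des <- build_f4_design(g, standard_model())
  expect_equal(dim(des$X), c(2, 4))
  fit <- qpadm(g, standard_model(), weight_se = FALSE)
  expect_equal(fit$df, 3)  # n_R - k = 5 - 2
  # clade-mate target: the row for the shared source is pure noise
  des6 <- build_f4_design(g, qpadm_model("6", "5", c("0", "7", "10", "12", "13")))
  z <- des6$X[1, ] / sqrt(diag(des6$fv$cov))
  expect_true(all(abs(z) < 4))
})

test_that("fit_rank closed forms and the brute-force rank-1 oracle agree", {
  X <- matrix(c(1.2, -0.4, 0.8, 2.1, -1.0, 0.3), 2, 3)
  cv <- diag(c(0.5, 1, 0.7, 0.3, 1.2, 0.9))
  expect_equal(fit_rank(X, cv, 2)$objective, 0)
  expect_equal(fit_rank(X, cv, 2)$E, X)
  f0 <- fit_rank(X, cv, 0)
  expect_equal(f0$objective,
               drop(crossprod(as.vector(X), solve(cv, as.vector(X)))))
  # generic numerical minimizer over E = a b' as the independent oracle
  f1 <- fit_rank(X, cv, 1)
  obj <- function(par) {
    E <- outer(par[1:2], par[3:5])
    d <- as.vector(X - E)
    drop(crossprod(d, solve(cv, d)))
  }
  sv <- svd(X)
  start <- c(sv$u[, 1] * sqrt(sv$d[1]), sv$v[, 1] * sqrt(sv$d[1]))
  oracle <- stats::optim(start, obj, method = "BFGS",
                         control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(f1$objective, oracle$value, tolerance = 1e-5)
  # the fitted matrix is rank deficient with u as its left null vector
  expect_lt(abs(drop(f1$u %*% f1$E)) |> max(), 1e-10)
})

test_that("an exact linear-combination target gives a perfect fit", {
  X <- outer(c(1, 2), rnorm(5))
  cv <- diag(0.1, 10)
  f <- fit_rank(X, cv, 1)
  expect_lt(f$objective, 1e-8)
  # u annihilates the rows; normalized weights recover the combination
  expect_lt(max(abs(drop(f$u %*% X))), 1e-4)
})

test_that("weights sum to one and carry jackknife standard errors", {
  g <- std_geno(1)
  fit <- qpadm(g, standard_model())
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$weight_se > 0))
  expect_true(fit$p_value >= 0 && fit$p_value <= 1)
  td <- tidy(fit)
  expect_equal(names(td), c("source", "weight", "se", "z"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$sources, "5+9")
})

test_that("the statistic is invariant to the ordering of references", {
  g <- std_geno(2)
  m1 <- standard_model()
  m2 <- qpadm_model("14", c("5", "9"), c("7", "13", "0", "12", "10"))
  f1 <- qpadm(g, m1, weight_se = FALSE)
  f2 <- qpadm(g, m2, weight_se = FALSE)
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-4)
  expect_equal(unname(f1$weights), unname(f2$weights), tolerance = 1e-3)
})

test_that("the clade test is the k = 1 rank-zero special case", {
  g <- std_geno(1)
  refs <- sort_pop_labels(setdiff(rotating_candidates("6"), "5"))
  ct <- clade_test(g, "6", "5", refs)
  expect_equal(ct$df, length(refs) - 1)
  expect_equal(unname(ct$weights), 1)
  # an admixed target never forms a clade with a single source
  ct14 <- clade_test(g, "14", "5",
                     sort_pop_labels(setdiff(rotating_candidates("14"), "5")))
  expect_lt(ct14$p_value, 0.05)
})

test_that("plausibility combines the P threshold and the closed weight range", {
  fit <- list(p_value = 0.051, weights = c(a = 0, b = 1))
  rule <- function(f, thr = 0.05) (f$p_value > thr) && all(f$weights >= 0 & f$weights <= 1)
  expect_true(rule(fit))
  expect_false(rule(list(p_value = 0.05, weights = c(0.5, 0.5))))   # strict >
  expect_false(rule(list(p_value = 0.5, weights = c(1.01, -0.01)))) # out of range
  # out-of-range weights are reported, never clamped
  g <- std_geno(1)
  f <- qpadm(g, qpadm_model("14", c("8", "9"),
                            sort_pop_labels(setdiff(rotating_candidates("14"),
                                                    c("8", "9")))),
             weight_se = FALSE)
  expect_false(all(f$weights >= 0 & f$weights <= 1))
})

test_that("P-value methods: finite-block tail converges to the chi-squared tail", {
  stat <- 7.3
  p_chi <- qpadmix:::qpadm_pvalue(stat, q = 3, nu = 1e7, method = "hotelling")
  expect_equal(p_chi, stats::pchisq(stat, 3, lower.tail = FALSE), tolerance = 1e-4)
  # at small block counts the finite-block tail is more conservative
  p_small <- qpadmix:::qpadm_pvalue(stat, q = 3, nu = 20, method = "hotelling")
  expect_gt(p_small, p_chi)
})
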