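test_that("cronbach_alpha matches its covariance closed form", {
  # two identical items: perfect consistency
  withr::with_seed(1, v <- rnorm(40))
  expect_equal(cronbach_alpha(cbind(v, v))$alpha, 1, tolerance = 1e-12)

  # unit variances, pairwise covariance 0.5, 3 items: alpha = 0.75 exactly
  Sg <- matrix(0.5, 3, 3); diag(Sg) <- 1
  dimnames(Sg) <- list(paste0("i", 1:3), paste0("i", 1:3))
  x <- data_with_exact_cov(60, Sg, seed = 2)
  expect_equal(cronbach_alpha(x)$alpha, 0.75, tolerance = 1e-12)

  # random matrices: implementation equals the covariance-matrix oracle
  withr::with_seed(3, {
    for (rep in 1:10) {
      m <- matrix(rnorm(30 * 5), 30, 5) + rnorm(30)  # shared row effect
      expect_equal(cronbach_alpha(m)$alpha, oracle_alpha_from_cov(cov(m)),
                   tolerance = 1e-12)
    }
  })

  # low-consistency data are flagged below the 0.7 threshold
  withr::with_seed(4, noise <- matrix(rnorm(200 * 4), 200, 4))
  low <- cronbach_alpha(noise)
  expect_true(low$flagged)
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "variance")
})

test_that("implied_covariance expands Lambda Phi Lambda' + Psi", {
  map2 <- setNames(c("F1", "F1"), c("a", "b"))
  Phi1 <- matrix(1, 1, 1, dimnames = list("F1", "F1"))
  expect_equal(unname(implied_covariance(c(1, 1), Phi1, c(0, 0), map2)),
               matrix(1, 2, 2))
  # zero loadings leave only the diagonal error variances
  expect_equal(unname(implied_covariance(c(0, 0), Phi1, c(2, 3), map2)),
               diag(c(2, 3)))

  # 4-item two-factor toy against hand matrix algebra
  map4 <- setNames(c("F1", "F1", "F2", "F2"), letters[1:4])
  Phi <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("F1", "F2"),
                                                      c("F1", "F2")))
  lam <- c(0.8, 0.6, 0.7, 0.5)
  psi <- c(0.36, 0.64, 0.51, 0.75)
  Sg <- implied_covariance(lam, Phi, psi, map4)
  expect_equal(unname(Sg["a", "b"]), 0.8 * 0.6)
  expect_equal(unname(Sg["a", "c"]), 0.8 * 0.5 * 0.7)
  expect_equal(unname(Sg["b", "d"]), 0.6 * 0.5 * 0.5)
  expect_equal(unname(diag(Sg)), lam^2 + psi)

  bad_phi <- matrix(c(1, 2, 2, 1), 2, dimnames = dimnames(Phi))
  expect_error(implied_covariance(lam, bad_phi, psi, map4), "positive definite")
})

test_that("ml_discrepancy is zero at equality, positive elsewhere", {
  Sg <- matrix(c(2, 0.3, 0.3, 1), 2)
  expect_equal(ml_discrepancy(Sg, Sg), 0, tolerance = 1e-12)
  expect_equal(ml_discrepancy(matrix(2, 1, 1), matrix(1, 1, 1)),
               1 - log(2), tolerance = 1e-12)
  withr::with_seed(8, {
    for (rep in 1:25) {
      p <- sample(2:5, 1)
      A <- matrix(rnorm(p * p), p); S <- crossprod(A) + diag(p)
      B <- matrix(rnorm(p * p), p); Sig <- crossprod(B) + diag(p)
      expect_gte(ml_discrepancy(S, Sig), 0)
    }
  })
  expect_error(ml_discrepancy(diag(0, 2), diag(2)), "positive definite")
})

test_that("fit_cfa recovers known parameters from synthetic factor data", {
  map <- three_factor_map(9)
  truth <- setNames(c(0.5, 0.65, 0.8, 0.55, 0.7, 0.9, 0.46, 0.6, 0.85),
                    names(map))
  cfg <- generator_config(seed = 12)
  gen <- generate_factor_responses(map, cfg, n = 2000, loadings = truth)
  expect_no_warning(fit <- fit_cfa(gen$x, map))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$loadings - truth)), 0.05)
  expect_lt(max(abs(fit$factor_corr - gen$factor_corr)), 0.05)
  std <- standardized_loadings(fit)
  expect_true(all(std$std_loading > 0.4 & std$std_loading < 0.95))
  expect_false(any(std$heywood))
})

test_that("a saturated one-factor model fits exactly with zero df", {
  map <- setNames(rep("F1", 3), c("a", "b", "c"))
  Phi1 <- matrix(1, 1, 1, dimnames = list("F1", "F1"))
  Sg <- implied_covariance(c(0.8, 0.7, 0.6), Phi1, c(0.36, 0.51, 0.64), map)
  fit <- fit_cfa_cov(Sg, n = 100, map = map)
  expect_lte(fit$fml, 1e-8)
  fi <- fit_indices(fit)
  expect_equal(fi$df, 0)
  expect_true(fi$saturated)
})

test_that("a sample covariance equal to an implied covariance is a fixed point", {
  map <- three_factor_map(6)
  lam <- setNames(seq(0.5, 0.85, length.out = 6), names(map))
  Phi <- matrix(0.55, 3, 3); diag(Phi) <- 1
  dimnames(Phi) <- list(c("F1", "F2", "F3"), c("F1", "F2", "F3"))
  Sg <- implied_covariance(lam, Phi, 1 - lam^2, map)
  fit <- fit_cfa_cov(Sg, n = 500, map = map)
  expect_lte(fit$fml, 1e-10)
  fi <- fit_indices(fit)
  expect_equal(fi$cmin, 0, tolerance = 1e-7)
  expect_equal(fi$srmr, 0, tolerance = 1e-6)
})

test_that("fit_indices computes CMIN, df, SRMR and classification flags", {
  map <- three_factor_map(30)
  # df for 30 items on three correlated factors: 465 - 63 = 402
  cfg <- generator_config(seed = 21)
  gen <- generate_factor_responses(map, cfg, n = 400)
  fit <- fit_cfa(gen$x, map)
  fi <- fit_indices(fit)
  expect_equal(fi$df, 402)
  expect_equal(fi$cmin, (400 - 1) * fit$fml, tolerance = 1e-12)
  # CMIN scales linearly in (n - 1) at fixed S
  fi2 <- fit_indices(fit, n = 800)
  expect_equal(fi2$cmin / fi$cmin, 799 / 399, tolerance = 1e-12)

  # classification boundaries via a synthetic fit with a chosen discrepancy
  fake_fit <- function(fml) {
    f <- fit; f$fml <- fml; f
  }
  cls <- function(ratio) {
    fit_indices(fake_fit(ratio * 402 / 399))$cmin_df_class
  }
  expect_equal(cls(2.281), "acceptable")
  expect_equal(cls(4.2), "debatable")
  expect_equal(cls(6.0), "poor")
})

test_that("an SRMR close to the 0.08 threshold still classifies acceptable", {
  # residual magnitudes 0.082 and 0.086 bracket the half-up rounding boundary
  map <- setNames(c("F1", "F1", "F1"), c("a", "b", "c"))
  mk <- function(r) {
    Phi1 <- matrix(1, 1, 1, dimnames = list("F1", "F1"))
    Sg <- implied_covariance(c(0.8, 0.7, 0.6), Phi1, c(0.36, 0.51, 0.64), map)
    S <- Sg
    # perturb one off-diagonal correlation by sqrt(6) * r so the root mean
    # square over the 6 unique elements is exactly r
    S["a", "b"] <- S["a", "b"] + sqrt(6) * r
    S["b", "a"] <- S["a", "b"]
    f <- structure(list(map = map, S = S, implied = Sg, n = 100,
                        fml = ml_discrepancy(S, Sg),
                        factor_corr = Phi1), class = "cfa_fit")
    fit_indices(f)
  }
  near <- mk(0.082)
  expect_equal(near$srmr, 0.082, tolerance = 1e-9)
  expect_true(near$srmr_acceptable)
  far <- mk(0.086)
  expect_false(far$srmr_acceptable)
})

test_that("standardized loadings follow lambda / sqrt(lambda^2 + psi)", {
  map <- setNames(c("F1", "F1"), c("a", "b"))
  fit <- structure(list(
    loadings = setNames(c(0.6, 1), c("a", "b")),
    error_vars = setNames(c(0.64, 0), c("a", "b")),
    factor_corr = matrix(1, 1, 1, dimnames = list("F1", "F1")),
    map = map), class = "cfa_fit")
  std <- standardized_loadings(fit)
  expect_equal(std$std_loading[std$item == "a"], 0.6)
  expect_equal(std$std_loading[std$item == "b"], 1)   # psi = 0 boundary
  expect_true(std$heywood[std$item == "b"])
})

test_that("the fit is invariant under respondent and item permutation", {
  map <- three_factor_map(6)
  cfg <- generator_config(seed = 31)
  gen <- generate_factor_responses(map, cfg, n = 300)
  fit <- fit_cfa(gen$x, map)
  perm_rows <- withr::with_seed(1, sample(nrow(gen$x)))
  fit_r <- fit_cfa(gen$x[perm_rows, ], map)
  expect_equal(fit_r$loadings, fit$loadings, tolerance = 1e-6)
  expect_equal(fit_r$fml, fit$fml, tolerance = 1e-8)

  perm_items <- c(4, 5, 6, 1, 2, 3)
  map_p <- map[perm_items]
  fit_p <- fit_cfa(gen$x[, perm_items], map_p)
  expect_equal(fit_p$loadings[names(map)], fit$loadings[names(map)],
               tolerance = 1e-6)
})
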