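# Reliability and construct validity of the evaluation scale: Cronbach's
# alpha, and a confirmatory factor analysis in which the third-layer items
# load each on exactly one of the three first-layer dimensions (simple
# structure, correlated factors), fitted by minimising the maximum-likelihood
# discrepancy between the sample and model-implied covariance matrices.
# Identification: factor variances fixed at 1, all loadings free.

#' Cronbach's alpha
#'
#' Internal-consistency reliability of an item set:
#' alpha = p/(p-1) * (1 - sum(item variances) / var(item sum)).
#' Values of 0.7 or above are conventionally satisfactory.
#'
#' @param x n-by-p matrix or data frame of item responses (no missing cells).
#' @param threshold satisfactory-reliability threshold (default 0.7).
#' @return list with `alpha`, `p`, `n` and `flagged` (TRUE when alpha is below
#'   the threshold).
#' @export
cronbach_alpha <- function(x, threshold = 0.7) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2) stop("need at least two items", call. = FALSE)
  if (any(!is.finite(x))) stop("missing cells in response matrix", call. = FALSE)
  total_var <- var(rowSums(x))
  if (total_var <= 0) stop("total-score variance is zero", call. = FALSE)
  item_var <- apply(x, 2, var)
  alpha <- p / (p - 1) * (1 - sum(item_var) / total_var)
  list(alpha = alpha, p = p, n = nrow(x), flagged = alpha < threshold)
}

# Build the p x nf simple-structure loading matrix from a factor map
# (named character vector: item id -> factor id).
loading_matrix <- function(loadings, map, factors = unique(unname(map))) {
  p <- length(map)
  L <- matrix(0, p, length(factors),
              dimnames = list(names(map), factors))
  L[cbind(seq_len(p), match(unname(map), factors))] <- loadings
  L
}

#' Model-implied covariance of a simple-structure factor model
#'
#' Sigma = Lambda Phi Lambda' + Psi, with Lambda the p-by-nf loading matrix
#' (one free loading per item), Phi the factor correlation matrix (unit
#' diagonal) and Psi the diagonal matrix of error variances.
#'
#' @param loadings numeric vector of loadings, one per item, in map order.
#' @param factor_corr nf-by-nf factor correlation matrix (positive definite).
#' @param error_vars numeric vector of error variances, one per item.
#' @param map named character vector mapping item id to factor id.
#' @return the p-by-p implied covariance matrix.
#' @export
implied_covariance <- function(loadings, factor_corr, error_vars, map) {
  ev <- tryCatch(chol(factor_corr), error = function(e) NULL)
  if (is.null(ev)) stop("factor correlation matrix is not positive definite",
                        call. = FALSE)
  factors <- colnames(factor_corr)
  if (is.null(factors)) factors <- unique(unname(map))
  L <- loading_matrix(loadings, map, factors)
  Sigma <- L %*% factor_corr %*% t(L) + diag(error_vars, nrow = length(map))
  dimnames(Sigma) <- list(names(map), names(map))
  Sigma
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p. Nonnegative, and zero iff
#' S = Sigma.
#'
#' @param S sample covariance matrix (symmetric positive definite).
#' @param Sigma implied covariance matrix (symmetric positive definite).
#' @return the scalar discrepancy.
#' @export
ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  if (!all(dim(S) == dim(Sigma))) stop("dimension mismatch", call. = FALSE)
  cS <- tryCatch(chol(S), error = function(e) NULL)
  cSig <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cS) || is.null(cSig)) {
    stop("covariance matrix not positive definite (condition problem)",
         call. = FALSE)
  }
  logdetS <- 2 * sum(log(diag(cS)))
  logdetSig <- 2 * sum(log(diag(cSig)))
  Sinv_ <- chol2inv(cSig)
  logdetSig + sum(S * Sinv_) - logdetS - p
}

# Pack/unpack the unconstrained parameter vector:
# [lambda (p), log psi (p), atanh phi (nf*(nf-1)/2, lower triangle by column)]
unpack_theta <- function(theta, p, nf) {
  lambda <- theta[seq_len(p)]
  psi <- exp(theta[p + seq_len(p)])
  z <- theta[2 * p + seq_len(nf * (nf - 1) / 2)]
  Phi <- diag(nf)
  Phi[lower.tri(Phi)] <- tanh(z)
  Phi[upper.tri(Phi)] <- t(Phi)[upper.tri(Phi)]
  list(lambda = lambda, psi = psi, Phi = Phi)
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimises [ml_discrepancy()] between the sample covariance (n - 1
#' denominator) and the implied covariance of the simple-structure model over
#' the free parameters: one loading and one error variance per item and the
#' factor correlations. Error variances are optimised on the log scale and
#' correlations through atanh, so the solution is always admissible
#' (psi > 0, |phi| < 1). Quasi-Newton (BFGS) with analytic gradients; start
#' values lambda = 0.5 sd(item), psi = 0.5 var(item), Phi = identity.
#'
#' @param x n-by-p matrix or data frame of item responses; columns named by
#'   item id.
#' @param map named character vector mapping each item id to its factor id.
#' @param max_iter iteration cap (default 1000).
#' @return object of class `cfa_fit`: `loadings`, `error_vars`, `factor_corr`,
#'   `implied`, `S`, `n`, `fml`, `converged`, `iterations`, `map`.
#' @export
fit_cfa <- function(x, map, max_iter = 1000) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- names(map)
  x <- x[, names(map), drop = FALSE]
  n <- nrow(x)
  if (n <= length(map)) {
    warning("sample size n = ", n, " does not exceed the number of items p = ",
            length(map), "; ML fit may be unstable", call. = FALSE)
  }
  S <- stats::cov(x)
  fit_cfa_cov(S, n, map, max_iter = max_iter)
}

#' Fit a confirmatory factor model from a covariance matrix
#'
#' Same model and optimiser as [fit_cfa()], starting from a sample covariance
#' matrix directly.
#'
#' @param S p-by-p sample covariance matrix with item ids as dimnames.
#' @param n sample size behind S.
#' @param map named character vector mapping each item id to its factor id.
#' @param max_iter iteration cap.
#' @return a `cfa_fit` object, see [fit_cfa()].
#' @export
fit_cfa_cov <- function(S, n, map, max_iter = 1000) {
  S <- as.matrix(S)
  if (!is.null(dimnames(S))) S <- S[names(map), names(map), drop = FALSE]
  p <- length(map)
  factors <- unique(unname(map))
  nf <- length(factors)
  fidx <- match(unname(map), factors)
  npair <- nf * (nf - 1) / 2
  pair_idx <- which(lower.tri(diag(nf)), arr.ind = TRUE)
  item_var <- diag(S)

  big <- 1e10
  objective <- function(theta) {
    par <- unpack_theta(theta, p, nf)
    L <- loading_matrix(par$lambda, map, factors)
    Sigma <- L %*% par$Phi %*% t(L) + diag(par$psi, p)
    cSig <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(cSig)) return(big)
    Sinv_ <- chol2inv(cSig)
    2 * sum(log(diag(cSig))) + sum(S * Sinv_) - logdetS - p
  }
  gradient <- function(theta) {
    par <- unpack_theta(theta, p, nf)
    L <- loading_matrix(par$lambda, map, factors)
    Sigma <- L %*% par$Phi %*% t(L) + diag(par$psi, p)
    cSig <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(cSig)) return(rep(0, length(theta)))
    SigInv <- chol2inv(cSig)
    G <- SigInv - SigInv %*% S %*% SigInv   # dF/dSigma
    GLP <- G %*% L %*% par$Phi
    g_lambda <- 2 * GLP[cbind(seq_len(p), fidx)]
    g_logpsi <- diag(G) * par$psi
    LtGL <- t(L) %*% G %*% L
    g_z <- numeric(npair)
    if (npair > 0) {
      phi_lt <- par$Phi[lower.tri(par$Phi)]
      g_z <- 2 * LtGL[pair_idx] * (1 - phi_lt^2)
    }
    c(g_lambda, g_logpsi, g_z)
  }

  cS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(cS)) stop("sample covariance matrix is not positive definite",
                        call. = FALSE)
  logdetS <- 2 * sum(log(diag(cS)))

  theta0 <- c(0.5 * sqrt(item_var), log(0.5 * item_var), rep(0, npair))
  opt <- optim(theta0, objective, gradient, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-14))
  # polish: restart once from the solution to tighten the gradient
  opt2 <- optim(opt$par, objective, gradient, method = "BFGS",
                control = list(maxit = max_iter, reltol = 1e-14))
  if (opt2$value <= opt$value) opt <- opt2

  par <- unpack_theta(opt$par, p, nf)
  gnorm <- max(abs(gradient(opt$par)))
  converged <- is.finite(opt$value) && opt$value < big / 2 && gnorm < 1e-5
  dimnames(par$Phi) <- list(factors, factors)
  Sigma <- implied_covariance(par$lambda, par$Phi, par$psi, map)
  structure(list(
    loadings = setNames(par$lambda, names(map)),
    error_vars = setNames(par$psi, names(map)),
    factor_corr = par$Phi,
    implied = Sigma, S = S, n = n, map = map,
    fml = opt$value, converged = converged,
    gradient_norm = gnorm,
    iterations = unname(opt$counts["function"])
  ), class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("<cfa_fit: %d items, %d factors, F_ML = %.6g, %s>\n",
              length(x$map), ncol(x$factor_corr), x$fml,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Absolute fit indices for a fitted confirmatory factor model
#'
#' CMIN = (n - 1) F_ML with df = p(p+1)/2 minus the number of free parameters
#' (2p loadings/error variances + nf(nf-1)/2 factor correlations); SRMR is the
#' root mean square of the correlation-metric residuals
#' (s_ij - sigma_ij)/sqrt(s_ii s_jj) over the p(p+1)/2 unique elements
#' (diagonal included). CMIN/df below 3 is classified widely acceptable,
#' below 5 debatable, otherwise poor; SRMR is acceptable when it rounds to the
#' threshold (0.08 by default) or below.
#'
#' @param fit a `cfa_fit`.
#' @param n sample size (defaults to the fit's).
#' @param thresholds list with `cmin_df` (c(3, 5)) and `srmr` (0.08).
#' @return list with `cmin`, `df`, `cmin_df`, `srmr`, `cmin_df_class`,
#'   `srmr_acceptable`, `saturated`.
#' @export
fit_indices <- function(fit, n = fit$n,
                        thresholds = list(cmin_df = c(3, 5), srmr = 0.08)) {
  p <- length(fit$map)
  nf <- ncol(fit$factor_corr)
  df <- p * (p + 1) / 2 - (2 * p + nf * (nf - 1) / 2)
  cmin <- (n - 1) * fit$fml
  S <- fit$S
  Sigma <- fit$implied
  d <- sqrt(diag(S))
  resid <- (S - Sigma) / tcrossprod(d)
  srmr <- sqrt(mean(resid[upper.tri(resid, diag = TRUE)]^2))
  saturated <- df <= 0
  cmin_df <- if (saturated) NA_real_ else cmin / df
  cmin_df_class <- if (saturated) "saturated"
    else if (cmin_df < thresholds$cmin_df[1]) "acceptable"
    else if (cmin_df < thresholds$cmin_df[2]) "debatable"
    else "poor"
  list(cmin = cmin, df = df, cmin_df = cmin_df, srmr = srmr,
       cmin_df_class = cmin_df_class,
       srmr_acceptable = round_half_up(srmr, 2) <= thresholds$srmr,
       saturated = saturated)
}

#' Standardized factor loadings
#'
#' With unit factor variances, the standardized loading of item j is
#' lambda_j / sqrt(lambda_j^2 + psi_j): the item's correlation with its
#' factor. Items with non-positive error variance are flagged as Heywood
#' cases.
#'
#' @param fit a `cfa_fit`.
#' @return tibble with `item`, `factor`, `loading`, `std_loading`, `heywood`.
#' @export
standardized_loadings <- function(fit) {
  lam <- fit$loadings
  psi <- fit$error_vars
  tibble::tibble(
    item = names(fit$map),
    factor = unname(fit$map),
    loading = unname(lam),
    std_loading = unname(lam / sqrt(lam^2 + pmax(psi, 0))),
    heywood = unname(psi <= 0)
  )
}
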