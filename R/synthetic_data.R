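# Seeded generators emulating the statistical structure of a competency-
# weighted two-round Delphi study and its validation survey: an expert panel
# of ~51 with competency scores in 51..89, importance ratings concentrated
# high on a 10-point scale (weighted means ~7.75-9.76, CVs ~0.05-0.21), and
# item responses from a three-correlated-factor latent model with
# standardized loadings ~0.46-0.91. All generators are pure functions of
# (config, seed).

#' Default generator configuration
#'
#' The defaults describe the study conditions the pipeline is designed for:
#' a panel of 51 experts whose competency sub-scores sum into 51..89; true
#' indicator importances drawn uniformly in 8..9.8 (so all indicators clear
#' the screening thresholds, as in a consensus panel); rater noise sd 0.8 on
#' the 10-point scale; no deletion votes; and standardized factor loadings in
#' 0.46..0.91 with inter-dimension correlations around 0.6.
#'
#' @param seed integer seed.
#' @param n_experts panel size.
#' @return a list of generator settings.
#' @export
generator_config <- function(seed = 1L, n_experts = 51L) {
  list(
    seed = as.integer(seed),
    n_experts = as.integer(n_experts),
    # per-dimension competency sub-score bounds (sums to [51, 89])
    competency_bounds = list(
      background = c(4, 9), knowhow = c(8, 18),
      anchored_behavior = c(33, 52), engagement = c(6, 10)
    ),
    importance_range = c(8, 9.8),  # true importance mu_j of each indicator
    rater_sd = 0.8,                # sd of rater noise on the Likert scale
    deletion_prob = 0,             # probability of a deletion vote (rating 0)
    loading_range = c(0.46, 0.91), # standardized loadings for factor data
    factor_corr = 0.6,             # common inter-factor correlation
    likert = FALSE                 # discretise factor responses to 1..10?
  )
}

#' Generate a synthetic expert panel
#'
#' Draws each competency sub-score uniformly within its configured bounds, so
#' total scores fall in the configured range and the whole panel clears the
#' inclusion threshold.
#'
#' @param config a [generator_config()].
#' @return tibble of expert profiles (one row per expert).
#' @export
generate_panel <- function(config = generator_config()) {
  b <- config$competency_bounds
  for (dim in names(COMPETENCY_CAPS)) {
    if (b[[dim]][1] < 0 || b[[dim]][2] > COMPETENCY_CAPS[[dim]] ||
        b[[dim]][1] > b[[dim]][2]) {
      stop("infeasible competency bounds for dimension '", dim, "'",
           call. = FALSE)
    }
  }
  n <- config$n_experts
  withr::with_seed(config$seed, {
    tibble::tibble(
      expert_id = sprintf("E%02d", seq_len(n)),
      background = runif(n, b$background[1], b$background[2]),
      knowhow = runif(n, b$knowhow[1], b$knowhow[2]),
      anchored_behavior = runif(n, b$anchored_behavior[1],
                                b$anchored_behavior[2]),
      engagement = runif(n, b$engagement[1], b$engagement[2])
    )
  })
}

#' Generate true indicator importances
#'
#' One true importance mu_j per active indicator, uniform in the configured
#' range (defaults keep every indicator above the screening thresholds).
#'
#' @param tree an `indicator_tree`.
#' @param config a [generator_config()].
#' @return named numeric vector of mu_j over active indicators.
#' @export
generate_importances <- function(tree, config = generator_config()) {
  ids <- active_indicators(tree)$id
  withr::with_seed(config$seed + 1L, {
    setNames(runif(length(ids), config$importance_range[1],
                   config$importance_range[2]), ids)
  })
}

#' Generate a Delphi rating table
#'
#' Each rating is clamp(round(mu_j + eps), 1, 10) with eps ~ N(0, sd^2);
#' deletion votes (rating 0) replace ratings independently with the
#' configured probability. Every panel expert rates every active indicator.
#'
#' @param tree an `indicator_tree`.
#' @param panel a panel from [select_panel()].
#' @param config a [generator_config()].
#' @param round round number to stamp on the records.
#' @param importances optional named vector of true importances; generated
#'   from the config when missing.
#' @return long-form rating tibble (`expert_id`, `indicator_id`, `round`,
#'   `rating`).
#' @export
generate_delphi_ratings <- function(tree, panel, config = generator_config(),
                                    round = 1L, importances = NULL) {
  if (is.null(importances)) importances <- generate_importances(tree, config)
  ids <- active_indicators(tree)$id
  experts <- panel$included$expert_id
  grid <- expand.grid(expert_id = experts, indicator_id = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withr::with_seed(config$seed + 100L * round, {
    mu <- importances[grid$indicator_id]
    rating <- pmin(pmax(round(mu + rnorm(nrow(grid), 0, config$rater_sd)), 1), 10)
    if (config$deletion_prob > 0) {
      del <- runif(nrow(grid)) < config$deletion_prob
      rating[del] <- 0
    }
    tibble::tibble(expert_id = grid$expert_id,
                   indicator_id = grid$indicator_id,
                   round = as.integer(round),
                   rating = as.integer(rating))
  })
}

#' Generate item responses from a correlated-factor model
#'
#' Responses follow x_i = Lambda f_i + eps_i with f ~ N(0, Phi) and
#' independent normal errors. In standardized mode (the default), loadings are
#' drawn in the configured range and error variances are 1 - lambda^2, so the
#' population item variances are 1 and the loadings are the standardized ones.
#' An optional Likert mode shifts responses onto the 1..10 scale and rounds.
#'
#' @param map named character vector mapping item id to factor id.
#' @param config a [generator_config()].
#' @param n number of respondents.
#' @param loadings optional named vector of true loadings (drawn when absent).
#' @param factor_corr optional factor correlation matrix (defaults to the
#'   config's common correlation).
#' @return list with `x` (n-by-p matrix), `loadings`, `factor_corr`.
#' @export
generate_factor_responses <- function(map, config = generator_config(),
                                      n = 500L, loadings = NULL,
                                      factor_corr = NULL) {
  factors <- unique(unname(map))
  nf <- length(factors)
  p <- length(map)
  if (is.null(factor_corr)) {
    factor_corr <- matrix(config$factor_corr, nf, nf)
    diag(factor_corr) <- 1
    dimnames(factor_corr) <- list(factors, factors)
  }
  cP <- tryCatch(chol(factor_corr), error = function(e) NULL)
  if (is.null(cP)) stop("factor correlation matrix is not positive definite",
                        call. = FALSE)
  withr::with_seed(config$seed + 7L, {
    if (is.null(loadings)) {
      loadings <- setNames(runif(p, config$loading_range[1],
                                 config$loading_range[2]), names(map))
    }
    psi <- 1 - loadings^2
    if (any(psi <= 0)) stop("standardized loadings must lie in (0, 1)",
                            call. = FALSE)
    L <- loading_matrix(loadings, map, factors)
    f <- matrix(rnorm(n * nf), n, nf) %*% cP
    x <- f %*% t(L) + matrix(rnorm(n * p), n, p) %*% diag(sqrt(psi), p)
    colnames(x) <- names(map)
    if (isTRUE(config$likert)) {
      x <- pmin(pmax(round(8.5 + 1.2 * x), 1), 10)
    }
  })
  list(x = x, loadings = loadings, factor_corr = factor_corr)
}
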