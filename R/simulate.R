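#' Configuration for synthetic trees and traits
#'
#' Bundles and validates the ground-truth parameters of a simulation:
#' tree size and pure-birth branching rate, regression coefficients,
#' Pagel's lambda and error variance of the trait model, whether to map
#' traits onto life-history-like magnitudes, and the seed.
#'
#' @param n_tips Number of tips (>= 3). Default 31, the study's sample size.
#' @param branching_rate Pure-birth speciation rate (> 0); tree depth is
#'   rescaled to 1 afterwards, so this only shapes the topology/node times.
#' @param true_beta Length-2 vector `(intercept, slope)` of the trait model.
#' @param true_lambda Pagel's lambda of the error covariance, in `[0, 1]`.
#' @param true_sigma2 Error variance (> 0, or 0 for a noiseless check).
#' @param life_history Map simulated traits onto Table-1-like magnitudes
#'   (lifespans in days, rearing periods, bounded percentages).
#' @param seed Integer seed; same seed, same output.
#' @return A validated list of class `synthetic_config`.
#' @export
syntheticConfig <- function(n_tips = 31L, branching_rate = 1,
                            true_beta = c(0, 1), true_lambda = 1,
                            true_sigma2 = 1, life_history = FALSE,
                            seed = 1L) {
  stopifnot(n_tips >= 3, branching_rate > 0,
            length(true_beta) == 2, all(is.finite(true_beta)),
            true_lambda >= 0, true_lambda <= 1,
            true_sigma2 >= 0, is.finite(seed))
  structure(list(n_tips = as.integer(n_tips),
                 branching_rate = branching_rate,
                 true_beta = true_beta, true_lambda = true_lambda,
                 true_sigma2 = true_sigma2,
                 life_history = isTRUE(life_history),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(state))
    assign(".Random.seed", state, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate an ultrametric pure-birth tree
#'
#' Draws a Yule (pure-birth) tree with `cfg$n_tips` tips at rate
#' `cfg$branching_rate` and rescales all branch lengths so the root-to-tip
#' depth is exactly 1. Tips are labelled `t1 ... tn`.
#'
#' @param cfg A `synthetic_config`.
#' @return An ultrametric `phylo`.
#' @export
simulateTree <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  tr <- .withSeed(cfg$seed,
                  ape::rphylo(cfg$n_tips, birth = cfg$branching_rate,
                              death = 0))
  depth <- max(.nodeDepths(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}

#' Simulate tip traits under the PGLS generating model
#'
#' The predictor `x` evolves by Brownian motion on the tree (mean 0, unit
#' rate): `x ~ N(0, C)`. The response is `y = b0 + b1 x + e` with
#' `e ~ N(0, sigma2 * C(lambda))`; both draws go through the Cholesky
#' factor of the respective covariance. With `cfg$life_history = TRUE` the
#' pair is additionally mapped, monotonically, onto magnitudes like those
#' of the study table: lifespans in [700, 22000] days, rearing periods in
#' [15, 2000] days and strictly below 95% of lifespan, and a bounded
#' percentage score in (0, 100).
#'
#' @param tree A `phylo` (typically from [simulateTree()]).
#' @param cfg A `synthetic_config`; `cfg$seed + 1` seeds the trait draw so
#'   tree and traits are independently reproducible.
#' @return A data frame with columns `species`, `x`, `y`, and in
#'   life-history mode also `lifespan_days`, `fw_days`, `cylinder_pct`.
#' @export
simulateTraits <- function(tree, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  C <- phyloVCV(tree)
  V <- cfg$true_sigma2 * lambdaTransform(C, cfg$true_lambda)
  n <- nrow(C)
  Ux <- chol(C)
  draw <- .withSeed(cfg$seed + 1L, {
    zx <- stats::rnorm(n)
    ze <- stats::rnorm(n)
    list(x = as.vector(crossprod(Ux, zx)),
         e = if (cfg$true_sigma2 == 0) numeric(n)
             else as.vector(crossprod(chol(V), ze)))
  })
  x <- draw$x
  y <- cfg$true_beta[1] + cfg$true_beta[2] * x + draw$e
  out <- data.frame(species = tree$tip.label, x = x, y = y,
                    stringsAsFactors = FALSE)
  if (cfg$life_history) {
    rng <- function(v) if (diff(range(v)) == 0) rep(0.5, length(v)) else
      (v - min(v)) / diff(range(v))
    lifespan <- pmin(pmax(exp(log(700) + rng(x) * (log(22000) - log(700))),
                          700), 22000)
    frac <- 0.005 + 0.24 * rng(y)          # rearing as a fraction of life
    fw <- pmin(pmax(lifespan * frac, 15), 2000, 0.95 * lifespan)
    out$lifespan_days <- lifespan
    out$fw_days <- fw
    out$cylinder_pct <- 100 * stats::plogis((y - mean(y)) /
                                            max(stats::sd(y), 1e-12))
  }
  out
}

#' Parameter-recovery experiment
#'
#' For each cell of a grid of true `(lambda, beta1)` values, simulates
#' `nReps` independent tree + trait datasets, fits the maximum-likelihood
#' PGLS, and summarizes estimator performance: mean, bias, RMSE and the
#' Monte-Carlo standard error of the slope estimate, the mean and RMSE of
#' lambda-hat, and the fraction of slope t-tests rejecting at `alpha`
#' (type-I error when `beta1 = 0`, power otherwise). Per-replicate seeds
#' derive deterministically from `baseSeed`, the cell index and the
#' replicate index. Failed fits are counted, not fatal.
#'
#' @param lambdas True lambda values (grid dimension 1).
#' @param beta1s True slope values (grid dimension 2).
#' @param nTips Tips per simulated tree.
#' @param nReps Replicates per cell.
#' @param baseSeed Base seed (keep small; derived seeds stay below 2^31).
#' @param sigma2 True error variance.
#' @param alpha Nominal level of the slope t-test.
#' @return Data frame, one row per cell.
#' @export
recoveryExperiment <- function(lambdas = c(0, 1), beta1s = 1, nTips = 100L,
                               nReps = 200L, baseSeed = 1L, sigma2 = 1,
                               alpha = 0.05) {
  cells <- expand.grid(lambda = lambdas, beta1 = beta1s,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    lam <- cells$lambda[ci]; b1 <- cells$beta1[ci]
    b1hat <- lamhat <- pslope <- rep(NA_real_, nReps)
    fails <- 0L
    for (r in seq_len(nReps)) {
      seed <- baseSeed + ci * 100000L + r
      cfg <- syntheticConfig(n_tips = nTips, true_beta = c(0, b1),
                             true_lambda = lam, true_sigma2 = sigma2,
                             seed = seed)
      res <- tryCatch({
        tr <- simulateTree(cfg)
        d <- simulateTraits(tr, cfg)
        C <- phyloVCV(tr)
        X <- designMatrix(x = stats::setNames(d$x, d$species))
        pglsFit(stats::setNames(d$y, d$species), X, C, lambda = "ML")
      }, error = function(e) NULL)
      if (is.null(res)) { fails <- fails + 1L; next }
      b1hat[r] <- res$coefficients[2]
      lamhat[r] <- res$lambda_hat
      pslope[r] <- res$p_values[2]
    }
    ok <- !is.na(b1hat)
    data.frame(lambda_true = lam, beta1_true = b1,
               n_tips = nTips, n_reps = nReps, n_fail = fails,
               beta1_mean = mean(b1hat[ok]),
               beta1_bias = mean(b1hat[ok]) - b1,
               beta1_rmse = sqrt(mean((b1hat[ok] - b1)^2)),
               beta1_se_mc = stats::sd(b1hat[ok]) / sqrt(sum(ok)),
               lambda_mean = mean(lamhat[ok]),
               lambda_rmse = sqrt(mean((lamhat[ok] - lam)^2)),
               reject_rate = mean(pslope[ok] < alpha))
  })
  do.call(rbind, rows)
}
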