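#' Descriptive summary of a trait vector
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and
#' maximum, at full precision; rounding is a reporting concern.
#'
#' @param x Numeric vector, length >= 2.
#' @return List with `n`, `mean`, `sd`, `min`, `max`.
#' @export
summarizeTrait <- function(x) {
  if (length(x) < 2L || any(!is.finite(x)))
    stop("need at least 2 finite values")
  list(n = length(x), mean = mean(x), sd = stats::sd(x),
       min = min(x), max = max(x))
}

#' Lilliefors normality statistic
#'
#' The Kolmogorov-Smirnov distance between the empirical CDF and the normal
#' CDF with mean and standard deviation estimated from the sample
#' (Lilliefors' correction). Both one-sided gaps are evaluated at every
#' order statistic:
#' `D = max_i max(i/n - F(x_(i)), F(x_(i)) - (i-1)/n)`.
#'
#' @param x Numeric vector, length >= 4, non-constant.
#' @return The statistic `D` in `[0, 1]`.
#' @export
lillieforsD <- function(x) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  s <- stats::sd(x)
  if (s == 0) stop("zero standard deviation; statistic undefined")
  Fh <- stats::pnorm(sort(x), mean = mean(x), sd = s)
  i <- seq_len(n)
  max(i / n - Fh, Fh - (i - 1) / n)
}

#' Monte-Carlo critical value of the Lilliefors statistic
#'
#' Simulates the null distribution of [lillieforsD()] (standard normal
#' samples of size `n`; the statistic is location-scale invariant) with a
#' fixed internal seed, so repeated calls agree. Results are cached per
#' `(n, nsim)` within a session.
#'
#' @param n Sample size.
#' @param alpha Upper-tail probability level(s).
#' @param nsim Number of null replicates (default 20000).
#' @return Critical value(s) `d` with `P(D > d) = alpha` under normality.
#' @export
lillieforsCrit <- function(n, alpha = c(0.20, 0.15, 0.10, 0.05, 0.01),
                           nsim = 20000) {
  key <- paste0("n", n, "_s", nsim)
  if (is.null(.lillieCache[[key]])) {
    state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(state))
      assign(".Random.seed", state, envir = globalenv()))
    set.seed(1836547)
    zs <- matrix(stats::rnorm(n * nsim), nrow = n)
    .lillieCache[[key]] <- sort(apply(zs, 2, lillieforsD))
  }
  d0 <- .lillieCache[[key]]
  stats::quantile(d0, probs = 1 - alpha, names = FALSE, type = 8)
}

.lillieCache <- new.env(parent = emptyenv())

#' Report a Lilliefors p-value bound
#'
#' Classifies a Lilliefors `D` against the critical values at the
#' conventional table levels (0.20, 0.15, 0.10, 0.05, 0.01) and returns a
#' textual bound, e.g. `"P < 0.010"` or `"P > 0.200"` — the granularity at
#' which such results are conventionally printed.
#'
#' @param D Statistic from [lillieforsD()].
#' @param n Sample size it was computed from.
#' @return A string bound.
#' @export
lillieforsBound <- function(D, n) {
  alphas <- c(0.20, 0.15, 0.10, 0.05, 0.01)
  crit <- lillieforsCrit(n, alphas)
  exceeded <- which(D > crit)
  if (!length(exceeded)) return("P > 0.200")
  sprintf("P < %.3f", alphas[max(exceeded)])
}

#' Count values satisfying a threshold comparison
#'
#' @param x Numeric vector.
#' @param op One of `">"`, `">="`, `"<"`, `"<="`.
#' @param threshold Comparison value.
#' @return Integer count.
#' @export
countWhere <- function(x, op = c(">", ">=", "<", "<="), threshold) {
  op <- match.arg(op)
  sum(get(op)(x, threshold))
}

#' Descriptive and normality statistics for the study traits
#'
#' One row per raw trait column (cylinder %, fledge/wean days, lifespan
#' days): n, mean, SD, min, max, the Lilliefors statistic and its p-value
#' bound.
#'
#' @param table A `trait_table` from [loadTraitTable()].
#' @return A data frame, one row per trait.
#' @export
descriptivesTable <- function(table) {
  cols <- c(cylinder_pct = "cylinder_pct", fw_days = "fw_days",
            lifespan_days = "lifespan_days")
  rows <- lapply(names(cols), function(nm) {
    x <- table[[cols[[nm]]]]
    s <- summarizeTrait(x)
    D <- lillieforsD(x)
    data.frame(trait = nm, n = s$n, mean = s$mean, sd = s$sd,
               min = s$min, max = s$max, ks_D = D,
               ks_p_bound = lillieforsBound(D, s$n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
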