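#' Generalized least squares under a phylogenetic covariance
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * C(lambda))`, where `C(lambda)`
#' is the Pagel-transformed phylogenetic variance-covariance matrix. With
#' `lambda = "ML"` (the default) the transform parameter is estimated by
#' maximizing the profile log-likelihood over `[0, 1]`; a numeric `lambda`
#' fixes it. `lambda = 0` reproduces ordinary least squares, `lambda = 1`
#' the pure Brownian-motion fit.
#'
#' The computation goes through the Cholesky factor of `C(lambda)`: both
#' sides of the model are rotated into an i.i.d. error space and solved by
#' QR, never by explicit matrix inversion. Two error-variance estimates are
#' kept: `sigma2_ml = e'V^{-1}e / n` (enters the likelihood) and
#' `sigma2_resid = e'V^{-1}e / (n - p)` (enters standard errors, as in
#' conventional PGLS software).
#'
#' `r2` is the generalized R-squared
#' `1 - (e'V^{-1}e) / ((y - mu)'V^{-1}(y - mu))` where `mu` is the GLS
#' (phylogenetic) mean of `y` under the same `V`, so that at `lambda = 0`
#' it coincides with the textbook OLS R-squared.
#'
#' @param y Named numeric response vector (names = species), or unnamed and
#'   aligned with `rownames(C)`.
#' @param X Design matrix with named columns including an intercept column,
#'   rows aligned with `y`. Use [designMatrix()] to build one. `NULL` fits
#'   an intercept-only model.
#' @param C Phylogenetic covariance matrix with `dimnames`.
#' @param lambda `"ML"` or a number in `[0, 1]`.
#' @param gridStep Step of the coarse profile pre-scan preceding local
#'   refinement of `lambda`. Default 0.01.
#' @return An object of class `pgls_fit`; see Details for fields.
#'
#' @details Fields of the returned object: `coefficients`, `std_errors`,
#' `t_values`, `p_values` (two-sided, t distribution on `df_resid = n - p`
#' degrees of freedom), `sigma2_ml`, `sigma2_resid`, `lambda_hat`,
#' `log_lik`, `r2`, `r2_adj`, `fitted`, `resid_raw` (`y - X beta`),
#' `resid_std` (standardized, see [standardizedResiduals()]),
#' `resid_phylo_student` and `outlier_flags` (see
#' [studentizedPhyloResiduals()]), plus the inputs needed by the
#' diagnostic helpers.
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' C <- phyloVCV(tr)
#' y <- c(A = 1, B = 1, C = 4)
#' fit <- pglsFit(y, NULL, C, lambda = 1)
#' coef(fit)  # phylogenetic mean 16/7
#' @export
pglsFit <- function(y, X = NULL, C, lambda = "ML", gridStep = 0.01) {
  .checkVCV(C)
  sp <- rownames(C)
  n <- length(y)
  if (n != nrow(C)) stop("length(y) must match nrow(C)")
  if (!is.null(names(y)) && !is.null(sp)) {
    if (!setequal(names(y), sp)) stop("names(y) do not match rownames(C)")
    y <- y[sp]
  }
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(sp, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("nrow(X) must match length(y)")
    if (!is.null(rownames(X)) && !is.null(sp)) {
      if (!setequal(rownames(X), sp)) stop("rownames(X) do not match C")
      X <- X[sp, , drop = FALSE]
    }
    if (is.null(colnames(X)))
      colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  }
  p <- ncol(X)
  if (n <= p) stop("need n > p observations")
  if (qr(X)$rank < p)
    stop("design matrix is rank deficient; drop collinear or constant predictors")

  if (identical(lambda, "ML")) {
    prof <- .profileLambda(y, X, C, gridStep)
    lam <- prof$lambda
  } else {
    if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
      stop("lambda must be \"ML\" or a single value in [0, 1]")
    lam <- lambda
  }
  g <- .glsAtLambda(y, X, C, lam)

  se <- sqrt(diag(g$XtXinv) * g$sigma2_resid)
  tval <- g$beta / se
  df <- n - p
  pval <- 2 * stats::pt(-abs(tval), df)

  # generalized R2 against the GLS-mean-only model under the same V
  ot <- backsolve(g$U, rep(1, n), transpose = TRUE)
  yt <- g$yt
  mu <- sum(ot * yt) / sum(ot * ot)
  tss <- sum((yt - ot * mu)^2)
  if (tss <= 0 && g$rss > 0)
    stop("zero total GLS sum of squares; R-squared undefined")
  r2 <- if (tss == 0) 1 else 1 - g$rss / tss
  r2adj <- 1 - (1 - r2) * (n - 1) / (n - p)

  fit <- structure(list(
    coefficients = stats::setNames(g$beta, colnames(X)),
    std_errors = stats::setNames(se, colnames(X)),
    t_values = stats::setNames(tval, colnames(X)),
    p_values = stats::setNames(pval, colnames(X)),
    df_resid = df,
    sigma2_ml = g$sigma2_ml,
    sigma2_resid = g$sigma2_resid,
    lambda_hat = lam,
    lambda_mode = if (identical(lambda, "ML")) "ML" else "fixed",
    log_lik = g$loglik,
    r2 = r2,
    r2_adj = r2adj,
    fitted = stats::setNames(g$fitted, sp),
    resid_raw = stats::setNames(g$resid, sp),
    species = sp,
    y = stats::setNames(y, sp),
    X = X,
    C = C,
    V = g$V,
    U = g$U
  ), class = "pgls_fit")
  fit$resid_std <- standardizedResiduals(fit)
  stud <- studentizedPhyloResiduals(fit)
  fit$resid_phylo_student <- stud$values
  fit$outlier_flags <- stud$flags
  fit
}

# residuals indistinguishable from exact zero at double precision
.allNegligible <- function(e, y) {
  all(abs(e) <= 1e-10 * max(abs(y), 1))
}

# GLS components at a fixed lambda, via Cholesky rotation + QR
.glsAtLambda <- function(y, X, C, lam) {
  V <- lambdaTransform(C, lam)
  U <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is singular at lambda = ", signif(lam, 6),
         "; jitter near-identical tips or prune duplicates", call. = FALSE))
  if (min(diag(U))^2 <= 1e-10 * max(diag(V)))
    stop("covariance matrix is numerically singular at lambda = ",
         signif(lam, 6),
         "; jitter near-identical tips or prune duplicates", call. = FALSE)
  Xt <- backsolve(U, X, transpose = TRUE)
  yt <- backsolve(U, y, transpose = TRUE)
  qf <- qr(Xt)
  beta <- qr.coef(qf, yt)
  rs <- yt - Xt %*% beta
  rss <- sum(rs^2)
  n <- length(y); p <- ncol(X)
  logdet <- 2 * sum(log(diag(U)))
  s2ml <- rss / n
  loglik <- if (rss == 0) Inf else
    -0.5 * (n * log(2 * pi * s2ml) + logdet + n)
  R <- qr.R(qf)
  XtXinv <- chol2inv(R)
  list(beta = as.vector(beta), rss = rss, sigma2_ml = s2ml,
       sigma2_resid = rss / (n - p), loglik = loglik,
       fitted = as.vector(X %*% beta), resid = as.vector(y - X %*% beta),
       XtXinv = XtXinv, U = U, V = V, Xt = Xt, yt = as.vector(yt))
}

# profile log-likelihood of lambda; coarse grid pre-scan then Brent
.profileLambda <- function(y, X, C, gridStep = 0.01, tol = 1e-6) {
  ll <- function(lam) .glsAtLambda(y, X, C, lam)$loglik
  grid <- seq(0, 1, by = gridStep)
  lls <- vapply(grid, ll, numeric(1))
  if (any(is.nan(lls) | is.na(lls)))
    stop("non-finite profile log-likelihood at lambda = ",
         grid[which(is.nan(lls) | is.na(lls))[1]])
  i <- which.max(lls)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) return(list(lambda = lo, loglik = lls[i]))
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = tol)
  if (opt$objective >= lls[i])
    list(lambda = opt$maximum, loglik = opt$objective)
  else
    list(lambda = grid[i], loglik = lls[i])
}

#' Profile the lambda log-likelihood on a grid
#'
#' Returns the profile log-likelihood of Pagel's lambda on an explicit
#' grid, mainly for plotting and for verifying the optimizer against a
#' dense grid argmax.
#'
#' @inheritParams pglsFit
#' @param grid Numeric vector of lambda values in `[0, 1]`.
#' @return A data frame with columns `lambda` and `log_lik`.
#' @export
lambdaProfile <- function(y, X, C, grid = seq(0, 1, by = 0.01)) {
  .checkVCV(C)
  if (is.null(X)) X <- matrix(1, length(y), 1,
                              dimnames = list(rownames(C), "(Intercept)"))
  data.frame(lambda = grid,
             log_lik = vapply(grid, function(l)
               .glsAtLambda(y, X, C, l)$loglik, numeric(1)))
}

#' Build a design matrix
#'
#' @param ... Named numeric predictor vectors (all the same length, named by
#'   species or aligned externally).
#' @param species Optional species labels used as rownames.
#' @param intercept Include a leading constant column (default `TRUE`).
#' @return A numeric matrix with named columns, intercept first.
#' @export
designMatrix <- function(..., species = NULL, intercept = TRUE) {
  cols <- list(...)
  if (!length(cols) && !intercept) stop("empty design")
  n <- if (length(cols)) length(cols[[1]]) else length(species)
  X <- do.call(cbind, cols)
  if (intercept) X <- cbind(`(Intercept)` = rep(1, n), X)
  if (is.null(species) && length(cols) && !is.null(names(cols[[1]])))
    species <- names(cols[[1]])
  rownames(X) <- species
  X
}

#' Standardized residuals of a PGLS fit
#'
#' The default `"tipvar"` mode divides each raw residual by its
#' model-implied standard deviation `sqrt(sigma2_resid * C[i, i])`, which
#' accounts for unequal root-to-tip depths. The `"zscore"` mode divides the
#' raw residual vector by its own sample standard deviation. On an
#' ultrametric tree the two differ only by a common scale factor, and all
#' downstream regression statistics that use the residuals as a predictor
#' (t, p, R-squared, lambda-hat) are invariant to that factor.
#'
#' @param fit A `pgls_fit`.
#' @param mode `"tipvar"` (default) or `"zscore"`.
#' @return Named numeric vector of standardized residuals.
#' @export
standardizedResiduals <- function(fit, mode = c("tipvar", "zscore")) {
  mode <- match.arg(mode)
  e <- fit$resid_raw
  if (.allNegligible(e, fit$y)) return(e * 0)
  if (fit$sigma2_resid <= 0 || stats::sd(e) == 0)
    stop("residual variance is zero; standardized residuals undefined")
  switch(mode,
         tipvar = e / sqrt(fit$sigma2_resid * diag(fit$C)),
         zscore = e / stats::sd(e))
}

#' Studentized phylogenetic residuals and outlier flags
#'
#' Rotates the raw residuals by the inverse lower Cholesky factor of the
#' fitted covariance `V = C(lambda_hat)` and internally studentizes them
#' with the hat-matrix leverages of the equivalently rotated design. With
#' an identity covariance this reduces to the classical internally
#' studentized OLS residuals. Values with magnitude at or above
#' `threshold` are flagged as outliers.
#'
#' @param fit A `pgls_fit`.
#' @param threshold Flagging threshold on the absolute value; default 3.
#' @return A list with `values` (named numeric) and `flags` (named logical).
#' @export
studentizedPhyloResiduals <- function(fit, threshold = 3) {
  if (.allNegligible(fit$resid_raw, fit$y)) {
    z <- stats::setNames(numeric(length(fit$resid_raw)), fit$species)
    return(list(values = z, flags = z != 0))
  }
  U <- fit$U
  Xt <- backsolve(U, fit$X, transpose = TRUE)
  et <- backsolve(U, fit$resid_raw, transpose = TRUE)
  qf <- qr(Xt)
  h <- rowSums(qr.Q(qf)[, seq_len(qf$rank), drop = FALSE]^2)
  s <- sqrt(fit$sigma2_resid)
  vals <- as.vector(et) / (s * sqrt(pmax(1 - h, .Machine$double.eps)))
  vals <- stats::setNames(vals, fit$species)
  list(values = vals, flags = abs(vals) >= threshold)
}

#' Diagnostic data for a PGLS fit
#'
#' Numeric coordinates for the two standard residual diagnostics: a normal
#' Q-Q plot of the rotated (phylogenetically whitened) residuals, with
#' theoretical quantiles at `(i - 0.5) / n`, and rotated residuals against
#' fitted values. Rendering is left to the caller.
#'
#' @param fit A `pgls_fit`.
#' @return A list of two data frames, `qq` (columns `theoretical`,
#'   `observed`) and `fitted_resid` (columns `fitted`, `resid_rotated`).
#' @export
diagnosticData <- function(fit) {
  et <- as.vector(backsolve(fit$U, fit$resid_raw, transpose = TRUE))
  n <- length(et)
  qq <- data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
                   observed = sort(et))
  list(qq = qq,
       fitted_resid = data.frame(fitted = as.vector(fit$fitted),
                                 resid_rotated = et))
}

#' @export
print.pgls_fit <- function(x, digits = 4, ...) {
  cat(sprintf("PGLS fit (lambda %s = %.4f), n = %d, df = %d\n",
              x$lambda_mode, x$lambda_hat, length(x$y), x$df_resid))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$std_errors,
               `t value` = x$t_values, `Pr(>|t|)` = x$p_values)
  print(round(tab, digits))
  cat(sprintf("sigma2 (ML) = %.4g, logLik = %.4f\n", x$sigma2_ml, x$log_lik))
  cat(sprintf("R2 = %.4f, adj. R2 = %.4f\n", x$r2, x$r2_adj))
  if (any(x$outlier_flags))
    cat("flagged |studentized residual| >= 3:",
        paste(names(which(x$outlier_flags)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$log_lik, df = length(object$coefficients) + 2,
            class = "logLik")
}

#' @export
residuals.pgls_fit <- function(object,
                               type = c("raw", "standardized", "studentized"),
                               ...) {
  type <- match.arg(type)
  switch(type,
         raw = object$resid_raw,
         standardized = object$resid_std,
         studentized = object$resid_phylo_student)
}

#' @export
fitted.pgls_fit <- function(object, ...) object$fitted

#' Serialize a PGLS fit
#'
#' `pglsFitTable()` returns the coefficient table as a data frame (one row
#' per term: estimate, se, t, df, p); `writePglsTsv()` writes it as TSV;
#' `pglsReport()` returns a list ready for JSON serialization with full
#' precision (lambda-hat, log-likelihood, R-squared and per-tip residuals).
#'
#' @param fit A `pgls_fit`.
#' @return See description.
#' @export
pglsFitTable <- function(fit) {
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$std_errors),
             t = unname(fit$t_values),
             df = fit$df_resid,
             p = unname(fit$p_values),
             stringsAsFactors = FALSE)
}

#' @rdname pglsFitTable
#' @param path Output file path.
#' @export
writePglsTsv <- function(fit, path) {
  utils::write.table(pglsFitTable(fit), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pglsFitTable
#' @export
pglsReport <- function(fit) {
  list(coefficients = as.list(fit$coefficients),
       std_errors = as.list(fit$std_errors),
       t_values = as.list(fit$t_values),
       p_values = as.list(fit$p_values),
       df_resid = fit$df_resid,
       lambda_hat = fit$lambda_hat,
       sigma2_ml = fit$sigma2_ml,
       sigma2_resid = fit$sigma2_resid,
       log_lik = fit$log_lik,
       r2 = fit$r2,
       r2_adj = fit$r2_adj,
       residuals = as.list(fit$resid_raw),
       residuals_standardized = as.list(fit$resid_std),
       residuals_studentized = as.list(fit$resid_phylo_student),
       outliers = names(which(fit$outlier_flags)))
}
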