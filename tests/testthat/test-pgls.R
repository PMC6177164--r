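test_that("GLS with an identity covariance reproduces OLS exactly", {
  set.seed(42)
  n <- 20
  x <- rnorm(n); y <- 1 + 2 * x + rnorm(n)
  sp <- paste0("t", 1:n)
  C <- diag(n); dimnames(C) <- list(sp, sp)
  X <- designMatrix(x = setNames(x, sp))
  fit <- pglsFit(setNames(y, sp), X, C, lambda = 1)

  ref <- summary(lm(y ~ x))
  expect_equal(unname(coef(fit)), unname(ref$coefficients[, 1]),
               tolerance = 1e-10)
  expect_equal(unname(fit$std_errors), unname(ref$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(unname(fit$t_values), unname(ref$coefficients[, 3]),
               tolerance = 1e-10)
  expect_equal(fit$r2, ref$r.squared, tolerance = 1e-10)
  expect_equal(fit$r2_adj, ref$adj.r.squared, tolerance = 1e-10)
  expect_equal(fit$df_resid, n - 2)
})

test_that("three-taxon phylogenetic mean equals the explicit-inverse value", {
  # oracle: closed-form GLS mean with C = [[2,1,0],[1,2,0],[0,0,2]]
  C <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  y <- c(A = 1, B = 1, C = 4)
  one <- rep(1, 3)
  oracle <- drop((t(one) %*% solve(C) %*% y) / (t(one) %*% solve(C) %*% one))
  expect_equal(oracle, 16 / 7, tolerance = 1e-12)

  tr <- parseNewick("((A:1,B:1):1,C:2);")
  fit <- pglsFit(y, NULL, phyloVCV(tr), lambda = 1)
  expect_equal(unname(coef(fit)), 16 / 7, tolerance = 1e-10)
})

test_that("an exactly linear response gives zero residuals and R2 = 1", {
  tr <- randomUltraTree(12, 3)
  C <- phyloVCV(tr)
  x <- setNames(seq_len(12), tr$tip.label)
  y <- 2 + 0.5 * x
  fit <- pglsFit(y, designMatrix(x = x), C, lambda = 1)
  expect_equal(unname(fit$resid_raw), rep(0, 12))
  expect_equal(fit$r2, 1)
  expect_equal(fit$sigma2_ml, 0)
  expect_equal(unname(fit$resid_std), rep(0, 12))
})

test_that("lambda = 0 fit coincides with OLS to 1e-8", {
  for (seed in 1:5) {
    tr <- randomUltraTree(15, seed)
    cfg <- syntheticConfig(n_tips = 15, true_lambda = 0.5, seed = seed)
    d <- simulateTraits(tr, cfg)
    C <- phyloVCV(tr)
    fit <- pglsFit(setNames(d$y, d$species),
                   designMatrix(x = setNames(d$x, d$species)), C, lambda = 0)
    ref <- summary(lm(y ~ x, data = d))
    expect_equal(unname(coef(fit)), unname(ref$coefficients[, 1]),
                 tolerance = 1e-8)
    expect_equal(unname(fit$std_errors), unname(ref$coefficients[, 2]),
                 tolerance = 1e-8)
    expect_equal(unname(fit$t_values), unname(ref$coefficients[, 3]),
                 tolerance = 1e-8)
  }
})

test_that("lambda = 1 slope equals the independent-contrasts slope", {
  sizes <- c(8, 10, 12, 15, 18, 20)
  for (seed in 1:6) {
    tr <- randomUltraTree(sizes[seed], 100 + seed)
    cfg <- syntheticConfig(n_tips = ape::Ntip(tr), true_lambda = 1,
                           seed = seed)
    d <- simulateTraits(tr, cfg)
    fit <- pglsFit(setNames(d$y, d$species),
                   designMatrix(x = setNames(d$x, d$species)),
                   phyloVCV(tr), lambda = 1)
    px <- ape::pic(setNames(d$x, d$species), tr)
    py <- ape::pic(setNames(d$y, d$species), tr)
    slope <- sum(px * py) / sum(px * px)   # regression through the origin
    expect_equal(unname(coef(fit)[2]), slope, tolerance = 1e-8)
  }
})

test_that("regression statistics are invariant to the branch-length unit", {
  tr <- randomUltraTree(20, 7)
  cfg <- syntheticConfig(n_tips = 20, true_lambda = 0.7, seed = 7)
  d <- simulateTraits(tr, cfg)
  y <- setNames(d$y, d$species)
  X <- designMatrix(x = setNames(d$x, d$species))
  base <- pglsFit(y, X, phyloVCV(tr), lambda = "ML")
  for (k in c(0.01, 1000)) {
    tr2 <- tr; tr2$edge.length <- tr2$edge.length * k
    fit <- pglsFit(y, X, phyloVCV(tr2), lambda = "ML")
    expect_equal(coef(fit), coef(base), tolerance = 1e-6)
    expect_equal(fit$std_errors, base$std_errors, tolerance = 1e-6)
    expect_equal(fit$t_values, base$t_values, tolerance = 1e-6)
    expect_equal(fit$p_values, base$p_values, tolerance = 1e-6)
    expect_equal(fit$r2, base$r2, tolerance = 1e-6)
    expect_equal(fit$r2_adj, base$r2_adj, tolerance = 1e-6)
    expect_equal(fit$lambda_hat, base$lambda_hat, tolerance = 1e-4)
    expect_equal(fit$sigma2_ml * k, base$sigma2_ml,
                 tolerance = 1e-6 * base$sigma2_ml)
  }
})

test_that("GLS normal equations hold on every fit", {
  for (seed in 1:5) {
    tr <- randomUltraTree(15, 20 + seed)
    cfg <- syntheticConfig(n_tips = 15, true_lambda = 0.5, seed = 30 + seed)
    d <- simulateTraits(tr, cfg)
    fit <- pglsFit(setNames(d$y, d$species),
                   designMatrix(x = setNames(d$x, d$species)),
                   phyloVCV(tr), lambda = "ML")
    g <- crossprod(fit$X, solve(fit$V, fit$resid_raw))
    expect_lt(max(abs(g)), 1e-8)
  }
})

test_that("optimizer lambda-hat matches a dense profile grid argmax", {
  for (seed in 1:5) {
    tr <- randomUltraTree(25, 40 + seed)
    cfg <- syntheticConfig(n_tips = 25, true_lambda = 0.6, seed = 40 + seed)
    d <- simulateTraits(tr, cfg)
    C <- phyloVCV(tr)
    y <- setNames(d$y, d$species)
    X <- designMatrix(x = setNames(d$x, d$species))
    fit <- pglsFit(y, X, C, lambda = "ML")
    prof <- lambdaProfile(y, X, C, grid = seq(0, 1, by = 0.001))
    expect_lt(abs(fit$lambda_hat - prof$lambda[which.max(prof$log_lik)]),
              0.001 + 1e-9)
  }
})

test_that("lambda is recovered at its endpoints on deep trees", {
  # independent noise (true lambda 0): lambda-hat should be small
  hits0 <- 0
  for (r in 1:10) {
    tr <- randomUltraTree(100, 300 + r)
    cfg <- syntheticConfig(n_tips = 100, true_lambda = 0, seed = 300 + r)
    d <- simulateTraits(tr, cfg)
    fit <- pglsFit(setNames(d$y, d$species),
                   designMatrix(x = setNames(d$x, d$species)),
                   phyloVCV(tr), lambda = "ML")
    if (fit$lambda_hat < 0.2) hits0 <- hits0 + 1
  }
  expect_gte(hits0, 8)

  # pure Brownian motion (true lambda 1): lambda-hat should be large
  lam1 <- numeric(10)
  for (r in 1:10) {
    tr <- randomUltraTree(100, 400 + r)
    cfg <- syntheticConfig(n_tips = 100, true_lambda = 1, seed = 400 + r)
    d <- simulateTraits(tr, cfg)
    fit <- pglsFit(setNames(d$y, d$species),
                   designMatrix(x = setNames(d$x, d$species)),
                   phyloVCV(tr), lambda = "ML")
    lam1[r] <- fit$lambda_hat
  }
  expect_gte(median(lam1), 0.9)
})

test_that("ML fit agrees with an independent PGLS implementation", {
  tr <- randomUltraTree(40, 77)
  cfg <- syntheticConfig(n_tips = 40, true_lambda = 0.6, seed = 77)
  d <- simulateTraits(tr, cfg)
  fit <- pglsFit(setNames(d$y, d$species),
                 designMatrix(x = setNames(d$x, d$species)),
                 phyloVCV(tr), lambda = "ML")
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corPagel(0.5, tr, form = ~species),
                   method = "ML")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$lambda_hat,
               unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
})

test_that("standardized residual modes differ only by scale on ultrametric trees", {
  tab <- studyTable()
  tree <- studyTree()
  s1 <- stage1Altriciality(tab, tree)
  tv <- standardizedResiduals(s1$fit, "tipvar")
  zs <- standardizedResiduals(s1$fit, "zscore")
  ratio <- tv / zs
  expect_lt(diff(range(ratio)), 1e-10)
})

test_that("downstream fit is invariant to uniform rescaling of the predictor", {
  tab <- studyTable()
  tree <- studyTree()
  s1 <- stage1Altriciality(tab, tree)
  acyl <- setNames(tab$asin_cyl, tab$species)
  f1 <- stage2Association(acyl, s1$altriciality, tree)
  f2 <- stage2Association(acyl, 10 * s1$altriciality, tree)
  expect_equal(f1$t_values[2], f2$t_values[2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(f1$p_values[2], f2$p_values[2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-8)
  expect_equal(f1$lambda_hat, f2$lambda_hat, tolerance = 1e-4)
  expect_equal(unname(coef(f2)[2] * 10), unname(coef(f1)[2]),
               tolerance = 1e-6)
})

test_that("studentized phylogenetic residuals generalize the OLS ones", {
  set.seed(9)
  n <- 15
  x <- rnorm(n); y <- 1 + x + rnorm(n)
  sp <- paste0("t", 1:n)
  C <- diag(n); dimnames(C) <- list(sp, sp)
  fit <- pglsFit(setNames(y, sp), designMatrix(x = setNames(x, sp)), C,
                 lambda = 1)
  ref <- rstandard(lm(y ~ x))
  expect_equal(unname(fit$resid_phylo_student), unname(ref),
               tolerance = 1e-10)
  expect_false(any(fit$outlier_flags))

  # a tip inflated by 10 residual SDs must be flagged
  tr <- randomUltraTree(60, 11)
  cfg <- syntheticConfig(n_tips = 60, true_lambda = 1, seed = 11)
  d <- simulateTraits(tr, cfg)
  base <- pglsFit(setNames(d$y, d$species),
                  designMatrix(x = setNames(d$x, d$species)),
                  phyloVCV(tr), lambda = 1)
  y2 <- d$y
  y2[5] <- y2[5] + 10 * sqrt(base$sigma2_resid * diag(phyloVCV(tr))[5])
  out <- pglsFit(setNames(y2, d$species),
                 designMatrix(x = setNames(d$x, d$species)),
                 phyloVCV(tr), lambda = 1)
  expect_true(out$outlier_flags[d$species[5]])
})

test_that("diagnostic data have the documented shape and conventions", {
  tab <- studyTable()
  s1 <- stage1Altriciality(tab, studyTree())
  dd <- diagnosticData(s1$fit)
  expect_equal(nrow(dd$qq), 31)
  expect_equal(dd$qq$theoretical, -rev(dd$qq$theoretical), tolerance = 1e-12)
  expect_equal(dd$qq$theoretical[1], qnorm(0.5 / 31))
  expect_false(is.unsorted(dd$qq$observed))
  expect_equal(nrow(dd$fitted_resid), 31)

  # constant (all-zero) residuals: degenerate ordinates, no crash
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  x <- c(A = 1, B = 2, C = 3)
  perfect <- pglsFit(2 * x, designMatrix(x = x), phyloVCV(tr), lambda = 1)
  expect_silent(dd0 <- diagnosticData(perfect))
  expect_equal(dd0$qq$observed, rep(0, 3))
})

test_that("fits are serializable to a coefficient table and report list", {
  tab <- studyTable()
  s1 <- stage1Altriciality(tab, studyTree())
  tb <- pglsFitTable(s1$fit)
  expect_equal(nrow(tb), 2)
  expect_named(tb, c("term", "estimate", "se", "t", "df", "p"))
  expect_equal(tb$df, c(29, 29))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  writePglsTsv(s1$fit, path)
  back <- read.delim(path)
  expect_equal(back$estimate, tb$estimate, tolerance = 1e-12)
  rep <- pglsReport(s1$fit)
  expect_equal(rep$df_resid, 29)
  expect_length(rep$residuals, 31)
  expect_length(rep$outliers, 0)
})

test_that("degenerate inputs are rejected with useful errors", {
  set.seed(123)
  tr <- randomUltraTree(8, 1)
  C <- phyloVCV(tr)
  y <- setNames(rnorm(8), tr$tip.label)
  x <- setNames(seq_len(8), tr$tip.label)
  # rank-deficient design (duplicated predictor direction)
  expect_error(pglsFit(y, designMatrix(a = x, b = 2 * x), C),
               "rank deficient")
  # singular covariance
  tr3 <- parseNewick("((A:1,B:1):1,C:2);")
  Cs <- phyloVCV(tr3)
  Cs["A", "B"] <- Cs["B", "A"] <- 2
  expect_error(pglsFit(c(A = 1, B = 2, C = 3), NULL, Cs, lambda = 1),
               "singular")
  # n <= p
  expect_error(pglsFit(c(A = 1, B = 2, C = 3),
                       designMatrix(a = c(A = 1, B = 2, C = 3),
                                    b = c(A = 2, B = 1, C = 0)),
                       phyloVCV(tr3)),
               "n > p")
})
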