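#' Stage 1: degree of altriciality
#'
#' PGLS of ln(fledge/wean age) on ln(lifespan) with Pagel's lambda
#' estimated by maximum likelihood on the tree pruned to the table species.
#' The standardized residuals of this fit are the derived trait used
#' downstream: species weaned or fledged later than their lifespan predicts
#' get positive values (more altricial), earlier ones negative.
#'
#' @param table A `trait_table`.
#' @param tree A `phylo` containing every table species.
#' @param residMode Standardization mode, see [standardizedResiduals()].
#' @return List with `fit` (a `pgls_fit`) and `altriciality` (named by
#'   species as written in the table).
#' @export
stage1Altriciality <- function(table, tree, residMode = c("tipvar", "zscore")) {
  residMode <- match.arg(residMode)
  m <- matchTreeTips(table, tree)
  C <- phyloVCV(m$tree, order = m$tips)
  y <- stats::setNames(table$ln_fw, m$tips)
  X <- designMatrix(ln_life = stats::setNames(table$ln_life, m$tips))
  fit <- pglsFit(y, X, C, lambda = "ML")
  altr <- standardizedResiduals(fit, mode = residMode)
  list(fit = fit, altriciality = stats::setNames(unname(altr), table$species))
}

#' Stage 2: self-control on the degree of altriciality (PGLS)
#'
#' PGLS of the angular-transformed cylinder-task score on the degree of
#' altriciality, lambda re-estimated by maximum likelihood. The stage-1
#' residuals enter as an observed predictor; no error propagation between
#' stages.
#'
#' @param asin_cyl Named numeric response (angular-transformed % success).
#' @param altriciality Named numeric predictor from [stage1Altriciality()].
#' @param tree A `phylo` containing the common species.
#' @return A `pgls_fit`.
#' @export
stage2Association <- function(asin_cyl, altriciality, tree) {
  sp <- names(asin_cyl)
  if (is.null(sp) || !setequal(sp, names(altriciality)))
    stop("asin_cyl and altriciality must be named by the same species")
  tips <- speciesToTip(sp)
  C <- phyloVCV(pruneTo(tree, tips), order = tips)
  y <- stats::setNames(unname(asin_cyl), tips)
  X <- designMatrix(
    altriciality = stats::setNames(unname(altriciality[sp]), tips))
  pglsFit(y, X, C, lambda = "ML")
}

#' Stage 2 under phylogenetic independence (OLS)
#'
#' The non-phylogenetic contrast model: the same regression with
#' `lambda` fixed at 0 (identity error correlation), which coincides with a
#' textbook ordinary least squares fit with `n - 2` residual df.
#'
#' @inheritParams stage2Association
#' @return A `pgls_fit` with `lambda_hat = 0`.
#' @export
stage2Ols <- function(asin_cyl, altriciality) {
  sp <- names(asin_cyl)
  if (is.null(sp) || !setequal(sp, names(altriciality)))
    stop("asin_cyl and altriciality must be named by the same species")
  n <- length(asin_cyl)
  C <- diag(n)
  dimnames(C) <- list(sp, sp)
  X <- designMatrix(
    altriciality = stats::setNames(unname(altriciality[sp]), sp))
  pglsFit(stats::setNames(unname(asin_cyl), sp), X, C, lambda = 0)
}

#' Run the full two-stage study
#'
#' Orchestrates the complete analysis: load and transform the trait table,
#' read and prune the chronogram, run the stage-1 altriciality regression,
#' the stage-2 PGLS (lambda = ML) and its OLS contrast (lambda = 0), and
#' assemble descriptive statistics, per-species plot data (observed points
#' plus the two fitted lines) and outlier flags into a single report.
#' With `outDir` set, the report is also serialized: `report.json` (full
#' precision), `stage1_fit.tsv`, `stage2_pgls_fit.tsv`, `stage2_ols_fit.tsv`
#' and `fig2_data.csv`. Identical inputs produce byte-identical output.
#'
#' @param tablePath CSV of species traits (default: bundled table).
#' @param treePath Newick chronogram (default: bundled fixture; pruned to
#'   the table species automatically).
#' @param arcsine Angular-transform convention for the cylinder score.
#' @param residMode Stage-1 residual standardization mode.
#' @param outDir Optional output directory, created if needed.
#' @return An object of class `study_report`: list with `stage1`,
#'   `altriciality`, `stage2_pgls`, `stage2_ols`, `descriptives`,
#'   `plot_data` and `table`.
#' @export
runStudy <- function(tablePath = system.file("extdata", "table1.csv",
                                             package = "altripgls"),
                     treePath = system.file("extdata", "chronogram_32sp.nwk",
                                            package = "altripgls"),
                     arcsine = c("sqrt", "linear"),
                     residMode = c("tipvar", "zscore"),
                     outDir = NULL) {
  arcsine <- match.arg(arcsine)
  residMode <- match.arg(residMode)
  table <- loadTraitTable(tablePath, arcsine = arcsine)
  tree <- readChronogram(treePath)

  s1 <- tryCatch(stage1Altriciality(table, tree, residMode = residMode),
                 error = function(e) stop("stage1: ", conditionMessage(e),
                                          call. = FALSE))
  acyl <- stats::setNames(table$asin_cyl, table$species)
  s2 <- tryCatch(stage2Association(acyl, s1$altriciality, tree),
                 error = function(e) stop("stage2_pgls: ", conditionMessage(e),
                                          call. = FALSE))
  s2o <- tryCatch(stage2Ols(acyl, s1$altriciality),
                  error = function(e) stop("stage2_ols: ", conditionMessage(e),
                                           call. = FALSE))

  altr <- s1$altriciality[table$species]
  plot_data <- data.frame(
    species = table$species,
    altriciality = unname(altr),
    asin_cyl = table$asin_cyl,
    fitted_pgls = unname(coef(s2)[1] + coef(s2)[2] * altr),
    fitted_ols = unname(coef(s2o)[1] + coef(s2o)[2] * altr),
    stringsAsFactors = FALSE)

  rep <- structure(list(stage1 = s1$fit,
                        altriciality = altr,
                        stage2_pgls = s2,
                        stage2_ols = s2o,
                        descriptives = descriptivesTable(table),
                        plot_data = plot_data,
                        table = table,
                        config = list(arcsine = arcsine,
                                      residMode = residMode)),
                   class = "study_report")
  if (!is.null(outDir)) writeStudyReport(rep, outDir)
  rep
}

#' Serialize a study report
#'
#' @param report A `study_report`.
#' @param outDir Directory to write into (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeStudyReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  json <- list(config = report$config,
               stage1 = pglsReport(report$stage1),
               altriciality = as.list(report$altriciality),
               stage2_pgls = pglsReport(report$stage2_pgls),
               stage2_ols = pglsReport(report$stage2_ols),
               descriptives = report$descriptives)
  jsonlite::write_json(json, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writePglsTsv(report$stage1, file.path(outDir, "stage1_fit.tsv"))
  writePglsTsv(report$stage2_pgls, file.path(outDir, "stage2_pgls_fit.tsv"))
  writePglsTsv(report$stage2_ols, file.path(outDir, "stage2_ols_fit.tsv"))
  utils::write.csv(report$plot_data, file.path(outDir, "fig2_data.csv"),
                   row.names = FALSE)
  invisible(outDir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Two-stage phylogenetic study, n =", nrow(x$table), "species\n\n")
  cat("Stage 1: ln(fledge/wean) ~ ln(lifespan)\n")
  print(x$stage1)
  cat("\nStage 2 (PGLS): asin(cylinder) ~ degree of altriciality\n")
  print(x$stage2_pgls)
  cat("\nStage 2 (OLS contrast, lambda = 0)\n")
  print(x$stage2_ols)
  invisible(x)
}
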