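#' Angular transform of a percentage
#'
#' The default `"sqrt"` convention is the standard variance-stabilizing
#' angular transform for proportions, `asin(sqrt(p / 100))` (radians); the
#' `"linear"` convention `asin(p / 100)` is retained as an alternative.
#'
#' @param p Percentage(s) in `[0, 100]`.
#' @param mode `"sqrt"` (default) or `"linear"`.
#' @return Numeric vector in radians.
#' @examples
#' arcsinePct(c(0, 25, 100))  # 0, pi/6, pi/2
#' @export
arcsinePct <- function(p, mode = c("sqrt", "linear")) {
  mode <- match.arg(mode)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100))
    stop("percentages must lie in [0, 100]")
  switch(mode, sqrt = asin(sqrt(p / 100)), linear = asin(p / 100))
}

#' Natural logarithm of a positive trait
#'
#' @param x Positive numeric vector.
#' @return `log(x)`.
#' @export
lnTransform <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("values must be finite and > 0")
  log(x)
}

# The bundled table keeps the source's spellings; tree tips use the
# accepted binomials. This explicit alias map is the only name bridging.
.speciesAliases <- c(
  "Columbia livia" = "Columba_livia",
  "Rhinopithecuas roxellana" = "Rhinopithecus_roxellana"
)

#' Map species names to tree tip labels
#'
#' Converts table species names (Latin binomials with spaces, including the
#' two legacy spellings preserved from the source table) to the underscored
#' tip labels of the bundled chronogram.
#'
#' @param species Character vector of species names.
#' @return Character vector of tip labels.
#' @export
speciesToTip <- function(species) {
  out <- ifelse(species %in% names(.speciesAliases),
                .speciesAliases[species],
                gsub(" ", "_", species))
  unname(out)
}

#' Load and validate the species trait table
#'
#' Reads the per-species table (cylinder-task % success, fledging/weaning
#' age, lifespan), validates every record, and appends the derived columns
#' `ln_fw`, `ln_life` and `asin_cyl`. The bundled file transcribes the
#' source data for 31 homeothermic species.
#'
#' @param path CSV path; defaults to the bundled table. Required columns:
#'   `species, family, common_name, cylinder_pct, fw_days, lifespan_days,
#'   taxon_class`.
#' @param arcsine Angular-transform convention passed to [arcsinePct()].
#' @return A data frame of class `trait_table` with the derived columns and
#'   attributes `arcsine` (convention used) and `tip_label`.
#' @export
loadTraitTable <- function(path = system.file("extdata", "table1.csv",
                                              package = "altripgls"),
                           arcsine = c("sqrt", "linear")) {
  arcsine <- match.arg(arcsine)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("species", "family", "common_name", "cylinder_pct",
                "fw_days", "lifespan_days", "taxon_class")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("cylinder_pct", "fw_days", "lifespan_days")) {
    if (!is.numeric(d[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[col]]))))
      stop(sprintf("non-numeric value in '%s' at row %s", col,
                   paste(bad, collapse = ", ")))
    }
  }
  dup <- d$species[duplicated(d$species)]
  if (length(dup))
    stop("duplicate species: ", paste(unique(dup), collapse = ", "))
  bad <- which(!(d$taxon_class %in% c("bird", "mammal")))
  if (length(bad))
    stop("taxon_class must be 'bird' or 'mammal' (row ",
         paste(bad, collapse = ", "), ")")
  bad <- which(d$cylinder_pct < 0 | d$cylinder_pct > 100)
  if (length(bad))
    stop("cylinder_pct outside [0, 100] at row ", paste(bad, collapse = ", "))
  bad <- which(d$fw_days <= 0 | d$lifespan_days <= 0)
  if (length(bad))
    stop("non-positive duration at row ", paste(bad, collapse = ", "))
  bad <- which(d$fw_days >= d$lifespan_days)
  if (length(bad))
    stop("fledge/wean age must be below lifespan (row ",
         paste(bad, collapse = ", "), ")")
  d <- deriveColumns(d, arcsine = arcsine)
  attr(d, "tip_label") <- speciesToTip(d$species)
  class(d) <- c("trait_table", "data.frame")
  d
}

#' Recompute the derived trait columns
#'
#' Deterministically (re)derives `ln_fw = ln(fw_days)`,
#' `ln_life = ln(lifespan_days)` and `asin_cyl` from the raw columns;
#' idempotent and row-order independent.
#'
#' @param d Trait data frame with raw columns.
#' @param arcsine Angular-transform convention.
#' @return The data frame with derived columns set and attribute `arcsine`.
#' @export
deriveColumns <- function(d, arcsine = c("sqrt", "linear")) {
  arcsine <- match.arg(arcsine)
  d$ln_fw <- lnTransform(d$fw_days)
  d$ln_life <- lnTransform(d$lifespan_days)
  d$asin_cyl <- arcsinePct(d$cylinder_pct, mode = arcsine)
  attr(d, "arcsine") <- arcsine
  d
}

#' Align a trait table with a phylogeny
#'
#' Verifies that every species in the table resolves to exactly one tip of
#' the tree, prunes the tree to those tips, and returns both, with the
#' covariance-ready species order fixed to the table's row order.
#'
#' @param table A `trait_table`.
#' @param tree A `phylo` whose tips include every table species.
#' @return List with `table`, `tree` (pruned) and `tips` (tip labels in
#'   table row order).
#' @export
matchTreeTips <- function(table, tree) {
  tips <- speciesToTip(table$species)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("species without a tree tip: ", paste(missing, collapse = ", "))
  list(table = table, tree = pruneTo(tree, tips), tips = tips)
}
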