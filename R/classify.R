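# Amino-acid classification under seven physicochemical schemes
# (hydropathy, volume, chemical, charge, hydrogen donor/acceptor, polarity,
# combined physicochemical), following the IMGT-style grouping of Pommie and
# colleagues. Memberships ship as an editable TSV (scheme, subgroup,
# residues); each scheme must partition the 20 standard residues, which is
# enforced on load.

CLASSIFICATION_SCHEMES <- c("hydropathy", "volume", "chemical", "charge",
                            "hydrogen_don_acc", "polarity", "physicochemical")

#' Load an amino-acid classification table
#'
#' @param path TSV with columns `scheme`, `subgroup`, `residues`; defaults to
#'   the bundled table.
#' @return Object of class `aa_classification`: a list mapping scheme ->
#'   named character vector (residue -> subgroup label).
#' @export
load_classification <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_classes.tsv", package = "matcompare",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    mc_input_error(sprintf("classification table not found: '%s'", path))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scheme", "subgroup", "residues")
  if (!all(need %in% names(tab))) {
    mc_input_error(sprintf(
      "classification table '%s' must have columns %s",
      path, paste(need, collapse = ", ")))
  }
  out <- list()
  for (sch in unique(tab$scheme)) {
    rows <- tab[tab$scheme == sch, , drop = FALSE]
    map <- character(0)
    for (k in seq_len(nrow(rows))) {
      res <- chars(toupper(rows$residues[k]))
      dup <- intersect(res, names(map))
      if (length(dup)) {
        mc_input_error(sprintf(
          "scheme '%s': residue %s assigned to both '%s' and '%s'",
          sch, dup[1L], map[dup[1L]], rows$subgroup[k]))
      }
      map[res] <- rows$subgroup[k]
    }
    missing <- setdiff(STANDARD_AA, names(map))
    if (length(missing)) {
      mc_input_error(sprintf(
        "scheme '%s' does not cover residues: %s",
        sch, paste(missing, collapse = ", ")))
    }
    extra <- setdiff(names(map), STANDARD_AA)
    if (length(extra)) {
      mc_input_error(sprintf(
        "scheme '%s' assigns non-standard residues: %s",
        sch, paste(extra, collapse = ", ")))
    }
    out[[sch]] <- map
  }
  structure(out, class = "aa_classification")
}

# Bundled table, loaded once per session.
classification_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_classification()
    cache
  }
})

#' Names of the available classification schemes
#' @param table An `aa_classification` (default: bundled).
#' @return Character vector of scheme names.
#' @export
classification_schemes <- function(table = NULL) {
  if (is.null(table)) table <- classification_default()
  names(table)
}

#' Classify a residue under a scheme
#'
#' @param residue Single residue code.
#' @param scheme Scheme name, e.g. `"charge"` or `"physicochemical"`.
#' @param table An `aa_classification` (default: bundled).
#' @return The subgroup label containing the residue, or `"unclassified"` for
#'   non-standard residues (and gaps).
#' @export
classify_residue <- function(residue, scheme, table = NULL) {
  if (is.null(table)) table <- classification_default()
  if (!inherits(table, "aa_classification")) {
    mc_input_error("table must come from load_classification()")
  }
  if (!is.character(scheme) || length(scheme) != 1L || !scheme %in% names(table)) {
    mc_input_error(sprintf("unknown classification scheme '%s'; available: %s",
                           as.character(scheme)[1L],
                           paste(names(table), collapse = ", ")))
  }
  if (!is.character(residue) || length(residue) != 1L || nchar(residue) != 1L) {
    mc_input_error("residue must be a single character")
  }
  residue <- toupper(residue)
  map <- table[[scheme]]
  if (!residue %in% names(map)) return("unclassified")
  unname(map[residue])
}
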