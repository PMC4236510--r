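# Rule tables: per-subfamily allowed residue sets at the four Ar/R filter
# positions plus auxiliary predicates. The published residue patterns are
# shipped as data (inst/extdata/rules_*.tsv), not code, so new rows are
# configuration. Multi-row subfamilies are unioned position-wise on load.

#' Load a subfamily rule table
#'
#' @param which `"fungal"` (the fungal MIP subgroups), `"plant"` (plant
#'   TIP/SIP patterns), or a path to a TSV with columns `subfamily, tm2,
#'   tm5, le1, le2, require_r_le2, max_mw, npa_pct` (comma-separated residue
#'   sets).
#' @return an object of class `mip_rules`: named list with, per subfamily,
#'   the four allowed residue sets, `require_r_le2`, an optional molecular
#'   weight ceiling `max_mw` (Daltons) and the published per-sequence NPA
#'   substitution percentage `npa_pct`.
#' @export
load_rule_table <- function(which = "fungal") {
  path <- if (which %in% c("fungal", "plant")) {
    system.file("extdata", paste0("rules_", which, ".tsv"), package = "mipscan",
                mustWork = TRUE)
  } else which
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  stopifnot(all(c("subfamily", "tm2", "tm5", "le1", "le2") %in% names(tab)))
  split_set <- function(x) sort(unique(unlist(strsplit(x, ",", fixed = TRUE))))
  out <- lapply(split(tab, factor(tab$subfamily, levels = unique(tab$subfamily))),
                function(rows) {
    list(
      tm2 = split_set(rows$tm2), tm5 = split_set(rows$tm5),
      le1 = split_set(rows$le1), le2 = split_set(rows$le2),
      require_r_le2 = all(as.logical(rows$require_r_le2)),
      max_mw = if (all(is.na(rows$max_mw))) NA_real_
               else min(rows$max_mw, na.rm = TRUE),
      npa_pct = if (all(is.na(rows$npa_pct))) NA_real_
                else rows$npa_pct[which(!is.na(rows$npa_pct))[1L]]
    )
  })
  structure(out, class = "mip_rules")
}

#' Rule-based subfamily candidates from an Ar/R filter
#'
#' Returns every subfamily whose four allowed residue sets contain the
#' observed selectivity-filter residues. A missing (unmapped) filter
#' position matches no subfamily. Auxiliary predicates: subfamilies with
#' `require_r_le2` additionally demand an arginine at LE2, and a subfamily
#' with a `max_mw` ceiling (SIP-like: small proteins) is only a candidate if
#' the sequence's molecular weight is known and below the ceiling.
#'
#' @param fv a feature vector from [compute_features()], or any list with an
#'   `arr` filter (and optionally `mw`).
#' @param rules a rule table from [load_rule_table()].
#' @return character vector of candidate subfamily labels (possibly empty).
#' @export
rule_classify <- function(fv, rules = load_rule_table("fungal")) {
  stopifnot(inherits(rules, "mip_rules"))
  arr <- fv$arr
  obs <- c(tm2 = arr$tm2, tm5 = arr$tm5, le1 = arr$le1, le2 = arr$le2)
  hits <- vapply(names(rules), function(lab) {
    r <- rules[[lab]]
    ok <- !is.na(obs) &
      c(obs[["tm2"]] %in% r$tm2, obs[["tm5"]] %in% r$tm5,
        obs[["le1"]] %in% r$le1, obs[["le2"]] %in% r$le2)
    if (!all(ok)) return(FALSE)
    if (r$require_r_le2 && !identical(obs[["le2"]], "R")) return(FALSE)
    if (!is.na(r$max_mw)) {
      if (is.null(fv$mw) || is.na(fv$mw) || fv$mw >= r$max_mw) return(FALSE)
    }
    TRUE
  }, logical(1L))
  names(rules)[hits]
}
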