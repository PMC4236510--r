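# Final subfamily calls: combine rule-based filter matching with tree clade
# assignment; aggregate group-level summaries and pairwise identity
# statistics.

#' Combine rule candidates and a clade label into a subfamily call
#'
#' The clade label wins whenever present: confidence is `rule+tree` if the
#' clade is among the rule candidates and `tree-only` otherwise. Without a
#' clade, a unique rule candidate yields `rule-only`; anything else is
#' `unclassified` with confidence `none`.
#'
#' @param rule_candidates character vector from [rule_classify()].
#' @param clade_label single subfamily label or `"unclassified"`/`NA`.
#' @return list with `label`, `confidence` (`rule+tree`, `tree-only`,
#'   `rule-only` or `none`) and `evidence`.
#' @export
combine_calls <- function(rule_candidates, clade_label = "unclassified") {
  if (is.null(clade_label) || is.na(clade_label)) clade_label <- "unclassified"
  has_clade <- !identical(clade_label, "unclassified")
  if (has_clade) {
    conf <- if (clade_label %in% rule_candidates) "rule+tree" else "tree-only"
    label <- clade_label
  } else if (length(rule_candidates) == 1L) {
    conf <- "rule-only"
    label <- rule_candidates
  } else {
    conf <- "none"
    label <- "unclassified"
  }
  list(label = label, confidence = conf,
       evidence = list(rule_candidates = rule_candidates,
                       clade_label = clade_label))
}

#' Per-subfamily summary table
#'
#' For each subfamily with at least one member: member count, observed
#' residue sets at the four filter positions (with within-group
#' frequencies), the percentage of members with at least one substituted
#' NPA box (1 decimal place), and means of loop-D length/charge, pI and
#' molecular weight. Empty subfamilies are omitted; the rows are invariant
#' to input order.
#'
#' @param calls list of calls from [combine_calls()] (or a character vector
#'   of labels), parallel to `fvs`.
#' @param fvs list of `mip_features` from [compute_features()].
#' @return data frame, one row per subfamily, ordered by label.
#' @export
summarize_group <- function(calls, fvs) {
  stopifnot(length(calls) == length(fvs), length(fvs) >= 1L)
  labels <- if (is.character(calls)) calls
    else vapply(calls, function(x) x$label, character(1L))
  fmt_set <- function(chars) {
    chars <- chars[!is.na(chars)]
    if (!length(chars)) return("")
    tab <- sort(table(chars), decreasing = TRUE)
    paste(sprintf("%s(%.2f)", names(tab), as.numeric(tab) / sum(tab)),
          collapse = ",")
  }
  rows <- lapply(sort(unique(labels)), function(lab) {
    sel <- which(labels == lab)
    f <- fvs[sel]
    subbed <- vapply(f, function(x) {
      !(isTRUE(x$npa_b$canonical) && isTRUE(x$npa_e$canonical))
    }, logical(1L))
    data.frame(
      subfamily = lab, n = length(sel),
      tm2 = fmt_set(vapply(f, function(x) x$arr$tm2 %||% NA_character_, character(1L))),
      tm5 = fmt_set(vapply(f, function(x) x$arr$tm5 %||% NA_character_, character(1L))),
      le1 = fmt_set(vapply(f, function(x) x$arr$le1 %||% NA_character_, character(1L))),
      le2 = fmt_set(vapply(f, function(x) x$arr$le2 %||% NA_character_, character(1L))),
      npa_substitution_pct = round(100 * mean(subbed), 1L),
      mean_loop_d_length = mean(vapply(f, function(x)
        as.numeric(x$loop_d_length %||% NA), numeric(1L)), na.rm = TRUE),
      mean_loop_d_charged = mean(vapply(f, function(x)
        as.numeric(x$loop_d_charged %||% NA), numeric(1L)), na.rm = TRUE),
      mean_pI = mean(vapply(f, function(x) x$pI, numeric(1L))),
      mean_mw = mean(vapply(f, function(x) x$mw, numeric(1L))),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Intra- and inter-group identity/similarity statistics
#'
#' Means over all unordered pairs of pairwise global-alignment identity and
#' similarity, within each group (diagonal) and across each pair of groups
#' (off-diagonal). Intra-group entries for singleton groups are `NA`.
#'
#' @param groups named list: subfamily label -> list of
#'   [protein_sequence()] records.
#' @param ... forwarded to [global_align()].
#' @return list of two symmetric matrices, `identity` and `similarity`
#'   (fractions in 0..1).
#' @export
group_identity_stats <- function(groups, ...) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  labs <- names(groups)
  k <- length(labs)
  idm <- simm <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  pair_stats <- function(sa, sb, same) {
    ids <- sims <- numeric(0)
    if (same) {
      n <- length(sa)
      if (n < 2L) return(c(NA_real_, NA_real_))
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        a <- global_align(sa[[i]], sa[[j]], ...)
        ids <- c(ids, a$identity); sims <- c(sims, a$similarity)
      }
    } else {
      for (x in sa) for (y in sb) {
        a <- global_align(x, y, ...)
        ids <- c(ids, a$identity); sims <- c(sims, a$similarity)
      }
    }
    c(mean(ids), mean(sims))
  }
  for (i in seq_len(k)) {
    for (j in i:k) {
      st <- pair_stats(groups[[i]], groups[[j]], same = i == j)
      idm[i, j] <- idm[j, i] <- st[1L]
      simm[i, j] <- simm[j, i] <- st[2L]
    }
  }
  list(identity = idm, similarity = simm)
}
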