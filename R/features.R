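# Per-sequence features: NPA boxes, Ar/R selectivity filter, isoelectric
# point, molecular weight, loop-D metrics, loop-E motif class and
# intra-helical salt bridge, interface conservation, and the three-criterion
# MIP validation.

#' Locate the two NPA boxes of a query via an anchor alignment
#'
#' The boxes are located positionally (not by string search): the three
#' residues aligned to the reference's loop-B and loop-E NPA positions are
#' read off the query. Any triplet qualifies as "NPA-like"; a box is
#' substituted wherever the triplet differs from `NPA`. A residue whose
#' reference position maps to a gap is recorded as `X` and counted as
#' substituted.
#'
#' @param query a [protein_sequence()].
#' @param aln alignment of `query` against `ref$seq` (see [global_align()]).
#' @param ref a [reference_annotation()].
#' @return list with elements `b` and `e`, each a `NpaBox`: `loop`,
#'   `triplet`, `canonical`, `substituted_offsets` (1-based offsets 1..3).
#' @export
locate_npa_boxes <- function(query, aln, ref) {
  box_at <- function(pos, loop) {
    q <- map_position(aln, pos + 0:2)
    chars <- ifelse(is.na(q), "X",
                    substring(query$residues, ifelse(is.na(q), 1L, q),
                              ifelse(is.na(q), 1L, q)))
    triplet <- paste(chars, collapse = "")
    subs <- which(chars != c("N", "P", "A"))
    list(loop = loop, triplet = triplet,
         canonical = identical(triplet, "NPA"),
         substituted_offsets = as.integer(subs),
         located = !all(chars == "X"))
  }
  b <- box_at(ref$npa_b_pos, "B")
  e <- box_at(ref$npa_e_pos, "E")
  if (!b$located && !e$located) {
    stop(sprintf("'%s': neither NPA box is mappable onto anchor '%s'",
                 query$id, ref$ref_id))
  }
  list(b = b, e = e)
}

#' Extract the aromatic/arginine selectivity filter
#'
#' Reads the query residues aligned to the reference's four filter positions
#' (TM2, TM5, LE1, LE2). Positions mapping to a gap are `NA`; the filter is
#' `complete` only when all four are mapped.
#'
#' @inheritParams locate_npa_boxes
#' @return an `ArRFilter`: list with `tm2`, `tm5`, `le1`, `le2` (single
#'   residues or `NA`) and `complete`.
#' @export
extract_arr_filter <- function(query, aln, ref) {
  q <- map_position(aln, ref$arr_positions)
  chars <- ifelse(is.na(q), NA_character_,
                  substring(query$residues, ifelse(is.na(q), 1L, q),
                            ifelse(is.na(q), 1L, q)))
  names(chars) <- names(ref$arr_positions)
  list(tm2 = chars[["tm2"]], tm5 = chars[["tm5"]], le1 = chars[["le1"]],
       le2 = chars[["le2"]], complete = !anyNA(chars))
}

#' Isoelectric point of a protein sequence
#'
#' pH at which the Henderson-Hasselbalch net charge over the ionizable side
#' chains (D, E, C, Y, H, K, R) and the two termini is zero, found by
#' bisection on pH 0..14 to a tolerance of 1e-4.
#'
#' @param seq a [protein_sequence()].
#' @param pka pKa set name (`"bjellqvist"`, the default, or `"emboss"`) or a
#'   list with elements `nterm`, `cterm`, `acidic`, `basic`.
#' @return pI in pH units.
#' @export
compute_pi <- function(seq, pka = "bjellqvist") {
  stopifnot(inherits(seq, "mip_seq"))
  if (is.character(pka)) {
    pka <- PKA_SETS[[match.arg(pka, names(PKA_SETS))]]
  }
  counts <- table(factor(split_residues(seq$residues), levels = AA_ALPHABET))
  net_charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - pka$nterm)) +
      sum(vapply(names(pka$basic), function(a) {
        counts[[a]] / (1 + 10^(ph - pka$basic[[a]]))
      }, numeric(1L)))
    neg <- 1 / (1 + 10^(pka$cterm - ph)) +
      sum(vapply(names(pka$acidic), function(a) {
        counts[[a]] / (1 + 10^(pka$acidic[[a]] - ph))
      }, numeric(1L)))
    pos - neg
  }
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Molecular weight of a protein sequence
#'
#' Sum of isotope-averaged residue masses plus one water mass.
#'
#' @param seq a [protein_sequence()].
#' @param on_x `"error"` (default) to refuse sequences containing `X`, or
#'   `"estimate"` to score `X` with the mean residue mass (flagged via the
#'   `estimated` attribute).
#' @return mass in Daltons.
#' @export
compute_mw <- function(seq, on_x = c("error", "estimate")) {
  stopifnot(inherits(seq, "mip_seq"))
  on_x <- match.arg(on_x)
  chars <- split_residues(seq$residues)
  if (!length(chars)) stop("empty sequence")
  nx <- sum(chars == "X")
  if (nx > 0L && on_x == "error") {
    stop(sprintf("'%s' contains X; exact mass undefined (use on_x = \"estimate\")",
                 seq$id))
  }
  mw <- sum(AA_MASS_AVG[chars[chars != "X"]]) + nx * mean(AA_MASS_AVG) +
    MASS_WATER
  if (nx > 0L) attr(mw, "estimated") <- TRUE
  mw
}

#' Loop-D length and charge
#'
#' Length of the loop between TM4 and TM5 and the number of charged residues
#' (D, E, K, R; histidine excluded) within it.
#'
#' @param seq a [protein_sequence()].
#' @param topo a `mip_topology` with at least 5 TM spans.
#' @return list with `length` and `charged_count`.
#' @export
loop_d_metrics <- function(seq, topo) {
  stopifnot(inherits(seq, "mip_seq"), inherits(topo, "mip_topology"))
  if (nrow(topo$tm_spans) < 5L) {
    stop("loop D undefined: fewer than 5 TM spans")
  }
  span <- c(start = unname(topo$tm_spans[4L, "end"]) + 1L,
            end = unname(topo$tm_spans[5L, "start"]) - 1L)
  res <- span_residues(seq, span)
  list(length = nchar(res),
       charged_count = sum(split_residues(res) %in% AA_CHARGED))
}

# fixed precedence: first match wins
MOTIF_PATTERNS <- list(
  "AQGP-core" = function(w) w[1] == "R" && w[2] == "D" && w[4] == "G" &&
    w[5] == "P" && w[6] == "R",
  "AQGP-delta" = function(w) w[1] == "R" && w[2] == "D" && w[4] == "G" &&
    w[5] != "P" && w[6] == "R",
  "XIP-type" = function(w) w[1] == "R" && w[2] == "C" && w[4] %in% c("G", "A"),
  "AQP-type" = function(w) w[1] == "R" && w[2] %in% c("S", "A") &&
    w[4] == "G" && w[5] %in% c("P", "A")
)

#' Classify the loop-E motif and detect the intra-helical salt bridge
#'
#' Examines the 6-residue window following the loop-E NPA box and assigns
#' the motif class with fixed precedence `AQGP-core` (RDxGPR) >
#' `AQGP-delta` (RDxG\[not-P\]R) > `XIP-type` (RCx\[G/A\]xx) > `AQP-type`
#' (R\[S/A\]xG\[P/A\]x) > `none`. The salt bridge is reported when an acidic
#' residue (D/E) at window offset i co-occurs with a basic residue (K/R) at
#' offset i+4 within the window.
#'
#' @param seq a [protein_sequence()].
#' @param loop_e_region length-2 vector `[start, end]` of the 6-residue
#'   window (1-based inclusive). A window extending past the sequence end
#'   yields class `none`.
#' @return list with `motif_class` and `salt_bridge`.
#' @export
detect_loop_e_motif <- function(seq, loop_e_region) {
  stopifnot(inherits(seq, "mip_seq"))
  s <- as.integer(loop_e_region[1L]); e <- as.integer(loop_e_region[2L])
  if (is.na(s) || s < 1L || e > length(seq) || e - s + 1L < 6L) {
    return(list(motif_class = "none", salt_bridge = FALSE))
  }
  w <- split_residues(substr(seq$residues, s, s + 5L))
  cls <- "none"
  for (nm in names(MOTIF_PATTERNS)) {
    if (MOTIF_PATTERNS[[nm]](w)) { cls <- nm; break }
  }
  bridge <- any(vapply(seq_len(2L), function(i) {
    w[i] %in% AA_ACIDIC && w[i + 4L] %in% AA_BASIC
  }, logical(1L)))
  list(motif_class = cls, salt_bridge = bridge)
}

#' Group conservation at the 17 helix-interface positions
#'
#' Counts how many of the reference's 17 interface positions map to a query
#' residue in the small/weakly-polar group (default G, A, S, T, C).
#' Unmappable positions count 0.
#'
#' @inheritParams locate_npa_boxes
#' @param group_set residue group (default `c("G","A","S","T","C")`).
#' @return integer in 0..17.
#' @export
interface_conservation <- function(query, aln, ref,
                                   group_set = AA_SMALL_POLAR) {
  q <- map_position(aln, ref$interface_positions)
  ok <- !is.na(q)
  chars <- substring(query$residues, q[ok], q[ok])
  sum(chars %in% group_set)
}

#' Three-criterion MIP validation
#'
#' A sequence is accepted as a MIP when (a) both NPA boxes are locatable
#' (canonical or NPA-like), (b) the topology has exactly six TM spans with
#' the loop-B and loop-E loops present, and (c) at least `min_conserved` of
#' the 17 interface positions carry the small/weakly-polar group residue.
#'
#' @param seq a [protein_sequence()].
#' @param fv feature vector from [compute_features()] (uses `npa_b`,
#'   `npa_e`, `interface_conserved`).
#' @param topo the sequence's `mip_topology`.
#' @param min_conserved minimum interface count (default 9, i.e. "most of"
#'   the 17 positions).
#' @return list with `is_mip` (logical) and `reasons` (character vector of
#'   failed criteria, empty when valid).
#' @export
validate_mip <- function(seq, fv, topo, min_conserved = 9L) {
  reasons <- character(0)
  boxes_ok <- !is.null(fv$npa_b) && !is.null(fv$npa_e) &&
    isTRUE(fv$npa_b$located) && isTRUE(fv$npa_e$located)
  if (!boxes_ok) {
    reasons <- c(reasons, "criterion-a: NPA boxes not locatable")
  }
  six_tm <- nrow(topo$tm_spans) == 6L &&
    span_length(topo$loop_spans[["LB"]]) > 0L &&
    span_length(topo$loop_spans[["LE"]]) > 0L
  if (!six_tm) {
    reasons <- c(reasons, sprintf(
      "criterion-b: %d TM spans (6 with loops B and E required)",
      nrow(topo$tm_spans)))
  }
  cons <- fv$interface_conserved
  if (is.null(cons) || is.na(cons) || cons < min_conserved) {
    reasons <- c(reasons, sprintf(
      "criterion-c: %s/17 interface positions conserved (>= %d required)",
      if (is.null(cons)) "0" else cons, min_conserved))
  }
  list(is_mip = length(reasons) == 0L, reasons = reasons)
}

#' Compute the full feature vector for one sequence
#'
#' Runs topology prediction, anchor selection and every per-sequence feature
#' extractor, then applies the three-criterion MIP validation.
#'
#' @param seq a [protein_sequence()].
#' @param refs reference annotations (default the synthetic
#'   [reference_set()]).
#' @param topo optional pre-computed topology (otherwise
#'   [predict_topology()] with defaults).
#' @param best optional pre-computed `list(ref, aln)` from
#'   [choose_reference()].
#' @param min_conserved forwarded to [validate_mip()].
#' @param pka forwarded to [compute_pi()].
#' @return an object of class `mip_features`.
#' @export
compute_features <- function(seq, refs = reference_set(), topo = NULL,
                             best = NULL, min_conserved = 9L,
                             pka = "bjellqvist") {
  if (is.null(topo)) topo <- predict_topology(seq)
  if (is.null(best)) best <- choose_reference(seq, refs)
  ref <- best$ref; aln <- best$aln
  boxes <- tryCatch(locate_npa_boxes(seq, aln, ref), error = function(e) NULL)
  arr <- extract_arr_filter(seq, aln, ref)
  ld <- tryCatch(loop_d_metrics(seq, topo), error = function(e)
    list(length = NA_integer_, charged_count = NA_integer_))
  wstart <- map_position(aln, ref$loop_e_motif_span["start"])
  motif <- if (is.na(wstart)) list(motif_class = "none", salt_bridge = FALSE)
    else detect_loop_e_motif(seq, c(wstart, wstart + 5L))
  fv <- list(
    id = seq$id,
    pI = compute_pi(seq, pka = pka),
    mw = as.numeric(compute_mw(seq, on_x = "estimate")),
    length = length(seq),
    npa_b = boxes$b, npa_e = boxes$e,
    arr = arr,
    loop_d_length = ld$length, loop_d_charged = ld$charged_count,
    loop_e_motif_class = motif$motif_class,
    salt_bridge = motif$salt_bridge,
    interface_conserved = interface_conservation(seq, aln, ref),
    ref_id = ref$ref_id,
    alignment_identity = aln$identity)
  v <- validate_mip(seq, fv, topo, min_conserved = min_conserved)
  fv$is_mip <- v$is_mip
  fv$reasons <- v$reasons
  class(fv) <- "mip_features"
  fv
}

#' @export
print.mip_features <- function(x, ...) {
  cat(sprintf(
    "<mip_features> %s: filter %s-%s-%s-%s NPA %s/%s motif %s pI %.2f MW %.0f %s\n",
    x$id, x$arr$tm2, x$arr$tm5, x$arr$le1, x$arr$le2,
    if (is.null(x$npa_b)) "?" else x$npa_b$triplet,
    if (is.null(x$npa_e)) "?" else x$npa_e$triplet,
    x$loop_e_motif_class, x$pI, x$mw,
    if (isTRUE(x$is_mip)) "[MIP]" else "[not MIP]"))
  invisible(x)
}

#' One-row data frame from a feature vector
#'
#' @param x a `mip_features` object.
#' @param ... unused.
#' @return data frame with the documented feature-table columns.
#' @export
as.data.frame.mip_features <- function(x, ...) {
  data.frame(
    id = x$id, length = x$length, pI = round(x$pI, 3), mw = round(x$mw, 1),
    npa_b = if (is.null(x$npa_b)) NA_character_ else x$npa_b$triplet,
    npa_e = if (is.null(x$npa_e)) NA_character_ else x$npa_e$triplet,
    npa_substituted = !(isTRUE(x$npa_b$canonical) && isTRUE(x$npa_e$canonical)),
    arr_tm2 = x$arr$tm2 %||% NA_character_,
    arr_tm5 = x$arr$tm5 %||% NA_character_,
    arr_le1 = x$arr$le1 %||% NA_character_,
    arr_le2 = x$arr$le2 %||% NA_character_,
    arr_complete = x$arr$complete,
    loop_d_length = x$loop_d_length, loop_d_charged = x$loop_d_charged,
    loop_e_motif_class = x$loop_e_motif_class,
    salt_bridge = x$salt_bridge,
    interface_conserved = x$interface_conserved,
    ref_id = x$ref_id,
    is_mip = x$is_mip,
    reasons = paste(x$reasons, collapse = "; "),
    stringsAsFactors = FALSE)
}

#' Position-frequency matrix for a loop region
#'
#' Tabulates residue frequencies column-wise for a set of sequences over a
#' region anchored at a reference NPA box; positions are reported relative
#' to the box's asparagine, designated 0 (sequence-logo convention).
#'
#' @param seqs list of [protein_sequence()] records.
#' @param refs reference annotations.
#' @param box `"E"` (default) or `"B"`: which NPA box anchors the region.
#' @param flank integer vector of relative positions to report (default
#'   -3..8).
#' @return numeric matrix, rows = relative positions, columns = residues.
#' @export
loop_pfm <- function(seqs, refs = reference_set(), box = c("E", "B"),
                     flank = -3:8) {
  box <- match.arg(box)
  alns <- batch_align_to_best(seqs, refs)
  counts <- matrix(0L, nrow = length(flank), ncol = length(AA_ALPHABET),
                   dimnames = list(as.character(flank), AA_ALPHABET))
  for (i in seq_along(seqs)) {
    ref <- alns[[i]]$ref
    anchor <- if (box == "E") ref$npa_e_pos else ref$npa_b_pos
    for (j in seq_along(flank)) {
      rp <- anchor + flank[j]
      if (rp < 1L || rp > length(ref$seq)) next
      q <- map_position(alns[[i]]$aln, rp)
      if (is.na(q)) next
      ch <- substr(seqs[[i]]$residues, q, q)
      counts[j, ch] <- counts[j, ch] + 1L
    }
  }
  sweep(counts, 1L, pmax(rowSums(counts), 1L), "/")
}
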