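# Annotated anchor sequences: the architecture of the six-TM hourglass fold,
# reference annotations (TM spans, NPA boxes, Ar/R filter positions, the 17
# helix-interface positions, loop-E motif window) and their file format.
#
# The deposited experimental template structures (AQP1/GlpF/AQPM) cannot be
# redistributed or fetched offline, so the anchors shipped by
# `reference_set()` are SYNTHETIC: canonical per-subfamily sequences built by
# the same architecture as the synthetic-data generator, with exactly known
# annotation. Real anchors derived from experimental structures can be
# supplied via `read_reference_annotations()`.

#' Known fungal MIP subfamily labels
#' @export
SUBFAMILIES <- c("AQP", "Fps1-like", "Yfl054-like", "alpha", "beta",
                 "gamma1", "gamma2", "delta", "XIP", "SIP-like")

# Per-subfamily sequence architecture: TM length 21 throughout; loop lengths
# chosen so that hydropathy-based topology recovery is reliable and the
# stated subfamily contrasts hold (SIP-like: longest, most charged loop D and
# short termini, hence the smallest protein; aquaglyceroporins: long termini).
mip_architecture <- function(label) {
  stopifnot(label %in% SUBFAMILIES)
  aqgp <- c("Fps1-like", "Yfl054-like", "alpha", "beta", "gamma1", "gamma2",
            "delta")
  tm <- 23L
  loops <- c(
    nt = if (label == "SIP-like") 8L else if (label == "AQP") 20L
         else if (label == "XIP") 25L else if (label == "Fps1-like") 60L else 40L,
    la = 15L, lb = 18L, lc = 15L,
    ld = if (label == "SIP-like") 26L else if (label == "AQP") 14L else 16L,
    le = 24L,
    ct = if (label == "SIP-like") 8L else if (label %in% aqgp) 30L else 20L
  )
  blocks <- c(loops["nt"], tm, loops["la"], tm, loops["lb"], tm, loops["lc"],
              tm, loops["ld"], tm, loops["le"], tm, loops["ct"])
  ends <- cumsum(blocks)
  starts <- ends - blocks + 1L
  tm_idx <- c(2L, 4L, 6L, 8L, 10L, 12L)
  tm_spans <- cbind(start = starts[tm_idx], end = ends[tm_idx])
  lb_start <- unname(starts[5L])
  ld_start <- unname(starts[9L])
  le_start <- unname(starts[11L])
  # interface offsets (within-TM, 0-based), kept away from the TM edges so
  # hydropathy runs stay intact, and avoiding the filter positions (+11)
  # TM5 hosts a filter position and sits between the charged loops D and E,
  # so it carries a single interface position; TM1 takes four
  iface_off <- list(c(5L, 9L, 13L, 17L), c(5L, 8L, 17L), c(5L, 11L, 17L),
                    c(5L, 11L, 17L), 8L, c(5L, 11L, 17L))
  interface <- unlist(lapply(seq_len(6L), function(i) {
    tm_spans[i, "start"] + iface_off[[i]]
  }))
  list(
    label = label,
    tm_len = tm,
    loop_lengths = loops,
    total_len = ends[13L],
    tm_spans = tm_spans,
    npa_b_pos = lb_start + 6L,            # box occupies +6..+8 of loop B
    npa_e_pos = le_start + 5L,            # box occupies +5..+7 of loop E
    arr_positions = c(tm2 = unname(tm_spans[2L, "start"] + 11L),
                      tm5 = unname(tm_spans[5L, "start"] + 11L),
                      le1 = le_start + 2L,
                      le2 = le_start + 8L),
    loop_e_motif_span = c(start = le_start + 8L, end = le_start + 13L),
    ld_span = c(start = ld_start, end = ld_start + loops[["ld"]] - 1L),
    interface_positions = unname(interface),
    # how many of the 17 interface positions carry the small/weakly polar
    # group residue in generated members (14 for SIP-like, as published)
    interface_group_n = if (label == "SIP-like") 14L else 16L
  )
}

#' Create a reference annotation
#'
#' An annotated anchor sequence carrying the six TM spans, the start
#' positions of the two NPA boxes, the four Ar/R filter positions, the 17
#' helix-interface positions and the loop-E motif window. All coordinates
#' are 1-based inclusive.
#'
#' @param ref_id anchor identifier.
#' @param seq a [protein_sequence()] record.
#' @param tm_spans 6 x 2 matrix of TM `[start, end]` intervals.
#' @param npa_b_pos,npa_e_pos start position of the loop-B / loop-E NPA box
#'   (each box covers three residues); the reference residues there must be
#'   exactly `NPA`.
#' @param arr_positions named integer vector with elements `tm2`, `tm5`,
#'   `le1`, `le2`; `tm2`/`tm5` must fall inside TM spans 2/5, `le1`/`le2`
#'   inside the loop between TM5 and TM6, with `le1 < le2`.
#' @param interface_positions integer vector of 17 positions.
#' @param loop_e_motif_span `[start, end]` of the 6-residue window following
#'   the loop-E NPA box.
#' @param subfamily optional subfamily label carried by the anchor (used for
#'   clade labeling).
#' @return an object of class `mip_ref`.
#' @export
reference_annotation <- function(ref_id, seq, tm_spans, npa_b_pos, npa_e_pos,
                                 arr_positions, interface_positions,
                                 loop_e_motif_span, subfamily = NA_character_) {
  stopifnot(inherits(seq, "mip_seq"), nrow(tm_spans) == 6L)
  tm_spans <- matrix(as.integer(tm_spans), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  res <- seq$residues
  for (p in c(npa_b_pos, npa_e_pos)) {
    if (substr(res, p, p + 2L) != "NPA") {
      stop(sprintf("reference '%s': residues at %d..%d are '%s', expected NPA",
                   ref_id, p, p + 2L, substr(res, p, p + 2L)))
    }
  }
  arr_positions <- arr_positions[c("tm2", "tm5", "le1", "le2")]
  if (anyNA(arr_positions)) stop("arr_positions must name tm2, tm5, le1, le2")
  in_span <- function(p, i) p >= tm_spans[i, 1L] && p <= tm_spans[i, 2L]
  if (!in_span(arr_positions["tm2"], 2L)) stop("arr tm2 position not in TM2")
  if (!in_span(arr_positions["tm5"], 5L)) stop("arr tm5 position not in TM5")
  le_lo <- tm_spans[5L, 2L] + 1L; le_hi <- tm_spans[6L, 1L] - 1L
  if (arr_positions["le1"] < le_lo || arr_positions["le2"] > le_hi ||
      arr_positions["le1"] >= arr_positions["le2"]) {
    stop("le1/le2 must lie inside loop E with le1 < le2")
  }
  if (length(interface_positions) != 17L) {
    stop("interface_positions must have length 17")
  }
  structure(
    list(ref_id = ref_id, seq = seq, tm_spans = tm_spans,
         npa_b_pos = as.integer(npa_b_pos), npa_e_pos = as.integer(npa_e_pos),
         arr_positions = vapply(arr_positions, as.integer, integer(1L)),
         interface_positions = as.integer(interface_positions),
         loop_e_motif_span = setNames(as.integer(loop_e_motif_span),
                                      c("start", "end")),
         subfamily = subfamily),
    class = "mip_ref")
}

#' @export
print.mip_ref <- function(x, ...) {
  cat(sprintf("<mip_ref> %s (%d aa, subfamily %s)\n", x$ref_id,
              length(x$seq), x$subfamily))
  invisible(x)
}

#' Synthetic reference anchor set
#'
#' One canonical annotated anchor per subfamily, built in code from the
#' package's sequence architecture (synthetic stand-ins for
#' structure-derived anchors, which cannot be shipped). Anchors carry
#' canonical NPA boxes and deterministic filter residues, and are suitable
#' both for position mapping and as labeled leaves for clade assignment.
#'
#' @param labels subfamily labels (default: all ten).
#' @return named list of `mip_ref` objects (names are `ref_id`s like
#'   `"REF_delta"`).
#' @export
reference_set <- function(labels = SUBFAMILIES) {
  out <- lapply(labels, function(lab) {
    tpl <- make_subfamily_template(lab)
    canonical_reference(tpl)
  })
  names(out) <- vapply(out, function(r) r$ref_id, character(1L))
  out
}

#' Write reference annotations to a JSON file
#'
#' @param refs list of `mip_ref` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_annotations <- function(refs, path) {
  payload <- lapply(unname(refs), function(r) {
    list(ref_id = r$ref_id, subfamily = r$subfamily,
         residues = r$seq$residues, description = r$seq$description,
         tm_spans = unname(apply(r$tm_spans, 1L, as.list)),
         npa_b_pos = r$npa_b_pos, npa_e_pos = r$npa_e_pos,
         arr_positions = as.list(r$arr_positions),
         interface_positions = r$interface_positions,
         loop_e_motif_span = as.list(r$loop_e_motif_span))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read reference annotations from a JSON file
#'
#' Inverse of [write_reference_annotations()]; use this to supply real
#' anchors derived from experimental MIP structures.
#'
#' @param path JSON file written by [write_reference_annotations()].
#' @return named list of `mip_ref` objects.
#' @export
read_reference_annotations <- function(path) {
  payload <- jsonlite::read_json(path)
  out <- lapply(payload, function(p) {
    reference_annotation(
      ref_id = p$ref_id,
      seq = protein_sequence(p$ref_id, p$residues,
                             description = p$description %||% ""),
      tm_spans = do.call(rbind, lapply(p$tm_spans, unlist)),
      npa_b_pos = p$npa_b_pos, npa_e_pos = p$npa_e_pos,
      arr_positions = unlist(p$arr_positions),
      interface_positions = unlist(p$interface_positions),
      loop_e_motif_span = unlist(p$loop_e_motif_span),
      subfamily = p$subfamily %||% NA_character_)
  })
  names(out) <- vapply(out, function(r) r$ref_id, character(1L))
  out
}
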