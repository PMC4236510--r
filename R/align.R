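# Global pairwise alignment (Needleman-Wunsch, affine gaps) and position
# mapping onto annotated reference channels. Alignment is computed by
# Biostrings::pairwiseAlignment; identity/similarity conventions and the
# position map are defined here.

#' Global pairwise alignment of two protein sequences
#'
#' Optimal global (Needleman-Wunsch) alignment with affine gap penalties.
#' Identity is the fraction of matching columns among mutually non-gap
#' columns (columns where either residue is `X` never count as matches);
#' similarity is the fraction of mutually non-gap columns with a positive
#' substitution score. With `identity_denom = "columns"` the denominator is
#' the full alignment length instead.
#'
#' @param a,b [protein_sequence()] records (`a` is the query, `b` the
#'   reference for [map_position()]).
#' @param matrix substitution matrix name or matrix (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 0.5).
#' @param identity_denom `"nongap"` (default) or `"columns"`.
#' @return an object of class `mip_alignment` with fields `aligned_query`,
#'   `aligned_ref`, `score`, `identity`, `similarity` and the internal
#'   ref-to-query position map.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, identity_denom = c("nongap", "columns")) {
  stopifnot(inherits(a, "mip_seq"), inherits(b, "mip_seq"))
  if (!nchar(a$residues) || !nchar(b$residues)) stop("empty sequence")
  identity_denom <- match.arg(identity_denom)
  mat <- substitution_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend,
    type = "global")
  new_alignment(as.character(Biostrings::alignedPattern(pa)),
                as.character(Biostrings::alignedSubject(pa)),
                score = Biostrings::score(pa), matrix = mat,
                identity_denom = identity_denom,
                query_id = a$id, ref_id = b$id)
}

# Build a mip_alignment from the two gapped rows.
new_alignment <- function(aq, ar, score, matrix, identity_denom = "nongap",
                          query_id = NA_character_, ref_id = NA_character_) {
  qc <- split_residues(aq)
  rc <- split_residues(ar)
  stopifnot(length(qc) == length(rc))
  nongap <- qc != "-" & rc != "-"
  denom <- if (identity_denom == "columns") length(qc) else sum(nongap)
  matches <- sum(nongap & qc == rc & qc != "X" & rc != "X")
  pos_score <- if (sum(nongap)) {
    idx <- cbind(match(qc[nongap], rownames(matrix)),
                 match(rc[nongap], colnames(matrix)))
    sum(matrix[idx] > 0, na.rm = TRUE)
  } else 0L
  # map: for each reference position, the query position aligned to it
  qpos <- cumsum(qc != "-")
  map <- ifelse(qc != "-", qpos, NA_integer_)[rc != "-"]
  structure(
    list(aligned_query = aq, aligned_ref = ar, score = unname(score),
         identity = if (denom) matches / denom else 0,
         similarity = if (denom) pos_score / denom else 0,
         map = as.integer(map), query_id = query_id, ref_id = ref_id),
    class = "mip_alignment")
}

#' @export
print.mip_alignment <- function(x, ...) {
  cat(sprintf("<mip_alignment> %s vs %s score=%.1f identity=%.3f similarity=%.3f\n",
              x$query_id, x$ref_id, x$score, x$identity, x$similarity))
  invisible(x)
}

#' Map a reference position onto the query
#'
#' @param aln a `mip_alignment` from [global_align()] (query = first input,
#'   reference = second).
#' @param ref_pos 1-based position in the ungapped reference.
#' @return the 1-based query position aligned to `ref_pos`, or `NA` if the
#'   reference position is aligned to a gap in the query.
#' @export
map_position <- function(aln, ref_pos) {
  stopifnot(inherits(aln, "mip_alignment"))
  if (any(ref_pos < 1L) || any(ref_pos > length(aln$map))) {
    stop("ref_pos out of range")
  }
  aln$map[ref_pos]
}

#' Select the best-matching annotated reference for a query
#'
#' Aligns the query against every reference and returns the one with maximal
#' alignment score; ties are broken by lexicographic `ref_id`.
#'
#' @param query a [protein_sequence()] record.
#' @param refs list of reference annotations (see
#'   [reference_annotation()]).
#' @param ... passed to [global_align()].
#' @return list with `ref` (the chosen reference) and `aln` (its
#'   `mip_alignment`).
#' @export
choose_reference <- function(query, refs, ...) {
  stopifnot(length(refs) >= 1L)
  ids <- vapply(refs, function(r) r$ref_id, character(1L))
  scores <- vapply(refs, function(r) {
    alignment_score(query, r$seq, ...)
  }, numeric(1L))
  best <- order(-scores, ids)[1L]
  list(ref = refs[[best]], aln = global_align(query, refs[[best]]$seq, ...))
}

# score-only alignment (fast path used by choose_reference and batch scans)
alignment_score <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                            gap_extend = 0.5, ...) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    substitutionMatrix = substitution_matrix(matrix),
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global", scoreOnly = TRUE)
}

# Batched choose_reference + full alignment for many queries: one vectorized
# scoreOnly call per reference, then one vectorized full alignment call per
# chosen-reference group. Returns a list (per query) of list(ref, aln).
batch_align_to_best <- function(seqs, refs, matrix = "BLOSUM62", gap_open = 10,
                                gap_extend = 0.5, identity_denom = "nongap") {
  if (!length(seqs)) return(list())
  ids <- vapply(refs, function(r) r$ref_id, character(1L))
  ord <- order(ids)
  refs <- refs[ord]
  ids <- ids[ord]
  mat <- substitution_matrix(matrix)
  qset <- as_aastringset(seqs)
  scores <- vapply(refs, function(r) {
    Biostrings::pairwiseAlignment(
      qset, Biostrings::AAString(r$seq$residues), substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend,
      type = "global", scoreOnly = TRUE)
  }, numeric(length(seqs)))
  if (length(seqs) == 1L) scores <- matrix(scores, nrow = 1L)
  best <- apply(scores, 1L, which.max)  # ties: first index = lexicographic id
  out <- vector("list", length(seqs))
  for (ri in unique(best)) {
    sel <- which(best == ri)
    pa <- Biostrings::pairwiseAlignment(
      qset[sel], Biostrings::AAString(refs[[ri]]$seq$residues),
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global")
    aq <- as.character(Biostrings::alignedPattern(pa))
    ar <- as.character(Biostrings::alignedSubject(pa))
    sc <- Biostrings::score(pa)
    for (j in seq_along(sel)) {
      out[[sel[j]]] <- list(
        ref = refs[[ri]],
        aln = new_alignment(aq[j], ar[j], sc[j], mat,
                            identity_denom = identity_denom,
                            query_id = seqs[[sel[j]]]$id, ref_id = ids[ri]))
    }
  }
  out
}
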