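# Six-transmembrane topology assignment: Kyte-Doolittle hydropathy profile,
# threshold-based TM span prediction, and import of externally predicted spans.

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Centered sliding-window mean of Kyte-Doolittle hydropathy values; at the
#' sequence ends the window shrinks to the available residues.
#'
#' @param seq a [protein_sequence()] record.
#' @param window odd window size, at most the sequence length (default 19, a
#'   standard transmembrane-detection setting).
#' @return numeric vector of per-residue scores.
#' @export
hydropathy_profile <- function(seq, window = 19L) {
  stopifnot(inherits(seq, "mip_seq"))
  n <- length(seq)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > n) stop("window larger than sequence length")
  v <- unname(KD_HYDROPATHY[split_residues(seq$residues)])
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

new_topology <- function(tm_spans, seq_len) {
  if (is.null(tm_spans) || NROW(tm_spans) == 0L) {
    tm_spans <- matrix(integer(0), ncol = 2L)
  }
  tm_spans <- matrix(as.integer(tm_spans), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  k <- nrow(tm_spans)
  if (k) {
    if (any(tm_spans[, 1L] > tm_spans[, 2L])) stop("invalid span: start > end")
    if (any(tm_spans < 1L) || any(tm_spans > seq_len)) {
      stop("span out of sequence range")
    }
    if (k > 1L && any(tm_spans[-1L, 1L] <= tm_spans[-k, 2L])) {
      stop("tm spans must be non-overlapping and strictly increasing")
    }
  }
  # loops: complements of the TM spans, named canonically for 6-TM topologies
  loop_names <- if (k == 6L) c("Nterm", "LA", "LB", "LC", "LD", "LE", "Cterm")
    else c("Nterm", if (k >= 2L) paste0("L", seq_len(k - 1L)), if (k >= 1L) "Cterm")
  bounds_start <- c(1L, if (k) tm_spans[, 2L] + 1L)
  bounds_end <- c(if (k) tm_spans[, 1L] - 1L, as.integer(seq_len))
  loops <- lapply(seq_along(bounds_start), function(i) {
    c(start = bounds_start[i], end = bounds_end[i])  # empty when start > end
  })
  names(loops) <- loop_names[seq_along(loops)]
  structure(list(tm_spans = tm_spans, loop_spans = loops,
                 seq_len = as.integer(seq_len)),
            class = "mip_topology")
}

#' @export
print.mip_topology <- function(x, ...) {
  cat(sprintf("<mip_topology> %d TM span(s) over %d residues\n",
              nrow(x$tm_spans), x$seq_len))
  invisible(x)
}

#' Predict transmembrane topology from hydropathy
#'
#' Maximal runs of positions whose windowed hydropathy is at or above
#' `threshold` become candidate TM spans. Runs longer than `max_len` are
#' split into near-equal contiguous pieces; runs shorter than `min_len` are
#' discarded unless their hydropathy peak reaches `peak_threshold` (the
#' classical two-cutoff refinement: a short run with a strongly hydrophobic
#' core is still a certain TM, while marginal short runs are noise). Loop
#' spans (including the termini) are the complements of the TM spans; for a
#' 6-TM topology they are named `Nterm, LA, LB, LC, LD, LE, Cterm`.
#'
#' @inheritParams hydropathy_profile
#' @param threshold hydropathy cutoff (default 1.6).
#' @param min_len,max_len allowed TM span lengths (defaults 15/30 residues).
#' @param peak_threshold upper cutoff rescuing short runs (default 2.6);
#'   only runs of at least `min_len - 6` positions qualify.
#' @return a `mip_topology` object (possibly with zero TM spans).
#' @export
predict_topology <- function(seq, window = 19L, threshold = 1.6,
                             min_len = 15L, max_len = 30L,
                             peak_threshold = 2.6) {
  stopifnot(inherits(seq, "mip_seq"))
  if (length(seq) < min_len) stop("sequence shorter than min_len")
  prof <- hydropathy_profile(seq, window = window)
  above <- prof >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spans <- cbind(starts[r$values], ends[r$values])
  out <- matrix(integer(0), ncol = 2L)
  if (NROW(spans)) {
    for (i in seq_len(nrow(spans))) {
      s <- spans[i, 1L]; e <- spans[i, 2L]
      L <- e - s + 1L
      if (L < min_len) {
        if (L >= min_len - 6L && max(prof[s:e]) >= peak_threshold) {
          out <- rbind(out, c(s, e))
        }
        next
      }
      k <- ceiling(L / max_len)
      cuts <- round(seq(s - 1L, e, length.out = k + 1L))
      for (j in seq_len(k)) {
        ps <- cuts[j] + 1L; pe <- cuts[j + 1L]
        if (pe - ps + 1L >= min_len) out <- rbind(out, c(ps, pe))
      }
    }
  }
  new_topology(out, length(seq))
}

#' Build a topology from externally supplied TM spans
#'
#' Accepts spans produced by an external predictor (e.g. TMHMM) verbatim.
#'
#' @param seq a [protein_sequence()] record.
#' @param spans two-column matrix (or list of length-2 vectors) of 1-based
#'   inclusive `[start, end]` TM intervals, sorted and within sequence
#'   bounds; an empty set yields a topology whose single `Nterm` loop covers
#'   the sequence.
#' @return a `mip_topology` object.
#' @export
import_topology <- function(seq, spans) {
  stopifnot(inherits(seq, "mip_seq"))
  if (is.list(spans)) spans <- do.call(rbind, spans)
  new_topology(spans, length(seq))
}

# interval helpers
span_length <- function(span) {
  if (is.null(span) || span["start"] > span["end"]) 0L
  else as.integer(span["end"] - span["start"] + 1L)
}

span_residues <- function(seq, span) {
  if (span_length(span) == 0L) return("")
  substr(seq$residues, span["start"], span["end"])
}
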