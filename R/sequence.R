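# ProteinSequence records and FASTA input/output.

#' Create a protein sequence record
#'
#' The unit flowing through the pipeline: an identifier, free-text
#' description, and an uppercase residue string over the 20 standard
#' amino-acid one-letter codes plus `X`.
#'
#' @param id unique identifier (first whitespace-delimited token of a FASTA
#'   header).
#' @param residues residue string; uppercased, whitespace and digits are
#'   stripped before validation.
#' @param description free-text description (rest of the FASTA header).
#' @param taxon_label optional taxon string.
#' @return an object of class `mip_seq`.
#' @examples
#' s <- protein_sequence("q1", "acDE")
#' s$residues  # "ACDE"
#' @export
protein_sequence <- function(id, residues, description = "", taxon_label = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  res <- normalize_residues(residues)
  bad <- which(!split_residues(res) %in% AA_ALPHABET)
  if (length(bad)) {
    stop(sprintf("record '%s': illegal residue character '%s' at position %d",
                 id, substr(res, bad[1L], bad[1L]), bad[1L]))
  }
  if (!nzchar(res)) stop(sprintf("record '%s': empty residue string", id))
  structure(
    list(id = id, description = description %||% "", residues = res,
         taxon_label = taxon_label),
    class = "mip_seq"
  )
}

normalize_residues <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  toupper(gsub("[[:space:][:digit:]]", "", x))
}

#' @export
print.mip_seq <- function(x, ...) {
  cat(sprintf("<mip_seq> %s (%d aa) %s\n", x$id, nchar(x$residues),
              x$description))
  invisible(x)
}

#' @export
length.mip_seq <- function(x) nchar(x$residues)

seq_ids <- function(seqs) vapply(seqs, function(s) s$id, character(1L))

as_aastringset <- function(seqs) {
  Biostrings::AAStringSet(setNames(
    vapply(seqs, function(s) s$residues, character(1L)), seq_ids(seqs)))
}

#' Read protein sequences from a FASTA file
#'
#' One record per FASTA entry, order preserved. Residues are uppercased and
#' whitespace/digits stripped; any remaining character outside the amino-acid
#' alphabet (20 codes plus X) is a parse error naming the record and
#' position. Record ids (first header token) must be unique.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return list of [protein_sequence()] records (empty list for an empty
#'   file).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) return(list())
  headers <- names(set)
  if (any(!nzchar(trimws(headers)))) {
    stop("malformed FASTA header: empty header at record ",
         which(!nzchar(trimws(headers)))[1L])
  }
  ids <- vapply(strsplit(trimws(headers), "[[:space:]]+"), `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in '", path, "': ", ids[duplicated(ids)][1L])
  }
  desc <- vapply(seq_along(headers), function(i) {
    h <- trimws(headers[i])
    sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", ids[i]),
               "[[:space:]]*"), "", h)
  }, character(1L))
  lapply(seq_along(set), function(i) {
    protein_sequence(ids[i], as.character(set[[i]]), description = desc[i])
  })
}

#' Write protein sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(seqs, f))` returns the
#' same records (ids, descriptions, residues).
#'
#' @param seqs list of [protein_sequence()] records.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(vapply(seqs, function(s) s$residues, character(1L)))
  names(set) <- vapply(seqs, function(s) {
    if (nzchar(s$description)) paste(s$id, s$description) else s$id
  }, character(1L))
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Remove redundant sequences by greedy identity clustering
#'
#' CD-HIT-like greedy incremental clustering: sequences are visited in
#' descending length order (ties broken by id), and a sequence is dropped if
#' its pairwise global-alignment identity (see [global_align()]) to an
#' already-kept sequence is at or above `identity_threshold`. Columns
#' containing `X` never count as matches.
#'
#' @param seqs list of [protein_sequence()] records (at least one).
#' @param identity_threshold fraction in (0, 1]; default 1.0 keeps everything
#'   except exact-identity duplicates.
#' @param ... passed to [global_align()] (scoring parameters).
#' @return list with `kept` (records, in visit order) and `removed_map`
#'   (named character vector: removed id -> retained id).
#' @export
dedup_sequences <- function(seqs, identity_threshold = 1.0, ...) {
  stopifnot(length(seqs) >= 1L)
  if (!is.numeric(identity_threshold) || length(identity_threshold) != 1L ||
      identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be a fraction in (0, 1]")
  }
  ids <- seq_ids(seqs)
  if (anyDuplicated(ids)) stop("duplicate sequence ids: ", ids[duplicated(ids)][1L])
  lens <- vapply(seqs, length, integer(1L))
  ord <- order(-lens, ids)
  kept <- list()
  removed <- character(0)
  for (k in ord) {
    s <- seqs[[k]]
    hit <- NULL
    for (r in kept) {
      aln <- global_align(s, r, ...)
      if (aln$identity >= identity_threshold) { hit <- r$id; break }
    }
    if (is.null(hit)) {
      kept[[length(kept) + 1L]] <- s
    } else {
      removed[s$id] <- hit
    }
  }
  list(kept = kept, removed_map = removed)
}
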