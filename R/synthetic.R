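# Synthetic MIP-like sequence generator. Emulates the six-TM hourglass
# architecture with loops B and E carrying the NPA boxes, subfamily-specific
# Ar/R filter compositions, per-box NPA substitution rates matching the
# published per-subfamily percentages, loop-D length/charge contrasts
# (longest and most charged in SIP-like) and per-subfamily loop-E motif
# classes. Every planted feature is recorded as ground truth.

MOTIF_CLASSES <- c("AQGP-core", "AQGP-delta", "AQP-type", "XIP-type", "none")

#' Synthetic-sequence template for a subfamily
#'
#' Builds the per-subfamily generation spec: a deterministic backbone laid
#' out by the package architecture (the "stated world" for that subfamily),
#' the allowed Ar/R filter residue sets (taken from the shipped rule table),
#' per-box NPA substitution rates whose combined per-sequence rate equals
#' the published subfamily percentage, the loop-E motif class, and loop-D
#' charge density. The backbone is fixed per label; per-sequence variation
#' comes from [generate_sequence()].
#'
#' @param label one of [SUBFAMILIES].
#' @param rules rule table supplying filter residue sets and NPA
#'   percentages.
#' @return an object of class `mip_synth_spec`.
#' @export
make_subfamily_template <- function(label, rules = load_rule_table("fungal")) {
  if (!label %in% SUBFAMILIES) stop("unknown subfamily label: ", label)
  arch <- mip_architecture(label)
  r <- rules[[label]]
  if (is.null(r)) stop("rule table has no row for ", label)
  aqgp_core <- c("Fps1-like", "Yfl054-like", "alpha", "beta", "gamma1", "gamma2")
  motif_class <- if (label %in% aqgp_core) "AQGP-core"
    else if (label == "delta") "AQGP-delta"
    else if (label == "AQP") "AQP-type"
    else if (label == "XIP") "XIP-type"
    else "none"
  pct <- r$npa_pct
  if (is.na(pct)) pct <- 0
  # place the whole substitution probability on the loop-E box (where the
  # substitution is characterized: the LE proline in delta/alpha/Fps1-like,
  # the LE alanine in SIP-like); delta additionally
  # substitutes the loop-B box in a minority of members while its loop-E box
  # is always substituted.
  proline_style <- label %in% c("delta", "alpha", "Fps1-like", "Yfl054-like")
  npa_e_sub <- list(rate = pct / 100, offset = if (proline_style) 2L else 3L,
                    repl = if (proline_style) c("L", "A", "S")
                           else c("S", "G", "V", "T"))
  npa_b_sub <- list(rate = 0, offset = 1L, repl = c("S", "H"))
  if (label == "delta") {
    npa_e_sub$rate <- 1.0
    npa_b_sub$rate <- 0.3
  }
  spec <- structure(
    list(label = label,
         tm_length = arch$tm_len,
         loop_lengths = arch$loop_lengths,
         filter_choice = list(tm2 = r$tm2, tm5 = r$tm5, le1 = r$le1,
                              le2 = r$le2),
         npa_b_sub = npa_b_sub, npa_e_sub = npa_e_sub,
         loop_e_motif_class = motif_class,
         loop_d_charge_frac = if (label == "SIP-like") 0.6 else 0.25,
         mutation_rate = 0.02,
         arch = arch,
         backbone = NULL),
    class = "mip_synth_spec")
  spec$backbone <- with_seed(label_seed(label), template_backbone(spec))
  spec
}

#' @export
print.mip_synth_spec <- function(x, ...) {
  cat(sprintf("<mip_synth_spec> %s (%d aa, motif %s, NPA rates B=%.2f E=%.2f)\n",
              x$label, x$arch$total_len, x$loop_e_motif_class,
              x$npa_b_sub$rate, x$npa_e_sub$rate))
  invisible(x)
}

# Deterministic backbone: TM cores from the strongly hydrophobic set, loops
# uniform over the 20 standard residues, interface positions carrying the
# small/weakly-polar group residues, canonical NPA boxes, canonical filter
# and motif residues. Caller seeds the RNG.
template_backbone <- function(spec) {
  arch <- spec$arch
  n <- arch$total_len
  res <- sample(AA_STANDARD, n, replace = TRUE)
  for (i in seq_len(6L)) {
    idx <- arch$tm_spans[i, "start"]:arch$tm_spans[i, "end"]
    res[idx] <- sample(AA_TM_BACKGROUND, length(idx), replace = TRUE)
  }
  # hydrophilic caps on the two loop residues flanking each TM (the
  # positive-inside/charged-flank character of real membrane proteins);
  # keeps hydropathy runs from bleeding across short loops
  capset <- c("K", "R", "D", "E", "N", "Q")
  for (i in seq_len(6L)) {
    lo <- arch$tm_spans[i, "start"] - 2L:1L
    hi <- arch$tm_spans[i, "end"] + 1L:2L
    at <- c(lo[lo >= 1L], hi[hi <= n])
    res[at] <- sample(capset, length(at), replace = TRUE)
  }
  gi <- arch$interface_positions
  ng <- arch$interface_group_n
  res[gi[seq_len(ng)]] <- sample(c("G", "A", "S", "T"), ng, replace = TRUE)
  if (ng < 17L) res[gi[(ng + 1L):17L]] <- sample(AA_TM_BACKGROUND,
                                                 17L - ng, replace = TRUE)
  res[arch$npa_b_pos + 0:2] <- c("N", "P", "A")
  res[arch$npa_e_pos + 0:2] <- c("N", "P", "A")
  pick <- function(set) if ("R" %in% set) "R" else set[1L]
  res[arch$arr_positions["tm2"]] <- spec$filter_choice$tm2[1L]
  res[arch$arr_positions["tm5"]] <- spec$filter_choice$tm5[1L]
  res[arch$arr_positions["le1"]] <- spec$filter_choice$le1[1L]
  res[arch$arr_positions["le2"]] <- pick(spec$filter_choice$le2)
  w <- arch$loop_e_motif_span["start"]:arch$loop_e_motif_span["end"]
  res[w] <- canonical_motif(spec$loop_e_motif_class,
                            le2 = res[arch$arr_positions["le2"]])
  res
}

canonical_motif <- function(class, le2 = "R") {
  switch(class,
         "AQGP-core" = c("R", "D", "L", "G", "P", "R"),
         "AQGP-delta" = c("R", "D", "L", "G", "A", "R"),
         "AQP-type" = c("R", "S", "L", "G", "P", "A"),
         "XIP-type" = c("R", "C", "L", "G", "A", "A"),
         "none" = c(le2, "S", "T", "N", "Q", "S"))
}

# Draw the per-sequence motif window for a class; window[1] must equal the
# drawn LE2 filter residue.
draw_motif <- function(class, le2) {
  x <- function(n = 1L) sample(AA_STANDARD, n, replace = TRUE)
  if (class %in% c("AQGP-core", "AQGP-delta", "XIP-type") && le2 != "R") {
    class <- "none"  # a non-arginine LE2 breaks the motif (XIP K members)
  }
  w <- switch(class,
    "AQGP-core" = c("R", "D", x(), "G", "P", "R"),
    "AQGP-delta" = c("R", "D", x(), "G",
                     sample(setdiff(AA_STANDARD, "P"), 1L), "R"),
    "AQP-type" = c("R", sample(c("S", "A"), 1L), x(), "G",
                   sample(c("P", "A"), 1L), sample(c("A", "C", "D", "S"), 1L)),
    "XIP-type" = c("R", "C", x(), sample(c("G", "A"), 1L), x(), x()),
    "none" = c(le2, sample(setdiff(AA_STANDARD, c("R")), 5L, replace = TRUE)))
  list(window = w, class = class)
}

#' Canonical annotated anchor for a subfamily template
#'
#' The template backbone itself, wrapped as a [reference_annotation()]
#' (canonical NPA boxes, deterministic filter residues). These synthetic
#' anchors are what [reference_set()] returns.
#'
#' @param spec a template from [make_subfamily_template()].
#' @return a `mip_ref`.
#' @export
canonical_reference <- function(spec) {
  stopifnot(inherits(spec, "mip_synth_spec"))
  arch <- spec$arch
  res <- spec$backbone
  # deterministic loop-D charges so the anchor shares the subfamily's loop-D
  # character
  k <- round(spec$loop_d_charge_frac * arch$loop_lengths[["ld"]])
  ld <- arch$ld_span["start"]:arch$ld_span["end"]
  if (k > 0) res[ld[seq_len(k)]] <- rep_len(AA_CHARGED, k)
  seq <- protein_sequence(paste0("REF_", spec$label),
                          paste(res, collapse = ""),
                          description = sprintf(
                            "synthetic canonical anchor subfamily=%s",
                            spec$label))
  reference_annotation(
    ref_id = paste0("REF_", spec$label), seq = seq,
    tm_spans = arch$tm_spans, npa_b_pos = arch$npa_b_pos,
    npa_e_pos = arch$npa_e_pos, arr_positions = arch$arr_positions,
    interface_positions = arch$interface_positions,
    loop_e_motif_span = arch$loop_e_motif_span, subfamily = spec$label)
}

#' Generate one synthetic MIP sequence with ground truth
#'
#' Starts from the subfamily backbone and plants, per sequence: the four
#' Ar/R filter residues (drawn from the subfamily's allowed sets), the two
#' NPA boxes (substituted at the subfamily's per-box rates), the loop-E
#' motif window and loop-D charged residues; background mutations are then
#' applied outside the planted sites (TM positions mutate within the
#' hydrophobic set, loop positions over all 20 residues) at
#' `mutation_rate`. Deterministic for a fixed seed.
#'
#' @param spec template from [make_subfamily_template()].
#' @param seed integer seed for this sequence.
#' @param id sequence identifier.
#' @param mutation_rate background per-residue mutation probability;
#'   defaults to the template's rate.
#' @return list with `seq` (a [protein_sequence()]) and `truth` (planted
#'   filter, NPA triplets, motif class and window, TM spans, loop-D span,
#'   label).
#' @export
generate_sequence <- function(spec, seed, id = NULL,
                              mutation_rate = spec$mutation_rate) {
  stopifnot(inherits(spec, "mip_synth_spec"))
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate in [0,1]")
  arch <- spec$arch
  if (is.null(id)) id <- sprintf("%s_s%d", gsub("[^A-Za-z0-9]", "", spec$label), seed)
  with_seed(seed, {
    res <- spec$backbone
    # filter residues
    filt <- c(tm2 = sample(spec$filter_choice$tm2, 1L),
              tm5 = sample(spec$filter_choice$tm5, 1L),
              le1 = sample(spec$filter_choice$le1, 1L),
              le2 = sample(spec$filter_choice$le2, 1L))
    res[arch$arr_positions] <- filt
    # NPA boxes
    plant_box <- function(sub) {
      box <- c("N", "P", "A")
      if (runif(1L) < sub$rate) {
        box[sub$offset] <- sample(sub$repl, 1L)
      }
      box
    }
    npa_b <- plant_box(spec$npa_b_sub)
    npa_e <- plant_box(spec$npa_e_sub)
    res[arch$npa_b_pos + 0:2] <- npa_b
    res[arch$npa_e_pos + 0:2] <- npa_e
    # loop-E motif window
    mot <- draw_motif(spec$loop_e_motif_class, filt[["le2"]])
    wspan <- arch$loop_e_motif_span["start"]:arch$loop_e_motif_span["end"]
    res[wspan] <- mot$window
    # loop-D charges, placed in the loop interior (the flanking positions
    # already carry the charged caps)
    ld <- arch$ld_span["start"]:arch$ld_span["end"]
    k <- round(spec$loop_d_charge_frac * length(ld))
    interior <- ld[3:(length(ld) - 2L)]
    if (k > 0) {
      at <- sample(interior, min(k, length(interior)))
      res[at] <- sample(AA_CHARGED, length(at), replace = TRUE)
    }
    # background mutations outside planted sites
    planted <- c(arch$arr_positions, arch$npa_b_pos + 0:2,
                 arch$npa_e_pos + 0:2, wspan, arch$interface_positions)
    if (mutation_rate > 0) {
      in_tm <- logical(length(res))
      for (i in seq_len(6L)) {
        in_tm[arch$tm_spans[i, "start"]:arch$tm_spans[i, "end"]] <- TRUE
      }
      hit <- which(runif(length(res)) < mutation_rate)
      hit <- setdiff(hit, planted)
      if (length(hit)) {
        tm_hit <- hit[in_tm[hit]]
        lp_hit <- hit[!in_tm[hit]]
        if (length(tm_hit)) res[tm_hit] <- sample(AA_TM_BACKGROUND,
                                                  length(tm_hit), replace = TRUE)
        if (length(lp_hit)) res[lp_hit] <- sample(AA_STANDARD,
                                                  length(lp_hit), replace = TRUE)
      }
    }
    list(
      seq = protein_sequence(id, paste(res, collapse = ""),
                             description = paste0("subfamily=", spec$label)),
      truth = list(
        id = id, label = spec$label, filter = filt,
        npa_b = paste(npa_b, collapse = ""),
        npa_e = paste(npa_e, collapse = ""),
        motif_class = mot$class,
        motif_window = paste(mot$window, collapse = ""),
        tm_spans = arch$tm_spans, ld_span = arch$ld_span))
  })
}

#' Generate a labeled synthetic dataset
#'
#' Per-sequence seeds are derived from the master seed by counter, so any
#' subset regenerates reproducibly; regeneration with the same arguments is
#' byte-identical. FASTA descriptions carry the ground-truth label
#' (`subfamily=<label>`).
#'
#' @param labels subfamily labels to generate.
#' @param n_per_label sequences per label.
#' @param seed master seed.
#' @param mutation_rate optional override of each template's background
#'   mutation rate.
#' @param templates optional pre-built templates (named by label).
#' @return list with `seqs` (list of records) and `truth` (data frame, one
#'   row per sequence: id, label, planted filter residues, NPA triplets,
#'   motif class and window).
#' @export
generate_dataset <- function(labels, n_per_label, seed, mutation_rate = NULL,
                             templates = NULL) {
  stopifnot(all(labels %in% SUBFAMILIES), n_per_label >= 1L)
  if (is.null(templates)) {
    templates <- lapply(labels, make_subfamily_template)
    names(templates) <- labels
  }
  seqs <- list()
  rows <- list()
  counter <- 0L
  for (lab in labels) {
    tpl <- templates[[lab]]
    for (i in seq_len(n_per_label)) {
      counter <- counter + 1L
      g <- generate_sequence(
        tpl, seed = derive_seed(seed, counter),
        id = sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", lab), i),
        mutation_rate = mutation_rate %||% tpl$mutation_rate)
      seqs[[length(seqs) + 1L]] <- g$seq
      t <- g$truth
      rows[[length(rows) + 1L]] <- data.frame(
        id = t$id, label = t$label,
        tm2 = t$filter[["tm2"]], tm5 = t$filter[["tm5"]],
        le1 = t$filter[["le1"]], le2 = t$filter[["le2"]],
        npa_b = t$npa_b, npa_e = t$npa_e,
        motif_class = t$motif_class, motif_window = t$motif_window,
        stringsAsFactors = FALSE)
    }
  }
  list(seqs = seqs, truth = do.call(rbind, rows))
}
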