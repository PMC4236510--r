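# End-to-end orchestration: configuration, the feature scan, and the full
# classification run (tree + rules + summary), with TSV/Newick outputs and a
# JSON run manifest.

#' Build a pipeline run configuration
#'
#' All thresholds of the pipeline in one place. Any field can be overridden;
#' defaults are the package's documented settings.
#'
#' @param input path to a FASTA file (or `NULL` when sequences are passed
#'   directly to the run functions).
#' @param reference_file optional JSON annotation file (see
#'   [read_reference_annotations()]); default: the synthetic
#'   [reference_set()].
#' @param rule_table `"fungal"`, `"plant"`, or a TSV path.
#' @param out_dir output directory (`NULL`: no files written).
#' @param dedup_threshold identity threshold for [dedup_sequences()]
#'   (`NA` disables deduplication).
#' @param tm_window,tm_threshold hydropathy window and cutoff.
#' @param min_conserved interface-conservation minimum for validation.
#' @param bootstrap_reps bootstrap replicates for the tree (default 100 to
#'   keep runs fast; the published protocol value is 1000).
#' @param support_threshold majority-rule / clade-assignment support cutoff.
#' @param seed master seed for all randomness.
#' @return a `mip_config` list.
#' @export
run_config <- function(input = NULL, reference_file = NULL,
                       rule_table = "fungal", out_dir = NULL,
                       dedup_threshold = NA, tm_window = 19L,
                       tm_threshold = 1.6, min_conserved = 9L,
                       bootstrap_reps = 100L, support_threshold = 50,
                       seed = 1L) {
  stopifnot(tm_window %% 2L == 1L, tm_threshold > 0,
            min_conserved >= 0L, min_conserved <= 17L,
            bootstrap_reps >= 1L,
            support_threshold >= 0, support_threshold <= 100)
  if (!is.na(dedup_threshold) &&
      (dedup_threshold <= 0 || dedup_threshold > 1)) {
    stop("dedup_threshold must be in (0, 1] or NA")
  }
  structure(list(input = input, reference_file = reference_file,
                 rule_table = rule_table, out_dir = out_dir,
                 dedup_threshold = dedup_threshold, tm_window = tm_window,
                 tm_threshold = tm_threshold, min_conserved = min_conserved,
                 bootstrap_reps = bootstrap_reps,
                 support_threshold = support_threshold,
                 seed = as.integer(seed)),
            class = "mip_config")
}

config_refs <- function(config) {
  if (!is.null(config$reference_file)) {
    read_reference_annotations(config$reference_file)
  } else {
    reference_set()
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(
    package = "mipscan",
    version = as.character(utils::packageVersion("mipscan")),
    timestamp = NULL,  # deliberately omitted: outputs must be byte-reproducible
    seed = config$seed,
    parameters = config[setdiff(names(config), c("input", "out_dir"))]),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Scan sequences: per-sequence features and MIP validation
#'
#' Reads the input FASTA (or takes `seqs` directly), optionally removes
#' redundancy, computes every per-sequence feature and the three-criterion
#' validation verdict, and (when `out_dir` is set) writes
#' `features.tsv` and a JSON run manifest.
#'
#' @param config a [run_config()].
#' @param seqs optional list of [protein_sequence()] records overriding
#'   `config$input`.
#' @return data frame of features (one row per sequence; zero rows for an
#'   empty input), invisibly carrying the `mip_features` list as attribute
#'   `"features"`.
#' @export
run_scan <- function(config = run_config(), seqs = NULL) {
  stopifnot(inherits(config, "mip_config"))
  if (is.null(seqs)) {
    if (is.null(config$input)) stop("no input: set config$input or pass seqs")
    if (!file.exists(config$input)) stop("unreadable input: ", config$input)
    seqs <- read_fasta(config$input)
  }
  n_in <- length(seqs)
  if (!is.na(config$dedup_threshold) && n_in > 1L) {
    seqs <- dedup_sequences(seqs, config$dedup_threshold)$kept
  }
  refs <- config_refs(config)
  empty <- data.frame()
  if (!length(seqs)) {
    message("run_scan: 0 sequences in")
    return(empty)
  }
  alns <- batch_align_to_best(seqs, refs)
  feats <- lapply(seq_along(seqs), function(i) {
    topo <- predict_topology(seqs[[i]], window = config$tm_window,
                             threshold = config$tm_threshold)
    compute_features(seqs[[i]], refs = refs, topo = topo, best = alns[[i]],
                     min_conserved = config$min_conserved)
  })
  tab <- do.call(rbind, lapply(feats, as.data.frame))
  message(sprintf("run_scan: %d in, %d after dedup, %d valid MIPs",
                  n_in, length(seqs), sum(tab$is_mip)))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(tab, file.path(config$out_dir, "features.tsv"))
    write_manifest(config, file.path(config$out_dir, "scan_manifest.json"),
                   extra = list(n_input = n_in, n_valid = sum(tab$is_mip)))
  }
  attr(tab, "features") <- feats
  tab
}

#' Classify sequences into subfamilies
#'
#' Full pipeline: feature scan, phylogeny of the valid MIPs together with
#' the labeled anchors (NJ + bootstrap + majority-rule collapse), clade
#' assignment, rule matching, combined per-sequence calls and the
#' per-subfamily summary. With fewer than 3 valid MIPs the phylogeny is
#' skipped (warning) and rule-only calls are emitted. Deterministic given
#' the config seed.
#'
#' @inheritParams run_scan
#' @return list with `calls` (data frame), `summary` (data frame),
#'   `tree` (a `phylo` or `NULL`) and `features` (data frame); files
#'   `calls.tsv`, `summary.tsv`, `tree.nwk` and `classify_manifest.json`
#'   are written when `out_dir` is set.
#' @export
run_classify <- function(config = run_config(), seqs = NULL) {
  stopifnot(inherits(config, "mip_config"))
  tab <- run_scan(config, seqs = seqs)
  feats <- attr(tab, "features")
  if (!NROW(tab)) {
    return(list(calls = data.frame(), summary = data.frame(), tree = NULL,
                features = tab))
  }
  refs <- config_refs(config)
  rules <- load_rule_table(config$rule_table)
  valid <- which(tab$is_mip)
  # rebuild the records from the scan (sequence order is preserved)
  if (is.null(seqs)) seqs <- read_fasta(config$input)
  if (!is.na(config$dedup_threshold) && length(seqs) > 1L) {
    seqs <- dedup_sequences(seqs, config$dedup_threshold)$kept
  }
  clades <- setNames(rep("unclassified", nrow(tab)), tab$id)
  tree <- NULL
  if (length(valid) >= 3L) {
    ref_labels <- setNames(
      vapply(refs, function(r) r$subfamily, character(1L)),
      vapply(refs, function(r) r$ref_id, character(1L)))
    ref_labels <- ref_labels[!is.na(ref_labels)]
    ref_seqs <- lapply(refs[names(ref_labels)], function(r) r$seq)
    tree_in <- c(seqs[valid], unname(ref_seqs))
    tree <- bootstrap_support(tree_in, refs = refs,
                              n_reps = config$bootstrap_reps,
                              seed = config$seed)
    tree <- majority_rule_collapse(tree, threshold = config$support_threshold)
    got <- assign_clades(tree, ref_labels,
                         support_threshold = config$support_threshold)
    clades[intersect(names(got), names(clades))] <-
      got[intersect(names(got), names(clades))]
  } else {
    warning("fewer than 3 valid MIPs: phylogeny skipped, rule-only calls")
  }
  calls <- lapply(seq_len(nrow(tab)), function(i) {
    cand <- rule_classify(feats[[i]], rules)
    combine_calls(cand, clades[[tab$id[i]]])
  })
  call_tab <- data.frame(
    id = tab$id,
    label = vapply(calls, `[[`, character(1L), "label"),
    confidence = vapply(calls, `[[`, character(1L), "confidence"),
    rule_candidates = vapply(calls, function(x)
      paste(x$evidence$rule_candidates, collapse = ","), character(1L)),
    clade_label = vapply(calls, function(x)
      x$evidence$clade_label, character(1L)),
    stringsAsFactors = FALSE)
  call_tab <- cbind(call_tab, tab[, c("arr_tm2", "arr_tm5", "arr_le1",
                                      "arr_le2", "npa_b", "npa_e",
                                      "loop_d_length", "loop_d_charged",
                                      "pI", "mw", "is_mip")])
  classified <- which(call_tab$label != "unclassified" & tab$is_mip)
  summ <- if (length(classified)) {
    summarize_group(call_tab$label[classified], feats[classified])
  } else data.frame()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(call_tab, file.path(config$out_dir, "calls.tsv"))
    if (NROW(summ)) write_tsv(summ, file.path(config$out_dir, "summary.tsv"))
    if (!is.null(tree)) ape::write.tree(tree,
                                        file.path(config$out_dir, "tree.nwk"))
    write_manifest(config, file.path(config$out_dir, "classify_manifest.json"),
                   extra = list(n_called = length(classified)))
  }
  list(calls = call_tab, summary = summ, tree = tree, features = tab)
}
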