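# synthetic_data: templates, sequence generation, datasets and their
# statistical properties

test_that("subfamily templates encode the published contrasts", {
  delta <- make_subfamily_template("delta")
  expect_equal(delta$filter_choice$le2, "R")
  sip <- make_subfamily_template("SIP-like")
  expect_true(all(sip$filter_choice$le2 %in% c("L", "I")))
  aqp <- make_subfamily_template("AQP")
  expect_gt(sip$loop_lengths[["ld"]], aqp$loop_lengths[["ld"]])
  expect_gt(sip$loop_d_charge_frac, aqp$loop_d_charge_frac)
  # per-box rates implement the published per-sequence percentages
  expect_equal(delta$npa_e_sub$rate, 1.0)
  expect_equal(make_subfamily_template("alpha")$npa_e_sub$rate, 0.958)
  expect_equal(make_subfamily_template("gamma2")$npa_e_sub$rate, 0)
  expect_error(make_subfamily_template("nope"), "unknown")
})

test_that("generation is deterministic per seed and distinct across seeds", {
  tpl <- make_subfamily_template("beta")
  g1 <- generate_sequence(tpl, seed = 5L)
  g2 <- generate_sequence(tpl, seed = 5L)
  g3 <- generate_sequence(tpl, seed = 6L)
  expect_identical(g1$seq$residues, g2$seq$residues)
  expect_false(identical(g1$seq$residues, g3$seq$residues))
})

test_that("planted features are recovered at mutation rate 0", {
  refs <- reference_set()
  for (lab in c("delta", "XIP", "SIP-like")) {
    tpl <- make_subfamily_template(lab)
    for (i in 1:3) {
      g <- generate_sequence(tpl, seed = 40L + i, mutation_rate = 0)
      best <- choose_reference(g$seq, refs)
      arr <- extract_arr_filter(g$seq, best$aln, best$ref)
      expect_equal(unname(c(arr$tm2, arr$tm5, arr$le1, arr$le2)),
                   unname(g$truth$filter), info = lab)
      boxes <- locate_npa_boxes(g$seq, best$aln, best$ref)
      expect_equal(boxes$b$triplet, g$truth$npa_b, info = lab)
      expect_equal(boxes$e$triplet, g$truth$npa_e, info = lab)
      fv <- compute_features(g$seq, refs = refs, best = best)
      expect_true(fv$is_mip, info = lab)
      expect_equal(fv$loop_e_motif_class, g$truth$motif_class, info = lab)
    }
  }
})

test_that("datasets have the requested shape and regenerate byte-identically", {
  ds <- generate_dataset(c("alpha", "delta", "SIP-like"), 5L, seed = 20L)
  expect_length(ds$seqs, 15L)
  expect_equal(unname(table(ds$truth$label)[c("alpha", "delta", "SIP-like")]),
               rep(5L, 3L), ignore_attr = TRUE)
  f1 <- tempfile(); f2 <- tempfile()
  on.exit(unlink(c(f1, f2)))
  write_fasta(generate_dataset(c("alpha", "delta"), 4L, seed = 21L)$seqs, f1)
  write_fasta(generate_dataset(c("alpha", "delta"), 4L, seed = 21L)$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("observed NPA substitution fractions converge to the spec rates", {
  n <- 400L
  ds <- generate_dataset(c("SIP-like"), n, seed = 22L)
  obs <- mean(ds$truth$npa_e != "NPA")
  rate <- make_subfamily_template("SIP-like")$npa_e_sub$rate  # 0.812
  tol <- 3 * sqrt(rate * (1 - rate) / n)                      # 3 binomial SDs
  expect_lt(abs(obs - rate), tol)
  expect_true(all(ds$truth$npa_b == "NPA"))  # loop-B box canonical here
})

test_that("SIP-like proteins are smaller than aquaglyceroporins", {
  mw_of <- function(lab) {
    ds <- generate_dataset(lab, 10L, seed = 23L)
    mean(vapply(ds$seqs, function(s)
      as.numeric(compute_mw(s, on_x = "estimate")), numeric(1L)))
  }
  m_sip <- mw_of("SIP-like")
  for (lab in c("alpha", "beta", "delta", "Fps1-like")) {
    expect_lt(m_sip, mw_of(lab))
  }
})

test_that("intra-group identity exceeds inter-group identity", {
  labs <- c("alpha", "delta", "SIP-like")
  ds <- generate_dataset(labs, 3L, seed = 24L)
  groups <- split(ds$seqs, ds$truth$label)
  stats <- group_identity_stats(groups)
  idm <- stats$identity
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i != j) expect_gt(idm[i, i], idm[i, j])
    }
  }
})

test_that("contradictory generation arguments are rejected", {
  tpl <- make_subfamily_template("alpha")
  expect_error(generate_sequence(tpl, seed = 1L, mutation_rate = 2), "0,1|\\[0")
  expect_error(generate_dataset("alpha", 0L, seed = 1L), "n_per_label")
})
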