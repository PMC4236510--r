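# features: NPA boxes, Ar/R filter, pI, MW, loop metrics, motif classes,
# interface conservation and MIP validation

refs_all <- reference_set()
ref_aqp <- refs_all[["REF_AQP"]]

# query = reference with selected positions replaced
mutate_ref <- function(ref, at, to) {
  ch <- strsplit(ref$seq$residues, "")[[1]]
  ch[at] <- to
  ps("q", paste(ch, collapse = ""))
}

test_that("NPA boxes are located positionally with 1-based offsets", {
  q <- ref_aqp$seq
  aln <- global_align(q, ref_aqp$seq)
  boxes <- locate_npa_boxes(q, aln, ref_aqp)
  expect_true(boxes$b$canonical)
  expect_true(boxes$e$canonical)
  expect_equal(boxes$b$triplet, "NPA")
  expect_length(boxes$b$substituted_offsets, 0L)

  # NPV planted at the loop-E box: substituted at the alanine position (3)
  q2 <- mutate_ref(ref_aqp, ref_aqp$npa_e_pos + 2L, "V")
  b2 <- locate_npa_boxes(q2, global_align(q2, ref_aqp$seq), ref_aqp)
  expect_equal(b2$e$triplet, "NPV")
  expect_false(b2$e$canonical)
  expect_equal(b2$e$substituted_offsets, 3L)

  # delta-style NLA: the proline position (2) is substituted
  q3 <- mutate_ref(ref_aqp, ref_aqp$npa_e_pos + 1L, "L")
  b3 <- locate_npa_boxes(q3, global_align(q3, ref_aqp$seq), ref_aqp)
  expect_equal(b3$e$triplet, "NLA")
  expect_equal(b3$e$substituted_offsets, 2L)
})

test_that("wholly unmappable NPA boxes raise a feature error", {
  res <- ref_aqp$seq$residues
  gap_at <- c(ref_aqp$npa_b_pos + 0:2, ref_aqp$npa_e_pos + 0:2)
  aq <- strsplit(res, "")[[1]]
  q <- ps("q", paste(aq[-gap_at], collapse = ""))
  aq[gap_at] <- "-"
  aln <- mipscan:::new_alignment(paste(aq, collapse = ""), res, score = 0,
                                 matrix = blosum62)
  expect_error(locate_npa_boxes(q, aln, ref_aqp), "NPA box")
})

test_that("Ar/R filter extraction reads the annotated positions", {
  q <- ref_aqp$seq
  aln <- global_align(q, ref_aqp$seq)
  arr <- extract_arr_filter(q, aln, ref_aqp)
  expect_true(arr$complete)
  anchor_chars <- strsplit(q$residues, "")[[1]][ref_aqp$arr_positions]
  expect_equal(c(arr$tm2, arr$tm5, arr$le1, arr$le2), anchor_chars)

  # planted SIP-like filter V, A, G, L (a published SIP-like pattern)
  ref_sip <- refs_all[["REF_SIP-like"]]
  q2 <- mutate_ref(ref_sip, ref_sip$arr_positions, c("V", "A", "G", "L"))
  arr2 <- extract_arr_filter(q2, global_align(q2, ref_sip$seq), ref_sip)
  expect_equal(c(arr2$tm2, arr2$tm5, arr2$le1, arr2$le2),
               c("V", "A", "G", "L"))

  # TM5 anchor region deleted: tm5 unmapped, filter incomplete
  tm5 <- ref_aqp$tm_spans[5L, ]
  ch <- strsplit(ref_aqp$seq$residues, "")[[1]]
  q3 <- ps("q3", paste(ch[-(tm5["start"]:tm5["end"])], collapse = ""))
  arr3 <- extract_arr_filter(q3, global_align(q3, ref_aqp$seq), ref_aqp)
  expect_true(is.na(arr3$tm5))
  expect_false(arr3$complete)
})

test_that("pI ordering, bisection accuracy and monotonicity", {
  expect_lt(compute_pi(ps("d", "DDDD")), compute_pi(ps("k", "KKKK")))
  got <- compute_pi(ps("gg", "GG"))
  expect_lt(abs(got - oracle_pi_grid("GG", mipscan:::PKA_SETS$bjellqvist)),
            2e-4)
  for (i in 1:4) {
    s <- random_seq("s", 50L, 700L + i)
    expect_gte(compute_pi(ps("sk", paste0(s$residues, "K"))) + 1e-6,
               compute_pi(s))
  }
  # K -> D swap strictly lowers pI
  s <- ps("x", "GGKGG")
  expect_gt(compute_pi(s), compute_pi(ps("y", "GGDGG")))
})

test_that("molecular weight matches hand sums and flags X", {
  # independent hand sum: glycine average residue mass + one water
  expect_lt(abs(compute_mw(ps("g", "G")) - (57.0519 + 18.01524)), 1e-3)
  expect_equal(compute_mw(ps("gg", "GG")),
               2 * compute_mw(ps("g", "G")) - mipscan:::MASS_WATER)
  expect_error(protein_sequence("e", ""), "empty")
  expect_error(compute_mw(ps("x", "GXG")), "X")
  est <- compute_mw(ps("x", "GXG"), on_x = "estimate")
  expect_true(isTRUE(attr(est, "estimated")))
})

test_that("loop D metrics count length and charged residues", {
  body <- paste0(strrep("A", 20), strrep("I", 15), strrep("A", 5),
                 strrep("I", 15), strrep("A", 5), strrep("I", 15),
                 strrep("A", 5), strrep("I", 15), "KKRDEDKK",
                 strrep("I", 15), strrep("A", 10))
  s <- ps("x", body)
  starts <- c(21, 41, 61, 81, 104)
  topo <- import_topology(s, cbind(starts, starts + 14L))
  expect_equal(loop_d_metrics(s, topo), list(length = 8L, charged_count = 8L))

  body2 <- sub("KKRDEDKK", strrep("G", 10), body)  # poly-G loop D
  s2 <- ps("y", body2)
  topo2 <- import_topology(s2, cbind(c(21, 41, 61, 81, 106), c(35, 55, 75, 95, 120)))
  expect_equal(loop_d_metrics(s2, topo2), list(length = 10L, charged_count = 0L))

  expect_error(loop_d_metrics(s, import_topology(s, cbind(21, 35))), "5 TM")
})

test_that("SIP-like templates have longer, more charged loop D than AQP", {
  sip <- make_subfamily_template("SIP-like")
  aqp <- make_subfamily_template("AQP")
  expect_gt(sip$loop_lengths[["ld"]], aqp$loop_lengths[["ld"]])
  mean_ld <- function(tpl) {
    vals <- vapply(1:8, function(i) {
      g <- generate_sequence(tpl, seed = 800L + i)
      topo <- predict_topology(g$seq)
      unlist(loop_d_metrics(g$seq, topo))
    }, numeric(2L))
    rowMeans(vals)
  }
  m_sip <- mean_ld(sip); m_aqp <- mean_ld(aqp)
  expect_gt(m_sip["length"], m_aqp["length"])
  expect_gt(m_sip["charged_count"], m_aqp["charged_count"])
})

test_that("loop-E motif classes follow the published patterns", {
  det <- function(w) detect_loop_e_motif(ps("w", w), c(1L, 6L))
  expect_equal(det("RDLGPR"), list(motif_class = "AQGP-core", salt_bridge = TRUE))
  expect_equal(det("RDLGLR"), list(motif_class = "AQGP-delta", salt_bridge = TRUE))
  expect_equal(det("RSLGPA"), list(motif_class = "AQP-type", salt_bridge = FALSE))
  expect_equal(det("RCLGAA"), list(motif_class = "XIP-type", salt_bridge = FALSE))
  expect_equal(det("LSTNQS")$motif_class, "none")
  # window extending past the sequence end
  expect_equal(detect_loop_e_motif(ps("w", "RDLG"), c(1L, 6L))$motif_class,
               "none")
  # salt bridge requires acidic at i with basic at i+4
  expect_true(det("DAAAKA")$salt_bridge)
  expect_true(det("ADAAAK")$salt_bridge)
  expect_false(det("DAAAAA")$salt_bridge)
  expect_false(det("AAKAAA")$salt_bridge)
})

test_that("interface conservation counts group residues at the 17 anchors", {
  q_all <- mutate_ref(ref_aqp, ref_aqp$interface_positions, "G")
  aln <- global_align(q_all, ref_aqp$seq)
  expect_equal(interface_conservation(q_all, aln, ref_aqp), 17L)
  q_none <- mutate_ref(ref_aqp, ref_aqp$interface_positions, "I")
  expect_equal(interface_conservation(q_none,
                                      global_align(q_none, ref_aqp$seq),
                                      ref_aqp), 0L)
  # SIP-like anchors plant exactly 14 group residues (the published count)
  ref_sip <- refs_all[["REF_SIP-like"]]
  q14 <- ref_sip$seq
  expect_equal(interface_conservation(q14, global_align(q14, ref_sip$seq),
                                      ref_sip), 14L)
})

test_that("validate_mip applies the three criteria", {
  g <- generate_sequence(make_subfamily_template("alpha"), seed = 900L,
                         mutation_rate = 0)
  fv <- compute_features(g$seq, refs = refs_all)
  expect_true(fv$is_mip)
  expect_length(fv$reasons, 0L)

  decoy <- tm_block_seq("decoy5", k = 5L)
  topo5 <- predict_topology(decoy)
  v5 <- validate_mip(decoy, list(npa_b = list(located = TRUE),
                                 npa_e = list(located = TRUE),
                                 interface_conserved = 17L), topo5)
  expect_false(v5$is_mip)
  expect_match(v5$reasons, "criterion-b", all = FALSE)

  v_a <- validate_mip(g$seq, list(npa_b = NULL, npa_e = NULL,
                                  interface_conserved = 17L),
                      predict_topology(g$seq))
  expect_false(v_a$is_mip)
  expect_match(v_a$reasons, "criterion-a", all = FALSE)
})

test_that("filter recovery degrades monotonically with loop mutation", {
  tpl <- make_subfamily_template("delta")
  recovery <- vapply(c(0, 0.25, 0.6), function(rate) {
    hits <- vapply(1:15, function(i) {
      g <- generate_sequence(tpl, seed = 1000L + i, mutation_rate = rate)
      best <- choose_reference(g$seq, refs_all)
      arr <- extract_arr_filter(g$seq, best$aln, best$ref)
      identical(unname(c(arr$tm2, arr$tm5, arr$le1, arr$le2)),
                unname(g$truth$filter))
    }, logical(1L))
    mean(hits)
  }, numeric(1L))
  expect_true(all(diff(recovery) <= 0))
  expect_equal(recovery[1L], 1)
})
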