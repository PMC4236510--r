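# classify: rule matching, call combination, group summaries and identity
# statistics

fake_fv <- function(id, filter, npa_b = "NPA", npa_e = "NPA", mw = 30000,
                    pI = 7, ld_len = 12L, ld_chg = 3L) {
  structure(list(
    id = id, pI = pI, mw = mw, length = 280L,
    npa_b = list(triplet = npa_b, canonical = npa_b == "NPA", located = TRUE),
    npa_e = list(triplet = npa_e, canonical = npa_e == "NPA", located = TRUE),
    arr = list(tm2 = filter[1], tm5 = filter[2], le1 = filter[3],
               le2 = filter[4], complete = !anyNA(filter)),
    loop_d_length = ld_len, loop_d_charged = ld_chg,
    loop_e_motif_class = "none", salt_bridge = FALSE,
    interface_conserved = 15L, is_mip = TRUE, reasons = character(0)),
    class = "mip_features")
}

test_that("rule_classify matches the published filter patterns", {
  rules <- load_rule_table("fungal")
  expect_true("delta" %in% rule_classify(fake_fv("x", c("F", "V", "I", "R")), rules))
  expect_true("SIP-like" %in%
    rule_classify(fake_fv("x", c("V", "A", "G", "L"), mw = 26000), rules))
  expect_true("Fps1-like" %in%
    rule_classify(fake_fv("x", c("W", "L", "T", "R")), rules))
  # SIP-like demands a small protein: same filter above the ceiling fails
  expect_false("SIP-like" %in%
    rule_classify(fake_fv("x", c("V", "A", "G", "L"), mw = 32000), rules))
  # a missing position matches nothing
  expect_length(rule_classify(fake_fv("x", c("F", NA, "I", "R")), rules), 0L)
})

test_that("plant rule table covers TIP/SIP patterns", {
  plant <- load_rule_table("plant")
  expect_true("TIP" %in% rule_classify(fake_fv("x", c("H", "I", "A", "R")), plant))
  expect_true("SIP" %in% rule_classify(fake_fv("x", c("V", "V", "P", "N")), plant))
})

test_that("combine_calls arbitrates rules and clades", {
  a <- combine_calls("delta", "delta")
  expect_equal(a[c("label", "confidence")],
               list(label = "delta", confidence = "rule+tree"))
  b <- combine_calls("SIP-like", "unclassified")
  expect_equal(b[c("label", "confidence")],
               list(label = "SIP-like", confidence = "rule-only"))
  c2 <- combine_calls(c("alpha", "beta"), "unclassified")
  expect_equal(c2[c("label", "confidence")],
               list(label = "unclassified", confidence = "none"))
  d <- combine_calls(character(0), "beta")
  expect_equal(d[c("label", "confidence")],
               list(label = "beta", confidence = "tree-only"))
})

test_that("summarize_group aggregates NPA percentages and omits empty groups", {
  fvs <- c(
    lapply(1:2, function(i) fake_fv(paste0("a", i), c("W", "G", "Y", "R"),
                                    npa_e = "NLA")),
    lapply(1:48, function(i) fake_fv(paste0("b", i), c("F", "V", "I", "R"),
                                     npa_e = if (i <= 46) "NPV" else "NPA")))
  calls <- c(rep("alpha", 2), rep("delta", 48))
  tab <- summarize_group(calls, fvs)
  expect_equal(nrow(tab), 2L)  # no empty subfamily rows
  expect_equal(tab$npa_substitution_pct[tab$subfamily == "alpha"], 100.0)
  expect_equal(tab$npa_substitution_pct[tab$subfamily == "delta"], 95.8)

  # invariance to input order
  perm <- sample(length(calls))
  tab2 <- summarize_group(calls[perm], fvs[perm])
  expect_equal(tab, tab2)
})

test_that("group identity statistics cover intra/inter cases", {
  twenty <- "MKVLFDEGHSTWYQNPARCI"
  same <- list(ps("s1", twenty), ps("s2", twenty))
  g1 <- list(ps("g1", strrep("AC", 10)), ps("g2", strrep("CA", 10)))
  stats <- group_identity_stats(list(same = same, other = g1))
  expect_equal(stats$identity["same", "same"], 1)
  expect_true(stats$identity["same", "other"] < 0.2)

  # disjoint alphabets: zero identity across groups
  gw <- list(ps("w1", strrep("W", 20)))
  gd <- list(ps("d1", strrep("D", 20)))
  st2 <- group_identity_stats(list(w = gw, d = gd))
  expect_equal(st2$identity["w", "d"], 0)
  expect_true(is.na(st2$identity["w", "w"]))  # singleton intra undefined

  # 3-sequence group mean equals the hand-enumerated pair average
  swap <- function(x, at, to) {
    ch <- strsplit(x, "")[[1]]; ch[at] <- to; paste(ch, collapse = "")
  }
  s1 <- twenty
  s2 <- swap(s1, 1:2, c("L", "R"))     # 18/20 vs s1
  s3 <- swap(s1, 1:4, c("L", "R", "I", "M"))  # 16/20 vs s1, 18/20 vs s2
  st3 <- group_identity_stats(list(g = list(ps("x1", s1), ps("x2", s2),
                                            ps("x3", s3))))
  expect_equal(st3$identity["g", "g"], mean(c(18, 16, 18) / 20))
})
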