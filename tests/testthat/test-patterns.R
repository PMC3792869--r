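test_that("reference positions map through gapped alignment columns", {
  m <- msa(c(ref = "A-CD", other = "ABCD"))
  expect_equal(unname(map_reference_positions(m, "ref", 2L)), 3L)

  m2 <- msa(c(ref = "ACDEF", other = "ACDEF"))
  expect_equal(unname(map_reference_positions(m2, "ref", 1:5)), 1:5)

  # planted gap pattern vs hand-computed non-gap prefix counts
  m3 <- msa(c(ref = "--AB-C-DE", other = "XXXXXXXXX"))
  expect_equal(unname(map_reference_positions(m3, "ref", 1:5)),
               c(3L, 4L, 6L, 8L, 9L))
  expect_error(map_reference_positions(m3, "ref", 6L), "beyond")
})

test_that("the interloop bridge sits at fixed offsets from the catalytic Asp and His", {
  tpl <- nprime_template()
  il <- interloop_bridge(tpl$seq, triad = tpl$triad)
  expect_equal(il$pos_i2, 194L)
  expect_equal(il$pos_i4, 222L)
  expect_equal(c(il$res_i2, il$res_i4), c("D", "H"))
  expect_equal(il$polarity, "acid_base")

  # offsets are structural constants of the rule
  expect_equal(il$pos_i2 + 2L, tpl$triad[2L])
  expect_equal(il$pos_i4 + 4L, tpl$triad[3L])

  # Est30-style arrangement: basic at Asp-2, acidic at His-4
  ch <- strsplit(tpl$seq, "")[[1]]
  ch[194] <- "R"; ch[222] <- "E"
  il2 <- interloop_bridge(paste(ch, collapse = ""), triad = tpl$triad)
  expect_equal(il2$polarity, "base_acid")

  ch[194] <- "A"
  expect_equal(interloop_bridge(paste(ch, collapse = ""),
                                triad = tpl$triad)$polarity, "absent")

  # direct positions bypass the triad (for enzymes with unannotated triads)
  expect_equal(interloop_bridge(tpl$seq, positions = c(194L, 222L))$polarity,
               "acid_base")
  expect_error(interloop_bridge("ACD", triad = c(1L, 2L, 300L)), "range")
})

test_that("hallmark profiles score present, substituted and absent pairs", {
  tpl <- nprime_template()
  cat_ <- hallmark_catalog()
  ch <- strsplit(tpl$seq, "")[[1]]

  sub <- ch; sub[3] <- "D"                      # E3 -> D: charge preserved
  ko <- ch; ko[54] <- "A"; ko[37] <- "A"        # two basic partners shaved
  gap <- ch; gap[140] <- "-"
  m <- msa(c(template = tpl$seq,
             subbed = paste(sub, collapse = ""),
             knocked = paste(ko, collapse = ""),
             gapped = paste(gap, collapse = "")))

  p_tpl <- hallmark_profile(m, "template", cat_$nprime_exclusive, "template")
  expect_true(all(p_tpl$state == "present"))
  expect_equal(attr(p_tpl, "n_present"), 5L)

  p_sub <- hallmark_profile(m, "subbed", cat_$nprime_exclusive, "template")
  expect_equal(p_sub$state[p_sub$acid_pos == 3], "substituted")
  expect_equal(sum(p_sub$state == "present"), 4L)

  p_ko <- hallmark_profile(m, "knocked", cat_$nprime_exclusive, "template")
  expect_equal(sum(p_ko$state == "absent"), 2L)

  p_gap <- hallmark_profile(m, "gapped", cat_$nprime_exclusive, "template")
  expect_equal(p_gap$state[p_gap$base_pos == 140], "absent")
})

test_that("the classification rule reproduces the three reference hallmark patterns", {
  tpl <- nprime_template()
  cat_ <- hallmark_catalog()
  m <- msa(c(template = tpl$seq, target = tpl$seq))
  p_np_full <- hallmark_profile(m, "target", cat_$nprime_exclusive, "template")
  il_ab <- interloop_bridge(tpl$seq, triad = tpl$triad)

  # N'-type evidence: five exclusive bridges + acid->base interloop
  expect_equal(classify_subfamily(p_np_full, NULL, il_ab)$label,
               "Nprime_familyXV")

  # N-type evidence: full six-bridge N pattern + base->acid interloop + alpha cap
  est30 <- rep("A", 249)
  np <- hallmark_catalog()$n_pattern
  est30[np$acid_pos] <- np$acid_aa
  est30[np$base_pos] <- np$base_aa
  est30 <- paste(est30, collapse = "")
  m_n <- msa(c(Est30 = est30, target = est30))
  p_n_full <- hallmark_profile(m_n, "target", np, "Est30")
  il_ba <- interloop_bridge(est30, positions = c(191L, 219L))
  expect_equal(il_ba$polarity, "base_acid")
  expect_equal(classify_subfamily(NULL, p_n_full, il_ba,
                                  cap_label = "alpha")$label, "N_familyXIII")

  # LipS-type evidence: alpha/beta cap, base->acid interloop, no catalog hits
  blank <- paste(rep("A", 249), collapse = "")
  m_b <- msa(c(template = tpl$seq, Est30 = est30, LipS = blank))
  p_np0 <- hallmark_profile(m_b, "LipS", cat_$nprime_exclusive, "template")
  p_n0 <- hallmark_profile(m_b, "LipS", np, "Est30")
  lips <- strsplit(blank, "")[[1]]; lips[100] <- "R"; lips[130] <- "E"
  il_lips <- interloop_bridge(paste(lips, collapse = ""),
                              positions = c(100L, 130L))
  expect_equal(classify_subfamily(p_np0, p_n0, il_lips,
                                  cap_label = "alpha_beta")$label, "LipS_like")
  # without cap metadata the same evidence degrades to unassigned
  expect_equal(classify_subfamily(p_np0, p_n0, il_lips)$label, "unassigned")

  # nothing at all
  il_none <- interloop_bridge("AAAAAAAA", positions = c(3L, 6L))
  expect_equal(classify_subfamily(p_np0, p_n0, il_none)$label, "unassigned")
})

test_that("classification is a pure function and tolerates one knocked-out bridge", {
  tpl <- nprime_template()
  cat_ <- hallmark_catalog()
  ch <- strsplit(tpl$seq, "")[[1]]
  ch[54] <- "A"  # one knockout: 4/5 survive
  m <- msa(c(template = tpl$seq, mut = paste(ch, collapse = "")))
  p <- hallmark_profile(m, "mut", cat_$nprime_exclusive, "template")
  il <- interloop_bridge(paste(ch, collapse = ""), triad = tpl$triad)
  c1 <- classify_subfamily(p, NULL, il)
  c2 <- classify_subfamily(p, NULL, il)
  expect_equal(c1$label, "Nprime_familyXV")
  expect_identical(c1$label, c2$label)

  # two knockouts (3/5) drop below the default threshold
  ch[37] <- "A"
  m2 <- msa(c(template = tpl$seq, mut = paste(ch, collapse = "")))
  p2 <- hallmark_profile(m2, "mut", cat_$nprime_exclusive, "template")
  expect_equal(classify_subfamily(p2, NULL, il)$label, "unassigned")
})

test_that("a simulated N' family is overwhelmingly called N-prime", {
  fam <- synth_msa_family(n = 20, knockout_rate = 0.1, seed = 202)
  cat_ <- hallmark_catalog()
  calls <- vapply(fam$truth$id, function(id) {
    p <- hallmark_profile(fam$msa, id, cat_$nprime_exclusive, "template")
    seq <- bridgestab:::msa_row(fam$msa, id)
    il <- interloop_bridge(seq, triad = fam$template$triad)
    classify_subfamily(p, NULL, il)$label
  }, character(1))
  expect_equal(unname(calls), fam$truth$expected_call)
  # every sequence keeping at least 4 of the 5 hallmark bridges is called N'
  expect_true(all(calls[fam$truth$surviving >= 4] == "Nprime_familyXV"))
})
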