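test_that("planted bridge geometries are realized exactly and recovered", {
  s <- synth_structure(data.frame(acid = "ASP", base = "ARG", dist_A = 3.3),
                       seed = 7)
  br <- detect_salt_bridges(s)
  expect_equal(nrow(br), 1L)
  expect_equal(br$min_dist_A, 3.3)
  truth <- attr(s, "truth")
  expect_equal(br$acid_resno, truth$acid_resno)
  expect_equal(br$base_resno, truth$base_resno)
})

test_that("decoys never create spurious bridges", {
  empty <- synth_structure(NULL, decoys = 10, seed = 3)
  expect_equal(nrow(detect_salt_bridges(empty)), 0L)

  pairs <- data.frame(acid = c("ASP", "GLU", "ASP", "GLU", "ASP"),
                      base = c("ARG", "LYS", "HIS", "ARG", "LYS"),
                      dist_A = c(2.8, 3.1, 3.4, 3.7, 4.0))
  for (sd in c(1, 5, 9)) {
    s <- synth_structure(pairs, decoys = 5, seed = sd)
    br <- detect_salt_bridges(s)
    truth <- attr(s, "truth")
    # recall 5/5 and precision 1.0, confirmed against the brute-force oracle
    expect_equal(nrow(br), 5L)
    expect_setequal(paste(br$acid_resno, br$base_resno),
                    paste(truth$acid_resno, truth$base_resno))
    bf <- brute_force_bridges(s)
    expect_equal(br$min_dist_A, bf$min_dist_A)
  }
})

test_that("structure generation is reproducible and validates distances", {
  pairs <- data.frame(acid = "GLU", base = "HIS", dist_A = 3.2)
  s1 <- synth_structure(pairs, decoys = 2, seed = 4)
  s2 <- synth_structure(pairs, decoys = 2, seed = 4)
  expect_identical(s1$atoms, s2$atoms)
  expect_error(synth_structure(data.frame(acid = "ASP", base = "ARG",
                                          dist_A = 1.9)),
               "exceed 2.0")
})

test_that("clean melting curves cross midway between baselines at the planted Tm", {
  bl <- list(aF = -20, bF = 0.02, aU = -4, bU = 0.05)
  cur <- synth_melting_curve(Tm_C = 64.2, dHm = 120, baselines = bl)
  yF <- bl$aF + bl$bF * cur$temp_C
  yU <- bl$aU + bl$bU * cur$temp_C
  fU <- (yF - cur$signal) / (yF - yU)
  mid_T <- approx(fU, cur$temp_C, xout = 0.5)$y
  expect_equal(mid_T, 64.2, tolerance = 1e-4)
})

test_that("a very large enthalpy degenerates to a step at Tm", {
  cur <- synth_melting_curve(Tm_C = 60, dHm = 5000, grid = seq(25, 90, 0.5))
  bl <- attr(cur, "truth")$baselines
  below <- cur$temp_C < 59
  above <- cur$temp_C > 61
  expect_equal(cur$signal[below], bl$aF + bl$bF * cur$temp_C[below],
               tolerance = 1e-6)
  expect_equal(cur$signal[above], bl$aU + bl$bU * cur$temp_C[above],
               tolerance = 1e-6)
})

test_that("noise respects the seed contract", {
  a <- synth_melting_curve(60, noise_sd = 0.02, seed = 1)
  b <- synth_melting_curve(60, noise_sd = 0.02, seed = 2)
  c2 <- synth_melting_curve(60, noise_sd = 0.02, seed = 2)
  expect_false(isTRUE(all.equal(a$signal, b$signal)))
  expect_identical(b$signal, c2$signal)
  clean <- synth_melting_curve(60, noise_sd = 0)
  expect_equal(mean(abs(a$signal - clean$signal)) <
                 0.1 * diff(range(clean$signal)), TRUE)
  expect_warning(synth_melting_curve(Tm_C = 99), "outside")
})

test_that("simulated families carry a correct truth table", {
  fam0 <- synth_msa_family(n = 8, knockout_rate = 0, seed = 5)
  expect_true(all(fam0$truth$expected_call == "Nprime_familyXV"))
  expect_true(all(fam0$truth$knocked_pairs == 0L))

  # knockout arithmetic: shaving 4 of 5 basic partners defeats the 4/5 rule
  tpl <- nprime_template()
  ch <- strsplit(tpl$seq, "")[[1]]
  ch[c(54, 37, 140, 178)] <- "A"
  m <- msa(c(template = tpl$seq, ko4 = paste(ch, collapse = "")))
  p <- hallmark_profile(m, "ko4", hallmark_catalog()$nprime_exclusive,
                        "template")
  il <- interloop_bridge(paste(ch, collapse = ""), triad = tpl$triad)
  expect_equal(classify_subfamily(p, NULL, il)$label, "unassigned")
})

test_that("background substitution rates land in the expected identity band", {
  fam <- synth_msa_family(n = 20, knockout_rate = 0, sub_rate = 0.1,
                          seed = 11)
  tpl <- strsplit(fam$template$seq, "")[[1]]
  mean_id <- mean(vapply(fam$truth$id, function(id) {
    a <- strsplit(bridgestab:::msa_row(fam$msa, id), "")[[1]]
    mean(a == tpl)
  }, numeric(1)))
  # one 10% background mutation pass: expected identity to the template ~0.9
  expect_gte(mean_id, 0.85)
  expect_lte(mean_id, 1.0)
})

test_that("additive matrices from trees are recovered by neighbor joining", {
  tr <- ape::read.tree(text = "((A:0.12,B:0.08):0.05,(C:0.1,D:0.03):0.07);")
  std <- synth_tree_data(tr)
  out <- nj_tree(std$dm)
  expect_equal(ape::dist.topo(ape::unroot(tr), out),
               structure(0, names = "PH85"), ignore_attr = TRUE)
  got <- ape::cophenetic.phylo(out)[rownames(std$dm), colnames(std$dm)]
  expect_lt(max(abs(got - std$dm)), 1e-9)

  # zero-length internal branch: still a valid resolution with ~0 branch
  tr0 <- ape::read.tree(text = "((A:0.1,B:0.1):0,(C:0.1,D:0.1):0);")
  out0 <- nj_tree(synth_tree_data(tr0)$dm)
  internal <- out0$edge.length[out0$edge[, 2] > length(out0$tip.label)]
  expect_lt(max(internal), 1e-12)
})

test_that("evolved sequences give Poisson distances near the path lengths", {
  tr <- ape::read.tree(text = "((A:0.08,B:0.12):0.04,(C:0.1,D:0.06):0.05);")
  std <- synth_tree_data(tr, seed = 21, sites = 1000)
  pd <- poisson_distance(std$msa)
  for (i in 1:3) for (j in (i + 1):4) {
    ids <- rownames(std$dm)
    L <- std$dm[i, j]
    p_true <- 1 - exp(-L)
    se_p <- sqrt(p_true * (1 - p_true) / 1000)
    se_d <- se_p / (1 - p_true)  # delta method through -ln(1-p)
    expect_lt(abs(pd$d[ids[i], ids[j]] - L), 3 * se_d + 0.01)
  }
})
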