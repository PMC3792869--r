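# Fixtures and independent oracles used across the suite. All fixtures are
# built in code; structures standing in for crystal structures are synthetic
# and named as such.

# ---- independent brute-force salt-bridge oracle (naive double loop) --------
brute_force_bridges <- function(s, cutoff = 4, include_his = TRUE,
                                rounding = 1) {
  a <- s$atoms[s$atoms$element != "H", , drop = FALSE]
  acid_def <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  base_def <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ")
  if (include_his) base_def$HIS <- c("ND1", "NE2")
  best <- list()
  for (i in seq_len(nrow(a))) {
    ri <- a$resid[i]
    if (is.null(acid_def[[ri]]) || !(a$elety[i] %in% acid_def[[ri]])) next
    for (j in seq_len(nrow(a))) {
      rj <- a$resid[j]
      if (is.null(base_def[[rj]]) || !(a$elety[j] %in% base_def[[rj]])) next
      if (a$resno[i] == a$resno[j] && a$chain[i] == a$chain[j]) next
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
      key <- paste(a$chain[i], a$resno[i], a$chain[j], a$resno[j])
      if (is.null(best[[key]]) || d < best[[key]]) best[[key]] <- d
    }
  }
  keep <- Filter(function(d) round(d, rounding) <= cutoff, best)
  if (length(keep) == 0L) {
    return(data.frame(acid_resno = integer(), base_resno = integer(),
                      min_dist_A = numeric()))
  }
  parts <- strsplit(names(keep), " ")
  out <- data.frame(
    acid_resno = as.integer(vapply(parts, `[`, "", 2L)),
    base_resno = as.integer(vapply(parts, `[`, "", 4L)),
    min_dist_A = round(unlist(keep), rounding)
  )
  out[order(out$acid_resno, out$base_resno), , drop = FALSE]
}

# ---- random charged structures for oracle-equivalence sweeps ---------------
random_charged_structure <- function(n_res = 12, box = 18, seed = 1) {
  set.seed(seed)
  types <- sample(c("ASP", "GLU", "ARG", "LYS", "HIS"), n_res, replace = TRUE)
  atom_names <- list(ASP = c("OD1", "OD2", "CG"), GLU = c("OE1", "OE2", "CD"),
                     ARG = c("NH1", "NH2", "NE"), LYS = c("NZ", "CE"),
                     HIS = c("ND1", "NE2", "CG"))
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    center <- runif(3, 0, box)
    nm <- atom_names[[types[i]]]
    offs <- matrix(rnorm(3 * length(nm), sd = 0.8), ncol = 3)
    data.frame(chain = "A", resno = i, insert = "", resid = types[i],
               elety = nm, element = substr(nm, 1, 1),
               x = center[1] + offs[, 1], y = center[2] + offs[, 2],
               z = center[3] + offs[, 3], o = 1, b = 0,
               stringsAsFactors = FALSE)
  }))
  bridgestab:::new_prot_struct(sprintf("random_%d", seed), atoms)
}

# ---- solid carbon shell to bury a region (for SASA/burial fixtures) --------
occlude_region <- function(s, center, radius = 9, spacing = 2.3,
                           clearance = 2.7, chain = "Z", start_resno = 900L) {
  g <- seq(-radius, radius, by = spacing)
  pts <- as.matrix(expand.grid(g, g, g))
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  pts <- sweep(pts, 2, center, "+")
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  keep <- vapply(seq_len(nrow(pts)), function(k) {
    min(sqrt(rowSums(sweep(xyz, 2, pts[k, ], "-")^2))) >= clearance
  }, logical(1))
  pts <- pts[keep, , drop = FALSE]
  cage <- data.frame(chain = chain,
                     resno = start_resno + seq_len(nrow(pts)) - 1L,
                     insert = "", resid = "GLY", elety = "CA", element = "C",
                     x = pts[, 1], y = pts[, 2], z = pts[, 3], o = 1, b = 0,
                     stringsAsFactors = FALSE)
  bridgestab:::new_prot_struct(s$id, rbind(s$atoms, cage))
}

pair_center <- function(s, resno_a, resno_b) {
  a <- s$atoms[s$atoms$resno %in% c(resno_a, resno_b), , drop = FALSE]
  colMeans(as.matrix(a[, c("x", "y", "z")]))
}

# ---- synthetic stand-in for the MGL H-257 / EstGtA2 bridge inventory -------
# Plants the eight conserved bridges at their published residue numbers and
# distances; the E3-R54 pair is encased in a dense carbon shell (most
# buried), D124-K178 in a leakier shell (second most buried), everything
# else left solvent-exposed. This is a synthetic fixture, not PDB 3RM3.
synthetic_mgl_pairs <- function(interloop_base = "ARG") {
  data.frame(
    acid = c("GLU", "GLU", "GLU", "GLU", "ASP", "ASP", "ASP", "ASP"),
    base = c("ARG", "ARG", "HIS", "ARG", "LYS", "HIS", interloop_base, "ARG"),
    dist_A = c(3.3, 3.9, 3.4, 3.6, 3.3, 3.5, 4.0, 3.6),
    acid_resno = c(3L, 12L, 78L, 66L, 124L, 148L, 194L, 205L),
    base_resno = c(54L, 37L, 110L, 140L, 178L, 197L, 222L, 220L),
    stringsAsFactors = FALSE
  )
}

synthetic_mgl_structure <- function(interloop_base = "ARG", buried = TRUE) {
  s <- synth_structure(synthetic_mgl_pairs(interloop_base), seed = 42)
  if (buried) {
    s <- occlude_region(s, pair_center(s, 3, 54), radius = 10,
                        spacing = 2.2, chain = "Y", start_resno = 500L)
    s <- occlude_region(s, pair_center(s, 124, 178), radius = 9,
                        spacing = 3.4, chain = "Z", start_resno = 900L)
  }
  s
}

# ---- synthetic homolog pair (EstGtA2-like vs MGL-like sequences) -----------
# 27 substitutions planted in the 249-residue N' template, including the
# His222 -> Arg interloop switch, away from hallmark/triad positions.
synthetic_homolog_pair <- function() {
  tpl <- nprime_template()
  ch <- strsplit(tpl$seq, "")[[1L]]
  special <- c(3, 12, 54, 37, 66, 140, 124, 178, 205, 220, 78, 110, 148, 197,
               97, 196, 226, 194)
  set.seed(89L)
  sites <- c(222L, sample(setdiff(seq_along(ch), c(special, 222L)), 26L))
  mut <- ch
  mut[222L] <- "R"
  all_aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (p in setdiff(sites, 222L)) mut[p] <- sample(setdiff(all_aas, ch[p]), 1L)
  list(estgta2_like = seq_record("EstGtA2_like", tpl$seq),
       mgl_like = seq_record("MGL_like", paste(mut, collapse = "")),
       n_planted = length(sites), triad = tpl$triad)
}

# ---- tiny hand-written PDB text fixtures -----------------------------------
write_toy_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N   GLY A   2       3.300   1.100   0.250  1.00  0.00           N",
    "ATOM      4  CA  GLY A   2       4.700   1.250  -0.500  1.00  0.00           C",
    "HETATM    5  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"), path)
  path
}

write_altloc_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60 12.00           C",
    "END"), path)
  path
}

write_multimodel_pdb <- function(path) {
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ENDMDL",
    "END"), path)
  path
}

# closed-form accessible area of two overlapping probe-expanded spheres
two_sphere_areas <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  cap <- function(Ra, Rb) {
    if (d >= Ra + Rb) return(0)
    h <- Ra - (d^2 + Ra^2 - Rb^2) / (2 * d)
    2 * pi * Ra * h
  }
  c(4 * pi * R1^2 - cap(R1, R2), 4 * pi * R2^2 - cap(R2, R1))
}
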