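# Seeded synthetic-data generators.
#
# Every generator emits the exact object (or file format) its consumer stage
# reads, with the planted ground truth attached, so each pipeline stage can
# be validated against known parameters without any external data.

# minimal side-chain templates in a local frame: the primary charged atom at
# the origin, remaining atoms trailing off in -x/+y so that the planted
# contact is always the minimum inter-residue charged distance
SIDECHAIN_TEMPLATES <- list(
  ASP = list(primary = "OD1",
             atoms = list(OD1 = c(0, 0, 0), OD2 = c(-0.6, 1.6, 0),
                          CG = c(-1.0, 0.6, 0), CB = c(-2.3, 1.2, 0.3),
                          CA = c(-3.4, 0.4, 0.9))),
  GLU = list(primary = "OE1",
             atoms = list(OE1 = c(0, 0, 0), OE2 = c(-0.6, 1.6, 0),
                          CD = c(-1.0, 0.6, 0), CG = c(-2.3, 1.2, 0.3),
                          CB = c(-3.3, 0.5, 0.8), CA = c(-4.4, 1.0, 1.2))),
  ARG = list(primary = "NH1",
             atoms = list(NH1 = c(0, 0, 0), NH2 = c(-0.4, 1.9, 0.4),
                          NE = c(-1.5, 0.2, 1.4), CZ = c(-0.7, 0.8, 0.6),
                          CD = c(-2.8, 0.8, 1.6), CA = c(-4.6, 0.6, 2.4))),
  LYS = list(primary = "NZ",
             atoms = list(NZ = c(0, 0, 0), CE = c(-1.2, 0.8, 0.2),
                          CD = c(-2.5, 0.2, 0.6), CA = c(-4.5, 1.0, 1.2))),
  HIS = list(primary = "NE2",
             atoms = list(NE2 = c(0, 0, 0), ND1 = c(-1.3, 1.7, 0.1),
                          CE1 = c(-0.4, 1.5, 0), CG = c(-2.2, 0.7, 0.2),
                          CB = c(-3.6, 1.0, 0.5), CA = c(-4.7, 0.2, 1.1)))
)

random_rotation <- function() {
  # QR-based uniform random rotation
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

place_residue <- function(resid, resno, origin, rot, flip = FALSE) {
  tpl <- SIDECHAIN_TEMPLATES[[resid]]
  coords <- do.call(rbind, tpl$atoms)
  if (flip) coords[, 1L] <- -coords[, 1L]  # face the partner along +x
  coords <- coords %*% t(rot)
  coords <- sweep(coords, 2, origin, "+")
  data.frame(chain = "A", resno = resno, insert = "", resid = resid,
             elety = names(tpl$atoms),
             element = substr(names(tpl$atoms), 1, 1),
             x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
             o = 1, b = 0, stringsAsFactors = FALSE)
}

#' Generate a structure with planted salt-bridge geometries
#'
#' Builds minimal charged side chains (charged atoms plus short stubs)
#' realizing each requested acid/base pair at exactly the planted minimum
#' charged-group distance. Pairs are spaced far apart, and decoy charged
#' residues are placed at least 6 Angstrom from everything, so the planted
#' pairs are exactly the detectable bridges. Each planted pair is rigidly
#' rotated at random (seeded), which exercises the detector's rotation
#' invariance.
#'
#' @param pairs data frame with columns \code{acid} (\code{"ASP"}/\code{"GLU"}),
#'   \code{base} (\code{"ARG"}/\code{"LYS"}/\code{"HIS"}) and \code{dist_A}
#'   (planted minimum distance, > 2); optional \code{acid_resno},
#'   \code{base_resno}.
#' @param decoys number of isolated charged decoy residues (default 0).
#' @param seed integer seed controlling pair orientations and decoy types.
#' @return a \code{prot_struct} with attribute \code{truth}: the pairs table
#'   with assigned residue numbers.
#' @export
synth_structure <- function(pairs, decoys = 0, seed = 1) {
  if (is.null(pairs)) {
    pairs <- data.frame(acid = character(), base = character(),
                        dist_A = numeric())
  }
  stopifnot(is.data.frame(pairs), decoys >= 0)
  if (nrow(pairs) > 0L && any(pairs$dist_A <= 2.0)) {
    stop("planted distances must exceed 2.0 Angstrom")
  }
  set.seed(seed)
  atoms <- NULL
  resno <- 0L
  truth <- pairs
  truth$acid_resno <- truth$base_resno <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    origin <- c(30 * (i - 1L), 0, 0)
    rot <- random_rotation()
    acid_no <- if (!is.null(pairs$acid_resno)) pairs$acid_resno[i] else resno + 1L
    base_no <- if (!is.null(pairs$base_resno)) pairs$base_resno[i] else resno + 2L
    resno <- max(resno, acid_no, base_no)
    # acid primary atom at local origin, base primary at (d, 0, 0),
    # base side chain flipped to trail away in +x; whole pair then rotated
    acid <- place_residue(pairs$acid[i], acid_no, c(0, 0, 0), diag(3))
    base <- place_residue(pairs$base[i], base_no, c(pairs$dist_A[i], 0, 0),
                          diag(3), flip = TRUE)
    both <- rbind(acid, base)
    xyz <- as.matrix(both[, c("x", "y", "z")]) %*% t(rot)
    both[, c("x", "y", "z")] <- sweep(xyz, 2, origin, "+")
    atoms <- rbind(atoms, both)
    truth$acid_resno[i] <- acid_no
    truth$base_resno[i] <- base_no
  }
  decoy_types <- c("ASP", "GLU", "ARG", "LYS", "HIS")
  for (k in seq_len(decoys)) {
    resno <- resno + 1L
    atoms <- rbind(atoms, place_residue(sample(decoy_types, 1L), resno,
                                        c(30 * (k - 1L), 60, 40),
                                        random_rotation()))
  }
  if (is.null(atoms)) stop("nothing to build: no pairs and no decoys")
  s <- new_prot_struct(sprintf("synthetic_%dpairs_%ddecoys", nrow(pairs), decoys),
                       atoms[order(atoms$resno), , drop = FALSE])
  attr(s, "truth") <- truth
  s
}

#' Generate a two-state thermal unfolding curve
#'
#' Evaluates the van't Hoff two-state signal model with sloping linear
#' baselines on a temperature grid and adds homoscedastic Gaussian noise
#' scaled to the clean signal span. \code{noise_sd = 0} returns the exact
#' model curve.
#'
#' @param Tm_C planted melting temperature, Celsius.
#' @param dHm planted van't Hoff enthalpy, kcal/mol (default 120).
#' @param baselines list \code{aF}, \code{bF}, \code{aU}, \code{bU}
#'   (intercepts/slopes vs Celsius).
#' @param grid temperature grid, Celsius (default 25 to 90 by 0.5).
#' @param noise_sd Gaussian noise SD as a fraction of the clean signal span
#'   (default 0).
#' @param seed integer seed (used only when \code{noise_sd > 0}).
#' @param ph optional pH annotation.
#' @return a \code{melting_curve} with attribute \code{truth}.
#' @export
synth_melting_curve <- function(Tm_C, dHm = 120,
                                baselines = list(aF = -20, bF = 0.02,
                                                 aU = -4, bU = 0.05),
                                grid = seq(25, 90, by = 0.5),
                                noise_sd = 0, seed = 1, ph = NA_real_) {
  if (Tm_C < min(grid) || Tm_C > max(grid)) {
    warning("planted Tm lies outside the temperature grid; fits will extrapolate")
  }
  clean <- two_state_signal(grid, Tm_C, dHm, baselines$aF, baselines$bF,
                            baselines$aU, baselines$bU)
  y <- clean
  if (noise_sd > 0) {
    set.seed(seed)
    y <- clean + rnorm(length(grid), 0, noise_sd * diff(range(clean)))
  }
  out <- melting_curve(grid, y, ph = ph)
  attr(out, "truth") <- list(Tm_C = Tm_C, dHm = dHm, baselines = baselines,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a chemical denaturation curve (linear extrapolation model)
#'
#' @param Cm_M planted midpoint, M.
#' @param m planted m-value, kcal/(mol M) (default 3).
#' @param baselines list \code{aF}, \code{bF}, \code{aU}, \code{bU}
#'   (intercepts/slopes vs concentration).
#' @param grid concentration grid, M (default 0 to 3 by 0.1).
#' @param noise_sd Gaussian noise SD as a fraction of the signal span.
#' @param seed integer seed (used only when \code{noise_sd > 0}).
#' @param temp_K temperature, Kelvin (default 298.15).
#' @return data frame (\code{conc_M}, \code{signal}) with attribute
#'   \code{truth}.
#' @export
synth_chem_curve <- function(Cm_M, m = 3,
                             baselines = list(aF = 1, bF = -0.02,
                                              aU = 0.15, bU = -0.01),
                             grid = seq(0, 3, by = 0.1),
                             noise_sd = 0, seed = 1, temp_K = 298.15) {
  fU <- 1 / (1 + exp(m * (Cm_M - grid) / (R_KCAL * temp_K)))
  clean <- (baselines$aF + baselines$bF * grid) * (1 - fU) +
    (baselines$aU + baselines$bU * grid) * fU
  y <- clean
  if (noise_sd > 0) {
    set.seed(seed)
    y <- clean + rnorm(length(grid), 0, noise_sd * diff(range(clean)))
  }
  out <- data.frame(conc_M = grid, signal = y)
  attr(out, "truth") <- list(Cm_M = Cm_M, m = m, baselines = baselines,
                             noise_sd = noise_sd, seed = seed,
                             temp_K = temp_K)
  out
}

#' Synthetic N'-subfamily template sequence
#'
#' A 249-residue sequence carrying the catalytic triad (Ser97, Asp196,
#' His226), the interloop bridge (D194, H222), the five N'-exclusive
#' hallmark bridges and the two shared His bridges at their published
#' positions; remaining positions are filled deterministically. This is a
#' synthetic stand-in with the hallmark architecture of a family XV
#' carboxylesterase, not a database sequence.
#'
#' @return list with \code{seq} (character), \code{triad} and
#'   \code{hallmarks} (the N'-exclusive catalog with positions).
#' @export
nprime_template <- function() {
  set.seed(20131008L)  # fixed: the template is a constant of the package
  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                 c("D", "E", "R", "K", "H"))  # neutral background
  ch <- sample(aas, 249, replace = TRUE)
  fixed <- c(`3` = "E", `12` = "E", `54` = "R", `37` = "R", `66` = "E",
             `140` = "R", `124` = "D", `178` = "K", `205` = "D", `220` = "R",
             `78` = "E", `110` = "H", `148` = "D", `197` = "H",
             `97` = "S", `196` = "D", `226` = "H", `194` = "D", `222` = "H")
  ch[as.integer(names(fixed))] <- fixed
  list(seq = paste(ch, collapse = ""), triad = c(97L, 196L, 226L),
       hallmarks = hallmark_catalog()$nprime_exclusive)
}

#' Generate a synthetic N'-family alignment with hallmark knockouts
#'
#' Derives \code{n} sequences from the N' template: each of the five
#' exclusive hallmark bridges is knocked out (basic partner replaced by Ala,
#' mimicking alanine shaving) independently with probability
#' \code{knockout_rate}, and background positions receive random
#' substitutions at rate \code{sub_rate}. Hallmark, triad and interloop
#' positions are never hit by background substitutions. Since all sequences
#' are equal length the set is returned as an alignment (no gaps).
#'
#' @param n number of derived sequences (default 20).
#' @param knockout_rate per-bridge knockout probability (default 0.1).
#' @param sub_rate per-background-position substitution probability
#'   (default 0.02).
#' @param seed integer seed.
#' @param template template as returned by [nprime_template()].
#' @return list with \code{msa} (an \code{aa_msa} whose first row is the
#'   template), \code{truth} (per-sequence surviving hallmark count and the
#'   expected subfamily call under the default thresholds) and
#'   \code{template}.
#' @export
synth_msa_family <- function(n = 20, knockout_rate = 0.1, sub_rate = 0.02,
                             seed = 1, template = nprime_template()) {
  stopifnot(knockout_rate >= 0, knockout_rate < 1, sub_rate >= 0, sub_rate < 1)
  set.seed(seed)
  tpl <- strsplit(template$seq, "")[[1L]]
  hm <- template$hallmarks
  special <- c(hm$acid_pos, hm$base_pos, template$triad,
               template$triad[2L] - 2L, template$triad[3L] - 4L,
               hallmark_catalog()$nprime_shared$acid_pos,
               hallmark_catalog()$nprime_shared$base_pos)
  all_aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- character(n)
  knocked <- integer(n)
  for (i in seq_len(n)) {
    ch <- tpl
    ko <- runif(nrow(hm)) < knockout_rate
    ch[hm$base_pos[ko]] <- "A"
    knocked[i] <- sum(ko)
    bg <- setdiff(which(runif(length(ch)) < sub_rate), special)
    for (p in bg) ch[p] <- sample(setdiff(all_aas, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  ids <- sprintf("seq%02d", seq_len(n))
  m <- msa(setNames(c(template$seq, seqs), c("template", ids)))
  truth <- data.frame(
    id = ids, knocked_pairs = knocked,
    surviving = nrow(hm) - knocked,
    expected_call = ifelse(nrow(hm) - knocked >= 4L, "Nprime_familyXV",
                           "unassigned"),
    stringsAsFactors = FALSE
  )
  list(msa = m, truth = truth, template = template)
}

#' Generate tree-structured distance and sequence data
#'
#' From a tree with branch lengths, returns the additive leaf-to-leaf
#' distance matrix (path lengths), and optionally sequences evolved along
#' the tree under a Poisson substitution process (each substitution draws a
#' uniformly random different amino acid), so that the expected
#' Poisson-corrected distance between two leaves approximates their path
#' length.
#'
#' @param tree an \pkg{ape} \code{phylo} with branch lengths.
#' @param seed integer seed (sequence evolution only).
#' @param sites number of sites to evolve; 0 (default) skips sequence
#'   generation.
#' @return list with \code{dm} (additive matrix), \code{msa} (an
#'   \code{aa_msa}, or NULL) and \code{tree}.
#' @export
synth_tree_data <- function(tree, seed = 1, sites = 0) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0))
  dm <- ape::cophenetic.phylo(tree)
  dm <- dm[tree$tip.label, tree$tip.label]
  m <- NULL
  if (sites > 0) {
    set.seed(seed)
    all_aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample(all_aas, sites, replace = TRUE)
    # parents precede children in a preorder edge walk
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
      b <- ord$edge.length[e]
      ch <- seqs[[par]]
      hit <- which(rpois(sites, b) > 0L)
      for (p in hit) ch[p] <- sample(setdiff(all_aas, ch[p]), 1L)
      seqs[[child]] <- ch
    }
    tip_seqs <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                       character(1))
    m <- msa(setNames(tip_seqs, tree$tip.label))
  }
  list(dm = dm, msa = m, tree = tree)
}
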