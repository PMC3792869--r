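# Shrake-Rupley solvent-accessible surface area.
#
# Each heavy atom is expanded by the probe radius and covered with a
# deterministic golden-spiral point lattice; a point is accessible when it
# lies outside every neighbouring expanded sphere. The deterministic lattice
# makes results bit-reproducible without a seed.

# van der Waals radii (Angstrom) by element; anything unlisted defaults to C
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
VDW_DEFAULT <- 1.70

# Theoretical maximum accessible areas (Angstrom^2) of residue X in an
# extended Gly-X-Gly tripeptide (Tien et al. 2013), used as the reference
# for relative SASA.
MAX_ASA_GXG <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

# n approximately evenly distributed unit vectors (golden-spiral lattice)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Computes per-atom and per-residue SASA with a rolling probe, plus relative
#' residue accessibility against the extended Gly-X-Gly reference areas.
#' Hydrogens are ignored. The sphere sampling uses a fixed golden-spiral
#' lattice, so results are deterministic for a given \code{n_points}.
#'
#' @param s a \code{prot_struct}.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960).
#' @return an object of class \code{sasa_result}: list with \code{atoms}
#'   (the heavy-atom table with an \code{sasa_A2} column), \code{residues}
#'   (per-residue \code{sasa_A2} and \code{rel_sasa}), \code{total_A2},
#'   \code{probe_A} and \code{n_points}.
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "prot_struct"), probe >= 0, n_points >= 32)
  a <- s$atoms[s$atoms$element != "H", , drop = FALSE]
  n <- nrow(a)
  if (n == 0L) stop("structure has no heavy atoms")

  r <- unname(VDW_RADII[a$element])
  r[is.na(r)] <- VDW_DEFAULT
  R <- r + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  sphere <- golden_spiral_points(n_points)

  # neighbour lists from the pairwise distance matrix (structures here are
  # small; a cell list is unnecessary)
  d2 <- as.matrix(stats::dist(xyz))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    pts <- sweep(sphere * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- pts[acc, 1L] - xyz[j, 1L]
      dy <- pts[acc, 2L] - xyz[j, 2L]
      dz <- pts[acc, 3L] - xyz[j, 3L]
      acc[acc] <- (dx * dx + dy * dy + dz * dz) >= R[j]^2
    }
    sasa[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }

  a$sasa_A2 <- sasa
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  res_sasa <- tapply(sasa, factor(key, levels = key[first]), sum)
  residues <- data.frame(
    chain = a$chain[first], resno = a$resno[first], insert = a$insert[first],
    resid = a$resid[first], sasa_A2 = as.numeric(res_sasa),
    stringsAsFactors = FALSE
  )
  residues$rel_sasa <- residues$sasa_A2 / unname(MAX_ASA_GXG[residues$resid])
  structure(list(atoms = a, residues = residues, total_A2 = sum(sasa),
                 probe_A = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d residues, total %.1f A^2 (probe %.2f A, %d points)\n",
              nrow(x$residues), x$total_A2, x$probe_A, x$n_points))
  invisible(x)
}

#' Classify salt-bridge burial from relative SASA
#'
#' Labels each bridge by the mean relative SASA of its two residues:
#' \code{buried} below \code{buried_max}, \code{exposed} above
#' \code{exposed_min}, \code{intermediate} otherwise. Bridges are also
#' rank-ordered from most to least buried.
#'
#' @param sasa a \code{sasa_result} for the same structure.
#' @param bridges a \code{saltbridge_set}.
#' @param buried_max,exposed_min burial thresholds on mean relative SASA
#'   (defaults 0.10 and 0.35).
#' @return \code{bridges} with \code{mean_rel_sasa}, \code{burial} and
#'   \code{burial_rank} (1 = most buried) columns filled.
#' @export
bridge_burial <- function(sasa, bridges, buried_max = 0.10,
                          exposed_min = 0.35) {
  stopifnot(inherits(sasa, "sasa_result"), inherits(bridges, "saltbridge_set"))
  res <- sasa$residues
  rkey <- paste(res$chain, res$resno, res$insert, sep = "\r")
  rel_of <- function(chain, resno, insert) {
    i <- match(paste(chain, resno, insert, sep = "\r"), rkey)
    if (is.na(i)) NA_real_ else res$rel_sasa[i]
  }
  mean_rel <- vapply(seq_len(nrow(bridges)), function(i) {
    ra <- rel_of(bridges$acid_chain[i], bridges$acid_resno[i], bridges$acid_insert[i])
    rb <- rel_of(bridges$base_chain[i], bridges$base_resno[i], bridges$base_insert[i])
    mean(c(ra, rb))
  }, numeric(1))
  if (anyNA(mean_rel)) {
    warning("bridge residue(s) missing from SASA result; left unlabeled")
  }
  bridges$mean_rel_sasa <- mean_rel
  bridges$burial <- ifelse(is.na(mean_rel), NA_character_,
                    ifelse(mean_rel < buried_max, "buried",
                    ifelse(mean_rel > exposed_min, "exposed", "intermediate")))
  bridges$burial_rank <- rank(mean_rel, ties.method = "first",
                              na.last = "keep")
  bridges
}
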