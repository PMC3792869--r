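# Geometric salt-bridge detection.
#
# A salt bridge is scored between an acidic side-chain carboxylate oxygen
# (Asp OD1/OD2, Glu OE1/OE2) and a basic side-chain nitrogen (Arg NH1/NH2/NE,
# Lys NZ, His ND1/NE2). The reported distance is the minimum over all
# acid-O x base-N atom pairs of the two residues (not a centroid distance),
# and the cutoff is applied after rounding, inclusive, so a pair printed as
# 4.0 A is detected at a 4 A cutoff.

ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS  <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                     HIS = c("ND1", "NE2"))

#' Detect salt bridges in a protein structure
#'
#' Finds all residue pairs formed by one acidic (Asp/Glu) and one basic
#' (Arg/Lys, optionally His) side chain whose minimum charged-group
#' inter-atomic distance, rounded to \code{rounding} decimals, is at most
#' \code{cutoff}. Histidine is treated as basic by default; at alkaline pH
#' (above ~7) His is largely neutral, so \code{include_his = FALSE} restricts
#' detection to Arg/Lys partners. Hydrogens are ignored.
#'
#' @param s a \code{prot_struct} (see [read_structure()]).
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @param include_his logical: count His ND1/NE2 as basic (default TRUE).
#' @param include_termini logical: also consider the backbone N of the first
#'   residue and the OXT of the last residue of each chain (default FALSE:
#'   side-chain bridges only).
#' @param rounding decimals used for the reported distance and the cutoff
#'   comparison (default 1).
#' @return a data frame of class \code{saltbridge_set}, one row per detected
#'   residue pair, sorted by acidic then basic residue number. Columns:
#'   chain/number/name of the acidic and basic residues, \code{min_dist_A},
#'   the closest atom pair, \code{n_contacts} (atom pairs within the cutoff)
#'   and \code{burial} (filled by [bridge_burial()]).
#' @export
detect_salt_bridges <- function(s, cutoff = 4.0, include_his = TRUE,
                                include_termini = FALSE, rounding = 1) {
  stopifnot(inherits(s, "prot_struct"), cutoff > 0)
  a <- s$atoms[s$atoms$element != "H", , drop = FALSE]

  basic_atoms <- BASIC_ATOMS
  if (!include_his) basic_atoms$HIS <- NULL

  acid <- charged_rows(a, ACIDIC_ATOMS)
  base <- charged_rows(a, basic_atoms)
  if (include_termini) {
    term <- terminus_rows(a)
    acid <- rbind(acid, term$acid)
    base <- rbind(base, term$base)
  }
  warn_truncated(a, ACIDIC_ATOMS, acid)
  warn_truncated(a, basic_atoms, base)

  empty <- saltbridge_frame()
  if (nrow(acid) == 0L || nrow(base) == 0L) return(empty)

  d <- sqrt(outer(acid$x, base$x, "-")^2 +
            outer(acid$y, base$y, "-")^2 +
            outer(acid$z, base$z, "-")^2)
  # never pair atoms of the same residue (possible when termini are included)
  same <- outer(acid$reskey, base$reskey, "==")
  d[same] <- Inf
  dr <- round(d, rounding)

  hit <- which(dr <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)

  pair_key <- paste(acid$reskey[hit[, 1L]], base$reskey[hit[, 2L]], sep = "|")
  rows <- lapply(split(seq_len(nrow(hit)), pair_key), function(idx) {
    ai <- hit[idx, 1L]; bi <- hit[idx, 2L]
    k <- which.min(d[cbind(ai, bi)])
    i <- ai[k]; j <- bi[k]
    data.frame(
      acid_chain = acid$chain[i], acid_resno = acid$resno[i],
      acid_insert = acid$insert[i], acid_resid = acid$resid[i],
      base_chain = base$chain[j], base_resno = base$resno[j],
      base_insert = base$insert[j], base_resid = base$resid[j],
      min_dist_A = round(d[i, j], rounding),
      acid_atom = acid$elety[i], base_atom = base$elety[j],
      n_contacts = length(idx), burial = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$acid_chain, out$acid_resno, out$base_resno), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("saltbridge_set", "data.frame")
  out
}

saltbridge_frame <- function() {
  out <- data.frame(
    acid_chain = character(), acid_resno = integer(), acid_insert = character(),
    acid_resid = character(), base_chain = character(), base_resno = integer(),
    base_insert = character(), base_resid = character(),
    min_dist_A = numeric(), acid_atom = character(), base_atom = character(),
    n_contacts = integer(), burial = character(), stringsAsFactors = FALSE
  )
  class(out) <- c("saltbridge_set", "data.frame")
  out
}

charged_rows <- function(atoms, groups) {
  keep <- rep(FALSE, nrow(atoms))
  for (res in names(groups)) {
    keep <- keep | (atoms$resid == res & atoms$elety %in% groups[[res]])
  }
  out <- atoms[keep, , drop = FALSE]
  out$reskey <- paste(out$chain, out$resno, out$insert, sep = "\r")
  out
}

terminus_rows <- function(atoms) {
  per_chain <- split(atoms, atoms$chain)
  acid <- base <- NULL
  for (ch in per_chain) {
    first <- ch$resno == min(ch$resno)
    last <- ch$resno == max(ch$resno)
    base <- rbind(base, ch[first & ch$elety == "N", , drop = FALSE])
    acid <- rbind(acid, ch[last & ch$elety %in% c("OXT", "O"), , drop = FALSE])
  }
  add_key <- function(x) {
    if (is.null(x) || nrow(x) == 0L) {
      x <- atoms[0, , drop = FALSE]
    }
    x$reskey <- paste(x$chain, x$resno, x$insert, sep = "\r")
    x
  }
  list(acid = add_key(acid), base = add_key(base))
}

warn_truncated <- function(atoms, groups, found) {
  cand <- atoms[atoms$resid %in% names(groups), , drop = FALSE]
  if (nrow(cand) == 0L) return(invisible())
  cand_key <- unique(paste(cand$chain, cand$resno, cand$insert, cand$resid))
  got_key <- unique(paste(found$chain, found$resno, found$insert, found$resid))
  missing <- setdiff(cand_key, got_key)
  if (length(missing) > 0L) {
    warning("charged residue(s) with no side-chain charged atoms skipped: ",
            paste(missing, collapse = "; "))
  }
  invisible()
}

#' Compare salt-bridge inventories between two structures
#'
#' Matches each bridge of \code{a} against \code{b} through a residue-number
#' mapping (e.g. from a structure alignment of homologs). A matched pair
#' whose residue identities agree at both ends is \code{"identical"}; a
#' matched pair where an end is substituted within its charge class (D/E, or
#' R/K/H) is \code{"conserved_substitution"}; a mapped pair not found in
#' \code{b} is \code{"absent"}; a bridge with an unmapped endpoint is
#' \code{"unalignable"}.
#'
#' @param a,b \code{saltbridge_set} objects (see [detect_salt_bridges()]).
#' @param mapping named integer vector mapping residue numbers of \code{a}
#'   (names) to residue numbers of \code{b} (values). Defaults to the
#'   identity mapping over the residues appearing in \code{a}.
#' @return \code{a} with added columns \code{status}, \code{b_acid_resid},
#'   \code{b_base_resid}, \code{b_min_dist_A}.
#' @export
conserved_bridges <- function(a, b, mapping = NULL) {
  stopifnot(inherits(a, "saltbridge_set"), inherits(b, "saltbridge_set"))
  if (is.null(mapping)) {
    nums <- unique(c(a$acid_resno, a$base_resno))
    mapping <- setNames(nums, nums)
  }
  map1 <- function(n) {
    v <- mapping[as.character(n)]
    if (is.na(v)) NA_integer_ else as.integer(v)
  }
  status <- character(nrow(a))
  b_acid <- b_base <- rep(NA_character_, nrow(a))
  b_dist <- rep(NA_real_, nrow(a))
  for (i in seq_len(nrow(a))) {
    ma <- map1(a$acid_resno[i]); mb <- map1(a$base_resno[i])
    if (is.na(ma) || is.na(mb)) {
      status[i] <- "unalignable"
      next
    }
    j <- which(b$acid_resno == ma & b$base_resno == mb)
    if (length(j) == 0L) {
      status[i] <- "absent"
      next
    }
    j <- j[1L]
    b_acid[i] <- b$acid_resid[j]; b_base[i] <- b$base_resid[j]
    b_dist[i] <- b$min_dist_A[j]
    same <- a$acid_resid[i] == b$acid_resid[j] &&
      a$base_resid[i] == b$base_resid[j]
    status[i] <- if (same) "identical" else "conserved_substitution"
  }
  out <- as.data.frame(a)
  out$status <- status
  out$b_acid_resid <- b_acid
  out$b_base_resid <- b_base
  out$b_min_dist_A <- b_dist
  class(out) <- c("bridge_comparison", "data.frame")
  out
}
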