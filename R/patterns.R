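# Hallmark salt-bridge catalogs, the interloop (i-2, i-4) rule and the
# subfamily classification decision.
#
# Thermostable Geobacillus-type carboxylesterases / monoacylglycerol lipases
# (family XV, N' subfamily) carry five exclusive salt bridges plus two
# His-containing bridges shared more widely; the Est30-like family XIII (N
# subfamily) carries a distinct six-bridge pattern. A further diagnostic is
# the polarity of the interloop bridge between the residue two positions
# before the catalytic Asp and the residue four positions before the
# catalytic His: acid->base in N', base->acid in N.

#' Built-in hallmark salt-bridge catalogs
#'
#' Position pairs of the diagnostic salt bridges. \code{nprime_exclusive}
#' (five pairs) and \code{nprime_shared} (two His-containing pairs) are in
#' EstGtA2 / MGL H-257 numbering; \code{n_pattern} (six pairs) is in
#' Est30 (1TQH) numbering. Each pair lists the acidic member first.
#'
#' @return a list of three data frames (\code{acid_pos}, \code{acid_aa},
#'   \code{base_pos}, \code{base_aa}) plus reference row identifiers.
#' @export
hallmark_catalog <- function() {
  list(
    nprime_exclusive = data.frame(
      acid_pos = c(3L, 12L, 66L, 124L, 205L),
      acid_aa  = c("E", "E", "E", "D", "D"),
      base_pos = c(54L, 37L, 140L, 178L, 220L),
      base_aa  = c("R", "R", "R", "K", "R"),
      stringsAsFactors = FALSE
    ),
    nprime_shared = data.frame(
      acid_pos = c(78L, 148L), acid_aa = c("E", "D"),
      base_pos = c(110L, 197L), base_aa = c("H", "H"),
      stringsAsFactors = FALSE
    ),
    n_pattern = data.frame(
      acid_pos = c(40L, 124L, 152L, 142L, 219L, 237L),
      acid_aa  = c("E", "E", "E", "E", "E", "D"),
      base_pos = c(37L, 165L, 139L, 144L, 191L, 216L),
      base_aa  = c("R", "K", "K", "K", "R", "K"),
      stringsAsFactors = FALSE
    ),
    reference = c(nprime_exclusive = "EstGtA2", nprime_shared = "EstGtA2",
                  n_pattern = "Est30")
  )
}

charge_class <- function(aa) {
  ifelse(aa %in% c("D", "E"), "acidic",
  ifelse(aa %in% c("R", "K", "H"), "basic", "none"))
}

#' Map reference residue positions to alignment columns
#'
#' Column \code{k} corresponds to reference position \code{p} when the
#' \code{p}-th non-gap character of the reference row sits in column
#' \code{k} (1-based).
#'
#' @param m an \code{aa_msa}.
#' @param reference_id row identifier of the reference sequence.
#' @param positions integer vector of (ungapped) reference residue numbers.
#' @return integer vector of column indices, named by position.
#' @export
map_reference_positions <- function(m, reference_id, positions) {
  stopifnot(inherits(m, "aa_msa"))
  chars <- strsplit(msa_row(m, reference_id), "")[[1L]]
  nongap <- which(chars != "-")
  if (any(positions < 1L) || any(positions > length(nongap))) {
    stop("position(s) beyond the ungapped reference length (",
         length(nongap), "): ",
         paste(positions[positions < 1L | positions > length(nongap)],
               collapse = ", "))
  }
  setNames(nongap[positions], positions)
}

#' Locate and type the interloop (i-2, i-4) salt bridge
#'
#' The interloop bridge joins the residue two positions before the catalytic
#' Asp to the residue four positions before the catalytic His. Its polarity
#' is \code{acid_base} when position (Asp-2) is D/E and position (His-4) is
#' R/K/H, \code{base_acid} for the reverse arrangement, and \code{absent}
#' otherwise.
#'
#' @param seq a \code{seq_record} or plain character sequence (ungapped).
#' @param triad integer vector \code{c(ser, asp, his)} of catalytic-triad
#'   positions in the sequence's own numbering.
#' @param positions alternative to \code{triad}: the two bridge positions
#'   \code{c(i2, i4)} given directly (for enzymes whose triad is not
#'   annotated).
#' @return an object of class \code{interloop_bridge}: list with
#'   \code{pos_i2}, \code{pos_i4}, \code{res_i2}, \code{res_i4},
#'   \code{polarity}.
#' @export
interloop_bridge <- function(seq, triad = NULL, positions = NULL) {
  ch <- seq_chars(seq)
  if (is.null(positions)) {
    if (is.null(triad) || length(triad) != 3L) {
      stop("supply either triad = c(ser, asp, his) or positions = c(i2, i4)")
    }
    positions <- c(triad[2L] - 2L, triad[3L] - 4L)
  }
  if (positions[1L] < 1L || positions[2L] > length(ch)) {
    stop("interloop positions out of sequence range: ",
         paste(positions, collapse = ", "))
  }
  r1 <- ch[positions[1L]]; r2 <- ch[positions[2L]]
  c1 <- charge_class(r1); c2 <- charge_class(r2)
  polarity <- if (c1 == "acidic" && c2 == "basic") "acid_base"
    else if (c1 == "basic" && c2 == "acidic") "base_acid"
    else "absent"
  structure(list(pos_i2 = positions[1L], pos_i4 = positions[2L],
                 res_i2 = r1, res_i4 = r2, polarity = polarity),
            class = "interloop_bridge")
}

#' @export
print.interloop_bridge <- function(x, ...) {
  cat(sprintf("<interloop_bridge> %s%d - %s%d: %s\n",
              x$res_i2, x$pos_i2, x$res_i4, x$pos_i4, x$polarity))
  invisible(x)
}

#' Score a sequence against a hallmark bridge catalog
#'
#' For each catalog pair, the target row is scored \code{present} when both
#' positions carry exactly the catalog identities, \code{substituted} when
#' both positions preserve the charge class (D/E interchangeable; R/K/H
#' interchangeable), and \code{absent} otherwise (including gaps).
#'
#' @param m an \code{aa_msa} containing both the catalog's reference row and
#'   the target row.
#' @param target_id row identifier of the sequence to score.
#' @param catalog one catalog data frame from [hallmark_catalog()].
#' @param reference_id row identifier of the catalog's reference sequence.
#' @return an object of class \code{hallmark_profile}: the catalog with
#'   target residues and a \code{state} column, plus count attributes
#'   (\code{n_present}, \code{n_substituted}, \code{n_scored}).
#' @export
hallmark_profile <- function(m, target_id, catalog, reference_id) {
  stopifnot(is.data.frame(catalog))
  tgt <- strsplit(msa_row(m, target_id), "")[[1L]]
  acid_col <- map_reference_positions(m, reference_id, catalog$acid_pos)
  base_col <- map_reference_positions(m, reference_id, catalog$base_pos)
  ta <- tgt[acid_col]; tb <- tgt[base_col]
  state <- vapply(seq_len(nrow(catalog)), function(i) {
    if (ta[i] == "-" || tb[i] == "-") return("absent")
    if (ta[i] == catalog$acid_aa[i] && tb[i] == catalog$base_aa[i]) {
      return("present")
    }
    if (charge_class(ta[i]) == "acidic" && charge_class(tb[i]) == "basic") {
      return("substituted")
    }
    "absent"
  }, character(1))
  out <- catalog
  out$target_acid <- ta
  out$target_base <- tb
  out$state <- state
  attr(out, "target_id") <- target_id
  attr(out, "n_present") <- sum(state == "present")
  attr(out, "n_substituted") <- sum(state == "substituted")
  attr(out, "n_scored") <- nrow(catalog)
  class(out) <- c("hallmark_profile", "data.frame")
  out
}

profile_hits <- function(profile) {
  if (is.null(profile)) return(0L)
  attr(profile, "n_present") + attr(profile, "n_substituted")
}

#' Assign a lipolytic enzyme to a subfamily from its hallmark evidence
#'
#' Applies, in order: (1) at least \code{nprime_min} of the five N'-exclusive
#' pairs present or substituted and an \code{acid_base} interloop polarity
#' gives \code{Nprime_familyXV}; (2) at least \code{n_min} of the six
#' N-pattern pairs and \code{base_acid} polarity gives \code{N_familyXIII};
#' (3) \code{base_acid} polarity with an alpha/beta cap and fewer than
#' \code{lips_max} hits in either catalog gives \code{LipS_like}; (4)
#' otherwise \code{unassigned}. The thresholds are configuration: the
#' underlying hallmark observations are qualitative and the defaults encode
#' a tolerant reading (one knocked-out pair does not change the call).
#'
#' @param profile_nprime [hallmark_profile()] against the N'-exclusive
#'   catalog (or NULL).
#' @param profile_n [hallmark_profile()] against the N-pattern catalog
#'   (or NULL).
#' @param interloop an [interloop_bridge()].
#' @param cap_label cap-domain architecture metadata: \code{"alpha_beta"},
#'   \code{"alpha"} or \code{"unknown"} (default; rule 3 then cannot fire).
#' @param nprime_min,n_min,lips_max rule thresholds (defaults 4, 5, 2).
#' @return an object of class \code{subfamily_call}: list with \code{label},
#'   \code{evidence} and \code{notes}.
#' @export
classify_subfamily <- function(profile_nprime, profile_n, interloop,
                               cap_label = c("unknown", "alpha_beta", "alpha"),
                               nprime_min = 4L, n_min = 5L, lips_max = 2L) {
  cap_label <- match.arg(cap_label)
  stopifnot(inherits(interloop, "interloop_bridge"))
  hits_np <- profile_hits(profile_nprime)
  hits_n <- profile_hits(profile_n)
  pol <- interloop$polarity

  label <- if (hits_np >= nprime_min && pol == "acid_base") {
    "Nprime_familyXV"
  } else if (hits_n >= n_min && pol == "base_acid") {
    "N_familyXIII"
  } else if (pol == "base_acid" && cap_label == "alpha_beta" &&
             hits_np < lips_max && hits_n < lips_max) {
    "LipS_like"
  } else {
    "unassigned"
  }
  notes <- sprintf(
    "N'-exclusive hits %d/%d; N-pattern hits %d/%d; interloop %s; cap %s",
    hits_np, if (is.null(profile_nprime)) 0L else attr(profile_nprime, "n_scored"),
    hits_n, if (is.null(profile_n)) 0L else attr(profile_n, "n_scored"),
    pol, cap_label)
  structure(list(label = label,
                 evidence = list(nprime = profile_nprime, n = profile_n,
                                 interloop = interloop, cap = cap_label),
                 notes = notes),
            class = "subfamily_call")
}

#' @export
print.subfamily_call <- function(x, ...) {
  cat(sprintf("<subfamily_call> %s (%s)\n", x$label, x$notes))
  invisible(x)
}
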