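# Structure, sequence and alignment I/O.
#
# Conventions shared by all downstream stages:
#  * author (PDB) residue numbers are authoritative and 1-based;
#  * only the first model of multi-model files is read;
#  * hydrogens are retained in the atom table but ignored by all geometry;
#  * waters and non-polymer heteroatoms are dropped on read.

# standard 20-residue 3-to-1 table; everything else (MSE, ligands, ...) -> 'X'
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# residue names accepted as polymer (modified residues kept as 'X' in sequence)
POLYMER_RESID <- c(names(AA_3TO1), "MSE", "SEC", "PYL")

#' Convert three-letter residue names to one-letter codes
#'
#' Uses the standard 20-residue table; any other residue name (including
#' modified residues such as MSE) maps to \code{"X"}.
#'
#' @param aa3 character vector of three-letter residue names.
#' @return character vector of one-letter codes.
#' @export
aa_three_to_one <- function(aa3) {
  out <- unname(AA_3TO1[toupper(aa3)])
  out[is.na(out)] <- "X"
  out
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (fixed columns, via \pkg{bio3d}), keeps polymer
#' residues only (waters and ligands are dropped; MSE and similar modified
#' residues are kept), resolves alternate locations, and preserves author
#' residue numbering. For multi-model files only the first model is used.
#'
#' @param path path to a PDB-format file.
#' @param altloc alternate-location policy: \code{"highest-occupancy"}
#'   (default; ties broken toward the alphabetically first altloc id) or
#'   \code{"first"} (first record encountered wins).
#' @param id structure identifier; defaults to the file name without extension.
#' @return an object of class \code{prot_struct}: a list with elements
#'   \code{id}, \code{atoms} (one row per atom: \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{elety}, \code{element}, \code{x},
#'   \code{y}, \code{z}, \code{o}, \code{b}) and \code{source_format}.
#' @seealso [extract_sequence()], [detect_salt_bridges()], [compute_sasa()]
#' @export
read_structure <- function(path, altloc = c("highest-occupancy", "first"),
                           id = NULL) {
  altloc <- match.arg(altloc)
  if (!file.exists(path)) {
    stop("structure file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(rec & !coords_parseable(lines))
  if (length(bad) > 0L) {
    stop(sprintf("unparseable coordinate record at line %d of %s: '%s'",
                 bad[1L], path, substr(lines[bad[1L]], 1L, 40L)))
  }
  # first model only
  mdl_end <- grep("^ENDMDL", lines)
  src <- path
  if (length(mdl_end) > 0L) {
    src <- tempfile(fileext = ".pdb")
    on.exit(unlink(src), add = TRUE)
    writeLines(c(lines[seq_len(mdl_end[1L] - 1L)], "END"), src)
  }
  pdb <- bio3d::read.pdb(src, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[toupper(at$resid) %in% POLYMER_RESID, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("no polymer residues found in ", path)
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0

  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- if (altloc == "first") {
      !duplicated(key)
    } else {
      # highest occupancy; ties -> alphabetically first altloc id
      ord <- order(key, -at$o, at$alt)
      sel <- ord[!duplicated(key[ord])]
      seq_len(nrow(at)) %in% sel
    }
    at <- at[keep, , drop = FALSE]
  }

  element <- toupper(at$elesy)
  element[is.na(element) | element == ""] <- guess_element(at$elety[is.na(element) | element == ""])
  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = toupper(at$resid), elety = at$elety, element = element,
    x = at$x, y = at$y, z = at$z, o = at$o, b = at$b,
    stringsAsFactors = FALSE
  )
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert), , drop = FALSE]
  rownames(atoms) <- NULL
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  new_prot_struct(id, atoms)
}

coords_parseable <- function(lines) {
  xyz <- cbind(substr(lines, 31, 38), substr(lines, 39, 46), substr(lines, 47, 54))
  ok <- matrix(!is.na(suppressWarnings(as.numeric(xyz))), ncol = 3)
  rowSums(ok) == 3L
}

guess_element <- function(elety) {
  # first alphabetic character of the atom name (handles '1HB' style names)
  vapply(elety, function(e) {
    ch <- regmatches(e, regexpr("[A-Za-z]", e))
    if (length(ch) == 0L) "C" else toupper(ch)
  }, character(1), USE.NAMES = FALSE)
}

new_prot_struct <- function(id, atoms) {
  stopifnot(nrow(atoms) > 0L, all(is.finite(atoms$x + atoms$y + atoms$z)))
  structure(list(id = id, atoms = atoms, source_format = "pdb"),
            class = "prot_struct")
}

#' @export
print.prot_struct <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf("<prot_struct> %s: %d residues, %d atoms, chains: %s\n",
              x$id, nrow(res), nrow(x$atoms),
              paste(unique(res$chain), collapse = ", ")))
  invisible(x)
}

# one row per residue, in structure order
residue_table <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             stringsAsFactors = FALSE)
}

#' Write a structure to a PDB file
#'
#' Coordinates are written in the fixed-width PDB format (3 decimals), so a
#' write/read round trip preserves residue numbering and coordinates to
#' 0.001 Angstrom.
#'
#' @param s a \code{prot_struct}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, insert = a$insert,
                   o = a$o, b = a$b, elesy = a$element)
  invisible(path)
}

#' Extract the one-letter sequence of a chain
#'
#' Residues appear in structure order; non-standard residues become
#' \code{"X"}. Gaps in author numbering do not insert gap characters.
#'
#' @param s a \code{prot_struct}.
#' @param chain chain identifier; default: the first chain in the structure.
#' @return a \code{seq_record}: list with \code{id} and \code{seq}.
#' @export
extract_sequence <- function(s, chain = NULL) {
  res <- residue_table(s)
  if (is.null(chain)) chain <- res$chain[1L]
  res <- res[res$chain == chain, , drop = FALSE]
  if (nrow(res) == 0L) {
    stop("chain '", chain, "' not found in structure ", s$id)
  }
  seq_record(paste0(s$id, "_", chain),
             paste(aa_three_to_one(res$resid), collapse = ""))
}

#' Create a sequence record
#'
#' @param id record identifier.
#' @param seq one-letter amino-acid string (gaps \code{"-"} allowed in
#'   alignment rows).
#' @return an object of class \code{seq_record}.
#' @export
seq_record <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  structure(list(id = id, seq = toupper(seq)), class = "seq_record")
}

# accept seq_record or plain character
seq_chars <- function(x) {
  s <- if (inherits(x, "seq_record")) x$seq else as.character(x)
  strsplit(toupper(s), "")[[1L]]
}

seq_string <- function(x) if (inherits(x, "seq_record")) x$seq else toupper(as.character(x))

#' Read sequences from a FASTA file
#'
#' Unequal record lengths are allowed (use [read_msa()] for alignments).
#' Duplicate identifiers are suffixed with \code{.2}, \code{.3}, ... with a
#' warning.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- names(seqs)
  ids[is.na(ids)] <- ""
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    warning("duplicate sequence ids in ", path, "; suffixing")
    ids <- make.unique(ids, sep = ".")
  }
  names(seqs) <- ids
  seqs
}

#' Read a multiple sequence alignment (FASTA or Clustal)
#'
#' The format is sniffed from the first non-blank line: \code{">"} starts a
#' FASTA alignment, a \code{CLUSTAL} header starts a Clustal alignment.
#'
#' @param path path to the alignment file.
#' @return an \code{aa_msa} object (see [msa()]).
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- lines[nzchar(trimws(lines))][1L]
  if (is.na(first)) stop("empty alignment file: ", path)
  if (startsWith(first, ">")) {
    seqs <- read_fasta(path)
  } else if (grepl("^CLUSTAL", toupper(first))) {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- toupper(as.character(aln))
  } else {
    stop("unrecognized alignment format (expected FASTA or Clustal): ", path)
  }
  msa(seqs)
}

#' Construct a multiple sequence alignment object
#'
#' @param seqs named character vector of equal-length gapped sequences
#'   (gap character \code{"-"}).
#' @return an object of class \code{aa_msa}: list with \code{ids},
#'   \code{seqs} and \code{ncol}.
#' @export
msa <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 2L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("alignment rows must be named")
  }
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(range(len), collapse = " vs "))
  }
  structure(list(ids = names(seqs), seqs = toupper(seqs), ncol = len[[1L]]),
            class = "aa_msa")
}

#' @export
print.aa_msa <- function(x, ...) {
  cat(sprintf("<aa_msa> %d sequences x %d columns\n", length(x$ids), x$ncol))
  invisible(x)
}

msa_row <- function(m, id) {
  i <- match(id, m$ids)
  if (is.na(i)) stop("sequence '", id, "' not found in alignment")
  m$seqs[[i]]
}
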