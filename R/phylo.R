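# Pairwise identity, Poisson-corrected distances and neighbor-joining.

#' Global pairwise identity between two protein sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, gap extend 0.5,
#' via \pkg{Biostrings}). Identity is the fraction of identical aligned
#' residue pairs over all aligned (both non-gap) pairs; terminal gap columns
#' are excluded, so expression-tag overhangs do not depress identity. The
#' mismatch count covers substitutions within aligned pairs only.
#'
#' @param a,b sequences (\code{seq_record} or plain character).
#' @return list with \code{identity} (fraction), \code{mismatches},
#'   \code{aligned_pairs} and \code{score}.
#' @export
pairwise_identity <- function(a, b) {
  sa <- seq_string(a); sb <- seq_string(b)
  if (nchar(sa) == 0L || nchar(sb) == 0L) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  both <- pc != "-" & sc != "-"
  core <- seq(min(which(both)), max(which(both)))
  aligned <- both[core]
  identical_n <- sum(aligned & pc[core] == sc[core])
  n_aligned <- sum(aligned)
  list(identity = identical_n / n_aligned,
       mismatches = n_aligned - identical_n,
       aligned_pairs = n_aligned,
       score = Biostrings::score(pa))
}

#' Poisson-corrected evolutionary distances from an alignment
#'
#' For every sequence pair, gap-containing columns are dropped pairwise and
#' the proportion of differing sites p is converted to the Poisson-corrected
#' distance d = -ln(1 - p), in expected amino-acid substitutions per site.
#'
#' @param m an \code{aa_msa}.
#' @return an object of class \code{poisson_dm}: list with \code{ids},
#'   \code{d} (distance matrix) and \code{p} (p-distance matrix).
#' @export
poisson_distance <- function(m) {
  stopifnot(inherits(m, "aa_msa"))
  chars <- do.call(rbind, strsplit(m$seqs, ""))
  n <- nrow(chars)
  p <- d <- matrix(0, n, n, dimnames = list(m$ids, m$ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(shared)) {
        stop("no shared non-gap columns between '", m$ids[i], "' and '",
             m$ids[j], "'")
      }
      pij <- mean(chars[i, shared] != chars[j, shared])
      if (pij >= 1) {
        stop("p-distance of 1 between '", m$ids[i], "' and '", m$ids[j],
             "': Poisson correction undefined")
      }
      p[i, j] <- p[j, i] <- pij
      d[i, j] <- d[j, i] <- -log(1 - pij)
    }
  }
  structure(list(ids = m$ids, d = d, p = p), class = "poisson_dm")
}

as_dist_matrix <- function(dm) {
  if (inherits(dm, "poisson_dm")) return(dm$d)
  if (inherits(dm, "dist")) return(as.matrix(dm))
  m <- as.matrix(dm)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q criterion. Ties in Q are
#' broken deterministically toward the lowest (row, column) index pair.
#' Negative branch lengths are clamped to zero with a warning. On an
#' additive matrix the leaf-to-leaf path lengths of the result reproduce the
#' input distances exactly (to numerical precision).
#'
#' @param dm a \code{poisson_dm}, \code{dist} or symmetric numeric matrix
#'   with labels.
#' @return an unrooted tree of class \code{phylo} (\pkg{ape}).
#' @export
nj_tree <- function(dm) {
  D <- as_dist_matrix(dm)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric")
  }
  if (any(diag(D) != 0)) stop("distance matrix has a non-zero diagonal")
  labels <- rownames(D)
  if (n < 2L) stop("need at least 2 taxa")
  clamp <- FALSE
  bl <- function(x) {
    if (x < 0) clamp <<- TRUE
    sprintf("%.12g", max(0, x))
  }
  if (n == 2L) {
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1L], bl(D[1, 2] / 2),
                   labels[2L], bl(D[1, 2] / 2))
    return(ape::read.tree(text = nwk))
  }

  node <- labels  # newick fragment for each active cluster
  while (n > 3L) {
    r <- rowSums(D)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        q <- (n - 2) * D[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) {
          bestq <- q; best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    merged <- sprintf("(%s:%s,%s:%s)", node[i], bl(li), node[j], bl(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node <- c(node[keep], merged)
    n <- n - 1L
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[1L], bl(la), node[2L], bl(lb), node[3L], bl(lc))
  if (clamp) warning("negative branch length(s) clamped to zero")
  ape::read.tree(text = nwk)
}
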