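#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` with `P` and `Q` the transition
#' and transversion proportions over positions where both sequences carry an
#' unambiguous base (pairwise deletion of gaps and `N`). A saturated pair
#' (non-positive logarithm argument) is reported as `Inf` with a warning.
#'
#' @param seq1,seq2 sequence strings.
#' @return numeric distance.
#' @export
k80_distance <- function(seq1, seq2) {
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  if (length(a) != length(b)) stop("sequences are not aligned (unequal length)")
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(use)
  if (n == 0) return(NA_real_)
  a <- a[use]; b <- b[use]
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("saturated sequence pair; distance reported as Inf")
    return(Inf)
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K80 distance matrix for an alignment
#' @param aln a [seq_alignment()].
#' @return symmetric matrix (class `dist`-compatible via [stats::as.dist()]).
#' @export
k80_matrix <- function(aln) {
  ids <- names(aln$sequences)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- k80_distance(aln$sequences[[i]], aln$sequences[[j]])
  }
  d
}

#' Neighbor-joining tree and per-species monophyly check
#'
#' Builds a neighbor-joining tree on K80 distances and tests, for every
#' label, whether its records form one side of a bipartition of the unrooted
#' tree (the unrooted notion of monophyly).
#'
#' @param aln a [seq_alignment()] (>= 4 records).
#' @param labels named character vector (or vector aligned to records) giving
#'   each record's species label; `NA` records (e.g. the outgroup) are
#'   excluded from the monophyly sets but kept in the tree.
#' @return list: `tree` (ape phylo), `newick` string, `monophyly` named
#'   logical per label.
#' @export
nj_monophyly <- function(aln, labels) {
  if (length(aln$sequences) < 4) stop("need at least 4 sequences for a tree")
  if (is.null(names(labels))) names(labels) <- names(aln$sequences)
  d <- k80_matrix(aln)
  if (any(!is.finite(d))) {
    ## cap saturated distances so the tree remains constructible
    mx <- max(d[is.finite(d)])
    d[!is.finite(d)] <- 2 * mx
  }
  tree <- ape::nj(stats::as.dist(d))
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  part_sets <- lapply(parts, function(idx) tips[idx])
  mono <- vapply(unique(labels[!is.na(labels)]), function(lab) {
    set <- names(labels)[!is.na(labels) & labels == lab]
    set <- intersect(set, tips)
    if (length(set) <= 1) return(TRUE)
    any(vapply(part_sets, function(s)
      setequal(s, set) || setequal(setdiff(tips, s), set), logical(1)))
  }, logical(1))
  list(tree = tree, newick = ape::write.tree(tree), monophyly = mono)
}
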