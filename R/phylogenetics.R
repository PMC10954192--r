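# Phylogenetic placement: Kimura two-parameter (K80) distances from a
# multiple alignment, UPGMA clustering (rooted, ultrametric), column
# bootstrap for clade support, Newick output, and the criterion-4 check that
# a sample consensus clusters with its assigned species.

#' Kimura-80 distance between two aligned sequences
#'
#' Alignment columns with a gap, N, or any ambiguity code in either sequence
#' are excluded.  With transition proportion P and transversion proportion Q
#' over the included columns, `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`.
#' When a logarithm argument is non-positive the distance is saturated and
#' flagged undefined.
#'
#' @param a,b aligned sequences (equal length, gaps as `-`).
#' @return list with `P`, `Q`, `d`, `n_sites`, `defined`.
#' @export
k80_distance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  use <- x %in% DNA_BASES & y %in% DNA_BASES
  n <- sum(use)
  if (n == 0L)
    return(list(P = NA_real_, Q = NA_real_, d = NA_real_, n_sites = 0L,
                defined = FALSE))
  x <- x[use]; y <- y[use]
  diff <- x != y
  purine <- c("A", "G")
  transition <- diff & ((x %in% purine) == (y %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    return(list(P = P, Q = Q, d = NA_real_, n_sites = n, defined = FALSE))
  list(P = P, Q = Q, d = -0.5 * log(a1 * sqrt(a2)), n_sites = n, defined = TRUE)
}

#' K80 distance matrix from a multiple alignment
#'
#' @param msa named character vector of aligned sequences.
#' @return symmetric numeric matrix (NA where a pairwise distance is
#'   undefined/saturated).
#' @export
k80_matrix <- function(msa) {
  n <- length(msa)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- k80_distance(msa[i], msa[j])
      D[i, j] <- D[j, i] <- if (d$defined) d$d else NA_real_
    }
  }
  D
}

#' Multiple sequence alignment via MAFFT
#'
#' Aligns the consensus and reference sequences with MAFFT (deterministic
#' progressive alignment; must be on PATH).  Input order is preserved.
#'
#' @param seqs named character vector of unaligned sequences (length >= 2,
#'   no empty sequence).
#' @param args extra MAFFT arguments.
#' @return named character vector of aligned (gapped, uppercase) sequences.
#' @export
build_msa <- function(seqs, args = c("--retree", "2", "--maxiterate", "0")) {
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  if (any(nchar(seqs) == 0L)) stop("cannot align a sequence of length 0")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named")
  if (Sys.which("mafft") == "") stop("mafft not found on PATH")
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  s <- Biostrings::DNAStringSet(gsub("-", "", toupper(seqs)))
  names(s) <- names(seqs)
  Biostrings::writeXStringSet(s, fin)
  status <- system2("mafft", c("--quiet", args, fin), stdout = fout)
  if (status != 0L) stop("mafft failed with exit status ", status)
  aln <- Biostrings::readDNAStringSet(fout)
  out <- toupper(as.character(aln))
  names(out) <- sub("\\s.*$", "", names(aln))
  out[names(seqs)]
}

#' UPGMA tree from a distance matrix
#'
#' Iteratively joins the closest pair of clusters; the distance from a new
#' cluster to the others is the size-weighted arithmetic mean, and each
#' node's height is half the joining distance, so the result is rooted and
#' ultrametric.  Ties in the minimal distance break by row-then-column order
#' of the current matrix (deterministic).
#'
#' @param D symmetric distance matrix with zero diagonal and no NA (an NA
#'   entry means a saturated/undefined distance: exclude that sequence).
#' @return an [ape::phylo] tree.
#' @export
upgma <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (anyNA(D))
    stop("distance matrix has undefined entries; exclude the offending sequence(s)")
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (n == 1L) stop("need at least 2 taxa")
  newick <- labels
  height <- rep(0, n)
  size <- rep(1L, n)
  A <- D
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.15g", x)
  while (length(active) > 1L) {
    m <- length(active)
    sub <- A[active, active, drop = FALSE]
    best <- c(NA_integer_, NA_integer_); bd <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (sub[i, j] < bd) { bd <- sub[i, j]; best <- c(i, j) }
    }
    ii <- active[best[1]]; jj <- active[best[2]]
    h <- bd / 2
    newick_new <- paste0("(", newick[ii], ":", fmt(h - height[ii]), ",",
                         newick[jj], ":", fmt(h - height[jj]), ")")
    # size-weighted mean distance to every other active cluster
    others <- setdiff(active, c(ii, jj))
    newd <- (size[ii] * A[ii, others] + size[jj] * A[jj, others]) /
      (size[ii] + size[jj])
    A[ii, others] <- newd; A[others, ii] <- newd
    newick[ii] <- newick_new
    height[ii] <- h
    size[ii] <- size[ii] + size[jj]
    active <- setdiff(active, jj)
  }
  ape::read.tree(text = paste0(newick[active], ";"))
}

# sorted tip-label sets of every internal node (root included)
tree_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  lab <- attr(pp, "labels")
  lapply(pp, function(idx) sort(lab[idx]))
}

#' Bootstrap support for the clades of a K80/UPGMA tree
#'
#' Alignment columns are resampled with replacement; the K80 distance matrix
#' and UPGMA tree are recomputed per replicate, and each original clade's
#' support is the percentage of replicates containing the same tip set as a
#' clade.  Replicates yielding a saturated (undefined) distance are dropped
#' from the denominator.
#'
#' @param msa named character vector of aligned sequences (>= 4 for an
#'   informative tree).
#' @param n_replicates bootstrap replicates (default 1000; 0 gives a tree
#'   with no support values).
#' @param seed integer seed for column resampling.
#' @return list with `tree` (original UPGMA tree, `node.label` = support,
#'   root unlabelled), `support` (per-internal-node percentage, original
#'   clade order), `n_effective` replicates used.
#' @export
bootstrap_support <- function(msa, n_replicates = 1000L, seed = 1L) {
  D <- k80_matrix(msa)
  tree <- upgma(D)
  if (n_replicates == 0L)
    return(list(tree = tree, support = NULL, n_effective = 0L))
  cols <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
  nc <- ncol(cols)
  orig <- tree_clades(tree)
  hits <- numeric(length(orig))
  used <- 0L
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      idx <- sample.int(nc, nc, replace = TRUE)
      rep_msa <- setNames(apply(cols[, idx, drop = FALSE], 1L, paste, collapse = ""),
                          names(msa))
      Dr <- k80_matrix(rep_msa)
      if (anyNA(Dr)) next
      used <- used + 1L
      rc <- tree_clades(upgma(Dr))
      key <- vapply(rc, paste, character(1), collapse = "\r")
      ok <- vapply(orig, function(cl) paste(cl, collapse = "\r") %in% key,
                   logical(1))
      hits <- hits + ok
    }
  })
  support <- if (used > 0L) 100 * hits / used else rep(NA_real_, length(orig))
  lbl <- sprintf("%.0f", support)
  lbl[1] <- ""   # root
  tree$node.label <- lbl
  list(tree = tree, support = support, n_effective = used)
}

#' Write / read a tree as Newick
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; bootstrap
#' supports travel as internal-node labels.
#'
#' @param tree an `ape::phylo`.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Patristic distances between all leaves (path lengths along the tree)
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return symmetric matrix of leaf-to-leaf path lengths.
#' @export
patristic_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Criterion-4 placement check
#'
#' True iff the panel reference leaf with minimal patristic distance to the
#' sample leaf belongs to the assigned species (ties break by panel order).
#' The human reference is a panel leaf like any other; it can win only if
#' the sample really sits closest to it.
#'
#' @param tree tree containing the sample leaf and the panel reference
#'   leaves (labelled by reference id).
#' @param sample_leaf sample tip label.
#' @param assigned_species scientific species name being authenticated.
#' @param panel the `ref_panel` (maps reference ids to species).
#' @return logical.
#' @export
placement_check <- function(tree, sample_leaf, assigned_species, panel) {
  stopifnot(inherits(panel, "ref_panel"))
  if (!(sample_leaf %in% tree$tip.label))
    stop("sample leaf '", sample_leaf, "' not in tree")
  ref_ids <- intersect(panel_ids(panel), tree$tip.label)
  miss <- setdiff(panel_ids(panel), tree$tip.label)
  if (length(miss))
    stop("panel leaf/leaves missing from tree: ", paste(miss, collapse = ", "))
  pd <- patristic_distances(tree)
  d <- pd[sample_leaf, ref_ids]
  nearest <- ref_ids[which.min(d)]   # ties -> first in panel order
  panel_get(panel, nearest)$species_scientific == assigned_species
}
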