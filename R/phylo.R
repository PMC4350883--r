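# Distance phylogenetics: p-distances with pairwise or complete deletion,
# Poisson correction, site-coverage filtering, neighbor joining and
# bootstrap support.  Tree agglomeration is delegated to ape; this module
# owns the distance definitions, the filtering semantics and the
# bootstrap bookkeeping.

alignment_rows <- function(alignment) {
  if (is.character(alignment)) {
    ids <- names(alignment) %||% paste0("seq", seq_along(alignment))
    return(list(ids = ids, residues = unname(alignment)))
  }
  list(ids = alignment$id, residues = alignment$residues)
}

#' Pairwise p-distances of a protein alignment
#'
#' Ambiguous positions are gaps (`-`) and `X`.  Under pairwise deletion,
#' columns where either row of a pair is ambiguous are excluded for that
#' pair; under complete deletion, columns with any ambiguity are excluded
#' globally first.
#'
#' @param alignment Tibble of aligned records (`id`, `residues`) or a
#'   named character vector of equal-length rows.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A `wrky_dist` object: list with `ids`, `d` (symmetric matrix
#'   of proportions of differing sites), `comparable_sites` (per-pair
#'   column counts) and `measure = "p"`.
#' @export
p_distance <- function(alignment, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  al <- alignment_rows(alignment)
  if (length(al$ids) < 2) stop_precondition("need >= 2 aligned rows")
  m <- residue_matrix(al$residues)
  amb <- m == "-" | m == "X"
  if (deletion == "complete") {
    keep <- colSums(amb) == 0
    m <- m[, keep, drop = FALSE]
    amb <- amb[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(al$ids, al$ids))
  cs <- matrix(ncol(m), n, n, dimnames = list(al$ids, al$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !amb[i, ] & !amb[j, ]
      n_ok <- sum(ok)
      if (n_ok == 0) {
        stop_degenerate(sprintf(
          "no comparable sites between %s and %s", al$ids[i], al$ids[j]))
      }
      p <- sum(m[i, ok] != m[j, ok]) / n_ok
      d[i, j] <- d[j, i] <- p
      cs[i, j] <- cs[j, i] <- n_ok
    }
  }
  structure(list(ids = al$ids, d = d, comparable_sites = cs, measure = "p"),
            class = "wrky_dist")
}

#' Poisson correction of a p-distance
#'
#' `d = -ln(1 - p)`, in units of amino-acid substitutions per site.
#'
#' @param p A proportion of differing sites in `[0, 1)`: scalar, vector,
#'   matrix, or a `wrky_dist` object (corrected elementwise).
#' @return Same shape as `p`; for a `wrky_dist` input a new `wrky_dist`
#'   with `measure = "poisson"`.
#' @export
poisson_correct <- function(p) {
  if (inherits(p, "wrky_dist")) {
    out <- p
    out$d <- poisson_correct(p$d)
    out$measure <- "poisson"
    return(out)
  }
  if (any(p < 0 | p >= 1)) {
    stop_domain("p must satisfy 0 <= p < 1 for Poisson correction")
  }
  -log(1 - p)
}

#' Filter alignment columns by site coverage
#'
#' Site coverage of a column is the fraction of rows with an unambiguous
#' residue (not gap, not X).  Columns are retained exactly when coverage
#' >= `min_coverage` — i.e. positions with coverage *below* the threshold
#' are eliminated.
#'
#' @param alignment Tibble of aligned records or character vector.
#' @param min_coverage Minimum coverage fraction, default 0.95.
#' @return The alignment with non-qualifying columns removed (same type
#'   as the input; row order unchanged).  A zero-column result triggers a
#'   `wrky_empty_alignment` warning, not an error.
#' @export
site_coverage_filter <- function(alignment, min_coverage = 0.95) {
  al <- alignment_rows(alignment)
  m <- residue_matrix(al$residues)
  cov <- colSums(m != "-" & m != "X") / nrow(m)
  keep <- cov >= min_coverage
  if (!any(keep)) {
    warn("site-coverage filter removed every column",
         class = "wrky_empty_alignment")
  }
  filtered <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  if (length(filtered) == 0) filtered <- rep("", nrow(m))
  if (is.character(alignment)) {
    return(setNames(filtered, names(alignment)))
  }
  out <- alignment
  out$residues <- filtered
  out
}

#' Neighbor-joining tree from a distance object
#'
#' Saitou-Nei agglomeration (via ape) on the distance matrix.  Negative
#' branch lengths are clamped to zero; the number of clamped branches is
#' recorded in the `clamped_branches` attribute and reported as a
#' warning.
#'
#' @param D A `wrky_dist` object (or a symmetric matrix with dimnames).
#' @return An `ape::phylo` tree of class `c("wrky_nj", "phylo")`.
#' @export
nj_tree <- function(D) {
  m <- if (inherits(D, "wrky_dist")) D$d else D
  if (nrow(m) < 3) stop_precondition("neighbor joining needs >= 3 taxa")
  tree <- ape::nj(m)
  clamped <- sum(tree$edge.length < 0)
  if (clamped > 0) {
    warn(sprintf("%d negative branch length(s) clamped to 0", clamped),
         class = "wrky_clamped_branches")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "clamped_branches") <- clamped
  class(tree) <- c("wrky_nj", class(tree))
  tree
}

# Non-trivial bipartitions of an unrooted tree as canonical keys: the
# side not containing the lexicographically smallest label, sorted and
# joined with "|".
bipartition_keys <- function(tree, with_sides = FALSE) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[chl]])
  }
  ref <- sort(tree$tip.label)[1]
  keys <- character(0); sides <- list()
  for (e in seq_len(nrow(tree$edge))) {
    chl <- tree$edge[e, 2]
    if (chl <= nt) next
    side <- tree$tip.label[desc[[chl]]]
    if (length(side) < 2 || length(side) > nt - 2) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    sides <- c(sides, list(sort(side)))
  }
  u <- !duplicated(keys)
  if (with_sides) list(keys = keys[u], sides = sides[u]) else keys[u]
}

canonical_key <- function(taxa, all_labels) {
  ref <- sort(all_labels)[1]
  if (ref %in% taxa) taxa <- setdiff(all_labels, taxa)
  paste(sort(taxa), collapse = "|")
}

#' Is a set of taxa monophyletic on an unrooted tree?
#'
#' True iff some edge bipartition separates exactly `taxa` from the rest.
#' Singletons, sets of all leaves and sets of all-but-one leaf are
#' trivially monophyletic on an unrooted tree.
#'
#' @param tree A `phylo` tree.
#' @param taxa Character vector of tip labels.
#' @return Logical flag.
#' @export
is_monophyletic <- function(tree, taxa) {
  labels <- tree$tip.label
  unknown <- setdiff(taxa, labels)
  if (length(unknown) > 0) {
    stop_precondition(sprintf("unknown taxa: %s",
                              paste(unknown, collapse = ", ")))
  }
  m <- length(unique(taxa))
  nt <- length(labels)
  if (m %in% c(1L, nt - 1L, nt)) return(TRUE)
  canonical_key(unique(taxa), labels) %in% bipartition_keys(tree)
}

#' Bootstrap support for the full-data NJ tree
#'
#' Alignment columns are resampled with replacement per replicate, the
#' distance pipeline (p-distance, Poisson correction, neighbor joining)
#' is re-run, and the support of each non-trivial bipartition of the
#' full-data tree is the fraction of replicate trees containing it.  The
#' generator is seeded once per call; replicate r uses the r-th draw
#' (support streams are therefore reproducible for fixed
#' `n_replicates`, but not stable across different `n_replicates`).
#'
#' @param alignment Tibble of aligned records or character vector.
#' @param n_replicates Number of bootstrap replicates (>= 1); default
#'   1000.
#' @param seed Integer seed.
#' @param deletion Deletion mode for [p_distance()].
#' @param min_coverage Optional site-coverage threshold applied to the
#'   full alignment before anything else (`NULL` to skip).
#' @return A `wrky_boot` list: `tree` (full-data NJ tree), `support`
#'   (tibble with `key`, `tips` list, `support`), `n_replicates`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L,
                              deletion = "pairwise", min_coverage = NULL) {
  if (n_replicates < 1) stop_precondition("n_replicates must be >= 1")
  if (!is.null(min_coverage)) {
    alignment <- site_coverage_filter(alignment, min_coverage)
  }
  al <- alignment_rows(alignment)
  # canonicalize taxon order so supports are invariant to input order
  ord <- order(al$ids)
  al <- list(ids = al$ids[ord], residues = al$residues[ord])
  alignment <- setNames(al$residues, al$ids)
  L <- unique(nchar(al$residues))
  if (length(L) != 1) stop_format("ragged alignment")
  full_tree <- nj_tree(poisson_correct(p_distance(alignment, deletion)))
  bp <- bipartition_keys(full_tree, with_sides = TRUE)
  counts <- setNames(rep(0L, length(bp$keys)), bp$keys)
  m <- residue_matrix(al$residues)
  set.seed(seed)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    rep_aln <- setNames(res, al$ids)
    rep_tree <- suppressWarnings(
      nj_tree(poisson_correct(p_distance(rep_aln, deletion))))
    hit <- bp$keys %in% bipartition_keys(rep_tree)
    counts[hit] <- counts[hit] + 1L
  }
  structure(list(
    tree = full_tree,
    support = tibble(key = bp$keys, tips = bp$sides,
                     support = as.numeric(counts) / n_replicates),
    n_replicates = n_replicates), class = "wrky_boot")
}

#' Support of the bipartition separating a taxon set, if present
#' @param boot A `wrky_boot` object.
#' @param taxa Taxa expected to form a clade.
#' @return The support fraction, or `NA` if the full-data tree has no
#'   such bipartition.
#' @export
clade_support <- function(boot, taxa) {
  key <- canonical_key(unique(taxa), boot$tree$tip.label)
  i <- match(key, boot$support$key)
  if (is.na(i)) return(NA_real_)
  boot$support$support[i]
}
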