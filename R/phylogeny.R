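#' Phylogenetic correlation matrix from a tree
#'
#' Builds the species-level correlation structure of a Brownian-motion trait:
#' entry (i, j) is the shared root-to-tip path length of species i and j
#' divided by total tree depth. The tree is pruned to the requested species
#' first. Trees without branch lengths get Grafen lengths
#' (see [grafen_lengths()]); non-ultrametric trees are standardized to a
#' correlation matrix by \eqn{V_{ij}/\sqrt{V_{ii} V_{jj}}}.
#'
#' Tip labels and requested species are compared after replacing underscores
#' with spaces (configurable), the convention mismatch that Newick files and
#' study tables most often disagree on. Species recorded under synonyms are
#' handled by an explicit alias map; no automatic taxonomic resolution is
#' attempted.
#'
#' @param tree an `ape::phylo` object, a path to a Newick file, or a Newick
#'   string.
#' @param species character vector of species to keep (need not be unique).
#' @param aliases optional two-column data.frame (`from`, `to`) mapping names
#'   used in the study table to tip labels.
#' @param normalize logical; treat underscores and spaces as equivalent
#'   (default TRUE).
#' @return a `phylo_corr`: a symmetric positive-semidefinite matrix with unit
#'   diagonal and species dimnames.
#' @examples
#' corr <- phylo_correlation("((A:1,B:1):1,C:2);", c("A", "B", "C"))
#' corr["A", "B"] # 0.5
#' @export
phylo_correlation <- function(tree, species, aliases = NULL,
                              normalize = TRUE) {
  tree <- as_phylo(tree)
  species <- unique(as.character(species))
  if (!is.null(aliases)) {
    aliases <- as.data.frame(aliases)
    if (ncol(aliases) < 2) stop("alias map needs two columns", call. = FALSE)
    idx <- match(species, aliases[[1]])
    species[!is.na(idx)] <- aliases[[2]][idx[!is.na(idx)]]
  }
  canon <- function(x) if (normalize) gsub("_", " ", x, fixed = TRUE) else x
  hit <- match(canon(species), canon(tree$tip.label))
  if (anyNA(hit)) {
    stop("species not found in tree: ",
         paste(species[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  tips <- tree$tip.label[hit]
  if (is.null(tree$edge.length)) tree <- grafen_lengths(tree)

  # shared path lengths are measured on the full tree, then subset, so that
  # a pair's shared history is kept even when the subset spans one clade
  # (pruning first and building then commute by construction)
  V <- ape::vcv(tree)
  depth <- max(diag(V))
  if (depth <= 0) stop("tree has zero depth", call. = FALSE)
  if (max(abs(diag(V) - depth)) < 1e-8 * depth) {
    A <- V / depth
  } else {
    A <- stats::cov2cor(V)
  }
  A <- A[tips, tips, drop = FALSE]
  # restore the names used by the caller (pre-alias, pre-normalization)
  lab <- species[match(canon(colnames(A)), canon(species))]
  dimnames(A) <- list(lab, lab)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  structure(A, class = c("phylo_corr", "matrix"))
}

#' @export
print.phylo_corr <- function(x, ...) {
  cat("Phylogenetic correlation matrix:", nrow(x), "species\n")
  cat("  off-diagonal range:",
      paste(signif(range(x[upper.tri(x)]), 3), collapse = " to "), "\n")
  invisible(x)
}

#' Assign Grafen branch lengths
#'
#' Gives a rooted topology ultrametric branch lengths by Grafen's method:
#' each internal node sits at a height proportional to its number of
#' descendant tips minus one, normalized so the tree has unit depth. Used as
#' the default for trees delivered without branch lengths (as open-tree
#' toolchains commonly return).
#'
#' @param tree an `ape::phylo` object, path, or Newick string; must be rooted.
#' @return an ultrametric `phylo` with unit depth.
#' @export
grafen_lengths <- function(tree) {
  tree <- as_phylo(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  tree <- ape::compute.brlen(tree, method = "Grafen", power = 1)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

# Accept phylo / file path / Newick string interchangeably.
as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (!is.character(tree) || length(tree) != 1) {
    stop("`tree` must be a phylo object, a file path, or a Newick string",
         call. = FALSE)
  }
  if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
}

#' Local phylogenetic signal (local Moran-type statistic)
#'
#' Per-species local indicator of phylogenetic association for a trait:
#' \deqn{I_i = \frac{n \,(x_i - \bar{x}) \sum_j w_{ij} (x_j - \bar{x})}
#'            {\sum_k (x_k - \bar{x})^2}}
#' with weights \eqn{w_{ij}} taken from the off-diagonal phylogenetic
#' correlations, row-standardized to sum to one. Positive \eqn{I_i} means the
#' species and its close relatives deviate from the mean in the same
#' direction. P-values come from permuting the trait values across tips.
#'
#' @param values named numeric vector of per-species statistics; names must
#'   match the correlation matrix labels (unnamed vectors are taken in matrix
#'   order).
#' @param corr a [phylo_correlation()] matrix (or any labelled correlation
#'   matrix).
#' @param n_perm number of permutations, at least 99.
#' @param seed integer seed for the permutation stream.
#' @param alternative `"two.sided"` (default) or `"greater"` (positive
#'   autocorrelation only).
#' @return a `local_signal` data.frame with columns `species`, `statistic`,
#'   `p_value`.
#' @export
local_phylo_signal <- function(values, corr, n_perm = 999, seed = 1,
                               alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  labels <- colnames(corr)
  n <- length(labels)
  if (n < 3) stop("need at least 3 species", call. = FALSE)
  if (n_perm < 99) stop("need at least 99 permutations", call. = FALSE)
  if (!is.null(names(values))) {
    if (!all(labels %in% names(values))) {
      stop("`values` names do not cover the correlation matrix species",
           call. = FALSE)
    }
    values <- values[labels]
  } else if (length(values) != n) {
    stop("`values` length does not match the correlation matrix",
         call. = FALSE)
  }

  W <- as.matrix(corr)
  diag(W) <- 0
  rs <- rowSums(W)
  W[rs > 0, ] <- W[rs > 0, ] / rs[rs > 0]

  local_i <- function(x) {
    z <- x - mean(x)
    ss <- sum(z^2)
    if (ss < .Machine$double.eps) return(rep(0, length(x)))
    length(x) * z * drop(W %*% z) / ss
  }

  obs <- local_i(values)
  if (all(obs == 0)) {
    warning("constant trait values: all local statistics 0, p = 1")
    out <- data.frame(species = labels, statistic = 0, p_value = 1)
    class(out) <- c("local_signal", "data.frame")
    return(out)
  }

  set.seed(seed)
  exceed <- numeric(n)
  for (b in seq_len(n_perm)) {
    ib <- local_i(sample(values))
    exceed <- exceed + if (alternative == "two.sided") {
      abs(ib) >= abs(obs)
    } else {
      ib >= obs
    }
  }
  out <- data.frame(
    species = labels,
    statistic = obs,
    p_value = (exceed + 1) / (n_perm + 1)
  )
  rownames(out) <- NULL
  class(out) <- c("local_signal", "data.frame")
  out
}
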