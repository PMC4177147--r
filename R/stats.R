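#' Singleton/shared variant ratio
#'
#' The star-likeness statistic r: the sum of terminal branch lengths divided
#' by the sum of internal branch lengths, each internal branch weighted by
#' one plus the summed internal branch length beneath its node:
#' \deqn{r = \frac{\sum_{b \in \mathrm{TER}} l_b}
#'            {\sum_{b \in \mathrm{INT}} l_b \,
#'             (1 + \sum_{b_i \in \mathrm{BEN}(b)} l_{b_i})}}
#' Terminal branches carry singletons (variants private to one chromosome);
#' internal branches carry shared variants, down-weighted further when they
#' sit above other internal structure. Internal means neither terminal nor
#' the (non-existent) root branch; "beneath" means internal branches in the
#' subtree below the branch's child node, excluding the branch itself.
#'
#' A perfect star has no internal branches; r is then `+Inf` with attribute
#' `star = TRUE` rather than an error, and downstream fitting treats it as a
#' worst-possible fit.
#'
#' The statistic is not scale-free (because of the `1 +` weighting), so it is
#' conventionally computed on trees normalised to total length 1; see
#' [tree_stats()], which normalises first.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param include_terminal_beneath If `TRUE`, terminal branch lengths are also
#'   counted in the "beneath" sums (an alternative reading of the weighting;
#'   off by default).
#' @return The ratio r (possibly `Inf`).
#' @examples
#' singleton_shared_ratio(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"))  # 2
#' @export
singleton_shared_ratio <- function(tree, include_terminal_beneath = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  len <- tr$edge.length
  nnode <- n + tr$Nnode
  beneath <- numeric(nnode)          # internal length strictly below each node
  for (e in seq_len(nrow(edge))) {   # postorder: children before parents
    ch <- edge[e, 2]
    own <- if (ch > n || include_terminal_beneath) len[e] else 0
    beneath[edge[e, 1]] <- beneath[edge[e, 1]] + beneath[ch] + own
  }
  terminal <- edge[, 2] <= n
  num <- sum(len[terminal])
  int <- !terminal
  if (!any(int)) {
    r <- Inf
    attr(r, "star") <- TRUE
    return(r)
  }
  num / sum(len[int] * (1 + beneath[edge[int, 2]]))
}

#' Pairwise coalescence depths
#'
#' For every unordered pair of tips, the depth of their most recent common
#' ancestor: the mean path length from the MRCA node down to the two tips of
#' the pair. On an ultrametric tree this is the unique MRCA-to-tip distance;
#' on SNP-count trees (not exactly ultrametric) the two-tip mean is used.
#'
#' @param tree A rooted `phylo` tree with branch lengths and at least 2 tips.
#' @return Numeric vector of length `choose(n, 2)`, ordered as the pairs
#'   (1,2), (1,3), ..., (n-1, n).
#' @examples
#' pairwise_tmrca_depths(parse_newick("(A:1,B:1,C:1);"))  # 1 1 1
#' @export
pairwise_tmrca_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (n < 2) stop("need at least 2 tips")
  mrca <- ape::mrca(tree)
  dmat <- ape::dist.nodes(tree)
  pairs <- utils::combn(n, 2)
  vapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    a <- mrca[i, j]
    (dmat[a, i] + dmat[a, j]) / 2
  }, numeric(1))
}

#' Summary statistic triple of a tree
#'
#' Normalises the tree to total branch length 1 and returns the three
#' statistics used to compare observed and simulated phylogenies:
#' \describe{
#'   \item{`r`}{the singleton/shared ratio ([singleton_shared_ratio()]);}
#'   \item{`tmrca_mean`}{the mean pairwise coalescence depth
#'     ([pairwise_tmrca_depths()]), in normalised-length units;}
#'   \item{`tmrca_sd`}{the population standard deviation (divide by the
#'     number of pairs) of those depths.}
#' }
#' Together these capture the time depth of the tree and how star-like it is:
#' a perfect star has `tmrca_sd = 0`, `tmrca_mean = 1/n`, `r = Inf`.
#' Because of the normalisation the triple is invariant to rescaling all
#' branch lengths.
#'
#' @param tree A rooted `phylo` tree with positive total branch length.
#' @return Named numeric vector `c(r, tmrca_mean, tmrca_sd)`.
#' @examples
#' tree_stats(haplogroup_fixture("E1b1a"))
#' @export
tree_stats <- function(tree) {
  nt <- normalize_tree(tree)
  r <- singleton_shared_ratio(nt)
  dep <- pairwise_tmrca_depths(nt)
  m <- mean(dep)
  c(r = as.numeric(r), tmrca_mean = m,
    tmrca_sd = sqrt(mean((dep - m)^2)))
}
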