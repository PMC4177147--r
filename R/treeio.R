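#' Parse a Newick string into a rooted tree
#'
#' Thin wrapper around [ape::read.tree()] that first checks parenthesis
#' balance so that malformed input fails with the character position of the
#' offending bracket. Polytomies are allowed; a basal multifurcation is kept
#' as a rooted polytomy (the trees handled here are rooted haplogroup
#' phylogenies, not unrooted trees).
#'
#' @param text A Newick string, e.g. `"(A:2,B:3,C:4);"`.
#' @return A `phylo` object.
#' @examples
#' parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' @seealso [write_newick()], [read_tree()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  depth <- 0
  chars <- strsplit(text, "")[[1]]
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") depth <- depth + 1
    if (chars[pos] == ")") {
      depth <- depth - 1
      if (depth < 0)
        stop(sprintf("unbalanced ')' at character %d of Newick string", pos))
    }
  }
  if (depth > 0)
    stop(sprintf("unclosed '(' in Newick string (%d open at end, position %d)",
                 depth, length(chars)))
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  tr
}

#' Read a tree from a Newick file
#'
#' @param file Path to a Newick (`.nwk`) file containing one tree.
#' @return A `phylo` object.
#' @export
read_tree <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""))
}

#' Write a tree as Newick
#'
#' Inverse of [parse_newick()]: the returned string re-parses to a tree with
#' the same topology and branch lengths (up to numeric formatting).
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge) || nrow(tree$edge) == 0) stop("empty tree")
  s <- ape::write.tree(tree, digits = 12)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Total branch length of a tree
#'
#' @param tree A `phylo` object.
#' @return Sum of all branch lengths.
#' @export
total_branch_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  sum(tree$edge.length)
}

#' Normalise a tree to total branch length 1
#'
#' Divides every branch length by the tree's total branch length, the
#' standardisation applied before any tree statistic is computed. Idempotent;
#' topology is untouched.
#'
#' @param tree A `phylo` object with positive total branch length.
#' @return The tree with branch lengths summing to 1.
#' @examples
#' normalize_tree(parse_newick("(A:2,B:3,C:5);"))$edge.length
#' @export
normalize_tree <- function(tree) {
  tot <- total_branch_length(tree)
  if (tot <= 0) stop("degenerate tree: total branch length is zero")
  tree$edge.length <- tree$edge.length / tot
  tree
}

#' Collapse a sequenced pedigree into a single branch
#'
#' When several sampled chromosomes come from one known pedigree they are not
#' independent draws from the population, so the whole clade is replaced by a
#' single tip. The new tip's branch length is the SNP count on the branch
#' shared by all pedigree members (the clade's stem) plus the mean, over
#' members, of each member's own SNP count measured from the clade's common
#' ancestor. All branches outside the clade are unchanged. With a single
#' member the tree is returned unchanged (stem plus private path is already
#' one branch).
#'
#' @param tree A `phylo` tree with SNP-count branch lengths.
#' @param pedigree_tips Character vector of tip labels; must form a clade
#'   that is not the whole tree.
#' @param label Label for the replacement tip; defaults to the first
#'   pedigree label.
#' @return The tree with the clade replaced by one tip.
#' @examples
#' tr <- parse_newick("((a:2,b:2):10,(c:1,d:3):5);")
#' collapse_pedigree(tr, c("a", "b"))  # tip of length 10 + mean(2, 2) = 12
#' @export
collapse_pedigree <- function(tree, pedigree_tips, label = pedigree_tips[1]) {
  stopifnot(inherits(tree, "phylo"))
  if (length(pedigree_tips) == 0) stop("empty pedigree tip set")
  if (!all(pedigree_tips %in% tree$tip.label))
    stop("pedigree tips not in tree: ",
         paste(setdiff(pedigree_tips, tree$tip.label), collapse = ", "))
  if (length(pedigree_tips) == 1) return(tree)
  if (length(pedigree_tips) == ape::Ntip(tree))
    stop("pedigree clade cannot be the whole tree")
  mrca <- ape::getMRCA(tree, pedigree_tips)
  desc <- ape::extract.clade(tree, mrca)$tip.label
  if (!setequal(desc, pedigree_tips))
    stop("pedigree tips do not form a clade (clade also contains: ",
         paste(setdiff(desc, pedigree_tips), collapse = ", "), ")")
  stem_edge <- which(tree$edge[, 2] == mrca)
  stem <- if (length(stem_edge)) tree$edge.length[stem_edge] else 0
  dmat <- ape::dist.nodes(tree)
  idx <- match(pedigree_tips, tree$tip.label)
  private <- dmat[mrca, idx]
  keep <- pedigree_tips[1]
  out <- ape::drop.tip(tree, setdiff(pedigree_tips, keep))
  tip_i <- match(keep, out$tip.label)
  out$edge.length[out$edge[, 2] == tip_i] <- stem + mean(private)
  out$tip.label[tip_i] <- label
  out
}

#' Collapse zero-length internal branches into polytomies
#'
#' An observed SNP tree cannot display an internal branch carrying no
#' variants: such branches are invisible in the data and appear as
#' polytomies. This applies the same convention to simulated SNP trees via
#' [ape::di2multi()], turning internal branches with fewer than `tol`
#' variants into polytomies. Terminal branches are never removed. The three
#' tree statistics are invariant under this operation (a zero-length branch
#' contributes nothing to any of them).
#'
#' @param tree A `phylo` tree with SNP-count branch lengths.
#' @param tol Collapse internal branches with length below this (default 0.5,
#'   i.e. zero SNP counts).
#' @return The tree with zero-length internal branches collapsed.
#' @export
collapse_zero_branches <- function(tree, tol = 0.5) {
  stopifnot(inherits(tree, "phylo"))
  ape::di2multi(tree, tol = tol)
}

#' Packaged example haplogroup trees
#'
#' Loads one of the two example Y-chromosome haplogroup phylogenies shipped
#' with the package: a 6-tip near-star tree standing in for the European R1b
#' lineage, and an 8-tip largely bifurcating tree with one trifurcation
#' standing in for the African E1b1a lineage. Branch lengths are integer SNP
#' counts.
#'
#' These are *synthetic* stand-ins, not sequencing data: each is a single
#' seeded draw from [make_synthetic_observed()] under the package's fitted
#' regime model for that continent ([europe_regime_spec()],
#' [africa_regime_spec()]), with zero-variant internal branches collapsed,
#' selected so that its topology matches the published description of the
#' corresponding empirical tree (R1b: a star with exactly one internal branch
#' of one SNP uniting three of the six chromosomes; E1b1a: bifurcating with
#' exactly one trifurcation) and its summary statistics sit close to the
#' scenario mean. See the package vignette for the construction.
#'
#' @param haplogroup `"R1b"` or `"E1b1a"`.
#' @return A `phylo` tree with integer SNP-count branch lengths.
#' @examples
#' tr <- haplogroup_fixture("R1b")
#' tree_stats(tr)
#' @export
haplogroup_fixture <- function(haplogroup = c("R1b", "E1b1a")) {
  haplogroup <- match.arg(haplogroup)
  fname <- switch(haplogroup, R1b = "r1b_synthetic.nwk",
                  E1b1a = "e1b1a_synthetic.nwk")
  path <- system.file("extdata", fname, package = "coalexp")
  if (path == "") stop("fixture file not found; is the package installed?")
  read_tree(path)
}
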