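# Brute-force oracles, independent of the package's implementations.

# all edges in the subtree below `node` (child-side node indices)
subtree_edges <- function(tree, node) {
  out <- integer(0)
  frontier <- node
  while (length(frontier)) {
    e <- which(tree$edge[, 1] %in% frontier)
    out <- c(out, e)
    frontier <- tree$edge[e, 2]
  }
  out
}

# singleton/shared ratio by direct enumeration of the formula
oracle_r <- function(tree, include_terminal_beneath = FALSE) {
  n <- length(tree$tip.label)
  lens <- tree$edge.length
  terminal <- tree$edge[, 2] <= n
  num <- sum(lens[terminal])
  int_edges <- which(!terminal)
  if (length(int_edges) == 0) return(Inf)
  denom <- 0
  for (e in int_edges) {
    below <- subtree_edges(tree, tree$edge[e, 2])
    keep <- if (include_terminal_beneath) below else
      below[tree$edge[below, 2] > n]
    denom <- denom + lens[e] * (1 + sum(lens[keep]))
  }
  num / denom
}

# path of nodes from a tip up to the root
root_path <- function(tree, node) {
  path <- node
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0) break
    node <- tree$edge[e, 1]
    path <- c(path, node)
  }
  path
}

path_length <- function(tree, from_anc, to_desc) {
  len <- 0
  node <- to_desc
  while (node != from_anc) {
    e <- which(tree$edge[, 2] == node)
    len <- len + tree$edge.length[e]
    node <- tree$edge[e, 1]
  }
  len
}

# pairwise MRCA depths by walking parent chains
oracle_depths <- function(tree) {
  n <- length(tree$tip.label)
  out <- numeric(0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    pi <- root_path(tree, i)
    pj <- root_path(tree, j)
    anc <- pi[pi %in% pj][1]
    out <- c(out, (path_length(tree, anc, i) + path_length(tree, anc, j)) / 2)
  }
  out
}

# coalescent waiting time by numeric integration of the hazard on a fine
# grid, inverted by interpolation
oracle_wait_time <- function(k, model, t0, u, gen_years = 30,
                             horizon = NULL, steps = 4e5) {
  cc <- k * (k - 1) / 2
  H <- -log(u)
  if (is.null(horizon))
    horizon <- (model$t_end_years + model$duration_years) / gen_years +
      10 * model$start_n / cc * max(H, 1)
  integrate_to <- function(hor) {
    tt <- seq(t0, t0 + hor, length.out = steps)
    rate <- cc / population_size_at(model, tt, gen_years)
    dt <- tt[2] - tt[1]
    cum <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))
    stats::approx(cum, tt - t0, xout = H)$y
  }
  s <- integrate_to(horizon)       # coarse pass brackets the hit time,
  integrate_to(s * 1.05)           # fine pass shrinks the step size
}

# a random tree with branch lengths, for property tests
rand_tree <- function(n) ape::rtree(n)
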