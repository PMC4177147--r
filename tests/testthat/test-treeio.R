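test_that("parse_newick reads balanced trees, stars and polytomies", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(total_branch_length(tr), 6)

  star <- parse_newick("(A:2,B:3,C:4);")
  expect_equal(ape::Ntip(star), 3)
  expect_equal(star$Nnode, 1)  # polytomy at the root
  expect_setequal(star$edge.length, c(2, 3, 4))
})

test_that("malformed Newick fails with the character position", {
  expect_error(parse_newick("(A:1,B:1"), "position")
  expect_error(parse_newick("(A:1,B:1));"), "character 10")
})

test_that("write_newick round-trips topology and branch lengths", {
  set.seed(41)
  for (n in c(3, 5, 10, 20)) {
    tr <- rand_tree(n)
    back <- parse_newick(write_newick(tr))
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE,
                                     tolerance = 1e-9))
  }
  star <- parse_newick("(A:2,B:3,C:4);")
  expect_true(ape::all.equal.phylo(star, parse_newick(write_newick(star)),
                                   use.edge.length = TRUE))
  expect_error(write_newick(structure(list(edge = NULL), class = "phylo")),
               "empty")
})

test_that("normalize_tree scales to total length 1 and is idempotent", {
  tr <- parse_newick("(A:2,B:3,C:5);")
  nt <- normalize_tree(tr)
  expect_equal(sort(nt$edge.length), c(0.2, 0.3, 0.5))
  expect_equal(total_branch_length(nt), 1, tolerance = 1e-12)
  expect_equal(normalize_tree(nt), nt)
  set.seed(5)
  for (i in 1:5) {
    t2 <- normalize_tree(rand_tree(8))
    expect_equal(total_branch_length(t2), 1, tolerance = 1e-12)
  }
  zero <- parse_newick("(A:0,B:0);")
  expect_error(normalize_tree(zero), "degenerate")
})

test_that("collapse_pedigree applies stem + mean(private) rule", {
  # 8 members, 2 private SNPs each, stem 10 -> single tip of length 12
  members <- paste0("(", paste0("m", 1:8, ":2", collapse = ","), "):10")
  tr <- parse_newick(paste0("(", members, ",x:5,y:7);"))
  out <- collapse_pedigree(tr, paste0("m", 1:8))
  expect_equal(ape::Ntip(out), 3)
  expect_equal(out$edge.length[out$edge[, 2] == match("m1", out$tip.label)], 12)
  # branches outside the clade untouched
  expect_equal(out$edge.length[out$edge[, 2] == match("x", out$tip.label)], 5)
  expect_equal(out$edge.length[out$edge[, 2] == match("y", out$tip.label)], 7)

  # privates 1 and 3 with stem 5 -> 5 + mean(1, 3) = 7
  tr2 <- parse_newick("((a:1,b:3):5,(c:1,d:3):2);")
  out2 <- collapse_pedigree(tr2, c("a", "b"))
  expect_equal(out2$edge.length[out2$edge[, 2] == match("a", out2$tip.label)], 7)

  # tip count drops by |pedigree| - 1; non-clade length sum unchanged
  expect_equal(ape::Ntip(tr) - ape::Ntip(out), 8 - 1)
  expect_equal(total_branch_length(out) - 12, 5 + 7)
})

test_that("collapse_pedigree handles single members and rejects non-clades", {
  tr <- parse_newick("((a:6,b:3):4,c:2);")
  expect_equal(collapse_pedigree(tr, "a"), tr)  # rule is identity at n = 1
  expect_error(collapse_pedigree(tr, character(0)), "empty")
  expect_error(collapse_pedigree(tr, c("a", "c")), "clade")
  expect_error(collapse_pedigree(tr, c("a", "z")), "not in tree")
})

test_that("collapse_zero_branches makes polytomies and preserves statistics", {
  tr <- parse_newick("(((A:5,B:6):0,C:4):3,(D:7,E:6):2);")
  out <- collapse_zero_branches(tr)
  expect_equal(out$Nnode, tr$Nnode - 1)
  expect_equal(ape::Ntip(out), 5)
  expect_equal(tree_stats(out), tree_stats(tr), tolerance = 1e-12)
})

test_that("packaged haplogroup stand-ins match their described shapes", {
  r1b <- haplogroup_fixture("R1b")
  expect_equal(ape::Ntip(r1b), 6)
  expect_true(all(r1b$edge.length == round(r1b$edge.length)))
  int <- which(r1b$edge[, 2] > ape::Ntip(r1b))
  expect_length(int, 1)                      # one internal branch only
  expect_equal(r1b$edge.length[int], 1)      # carrying a single variant
  clade <- ape::extract.clade(r1b, r1b$edge[int, 2])
  expect_equal(ape::Ntip(clade), 3)          # uniting three chromosomes

  e1b <- haplogroup_fixture("E1b1a")
  expect_equal(ape::Ntip(e1b), 8)
  expect_true(all(e1b$edge.length == round(e1b$edge.length)))
  # bifurcating except exactly one trifurcation
  kids <- table(e1b$edge[, 1])
  expect_equal(sort(unname(kids), decreasing = TRUE)[1], 3)
  expect_true(all(kids[-which.max(kids)] == 2))
  expect_equal(e1b$Nnode, 8 - 2)  # one fewer node than fully bifurcating

  # the star-like tree is shallower-spread than the bifurcating one
  expect_lt(tree_stats(r1b)[["tmrca_sd"]], tree_stats(e1b)[["tmrca_sd"]])
})
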