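test_that("progressive alignment is gap-free for identical sequences and optimal for pairs", {
  a <- seq_record("a", "ACGTACGTACGTACGTACGTACGT")
  al <- progressive_align(list(a, seq_record("b", a$residues)))
  expect_false(grepl("-", al$records[[1]]$residues, fixed = TRUE))
  expect_equal(al$records[[1]]$residues, al$records[[2]]$residues)

  # pairwise profile alignment achieves the exhaustive DP optimum
  set.seed(131)
  for (i in 1:10) {
    x <- rand_seq(sample(10:30, 1)); y <- rand_seq(sample(10:30, 1))
    al2 <- progressive_align(list(seq_record("x", x), seq_record("y", y)))
    sc <- 0; gx <- gy <- FALSE
    xv <- strsplit(al2$records[[1]]$residues, "")[[1]]
    yv <- strsplit(al2$records[[2]]$residues, "")[[1]]
    for (k in seq_along(xv)) {
      if (xv[k] == "-") { sc <- sc - if (gx) 1 else 4; gx <- TRUE; gy <- FALSE }
      else if (yv[k] == "-") { sc <- sc - if (gy) 1 else 4
                               gy <- TRUE; gx <- FALSE }
      else { sc <- sc + if (xv[k] == yv[k]) 1 else -1; gx <- gy <- FALSE }
    }
    expect_equal(sc, nw_score_oracle(x, y, open = 4, ext = 1))
  }

  # single sequence passes through
  expect_length(progressive_align(list(a))$records, 1L)
})

test_that("p-distances follow pairwise deletion and match the examples", {
  rec <- function(id, s) seq_record(id, s)
  d1 <- p_distance_matrix(alignment(list(rec("a", "ACGT"), rec("b", "ACGA"))))
  expect_equal(d1$d["a", "b"], 0.25)
  expect_equal(d1$retained_sites["a", "b"], 4L)
  d2 <- p_distance_matrix(alignment(list(rec("a", "ACNTT"),
                                         rec("b", "ACGTA"))))
  expect_equal(d2$d["a", "b"], 0.25)
  expect_equal(d2$retained_sites["a", "b"], 4L)
  # zero retained sites is an error naming the pair
  expect_error(p_distance_matrix(alignment(list(rec("a", "NN"),
                                                rec("b", "AC")))),
               "a / b")
})

test_that("p-distance matrix equals a naive per-pair recount on random alignments", {
  set.seed(141)
  alphabet <- c("A", "C", "G", "T", "N", "-")
  for (trial in 1:30) {
    n <- sample(3:6, 1); L <- sample(20:60, 1)
    strings <- vapply(seq_len(n), function(i)
      paste(sample(alphabet, L, TRUE, prob = c(rep(0.22, 4), 0.06, 0.06)),
            collapse = ""), "")
    recs <- lapply(seq_len(n), function(i) seq_record(paste0("t", i),
                                                      strings[i]))
    got <- p_distance_matrix(alignment(recs))
    oracle <- pdist_recount_oracle(strings)
    expect_equal(unname(got$d), oracle$d)
    expect_equal(unname(got$retained_sites) - diag(diag(
      unname(got$retained_sites))), oracle$retained)
  }
})

test_that("p-distances are permutation-equivariant in taxa order", {
  set.seed(151)
  recs <- lapply(1:5, function(i) seq_record(paste0("t", i), rand_seq(40)))
  d1 <- p_distance_matrix(alignment(recs))
  ord <- c(3, 1, 5, 2, 4)
  d2 <- p_distance_matrix(alignment(recs[ord]))
  expect_equal(d2$d[d1$taxa, d1$taxa], d1$d)
})

test_that("NJ reproduces additive distances exactly (path-length oracle)", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
              dimnames = list(labs, labs))
  tr <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tr)[labs, labs], d, tolerance = 1e-12)
  expect_equal(tree_length(tr), 11)

  # three taxa: closed-form three-point solution
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(d3)
  expect_equal(ape::cophenetic.phylo(t3)[c("a", "b", "c"), c("a", "b", "c")],
               d3, tolerance = 1e-12)
  expect_error(neighbor_joining(d3[1:2, 1:2]), "at least 3")
  dn <- d; dn[1, 2] <- 99
  expect_error(neighbor_joining(dn), "symmetric")
})

test_that("NJ on random additive matrices recovers all path lengths within 1e-9", {
  set.seed(161)
  for (trial in 1:30) {
    n <- sample(4:8, 1)
    src <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    D <- ape::cophenetic.phylo(src)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    tr <- neighbor_joining(D)
    got <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(got - D)), 1e-9)
    # and the topology agrees with an independent NJ implementation
    expect_equal(phangorn::RF.dist(tr, ape::nj(D)), 0)
  }
})

test_that("ultrametric four-taxon matrices give the correct sister pairing", {
  labs <- c("A", "B", "C", "D")
  # A-B split at height 1, C-D at height 2, root at 5
  d <- matrix(c(0, 2, 10, 10, 2, 0, 10, 10, 10, 10, 0, 4, 10, 10, 4, 0),
              4, 4, dimnames = list(labs, labs))
  tr <- neighbor_joining(d)
  expect_true(monophyly_test(tr, c("A", "B"), "D"))
  expect_true(monophyly_test(tr, c("A", "B", "C"), "D"))
  expect_false(monophyly_test(tr, c("A", "C"), "D"))
})

test_that("tree length sums branches, clamping negatives", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(tree_length(star), 3)
  d <- matrix(c(0, 0.1, 0.5, 0.1, 0, 0.5, 0.5, 0.5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d[1, 2] <- d[2, 1] <- 0.0001; d[1, 3] <- d[3, 1] <- 0.1
  expect_warning(tr <- neighbor_joining(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports behave at the edges and reproduce under a seed", {
  set.seed(171)
  base <- rand_seq(120)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    i <- sample(seq_along(v), k)
    v[i] <- vapply(v[i], function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                    b), 1), "")
    paste(v, collapse = "")
  }
  # two identical rows, three scattered others
  recs <- list(seq_record("x1", base), seq_record("x2", base),
               seq_record("y1", mut(base, 45)), seq_record("y2", mut(base, 45)),
               seq_record("z", mut(base, 60)))
  aln <- alignment(recs)
  bt <- bootstrap_supports(aln, replicates = 50L, seed = 5L)
  expect_true(all(stats::na.omit(bt$node.label) >= 0 &
                    stats::na.omit(bt$node.label) <= 100))
  # the identical pair's bipartition has full support
  pair_node <- ape::getMRCA(ape::root(bt, "z", resolve.root = TRUE),
                            c("x1", "x2"))
  expect_true(monophyly_test(bt, c("x1", "x2"), "z"))
  bt2 <- bootstrap_supports(aln, replicates = 50L, seed = 5L)
  expect_identical(bt$node.label, bt2$node.label)
  b1 <- bootstrap_supports(aln, replicates = 1L, seed = 7L)
  expect_true(all(stats::na.omit(b1$node.label) %in% c(0, 100)))
})

test_that("strongly supported splits converge to full support at high replicates", {
  set.seed(181)
  base <- rand_seq(150)
  v <- strsplit(base, "")[[1]]
  far <- v; far[1:70] <- vapply(far[1:70], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  aln <- alignment(list(
    seq_record("a1", base), seq_record("a2", base),
    seq_record("b1", paste(far, collapse = "")),
    seq_record("b2", paste(far, collapse = "")),
    seq_record("out", rand_seq(150))))
  bt <- bootstrap_supports(aln, replicates = 300L, seed = 3L)
  rt <- ape::root(bt, "out", resolve.root = TRUE)
  lab <- bt$node.label
  expect_gte(max(lab, na.rm = TRUE), 95)
})

test_that("monophyly test matches ape on explicit clade enumeration", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,O:1):1);")
  expect_true(monophyly_test(tr, c("A", "B"), "O"))
  expect_true(monophyly_test(tr, c("A", "B", "C", "D"), "O"))
  expect_false(monophyly_test(tr, c("A", "C"), "O"))
  expect_false(monophyly_test(tr, c("B", "C", "D"), "O"))
  expect_true(monophyly_test(tr, "C", "O"))
  expect_true(monophyly_test(tr, setdiff(tr$tip.label, "O"), "O"))
  expect_error(monophyly_test(tr, "nope", "O"), "unknown")
  for (sub in list(c("A", "B"), c("A", "C"), c("C", "D", "E"))) {
    rt <- ape::root(tr, "O", resolve.root = TRUE)
    expect_equal(monophyly_test(tr, sub, "O"),
                 ape::is.monophyletic(rt, sub))
  }
})

test_that("relative-rate dating: clock limit, midpoint calibration, closed form", {
  # clock-like: all root-to-tip paths equal -> rates 1, ages proportional
  tr <- ape::read.tree(text = "((A:2,B:2):1,(C:1,D:1):2,O:5);")
  tt <- reltime_dating(tr, "O", c("A", "C"))
  expect_equal(unname(tt$rates), rep(1, length(tt$rates)))
  expect_equal(unname(tt$ages[["node5"]]), 67.0)
  expect_equal(unname(tt$ages[["node6"]]), 67 * 2 / 3)
  expect_equal(unname(tt$ages[["node7"]]), 67 * 1 / 3)

  # two-rate four-taxon tree: hand-derived closed form for the two-level
  # recursion. With (A:2,B:2) vs (C:1,D:1) and unit stem branches, the
  # weighted mean tip paths are w(AB)=2, w(CD)=1, w(root)=(2*3+2*2)/4=2.5,
  # so ages are 67, 67*(2/2.5)=53.6, 67*(1/2.5)=26.8.
  tr2 <- ape::read.tree(text = "(((A:2,B:2):1,(C:1,D:1):1):1,O:4);")
  tt2 <- reltime_dating(tr2, "O", c("A", "C"))
  ages <- sort(unname(tt2$ages[tt2$ages > 0]), decreasing = TRUE)
  expect_lt(max(abs(ages - c(67, 53.6, 26.8))), 1e-9)

  # ages decrease monotonically from root to tips
  for (e in seq_len(nrow(tt2$edge))) {
    expect_gt(tt2$ages[tt2$edge[e, 1]], tt2$ages[tt2$edge[e, 2]] - 1e-12)
  }
  # calibrated node age sits inside the interval
  expect_gte(tt2$ages[tt2$calibrated_node], 66)
  expect_lte(tt2$ages[tt2$calibrated_node], 68)
  # degenerate input: zero-length terminal subtree
  tr3 <- ape::read.tree(text = "((A:0,B:0):1,(C:1,D:1):1,O:3);")
  expect_error(reltime_dating(tr3, "O", c("A", "C")), "zero")
  expect_error(reltime_dating(tr2, "O", c("A", "nope")), "unknown")
})
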