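## Distance phylogenetics: simple progressive multiple alignment,
## p-distances with pairwise deletion, neighbor-joining, bootstrap
## supports, monophyly tests and relative-rate (RelTime-style) dating.

#' Multiple sequence alignment container
#'
#' @param records List of equal-length gapped `seq_record`s.
#' @return An `alignment` object.
#' @export
alignment <- function(records) {
  lens <- vapply(records, function(r) nchar(r$residues), 1L)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  structure(list(records = records), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d sequences x %d columns\n",
              length(x$records), nchar(x$records[[1]]$residues)))
  invisible(x)
}

.aln_matrix <- function(aln) {
  do.call(rbind, lapply(aln$records, function(r) {
    strsplit(toupper(r$residues), "", fixed = TRUE)[[1]]
  }))
}

# profile of a set of gapped strings: 5 x L frequency matrix (A,C,G,T,-);
# ambiguity codes count as gaps for scoring purposes
.profile <- function(strings) {
  m <- do.call(rbind, strsplit(toupper(strings), "", fixed = TRUE))
  P <- vapply(c("A", "C", "G", "T"), function(b) colMeans(m == b),
              numeric(ncol(m)))
  t(cbind(P, `-` = 1 - rowSums(P)))
}

#' Progressive multiple alignment
#'
#' A documented simple substitute for a full multiple aligner: the guide
#' tree comes from shared k-mer distances (average-linkage clustering) and
#' groups are merged by affine-gap profile-profile dynamic programming
#' (match +1, mismatch -1, gap opening -4, extension -1), with fixed
#' deterministic tie-breaking. An externally aligned FASTA can be supplied
#' downstream instead; single sequences pass through as a 1-row alignment.
#'
#' @param seqs List of `seq_record`s.
#' @param k Guide-tree k-mer size.
#' @return An [alignment()].
#' @export
progressive_align <- function(seqs, k = 6L) {
  n <- length(seqs)
  if (n == 0L) stop("no sequences")
  if (n == 1L) return(alignment(seqs))
  kmers <- lapply(seqs, function(r) {
    s <- toupper(r$residues)
    unique(substring(s, seq_len(max(nchar(s) - k + 1L, 1L)),
                     pmin(seq_len(max(nchar(s) - k + 1L, 1L)) + k - 1L,
                          nchar(s))))
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sh <- length(intersect(kmers[[i]], kmers[[j]]))
      D[i, j] <- D[j, i] <- 1 - sh / min(length(kmers[[i]]),
                                         length(kmers[[j]]))
    }
  }
  hc <- hclust(as.dist(D), method = "average")
  groups <- lapply(seq_len(n), function(i) {
    list(idx = i, strings = toupper(seqs[[i]]$residues))
  })
  merged <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    pick <- function(x) if (x < 0L) groups[[-x]] else merged[[x]]
    g1 <- pick(hc$merge[step, 1]); g2 <- pick(hc$merge[step, 2])
    P1 <- .profile(g1$strings); P2 <- .profile(g2$strings)
    m1 <- colSums(P1[1:4, , drop = FALSE])
    m2 <- colSums(P2[1:4, , drop = FALSE])
    S <- 2 * crossprod(P1[1:4, , drop = FALSE], P2[1:4, , drop = FALSE]) -
      outer(m1, m2)
    r <- .affine_dp(S, 4, 1)
    expand <- function(strings, path) {
      vapply(strings, function(s) {
        v <- strsplit(s, "", fixed = TRUE)[[1]]
        paste(ifelse(is.na(path), "-", v[path]), collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    merged[[step]] <- list(idx = c(g1$idx, g2$idx),
                           strings = c(expand(g1$strings, r$path_i),
                                       expand(g2$strings, r$path_j)))
  }
  res <- merged[[n - 1L]]
  ord <- order(res$idx)
  alignment(lapply(ord, function(o) {
    seq_record(seqs[[res$idx[o]]]$id, res$strings[o],
               seqs[[res$idx[o]]]$description)
  }))
}

#' p-distance matrix with pairwise deletion
#'
#' For each sequence pair, alignment columns holding a gap or any
#' non-A/C/G/T code in either row are removed; the distance is the
#' proportion of differing retained sites, and the per-pair retained-site
#' count is recorded.
#'
#' @param aln An [alignment()] (or list of equal-length `seq_record`s).
#' @param pairwise_deletion If `FALSE`, columns with any ambiguous position
#'   in any row are removed globally (complete deletion).
#' @return A `dist_matrix`: list with `taxa`, `d`, `retained_sites`.
#' @export
p_distance_matrix <- function(aln, pairwise_deletion = TRUE) {
  if (!inherits(aln, "alignment")) aln <- alignment(aln)
  m <- .aln_matrix(aln)
  taxa <- vapply(aln$records, function(r) r$id, "")
  good <- matrix(m %in% c("A", "C", "G", "T"), nrow(m), ncol(m))
  if (!pairwise_deletion) {
    keep <- colSums(good) == nrow(m)
    m <- m[, keep, drop = FALSE]
    good <- good[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n); ret <- matrix(0L, n, n)
  diag(ret) <- as.integer(rowSums(good))
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      ok <- good[i, ] & good[j, ]
      r <- sum(ok)
      if (r == 0L) stop("no retained sites for pair ", taxa[i], " / ",
                        taxa[j])
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / r
      ret[i, j] <- ret[j, i] <- r
    }
  }
  dimnames(d) <- dimnames(ret) <- list(taxa, taxa)
  structure(list(taxa = taxa, d = d, retained_sites = ret),
            class = "dist_matrix")
}

.as_dmat <- function(D) {
  if (inherits(D, "dist_matrix")) return(D$d)
  if (inherits(D, "dist")) return(as.matrix(D))
  D
}

#' Neighbor-joining tree
#'
#' The Saitou-Nei agglomeration with the standard Q-criterion; ties are
#' broken by the smallest taxon-pair index so runs are reproducible.
#' Negative branch-length estimates are clamped to zero with a warning.
#'
#' @param D A `dist_matrix`, `dist`, or symmetric numeric matrix with
#'   dimnames.
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(D) {
  d <- .as_dmat(D)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric")
  }
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  nodes <- labs                      # current newick fragment per node
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  while (n > 3L) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    new_node <- sprintf("(%s:%.15g,%s:%.15g)", nodes[i], bl(bi),
                        nodes[j], bl(bj))
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nodes <- c(nodes[keep], new_node)
    n <- n - 1L
  }
  ba <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  bb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  bc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);", nodes[1], bl(ba),
                 nodes[2], bl(bb), nodes[3], bl(bc))
  if (clamped) warning("negative NJ branch length(s) clamped to 0")
  ape::read.tree(text = nwk)
}

#' Total tree length
#' @param tree A `phylo`.
#' @return Sum of all branch lengths.
#' @export
tree_length <- function(tree) {
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length, na.rm = TRUE)
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Columns are resampled with replacement `replicates` times; each
#' replicate is re-aligned by nothing (columns are independent) and passed
#' through [p_distance_matrix()] + [neighbor_joining()]. The support of
#' each internal bipartition of the full-data tree is the percentage of
#' replicate trees containing it, stored in `node.label`.
#'
#' @param aln An [alignment()].
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed (reproducible supports).
#' @return The full-data `phylo` with integer `node.label` supports
#'   (0-100; the root position carries NA).
#' @export
bootstrap_supports <- function(aln, replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  full <- neighbor_joining(p_distance_matrix(aln))
  m <- .aln_matrix(aln)
  ids <- vapply(aln$records, function(r) r$id, "")
  reps <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rec <- lapply(seq_along(ids), function(i) {
      seq_record(ids[i], paste(m[i, cols], collapse = ""))
    })
    reps[[b]] <- suppressWarnings(neighbor_joining(p_distance_matrix(
      alignment(rec))))
  }
  class(reps) <- "multiPhylo"
  cnt <- ape::prop.clades(full, reps, rooted = FALSE)
  full$node.label <- round(100 * cnt / replicates)
  full
}

# leaf descendant sets per internal node of a rooted tree
.clades <- function(tree) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets[(n + 1L):(n + tree$Nnode)]
}

#' Test whether a taxon set is monophyletic
#'
#' The tree is rooted on `outgroup`; the test is `TRUE` iff the set is
#' exactly the leaf set of one clade (a single leaf always is).
#'
#' @param tree A `phylo`.
#' @param taxa Character vector of tip labels.
#' @param outgroup A tip label used to root the tree.
#' @return Logical.
#' @export
monophyly_test <- function(tree, taxa, outgroup) {
  stopifnot(length(taxa) >= 1L)
  unknown <- setdiff(c(taxa, outgroup), tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) == 1L) return(TRUE)
  rt <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  target <- sort(unique(taxa))
  any(vapply(.clades(rt), function(s) identical(sort(s), target), TRUE))
}

#' Relative-rate (RelTime-style) divergence dating
#'
#' The tree is rooted on the outgroup, which is then excluded from rate
#' averaging. Relative node times are tip-count-weighted mean root-to-tip
#' path lengths computed bottom-up: for node u with children c,
#' `t(u) = sum(n_c * (b_c + t(c))) / sum(n_c)`, so each internal branch's
#' implied rate `b_c / (t(u) - t(c))` is a weighted average of its
#' descendant lineage rates; a clock-like tree yields all rates 1 and times
#' equal to node depths. Absolute ages scale relative times so the
#' calibrated node sits at the midpoint of the calibration interval
#' (clipped into the interval).
#'
#' @param tree A `phylo` with branch lengths.
#' @param outgroup Tip label of the outgroup.
#' @param calibration_tips Character vector of two ingroup tip labels whose
#'   most recent common ancestor is the calibrated node.
#' @param calibration_ma Numeric `c(min, max)` age interval in Ma.
#' @return A `time_tree`: list with `tree` (rooted ingroup `phylo`), `ages`
#'   (named vector, Ma, tips at 0), `rates` (per-edge relative rates),
#'   `calibrated_node`, `calibration_ma`.
#' @export
reltime_dating <- function(tree, outgroup, calibration_tips,
                           calibration_ma = c(66, 68)) {
  stopifnot(length(calibration_tips) == 2L, length(calibration_ma) == 2L)
  unknown <- setdiff(c(outgroup, calibration_tips), tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  rt <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ing <- ape::drop.tip(rt, outgroup)
  n <- length(ing$tip.label)
  po <- ape::reorder.phylo(ing, "postorder")
  ntot <- n + ing$Nnode
  w <- numeric(ntot)       # relative time of each node (tips 0)
  cnt <- integer(ntot); cnt[seq_len(n)] <- 1L
  acc <- numeric(ntot)     # sum of n_c * (b_c + w_c) per parent
  rates <- numeric(nrow(po$edge))
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    if (ch > n) w[ch] <- acc[ch] / cnt[ch]   # subtree done in postorder
    acc[p] <- acc[p] + cnt[ch] * (po$edge.length[e] + w[ch])
    cnt[p] <- cnt[p] + cnt[ch]
  }
  root <- n + 1L
  w[root] <- acc[root] / cnt[root]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    dt <- w[p] - w[ch]
    if (dt <= 0) stop("undefined rate: zero elapsed time above node ", ch)
    rates[e] <- po$edge.length[e] / dt
  }
  cal_node <- ape::getMRCA(ing, calibration_tips)
  if (w[cal_node] <= 0) stop("calibrated node has zero relative age")
  mid <- mean(calibration_ma)
  scale <- mid / w[cal_node]
  ages <- w * scale
  ages[cal_node] <- min(max(ages[cal_node], calibration_ma[1]),
                        calibration_ma[2])
  names(ages) <- c(ing$tip.label, paste0("node", (n + 1L):ntot))
  structure(list(tree = ing, ages = ages, rates = rates,
                 edge = po$edge,
                 calibrated_node = cal_node,
                 calibration_ma = calibration_ma), class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("<time_tree> %d tips; calibrated node %d at %.2f Ma [%g, %g]\n",
              length(x$tree$tip.label), x$calibrated_node,
              x$ages[x$calibrated_node], x$calibration_ma[1],
              x$calibration_ma[2]))
  invisible(x)
}

#' Node ages and branch rates of a time tree as a table
#' @param tt A `time_tree`.
#' @return data.frame with node, age_ma; branch rates attached as attribute.
#' @export
timetree_table <- function(tt) {
  data.frame(node = names(tt$ages), age_ma = unname(tt$ages),
             stringsAsFactors = FALSE)
}
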