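# Independent oracles used by the tests. These deliberately re-derive
# results by the most transparent method available (plain recursion,
# exhaustive closure, per-column recount) and share no code with the
# package implementations they check.

# Plain-recursion affine Needleman-Wunsch score with the package's scoring
# convention (gap of length L costs open + (L-1) * ext), memoized over
# (i, j, state); state 1 = match, 2 = gap in a, 3 = gap in b.
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, open = 5,
                            ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == 0 && j == 0) {
      if (state == 1) 0 else -Inf        # gaps must open, even at the edge
    } else {
      best <- -Inf
      if (i > 0 && j > 0 && state == 1) {
        s <- if (av[i] == bv[j]) match else mismatch
        best <- max(best, s + max(rec(i - 1, j - 1, 1), rec(i - 1, j - 1, 2),
                                  rec(i - 1, j - 1, 3)))
      }
      if (j > 0 && state == 2) {
        best <- max(best, rec(i, j - 1, 2) - ext, rec(i, j - 1, 1) - open)
      }
      if (i > 0 && state == 3) {
        best <- max(best, rec(i - 1, j, 3) - ext, rec(i - 1, j, 1) - open)
      }
      best
    }
    memo[[key]] <- res
    res
  }
  max(rec(n, m, 1), rec(n, m, 2), rec(n, m, 3))
}

# Transitive closure of the thresholded identity graph by boolean matrix
# powering; returns the partition as a sorted list of sorted id vectors.
closure_oracle <- function(idm, threshold) {
  n <- nrow(idm)
  adj <- idm > threshold
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) reach <- (reach %*% adj) > 0
  seen <- rep(FALSE, n)
  out <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    grp <- which(reach[i, ])
    seen[grp] <- TRUE
    out[[length(out) + 1L]] <- sort(rownames(idm)[grp])
  }
  out[order(vapply(out, function(g) g[1], ""))]
}

# Per-pair, per-column p-distance recount.
pdist_recount_oracle <- function(strings) {
  m <- do.call(rbind, strsplit(toupper(strings), ""))
  n <- nrow(m)
  d <- matrix(0, n, n); ret <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diffs <- 0L; kept <- 0L
      for (col in seq_len(ncol(m))) {
        x <- m[i, col]; y <- m[j, col]
        if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
          kept <- kept + 1L
          if (x != y) diffs <- diffs + 1L
        }
      }
      d[i, j] <- diffs / kept
      ret[i, j] <- kept
    }
  }
  list(d = d, retained = ret)
}

# Sorted partition representation for set comparison.
canon_partition <- function(p) {
  q <- lapply(p, sort)
  unname(q[order(vapply(q, function(g) g[1], ""))])
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Pig-shaped defect plan touching every defect kind.
all_kinds_plan <- function() {
  data.frame(
    gene = c("V1.2", "V1.3", "V1.4", "J2.1", "J1.2", "C4"),
    kind = c("stop_codon", "frameshift", "donor_site", "rs_heptamer_core",
             "j_motif_second_position", "frameshift"),
    stringsAsFactors = FALSE)
}

expected_functionality <- function(kind) {
  if (kind %in% c("stop_codon", "frameshift")) "P" else "ORF"
}
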