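#' Pairwise identity matrix over V coding regions
#'
#' Computes [pairwise_identity()] (global alignment, terminal gaps excluded)
#' for every pair of sequences. For V subgrouping the inputs should be the
#' L-PART1+V-EXON coding regions.
#'
#' @param seqs List of `seq_record`s (or named character vector).
#' @return List of class `identity_matrix` with `ids`, `identity`
#'   (symmetric, unit diagonal) and `aligned_columns` matrices.
#' @export
identity_matrix <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- lapply(seq_along(seqs), function(i) {
      seq_record(names(seqs)[i] %||% paste0("seq", i), seqs[i])
    })
  }
  ids <- vapply(seqs, function(r) r$id, "")
  n <- length(seqs)
  idm <- diag(1, n); alc <- matrix(0L, n, n)
  diag(alc) <- vapply(seqs, function(r) nchar(r$residues), 1L)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        p <- pairwise_identity(seqs[[i]], seqs[[j]])
        idm[i, j] <- idm[j, i] <- p[["identity"]]
        alc[i, j] <- alc[j, i] <- p[["aligned_columns"]]
      }
    }
  }
  dimnames(idm) <- dimnames(alc) <- list(ids, ids)
  structure(list(ids = ids, identity = idm, aligned_columns = alc),
            class = "identity_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition V genes into subgroups at an identity threshold
#'
#' Two genes belong to the same subgroup when their nucleotide identity over
#' the coding region exceeds `threshold` (strictly more than, per the
#' standard 75% rule); the partition is the transitive closure of this
#' pairwise relation (single linkage). Subgroups are ordered by the leftmost
#' genomic position of their members (or input order when no positions are
#' given) and members keep input order.
#'
#' @param seqs List of `seq_record`s, a named character vector, or a
#'   precomputed `identity_matrix`.
#' @param threshold Identity threshold in (0, 1); default 0.75.
#' @param positions Optional numeric vector (same order as `seqs`) of
#'   genomic start positions used to order the subgroups.
#' @return List of character vectors of gene ids (the partition).
#' @export
assign_subgroups <- function(seqs, threshold = 0.75, positions = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  im <- if (inherits(seqs, "identity_matrix")) seqs else identity_matrix(seqs)
  n <- length(im$ids)
  if (is.null(positions)) positions <- seq_len(n)
  # union-find over the thresholded graph
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq(i + 1L, length.out = max(n - i, 0L))) {
      if (im$identity[i, j] > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), roots)
  ord <- order(vapply(groups, function(g) min(positions[g]), 1))
  unname(lapply(groups[ord], function(g) im$ids[g]))
}

#' Subgroup summary table
#'
#' @param partition Output of [assign_subgroups()].
#' @return data.frame with columns `gene` and `subgroup` (1-based labels).
#' @export
subgroup_table <- function(partition) {
  do.call(rbind, lapply(seq_along(partition), function(k) {
    data.frame(gene = partition[[k]], subgroup = k, stringsAsFactors = FALSE)
  }))
}
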