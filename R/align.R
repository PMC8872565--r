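# Affine-gap global dynamic programming over an arbitrary column-pair score
# matrix. The horizontal gap state is vectorized with a running-maximum
# identity: X[i,j] = max_{k<j} (M[i,k] + k*ge) - go - (j-1)*ge, so each row
# costs O(m) vector work instead of an O(m) scalar loop. Scores are integer
# sums stored as doubles, so exact equality is safe during traceback.
#
# Gap cost convention: a gap of length L costs go + (L-1)*ge, i.e. the first
# gapped column pays the opening penalty and each further column the
# extension penalty. Gap states open only from the match state (no direct
# X<->Y transition), the usual simplification for DNA-scale scoring.
.affine_dp <- function(S, go, ge) {
  n <- nrow(S); m <- ncol(S)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in sequence 1 (consumes columns of 2)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in sequence 2 (consumes rows of 1)
  M[1L, 1L] <- 0
  if (m >= 1L) X[1L, 2L:(m + 1L)] <- -go - ge * (0L:(m - 1L))
  if (n >= 1L) Y[2L:(n + 1L), 1L] <- -go - ge * (0L:(n - 1L))
  js <- seq_len(m)
  for (i in seq_len(n)) {
    prev_best <- pmax(M[i, ], X[i, ], Y[i, ])
    M[i + 1L, js + 1L] <- S[i, ] + prev_best[js]
    Y[i + 1L, ] <- pmax(M[i, ] - go, Y[i, ] - ge)
    t <- cummax(M[i + 1L, js] + ge * (0L:(m - 1L)))
    X[i + 1L, js + 1L] <- t - go - ge * (js - 1L)
  }
  # traceback
  i <- n; j <- m
  sc <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  state <- which.max(sc)
  path_i <- integer(0); path_j <- integer(0)
  while (i > 0L || j > 0L) {
    if (state == 1L) {                      # match/mismatch
      path_i <- c(i, path_i); path_j <- c(j, path_j)
      v <- M[i + 1L, j + 1L] - S[i, j]
      i <- i - 1L; j <- j - 1L
      if (i == 0L && j == 0L) break
      state <- which.max(c(M[i + 1L, j + 1L], X[i + 1L, j + 1L],
                           Y[i + 1L, j + 1L]) - v)  # ties: prefer M
    } else if (state == 2L) {               # gap in seq1
      path_i <- c(NA_integer_, path_i); path_j <- c(j, path_j)
      from_m <- X[i + 1L, j + 1L] == M[i + 1L, j] - go
      j <- j - 1L
      state <- if (from_m) 1L else 2L
      if (i == 0L && j == 0L) break
    } else {                                # gap in seq2
      path_i <- c(i, path_i); path_j <- c(NA_integer_, path_j)
      from_m <- Y[i + 1L, j + 1L] == M[i, j + 1L] - go
      i <- i - 1L
      state <- if (from_m) 1L else 3L
      if (i == 0L && j == 0L) break
    }
  }
  list(score = max(sc), path_i = path_i, path_j = path_j)
}

#' Global pairwise alignment of two nucleotide strings
#'
#' Needleman-Wunsch with affine gaps: match +1, mismatch -1, gap opening -5
#' and gap extension -1 by default (a gap of length L costs 5 + (L-1)).
#'
#' @param a,b Nucleotide strings or `seq_record`s.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters (penalties
#'   positive).
#' @return List with `score`, `aligned_a`, `aligned_b`.
#' @export
nw_align <- function(a, b, match = 1, mismatch = -1, gap_open = 5,
                     gap_ext = 1) {
  if (inherits(a, "seq_record")) a <- a$residues
  if (inherits(b, "seq_record")) b <- b$residues
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  S <- ifelse(outer(av, bv, "=="), match, mismatch)
  r <- .affine_dp(S, gap_open, gap_ext)
  list(score = r$score,
       aligned_a = paste(ifelse(is.na(r$path_i), "-", av[r$path_i]),
                         collapse = ""),
       aligned_b = paste(ifelse(is.na(r$path_j), "-", bv[r$path_j]),
                         collapse = ""))
}

#' Pairwise nucleotide identity over a global alignment
#'
#' Identity is the number of matching columns divided by the number of
#' alignment columns after excluding columns that fall inside a terminal gap
#' of either sequence, so length differences at the ends do not dominate the
#' denominator.
#'
#' @inheritParams nw_align
#' @return Named numeric vector `c(identity = , aligned_columns = )`.
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # identity 0.75 over 4 columns
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1, gap_open = 5,
                              gap_ext = 1) {
  al <- nw_align(a, b, match, mismatch, gap_open, gap_ext)
  av <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  bv <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  keep <- rep(TRUE, length(av))
  for (v in list(av, bv)) {
    ng <- which(v != "-")
    if (length(ng) == 0L) next
    if (ng[1] > 1L) keep[seq_len(ng[1] - 1L)] <- FALSE
    if (ng[length(ng)] < length(v)) keep[(ng[length(ng)] + 1L):length(v)] <- FALSE
  }
  cols <- sum(keep)
  matches <- sum(av[keep] == bv[keep] & av[keep] != "-")
  c(identity = if (cols > 0L) matches / cols else 0,
    aligned_columns = cols)
}

# Best gapless local identity of `query` inside `subject` via Biostrings;
# returns NULL if nothing reaches min_identity. Used where a reference exon
# or regulatory element is searched inside a locus.
.local_hit <- function(query, subject, min_identity = 0.6,
                       with_indels = FALSE) {
  q <- Biostrings::DNAString(toupper(query))
  s <- Biostrings::DNAString(toupper(subject))
  mm <- floor((1 - min_identity) * length(q))
  h <- Biostrings::matchPattern(q, s, max.mismatch = mm,
                                with.indels = with_indels)
  if (length(h) == 0L) return(NULL)
  # pick the hit with fewest mismatches; ties -> leftmost
  nm <- vapply(seq_along(h), function(i) {
    hs <- as.character(h[[i]])
    if (nchar(hs) == nchar(query) && !with_indels) {
      sum(strsplit(hs, "")[[1]] != strsplit(toupper(query), "")[[1]])
    } else {
      # indel hit: score by alignment
      al <- pairwise_identity(query, hs)
      round((1 - al[["identity"]]) * nchar(query))
    }
  }, numeric(1))
  i <- which.min(nm)
  list(start = Biostrings::start(h)[i], end = Biostrings::end(h)[i],
       mismatches = nm[i],
       identity = 1 - nm[i] / nchar(query))
}
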