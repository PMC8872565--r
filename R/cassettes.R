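## Duplication architecture of the locus: dot-plot self-alignment,
## V-J-(J)-C cassette decomposition, cassette naming, PJ/En regulatory
## elements and STAT motifs, homology-block painting.

# Exact k-mer seed matches between two strings, chained along equal
# diagonals (offset = pos2 - pos1) allowing gaps <= max_gap between seed
# ends; runs shorter than min_run are dropped. `mask1`/`mask2` are logical
# vectors marking positions whose seeds are suppressed (lowercase-masked).
.kmer_runs <- function(s1, s2, k, max_gap, min_run, self = FALSE,
                       mask1 = NULL, mask2 = NULL, max_occ = 100L) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 < k || n2 < k) return(NULL)
  valid <- function(s, n, mask) {
    st <- seq_len(n - k + 1L)
    km <- substring(toupper(s), st, st + k - 1L)
    ok <- !grepl("[^ACGT]", km)
    if (!is.null(mask)) {
      cm <- cumsum(mask)
      ok <- ok & (cm[st + k - 1L] - c(0, cm)[st]) == 0L
    }
    list(st = st[ok], km = km[ok])
  }
  a <- valid(s1, n1, mask1)
  b <- if (self) a else valid(s2, n2, mask2)
  ia <- split(a$st, a$km)
  ia <- ia[lengths(ia) <= max_occ]
  ib <- if (self) ia else split(b$st, b$km)
  shared <- intersect(names(ia), names(ib))
  if (length(shared) == 0L) return(NULL)
  p1 <- rep(unlist(ia[shared], use.names = FALSE),
            times = rep(lengths(ib[shared]), lengths(ia[shared])))
  p2 <- unlist(lapply(shared, function(kk) {
    rep(ib[[kk]], times = length(ia[[kk]]))
  }), use.names = FALSE)
  # rep() above repeats per kmer: rebuild p1 correctly
  p1 <- unlist(lapply(shared, function(kk) {
    rep(ia[[kk]], each = length(ib[[kk]]))
  }), use.names = FALSE)
  if (self) {
    keep <- p2 > p1
    p1 <- p1[keep]; p2 <- p2[keep]
  }
  if (length(p1) == 0L) return(NULL)
  off <- p2 - p1
  runs <- NULL
  for (d in sort(unique(off))) {
    x <- sort(p1[off == d])
    brk <- c(0L, which(diff(x) > max_gap + k), length(x))
    for (bi in seq_len(length(brk) - 1L)) {
      seg <- x[(brk[bi] + 1L):brk[bi + 1L]]
      len <- seg[length(seg)] + k - seg[1]
      if (len >= min_run) {
        runs <- rbind(runs, data.frame(start1 = seg[1], start2 = seg[1] + d,
                                       length = len, offset = abs(d)))
      }
    }
  }
  runs
}

#' Dot-plot self-alignment of a locus
#'
#' Chains exact k-mer self-matches along equal diagonals; parallel
#' off-diagonal runs reveal tandemly duplicated cassettes (n near-identical
#' cassettes produce n-1 lines parallel to the main diagonal). Lowercase
#' (masked) positions seed no matches but keep their coordinates.
#'
#' @param seq A `seq_record`.
#' @param k Seed k-mer size (>= 8).
#' @param max_gap Maximum gap (nt) between chained seeds on one diagonal.
#' @param min_run Minimum reported run length (nt).
#' @return data.frame of diagonal runs (`start1`, `start2`, `length`,
#'   `offset`); the main diagonal is always reported once, and every
#'   off-diagonal run appears with its mirror partner.
#' @export
self_dotplot <- function(seq, k = 12L, max_gap = 50L, min_run = 200L) {
  stopifnot(k >= 8L)
  s <- seq$residues
  mask <- strsplit(s, "", fixed = TRUE)[[1]] %in% letters
  runs <- .kmer_runs(s, s, k, max_gap, min_run, self = TRUE,
                     mask1 = mask)
  main <- data.frame(start1 = 1L, start2 = 1L, length = nchar(s), offset = 0L)
  if (is.null(runs)) return(main)
  mirror <- data.frame(start1 = runs$start2, start2 = runs$start1,
                       length = runs$length, offset = runs$offset)
  out <- rbind(main, runs, mirror)
  out[order(out$offset, out$start1), , drop = FALSE]
}

#' Merge off-diagonal runs into duplication units
#'
#' Runs whose intervals overlap on both sides are merged; each unit reports
#' the two homologous intervals and the annotated genes each one covers
#' (e.g. a J-C / J-C unit).
#'
#' @param runs Output of [self_dotplot()].
#' @param annotations List of `gene_annotation`s (may be empty).
#' @return List of units: `side1`, `side2` (`genomic_interval`s),
#'   `genes1`, `genes2` (character vectors).
#' @export
detect_duplication_units <- function(runs, annotations = list()) {
  off <- runs[runs$offset > 0L & runs$start2 > runs$start1, , drop = FALSE]
  if (nrow(off) == 0L) return(list())
  iv1 <- cbind(off$start1, off$start1 + off$length - 1L)
  iv2 <- cbind(off$start2, off$start2 + off$length - 1L)
  n <- nrow(off)
  ovl <- function(a, b, i, j) a[i, 1] <= b[j, 2] && b[j, 1] <= a[i, 2]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq(i + 1L, length.out = n - i)) {
      if (ovl(iv1, iv1, i, j) && ovl(iv2, iv2, i, j)) {
        g <- igraph::add_edges(g, c(i, j))
      }
    }
  }
  comp <- igraph::components(g)$membership
  spans <- lapply(annotations, gene_span)
  genes_in <- function(lo, hi) {
    hits <- vapply(spans, function(s) s$start <= hi && lo <= s$end, TRUE)
    vapply(annotations[hits], function(a) a$name, "")
  }
  lapply(split(seq_len(n), comp), function(idx) {
    lo1 <- min(iv1[idx, 1]); hi1 <- max(iv1[idx, 2])
    lo2 <- min(iv2[idx, 1]); hi2 <- max(iv2[idx, 2])
    sid <- "locus"
    list(side1 = genomic_interval(sid, lo1, hi1),
         side2 = genomic_interval(sid, lo2, hi2),
         genes1 = genes_in(lo1, hi1), genes2 = genes_in(lo2, hi2))
  })
}

#' Decompose ordered annotations into V-J-(J)-C cassettes
#'
#' Cuts the gene order immediately after each C gene; each block must match
#' the pattern V* J+ C. Blocks violating the pattern (or trailing genes
#' after the last C) are reported in `anomalies`, not silently dropped.
#'
#' @param annotations List of `gene_annotation`s (single orientation).
#' @return List with `cassettes` (list of `cassette` objects named
#'   cassette1..n) and `anomalies` (list of character vectors of gene names
#'   with a `reason` attribute).
#' @export
build_cassettes <- function(annotations) {
  if (length(annotations) == 0L || !any(vapply(annotations, function(g)
    g$gene_type == "C", TRUE))) {
    stop("no C gene present: cannot define cassettes")
  }
  ord <- order(vapply(annotations, function(g) gene_span(g)$start, 1L))
  genes <- annotations[ord]
  types <- vapply(genes, function(g) g$gene_type, "")
  cuts <- which(types == "C")
  blocks <- list(); from <- 1L
  for (cc in cuts) { blocks[[length(blocks) + 1L]] <- from:cc; from <- cc + 1L }
  trailing <- if (from <= length(genes)) from:length(genes) else integer(0)
  cassettes <- list(); anomalies <- list()
  for (b in blocks) {
    pat <- paste(types[b], collapse = "")
    if (grepl("^V*J+C$", pat)) {
      k <- length(cassettes) + 1L
      gs <- genes[b]
      sp <- genomic_interval(gene_span(gs[[1]])$seq_id,
                             gene_span(gs[[1]])$start,
                             gene_span(gs[[length(gs)]])$end)
      cassettes[[k]] <- structure(list(name = sprintf("cassette%d", k),
                                       genes = gs, pj = NULL, en = NULL,
                                       span = sp), class = "cassette")
    } else {
      an <- vapply(genes[b], function(g) g$name, "")
      attr(an, "reason") <- sprintf("block '%s' violates V*J+C", pat)
      anomalies[[length(anomalies) + 1L]] <- an
    }
  }
  if (length(trailing)) {
    an <- vapply(genes[trailing], function(g) g$name, "")
    attr(an, "reason") <- "trailing genes after last C"
    anomalies[[length(anomalies) + 1L]] <- an
  }
  list(cassettes = cassettes, anomalies = anomalies)
}

#' @export
print.cassette <- function(x, ...) {
  cat(sprintf("<cassette> %s: %s [%d-%d]\n", x$name,
              paste(vapply(x$genes, function(g) g$name, ""), collapse = " "),
              x$span$start, x$span$end))
  invisible(x)
}

#' Name cassettes by orthology to a labelled reference set
#'
#' Each query cassette takes the cassette label of the reference C gene
#' nearest to its own C gene by [pairwise_identity()]; exact ties are
#' resolved by the nearest reference V gene; queries below `min_identity`
#' become `novel-n`.
#'
#' @param cassettes List of `cassette` objects (genes carry `sequence`).
#' @param reference_genes List of `seq_record`s whose description contains
#'   `cassette=<label> type=<V|J|C>`.
#' @param min_identity Identity below which a cassette is called novel.
#' @return The cassettes with `name` set.
#' @export
name_cassettes <- function(cassettes, reference_genes, min_identity = 0.6) {
  if (length(reference_genes) == 0L) stop("empty cassette reference set")
  meta <- lapply(reference_genes, function(r) {
    lab <- sub(".*cassette=(\\S+).*", "\\1", r$description)
    typ <- sub(".*type=(\\S+).*", "\\1", r$description)
    list(lab = lab, typ = typ, seq = r$residues)
  })
  refs_c <- Filter(function(m) m$typ == "C", meta)
  refs_v <- Filter(function(m) m$typ == "V", meta)
  if (length(refs_c) == 0L) stop("reference set has no C genes")
  novel <- 0L
  for (k in seq_along(cassettes)) {
    cas <- cassettes[[k]]
    cseq <- Filter(function(g) g$gene_type == "C", cas$genes)[[1]]$sequence
    idv <- vapply(refs_c, function(m)
      pairwise_identity(cseq, m$seq)[["identity"]], 1)
    best <- max(idv)
    if (best < min_identity) {
      novel <- novel + 1L
      cassettes[[k]]$name <- sprintf("novel-%d", novel)
      next
    }
    tied <- which(abs(idv - best) < 1e-12)
    if (length(tied) > 1L && length(refs_v) > 0L) {
      vg <- Filter(function(g) g$gene_type == "V", cas$genes)
      if (length(vg) > 0L) {
        vseq <- vg[[1]]$sequence
        vb <- vapply(tied, function(ti) {
          cand <- Filter(function(m) m$lab == refs_c[[ti]]$lab, refs_v)
          if (length(cand) == 0L) return(-1)
          max(vapply(cand, function(m)
            pairwise_identity(vseq, m$seq)[["identity"]], 1))
        }, 1)
        tied <- tied[which.max(vb)]
      }
    }
    cassettes[[k]]$name <- refs_c[[tied[1]]]$lab
  }
  cassettes
}

#' Scan for STAT consensus motifs (TTCNNNGAA)
#'
#' Reports every occurrence on both strands (the consensus is its own
#' reverse complement, so reverse-strand hits are occurrences on the
#' reverse-complemented sequence mapped back to forward coordinates).
#' Overlapping occurrences are all reported; coordinates are 1-based.
#'
#' @param seq A `seq_record`.
#' @param region Optional `genomic_interval` restricting the scan.
#' @return data.frame with `start`, `end`, `strand`, `matched_text`.
#' @export
scan_stat_motifs <- function(seq, region = NULL) {
  s <- toupper(seq$residues)
  off <- 0L
  if (!is.null(region)) {
    s <- substr(s, region$start, region$end)
    off <- region$start - 1L
  }
  pat <- "(?=TTC...GAA)"
  fwd <- gregexpr(pat, s, perl = TRUE)[[1]]
  rc <- revcomp(s)
  rev <- gregexpr(pat, rc, perl = TRUE)[[1]]
  n <- nchar(s)
  out <- NULL
  if (fwd[1] != -1L) {
    out <- data.frame(start = as.integer(fwd) + off,
                      end = as.integer(fwd) + 8L + off, strand = "+",
                      matched_text = substring(s, fwd, fwd + 8L))
  }
  if (rev[1] != -1L) {
    st <- n - (as.integer(rev) + 8L) + 1L
    out <- rbind(out, data.frame(start = st + off, end = st + 8L + off,
                                 strand = "-",
                                 matched_text = substring(rc, rev, rev + 8L)))
  }
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), matched_text = character()))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# longest contiguous stretch of the match vector with mean >= min_frac
.longest_block <- function(match, min_frac = 0.8) {
  n <- length(match)
  cs <- c(0, cumsum(match))
  best <- 0L
  for (i in seq_len(n)) {
    # longest j >= i with (cs[j+1]-cs[i]) / (j-i+1) >= min_frac
    for (j in n:i) {
      if (j - i + 1L <= best) break
      if ((cs[j + 1L] - cs[i]) >= min_frac * (j - i + 1L)) {
        best <- j - i + 1L
        break
      }
    }
  }
  best
}

#' Locate PJ and En regulatory elements of a cassette
#'
#' The germline J promoter (PJ) is searched in the 2 kb window upstream of
#' the C-distal J gene; the enhancer-like element (En) in the 4 kb window
#' downstream of the C gene 3' end (it sits about 2 kb out). The best local
#' match of the reference element at >= `min_identity` is accepted, and the
#' length of the conserved core (longest block at >= 80% identity) is
#' reported.
#'
#' @param cassette A `cassette`.
#' @param seq The locus `seq_record`.
#' @param ref_pj,ref_en Reference element `seq_record`s.
#' @param min_identity Minimum acceptance identity.
#' @return The cassette with `pj`, `en` (`genomic_interval` or `NULL`) and
#'   `pj_core`, `en_core` (conserved-core lengths, nt) set.
#' @export
locate_regulatory_elements <- function(cassette, seq, ref_pj, ref_en,
                                       min_identity = 0.6) {
  s <- toupper(seq$residues)
  n <- nchar(s)
  search <- function(ref, lo, hi) {
    lo <- max(1L, lo); hi <- min(n, hi)
    if (hi - lo + 1L < nchar(ref$residues) / 2) return(NULL)
    win <- substr(s, lo, hi)
    hit <- .local_hit(ref$residues, win, min_identity)
    if (is.null(hit)) return(NULL)
    a <- strsplit(toupper(ref$residues), "")[[1]]
    b <- strsplit(substr(win, hit$start, hit$end), "")[[1]]
    core <- if (length(a) == length(b)) .longest_block(a == b) else NA_integer_
    list(interval = genomic_interval(seq$id, lo + hit$start - 1L,
                                     lo + hit$end - 1L),
         identity = hit$identity, core = core)
  }
  jg <- Filter(function(g) g$gene_type == "J", cassette$genes)
  cg <- Filter(function(g) g$gene_type == "C", cassette$genes)[[1]]
  jstart <- min(vapply(jg, function(g) gene_span(g)$start, 1L))
  pj <- search(ref_pj, jstart - 2000L, jstart - 1L)
  cend <- gene_span(cg)$end
  en <- search(ref_en, cend, cend + 4000L)
  if (is.null(pj)) warning("no PJ element found for ", cassette$name)
  if (is.null(en)) warning("no En element found for ", cassette$name)
  cassette$pj <- pj$interval; cassette$pj_core <- pj$core
  cassette$en <- en$interval; cassette$en_core <- en$core
  cassette
}

#' Shared homology blocks across cassette sequences
#'
#' Anchors are exact k-mer matches shared by at least two sequences,
#' chained collinearly per sequence pair and merged into blocks; the output
#' is one row per (block, sequence) interval, a text representation of the
#' colored-block synteny painting used for cassette comparisons.
#'
#' @param cassette_seqs List of >= 2 `seq_record`s.
#' @param k Anchor k-mer size.
#' @param max_gap,min_run Chaining parameters (see [self_dotplot()]).
#' @return data.frame with `block`, `seq_id`, `start`, `end`.
#' @export
homology_block_painting <- function(cassette_seqs, k = 12L, max_gap = 50L,
                                    min_run = 100L) {
  stopifnot(length(cassette_seqs) >= 2L)
  ids <- vapply(cassette_seqs, function(r) r$id, "")
  segs <- NULL   # one row per run side: seq index, start, end, run id
  rid <- 0L
  for (i in seq_len(length(cassette_seqs) - 1L)) {
    for (j in (i + 1L):length(cassette_seqs)) {
      runs <- .kmer_runs(cassette_seqs[[i]]$residues,
                         cassette_seqs[[j]]$residues, k, max_gap, min_run)
      if (is.null(runs)) next
      for (r in seq_len(nrow(runs))) {
        rid <- rid + 1L
        segs <- rbind(segs,
                      data.frame(seq = i, start = runs$start1[r],
                                 end = runs$start1[r] + runs$length[r] - 1L,
                                 run = rid),
                      data.frame(seq = j, start = runs$start2[r],
                                 end = runs$start2[r] + runs$length[r] - 1L,
                                 run = rid))
      }
    }
  }
  if (is.null(segs)) {
    return(data.frame(block = integer(), seq_id = character(),
                      start = integer(), end = integer()))
  }
  # connect the two sides of each run, and overlapping segments on the
  # same sequence; components are blocks
  g <- igraph::make_empty_graph(nrow(segs), directed = FALSE)
  for (r in unique(segs$run)) {
    idx <- which(segs$run == r)
    g <- igraph::add_edges(g, c(idx[1], idx[2]))
  }
  for (sq in unique(segs$seq)) {
    idx <- which(segs$seq == sq)
    idx <- idx[order(segs$start[idx])]
    if (length(idx) < 2L) next
    for (t in seq_len(length(idx) - 1L)) {
      if (segs$start[idx[t + 1L]] <= segs$end[idx[t]]) {
        g <- igraph::add_edges(g, c(idx[t], idx[t + 1L]))
      }
    }
  }
  comp <- igraph::components(g)$membership
  out <- NULL
  for (b in sort(unique(comp))) {
    idx <- which(comp == b)
    for (sq in unique(segs$seq[idx])) {
      ii <- idx[segs$seq[idx] == sq]
      out <- rbind(out, data.frame(block = b, seq_id = ids[sq],
                                   start = min(segs$start[ii]),
                                   end = max(segs$end[ii])))
    }
  }
  out[order(out$block, out$seq_id), , drop = FALSE]
}
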