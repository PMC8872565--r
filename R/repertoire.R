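## Assignment of rearranged V-J-C cDNAs to germline genes, junction
## extraction, intra-cassette preference statistics and degenerate-primer
## matching.

#' Germline reference for transcript assignment
#'
#' Packages the per-gene matching segments used against cDNAs: the V exon
#' (transcripts start at the V exon, the leader being spliced upstream of
#' the RACE products considered here), the J segment, and the C EX1 (the
#' exon the reverse primers sit in). Cassette membership drives the
#' intra-cassette call.
#'
#' @param truth A `truth_set` from [generate_locus()], or `NULL` if the
#'   remaining arguments are given directly.
#' @param segments Named list: per gene, list(type, cassette, seq).
#' @param c_order Character vector of C gene names in genomic order (used
#'   for the J-proximal C test).
#' @return A `germline_ref` object.
#' @export
germline_ref <- function(truth = NULL, segments = NULL, c_order = NULL) {
  if (!is.null(truth)) {
    segments <- lapply(truth$segments, function(s) {
      list(type = s$type, cassette = s$cassette,
           seq = switch(s$type, V = s$v_exon, J = s$coding, C = s$ex1))
    })
    cs <- names(segments)[vapply(segments, function(s) s$type == "C", TRUE)]
    c_order <- cs[order(vapply(cs, function(g)
      gene_span(truth$genes[[g]])$start, 1L))]
  }
  structure(list(segments = segments, c_order = c_order),
            class = "germline_ref")
}

# best local alignment among a set of germline segments inside one cdna;
# one batched pairwiseAlignment call per gene type keeps the S4 overhead
# constant
.best_local_set <- function(segments, cdna, min_identity, min_coverage) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(toupper(unlist(segments))),
    Biostrings::DNAString(toupper(cdna)), type = "local")
  idv <- Biostrings::pid(al) / 100
  pat <- Biostrings::pattern(al); sub <- Biostrings::subject(al)
  cov <- (Biostrings::end(pat) - Biostrings::start(pat) + 1L) /
    nchar(unlist(segments))
  ok <- idv >= min_identity & cov >= min_coverage
  if (!any(ok)) return(NULL)
  ord <- order(-idv, -cov)
  best <- ord[ok[ord]][1]
  list(gene = names(segments)[best],
       h = list(identity = idv[best], coverage = cov[best],
                q_start = Biostrings::start(sub)[best],
                q_end = Biostrings::end(sub)[best],
                s_start = Biostrings::start(pat)[best],
                s_end = Biostrings::end(pat)[best],
                pattern = as.character(Biostrings::alignedPattern(al[best])),
                subject = as.character(Biostrings::alignedSubject(al[best]))))
}

#' Assign one cDNA to germline V, J and C genes
#'
#' For each gene type the best local alignment wins, provided it reaches
#' `min_identity` over at least `min_coverage` of the germline segment
#' (V against the cDNA 5' portion; J and C against the remainder). The
#' junction is the cDNA stretch strictly between the V and J matches;
#' `intra_cassette` records whether V and J share a cassette, and
#' `c_is_j_proximal` whether the assigned C is the first C downstream of
#' the assigned J.
#'
#' @param cdna A `seq_record`.
#' @param germline A [germline_ref()].
#' @param min_identity,min_coverage Assignment thresholds.
#' @return A `transcript_assignment`: list with per-type gene, identity,
#'   junction, mismatches, intra_cassette, c_is_j_proximal.
#' @export
assign_transcript <- function(cdna, germline, min_identity = 0.85,
                              min_coverage = 0.8) {
  seg <- germline$segments
  types <- vapply(seg, function(s) s$type, "")
  if (!all(c("V", "J", "C") %in% types)) {
    stop("germline reference needs at least one gene of each type")
  }
  s <- toupper(cdna$residues)
  hits <- list()
  for (ty in c("V", "J", "C")) {
    cand <- names(seg)[types == ty]
    segs <- setNames(vapply(cand, function(g) seg[[g]]$seq, ""), cand)
    hits[[ty]] <- .best_local_set(segs, s, min_identity, min_coverage)
  }
  mism <- list()
  for (ty in names(hits)) {
    b <- hits[[ty]]
    if (is.null(b)) next
    pa <- strsplit(b$h$pattern, "")[[1]]; su <- strsplit(b$h$subject, "")[[1]]
    bad <- which(pa != su & pa != "-" & su != "-")
    for (p in bad) {
      mism[[length(mism) + 1L]] <- data.frame(
        gene = b$gene, position = b$h$s_start + p - 1L,
        germline = pa[p], observed = su[p], stringsAsFactors = FALSE)
    }
  }
  junction <- NA_character_
  if (!is.null(hits$V) && !is.null(hits$J) &&
      hits$J$h$q_start > hits$V$h$q_end + 1L) {
    junction <- substr(s, hits$V$h$q_end + 1L, hits$J$h$q_start - 1L)
  } else if (!is.null(hits$V) && !is.null(hits$J)) {
    junction <- ""
  }
  intra <- if (!is.null(hits$V) && !is.null(hits$J)) {
    seg[[hits$V$gene]]$cassette == seg[[hits$J$gene]]$cassette
  } else NA
  cjp <- if (!is.null(hits$J) && !is.null(hits$C)) {
    jcas <- seg[[hits$J$gene]]$cassette
    cofj <- germline$c_order[match(TRUE, vapply(germline$c_order, function(g)
      seg[[g]]$cassette >= jcas, TRUE))]
    identical(hits$C$gene, cofj)
  } else NA
  structure(list(
    cdna_id = cdna$id,
    v_gene = if (is.null(hits$V)) NA_character_ else hits$V$gene,
    v_identity = if (is.null(hits$V)) NA_real_ else hits$V$h$identity,
    j_gene = if (is.null(hits$J)) NA_character_ else hits$J$gene,
    j_identity = if (is.null(hits$J)) NA_real_ else hits$J$h$identity,
    c_gene = if (is.null(hits$C)) NA_character_ else hits$C$gene,
    c_identity = if (is.null(hits$C)) NA_real_ else hits$C$h$identity,
    junction = junction,
    mismatches = if (length(mism)) do.call(rbind, mism) else
      data.frame(gene = character(), position = integer(),
                 germline = character(), observed = character()),
    intra_cassette = intra, c_is_j_proximal = cjp),
    class = "transcript_assignment")
}

#' Assign a whole repertoire (vectorized fast path)
#'
#' cDNAs are first assigned by exact (trim-tolerant) matching: a V whose
#' exon prefix (allowing up to `trim_max` nt trimmed from the V 3' end)
#' starts the cDNA, a J segment found as an exact substring (allowing 5'
#' trimming), and a C whose EX1 ends the cDNA. Transcripts not resolved
#' this way fall back to [assign_transcript()]. At zero germline
#' divergence the fast path resolves essentially everything.
#'
#' @param cdnas List of `seq_record`s.
#' @param germline A [germline_ref()].
#' @param trim_max Maximum trimming considered by the exact path (nt).
#' @param ... Passed to [assign_transcript()] for the fallback.
#' @return data.frame, one row per cDNA: v_gene, j_gene, c_gene, junction,
#'   intra_cassette, c_is_j_proximal, method.
#' @export
assign_repertoire <- function(cdnas, germline, trim_max = 3L, ...) {
  seg <- germline$segments
  types <- vapply(seg, function(s) s$type, "")
  ss <- vapply(cdnas, function(r) toupper(r$residues), "")
  n <- length(ss)
  v_gene <- j_gene <- c_gene <- rep(NA_character_, n)
  v_end <- j_start <- rep(NA_integer_, n)
  # V: longest trimmed-prefix match wins
  for (g in names(seg)[types == "V"]) {
    q <- toupper(seg[[g]]$seq)
    for (t in 0:trim_max) {
      p <- substr(q, 1L, nchar(q) - t)
      hit <- is.na(v_gene) & startsWith(ss, p)
      v_gene[hit] <- g
      v_end[hit] <- nchar(p)
    }
  }
  # C: suffix match on EX1
  for (g in names(seg)[types == "C"]) {
    hit <- is.na(c_gene) & endsWith(ss, toupper(seg[[g]]$seq))
    c_gene[hit] <- g
  }
  # J: exact substring (5' trimmed), searched after the V match
  sset <- Biostrings::DNAStringSet(ss)
  vend0 <- ifelse(is.na(v_end), 0L, v_end)
  for (g in names(seg)[types == "J"]) {
    q <- toupper(seg[[g]]$seq)
    for (t in 0:trim_max) {
      if (all(!is.na(j_gene))) break
      p <- Biostrings::DNAString(substr(q, t + 1L, nchar(q)))
      si <- Biostrings::startIndex(Biostrings::vmatchPattern(p, sset))
      st <- vapply(seq_len(n), function(i) {
        x <- si[[i]]
        # chance coincidences at the junction can let the V prefix overrun
        # the J start by up to trim_max nt
        x <- x[x > vend0[i] - trim_max]
        if (length(x)) x[1] else NA_integer_
      }, 1L)
      hit <- is.na(j_gene) & !is.na(st)
      j_gene[hit] <- g
      j_start[hit] <- st[hit]
    }
  }
  out <- data.frame(cdna_id = vapply(cdnas, function(r) r$id, ""),
                    v_gene = v_gene, j_gene = j_gene, c_gene = c_gene,
                    junction = NA_character_, intra_cassette = NA,
                    c_is_j_proximal = NA, method = "exact",
                    stringsAsFactors = FALSE)
  done <- !is.na(v_gene) & !is.na(j_gene) & !is.na(c_gene)
  out$junction[done] <- substr(ss[done], v_end[done] + 1L,
                               j_start[done] - 1L)
  cas <- function(g) vapply(g, function(x)
    if (is.na(x)) NA_integer_ else seg[[x]]$cassette, 1L)
  out$intra_cassette[done] <- cas(v_gene[done]) == cas(j_gene[done])
  jc <- cas(j_gene)
  cofj <- vapply(jc, function(k) {
    if (is.na(k)) return(NA_character_)
    germline$c_order[match(TRUE, vapply(germline$c_order, function(g)
      seg[[g]]$cassette >= k, TRUE))]
  }, "")
  out$c_is_j_proximal[done] <- out$c_gene[done] == cofj[done]
  for (i in which(!done)) {
    a <- assign_transcript(cdnas[[i]], germline, ...)
    out[i, c("v_gene", "j_gene", "c_gene")] <- c(a$v_gene, a$j_gene,
                                                 a$c_gene)
    out$junction[i] <- a$junction
    out$intra_cassette[i] <- a$intra_cassette
    out$c_is_j_proximal[i] <- a$c_is_j_proximal
    out$method[i] <- "alignment"
  }
  out
}

#' Summarize a repertoire assignment table
#'
#' Reports per V x J pair counts, the intra-cassette fraction with an exact
#' binomial 95% confidence interval, the fraction of transcripts spliced to
#' the J-proximal C, and the number of distinct transcripts after
#' exact-sequence deduplication (order-independent).
#'
#' @param assignments data.frame from [assign_repertoire()] (or a list of
#'   `transcript_assignment`s).
#' @param sequences Optional character vector of the cDNA sequences (for
#'   the distinct-transcript count).
#' @return List with `vj_counts`, `n`, `intra_fraction`, `intra_ci`,
#'   `c_proximal_fraction`, `n_distinct`.
#' @export
repertoire_summary <- function(assignments, sequences = NULL) {
  if (is.list(assignments) && !is.data.frame(assignments)) {
    assignments <- do.call(rbind, lapply(assignments, function(a) {
      data.frame(v_gene = a$v_gene, j_gene = a$j_gene, c_gene = a$c_gene,
                 intra_cassette = a$intra_cassette,
                 c_is_j_proximal = a$c_is_j_proximal,
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(nrow(assignments) >= 1L)
  vj <- as.data.frame(table(v = assignments$v_gene, j = assignments$j_gene))
  vj <- vj[vj$Freq > 0L, , drop = FALSE]
  ic <- assignments$intra_cassette[!is.na(assignments$intra_cassette)]
  bt <- if (length(ic)) binom.test(sum(ic), length(ic)) else NULL
  cp <- assignments$c_is_j_proximal[!is.na(assignments$c_is_j_proximal)]
  list(vj_counts = vj,
       n = nrow(assignments),
       intra_fraction = if (length(ic)) mean(ic) else NA_real_,
       intra_ci = if (!is.null(bt)) unname(bt$conf.int) else c(NA, NA),
       c_proximal_fraction = if (length(cp)) mean(cp) else NA_real_,
       n_distinct = if (!is.null(sequences))
         length(unique(toupper(sequences))) else NA_integer_)
}

#' Degenerate PCR primer
#'
#' The `code_map` defaults to the IUPAC nucleotide codes but can be
#' overridden to honor a primer's printed definition even where it
#' conflicts with the standard (e.g. a published "Y is A or G").
#'
#' @param name Primer name.
#' @param pattern Primer sequence 5'->3' over the code alphabet.
#' @param code_map Named list mapping each code character to its allowed
#'   bases.
#' @return A `degenerate_primer`.
#' @export
degenerate_primer <- function(name, pattern,
                              code_map = NULL) {
  if (is.null(code_map)) {
    code_map <- lapply(Biostrings::IUPAC_CODE_MAP, function(x)
      strsplit(x, "")[[1]])
  }
  chars <- unique(strsplit(toupper(pattern), "")[[1]])
  missing <- setdiff(chars, names(code_map))
  if (length(missing)) stop("pattern characters without code_map entry: ",
                            paste(missing, collapse = ", "))
  structure(list(name = name, pattern = toupper(pattern),
                 code_map = code_map), class = "degenerate_primer")
}

#' Match a degenerate primer on both strands
#'
#' A hit requires every primer position to be an allowed base, with at most
#' `max_mismatch` exceptions. Reverse-strand hits correspond to the primer
#' annealing to the forward strand (i.e. the reverse complement of the
#' primer occurring in the sequence); coordinates are forward, 1-based.
#'
#' @param seq A `seq_record`.
#' @param primer A [degenerate_primer()].
#' @param max_mismatch Allowed mismatching positions.
#' @return data.frame with `start`, `end`, `strand`, `matched_text`.
#' @export
match_primer <- function(seq, primer, max_mismatch = 0L) {
  s <- toupper(seq$residues)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  pat <- strsplit(primer$pattern, "", fixed = TRUE)[[1]]
  w <- length(pat)
  n <- length(v)
  scan <- function(vv) {
    if (n < w) return(integer(0))
    mm <- numeric(n - w + 1L)
    for (j in seq_len(w)) {
      allowed <- primer$code_map[[pat[j]]]
      mm <- mm + !(vv[j:(n - w + j)] %in% allowed)
    }
    which(mm <= max_mismatch)
  }
  out <- NULL
  fw <- scan(v)
  if (length(fw)) {
    out <- data.frame(start = fw, end = fw + w - 1L, strand = "+",
                      matched_text = substring(s, fw, fw + w - 1L))
  }
  rv <- scan(strsplit(revcomp(s), "", fixed = TRUE)[[1]])
  if (length(rv)) {
    st <- n - (rv + w - 1L) + 1L
    out <- rbind(out, data.frame(start = st, end = st + w - 1L,
                                 strand = "-",
                                 matched_text = substring(s, st, st + w - 1L)))
  }
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), matched_text = character()))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' The study's RACE primers
#'
#' GL1L (C EX1 reverse primer shared by several C genes) and GL2L (nested
#' reverse primer) with GL2L's code map as printed: Y = A or G, which
#' deliberately overrides the IUPAC meaning of Y (C or T).
#'
#' @return Named list of [degenerate_primer()]s.
#' @export
race_primers <- function() {
  list(
    GL1L = degenerate_primer("GL1L", "TCCAGAAGACAAAGGTATGTTCCA"),
    GL2L = degenerate_primer("GL2L", "TATYTCAGCAATYGAAGGAAG",
                             code_map = c(
                               lapply(Biostrings::IUPAC_CODE_MAP, function(x)
                                 strsplit(x, "")[[1]])[c("A", "C", "G", "T",
                                                         "N")],
                               list(Y = c("A", "G")))))
}
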