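## Synthetic TRG locus generator.
##
## A locus is assembled from typed "tokens" (leader, intron, exon, RS,
## PJ, J segment, C exons, En, spacers ...) so that ground-truth coordinates
## can be read off the token boundaries after every edit. Cassette copies are
## mutated independently from common ancestral parts, which makes the
## expected pairwise identity between two copies (1 - divergence)^2.
## Substitutions are drawn per site and then filtered through per-token
## constraints that mimic purifying selection on functional elements: RS
## cores, splice dinucleotides, start codons, the J FGXG motif, planted STAT
## motifs and primer sites stay intact, and substitutions that would create
## an in-frame stop codon (or a spurious ATG/GT where it would make gene
## structure ambiguous) are rejected. Defects are then planted exactly as
## requested, so the truth labels are guaranteed correct by construction.

STOP_CODONS <- c("TAA", "TAG", "TGA")
RS_HEPTAMER <- "CACAGTG"
RS_NONAMER <- "ACAAAAACC"
STAT_MOTIF <- "TTCNNNGAA"
GL1L_PRIMER <- "TCCAGAAGACAAAGGTATGTTCCA"
GL2L_PRIMER <- "TATYTCAGCAATYGAAGGAAG"

#' Specification of a synthetic TRG locus
#'
#' Defines the cassette architecture and evolutionary parameters of a
#' generated locus. Defaults follow the segment sizes typical of TR gamma
#' genes: 45 nt leader (L-PART1), 300 nt V exon, J segments of 49-58 nt, a
#' C gene with a 294 nt EX1, 75 nt EX2 copies and a 150 nt EX3, a 598 nt PJ
#' and a 771 nt En element (the lengths of the human reference elements),
#' with the En placed 2 kb downstream of the C gene.
#'
#' @param n_cassettes Number of V-J-(J)-C cassettes (>= 1).
#' @param v_per_cassette,j_per_cassette Integer vectors (length
#'   `n_cassettes`) of V and J gene counts per cassette.
#' @param ex2_copies_per_cassette EX2 copy number per cassette (1-3).
#' @param divergence Per-site substitution probability applied to each
#'   cassette copy relative to the ancestral parts (0-0.5).
#' @param indel_rate Per-site indel probability in unconstrained spacer
#'   tokens (0 disables; indels are never placed in genes or elements).
#' @param defect_plan `NULL`, or a data.frame with columns `gene`, `kind`;
#'   gene labels are `V<c>.<i>`, `J<c>.<i>`, `C<c>` and kinds one of
#'   `stop_codon`, `frameshift`, `rs_heptamer_core`,
#'   `j_motif_second_position`, `donor_site`.
#' @param intergenic_len Flanking intergenic length at both locus ends.
#' @param seed Integer seed; output is byte-identical for identical
#'   (spec, seed).
#' @param v_families Optional list (length `n_cassettes`) of integer vectors
#'   assigning each V gene to an ancestral family; V genes of the same
#'   family descend from one ancestral sequence (default: all family 1).
#'   The family partition is the planted subgroup truth.
#' @param leader_len,v_intron_len,v_exon_len,ex1_len,ex2_len,ex3_len,
#'   c_intron_len,utr3_len,pj_len,en_len,en_offset Segment sizes (nt).
#' @return A `locus_spec` list.
#' @export
locus_spec <- function(n_cassettes, v_per_cassette, j_per_cassette,
                       ex2_copies_per_cassette = rep(1L, n_cassettes),
                       divergence = 0.05, indel_rate = 0,
                       defect_plan = NULL, intergenic_len = 1000L, seed = 1L,
                       v_families = NULL,
                       leader_len = 45L, v_intron_len = 100L,
                       v_exon_len = 300L, ex1_len = 294L, ex2_len = 75L,
                       ex3_len = 150L, c_intron_len = 120L, utr3_len = 200L,
                       pj_len = 598L, en_len = 771L, en_offset = 2000L) {
  stopifnot(n_cassettes >= 1L,
            length(v_per_cassette) == n_cassettes,
            length(j_per_cassette) == n_cassettes,
            length(ex2_copies_per_cassette) == n_cassettes,
            all(j_per_cassette >= 1L), all(v_per_cassette >= 0L),
            all(ex2_copies_per_cassette %in% 1:3),
            divergence >= 0, divergence <= 0.5,
            leader_len %% 3L == 0L, v_exon_len %% 3L == 0L,
            ex1_len %% 3L == 0L, ex2_len %% 3L == 0L, ex3_len %% 3L == 0L,
            v_intron_len >= 80L)
  if (is.null(v_families)) {
    v_families <- lapply(v_per_cassette, function(k) rep(1L, k))
  }
  stopifnot(length(v_families) == n_cassettes,
            all(vapply(v_families, length, 1L) == v_per_cassette))
  if (!is.null(defect_plan)) {
    stopifnot(is.data.frame(defect_plan),
              all(c("gene", "kind") %in% names(defect_plan)))
    ok <- defect_plan$kind %in% c("stop_codon", "frameshift",
                                  "rs_heptamer_core",
                                  "j_motif_second_position", "donor_site")
    if (!all(ok)) stop("unknown defect kind: ",
                       paste(defect_plan$kind[!ok], collapse = ", "))
  }
  structure(list(n_cassettes = as.integer(n_cassettes),
                 v_per_cassette = as.integer(v_per_cassette),
                 j_per_cassette = as.integer(j_per_cassette),
                 ex2_copies_per_cassette = as.integer(ex2_copies_per_cassette),
                 divergence = divergence, indel_rate = indel_rate,
                 defect_plan = defect_plan,
                 intergenic_len = as.integer(intergenic_len),
                 seed = as.integer(seed), v_families = v_families,
                 leader_len = as.integer(leader_len),
                 v_intron_len = as.integer(v_intron_len),
                 v_exon_len = as.integer(v_exon_len),
                 ex1_len = as.integer(ex1_len), ex2_len = as.integer(ex2_len),
                 ex3_len = as.integer(ex3_len),
                 c_intron_len = as.integer(c_intron_len),
                 utr3_len = as.integer(utr3_len), pj_len = as.integer(pj_len),
                 en_len = as.integer(en_len),
                 en_offset = as.integer(en_offset)),
            class = "locus_spec")
}

#' Pig-shaped locus specification
#'
#' Four cassettes with V counts 5,1,1,1 and J counts 2,2,1,1 (eight V, six
#' J, four C genes); the first cassette's C gene carries a single EX2 and
#' the others three, mirroring the TRGC5/TRGC6/TRGC3/TRGC4 architecture.
#'
#' @param divergence,defect_plan,seed,... Passed to [locus_spec()].
#' @return A `locus_spec`.
#' @export
pig_locus_spec <- function(divergence = 0.10, defect_plan = NULL, seed = 1L,
                           ...) {
  locus_spec(n_cassettes = 4L, v_per_cassette = c(5L, 1L, 1L, 1L),
             j_per_cassette = c(2L, 2L, 1L, 1L),
             ex2_copies_per_cassette = c(1L, 3L, 3L, 3L),
             divergence = divergence, defect_plan = defect_plan, seed = seed,
             ...)
}

## ---- random-sequence helpers (all use the session RNG) ----

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random sequence free of in-frame stops (if frame_stop) and of the given
# motifs anywhere; violations are repaired by point resampling.
.constrained_dna <- function(n, frame_stop = FALSE,
                             forbid_motifs = character()) {
  v <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  for (iter in 1:300) {
    bad <- integer(0)
    if (frame_stop && n >= 3L) {
      st <- 3L * seq_len(n %/% 3L) - 2L
      cod <- paste0(v[st], v[st + 1L], v[st + 2L])
      hit <- which(cod %in% STOP_CODONS)
      if (length(hit)) bad <- c(bad, st[hit] + 1L)  # middle base of codon
    }
    s <- paste(v, collapse = "")
    for (m in forbid_motifs) {
      occ <- gregexpr(m, s, fixed = TRUE)[[1]]
      if (occ[1] != -1L) bad <- c(bad, occ + 1L)
    }
    if (length(bad) == 0L) return(s)
    for (p in unique(bad)) v[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                  v[p]), 1L)
  }
  stop("could not satisfy sequence constraints")  # nocov
}

# J segment: phase nucleotide + codons, with F,G,x,G,A motif placed so that
# two codons follow it, and no GT dinucleotide (and no stop) downstream of
# the motif's last G so that the donor search is unambiguous.
.make_j_seg <- function(len) {
  stopifnot(len %% 3L == 1L)
  k <- (len - 1L) %/% 3L                      # number of codons
  aa_codon <- function(aa) switch(aa, F = "TTT", G = "GGA", A = "GCC")
  repeat {
    body <- .constrained_dna(3L * k, frame_stop = TRUE)
    cod <- substring(body, 3L * seq_len(k) - 2L, 3L * seq_len(k))
    cod[k - 4L] <- aa_codon("F")
    cod[k - 3L] <- aa_codon("G")
    cod[k - 1L] <- aa_codon("G")
    cod[k] <- aa_codon("A")
    s <- paste0(sample(c("A", "C", "G", "T"), 1L), paste(cod, collapse = ""))
    tail_start <- 1L + 3L * (k - 1L)          # after the motif's last G
    if (!grepl("GT", substr(s, tail_start, len), fixed = TRUE) &&
        !grepl("T$", s)) {                    # donor GT follows; avoid ..T|GT
      mid <- substring(s, 2L + 3L * (seq_len(k) - 1L), 1L + 3L * seq_len(k))
      if (!any(mid %in% STOP_CODONS)) return(s)
    }
  }
}

.plant_motif <- function(s, motif, pos) {
  m <- strsplit(motif, "", fixed = TRUE)[[1]]
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  conc <- c(A = "A", C = "C", G = "G", T = "T", N = NA, Y = NA)
  for (i in seq_along(m)) {
    b <- conc[[m[i]]]
    if (!is.na(b)) v[pos + i - 1L] <- b
  }
  paste(v, collapse = "")
}

## ---- token machinery ----

.tok <- function(type, content, cassette = NA_integer_, gene = NA_character_,
                 part = type) {
  list(type = type, content = content, cassette = cassette, gene = gene,
       part = part)
}

# Constraint set for mutating one token: positions that may never change,
# whether in-frame stops are rejected (frame offset 0-based), motifs whose
# creation is rejected and the region (relative) where that applies.
.token_constraints <- function(tk) {
  n <- nchar(tk$content)
  protect <- logical(n)
  frame <- NA_integer_
  forbid <- list()
  switch(tk$type,
    leader = {
      protect[1:3] <- TRUE                   # ATG
      frame <- 0L
      forbid <- list(list(motif = "ATG", from = 2L, to = n),
                     list(motif = "GT", from = 1L, to = n))
    },
    v_gap = {
      forbid <- list(list(motif = "ATG", from = 1L, to = n))
    },
    v_intron = {
      protect[(n - 11L):n] <- TRUE           # polypyrimidine tract + AG
      forbid <- list(list(motif = "ATG", from = 1L, to = n),
                     list(motif = "GT", from = 1L, to = 31L))
    },
    v_exon = {
      frame <- 0L
      forbid <- list(list(motif = "AG", from = 1L, to = 11L))
    },
    rs = {
      protect[1:7] <- TRUE
      protect[(n - 8L):n] <- TRUE
    },
    j_seg = {
      k <- (n - 1L) %/% 3L
      mpos <- function(ci) (2L + 3L * (ci - 1L)):(1L + 3L * ci)
      protect[c(mpos(k - 4L), mpos(k - 3L), mpos(k - 1L))] <- TRUE  # F,G,G
      frame <- 1L
      forbid <- list(list(motif = "GT", from = 2L + 3L * (k - 1L), to = n))
    },
    donor = { protect[] <- TRUE },
    j_gap = {
      forbid <- list(list(motif = "GT", from = 1L, to = min(31L, n)))
    },
    jc_gap = { protect[(n - 11L):n] <- TRUE },
    ex1 = {
      frame <- 0L
      ps <- attr(tk$content, "protect_sites")
      if (!is.null(ps)) for (r in ps) protect[r[1]:r[2]] <- TRUE
    },
    ex2 = { frame <- 0L },
    ex3 = {
      frame <- 0L
      protect[(n - 2L):n] <- TRUE            # terminal stop codon
    },
    c_intron = { protect[c(1:2, (n - 11L):n)] <- TRUE },
    pj = ,
    en = {
      sp <- attr(tk$content, "stat_pos")
      protect[c(sp:(sp + 2L), (sp + 6L):(sp + 8L))] <- TRUE  # TTC ... GAA
    }
  )
  list(protect = protect, frame = frame, forbid = forbid)
}

# Apply per-site substitutions at the given rate, honoring constraints.
.mutate_token <- function(tk, rate) {
  n <- nchar(tk$content)
  if (rate <= 0 || n == 0L) return(tk)
  cs <- .token_constraints(tk)
  v <- strsplit(as.character(tk$content), "", fixed = TRUE)[[1]]
  hit <- which(runif(n) < rate & !cs$protect)
  for (p in hit) {
    new <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
    old <- v[p]; v[p] <- new
    ok <- TRUE
    if (!is.na(cs$frame)) {
      ci <- (p - 1L - cs$frame) %/% 3L
      st <- cs$frame + 3L * ci + 1L
      if (st >= 1L && st + 2L <= n &&
          paste0(v[st], v[st + 1L], v[st + 2L]) %in% STOP_CODONS) ok <- FALSE
    }
    if (ok) for (f in cs$forbid) {
      w <- nchar(f$motif)
      lo <- max(f$from, p - w + 1L); hi <- min(f$to - w + 1L, p)
      if (lo <= hi) {
        for (s0 in lo:hi) {
          if (paste(v[s0:(s0 + w - 1L)], collapse = "") == f$motif) {
            ok <- FALSE; break
          }
        }
      }
    }
    if (!ok) v[p] <- old
  }
  out <- paste(v, collapse = "")
  attributes(out) <- attributes(tk$content)
  tk$content <- out
  tk
}

# Indels only in unconstrained spacer tokens, so annotations stay valid.
.indel_token <- function(tk, rate) {
  if (rate <= 0) return(tk)
  if (!tk$type %in% c("v_gap", "j_gap", "pj_gap", "en_gap", "tail_gap",
                      "intergenic", "utr3")) return(tk)
  v <- strsplit(tk$content, "", fixed = TRUE)[[1]]
  n <- length(v)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0L) return(tk)
  del <- hit[seq_along(hit) %% 2L == 1L]
  ins <- hit[seq_along(hit) %% 2L == 0L]
  keep <- setdiff(seq_len(n), del)
  out <- character(0)
  for (i in keep) {
    out <- c(out, v[i])
    if (i %in% ins) out <- c(out, sample(c("A", "C", "G", "T"), 1L))
  }
  tk$content <- paste(out, collapse = "")
  tk
}

## ---- ancestral parts ----

.make_leader <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 12L)
  repeat {
    s <- paste0("ATG", .constrained_dna(len - 3L, frame_stop = TRUE,
                                        forbid_motifs = c("ATG", "GT")))
    if (!grepl("GT", s, fixed = TRUE) &&
        gregexpr("ATG", s, fixed = TRUE)[[1]][1] == 1L &&
        length(gregexpr("ATG", s, fixed = TRUE)[[1]]) == 1L) return(s)
  }
}

.make_element <- function(len) {
  pos <- sample(seq(10L, len - 20L), 1L)
  s <- .plant_motif(.rand_dna(len), STAT_MOTIF, pos)
  attr(s, "stat_pos") <- pos
  s
}

.make_ex1 <- function(len) {
  s <- .constrained_dna(len, frame_stop = TRUE)
  sites <- list()
  if (len >= 240L) {
    gl2l_site <- revcomp(chartr("Y", "A", sub("Y([^Y]*)$", "G\\1",
                                              GL2L_PRIMER)))
    gl1l_site <- revcomp(GL1L_PRIMER)
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    v[151:(150L + nchar(gl2l_site))] <- strsplit(gl2l_site, "")[[1]]
    v[199:(198L + nchar(gl1l_site))] <- strsplit(gl1l_site, "")[[1]]
    s <- paste(v, collapse = "")
    sites <- list(c(151L, 150L + nchar(gl2l_site)),
                  c(199L, 198L + nchar(gl1l_site)))
    stopifnot(!has_internal_stop(s, skip_last = FALSE))
  }
  attr(s, "protect_sites") <- sites
  s
}

.ancestral_parts <- function(spec) {
  fams <- sort(unique(unlist(spec$v_families)))
  j_len_cycle <- c(52L, 49L, 58L, 55L)
  parts <- list(
    leader = lapply(fams, function(f) .make_leader(spec$leader_len)),
    v_intron = lapply(fams, function(f) {
      # donor-proximal region kept GT-free and acceptor preceded by a
      # polypyrimidine tract (splice-region conservation)
      paste0(.constrained_dna(30L, forbid_motifs = c("ATG", "GT")),
             .constrained_dna(spec$v_intron_len - 42L, forbid_motifs = "ATG"),
             "TTTCCTTTCC", "AG")
    }),
    v_exon = lapply(fams, function(f) {
      # exon head kept AG-free so the true acceptor cannot be shadowed by
      # an exon-internal acceptor when a frameshift is planted
      paste0(.constrained_dna(12L, frame_stop = TRUE, forbid_motifs = "AG"),
             .constrained_dna(spec$v_exon_len - 12L, frame_stop = TRUE))
    }),
    v_gap = .constrained_dna(150L, forbid_motifs = "ATG"),
    rs23 = paste0(RS_HEPTAMER, .rand_dna(23L), RS_NONAMER),
    rs12 = paste0(RS_HEPTAMER, .rand_dna(12L), RS_NONAMER),
    j_seg = lapply(seq_len(max(spec$j_per_cassette)), function(i) {
      .make_j_seg(j_len_cycle[((i - 1L) %% 4L) + 1L])
    }),
    j_gap = paste0(.constrained_dna(30L, forbid_motifs = "GT"),
                   .rand_dna(90L)),
    pj = .make_element(spec$pj_len),
    pj_gap = .rand_dna(200L),
    jc_gap = paste0(.rand_dna(188L), "TTTCCTTTCC", "AG"),
    ex1 = .make_ex1(spec$ex1_len),
    ex2 = .constrained_dna(spec$ex2_len, frame_stop = TRUE),
    ex3 = paste0(.constrained_dna(spec$ex3_len - 3L, frame_stop = TRUE),
                 "TGA"),
    c_intron = paste0("GT", .rand_dna(spec$c_intron_len - 14L),
                      "TTTCCTTTCC", "AG"),
    utr3 = .rand_dna(spec$utr3_len),
    en_gap = .rand_dna(max(spec$en_offset - spec$utr3_len, 50L)),
    en = .make_element(spec$en_len),
    tail_gap = .rand_dna(300L)
  )
  names(parts$leader) <- names(parts$v_intron) <- names(parts$v_exon) <- fams
  parts
}

## ---- defects ----

.edit_sub <- function(s, pos, repl) {
  a <- attributes(s)
  v <- strsplit(as.character(s), "", fixed = TRUE)[[1]]
  v[pos:(pos + nchar(repl) - 1L)] <- strsplit(repl, "")[[1]]
  out <- paste(v, collapse = "")
  attributes(out) <- a
  out
}

.edit_del <- function(s, pos) {
  a <- attributes(s)
  v <- strsplit(as.character(s), "", fixed = TRUE)[[1]]
  out <- paste(v[-pos], collapse = "")
  attributes(out) <- a
  out
}

# kind -> functionality grade
.defect_grade <- function(kind) {
  if (kind %in% c("stop_codon", "frameshift")) "P" else "ORF"
}

.apply_defect <- function(tokens, gene, kind) {
  idx <- which(vapply(tokens, function(t) identical(t$gene, gene), TRUE))
  if (length(idx) == 0L) stop("defect_plan names unknown gene: ", gene)
  type <- substr(gene, 1L, 1L)
  find_part <- function(part) {
    i <- idx[vapply(tokens[idx], function(t) t$part == part, TRUE)]
    if (length(i) == 0L) stop("gene ", gene, " has no part ", part)
    i[1]
  }
  if (kind == "stop_codon") {
    if (type == "V") {
      i <- find_part("V-EXON")
      tokens[[i]]$content <- .edit_sub(tokens[[i]]$content, 148L, "TAA")
    } else if (type == "J") {
      i <- find_part("J-REGION")
      tokens[[i]]$content <- .edit_sub(tokens[[i]]$content, 14L, "TAA")
    } else {
      i <- find_part("EX1")
      tokens[[i]]$content <- .edit_sub(tokens[[i]]$content, 58L, "TAA")
    }
  } else if (kind == "frameshift") {
    if (type == "V") {
      i <- find_part("V-EXON")
      tokens[[i]]$content <- .edit_del(tokens[[i]]$content, 150L)
    } else if (type == "C") {
      i <- find_part("EX1")
      tokens[[i]]$content <- .edit_del(tokens[[i]]$content, 114L)
    } else stop("frameshift defects are defined for V and C genes only")
  } else if (kind == "rs_heptamer_core") {
    i <- find_part(if (type == "V") "rs23" else "rs12")
    tokens[[i]]$content <- .edit_sub(tokens[[i]]$content, 1L, "T")
  } else if (kind == "j_motif_second_position") {
    if (type != "J") stop("j_motif defects apply to J genes")
    i <- find_part("J-REGION")
    k <- (nchar(tokens[[i]]$content) - 1L) %/% 3L
    pos <- 2L + 3L * (k - 4L)                 # start of the first G codon
    tokens[[i]]$content <- .edit_sub(tokens[[i]]$content, pos, "GCT")
  } else if (kind == "donor_site") {
    part <- switch(type, V = "leader_donor", J = "j_donor", C = "intron1")
    i <- find_part(part)
    tokens[[i]]$content <- .edit_sub(tokens[[i]]$content, 2L, "C")
  }
  tokens
}

## ---- locus assembly ----

#' Generate a synthetic TRG locus with ground truth
#'
#' Emits a locus sequence built as
#' intergenic - cassette x n - intergenic, each cassette being
#' (V blocks) PJ (J blocks) C-gene En, with all functional elements planted
#' at known coordinates and an exact [truth_set] describing every gene,
#' cassette, regulatory element and defect. Fully reproducible for a fixed
#' `(spec, seed)`.
#'
#' @param spec A [locus_spec()].
#' @return List with `sequence` (a `seq_record`) and `truth` (a `truth_set`
#'   list: `genes`, `cassettes`, `regulatory`, `segments`, `v_family`,
#'   `reference_c`, `reference_pj`, `reference_en`, `spec`).
#' @export
generate_locus <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  parts <- .ancestral_parts(spec)
  tokens <- list(.tok("intergenic", .rand_dna(spec$intergenic_len)))
  ex2_labels <- c("EX2A", "EX2B", "EX2C")
  for (ci in seq_len(spec$n_cassettes)) {
    for (vi in seq_len(spec$v_per_cassette[ci])) {
      g <- sprintf("V%d.%d", ci, vi)
      fam <- as.character(spec$v_families[[ci]][vi])
      tokens <- c(tokens, list(
        .tok("v_gap", parts$v_gap, ci),
        .tok("leader", parts$leader[[fam]], ci, g, "L-PART1"),
        .tok("donor", "GT", ci, g, "leader_donor"),
        .tok("v_intron", parts$v_intron[[fam]], ci, g, "v_intron"),
        .tok("v_exon", parts$v_exon[[fam]], ci, g, "V-EXON"),
        .tok("rs", parts$rs23, ci, g, "rs23")))
    }
    tokens <- c(tokens, list(.tok("pj", parts$pj, ci),
                             .tok("pj_gap", parts$pj_gap, ci)))
    for (ji in seq_len(spec$j_per_cassette[ci])) {
      g <- sprintf("J%d.%d", ci, ji)
      tokens <- c(tokens, list(
        .tok("rs", parts$rs12, ci, g, "rs12"),
        .tok("j_seg", parts$j_seg[[ji]], ci, g, "J-REGION"),
        .tok("donor", "GT", ci, g, "j_donor"),
        .tok("j_gap", parts$j_gap, ci)))
    }
    g <- sprintf("C%d", ci)
    tokens <- c(tokens, list(.tok("jc_gap", parts$jc_gap, ci),
                             .tok("ex1", parts$ex1, ci, g, "EX1"),
                             .tok("c_intron", parts$c_intron, ci, g,
                                  "intron1")))
    for (k in seq_len(spec$ex2_copies_per_cassette[ci])) {
      tokens <- c(tokens, list(
        .tok("ex2", parts$ex2, ci, g, ex2_labels[k]),
        .tok("c_intron", parts$c_intron, ci, g, paste0("intron", k + 1L))))
    }
    tokens <- c(tokens, list(.tok("ex3", parts$ex3, ci, g, "EX3"),
                             .tok("utr3", parts$utr3, ci, g, "UTR3"),
                             .tok("en_gap", parts$en_gap, ci),
                             .tok("en", parts$en, ci),
                             .tok("tail_gap", parts$tail_gap, ci)))
  }
  tokens <- c(tokens, list(.tok("intergenic", .rand_dna(spec$intergenic_len))))

  # divergence between cassette copies, then indels in free spacers
  tokens <- lapply(tokens, function(tk) {
    if (is.na(tk$cassette)) return(tk)
    .indel_token(.mutate_token(tk, spec$divergence), spec$indel_rate)
  })

  # plant defects exactly as requested
  defect_map <- list()
  if (!is.null(spec$defect_plan)) {
    for (r in seq_len(nrow(spec$defect_plan))) {
      g <- spec$defect_plan$gene[r]; kind <- spec$defect_plan$kind[r]
      tokens <- .apply_defect(tokens, g, kind)
      defect_map[[g]] <- c(defect_map[[g]], kind)
    }
  }

  .assemble_truth(tokens, spec, parts, defect_map)
}

.assemble_truth <- function(tokens, spec, parts, defect_map) {
  seq_id <- sprintf("synthetic_locus_seed%d", spec$seed)
  contents <- vapply(tokens, function(t) as.character(t$content), "")
  lens <- nchar(contents)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  locus <- paste(contents, collapse = "")

  iv <- function(i) genomic_interval(seq_id, starts[i], ends[i])
  tk_gene <- vapply(tokens, function(t) ifelse(is.na(t$gene), "", t$gene), "")
  tk_part <- vapply(tokens, function(t) t$part, "")
  tk_cas <- vapply(tokens, function(t) ifelse(is.na(t$cassette), 0L,
                                              t$cassette), 0L)

  gene_names <- unique(tk_gene[tk_gene != ""])
  genes <- list(); segments <- list()
  for (g in gene_names) {
    idx <- which(tk_gene == g)
    type <- substr(g, 1L, 1L)
    kinds <- defect_map[[g]]
    fun <- if (is.null(kinds)) "F" else
      if (any(vapply(kinds, .defect_grade, "") == "P")) "P" else "ORF"
    exset <- list(); rs <- NULL
    for (i in idx) {
      p <- tk_part[i]
      if (p %in% c("L-PART1", "V-EXON", "J-REGION", "EX1", "EX2A", "EX2B",
                   "EX2C", "EX3")) {
        exset[[p]] <- iv(i)
      } else if (p %in% c("rs23", "rs12")) {
        cont <- contents[i]
        rs <- rs_signal(heptamer = substr(cont, 1L, 7L),
                        spacer_length = nchar(cont) - 16L,
                        nonamer = substr(cont, nchar(cont) - 8L, nchar(cont)),
                        interval = iv(i),
                        nominal = if (p == "rs23") 23L else 12L)
      }
    }
    ga <- gene_annotation(g, type, exset, rs = rs, functionality = fun,
                          defects = if (is.null(kinds)) character() else kinds)
    ga$cassette <- tk_cas[idx[1]]
    coding_parts <- switch(type, V = c("L-PART1", "V-EXON"), J = "J-REGION",
                           C = c("EX1", "EX2A", "EX2B", "EX2C", "EX3"))
    coding <- paste(vapply(intersect(coding_parts, names(exset)),
                           function(p) substr(locus, exset[[p]]$start,
                                              exset[[p]]$end), ""),
                    collapse = "")
    ga$sequence <- coding
    genes[[g]] <- ga
    segments[[g]] <- list(type = type, cassette = tk_cas[idx[1]],
                          coding = coding,
                          v_exon = if (type == "V")
                            substr(locus, exset[["V-EXON"]]$start,
                                   exset[["V-EXON"]]$end) else NULL,
                          ex1 = if (type == "C")
                            substr(locus, exset[["EX1"]]$start,
                                   exset[["EX1"]]$end) else NULL)
  }

  regulatory <- list()
  cassettes <- list()
  for (ci in seq_len(spec$n_cassettes)) {
    pj_i <- which(tk_part == "pj" & tk_cas == ci)
    en_i <- which(tk_part == "en" & tk_cas == ci)
    regulatory <- c(regulatory,
                    list(list(kind = "PJ", cassette = ci, interval = iv(pj_i)),
                         list(kind = "En", cassette = ci,
                              interval = iv(en_i))))
    cg <- genes[vapply(genes, function(x) x$cassette == ci, TRUE)]
    cg <- cg[order(vapply(cg, function(x) gene_span(x)$start, 1L))]
    sp <- genomic_interval(seq_id,
                           min(vapply(cg, function(x) gene_span(x)$start, 1L)),
                           max(ends[en_i]))
    cassettes[[ci]] <- structure(list(name = sprintf("cassette%d", ci),
                                      genes = cg, pj = iv(pj_i),
                                      en = iv(en_i), span = sp),
                                 class = "cassette")
  }

  v_family <- unlist(lapply(seq_len(spec$n_cassettes), function(ci) {
    if (spec$v_per_cassette[ci] == 0L) return(NULL)
    setNames(spec$v_families[[ci]],
             sprintf("V%d.%d", ci, seq_len(spec$v_per_cassette[ci])))
  }))

  truth <- structure(list(
    genes = genes, cassettes = cassettes, regulatory = regulatory,
    segments = segments, v_family = v_family,
    reference_c = list(seq_record("ref_EX1", as.character(parts$ex1), "EX1"),
                       seq_record("ref_EX2", as.character(parts$ex2), "EX2"),
                       seq_record("ref_EX3", as.character(parts$ex3), "EX3")),
    reference_pj = seq_record("ref_PJ", as.character(parts$pj)),
    reference_en = seq_record("ref_En", as.character(parts$en)),
    spec = spec), class = "truth_set")

  list(sequence = seq_record(seq_id, locus,
                             sprintf("synthetic TRG locus (%d cassettes)",
                                     spec$n_cassettes)),
       truth = truth)
}

#' Simulate a rearranged V-J-C cDNA repertoire from a truth set
#'
#' Each transcript is a V-exon prefix (with 0-`v_trim_max` nt trimmed from
#' its 3' end), a junction of 0-`junction_insert_max` random inserted
#' nucleotides, a J segment (with 0-`j_trim_max` nt trimmed from its 5'
#' end), and the EX1 of the C gene of the J's cassette. With probability
#' `trans_cassette_rate` the J (and hence its C) is drawn from a different
#' cassette than the V. Only functional (F) genes are used.
#'
#' @param truth A `truth_set` from [generate_locus()].
#' @param n Number of transcripts.
#' @param trans_cassette_rate Probability of a trans-cassette V-J join.
#' @param junction_insert_max Maximum number of inserted junction bases.
#' @param seed Integer seed.
#' @param v_trim_max,j_trim_max Maximum exonuclease trimming (nt).
#' @return List with `records` (seq_records) and `table` (data.frame:
#'   cdna_id, v_gene, j_gene, c_gene, junction, intra_cassette).
#' @export
generate_repertoire <- function(truth, n, trans_cassette_rate = 0.25,
                                junction_insert_max = 8L, seed = 1L,
                                v_trim_max = 3L, j_trim_max = 3L) {
  if (n < 0L) stop("n must be non-negative")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  seg <- truth$segments
  fun_ok <- vapply(truth$genes, function(g)
    g$functionality == "F" || g$rescued_by_cdna, TRUE)
  typ <- vapply(seg, function(s) s$type, "")
  cas <- vapply(seg, function(s) s$cassette, 1L)
  f_v <- names(seg)[typ == "V" & fun_ok]
  f_j <- names(seg)[typ == "J" & fun_ok]
  f_c <- names(seg)[typ == "C" & fun_ok]
  jc_cas <- intersect(cas[f_j], cas[f_c])      # cassettes usable on the J side
  v_ok <- f_v[cas[f_v] %in% jc_cas]
  if (length(v_ok) == 0L || length(jc_cas) == 0L) {
    stop("no cassette with functional V, J and C genes")
  }
  bases <- c("A", "C", "G", "T")
  recs <- vector("list", n)
  tab <- vector("list", n)
  for (i in seq_len(n)) {
    v <- sample(v_ok, 1L)
    vcas <- cas[[v]]
    trans <- length(jc_cas) > 1L && runif(1) < trans_cassette_rate
    others <- setdiff(jc_cas, vcas)
    target_cas <- if (trans) others[sample.int(length(others), 1L)] else vcas
    j <- sample(f_j[cas[f_j] == target_cas], 1L)
    cg <- f_c[cas[f_c] == target_cas][1]
    vs <- seg[[v]]$v_exon
    vt <- sample(0:v_trim_max, 1L)
    jt <- sample(0:j_trim_max, 1L)
    ins <- paste(sample(bases, sample(0:junction_insert_max, 1L),
                        replace = TRUE), collapse = "")
    js <- seg[[j]]$coding
    tr <- paste0(substr(vs, 1L, nchar(vs) - vt), ins,
                 substr(js, jt + 1L, nchar(js)), seg[[cg]]$ex1)
    id <- sprintf("cdna%05d", i)
    recs[[i]] <- seq_record(id, tr,
                            sprintf("V=%s J=%s C=%s", v, j, cg))
    tab[[i]] <- data.frame(cdna_id = id, v_gene = v, j_gene = j, c_gene = cg,
                           junction = ins, intra_cassette = !trans,
                           stringsAsFactors = FALSE)
  }
  list(records = recs,
       table = if (n > 0L) do.call(rbind, tab) else
         data.frame(cdna_id = character(), v_gene = character(),
                    j_gene = character(), c_gene = character(),
                    junction = character(), intra_cassette = logical()))
}
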