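test_that("self dot-plot reports only the main diagonal on random sequence", {
  set.seed(606)
  r <- seq_record("r", rand_seq(10000))
  runs <- self_dotplot(r)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$offset, 0L)
  expect_equal(runs$length, 10000L)
})

test_that("a tandem duplication appears as an off-diagonal run with its mirror", {
  set.seed(707)
  x <- rand_seq(5000)
  r <- seq_record("r", paste0(x, x))
  runs <- self_dotplot(r)
  off <- runs[runs$offset > 0, , drop = FALSE]
  expect_gte(nrow(off), 2L)            # the run and its mirror
  expect_true(any(off$offset == 5000L & off$length > 4500L))
  # mirror symmetry: each off-diagonal run has its transposed partner
  key <- paste(off$start1, off$start2)
  mirror_key <- paste(off$start2, off$start1)
  expect_true(all(mirror_key %in% key))
})

test_that("masked (lowercase) regions seed no dot-plot matches", {
  set.seed(808)
  x <- rand_seq(3000)
  dup <- seq_record("m", paste0(x, tolower(x)))
  runs <- self_dotplot(dup)
  expect_equal(nrow(runs[runs$offset > 0, ]), 0L)
})

test_that("zero-divergence four-cassette locus shows >= 3 parallel lines", {
  gl <- generate_locus(pig_locus_spec(divergence = 0, seed = 1L))
  runs <- self_dotplot(gl$sequence)
  off <- runs[runs$offset > 0 & runs$start2 > runs$start1, , drop = FALSE]
  expect_gte(length(unique(off$offset)), 3L)
})

test_that("duplication units merge runs and list covered genes", {
  set.seed(909)
  gl <- generate_locus(locus_spec(2, c(1, 1), c(1, 1), divergence = 0,
                                  seed = 17L))
  runs <- self_dotplot(gl$sequence)
  units <- detect_duplication_units(runs, gl$truth$genes)
  expect_gte(length(units), 1L)
  big <- units[[which.max(vapply(units, function(u)
    interval_length(u$side1), 1L))]]
  expect_true(all(c("V1.1", "J1.1", "C1") %in% big$genes1))
  expect_true(all(c("V2.1", "J2.1", "C2") %in% big$genes2))
  expect_equal(detect_duplication_units(runs[runs$offset == 0, ],
                                        gl$truth$genes), list())
})

test_that("build_cassettes cuts after each C and reports anomalies", {
  mk <- function(name, type, at) {
    gene_annotation(name, type,
                    setNames(list(genomic_interval("L", at, at + 10)),
                             switch(type, V = "V-EXON", J = "J-REGION",
                                    C = "EX1")))
  }
  pig_order <- c(rep("V", 5), "J", "J", "C", "V", "J", "J", "C",
                 "V", "J", "C", "V", "J", "C")
  genes <- lapply(seq_along(pig_order), function(i)
    mk(paste0(pig_order[i], i), pig_order[i], i * 100))
  bc <- build_cassettes(genes)
  expect_length(bc$cassettes, 4L)
  expect_length(bc$anomalies, 0L)
  vc <- vapply(bc$cassettes, function(cs)
    sum(vapply(cs$genes, function(g) g$gene_type == "V", TRUE)), 1L)
  jc <- vapply(bc$cassettes, function(cs)
    sum(vapply(cs$genes, function(g) g$gene_type == "J", TRUE)), 1L)
  expect_equal(vc, c(5L, 1L, 1L, 1L))
  expect_equal(jc, c(2L, 2L, 1L, 1L))

  single <- build_cassettes(list(mk("V1", "V", 100), mk("J1", "J", 200),
                                 mk("C1", "C", 300)))
  expect_length(single$cassettes, 1L)

  orphan <- build_cassettes(list(mk("J1", "J", 100), mk("C1", "C", 200),
                                 mk("V1", "V", 300)))
  expect_length(orphan$cassettes, 1L)
  expect_length(orphan$anomalies, 1L)
  expect_equal(unclass(orphan$anomalies[[1]])[1], "V1",
               ignore_attr = TRUE)

  expect_error(build_cassettes(list(mk("V1", "V", 100))), "no C gene")
})

test_that("cassette count always equals the number of C genes", {
  for (seed in 1:3) {
    gl <- generate_locus(locus_spec(3, c(2, 1, 0), c(1, 2, 1), seed = seed))
    bc <- build_cassettes(gl$truth$genes)
    expect_equal(length(bc$cassettes),
                 sum(vapply(gl$truth$genes, function(g)
                   g$gene_type == "C", TRUE)))
  }
})

test_that("cassettes are named by nearest reference identity with V tie-break", {
  gl <- generate_locus(pig_locus_spec(divergence = 0.08, seed = 19L))
  bc <- build_cassettes(gl$truth$genes)
  labels <- c("TRGC5", "TRGC6", "TRGC3", "TRGC4")
  refs <- unlist(lapply(seq_along(gl$truth$cassettes), function(k) {
    cs <- gl$truth$cassettes[[k]]
    lapply(cs$genes, function(g) {
      seq_record(paste0("ref", g$name), g$sequence,
                 sprintf("cassette=%s type=%s", labels[k], g$gene_type))
    })
  }), recursive = FALSE)
  named <- name_cassettes(bc$cassettes, refs)
  expect_equal(vapply(named, function(cs) cs$name, ""), labels)
  # all references dissimilar -> novel
  fake <- list(seq_record("x", rand_seq(900), "cassette=TRGC9 type=C"))
  nv <- name_cassettes(bc$cassettes[1], fake)
  expect_equal(nv[[1]]$name, "novel-1")
  expect_error(name_cassettes(bc$cassettes, list()), "empty")
})

test_that("STAT motif scan matches an independent regex oracle on both strands", {
  h <- scan_stat_motifs(seq_record("x", "GGTTCAAAGAAGG"))
  expect_equal(h$start[h$strand == "+"], 3L)
  # a motif that is its own reverse complement hits both strands at 1
  h2 <- scan_stat_motifs(seq_record("x", "TTCTTTGAA"))
  expect_equal(nrow(h2), 2L)
  expect_setequal(h2$strand, c("-", "+"))
  expect_equal(h2$start, c(1L, 1L))
  expect_equal(nrow(scan_stat_motifs(seq_record("x", "TTCAAAGAG"))), 0L)

  set.seed(111)
  for (trial in 1:40) {
    s <- rand_seq(1000)
    got <- scan_stat_motifs(seq_record("x", s))
    fwd <- gregexpr("(?=TTC...GAA)", s, perl = TRUE)[[1]]
    fwd <- if (fwd[1] == -1L) integer(0) else as.integer(fwd)
    rc <- revcomp(s)
    rev <- gregexpr("(?=TTC...GAA)", rc, perl = TRUE)[[1]]
    rev <- if (rev[1] == -1L) integer(0) else
      sort(1000L - (as.integer(rev) + 8L) + 1L)
    expect_equal(sort(got$start[got$strand == "+"]), sort(fwd))
    expect_equal(sort(got$start[got$strand == "-"]), rev)
  }
})

test_that("PJ and En elements are located in their windows", {
  gl <- generate_locus(locus_spec(2, c(1, 1), c(2, 1), divergence = 0.10,
                                  seed = 23L))
  bc <- build_cassettes(gl$truth$genes)
  for (k in seq_along(bc$cassettes)) {
    cs <- locate_regulatory_elements(bc$cassettes[[k]], gl$sequence,
                                     gl$truth$reference_pj,
                                     gl$truth$reference_en)
    tpj <- gl$truth$regulatory[[2 * k - 1]]$interval
    ten <- gl$truth$regulatory[[2 * k]]$interval
    expect_false(is.null(cs$pj))
    expect_false(is.null(cs$en))
    expect_lte(max(cs$pj$start, tpj$start), min(cs$pj$end, tpj$end))
    expect_lte(max(cs$en$start, ten$start), min(cs$en$end, ten$end))
    expect_gt(cs$pj_core, 50L)
  }
  # no similarity above threshold -> element absent with a warning
  noisy <- seq_record("n", rand_seq(700))
  expect_warning(expect_warning(
    locate_regulatory_elements(bc$cassettes[[1]], gl$sequence, noisy, noisy),
    "no PJ"), "no En")
})

test_that("homology block painting recovers shared and private segments", {
  set.seed(121)
  p <- rand_seq(2000); q <- rand_seq(1500); r <- rand_seq(1200)
  a <- seq_record("a", paste0(p, q))
  b <- seq_record("b", paste0(p, r, q))
  two <- homology_block_painting(list(a, b))
  expect_gte(length(unique(two$block)), 2L)
  # every block present in both sequences here (r is private, no block)
  for (blk in unique(two$block)) {
    expect_setequal(two$seq_id[two$block == blk], c("a", "b"))
  }
  # identical sequences give a single full-length block
  one <- homology_block_painting(list(seq_record("x", p),
                                      seq_record("y", p)))
  expect_equal(length(unique(one$block)), 1L)
  expect_equal(one$start, c(1L, 1L))
  # three diverged cassette copies share a block covering the C gene
  gl <- generate_locus(locus_spec(3, c(1, 1, 1), c(1, 1, 1),
                                  divergence = 0.05, seed = 29L))
  seqs <- lapply(seq_along(gl$truth$cassettes), function(k) {
    cs <- gl$truth$cassettes[[k]]
    seq_record(paste0("cas", k),
               substr(gl$sequence$residues, cs$span$start, cs$span$end))
  })
  paint <- homology_block_painting(seqs, k = 12L, min_run = 100L)
  shared3 <- unique(paint$block[ave(paint$block, paint$block,
                                    FUN = length) == 3])
  expect_gte(length(shared3), 1L)
})
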