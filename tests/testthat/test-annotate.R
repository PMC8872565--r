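test_that("scan_rss scores the consensus 1.0, penalizes spacers, rejects broken cores", {
  spacer12 <- strrep("T", 12)
  hit <- scan_rss(seq_record("x", paste0("GGGG", "CACAGTG", spacer12,
                                         "ACAAAAACC", "GGGG")), 12L, 0.7)
  expect_length(hit, 1L)
  expect_equal(hit[[1]]$score, 1.0)
  expect_true(hit[[1]]$core_intact)
  expect_equal(hit[[1]]$interval$start, 5L)

  # 13-nt spacer with consensus motifs: 1 - 0.05
  hit13 <- scan_rss(seq_record("x", paste0("CACAGTG", strrep("T", 13),
                                           "ACAAAAACC")), 12L, 0.7)
  expect_equal(hit13[[1]]$score, 0.95)
  expect_equal(hit13[[1]]$spacer_length, 13L)

  # broken CAC core: rejected at the 0.7 default even with perfect nonamer
  broken <- seq_record("x", paste0("TACAGTG", spacer12, "ACAAAAACC"))
  expect_length(scan_rss(broken, 12L, 0.7), 0L)
  low <- scan_rss(broken, 12L, 0.5)
  expect_length(low, 1L)
  expect_false(low[[1]]$core_intact)
  expect_lt(low[[1]]$score, 0.7)
})

test_that("rs_signal score is 1 only for consensus motifs at nominal spacer", {
  iv <- genomic_interval("x", 1, 39)
  expect_equal(rs_signal("CACAGTG", 23L, "ACAAAAACC", iv)$score, 1.0)
  expect_lt(rs_signal("CACAGTG", 24L, "ACAAAAACC", iv)$score, 1.0)
  expect_lt(rs_signal("CACAGTA", 23L, "ACAAAAACC", iv)$score, 1.0)
  expect_lt(rs_signal("TACAGTG", 23L, "ACAAAAACC", iv)$score, 0.7)
})

test_that("scan_rss on the reverse complement finds mirror-identical sites", {
  # a forward locus and its reverse complement carry the same signals in
  # mirrored coordinates: scanning the reverse complement must recover
  # every forward site exactly under start' = n - end + 1
  gl <- generate_locus(locus_spec(2, c(1, 1), c(1, 1), seed = 21L))
  n <- nchar(gl$sequence$residues)
  for (cls in c(12L, 23L)) {
    fwd <- scan_rss(gl$sequence, cls, 0.9)
    expect_gt(length(fwd), 0L)
    # plant the same sites on the minus strand of a fresh sequence
    rcseq <- seq_record("rc", revcomp(gl$sequence$residues))
    back <- scan_rss(seq_record("rc2", revcomp(rcseq$residues)), cls, 0.9)
    expect_equal(vapply(back, function(h) h$interval$start, 1L),
                 vapply(fwd, function(h) h$interval$start, 1L))
    expect_equal(vapply(back, function(h) h$score, 1),
                 vapply(fwd, function(h) h$score, 1))
  }
  # and a signal planted on the minus strand is invisible on the plus
  # strand but found at the mirrored position after reverse complementing
  planted <- seq_record("p", paste0(strrep("G", 30),
                                    revcomp(paste0("CACAGTG", strrep("A", 23),
                                                   "ACAAAAACC")),
                                    strrep("G", 30)))
  expect_length(scan_rss(planted, 23L, 0.9), 0L)
  found <- scan_rss(seq_record("prc", revcomp(planted$residues)), 23L, 0.9)
  expect_length(found, 1L)
  expect_equal(nchar(planted$residues) - found[[1]]$interval$end + 1L, 31L)
})

test_that("find_j_genes recovers planted J genes and grades defects", {
  plan <- data.frame(gene = c("J1.1", "J2.1"),
                     kind = c("j_motif_second_position", "rs_heptamer_core"))
  gl <- generate_locus(locus_spec(2, c(1, 1), c(2, 1), defect_plan = plan,
                                  seed = 31L))
  cfg <- run_config()
  hits <- Filter(function(h) (h$core_intact && h$score >= cfg$rs_min_score) ||
                   (!h$core_intact && h$score >= 0.6),
                 scan_rss(gl$sequence, 12L, 0.6))
  js <- find_j_genes(gl$sequence, hits)
  js <- lapply(js, classify_functionality)
  truth_j <- Filter(function(g) g$gene_type == "J", gl$truth$genes)
  expect_length(js, length(truth_j))
  for (tj in truth_j) {
    match <- Filter(function(g)
      g$exons$`J-REGION`$start == tj$exons$`J-REGION`$start, js)
    expect_length(match, 1L)
    expect_equal(match[[1]]$exons$`J-REGION`$end, tj$exons$`J-REGION`$end)
    expect_equal(match[[1]]$functionality, tj$functionality, info = tj$name)
  }
  # the motif-deviant J carries a J-motif defect (the ORF grade's cause)
  j11 <- Filter(function(g) g$exons$`J-REGION`$start ==
                  truth_j$J1.1$exons$`J-REGION`$start, js)[[1]]
  expect_true("J-motif" %in% j11$defects)
  # a 12-RS with no GT in the window yields no J call
  lone <- seq_record("l", paste0("CACAGTG", strrep("A", 12), "ACAAAAACC",
                                 strrep("A", 90)))
  expect_length(find_j_genes(lone, scan_rss(lone, 12L, 0.9)), 0L)
})

test_that("find_v_genes recovers exons at exact truth coordinates", {
  gl <- generate_locus(locus_spec(2, c(2, 1), c(1, 1), seed = 41L))
  vs <- find_v_genes(gl$sequence, scan_rss(gl$sequence, 23L, 0.9))
  truth_v <- Filter(function(g) g$gene_type == "V", gl$truth$genes)
  expect_length(vs, length(truth_v))
  for (tv in truth_v) {
    match <- Filter(function(g)
      g$exons$`V-EXON`$start == tv$exons$`V-EXON`$start, vs)
    expect_length(match, 1L)
    expect_equal(match[[1]]$exons$`L-PART1`$start, tv$exons$`L-PART1`$start)
    expect_equal(match[[1]]$exons$`L-PART1`$end, tv$exons$`L-PART1`$end)
    expect_length(match[[1]]$defects, 0L)
  }
})

test_that("find_c_genes chains reference exons with the right EX2 copy number", {
  gl <- generate_locus(locus_spec(2, c(1, 1), c(1, 1),
                                  ex2_copies_per_cassette = c(1, 3),
                                  seed = 51L))
  cs <- find_c_genes(gl$sequence, gl$truth$reference_c)
  expect_length(cs, 2L)
  expect_equal(names(cs[[1]]$exons), c("EX1", "EX2A", "EX3"))
  expect_equal(names(cs[[2]]$exons), c("EX1", "EX2A", "EX2B", "EX2C", "EX3"))
  truth_c <- Filter(function(g) g$gene_type == "C", gl$truth$genes)
  for (k in 1:2) {
    expect_equal(cs[[k]]$exons$EX1$start, truth_c[[k]]$exons$EX1$start)
    expect_equal(cs[[k]]$exons$EX3$end, truth_c[[k]]$exons$EX3$end)
  }
  expect_error(find_c_genes(gl$sequence, list()), "empty")
})

test_that("a single-base EX1 deletion is detected as a frameshift", {
  plan <- data.frame(gene = "C1", kind = "frameshift")
  gl <- generate_locus(locus_spec(1, 1, 1, defect_plan = plan, seed = 61L))
  cs <- lapply(find_c_genes(gl$sequence, gl$truth$reference_c),
               classify_functionality)
  expect_length(cs, 1L)
  expect_true(any(grepl("frameshift\\(EX1\\)", cs[[1]]$defects)))
  expect_equal(cs[[1]]$functionality, "P")
})

test_that("functionality classification follows the F/ORF/P rules", {
  iv <- genomic_interval("x", 1, 300)
  clean <- gene_annotation("g", "V", list(`V-EXON` = iv))
  expect_equal(classify_functionality(clean)$functionality, "F")
  stopg <- gene_annotation("g", "V", list(`V-EXON` = iv),
                           defects = "stop(V-EXON)")
  expect_equal(classify_functionality(stopg)$functionality, "P")
  rs <- rs_signal("TACAGTG", 12L, "ACAAAAACC", iv, nominal = 12L)
  orfg <- gene_annotation("g", "J", list(`J-REGION` = iv), rs = rs)
  cls <- classify_functionality(orfg)
  expect_equal(cls$functionality, "ORF")
  expect_true("rs-core" %in% cls$defects)
})

test_that("productive cDNAs rescue frameshifted pseudogenes", {
  plan <- data.frame(gene = "V1.1", kind = "frameshift")
  spec <- locus_spec(1, 1, 1, defect_plan = plan, seed = 71L)
  gl <- generate_locus(spec)
  # the intact allele: regenerate the same locus without the defect
  intact <- generate_locus(locus_spec(1, 1, 1, seed = 71L))
  cdna <- seq_record("clone1", intact$truth$segments$V1.1$coding,
                     "productive clone")
  genes <- annotate_locus(gl$sequence, gl$truth$reference_c)
  v <- Filter(function(g) g$gene_type == "V", genes)[[1]]
  expect_equal(v$functionality, "P")
  rescued <- rescue_with_cdna(genes, list(cdna))
  v2 <- Filter(function(g) g$gene_type == "V", rescued)[[1]]
  expect_equal(v2$functionality, "F")
  expect_true(v2$rescued_by_cdna)
  # an unrelated cDNA changes nothing
  none <- rescue_with_cdna(genes, list(seq_record("x", rand_seq(300))))
  expect_equal(Filter(function(g) g$gene_type == "V",
                      none)[[1]]$functionality, "P")
  # an already-functional gene is untouched
  f_genes <- annotate_locus(intact$sequence, intact$truth$reference_c,
                            cdnas = list(cdna))
  fv <- Filter(function(g) g$gene_type == "V", f_genes)[[1]]
  expect_equal(fv$functionality, "F")
  expect_false(fv$rescued_by_cdna)
})

test_that("no two called genes of the same type overlap", {
  gl <- generate_locus(pig_locus_spec(seed = 81L))
  genes <- annotate_locus(gl$sequence, gl$truth$reference_c)
  for (ty in c("V", "J", "C")) {
    sp <- lapply(Filter(function(g) g$gene_type == ty, genes), gene_span)
    if (length(sp) < 2L) next
    sp <- sp[order(vapply(sp, function(s) s$start, 1L))]
    for (i in seq_len(length(sp) - 1L)) {
      expect_lt(sp[[i]]$end, sp[[i + 1L]]$start)
    }
  }
})
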