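#' Read a FASTA file into a list of seq_records
#'
#' Case is preserved (lowercase = masked). Record order follows the file.
#' Parsing is delegated to seqinr; records are validated against the IUPAC
#' alphabet and a parse error names the offending record.
#'
#' @param path Path to a FASTA file.
#' @return List of [seq_record()]s (empty list for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(list())
  raw <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                            whole.header = TRUE)
  lapply(seq_along(raw), function(i) {
    header <- attr(raw[[i]], "Annot")
    header <- sub("^>", "", header)
    id <- sub("\\s.*$", "", header)
    desc <- sub("^\\S+\\s*", "", header)
    res <- tryCatch(seq_record(id, as.character(raw[[i]]), desc),
                    error = function(e) {
                      stop("record ", i, " ('", id, "'): ", conditionMessage(e),
                           call. = FALSE)
                    })
    res
  })
}

#' Write seq_records to FASTA
#'
#' @param records List of `seq_record`s (or a single one).
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    s <- r$residues
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write gene annotations as GFF3
#'
#' Emits one `gene` feature per annotation plus one `exon` feature per exon,
#' with `ID`, `gene_type`, `functionality` and (when present) `cassette`
#' attributes. Coordinates are the 1-based closed intervals used throughout.
#'
#' @param annotations List of `gene_annotation`s.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, path, source = "trgkit") {
  lines <- "##gff-version 3"
  for (g in annotations) {
    sp <- gene_span(g)
    attrs <- sprintf("ID=%s;gene_type=%s;functionality=%s", g$name,
                     g$gene_type, g$functionality)
    if (!is.null(g$cassette)) attrs <- paste0(attrs, ";cassette=", g$cassette)
    if (length(g$defects)) {
      attrs <- paste0(attrs, ";defects=", paste(g$defects, collapse = ","))
    }
    lines <- c(lines, paste(sp$seq_id, source, "gene", sp$start, sp$end, ".",
                            sp$strand, ".", attrs, sep = "\t"))
    for (i in seq_along(g$exons)) {
      e <- g$exons[[i]]
      ea <- sprintf("ID=%s.exon%d;Parent=%s;exon_label=%s", g$name, i,
                    g$name, names(g$exons)[i])
      lines <- c(lines, paste(e$seq_id, source, "exon", e$start, e$end, ".",
                              e$strand, ".", ea, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a trgkit GFF3 annotation back into gene_annotations
#'
#' Inverse of [write_gff3()] for files this package wrote (gene + exon rows).
#'
#' @param path GFF3 path.
#' @return List of `gene_annotation`s.
#' @export
read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) == 0L) return(list())
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  attr_get <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
    if (length(m) == 0L) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  genes <- which(f[, 3] == "gene")
  lapply(genes, function(i) {
    id <- attr_get(f[i, 9], "ID")
    ex_rows <- which(f[, 3] == "exon" &
                       vapply(f[, 9], attr_get, "", key = "Parent") == id)
    exons <- lapply(ex_rows, function(j) {
      genomic_interval(f[j, 1], as.integer(f[j, 4]), as.integer(f[j, 5]),
                       f[j, 7])
    })
    names(exons) <- vapply(f[ex_rows, 9], attr_get, "", key = "exon_label")
    dfs <- attr_get(f[i, 9], "defects")
    gene_annotation(id, attr_get(f[i, 9], "gene_type"), exons,
                    functionality = attr_get(f[i, 9], "functionality"),
                    defects = if (is.na(dfs)) character() else
                      strsplit(dfs, ",", fixed = TRUE)[[1]])
  })
}

#' Newick round-trip helpers
#'
#' Thin wrappers over ape with a fixed branch-length precision so that a
#' write/read cycle is bit-identical for the printed digits.
#'
#' @param tree An ape `phylo`.
#' @param path File path.
#' @param digits Branch-length digits written.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`.
#' @export
write_newick <- function(tree, path, digits = 10L) {
  if (!is.null(tree$edge.length)) {
    if (any(tree$edge.length < 0)) stop("negative branch lengths")
    tree$edge.length <- round(tree$edge.length, digits)
  }
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

## ---- small sequence utilities used across modules ----

#' Reverse complement of a nucleotide string (case preserved)
#' @param s Nucleotide string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(s) {
  chartr("ACGTUacgtuRYSWKMBDHVNryswkmbdhvn",
         "TGCAAtgcaaYRSWMKVHDBNyrswmkvhdbn",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Translate a nucleotide string (frame 0, standard code)
#' @param s Nucleotide string; trailing partial codon ignored.
#' @return Amino-acid string; `*` marks stops, `X` codons with ambiguity.
#' @export
translate_nt <- function(s) {
  s <- toupper(s)
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

has_internal_stop <- function(s, skip_last = TRUE) {
  aa <- translate_nt(s)
  if (skip_last && nchar(aa) > 0L) aa <- substr(aa, 1L, nchar(aa) - 1L)
  grepl("*", aa, fixed = TRUE)
}

#' Extract the subsequence of a record over an interval
#' @param record A `seq_record`.
#' @param iv A `genomic_interval` (on the record's coordinates).
#' @return Character string.
#' @export
subseq_at <- function(record, iv) {
  substr(record$residues, iv$start, iv$end)
}
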