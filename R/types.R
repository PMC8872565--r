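#' Sequence record
#'
#' A minimal nucleotide sequence container that, unlike `DNAStringSet`,
#' preserves letter case: uppercase letters are unmasked sequence, lowercase
#' letters are masked (e.g. RepeatMasker output). Gap characters (`-`) are
#' permitted when the record is part of an alignment.
#'
#' @param id Record identifier (string).
#' @param residues Nucleotide string over the IUPAC alphabet; case preserved.
#' @param description Optional free-text description.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  if (nchar(residues) == 0L) stop("residues must be non-empty")
  bad <- gsub("[ACGTURYSWKMBDHVN.-]", "", toupper(residues))
  if (nchar(bad) > 0L) {
    stop("illegal residue character(s): ", substr(bad, 1L, 10L))
  }
  structure(list(id = id, residues = residues, description = description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d nt) %s\n", x$id, nchar(x$residues),
              x$description))
  invisible(x)
}

#' Genomic interval
#'
#' 1-based, fully closed coordinates (NCBI convention). Endpoints may be
#' given in either order, as is common for minus-strand features quoted
#' high-to-low; they are stored sorted.
#'
#' @param seq_id Sequence identifier.
#' @param start,end Interval endpoints (1-based, inclusive).
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(seq_id, start, end, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  lo <- min(start, end); hi <- max(start, end)
  if (lo < 1L) stop("coordinates are 1-based; start must be >= 1")
  structure(list(seq_id = seq_id, start = as.integer(lo),
                 end = as.integer(hi), strand = strand),
            class = "genomic_interval")
}

#' Interval length
#'
#' Length of a closed interval, `|high - low| + 1`, symmetric in the order
#' the endpoints were written.
#'
#' @param iv A `genomic_interval`, or a numeric vector of two endpoints.
#' @return Integer length.
#' @examples
#' interval_length(c(38276916, 38276319))  # 598
#' @export
interval_length <- function(iv) {
  if (inherits(iv, "genomic_interval")) {
    return(iv$end - iv$start + 1L)
  }
  stopifnot(is.numeric(iv), length(iv) == 2L)
  as.integer(abs(iv[2] - iv[1]) + 1)
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:%d-%d(%s)\n", x$seq_id, x$start, x$end, x$strand))
  invisible(x)
}

#' Gene annotation
#'
#' One V, J or C gene with its exons, optional RS element, functionality
#' verdict and defect list.
#'
#' @param name Gene name.
#' @param gene_type `"V"`, `"J"` or `"C"`.
#' @param exons Named list of `genomic_interval`s; names are exon labels
#'   (`L-PART1`, `V-EXON`, `J-REGION`, `EX1`, `EX2A`, `EX2B`, `EX2C`, `EX3`).
#' @param rs Optional `rs_signal`.
#' @param functionality `"F"`, `"ORF"` or `"P"`.
#' @param defects Character vector of defect descriptions.
#' @param rescued_by_cdna Logical; `TRUE` if a pseudogene call was rescued by
#'   a productive cDNA.
#' @param sequence Optional coding sequence (concatenated exons).
#' @return A `gene_annotation` object.
#' @export
gene_annotation <- function(name, gene_type, exons, rs = NULL,
                            functionality = "F", defects = character(),
                            rescued_by_cdna = FALSE, sequence = NULL) {
  stopifnot(gene_type %in% c("V", "J", "C"),
            functionality %in% c("F", "ORF", "P"))
  structure(list(name = name, gene_type = gene_type, exons = exons, rs = rs,
                 functionality = functionality, defects = defects,
                 rescued_by_cdna = rescued_by_cdna, sequence = sequence),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene> %s [%s] %s%s exons: %s defects: %s\n",
              x$name, x$gene_type, x$functionality,
              if (x$rescued_by_cdna) " (rescued)" else "",
              paste(names(x$exons), collapse = ","),
              if (length(x$defects)) paste(x$defects, collapse = ";") else "-"))
  invisible(x)
}

#' Genomic span of a gene (first exon start to last exon end)
#' @param gene A `gene_annotation`.
#' @return A `genomic_interval`.
#' @export
gene_span <- function(gene) {
  st <- min(vapply(gene$exons, function(e) e$start, integer(1)))
  en <- max(vapply(gene$exons, function(e) e$end, integer(1)))
  genomic_interval(gene$exons[[1]]$seq_id, st, en, gene$exons[[1]]$strand)
}

#' Flatten a list of gene annotations to a data frame
#'
#' One row per gene: name, type, span, functionality, defects, exon count.
#'
#' @param genes List of `gene_annotation`s.
#' @return A data.frame.
#' @export
annotation_table <- function(genes) {
  if (length(genes) == 0L) {
    return(data.frame(name = character(), gene_type = character(),
                      start = integer(), end = integer(),
                      functionality = character(), defects = character(),
                      n_exons = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(genes, function(g) {
    sp <- gene_span(g)
    data.frame(name = g$name, gene_type = g$gene_type,
               start = sp$start, end = sp$end,
               functionality = g$functionality,
               defects = paste(g$defects, collapse = ";"),
               n_exons = length(g$exons), stringsAsFactors = FALSE)
  }))
}

#' Run configuration with documented defaults
#'
#' Central tunable parameters. All values can be overridden via `...` and the
#' whole object round-trips through a YAML config file.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @details Defaults: `rs_min_score` 0.9 (acceptance threshold for canonical
#'   RS hits; under the 0.6/0.4 heptamer/nonamer weighting a lower cutoff
#'   admits perfect-heptamer sites with near-random nonamers at about one
#'   per 10 kb, so the pipeline requires strong support from both motifs),
#'   `rs_broken_core_min_score` 0.6 (threshold on the penalized
#'   score under which heptamers without the CAC core are still reported as
#'   ORF-grade candidates), `spacer_tolerance` 1 nt, `identity_threshold`
#'   0.75 (V subgroups), `bootstrap_replicates` 100, `calibration_ma`
#'   c(66, 68), `seed` 1.
#' @export
run_config <- function(...) {
  cfg <- list(
    rs_min_score = 0.9,
    rs_broken_core_min_score = 0.6,
    spacer_tolerance = 1L,
    identity_threshold = 0.75,
    bootstrap_replicates = 100L,
    calibration_ma = c(66, 68),
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path File path for the YAML serialization.
#' @param cfg A `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}
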