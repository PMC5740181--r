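#' Read and write pooled depth tables
#'
#' Tab-separated, one row per marker: `marker_id`, `chrom`, `pos` (bp,
#' 1-based), `Maa`, `Mab`, `Paa`, `Pab`.
#'
#' @param path File path.
#' @return `read_pool_depths`: the depth `data.frame`.
#' @export
read_pool_depths <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos", "Maa", "Mab", "Paa", "Pab")
  if (!all(need %in% names(d)))
    stop("depth file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

#' @rdname read_pool_depths
#' @param depths Depth `data.frame`.
#' @export
write_pool_depths <- function(depths, path) {
  utils::write.table(depths, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-individual genotypes and phenotypes
#'
#' Tab-separated: `individual_id`, `family`, `phenotype`, then one column
#' per marker with genotype `aa` or `ab`.
#'
#' @param pop A `bc1_population`.
#' @param path File path.
#' @export
write_individuals <- function(pop, path) {
  g <- matrix(c("aa", "ab")[pop$genotypes + 1L], nrow = nrow(pop$genotypes),
              dimnames = dimnames(pop$genotypes))
  out <- data.frame(individual_id = sprintf("I%05d", seq_along(pop$phenotypes)),
                    family = pop$family,
                    phenotype = pop$phenotypes,
                    g, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export 1-based inclusive intervals as BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention (`bed_start = start - 1`, `bed_end = end`) and
#' writes a BED6 file via rtracklayer.
#'
#' @param tab `data.frame` with `chrom`, `start`, `end` and optionally a
#'   `name` column (else `marker_id`/`gene_id`/row number).
#' @param path Output path.
#' @param score Numeric score column (default 0).
#' @export
export_bed <- function(tab, path, score = 0) {
  nm <- if ("name" %in% names(tab)) tab$name
  else if ("marker_id" %in% names(tab)) tab$marker_id
  else if ("gene_id" %in% names(tab)) tab$gene_id
  else as.character(seq_len(nrow(tab)))
  gr <- GenomicRanges::GRanges(as.character(tab$chrom),
                               IRanges::IRanges(tab$start, tab$end),
                               name = nm, score = rep_len(score, nrow(tab)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene annotation from GFF3, BED or TSV
#'
#' GFF3/BED files are parsed with rtracklayer (BED start converted back to
#' 1-based); for GFF3, `gene`-type records are used when present. A TSV is
#' expected to already carry `gene_id`, `chrom`, `start`, `end`.
#'
#' @param path Annotation file (`.gff`, `.gff3`, `.bed`, else TSV).
#' @return `data.frame`: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3", "bed")) {
    gr <- rtracklayer::import(path)
    if (ext != "bed" && "type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    id <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID
    else if ("name" %in% names(S4Vectors::mcols(gr))) gr$name
    else as.character(seq_along(gr))
    data.frame(gene_id = as.character(id),
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
}

#' Read per-gene, per-tissue EST counts
#'
#' Long TSV: `gene_id`, `tissue`, `count`.
#'
#' @param path File path.
#' @return The counts `data.frame`.
#' @export
read_est_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tissue", "count") %in% names(d)))
    stop("EST file must have columns gene_id, tissue, count", call. = FALSE)
  d
}
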