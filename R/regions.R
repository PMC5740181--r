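#' Define candidate linkage regions around positive markers
#'
#' Each confirmed marker anchors a window `[pos - half_width_bp,
#' pos + half_width_bp]` (1-based, inclusive) — by default +/-150 kb, i.e.
#' a 300 kb region, roughly one centimorgan of physical distance in the
#' silkworm genome. Windows are clipped at position 1 and, when chromosome
#' lengths are supplied, at the chromosome end; overlapping or directly
#' adjacent windows on a chromosome are merged and the merged region
#' records every contributing marker.
#'
#' @param positives `data.frame` with `marker_id`, `chrom`, `pos`.
#' @param half_width_bp Half-width in bp (> 0; default 150000).
#' @param chrom_lengths Optional named vector of chromosome lengths (bp);
#'   unknown chromosomes are clipped only at 1 with a warning.
#' @return `data.frame`: `chrom`, `start`, `end` (1-based inclusive),
#'   `width`, `source_markers` (comma-separated ids), sorted.
#' @export
define_regions <- function(positives, half_width_bp = 150000,
                           chrom_lengths = NULL) {
  if (half_width_bp <= 0) stop("half_width_bp must be > 0", call. = FALSE)
  positives <- as.data.frame(positives)
  stopifnot(all(c("marker_id", "chrom", "pos") %in% names(positives)))
  if (!nrow(positives))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), width = integer(),
                      source_markers = character()))
  chrom <- as.character(positives$chrom)
  start <- pmax(1, positives$pos - half_width_bp)
  end <- positives$pos + half_width_bp
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[chrom]
    known <- !is.na(len)
    end[known] <- pmin(end[known], len[known])
    if (any(!known))
      warning("unknown chromosome length for: ",
              paste(unique(chrom[!known]), collapse = ", "),
              "; clipped at 1 only")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               marker_id = positives$marker_id)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  src <- tapply(gr$marker_id[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits),
                function(x) paste(x, collapse = ","))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    width = GenomicRanges::width(merged),
    source_markers = as.character(src[as.character(seq_along(merged))]),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes overlapping candidate regions
#'
#' Returns annotation genes overlapping any region by at least 1 bp
#' (any-overlap rule, not containment — boundary genes are candidates
#' too), deduplicated by `gene_id`.
#'
#' @param regions Region table as from [define_regions()].
#' @param annotation Gene `data.frame`: `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), optional `strand` and extra columns.
#'   Rows with a malformed interval (`NA` or `end < start`) are skipped
#'   and counted in a warning.
#' @return The overlapping annotation rows, deduplicated.
#' @export
genes_in_regions <- function(regions, annotation) {
  annotation <- as.data.frame(annotation)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(annotation)))
  bad <- is.na(annotation$start) | is.na(annotation$end) |
    annotation$end < annotation$start
  if (any(bad)) {
    warning(sum(bad), " malformed annotation record(s) skipped")
    annotation <- annotation[!bad, , drop = FALSE]
  }
  if (!nrow(regions) || !nrow(annotation))
    return(annotation[0, , drop = FALSE])
  reg <- GenomicRanges::GRanges(as.character(regions$chrom),
                                IRanges::IRanges(regions$start, regions$end))
  gen <- GenomicRanges::GRanges(as.character(annotation$chrom),
                                IRanges::IRanges(annotation$start, annotation$end))
  hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(gen, reg)))
  out <- annotation[sort(hit), , drop = FALSE]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen candidate genes by EST evidence
#'
#' Retains genes with an EST count strictly greater than zero in EVERY
#' required tissue — the expressed-in-silk-gland-and-embryo candidate
#' filter. A gene missing a tissue entirely counts as zero there. An empty
#' `required_tissues` set is a vacuous filter (all genes retained).
#'
#' @param genes Gene table with `gene_id` (e.g. from [genes_in_regions()]).
#' @param est_counts Long `data.frame`: `gene_id`, `tissue`, `count`.
#' @param required_tissues Character vector of tissue names; default the
#'   5th-instar silk gland and embryo.
#' @return List: `candidates` (the retained gene rows), `counts` (wide
#'   per-gene x tissue count matrix for all screened genes, for
#'   heatmap-style summaries).
#' @export
est_screen <- function(genes, est_counts,
                       required_tissues = c("silk_gland_5th_instar", "embryo")) {
  genes <- as.data.frame(genes)
  stopifnot("gene_id" %in% names(genes))
  est_counts <- as.data.frame(est_counts)
  if (any(est_counts$count < 0)) stop("EST counts must be >= 0", call. = FALSE)
  tissues <- union(required_tissues, unique(est_counts$tissue))
  wide <- matrix(0, nrow(genes), length(tissues),
                 dimnames = list(genes$gene_id, tissues))
  rel <- est_counts[est_counts$gene_id %in% genes$gene_id, , drop = FALSE]
  if (nrow(rel))
    wide[cbind(match(rel$gene_id, genes$gene_id),
               match(rel$tissue, tissues))] <- rel$count
  keep <- if (length(required_tissues))
    rowSums(wide[, required_tissues, drop = FALSE] > 0) == length(required_tissues)
  else rep(TRUE, nrow(genes))
  miss <- setdiff(required_tissues, unique(est_counts$tissue))
  if (length(miss))
    message("tissue(s) absent from EST table treated as count 0: ",
            paste(miss, collapse = ", "))
  candidates <- genes[keep, , drop = FALSE]
  rownames(candidates) <- NULL
  list(candidates = candidates, counts = wide)
}
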