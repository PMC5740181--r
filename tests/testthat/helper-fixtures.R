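# Small shared fixtures, built in code.

# A tiny hand-checkable depth table.
tiny_depths <- function() {
  data.frame(
    marker_id = c("m1", "m2", "m3", "m4"),
    chrom = c(1, 1, 2, 2),
    pos = c(100L, 200L, 100L, 200L),
    Maa = c(50, 100, 60, 10),
    Mab = c(60, 0, 60, 10),
    Paa = c(50, 50, 60, 10),
    Pab = c(60, 75, 60, 10),
    stringsAsFactors = FALSE
  )
}

# Compact design for fast simulation tests. Enough markers that one
# linked chromosome does not dominate the scan-wide spread, enough
# individuals that pool composition noise stays small.
small_design <- function(seed = 1L, qtl = NULL, ...) {
  if (is.null(qtl))
    qtl <- data.frame(chrom = integer(), pos_cm = numeric(), effect = numeric())
  cross_design(n_families = 4, family_size_range = c(90, 110),
               n_chromosomes = 8, chrom_length_cm = 50,
               marker_spacing_cm = 5, qtl = qtl, seed = seed, ...)
}

# Brute-force all-pairs interval overlap (1-based inclusive): the oracle
# for genes_in_regions.
brute_overlap <- function(regions, genes) {
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    any(regions$chrom == genes$chrom[i] &
          regions$start <= genes$end[i] &
          regions$end >= genes$start[i])
  }, logical(1))
  out <- genes[hit, , drop = FALSE]
  out[!duplicated(out$gene_id), , drop = FALSE]
}

# Brute-force run scanner: the oracle for call_clusters. Walks every
# position-sorted chromosome and grows runs gap by gap.
brute_clusters <- function(degs, threshold_bp) {
  res <- list()
  for (ch in unique(degs$chrom)) {
    pos <- sort(degs$pos[degs$chrom == ch])
    if (length(pos) < 3) next
    i <- 1
    while (i < length(pos)) {
      j <- i
      while (j < length(pos) && (pos[j + 1] - pos[j]) < threshold_bp) j <- j + 1
      if (j - i + 1 >= 3)
        res[[length(res) + 1]] <- data.frame(chrom = ch, start = pos[i],
                                             end = pos[j], n_genes = j - i + 1)
      i <- j + 1
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_genes = integer()))
  do.call(rbind, res)
}
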