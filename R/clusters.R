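#' Adjacent-gene intervals per chromosome
#'
#' Sorts genes by position within each chromosome and returns the
#' successive position differences. Intervals never cross a chromosome
#' boundary; duplicate positions yield zero intervals (allowed, counted in
#' a message).
#'
#' @param degs `data.frame` with `chrom` and `pos` (one row per gene).
#' @return `data.frame`: `chrom`, `left_gene`, `right_gene` (row labels or
#'   `gene_id` when present), `interval` (bp).
#' @export
adjacent_intervals <- function(degs) {
  degs <- as.data.frame(degs)
  stopifnot(all(c("chrom", "pos") %in% names(degs)))
  ids <- if ("gene_id" %in% names(degs)) degs$gene_id else as.character(seq_len(nrow(degs)))
  out <- lapply(split(seq_len(nrow(degs)), degs$chrom), function(ix) {
    if (length(ix) < 2) return(NULL)
    o <- ix[order(degs$pos[ix])]
    data.frame(chrom = degs$chrom[o[1]],
               left_gene = ids[o[-length(o)]],
               right_gene = ids[o[-1]],
               interval = diff(degs$pos[o]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), left_gene = character(),
                      right_gene = character(), interval = numeric())
  nzero <- sum(out$interval == 0)
  if (nzero) message(nzero, " zero interval(s) from duplicate positions")
  rownames(out) <- NULL
  out
}

#' Expected adjacent-gene interval under uniform placement
#'
#' The genome-wide expectation: total genome size divided by the number of
#' genes.
#'
#' @param genome_size Total genome size, bp.
#' @param n_genes Number of genes (>= 1).
#' @return Expected interval in bp.
#' @export
expected_interval <- function(genome_size, n_genes) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  genome_size / n_genes
}

#' Summarise observed-vs-expected interval ratios
#'
#' For each adjacent pair, the ratio of its observed interval to the
#' expected interval. Reports the fraction of pairs strictly below 1
#' (closer than expected) and strictly below 0.1 (the tight-clustering
#' fraction), plus a histogram over configurable ratio bins. Under uniform
#' gene placement, spacings are approximately exponential with mean equal
#' to the expectation, so the below-0.1 fraction tends to
#' `1 - exp(-0.1) ~ 0.095`.
#'
#' @param intervals Numeric vector of intervals (bp), or the `data.frame`
#'   from [adjacent_intervals()].
#' @param expected Expected interval (bp, > 0).
#' @param breaks Ratio bin edges for the histogram.
#' @return List: `n_pairs`, `fraction_below_1`, `fraction_below_0.1`,
#'   `histogram` (counts per bin), `breaks`.
#' @export
ratio_summary <- function(intervals, expected,
                          breaks = c(0, 0.1, 0.25, 0.5, 1, 2, 5, Inf)) {
  if (expected <= 0) stop("expected must be > 0", call. = FALSE)
  if (is.data.frame(intervals)) intervals <- intervals$interval
  ratio <- intervals / expected
  h <- table(cut(ratio, breaks, right = FALSE, include.lowest = TRUE))
  list(n_pairs = length(ratio),
       fraction_below_1 = mean(ratio < 1),
       fraction_below_0.1 = mean(ratio < 0.1),
       histogram = h,
       breaks = breaks)
}

#' Call gene clusters from positions
#'
#' A gene cluster is a maximal run of three or more consecutive genes (in
#' position order, per chromosome) whose every adjacent interval is
#' strictly below the threshold. The threshold is either an absolute
#' distance in bp (`"absolute"`, default 30 kb — about the average gene
#' interval genome-wide) or a fraction of the expected interval
#' (`"fraction"`, e.g. 0.1). Both conventions are in circulation for the
#' same analysis; [cluster_report()] runs both side by side and flags
#' disagreement.
#'
#' @param degs `data.frame` with `chrom`, `pos` (and optional `gene_id`).
#' @param threshold_mode `"absolute"` or `"fraction"`.
#' @param threshold_value Threshold in bp (absolute) or as a fraction of
#'   the expected interval; must be > 0.
#' @param genome_size Required in fraction mode (for the expectation);
#'   taken from `attr(degs, "genome_size")` when present.
#' @return `data.frame` of cluster calls: `chrom`, `start`, `end`, `span`,
#'   `n_genes`, `gene_ids` (comma-separated, in position order), with the
#'   effective bp `threshold` as an attribute.
#' @export
call_clusters <- function(degs, threshold_mode = c("absolute", "fraction"),
                          threshold_value = 30000,
                          genome_size = attr(degs, "genome_size")) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_value <= 0) stop("threshold_value must be > 0", call. = FALSE)
  degs <- as.data.frame(degs)
  ids <- if ("gene_id" %in% names(degs)) degs$gene_id else as.character(seq_len(nrow(degs)))
  thr <- if (threshold_mode == "absolute") threshold_value else {
    if (is.null(genome_size))
      stop("fraction mode needs genome_size", call. = FALSE)
    threshold_value * expected_interval(genome_size, nrow(degs))
  }
  calls <- lapply(split(seq_len(nrow(degs)), degs$chrom), function(ix) {
    o <- ix[order(degs$pos[ix])]
    if (length(o) < 3) return(NULL)
    pos <- degs$pos[o]
    ok <- diff(pos) < thr              # strict: interval == threshold breaks
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values & r$lengths >= 2)   # >=2 qualifying gaps = >=3 genes
    if (!length(runs)) return(NULL)
    do.call(rbind, lapply(runs, function(k) {
      gi <- starts[k]:(ends[k] + 1)            # gap i joins genes i, i+1
      data.frame(chrom = degs$chrom[o[1]],
                 start = pos[gi[1]], end = pos[gi[length(gi)]],
                 span = pos[gi[length(gi)]] - pos[gi[1]],
                 n_genes = length(gi),
                 gene_ids = paste(ids[o[gi]], collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      span = numeric(), n_genes = integer(), gene_ids = character())
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold_bp") <- thr
  attr(out, "threshold_mode") <- threshold_mode
  out
}

#' Side-by-side cluster report under both threshold conventions
#'
#' Runs [call_clusters()] in absolute mode (default 30 kb) and in fraction
#' mode (default 10% of the expected interval), together with the ratio
#' summary, and flags when the two conventions disagree on the number of
#' clusters.
#'
#' @param degs Gene position table (with `genome_size` attribute or
#'   explicit argument).
#' @param absolute_bp Absolute threshold, bp.
#' @param fraction Fractional threshold.
#' @param genome_size Genome size, bp.
#' @return List: `ratio` (from [ratio_summary()]), `absolute`, `fraction`
#'   (cluster tables), `size_histogram` (cluster sizes, absolute mode),
#'   `agree` (logical), `expected` (bp).
#' @export
cluster_report <- function(degs, absolute_bp = 30000, fraction = 0.1,
                           genome_size = attr(degs, "genome_size")) {
  if (is.null(genome_size)) stop("genome_size required", call. = FALSE)
  ints <- adjacent_intervals(degs)
  expd <- expected_interval(genome_size, nrow(degs))
  abs_calls <- call_clusters(degs, "absolute", absolute_bp)
  frac_calls <- call_clusters(degs, "fraction", fraction,
                              genome_size = genome_size)
  list(ratio = ratio_summary(ints$interval, expd),
       absolute = abs_calls,
       fraction = frac_calls,
       size_histogram = table(abs_calls$n_genes),
       per_chrom = table(abs_calls$chrom),
       agree = nrow(abs_calls) == nrow(frac_calls),
       expected = expd)
}

#' Permutation null test for gene clustering
#'
#' Re-places the observed per-chromosome gene counts uniformly at random
#' `n_permutations` times and compares (a) the number of clusters called
#' and (b) the fraction of adjacent intervals below the expected interval
#' against the observed values. Empirical p-values use the +1 correction.
#'
#' @param degs Gene position table with `chrom`, `pos`; chromosome lengths
#'   from `attr(degs, "chrom_lengths")` or `chrom_lengths`.
#' @param n_permutations Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param threshold_mode,threshold_value Passed to [call_clusters()].
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @return List: `p_cluster_count`, `p_fraction_below_1`,
#'   `observed_clusters`, `observed_fraction_below_1`, `null_clusters`
#'   (vector of permuted counts).
#' @export
cluster_null_test <- function(degs, n_permutations = 1000, seed = 1L,
                              threshold_mode = "absolute",
                              threshold_value = 30000,
                              chrom_lengths = attr(degs, "chrom_lengths")) {
  if (n_permutations < 100) stop("n_permutations must be >= 100", call. = FALSE)
  if (is.null(chrom_lengths)) stop("chrom_lengths required", call. = FALSE)
  genome_size <- sum(chrom_lengths)
  expd <- expected_interval(genome_size, nrow(degs))
  obs_calls <- nrow(call_clusters(degs, threshold_mode, threshold_value,
                                  genome_size = genome_size))
  obs_frac <- ratio_summary(adjacent_intervals(degs)$interval,
                            expd)$fraction_below_1
  counts <- table(factor(degs$chrom, levels = names(chrom_lengths)))
  set.seed(seed)
  null_calls <- integer(n_permutations)
  null_frac <- numeric(n_permutations)
  for (i in seq_len(n_permutations)) {
    sim <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      k <- counts[[ch]]
      if (!k) return(NULL)
      data.frame(chrom = ch,
                 pos = floor(stats::runif(k) * chrom_lengths[[ch]]) + 1,
                 stringsAsFactors = FALSE)
    }))
    null_calls[i] <- nrow(call_clusters(sim, threshold_mode, threshold_value,
                                        genome_size = genome_size))
    null_frac[i] <- ratio_summary(adjacent_intervals(sim)$interval,
                                  expd)$fraction_below_1
  }
  list(p_cluster_count = (sum(null_calls >= obs_calls) + 1) / (n_permutations + 1),
       p_fraction_below_1 = (sum(null_frac >= obs_frac) + 1) / (n_permutations + 1),
       observed_clusters = obs_calls,
       observed_fraction_below_1 = obs_frac,
       null_clusters = null_calls)
}
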