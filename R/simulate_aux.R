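#' Simulate gene (DEG) genomic positions
#'
#' Places `n_genes` gene midpoints on a genome, either uniformly at random
#' (the null for cluster statistics: adjacent spacings then approximate an
#' exponential law with mean `genome_size / n_genes`) or with a stated
#' fraction of genes laid down in tight runs, emulating clustered
#' differentially expressed genes.
#'
#' @param n_genes Number of genes (>= 2).
#' @param genome_size Total genome size in bp. When `chrom_lengths` is
#'   given it must equal their sum.
#' @param mode `"uniform"` or `"clustered"`.
#' @param cluster_fraction Fraction of genes placed in runs (clustered mode).
#' @param cluster_size Genes per run.
#' @param cluster_gap Within-run gap between consecutive genes, bp.
#' @param chrom_lengths Optional named vector of chromosome lengths (bp);
#'   default one chromosome spanning the genome.
#' @param min_gap Minimum feasible spacing used only for the capacity check.
#' @param seed Integer seed.
#' @return A `data.frame` (`gene_id`, `chrom`, `pos`) with attributes
#'   `genome_size` and `chrom_lengths`.
#' @export
simulate_deg_positions <- function(n_genes, genome_size,
                                   mode = c("uniform", "clustered"),
                                   cluster_fraction = 0.5,
                                   cluster_size = 5L,
                                   cluster_gap = 1000,
                                   chrom_lengths = NULL,
                                   min_gap = 1,
                                   seed = 1L) {
  mode <- match.arg(mode)
  if (n_genes < 2) stop("n_genes must be >= 2", call. = FALSE)
  if (is.null(chrom_lengths)) chrom_lengths <- c(chr1 = genome_size)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (abs(sum(chrom_lengths) - genome_size) > 0.5)
    stop("chrom_lengths must sum to genome_size", call. = FALSE)
  if (genome_size < n_genes * min_gap)
    stop("genome_size too small to host ", n_genes, " genes at spacing ",
         min_gap, call. = FALSE)
  set.seed(seed)

  place_uniform <- function(k) {
    chrom <- sample(names(chrom_lengths), k, replace = TRUE,
                    prob = chrom_lengths / sum(chrom_lengths))
    pos <- floor(stats::runif(k) * chrom_lengths[chrom]) + 1
    data.frame(chrom = chrom, pos = as.numeric(pos), stringsAsFactors = FALSE)
  }

  if (mode == "uniform") {
    out <- place_uniform(n_genes)
  } else {
    n_clustered <- round(cluster_fraction * n_genes)
    n_runs <- ceiling(n_clustered / cluster_size)
    runs <- vector("list", n_runs)
    left <- n_clustered
    for (i in seq_len(n_runs)) {
      k <- min(cluster_size, left); left <- left - k
      span <- (k - 1) * cluster_gap
      ch <- sample(names(chrom_lengths), 1, prob = chrom_lengths / sum(chrom_lengths))
      anchor <- floor(stats::runif(1) * max(1, chrom_lengths[ch] - span)) + 1
      runs[[i]] <- data.frame(chrom = ch,
                              pos = anchor + cluster_gap * (seq_len(k) - 1),
                              stringsAsFactors = FALSE)
    }
    out <- rbind(do.call(rbind, runs), place_uniform(n_genes - n_clustered))
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out <- data.frame(gene_id = sprintf("G%05d", seq_len(nrow(out))),
                    chrom = out$chrom, pos = out$pos,
                    stringsAsFactors = FALSE)
  attr(out, "genome_size") <- genome_size
  attr(out, "chrom_lengths") <- chrom_lengths
  rownames(out) <- NULL
  out
}

#' Simulate expression, phenotype and gland-volume tables
#'
#' Generates the three small tables the expression-association stage
#' consumes: relative expression per strain, cocoon shell weight (CSW) per
#' strain, relative expression per day of the 5th instar, and silk-gland
#' volume per day. Under `association = "positive"` strain expression is an
#' increasing (noisy) function of CSW and daily expression tracks the daily
#' gland-volume increment; under `"none"` expression is independent noise.
#'
#' Gland volume follows a logistic-style growth curve over the instar, so
#' increments rise to a mid-instar peak and fall towards wandering — the
#' shape against which a growth-tracking expression profile is scored.
#'
#' @param n_strains Number of strains (>= 4); default 12.
#' @param n_days Number of 5th-instar days (>= 3); default 7.
#' @param association `"positive"` or `"none"`.
#' @param noise_sd Relative noise level on expression (0 = noise-free).
#' @param seed Integer seed.
#' @return A list of `data.frame`s: `expression_strain` (`strain`, `expr`),
#'   `csw` (`strain`, `csw` in grams), `expression_day` (`day`, `expr`),
#'   `gland_volume` (`day`, `volume`).
#' @export
simulate_expression_tables <- function(n_strains = 12L, n_days = 7L,
                                       association = c("positive", "none"),
                                       noise_sd = 0.1, seed = 1L) {
  association <- match.arg(association)
  if (n_strains < 4) stop("n_strains must be >= 4", call. = FALSE)
  if (n_days < 3) stop("n_days must be >= 3", call. = FALSE)
  set.seed(seed)

  strains <- sprintf("S%02d", seq_len(n_strains))
  csw <- sort(stats::runif(n_strains, 0.10, 0.50))       # grams, strain spread
  days <- seq_len(n_days)
  volume <- 100 / (1 + exp(-1.2 * (days - n_days / 2)))  # logistic growth
  incr <- c(NA, diff(volume))

  if (association == "positive") {
    expr_s <- 1 + 4 * (csw - min(csw)) / diff(range(csw)) +
      stats::rnorm(n_strains, sd = noise_sd)
    base <- incr[-1] / max(incr[-1])
    expr_d <- c(base[1], base) + stats::rnorm(n_days, sd = noise_sd)
  } else {
    expr_s <- 1 + stats::rnorm(n_strains, sd = max(noise_sd, 1e-8))
    expr_d <- 1 + stats::rnorm(n_days, sd = max(noise_sd, 1e-8))
  }
  list(
    expression_strain = data.frame(strain = strains, expr = pmax(expr_s, 0)),
    csw = data.frame(strain = strains, csw = csw),
    expression_day = data.frame(day = days, expr = pmax(expr_d, 0)),
    gland_volume = data.frame(day = days, volume = volume)
  )
}
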