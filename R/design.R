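#' Describe a BC1 pooled-sequencing cross design
#'
#' A `cross_design` collects everything [simulate_bc1()] needs to generate a
#' backcross (BC1) mapping population of the kind used for extreme-phenotype
#' pool sequencing: the family structure, the marker map, the planted QTLs
#' and the phenotype model. Defaults mirror a silkworm cocoon-shell-weight
#' mapping design: 7 single-pair families ("moth areas") of 127-174 male
#' offspring, roughly 10% of each family selected into each phenotype tail,
#' and pooled sequencing at an average marker depth of 245x.
#'
#' The genetic map is a set of equally sized chromosomes carrying markers at
#' a fixed centimorgan spacing. Physical coordinates are derived at 300 kb
#' per cM, the conventional silkworm genome-wide average.
#'
#' @param n_families Number of independent families (single-pair matings).
#' @param family_size_range Length-2 integer vector; each family size is
#'   drawn uniformly from this inclusive range.
#' @param pool_fraction Fraction of each family selected into each phenotype
#'   tail (low and high pools). Must lie in (0, 0.5].
#' @param qtl `data.frame` with columns `chrom` (integer chromosome index),
#'   `pos_cm` (map position, cM) and `effect` (phenotype shift, in grams,
#'   added when the QTL genotype is heterozygous `ab`). Use a zero-row frame
#'   or `effect = 0` for a null design.
#' @param baseline_csw Baseline phenotype mean (grams) for the recurrent
#'   homozygous background.
#' @param phenotype_noise_sd Standard deviation (grams) of the Gaussian
#'   residual added to each individual's phenotype.
#' @param n_chromosomes,chrom_length_cm,marker_spacing_cm Map geometry:
#'   number of chromosomes, length of each (cM), and marker spacing (cM).
#'   Markers sit at 0, spacing, 2*spacing, ... along each chromosome.
#' @param mean_depth Average pooled sequencing depth per marker per pool.
#' @param bp_per_cm Physical scale used to assign base-pair coordinates.
#' @param seed Master seed; all downstream stages derive child seeds from it
#'   deterministically.
#'
#' @return An object of class `cross_design` (a validated list).
#' @seealso [simulate_bc1()], [build_pools()], [pooled_depths()]
#' @examples
#' d <- cross_design(qtl = data.frame(chrom = 11, pos_cm = 25, effect = 0.1))
#' d
#' @export
cross_design <- function(n_families = 7L,
                         family_size_range = c(127L, 174L),
                         pool_fraction = 0.10,
                         qtl = data.frame(chrom = integer(), pos_cm = numeric(),
                                          effect = numeric()),
                         baseline_csw = 0.35,
                         phenotype_noise_sd = 0.05,
                         n_chromosomes = 28L,
                         chrom_length_cm = 50,
                         marker_spacing_cm = 5,
                         mean_depth = 245,
                         bp_per_cm = 300000,
                         seed = 1L) {
  stopifnot(length(family_size_range) == 2L,
            family_size_range[1] >= 1, family_size_range[1] <= family_size_range[2])
  if (!(pool_fraction > 0 && pool_fraction <= 0.5))
    stop("pool_fraction must lie in (0, 0.5]", call. = FALSE)
  if (mean_depth <= 0) stop("mean_depth must be > 0", call. = FALSE)
  if (n_families < 1) stop("need at least one family", call. = FALSE)
  if (marker_spacing_cm <= 0 || chrom_length_cm <= 0 || n_chromosomes < 1)
    stop("map geometry must be positive", call. = FALSE)
  qtl <- as.data.frame(qtl)
  if (nrow(qtl)) {
    stopifnot(all(c("chrom", "pos_cm", "effect") %in% names(qtl)))
    bad <- qtl$chrom < 1 | qtl$chrom > n_chromosomes |
      qtl$pos_cm < 0 | qtl$pos_cm > chrom_length_cm
    if (any(bad))
      stop("QTL outside the simulated map: chrom ", qtl$chrom[bad][1],
           " pos ", qtl$pos_cm[bad][1], " cM (map has ", n_chromosomes,
           " chromosomes of ", chrom_length_cm, " cM)", call. = FALSE)
  }
  structure(list(
    n_families = as.integer(n_families),
    family_size_range = as.integer(family_size_range),
    pool_fraction = pool_fraction,
    qtl = qtl,
    baseline_csw = baseline_csw,
    phenotype_noise_sd = phenotype_noise_sd,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_cm = chrom_length_cm,
    marker_spacing_cm = marker_spacing_cm,
    mean_depth = mean_depth,
    bp_per_cm = bp_per_cm,
    seed = as.integer(seed)
  ), class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat("BC1 pooled-sequencing cross design\n")
  cat(sprintf("  families: %d, sizes %d-%d, pool fraction %.3g per tail\n",
              x$n_families, x$family_size_range[1], x$family_size_range[2],
              x$pool_fraction))
  cat(sprintf("  map: %d chromosomes x %g cM, markers every %g cM (%d markers)\n",
              x$n_chromosomes, x$chrom_length_cm, x$marker_spacing_cm,
              x$n_chromosomes * (floor(x$chrom_length_cm / x$marker_spacing_cm) + 1L)))
  cat(sprintf("  phenotype: baseline %g g, noise sd %g g; mean depth %gx\n",
              x$baseline_csw, x$phenotype_noise_sd, x$mean_depth))
  if (nrow(x$qtl)) {
    cat("  QTLs:\n")
    for (i in seq_len(nrow(x$qtl)))
      cat(sprintf("    chr%d @ %g cM, effect %+g g\n",
                  x$qtl$chrom[i], x$qtl$pos_cm[i], x$qtl$effect[i]))
  } else cat("  QTLs: none (null design)\n")
  invisible(x)
}

# Deterministic child seed from a master seed; keeps values in 32-bit range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(offset)) %% 2147483647)
}

# Haldane map function: recombination fraction for a distance in cM.
haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))
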