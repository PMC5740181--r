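#' Simulate a BC1 mapping population
#'
#' Generates individual marker genotypes and phenotypes for a backcross
#' population of the form P1 x (P1 x P2), in which every individual is
#' either homozygous for the recurrent-parent allele (`aa`) or heterozygous
#' (`ab`) at each locus. Gametes are produced chromosome by chromosome as a
#' Markov chain along the marker map with Haldane recombination fractions
#' between adjacent loci, so unlinked markers segregate 1:1 and linked
#' markers show map-consistent association. The phenotype is
#' `baseline + sum(effect * [QTL genotype == ab]) + Gaussian noise`.
#'
#' QTLs may sit between markers: they are simulated as hidden loci inserted
#' into the chain and are not reported as markers.
#'
#' @param design A [cross_design()].
#' @return An object of class `bc1_population`: a list with
#'   `genotypes` (individuals x markers integer matrix, 0 = `aa`,
#'   1 = `ab`), `phenotypes` (grams), `family` (integer family id per
#'   individual), `map` (`data.frame`: `marker_id`, `chrom`, `pos_cm`,
#'   `pos_bp`), `qtl_genotypes` (individuals x QTL matrix) and `truth`
#'   (the design's QTL table).
#' @examples
#' pop <- simulate_bc1(cross_design(seed = 42))
#' table(pop$genotypes[, 1]) # ~1:1 aa:ab
#' @export
simulate_bc1 <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  set.seed(child_seed(design$seed, 1L))

  size_choices <- design$family_size_range[1]:design$family_size_range[2]
  sizes <- size_choices[sample.int(length(size_choices), design$n_families,
                                   replace = TRUE)]
  n <- sum(sizes)
  family <- rep(seq_len(design$n_families), times = sizes)

  # loci per chromosome: markers at 0, s, 2s, ... plus hidden QTL positions
  marker_pos <- seq(0, design$chrom_length_cm, by = design$marker_spacing_cm)
  geno_cols <- vector("list", design$n_chromosomes)
  qtl_geno <- matrix(0L, n, nrow(design$qtl))
  map_list <- vector("list", design$n_chromosomes)

  for (ch in seq_len(design$n_chromosomes)) {
    qtl_here <- which(design$qtl$chrom == ch)
    pos <- sort(unique(c(marker_pos, design$qtl$pos_cm[qtl_here])))
    m <- length(pos)
    g <- matrix(0L, n, m)
    g[, 1] <- as.integer(stats::runif(n) < 0.5)
    if (m > 1) {
      r <- haldane_r(diff(pos))
      for (j in 2:m) {
        swap <- stats::runif(n) < r[j - 1]
        g[, j] <- ifelse(swap, 1L - g[, j - 1], g[, j - 1])
      }
    }
    is_marker <- pos %in% marker_pos
    geno_cols[[ch]] <- g[, is_marker, drop = FALSE]
    map_list[[ch]] <- data.frame(
      chrom = ch, pos_cm = pos[is_marker],
      stringsAsFactors = FALSE)
    for (q in qtl_here) {
      j <- match(design$qtl$pos_cm[q], pos)
      qtl_geno[, q] <- g[, j]
    }
  }

  genotypes <- do.call(cbind, geno_cols)
  map <- do.call(rbind, map_list)
  map$marker_id <- sprintf("M%02d_%03d", map$chrom, round(map$pos_cm))
  map$pos_bp <- as.integer(round(map$pos_cm * design$bp_per_cm)) + 1L
  map <- map[, c("marker_id", "chrom", "pos_cm", "pos_bp")]
  colnames(genotypes) <- map$marker_id

  effects <- if (nrow(design$qtl)) as.numeric(qtl_geno %*% design$qtl$effect) else 0
  phenotypes <- design$baseline_csw + effects +
    stats::rnorm(n, sd = design$phenotype_noise_sd)

  structure(list(
    genotypes = genotypes,
    phenotypes = phenotypes,
    family = family,
    map = map,
    qtl_genotypes = qtl_geno,
    truth = design$qtl,
    design = design
  ), class = "bc1_population")
}

#' @export
print.bc1_population <- function(x, ...) {
  cat(sprintf("BC1 population: %d individuals in %d families, %d markers on %d chromosomes\n",
              length(x$phenotypes), length(unique(x$family)),
              ncol(x$genotypes), length(unique(x$map$chrom))))
  cat(sprintf("  phenotype: mean %.4g g, sd %.3g g; %d planted QTL(s)\n",
              mean(x$phenotypes), stats::sd(x$phenotypes), nrow(x$truth)))
  invisible(x)
}

#' Select extreme-phenotype pools within each family
#'
#' Within every family, individuals are ordered by (phenotype, index) — a
#' stable order — and the first `floor(fraction * n)` (at least 1) go to the
#' low pool, the last as many to the high pool. Selecting per family rather
#' than over the pooled population removes between-family phenotype shifts
#' from the selection, which is the point of family-wise extreme selection.
#' At `pool_fraction = 0.5` the two pools partition each family; with
#' all-equal phenotypes selection falls back to index order.
#'
#' @param pop A `bc1_population`.
#' @param pool_fraction Fraction per tail, in (0, 0.5]. Defaults to the
#'   design's value.
#' @return A list with integer index vectors `low_ids` and `high_ids`
#'   (positions into the population), plus `per_family` sizes.
#' @export
build_pools <- function(pop, pool_fraction = pop$design$pool_fraction) {
  stopifnot(inherits(pop, "bc1_population"))
  if (!(pool_fraction > 0 && pool_fraction <= 0.5))
    stop("pool_fraction must lie in (0, 0.5]", call. = FALSE)
  fams <- unique(pop$family)
  low <- integer(0); high <- integer(0); per <- integer(0)
  for (f in fams) {
    idx <- which(pop$family == f)
    if (!length(idx)) stop("empty family: ", f, call. = FALSE)
    k <- max(1L, floor(pool_fraction * length(idx)))
    ord <- idx[order(pop$phenotypes[idx], idx)]
    low <- c(low, utils::head(ord, k))
    high <- c(high, utils::tail(ord, k))
    per <- c(per, k)
  }
  list(low_ids = low, high_ids = high,
       per_family = stats::setNames(per, fams))
}

#' Simulate pooled sequencing depths over the selected pools
#'
#' Emulates pooled sequencing of the low (`M`) and high (`P`) phenotype
#' pools: at each marker the total pool depth is Poisson around
#' `mean_depth`, and reads are assigned to the `aa` / `ab` depth channels
#' from the pool's true genotype composition.
#'
#' Two read-assignment conventions are available. Under `"allele"` (the
#' default) only alleles are observable: `aa` individuals emit recurrent
#' (`a`) alleles only, heterozygotes emit `a` and `b` equally, and `a` reads
#' land in the `aa` channel, `b` reads in the `ab` channel — so channel
#' counts are binomial with success probability `f_aa + f_ab / 2`. Under
#' `"dosage"` reads are first attributed to the emitting genotype class and
#' heterozygote reads are split half-and-half between the channels
#' deterministically (odd read to the `aa` channel). For a two-genotype BC1
#' pool the `aa`-channel mean is identical under both conventions; they
#' differ in the heterozygote sampling noise.
#'
#' `error_rate` flips each read's channel independently with the given
#' probability.
#'
#' @param pop A `bc1_population`.
#' @param low_ids,high_ids Pool membership as returned by [build_pools()].
#' @param mean_depth Mean total depth per marker per pool.
#' @param error_rate Per-read channel flip probability.
#' @param convention `"allele"` or `"dosage"` (see Details).
#' @param seed Integer seed (defaults to a child of the design seed).
#' @return A `data.frame` of pooled depth records: `marker_id`, `chrom`,
#'   `pos` (bp, 1-based), `Maa`, `Mab` (low pool), `Paa`, `Pab` (high pool).
#' @export
pooled_depths <- function(pop, low_ids, high_ids,
                          mean_depth = pop$design$mean_depth,
                          error_rate = 0,
                          convention = c("allele", "dosage"),
                          seed = child_seed(pop$design$seed, 2L)) {
  stopifnot(inherits(pop, "bc1_population"))
  convention <- match.arg(convention)
  if (length(intersect(low_ids, high_ids)))
    stop("pools must be disjoint", call. = FALSE)
  if (mean_depth <= 0) stop("mean_depth must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate > 1)
    stop("error_rate must lie in [0, 1]", call. = FALSE)
  set.seed(seed)

  m <- ncol(pop$genotypes)
  one_pool <- function(ids) {
    f_ab <- colMeans(pop$genotypes[ids, , drop = FALSE])
    depth <- stats::rpois(m, mean_depth)
    if (convention == "allele") {
      p_a <- (1 - f_ab) + f_ab / 2          # P(read carries the a allele)
      p_eff <- p_a * (1 - error_rate) + (1 - p_a) * error_rate
      aa <- stats::rbinom(m, depth, p_eff)
    } else {
      from_aa <- stats::rbinom(m, depth, 1 - f_ab)
      het <- depth - from_aa
      aa <- from_aa + ceiling(het / 2)       # deterministic half split
      if (error_rate > 0) {
        flips_out <- stats::rbinom(m, aa, error_rate)
        flips_in <- stats::rbinom(m, depth - aa, error_rate)
        aa <- aa - flips_out + flips_in
      }
    }
    cbind(aa = aa, ab = depth - aa)
  }

  lo <- one_pool(low_ids)
  hi <- one_pool(high_ids)
  data.frame(
    marker_id = pop$map$marker_id,
    chrom = pop$map$chrom,
    pos = pop$map$pos_bp,
    Maa = lo[, "aa"], Mab = lo[, "ab"],
    Paa = hi[, "aa"], Pab = hi[, "ab"],
    stringsAsFactors = FALSE
  )
}

#' Count pooled individuals' genotypes at markers
#'
#' Tabulates `aa` / `ab` individual counts per marker within the low and
#' high pools — the individual-genotyping analogue of [pooled_depths()],
#' used by the confirmation stage, where counts come from genotyping each
#' pooled individual one by one rather than from reads.
#'
#' @inheritParams pooled_depths
#' @param markers Optional character vector of marker ids to restrict to.
#' @return A `data.frame` with `marker_id`, `chrom`, `pos`, `Maa`, `Mab`,
#'   `Paa`, `Pab` where the four counts are numbers of individuals.
#' @export
genotype_counts <- function(pop, low_ids, high_ids, markers = NULL) {
  stopifnot(inherits(pop, "bc1_population"))
  g <- pop$genotypes
  keep <- if (is.null(markers)) seq_len(ncol(g)) else match(markers, colnames(g))
  if (anyNA(keep)) stop("unknown marker id(s): ",
                        paste(markers[is.na(keep)], collapse = ", "), call. = FALSE)
  n_ab_low <- colSums(g[low_ids, keep, drop = FALSE])
  n_ab_high <- colSums(g[high_ids, keep, drop = FALSE])
  data.frame(
    marker_id = pop$map$marker_id[keep],
    chrom = pop$map$chrom[keep],
    pos = pop$map$pos_bp[keep],
    Maa = length(low_ids) - n_ab_low, Mab = n_ab_low,
    Paa = length(high_ids) - n_ab_high, Pab = n_ab_high,
    stringsAsFactors = FALSE
  )
}
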