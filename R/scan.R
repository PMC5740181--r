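#' SNP-index and its pool contrast from pooled depth counts
#'
#' For each marker with low-pool depths `Maa`, `Mab` and high-pool depths
#' `Paa`, `Pab`, computes
#' \deqn{SNP\_index(aa) = Maa / (Paa + Maa),\quad
#'       SNP\_index(ab) = Mab / (Pab + Mab),}
#' and their contrast `delta = SNP_index(aa) - SNP_index(ab)`. A marker
#' whose `aa` or `ab` channel has zero total depth has no defined index and
#' is flagged `defined = FALSE`; the scan excludes (never imputes) such
#' markers.
#'
#' @param depths `data.frame` with columns `Maa`, `Mab`, `Paa`, `Pab`
#'   (and optionally `marker_id`, `chrom`, `pos`, carried through).
#' @return The input with `snp_index_aa`, `snp_index_ab`, `delta` and
#'   logical `defined` appended.
#' @export
snp_index <- function(depths) {
  depths <- as.data.frame(depths)
  need <- c("Maa", "Mab", "Paa", "Pab")
  if (!all(need %in% names(depths)))
    stop("depth table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(depths[need] < 0)) stop("depth counts must be >= 0", call. = FALSE)
  den_aa <- depths$Paa + depths$Maa
  den_ab <- depths$Pab + depths$Mab
  defined <- den_aa > 0 & den_ab > 0
  depths$snp_index_aa <- ifelse(den_aa > 0, depths$Maa / den_aa, NA_real_)
  depths$snp_index_ab <- ifelse(den_ab > 0, depths$Mab / den_ab, NA_real_)
  depths$delta <- depths$snp_index_aa - depths$snp_index_ab
  depths$defined <- defined
  depths
}

#' Genome-wide Z scores for the SNP-index contrast
#'
#' Standardises each marker's `delta` against the scan-wide location and
#' spread: `Z = (delta - mu0) / scale`, where `mu0` is the mean of all
#' deltas and `S` their sample standard deviation. Two scalings are
#' provided: `mode = "verbatim"` uses `scale = S / sqrt(n)` (the one-sample
#' Z-test form written in the source methodology, which grows with the
#' number of markers `n`), and `mode = "classic"` uses `scale = S`, the
#' ordinary standardisation under which null Z scores are approximately
#' standard normal. `"verbatim"` reproduces published scan arithmetic;
#' `"classic"` is the calibrated choice for simulation-based inference.
#'
#' @param deltas Numeric vector of per-marker delta values (length >= 2).
#' @param mode `"verbatim"` or `"classic"`.
#' @return A list: `z` (vector), `mu0`, `S` (sample sd), `n`, `mode`.
#' @export
z_scores <- function(deltas, mode = c("verbatim", "classic")) {
  mode <- match.arg(mode)
  deltas <- as.numeric(deltas)
  n <- length(deltas)
  if (n < 2) stop("need at least 2 markers to standardise", call. = FALSE)
  mu0 <- mean(deltas)
  S <- stats::sd(deltas)
  if (S == 0)
    stop("all delta values are identical (S = 0); Z scores undefined",
         call. = FALSE)
  scale <- if (mode == "verbatim") S / sqrt(n) else S
  list(z = (deltas - mu0) / scale, mu0 = mu0, S = S, n = n, mode = mode)
}

#' Normal-tail p-value from a Z score
#'
#' One-sided: `p = 1 - Phi(z)`, the upper-tail normal probability (the
#' spreadsheet `1 - NORMSDIST(z)` convention). Two-sided: `p = 2 * (1 -
#' Phi(z))` — deliberately NOT folded through `|z|` and NOT capped at 1, so
#' a negative z yields p > 1. This uncapped convention is what published
#' confirmation tables print (e.g. p = 1.8190 for z = -1.3376) and keeps
#' `p(z) + p(-z) = 2` exactly.
#'
#' @param z Numeric vector of Z scores (finite).
#' @param sided `"one"` or `"two"`.
#' @return Numeric vector of p-values.
#' @export
p_from_z <- function(z, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  p <- stats::pnorm(z, lower.tail = FALSE)
  if (sided == "two") p <- 2 * p
  p
}

#' Multiple-testing adjustment with an explicit test count
#'
#' Adjusts p-values for `n_tests` comparisons, where `n_tests` may exceed
#' the number of supplied p-values — the supplied set is then treated as
#' the smallest `length(p)` of `n_tests` tests (the usual situation when
#' only a scan's top markers are tabulated). `"bonferroni"` returns the
#' plain product `p * n_tests`, uncapped. `"bh"` returns the
#' Benjamini-Hochberg step-up value: with p sorted ascending,
#' `q_(i) = min over j >= i of p_(j) * n_tests / j`.
#'
#' @param p Numeric vector of p-values (>= 0).
#' @param method `"bh"` or `"bonferroni"`.
#' @param n_tests Total number of tests; defaults to `length(p)`.
#' @return Adjusted values in the input order.
#' @export
adjust_fdr <- function(p, method = c("bh", "bonferroni"),
                       n_tests = length(p)) {
  method <- match.arg(method)
  if (any(p < 0)) stop("p-values must be >= 0", call. = FALSE)
  if (n_tests < length(p))
    stop("n_tests must be >= length(p)", call. = FALSE)
  if (method == "bonferroni") return(p * n_tests)
  o <- order(p)
  ranked <- p[o] * n_tests / seq_along(p)
  q <- rev(cummin(rev(ranked)))
  out <- numeric(length(p))
  out[o] <- q
  out
}

#' Retain markers with adequate total coverage
#'
#' Keeps markers whose summed depth across the four channels is strictly
#' greater than `min_coverage` (the "more than 5x" rule).
#'
#' @param depths Pooled depth `data.frame` (columns `Maa`, `Mab`, `Paa`,
#'   `Pab`).
#' @param min_coverage Coverage cutoff; strict inequality.
#' @return The filtered `data.frame`.
#' @export
filter_polymorphic <- function(depths, min_coverage = 5) {
  if (min_coverage < 0) stop("min_coverage must be >= 0", call. = FALSE)
  total <- depths$Maa + depths$Mab + depths$Paa + depths$Pab
  depths[total > min_coverage, , drop = FALSE]
}

#' Genome-wide SNP-index scan of pooled depth tables
#'
#' The front door of the package: filters markers by coverage, computes
#' SNP-indices and their contrast, standardises to Z scores, converts to
#' normal-tail p-values, adjusts for multiple testing and flags linked
#' markers at an adjusted-value threshold.
#'
#' Markers failing the coverage filter or with an undefined index (zero
#' depth in the `aa` or `ab` channel) are excluded from the scan and listed
#' in the returned object's `excluded` table with a reason; they never
#' enter `mu0`, `S` or `n`.
#'
#' Note on defaults: the multiple-testing default is Benjamini-Hochberg
#' step-up even though the source methodology names Bonferroni — the
#' published calls (14 markers whose largest raw p is 7.03e-5 among 9,143
#' tests at threshold 0.05) are arithmetically consistent only with BH.
#' `summary()` surfaces this whenever `method = "bh"`.
#'
#' @param depths Pooled depth `data.frame`: `marker_id`, `chrom`, `pos`,
#'   `Maa`, `Mab`, `Paa`, `Pab` (as written by [pooled_depths()] or
#'   [read_pool_depths()]).
#' @param min_coverage Total-depth cutoff, strict (default 5).
#' @param fdr_threshold Linked-marker threshold on the adjusted value.
#' @param method `"bh"` or `"bonferroni"` (see Note).
#' @param sided `"one"` (scan default) or `"two"`.
#' @param z_mode `"verbatim"` (verbatim scaling `S/sqrt(n)`) or `"classic"`
#'   (`S`); see [z_scores()].
#' @param n_tests Total test count for the adjustment; defaults to the
#'   number of markers entering the scan.
#' @return An object of class `bsa_scan`: list with `markers` (per-marker
#'   results incl. `z`, `p`, `fdr`, `linked`), `excluded`, `mu0`, `S`, `n`,
#'   and `params`.
#' @examples
#' d <- data.frame(marker_id = c("a", "b", "c"), chrom = 1, pos = 1:3,
#'                 Maa = c(60, 50, 40), Mab = c(40, 50, 60),
#'                 Paa = c(40, 50, 60), Pab = c(60, 50, 40))
#' s <- bsa_scan(d, z_mode = "classic")
#' summary(s)
#' @export
bsa_scan <- function(depths, min_coverage = 5, fdr_threshold = 0.05,
                     method = c("bh", "bonferroni"),
                     sided = c("one", "two"),
                     z_mode = c("verbatim", "classic"),
                     n_tests = NULL) {
  method <- match.arg(method)
  sided <- match.arg(sided)
  z_mode <- match.arg(z_mode)
  depths <- as.data.frame(depths)
  if (!"marker_id" %in% names(depths))
    depths$marker_id <- sprintf("m%d", seq_len(nrow(depths)))

  kept <- filter_polymorphic(depths, min_coverage)
  n_lowcov <- nrow(depths) - nrow(kept)
  idx <- snp_index(kept)
  excluded <- rbind(
    if (n_lowcov) data.frame(marker_id = setdiff(depths$marker_id, kept$marker_id),
                             reason = "low_coverage", stringsAsFactors = FALSE),
    if (any(!idx$defined)) data.frame(marker_id = idx$marker_id[!idx$defined],
                                      reason = "undefined_index",
                                      stringsAsFactors = FALSE))
  if (is.null(excluded))
    excluded <- data.frame(marker_id = character(), reason = character())
  tested <- idx[idx$defined, , drop = FALSE]
  if (nrow(tested) < 2)
    stop("fewer than 2 markers remain after filtering; cannot standardise",
         call. = FALSE)
  if (is.null(n_tests)) n_tests <- nrow(tested)

  zs <- z_scores(tested$delta, mode = z_mode)
  tested$z <- zs$z
  tested$p <- p_from_z(zs$z, sided = sided)
  tested$fdr <- adjust_fdr(tested$p, method = method, n_tests = n_tests)
  tested$linked <- tested$fdr < fdr_threshold
  tested$defined <- NULL
  rownames(tested) <- NULL

  structure(list(
    markers = tested,
    excluded = excluded,
    mu0 = zs$mu0, S = zs$S, n = zs$n,
    params = list(min_coverage = min_coverage, fdr_threshold = fdr_threshold,
                  method = method, sided = sided, z_mode = z_mode,
                  n_tests = n_tests)
  ), class = "bsa_scan")
}

#' Extract linked markers from a scan
#'
#' @param scan A `bsa_scan` object, or a `data.frame` with an `fdr` column.
#' @param fdr_threshold Threshold; markers with `fdr` strictly below it are
#'   linked. Defaults to the scan's own threshold.
#' @return The linked subset of the marker table.
#' @export
call_linked <- function(scan, fdr_threshold = NULL) {
  tab <- if (inherits(scan, "bsa_scan")) scan$markers else as.data.frame(scan)
  if (is.null(fdr_threshold)) {
    fdr_threshold <- if (inherits(scan, "bsa_scan"))
      scan$params$fdr_threshold else 0.05
  }
  out <- tab[tab$fdr < fdr_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat(sprintf("SNP-index scan: %d markers tested (%d excluded), %d linked at %s < %g\n",
              x$n, nrow(x$excluded), sum(x$markers$linked),
              toupper(x$params$method), x$params$fdr_threshold))
  cat(sprintf("  mu0 = %.5g, S = %.5g, z mode = %s, %s-sided p, n_tests = %d\n",
              x$mu0, x$S, x$params$z_mode, x$params$sided, x$params$n_tests))
  invisible(x)
}

#' @export
summary.bsa_scan <- function(object, ...) {
  linked <- call_linked(object)
  per_chrom <- if (nrow(linked) && "chrom" %in% names(linked))
    table(linked$chrom) else table(character())
  out <- list(n_tested = object$n,
              n_excluded = nrow(object$excluded),
              excluded_reasons = table(object$excluded$reason),
              n_linked = nrow(linked),
              linked_per_chrom = per_chrom,
              linked = linked,
              params = object$params,
              mu0 = object$mu0, S = object$S)
  class(out) <- "summary.bsa_scan"
  out
}

#' @export
print.summary.bsa_scan <- function(x, ...) {
  cat(sprintf("SNP-index scan summary\n  tested: %d   excluded: %d   linked: %d (%s < %g)\n",
              x$n_tested, x$n_excluded, x$n_linked,
              toupper(x$params$method), x$params$fdr_threshold))
  if (x$n_linked) {
    cat("  linked markers per chromosome:\n")
    print(x$linked_per_chrom)
  }
  if (x$params$method == "bh")
    cat("  note: adjustment is Benjamini-Hochberg step-up; the methodology\n",
        "  this scan follows names Bonferroni, but its published calls are\n",
        "  consistent only with BH. Use method = 'bonferroni' to compare.\n",
        sep = "")
  invisible(x)
}

#' @export
as.data.frame.bsa_scan <- function(x, ...) x$markers

#' Plot a SNP-index scan
#'
#' Manhattan-style plot of -log10 of the adjusted value along the genome,
#' with linked markers highlighted and the calling threshold drawn.
#'
#' @param x A `bsa_scan` object.
#' @param y Ignored.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bsa_scan <- function(x, y, ...) {
  m <- x$markers
  chrom <- as.integer(factor(m$chrom))
  offs <- c(0, cumsum(tapply(m$pos, chrom, max)))
  gx <- m$pos + offs[chrom]
  graphics::plot(gx, -log10(pmax(m$fdr, 1e-300)),
                 col = ifelse(m$linked, "red", c("grey30", "grey60")[1 + chrom %% 2]),
                 pch = 20, xlab = "genome position (bp, concatenated)",
                 ylab = expression(-log[10](adjusted~p)), ...)
  graphics::abline(h = -log10(x$params$fdr_threshold), col = "blue", lty = 2)
  invisible(x)
}
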