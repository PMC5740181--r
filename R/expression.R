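#' Daily growth increments of the silk gland
#'
#' From a volume-by-day table computes, for every day after the first, the
#' absolute increment `V_t - V_{t-1}` and the relative growth ratio
#' `(V_t - V_{t-1}) / V_{t-1}`. Shrinkage (negative increments) is allowed;
#' a zero previous volume leaves that day's ratio undefined (`NA`) with a
#' flag.
#'
#' @param volumes `data.frame` with `day` and `volume` (>= 2 rows), or a
#'   numeric vector of volumes in day order.
#' @return `data.frame`: `day`, `increment`, `ratio`, `ratio_defined`.
#' @export
growth_increments <- function(volumes) {
  if (is.numeric(volumes))
    volumes <- data.frame(day = seq_along(volumes), volume = volumes)
  volumes <- volumes[order(volumes$day), , drop = FALSE]
  if (nrow(volumes) < 2) stop("need >= 2 days", call. = FALSE)
  v <- volumes$volume
  inc <- diff(v)
  prev <- v[-length(v)]
  data.frame(day = volumes$day[-1],
             increment = inc,
             ratio = ifelse(prev > 0, inc / prev, NA_real_),
             ratio_defined = prev > 0)
}

# Seeded permutation p-value for a statistic under label shuffling.
# Two-sided: fraction of permuted |stat| >= observed |stat|, with the
# +1 correction so p is never exactly 0.
perm_p <- function(x, y, stat, n_perm, seed) {
  obs <- stat(x, y)
  if (!is.finite(obs)) return(list(stat = obs, p = NA_real_))
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    s <- stat(x, sample(y))
    if (is.finite(s) && abs(s) >= abs(obs)) hits <- hits + 1L
  }
  list(stat = obs, p = (hits + 1) / (n_perm + 1))
}

#' Association between temporal expression and gland growth
#'
#' Correlates a gene's day-by-day expression with the silk gland's daily
#' growth increments — the pattern match that distinguishes a
#' growth-tracking gene (expression peaks when the gland grows fastest)
#' from a negatively associated one. Both Pearson and Spearman
#' correlations are reported, against the increment and against its
#' negative, with seeded permutation p-values.
#'
#' @param expr `data.frame` with `day` and `expr` (expression on the days
#'   AFTER the first, or on all days — days are aligned to the increment
#'   table by label).
#' @param increments Output of [growth_increments()] (or a `data.frame`
#'   with `day` and `increment`).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return `data.frame` with one row per (method, direction):
#'   `method`, `direction`, `estimate`, `p_perm`, `n`.
#' @export
temporal_association <- function(expr, increments, n_perm = 10000, seed = 1L) {
  m <- merge(expr, increments[, c("day", "increment")], by = "day")
  if (nrow(m) < 3) stop("need >= 3 aligned day pairs", call. = FALSE)
  if (stats::sd(m$expr) == 0 || stats::sd(m$increment) == 0) {
    warning("zero-variance series; correlation undefined")
    return(data.frame(method = c("pearson", "spearman"),
                      direction = "increment",
                      estimate = NA_real_, p_perm = NA_real_, n = nrow(m)))
  }
  grid <- expand.grid(method = c("pearson", "spearman"),
                      direction = c("increment", "neg_increment"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    y <- if (grid$direction[i] == "increment") m$increment else -m$increment
    st <- function(a, b)
      suppressWarnings(stats::cor(a, b, method = grid$method[i]))
    pp <- perm_p(m$expr, y, st, n_perm, child_seed(seed, i))
    data.frame(method = grid$method[i], direction = grid$direction[i],
               estimate = pp$stat, p_perm = pp$p, n = nrow(m))
  })
  do.call(rbind, res)
}

#' Association between strain expression and cocoon shell weight
#'
#' Tests whether a gene's silk-gland expression tracks cocoon shell weight
#' (CSW) across strains. `"correlate"` mode reports the Spearman
#' correlation of expression with CSW plus a seeded permutation p-value.
#' `"split"` mode partitions strains at the CSW median into high and low
#' groups and tests the difference in mean expression with a permutation
#' test using the Welch t statistic. All-equal CSW makes the split
#' undefined; the function then falls back to correlate mode with a
#' warning.
#'
#' @param expr `data.frame` with `strain`, `expr`.
#' @param csw `data.frame` with `strain`, `csw`.
#' @param mode `"correlate"` or `"split"`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List: `mode`, `estimate` (rho, or high-low mean difference),
#'   `statistic` (rho or Welch t), `p_perm`, `n_strains`, and for split
#'   mode the `groups` assignment.
#' @export
csw_association <- function(expr, csw, mode = c("correlate", "split"),
                            n_perm = 10000, seed = 1L) {
  mode <- match.arg(mode)
  m <- merge(expr, csw, by = "strain")
  if (nrow(m) < 4) stop("need >= 4 strains present in both tables", call. = FALSE)
  if (mode == "split" && stats::sd(m$csw) == 0) {
    warning("all CSW equal; median split undefined, falling back to correlate")
    mode <- "correlate"
  }
  if (mode == "correlate") {
    st <- function(a, b)
      suppressWarnings(stats::cor(a, b, method = "spearman"))
    pp <- perm_p(m$expr, m$csw, st, n_perm, child_seed(seed, 1L))
    return(list(mode = "correlate", estimate = pp$stat, statistic = pp$stat,
                p_perm = pp$p, n_strains = nrow(m)))
  }
  hi <- m$csw > stats::median(m$csw)
  # median split can be unbalanced with ties at the median; that is fine
  welch_t <- function(x, g) {
    a <- x[g]; b <- x[!g]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    d <- mean(a) - mean(b)
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    if (se == 0) return(if (d == 0) 0 else sign(d) * Inf)
    d / se
  }
  obs_diff <- mean(m$expr[hi]) - mean(m$expr[!hi])
  pp <- perm_p(m$expr, hi, function(a, b) welch_t(a, b), n_perm,
               child_seed(seed, 2L))
  list(mode = "split", estimate = obs_diff, statistic = pp$stat,
       p_perm = pp$p, n_strains = nrow(m),
       groups = stats::setNames(ifelse(hi, "high", "low"), m$strain))
}
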