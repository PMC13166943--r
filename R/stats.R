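#' Percent change from the vehicle-group mean
#'
#' The pharmacodynamic normalization used to compare assays on a common
#' scale: \code{100 * (sample - vehicleMean) / vehicleMean}. The vehicle
#' group transformed about its own mean averages to exactly 0.
#'
#' @param sampleValue numeric value(s).
#' @param vehicleMean mean of the vehicle (reference) group; must be
#'   non-zero.
#' @return percent change (vectorized over \code{sampleValue}).
#' @export
percentChangeFromVehicle <- function(sampleValue, vehicleMean) {
  if (!is.finite(vehicleMean) || vehicleMean == 0)
    stopf("undefined baseline: vehicle mean is zero or non-finite")
  100 * (sampleValue - vehicleMean) / vehicleMean
}

## exact null distribution of the rank-sum of a size-na subset of ranks
## 1..N: count[s+1] = number of subsets with sum s (classic DP)
rankSumCounts <- function(na, N) {
  maxsum <- sum((N - na + 1):N)
  dp <- matrix(0, nrow = na + 1, ncol = maxsum + 1)
  dp[1, 1] <- 1
  for (m in seq_len(N)) {
    kmax <- min(m, na)
    for (k in kmax:1) {
      shifted <- c(rep(0, m), dp[k, seq_len(maxsum + 1 - m)])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  dp[na + 1, ]
}

#' Unpaired two-sample Mann-Whitney comparison
#'
#' U is computed by the rank-sum route with midranks for ties. The
#' two-sided p-value is exact -- full enumeration of the
#' \code{choose(nA+nB, nA)} group assignments via a counting recursion --
#' when the pooled sample is tie-free and \code{nA + nB <= exactCutoff}
#' (default 16); otherwise the tie-corrected normal approximation with
#' continuity correction is used. The two-sided exact convention is
#' tail-doubling of the smaller one-sided tail, capped at 1.
#'
#' @param a,b numeric vectors (each non-empty; NA dropped).
#' @param groupA,groupB labels recorded in the result.
#' @param exactCutoff maximum pooled size for the exact path.
#' @return a [GroupComparison-class].
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitney <- function(a, b, groupA = "a", groupB = "b",
                        exactCutoff = 16L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stopf("empty group")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)  # midranks
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && N <= exactCutoff) {
    counts <- rankSumCounts(na, N)
    w <- U + na * (na + 1) / 2       # rank-sum; counts indexed by sum s at s+1
    total <- choose(N, na)
    sums <- seq_along(counts) - 1
    pLe <- sum(counts[sums <= w]) / total
    pGe <- sum(counts[sums >= w]) / total
    p <- min(1, 2 * min(pLe, pGe))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tab <- table(pooled)
    tieTerm <- sum(tab^3 - tab) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tieTerm)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- sign(U - mu) * 0.5
      z <- (U - mu - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  new("GroupComparison", groupA = groupA, groupB = groupB,
      nA = as.integer(na), nB = as.integer(nb), uStatistic = U,
      pValue = p, method = method)
}

#' Spearman rank concordance between two paired assays
#'
#' rho is the product-moment correlation of the midranks of x and y; the
#' two-sided p-value comes from the large-sample t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on n - 2 degrees of
#' freedom (no exact enumeration path is implemented). A constant input
#' leaves rho undefined (NA, with a note).
#'
#' @param x,y numeric vectors of equal length (n >= 3; pairs with NA
#'   dropped).
#' @return a [Concordance-class].
#' @export
spearmanConcordance <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stopf("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(new("Concordance", rho = NA_real_, pValue = NA_real_,
               n = as.integer(n), method = "t_approx",
               note = "constant input: rho undefined"))
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new("Concordance", rho = rho, pValue = p, n = as.integer(n),
      method = "t_approx", note = "")
}

#' Per-group summaries and pairwise Mann-Whitney contrasts
#'
#' Summarizes one endpoint metric over treatment groups (mean, SD, n of
#' non-missing values) and runs the configured contrasts (default: every
#' non-reference group against the reference/vehicle group). Missing
#' values are excluded and n reflects the exclusions. The unit of
#' analysis is the record (ROI/core) by default; set
#' \code{aggregateBy = "specimen_id"} to average to per-animal means
#' first.
#'
#' @param records data.frame of quantitation records.
#' @param metric name of the metric column to summarize.
#' @param reference reference (vehicle) group label; default the first
#'   group in order of appearance.
#' @param contrasts optional list of \code{c(groupA, groupB)} pairs
#'   overriding the default each-vs-reference set.
#' @param aggregateBy optional column name; records are averaged within
#'   its levels (per group) before testing.
#' @param holm apply Holm adjustment across the contrasts (off by
#'   default; the endpoints are reported unadjusted).
#' @param evaluableOnly drop records flagged non-evaluable (default TRUE
#'   when the column is filled in).
#' @return list with \code{summary} (data.frame: group, n, mean, sd) and
#'   \code{comparisons} (data.frame: group_a, group_b, n_a, n_b, u, p,
#'   p_adj, method).
#' @export
summarizeGroups <- function(records, metric, reference = NULL,
                            contrasts = NULL, aggregateBy = NULL,
                            holm = FALSE, evaluableOnly = TRUE) {
  if (!metric %in% names(records)) stopf("unknown metric '%s'", metric)
  if (evaluableOnly && "evaluable" %in% names(records) &&
      !all(is.na(records$evaluable)))
    records <- records[records$evaluable %in% TRUE, , drop = FALSE]
  records <- records[!is.na(records[[metric]]), , drop = FALSE]
  if (nrow(records) == 0) stopf("no non-missing values for '%s'", metric)
  if (!is.null(aggregateBy)) {
    agg <- stats::aggregate(records[[metric]],
                            by = list(group = records$group,
                                      unit = records[[aggregateBy]]),
                            FUN = mean)
    records <- data.frame(group = agg$group, value = agg$x,
                          stringsAsFactors = FALSE)
  } else {
    records <- data.frame(group = records$group, value = records[[metric]],
                          stringsAsFactors = FALSE)
  }
  groups <- unique(records$group)
  vals <- split(records$value, factor(records$group, levels = groups))
  summary <- data.frame(
    group = groups,
    n = vapply(vals, length, integer(1)),
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (is.null(reference)) reference <- groups[1]
  if (is.null(contrasts)) {
    if (!reference %in% groups) stopf("reference group '%s' absent", reference)
    contrasts <- lapply(setdiff(groups, reference),
                        function(g) c(g, reference))
  }
  if (length(contrasts) == 0) {
    comparisons <- data.frame(group_a = character(0), group_b = character(0),
                              n_a = integer(0), n_b = integer(0),
                              u = numeric(0), p = numeric(0),
                              method = character(0), p_adj = numeric(0),
                              stringsAsFactors = FALSE)
    return(list(summary = summary, comparisons = comparisons))
  }
  comps <- lapply(contrasts, function(ct) {
    ga <- ct[1]; gb <- ct[2]
    if (!ga %in% groups || !gb %in% groups)
      stopf("contrast group missing after exclusions: %s vs %s", ga, gb)
    r <- mannWhitney(vals[[ga]], vals[[gb]], groupA = ga, groupB = gb)
    data.frame(group_a = ga, group_b = gb, n_a = r@nA, n_b = r@nB,
               u = r@uStatistic, p = r@pValue, method = r@method,
               stringsAsFactors = FALSE)
  })
  comparisons <- do.call(rbind, comps)
  comparisons$p_adj <- if (holm) stats::p.adjust(comparisons$p, "holm")
                       else comparisons$p
  list(summary = summary, comparisons = comparisons)
}
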