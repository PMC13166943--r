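# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: explicit per-pixel loops and full enumeration.

# count pixels TRUE in every supplied mask, by explicit nested loops
loopCountIntersection <- function(...) {
  masks <- list(...)
  nr <- nrow(masks[[1]]); nc <- ncol(masks[[1]])
  count <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    all_on <- TRUE
    for (m in masks) if (!m[i, j]) { all_on <- FALSE; break }
    if (all_on) count <- count + 1L
  }
  count
}

# connected-component count by recursive-free flood fill (stack-based)
floodFillCount <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8L)
    list(c(-1,0), c(1,0), c(0,-1), c(0,1),
         c(-1,-1), c(-1,1), c(1,-1), c(1,1))
  else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  count <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] && !seen[i, j]) {
      count <- count + 1L
      stack <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (o in offs) {
          r <- p[1] + o[1]; cc <- p[2] + o[2]
          if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
              mask[r, cc] && !seen[r, cc]) {
            seen[r, cc] <- TRUE
            stack[[length(stack) + 1L]] <- c(r, cc)
          }
        }
      }
    }
  }
  count
}

# exact two-sided Mann-Whitney p by enumerating every group assignment
enumerateMannWhitneyP <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  uOf <- function(idx) {
    rk <- rank(pooled)
    sum(rk[idx]) - na * (na + 1) / 2
  }
  uObs <- uOf(seq_len(na))
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, uOf)
  pLe <- mean(us <= uObs)
  pGe <- mean(us >= uObs)
  min(1, 2 * min(pLe, pGe))
}

# Spearman rho by hand-assigned midranks then textbook Pearson formula
midrankPearsonRho <- function(x, y) {
  midrank <- function(v) {
    s <- sort(v)
    vapply(v, function(vi) mean(which(s == vi)), numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# paint a disk into a logical matrix (constructed-truth geometry)
diskMask <- function(nr, nc, row, col, radius) {
  rg <- matrix(seq_len(nr), nr, nc)
  cg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rg - row)^2 + (cg - col)^2 <= radius^2
}

# minimal stack with the given matrices as channels
testStack <- function(..., pixelSizeUm = 0.5) {
  channelStack(list(...), pixelSizeUm = pixelSizeUm, fieldId = "test")
}

# random logical matrix under a fixed seed
randomMask <- function(seed, nr = 128, nc = 128, p = 0.5) {
  set.seed(seed)
  matrix(runif(nr * nc) < p, nr, nc)
}

# fixed thresholds for noise-free recovery tests
fixedThresholds <- function(cut = 500) {
  list(total_met = deriveThreshold(NULL, "total_met", "fixed", cut),
       phospho_met = deriveThreshold(NULL, "phospho_met", "fixed", cut))
}
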