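test_that("percent change from vehicle follows the formula", {
  expect_equal(percentChangeFromVehicle(8, 10), -20)
  expect_equal(percentChangeFromVehicle(10, 10), 0)
  expect_error(percentChangeFromVehicle(5, 0), "undefined baseline")
  # the vehicle group about its own mean averages to exactly 0
  set.seed(14)
  veh <- rnorm(12, 50, 8)
  expect_equal(mean(percentChangeFromVehicle(veh, mean(veh))), 0)
})

test_that("fully separated small groups give U = 0 and exact p = 0.1", {
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r@uStatistic, 0)
  expect_equal(r@pValue, 0.1)  # 2 of the 20 arrangements as extreme
  expect_identical(r@method, "exact")
})

test_that("identical groups give U = n^2/2 and p = 1", {
  x <- c(3, 1, 4, 1, 5)
  r <- mannWhitney(x, x)
  expect_equal(r@uStatistic, length(x)^2 / 2)
  expect_equal(r@pValue, 1)
})

test_that("exact p equals the full-enumeration oracle for small samples", {
  set.seed(55)
  for (rep in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    vals <- sample(1:50, na + nb)  # tie-free
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    r <- mannWhitney(a, b)
    expect_identical(r@method, "exact")
    expect_equal(r@pValue, enumerateMannWhitneyP(a, b))
  }
})

test_that("U statistics of the two orientations sum to nA*nB", {
  set.seed(56)
  for (rep in 1:10) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1))
    expect_equal(mannWhitney(a, b)@uStatistic +
                   mannWhitney(b, a)@uStatistic,
                 length(a) * length(b))
  }
})

test_that("rank-based p-values are invariant to monotone transforms", {
  set.seed(57)
  a <- rexp(7); b <- rexp(9) * 1.8
  p0 <- mannWhitney(a, b)@pValue
  for (f in list(function(x) x^3, function(x) log1p(x),
                 function(x) 10 * x - 2))
    expect_equal(mannWhitney(f(a), f(b))@pValue, p0)
  rho0 <- spearmanConcordance(a[1:7], b[1:7])@rho
  expect_equal(spearmanConcordance(a[1:7]^3, log1p(b[1:7]))@rho, rho0)
})

test_that("exact and normal-approximation paths agree within 0.02 at n=8", {
  set.seed(58)
  for (rep in 1:10) {
    vals <- sample(1:1000, 16)
    a <- vals[1:8]; b <- vals[9:16]
    pExact <- mannWhitney(a, b)@pValue
    pApprox <- mannWhitney(a, b, exactCutoff = 0L)@pValue
    expect_lt(abs(pExact - pApprox), 0.02)
  }
})

test_that("ties route to the tie-corrected normal approximation", {
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  r <- mannWhitney(a, b)
  expect_identical(r@method, "normal_approx")
  # independent cross-check against R's own implementation
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                           correct = TRUE))
  expect_equal(r@pValue, w$p.value)
  expect_equal(r@uStatistic, unname(w$statistic))
})

test_that("spearman handles monotone, antitone, tied and constant input", {
  expect_equal(spearmanConcordance(1:4, c(10, 20, 30, 40))@rho, 1)
  expect_equal(spearmanConcordance(1:4, c(40, 30, 20, 10))@rho, -1)
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  s <- spearmanConcordance(x, y)
  expect_equal(s@rho, midrankPearsonRho(x, y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(s@rho, unname(ct$estimate))
  const <- spearmanConcordance(c(5, 5, 5, 5), y)
  expect_true(is.na(const@rho))
  expect_match(const@note, "constant")
  expect_error(spearmanConcordance(1:4, 1:5), "length mismatch")
  expect_error(spearmanConcordance(1:2, 1:2), "at least 3")
})

test_that("spearman detects strong concordance in a PD-style paired design", {
  # IFA-vs-orthogonal-assay style: same underlying suppression, noisy
  set.seed(60)
  true <- c(rnorm(4, 0, 6), rnorm(4, -45, 8), rnorm(4, -80, 5))
  ifa <- true + rnorm(12, 0, 5)
  elisa <- true + rnorm(12, 0, 5)
  s <- spearmanConcordance(ifa, elisa)
  expect_gt(s@rho, 0.8)
  expect_lt(s@pValue, 0.001)
})

test_that("group summaries exclude missing values and run contrasts", {
  rec <- data.frame(
    group = rep(c("vehicle", "treated"), each = 4),
    specimen_id = rep(c("v1", "v2", "t1", "t2"), each = 2),
    value = c(10, 11, 12, 13, 2, 3, NA, 4),
    evaluable = TRUE, stringsAsFactors = FALSE)
  res <- summarizeGroups(rec, "value", reference = "vehicle")
  expect_equal(res$summary$n[res$summary$group == "treated"], 3L)  # NA dropped
  expect_equal(res$summary$mean[res$summary$group == "vehicle"], 11.5)
  expect_identical(res$comparisons$group_b, "vehicle")
  expect_lt(res$comparisons$p, 0.06)
  # constant equal groups: p = 1
  rec2 <- data.frame(group = rep(c("a", "b"), each = 3),
                     value = rep(5, 6), evaluable = TRUE,
                     stringsAsFactors = FALSE)
  res2 <- summarizeGroups(rec2, "value", reference = "a")
  expect_equal(res2$summary$sd, c(0, 0))
  expect_equal(res2$comparisons$p, 1)
  # per-animal aggregation collapses cores first
  resAgg <- summarizeGroups(rec, "value", reference = "vehicle",
                            aggregateBy = "specimen_id")
  expect_equal(sort(resAgg$summary$n), c(2L, 2L))
  expect_error(summarizeGroups(rec, "no_such_metric"), "unknown metric")
})

test_that("dose series means decrease for phospho but not total", {
  base <- scenePreset("high", 70)
  series <- generateDoseResponseSeries(base, doses = c(0, 1, 10), ic50 = 1,
                                       nReps = 3L, seed = 70)
  rows <- lapply(series, function(e) {
    masks <- segmentCompartments(e$stack)
    r <- quantifyField(e$stack, masks, fixedThresholds(),
                       specimenId = sprintf("d%g_r%d", e$dose, e$rep),
                       group = sprintf("d%g", e$dose))
    r
  })
  rec <- do.call(rbind, rows)
  rec$evaluable <- TRUE
  phos <- summarizeGroups(rec, "area_per_cell_um2_phospho_met",
                          reference = "d0")$summary
  tot <- summarizeGroups(rec, "area_per_cell_um2_total_met",
                         reference = "d0")$summary
  phosMeans <- phos$mean[match(c("d0", "d1", "d10"), phos$group)]
  expect_true(all(diff(phosMeans) < 0))
  totMeans <- tot$mean[match(c("d0", "d1", "d10"), tot$group)]
  expect_lt(diff(range(totMeans)) / mean(totMeans), 0.10)
})
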