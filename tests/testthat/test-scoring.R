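test_that("selectivity score is mean-subtraction with translation covariance", {
  expect_equal(selectivity_score(c(A = 1, B = 1, C = 1), "A"), 0)
  prof <- c(2.0, rep(0, 17))
  names(prof) <- sprintf("P%02d", 1:18)
  expect_equal(selectivity_score(prof, "P01"), 2.0)

  withr::with_seed(1, {
    z <- rnorm(18)
    names(z) <- sprintf("P%02d", 1:18)
    oracle <- z[["P05"]] - mean(z[setdiff(names(z), "P05")])
    expect_equal(selectivity_score(z, "P05"), oracle, tolerance = 1e-12)
    # adding delta to the target entry adds delta to the score
    z2 <- z
    z2[["P05"]] <- z2[["P05"]] + 0.7
    expect_equal(selectivity_score(z2, "P05"),
                 selectivity_score(z, "P05") + 0.7, tolerance = 1e-12)
  })
  expect_error(selectivity_score(c(A = 1), "A"), "at least 2")
})

make_kinetics <- function(df) {
  # expand per-substrate endpoint fold changes into two-replicate kinetics
  dplyr::bind_rows(lapply(seq_len(nrow(df)), function(i) {
    tibble::tibble(
      substrate = df$substrate[i], protease = df$protease[i],
      replicate = rep(c("r1", "r2"), each = 2),
      time_min = rep(c(0, 60), 2),
      fluorescence = c(100, 100 * df$fc[i], 100, 100 * df$fc[i]))
  }))
}

test_that("screen efficiencies follow the printed transform", {
  # three-substrate toy panel, checked by hand:
  # controls: FC 1.0 each -> cut = 1.0 + 3*0 = 1; cleaved iff FC > 1
  kin <- make_kinetics(tibble::tibble(
    substrate = c("s1", "s2", "s3", "b1", "b2"),
    protease = c("E", "E", "E", "none", "none"),
    fc = c(5, 3, 1.0, 1, 1)))
  eff <- suppressWarnings(efficiency_from_screen(kin, control_label = "none"))
  eff <- eff[order(eff$substrate), ]
  # FC_max = 5, FC_minbar = mean(non-cleaved) = 1 -> s2: 3/(5-1) = 0.75
  expect_equal(eff$efficiency, c(1, 0.75, 0))
  expect_equal(eff$cleaved, c(TRUE, TRUE, FALSE))

  # the top substrate is exactly 1; non-cleaved exactly 0 regardless of signal
  expect_equal(max(eff$efficiency), 1)
  expect_equal(eff$efficiency[eff$substrate == "s3"], 0)

  # plain FC/FCmax reading when use_fc_min is off -> s2: 3/5
  eff2 <- efficiency_from_screen(kin, control_label = "none", use_fc_min = FALSE)
  expect_equal(sort(eff2$efficiency, decreasing = TRUE), c(1, 0.6, 0))

  # replicate averaging happens before the transform
  kin_uneven <- dplyr::bind_rows(
    tibble::tibble(substrate = "s1", protease = "E", replicate = "r1",
                   time_min = c(0, 60), fluorescence = c(100, 400)),
    tibble::tibble(substrate = "s1", protease = "E", replicate = "r2",
                   time_min = c(0, 60), fluorescence = c(100, 600)),
    tibble::tibble(substrate = "s2", protease = "E", replicate = "r1",
                   time_min = c(0, 60), fluorescence = c(100, 110)))
  eff3 <- efficiency_from_screen(kin_uneven)  # floor 1.2, no controls
  expect_equal(eff3$activity[eff3$substrate == "s1"], 5)  # mean(4, 6)
  expect_false(eff3$cleaved[eff3$substrate == "s2"])

  # no cleaved substrates -> zeros with warning
  kin0 <- make_kinetics(tibble::tibble(substrate = c("s1", "s2"),
                                       protease = "E", fc = c(1.0, 1.1)))
  expect_warning(e0 <- efficiency_from_screen(kin0), "no cleaved")
  expect_equal(e0$efficiency, c(0, 0))
})

test_that("threshold fitting maximises Youden's J and matches a brute-force scan", {
  # perfectly separated scores -> midpoint of the gap
  d <- tibble::tibble(protease = "E",
                      zhat = c(-2, -1, -0.5, 1.5, 2, 3),
                      cleaved = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  tab <- fit_cleavage_thresholds(d)
  expect_equal(tab$threshold, (-0.5 + 1.5) / 2)
  expect_equal(tab$youden_j, 1)
  expect_false(tab$imputed)

  # brute-force scan oracle on a 40-point noisy set
  withr::with_seed(2, {
    z <- rnorm(40)
    y <- runif(40) < plogis(2 * z)
  })
  d2 <- tibble::tibble(protease = "E", zhat = z, cleaved = y)
  tab2 <- suppressWarnings(fit_cleavage_thresholds(d2))
  grid <- sort(unique(z))
  jj <- vapply(grid, function(t) mean(z[y] > t) + mean(z[!y] <= t) - 1, numeric(1))
  best_j <- max(vapply(c(grid - 1e-9, max(grid) + 1), function(t)
    mean(z[y] > t) + mean(z[!y] <= t) - 1, numeric(1)))
  got_j <- mean(z[y] > tab2$threshold) + mean(z[!y] <= tab2$threshold) - 1
  expect_equal(got_j, best_j, tolerance = 1e-12)

  # independent labels -> low-confidence warning
  withr::with_seed(3, {
    d3 <- tibble::tibble(protease = "E", zhat = rnorm(60),
                         cleaved = sample(c(TRUE, FALSE), 60, TRUE))
  })
  expect_warning(fit_cleavage_thresholds(d3), "low-confidence")
})

test_that("imputed thresholds equal the mean of fitted thresholds exactly", {
  withr::with_seed(4, {
    d <- dplyr::bind_rows(lapply(sprintf("E%02d", 1:12), function(p) {
      z <- rnorm(30)
      tibble::tibble(protease = p, zhat = z, cleaved = z + rnorm(30, sd = 0.5) > 0.3)
    }))
  })
  panel <- sprintf("E%02d", 1:18)
  tab <- suppressWarnings(fit_cleavage_thresholds(d, panel = panel))
  expect_equal(nrow(tab), 18)
  expect_equal(sum(tab$imputed), 6)
  expect_equal(unique(tab$threshold[tab$imputed]),
               mean(tab$threshold[!tab$imputed]), tolerance = 1e-12)

  # single-class protease is imputed too
  d_single <- dplyr::bind_rows(d, tibble::tibble(protease = "E13",
                                                 zhat = rnorm(10),
                                                 cleaved = TRUE))
  tab2 <- suppressWarnings(fit_cleavage_thresholds(d_single,
                                                   panel = c(sprintf("E%02d", 1:12), "E13")))
  expect_true(tab2$imputed[tab2$protease == "E13"])
})

test_that("cleavage classification uses strict thresholds and hand-counted metrics", {
  thr <- suppressWarnings(fit_cleavage_thresholds(
    tibble::tibble(protease = "E", zhat = c(-1, 1), cleaved = c(FALSE, TRUE))))
  expect_equal(thr$threshold, 0)
  preds <- matrix(c(0, 0.5, -0.2), 3, 1, dimnames = list(NULL, "E"))
  calls <- classify_cleaved(preds, thr)
  expect_equal(calls$cleaved, c(FALSE, TRUE, FALSE))  # boundary not cleaved

  # monotonicity in zhat
  withr::with_seed(5, zz <- sort(rnorm(20)))
  calls2 <- classify_cleaved(matrix(zz, 20, 1, dimnames = list(NULL, "E")), thr)
  expect_true(all(diff(calls2$cleaved) >= 0))

  # hand-counted confusion metrics on a 10-point toy
  calls3 <- tibble::tibble(
    protease = "E",
    cleaved = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    cleaved_true = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE))
  m <- classification_metrics(calls3)
  # TP = 3, FN = 2, TN = 3, FP = 2
  expect_equal(m$sensitivity, 3 / 5)
  expect_equal(m$specificity, 3 / 5)
  expect_equal(m$accuracy, 6 / 10)
})

test_that("corrected efficiency matches elementwise recomputation and its invariances", {
  withr::with_seed(6, {
    zhat <- matrix(rnorm(100, 1, 1.2), 20, 5,
                   dimnames = list(NULL, sprintf("E%d", 1:5)))
  })
  thr <- tibble::tibble(protease = sprintf("E%d", 1:5),
                        threshold = c(0.5, 1, 0.2, 2.5, 0.983))
  E <- corrected_efficiency(zhat, thr)
  for (j in 1:5) {
    ex <- zhat[, j] - thr$threshold[j]
    expected <- ifelse(ex > 0, ex / max(ex[ex > 0]), 0)
    if (!any(ex > 0)) expected <- rep(0, 20)
    expect_equal(E[, j], expected, tolerance = 1e-12, ignore_attr = TRUE)
    if (any(ex > 0)) expect_equal(max(E[, j]), 1)
  }
  # boundary: exactly at threshold -> non-cleaved
  zb <- matrix(c(0.5, 1.5), 2, 1, dimnames = list(NULL, "E1"))
  Eb <- corrected_efficiency(zb, thr)
  expect_equal(unname(Eb[1, 1]), 0)
  expect_equal(unname(Eb[2, 1]), 1)

  # invariance to common positive rescaling of the excess within a column
  z2 <- zhat
  z2[, 1] <- thr$threshold[1] + 3.7 * (zhat[, 1] - thr$threshold[1])
  expect_equal(corrected_efficiency(z2, thr)[, 1], E[, 1], tolerance = 1e-12)
})

test_that("corrected selectivity is bounded and exact", {
  E <- rbind(c(1, 0, 0), c(0.5, 0.5, 0.5), c(0, 1, 1))
  colnames(E) <- c("A", "B", "C")
  cs <- corrected_selectivity(E, "A")
  expect_equal(cs, c(1, 0, -1))
  withr::with_seed(7, {
    Er <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
    oracle <- Er[, "B"] - (Er[, "A"] + Er[, "C"]) / 2
    expect_equal(corrected_selectivity(Er, "B"), oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(abs(corrected_selectivity(Er, "B")) <= 1))
  })
})

test_that("quadrant assignment uses strict cuts and matches hand tallies", {
  expect_equal(as.character(quadrant_assign(0.5, 3.0)), "high_eff_high_sel")
  expect_equal(as.character(quadrant_assign(0.4, 2.4)), "low_eff_low_sel")
  e <- c(0.5, 0.3, 0.9, 0.1, 0.41)
  s <- c(3, 3, 1, 1, 2.41)
  q <- quadrant_assign(e, s)
  expect_equal(as.integer(table(q)), c(1L, 1L, 1L, 2L))
  # kinetics reader validates non-negative fluorescence
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("substrate,protease,replicate,time_min,fluorescence",
               "s1,E,r1,0,-5"), p)
  expect_error(suppressMessages(read_kinetics(p)), "negative")
})
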