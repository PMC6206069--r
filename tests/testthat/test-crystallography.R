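test_that("sigma_ref fitting follows delta = sigma_ref - sigma", {
  expect_equal(fit_sigma_ref(25.8, 5.0)$sigma_ref, 30.8)
  expect_equal(fit_sigma_ref(c(20, 25), c(9, 6))$sigma_ref, 30.0)
  # exact consistency: pairs generated from a known reference recover it
  set.seed(2)
  sig <- runif(20, 20, 35)
  fit <- fit_sigma_ref(sig, 30.8 - sig)
  expect_equal(fit$sigma_ref, 30.8, tolerance = 1e-12)
  expect_equal(fit$slope, -1, tolerance = 1e-9)
  expect_error(fit_sigma_ref(numeric(0), numeric(0)), "at least one")
})

test_that("shift conversion uses the standard 1H and 13C reference scales", {
  scale <- c(H = 30.8, C = 169.5)
  expect_equal(to_shifts(30.8, scale, "H"), 0.0)
  expect_equal(to_shifts(69.5, scale, "C"), 100.0)
  # round trip
  sig <- c(28.1, 30.2, 25.7)
  expect_equal(scale[["H"]] - to_shifts(sig, scale, "H"), sig)
  expect_error(to_shifts(10, scale, "N"), "sigma_ref for element N")
})

test_that("equivalent-nucleus aggregation is the unweighted group mean", {
  exp1 <- experiment_shifts(c("a", "b"), c("H", "H"), c(1.5, 4.0),
                            list(1L, c(2L, 3L, 4L)))
  delta <- c(1.0, 1.0, 2.0, 3.0)
  agg <- aggregate_predicted(delta, exp1)
  expect_equal(unname(agg), c(1.0, 2.0))
  expect_equal(names(agg), c("a", "b"))
  expect_error(aggregate_predicted(c(1, 2), exp1), "out of range")
  expect_error(aggregate_predicted(delta, exp1,
                                   species = c("H", "H", "C", "H")),
               "wrong element")
  expect_error(experiment_shifts(c("a", "b"), c("H", "H"), c(1, 2),
                                 list(1L, 1L)), "overlap")
})

test_that("experimental RMSE is an unweighted mean over resonances", {
  exp1 <- experiment_shifts(c("a", "b"), c("H", "H"), c(1, 2),
                            list(1L, 2L))
  expect_equal(rmse_vs_experiment(c(a = 1, b = 2), exp1), 0)
  expect_equal(rmse_vs_experiment(c(a = 2, b = 1), exp1), 1.0)
  # order of names must not matter
  expect_equal(rmse_vs_experiment(c(b = 1, a = 2), exp1), 1.0)
  expect_error(rmse_vs_experiment(c(a = 1, c = 2), exp1), "mismatch")
})

test_that("candidate ranking sorts by RMSE with id tie-break and threshold", {
  exp1 <- experiment_shifts(c("a", "b"), c("H", "H"), c(1, 2),
                            list(1L, 2L))
  cands <- list(far = c(a = 3, b = 4), exact = c(a = 1, b = 2),
                near = c(a = 1.3, b = 2.3))
  rk <- rank_candidates(cands, exp1, threshold = 0.49)
  expect_equal(rk$id, c("exact", "near", "far"))
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$accepted, c(TRUE, TRUE, FALSE))
  expect_equal(rk$rmse_ppm[1], 0)
  # ties break by structure id
  tie <- rank_candidates(list(zz = c(a = 1.1, b = 2.1),
                              aa = c(a = 0.9, b = 1.9)), exp1)
  expect_equal(tie$id, c("aa", "zz"))
  # threshold monotonicity: raising it never un-accepts
  for (th in c(0.1, 0.5, 1, 5)) {
    rk_lo <- rank_candidates(cands, exp1, threshold = th)
    rk_hi <- rank_candidates(cands, exp1, threshold = th + 0.5)
    expect_true(all(rk_hi$accepted[match(rk_lo$id[rk_lo$accepted],
                                         rk_hi$id)]))
  }
  expect_error(rank_candidates(list(), exp1), "at least one")
})

test_that("rank order is invariant to a common shielding offset with refit", {
  # shifting all predicted shieldings by a constant and refitting sigma_ref
  # on the same assignments leaves the candidate ranking unchanged
  set.seed(9)
  exp1 <- experiment_shifts(paste0("r", 1:6), rep("H", 6),
                            runif(6, 0, 8), as.list(1:6))
  sigma_cand <- lapply(1:4, function(k) runif(6, 22, 31))
  names(sigma_cand) <- paste0("cand", 1:4)
  rank_of <- function(offset) {
    sref <- fit_sigma_ref(sigma_cand[[1]] + offset, exp1$shift_ppm)$sigma_ref
    preds <- lapply(sigma_cand, function(s) {
      v <- sref - (s + offset); names(v) <- exp1$label; v
    })
    rank_candidates(preds, exp1)$id
  }
  expect_identical(rank_of(0), rank_of(12.3))
  expect_identical(rank_of(0), rank_of(-5.5))
})

test_that("experiment tables read 0-based atom groups from CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,element,shift_ppm,atom_indices",
               "me,H,1.2,0;1;2",
               "oh,H,4.5,3"), f)
  ex <- read_experiment(f)
  expect_equal(ex$label, c("me", "oh"))
  expect_equal(ex$groups, list(1:3, 4L))
  expect_equal(ex$shift_ppm, c(1.2, 4.5))
})
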