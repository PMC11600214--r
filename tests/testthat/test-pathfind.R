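test_that("NEB finds straight paths on flat and valley landscapes", {
  flat <- make_analytic_landscape("flat")
  p <- neb_search(flat$fes, c(0.1, 0.1), c(0.9, 0.9), 0.6, seed = 2)
  cell <- min(diff(flat$fes$cv1)[1], diff(flat$fes$cv2)[1])
  # beads on the diagonal within grid tolerance
  expect_lt(max(abs(p$nodes[, 2] - p$nodes[, 1])), 2 * cell)
  expect_equal(p$barrier, 0)
  expect_equal(p$nodes[1, ], c(0.1, 0.1), tolerance = 1e-10,
               ignore_attr = TRUE)

  # quadratic valley F = y^2: beads converge to the valley floor
  x <- seq(-0.2, 1.2, length.out = 50)
  y <- seq(-0.5, 0.5, length.out = 50)
  fes <- free_energy_surface(x, y, outer(rep(1, 50), 40 * y^2))
  pv <- neb_search(fes, c(0, 0), c(1, 0), 0.6, seed = 3)
  expect_lt(max(abs(pv$nodes[, 2])), y[2] - y[1] + 1e-9)
})

test_that("NEB restarts bound the minimax barrier and their best attains it", {
  land <- make_analytic_landscape("random_smooth", n1 = 50, n2 = 50,
                                  seed = 31)
  orc <- minimax_path_oracle(land)
  tol2 <- 2 * max(abs(diff(land$fes$F)),
                  abs(t(diff(t(land$fes$F)))))
  barriers <- numeric(20)
  for (s in 1:20) {
    p <- neb_search(land$fes, land$start, land$end, 0.6, seed = s)
    expect_gt(p$barrier, orc$barrier - tol2) # cannot beat the oracle
    barriers[s] <- p$barrier
  }
  # individual random restarts land in whatever valley they started
  # near; the restart protocol exists because their minimum, not their
  # typical value, tracks the optimum
  expect_lt(min(barriers), orc$barrier + tol2)
})

test_that("stochastic walks accept correctly and find the channel saddle", {
  flat <- make_analytic_landscape("flat")
  w <- stochastic_walk(flat$fes, c(0.1, 0.1), c(0.9, 0.9), 120, seed = 4,
                       max_steps = 1e5)
  expect_false(is.null(w)) # every proposal accepted on a flat surface
  expect_equal(w$barrier, 0)
  # loop-pruned: no repeated cells
  expect_equal(anyDuplicated(paste(w$nodes[, 1], w$nodes[, 2])), 0)

  ch <- make_analytic_landscape("channel", barrier = 5)
  ok <- 0; succ <- 0
  for (s in 1:100) {
    w <- stochastic_walk(ch$fes, ch$start, ch$end, 120, seed = s)
    if (!is.null(w)) {
      succ <- succ + 1
      if (abs(w$barrier - 5) < 0.3) ok <- ok + 1
    }
  }
  expect_gte(succ, 90)
  expect_gte(ok / succ, 0.95)
})

test_that("the two-round search produces the documented candidate counts", {
  dw <- make_analytic_landscape("double_well", barrier = 8)
  cfg <- path_search_config(n_neb_repeats = 5, n_walks = 4)
  res <- two_round_search(dw$fes, dw$start, dw$end, cfg, seed = 3)
  expect_length(res$candidates, 5 * 4 + 4)
  expect_equal(sum(vapply(res$candidates, `[[`, character(1),
                          "method") == "NEB"), 20)
  # best is the lowest barrier; transition state within one cell of
  # the analytic saddle
  barriers <- vapply(res$candidates, `[[`, numeric(1), "barrier")
  expect_equal(res$best$barrier, min(barriers))
  cell <- diff(dw$fes$cv1)[1]
  expect_lt(abs(res$ts_location[1] - 0), 2 * cell)
  expect_lt(abs(res$ts_location[2] - 0), 2 * cell)
  # every candidate's ts_index attains its maximum F
  for (p in res$candidates[1:5])
    expect_equal(p$F[p$ts_index], max(p$F))

  # a single-minimum surface is rejected
  x <- seq(0, 1, length.out = 30)
  bowl <- free_energy_surface(x, x,
                              outer((x - 0.5)^2, (x - 0.5)^2, `+`) * 50)
  expect_error(two_round_search(bowl, c(0.45, 0.5), c(0.55, 0.5), cfg),
               "not separable")
})

test_that("search results serialize to the documented tables", {
  dw <- make_analytic_landscape("double_well", barrier = 8)
  cfg <- path_search_config(n_neb_repeats = 2, n_walks = 2)
  res <- two_round_search(dw$fes, dw$start, dw$end, cfg, seed = 5)
  pre <- tempfile()
  summ <- write_path_search(res, pre)
  expect_true(file.exists(paste0(pre, "_candidates.tsv")))
  expect_true(file.exists(paste0(pre, "_nodes.tsv")))
  cand <- read.table(paste0(pre, "_candidates.tsv"), header = TRUE)
  expect_equal(nrow(cand), 10)
  expect_equal(min(cand$barrier), res$best$barrier, tolerance = 1e-9)
})

test_that("the transition-state ensemble averages selected frames", {
  n <- 8
  x0 <- random_test_chain(n, 2)
  frames <- array(0, c(n, 3, 5))
  for (f in 1:5) frames[, , f] <- x0 + 0.01 * (f - 3)
  cvs <- cbind(seq(0.1, 0.5, length.out = 5), 0.3)

  # all frames identical: mean equals the single-frame matrix
  same <- array(rep(x0, 3), c(n, 3, 3))
  r <- extract_ts_ensemble(same, cbind(c(.2, .2, .2), .2), c(0.2, 0.2))
  expect_equal(r$mean_dist, as.matrix(dist(x0)), ignore_attr = TRUE)
  expect_equal(r$n_frames, 3)

  # window selection + arithmetic mean, against a direct frame loop
  r2 <- extract_ts_ensemble(frames, cvs, c(0.3, 0.3), window = 0.11)
  sel <- which(abs(cvs[, 1] - 0.3) <= 0.11)
  acc <- matrix(0, n, n)
  for (f in sel) acc <- acc + as.matrix(dist(frames[, , f]))
  expect_equal(r2$mean_dist, acc / length(sel), ignore_attr = TRUE)
  expect_equal(r2$frame_idx, sel)

  # two frames with pair distances 0.8 and 1.2 nm average to 1.0
  p2 <- array(0, c(2, 3, 2))
  p2[2, 1, 1] <- 0.8; p2[2, 1, 2] <- 1.2
  r3 <- extract_ts_ensemble(p2, cbind(c(0, 0), c(0, 0)), c(0, 0))
  expect_equal(r3$mean_dist[1, 2], 1.0)

  expect_error(extract_ts_ensemble(frames, cvs, c(9, 9)), "no trajectory")
})
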