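toy40 <- make_toy_two_state(40, 90, seed = 1)
model40 <- build_dual_basin(toy40$pair)

test_that("dual-basin construction partitions contacts correctly", {
  a <- toy40$pair$state_a
  same <- build_dual_basin(state_pair("same", a, a))
  expect_equal(nrow(same$contacts_unique_a), 0)
  expect_equal(nrow(same$contacts_unique_b), 0)

  # the generator's brute-force unique sets coincide with the model's
  key <- function(m) paste(m[, 1], m[, 2])
  expect_setequal(key(model40$contacts_unique_b),
                  key(toy40$known_unique_contacts$b))
  expect_setequal(key(model40$contacts_unique_a),
                  key(toy40$known_unique_contacts$a))

  # contact lists are disjoint and respect |i - j| >= 4
  all_c <- rbind(model40$contacts_common, model40$contacts_unique_a,
                 model40$contacts_unique_b)
  expect_equal(anyDuplicated(key(all_c)), 0)
  expect_true(all(abs(all_c[, 1] - all_c[, 2]) >= 4))
  expect_true(all(all_c[, 3] > 0))

  # four mapped residues is the smallest simulable pair (the
  # container itself rejects anything shorter)
  mini <- build_dual_basin(state_pair("small", random_test_structure(4, 1),
                                      random_test_structure(4, 2)))
  expect_equal(mini$n, 4)
  expect_equal(nrow(mini$bonds), 3)
})

test_that("state A is a stationary point of the A-side potential", {
  pe <- potential_energy(model40, toy40$pair$state_a$coords,
                         include = "a")
  expect_lt(max(abs(pe$forces)), 1e-3)
  # each contact at its minimum contributes -epsilon
  expect_equal(pe$terms[["contact"]], -1.0 * nrow(model40$contacts_common))
})

test_that("analytic forces equal finite differences", {
  set.seed(12)
  X <- toy40$pair$state_a$coords + matrix(rnorm(120, 0, 0.02), 40)
  pe <- potential_energy(model40, X)
  h <- 1e-6
  fd <- matrix(0, 40, 3)
  for (i in 1:40) {
    for (k in 1:3) {
      Xp <- X; Xp[i, k] <- Xp[i, k] + h
      Xm <- X; Xm[i, k] <- Xm[i, k] - h
      fd[i, k] <- -(potential_energy(model40, Xp)$energy -
                      potential_energy(model40, Xm)$energy) / (2 * h)
    }
  }
  expect_lt(max(abs(pe$forces - fd)) / max(abs(fd)), 1e-4)

  # translation invariance
  pe2 <- potential_energy(model40, sweep(X, 2, c(1, -2, 3), "+"))
  expect_equal(pe2$energy, pe$energy, tolerance = 1e-10)
})

test_that("the RMSD collective variable matches the superposition", {
  x <- toy40$pair$state_a$coords
  expect_equal(cv_rmsd(x, toy40$pair$state_a), 0)
  th <- 0.5
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
               c(0, 0, 1))
  expect_lt(cv_rmsd(sweep(x %*% rot, 2, c(1, 1, 1), "+"),
                    toy40$pair$state_a), 1e-10)
  expect_equal(cv_rmsd(toy40$pair$state_b$coords, toy40$pair$state_a),
               toy40$known_rmsd)
})

test_that("both endpoint structures sit in basins at low temperature", {
  for (st in c("a", "b")) {
    ref <- if (st == "a") toy40$pair$state_a else toy40$pair$state_b
    r <- run_md(model40, sim_params(n_steps = 1e4, temperature = 30,
                                    gamma = 5), seed = 3,
                coords0 = ref$coords)
    expect_lt(cv_rmsd(r$final, ref), 0.3)
  }
})

test_that("microcanonical integration conserves energy", {
  r <- run_md(model40, sim_params(n_steps = 2e4, temperature = 50,
                                  gamma = 0, dt = 5e-4,
                                  save_stride = 10),
              seed = 5, coords0 = toy40$pair$state_b$coords)
  etot <- r$epot + r$ekin
  drift <- abs(coef(lm(etot ~ seq_along(etot)))[2]) * 100 # per 1e3 steps
  expect_lt(drift, 1e-3)
})

test_that("unbiased thermostatted runs show no energy drift trend", {
  r <- run_md(model40, sim_params(n_steps = 1e4, temperature = 80,
                                  gamma = 10, save_stride = 10),
              seed = 6, coords0 = toy40$pair$state_b$coords)
  half <- r$epot[-(1:500)] # after thermalization
  fit <- summary(lm(half ~ seq_along(half)))$coefficients
  slope <- fit[2, 1]; se <- fit[2, 2]
  expect_true(abs(slope) < 2.58 * se + 1e-5)
})

test_that("metadynamics deposits hills on schedule and well-tempers", {
  run <- run_metadynamics(model40,
                          sim_params(n_steps = 1e4, temperature = 120,
                                     gamma = 1, save_stride = 100),
                          metad_params(stride = 500), seed = 7)
  expect_equal(nrow(run$hills), 20)
  expect_true(all(diff(run$hills$step) == 500))
  expect_true(all(run$hills$height > 0))
  expect_true(all(run$hills$height <= 1.0))

  # on the analytic double-well particle (which keeps revisiting its
  # start basin) the well-tempered heights there decay in the
  # visit-averaged sense
  dwr <- pathcg:::cpp_metad_double_well(10, 20, as.integer(3e5), 0.005,
                                        200, 2.0, 4L, 500L, 1.0, 0.05,
                                        50, 1.0)
  hd <- as.data.frame(dwr$hills)
  names(hd) <- c("step", "cv1", "cv2", "width1", "width2", "height")
  left <- hd[abs(hd$cv1 + 1) < 0.25, ]
  expect_gt(nrow(left), 10)
  n1 <- nrow(left)
  expect_lt(mean(tail(left$height, n1 %/% 3)),
            mean(head(left$height, n1 %/% 3)))
})

test_that("blow-ups abort with the step number", {
  expect_error(
    run_md(model40, sim_params(n_steps = 1000, dt = 0.05,
                               temperature = 300, gamma = 1),
           seed = 1),
    "blew up at step", class = "pathcg_blowup")
})

test_that("the FES estimator reproduces single-hill and plateau limits", {
  hills <- data.frame(step = 500, cv1 = 0.5, cv2 = 0.5, width1 = 0.05,
                      width2 = 0.05, height = 1.0)
  fes <- compute_fes(hills, c(0, 1), c(0, 1), 51, 51,
                     bias_factor = 1e6)
  ic <- c(which.min(abs(fes$cv1 - 0.5)), which.min(abs(fes$cv2 - 0.5)))
  expect_equal(fes$F[ic[1], ic[2]], 0) # hill center is the minimum
  expect_equal(max(fes$F), 1.0, tolerance = 1e-3) # depth ~ h
  # far corners form a flat plateau at the full deposited bias
  expect_equal(fes$F[1, 1], max(fes$F), tolerance = 1e-3)
  expect_equal(fes$F[51, 51], max(fes$F), tolerance = 1e-3)
})

test_that("hills and FES files round-trip", {
  run <- run_metadynamics(model40,
                          sim_params(n_steps = 5e3, temperature = 120,
                                     gamma = 1, save_stride = 100),
                          metad_params(stride = 500), seed = 9)
  hf <- tempfile()
  write_hills(run$hills, hf)
  back <- read_hills(hf)
  expect_equal(back$cv1, run$hills$cv1, tolerance = 1e-8)
  expect_equal(attr(back, "bias_factor"), 50)

  fes <- compute_fes(run$hills, c(0, 2), c(0, 2), 21, 21)
  ff <- tempfile()
  write_fes(fes, ff)
  fes2 <- read_fes(ff)
  expect_equal(fes2$F, fes$F, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fes2$cv1, fes$cv1, tolerance = 1e-10)
})

test_that("independent seeds give consistent free-energy surfaces", {
  runs <- lapply(c(7, 17), function(s)
    run_metadynamics(model40,
                     sim_params(n_steps = 3e5, temperature = 120,
                                gamma = 1, save_stride = 500),
                     metad_params(), seed = s))
  r1 <- range(c(runs[[1]]$hills$cv1, runs[[2]]$hills$cv1))
  r2 <- range(c(runs[[1]]$hills$cv2, runs[[2]]$hills$cv2))
  f1 <- compute_fes(runs[[1]]$hills, r1, r2, 40, 40)
  f2 <- compute_fes(runs[[2]]$hills, r1, r2, 40, 40)
  near <- function(run) {
    gx <- rep(f1$cv1, times = 40); gy <- rep(f1$cv2, each = 40)
    ok <- logical(1600)
    for (k in seq_len(nrow(run$hills)))
      ok <- ok | ((gx - run$hills$cv1[k])^2 +
                    (gy - run$hills$cv2[k])^2 < 0.2^2)
    matrix(ok, 40, 40)
  }
  joint <- near(runs[[1]]) & near(runs[[2]])
  expect_gt(sum(joint), 200)
  d <- f1$F[joint] - f2$F[joint]
  # surfaces are defined up to a constant; desk-scale runs agree to a
  # few kB*T (kB*T = 1 kJ/mol here) over the jointly sampled region
  expect_lt(sd(d), 4.0)
})
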