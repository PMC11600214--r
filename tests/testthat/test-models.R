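# A small configuration keeps the unit tests fast; the full-size
# architecture is exercised by the acceptance suite.
small_cfg <- function(n_heads = 1, seed = 1)
  hes_config(n_res_blocks = 2, channels = 16, head_cells = 16,
             n_heads = n_heads, seed = seed)

small_corpus <- function(n, rule = "midpoint", seed = 1)
  make_synthetic_training_corpus(n, l_range = c(16, 16), rule = rule,
                                 seed = seed)

test_that("the forward pass is symmetric, ordered and deterministic", {
  cfg <- small_cfg()
  m <- hes_init(cfg)
  co <- small_corpus(1, seed = 3)
  da <- co[[1]]$da; db <- co[[1]]$db

  p1 <- suppressWarnings(hes_forward(m, da, db))
  expect_identical(unclass(p1), t(unclass(p1))) # exact symmetry
  expect_true(all(p1 >= 0 & p1 < 1))

  # channel order matters: swapping A and B changes the prediction
  p2 <- suppressWarnings(hes_forward(m, db, da))
  expect_false(isTRUE(all.equal(unclass(p1), unclass(p2))))

  # bitwise-identical repeated forward pass
  p3 <- suppressWarnings(hes_forward(m, da, db))
  expect_identical(unclass(p1), unclass(p3))

  # identical seeds give identical weights
  expect_identical(hes_init(cfg)$params, hes_init(cfg)$params)

  expect_error(suppressWarnings(hes_forward(m, da[1:2, 1:2], db[1:2, 1:2])),
               ">= kernel")
})

test_that("the weighted loss applies the 5:1 unique weighting", {
  co <- small_corpus(1, seed = 5)
  e <- co[[1]]
  expect_equal(weighted_loss(e$target, e$target, e$masks), 0)

  # identical unit errors on one unique vs one non-unique pair
  uid <- which(e$masks$unique & upper.tri(e$masks$unique),
               arr.ind = TRUE)[1, ]
  nid <- which(e$masks$non_unique & upper.tri(e$masks$non_unique),
               arr.ind = TRUE)[1, ]
  pu <- e$target
  pu[uid[1], uid[2]] <- pu[uid[1], uid[2]] + 1
  pu[uid[2], uid[1]] <- pu[uid[2], uid[1]] + 1
  pn <- e$target
  pn[nid[1], nid[2]] <- pn[nid[1], nid[2]] + 1
  pn[nid[2], nid[1]] <- pn[nid[2], nid[1]] + 1
  expect_equal(weighted_loss(pu, e$target, e$masks) /
                 weighted_loss(pn, e$target, e$masks), 5)

  # brute-force double-loop oracle
  set.seed(9)
  pred <- e$target + matrix(rnorm(256, 0, 0.1), 16)
  pred <- (pred + t(pred)) / 2
  acc <- 0; np <- 0
  for (i in 1:16) for (j in 1:16) {
    w <- if (e$masks$unique[i, j]) 5 else if (e$masks$non_unique[i, j]) 1 else 0
    acc <- acc + w * (pred[i, j] - e$target[i, j])^2
    np <- np + (w > 0)
  }
  expect_equal(weighted_loss(pred, e$target, e$masks), acc / np,
               tolerance = 1e-12)

  # the C++ training loss agrees with the R definition
  m <- hes_init(small_cfg())
  lg <- pathcg:::cpp_net_loss_grad(m$params, m$config,
                                   pathcg:::stack_input(e$da, e$db),
                                   array(e$target, c(16, 16, 1)),
                                   mask_weights(e$masks))
  fwd <- pathcg:::cpp_net_forward(m$params, m$config,
                                  pathcg:::stack_input(e$da, e$db),
                                  clamp = FALSE)
  expect_equal(lg$loss, weighted_loss(fwd[, , 1], e$target, e$masks),
               tolerance = 1e-5)
})

test_that("training is seeded, monotone under lr 0, and learns", {
  co <- small_corpus(6, seed = 2)
  cfg <- small_cfg()

  # lr = 0: loss history constant
  cfg0 <- cfg; cfg0$learning_rate <- 0
  m0 <- train_hes(co, cfg0, epochs = 3, seed = 4)
  expect_equal(diff(m0$history$train_loss), c(0, 0), tolerance = 1e-12)

  # identical seeds give identical loss curves and parameters
  m1 <- train_hes(co, cfg, epochs = 4, seed = 4)
  m2 <- train_hes(co, cfg, epochs = 4, seed = 4)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(m1$params, m2$params)

  # loss drops substantially on a learnable corpus
  m3 <- train_hes(co, cfg, epochs = 25, seed = 4)
  h <- m3$history$train_loss
  expect_lt(tail(h, 1), 0.4 * h[1])

  # validation split drives checkpoint selection
  m4 <- train_hes(co, cfg, val_idx = 5:6, epochs = 5, seed = 4)
  expect_false(any(is.na(m4$history$val_loss)))
  expect_equal(m4$best_val, min(m4$history$val_loss), tolerance = 1e-12)
})

test_that("unique-contact evaluation matches textbook formulas", {
  co <- small_corpus(1, seed = 8)
  e <- co[[1]]
  ev <- evaluate_unique(e$target, e$target, e$masks)
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$mae, 0)

  shift <- e$target + 0.1
  ev2 <- evaluate_unique(shift, e$target, e$masks)
  expect_equal(ev2$pearson_r, 1)
  expect_equal(ev2$mae, 0.1)

  set.seed(3)
  noisy <- e$target + matrix(rnorm(256, 0, 0.05), 16)
  sel <- e$masks$unique & upper.tri(e$masks$unique)
  x <- noisy[sel]; y <- e$target[sel]
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ev3 <- evaluate_unique(noisy, e$target, e$masks)
  expect_equal(ev3$pearson_r, r_manual, tolerance = 1e-12)
  expect_equal(ev3$mae, mean(abs(x - y)), tolerance = 1e-12)

  none <- contact_masks(matrix(0.1, 16, 16), matrix(0.1, 16, 16))
  expect_error(evaluate_unique(noisy, e$target, none), "unique-contact")
})

test_that("pathway prediction interpolates through the three anchors", {
  cfg <- small_cfg(n_heads = 3)
  m <- hes_init(cfg)
  co <- small_corpus(1, seed = 12)
  da <- co[[1]]$da; db <- co[[1]]$db
  pp <- suppressWarnings(predict_pathway(m, da, db, n_points = 5))
  expect_length(pp$series, 5)
  expect_equal(pp$series[[1]], unclass(da), ignore_attr = TRUE)
  expect_equal(pp$series[[5]], unclass(db), ignore_attr = TRUE)
  expect_equal(pp$series[[2]], pp$anchors[, , 1], ignore_attr = TRUE)
  expect_equal(pp$series[[4]], pp$anchors[, , 3], ignore_attr = TRUE)
  for (s in pp$series) expect_equal(s, t(s), ignore_attr = TRUE)

  # the midpoint of a 9-point series between anchors is their mean
  pp9 <- suppressWarnings(predict_pathway(m, da, db, n_points = 9))
  expect_equal(pp9$series[[2]],
               (unclass(da) + pp$anchors[, , 1]) / 2,
               tolerance = 1e-6, ignore_attr = TRUE)

  m1 <- hes_init(small_cfg(n_heads = 1))
  expect_error(predict_pathway(m1, da, db), "3-head")
})

test_that("checkpoints round-trip through the text format", {
  cfg <- small_cfg()
  co <- small_corpus(2, seed = 6)
  m <- train_hes(co, cfg, epochs = 2, seed = 1)
  f <- tempfile()
  save_hes_model(m, f)
  m2 <- load_hes_model(f)
  expect_equal(m2$params, m$params, tolerance = 1e-15)
  p1 <- hes_forward(m, co[[1]]$da, co[[1]]$db)
  p2 <- hes_forward(m2, co[[1]]$da, co[[1]]$db)
  expect_identical(unclass(p1), unclass(p2))
})

test_that("degenerate corpora are flagged", {
  co <- small_corpus(2, seed = 7)
  for (i in 1:2) co[[i]]$target <- matrix(0.3, 16, 16)
  expect_warning(train_hes(co, small_cfg(), epochs = 1, seed = 1),
                 "degenerate")
})
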