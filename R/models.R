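# Residual-CNN predictor of transition-state distance matrices
# (high-energy-state module) and its three-anchor pathway extension,
# with the 5:1 unique/non-unique weighted loss, SGD training, and
# unique-contact evaluation.

#' Network and training configuration
#'
#' Defaults follow the reference architecture: an 8-block residual CNN
#' with 64 channels and kernel 3, a per-position head of 64 cells
#' (1x1 convolution stack 64 -> 64 -> 1), plain SGD with learning
#' rate 0.001, and a 5:1 weight ratio between unique and non-unique
#' residue pairs in the loss.
#'
#' @param n_res_blocks Number of residual blocks.
#' @param channels Feature channels.
#' @param kernel Convolution kernel size (odd).
#' @param head_cells Hidden cells of the per-position head.
#' @param learning_rate SGD learning rate.
#' @param unique_weight Loss weight of unique-contact pairs relative
#'   to non-unique pairs.
#' @param n_heads 1 for the transition-state predictor, 3 for the
#'   pathway model (states 2, 3, 4).
#' @param seed Seed for weight initialization.
#' @return A list of class `hes_config`.
#' @export
hes_config <- function(n_res_blocks = 8, channels = 64, kernel = 3,
                       head_cells = 64, learning_rate = 0.001,
                       unique_weight = 5, n_heads = 1, seed = 1) {
  stopifnot(n_res_blocks >= 0, channels >= 1, kernel %% 2 == 1,
            head_cells >= 1, learning_rate >= 0, unique_weight > 0,
            n_heads %in% c(1L, 3L))
  structure(list(n_res_blocks = as.integer(n_res_blocks),
                 channels = as.integer(channels),
                 kernel = as.integer(kernel),
                 head_cells = as.integer(head_cells),
                 learning_rate = learning_rate,
                 unique_weight = unique_weight,
                 n_heads = as.integer(n_heads),
                 in_channels = 2L, seed = as.integer(seed)),
            class = "hes_config")
}

#' Initialize an untrained model
#'
#' He-normal weight initialization with the configured seed; two runs
#' with the same seed give bitwise-identical parameters.
#'
#' @param config A [hes_config()].
#' @return A list of class `hes_model` with `params`, `config`,
#'   `trained`.
#' @export
hes_init <- function(config = hes_config()) {
  params <- cpp_net_init(config, config$seed)
  structure(list(params = params, config = config, trained = FALSE,
                 history = NULL),
            class = "hes_model")
}

#' @export
print.hes_model <- function(x, ...) {
  cat(sprintf(
    "<hes_model> %d res-blocks x %d ch, %d head(s), %s (%d parameters)\n",
    x$config$n_res_blocks, x$config$channels, x$config$n_heads,
    if (x$trained) "trained" else "untrained", length(x$params)))
  invisible(x)
}

stack_input <- function(da, db) {
  L <- nrow(da)
  if (!all(dim(da) == c(L, L)) || !all(dim(db) == c(L, L)))
    stop("features must be square and equally sized")
  array(c(unclass(da), unclass(db)), dim = c(L, L, 2))
}

as_target_array <- function(target, n_heads) {
  if (is.matrix(target)) {
    if (n_heads != 1)
      stop("model has ", n_heads, " heads; supply an L x L x ",
           n_heads, " target array")
    array(unclass(target), dim = c(dim(target), 1))
  } else {
    stopifnot(length(dim(target)) == 3, dim(target)[3] == n_heads)
    target
  }
}

#' Forward pass: predict the transition-state distance feature
#'
#' Stacks the two state features as an L x L x 2 tensor, runs the
#' residual CNN, symmetrizes each head output with its transpose and
#' clamps it to \[0, 1).  Channel order is (A, B): swapping the inputs
#' changes the prediction.
#'
#' @param model A [hes_init()] or trained model.
#' @param da,db Distance features of states A and B.
#' @return For a 1-head model, an L x L `distance_feature`; for a
#'   3-head model an L x L x 3 array (states 2, 3, 4).
#' @export
hes_forward <- function(model, da, db) {
  if (!model$trained)
    warning("model is untrained; predictions are noise")
  out <- cpp_net_forward(model$params, model$config, stack_input(da, db))
  if (model$config$n_heads == 1) {
    d <- out[, , 1]
    attr(d, "source") <- "predicted"
    class(d) <- c("distance_feature", class(d))
    d
  } else out
}

#' Loss weight matrix from contact masks
#'
#' `unique_weight` on unique-contact pairs, 1 on non-unique pairs, 0
#' on pairs excluded from the masks (|i - j| < min_sep).
#'
#' @param masks A [contact_masks()].
#' @param unique_weight Relative weight of unique pairs (default 5).
#' @return Numeric matrix of per-pair loss weights.
#' @export
mask_weights <- function(masks, unique_weight = 5) {
  unique_weight * masks$unique + 1 * masks$non_unique
}

#' Weighted squared-error loss over residue pairs
#'
#' Squared prediction errors weighted `unique_weight`:1 between
#' unique-contact and non-unique pairs, averaged over the included
#' pairs.  The ratio of the two weights is what matters; the
#' per-pair normalization keeps gradients comparable across protein
#' sizes.
#'
#' @param pred,target Predicted and target feature matrices (or
#'   L x L x n_heads arrays; the loss is then averaged over heads).
#' @param masks A [contact_masks()].
#' @param unique_weight Relative weight of unique pairs (default 5).
#' @return Scalar loss (0 iff pred equals target on included pairs).
#' @export
weighted_loss <- function(pred, target, masks, unique_weight = 5) {
  w <- mask_weights(masks, unique_weight)
  pred <- unclass(pred)
  nh <- if (length(dim(pred)) == 3) dim(pred)[3] else 1L
  pred <- as_target_array(pred, nh)
  target <- as_target_array(unclass(target), nh)
  stopifnot(all(dim(pred) == dim(target)))
  npair <- sum(w > 0)
  nh <- dim(pred)[3]
  tot <- 0
  for (h in seq_len(nh)) {
    e <- pred[, , h] - target[, , h]
    tot <- tot + sum(w * e * e)
  }
  tot / (npair * nh)
}

#' Assemble a training example
#'
#' @param da,db State features (L x L).
#' @param target Target feature: L x L matrix (1-head) or L x L x 3
#'   array (pathway model: states 2, 3, 4).
#' @param masks A [contact_masks()]; defaults to masks computed from
#'   `da`, `db`.
#' @return A list of class `training_example`.
#' @export
training_example <- function(da, db, target, masks = NULL) {
  if (is.null(masks)) masks <- contact_masks(da, db)
  structure(list(da = unclass(da), db = unclass(db), target = target,
                 masks = masks),
            class = "training_example")
}

#' Train the model by plain SGD
#'
#' One SGD update per example on the weighted loss (summed over the
#' three anchor states for the pathway model), with per-epoch train /
#' validation loss logging.  The returned model carries the
#' best-validation parameters (final parameters when no validation
#' split is given).
#'
#' @param corpus List of [training_example()]s.
#' @param config A [hes_config()].
#' @param model Optional warm-start model (default: fresh
#'   [hes_init()]).
#' @param val_idx Indices of validation examples (may be empty).
#' @param epochs Epoch budget.
#' @param stop_train_loss Early-stop threshold on the epoch-mean
#'   training loss (default 0: never).
#' @param seed Shuffling seed.
#' @return A trained `hes_model` with a `history` data frame
#'   (epoch, train_loss, val_loss) and `steps`.
#' @export
train_hes <- function(corpus, config = hes_config(), model = NULL,
                         val_idx = integer(), epochs = 50,
                         stop_train_loss = 0, seed = 1) {
  stopifnot(length(corpus) >= 1)
  if (is.null(model)) model <- hes_init(config) else
    config <- model$config
  xs <- lapply(corpus, function(e) stack_input(e$da, e$db))
  ys <- lapply(corpus, function(e)
    as_target_array(e$target, config$n_heads))
  ws <- lapply(corpus, function(e)
    mask_weights(e$masks, config$unique_weight))
  train_idx <- setdiff(seq_along(corpus), val_idx)
  if (!length(train_idx)) stop("no training examples left")
  targ <- vapply(ys, function(y) stats::sd(y), numeric(1))
  if (all(targ < 1e-12))
    warning("all targets are constant; degenerate corpus")
  res <- cpp_net_train(model$params, config, xs, ys, ws,
                       as.integer(train_idx), as.integer(val_idx),
                       config$learning_rate, as.integer(epochs),
                       as.integer(seed), stop_train_loss)
  structure(list(
    params = res$params, config = config, trained = TRUE,
    history = data.frame(epoch = res$epoch, train_loss = res$train_loss,
                         val_loss = res$val_loss),
    steps = res$steps, best_val = res$best_val),
    class = "hes_model")
}

#' Save / load a model checkpoint
#'
#' Plain-text checkpoint: a JSON header line with the configuration
#' followed by one parameter per line.
#'
#' @param model A `hes_model`.
#' @param path File path.
#' @return `save_hes_model` the path invisibly; `load_hes_model` the model.
#' @export
save_hes_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(
    c(unclass(model$config), list(trained = model$trained)),
    auto_unbox = TRUE), con)
  writeLines(format(model$params, digits = 17, scientific = TRUE,
                    trim = TRUE), con)
  invisible(path)
}

#' @rdname save_hes_model
#' @export
load_hes_model <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  cfg <- hes_config(hdr$n_res_blocks, hdr$channels, hdr$kernel,
                    hdr$head_cells, hdr$learning_rate,
                    hdr$unique_weight, hdr$n_heads, hdr$seed)
  structure(list(params = as.numeric(lines[-1]), config = cfg,
                 trained = isTRUE(hdr$trained), history = NULL),
            class = "hes_model")
}

#' Evaluate predictions on unique-contact pairs
#'
#' Pearson correlation and mean absolute error restricted to the
#' unique-contact entries of the upper triangle, since common
#' contacts barely change along the pathway.
#'
#' @param pred,sim_target Predicted and simulated target features.
#' @param masks A [contact_masks()].
#' @return List with `pearson_r`, `mae`, `n_pairs`.
#' @export
evaluate_unique <- function(pred, sim_target, masks) {
  sel <- masks$unique & upper.tri(masks$unique)
  if (sum(sel) < 2)
    stop("need at least 2 unique-contact pairs to evaluate")
  p <- unclass(pred)[sel]
  t <- unclass(sim_target)[sel]
  list(pearson_r = cor(p, t), mae = mean(abs(p - t)),
       n_pairs = sum(sel))
}

#' Predict the full pathway feature series
#'
#' The three heads of a pathway model give the anchor features of
#' states 2, 3 (high-energy) and 4; the full series is an elementwise
#' piecewise-linear interpolation through \[A, s2, s3, s4, B\]
#' resampled to `n_points` (so `n_points = 5` returns exactly the
#' anchors with the endpoint features).
#'
#' @param model A trained 3-head `hes_model`.
#' @param da,db Endpoint distance features.
#' @param n_points Series length (>= 5).
#' @return List of class `path_prediction` with `anchors` (L x L x 3)
#'   and `series` (list of `n_points` symmetric matrices from A to B).
#' @export
predict_pathway <- function(model, da, db, n_points = 5) {
  if (model$config$n_heads != 3)
    stop("pathway prediction needs a 3-head model")
  stopifnot(n_points >= 5)
  if (!model$trained) warning("model is untrained; predictions are noise")
  anchors <- cpp_net_forward(model$params, model$config,
                             stack_input(da, db))
  knots <- list(unclass(da), anchors[, , 1], anchors[, , 2],
                anchors[, , 3], unclass(db))
  tk <- seq(0, 1, length.out = 5)
  series <- lapply(seq(0, 1, length.out = n_points), function(t) {
    s <- max(1, min(4, findInterval(t, tk, rightmost.closed = TRUE)))
    f <- (t - tk[s]) / (tk[s + 1] - tk[s])
    (1 - f) * knots[[s]] + f * knots[[s + 1]]
  })
  structure(list(anchors = anchors, series = series,
                 n_points = n_points),
            class = "path_prediction")
}

#' @export
print.path_prediction <- function(x, ...) {
  cat(sprintf(
    "<path_prediction> %d x %d features, %d points (3 anchors + endpoints)\n",
    nrow(x$series[[1]]), ncol(x$series[[1]]), x$n_points))
  invisible(x)
}
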