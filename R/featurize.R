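# Sigmoid distance features, contact masks, residue-importance scores
# and the max-fold pathway metric.

#' Sigmoid distance transform
#'
#' D(r) = 1 - (1 + e^(1 - r))^-1 with r in nm: strictly decreasing,
#' D = 0.5 exactly at r = 1 nm (the contact threshold), D -> 0 for
#' large r, and D(0) = 1 - 1/(1 + e) at the diagonal.
#'
#' @param r Distances in nm (scalar, vector or matrix); must be
#'   finite and non-negative.
#' @return D of the same shape, entries in (0, 1 - 1/(1+e)\].
#' @export
sigmoid_distance <- function(r) {
  if (any(!is.finite(r)) || any(r < 0))
    stop("distances must be finite and >= 0")
  1 - 1 / (1 + exp(1 - r))
}

#' Inverse of the sigmoid distance transform
#'
#' @param d Feature values strictly inside (0, 1).
#' @return Distances r in nm with `sigmoid_distance(r) = d` (r may be
#'   negative for d above the r = 0 value).
#' @export
inverse_sigmoid_distance <- function(d) {
  if (any(d <= 0) || any(d >= 1)) stop("d must lie strictly in (0, 1)")
  1 - log(d / (1 - d))
}

#' Distance feature of a structure or distance matrix
#'
#' @param x A [ca_structure()], coordinate matrix, or an N x N
#'   distance matrix in nm.
#' @param source Label recorded with the feature ("state_a",
#'   "state_b", "ts_sim", "predicted", ...).
#' @return An N x N symmetric matrix of class `distance_feature`.
#' @export
distance_feature <- function(x, source = "state_a") {
  r <- if (is.matrix(x) && nrow(x) == ncol(x) &&
             isTRUE(all.equal(unname(x), unname(t(x)), tolerance = 1e-8)))
    x else pairwise_ca_distances(x)
  d <- sigmoid_distance(r)
  attr(d, "source") <- source
  class(d) <- c("distance_feature", class(d))
  d
}

#' Unique / common contact masks from two state features
#'
#' A contact is D >= 0.5 (mean C-alpha distance <= 1 nm).  `unique`
#' marks pairs in contact in exactly one state, `common` in both;
#' `non_unique` is the complement of `unique`.  Pairs with sequence
#' separation |i - j| < `min_sep` (and the diagonal) are excluded from
#' all masks.
#'
#' @param da,db Features of states A and B (equal size).
#' @param min_sep Minimum sequence separation (default 3).
#' @return List of class `contact_masks` with logical matrices
#'   `unique`, `common`, `non_unique`, `contact_a`, `contact_b`.
#' @export
contact_masks <- function(da, db, min_sep = 3) {
  if (!all(dim(da) == dim(db))) stop("feature shapes differ")
  ca <- unclass(da) >= 0.5
  cb <- unclass(db) >= 0.5
  keep <- abs(row(ca) - col(ca)) >= min_sep
  uni <- xor(ca, cb) & keep
  com <- ca & cb & keep
  structure(list(unique = uni, common = com,
                 non_unique = !uni & keep,
                 contact_a = ca & keep, contact_b = cb & keep,
                 min_sep = min_sep),
            class = "contact_masks")
}

#' @export
print.contact_masks <- function(x, ...) {
  cat(sprintf(
    "<contact_masks> %d x %d: %d unique, %d common contact pairs (upper triangle)\n",
    nrow(x$unique), ncol(x$unique), sum(x$unique[upper.tri(x$unique)]),
    sum(x$common[upper.tri(x$common)])))
  invisible(x)
}

#' Per-residue importance from contact loss at the transition state
#'
#' For each residue i the negative entries of the difference feature
#' dD = D_TS - D_native are summed over j (and sign-flipped), so the
#' score measures how much contact weight the residue loses at the
#' transition state; residues with high scores are candidate
#' regulators of the transition.
#'
#' @param d_ts,d_native Distance features of the transition state and
#'   the native state (equal size).
#' @return Numeric vector of non-negative per-residue scores.
#' @export
residue_importance <- function(d_ts, d_native) {
  if (!all(dim(d_ts) == dim(d_native))) stop("feature shapes differ")
  dd <- unclass(d_ts) - unclass(d_native)
  unname(rowSums(-pmin(dd, 0)))
}

#' Max-fold ratio of a property along a pathway
#'
#' max(x_path) / max(x_A, x_B): how far a property (surface area,
#' radius of gyration, ...) rises along the transition pathway beyond
#' its larger endpoint value.
#'
#' @param x_path Property values along the pathway (non-empty).
#' @param x_a,x_b Property values of the two endpoint structures.
#' @return The max-fold ratio.
#' @export
max_fold <- function(x_path, x_a, x_b) {
  stopifnot(length(x_path) >= 1)
  denom <- max(x_a, x_b)
  if (!is.finite(denom) || denom <= 0)
    stop("max(x_a, x_b) must be positive")
  max(x_path) / denom
}

#' Write / read a matrix as a tab-separated dump
#'
#' Plain numeric matrix dump used for features and masks.
#'
#' @param m Matrix (logical masks are written as 0/1).
#' @param path File path.
#' @return `write_matrix_tsv` the path invisibly; `read_matrix_tsv`
#'   the numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  write.table(`storage.mode<-`(unclass(m), "numeric"), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = FALSE))
}
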