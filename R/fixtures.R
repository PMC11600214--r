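# Synthetic fixtures and independent brute-force oracles: toy
# two-state hinge proteins, analytic 2D landscapes with known saddles,
# the exact widest-path (minimax) barrier oracle, and rule-based
# training corpora.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# brute-force contact scan, independent of build_dual_basin
brute_contacts <- function(coords, cutoff = 0.8, min_sep = 4) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i < min_sep) next
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff)
        out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(0L, 0, 2) else out
}

# Rodrigues rotation of points about the axis through p0 along u.
rotate_about <- function(p, p0, u, theta) {
  u <- u / sqrt(sum(u^2))
  v <- sweep(p, 2, p0)
  cr <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
              u[3] * v[, 1] - u[1] * v[, 3],
              u[1] * v[, 2] - u[2] * v[, 1])
  out <- cos(theta) * v + sin(theta) * cr +
    (1 - cos(theta)) * ((v %*% u) %*% t(u))
  sweep(out, 2, p0, "+")
}

#' Toy two-state hinge protein
#'
#' Two helical arms joined by a four-residue linker.  State B is the
#' closed form: the arms pack antiparallel against each other with a
#' dense inter-arm contact set.  State A opens the hinge: the second
#' arm is rotated rigidly by `hinge_angle_deg` about the axis through
#' the last two linker residues, which breaks the inter-arm contacts
#' while leaving every bond and angle identical between the states
#' (the hinge dihedrals are the only bonded terms that differ).  All
#' ground-truth fields (`known_rmsd`, `known_unique_contacts`,
#' `hinge_residues`) are computed by direct brute-force scans at
#' generation time.  `hinge_residues` are the residues whose contact
#' environment changes most between the states (at least 60% of the
#' maximal per-residue unique-contact count).
#'
#' @param n_residues Chain length (>= 20; default 40).
#' @param hinge_angle_deg Opening rotation in degrees (default 90;
#'   about 1.3 nm RMSD at 90 degrees for 40 residues).
#' @param seed Seed for the random sequence.
#' @param contact_cutoff Contact cutoff (nm) for the ground-truth
#'   scans.
#' @return List of class `toy_two_state` with `pair` (a
#'   [state_pair()]), `known_rmsd`, `known_unique_contacts` (lists
#'   `a`, `b`), `hinge_residues`, and the arm/linker index ranges.
#' @export
make_toy_two_state <- function(n_residues = 40, hinge_angle_deg = 90,
                               seed = 1, contact_cutoff = 0.8) {
  stopifnot(n_residues >= 20)
  if (hinge_angle_deg == 0)
    warning("hinge angle 0: the two states are identical")
  n_link <- 4L
  na <- (n_residues - n_link) %/% 2L
  nb <- n_residues - n_link - na
  rise <- 0.15; rad <- 0.23; omega <- 100 * pi / 180

  seqc <- with_seed(seed, sample(AA20, n_residues, replace = TRUE))

  arm1 <- t(vapply(0:(na - 1), function(i)
    c(rise * i, rad * cos(omega * i), rad * sin(omega * i)),
    numeric(3)))
  x1 <- arm1[na, 1]
  l3 <- c(x1 + 0.80, -0.15, 0.62)
  l4 <- c(x1 + 0.80, 0.20, 0.67)
  link <- rbind(c(x1 + 0.30, -0.10, 0.17),
                c(x1 + 0.55, 0.05, 0.40), l3, l4)
  arm2 <- t(vapply(0:(nb - 1), function(j)
    c(x1 + 0.35 - rise * j, rad * cos(-pi / 2 - omega * j),
      0.80 + rad * sin(-pi / 2 - omega * j)), numeric(3)))
  xb <- rbind(arm1, link, arm2) # closed state
  arm2_idx <- (na + n_link + 1):n_residues
  xa <- xb # open state: rotate the second arm about the hinge axis
  xa[arm2_idx, ] <- rotate_about(xb[arm2_idx, , drop = FALSE], l4,
                                 l4 - l3,
                                 hinge_angle_deg * pi / 180)

  ss <- paste(c(rep("H", na), rep("C", n_link), rep("H", nb)),
              collapse = "")
  seqs <- paste(seqc, collapse = "")
  sa <- ca_structure("toyA", seqs, xa, ss = ss, source = "toy fixture")
  sb <- ca_structure("toyB", seqs, xb, ss = ss, source = "toy fixture")
  pair <- state_pair("toy_hinge", sa, sb)

  ca <- brute_contacts(xa, contact_cutoff)
  cb <- brute_contacts(xb, contact_cutoff)
  key_a <- paste(ca[, 1], ca[, 2])
  key_b <- paste(cb[, 1], cb[, 2])
  ua <- ca[!(key_a %in% key_b), , drop = FALSE]
  ub <- cb[!(key_b %in% key_a), , drop = FALSE]
  cnt <- tabulate(c(ua, ub), nbins = n_residues)
  hinge <- if (max(cnt) > 0) which(cnt >= 0.6 * max(cnt)) else integer()

  structure(
    list(pair = pair, known_rmsd = superpose_rmsd(xa, xb)$rmsd,
         known_unique_contacts = list(a = ua, b = ub),
         known_common_contacts = ca[key_a %in% key_b, , drop = FALSE],
         hinge_residues = hinge,
         arm1 = c(1L, na), linker = c(na + 1L, na + n_link),
         arm2 = range(arm2_idx), hinge_angle_deg = hinge_angle_deg),
    class = "toy_two_state")
}

#' @export
print.toy_two_state <- function(x, ...) {
  cat(sprintf(
    "<toy_two_state> %d residues, hinge %g deg, rmsd %.3f nm, unique contacts A %d / B %d\n",
    length(x$pair$state_a), x$hinge_angle_deg, x$known_rmsd,
    nrow(x$known_unique_contacts$a), nrow(x$known_unique_contacts$b)))
  invisible(x)
}

#' Analytic 2D free-energy landscapes with known features
#'
#' Closed-form surfaces sampled on a regular grid:
#' \describe{
#'   \item{flat}{F = 0 on \[0,1\]^2; no saddle.}
#'   \item{double_well}{F = b (x^2 - 1)^2 + ky y^2 on
#'     \[-1.6, 1.6\] x \[-0.8, 0.8\]; minima (+-1, 0), saddle (0, 0),
#'     barrier exactly `b`.}
#'   \item{channel}{high walls except a narrow channel along
#'     y = 0.5 carrying one Gaussian bump of height `b` at x = 0.5;
#'     saddle (0.5, 0.5), barrier `b`.}
#'   \item{random_smooth}{sum of `n_gauss` random Gaussians of
#'     amplitude +-`amplitude`; regenerated with shifted seeds until
#'     two separable basins exist.  `start`/`end` are the two lowest
#'     separable local minima.}
#' }
#'
#' @param kind One of "flat", "double_well", "channel",
#'   "random_smooth".
#' @param n1,n2 Grid size (default 50 x 50).
#' @param barrier Barrier parameter b in kJ/mol (default 10).
#' @param ky Transverse stiffness of the double well (default 20).
#' @param amplitude,n_gauss Random-landscape parameters.
#' @param seed Seed for "random_smooth".
#' @return List of class `analytic_landscape` with `fes`, `kind`,
#'   `known_saddle`, `known_barrier`, `start`, `end`.
#' @export
make_analytic_landscape <- function(kind = c("flat", "double_well",
                                             "channel", "random_smooth"),
                                    n1 = 50, n2 = 50, barrier = 10,
                                    ky = 20, amplitude = 6, n_gauss = 12,
                                    seed = 1) {
  kind <- match.arg(kind)
  known_saddle <- NULL; known_barrier <- NA_real_
  if (kind == "flat") {
    x <- seq(0, 1, length.out = n1); y <- seq(0, 1, length.out = n2)
    F <- matrix(0, n1, n2)
    start <- c(x[2], y[2]); end <- c(x[n1 - 1], y[n2 - 1])
  } else if (kind == "double_well") {
    x <- seq(-1.6, 1.6, length.out = n1)
    y <- seq(-0.8, 0.8, length.out = n2)
    F <- outer(barrier * (x^2 - 1)^2, ky * y^2, `+`)
    known_saddle <- c(0, 0); known_barrier <- barrier
    start <- c(-1, 0); end <- c(1, 0)
  } else if (kind == "channel") {
    x <- seq(0, 1, length.out = n1); y <- seq(0, 1, length.out = n2)
    wall <- 100
    inchan <- abs(y - 0.5) <= 1.2 * (y[2] - y[1])
    F <- matrix(wall, n1, n2)
    F[, inchan] <- outer(barrier * exp(-(x - 0.5)^2 / 0.005),
                         rep(1, sum(inchan)))
    known_saddle <- c(0.5, 0.5); known_barrier <- barrier
    start <- c(x[2], 0.5); end <- c(x[n1 - 1], 0.5)
  } else {
    x <- seq(0, 1, length.out = n1); y <- seq(0, 1, length.out = n2)
    for (try in 0:50) {
      F <- matrix(0, n1, n2)
      with_seed(seed + 1000L * try, {
        for (g in seq_len(n_gauss)) {
          cx <- runif(1, 0.05, 0.95); cy <- runif(1, 0.05, 0.95)
          a <- runif(1, -amplitude, amplitude)
          w <- runif(1, 0.08, 0.25)
          F <- F + a * exp(-(outer((x - cx)^2, (y - cy)^2, `+`)) /
                             (2 * w^2))
        }
      })
      mins <- find_local_minima(F)
      se <- pick_separable_minima(F, mins)
      if (!is.null(se)) {
        start <- c(x[se$start[1]], y[se$start[2]])
        end <- c(x[se$end[1]], y[se$end[2]])
        break
      }
      if (try == 50) stop("could not generate a two-basin landscape")
    }
  }
  structure(list(fes = free_energy_surface(x, y, F), kind = kind,
                 known_saddle = known_saddle,
                 known_barrier = known_barrier,
                 start = start, end = end, seed = seed),
            class = "analytic_landscape")
}

find_local_minima <- function(F) {
  n1 <- nrow(F); n2 <- ncol(F)
  out <- NULL
  for (i in 2:(n1 - 1)) {
    for (j in 2:(n2 - 1)) {
      if (F[i, j] < F[i - 1, j] && F[i, j] < F[i + 1, j] &&
          F[i, j] < F[i, j - 1] && F[i, j] < F[i, j + 1])
        out <- rbind(out, c(i, j))
    }
  }
  out
}

# two lowest local minima separated by a positive minimax barrier
pick_separable_minima <- function(F, mins, min_barrier = 1.0) {
  if (is.null(mins) || nrow(mins) < 2) return(NULL)
  ord <- order(F[mins])
  mins <- mins[ord, , drop = FALSE]
  a <- mins[1, ]
  for (k in 2:nrow(mins)) {
    b <- mins[k, ]
    thr <- minimax_threshold(F, a, b)
    if (thr - max(F[a[1], a[2]], F[b[1], b[2]]) >= min_barrier)
      return(list(start = a, end = b))
  }
  NULL
}

# 4-connected BFS reachability under a threshold (oracle internals)
oracle_connected <- function(F, sc, ec, level) {
  n1 <- nrow(F); n2 <- ncol(F)
  if (F[sc[1], sc[2]] > level || F[ec[1], ec[2]] > level) return(FALSE)
  seen <- matrix(FALSE, n1, n2)
  qi <- integer(n1 * n2); qj <- integer(n1 * n2)
  qi[1] <- sc[1]; qj[1] <- sc[2]
  seen[sc[1], sc[2]] <- TRUE
  head <- 1L; tail <- 1L
  while (head <= tail) {
    ci <- qi[head]; cj <- qj[head]; head <- head + 1L
    if (ci == ec[1] && cj == ec[2]) return(TRUE)
    if (ci > 1 && !seen[ci - 1, cj] && F[ci - 1, cj] <= level) {
      tail <- tail + 1L; qi[tail] <- ci - 1L; qj[tail] <- cj
      seen[ci - 1, cj] <- TRUE
    }
    if (ci < n1 && !seen[ci + 1, cj] && F[ci + 1, cj] <= level) {
      tail <- tail + 1L; qi[tail] <- ci + 1L; qj[tail] <- cj
      seen[ci + 1, cj] <- TRUE
    }
    if (cj > 1 && !seen[ci, cj - 1] && F[ci, cj - 1] <= level) {
      tail <- tail + 1L; qi[tail] <- ci; qj[tail] <- cj - 1L
      seen[ci, cj - 1] <- TRUE
    }
    if (cj < n2 && !seen[ci, cj + 1] && F[ci, cj + 1] <= level) {
      tail <- tail + 1L; qi[tail] <- ci; qj[tail] <- cj + 1L
      seen[ci, cj + 1] <- TRUE
    }
  }
  FALSE
}

minimax_threshold <- function(F, sc, ec) {
  lv <- sort(unique(as.vector(F)))
  lv <- lv[lv >= max(F[sc[1], sc[2]], F[ec[1], ec[2]])]
  lo <- 1L; hi <- length(lv)
  if (!oracle_connected(F, sc, ec, lv[hi]))
    stop("start and end are disconnected on the grid")
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (oracle_connected(F, sc, ec, lv[mid])) hi <- mid else
      lo <- mid + 1L
  }
  lv[lo]
}

#' Exact widest-path (minimax) barrier oracle
#'
#' Binary search over the sorted grid values with 4-connected flood
#' fill: the lowest threshold t such that start and end are connected
#' through cells with F <= t.  Exhaustive and deterministic; serves as
#' the independent reference for [two_round_search()].
#'
#' @param fes A [free_energy_surface()] (or an `analytic_landscape`).
#' @param start,end CV-space points; default taken from the landscape
#'   object.
#' @return List with `barrier` (t - F(start)), `threshold` (t), and
#'   `path` (one optimal cell path as an m x 2 matrix of CV points).
#' @export
minimax_path_oracle <- function(fes, start = NULL, end = NULL) {
  if (inherits(fes, "analytic_landscape")) {
    if (is.null(start)) start <- fes$start
    if (is.null(end)) end <- fes$end
    fes <- fes$fes
  }
  if (is.null(start) || is.null(end))
    stop("start/end required for a bare free_energy_surface")
  sc <- fes_cell(fes, start)
  ec <- fes_cell(fes, end)
  thr <- minimax_threshold(fes$F, sc, ec)
  # one optimal path via BFS at the threshold level
  n1 <- nrow(fes$F); n2 <- ncol(fes$F)
  prev <- array(NA_integer_, c(n1, n2, 2))
  seen <- matrix(FALSE, n1, n2)
  queue <- list(sc)
  seen[sc[1], sc[2]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur[1] == ec[1] && cur[2] == ec[2]) break
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
      if (ni >= 1 && ni <= n1 && nj >= 1 && nj <= n2 &&
          !seen[ni, nj] && fes$F[ni, nj] <= thr) {
        seen[ni, nj] <- TRUE
        prev[ni, nj, ] <- cur
        queue <- c(queue, list(c(ni, nj)))
      }
    }
  }
  path <- ec
  cur <- ec
  while (!(cur[1] == sc[1] && cur[2] == sc[2])) {
    cur <- prev[cur[1], cur[2], ]
    if (any(is.na(cur))) break
    path <- rbind(cur, path)
  }
  list(barrier = thr - fes$F[sc[1], sc[2]], threshold = thr,
       path = cbind(fes$cv1[path[, 1]], fes$cv2[path[, 2]]))
}

# a compact random chain with realistic contact density
random_compact_chain <- function(L) {
  d <- matrix(rnorm(3), 1)
  d <- d / sqrt(sum(d^2))
  dirs <- matrix(0, L - 1, 3)
  for (k in seq_len(L - 1)) {
    d <- 0.75 * d + 0.66 * rnorm(3)
    d <- d / sqrt(sum(d^2))
    dirs[k, ] <- d
  }
  x <- rbind(0, apply(dirs * 0.38, 2, cumsum))
  # compact until the mean long-range contact count is protein-like
  for (it in 1:60) {
    dm <- as.matrix(stats::dist(x))
    sep <- abs(row(dm) - col(dm))
    cpr <- sum(dm < 1.0 & sep >= 3) / L
    if (cpr >= 6 || min(dm[sep >= 2]) < 0.30) break
    x <- sweep(x, 2, colMeans(x))
    x <- x * 0.96
  }
  x
}

#' Rule-based synthetic training corpus
#'
#' Each example draws two random compact chains of the same length,
#' featurizes them (states A and B), and sets the transition-state
#' target by a known deterministic rule on unique-contact pairs
#' (elementwise min, geometric mean, or midpoint of the two state
#' features) with the midpoint elsewhere.  A model that recovers the
#' rule on held-out examples demonstrates that the architecture can
#' learn deterministic transition-state maps.
#'
#' @param n_examples Number of examples.
#' @param l_range Chain-length range `c(lo, hi)` (default both 32).
#' @param rule "elementwise_min", "geometric_mean" or "midpoint".
#' @param seed Integer seed; the corpus is bitwise reproducible.
#' @return List of [training_example()]s; attribute `rule` records
#'   the generating rule.
#' @export
make_synthetic_training_corpus <- function(n_examples, l_range = c(32, 32),
                                           rule = c("elementwise_min",
                                                    "geometric_mean",
                                                    "midpoint"),
                                           seed = 1) {
  rule <- match.arg(rule)
  fr <- switch(rule,
               elementwise_min = function(a, b) pmin(a, b),
               geometric_mean = function(a, b) sqrt(a * b),
               midpoint = function(a, b) (a + b) / 2)
  corpus <- with_seed(seed, lapply(seq_len(n_examples), function(e) {
    L <- if (l_range[1] == l_range[2]) l_range[1] else
      sample(l_range[1]:l_range[2], 1)
    da <- distance_feature(random_compact_chain(L), "state_a")
    db <- distance_feature(random_compact_chain(L), "state_b")
    masks <- contact_masks(da, db)
    target <- (unclass(da) + unclass(db)) / 2
    target[masks$unique] <- fr(unclass(da), unclass(db))[masks$unique]
    training_example(da, db, target, masks)
  }))
  attr(corpus, "rule") <- rule
  attr(corpus, "seed") <- seed
  corpus
}
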