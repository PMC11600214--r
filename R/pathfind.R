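# Two-round transition-pathway search on a free-energy surface:
# nudged-elastic-band relaxation from random bead placements (round 1)
# and Metropolis-accepted stochastic grid walks (round 2), followed by
# lowest-barrier selection and transition-state localization.

fes_cell <- function(fes, pt) {
  c(which.min(abs(fes$cv1 - pt[1])), which.min(abs(fes$cv2 - pt[2])))
}

fes_at <- function(fes, pts) {
  pts <- matrix(pts, ncol = 2)
  cpp_bilinear(fes$F, fes$cv1, fes$cv2, pts[, 1], pts[, 2])
}

fes_cell_size <- function(fes) {
  min(diff(fes$cv1)[1], diff(fes$cv2)[1])
}

in_domain <- function(fes, pt) {
  pt[1] >= min(fes$cv1) && pt[1] <= max(fes$cv1) &&
    pt[2] >= min(fes$cv2) && pt[2] <= max(fes$cv2)
}

# resample a polyline at roughly `spacing` arc-length steps
densify_path <- function(nodes, spacing) {
  seg <- sqrt(rowSums(diff(nodes)^2))
  if (!nrow(nodes) || sum(seg) == 0) return(nodes)
  s <- c(0, cumsum(seg))
  m <- max(2L, ceiling(s[length(s)] / spacing) + 1L)
  at <- seq(0, s[length(s)], length.out = m)
  cbind(approx(s, nodes[, 1], xout = at)$y,
        approx(s, nodes[, 2], xout = at)$y)
}

candidate_path <- function(fes, nodes, method, params, seed) {
  Fv <- fes_at(fes, nodes)
  ts <- which.max(Fv)
  arc <- sum(sqrt(rowSums(diff(nodes)^2)))
  structure(
    list(nodes = nodes, F = Fv, barrier = max(Fv) - Fv[1],
         ts_index = ts, ts_location = nodes[ts, ], method = method,
         params = params, seed = seed, arc_length = arc,
         mean_F = mean(Fv)),
    class = "candidate_path")
}

#' @export
print.candidate_path <- function(x, ...) {
  cat(sprintf(
    "<candidate_path> %s (%s): barrier %.3f kJ/mol, TS at (%.3f, %.3f)\n",
    x$method, format(x$params), x$barrier, x$ts_location[1],
    x$ts_location[2]))
  invisible(x)
}

#' Nudged-elastic-band path search on a free-energy surface
#'
#' Beads (default 7) are placed at random in the landscape with the
#' endpoints fixed at the two basins, then relaxed for `iters`
#' iterations under the landscape force perpendicular to the path
#' (bilinear-interpolated gradient) plus spring forces between
#' neighbors.  The converged bead polyline is densified along its
#' segments for barrier evaluation.
#'
#' @param fes A [free_energy_surface()].
#' @param start,end CV-space points `c(cv1, cv2)` of the two basins.
#' @param k_spring Spring constant (relative weight).
#' @param n_beads Number of beads (default 7).
#' @param iters Relaxation iterations (default 1000).
#' @param seed Integer RNG seed for the random bead placement.
#' @return A `candidate_path` with `nodes`, `barrier` (max F along the
#'   path minus F at the start), `ts_index`, `ts_location`.
#' @export
neb_search <- function(fes, start, end, k_spring, n_beads = 7,
                       iters = 1000, seed = 1) {
  if (!in_domain(fes, start) || !in_domain(fes, end))
    stop("start/end outside the FES domain")
  if (any(!is.finite(fes$F))) stop("non-finite free energy on the grid")
  beads <- cpp_neb(fes$F, fes$cv1, fes$cv2, start[1], start[2],
                   end[1], end[2], k_spring, as.integer(n_beads),
                   as.integer(iters), as.integer(seed))
  nodes <- densify_path(beads, 0.25 * fes_cell_size(fes))
  candidate_path(fes, nodes, "NEB", k_spring, seed)
}

#' Stochastic grid walk between two basins
#'
#' From the current grid cell a uniformly chosen 4-neighbor is
#' accepted with probability `min(1, exp(-dG / kB T))`; the walk runs
#' until the end cell is reached or `max_steps` proposals are
#' exhausted.  Self-intersections are pruned, so the returned path is
#' loop-free.
#'
#' @param fes A [free_energy_surface()].
#' @param start,end CV-space points of the two basins.
#' @param temperature Walk temperature in K (sets kB*T for the
#'   acceptance rule).
#' @param seed Integer RNG seed.
#' @param max_steps Proposal budget (default 2e5).
#' @return A `candidate_path`, or `NULL` when the end cell was not
#'   reached (the caller is expected to reseed and retry).
#' @export
stochastic_walk <- function(fes, start, end, temperature = 120,
                            seed = 1, max_steps = 2e5) {
  sc <- fes_cell(fes, start)
  ec <- fes_cell(fes, end)
  kT <- .kB * temperature
  cells <- cpp_walk(fes$F, sc[1] - 1L, sc[2] - 1L, ec[1] - 1L,
                    ec[2] - 1L, kT, as.integer(max_steps),
                    as.integer(seed))
  if (!nrow(cells)) return(NULL)
  nodes <- cbind(fes$cv1[cells[, 1] + 1L], fes$cv2[cells[, 2] + 1L])
  candidate_path(fes, nodes, "walk", temperature, seed)
}

# 4-connected reachability of end from start using only cells with
# F <= level (basin-separability check)
cells_connected <- function(F, sc, ec, level) {
  n1 <- nrow(F); n2 <- ncol(F)
  ok <- F <= level
  if (!ok[sc[1], sc[2]] || !ok[ec[1], ec[2]]) return(FALSE)
  seen <- matrix(FALSE, n1, n2)
  queue <- matrix(sc, ncol = 2)
  seen[sc[1], sc[2]] <- TRUE
  while (nrow(queue)) {
    cur <- queue[nrow(queue), ]
    queue <- queue[-nrow(queue), , drop = FALSE]
    if (cur[1] == ec[1] && cur[2] == ec[2]) return(TRUE)
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
      if (ni >= 1 && ni <= n1 && nj >= 1 && nj <= n2 &&
          ok[ni, nj] && !seen[ni, nj]) {
        seen[ni, nj] <- TRUE
        queue <- rbind(queue, c(ni, nj))
      }
    }
  }
  FALSE
}

#' Configuration for the two-round pathway search
#'
#' Defaults: 100 NEB restarts for each of the four spring constants
#' 0.3, 0.6, 0.9, 1.2, plus 50 stochastic walks, giving 450 candidate
#' paths.
#'
#' @param n_neb_repeats NEB restarts per spring constant.
#' @param springs Spring constants (relative weights).
#' @param n_beads,neb_iters NEB bead count and iterations.
#' @param n_walks Number of successful stochastic walks required.
#' @param walk_temperature Walk temperature in K.
#' @param walk_max_steps Proposal budget per walk attempt.
#' @param max_walk_attempts Attempt cap before giving up.
#' @return A list of class `path_search_config`.
#' @export
path_search_config <- function(n_neb_repeats = 100,
                               springs = c(0.3, 0.6, 0.9, 1.2),
                               n_beads = 7, neb_iters = 1000,
                               n_walks = 50, walk_temperature = 120,
                               walk_max_steps = 2e5,
                               max_walk_attempts = 50 * 200) {
  structure(as.list(environment()), class = "path_search_config")
}

#' Two-round transition-pathway search
#'
#' Round 1: `n_neb_repeats` NEB relaxations from random bead
#' placements for each spring constant.  Round 2: stochastic walks,
#' reseeded until `n_walks` successes.  The candidate with the lowest
#' barrier is the transition pathway; ties are broken by shorter arc
#' length, then lower mean free energy.  Its maximum-F node is the
#' transition state.
#'
#' @param fes A [free_energy_surface()].
#' @param start,end CV-space points of the two basins.
#' @param config A [path_search_config()].
#' @param seed Integer master seed (individual searches derive their
#'   own seeds from it).
#' @return List of class `path_search_result` with `candidates`,
#'   `best`, `ts_location`.
#' @export
two_round_search <- function(fes, start, end,
                             config = path_search_config(), seed = 1) {
  sc <- fes_cell(fes, start)
  ec <- fes_cell(fes, end)
  if (all(sc == ec))
    stop("start and end fall in the same grid cell; basins not separable")
  lev <- max(fes$F[sc[1], sc[2]], fes$F[ec[1], ec[2]]) + 1e-9
  if (cells_connected(fes$F, sc, ec, lev))
    stop("basins not separable: start and end are connected without ",
         "climbing in free energy (single minimum?)")

  candidates <- vector("list",
                       config$n_neb_repeats * length(config$springs) +
                         config$n_walks)
  ci <- 0L
  s <- 0L
  for (k in config$springs) {
    for (r in seq_len(config$n_neb_repeats)) {
      s <- s + 1L
      ci <- ci + 1L
      candidates[[ci]] <- neb_search(fes, start, end, k,
                                     config$n_beads, config$neb_iters,
                                     seed = seed * 1009L + s)
    }
  }
  n_ok <- 0L
  attempt <- 0L
  while (n_ok < config$n_walks) {
    attempt <- attempt + 1L
    if (attempt > config$max_walk_attempts)
      stop("stochastic walks kept failing; increase walk_max_steps")
    w <- stochastic_walk(fes, start, end, config$walk_temperature,
                         seed = seed * 2003L + attempt,
                         max_steps = config$walk_max_steps)
    if (is.null(w)) next
    n_ok <- n_ok + 1L
    ci <- ci + 1L
    candidates[[ci]] <- w
  }

  barriers <- vapply(candidates, `[[`, numeric(1), "barrier")
  arcs <- vapply(candidates, `[[`, numeric(1), "arc_length")
  meanf <- vapply(candidates, `[[`, numeric(1), "mean_F")
  best <- candidates[[order(barriers, arcs, meanf)[1]]]
  structure(
    list(candidates = candidates, best = best,
         ts_location = best$ts_location),
    class = "path_search_result")
}

#' @export
print.path_search_result <- function(x, ...) {
  cat(sprintf(
    "<path_search_result> %d candidates; best: %s barrier %.3f kJ/mol, TS (%.3f, %.3f)\n",
    length(x$candidates), x$best$method, x$best$barrier,
    x$ts_location[1], x$ts_location[2]))
  invisible(x)
}

#' Write candidate paths and the search summary
#'
#' `<prefix>_candidates.tsv` holds one row per candidate (method,
#' param, seed, barrier, arc_length, n_nodes); `<prefix>_nodes.tsv`
#' the node lists keyed by candidate index; `<prefix>_summary.tsv` the
#' best path and transition-state location.
#'
#' @param result A `path_search_result`.
#' @param prefix Output path prefix.
#' @return Invisibly, the summary data frame.
#' @export
write_path_search <- function(result, prefix) {
  cand <- data.frame(
    index = seq_along(result$candidates),
    method = vapply(result$candidates, `[[`, character(1), "method"),
    param = vapply(result$candidates, function(p)
      as.numeric(p$params[1]), numeric(1)),
    seed = vapply(result$candidates, `[[`, numeric(1), "seed"),
    barrier = vapply(result$candidates, `[[`, numeric(1), "barrier"),
    arc_length = vapply(result$candidates, `[[`, numeric(1),
                        "arc_length"),
    n_nodes = vapply(result$candidates, function(p) nrow(p$nodes),
                     integer(1)))
  write.table(cand, paste0(prefix, "_candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  nodes <- do.call(rbind, lapply(seq_along(result$candidates),
                                 function(i) {
    cbind(index = i, cv1 = result$candidates[[i]]$nodes[, 1],
          cv2 = result$candidates[[i]]$nodes[, 2])
  }))
  write.table(as.data.frame(nodes), paste0(prefix, "_nodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- data.frame(best_method = result$best$method,
                     best_barrier = result$best$barrier,
                     ts_cv1 = result$ts_location[1],
                     ts_cv2 = result$ts_location[2])
  write.table(summ, paste0(prefix, "_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(summ)
}

#' Transition-state ensemble distance matrix from a trajectory
#'
#' Selects the frames whose collective variables fall inside the
#' window `ts_location +/- window` on both axes and averages their
#' pairwise C-alpha distance matrices.
#'
#' @param frames N x 3 x n_frames coordinate array (nm), or a
#'   `metad_run`.
#' @param cv_series n_frames x 2 matrix of (RMSD_A, RMSD_B); taken
#'   from the run when `frames` is a `metad_run`.
#' @param ts_location CV-space point `c(cv1, cv2)`.
#' @param window Half-width of the selection box in nm (default 0.08,
#'   i.e. +/- 0.8 Angstrom).
#' @return List with `mean_dist` (N x N nm), `frame_idx`, `n_frames`.
#' @export
extract_ts_ensemble <- function(frames, cv_series = NULL, ts_location,
                                window = 0.08) {
  if (inherits(frames, "metad_run")) {
    cv_series <- frames$cvs
    frames <- frames$frames
  }
  stopifnot(length(dim(frames)) == 3, !is.null(cv_series),
            nrow(cv_series) == dim(frames)[3])
  sel <- which(abs(cv_series[, 1] - ts_location[1]) <= window &
                 abs(cv_series[, 2] - ts_location[2]) <= window)
  if (!length(sel))
    stop("no trajectory frames inside the transition-state window; ",
         "sample longer or widen the window")
  n <- dim(frames)[1]
  acc <- matrix(0, n, n)
  for (f in sel)
    acc <- acc + as.matrix(stats::dist(frames[, , f]))
  list(mean_dist = acc / length(sel), frame_idx = sel,
       n_frames = length(sel))
}
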