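# Conversion of predicted distance features into C-alpha structures:
# a single-basin model of the reference state with contacts in the
# changing regions replaced by predicted distance restraints, relaxed
# by restrained simulated annealing.

#' Build a restrained single-basin model
#'
#' Starts from the single-basin (state A) terms of a dual-basin model
#' built on `ref` alone, removes every native contact that falls
#' inside the listed changing regions, and adds a flat-bottom distance
#' restraint for every predicted contact (D >= 0.5) in those regions,
#' with equilibrium distance obtained by inverting the sigmoid
#' transform at the predicted D.
#'
#' @param ref Reference [ca_structure()] (the state the pathway leaves
#'   from).
#' @param predicted Predicted `distance_feature` (L x L, L matching
#'   `ref`).
#' @param changing_regions List of region pairs; each element is
#'   `list(c(i_lo, i_hi), c(j_lo, j_hi))` of 1-based residue ranges
#'   whose mutual contacts are replaced.
#' @param strength Restraint strength in kJ/mol (default 2.0).
#' @param flat_width Flat-bottom half-width in nm (default 0.05).
#' @param min_sep Minimum |i - j| for a restraint (default 4, the
#'   contact convention).
#' @param ... Passed to [build_dual_basin()] (cutoff, force
#'   constants).
#' @return A list of class `restraint_model`.
#' @export
build_restraint_model <- function(ref, predicted, changing_regions = list(),
                                  strength = 2.0, flat_width = 0.05,
                                  min_sep = 4, ...) {
  n <- length(ref)
  if (!all(dim(predicted) == c(n, n)))
    stop("predicted feature does not match the reference size")
  for (reg in changing_regions) {
    rng <- c(reg[[1]], reg[[2]])
    if (any(rng < 1) || any(rng > n))
      stop("changing region out of sequence bounds (1..", n, ")")
  }
  base <- build_dual_basin(state_pair(ref$id, ref, ref), ...)

  in_regions <- matrix(FALSE, n, n)
  for (reg in changing_regions) {
    i <- reg[[1]][1]:reg[[1]][2]
    j <- reg[[2]][1]:reg[[2]][2]
    in_regions[i, j] <- TRUE
    in_regions[j, i] <- TRUE
  }

  # drop native contacts inside the regions (A == B here, so all
  # contacts are "common")
  keep <- !in_regions[base$contacts_common[, 1:2, drop = FALSE]]
  removed <- base$contacts_common[!keep, , drop = FALSE]
  base$contacts_common <- base$contacts_common[keep, , drop = FALSE]

  pred <- unclass(predicted)
  sel <- which(in_regions & upper.tri(pred) &
                 abs(row(pred) - col(pred)) >= min_sep & pred >= 0.5,
               arr.ind = TRUE)
  restraints <- if (nrow(sel))
    cbind(sel, inverse_sigmoid_distance(pred[sel]), strength)
  else matrix(0, 0, 4)
  colnames(restraints) <- c("i", "j", "r0", "k")

  structure(list(base = base, removed_pairs = removed,
                 restraints = restraints, strength = strength,
                 flat_width = flat_width, ref = ref),
            class = "restraint_model")
}

#' @export
print.restraint_model <- function(x, ...) {
  cat(sprintf(
    "<restraint_model> %d residues: %d native contacts kept, %d removed, %d restraints (k = %g kJ/mol)\n",
    x$base$n, nrow(x$base$contacts_common), nrow(x$removed_pairs),
    nrow(x$restraints), x$strength))
  invisible(x)
}

assemble_restraint_model <- function(model) {
  assemble_model(model$base, include = "common",
                 restraints = model$restraints,
                 flat_width = model$flat_width)
}

# squared restraint violations beyond the flat bottom, per restraint
restraint_violation <- function(coords, restraints, flat_width) {
  if (!nrow(restraints)) return(numeric())
  d <- sqrt(rowSums((coords[restraints[, 1], , drop = FALSE] -
                       coords[restraints[, 2], , drop = FALSE])^2))
  pmax(abs(d - restraints[, 3]) - flat_width, 0)^2
}

#' Restrained simulated annealing
#'
#' Independent Langevin runs with a linear temperature ramp from
#' `t_start` to `t_end`; the final frame of each run is returned as a
#' structure.  A run whose coordinates blow up is reported as failed
#' while the others are kept.
#'
#' @param model A [build_restraint_model()] model.
#' @param n_runs Number of annealing runs (default 10).
#' @param t_start,t_end Temperature ramp in K (default 100 -> 10).
#' @param n_steps Steps per run (default 3e6).
#' @param seed Integer seed; run r uses `seed + r`.
#' @param coords0 Starting coordinates (default: the reference state).
#' @param dt,gamma,mass Integrator settings.
#' @return List of class `annealing_result`: `structures` (one
#'   [ca_structure()] per successful run), `summary` data frame (run,
#'   final_violation, final_energy, rmsd_to_ref, bond_ok), `failed`
#'   run indices.
#' @export
simulated_annealing <- function(model, n_runs = 10, t_start = 100,
                                t_end = 10, n_steps = 3e6, seed = 1,
                                coords0 = NULL, dt = 5e-4, gamma = 0.5,
                                mass = 1) {
  stopifnot(t_start > 0, t_end > 0, n_steps >= 1, n_runs >= 1)
  if (is.null(coords0)) coords0 <- model$ref$coords
  cm <- assemble_restraint_model(model)
  structures <- list()
  rows <- list()
  failed <- integer()
  ref_bonds <- model$base$bonds[, 3]
  for (r in seq_len(n_runs)) {
    res <- cpp_run_md(cm, as.matrix(coords0), as.integer(n_steps), dt,
                      t_start, t_end, gamma, as.integer(seed + r),
                      as.integer(max(1, floor(n_steps / 10))), mass)
    if (isTRUE(res$blown_up)) {
      failed <- c(failed, r)
      next
    }
    X <- res$final
    bl <- sqrt(rowSums((X[-1, , drop = FALSE] -
                          X[-nrow(X), , drop = FALSE])^2))
    viol <- restraint_violation(X, model$restraints, model$flat_width)
    st <- ca_structure(sprintf("%s_anneal%d", model$ref$id, r),
                       model$ref$sequence, X, ss = model$ref$ss,
                       source = "simulated_annealing")
    structures <- c(structures, list(st))
    rows[[length(rows) + 1]] <- data.frame(
      run = r,
      final_violation = if (length(viol)) mean(viol) else 0,
      final_energy = res$epot[length(res$epot)],
      rmsd_to_ref = superpose_rmsd(X, model$ref$coords)$rmsd,
      bond_ok = all(abs(bl - ref_bonds) / ref_bonds < 0.10))
  }
  structure(list(structures = structures,
                 summary = if (length(rows)) do.call(rbind, rows)
                 else NULL,
                 failed = failed),
            class = "annealing_result")
}

#' @export
print.annealing_result <- function(x, ...) {
  cat(sprintf(
    "<annealing_result> %d structures (%d failed runs); mean violation %.4g\n",
    length(x$structures), length(x$failed),
    if (!is.null(x$summary)) mean(x$summary$final_violation) else NA))
  invisible(x)
}

#' Select the structure best satisfying the restraints
#'
#' @param structures List of [ca_structure()]s (or an
#'   `annealing_result`).
#' @param restraints Restraint matrix (i, j, r0, k) or a
#'   [build_restraint_model()] model.
#' @param flat_width Flat-bottom half-width used for scoring.
#' @return The structure minimizing the mean squared restraint
#'   violation, with the score attached as attribute
#'   `restraint_score`.
#' @export
select_best <- function(structures, restraints, flat_width = 0.05) {
  if (inherits(structures, "annealing_result"))
    structures <- structures$structures
  if (!length(structures)) stop("no structures to select from")
  if (inherits(restraints, "restraint_model")) {
    flat_width <- restraints$flat_width
    restraints <- restraints$restraints
  }
  score <- vapply(structures, function(s) {
    v <- restraint_violation(s$coords, restraints, flat_width)
    if (length(v)) mean(v) else 0
  }, numeric(1))
  best <- structures[[which.min(score)]]
  attr(best, "restraint_score") <- min(score)
  best
}
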