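# Dual-basin C-alpha structure-based model, Langevin dynamics with
# well-tempered metadynamics over (RMSD_A, RMSD_B), and free-energy
# surface estimation from the deposited hills.

#' Simulation parameters
#'
#' Units: ps (dt), K (temperature), ps^-1 (friction), reduced mass 1
#' per bead.  The default temperature corresponds to k_B T close to
#' one contact-well depth (epsilon = 1 kJ/mol), i.e. slightly below the
#' folding temperature of the toy fixtures; friction is in the low
#' friction limit.
#'
#' @param n_steps Number of integration steps.
#' @param dt Time step in ps.
#' @param temperature Temperature in K.
#' @param gamma Langevin friction in ps^-1 (0 gives microcanonical
#'   velocity-Verlet integration).
#' @param save_stride Save a frame every this many steps.
#' @param mass Bead mass (reduced units).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_steps = 1e5, dt = 5e-4, temperature = 120,
                       gamma = 0.1, save_stride = 100, mass = 1) {
  stopifnot(n_steps >= 1, dt > 0, temperature >= 0, gamma >= 0,
            save_stride >= 1, mass > 0)
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 temperature = temperature, gamma = gamma,
                 save_stride = as.integer(save_stride), mass = mass),
            class = "sim_params")
}

#' Well-tempered metadynamics parameters
#'
#' Defaults: a Gaussian deposited every 500 steps with initial height
#' 1.0 kJ/mol, width 0.05 (CV units, nm), bias factor 50.
#'
#' @param stride Deposition stride in steps.
#' @param height0 Initial hill height in kJ/mol.
#' @param width Gaussian width in CV units.
#' @param bias_factor Well-tempered bias factor (> 1).
#' @return A list of class `metad_params`.
#' @export
metad_params <- function(stride = 500, height0 = 1.0, width = 0.05,
                         bias_factor = 50) {
  stopifnot(stride >= 1, height0 > 0, width > 0, bias_factor > 1)
  structure(list(stride = as.integer(stride), height0 = height0,
                 width = width, bias_factor = bias_factor),
            class = "metad_params")
}

#' Build a dual-basin C-alpha structure-based model
#'
#' Bonded terms (bonds, angles, dihedrals) are taken from the state-A
#' geometry of the mapped residues.  Native contacts (|i - j| >= 4,
#' C-alpha distance below `contact_cutoff`) are partitioned into
#' common (present in both states, equilibrium distance the mean of
#' the two native distances), unique-A and unique-B (equilibrium
#' distance from the owning state); every contact is a 12-10 well of
#' depth `epsilon`.  Non-contact pairs with |i - j| >= 4 interact by a
#' truncated-shifted r^-12 excluded volume.  Dihedral strength is
#' halved on residues whose secondary structure differs between the
#' states (configurable to "exclude" them entirely).
#'
#' @param pair A [state_pair()].
#' @param contact_cutoff Contact cutoff in nm (default 0.8).
#' @param epsilon Contact well depth in kJ/mol (default 1.0).
#' @param k_bond,k_angle,k_dihedral Bonded force constants
#'   (kJ/mol/nm^2, kJ/mol/rad^2, kJ/mol).
#' @param ss_conflict How to treat dihedrals on residues whose ss
#'   differs between states: "halve" (default) or "exclude".
#' @param sigma_rep,rcut_rep Excluded-volume radius and cutoff (nm).
#' @return A list of class `dual_basin_model`.
#' @export
build_dual_basin <- function(pair, contact_cutoff = 0.8, epsilon = 1.0,
                             k_bond = 10000, k_angle = 40,
                             k_dihedral = 1.0,
                             ss_conflict = c("halve", "exclude"),
                             sigma_rep = 0.4, rcut_rep = 0.75) {
  ss_conflict <- match.arg(ss_conflict)
  if (nrow(pair$residue_map) < 4) stop("need at least 4 mapped residues")
  ms <- mapped_structures(pair)
  xa <- ms$a$coords
  xb <- ms$b$coords
  n <- nrow(xa)

  bond_r <- sqrt(rowSums((xa[-1, , drop = FALSE] -
                            xa[-n, , drop = FALSE])^2))
  bonds <- cbind(seq_len(n - 1), 2:n, bond_r, k_bond)

  angle_of <- function(x, i, j, k) {
    u <- x[i, ] - x[j, ]; v <- x[k, ] - x[j, ]
    acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  angles <- if (n >= 3)
    cbind(1:(n - 2), 2:(n - 1), 3:n,
          vapply(1:(n - 2), function(i) angle_of(xa, i, i + 1, i + 2),
                 numeric(1)), k_angle)
  else matrix(0, 0, 5)

  dihedral_of <- function(x, i) {
    b1 <- x[i + 1, ] - x[i, ]; b2 <- x[i + 2, ] - x[i + 1, ]
    b3 <- x[i + 3, ] - x[i + 2, ]
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
            n1[1] * n2[2] - n1[2] * n2[1])
    atan2(sum(m1 * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  }
  if (n >= 4) {
    kd <- rep(k_dihedral, n - 3)
    ssa <- ms$a$ss; ssb <- ms$b$ss
    if (!is.null(ssa) && !is.null(ssb)) {
      ca <- strsplit(ssa, "")[[1]]; cb <- strsplit(ssb, "")[[1]]
      differs <- ca != cb
      for (i in 1:(n - 3)) {
        if (any(differs[i:(i + 3)]))
          kd[i] <- if (ss_conflict == "halve") k_dihedral / 2 else 0
      }
    }
    dihedrals <- cbind(1:(n - 3), 2:(n - 2), 3:(n - 1), 4:n,
                       vapply(1:(n - 3), function(i) dihedral_of(xa, i),
                              numeric(1)), kd)
    dihedrals <- dihedrals[dihedrals[, 6] > 0, , drop = FALSE]
  } else dihedrals <- matrix(0, 0, 6)

  da <- pairwise_ca_distances(xa)
  db <- pairwise_ca_distances(xb)
  sep <- abs(row(da) - col(da))
  cand <- upper.tri(da) & sep >= 4
  in_a <- cand & da < contact_cutoff
  in_b <- cand & db < contact_cutoff
  idx_common <- which(in_a & in_b, arr.ind = TRUE)
  idx_ua <- which(in_a & !in_b, arr.ind = TRUE)
  idx_ub <- which(in_b & !in_a, arr.ind = TRUE)
  contacts_common <- cbind(idx_common,
                           (da[idx_common] + db[idx_common]) / 2)
  contacts_unique_a <- cbind(idx_ua, da[idx_ua])
  contacts_unique_b <- cbind(idx_ub, db[idx_ub])
  colnames(contacts_common) <- colnames(contacts_unique_a) <-
    colnames(contacts_unique_b) <- c("i", "j", "r0")

  non_contact <- which(cand & !(in_a | in_b), arr.ind = TRUE)

  structure(
    list(n = n, bonds = bonds, angles = angles, dihedrals = dihedrals,
         contacts_common = contacts_common,
         contacts_unique_a = contacts_unique_a,
         contacts_unique_b = contacts_unique_b,
         repulsion = non_contact, epsilon = epsilon,
         sigma_rep = sigma_rep, rcut_rep = rcut_rep,
         contact_cutoff = contact_cutoff,
         ref_a = ms$a, ref_b = ms$b, protein_id = pair$protein_id),
    class = "dual_basin_model")
}

#' @export
print.dual_basin_model <- function(x, ...) {
  cat(sprintf(
    "<dual_basin_model> %s: %d residues, contacts common %d / unique-A %d / unique-B %d\n",
    x$protein_id, x$n, nrow(x$contacts_common),
    nrow(x$contacts_unique_a), nrow(x$contacts_unique_b)))
  invisible(x)
}

# Assemble the C++-facing model list with the requested contact sets
# active.  `include`: "both" (dual basin), "a", "b" (single basin on
# one state: that state's unique contacts + common), "common", "none".
assemble_model <- function(model, include = "both",
                           restraints = NULL, flat_width = 0.05) {
  pick <- switch(include,
    both = rbind(model$contacts_common, model$contacts_unique_a,
                 model$contacts_unique_b),
    a = rbind(model$contacts_common, model$contacts_unique_a),
    b = rbind(model$contacts_common, model$contacts_unique_b),
    common = model$contacts_common,
    none = matrix(0, 0, 3),
    stop("unknown contact subset: ", include))
  contacts <- if (nrow(pick)) cbind(pick, model$epsilon) else
    matrix(0, 0, 4)
  list(n = model$n,
       bonds = to_c_idx(model$bonds, 2),
       angles = to_c_idx(model$angles, 3),
       dihedrals = to_c_idx(model$dihedrals, 4),
       contacts = to_c_idx(contacts, 2),
       repulsion = to_c_idx(model$repulsion, 2),
       restraints = if (is.null(restraints) || !nrow(restraints))
         matrix(0, 0, 4) else to_c_idx(restraints, 2),
       sigma_rep = model$sigma_rep, rcut_rep = model$rcut_rep,
       flat_width = flat_width)
}

# convert the first k columns from 1-based to 0-based indices
to_c_idx <- function(m, k) {
  m <- as.matrix(m)
  if (!nrow(m)) return(m)
  m[, 1:k] <- m[, 1:k] - 1
  unname(m)
}

#' Potential energy and forces of a model
#'
#' @param model A [build_dual_basin()] model (or restraint model from
#'   [build_restraint_model()]).
#' @param coords N x 3 coordinate matrix in nm.
#' @param include Which contact sets are active: "both" (default),
#'   "a", "b", "common", "none".
#' @return List with `energy` (kJ/mol), `forces` (N x 3, kJ/mol/nm),
#'   and a named `terms` breakdown.
#' @export
potential_energy <- function(model, coords, include = "both") {
  cm <- if (inherits(model, "restraint_model"))
    assemble_restraint_model(model) else assemble_model(model, include)
  if (nrow(coords) != cm$n) stop("coords size does not match model")
  cpp_energy_forces(as.matrix(coords), cm)
}

#' Best-fit RMSD collective variable
#'
#' @param coords N x 3 coordinates (nm).
#' @param ref Reference [ca_structure()] or coordinate matrix.
#' @return RMSD in nm after optimal superposition.
#' @export
cv_rmsd <- function(coords, ref) {
  superpose_rmsd(get_coords(coords), get_coords(ref))$rmsd
}

stop_blowup <- function(res, what) {
  if (isTRUE(res$blown_up)) {
    cond <- structure(
      class = c("pathcg_blowup", "error", "condition"),
      list(message = sprintf(
        "%s blew up at step %d (non-finite coordinates); last stable frame attached as `last_frame`",
        what, res$blow_step),
        call = NULL,
        last_frame = if (res$n_saved > 0)
          res$frames[, , res$n_saved] else NULL))
    stop(cond)
  }
  invisible(res)
}

#' Run unbiased Langevin (or microcanonical) dynamics
#'
#' BAOAB Langevin integration; with `gamma = 0` the O-step is the
#' identity and the scheme reduces to energy-conserving velocity
#' Verlet.
#'
#' @param model A model from [build_dual_basin()].
#' @param sim A [sim_params()].
#' @param seed Integer RNG seed.
#' @param coords0 Starting coordinates (defaults to state A).
#' @param include Active contact sets (see [potential_energy()]).
#' @return List of class `md_run` with `frames` (N x 3 x n_saved),
#'   `epot`, `ekin`, `final` coordinates.
#' @export
run_md <- function(model, sim, seed, coords0 = NULL, include = "both") {
  if (is.null(coords0)) coords0 <- model$ref_a$coords
  cm <- assemble_model(model, include)
  res <- cpp_run_md(cm, as.matrix(coords0), sim$n_steps, sim$dt,
                    sim$temperature, -1, sim$gamma, as.integer(seed),
                    sim$save_stride, sim$mass)
  stop_blowup(res, "unbiased run")
  structure(res[c("frames", "epot", "ekin", "final", "n_saved")],
            class = "md_run")
}

#' Run well-tempered metadynamics over (RMSD_A, RMSD_B)
#'
#' Langevin (BAOAB) dynamics on the dual-basin model with a
#' well-tempered metadynamics bias over the two collective variables
#' RMSD to state A and RMSD to state B.  Every `metad$stride` steps a
#' Gaussian of height `height0 * exp(-V_bias / (kB * dT))`,
#' `dT = (bias_factor - 1) * T`, is deposited at the current CV
#' position; the bias force enters the physical force through the
#' analytic best-fit RMSD gradient.
#'
#' @param model A [build_dual_basin()] model.
#' @param sim A [sim_params()].
#' @param metad A [metad_params()].
#' @param seed Integer RNG seed.
#' @param coords0 Starting coordinates (defaults to state A).
#' @param well_tempered Set FALSE for standard (constant-height)
#'   metadynamics.
#' @return List of class `metad_run` with `frames` (N x 3 x n_saved),
#'   `cvs` (n_saved x 2), `hills` data frame, `final`, and the
#'   parameters used.
#' @export
run_metadynamics <- function(model, sim, metad, seed, coords0 = NULL,
                             well_tempered = TRUE) {
  if (is.null(coords0)) coords0 <- model$ref_a$coords
  cm <- assemble_model(model, "both")
  res <- cpp_run_metad(cm, as.matrix(coords0), model$ref_a$coords,
                       model$ref_b$coords, sim$n_steps, sim$dt,
                       sim$temperature, sim$gamma, as.integer(seed),
                       sim$save_stride, metad$stride, metad$height0,
                       metad$width, metad$bias_factor, sim$mass,
                       well_tempered)
  stop_blowup(res, "metadynamics run")
  hills <- as.data.frame(res$hills)
  names(hills) <- c("step", "cv1", "cv2", "width1", "width2", "height")
  attr(hills, "bias_factor") <- metad$bias_factor
  attr(hills, "temperature") <- sim$temperature
  structure(
    list(frames = res$frames, cvs = res$cvs, hills = hills,
         final = res$final, n_saved = res$n_saved, sim = sim,
         metad = metad, seed = seed),
    class = "metad_run")
}

#' @export
print.metad_run <- function(x, ...) {
  cat(sprintf(
    "<metad_run> %d frames, %d hills, CV ranges [%.2f, %.2f] x [%.2f, %.2f] nm\n",
    x$n_saved, nrow(x$hills), min(x$cvs[, 1]), max(x$cvs[, 1]),
    min(x$cvs[, 2]), max(x$cvs[, 2])))
  invisible(x)
}

#' Construct a free-energy surface object
#'
#' @param cv1,cv2 Grid-center coordinate vectors (regular spacing).
#' @param F Matrix of free energies, rows indexing `cv1`; shifted so
#'   the minimum is 0.
#' @return Object of class `free_energy_surface` with grid centers,
#'   edges and `F`.
#' @export
free_energy_surface <- function(cv1, cv2, F) {
  F <- as.matrix(F)
  stopifnot(nrow(F) == length(cv1), ncol(F) == length(cv2),
            all(is.finite(F)))
  F <- F - min(F)
  d1 <- diff(cv1)[1]; d2 <- diff(cv2)[1]
  structure(list(cv1 = cv1, cv2 = cv2,
                 cv1_edges = c(cv1 - d1 / 2, cv1[length(cv1)] + d1 / 2),
                 cv2_edges = c(cv2 - d2 / 2, cv2[length(cv2)] + d2 / 2),
                 F = F),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf(
    "<free_energy_surface> %d x %d grid, F in [0, %.2f] kJ/mol\n",
    nrow(x$F), ncol(x$F), max(x$F)))
  invisible(x)
}

#' Estimate the free-energy surface from a hills log
#'
#' Well-tempered estimator F(s) = -(gamma / (gamma - 1)) * V_bias(s)
#' with V_bias the sum of deposited Gaussians, evaluated on a regular
#' grid and shifted so the minimum is zero.
#'
#' @param hills Hills data frame (from [run_metadynamics()] or
#'   [read_hills()]).
#' @param cv1_range,cv2_range Grid ranges `c(lo, hi)`; default spans
#'   the hill centers with a margin of 3 widths.
#' @param n1,n2 Number of grid cells per axis.
#' @param bias_factor Well-tempered bias factor; default taken from
#'   the hills attributes.
#' @return A [free_energy_surface()].
#' @export
compute_fes <- function(hills, cv1_range = NULL, cv2_range = NULL,
                        n1 = 50, n2 = 50, bias_factor = NULL) {
  stopifnot(nrow(hills) > 0)
  if (is.null(bias_factor)) bias_factor <- attr(hills, "bias_factor")
  if (is.null(bias_factor))
    stop("bias_factor neither supplied nor attached to hills")
  w <- hills$width1[1]
  if (is.null(cv1_range))
    cv1_range <- range(hills$cv1) + c(-3, 3) * w
  if (is.null(cv2_range))
    cv2_range <- range(hills$cv2) + c(-3, 3) * w
  out1 <- hills$cv1 < cv1_range[1] | hills$cv1 > cv1_range[2]
  out2 <- hills$cv2 < cv2_range[1] | hills$cv2 > cv2_range[2]
  clipped <- mean(out1 | out2)
  if (clipped > 0)
    warning(sprintf("%.1f%% of hill centers fall outside the grid",
                    100 * clipped))
  x <- seq(cv1_range[1], cv1_range[2], length.out = n1)
  y <- seq(cv2_range[1], cv2_range[2], length.out = n2)
  V <- matrix(0, n1, n2)
  for (k in seq_len(nrow(hills))) {
    gx <- exp(-(x - hills$cv1[k])^2 / (2 * hills$width1[k]^2))
    gy <- exp(-(y - hills$cv2[k])^2 / (2 * hills$width2[k]^2))
    V <- V + hills$height[k] * outer(gx, gy)
  }
  free_energy_surface(x, y, -(bias_factor / (bias_factor - 1)) * V)
}

#' Write / read a hills log
#'
#' Whitespace-delimited text, one row per deposited Gaussian
#' (step cv1 cv2 width1 width2 height), with `#!` header comments
#' carrying the deposition parameters.
#'
#' @param hills Hills data frame.
#' @param path File path.
#' @return `write_hills` the path invisibly; `read_hills` the data
#'   frame with `bias_factor` / `temperature` attributes restored.
#' @export
write_hills <- function(hills, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#! FIELDS step cv1 cv2 width1 width2 height",
    sprintf("#! SET bias_factor %g", attr(hills, "bias_factor") %||% NA),
    sprintf("#! SET temperature %g", attr(hills, "temperature") %||% NA)),
    con)
  write.table(format(hills, digits = 10, trim = TRUE), con,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#!")]
  df <- read.table(text = lines[!startsWith(lines, "#")],
                   col.names = c("step", "cv1", "cv2", "width1",
                                 "width2", "height"))
  grab <- function(key) {
    m <- grep(paste0("#! SET ", key), meta, value = TRUE)
    if (length(m)) as.numeric(sub(paste0(".*", key, " "), "", m[1]))
    else NULL
  }
  attr(df, "bias_factor") <- grab("bias_factor")
  attr(df, "temperature") <- grab("temperature")
  df
}

#' Write / read a free-energy surface as a tab-separated grid
#'
#' Columns cv1, cv2, F over all grid centers.
#'
#' @param fes A [free_energy_surface()].
#' @param path File path.
#' @return `write_fes` the path invisibly; `read_fes` a
#'   [free_energy_surface()].
#' @export
write_fes <- function(fes, path) {
  df <- data.frame(cv1 = rep(fes$cv1, times = length(fes$cv2)),
                   cv2 = rep(fes$cv2, each = length(fes$cv1)),
                   F = as.vector(fes$F))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  cv1 <- sort(unique(df$cv1))
  cv2 <- sort(unique(df$cv2))
  F <- matrix(df$F[order(df$cv2, df$cv1)], length(cv1), length(cv2))
  free_energy_surface(cv1, cv2, F)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
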