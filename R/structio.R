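# Core structural types and geometry: C-alpha structures, PDB parsing,
# Kabsch superposition, radius of gyration, approximate SASA, distances.

#' Effective residue radii used by [approx_sasa()]
#'
#' Radii (nm) of the volume-equivalent sphere for each amino-acid type,
#' derived from mean residue volumes.  Unknown residue types fall back
#' to the mean radius.
#'
#' @return Named numeric vector of radii in nm.
#' @export
residue_radii <- function() {
  r <- (3 * AA_VOLUME / (4 * pi))^(1 / 3) / 10 # A -> nm
  round(r, 4)
}

#' Construct a C-alpha structure
#'
#' The elementary container of the package: one chain represented by its
#' sequence and C-alpha coordinates in nm, with an optional per-residue
#' secondary-structure string over the alphabet H (helix), E (strand),
#' C (coil).
#'
#' @param id Identifier string.
#' @param sequence One-letter amino-acid string.
#' @param coords N x 3 numeric matrix of C-alpha positions in nm.
#' @param ss Optional secondary-structure string (H/E/C), length N.
#' @param source Free-text provenance (file, chain).
#' @return An object of class `ca_structure`.
#' @export
ca_structure <- function(id, sequence, coords, ss = NULL, source = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nchar(sequence)
  if (nrow(coords) != n)
    stop("coords has ", nrow(coords), " rows but sequence has ", n,
         " residues")
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(ss)) {
    if (nchar(ss) != n) stop("ss length differs from sequence length")
    if (grepl("[^HEC]", ss)) stop("ss may only contain H, E, C")
  }
  structure(
    list(id = id, sequence = sequence, coords = coords, ss = ss,
         source = source),
    class = "ca_structure"
  )
}

#' @export
print.ca_structure <- function(x, ...) {
  cat("<ca_structure> ", x$id, ": ", nchar(x$sequence), " residues",
      if (!is.null(x$ss)) " (+ss)", "\n", sep = "")
  invisible(x)
}

#' @export
length.ca_structure <- function(x) nchar(x$sequence)

seq_chars <- function(struct) strsplit(struct$sequence, "")[[1]]

#' Read one chain of a PDB file as a C-alpha structure
#'
#' Parses `ATOM` records only, keeps one CA per residue (highest
#' occupancy among altlocs, ties resolved to the first encountered),
#' orders residues by author residue number with insertion codes, and
#' converts coordinates from Angstrom to nm.
#'
#' @param pdb Path to a PDB file, or PDB-format text (single string with
#'   newlines, or a character vector of lines).
#' @param chain_id Single chain identifier.
#' @return A [ca_structure()].
#' @examples
#' pdb <- system.file("extdata", "toy_hinge_closed_synthetic.pdb",
#'                    package = "pathcg")
#' read_ca_structure(pdb, "A")
#' @export
read_ca_structure <- function(pdb, chain_id) {
  src <- "text"
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    src <- pdb
    lines <- readLines(pdb, warn = FALSE)
  } else if (length(pdb) == 1L) {
    lines <- strsplit(pdb, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- pdb
  }
  lines <- lines[startsWith(lines, "ATOM")]
  if (!length(lines)) stop("no ATOM records in input")
  chain <- substr(lines, 22, 22)
  if (!any(chain == chain_id))
    stop("chain '", chain_id, "' not found (chains present: ",
         paste(sort(unique(chain)), collapse = ", "), ")")
  lines <- lines[chain == chain_id]
  atom <- trimws(substr(lines, 13, 16))
  altloc <- substr(lines, 17, 17)
  resname <- trimws(substr(lines, 18, 20))
  resseq <- as.integer(substr(lines, 23, 26))
  icode <- substr(lines, 27, 27)
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  xyz <- cbind(as.numeric(substr(lines, 31, 38)),
               as.numeric(substr(lines, 39, 46)),
               as.numeric(substr(lines, 47, 54)))

  reskey <- paste0(resseq, "|", icode)
  ord <- order(resseq, icode)
  ukeys <- unique(reskey[ord])
  is_ca <- atom == "CA"
  no_ca <- setdiff(ukeys, unique(reskey[is_ca]))
  if (length(no_ca))
    stop("residue(s) without a CA atom: ",
         paste(gsub("\\|", "", no_ca), collapse = ", "))

  idx <- vapply(ukeys, function(k) {
    cand <- which(reskey == k & is_ca)
    cand[order(-occ[cand], seq_along(cand))][1]
  }, integer(1))
  seq1 <- AA3TO1[resname[idx]]
  seq1[is.na(seq1)] <- "X"
  ca_structure(
    id = chain_id,
    sequence = paste(seq1, collapse = ""),
    coords = xyz[idx, , drop = FALSE] / 10,
    source = paste0(src, ":", chain_id)
  )
}

#' Write a C-alpha structure as a CA-only PDB file
#'
#' @param struct A [ca_structure()].
#' @param path Output path.
#' @param model Optional model number for multi-model files.
#' @param append Append to an existing file.
#' @return Invisibly, the path.
#' @export
write_ca_pdb <- function(struct, path, model = NULL, append = FALSE) {
  aa1to3 <- setNames(names(AA3TO1)[1:20], AA3TO1[1:20])
  s <- seq_chars(struct)
  res3 <- ifelse(s %in% names(aa1to3), aa1to3[s], "UNK")
  xyz <- struct$coords * 10
  rec <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(s), res3, seq_along(s), xyz[, 1], xyz[, 2], xyz[, 3])
  out <- c(if (!is.null(model)) sprintf("MODEL     %4d", model),
           rec, "TER", if (!is.null(model)) "ENDMDL")
  if (append) cat(out, file = path, sep = "\n", append = TRUE)
  else writeLines(out, path)
  invisible(path)
}

#' Write / read a C-alpha structure as a tab-separated table
#'
#' Columns: res_index, aa, x_nm, y_nm, z_nm, ss.
#'
#' @param struct A [ca_structure()].
#' @param path File path.
#' @return `write_ca_table` returns the path invisibly;
#'   `read_ca_table` returns a [ca_structure()].
#' @export
write_ca_table <- function(struct, path) {
  df <- data.frame(
    res_index = seq_len(length(struct)),
    aa = seq_chars(struct),
    x_nm = struct$coords[, 1], y_nm = struct$coords[, 2],
    z_nm = struct$coords[, 3],
    ss = if (is.null(struct$ss)) "." else strsplit(struct$ss, "")[[1]]
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ca_table
#' @param id Identifier for the structure read back.
#' @export
read_ca_table <- function(path, id = basename(path)) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("integer", "character", rep("numeric", 3),
                                  "character"))
  ss <- paste(df$ss, collapse = "")
  ca_structure(id, paste(df$aa, collapse = ""),
               as.matrix(df[, c("x_nm", "y_nm", "z_nm")]),
               ss = if (grepl("\\.", ss)) NULL else ss,
               source = path)
}

get_coords <- function(x) {
  if (inherits(x, "ca_structure")) x$coords else {
    x <- as.matrix(x); storage.mode(x) <- "double"; x
  }
}

#' Optimal (Kabsch) superposition RMSD
#'
#' Least-squares rigid-body superposition of two equally sized C-alpha
#' coordinate sets.  The rotation/translation map `y` onto `x`.
#'
#' @param x,y N x 3 coordinate matrices (nm) or [ca_structure()]s.
#' @param subset Optional integer vector of residue indices used both
#'   for the fit and the RMSD.
#' @return A list of class `superposition` with elements `rmsd` (nm),
#'   `rotation` (3 x 3, applied to centered `y`), `translation`,
#'   `degenerate` (TRUE when the point set is collinear so the rotation
#'   is not unique).
#' @export
superpose_rmsd <- function(x, y, subset = NULL) {
  x <- get_coords(x); y <- get_coords(y)
  if (!is.null(subset)) {
    x <- x[subset, , drop = FALSE]
    y <- y[subset, , drop = FALSE]
  }
  if (nrow(x) != nrow(y)) stop("coordinate sets differ in size")
  if (nrow(x) < 3) stop("need at least 3 points for superposition")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  # collinearity check on either set
  degenerate <- min(svd(xc, nu = 0, nv = 0)$d[2],
                    svd(yc, nu = 0, nv = 0)$d[2]) < 1e-10
  h <- crossprod(yc, xc)
  sv <- svd(h)
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- yc %*% rot
  rmsd <- sqrt(mean(rowSums((xc - fitted)^2)))
  structure(list(rmsd = rmsd, rotation = rot,
                 translation = cx - cy %*% rot, degenerate = degenerate),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.6f nm%s\n", x$rmsd,
              if (x$degenerate) " (degenerate: collinear points)" else ""))
  invisible(x)
}

#' Radius of gyration of a C-alpha structure
#'
#' Unweighted root-mean-square distance of the C-alpha positions from
#' their centroid.
#'
#' @param struct A [ca_structure()] or coordinate matrix.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(struct) {
  xyz <- get_coords(struct)
  c0 <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, c0)^2)))
}

#' Pairwise C-alpha distance matrix
#'
#' @param struct A [ca_structure()] or coordinate matrix.
#' @return Symmetric N x N matrix of distances in nm with zero diagonal.
#' @export
pairwise_ca_distances <- function(struct) {
  as.matrix(stats::dist(get_coords(struct)))
}

# Deterministic golden-spiral points on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Approximate solvent-accessible surface area on C-alpha spheres
#'
#' Shrake-Rupley-style sphere sampling: each residue is a sphere of
#' volume-equivalent radius (see [residue_radii()]) centered at its
#' C-alpha; sample points on the probe-inflated sphere are tested for
#' occlusion by every other inflated sphere.  Deterministic for a fixed
#' number of sample points.
#'
#' @param struct A [ca_structure()].
#' @param n_points Sample points per sphere (default 960).
#' @param probe Probe radius in nm (default 0.14, water).
#' @return A list of class `surface_areas` with `total`, `polar`,
#'   `hydrophobic` (nm^2); `total = polar + hydrophobic` by
#'   construction.
#' @export
approx_sasa <- function(struct, n_points = 960, probe = 0.14) {
  xyz <- get_coords(struct)
  s <- seq_chars(struct)
  rad <- residue_radii()
  r <- unname(rad[s])
  r[is.na(r)] <- mean(rad)
  r <- r + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 > r[j]^2
      if (!any(exposed)) break
    }
    area[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }
  hydro <- s %in% AA_HYDROPHOBIC | !(s %in% names(AA_VOLUME))
  structure(list(total = sum(area), polar = sum(area[!hydro]),
                 hydrophobic = sum(area[hydro]), per_residue = area),
            class = "surface_areas")
}

#' @export
print.surface_areas <- function(x, ...) {
  cat(sprintf(
    "<surface_areas> total %.3f nm^2 (polar %.3f, hydrophobic %.3f)\n",
    x$total, x$polar, x$hydrophobic))
  invisible(x)
}

#' Construct a two-state pair
#'
#' Two aligned C-alpha structures of the same protein (states A and B)
#' with a residue mapping.  Mapped indices must be strictly increasing
#' in both structures; substitutions between mapped residues are
#' recorded rather than rejected.  Whether the pair is large enough for
#' the multi-state dataset rules is decided by [evaluate_ms_pair()], not
#' by this container.
#'
#' @param protein_id Identifier.
#' @param state_a,state_b [ca_structure()]s.
#' @param residue_map Two-column integer matrix of 1-based indices
#'   (index_a, index_b).  Defaults to the identity map when both
#'   structures have the same length.
#' @return An object of class `state_pair`.
#' @export
state_pair <- function(protein_id, state_a, state_b, residue_map = NULL) {
  stopifnot(inherits(state_a, "ca_structure"),
            inherits(state_b, "ca_structure"))
  if (is.null(residue_map)) {
    if (length(state_a) != length(state_b))
      stop("structures differ in length; supply residue_map")
    residue_map <- cbind(seq_len(length(state_a)), seq_len(length(state_b)))
  }
  residue_map <- as.matrix(residue_map)
  storage.mode(residue_map) <- "integer"
  if (ncol(residue_map) != 2) stop("residue_map must have two columns")
  if (nrow(residue_map) < 4) stop("need at least 4 mapped residues")
  if (any(diff(residue_map[, 1]) <= 0) || any(diff(residue_map[, 2]) <= 0))
    stop("mapped indices must be strictly increasing in both structures")
  if (any(residue_map[, 1] > length(state_a)) ||
      any(residue_map[, 2] > length(state_b)) || any(residue_map < 1))
    stop("residue_map indices out of bounds")
  sa <- seq_chars(state_a)[residue_map[, 1]]
  sb <- seq_chars(state_b)[residue_map[, 2]]
  subs <- which(sa != sb)
  structure(
    list(protein_id = protein_id, state_a = state_a, state_b = state_b,
         residue_map = residue_map,
         substitutions = if (length(subs))
           data.frame(index_a = residue_map[subs, 1],
                      index_b = residue_map[subs, 2],
                      aa_a = sa[subs], aa_b = sb[subs]) else NULL),
    class = "state_pair"
  )
}

#' @export
print.state_pair <- function(x, ...) {
  cat("<state_pair> ", x$protein_id, ": ", nrow(x$residue_map),
      " mapped residues", if (!is.null(x$substitutions))
        paste0(", ", nrow(x$substitutions), " substitutions"), "\n",
      sep = "")
  invisible(x)
}

# Extract the mapped sub-structures of a pair as two equally indexed
# ca_structures (used by the simulation and curation layers).
mapped_structures <- function(pair) {
  m <- pair$residue_map
  a <- pair$state_a; b <- pair$state_b
  list(
    a = ca_structure(paste0(pair$protein_id, "_A"),
                     paste(seq_chars(a)[m[, 1]], collapse = ""),
                     a$coords[m[, 1], , drop = FALSE],
                     ss = if (!is.null(a$ss))
                       paste(strsplit(a$ss, "")[[1]][m[, 1]], collapse = ""),
                     source = a$source),
    b = ca_structure(paste0(pair$protein_id, "_B"),
                     paste(seq_chars(b)[m[, 2]], collapse = ""),
                     b$coords[m[, 2], , drop = FALSE],
                     ss = if (!is.null(b$ss))
                       paste(strsplit(b$ss, "")[[1]][m[, 2]], collapse = ""),
                     source = b$source)
  )
}
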