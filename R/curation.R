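# Dataset-curation rules for multi-state (MS) versus single-state (SS)
# proteins, the transition-category classification, and contact-type
# frequency statistics over the 210 unordered residue-type pairs.

#' The 210 unordered residue-type pair labels
#'
#' @return Character vector like "AA", "AC", ..., "YY" (alphabetical
#'   within each pair), length 210.
#' @export
contact_types <- function() {
  m <- outer(AA20, AA20, paste0)
  m[upper.tri(m, diag = TRUE)]
}

pair_type <- function(p, q) {
  ifelse(p <= q, paste0(p, q), paste0(q, p))
}

#' Global sequence identity between two sequences
#'
#' Needleman-Wunsch global alignment with a simple identity scoring
#' matrix (match 1, mismatch 0) and affine gaps (open 10, extend 0.5),
#' via Biostrings.  Identity is the fraction of matched positions over
#' aligned (non-gap) columns.
#'
#' @param seq_a,seq_b One-letter amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(seq_a, seq_b) {
  letters20 <- unique(c(strsplit(seq_a, "")[[1]], strsplit(seq_b, "")[[1]],
                        AA20, "X"))
  sub <- matrix(0, length(letters20), length(letters20),
                dimnames = list(letters20, letters20))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = sub,
    gapOpening = 10, gapExtension = 0.5)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  if (nm + nmm == 0) return(0)
  nm / (nm + nmm)
}

# Trim leading/trailing terminal loops before RMSD: drop leading and
# trailing runs of coil ('C') when ss is available on both mapped
# states; otherwise the residue map itself (already restricted to
# mapped residues) is used as-is.
trimmed_map_indices <- function(pair) {
  m <- pair$residue_map
  keep <- seq_len(nrow(m))
  ssa <- pair$state_a$ss; ssb <- pair$state_b$ss
  if (!is.null(ssa) && !is.null(ssb)) {
    ca <- strsplit(ssa, "")[[1]][m[, 1]]
    cb <- strsplit(ssb, "")[[1]][m[, 2]]
    loop <- ca == "C" & cb == "C"
    core <- which(!loop)
    if (length(core) >= 3) keep <- core[1]:core[length(core)]
  }
  keep
}

# Longest internal gap (unmapped run in either structure) of a pair.
longest_gap <- function(pair) {
  m <- pair$residue_map
  if (nrow(m) < 2) return(0L)
  ga <- diff(m[, 1]) - 1L
  gb <- diff(m[, 2]) - 1L
  max(0L, ga, gb)
}

#' Evaluate the multi-state (MS) dataset rules for a structure pair
#'
#' A pair qualifies as two states of a multi-state protein when all
#' three criteria hold: sequence identity > 0.90, superposition RMSD
#' > 0.5 nm with terminal loops excluded, and longest alignment gap
#' < 21 residues.  Sequences must be longer than 50 residues to enter
#' the dataset at all.
#'
#' @param pair A [state_pair()].
#' @return A list of class `pair_decision` with `is_ms`, `seq_identity`,
#'   `rmsd_nm`, `longest_gap` and a character vector `reasons`.
#' @export
evaluate_ms_pair <- function(pair) {
  if (nrow(pair$residue_map) == 0) stop("empty residue_map")
  reasons <- character()
  len_ok <- length(pair$state_a) > 50 && length(pair$state_b) > 50
  if (!len_ok) reasons <- c(reasons, "length: sequence length must be > 50")
  ident <- sequence_identity(pair$state_a$sequence, pair$state_b$sequence)
  if (ident <= 0.90)
    reasons <- c(reasons, sprintf("identity: %.3f <= 0.90", ident))
  keep <- trimmed_map_indices(pair)
  m <- pair$residue_map[keep, , drop = FALSE]
  sp <- superpose_rmsd(pair$state_a$coords[m[, 1], , drop = FALSE],
                       pair$state_b$coords[m[, 2], , drop = FALSE])
  if (sp$rmsd <= 0.5)
    reasons <- c(reasons, sprintf("rmsd: %.3f nm <= 0.5 nm", sp$rmsd))
  gap <- longest_gap(pair)
  if (gap >= 21)
    reasons <- c(reasons, sprintf("gap: %d residues >= 21", gap))
  structure(
    list(is_ms = len_ok && ident > 0.90 && sp$rmsd > 0.5 && gap < 21,
         seq_identity = ident, rmsd_nm = sp$rmsd, longest_gap = gap,
         reasons = if (length(reasons)) reasons else "all criteria met"),
    class = "pair_decision")
}

#' @export
print.pair_decision <- function(x, ...) {
  cat(sprintf(
    "<pair_decision> is_ms = %s (identity %.3f, rmsd %.3f nm, gap %d)\n",
    x$is_ms, x$seq_identity, x$rmsd_nm, x$longest_gap))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Evaluate the single-state (SS) cluster rule
#'
#' A cluster of structures is single-state when it has more than five
#' members and the largest pairwise superposition RMSD is below 0.2 nm;
#' the shortest-sequence member is then returned as the representative.
#'
#' @param structures List of [ca_structure()]s of equal length.
#' @return The representative [ca_structure()], or `NULL` when the
#'   cluster does not qualify.
#' @export
evaluate_ss_cluster <- function(structures) {
  stopifnot(length(structures) >= 1)
  if (length(structures) <= 5) return(NULL)
  n <- length(structures)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # members may differ slightly in length (the representative is
      # the shortest); superpose over the common prefix
      l <- min(length(structures[[i]]), length(structures[[j]]))
      if (superpose_rmsd(structures[[i]]$coords[1:l, , drop = FALSE],
                         structures[[j]]$coords[1:l, , drop = FALSE]
                         )$rmsd >= 0.2)
        return(NULL)
    }
  }
  lens <- vapply(structures, length, integer(1))
  structures[[which.min(lens)]]
}

#' Classify the transition of a two-state pair into Categories I-IV
#'
#' Rules applied to the mapped residues, in order: more than five
#' residues swapping between helix and strand gives Category IV (global
#' fold change); otherwise more than five residues changing from helix
#' or strand to loop gives Category III (local unfolding); otherwise
#' Categories I and II (inter- versus intra-domain motion) are
#' separated by a rigid-block heuristic on the distance-difference
#' matrix: residues are clustered so that within-block distance changes
#' stay below `block_tol`, and the pair is Category I when at least two
#' blocks of at least `min_block` residues move relative to each other.
#'
#' @param pair A [state_pair()]; both states must carry `ss`.
#' @param block_tol Within-block |d_A - d_B| tolerance in nm
#'   (default 0.2).
#' @param min_block Minimum rigid-block size in residues (default 30).
#' @return List of class `transition_category` with `category`
#'   ("I".."IV"), `n_fold_to_loop`, `n_helix_sheet_swap`, `rationale`.
#' @export
classify_transition <- function(pair, block_tol = 0.2, min_block = 30) {
  if (is.null(pair$state_a$ss) || is.null(pair$state_b$ss))
    stop("classify_transition requires ss strings on both states; ",
         "supply per-residue H/E/C codes")
  m <- pair$residue_map
  sa <- strsplit(pair$state_a$ss, "")[[1]][m[, 1]]
  sb <- strsplit(pair$state_b$ss, "")[[1]][m[, 2]]
  n_swap <- sum((sa == "H" & sb == "E") | (sa == "E" & sb == "H"))
  n_f2l <- sum((sa %in% c("H", "E") & sb == "C") |
                 (sa == "C" & sb %in% c("H", "E")))
  if (n_swap > 5) {
    cat_ <- "IV"
    why <- sprintf("%d residues swap between helix and strand (> 5)",
                   n_swap)
  } else if (n_f2l > 5) {
    cat_ <- "III"
    why <- sprintf("%d residues change between helix/strand and loop (> 5)",
                   n_f2l)
  } else {
    da <- pairwise_ca_distances(pair$state_a$coords[m[, 1], , drop = FALSE])
    db <- pairwise_ca_distances(pair$state_b$coords[m[, 2], , drop = FALSE])
    dd <- abs(da - db)
    blocks <- stats::cutree(
      stats::hclust(stats::as.dist(dd), method = "complete"),
      h = block_tol)
    sizes <- table(blocks)
    big <- names(sizes)[sizes >= min_block]
    moving <- 0L
    if (length(big) >= 2) {
      # blocks that actually move relative to another big block
      for (bi in big) {
        others <- setdiff(big, bi)
        rel <- vapply(others, function(bj) {
          max(dd[blocks == bi, blocks == bj])
        }, numeric(1))
        if (any(rel > block_tol)) moving <- moving + 1L
      }
    }
    if (moving >= 2) {
      cat_ <- "I"
      why <- sprintf("%d rigid blocks of >= %d residues move relative to each other",
                     moving, min_block)
    } else {
      cat_ <- "II"
      why <- "structural rearrangement confined within one rigid block"
    }
  }
  structure(list(category = cat_, n_fold_to_loop = n_f2l,
                 n_helix_sheet_swap = n_swap, rationale = why),
            class = "transition_category")
}

#' @export
print.transition_category <- function(x, ...) {
  cat("<transition_category> Category ", x$category, ": ", x$rationale,
      "\n", sep = "")
  invisible(x)
}

# Count residue-type pair contacts of one structure with separation in
# the open interval (0.3, 1.0) nm; returns named counts over the types
# present plus per-type residue counts.
count_contacts_one <- function(struct, lo = 0.3, hi = 1.0) {
  s <- seq_chars(struct)
  d <- pairwise_ca_distances(struct)
  idx <- which(upper.tri(d) & d > lo & d < hi, arr.ind = TRUE)
  tp <- if (nrow(idx)) pair_type(s[idx[, 1]], s[idx[, 2]]) else character()
  list(npq = table(tp), nres = table(s))
}

freq_from_counts <- function(npq, nres) {
  types <- contact_types()
  f <- setNames(numeric(length(types)), types)
  if (!length(npq)) return(f)
  for (tp in names(npq)) {
    p <- substr(tp, 1, 1); q <- substr(tp, 2, 2)
    np <- nres[p]; nq <- nres[q]
    if (!is.na(np) && !is.na(nq) && np > 0 && nq > 0 && tp %in% types)
      f[tp] <- as.numeric(npq[tp]) / (as.numeric(np) * as.numeric(nq))
  }
  f
}

#' Contact-type frequencies over a dataset
#'
#' For each of the 210 unordered residue-type pairs pq, the frequency
#' F_pq = (1/n) * sum_i N^i_pq / (N^i_p N^i_q), where N^i_pq counts
#' C-alpha pairs of type pq with separation strictly between 0.3 and
#' 1.0 nm in protein i, and N^i_p, N^i_q count residues of each type.
#' A protein lacking residue type p or q contributes 0 to that type.
#' For [state_pair()] inputs, both states are counted and the two
#' per-state frequencies averaged.
#'
#' @param dataset List of [ca_structure()]s or of [state_pair()]s.
#' @param kind Label stored with the result ("MS", "SS", ...).
#' @return List of class `contact_type_stats` with `F` (named vector of
#'   210 frequencies), `n_proteins`, `kind`.
#' @export
contact_frequency <- function(dataset, kind = "MS") {
  stopifnot(length(dataset) >= 1)
  acc <- setNames(numeric(210), contact_types())
  for (item in dataset) {
    if (inherits(item, "state_pair")) {
      ms <- mapped_structures(item)
      ca <- count_contacts_one(ms$a); cb <- count_contacts_one(ms$b)
      fi <- (freq_from_counts(ca$npq, ca$nres) +
               freq_from_counts(cb$npq, cb$nres)) / 2
    } else {
      cc <- count_contacts_one(item)
      fi <- freq_from_counts(cc$npq, cc$nres)
    }
    acc <- acc + fi
  }
  structure(list(F = acc / length(dataset), n_proteins = length(dataset),
                 kind = kind),
            class = "contact_type_stats")
}

#' @export
print.contact_type_stats <- function(x, ...) {
  topn <- sort(x$F, decreasing = TRUE)[1:5]
  cat("<contact_type_stats> ", x$kind, ", n = ", x$n_proteins,
      "; top types: ", paste(names(topn), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Multi-state frequency ratio per contact type
#'
#' R_pq = 2 F^MS_pq / (F^MS_pq + F^SS_pq), in \[0, 2\]; types absent
#' from both datasets are reported as NA rather than 0.
#'
#' @param f_ms,f_ss [contact_frequency()] results over the same types.
#' @return Named numeric vector of 210 ratios (NA where undefined).
#' @export
ms_frequency_ratio <- function(f_ms, f_ss) {
  stopifnot(identical(names(f_ms$F), names(f_ss$F)))
  denom <- f_ms$F + f_ss$F
  r <- ifelse(denom > 0, 2 * f_ms$F / denom, NA_real_)
  setNames(r, names(f_ms$F))
}

#' Changed-contact frequencies over a dataset of pairs
#'
#' Counts residue pairs whose C-alpha distance changes by at least
#' 0.5 nm between the two states: new contacts (d_B <= d_A - 0.5 nm)
#' plus broken contacts (d_B >= d_A + 0.5 nm), normalized per protein
#' by N^i_p N^i_q as in [contact_frequency()] and averaged over
#' proteins.
#'
#' @param dataset List of [state_pair()]s.
#' @return A `contact_type_stats` with kind "changed".
#' @export
changed_contact_frequency <- function(dataset) {
  stopifnot(length(dataset) >= 1)
  acc <- setNames(numeric(210), contact_types())
  for (pair in dataset) {
    stopifnot(inherits(pair, "state_pair"))
    ms <- mapped_structures(pair)
    s <- seq_chars(ms$a)
    da <- pairwise_ca_distances(ms$a)
    db <- pairwise_ca_distances(ms$b)
    changed <- which(upper.tri(da) & abs(db - da) >= 0.5, arr.ind = TRUE)
    tp <- if (nrow(changed))
      pair_type(s[changed[, 1]], s[changed[, 2]]) else character()
    acc <- acc + freq_from_counts(table(tp), table(s))
  }
  structure(list(F = acc / length(dataset), n_proteins = length(dataset),
                 kind = "changed"),
            class = "contact_type_stats")
}

#' Write the contact-type statistics table
#'
#' Tab-separated table with one row per contact type: type, F_ms, F_ss,
#' R, F_changed.
#'
#' @param f_ms,f_ss,f_changed `contact_type_stats` objects (any may be
#'   NULL to omit its column).
#' @param path Output path.
#' @return Invisibly, the data frame written.
#' @export
write_contact_stats <- function(path, f_ms = NULL, f_ss = NULL,
                                f_changed = NULL) {
  df <- data.frame(type = contact_types())
  if (!is.null(f_ms)) df$F_ms <- unname(f_ms$F)
  if (!is.null(f_ss)) df$F_ss <- unname(f_ss$F)
  if (!is.null(f_ms) && !is.null(f_ss))
    df$R <- unname(ms_frequency_ratio(f_ms, f_ss))
  if (!is.null(f_changed)) df$F_changed <- unname(f_changed$F)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
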