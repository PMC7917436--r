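#' Distance definitions
#'
#' Labeled heavy-atom distance definitions (the d1..d22 style map of the
#' H-bond network around the chromophore). Each definition names a donor and
#' an acceptor atom by (residue number, atom name); hydrogens are never part
#' of a definition — the in/out thresholds are on the heavy-atom scale.
#'
#' @param path CSV file with columns `label, resno_a, elety_a, resno_b, elety_b`.
#' @return data.frame of class `distance_defs`.
#' @export
read_distance_defs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "resno_a", "elety_a", "resno_b", "elety_b")
  if (!all(req %in% names(df)))
    stop("distance definition file needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$label)) stop("duplicate distance labels")
  class(df) <- c("distance_defs", "data.frame")
  df
}

#' @rdname read_distance_defs
#' @param label,resno_a,elety_a,resno_b,elety_b vectors defining one distance
#'   per element.
#' @export
distance_defs <- function(label, resno_a, elety_a, resno_b, elety_b) {
  df <- data.frame(label = label, resno_a = resno_a, elety_a = elety_a,
                   resno_b = resno_b, elety_b = elety_b,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$label)) stop("duplicate distance labels")
  class(df) <- c("distance_defs", "data.frame")
  df
}

#' Compute labeled inter-atomic distances along a trajectory
#'
#' Euclidean distances in Angstrom between each definition's two atoms, for
#' every frame.
#'
#' @param frames a [frameset()].
#' @param defs a [distance_defs()] table.
#' @return data.frame with a `frame` column and one column per label.
#' @export
compute_distances <- function(frames, defs) {
  out <- data.frame(frame = seq_len(n_frames(frames)))
  for (i in seq_len(nrow(defs))) {
    ia <- tryCatch(
      resolve_atoms(frames, data.frame(resno = defs$resno_a[i],
                                       elety = defs$elety_a[i])),
      error = function(e) stop("distance ", defs$label[i], ": ",
                               conditionMessage(e), call. = FALSE))
    ib <- tryCatch(
      resolve_atoms(frames, data.frame(resno = defs$resno_b[i],
                                       elety = defs$elety_b[i])),
      error = function(e) stop("distance ", defs$label[i], ": ",
                               conditionMessage(e), call. = FALSE))
    dxyz <- frames$xyz[, xyz_index(ia), drop = FALSE] -
            frames$xyz[, xyz_index(ib), drop = FALSE]
    out[[defs$label[i]]] <- sqrt(rowSums(dxyz^2))
  }
  out
}

#' Side-chain dihedral angle series
#'
#' Signed dihedral of four atoms per frame, in degrees in (-180, 180], using
#' the standard convention (positive when the far bond rotates clockwise
#' viewed along the central bond). Frames where three consecutive atoms are
#' collinear yield `NA` with a warning rather than aborting.
#'
#' @param frames a [frameset()].
#' @param selectors four atom selectors (see [resolve_atoms()]).
#' @param label optional series label.
#' @return data.frame with columns `frame`, `angle`.
#' @export
compute_dihedral <- function(frames, selectors, label = "dihedral") {
  idx <- resolve_atoms(frames, selectors)
  if (length(idx) != 4L) stop("a dihedral needs exactly 4 atom selectors")
  cols <- xyz_index(idx)
  ang <- vapply(seq_len(n_frames(frames)), function(f) {
    v <- frames$xyz[f, cols]
    a <- suppressWarnings(bio3d::torsion.xyz(v, atm.inc = 4))
    as.numeric(a[1])
  }, numeric(1))
  bad <- !is.finite(ang)
  if (any(bad)) {
    warning(sum(bad), " frame(s) with collinear atoms in ", label,
            "; flagged as missing")
    ang[bad] <- NA_real_
  }
  # map -180 -> 180 to keep the (-180, 180] range convention
  ang[!is.na(ang) & ang <= -180] <- ang[!is.na(ang) & ang <= -180] + 360
  data.frame(frame = seq_len(n_frames(frames)), angle = ang)
}

#' Ring RMSD after rigid superposition on a fit set
#'
#' For each frame, the fit atoms are superposed onto the reference frame's
#' fit atoms by least-squares rotation + translation (reflections excluded),
#' and the RMSD is then computed over the target atoms without refitting on
#' them. This is the scheme used for chromophore-ring mobility: align on the
#' (rigid) protein scaffold, measure the isoalloxazine ring.
#'
#' @param frames a [frameset()].
#' @param fit_selectors selectors for the atoms used in the superposition
#'   (at least 3).
#' @param target_selectors selectors for the atoms the RMSD is computed over.
#' @param reference a single-frame [frameset()] containing all fit and
#'   target atoms.
#' @return data.frame with columns `frame`, `rmsd` (Angstrom).
#' @export
compute_ring_rmsd <- function(frames, fit_selectors, target_selectors,
                              reference) {
  if (n_frames(reference) != 1L) stop("reference must contain exactly 1 frame")
  fit_m <- resolve_atoms(frames, fit_selectors)
  tgt_m <- resolve_atoms(frames, target_selectors)
  fit_r <- resolve_atoms(reference, fit_selectors)
  tgt_r <- resolve_atoms(reference, target_selectors)
  if (length(fit_m) < 3L) stop("need at least 3 fit atoms for superposition")
  ref_xyz <- as.vector(reference$xyz[1, ])
  fitted <- bio3d::fit.xyz(fixed = ref_xyz, mobile = frames$xyz,
                           fixed.inds = xyz_index(fit_r),
                           mobile.inds = xyz_index(fit_m))
  if (is.vector(fitted)) fitted <- matrix(fitted, nrow = 1)
  tgt_cols_m <- xyz_index(tgt_m)
  tgt_cols_r <- xyz_index(tgt_r)
  ref_t <- ref_xyz[tgt_cols_r]
  d <- sweep(fitted[, tgt_cols_m, drop = FALSE], 2, ref_t)
  rmsd <- sqrt(rowSums(d^2) / length(tgt_m))
  data.frame(frame = seq_len(n_frames(frames)), rmsd = rmsd)
}
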