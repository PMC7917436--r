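#' Default van der Waals radius table (Bondi)
#'
#' Element radii in Angstrom used as Gaussian widths for the pseudo-density
#' overlap metric.
#'
#' @param path optional two-column CSV (`element`, `radius`) overriding the
#'   built-in set.
#' @return named numeric vector of radii.
#' @export
vdw_radii <- function(path = NULL) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, F = 1.47,
         CL = 1.75, BR = 1.85, I = 1.98)
  if (!is.null(path)) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("element", "radius") %in% names(tab)))
      stop("radius table needs columns element, radius")
    r[toupper(tab$element)] <- tab$radius
  }
  if (any(r <= 0)) stop("van der Waals radii must be positive")
  r
}

#' Build a van der Waals pseudo-density for a molecular fragment
#'
#' The fragment's pseudo-electronic density is a sum of unit-normalized
#' isotropic 3-D Gaussians centered on its heavy atoms, with standard
#' deviations equal to the elements' van der Waals radii. Hydrogens are
#' excluded.
#'
#' @param frames a [frameset()].
#' @param fragment_selectors selectors (see [resolve_atoms()]) for the
#'   fragment's atoms; hydrogens among them are dropped.
#' @param radius_table named radii from [vdw_radii()].
#' @param frame frame index to take coordinates from.
#' @param label fragment label.
#' @return object of class `pseudo_density` with `centers` (matrix) and
#'   `sigma` (vector).
#' @export
build_pseudo_density <- function(frames, fragment_selectors,
                                 radius_table = vdw_radii(),
                                 frame = 1L, label = "fragment") {
  idx <- resolve_atoms(frames, fragment_selectors)
  el <- toupper(frames$atoms$elesy[idx])
  heavy <- el != "H"
  if (!any(heavy))
    stop("fragment '", label, "' contains no heavy atoms")
  idx <- idx[heavy]; el <- el[heavy]
  missing <- setdiff(unique(el), names(radius_table))
  if (length(missing) > 0)
    stop("element(s) missing from radius table: ",
         paste(missing, collapse = ", "))
  co <- matrix(frames$xyz[frame, xyz_index(idx)], ncol = 3, byrow = TRUE)
  pseudo_density(co, radius_table[el], label)
}

#' @rdname build_pseudo_density
#' @param centers n x 3 matrix of heavy-atom centers (Angstrom).
#' @param sigma per-center Gaussian widths (Angstrom).
#' @export
pseudo_density <- function(centers, sigma, label = "fragment") {
  centers <- matrix(as.numeric(centers), ncol = 3)
  sigma <- as.numeric(sigma)
  if (nrow(centers) < 1) stop("a pseudo-density needs at least one center")
  if (length(sigma) == 1) sigma <- rep(sigma, nrow(centers))
  if (length(sigma) != nrow(centers))
    stop("sigma length must match the number of centers")
  if (any(sigma <= 0)) stop("Gaussian widths must be positive")
  structure(list(centers = centers, sigma = sigma, label = label),
            class = "pseudo_density")
}

# closed-form integral of a product of two sums of unit-normalized
# isotropic 3-D Gaussians: each pair contributes
# (2 pi (s_i^2 + s_j^2))^(-3/2) exp(-d_ij^2 / (2 (s_i^2 + s_j^2)))
gaussian_cross_overlap <- function(a, b) {
  s2 <- outer(a$sigma^2, b$sigma^2, `+`)
  d2 <- outer(rowSums(a$centers^2), rowSums(b$centers^2), `+`) -
        2 * a$centers %*% t(b$centers)
  d2[d2 < 0] <- 0
  sum((2 * pi * s2)^(-1.5) * exp(-d2 / (2 * s2)))
}

#' Pseudo-density overlap between two fragments
#'
#' Raw overlap integral of the two pseudo-densities (Angstrom^-3), evaluated
#' in closed form, plus the Carbo-style normalized index
#' `raw / sqrt(self_A * self_B)`, a dimensionless similarity in `[0, 1]`
#' that is comparable across fragments of different atom counts.
#'
#' @param a,b `pseudo_density` objects.
#' @return list with `raw` and `normalized`.
#' @export
overlap <- function(a, b) {
  stopifnot(inherits(a, "pseudo_density"), inherits(b, "pseudo_density"))
  raw <- gaussian_cross_overlap(a, b)
  self_a <- gaussian_cross_overlap(a, a)
  self_b <- gaussian_cross_overlap(b, b)
  list(raw = raw, normalized = raw / sqrt(self_a * self_b))
}

#' Per-frame overlap series between two fragments
#'
#' Evaluates the pseudo-density overlap for every frame and summarizes the
#' distribution (this is the "crowding" observable: how tightly an apolar
#' side chain packs against the chromophore ring along the trajectory).
#'
#' @param frames a [frameset()].
#' @param frag_a,frag_b fragment selectors.
#' @param radius_table named radii from [vdw_radii()].
#' @return data.frame with columns `frame`, `raw`, `normalized`; attribute
#'   `summary` holds mean and quantiles of the normalized overlap.
#' @export
overlap_series <- function(frames, frag_a, frag_b,
                           radius_table = vdw_radii()) {
  nf <- n_frames(frames)
  raw <- numeric(nf); nrm <- numeric(nf)
  for (f in seq_len(nf)) {
    da <- build_pseudo_density(frames, frag_a, radius_table, frame = f,
                               label = "A")
    db <- build_pseudo_density(frames, frag_b, radius_table, frame = f,
                               label = "B")
    o <- overlap(da, db)
    raw[f] <- o$raw; nrm[f] <- o$normalized
  }
  out <- data.frame(frame = seq_len(nf), raw = raw, normalized = nrm)
  attr(out, "summary") <- c(mean = mean(nrm),
                            stats::quantile(nrm, c(0.05, 0.25, 0.5, 0.75, 0.95)))
  out
}
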