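#' Spectral density from a discrete vibronic mode set
#'
#' A set of (frequency, Huang-Rhys factor) pairs defining the homogeneous
#' vibronic lineshape; the total reorganization energy
#' `lambda = sum_k S_k * omega_k` is carried on the object.
#'
#' @param frequency_cm1 mode frequencies (cm^-1, > 0).
#' @param huang_rhys dimensionless Huang-Rhys factors (>= 0).
#' @return object of class `spectral_density`.
#' @export
spectral_density <- function(frequency_cm1, huang_rhys) {
  if (length(frequency_cm1) == 0) stop("mode list must be non-empty")
  if (length(frequency_cm1) != length(huang_rhys))
    stop("frequency and Huang-Rhys vectors differ in length")
  if (any(frequency_cm1 <= 0)) stop("mode frequencies must be positive")
  if (any(huang_rhys < 0)) stop("Huang-Rhys factors must be non-negative")
  structure(list(modes = data.frame(frequency_cm1 = frequency_cm1,
                                    huang_rhys = huang_rhys),
                 reorganization = sum(huang_rhys * frequency_cm1)),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("spectral_density: %d modes, lambda = %.1f cm^-1\n",
              nrow(x$modes), x$reorganization))
  invisible(x)
}

#' Read a mode set from CSV
#'
#' Accepts either columns (`frequency_cm1`, `huang_rhys`) or
#' (`frequency_cm1`, `gradient_projection`); the latter is converted through
#' [huang_rhys_from_gradient()].
#'
#' @param path CSV path.
#' @return a [spectral_density()].
#' @export
read_mode_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("huang_rhys" %in% names(df))
    spectral_density(df$frequency_cm1, df$huang_rhys)
  else if ("gradient_projection" %in% names(df))
    huang_rhys_from_gradient(df$frequency_cm1, df$gradient_projection)
  else stop("mode CSV needs huang_rhys or gradient_projection column")
}

#' Huang-Rhys factors from excited-state gradient projections
#'
#' In the vertical-gradient approximation the excited-state gradient at the
#' ground-state minimum, projected on normal mode k (`g_k`, in Hartree per
#' mass-weighted atomic-unit displacement), gives the dimensionless
#' displacement `Delta_k = g_k / omega_k^2` and the Huang-Rhys factor
#' `S_k = g_k^2 / (2 hbar omega_k^3)` (atomic units, hbar = 1). Frequencies
#' are supplied in cm^-1 and converted internally.
#'
#' @param frequency_cm1 mode frequencies (cm^-1, > 0).
#' @param gradient_projections per-mode gradient projections (atomic units).
#' @return a [spectral_density()].
#' @export
huang_rhys_from_gradient <- function(frequency_cm1, gradient_projections) {
  if (length(frequency_cm1) != length(gradient_projections))
    stop("frequency and gradient vectors differ in length")
  if (any(frequency_cm1 <= 0))
    stop("zero or negative mode frequency")
  w_au <- frequency_cm1 / HARTREE_TO_CM1
  s <- gradient_projections^2 / (2 * w_au^3)
  spectral_density(frequency_cm1, s)
}

#' Homogeneous absorption lineshape by the second-order cumulant / DHO
#' formalism
#'
#' Computes the lineshape function
#' `g(t) = sum_k S_k * (coth(hbar w_k / 2 kB T) (1 - cos w_k t) + i sin w_k t)`
#' and the spectrum
#' `sigma(w) = Re integral_0^inf exp(i (w - w00) t - g(t) - Gamma t) dt`,
#' exact for displaced harmonic oscillators. The grid is relative to the 0-0
#' origin (`w = 0` is the 0-0 line; the vertical excitation energy sits at
#' `+lambda`). The time integral is evaluated by FFT with adaptive length;
#' the result is area-normalized to 1 on the grid. If more than 1% of the
#' analytic total area (`pi`, since g(0) = 0) falls outside the grid, a
#' coverage error is raised.
#'
#' @param sd a [spectral_density()].
#' @param temperature temperature in K (0 gives the zero-temperature limit).
#' @param broadening Lorentzian homogeneous broadening Gamma (cm^-1, > 0).
#' @param grid wavenumber grid relative to the 0-0 origin (cm^-1, strictly
#'   increasing); default spans `[-8000, lambda + 8000]` in 2 cm^-1 steps.
#' @return object of class `lineshape` with `grid`, `intensity` and
#'   `metadata`.
#' @export
cumulant_lineshape <- function(sd, temperature = 300, broadening = 100,
                               grid = NULL) {
  stopifnot(inherits(sd, "spectral_density"))
  if (broadening <= 0) stop("broadening must be positive")
  if (temperature < 0) stop("temperature must be non-negative")
  w <- sd$modes$frequency_cm1
  S <- sd$modes$huang_rhys
  lambda <- sd$reorganization
  if (is.null(grid))
    grid <- seq(-8000, lambda + 8000, by = 2)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  coth <- if (temperature == 0) rep(1, length(w))
          else 1 / tanh(w / (2 * KB_CM1 * temperature))

  wmax <- max(abs(range(grid)), w)
  dt <- pi / (4 * wmax)                     # Nyquist with 4x margin
  t_need <- max(30 / broadening, 4096 * dt)
  N <- 2^ceiling(log2(t_need / dt))
  tt <- (0:(N - 1)) * dt
  ph <- outer(w, tt)                        # K x N phase matrix
  g <- as.vector((S * coth) %*% (1 - cos(ph))) +
       1i * as.vector(S %*% sin(ph))
  f <- exp(-g - broadening * tt)
  if (Mod(f[N]) > 1e-6)
    warning("time-domain signal not fully damped; increase broadening")
  f[1] <- f[1] / 2                          # trapezoid endpoint at t = 0
  spec <- Re(stats::fft(f, inverse = TRUE)) * dt
  om <- 2 * pi * (0:(N - 1)) / (N * dt)
  neg <- om > pi / dt
  om[neg] <- om[neg] - 2 * pi / dt
  ord <- order(om)
  vals <- stats::approx(om[ord], spec[ord], xout = grid)$y
  if (anyNA(vals)) stop("grid extends beyond the resolvable frequency range")
  area <- .trapz(grid, pmax(vals, 0))
  if (area < 0.99 * pi)
    stop("grid too narrow: >= 1% of the lineshape area falls outside it")
  intensity <- pmax(vals, 0) / area
  structure(list(grid = grid, intensity = intensity,
                 metadata = list(temperature = temperature,
                                 broadening = broadening,
                                 reorganization = lambda,
                                 origin = "0-0 line at grid zero",
                                 shift = 0)),
            class = "lineshape")
}

#' @export
print.lineshape <- function(x, ...) {
  cat(sprintf("lineshape: %d grid points in [%.0f, %.0f] cm^-1\n",
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Ensemble absorption spectrum from per-snapshot electronic records
#'
#' `I(w) = sum_j |mu01_j|^2 sigma(w - w01_j)`: the homogeneous lineshape is
#' placed at each snapshot's vertical excitation energy (the record's `w01`
#' sits at the lineshape origin) and weighted by its squared transition
#' dipole. Energies in eV are converted with 1 eV = 8065.544 cm^-1.
#'
#' @param records data.frame with columns `exc_eV`, `mux`, `muy`, `muz`
#'   (dipoles in arbitrary consistent units).
#' @param lineshape a [cumulant_lineshape()] result (relative grid).
#' @param grid absolute wavenumber grid; default covers all records plus the
#'   lineshape support.
#' @return a `lineshape` on the absolute wavenumber axis (not normalized).
#' @export
ensemble_spectrum <- function(records, lineshape, grid = NULL) {
  if (nrow(records) < 1) stop("at least one electronic record is required")
  w01 <- ev_to_cm1(records$exc_eV)
  mu2 <- if (all(c("mux", "muy", "muz") %in% names(records)))
    records$mux^2 + records$muy^2 + records$muz^2 else rep(1, nrow(records))
  if (is.null(grid)) {
    step <- stats::median(diff(lineshape$grid))
    grid <- seq(min(w01) + min(lineshape$grid),
                max(w01) + max(lineshape$grid), by = step)
  }
  total <- numeric(length(grid))
  for (j in seq_len(nrow(records))) {
    total <- total + mu2[j] *
      stats::approx(lineshape$grid + w01[j], lineshape$intensity,
                    xout = grid, yleft = 0, yright = 0)$y
  }
  structure(list(grid = grid, intensity = total,
                 metadata = c(lineshape$metadata,
                              list(n_records = nrow(records)))),
            class = "lineshape")
}

#' Population-weighted average of cluster spectra
#'
#' Pointwise population-weighted sum of per-cluster spectra on a common
#' grid; populations are renormalized over the supplied clusters.
#'
#' @param cluster_spectra named list of `lineshape` objects on an identical
#'   grid.
#' @param populations numeric weights (>= 0), same order/names.
#' @return a `lineshape`.
#' @export
weighted_average_spectra <- function(cluster_spectra, populations) {
  if (length(cluster_spectra) != length(populations))
    stop("one population per cluster spectrum is required")
  if (any(populations < 0)) stop("populations must be non-negative")
  if (sum(populations) <= 0) stop("populations sum to zero")
  w <- populations / sum(populations)
  g0 <- cluster_spectra[[1]]$grid
  for (sp in cluster_spectra)
    if (!isTRUE(all.equal(sp$grid, g0)))
      stop("cluster spectra are on different grids")
  total <- Reduce(`+`, Map(function(sp, wi) wi * sp$intensity,
                           cluster_spectra, w))
  structure(list(grid = g0, intensity = total,
                 metadata = list(weights = w,
                                 n_clusters = length(cluster_spectra))),
            class = "lineshape")
}

#' Normalize a spectrum to unit maximum and apply a rigid shift
#'
#' Standard plotting convention for computed absorption spectra: intensities
#' scaled so the maximum is exactly 1 and the wavenumber axis rigidly
#' shifted (e.g. by -3500 cm^-1 to match an experimental band maximum).
#' Both operations are recorded in the metadata.
#'
#' @param spec a `lineshape`.
#' @param shift rigid wavenumber shift in cm^-1.
#' @return a `lineshape`.
#' @export
normalize_and_shift <- function(spec, shift = -3500) {
  m <- max(spec$intensity)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize an all-zero spectrum")
  meta <- spec$metadata
  meta$normalized <- TRUE
  meta$shift <- (if (is.null(meta$shift)) 0 else meta$shift) + shift
  structure(list(grid = spec$grid + shift, intensity = spec$intensity / m,
                 metadata = meta),
            class = "lineshape")
}

#' Per-cluster Stokes-shift table with population-weighted averages
#'
#' For every record the Stokes shift is `(EXC - EMI) * 8065.544` cm^-1;
#' cluster rows are per-record means, and the weighted-average row uses the
#' populations renormalized over the clusters present. Records without an
#' emission energy are excluded with a message. Averaging happens before any
#' rounding; [format_stokes_table()] applies the conventional display
#' rounding (2 decimals for eV, integer cm^-1).
#'
#' @param records data.frame with `cluster`, `exc_eV`, `emi_eV`.
#' @param populations named numeric vector of cluster populations.
#' @return data.frame with rows per cluster plus an `avg` row; columns
#'   `cluster`, `population`, `exc_eV`, `emi_eV`, `ss_cm1`.
#' @export
stokes_table <- function(records, populations) {
  drop <- is.na(records$emi_eV)
  if (any(drop)) {
    message(sum(drop), " record(s) without emission energy excluded")
    records <- records[!drop, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no usable records")
  if (any(records$exc_eV <= 0 | records$emi_eV <= 0))
    stop("energies must be positive")
  clusters <- unique(as.character(records$cluster))
  if (!all(clusters %in% names(populations)))
    stop("populations missing for cluster(s): ",
         paste(setdiff(clusters, names(populations)), collapse = ", "))
  ss <- (records$exc_eV - records$emi_eV) * EV_TO_CM1
  rows <- do.call(rbind, lapply(clusters, function(cl) {
    sel <- records$cluster == cl
    data.frame(cluster = cl,
               population = unname(populations[[cl]]),
               exc_eV = mean(records$exc_eV[sel]),
               emi_eV = mean(records$emi_eV[sel]),
               ss_cm1 = mean(ss[sel]))
  }))
  rbind(rows, cbind(data.frame(cluster = "avg", population = sum(rows$population)),
                    stokes_weighted_average(rows, rows$population)))
}

#' Population-weighted average of per-cluster energy rows
#'
#' Weighted means of the excitation, emission and Stokes-shift columns using
#' renormalized populations. This is the operation that turns a per-cluster
#' energy table into its weighted-average row.
#'
#' @param cluster_table data.frame with columns `exc_eV`, `emi_eV`, `ss_cm1`.
#' @param populations weights (any positive scale; renormalized internally).
#' @return one-row data.frame with `exc_eV`, `emi_eV`, `ss_cm1`.
#' @export
stokes_weighted_average <- function(cluster_table, populations) {
  if (length(populations) != nrow(cluster_table))
    stop("one population per cluster row is required")
  if (any(populations < 0) || sum(populations) <= 0)
    stop("populations must be non-negative with positive sum")
  w <- populations / sum(populations)
  data.frame(exc_eV = sum(w * cluster_table$exc_eV),
             emi_eV = sum(w * cluster_table$emi_eV),
             ss_cm1 = sum(w * cluster_table$ss_cm1))
}

#' @rdname stokes_table
#' @param table a Stokes table (unrounded).
#' @export
format_stokes_table <- function(table) {
  out <- table
  out$exc_eV <- sprintf("%.2f", table$exc_eV)
  out$emi_eV <- sprintf("%.2f", table$emi_eV)
  out$ss_cm1 <- sprintf("%d", round(table$ss_cm1))
  out
}

#' Reporting-consistency check for a Stokes table
#'
#' With eV energies rounded to 2 decimals and Stokes shifts to integers, the
#' recomputed `(EXC - EMI) * 8065.544` can differ from the reported shift by
#' at most ~81 cm^-1 (the rounding bound: 0.01 eV). Returns the maximum
#' discrepancy over rows.
#'
#' @param table data.frame with `exc_eV`, `emi_eV`, `ss_cm1` (reported,
#'   i.e. rounded, values).
#' @return maximum absolute discrepancy in cm^-1.
#' @export
stokes_consistency <- function(table) {
  max(abs(table$ss_cm1 - (table$exc_eV - table$emi_eV) * EV_TO_CM1))
}

#' Mean-excitation shift between two clusters
#'
#' Difference of mean vertical excitation energies (cluster `a` minus
#' cluster `b`), converted to cm^-1. This quantifies e.g. the blue shift
#' caused by losing the glutamine-flavin H-bond (out minus in).
#'
#' @param records data.frame with `cluster`, `exc_eV`.
#' @param cluster_a,cluster_b cluster ids.
#' @return shift in cm^-1.
#' @export
cluster_shift <- function(records, cluster_a, cluster_b) {
  ea <- records$exc_eV[records$cluster == cluster_a]
  eb <- records$exc_eV[records$cluster == cluster_b]
  if (length(ea) == 0 || length(eb) == 0)
    stop("empty cluster in shift computation")
  (mean(ea) - mean(eb)) * EV_TO_CM1
}

#' @rdname cluster_shift
#' @param x shift in cm^-1.
#' @export
round_to_hundred <- function(x) 100 * round(x / 100)
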