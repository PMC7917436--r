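#' Configuration for the synthetic pocket-dynamics generator
#'
#' The generator emulates the features of a microsecond flavin-pocket MD
#' study that the downstream analysis consumes, with a known ground truth:
#' two-state (in/out) side-chain dynamics on a frame grid with hundreds-of-ns
#' dwell times, cluster-dependent excitation/emission energy distributions on
#' the scale of flavoprotein QM/MM results (~3.2 eV excitation), and a
#' discrete vibronic mode set producing a two-band absorption envelope.
#'
#' Two dynamics modes are available. By default each tracked residue follows
#' its own two-state discrete-time Markov chain whose transition
#' probabilities reproduce the configured mean dwell times (exponential
#' dwell approximation). Alternatively, `classes` plants an explicit set of
#' conformational classes with prescribed stationary populations: a single
#' hidden Markov chain over classes with transition probabilities
#' `P(c -> c') = alpha * pop(c')` for `c != c'`, which has exactly the
#' configured populations as its stationary distribution; each class maps to
#' a definite in/out state per residue.
#'
#' @param n_frames number of frames (>= 1).
#' @param frame_spacing frame spacing in ns.
#' @param residues named list; each element a list with `in_mean`, `in_sd`,
#'   `out_mean`, `out_sd` (Angstrom), `dwell_in`, `dwell_out` (ns) and
#'   optionally `distance` (column label, default `d1`, `d2`, ...).
#' @param classes optional planted-class list; each element a list with
#'   `name`, `population`, and `states` (named character vector mapping every
#'   tracked residue to `"in"` or `"out"`).
#' @param class_dwell mean dwell (ns) of a 50%-populated class in planted
#'   mode; classes with population p dwell `class_dwell/(2*(1-p))` ns.
#' @param stable_distances named list of always-formed H-bond columns, each
#'   with `mean` and `sd` (Angstrom); these pad the feature set the way the
#'   persistent pocket H-bonds do.
#' @param energy_model named list (one entry per conformational class, `IN`
#'   and `OUT` by default) with `exc_mean`, `exc_sd`, `emi_mean`, `emi_sd`
#'   in eV.
#' @param dihedral_modes list with `flipped` and `unflipped`, each
#'   `list(mean, sd)` in degrees, describing the rotamer states of the
#'   apolar side chains.
#' @param mode_set data.frame with columns `frequency_cm1`, `huang_rhys`.
#' @param min_distance hard lower truncation for generated distances (Angstrom).
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_frames,
                             frame_spacing = 1,
                             residues = default_residues(),
                             classes = NULL,
                             class_dwell = 250,
                             stable_distances = list(
                               d4 = list(mean = 2.9, sd = 0.15),
                               d5 = list(mean = 3.0, sd = 0.15)),
                             energy_model = default_energy_model(),
                             dihedral_modes = list(
                               flipped   = list(mean = 65,  sd = 10),
                               unflipped = list(mean = -55, sd = 10)),
                             mode_set = default_mode_set(),
                             min_distance = 1.5,
                             seed = 1L) {
  if (!is.numeric(n_frames) || n_frames < 1)
    stop("n_frames must be >= 1")
  if (frame_spacing <= 0) stop("frame_spacing must be positive")
  if (length(residues) < 1) stop("at least one tracked residue is required")
  for (nm in names(residues)) {
    r <- residues[[nm]]
    need <- c("in_mean", "in_sd", "out_mean", "out_sd", "dwell_in", "dwell_out")
    if (!all(need %in% names(r)))
      stop("residue ", nm, " is missing fields: ",
           paste(setdiff(need, names(r)), collapse = ", "))
    if (r$in_sd <= 0 || r$out_sd <= 0)
      stop("residue ", nm, ": state sds must be positive")
    if (r$dwell_in <= frame_spacing || r$dwell_out <= frame_spacing)
      stop("residue ", nm, ": dwell times must exceed the frame spacing")
  }
  for (i in seq_along(residues))
    if (is.null(residues[[i]]$distance))
      residues[[i]]$distance <- paste0("d", i)
  if (!is.null(classes)) {
    pops <- vapply(classes, function(cl) cl$population, numeric(1))
    if (abs(sum(pops) - 1) > 1e-9) stop("class populations must sum to 1")
    if (any(pops <= 0)) stop("class populations must be positive")
    if (class_dwell <= frame_spacing)
      stop("class_dwell must exceed the frame spacing")
    for (cl in classes)
      if (!all(names(residues) %in% names(cl$states)))
        stop("class ", cl$name, " does not map every tracked residue")
  }
  for (nm in names(stable_distances)) {
    s <- stable_distances[[nm]]
    if (s$sd <= 0) stop("stable distance ", nm, ": sd must be positive")
  }
  for (nm in names(energy_model)) {
    e <- energy_model[[nm]]
    if (e$exc_mean <= 0 || e$emi_mean <= 0)
      stop("energy model ", nm, ": energies must be positive")
    if (e$exc_sd < 0 || e$emi_sd < 0)
      stop("energy model ", nm, ": sds must be non-negative")
  }
  validate_modes(mode_set)
  structure(list(n_frames = as.integer(n_frames),
                 frame_spacing = frame_spacing,
                 residues = residues, classes = classes,
                 class_dwell = class_dwell,
                 stable_distances = stable_distances,
                 energy_model = energy_model,
                 dihedral_modes = dihedral_modes,
                 mode_set = mode_set,
                 min_distance = min_distance,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Defaults emulate a glutamine/asparagine pair hydrogen-bonded to the flavin
# ring: in-state heavy-atom distance 2.9 +/- 0.2 A, out-state 6.5 +/- 0.8 A
# (straddling the 4 / 5 A in/out thresholds with a clear gap), switching on
# the 250 ns scale.
default_residues <- function() {
  list(Q489 = list(in_mean = 2.9, in_sd = 0.2, out_mean = 6.5, out_sd = 0.8,
                   dwell_in = 250, dwell_out = 250),
       N468 = list(in_mean = 2.9, in_sd = 0.2, out_mean = 6.5, out_sd = 0.8,
                   dwell_in = 250, dwell_out = 250))
}

# Energy scale anchored to flavoprotein QM/MM vertical energies: losing the
# glutamine H-bond blue-shifts excitation by ~0.05 eV (~400 cm^-1).
default_energy_model <- function() {
  list(IN  = list(exc_mean = 3.22, exc_sd = 0.02, emi_mean = 2.82, emi_sd = 0.02),
       OUT = list(exc_mean = 3.27, exc_sd = 0.02, emi_mean = 2.88, emi_sd = 0.02))
}

# A compact flavin-like mode set: two dominant ring stretches plus a
# low-frequency mode; yields the characteristic two-band vibronic envelope.
default_mode_set <- function() {
  data.frame(frequency_cm1 = c(250, 1360, 1560),
             huang_rhys    = c(0.35, 0.45, 0.25))
}

validate_modes <- function(mode_set) {
  if (!is.data.frame(mode_set) || nrow(mode_set) == 0)
    stop("mode_set must be a non-empty data.frame")
  if (!all(c("frequency_cm1", "huang_rhys") %in% names(mode_set)))
    stop("mode_set needs columns frequency_cm1, huang_rhys")
  if (any(mode_set$frequency_cm1 <= 0)) stop("mode frequencies must be positive")
  if (any(mode_set$huang_rhys < 0)) stop("Huang-Rhys factors must be non-negative")
  invisible(mode_set)
}

# two-state residue chain: geometric dwell with mean dwell/spacing frames
simulate_two_state <- function(n, p_leave_in, p_leave_out) {
  pi_in <- p_leave_out / (p_leave_in + p_leave_out)
  s <- character(n)
  s[1] <- if (stats::runif(1) < pi_in) "in" else "out"
  u <- stats::runif(n - 1)
  for (t in seq_len(n - 1)) {
    p <- if (s[t] == "in") p_leave_in else p_leave_out
    s[t + 1] <- if (u[t] < p) setdiff(c("in", "out"), s[t]) else s[t]
  }
  s
}

simulate_class_chain <- function(n, pops, alpha) {
  k <- length(pops)
  s <- integer(n)
  s[1] <- sample.int(k, 1, prob = pops)
  u <- stats::runif(n - 1)
  # P(c -> c') = alpha * pop(c'), c' != c; stay otherwise
  cum <- cumsum(pops)
  for (t in seq_len(n - 1)) {
    c0 <- s[t]
    p_leave <- alpha * (1 - pops[c0])
    if (u[t] < p_leave) {
      # jump to c' != c0 with probability proportional to pop(c')
      v <- stats::runif(1) * (1 - pops[c0])
      acc <- 0
      for (j in seq_len(k)) {
        if (j == c0) next
        acc <- acc + pops[j]
        if (v <= acc) { s[t + 1] <- j; break }
      }
      if (s[t + 1] == 0L) s[t + 1] <- setdiff(seq_len(k), c0)[1]
    } else s[t + 1] <- c0
  }
  s
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Generate a synthetic pocket trajectory with known ground truth
#'
#' Simulates in/out side-chain dynamics for every tracked residue, draws
#' state-conditional H-bond distances (Gaussian, truncated below
#' `min_distance`), and embeds them as coordinates: acceptor pseudo-atoms sit
#' on a fixed scaffold and each donor moves along its own axis so that the
#' recomputed donor-acceptor distance equals the generated series exactly.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `frames` ([frameset()]), `distances`
#'   (data.frame, one column per labeled distance), and `truth`
#'   (per-frame residue states, per-frame conformational class,
#'   class populations, and the planted class series when applicable).
#' @export
generate_pocket_trajectory <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_frames
  resnames <- names(config$residues)
  nr <- length(resnames)

  class_series <- NULL
  if (is.null(config$classes)) {
    states <- matrix("", n, nr, dimnames = list(NULL, resnames))
    for (j in seq_len(nr)) {
      r <- config$residues[[j]]
      states[, j] <- simulate_two_state(
        n,
        p_leave_in  = config$frame_spacing / r$dwell_in,
        p_leave_out = config$frame_spacing / r$dwell_out)
    }
  } else {
    pops <- vapply(config$classes, function(cl) cl$population, numeric(1))
    alpha <- 2 * config$frame_spacing / config$class_dwell
    if (alpha * max(1 - pops) >= 1)
      stop("class_dwell too short for the configured populations")
    idx <- simulate_class_chain(n, pops, alpha)
    class_series <- vapply(config$classes, function(cl) cl$name, "")[idx]
    states <- matrix("", n, nr, dimnames = list(NULL, resnames))
    for (j in seq_len(nr)) {
      per_class <- vapply(config$classes,
                          function(cl) cl$states[[resnames[j]]], "")
      states[, j] <- per_class[idx]
    }
  }

  dist_tab <- data.frame(frame = seq_len(n))
  for (j in seq_len(nr)) {
    r <- config$residues[[j]]
    d <- numeric(n)
    is_in <- states[, j] == "in"
    d[is_in]  <- rnorm_trunc(sum(is_in),  r$in_mean,  r$in_sd,
                             config$min_distance)
    d[!is_in] <- rnorm_trunc(sum(!is_in), r$out_mean, r$out_sd,
                             config$min_distance)
    dist_tab[[r$distance]] <- d
  }
  for (nm in names(config$stable_distances)) {
    s <- config$stable_distances[[nm]]
    dist_tab[[nm]] <- rnorm_trunc(n, s$mean, s$sd, config$min_distance)
  }

  frames <- embed_distances(dist_tab, config)

  frame_class <- apply(states, 1, function(s)
    if (any(s == "out")) "OUT" else "IN")
  pop_tab <- table(if (is.null(class_series)) frame_class else class_series)
  truth <- list(states = states,
                class = frame_class,
                class_series = class_series,
                populations = as.numeric(pop_tab) / n,
                population_names = names(pop_tab),
                energy_means = lapply(config$energy_model, function(e)
                  c(exc = e$exc_mean, emi = e$emi_mean)))
  list(frames = frames, distances = dist_tab, truth = truth)
}

# Acceptors on a fixed scaffold, donors displaced along x by the generated
# distance: the distance <-> coordinate round trip is exact.
embed_distances <- function(dist_tab, config) {
  labels <- setdiff(names(dist_tab), "frame")
  resnames <- names(config$residues)
  donor_names <- c("NE2", "ND2", "ND1", "OG", "OG1", "NZ")
  res3 <- c(Q = "GLN", N = "ASN", H = "HIS", S = "SER", T = "THR", K = "LYS")
  acceptor_names <- c("O4", "O2", "N5", "N1", "N3", "O4P", "O2P", "N10",
                      paste0("OX", seq_len(max(0, length(labels) - 8))))
  atoms <- data.frame(elety = character(0), resid = character(0),
                      resno = integer(0), elesy = character(0))
  n <- nrow(dist_tab)
  xyz <- matrix(0, n, 0)
  for (k in seq_along(labels)) {
    lab <- labels[k]
    j <- match(lab, vapply(config$residues, `[[`, "", "distance"))
    if (!is.na(j)) {
      letter <- substr(resnames[j], 1, 1)
      resid <- if (letter %in% names(res3)) res3[[letter]] else "UNK"
      resno <- suppressWarnings(as.integer(gsub("[^0-9]", "", resnames[j])))
      if (is.na(resno)) resno <- 100L + j
      delety <- donor_names[(j - 1) %% length(donor_names) + 1]
    } else {
      resid <- "UNK"
      resno <- 200L + k
      delety <- "NX"
    }
    y0 <- 8 * k
    atoms <- rbind(atoms,
                   data.frame(elety = acceptor_names[k], resid = "FMN",
                              resno = 1L,
                              elesy = guess_element(acceptor_names[k])),
                   data.frame(elety = delety, resid = resid, resno = resno,
                              elesy = guess_element(delety)))
    acc <- cbind(0, y0, 0)[rep(1, n), , drop = FALSE]
    don <- cbind(dist_tab[[lab]], y0, 0)
    xyz <- cbind(xyz, acc, don)
  }
  frameset(atoms, xyz)
}

#' Generate per-snapshot electronic records from ground-truth classes
#'
#' One record per requested frame, with class-conditional Gaussian
#' excitation/emission energies (eV) and a near-unit transition dipole.
#' Records are redrawn until excitation strictly exceeds emission, which the
#' configured class means must already satisfy.
#'
#' @param truth ground truth from [generate_pocket_trajectory()].
#' @param config the [synthetic_config()] used to generate it.
#' @param frames optional integer vector of frame indices (default: all).
#' @return data.frame with columns `snapshot`, `cluster`, `exc_eV`,
#'   `emi_eV`, `mux`, `muy`, `muz`.
#' @export
generate_electronic_records <- function(truth, config, frames = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cls <- if (!is.null(truth$class_series)) truth$class_series else truth$class
  if (is.null(frames)) frames <- seq_along(cls)
  present <- unique(cls[frames])
  missing <- setdiff(present, names(config$energy_model))
  if (length(missing) > 0)
    stop("energy model has no entry for class(es): ",
         paste(missing, collapse = ", "))
  for (nm in names(config$energy_model)) {
    e <- config$energy_model[[nm]]
    if (e$emi_mean >= e$exc_mean)
      stop("energy model ", nm,
           ": emission mean must be below excitation mean")
  }
  set.seed(config$seed + 1L)
  m <- length(frames)
  exc <- numeric(m); emi <- numeric(m)
  for (nm in present) {
    sel <- which(cls[frames] == nm)
    e <- config$energy_model[[nm]]
    exc[sel] <- stats::rnorm(length(sel), e$exc_mean, e$exc_sd)
    emi[sel] <- stats::rnorm(length(sel), e$emi_mean, e$emi_sd)
    bad <- sel[emi[sel] >= exc[sel]]
    while (length(bad) > 0) {
      exc[bad] <- stats::rnorm(length(bad), e$exc_mean, e$exc_sd)
      emi[bad] <- stats::rnorm(length(bad), e$emi_mean, e$emi_sd)
      bad <- bad[emi[bad] >= exc[bad]]
    }
  }
  mu <- matrix(stats::rnorm(3 * m, 0, 0.05), m, 3)
  mu[, 3] <- mu[, 3] + 1
  data.frame(snapshot = frames, cluster = cls[frames],
             exc_eV = exc, emi_eV = emi,
             mux = mu[, 1], muy = mu[, 2], muz = mu[, 3])
}

#' Build the configured vibronic mode set
#'
#' Returns the configured modes as a [spectral_density()]; the total
#' reorganization energy lambda = sum_k S_k * omega_k is carried on the
#' object.
#'
#' @param config a [synthetic_config()], or a bare data.frame with columns
#'   `frequency_cm1` and `huang_rhys`.
#' @return a `spectral_density`.
#' @export
generate_mode_set <- function(config) {
  modes <- if (inherits(config, "synthetic_config")) config$mode_set else config
  validate_modes(modes)
  spectral_density(modes$frequency_cm1, modes$huang_rhys)
}

#' Generate a toy chromophore-ring / apolar-side-chain system
#'
#' Emulates the "crowding" geometry: a planar fused-ring stand-in for the
#' isoalloxazine ring, an apolar side-chain fragment at a configurable mean
#' separation, and a rigid scaffold used as the superposition reference.
#' Ring mobility is controlled by an isotropic jitter whose magnitude sets
#' the expected ring RMSD; a crowded pocket is emulated with a small
#' separation and small jitter, a loose one with a large separation and
#' larger jitter.
#'
#' @param n_frames number of frames.
#' @param separation mean closest-approach distance ring/side-chain (Angstrom).
#' @param separation_sd frame-to-frame sd of the separation.
#' @param ring_jitter_sd expected ring RMSD scale (Angstrom).
#' @param seed integer seed.
#' @return list with `frames`, `reference` (ideal single-frame geometry),
#'   and selector data.frames `ring_sel`, `side_sel`, `scaffold_sel`.
#' @export
generate_crowding_frames <- function(n_frames, separation = 3.5,
                                     separation_sd = 0.15,
                                     ring_jitter_sd = 0.3, seed = 1L) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  ring0 <- rbind(cbind(1.4 * cos(th), 1.4 * sin(th), 0),
                 c(2.8, 1.2, 0), c(2.8, -1.2, 0), c(3.5, 0, 0))
  ring_el <- c("C", "C", "N", "C", "N", "C", "C", "N", "O")
  ring_name <- c("C5A", "C6", "N7", "C8", "N9", "C9A", "C4A", "N10", "O4")
  scaf0 <- rbind(c(0, 0, 12), c(12, 0, -12), c(-12, 12, -12), c(-12, -12, -12))
  side_k <- 0:3
  atoms <- data.frame(
    elety = c(ring_name, paste0("CD", side_k + 1), paste0("CA", 1:4)),
    resid = c(rep("FMN", 9), rep("LEU", 4), rep("GLY", 4)),
    resno = c(rep(1L, 9), rep(472L, 4), 900L + 1:4),
    elesy = c(ring_el, rep("C", 4), rep("C", 4)))
  n_at <- nrow(atoms)
  xyz <- matrix(0, n_frames, 3 * n_at)
  side0 <- function(sep) cbind(3.5 + sep + 1.5 * side_k, 0.3 * side_k, 0)
  for (f in seq_len(n_frames)) {
    ring <- ring0 + matrix(stats::rnorm(27, 0, ring_jitter_sd / sqrt(3)), 9, 3)
    sep <- max(1.5, stats::rnorm(1, separation, separation_sd))
    co <- rbind(ring, side0(sep), scaf0)
    xyz[f, ] <- as.vector(t(co))
  }
  ref <- frameset(atoms, as.vector(t(rbind(ring0, side0(separation), scaf0))))
  list(frames = frameset(atoms, xyz),
       reference = ref,
       ring_sel = data.frame(resno = 1L, elety = ring_name),
       side_sel = data.frame(resno = 472L, elety = paste0("CD", side_k + 1)),
       scaffold_sel = data.frame(resno = 900L + 1:4, elety = paste0("CA", 1:4)))
}
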