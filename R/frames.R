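#' Trajectory frame sets
#'
#' A `frameset` is an ordered trajectory of labeled atom coordinates: a fixed
#' atom roster shared by all frames plus an `n_frames x (3 * n_atoms)` matrix
#' of coordinates in Angstrom, following the flat xyz layout used by bio3d
#' (x1, y1, z1, x2, ...).
#'
#' @param atoms data.frame with columns `elety` (atom name), `resid`
#'   (residue name), `resno` (residue number) and optionally `elesy`
#'   (element symbol; derived from the atom name when absent).
#' @param xyz numeric matrix, one row per frame, `3 * nrow(atoms)` columns.
#' @return an object of class `frameset`.
#' @export
frameset <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms)
  req <- c("elety", "resid", "resno")
  if (!all(req %in% names(atoms)))
    stop("atom roster must have columns: ", paste(req, collapse = ", "))
  if (is.null(atoms$elesy))
    atoms$elesy <- guess_element(atoms$elety)
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns; expected ", 3L * nrow(atoms))
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in frame set")
  structure(list(atoms = atoms, xyz = xyz), class = "frameset")
}

#' @export
print.frameset <- function(x, ...) {
  cat(sprintf("frameset: %d frames x %d atoms (%d residues)\n",
              nrow(x$xyz), nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

#' @rdname frameset
#' @param x a `frameset`.
#' @export
n_frames <- function(x) nrow(x$xyz)

#' @rdname frameset
#' @export
n_atoms <- function(x) nrow(x$atoms)

# Element symbol from a PDB-style atom name: strip digits/primes, first
# letter. Good enough for the heavy-atom rosters this package works with.
guess_element <- function(elety) {
  s <- gsub("[^A-Za-z]", "", elety)
  toupper(substr(s, 1, 1))
}

#' Resolve atom selectors against a frameset roster
#'
#' Selectors are (residue number, atom name) pairs, given either as a
#' data.frame with columns `resno` and `elety` or as strings `"489:NE2"`.
#' Each selector must resolve to exactly one atom.
#'
#' @param frames a `frameset`.
#' @param selectors data.frame or character vector of `"resno:atomname"`.
#' @return integer vector of atom indices into the roster.
#' @export
resolve_atoms <- function(frames, selectors) {
  sel <- as_selector_df(selectors)
  idx <- integer(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    hit <- which(frames$atoms$resno == sel$resno[i] &
                 frames$atoms$elety == sel$elety[i])
    if (length(hit) != 1L)
      stop("selector ", sel$resno[i], ":", sel$elety[i], " resolves to ",
           length(hit), " atoms (need exactly 1)")
    idx[i] <- hit
  }
  idx
}

as_selector_df <- function(selectors) {
  if (is.character(selectors)) {
    parts <- strsplit(selectors, ":", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("string selectors must look like \"489:NE2\"")
    data.frame(resno = as.integer(vapply(parts, `[`, "", 1L)),
               elety = vapply(parts, `[`, "", 2L))
  } else {
    df <- as.data.frame(selectors)
    if (!all(c("resno", "elety") %in% names(df)))
      stop("selector data.frame needs columns resno, elety")
    df
  }
}

# xyz column indices (x,y,z) for atom indices
xyz_index <- function(atom_idx) {
  as.vector(rbind(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx))
}

#' Read a trajectory from a multi-model PDB or XYZ file
#'
#' Multi-model PDB files (one `MODEL`/`ENDMDL` block per frame) are parsed
#' with bio3d; XYZ files use the plain repeated-block dialect
#' (atom count line, comment line, then `element x y z` records).
#' All frames must share the same atom roster.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @return a `frameset`.
#' @export
read_frames <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", xyz = "xyz",
                     stop("cannot infer trajectory format from extension '",
                          ext, "'"))
  }
  if (file.info(path)$size == 0 || length(readLines(path, n = 1)) == 0)
    stop("empty trajectory file: ", path)
  if (format == "pdb") read_frames_pdb(path) else read_frames_xyz(path)
}

read_frames_pdb <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("no ATOM records in ", path)
  # bio3d aborts internally on inconsistent rosters; double-check the
  # frame x coordinate matrix is rectangular and complete
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (anyNA(xyz))
    stop("atom roster differs between MODEL blocks in ", path)
  atoms <- data.frame(elety = pdb$atom$elety,
                      resid = pdb$atom$resid,
                      resno = pdb$atom$resno,
                      elesy = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                                     guess_element(pdb$atom$elety),
                                     toupper(trimws(pdb$atom$elesy))))
  frameset(atoms, unclass(xyz))
}

read_frames_xyz <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) == 0) stop("empty trajectory file: ", path)
  frames <- list()
  i <- 1L
  roster <- NULL
  while (i <= length(ln)) {
    nat <- suppressWarnings(as.integer(trimws(ln[i])))
    if (is.na(nat) || nat < 1) stop("bad atom count at line ", i, " of ", path)
    if (i + 1L + nat > length(ln)) stop("truncated XYZ block in ", path)
    rec <- ln[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(rec), "[[:space:]]+")
    if (any(lengths(tok) < 4L)) stop("malformed XYZ atom record in ", path)
    el <- vapply(tok, `[`, "", 1L)
    co <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (is.null(roster)) roster <- el
    else if (!identical(roster, el))
      stop("atom roster differs between frames in ", path)
    frames[[length(frames) + 1L]] <- as.vector(t(co))
    i <- i + 2L + nat
  }
  atoms <- data.frame(elety = roster, resid = "UNK",
                      resno = seq_along(roster), elesy = toupper(roster))
  frameset(atoms, do.call(rbind, frames))
}

#' Write a trajectory to multi-model PDB or XYZ
#'
#' @param frames a `frameset`.
#' @param path output path.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "pdb") {
    a <- frames$atoms
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(n_frames(frames))) {
      writeLines(sprintf("MODEL     %4d", f), con)
      co <- matrix(frames$xyz[f, ], ncol = 3, byrow = TRUE)
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        seq_len(nrow(a)), formatC(a$elety, width = 3), a$resid, a$resno,
        co[, 1], co[, 2], co[, 3], a$elesy), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(n_frames(frames))) {
      co <- matrix(frames$xyz[f, ], ncol = 3, byrow = TRUE)
      writeLines(as.character(n_atoms(frames)), con)
      writeLines(sprintf("frame %d", f), con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                         frames$atoms$elesy, co[, 1], co[, 2], co[, 3]), con)
    }
  }
  invisible(path)
}
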