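# In-memory representation of atomic systems and their labels, plus the two
# on-disk training-data layouts: a per-system directory of full-precision
# text matrices and a single-file hierarchical container (R serialization of
# the same arrays).  Units are fixed: energies eV, coordinates and cell
# Angstrom, forces eV/Angstrom, virials eV; no conversion happens inside the
# package.

#' Construct a single configuration (frame)
#'
#' @param species integer vector of 0-based species indices, one per atom.
#' @param coords `N x 3` Cartesian coordinates (Angstrom).
#' @param cell `3 x 3` matrix of cell row-vectors (Angstrom), or `NULL` for
#'   an open-boundary frame.
#' @return object of class `dp_frame` with fields `n_atoms`, `species`,
#'   `coords`, `cell`, `pbc`.
#' @export
dp_frame <- function(species, coords, cell = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be N x 3", call. = FALSE)
  if (length(species) != nrow(coords))
    stop("species length ", length(species), " does not match ",
         nrow(coords), " coordinate rows", call. = FALSE)
  if (!all(is.finite(coords))) stop("coords must be finite", call. = FALSE)
  pbc <- !is.null(cell)
  if (pbc) {
    cell <- as.matrix(cell)
    if (!all(dim(cell) == c(3L, 3L))) stop("cell must be 3 x 3", call. = FALSE)
    if (det(cell) <= 0)
      stop("cell must have positive determinant (volume > 0)", call. = FALSE)
  }
  structure(list(n_atoms = nrow(coords), species = as.integer(species),
                 coords = coords, cell = cell, pbc = pbc),
            class = "dp_frame")
}

#' @export
print.dp_frame <- function(x, ...) {
  cat("Frame:", x$n_atoms, "atoms,",
      if (x$pbc) "periodic" else "open boundary", "\n")
  invisible(x)
}

LABEL_FIELDS <- c("energy", "force", "virial", "delta_energy",
                  "atomic_tensor", "aparam", "fparam")

#' Construct a label set for one frame
#'
#' All fields are optional; absent labels stay absent (they are never
#' zero-filled).  Per-atom arrays must match the frame's atom count, which
#' is checked when the labels are attached to a system.
#'
#' @param energy scalar energy (eV).
#' @param force `N x 3` forces (eV/Angstrom).
#' @param virial `3 x 3` virial tensor (eV).
#' @param delta_energy scalar energy difference label (eV).
#' @param atomic_tensor `N x 3` (vector) or `N x 9` (flattened matrix)
#'   per-atom tensor labels.
#' @param aparam `N x Np` per-atom parameters.
#' @param fparam length-`Nq` per-frame parameters.
#' @return object of class `dp_labels`.
#' @export
dp_labels <- function(energy = NULL, force = NULL, virial = NULL,
                      delta_energy = NULL, atomic_tensor = NULL,
                      aparam = NULL, fparam = NULL) {
  l <- list(energy = energy, force = if (!is.null(force)) as.matrix(force),
            virial = if (!is.null(virial)) as.matrix(virial),
            delta_energy = delta_energy,
            atomic_tensor = if (!is.null(atomic_tensor)) as.matrix(atomic_tensor),
            aparam = if (!is.null(aparam)) as.matrix(aparam),
            fparam = if (!is.null(fparam)) as.numeric(fparam))
  structure(l[!vapply(l, is.null, TRUE)], class = "dp_labels")
}

check_labels <- function(labels, n_atoms) {
  if (!is.null(labels$force) && nrow(labels$force) != n_atoms)
    stop("force label rows do not match atom count", call. = FALSE)
  if (!is.null(labels$virial) && !all(dim(labels$virial) == c(3L, 3L)))
    stop("virial label must be 3 x 3", call. = FALSE)
  if (!is.null(labels$atomic_tensor) && nrow(labels$atomic_tensor) != n_atoms)
    stop("atomic_tensor label rows do not match atom count", call. = FALSE)
  if (!is.null(labels$aparam) && nrow(labels$aparam) != n_atoms)
    stop("aparam label rows do not match atom count", call. = FALSE)
  invisible(TRUE)
}

#' Construct a system dataset
#'
#' A system is a list of frames that share one species vector (and hence one
#' atom count), the natural unit of rectangular training batches.
#'
#' @param type_map character vector of species names; `species` indices
#'   refer into it (0-based).
#' @param frames list of `list(frame = dp_frame, labels = dp_labels)` (the
#'   `labels` entry may be `NULL`).
#' @param provenance free-text provenance string.
#' @return object of class `dp_system`.
#' @export
dp_system <- function(type_map, frames, provenance = "") {
  if (length(frames) < 1L) stop("a system needs at least one frame",
                                call. = FALSE)
  sp <- frames[[1L]]$frame$species
  if (any(sp < 0L) || any(sp >= length(type_map)))
    stop("species index out of range of type_map", call. = FALSE)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]$frame
    if (!identical(fr$species, sp))
      stop("frame ", k, " has a different species vector; ",
           "all frames of a system must share one", call. = FALSE)
    if (!is.null(frames[[k]]$labels)) check_labels(frames[[k]]$labels,
                                                   fr$n_atoms)
  }
  pbc <- vapply(frames, function(f) f$frame$pbc, TRUE)
  if (!all(pbc == pbc[1L]))
    stop("mixed periodic/open frames in one system are not supported",
         call. = FALSE)
  structure(list(type_map = as.character(type_map), frames = frames,
                 species = sp, provenance = provenance),
            class = "dp_system")
}

#' @export
print.dp_system <- function(x, ...) {
  lab <- names(x$frames[[1L]]$labels)
  cat("System:", length(x$frames), "frames,",
      length(x$species), "atoms (",
      paste(x$type_map, collapse = ", "), "),",
      if (x$frames[[1L]]$frame$pbc) "periodic" else "open", "\n")
  cat("Labels:", if (length(lab)) paste(lab, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Number of frames in a system
#' @param ds a `dp_system`.
#' @export
n_frames <- function(ds) length(ds$frames)

# columnar views used by the writers -------------------------------------

system_to_arrays <- function(ds) {
  n <- length(ds$species)
  nf <- length(ds$frames)
  get_lab <- function(name) lapply(ds$frames, function(f) f$labels[[name]])
  have <- function(ls) all(!vapply(ls, is.null, TRUE))
  arrays <- list(
    coord = t(vapply(ds$frames, function(f) as.vector(t(f$frame$coords)),
                     numeric(3L * n))))
  if (ds$frames[[1L]]$frame$pbc)
    arrays$box <- t(vapply(ds$frames, function(f) as.vector(t(f$frame$cell)),
                           numeric(9L)))
  lab <- function(name, fn) {
    ls <- get_lab(name)
    if (have(ls)) arrays[[name]] <<- t(vapply(ls, fn, fn(ls[[1L]])))
  }
  ls <- get_lab("energy")
  if (have(ls)) arrays$energy <- matrix(vapply(ls, identity, 0), ncol = 1L)
  lab("force", function(x) as.vector(t(x)))
  lab("virial", function(x) as.vector(t(x)))
  ls <- get_lab("delta_energy")
  if (have(ls)) arrays$delta_energy <- matrix(vapply(ls, identity, 0),
                                              ncol = 1L)
  lab("atomic_tensor", function(x) as.vector(t(x)))
  lab("aparam", function(x) as.vector(t(x)))
  lab("fparam", function(x) as.numeric(x))
  arrays
}

arrays_to_system <- function(type_map, species, arrays, pbc, provenance = "") {
  n <- length(species)
  nf <- nrow(arrays$coord)
  frames <- vector("list", nf)
  pick_row <- function(name, k, ncol_row) {
    a <- arrays[[name]]
    if (is.null(a)) return(NULL)
    matrix(a[k, ], ncol = ncol_row, byrow = TRUE)
  }
  for (k in seq_len(nf)) {
    cell <- if (pbc) matrix(arrays$box[k, ], 3L, 3L, byrow = TRUE) else NULL
    fr <- dp_frame(species, pick_row("coord", k, 3L), cell)
    at <- arrays$atomic_tensor
    labels <- dp_labels(
      energy = if (!is.null(arrays$energy)) arrays$energy[k, 1L],
      force = pick_row("force", k, 3L),
      virial = if (!is.null(arrays$virial))
        matrix(arrays$virial[k, ], 3L, 3L, byrow = TRUE),
      delta_energy = if (!is.null(arrays$delta_energy))
        arrays$delta_energy[k, 1L],
      atomic_tensor = if (!is.null(at)) matrix(at[k, ], nrow = n, byrow = TRUE),
      aparam = if (!is.null(arrays$aparam))
        matrix(arrays$aparam[k, ], nrow = n, byrow = TRUE),
      fparam = if (!is.null(arrays$fparam)) arrays$fparam[k, ])
    frames[[k]] <- list(frame = fr,
                        labels = if (length(labels)) labels else NULL)
  }
  dp_system(type_map, frames, provenance)
}

# text matrices round-trip doubles bit-exactly through %.17g
write_txt_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(m)))
    writeLines(paste(sprintf("%.17g", m[k, ]), collapse = " "), con)
}

read_txt_matrix <- function(path, name) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  lens <- lengths(rows)
  if (length(unique(lens)) > 1L)
    stop("format error in array '", name, "': ragged rows in ", path,
         call. = FALSE)
  m <- do.call(rbind, rows)
  if (anyNA(m))
    stop("format error in array '", name, "': non-numeric entries in ",
         path, call. = FALSE)
  m
}

#' Write a system dataset to disk
#'
#' `"dir"` writes the per-system directory layout: `type_map.raw` (one
#' species name per line), `type.raw` (per-atom 0-based species indices) and
#' a `set.000/` subdirectory with one text matrix per array — `coord`
#' (`Nf x 3N`), `box` (`Nf x 9`, cell rows concatenated; absent for open
#' boundaries), `energy` (`Nf x 1`), `force` (`Nf x 3N`), `virial`
#' (`Nf x 9`), `delta_energy`, `atomic_tensor`, `aparam`, `fparam`.
#' `"container"` writes one hierarchical single file holding the same arrays
#' for one or more named systems.  Both formats round-trip all numeric
#' payloads bit-exactly.
#'
#' @param ds a `dp_system`.
#' @param path target directory (`"dir"`) or file (`"container"`).
#' @param format `"dir"` or `"container"`.
#' @export
write_system <- function(ds, path, format = c("dir", "container")) {
  format <- match.arg(format)
  arrays <- system_to_arrays(ds)
  if (format == "dir") {
    setdir <- file.path(path, "set.000")
    dir.create(setdir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(setdir))
      stop("cannot create directory ", path, call. = FALSE)
    writeLines(ds$type_map, file.path(path, "type_map.raw"))
    writeLines(as.character(ds$species), file.path(path, "type.raw"))
    for (name in names(arrays))
      write_txt_matrix(arrays[[name]], file.path(setdir, paste0(name, ".txt")))
  } else {
    payload <- list(systems = list(system = list(
      type_map = ds$type_map, species = ds$species,
      pbc = ds$frames[[1L]]$frame$pbc, provenance = ds$provenance,
      arrays = arrays)))
    saveRDS(payload, path)
  }
  invisible(path)
}

#' Read a system dataset from disk
#'
#' Accepts either layout written by [write_system()]: a system directory or
#' a single-file container.  Optional labels that are absent on disk stay
#' absent in memory.
#'
#' @param path directory or container file.
#' @param system for containers holding several systems, the name or index
#'   of the one to read.
#' @return a `dp_system`.
#' @export
read_system <- function(path, system = 1L) {
  if (dir.exists(path)) {
    tm_file <- file.path(path, "type_map.raw")
    ty_file <- file.path(path, "type.raw")
    if (!file.exists(tm_file) || !file.exists(ty_file))
      stop("not a system directory (missing type_map.raw/type.raw): ", path,
           call. = FALSE)
    type_map <- readLines(tm_file)
    species <- as.integer(readLines(ty_file))
    setdir <- file.path(path, "set.000")
    arrays <- list()
    for (name in c("coord", "box", "energy", "force", "virial",
                   "delta_energy", "atomic_tensor", "aparam", "fparam")) {
      f <- file.path(setdir, paste0(name, ".txt"))
      if (file.exists(f)) arrays[[name]] <- read_txt_matrix(f, name)
    }
    if (is.null(arrays$coord))
      stop("format error: missing array 'coord' in ", setdir, call. = FALSE)
    if (ncol(arrays$coord) != 3L * length(species))
      stop("consistency error: 'coord' has ", ncol(arrays$coord),
           " columns, expected 3 x ", length(species), " atoms",
           call. = FALSE)
    if (!is.null(arrays$force) && ncol(arrays$force) != 3L * length(species))
      stop("consistency error: 'force' columns do not match 3N",
           call. = FALSE)
    arrays_to_system(type_map, species, arrays, pbc = !is.null(arrays$box),
                     provenance = path)
  } else if (file.exists(path)) {
    payload <- readRDS(path)
    if (is.null(payload$systems))
      stop("format error: ", path, " is not a system container",
           call. = FALSE)
    g <- payload$systems[[system]]
    if (is.null(g)) stop("system '", system, "' not found in ", path,
                         call. = FALSE)
    arrays_to_system(g$type_map, g$species, g$arrays, g$pbc, g$provenance)
  } else stop("path does not exist: ", path, call. = FALSE)
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Split a system into training and validation parts
#'
#' Disjoint, exhaustive, deterministic split of the frames given a seed.
#'
#' @param ds a `dp_system` with at least 2 frames.
#' @param val_fraction fraction of frames held out, in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `val`, both `dp_system`.
#' @export
split_dataset <- function(ds, val_fraction, seed) {
  nf <- length(ds$frames)
  if (nf < 2L) stop("cannot split a system with fewer than 2 frames",
                    call. = FALSE)
  if (!(val_fraction > 0 && val_fraction < 1))
    stop("val_fraction must be in (0, 1)", call. = FALSE)
  n_val <- max(1L, min(nf - 1L, round(nf * val_fraction)))
  val_idx <- sort(with_seed(seed, sample.int(nf, n_val)))
  train_idx <- setdiff(seq_len(nf), val_idx)
  list(train = dp_system(ds$type_map, ds$frames[train_idx], ds$provenance),
       val = dp_system(ds$type_map, ds$frames[val_idx], ds$provenance))
}
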