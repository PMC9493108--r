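## Domain containers and file plumbing shared by every pipeline stage.
##
## Conventions (stated once, used everywhere):
##   * coordinates are right-handed, in Angstrom; the map origin is the
##     corner of voxel (0,0,0);
##   * image pixel (1,1) is top-left in R's matrix sense, pixel centers
##     at integer positions;
##   * in-plane shifts are stored in pixels (converted to Angstrom only
##     in reports, via the pixel size);
##   * per-particle metadata is a self-describing tab-separated table
##     with one header line (columns: index, amp_1..amp_M, rot, tilt,
##     psi, sx, sy, defocus, provenance).

# ---------------------------------------------------------------------
# CoarseModel

#' Construct a coarse point model (atoms or pseudoatoms)
#'
#' @param coords N x 3 numeric matrix of positions in Angstrom.
#' @param labels Optional data frame with per-point columns `resno`,
#'   `chain`, `name`, `kind` (`"atom"` or `"pseudoatom"`); a default is
#'   synthesised when omitted.
#' @param masses Per-point positive weights (default 1).
#' @param gaussian_sigma Width (Angstrom) used when rendering the
#'   points as isotropic 3D Gaussians.
#' @return An object of class `coarse_model`.
#' @export
coarse_model <- function(coords, labels = NULL, masses = NULL,
                         gaussian_sigma = 1.0) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 2L) stop("a coarse model needs at least 2 points")
  if (ncol(coords) != 3L) stop("coords must be N x 3")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (is.null(masses)) masses <- rep(1.0, n)
  if (length(masses) != n || any(masses <= 0))
    stop("masses must be positive, one per point")
  if (is.null(labels)) {
    labels <- data.frame(resno = seq_len(n), chain = "A",
                         name = "CA", kind = "pseudoatom",
                         stringsAsFactors = FALSE)
  }
  if (nrow(labels) != n) stop("labels must have one row per point")
  structure(list(coords = coords, labels = labels, masses = masses,
                 gaussian_sigma = gaussian_sigma),
            class = "coarse_model")
}

#' @export
print.coarse_model <- function(x, ...) {
  cat(sprintf("coarse_model: %d points (%s), sigma = %.3g A\n",
              nrow(x$coords), paste(unique(x$labels$kind), collapse = "/"),
              x$gaussian_sigma))
  invisible(x)
}

#' Read an atomic or coarse-grain model from a PDB file
#'
#' Points are returned in file order.  `selection` keeps only atoms
#' whose names match (e.g. `c("CA", "P")` for the usual protein/nucleic
#' coarse-graining); with no selection all ATOM/HETATM records are kept.
#'
#' @param path Path to a PDB-format file.
#' @param selection Optional character vector of atom names to retain.
#' @param gaussian_sigma Rendering width passed to [coarse_model()].
#' @return A [coarse_model()].
#' @export
read_model <- function(path, selection = NULL, gaussian_sigma = 1.0) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop(sprintf("cannot parse PDB file '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  atoms <- pdb$atom
  if (!is.null(selection)) {
    keep <- trimws(atoms$elety) %in% selection
    if (!any(keep))
      stop(sprintf("selection {%s} matches no atoms in '%s'",
                   paste(selection, collapse = ","), path), call. = FALSE)
    atoms <- atoms[keep, , drop = FALSE]
  }
  coords <- cbind(atoms$x, atoms$y, atoms$z)
  labels <- data.frame(resno = atoms$resno,
                       chain = as.character(atoms$chain),
                       name = trimws(atoms$elety),
                       kind = "atom", stringsAsFactors = FALSE)
  coarse_model(coords, labels = labels, gaussian_sigma = gaussian_sigma)
}

#' Write a (multi-model) PDB trajectory of coarse models
#'
#' Each frame becomes one MODEL/ENDMDL block of CA-style ATOM records;
#' a single model is written as a plain PDB.
#'
#' @param models A `coarse_model` or a list of them (identical sizes).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(models, path) {
  if (inherits(models, "coarse_model")) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    lab <- m$labels
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(m$coords)) %% 100000L,
      substr(lab$name, 1, 4), "ALA",
      substr(ifelse(is.na(lab$chain) | lab$chain == "", "A", lab$chain), 1, 1),
      lab$resno %% 10000L,
      m$coords[, 1], m$coords[, 2], m$coords[, 3], 1.0, 0.0)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------
# DensityMap + MRC I/O

#' Construct a cubic 3D density map
#'
#' @param data 3D numeric array with equal extents (the pipeline
#'   assumes cubic grids).
#' @param voxel_size Isotropic voxel size in Angstrom (> 0).
#' @param origin Offset of voxel (0,0,0) in Angstrom.
#' @return An object of class `density_map`.
#' @export
density_map <- function(data, voxel_size, origin = c(0, 0, 0)) {
  d <- dim(data)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop(sprintf("density maps must be cubic; got %s",
                 paste(d, collapse = " x ")))
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d^3 voxels, %.4g A/voxel\n",
              dim(x$data)[1], x$voxel_size))
  invisible(x)
}

.mrc_write_raw <- function(path, data, voxel_size, origin = c(0, 0, 0)) {
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d[1], d[2], d[3], 2L)), con, size = 4,
           endian = "little")                       # nx ny nz mode
  writeBin(integer(3), con, size = 4, endian = "little")  # nxstart..
  writeBin(as.integer(d), con, size = 4, endian = "little")  # mx my mz
  writeBin(as.numeric(d) * voxel_size, con, size = 4,
           endian = "little")                       # cella
  writeBin(c(90, 90, 90), con, size = 4, endian = "little") # cellb
  writeBin(1:3, con, size = 4, endian = "little")   # mapc mapr maps
  writeBin(c(min(data), max(data), mean(data)), con, size = 4,
           endian = "little")                       # dmin dmax dmean
  writeBin(c(1L, 0L), con, size = 4, endian = "little")  # ispg nsymbt
  writeBin(integer(25), con, size = 4, endian = "little") # extra
  writeBin(as.numeric(origin), con, size = 4, endian = "little") # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  writeBin(stats::sd(as.numeric(data)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")    # nlabl
  writeBin(raw(800), con)                           # labels
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

.mrc_read_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # cellb
  readBin(con, "integer", n = 3, size = 4, endian = "little")  # mapc..
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # dmin..
  readBin(con, "integer", n = 2, size = 4, endian = "little")  # ispg nsymbt
  readBin(con, "integer", n = 25, size = 4, endian = "little") # extra
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 1024)
  nx <- hdr_i[1]; ny <- hdr_i[2]; nz <- hdr_i[3]; mode <- hdr_i[4]
  if (mode != 2L)
    stop(sprintf("unsupported MRC mode %d (only mode 2 float32)", mode))
  v <- readBin(con, "numeric", n = nx * ny * nz, size = 4,
               endian = "little")
  mx <- hdr_i[8]
  voxel <- if (mx > 0) cella[1] / mx else 1
  list(data = array(v, dim = c(nx, ny, nz)), voxel_size = voxel,
       origin = origin)
}

#' Read / write cubic density maps in MRC format (mode-2 float)
#'
#' `write_map` followed by `read_map` is the identity for the voxel data
#' and voxel size within float32 precision.  Non-cubic files are
#' rejected because the pipeline assumes cubic grids.
#'
#' @param path File path.
#' @param map A [density_map()].
#' @return `read_map`: a [density_map()]; `write_map`: `path`,
#'   invisibly.
#' @export
read_map <- function(path) {
  raw <- .mrc_read_raw(path)
  d <- dim(raw$data)
  if (length(unique(d)) != 1L)
    stop(sprintf("map in '%s' is %s, not cubic", path,
                 paste(d, collapse = " x ")))
  density_map(raw$data, raw$voxel_size, raw$origin)
}

#' @rdname read_map
#' @export
write_map <- function(path, map) {
  stopifnot(inherits(map, "density_map"))
  .mrc_write_raw(path, map$data, map$voxel_size, map$origin)
}

# ---------------------------------------------------------------------
# Particle records (per-image metadata)

#' CTF parameter set
#'
#' @param voltage_kV Accelerating voltage (> 0), kilovolt.
#' @param cs_mm Spherical aberration (>= 0), millimetre.
#' @param defocus_um Signed defocus, micrometre, stored as printed in
#'   the acquisition conventions (negative here means the configuration
#'   whose phase term has a negative quadratic coefficient; only the
#'   CTF magnitude matters downstream once images are phase-flipped).
#' @param amplitude_contrast Fraction in `[0, 1)`.
#' @return An object of class `ctf_params`.
#' @export
ctf_params <- function(voltage_kV = 200, cs_mm = 2, defocus_um = -0.5,
                       amplitude_contrast = 0.1) {
  if (voltage_kV <= 0) stop("voltage_kV must be > 0")
  if (cs_mm < 0) stop("cs_mm must be >= 0")
  if (amplitude_contrast < 0 || amplitude_contrast >= 1)
    stop("amplitude_contrast must be in [0, 1)")
  structure(list(voltage_kV = voltage_kV, cs_mm = cs_mm,
                 defocus_um = defocus_um,
                 amplitude_contrast = amplitude_contrast),
            class = "ctf_params")
}

#' Build a per-particle metadata table
#'
#' One row per image: normal-mode amplitudes, ZYZ Euler angles
#' (degrees), in-plane shifts (pixels), defocus (micrometre) and a
#' provenance tag (`ground_truth`, `hemnma` or `inferred`).
#'
#' @param amplitudes K x M numeric matrix of normal-mode amplitudes.
#' @param euler K x 3 matrix of (rot, tilt, psi) in degrees.
#' @param shift K x 2 matrix of (sx, sy) in pixels.
#' @param defocus Length-K (or scalar) defocus in micrometre.
#' @param provenance Character scalar or length-K vector.
#' @return A data frame of class `particle_records` with columns
#'   `index`, `amp_1..amp_M`, `rot`, `tilt`, `psi`, `sx`, `sy`,
#'   `defocus`, `provenance`.
#' @export
particle_records <- function(amplitudes, euler, shift, defocus = 0,
                             provenance = "ground_truth") {
  amplitudes <- as.matrix(amplitudes)
  euler <- as.matrix(euler)
  shift <- as.matrix(shift)
  k <- nrow(amplitudes)
  stopifnot(nrow(euler) == k, ncol(euler) == 3L,
            nrow(shift) == k, ncol(shift) == 2L)
  prov <- rep_len(provenance, k)
  ok <- prov %in% c("ground_truth", "hemnma", "inferred")
  if (!all(ok)) stop("unknown provenance tag: ", prov[!ok][1])
  df <- data.frame(index = seq_len(k) - 1L)
  m <- ncol(amplitudes)
  for (j in seq_len(m)) df[[paste0("amp_", j)]] <- amplitudes[, j]
  df$rot <- euler[, 1] %% 360
  df$tilt <- euler[, 2]
  df$psi <- euler[, 3] %% 360
  df$sx <- shift[, 1]
  df$sy <- shift[, 2]
  df$defocus <- rep_len(defocus, k)
  df$provenance <- prov
  class(df) <- c("particle_records", "data.frame")
  df
}

#' Extract the amplitude matrix from a metadata table
#' @param records A [particle_records()] table.
#' @return K x M numeric matrix.
#' @export
records_amplitudes <- function(records) {
  cols <- grep("^amp_", names(records), value = TRUE)
  as.matrix(records[, cols, drop = FALSE])
}

#' Extract Euler angles / shifts / quaternions from a metadata table
#' @param records A [particle_records()] table.
#' @return `records_euler`: K x 3 matrix (degrees); `records_shift`:
#'   K x 2 matrix (pixels); `records_quaternion`: K x 4 matrix of
#'   canonical unit quaternions.
#' @export
records_euler <- function(records) {
  as.matrix(records[, c("rot", "tilt", "psi")])
}

#' @rdname records_euler
#' @export
records_shift <- function(records) {
  as.matrix(records[, c("sx", "sy")])
}

#' @rdname records_euler
#' @export
records_quaternion <- function(records) {
  e <- records_euler(records)
  t(apply(e, 1, function(a) euler_to_quaternion(a[1], a[2], a[3])))
}

.metadata_mandatory <- c("index", "rot", "tilt", "psi", "sx", "sy",
                         "defocus", "provenance")

#' Read / write per-particle metadata as a TSV table
#'
#' The table is self-describing (one header line, tab-separated) and
#' round-trips losslessly: text columns bitwise, numeric columns at
#' full double precision.  Angles are stored in degrees, shifts in
#' pixels.
#'
#' @param path File path.
#' @param records A [particle_records()] table.
#' @param n_modes Optional expected number of amplitude columns; a
#'   mismatch is an error.
#' @return `read_metadata`: a [particle_records()] table (possibly with
#'   zero rows); `write_metadata`: `path`, invisibly.
#' @export
read_metadata <- function(path, n_modes = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = NA)
  missing_cols <- setdiff(.metadata_mandatory, names(df))
  if (length(missing_cols))
    stop(sprintf("metadata '%s' lacks mandatory column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  amp_cols <- grep("^amp_", names(df), value = TRUE)
  if (!is.null(n_modes) && length(amp_cols) != n_modes)
    stop(sprintf(
      "metadata '%s' has %d amplitude columns, expected %d",
      path, length(amp_cols), n_modes))
  if (nrow(df) == 0L) df$provenance <- character(0)
  class(df) <- c("particle_records", "data.frame")
  df
}

#' @rdname read_metadata
#' @export
write_metadata <- function(path, records) {
  df <- as.data.frame(records)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- formatC(df[[j]], format = "g", digits = 17)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------
# Particle stacks

#' Construct a particle image stack
#'
#' @param images L x L x K numeric array (K images of L x L pixels; L
#'   must be even because downscaling halves it).
#' @param pixel_size Pixel size in Angstrom.
#' @param records A [particle_records()] table with K rows.
#' @return An object of class `particle_stack`.
#' @export
particle_stack <- function(images, pixel_size, records) {
  d <- dim(images)
  if (length(d) != 3L || d[1] != d[2]) stop("images must be L x L x K")
  if (d[1] %% 2L != 0L) stop("image side must be even")
  if (nrow(records) != d[3])
    stop(sprintf("%d records for %d images", nrow(records), d[3]))
  structure(list(images = images, pixel_size = as.numeric(pixel_size),
                 records = records),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("particle_stack: %d images of %d x %d px, %.4g A/px\n",
              d[3], d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Read / write a particle image stack in MRC stack format
#'
#' The companion metadata table travels separately (see
#' [read_metadata()]); `read_stack` attaches it when given.
#'
#' @param path MRC file path.
#' @param stack A [particle_stack()].
#' @param metadata Optional metadata TSV path for `read_stack`.
#' @return `read_stack`: a [particle_stack()]; `write_stack`: `path`.
#' @export
read_stack <- function(path, metadata = NULL) {
  raw <- .mrc_read_raw(path)
  d <- dim(raw$data)
  records <- if (!is.null(metadata)) read_metadata(metadata)
  else particle_records(matrix(0, d[3], 1),
                        matrix(0, d[3], 3), matrix(0, d[3], 2))
  particle_stack(raw$data, raw$voxel_size, records)
}

#' @rdname read_stack
#' @export
write_stack <- function(path, stack) {
  .mrc_write_raw(path, stack$images, stack$pixel_size)
  invisible(path)
}

# ---------------------------------------------------------------------
# Config + logging plumbing

#' Read a key = value configuration file
#'
#' Lines are `key = value`; `#` starts a comment; values that parse as
#' numbers become numeric, comma-separated values become vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' Log a pipeline message with a timestamp
#'
#' Used by the CLI stages to record configs, seeds and artifact
#' checksums.
#'
#' @param ... Passed to [sprintf()] (format string first).
#' @param file Optional log file to append to (also echoed to stderr).
#' @export
log_msg <- function(..., file = NULL) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(...))
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE, sep = "")
  message(msg)
  invisible(msg)
}

#' MD5 checksum of a file (for stage logs)
#' @param path File path.
#' @return Character checksum.
#' @export
file_checksum <- function(path) unname(tools::md5sum(path))
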