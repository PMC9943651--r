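#' Construct a structure model
#'
#' A thin container for atomic coordinates: a data frame of atom records
#' (one row per ATOM/HETATM record, altlocs kept as separate rows) plus a
#' source identifier. Columns: \code{serial}, \code{name}, \code{altloc},
#' \code{resname}, \code{chain}, \code{resno}, \code{insert}, \code{x},
#' \code{y}, \code{z} (Angstrom), \code{occupancy}, \code{b_factor}
#' (Angstrom^2), \code{element}.
#'
#' @param atoms Data frame of atom records.
#' @param source_id File name or accession the model came from.
#' @return Object of class \code{structure_model}.
#' @export
structure_model <- function(atoms, source_id = "") {
  need <- c("serial", "name", "altloc", "resname", "chain", "resno",
            "insert", "x", "y", "z", "occupancy", "b_factor", "element")
  if (nrow(atoms) == 0L) {
    atoms <- data.frame(serial = integer(), name = character(),
                        altloc = character(), resname = character(),
                        chain = character(), resno = integer(),
                        insert = character(), x = numeric(), y = numeric(),
                        z = numeric(), occupancy = numeric(),
                        b_factor = numeric(), element = character(),
                        stringsAsFactors = FALSE)
  }
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lacks column(s): ", paste(miss, collapse = ", "))
  atoms <- atoms[, need]
  if (nrow(atoms)) {
    if (any(!is.finite(atoms$occupancy)) ||
        any(atoms$occupancy < 0) || any(atoms$occupancy > 1))
      stop("occupancy must lie in [0, 1]")
    if (any(atoms$b_factor < 0)) stop("b_factor must be >= 0")
    if (any(!nzchar(atoms$element))) stop("element must be non-empty")
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name,
                 atoms$altloc, sep = "|")
    if (anyDuplicated(key))
      stop("duplicate (chain, resno, insert, name, altloc) atom records")
  }
  structure(list(atoms = atoms, source_id = source_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, chains: %s\n",
              x$source_id, nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parses ATOM/HETATM records (treated identically) into a
#' \code{\link{structure_model}}. Altloc records are kept, one atom record
#' per file record. Missing occupancy defaults to 1.0 and missing B-factor
#' to 0.0; a blank element field is inferred from the atom name.
#'
#' @param path Path to the file.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"mmcif"}.
#' @return A \code{\link{structure_model}}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    n_rec <- sum(grepl("^(ATOM  |HETATM)", lines))
    if (n_rec == 0L) return(structure_model(data.frame(), basename(path)))
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE)),
      error = function(e) stop("PDB parse error in '", basename(path), "': ",
                               conditionMessage(e)))
    a <- pdb$atom
  } else {
    if (!any(grepl("^(ATOM|HETATM)", lines)))
      return(structure_model(data.frame(), basename(path)))
    cif <- tryCatch(
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE)),
      error = function(e) stop("mmCIF parse error in '", basename(path),
                               "': ", conditionMessage(e)))
    a <- cif$atom
  }
  blank <- function(v) ifelse(is.na(v), "", as.character(v))
  ele <- blank(a$elesy)
  fix <- !nzchar(trimws(ele))
  if (any(fix)) ele[fix] <- bio3d::atom2ele(a$elety[fix])
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = as.character(a$elety),
    altloc = blank(a$alt),
    resname = as.character(a$resid),
    chain = blank(a$chain),
    resno = as.integer(a$resno),
    insert = blank(a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1.0, a$o),
    b_factor = ifelse(is.na(a$b), 0.0, a$b),
    element = trimws(toupper(ele)),
    stringsAsFactors = FALSE)
  structure_model(atoms, basename(path))
}

#' Write a structure model to a PDB file
#'
#' @param model A \code{\link{structure_model}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   eleno = a$serial, elety = a$name,
                   alt = ifelse(nzchar(a$altloc), a$altloc, ""),
                   resid = a$resname, chain = a$chain, resno = a$resno,
                   insert = ifelse(nzchar(a$insert), a$insert, ""),
                   o = a$occupancy, b = a$b_factor, elesy = a$element)
  invisible(path)
}

#' Construct a density grid
#'
#' A 3-D scalar map on an axis-aligned orthogonal grid. \code{values} is a
#' 3-D array indexed (x, y, z); \code{origin} is the position (Angstrom) of
#' voxel (1,1,1); \code{spacing} the voxel edge lengths (Angstrom).
#' \code{sigma} is the scale in which the map values are expressed: map
#' value / sigma is the height in sigma units. By default sigma is the
#' standard deviation of the values over the whole grid.
#'
#' @param values 3-D numeric array.
#' @param origin Numeric 3-vector, Angstrom.
#' @param spacing Numeric 3-vector, Angstrom per voxel (> 0).
#' @param sigma Optional scale override (e.g. 1 for maps already in sigma
#'   units).
#' @return Object of class \code{density_grid} with a \code{usable} flag
#'   (FALSE when sigma is 0, i.e. a constant map).
#' @export
density_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                         sigma = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            length(origin) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("spacing components must be > 0")
  if (is.null(sigma)) sigma <- stats::sd(as.numeric(values))
  usable <- is.finite(sigma) && sigma > 0
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing),
                 dimensions = dim(values), sigma = sigma, usable = usable),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid %dx%dx%d, spacing %.3g/%.3g/%.3g A, sigma = %.4g%s\n",
              x$dimensions[1], x$dimensions[2], x$dimensions[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$sigma,
              if (x$usable) "" else " (UNUSABLE: constant map)"))
  invisible(x)
}

#' Write a density grid as a CCP4/MRC map (mode 2, float32)
#'
#' Writes an orthogonal P1 map with axis order x, y, z. The grid origin is
#' stored in the MRC-2014 ORIGIN header words.
#'
#' @param grid A \code{\link{density_grid}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_map <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- grid$dimensions
  cell <- grid$spacing * d
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.numeric(grid$values)
  wi(d)                   # NC NR NS
  wi(2)                   # MODE 2 = float32
  wi(c(0, 0, 0))          # NCSTART NRSTART NSSTART (origin kept in ORIGIN)
  wi(d)                   # MX MY MZ
  wf(c(cell, 90, 90, 90)) # CELLA + CELLB
  wi(c(1, 2, 3))          # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))
  wi(1)                   # ISPG
  wi(0)                   # NSYMBT
  wi(rep(0L, 25))         # EXTRA (words 26-50 region start)
  wf(grid$origin)         # ORIGIN (words 50-52, MRC-2014)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v))        # RMS
  wi(0)                   # NLABL
  writeBin(raw(800), con) # 10 empty 80-char labels
  wf(v)
  invisible(path)
}

#' Read a CCP4/MRC density map
#'
#' Supports mode-2 (float32) maps with orthogonal cells. The axis-order
#' header words (MAPC/MAPR/MAPS) are honoured: data are permuted to
#' (x, y, z) storage regardless of file ordering. Sigma is recomputed as
#' the standard deviation over all voxels; a constant map is returned with
#' \code{usable = FALSE}.
#'
#' @param path Path to the map file.
#' @return A \code{\link{density_grid}}.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) stop("truncated map header in '", path, "'")
  ri <- function(words) readBin(hdr_raw[(words[1] * 4 - 3):(words[2] * 4)],
                                "integer", n = diff(words) + 1, size = 4,
                                endian = "little")
  rf <- function(words) readBin(hdr_raw[(words[1] * 4 - 3):(words[2] * 4)],
                                "numeric", n = diff(words) + 1, size = 4,
                                endian = "little")
  magic <- rawToChar(hdr_raw[(53 * 4 - 3):(53 * 4 - 0)])
  if (magic != "MAP ") stop("not a CCP4/MRC map (bad magic): '", path, "'")
  ncrs <- ri(c(1, 3))
  mode <- ri(c(4, 4))
  if (mode != 2) stop("unsupported map mode ", mode, " (only mode 2/float32)")
  nstart <- ri(c(5, 7))
  mxyz <- ri(c(8, 10))
  cell <- rf(c(11, 16))
  if (any(abs(cell[4:6] - 90) > 1e-3))
    stop("non-orthogonal map cells are not supported")
  mapcrs <- ri(c(17, 19))
  if (!setequal(mapcrs, 1:3)) stop("invalid MAPC/MAPR/MAPS fields")
  origin_w <- rf(c(50, 52))
  spacing <- cell[1:3] / mxyz
  n <- prod(ncrs)
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(v) < n) stop("truncated map data in '", path, "'")
  arr <- array(v, dim = ncrs)             # dims in (col, row, section) axes
  perm <- match(1:3, mapcrs)              # -> (x, y, z)
  arr <- aperm(arr, perm)
  start_xyz <- nstart[perm]
  origin <- if (any(origin_w != 0)) origin_w else start_xyz * spacing
  density_grid(arr, origin = origin, spacing = spacing)
}

# --- titration tables ------------------------------------------------------

.titr_cols <- c("oligo", "condition", "replicate", "probe_conc_uM",
                "protein_conc_uM", "anisotropy")

#' Read a titration table (CSV) into titration series
#'
#' Expected columns: \code{oligo}, \code{condition}, \code{replicate},
#' \code{probe_conc_uM}, \code{protein_conc_uM}, \code{anisotropy}.
#' Rows are grouped by (oligo, condition, replicate) into one
#' \code{\link{titration_series}} each. Extra columns are ignored with a
#' warning; a missing required column is a schema error.
#'
#' @param path CSV path.
#' @return Named list of \code{titration_series}.
#' @export
read_titrations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.titr_cols, names(df))
  if (length(miss))
    stop("titration CSV lacks required column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), .titr_cols)
  if (length(extra))
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  if (any(df$protein_conc_uM < 0))
    stop("negative protein concentration in titration table")
  if (any(df$probe_conc_uM <= 0))
    stop("probe concentration must be > 0")
  key <- interaction(df$oligo, df$condition, df$replicate, drop = TRUE,
                     sep = "|")
  out <- lapply(split(df, key), function(g) {
    titration_series(probe_conc = g$probe_conc_uM[1],
                     protein_conc = g$protein_conc_uM,
                     anisotropy = g$anisotropy,
                     oligo = g$oligo[1], condition = g$condition[1],
                     replicate_id = g$replicate[1])
  })
  out[order(names(out))]
}

#' Write titration series to CSV
#'
#' @param series List of \code{titration_series}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_titrations <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(oligo = s$oligo, condition = s$condition,
               replicate = s$replicate_id, probe_conc_uM = s$probe_conc,
               protein_conc_uM = s$protein_conc, anisotropy = s$anisotropy,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write stereo calls to CSV
#'
#' Columns: \code{linkage_id}, \code{chain}, \code{res5}, \code{res3},
#' \code{call}, \code{peak_Rp_sigma}, \code{peak_Sp_sigma},
#' \code{b_factor}, \code{reliable}.
#'
#' @param calls A stereo-call data frame from \code{\link{call_strand}}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_calls <- function(calls, path) {
  need <- c("linkage_id", "chain", "res5", "res3", "call",
            "peak_Rp_sigma", "peak_Sp_sigma", "b_factor", "reliable")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("calls lacks column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(calls[, need], path, row.names = FALSE)
  invisible(path)
}
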