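#' Specification of a synthetic PS-strand fixture
#'
#' Describes a single-stranded idealized PS oligonucleotide: its length,
#' the programmed stereochemistry of each internucleotide linkage
#' (\code{"Rp"}, \code{"Sp"} or \code{"mixed"}), the B-factor profile
#' along the linkages, and map-noise/seed settings for the matching
#' synthetic anomalous map.
#'
#' @param n_nucleotides Strand length (>= 2).
#' @param stereo_pattern Character vector of length
#'   \code{n_nucleotides - 1} over \code{c("Rp","Sp","mixed")}.
#' @param b_profile Numeric B-factors (Angstrom^2), same length as
#'   \code{stereo_pattern} (default 30 everywhere).
#' @param map_noise_sigma Gaussian voxel noise of the synthetic map, in
#'   sigma units.
#' @param seed Integer seed for all randomness of the fixture.
#' @return Object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_nucleotides, stereo_pattern,
                         b_profile = rep(30, n_nucleotides - 1),
                         map_noise_sigma = 0, seed = 1) {
  stopifnot(n_nucleotides >= 2)
  if (length(stereo_pattern) != n_nucleotides - 1)
    stop("stereo_pattern must have length n_nucleotides - 1")
  if (!all(stereo_pattern %in% c("Rp", "Sp", "mixed")))
    stop("stereo_pattern entries must be 'Rp', 'Sp' or 'mixed'")
  if (length(b_profile) != n_nucleotides - 1)
    stop("b_profile must have length n_nucleotides - 1")
  structure(list(n_nucleotides = as.integer(n_nucleotides),
                 stereo_pattern = stereo_pattern,
                 b_profile = as.numeric(b_profile),
                 map_noise_sigma = map_noise_sigma,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Build an idealized PS-DNA strand with programmed stereochemistry
#'
#' Constructs a single-stranded backbone on idealized B-form helical
#' parameters (twist 36 deg, rise 3.38 A, phosphate radius 8.9 A) with
#' metrically correct phosphate-group geometry: bridging P-O bonds 1.59 A
#' at the tetrahedral angle, non-bridging P-O 1.48 A and P-S 1.95 A. Per
#' the programmed pattern the sulfur is placed at the Rp or Sp
#' non-bridging site; \code{"mixed"} linkages get two 0.5-occupancy
#' altloc conformers (A: Rp sulfur, B: Sp sulfur), the standard
#' dual-conformer modelling convention for unresolved stereochemistry.
#' Sugar/base fidelity is a non-goal; only backbone atoms are built.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @return A \code{\link{structure_model}} (chain A, residues DT1..DTn).
#' @export
build_ps_strand <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_nucleotides
  twist <- 36 * pi / 180; rise <- 3.38; radius <- 8.9
  helix <- function(i) c(radius * cos(i * twist), radius * sin(i * twist),
                         i * rise)
  rows <- list()
  serial <- 0L
  add <- function(name, altloc, resno, pos, occ, b, ele) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, altloc = altloc, resname = "DT",
      chain = "A", resno = resno, insert = "", x = pos[1], y = pos[2],
      z = pos[3], occupancy = occ, b_factor = b, element = ele,
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(n - 1)) {            # linkage j: residues j -> j+1
    p <- helix(j)
    tangent <- helix(j + 1) - helix(j - 1)
    tangent <- tangent / sqrt(sum(tangent^2))
    nrm <- -c(cos(j * twist), sin(j * twist), 0)  # toward helix axis
    nrm <- nrm - sum(nrm * tangent) * tangent
    nrm <- nrm / sqrt(sum(nrm^2))
    prp <- c(tangent[2] * nrm[3] - tangent[3] * nrm[2],
             tangent[3] * nrm[1] - tangent[1] * nrm[3],
             tangent[1] * nrm[2] - tangent[2] * nrm[1])
    half_b <- 104.0 / 2 * pi / 180       # bridging O-P-O angle
    d_o5 <- sin(half_b) * tangent - cos(half_b) * nrm
    d_o3 <- -sin(half_b) * tangent - cos(half_b) * nrm
    bis <- -(d_o5 + d_o3); bis <- bis / sqrt(sum(bis^2))
    half_nb <- 119.6 / 2 * pi / 180      # non-bridging O-P-O angle
    site1 <- p + 1.95 * (cos(half_nb) * bis + sin(half_nb) * prp)
    site2 <- p + 1.95 * (cos(half_nb) * bis - sin(half_nb) * prp)
    b <- spec$b_profile[j]
    o5 <- p + 1.59 * d_o5
    o3 <- p + 1.59 * d_o3
    add("P", "", j + 1L, p, 1, b, "P")
    add("O5'", "", j + 1L, o5, 1, b, "O")
    add("O3'", "", j, o3, 1, b, "O")
    # which geometric site is Rp for this local geometry
    vol1 <- .chirality_volume(site1 - p, o3 - p, o5 - p, site2 - p)
    rp_site <- if (vol1 < 0) site1 else site2
    sp_site <- if (vol1 < 0) site2 else site1
    scl <- function(site, bond) p + (site - p) * bond / 1.95
    pat <- spec$stereo_pattern[j]
    if (pat == "Rp") {
      add("SP1", "", j + 1L, rp_site, 1, b, "S")
      add("OP2", "", j + 1L, scl(sp_site, 1.48), 1, b, "O")
    } else if (pat == "Sp") {
      add("SP1", "", j + 1L, sp_site, 1, b, "S")
      add("OP2", "", j + 1L, scl(rp_site, 1.48), 1, b, "O")
    } else {                             # mixed: dual 0.5-occupancy altlocs
      add("SP1", "A", j + 1L, rp_site, 0.5, b, "S")
      add("OP2", "A", j + 1L, scl(sp_site, 1.48), 0.5, b, "O")
      add("SP1", "B", j + 1L, sp_site, 0.5, b, "S")
      add("OP2", "B", j + 1L, scl(rp_site, 1.48), 0.5, b, "O")
    }
  }
  structure_model(do.call(rbind, rows),
                  sprintf("synthetic_ps_strand_n%d", n))
}

#' Render a synthetic anomalous difference map for a model
#'
#' Places an isotropic Gaussian blob of the stated height (sigma units)
#' at every sulfur atom, weighted by occupancy, on an orthogonal grid
#' covering the model with padding, and adds Gaussian voxel noise. The
#' returned grid is sigma-normalised by construction (\code{sigma = 1}):
#' its values are already in sigma units.
#'
#' @param model A \code{\link{structure_model}} containing sulfur atoms.
#' @param blob_sigma_height Peak height of each full-occupancy sulfur, in
#'   sigma units. The default 8 emulates a well-measured sulfur anomalous
#'   peak: a half-occupancy site (a 50/50 Rp/Sp mixture) still reaches
#'   4 sigma, above the conventional 3.5 sigma contour.
#' @param blob_width Gaussian width (SD) of the blob, Angstrom
#'   (default 0.9, matching the ~2 A anomalous-resolution regime).
#' @param noise Voxel noise SD in sigma units (default 0).
#' @param spacing Grid spacing, Angstrom (default 0.5).
#' @param pad Padding around the model bounding box, Angstrom.
#' @param seed Integer seed for the voxel noise.
#' @return A \code{\link{density_grid}} with \code{sigma = 1}.
#' @export
render_anomalous_map <- function(model, blob_sigma_height = 8,
                                 blob_width = 0.9, noise = 0,
                                 spacing = 0.5, pad = 4, seed = 1) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  s_atoms <- a[toupper(a$element) == "S", , drop = FALSE]
  if (nrow(s_atoms) == 0L)
    warning("model contains no sulfur atoms; rendering an empty map")
  lo <- c(min(a$x), min(a$y), min(a$z)) - pad
  hi <- c(max(a$x), max(a$y), max(a$z)) + pad
  dims <- pmax(ceiling((hi - lo) / spacing) + 1, 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  vals <- if (noise > 0) {
    array(stats::rnorm(prod(dims), 0, noise), dim = dims)
  } else array(0, dim = dims)
  gx <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  gy <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  gz <- lo[3] + (seq_len(dims[3]) - 1) * spacing
  cut <- 4 * blob_width
  for (k in seq_len(nrow(s_atoms))) {
    sp <- as.numeric(s_atoms[k, c("x", "y", "z")])
    amp <- blob_sigma_height * s_atoms$occupancy[k]
    ix <- which(abs(gx - sp[1]) <= cut)
    iy <- which(abs(gy - sp[2]) <= cut)
    iz <- which(abs(gz - sp[3]) <= cut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    ex <- exp(-(gx[ix] - sp[1])^2 / (2 * blob_width^2))
    ey <- exp(-(gy[iy] - sp[2])^2 / (2 * blob_width^2))
    ez <- exp(-(gz[iz] - sp[3])^2 / (2 * blob_width^2))
    vals[ix, iy, iz] <- vals[ix, iy, iz] + amp * outer(ex, outer(ey, ez))
  }
  density_grid(vals, origin = lo, spacing = rep(spacing, 3), sigma = 1)
}

#' Generate a synthetic binding-titration fixture
#'
#' Simulates replicate titrations for one or more oligo/condition systems
#' from given ground-truth parameters, writes them as a titration CSV,
#' and records the generating parameters in a sidecar JSON for recovery
#' tests.
#'
#' @param systems Named list; each element a list with \code{params}
#'   (\code{\link{binding_params}}), \code{oligo}, \code{condition}.
#' @param design Titration design (\code{\link{titration_design}}).
#' @param noise_sd Anisotropy noise SD (default 2\% of a 0.15 anisotropy
#'   change, i.e. 0.003).
#' @param seed Integer seed.
#' @param path Output CSV path.
#' @param truth_path Output JSON sidecar path (default: \code{path} with
#'   \code{"_truth.json"}).
#' @return Invisibly, a list of all generated series.
#' @export
make_binding_fixture <- function(systems, design = titration_design(),
                                 noise_sd = 0.003, seed = 1, path,
                                 truth_path = NULL) {
  if (is.null(truth_path))
    truth_path <- sub("\\.csv$", "_truth.json", path)
  all_series <- list()
  truth <- list()
  for (i in seq_along(systems)) {
    sys <- systems[[i]]
    ser <- simulate_titration(sys$params, design, noise_sd,
                              seed = seed + i - 1,
                              oligo = sys$oligo, condition = sys$condition)
    all_series <- c(all_series, ser)
    truth[[paste(sys$oligo, sys$condition, sep = "|")]] <- list(
      k_d = sys$params$k_d, a0 = sys$params$a0, da = sys$params$da,
      ns = sys$params$ns, noise_sd = noise_sd, seed = seed + i - 1)
  }
  write_titrations(all_series, path)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(all_series)
}

#' Write a complete fixture set to a directory
#'
#' Produces, under \code{dir}: \code{model.pdb} (idealized PS strand with
#' a programmed stereo pattern), \code{anom.ccp4} (matching synthetic
#' anomalous map), \code{titrations.csv} + \code{titrations_truth.json}
#' (synthetic triplicate titrations for Ca2+/Mg2+/EGTA-like conditions),
#' and \code{truth.json} (the programmed stereo pattern). All outputs are
#' deterministic in \code{seed}.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer seed.
#' @return Invisibly, the directory path.
#' @export
make_fixtures <- function(dir, seed = 7) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  pattern <- sample(c("Rp", "Sp", "mixed"), 14, replace = TRUE,
                    prob = c(0.45, 0.35, 0.2))
  spec <- fixture_spec(15, pattern, map_noise_sigma = 0.3, seed = seed)
  model <- build_ps_strand(spec)
  write_structure(model, file.path(dir, "model.pdb"))
  grid <- render_anomalous_map(model, noise = spec$map_noise_sigma,
                               seed = seed)
  write_map(grid, file.path(dir, "anom.ccp4"))
  systems <- list(
    list(params = binding_params(9.3, 0.10, 0.15, 2e-4),
         oligo = "synthetic-15mer", condition = "Ca2+"),
    list(params = binding_params(12.0, 0.10, 0.15, 2e-4),
         oligo = "synthetic-15mer", condition = "Mg2+"),
    list(params = binding_params(60.0, 0.10, 0.15, 2e-4),
         oligo = "synthetic-15mer", condition = "EGTA"))
  make_binding_fixture(systems, seed = seed,
                       path = file.path(dir, "titrations.csv"),
                       truth_path = file.path(dir, "titrations_truth.json"))
  jsonlite::write_json(list(stereo_pattern = pattern, seed = seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
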