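# Non-bridging atom names recognised at a phosphorothioate linkage.
# Sulfur substitutions appear in deposited models as SP1/SP2 (or S1P/S2P);
# oxygens as OP1/OP2.
.NONBRIDGE_NAMES <- c("OP1", "OP2", "SP1", "SP2", "S1P", "S2P", "O1P", "O2P")

.vec3 <- function(row) as.numeric(c(row$x, row$y, row$z))

#' Extract phosphorothioate linkages from a structure model
#'
#' One linkage per internucleotide phosphate: the P, O5' of the 3'-side
#' residue, the O3' of the 5'-side residue, and the non-bridging candidate
#' atoms (OP1/OP2 and/or their sulfur substitutions, all altlocs).
#' Linkages are numbered 5' to 3' starting at 1 within each chain.
#' A linkage whose backbone atoms are incomplete is skipped with a
#' warning. \code{mean_b} is the mean B-factor over the phosphate-group
#' atoms (P, O5', O3', non-bridging).
#'
#' @param model A \code{\link{structure_model}} containing nucleic-acid
#'   residues.
#' @param chains Optional character vector restricting to these chains.
#' @return List of \code{ps_linkage} objects.
#' @export
extract_linkages <- function(model, chains = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  out <- list()
  for (ch in unique(a$chain)) {
    ac <- a[a$chain == ch, , drop = FALSE]
    resnos <- sort(unique(ac$resno))
    k <- 0L
    for (i in seq_along(resnos)[-length(resnos)]) {
      r5 <- resnos[i]; r3 <- resnos[i + 1]
      res5 <- ac[ac$resno == r5, , drop = FALSE]
      res3 <- ac[ac$resno == r3, , drop = FALSE]
      p_row <- res3[res3$name == "P", , drop = FALSE]
      o5_row <- res3[res3$name == "O5'", , drop = FALSE]
      o3_row <- res5[res5$name == "O3'", , drop = FALSE]
      nb <- res3[res3$name %in% .NONBRIDGE_NAMES, , drop = FALSE]
      k <- k + 1L
      if (nrow(p_row) < 1 || nrow(o5_row) < 1 || nrow(o3_row) < 1 ||
          nrow(nb) < 1) {
        warning(sprintf("chain %s linkage %d (%d-%d): missing backbone atom, skipped",
                        ch, k, r5, r3))
        next
      }
      nonbridge <- data.frame(
        name = nb$name, altloc = nb$altloc,
        x = nb$x, y = nb$y, z = nb$z,
        occupancy = nb$occupancy, b_factor = nb$b_factor,
        element = nb$element, stringsAsFactors = FALSE)
      grp_b <- c(p_row$b_factor[1], o5_row$b_factor[1], o3_row$b_factor[1],
                 nb$b_factor)
      lk <- structure(list(
        linkage_id = k, chain = ch,
        res5 = paste0(res5$resname[1], r5),
        res3 = paste0(res3$resname[1], r3),
        p_pos = .vec3(p_row[1, ]), o5_pos = .vec3(o5_row[1, ]),
        o3_pos = .vec3(o3_row[1, ]),
        nonbridge = nonbridge, mean_b = mean(grp_b)),
        class = "ps_linkage")
      # geometric sanity: P-O distances and non-coplanarity
      d_o5 <- sqrt(sum((lk$p_pos - lk$o5_pos)^2))
      d_o3 <- sqrt(sum((lk$p_pos - lk$o3_pos)^2))
      if (d_o5 < 1.2 || d_o5 > 2.5 || d_o3 < 1.2 || d_o3 > 2.5) {
        warning(sprintf("chain %s linkage %d: implausible P-O distances, skipped",
                        ch, k))
        next
      }
      out[[length(out) + 1L]] <- lk
    }
  }
  out
}

#' @export
print.ps_linkage <- function(x, ...) {
  cat(sprintf("ps_linkage %d (chain %s, %s-%s): %d non-bridging atoms, mean B = %.1f A^2\n",
              x$linkage_id, x$chain, x$res5, x$res3, nrow(x$nonbridge),
              x$mean_b))
  invisible(x)
}

# The two candidate non-bridging positions of a linkage. Uses the distinct
# positions of the modelled non-bridging atoms when two are present;
# otherwise constructs ideal tetrahedral sites from the P/O5'/O3' geometry
# (P-S bond length 1.95 A).
.candidate_sites <- function(linkage, bond = 1.95) {
  nb <- linkage$nonbridge
  pos <- unique(round(cbind(nb$x, nb$y, nb$z), 3))
  if (nrow(pos) >= 2) {
    # pick the two most separated distinct positions
    dmat <- as.matrix(stats::dist(pos))
    ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
    return(list(pos[ij[1], ], pos[ij[2], ]))
  }
  p <- linkage$p_pos
  d1 <- (linkage$o5_pos - p); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- (linkage$o3_pos - p); d2 <- d2 / sqrt(sum(d2^2))
  bis <- -(d1 + d2); bis <- bis / sqrt(sum(bis^2))
  prp <- c(d1[2] * d2[3] - d1[3] * d2[2],
           d1[3] * d2[1] - d1[1] * d2[3],
           d1[1] * d2[2] - d1[2] * d2[1])
  prp <- prp / sqrt(sum(prp^2))
  half <- 119.6 / 2 * pi / 180  # half the O-P-O (non-bridging) angle
  list(p + bond * (cos(half) * bis + sin(half) * prp),
       p + bond * (cos(half) * bis - sin(half) * prp))
}

# Signed tetrahedral volume for substituents ordered by CIP priority
# S > O3' > O5' > O(non-bridging): (v1-v4) . ((v2-v4) x (v3-v4)).
.chirality_volume <- function(s_pos, o3_pos, o5_pos, other_pos) {
  a <- s_pos - other_pos; b <- o3_pos - other_pos; c <- o5_pos - other_pos
  a[1] * (b[2] * c[3] - b[3] * c[2]) -
    a[2] * (b[1] * c[3] - b[3] * c[1]) +
    a[3] * (b[1] * c[2] - b[2] * c[1])
}

#' Assign Rp/Sp configuration for a sulfur placement
#'
#' Given a linkage and which of its two candidate non-bridging sites holds
#' the sulfur, returns the CIP configuration at phosphorus. Priorities are
#' S > O3' > O5' > O(non-bridging); the label follows the sign of the
#' signed volume of the priority-ordered substituents. The sign-to-label
#' mapping (negative volume = Rp) was calibrated once against an
#' independent CIP construction (lowest priority pointing away from the
#' viewer, clockwise 1-2-3 = R) and is frozen here.
#'
#' @param linkage A \code{ps_linkage}.
#' @param sulfur_site Which candidate site (1 or 2, in
#'   \code{.candidate_sites} order) carries the sulfur, or a numeric
#'   3-vector giving the sulfur position directly (the other candidate
#'   site is then the non-bridging oxygen).
#' @param volume_threshold Minimum |normalised volume| accepted; flatter
#'   geometry raises an error.
#' @return \code{"Rp"} or \code{"Sp"}.
#' @export
assign_chirality <- function(linkage, sulfur_site = 1,
                             volume_threshold = 0.05) {
  stopifnot(inherits(linkage, "ps_linkage"))
  sites <- .candidate_sites(linkage)
  if (length(sulfur_site) == 3) {
    s_pos <- as.numeric(sulfur_site)
    d <- c(sqrt(sum((s_pos - sites[[1]])^2)), sqrt(sum((s_pos - sites[[2]])^2)))
    other <- sites[[which.max(d)]]
  } else {
    stopifnot(sulfur_site %in% c(1, 2))
    s_pos <- sites[[sulfur_site]]
    other <- sites[[3 - sulfur_site]]
  }
  p <- linkage$p_pos
  vol <- .chirality_volume(s_pos - p, linkage$o3_pos - p,
                           linkage$o5_pos - p, other - p)
  scale <- prod(sqrt(c(sum((s_pos - p)^2), sum((linkage$o3_pos - p)^2),
                       sum((linkage$o5_pos - p)^2), sum((other - p)^2)))^(3 / 4))
  if (abs(vol) < volume_threshold * scale)
    stop("near-degenerate (coplanar) geometry: chirality indeterminate")
  if (vol < 0) "Rp" else "Sp"
}

# site index (1 or 2 of .candidate_sites) that corresponds to Rp
.rp_site_index <- function(linkage) {
  if (assign_chirality(linkage, 1) == "Rp") 1L else 2L
}

# trilinear interpolation of grid values at points (n x 3 matrix, Angstrom)
.interp_grid <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3)
  fr <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")
  d <- grid$dimensions
  if (any(fr < -1e-9) || any(sweep(fr, 2, d - 1) > 1e-9))
    stop("position outside grid bounds")
  fr <- pmin(pmax(fr, 0), matrix(rep(d - 1, each = nrow(fr)), ncol = 3) - 1e-12)
  i0 <- pmin(floor(fr), matrix(rep(d - 2, each = nrow(fr)), ncol = 3))
  i0 <- pmax(i0, 0)
  t <- fr - i0
  v <- grid$values
  out <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    i <- i0[k, ] + 1  # 1-based corner
    tx <- t[k, 1]; ty <- t[k, 2]; tz <- t[k, 3]
    c00 <- v[i[1], i[2], i[3]] * (1 - tx) + v[i[1] + 1, i[2], i[3]] * tx
    c10 <- v[i[1], i[2] + 1, i[3]] * (1 - tx) + v[i[1] + 1, i[2] + 1, i[3]] * tx
    c01 <- v[i[1], i[2], i[3] + 1] * (1 - tx) + v[i[1] + 1, i[2], i[3] + 1] * tx
    c11 <- v[i[1], i[2] + 1, i[3] + 1] * (1 - tx) +
      v[i[1] + 1, i[2] + 1, i[3] + 1] * tx
    c0 <- c00 * (1 - ty) + c10 * ty
    c1 <- c01 * (1 - ty) + c11 * ty
    out[k] <- c0 * (1 - tz) + c1 * tz
  }
  out
}

#' Peak height of a density map near a position
#'
#' Maximum trilinearly interpolated map value over the query position and
#' all grid nodes within \code{radius} of it, expressed in sigma units
#' (divided by the grid's sigma).
#'
#' @param grid A \code{\link{density_grid}} (must be usable, sigma > 0).
#' @param position Numeric 3-vector, Angstrom.
#' @param radius Search radius, Angstrom (default 1.0).
#' @return Peak height in sigma units.
#' @export
peak_height <- function(grid, position, radius = 1.0) {
  stopifnot(inherits(grid, "density_grid"))
  if (!grid$usable) stop("grid is unusable (sigma = 0)")
  position <- as.numeric(position)
  d <- grid$dimensions
  # candidate nodes within radius
  rng <- lapply(1:3, function(ax) {
    lo <- floor((position[ax] - radius - grid$origin[ax]) / grid$spacing[ax])
    hi <- ceiling((position[ax] + radius - grid$origin[ax]) / grid$spacing[ax])
    seq(max(lo, 0), min(hi, d[ax] - 1))
  })
  nodes <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  node_pos <- sweep(sweep(nodes, 2, grid$spacing, "*"), 2, grid$origin, "+")
  keep <- rowSums(sweep(node_pos, 2, position)^2) <= radius^2
  pts <- rbind(position, node_pos[keep, , drop = FALSE])
  max(.interp_grid(grid, pts)) / grid$sigma
}

#' Classify a PS linkage from the anomalous map
#'
#' Implements the stereo call: a linkage whose phosphate-group mean
#' B-factor exceeds \code{b_max} is unreliable (density uninterpretable)
#' and is called indeterminate. Otherwise the anomalous peak heights at
#' the two candidate non-bridging sites are measured; if neither reaches
#' \code{threshold_sigma} the call is indeterminate; if one site reaches
#' it and exceeds the other by at least \code{ratio_margin}-fold, that
#' single configuration is called; if both reach it within the margin the
#' linkage is a mixed Rp/Sp population (the dual 0.5-occupancy modelling
#' convention).
#'
#' @param grid Sigma-normalised \code{\link{density_grid}}.
#' @param linkage A \code{ps_linkage}.
#' @param threshold_sigma Peak threshold in sigma units (default 3.5, the
#'   conventional anomalous-map contour level).
#' @param b_max Reliability B-factor cutoff, Angstrom^2 (default 60).
#' @param ratio_margin Dominance ratio separating a single call from a
#'   mixed one (default 1.5).
#' @param radius Peak search radius, Angstrom.
#' @return A one-row data frame (class \code{stereo_call}) with columns
#'   \code{linkage_id}, \code{chain}, \code{res5}, \code{res3},
#'   \code{call}, \code{peak_Rp_sigma}, \code{peak_Sp_sigma},
#'   \code{b_factor}, \code{reliable}, \code{rationale}.
#' @export
classify_linkage <- function(grid, linkage, threshold_sigma = 3.5,
                             b_max = 60, ratio_margin = 1.5, radius = 1.0) {
  stopifnot(inherits(grid, "density_grid"), inherits(linkage, "ps_linkage"))
  mk <- function(call, rp, sp, reliable, why) {
    structure(data.frame(linkage_id = linkage$linkage_id,
                         chain = linkage$chain, res5 = linkage$res5,
                         res3 = linkage$res3, call = call,
                         peak_Rp_sigma = rp, peak_Sp_sigma = sp,
                         b_factor = linkage$mean_b, reliable = reliable,
                         rationale = why, stringsAsFactors = FALSE),
              class = c("stereo_call", "data.frame"))
  }
  if (linkage$mean_b > b_max)
    return(mk("indeterminate", NA_real_, NA_real_, FALSE,
              sprintf("mean B %.1f > %.0f A^2: density unreliable",
                      linkage$mean_b, b_max)))
  sites <- .candidate_sites(linkage)
  rp_i <- .rp_site_index(linkage)
  peak_rp <- tryCatch(peak_height(grid, sites[[rp_i]], radius),
                      error = function(e)
                        stop("model/map frame mismatch: ",
                             conditionMessage(e)))
  peak_sp <- tryCatch(peak_height(grid, sites[[3 - rp_i]], radius),
                      error = function(e)
                        stop("model/map frame mismatch: ",
                             conditionMessage(e)))
  above <- c(peak_rp, peak_sp) >= threshold_sigma
  if (!any(above))
    return(mk("indeterminate", peak_rp, peak_sp, TRUE,
              sprintf("no anomalous density >= %.1f sigma at either site",
                      threshold_sigma)))
  if (all(above) &&
      max(peak_rp, peak_sp) < ratio_margin * min(peak_rp, peak_sp))
    return(mk("mixed", peak_rp, peak_sp, TRUE,
              "density evenly distributed at both non-bridging sites"))
  if (peak_rp >= peak_sp * ratio_margin || (above[1] && !above[2]))
    if (peak_rp >= threshold_sigma)
      return(mk("Rp", peak_rp, peak_sp, TRUE,
                "anomalous density clearly at the Rp site"))
  if (peak_sp >= threshold_sigma &&
      (peak_sp >= peak_rp * ratio_margin || !above[1]))
    return(mk("Sp", peak_rp, peak_sp, TRUE,
              "anomalous density clearly at the Sp site"))
  mk("mixed", peak_rp, peak_sp, TRUE,
     "density at both non-bridging sites within the dominance margin")
}

#' Call the stereochemistry of every PS linkage of a strand
#'
#' Runs \code{\link{extract_linkages}} and \code{\link{classify_linkage}}
#' over the selected chains and returns one call per linkage in 5'-to-3'
#' order, with a summary count by label attached as attribute
#' \code{"summary"}.
#'
#' @inheritParams classify_linkage
#' @param model A \code{\link{structure_model}}.
#' @param chains Optional chain selection.
#' @return Data frame of stereo calls (one row per linkage).
#' @export
call_strand <- function(grid, model, chains = NULL, threshold_sigma = 3.5,
                        b_max = 60, ratio_margin = 1.5, radius = 1.0) {
  linkages <- extract_linkages(model, chains)
  calls <- do.call(rbind, lapply(linkages, function(lk)
    classify_linkage(grid, lk, threshold_sigma, b_max, ratio_margin, radius)))
  if (is.null(calls)) calls <- data.frame()
  attr(calls, "summary") <- if (nrow(calls)) table(calls$call) else table(character())
  calls
}
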