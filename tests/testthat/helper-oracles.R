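# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Vectorised bisection solver for the specific-complex equilibrium:
# k_d * x = (P' - x)(R - x) on [0, min(P', R)], P' = prot * (1 - ns).
bisect_bound <- function(prot, rna, k_d, ns = 0, iters = 200) {
  pp <- prot * (1 - ns)
  lo <- rep(0, length(pp))
  hi <- pmin(pp, rna)
  f <- function(x) k_d * x - (pp - x) * (rna - x)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    pos <- f(mid) > 0
    hi <- ifelse(pos, mid, hi)
    lo <- ifelse(pos, lo, mid)
  }
  (lo + hi) / 2
}

# Independent CIP R/S determination at a tetrahedral centre: project the
# three highest-priority substituents onto the plane perpendicular to the
# centre->lowest-priority direction, view from the side opposite the
# lowest-priority substituent, and read the 1->2->3 angular sense
# (clockwise = R).
cip_label <- function(center, v1, v2, v3, v4) {
  d <- (v4 - center); d <- d / sqrt(sum(d^2))   # toward lowest priority
  # orthonormal basis (e1, e2) of the viewing plane, right-handed with -d
  # as the viewing direction (viewer opposite v4 looking at the centre)
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  ang <- vapply(list(v1, v2, v3), function(v) {
    u <- v - center
    atan2(sum(u * e2), sum(u * e1))
  }, numeric(1))
  # sense of traversal 1 -> 2 -> 3 seen by the viewer: with the viewer
  # looking along +d, increasing atan2 angle in the (e1, e2) basis appears
  # clockwise, so a positive signed circular step means clockwise = R.
  step12 <- (ang[2] - ang[1]) %% (2 * pi)
  if (step12 < pi) "R" else "S"
}

# random rigid transformation (rotation from a random quaternion + shift)
random_rigid <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  list(R = R, t = stats::rnorm(3, 0, 10))
}

apply_rigid <- function(model, rig) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rig$R)
  xyz <- sweep(xyz, 2, rig$t, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

reflect_model <- function(model) {
  model$atoms$x <- -model$atoms$x
  model
}

# direct RMSD after an independent Kabsch fit (quaternion-free, via
# eigen of the 4x4 key matrix -- classic quaternion superposition)
quat_rmsd <- function(ref, mob) {
  cr <- colMeans(ref); cm <- colMeans(mob)
  P <- sweep(ref, 2, cr); Q <- sweep(mob, 2, cm)
  M <- t(Q) %*% P
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(ref)
  sqrt(max(e2, 0))
}

# a compact synthetic protein chain: n CA positions on a smooth helix-like
# curve with 3.8 A spacing, plus residue names cycling over amino acids
synthetic_ca_chain <- function(n, chain = "A", seed = 1, resno_offset = 0) {
  set.seed(seed)
  aas <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  t <- seq_len(n)
  xyz <- cbind(10 * cos(t / 3) + 0.3 * cumsum(stats::rnorm(n)),
               10 * sin(t / 3) + 0.3 * cumsum(stats::rnorm(n)),
               1.5 * t)
  resnames <- aas[(t * 7) %% 20 + 1]
  structure_model(data.frame(
    serial = t, name = "CA", altloc = "", resname = resnames,
    chain = chain, resno = t + resno_offset, insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = 20, element = "C",
    stringsAsFactors = FALSE), "synthetic_chain")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# brute-force rotation search: global random sampling followed by shrinking
# axis-angle refinement around the incumbent; translation handled by
# centroid alignment
brute_rotation_rmsd <- function(ref, mob, n_global = 500, n_refine = 40) {
  P <- sweep(ref, 2, colMeans(ref))
  Q <- sweep(mob, 2, colMeans(mob))
  score <- function(R) sqrt(mean(rowSums((Q %*% t(R) - P)^2)))
  axis_angle <- function(axis, ang) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  }
  best_R <- diag(3); best <- score(best_R)
  for (i in seq_len(n_global)) {
    R <- random_rigid(5000 + i)$R
    s <- score(R)
    if (s < best) { best <- s; best_R <- R }
  }
  step <- 0.5
  for (round in seq_len(n_refine)) {
    improved <- FALSE
    for (i in 1:40) {
      R <- axis_angle(stats::rnorm(3), stats::rnorm(1, 0, step)) %*% best_R
      s <- score(R)
      if (s < best) { best <- s; best_R <- R; improved <- TRUE }
    }
    if (!improved) step <- step / 2
    if (step < 1e-5) break
  }
  best
}

# helper: a bare model from atom tuples (name, resname, chain, resno, xyz, ele)
tiny_model <- function(rows) {
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(serial = i, name = r$name, altloc = "",
               resname = r$resname, chain = r$chain, resno = r$resno,
               insert = "", x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               occupancy = if (is.null(r$occ)) 1 else r$occ,
               b_factor = 20, element = r$ele, stringsAsFactors = FALSE)
  }))
  structure_model(df, "synthetic_tiny")
}

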