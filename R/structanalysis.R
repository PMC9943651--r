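# Bondi van der Waals radii (Angstrom) for the elements met in
# protein/oligonucleotide models; metals get ionic-ish working values.
.BONDI <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
            "F" = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
            MG = 1.73, CA = 2.31, ZN = 1.39, "NA" = 2.27, K = 2.75,
            MN = 2.05)

.vdw_radius <- function(element, label = element) {
  r <- .BONDI[toupper(element)]
  if (any(is.na(r)))
    stop("no van der Waals radius for element '",
         paste(unique(element[is.na(r)]), collapse = "', '"),
         "' (atom ", paste(label[is.na(r)], collapse = ", "), ")")
  unname(r)
}

#' Select atoms of a structure model
#'
#' Returns the integer row indices of \code{model$atoms} matching every
#' supplied filter.
#'
#' @param model A \code{\link{structure_model}}.
#' @param chain,resno,name,resname,element Optional filters (vectors).
#' @param kind \code{"protein"}, \code{"nucleic"} or \code{"water"} to
#'   restrict by residue class (by residue name).
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL, name = NULL,
                         resname = NULL, element = NULL, kind = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(element)) keep <- keep & toupper(a$element) %in% toupper(element)
  if (!is.null(kind)) {
    kind <- match.arg(kind, c("protein", "nucleic", "water"))
    keep <- keep & switch(kind,
      protein = a$resname %in% names(.AA3TO1),
      nucleic = a$resname %in% c("A", "C", "G", "U", "T", "DA", "DC", "DG",
                                 "DT", "DU", "5MC", "PST"),
      water = a$resname %in% c("HOH", "WAT", "H2O"))
  }
  which(keep)
}

# keep only the highest-occupancy altloc of each (chain,resno,insert,name)
.primary_altloc <- function(atoms, idx) {
  a <- atoms[idx, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$insert, a$name, sep = "|")
  keep <- unlist(lapply(split(seq_along(idx), key), function(g) {
    g[which.max(a$occupancy[g])]
  }), use.names = FALSE)
  sort(idx[keep])
}

#' Detect protein-oligonucleotide contacts
#'
#' Two atoms are in contact when their distance does not exceed the sum
#' of their Bondi van der Waals radii plus \code{vdw_tolerance}. A contact
#' is \code{polar} when both atoms are polar-capable (N or O, or S as
#' acceptor paired with N/O) and within \code{polar_cutoff};
#' otherwise \code{vdw_hydrophobic} when at least one partner is carbon
#' or sulfur, else \code{other}. Unless \code{all_altlocs}, only the
#' highest-occupancy conformer of each atom is considered.
#'
#' @param model A \code{\link{structure_model}}.
#' @param sel_a,sel_b Disjoint, non-empty integer atom selections (from
#'   \code{\link{select_atoms}}).
#' @param vdw_tolerance Distance slack added to the radius sum, Angstrom.
#' @param polar_cutoff Polar-contact distance cutoff, Angstrom.
#' @param all_altlocs Keep all alternate conformers.
#' @return Data frame with one row per contact: indices \code{ia},
#'   \code{ib}, \code{distance}, \code{kind}, \code{pair_label}.
#' @export
find_contacts <- function(model, sel_a, sel_b, vdw_tolerance = 0.5,
                          polar_cutoff = 3.5, all_altlocs = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  if (length(sel_a) == 0L || length(sel_b) == 0L)
    stop("selections must be non-empty")
  if (length(intersect(sel_a, sel_b)))
    stop("selections must be disjoint")
  a <- model$atoms
  if (!all_altlocs) {
    sel_a <- .primary_altloc(a, sel_a)
    sel_b <- .primary_altloc(a, sel_b)
  }
  xa <- as.matrix(a[sel_a, c("x", "y", "z")])
  xb <- as.matrix(a[sel_b, c("x", "y", "z")])
  ra <- .vdw_radius(a$element[sel_a], a$name[sel_a])
  rb <- .vdw_radius(a$element[sel_b], a$name[sel_b])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  cut <- outer(ra, rb, "+") + vdw_tolerance
  hit <- which(dmat <= cut, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(data.frame(ia = integer(), ib = integer(), distance = numeric(),
                      kind = character(), pair_label = character(),
                      stringsAsFactors = FALSE))
  ia <- sel_a[hit[, 1]]; ib <- sel_b[hit[, 2]]
  dist <- dmat[hit]
  ea <- toupper(a$element[ia]); eb <- toupper(a$element[ib])
  polar_pair <- (ea %in% c("N", "O") & eb %in% c("N", "O")) |
    (ea == "S" & eb %in% c("N", "O")) | (eb == "S" & ea %in% c("N", "O"))
  kind <- ifelse(polar_pair & dist <= polar_cutoff, "polar",
                 ifelse(ea %in% c("C", "S") | eb %in% c("C", "S"),
                        "vdw_hydrophobic", "other"))
  lab <- function(i) sprintf("%s(%s%d)", a$name[i], a$resname[i], a$resno[i])
  data.frame(ia = ia, ib = ib, distance = dist, kind = kind,
             pair_label = paste0(vapply(ia, lab, ""), "...",
                                 vapply(ib, lab, "")),
             stringsAsFactors = FALSE)
}

#' Water-mediated polar bridges between two selections
#'
#' Finds water oxygen atoms forming a polar contact (within
#' \code{polar_cutoff}) with both selections simultaneously: the
#' classic water bridge between an oligonucleotide backbone atom and a
#' protein backbone carbonyl.
#'
#' @inheritParams find_contacts
#' @return Data frame: \code{water} (atom index), \code{ia}, \code{ib},
#'   \code{dist_a}, \code{dist_b}, \code{label}.
#' @export
find_water_bridges <- function(model, sel_a, sel_b, polar_cutoff = 3.5) {
  w <- select_atoms(model, kind = "water", element = "O")
  if (length(w) == 0L)
    return(data.frame(water = integer(), ia = integer(), ib = integer(),
                      dist_a = numeric(), dist_b = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  a <- model$atoms
  polar <- function(sel) sel[toupper(a$element[sel]) %in% c("N", "O", "S")]
  sel_a <- polar(sel_a); sel_b <- polar(sel_b)
  out <- list()
  for (wi in w) {
    wp <- as.numeric(a[wi, c("x", "y", "z")])
    da <- sqrt(colSums((t(as.matrix(a[sel_a, c("x", "y", "z")])) - wp)^2))
    db <- sqrt(colSums((t(as.matrix(a[sel_b, c("x", "y", "z")])) - wp)^2))
    if (any(da <= polar_cutoff) && any(db <= polar_cutoff)) {
      i <- sel_a[which.min(da)]; j <- sel_b[which.min(db)]
      out[[length(out) + 1L]] <- data.frame(
        water = wi, ia = i, ib = j, dist_a = min(da), dist_b = min(db),
        label = sprintf("%s(%s%d)...HOH...%s(%s%d)",
                        a$name[i], a$resname[i], a$resno[i],
                        a$name[j], a$resname[j], a$resno[j]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(water = integer(), ia = integer(), ib = integer(),
               dist_a = numeric(), dist_b = numeric(), label = character(),
               stringsAsFactors = FALSE)
}

#' Rank residues by hydrophobic contacts to PS sulfur atoms
#'
#' From a contact table, keeps hydrophobic van der Waals contacts in which
#' one partner is a sulfur atom, and ranks the residues of the opposite
#' partner by contact count (ties broken by minimum distance).
#'
#' @param contacts Contact table from \code{\link{find_contacts}}.
#' @param model The \code{\link{structure_model}} the indices refer to.
#' @return Data frame: \code{chain}, \code{resname}, \code{resno},
#'   \code{n_contacts}, \code{min_distance}, ranked.
#' @export
summarize_pocket <- function(contacts, model) {
  if (nrow(contacts) == 0L)
    return(data.frame(chain = character(), resname = character(),
                      resno = integer(), n_contacts = integer(),
                      min_distance = numeric(), stringsAsFactors = FALSE))
  a <- model$atoms
  h <- contacts[contacts$kind == "vdw_hydrophobic", , drop = FALSE]
  sa <- toupper(a$element[h$ia]) == "S"
  sb <- toupper(a$element[h$ib]) == "S"
  h <- h[sa | sb, , drop = FALSE]
  if (nrow(h) == 0L) return(summarize_pocket(h[0, ], model))
  partner <- ifelse(toupper(a$element[h$ia]) == "S", h$ib, h$ia)
  df <- data.frame(chain = a$chain[partner], resname = a$resname[partner],
                   resno = a$resno[partner], distance = h$distance,
                   stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(df, paste(df$chain, df$resno)), function(g)
    data.frame(chain = g$chain[1], resname = g$resname[1], resno = g$resno[1],
               n_contacts = nrow(g), min_distance = min(g$distance),
               stringsAsFactors = FALSE)))
  agg[order(-agg$n_contacts, agg$min_distance), , drop = FALSE]
}

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
             MSE = "M", SEC = "U")

# Calpha table of one chain: resno + coordinates + one-letter code,
# highest-occupancy altloc only
.ca_table <- function(model, chain) {
  idx <- select_atoms(model, chain = chain, name = "CA", kind = "protein")
  idx <- .primary_altloc(model$atoms, idx)
  a <- model$atoms[idx, , drop = FALSE]
  a <- a[order(a$resno), , drop = FALSE]
  data.frame(resno = a$resno, aa = unname(.AA3TO1[a$resname]),
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

#' Pair C-alpha atoms of two protein chains by sequence alignment
#'
#' Aligns the one-letter sequences globally (identity scoring, affine
#' gaps) and pairs the C-alpha atoms of aligned, identical residues.
#'
#' @param model_a,model_b \code{\link{structure_model}} objects.
#' @param chain_a,chain_b Chain identifiers.
#' @param min_pairs Minimum acceptable number of pairs (default 30).
#' @return List: \code{xyz_a}, \code{xyz_b} (n x 3 matrices),
#'   \code{resno_a}, \code{resno_b}, \code{n}.
#' @export
match_calpha <- function(model_a, model_b, chain_a, chain_b,
                         min_pairs = 30) {
  ta <- .ca_table(model_a, chain_a)
  tb <- .ca_table(model_b, chain_b)
  if (nrow(ta) == 0L || nrow(tb) == 0L)
    stop("no protein C-alpha atoms in the selected chain(s)")
  letters_all <- unique(c(ta$aa, tb$aa))
  sm <- matrix(-1, length(letters_all), length(letters_all),
               dimnames = list(letters_all, letters_all))
  diag(sm) <- 2
  aln <- Biostrings::pairwiseAlignment(
    paste(ta$aa, collapse = ""), paste(tb$aa, collapse = ""),
    type = "global", substitutionMatrix = sm,
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- ib <- 0L
  keep_a <- integer(); keep_b <- integer()
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (pb[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && pb[k] != "-" && pa[k] == pb[k]) {
      keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
    }
  }
  if (length(keep_a) < min_pairs)
    stop("insufficient overlap: only ", length(keep_a),
         " aligned identical residues (need >= ", min_pairs, ")")
  list(xyz_a = as.matrix(ta[keep_a, c("x", "y", "z")]),
       xyz_b = as.matrix(tb[keep_b, c("x", "y", "z")]),
       resno_a = ta$resno[keep_a], resno_b = tb$resno[keep_b],
       n = length(keep_a))
}

# One Kabsch least-squares fit of mob onto ref (both n x 3).
# Returns rotation R, translation t with fitted = mob %*% t(R) + t.
.kabsch <- function(ref, mob) {
  cr <- colMeans(ref); cm <- colMeans(mob)
  P <- sweep(ref, 2, cr); Q <- sweep(mob, 2, cm)
  H <- t(Q) %*% P
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cr - as.numeric(R %*% cm)
  list(rotation = R, translation = t)
}

#' Superpose paired coordinate sets (Kabsch with outlier rejection)
#'
#' Computes the closed-form least-squares rotation (SVD with reflection
#' correction), then iterates: recompute per-pair deviations, reject
#' pairs deviating more than \code{reject_sigma} times the current RMSD,
#' refit on the kept pairs. Stops when no pair is rejected or after
#' \code{max_cycles} cycles. The RMSD reported is over the kept pairs.
#'
#' @param pairs A list with \code{xyz_a} (reference) and \code{xyz_b}
#'   (mobile), n x 3 matrices, e.g. from \code{\link{match_calpha}};
#'   or a single n x 3 matrix for \code{xyz_a} with \code{xyz_b} given
#'   separately.
#' @param xyz_b Mobile coordinates when \code{pairs} is a matrix.
#' @param reject_sigma Deviation multiple for rejection (default 2.0).
#' @param max_cycles Maximum rejection cycles (default 5).
#' @return Object of class \code{superposition_result}: \code{rotation}
#'   (3 x 3, det +1), \code{translation}, \code{rmsd} (Angstrom),
#'   \code{n_atoms} (kept pairs), \code{rejected} (indices into the
#'   input pairs), \code{rmsd_history}.
#' @export
superpose <- function(pairs, xyz_b = NULL, reject_sigma = 2.0,
                      max_cycles = 5) {
  if (is.list(pairs) && !is.null(pairs$xyz_a)) {
    ref <- pairs$xyz_a; mob <- pairs$xyz_b
  } else {
    ref <- as.matrix(pairs); mob <- as.matrix(xyz_b)
  }
  stopifnot(is.matrix(ref), is.matrix(mob), ncol(ref) == 3,
            all(dim(ref) == dim(mob)))
  n <- nrow(ref)
  if (n < 3) stop("need at least 3 pairs to superpose")
  if (svd(sweep(ref, 2, colMeans(ref)))$d[2] < 1e-8)
    stop("degenerate (collinear) reference coordinates")
  keep <- rep(TRUE, n)
  hist <- numeric()
  fit <- NULL
  for (cycle in seq_len(max_cycles + 1L)) {
    fit <- .kabsch(ref[keep, , drop = FALSE], mob[keep, , drop = FALSE])
    fitted <- mob %*% t(fit$rotation) +
      matrix(fit$translation, n, 3, byrow = TRUE)
    dev <- sqrt(rowSums((fitted - ref)^2))
    rmsd <- sqrt(mean(dev[keep]^2))
    hist <- c(hist, rmsd)
    if (cycle > max_cycles) break
    if (rmsd < 1e-12) break  # exact superposition: nothing to reject
    rej <- keep & dev > reject_sigma * rmsd
    if (!any(rej)) break
    if (sum(keep & !rej) < 3) break
    keep <- keep & !rej
  }
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = hist[length(hist)], n_atoms = sum(keep),
                 rejected = which(!keep), rmsd_history = hist),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.3f A over %d atoms (%d rejected, %d cycles)\n",
              x$rmsd, x$n_atoms, length(x$rejected), length(x$rmsd_history)))
  invisible(x)
}
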