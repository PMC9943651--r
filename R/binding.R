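#' Binding model parameters
#'
#' Container for the parameters of the 1:1 binding isotherm with a
#' noncompetitive nonspecific term: the dissociation constant \code{k_d}
#' (uM), the anisotropy baseline \code{a0}, the anisotropy change upon
#' binding \code{da}, and the nonspecific fraction \code{ns} in [0, 1).
#' The nonspecific term sequesters \code{ns * prot_total} of the protein
#' into a complex that contributes to the anisotropy signal but does not
#' compete with specific binding.
#'
#' @param k_d Dissociation constant, uM. Must be > 0.
#' @param a0 Anisotropy baseline (dimensionless).
#' @param da Anisotropy change upon binding (dimensionless, finite).
#' @param ns Nonspecific binding fraction in [0, 1).
#' @return An object of class \code{binding_params}.
#' @export
binding_params <- function(k_d, a0, da, ns = 0) {
  stopifnot(is.numeric(k_d), length(k_d) == 1L, is.finite(k_d),
            is.numeric(a0), length(a0) == 1L, is.finite(a0),
            is.numeric(da), length(da) == 1L, is.finite(da),
            is.numeric(ns), length(ns) == 1L, is.finite(ns))
  if (k_d <= 0) stop("k_d must be > 0")
  if (ns < 0 || ns >= 1) stop("ns must lie in [0, 1)")
  structure(list(k_d = k_d, a0 = a0, da = da, ns = ns),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("binding_params: K_D = %.4g uM, A0 = %.4g, dA = %.4g, NS = %.4g\n",
              x$k_d, x$a0, x$da, x$ns))
  invisible(x)
}

#' Concentration of the specific protein-RNA complex
#'
#' Solves the 1:1 equilibrium for the specific complex concentration
#' given total protein, total probe (labelled oligonucleotide), K_D and
#' the nonspecific fraction \code{ns}. The nonspecific interaction reduces
#' the protein pool available for specific binding to
#' \code{prot_total * (1 - ns)}. Mass action then yields a quadratic in the
#' complex concentration whose physically meaningful root is
#' \deqn{x = (b - \sqrt{b^2 - 4 P' R}) / 2,\quad b = P' + R + K_D,}
#' with \eqn{P' = \mathrm{prot}(1-\mathrm{ns})}, \eqn{R} the total probe.
#' The "minus" root is the physical one: the other root exceeds
#' \eqn{\min(P', R)}. Computed in the numerically stable form
#' \eqn{2 P' R / (b + \sqrt{b^2 - 4 P' R})} to avoid cancellation.
#'
#' @param prot_total Total protein concentration(s), uM (vectorised).
#' @param rna_total Total probe concentration, uM (> 0).
#' @param k_d Dissociation constant, uM (>= 0).
#' @param ns Nonspecific fraction in [0, 1).
#' @return Specific complex concentration(s), uM, in
#'   \code{[0, min(prot_total * (1 - ns), rna_total)]}.
#' @export
bound_complex <- function(prot_total, rna_total, k_d, ns = 0) {
  if (any(!is.finite(prot_total)) || any(prot_total < 0))
    stop("prot_total must be finite and >= 0")
  if (!is.numeric(rna_total) || length(rna_total) != 1L || rna_total <= 0)
    stop("rna_total must be a single value > 0")
  if (!is.numeric(k_d) || length(k_d) != 1L || k_d < 0)
    stop("k_d must be a single value >= 0")
  if (!is.numeric(ns) || length(ns) != 1L || ns < 0 || ns >= 1)
    stop("ns must lie in [0, 1)")
  p <- prot_total * (1 - ns)
  b <- p + rna_total + k_d
  disc <- b * b - 4 * p * rna_total
  disc[disc < 0] <- 0  # guard tiny negative round-off
  x <- 2 * p * rna_total / (b + sqrt(disc))
  pmin(pmax(x, 0), pmin(p, rna_total))
}

#' Predicted fluorescence anisotropy
#'
#' Evaluates the titration model
#' \deqn{A = A_0 + \Delta A \, (\mathrm{Prot_{RNA}} + \mathrm{NS}\cdot
#'   \mathrm{Prot_{total}}) / \mathrm{RNA_{total}}}
#' where the specific complex \eqn{\mathrm{Prot_{RNA}}} comes from
#' \code{\link{bound_complex}} and the nonspecific complex
#' \eqn{\mathrm{NS}\cdot\mathrm{Prot_{total}}} contributes to the signal
#' with the same anisotropy change. Note the nonspecific term grows
#' linearly in total protein without saturating; this is a property of the
#' model as formulated, kept deliberately.
#'
#' @param params A \code{\link{binding_params}} object.
#' @param prot_total Total protein concentration(s), uM (vectorised).
#' @param rna_total Total probe concentration, uM (> 0).
#' @return Predicted anisotropy value(s).
#' @export
predict_anisotropy <- function(params, prot_total, rna_total) {
  stopifnot(inherits(params, "binding_params"))
  if (!is.numeric(rna_total) || length(rna_total) != 1L || rna_total <= 0)
    stop("rna_total must be a single value > 0")
  x <- bound_complex(prot_total, rna_total, params$k_d, params$ns)
  params$a0 + params$da * (x + params$ns * prot_total) / rna_total
}

#' Default titration design
#'
#' Twelve log-spaced protein concentrations spanning 0.1-120 uM with a
#' 50 nM (0.05 uM) probe, measured in triplicate: the standard plate
#' layout emulated by the simulator.
#'
#' @param n_points Number of protein concentrations.
#' @param prot_min,prot_max Range of the protein series, uM.
#' @param probe_conc Probe concentration, uM.
#' @param n_replicates Number of replicate series.
#' @return A list with elements \code{probe_conc}, \code{protein_conc},
#'   \code{n_replicates}.
#' @export
titration_design <- function(n_points = 12, prot_min = 0.1, prot_max = 120,
                             probe_conc = 0.05, n_replicates = 3) {
  stopifnot(n_points >= 2, prot_min > 0, prot_max > prot_min, probe_conc > 0,
            n_replicates >= 1)
  list(probe_conc = probe_conc,
       protein_conc = exp(seq(log(prot_min), log(prot_max),
                              length.out = n_points)),
       n_replicates = as.integer(n_replicates))
}

#' Simulate replicate anisotropy titrations
#'
#' Generates replicate titration series from the binding model with
#' additive homoscedastic Gaussian noise. Reproducible for a given seed.
#'
#' @param params A \code{\link{binding_params}} object (ground truth).
#' @param design A design list from \code{\link{titration_design}}.
#' @param noise_sd Gaussian noise standard deviation, anisotropy units (>= 0).
#' @param seed Integer RNG seed.
#' @param oligo,condition Labels attached to each series.
#' @return A list of \code{titration_series} objects (one per replicate).
#' @export
simulate_titration <- function(params, design = titration_design(),
                               noise_sd = 0, seed = 1,
                               oligo = "synthetic", condition = "Ca2+") {
  stopifnot(inherits(params, "binding_params"), noise_sd >= 0)
  grid <- design$protein_conc
  if (length(grid) == 0L) stop("empty protein concentration grid")
  if (any(grid < 0)) stop("protein concentrations must be >= 0")
  mu <- predict_anisotropy(params, grid, design$probe_conc)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lapply(seq_len(design$n_replicates), function(r) {
    titration_series(probe_conc = design$probe_conc,
                     protein_conc = grid,
                     anisotropy = mu + stats::rnorm(length(grid), 0, noise_sd),
                     oligo = oligo, condition = condition, replicate_id = r)
  })
}

# save/restore global RNG state so simulators do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' One replicate titration series
#'
#' @param probe_conc Probe (labelled oligonucleotide) concentration, uM (> 0).
#' @param protein_conc Vector of total protein concentrations, uM (>= 0).
#' @param anisotropy Vector of measured anisotropy values (same length).
#' @param oligo Oligonucleotide label.
#' @param condition Condition label (e.g. \code{"Ca2+"}, \code{"Mg2+"},
#'   \code{"EGTA"}).
#' @param replicate_id Integer replicate index.
#' @return An object of class \code{titration_series}.
#' @export
titration_series <- function(probe_conc, protein_conc, anisotropy,
                             oligo = "oligo", condition = "cond",
                             replicate_id = 1L) {
  if (length(protein_conc) != length(anisotropy))
    stop("protein_conc and anisotropy must have the same length")
  if (any(protein_conc < 0)) stop("protein_conc must be >= 0")
  if (!is.numeric(probe_conc) || probe_conc <= 0) stop("probe_conc must be > 0")
  structure(list(probe_conc = probe_conc,
                 protein_conc = as.numeric(protein_conc),
                 anisotropy = as.numeric(anisotropy),
                 oligo = as.character(oligo),
                 condition = as.character(condition),
                 replicate_id = as.integer(replicate_id)),
            class = "titration_series")
}

# Stack a list of series into one data.frame of points
.stack_series <- function(series) {
  stopifnot(length(series) >= 1L)
  for (s in series) stopifnot(inherits(s, "titration_series"))
  probe <- unique(vapply(series, `[[`, numeric(1), "probe_conc"))
  if (length(probe) != 1L)
    stop("all series in a global fit must share probe_conc")
  do.call(rbind, lapply(seq_along(series), function(i) {
    s <- series[[i]]
    data.frame(series = i, replicate = s$replicate_id,
               prot = s$protein_conc, anis = s$anisotropy)
  }))
}

# residuals (model - data) for the stacked points
.binding_resid <- function(par, dat, probe, ns_free) {
  ns <- if (ns_free) par[["ns"]] else 0
  p <- binding_params(max(par[["k_d"]], 1e-12), par[["a0"]], par[["da"]],
                      min(max(ns, 0), 1 - 1e-12))
  predict_anisotropy(p, dat$prot, probe) - dat$anis
}

#' Global fit of the binding model across replicate series
#'
#' Fits shared K_D, A0, dA (and NS unless \code{ns_free = FALSE}, in which
#' case NS is fixed at 0) to all non-excluded points of all series by
#' bounded nonlinear least squares (Levenberg-Marquardt), with a small
#' deterministic multistart around heuristic starting values (A0 = minimum
#' anisotropy, dA = observed range, K_D = protein concentration at
#' half-range, NS = 0.01). Standard errors come from the local quadratic
#' approximation at the optimum. The AIC reported is the least-squares form
#' \eqn{n \ln(\mathrm{RSS}/n) + 2k} with \eqn{k} = number of free model
#' parameters + 1 for the noise scale.
#'
#' @param series List of \code{titration_series} sharing one probe
#'   concentration; each series must have at least 4 points.
#' @param ns_free If \code{TRUE} the nonspecific fraction is a free
#'   parameter; otherwise fixed at 0.
#' @param exclude Optional logical mask over the stacked points (in series
#'   order) marking points to leave out of the fit (e.g. outliers).
#' @param n_starts Number of deterministic multistart perturbations.
#' @return An object of class \code{binding_fit} with elements
#'   \code{params}, \code{std_errors}, \code{rss}, \code{n_points},
#'   \code{aic}, \code{ns_model}, \code{outlier_mask}, \code{converged}.
#' @export
fit_global <- function(series, ns_free = TRUE, exclude = NULL, n_starts = 5) {
  dat_all <- .stack_series(series)
  for (s in series)
    if (length(s$protein_conc) < 4L) stop("each series needs >= 4 points")
  if (is.null(exclude)) exclude <- rep(FALSE, nrow(dat_all))
  stopifnot(length(exclude) == nrow(dat_all))
  dat <- dat_all[!exclude, , drop = FALSE]
  probe <- series[[1]]$probe_conc

  a0_0 <- min(dat$anis)
  da_0 <- max(dat$anis) - min(dat$anis)
  if (da_0 <= 0) da_0 <- 1e-3
  half <- a0_0 + da_0 / 2
  kd_0 <- dat$prot[which.min(abs(dat$anis - half))]
  if (!is.finite(kd_0) || kd_0 <= 0) kd_0 <- stats::median(dat$prot[dat$prot > 0])

  # deterministic multistart: perturb K_D geometrically, dA mildly
  kd_mult <- c(1, 0.2, 5, 0.05, 20, 0.5, 2)[seq_len(max(1, n_starts))]
  lower <- c(k_d = 1e-6, a0 = -10, da = -10)
  upper <- c(k_d = 1e6, a0 = 10, da = 10)
  if (ns_free) {
    lower <- c(lower, ns = 0)
    upper <- c(upper, ns = 1 - 1e-9)
  }

  best <- NULL
  for (m in kd_mult) {
    start <- c(k_d = kd_0 * m, a0 = a0_0, da = da_0)
    if (ns_free) start <- c(start, ns = 0.01)
    start <- pmin(pmax(start, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = .binding_resid, dat = dat, probe = probe,
                         ns_free = ns_free,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(.binding_fit(NULL, NA, dat_all, exclude, ns_free, converged = FALSE))

  fit <- best$fit
  conv <- fit$info %in% 1:4
  par <- fit$par
  k_free <- length(par)
  n <- nrow(dat)
  rss <- best$rss
  # covariance from J'J at the optimum
  se <- rep(NA_real_, k_free)
  names(se) <- names(par)
  perfect <- rss <= 1e-20 * n  # numerically exact fit (noiseless data)
  if (perfect) {
    se[] <- 0
  } else if (n > k_free) {
    jtj <- fit$hessian
    cv <- tryCatch(solve(jtj) * rss / (n - k_free), error = function(e) NULL)
    if (!is.null(cv)) {
      dg <- diag(cv)
      se <- ifelse(dg >= 0, sqrt(dg), NA_real_)
      names(se) <- names(par)
    }
  }
  # flat-data identifiability guard: if dA is indistinguishable from 0 the
  # K_D is meaningless -- report non-convergence rather than a spurious fit
  if (perfect) {
    if (abs(par[["da"]]) < 1e-8) conv <- FALSE
  } else if (is.na(se[["da"]]) || abs(par[["da"]]) < 2 * se[["da"]]) {
    conv <- FALSE
  }

  params <- binding_params(par[["k_d"]], par[["a0"]], par[["da"]],
                           if (ns_free) par[["ns"]] else 0)
  .binding_fit(params, se, dat_all, exclude, ns_free, converged = conv,
               rss = rss)
}

.binding_fit <- function(params, se, dat_all, exclude, ns_free, converged,
                         rss = NA_real_) {
  n <- sum(!exclude)
  k <- if (ns_free) 5L else 4L  # free params + noise scale
  aic <- if (is.finite(rss) && rss > 0) n * log(rss / n) + 2 * k else NA_real_
  structure(list(params = params, std_errors = se, rss = rss,
                 n_points = n, aic = aic, ns_model = ns_free,
                 outlier_mask = exclude, converged = converged,
                 data = dat_all),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("binding_fit (%s, %s): n = %d, RSS = %.4g, AIC = %.2f\n",
              if (x$ns_model) "NS free" else "NS = 0",
              if (x$converged) "converged" else "NOT converged",
              x$n_points, x$rss, x$aic))
  if (!is.null(x$params)) {
    se <- x$std_errors
    cat(sprintf("  K_D = %.4g +/- %.2g uM\n", x$params$k_d, se[["k_d"]]))
    cat(sprintf("  A0  = %.4g +/- %.2g\n", x$params$a0, se[["a0"]]))
    cat(sprintf("  dA  = %.4g +/- %.2g\n", x$params$da, se[["da"]]))
    if (x$ns_model)
      cat(sprintf("  NS  = %.4g +/- %.2g\n", x$params$ns, se[["ns"]]))
  }
  invisible(x)
}

#' Choose between the NS-free and NS = 0 fits by AIC
#'
#' Compares the Akaike Information Criterion (least-squares form,
#' \eqn{n\ln(\mathrm{RSS}/n) + 2k}) of the fit with the nonspecific term
#' free against the fit with NS fixed at 0, on identical point sets.
#' The lower AIC wins; on a tie the simpler NS = 0 model is kept.
#'
#' @param fit_ns \code{binding_fit} with \code{ns_model = TRUE}.
#' @param fit_no_ns \code{binding_fit} with \code{ns_model = FALSE}.
#' @return A list: \code{fit} (the chosen \code{binding_fit}),
#'   \code{ns_selected} (logical), \code{delta_aic}
#'   (\code{aic_ns - aic_no_ns}), \code{aic_ns}, \code{aic_no_ns}.
#' @export
select_model <- function(fit_ns, fit_no_ns) {
  stopifnot(inherits(fit_ns, "binding_fit"), inherits(fit_no_ns, "binding_fit"))
  if (!fit_ns$ns_model || fit_no_ns$ns_model)
    stop("select_model expects (NS-free fit, NS = 0 fit) in that order")
  if (fit_ns$n_points != fit_no_ns$n_points ||
      !identical(fit_ns$outlier_mask, fit_no_ns$outlier_mask))
    stop("fits must be computed on identical point sets")
  delta <- fit_ns$aic - fit_no_ns$aic
  ns_sel <- is.finite(delta) && delta < 0  # tie (delta == 0) -> simpler model
  list(fit = if (ns_sel) fit_ns else fit_no_ns,
       ns_selected = ns_sel, delta_aic = delta,
       aic_ns = fit_ns$aic, aic_no_ns = fit_no_ns$aic)
}

#' Flag outlier points by studentized residuals
#'
#' Computes internally studentized residuals at the fitted optimum
#' (residual divided by \eqn{s\sqrt{1 - h_{ii}}}, leverages from the
#' Jacobian) and flags points with absolute value above \code{cutoff}.
#' This is a single screening pass: callers refit once on the reduced set
#' rather than iterating to exhaustion. If more than \code{max_frac} of
#' the points would be flagged the function refuses, signalling model
#' misfit rather than isolated outliers.
#'
#' @param fit A converged \code{binding_fit}.
#' @param series The series the fit was computed on.
#' @param cutoff Studentized-residual threshold (default 3).
#' @param max_frac Maximum tolerated flagged fraction (default 0.2).
#' @return Logical mask over the stacked points (TRUE = outlier).
#' @export
flag_outliers <- function(fit, series, cutoff = 3, max_frac = 0.2) {
  stopifnot(inherits(fit, "binding_fit"))
  if (!fit$converged) stop("flag_outliers requires a converged fit")
  dat <- .stack_series(series)
  probe <- series[[1]]$probe_conc
  keep <- !fit$outlier_mask
  d <- dat[keep, , drop = FALSE]
  p <- fit$params
  par <- c(k_d = p$k_d, a0 = p$a0, da = p$da)
  if (fit$ns_model) par <- c(par, ns = p$ns)
  res <- .binding_resid(par, d, probe, fit$ns_model)
  # numeric Jacobian of residuals wrt parameters
  J <- sapply(seq_along(par), function(j) {
    h <- max(1e-7, abs(par[j]) * 1e-7)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- max(pm[j] - h, if (names(par)[j] %in% c("k_d", "ns")) 0 else -Inf)
    (.binding_resid(pp, d, probe, fit$ns_model) -
       .binding_resid(pm, d, probe, fit$ns_model)) / (pp[j] - pm[j])
  })
  k <- length(par)
  n <- nrow(d)
  s2 <- sum(res^2) / max(n - k, 1)
  if (s2 <= 1e-20) return(fit$outlier_mask)  # exact fit: nothing to flag
  H <- J %*% tryCatch(solve(crossprod(J)), error = function(e) {
    .pinv(crossprod(J))
  }) %*% t(J)
  h <- pmin(pmax(diag(H), 0), 1 - 1e-8)
  rstud <- res / sqrt(s2 * (1 - h))
  flagged_local <- abs(rstud) > cutoff
  if (mean(flagged_local) > max_frac)
    stop(sprintf("%.0f%% of points exceed the outlier cutoff; this indicates model misfit, not outliers",
                 100 * mean(flagged_local)))
  mask <- fit$outlier_mask
  mask[keep] <- flagged_local
  mask
}

# Moore-Penrose pseudoinverse via svd (fallback for rank-deficient systems)
.pinv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Full binding analysis of one condition
#'
#' The complete per-condition pipeline: fit both the NS-free and NS = 0
#' models globally, select by AIC, screen the selected fit for outliers
#' (single pass, studentized residual > 3), and on any removal refit both
#' models on the reduced set and reselect.
#'
#' @param series List of \code{titration_series} for one oligo/condition.
#' @param ns One of \code{"auto"} (AIC selection), \code{"on"}, \code{"off"}.
#' @param outlier_pass If TRUE, run the single outlier screen + refit.
#' @return A list: \code{fit} (final \code{binding_fit}), \code{decision}
#'   (from \code{\link{select_model}}, or NULL when \code{ns != "auto"}),
#'   \code{fit_ns}, \code{fit_no_ns} (final-pass fits where computed),
#'   \code{outliers} (integer indices of removed points).
#' @export
fit_binding <- function(series, ns = c("auto", "on", "off"),
                        outlier_pass = TRUE) {
  ns <- match.arg(ns)
  run <- function(exclude) {
    if (ns == "on") {
      f <- fit_global(series, ns_free = TRUE, exclude = exclude)
      list(fit = f, decision = NULL, fit_ns = f, fit_no_ns = NULL)
    } else if (ns == "off") {
      f <- fit_global(series, ns_free = FALSE, exclude = exclude)
      list(fit = f, decision = NULL, fit_ns = NULL, fit_no_ns = f)
    } else {
      f1 <- fit_global(series, ns_free = TRUE, exclude = exclude)
      f0 <- fit_global(series, ns_free = FALSE, exclude = exclude)
      dec <- select_model(f1, f0)
      list(fit = dec$fit, decision = dec, fit_ns = f1, fit_no_ns = f0)
    }
  }
  first <- run(NULL)
  out <- first
  if (outlier_pass && first$fit$converged) {
    mask <- tryCatch(flag_outliers(first$fit, series), error = function(e) NULL)
    if (!is.null(mask) && any(mask)) out <- run(mask)
  }
  out$outliers <- which(out$fit$outlier_mask)
  out
}

#' Number of discrete PS stereoisomers of an n-mer
#'
#' A stereorandom phosphorothioate n-mer is a mixture of \eqn{2^{n-1}}
#' discrete Rp/Sp stereoisomers (one stereocenter per internucleotide
#' linkage).
#'
#' @param n Oligonucleotide length in nucleotides (>= 1).
#' @return \eqn{2^{n-1}} as a double (exact for n <= 53).
#' @export
stereoisomer_count <- function(n) {
  stopifnot(is.numeric(n), n >= 1, n == round(n))
  2^(n - 1)
}
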