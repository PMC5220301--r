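# PMF construction from mean-force samples, uncertainty propagation, and
# standard-state Kd / binding free energy.
#
# Convention note: the relation used throughout is
#   deltaG_bind = RT * ln(Kd / 1 M),
# which reproduces the canonical weak-dimer reference pair (5 mM at 300 K
# <-> -3.1 kcal/mol). Ka comes from the 1-D radial configurational integral
#   Ka = (1/V0) * Int_bound 4 pi r^2 exp(-W(r)/RT) dr,
# with V0 = 1.661 nm^3 the volume per molecule at the 1 M standard state.

#' @name thermo-constants
#' @title Thermodynamic constants
#' @description Gas constant in kcal/(mol K) and the 1 M standard-state
#'   volume per molecule in nm^3.
#' @export
GAS_CONSTANT_KCAL <- 1.9872e-3

#' @rdname thermo-constants
#' @export
STANDARD_STATE_VOLUME_NM3 <- 1.661

#' Mean-force profile container
#'
#' @param r strictly increasing grid of inter-monomer COM distances (nm).
#' @param force mean force at each grid point, kcal/(mol nm).
#' @param stderr pointwise standard error of the mean force (same units).
#' @return a `MeanForceProfile`.
#' @export
mean_force_profile <- function(r, force, stderr = rep(0, length(r))) {
  r <- as.numeric(r); force <- as.numeric(force); stderr <- as.numeric(stderr)
  if (length(r) < 3) stop("need at least 3 grid points")
  if (any(diff(r) <= 0)) stop("grid must be strictly increasing")
  if (length(force) != length(r) || length(stderr) != length(r))
    stop("force/stderr length must match grid")
  if (any(stderr < 0)) stop("standard errors must be non-negative")
  structure(list(r = r, force = force, stderr = stderr),
            class = "MeanForceProfile")
}

#' Read / write mean-force and PMF profiles as 3-column TSV
#' @param path TSV file with columns `r_nm`, `value`, `stderr`.
#' @return a `MeanForceProfile` ([read_mean_force()]) or `path`.
#' @export
read_mean_force <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  mean_force_profile(d[[1]], d[[2]], if (ncol(d) >= 3) d[[3]] else 0)
}

#' @rdname read_mean_force
#' @param profile a `MeanForceProfile` or `PMFProfile`.
#' @export
write_profile_tsv <- function(profile, path) {
  if (inherits(profile, "MeanForceProfile"))
    d <- data.frame(r_nm = profile$r, value = profile$force,
                    stderr = profile$stderr)
  else
    d <- data.frame(r_nm = profile$r, value = profile$W, stderr = profile$error)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Integrate a mean-force profile into a PMF
#'
#' `W(r) = -Int F dr` by the trapezoid rule, accumulated from the outer
#' (reference) edge of the grid inward, then shifted so the mean of `W` over
#' the reference window is zero. Pointwise error is the quadrature
#' accumulation of per-segment variances
#' `(dr/2)^2 (s_k^2 + s_{k+1}^2)` moving away from the reference edge, so it
#' is non-decreasing toward small `r`.
#'
#' @param profile a `MeanForceProfile`.
#' @param reference_from left edge of the reference (unbound) window (nm);
#'   the window runs to the end of the grid. A reference `d_COM > 4.6 nm`
#'   is the conventional unbound state for small GTPase dimers.
#' @return a `PMFProfile`: list with `r`, `W` (kcal/mol), `error`,
#'   `reference_window`.
#' @export
integrate_mean_force <- function(profile, reference_from = 4.6) {
  stopifnot(inherits(profile, "MeanForceProfile"))
  r <- profile$r; F <- profile$force; s <- profile$stderr
  n <- length(r)
  if (reference_from < r[1] || reference_from > r[n])
    stop("reference window must lie inside the grid")
  ref_idx <- which(r >= reference_from)
  if (length(ref_idx) < 1) stop("empty reference window")

  # trapezoid cumulative integral of F from the outer edge inward:
  # W(r_k) = -Int_{r_n}^{r_k} F dr = +Int_{r_k}^{r_n} F dr
  seg <- diff(r) / 2 * (F[-n] + F[-1])          # Int over [r_k, r_k+1]
  W <- c(rev(cumsum(rev(seg))), 0)              # W[k] = sum segs k..n-1
  W <- W - mean(W[ref_idx])

  segvar <- (diff(r) / 2)^2 * (s[-n]^2 + s[-1]^2)
  evar <- c(rev(cumsum(rev(segvar))), 0)        # accumulated from outer edge
  structure(list(r = r, W = W, error = sqrt(evar),
                 reference_window = c(reference_from, r[n])),
            class = "PMFProfile")
}

#' @export
print.PMFProfile <- function(x, ...) {
  cat(sprintf("PMFProfile: %d points on [%.2f, %.2f] nm, min W = %.2f kcal/mol\n",
              length(x$r), min(x$r), max(x$r), min(x$W)))
  invisible(x)
}

#' Local minima of a PMF
#'
#' A grid point is reported when it is a strict local minimum and its depth
#' — the smaller of the two flanking barrier heights (maximum of `W` between
#' the minimum and the grid edge or the next lower point on each side) minus
#' `W` at the minimum — is at least `depth_min`.
#'
#' @param pmf a `PMFProfile`.
#' @param depth_min minimum depth (kcal/mol).
#' @return data.frame with columns `r`, `W`, `depth`, sorted by `r`.
#' @export
find_minima <- function(pmf, depth_min = 0.2) {
  W <- pmf$W; r <- pmf$r; n <- length(W)
  if (n < 3) stop("need at least 3 grid points")
  out <- data.frame(r = numeric(0), W = numeric(0), depth = numeric(0))
  for (k in 2:(n - 1)) {
    if (!(W[k] < W[k - 1] && W[k] <= W[k + 1])) next
    # barrier on each side: highest point before W drops below W[k]
    lb <- k - 1
    while (lb > 1 && W[lb] >= W[k]) lb <- lb - 1
    rb <- k + 1
    while (rb < n && W[rb] >= W[k]) rb <- rb + 1
    left <- max(W[lb:(k - 1)]); right <- max(W[(k + 1):rb])
    depth <- min(left, right) - W[k]
    if (depth >= depth_min)
      out <- rbind(out, data.frame(r = r[k], W = W[k], depth = depth))
  }
  out[order(out$r), , drop = FALSE]
}

# default bound window: grid start to the first point past the principal
# minimum where W rises to -RT (thermal boundary of the well)
bound_window_from_w <- function(r, W, temperature) {
  RT <- GAS_CONSTANT_KCAL * temperature
  k_min <- which.min(W)
  k_up <- k_min
  while (k_up < length(r) && W[k_up] < -RT) k_up <- k_up + 1
  if (k_up == k_min && k_min < length(r)) k_up <- k_min + 1
  c(r[1], r[k_up])
}

#' Standard-state Kd and binding free energy from a PMF
#'
#' The association constant is the 1-D radial configurational integral
#' `Ka = (1/V0) Int_bound 4 pi r^2 exp(-W/RT) dr` with `V0 = 1.661 nm^3`
#' (one molecule per litre at 1 M); `Kd = 1/Ka` in molar and
#' `deltaG_bind = RT ln(Kd / 1 M)`. The reference window must be flat
#' (`max |W| < 0.2 kcal/mol`) for the unbound state to be meaningful. When
#' the profile carries force-derived pointwise errors, the Kd uncertainty is
#' propagated linearly through the (correlated) trapezoid weights.
#'
#' @param pmf a `PMFProfile` from [integrate_mean_force()].
#' @param bound_window `c(r_lo, r_hi)` in nm, or `NULL` for the default:
#'   from the grid start to the first point past the principal minimum where
#'   `W >= -RT`.
#' @param temperature K.
#' @param jacobian `"radial"` (4 pi r^2 volume element; default) or
#'   `"none"` (unit 1 nm^2 cross-section, for comparison only).
#' @param force_stderr optional vector of per-point mean-force standard
#'   errors (from the profile that generated the PMF). When given, the Kd
#'   uncertainty is propagated parametrically: force noise is resampled,
#'   re-integrated and pushed through the same windowing and integral, so
#'   the reported standard error includes the window-selection sensitivity.
#' @param n_resample resamples for the parametric error propagation.
#' @return a `BindingEstimate`: list with `kd` (molar), `dg` (kcal/mol),
#'   `kd_stderr` (molar, when errors supplied), `temperature`,
#'   `bound_window`, `minima`.
#' @export
kd_from_pmf <- function(pmf, bound_window = NULL, temperature = 300,
                        jacobian = c("radial", "none"), force_stderr = NULL,
                        n_resample = 200) {
  jacobian <- match.arg(jacobian)
  stopifnot(inherits(pmf, "PMFProfile"))
  r <- pmf$r; W <- pmf$W
  RT <- GAS_CONSTANT_KCAL * temperature
  ref_idx <- which(r >= pmf$reference_window[1])
  if (max(abs(W[ref_idx])) >= 0.2)
    stop("reference window is not flat (max |W| >= 0.2 kcal/mol); ",
         "extend the profile to larger separations")
  window_given <- !is.null(bound_window)

  kd_of <- function(Wv, bw) {
    if (bw[1] < r[1] - 1e-9 || bw[2] > r[length(r)] + 1e-9)
      stop("bound window outside grid")
    keep <- r >= bw[1] - 1e-9 & r <= bw[2] + 1e-9
    if (sum(keep) < 2) stop("bound window contains fewer than 2 grid points")
    rb <- r[keep]; Wb <- Wv[keep]
    jac <- if (jacobian == "radial") 4 * pi * rb^2 else rep(1, length(rb))
    g <- jac * exp(-Wb / RT)
    vol <- sum(diff(rb) / 2 * (g[-length(g)] + g[-1]))   # nm^3
    STANDARD_STATE_VOLUME_NM3 / vol
  }

  if (!window_given) bound_window <- bound_window_from_w(r, W, temperature)
  kd <- kd_of(W, bound_window)

  kd_stderr <- NA_real_
  if (!is.null(force_stderr) && any(force_stderr > 0)) {
    n <- length(r)
    kd_stderr <- with_seed(20109L, {
      reps <- vapply(seq_len(n_resample), function(b) {
        eps <- rnorm(n, 0, force_stderr)
        dseg <- diff(r) / 2 * (eps[-n] + eps[-1])
        dW <- c(rev(cumsum(rev(dseg))), 0)
        dW <- dW - mean(dW[ref_idx])
        Wb <- W + dW
        bw <- if (window_given) bound_window
          else bound_window_from_w(r, Wb, temperature)
        kd_of(Wb, bw)
      }, numeric(1))
      sd(reps)
    })
  }

  structure(list(kd = kd, dg = dg_from_kd(kd, temperature),
                 kd_stderr = kd_stderr, temperature = temperature,
                 bound_window = bound_window,
                 minima = find_minima(pmf, depth_min = 0)),
            class = "BindingEstimate")
}

#' @export
print.BindingEstimate <- function(x, ...) {
  cat(sprintf("BindingEstimate: Kd = %.3g M (deltaG = %.2f kcal/mol at %g K), bound [%.2f, %.2f] nm\n",
              x$kd, x$dg, x$temperature, x$bound_window[1], x$bound_window[2]))
  invisible(x)
}

#' Convert between Kd and binding free energy
#'
#' `deltaG_bind = RT ln(Kd / 1 M)` and its inverse. At 300 K a 5 mM
#' dissociation constant corresponds to -3.1 kcal/mol.
#'
#' @param kd dissociation constant, molar.
#' @param temperature K.
#' @return kcal/mol ([dg_from_kd()]) or molar ([kd_from_dg()]).
#' @export
dg_from_kd <- function(kd, temperature = 300) {
  if (any(kd <= 0)) stop("Kd must be positive")
  GAS_CONSTANT_KCAL * temperature * log(kd)
}

#' @rdname dg_from_kd
#' @param dg binding free energy, kcal/mol.
#' @export
kd_from_dg <- function(dg, temperature = 300) {
  exp(dg / (GAS_CONSTANT_KCAL * temperature))
}

#' Fold-difference in affinity between two binding estimates
#'
#' @param estimate_a,estimate_b `BindingEstimate`s (or lists with `kd` and
#'   `temperature`). A ratio > 1 means `a` binds more strongly.
#' @return `Kd_b / Kd_a` (dimensionless).
#' @export
fold_ratio <- function(estimate_a, estimate_b) {
  if (!isTRUE(all.equal(estimate_a$temperature, estimate_b$temperature)))
    stop("estimates must be at the same temperature")
  estimate_b$kd / estimate_a$kd
}
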