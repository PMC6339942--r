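#' Exponential restitution parameters
#'
#' Rate dependence of conduction velocity (CV) and effective refractory
#' period (ERP) is modeled as an exponential approach to an asymptote,
#' `value(BCL) = A - B * exp(-BCL / C)`, where BCL is the basic cycle length
#' (time since the node's previous activation, ms). `A` is the long-BCL
#' asymptote (mm/s for CV, ms for ERP), `B` the decay amplitude and `C` the
#' decay constant in ms. BCL values outside the declared validity range are
#' clamped; the curves are fits and not valid as `BCL -> 0`.
#'
#' @param A asymptotic value (mm/s for CV, ms for ERP), `> 0`.
#' @param B decay amplitude (same units as `A`).
#' @param C decay constant, ms, `> 0`.
#' @param quantity `"CV"` or `"ERP"`.
#' @param bcl_range validity range `[BCLmin, BCLmax]` in ms used to verify
#'   positivity.
#' @return an object of class `restitution_params`.
#' @export
restitution_params <- function(A, B, C, quantity = c("CV", "ERP"),
                               bcl_range = c(200, 1000)) {
  quantity <- match.arg(quantity)
  if (C <= 0) stop("decay constant C must be > 0")
  if (A <= 0) stop("asymptote A must be > 0")
  if (A - B * exp(-bcl_range[1] / C) <= 0) {
    stop("restitution curve non-positive at BCLmin")
  }
  structure(list(A = A, B = B, C = C, quantity = quantity),
            class = "restitution_params")
}

resti_eval <- function(params, bcl, bcl_range) {
  if (any(!is.finite(bcl))) stop("non-finite BCL")
  bcl <- pmin(pmax(bcl, bcl_range[1]), bcl_range[2])
  params$A - params$B * exp(-bcl / params$C)
}

#' Evaluate restitution curves
#'
#' `cv_at` returns conduction velocity in mm/s, `erp_at` the effective
#' refractory period in ms, both at the given BCL (clamped to the validity
#' range). For `B >= 0` the curves are monotone non-decreasing in BCL.
#'
#' @param params a `restitution_params` of the matching quantity.
#' @param bcl basic cycle length, ms (vectorised).
#' @param bcl_range clamping range, ms.
#' @return numeric vector.
#' @export
cv_at <- function(params, bcl, bcl_range = c(200, 1000)) {
  if (params$quantity != "CV") stop("params are not a CV curve")
  resti_eval(params, bcl, bcl_range)
}

#' @rdname cv_at
#' @export
erp_at <- function(params, bcl, bcl_range = c(200, 1000)) {
  if (params$quantity != "ERP") stop("params are not an ERP curve")
  resti_eval(params, bcl, bcl_range)
}

#' Substrate configuration
#'
#' Per-region electrophysiological substrate: CV and ERP restitution curves
#' plus the anisotropy ratio `k` (the tensor eigenvalue along the fiber;
#' along-fiber speed exceeds cross-fiber speed by `sqrt(k)`). Every region
#' label used by a mesh must have an entry or fall back to the declared
#' default region.
#'
#' @param regions named list; each element is a list with components `cv`
#'   and `erp` (each either a `restitution_params` or a list/vector with
#'   `A`, `B`, `C`) and `k >= 1`.
#' @param default name of the fallback region entry.
#' @param bcl_range global BCL validity range, ms.
#' @param name optional preset name.
#' @return an object of class `substrate_config`.
#' @export
substrate_config <- function(regions, default = names(regions)[1],
                             bcl_range = c(200, 1000), name = NULL) {
  stopifnot(length(regions) >= 1L, !is.null(names(regions)))
  regions <- lapply(regions, function(r) {
    if (is.null(r$k)) r$k <- 1
    if (r$k < 1) stop("anisotropy ratio k must be >= 1")
    for (q in c("cv", "erp")) {
      v <- r[[q]]
      if (!inherits(v, "restitution_params")) {
        v <- as.list(v)
        if (is.null(v$B)) v$B <- 0
        if (is.null(v$C)) v$C <- 1
        r[[q]] <- restitution_params(v$A, v$B, v$C,
                                     quantity = toupper(q),
                                     bcl_range = bcl_range)
      }
    }
    r
  })
  if (!default %in% names(regions)) stop("default region not in regions")
  structure(list(regions = regions, default = default,
                 bcl_range = bcl_range, name = name),
            class = "substrate_config")
}

cfg_region <- function(cfg, label) {
  r <- cfg$regions[[label]]
  if (is.null(r)) r <- cfg$regions[[cfg$default]]
  r
}

#' Wavelength at a BCL
#'
#' The reentry wavelength WL = CV(BCL) * ERP(BCL) in mm (mm/ms times ms):
#' the minimal circuit length able to sustain reentry at that rate.
#'
#' @param cfg a `substrate_config`.
#' @param region region label (must be known or covered by the default).
#' @param bcl basic cycle length, ms.
#' @return wavelength in mm.
#' @export
wavelength_at <- function(cfg, region, bcl) {
  if (!region %in% names(cfg$regions)) stop("unknown region: ", region)
  r <- cfg$regions[[region]]
  cv_at(r$cv, bcl, cfg$bcl_range) / 1000 * erp_at(r$erp, bcl, cfg$bcl_range)
}

#' Fit an exponential restitution curve
#'
#' Nonlinear least-squares fit of `A - B * exp(-BCL/C)` to sampled
#' (BCL, value) pairs, via Gauss-Newton with Levenberg damping.
#' Initialisation: `A0 = max(value)`, `B0 = max - min`, `C0 = range/3`.
#'
#' @param bcl sampled basic cycle lengths, ms (`>= 4` distinct values).
#' @param value measured CV (mm/s) or ERP (ms).
#' @param quantity `"CV"` or `"ERP"`.
#' @param max_iter iteration cap.
#' @return a `restitution_params` with attributes `residual_norm` and
#'   `converged`.
#' @export
fit_restitution <- function(bcl, value, quantity = c("CV", "ERP"),
                            max_iter = 200) {
  quantity <- match.arg(quantity)
  if (length(bcl) < 4L) stop("need at least 4 samples")
  if (length(unique(bcl)) < 3L) stop("degenerate samples: constant BCL")
  A <- max(value)
  B <- max(value) - min(value)
  C <- diff(range(bcl)) / 3
  if (B < 1e-12) B <- 1e-6
  th <- c(A, B, C)
  res_fun <- function(th) th[1] - th[2] * exp(-bcl / th[3]) - value
  lambda <- 1e-3
  r <- res_fun(th)
  cost <- sum(r^2)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    e <- exp(-bcl / th[3])
    J <- cbind(1, -e, -th[2] * e * bcl / th[3]^2)
    g <- crossprod(J, r)
    H <- crossprod(J)
    step <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12), -g),
                     error = function(e) NULL)
    if (is.null(step)) { lambda <- lambda * 10; next }
    th2 <- th + as.numeric(step)
    th2[3] <- max(th2[3], 1e-6)
    r2 <- res_fun(th2)
    cost2 <- sum(r2^2)
    if (cost2 < cost) {
      rel <- (cost - cost2) / max(cost, 1e-300)
      th <- th2; r <- r2; cost <- cost2
      lambda <- max(lambda / 5, 1e-12)
      if (rel < 1e-14 || cost < 1e-24) { conv <- TRUE; break }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e12) { conv <- sum(g^2) < 1e-12; break }
    }
  }
  if (!conv && sum(crossprod(J, r)^2) < 1e-8 * max(1, cost)) conv <- TRUE
  if (!conv) warning("restitution fit did not converge")
  out <- restitution_params(th[1], th[2], th[3], quantity = quantity,
                            bcl_range = range(bcl))
  attr(out, "residual_norm") <- sqrt(cost)
  attr(out, "converged") <- conv
  out
}

#' BCL sampling grid linear in frequency
#'
#' The standard restitution protocol samples `n` BCLs between `lo` and `hi`
#' ms spaced linearly in frequency (1/BCL).
#' @param n number of samples.
#' @param lo,hi BCL range, ms.
#' @return numeric vector of BCLs, ms, increasing.
#' @export
bcl_grid_freq <- function(n = 50, lo = 200, hi = 1000) {
  sort(1 / seq(1 / hi, 1 / lo, length.out = n))
}

#' Illustrative substrate presets
#'
#' Ships small parameter sets for demonstrations and tests. The values are
#' ILLUSTRATIVE: they reproduce the qualitative behaviour of published atrial
#' restitution data (ERP plateaus in the 250-330 ms range, control CV around
#' 450-700 mm/s, slower remodeled substrates) but are not fitted to any
#' particular measurement; scientific use requires an explicit
#' [substrate_config()].
#'
#' @param preset one of `"uniform"` (constant CV 700 mm/s, ERP 250 ms,
#'   isotropic), `"clinical_example"` (constant CV 650 mm/s, ERP 250 ms),
#'   `"control"` (restituting CV with plateau 454 mm/s, ERP plateau 318 ms),
#'   `"caf_like"` (shortened ERP, slowed CV, chronic-AF-like).
#' @param k anisotropy ratio applied to the base region.
#' @return a `substrate_config`.
#' @export
default_substrate <- function(preset = c("uniform", "clinical_example",
                                         "control", "caf_like"), k = 1) {
  preset <- match.arg(preset)
  base <- switch(preset,
    uniform = list(cv = list(A = 700, B = 0, C = 1),
                   erp = list(A = 250, B = 0, C = 1), k = k),
    clinical_example = list(cv = list(A = 650, B = 0, C = 1),
                            erp = list(A = 250, B = 0, C = 1), k = k),
    control = list(cv = list(A = 454, B = 120, C = 180),
                   erp = list(A = 318, B = 90, C = 200), k = k),
    caf_like = list(cv = list(A = 380, B = 60, C = 150),
                    erp = list(A = 210, B = 40, C = 160), k = k))
  substrate_config(list(default = base), default = "default",
                   name = paste0("illustrative_", preset))
}
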