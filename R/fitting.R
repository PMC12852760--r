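## Relaxation fitting: the joint dual-polarity steady-state model, plain
## monoexponential decays, B1 nutation curves and pixel-wise maps.
##
## The steady-state decay model fitted jointly to the +Z and -Z curves is
##   SI_{+/-Z}(t) = SI0_{+/-Z} exp(-R t) - S_SS (1 - exp(-R t))
## with shared R and S_SS. Given R the model is linear in
## (SI0_plus, SI0_minus, S_SS), so all fits use variable projection: the
## profiled residual sum of squares is scanned over a deterministic log-spaced
## R grid and refined by golden-section search, making the fit deterministic
## and immune to local minima of the full nonlinear problem.

ss_design <- function(tt, R) {
  e <- exp(-R * tt)
  n <- length(tt)
  z <- numeric(n)
  rbind(cbind(e, z, -(1 - e)),
        cbind(z, e, -(1 - e)))
}

# deterministic 1-D profile minimisation over R
profile_min <- function(rss_fun, lower = 1e-3, upper = 1e4, n_grid = 200) {
  grid <- exp(seq(log(lower), log(upper), length.out = n_grid))
  vals <- vapply(grid, rss_fun, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(rss_fun, c(lo, hi), tol = 1e-13)
  list(R = opt$minimum, rss = opt$objective,
       at_bound = i %in% c(1L, n_grid))
}

split_curves <- function(curve_plus, curve_minus) {
  if (is.null(curve_minus)) {
    if (!("polarity" %in% names(curve_plus)))
      stop("fit_ss_model: provide curve_minus or a decay_curves tibble with a polarity column")
    cp <- curve_plus[curve_plus$polarity == "+Z", ]
    cm <- curve_plus[curve_plus$polarity == "-Z", ]
  } else {
    cp <- curve_plus
    cm <- curve_minus
  }
  list(cp = cp, cm = cm)
}

#' Fit the dual-polarity steady-state decay model
#'
#' Jointly fits \eqn{SI_{\pm Z}(t) = SI_{0,\pm Z} e^{-Rt} - S_{SS}(1-e^{-Rt})}
#' to a pair of +Z / -Z decay curves sharing one time grid, by least squares
#' over \eqn{(R, SI_{0,+}, SI_{0,-}, S_{SS})}. R is constrained to
#' `[0, 1e4]` 1/s. The fit is deterministic (variable projection with a fixed
#' search grid).
#'
#' @param curve_plus either a `decay_curves` tibble (from
#'   [simulate_decay_curves()] or built manually with columns `time`,
#'   `signal`, `polarity`) containing both polarities, or a data frame with
#'   `time` and `signal` for the +Z curve.
#' @param curve_minus the -Z curve (`time`, `signal`), if not supplied via
#'   `curve_plus`.
#' @param fix_ss0 if `TRUE`, fixes `S_SS = 0` (the model then nests the plain
#'   monoexponential decay).
#' @return An object of class `raff_ss_fit`: list with `R` (1/s), `SI0_plus`,
#'   `SI0_minus`, `S_SS`, `SS_fraction` (`S_SS / SI0_plus`), `residual_norm`,
#'   `converged`, and the fitted data.
#' @examples
#' tt <- seq(0, 0.144, length.out = 33)
#' si <- function(s0) s0 * exp(-3.83 * tt) + 0.69 * (1 - exp(-3.83 * tt))
#' fit <- fit_ss_model(data.frame(time = tt, signal = si(1)),
#'                     data.frame(time = tt, signal = si(-1)))
#' fit$R
#' @export
fit_ss_model <- function(curve_plus, curve_minus = NULL, fix_ss0 = FALSE) {
  sc <- split_curves(curve_plus, curve_minus)
  tt <- sc$cp$time
  if (length(tt) < 3) stop("fit_ss_model: need at least 3 time points")
  if (length(sc$cm$time) != length(tt) ||
      any(abs(sc$cm$time - tt) > 1e-12 * max(1, max(abs(tt)))))
    stop("fit_ss_model: +Z and -Z curves must share the same time grid")
  y <- c(sc$cp$signal, sc$cm$signal)
  rss_fun <- function(R) {
    X <- ss_design(tt, R)
    if (fix_ss0) X <- X[, 1:2, drop = FALSE]
    cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(cf)) return(sum(y^2))
    sum((X %*% cf - y)^2)
  }
  pm <- profile_min(rss_fun)
  X <- ss_design(tt, pm$R)
  if (fix_ss0) X <- X[, 1:2, drop = FALSE]
  cf <- unname(qr.solve(X, y))
  s_ss <- if (fix_ss0) 0 else cf[3]
  structure(list(
    R = unname(pm$R),
    SI0_plus = cf[1], SI0_minus = cf[2], S_SS = s_ss,
    SS_fraction = if (abs(cf[1]) > 0) s_ss / cf[1] else NA_real_,
    residual_norm = sqrt(pm$rss),
    converged = !pm$at_bound && is.finite(pm$rss),
    data = tibble::tibble(time = rep(tt, 2), signal = y,
                          polarity = rep(c("+Z", "-Z"), each = length(tt)))
  ), class = "raff_ss_fit")
}

#' @export
print.raff_ss_fit <- function(x, ...) {
  cat(sprintf("<raff_ss_fit> R = %.4g 1/s, SS fraction = %.4g (|%.4g|), converged: %s\n",
              x$R, x$SS_fraction, abs(x$SS_fraction), x$converged))
  invisible(x)
}

#' Fit a monoexponential decay
#'
#' Least-squares fit of \eqn{S(t) = S_0 e^{-t/T}} by variable projection over
#' the rate `1/T`. For degenerate input (effectively constant signal) the fit
#' hits the rate bound and is flagged not converged with `T = Inf`.
#'
#' @param curve a data frame with columns `time` and `signal`, or a numeric
#'   vector of signals with `times` supplied.
#' @param times time grid (s) when `curve` is a bare numeric vector.
#' @return An object of class `raff_monoexp_fit`: `T` (s), `S0`,
#'   `residual_norm`, `converged`.
#' @export
fit_monoexp <- function(curve, times = NULL) {
  if (is.numeric(curve) && !is.null(times)) {
    tt <- times; y <- curve
  } else {
    tt <- curve$time; y <- curve$signal
  }
  if (length(tt) < 3) stop("fit_monoexp: need at least 3 time points")
  if (all(y == 0)) stop("fit_monoexp: all-zero signal")
  rss_fun <- function(R) {
    e <- exp(-R * tt)
    a <- sum(e * y) / sum(e * e)
    sum((a * e - y)^2)
  }
  pm <- profile_min(rss_fun, lower = 1e-4, upper = 1e5)
  e <- exp(-pm$R * tt)
  s0 <- sum(e * y) / sum(e * e)
  converged <- !pm$at_bound
  structure(list(
    T = if (converged) 1 / pm$R else Inf,
    R = pm$R, S0 = s0,
    residual_norm = sqrt(pm$rss),
    converged = converged
  ), class = "raff_monoexp_fit")
}

#' @export
print.raff_monoexp_fit <- function(x, ...) {
  cat(sprintf("<raff_monoexp_fit> T = %.4g s, S0 = %.4g, converged: %s\n",
              x$T, x$S0, x$converged))
  invisible(x)
}

#' Fit a B1 nutation curve
#'
#' Fits \eqn{S(t) = A \cos(2\pi f t)} to a hard-pulse nutation experiment and
#' returns the nutation frequency `f` in Hz (the effective B1 amplitude). The
#' frequency is profiled over a deterministic grid and refined; the amplitude
#' is solved linearly.
#'
#' @param durations pulse durations (s), at least 4 spanning at least half a
#'   nutation period.
#' @param signals measured signals at each duration.
#' @param f_range frequency search range (Hz).
#' @return A list with `b1_hz`, `amplitude`, `residual_norm`, `converged`.
#' @export
fit_b1_nutation <- function(durations, signals, f_range = c(50, 5000)) {
  if (length(durations) < 4) stop("fit_b1_nutation: need at least 4 points")
  if (length(signals) != length(durations))
    stop("fit_b1_nutation: durations and signals must have equal length")
  rss_fun <- function(f) {
    cf <- cos(2 * pi * f * durations)
    a <- sum(cf * signals) / sum(cf * cf)
    sum((a * cf - signals)^2)
  }
  grid <- seq(f_range[1], f_range[2], length.out = 2000)
  vals <- vapply(grid, rss_fun, numeric(1))
  i <- which.min(vals)
  opt <- stats::optimize(rss_fun, c(grid[max(1, i - 1)], grid[min(2000, i + 1)]),
                         tol = 1e-10)
  cf <- cos(2 * pi * opt$minimum * durations)
  a <- sum(cf * signals) / sum(cf * cf)
  if (max(durations) * opt$minimum < 0.5)
    warning("fit_b1_nutation: durations span less than half a nutation period")
  list(b1_hz = opt$minimum, amplitude = a,
       residual_norm = sqrt(opt$objective),
       converged = !(i %in% c(1L, 2000L)))
}

## ---------------------------------------------------------------------------
## Pixel-wise maps

new_relax_map <- function(values, ss, s0, valid, method_label, units) {
  structure(list(values = values, ss = ss, s0 = s0, valid = valid,
                 method_label = method_label, units = units),
            class = "relax_map")
}

#' Pixel-wise relaxation mapping
#'
#' Fits every in-mask pixel of an image stack independently, either with the
#' monoexponential decay model or with the joint dual-polarity steady-state
#' model (supply the -Z stack via `paired_stack`). Out-of-mask or
#' non-converged pixels are `NA` in the returned maps. Fitting is vectorised:
#' the profiled residual over the shared rate grid is computed for all pixels
#' at once, followed by a per-pixel deterministic refinement, so results do
#' not depend on pixel ordering.
#'
#' @param image_stack numeric 3-D array, time x rows x cols.
#' @param times acquisition time grid (s), length `dim(image_stack)[1]`.
#' @param model `"monoexp"` or `"ss_model"`.
#' @param mask logical rows x cols matrix of pixels to fit; default all.
#' @param paired_stack the -Z image stack for `"ss_model"`.
#' @param method_label label stored in the map.
#' @return A `relax_map`: list with `values` (fitted relaxation time T, s),
#'   `ss` (steady-state fraction map for `"ss_model"`, else `NULL`), `s0`,
#'   `valid` (logical matrix), `method_label` and `units`.
#' @export
fit_map <- function(image_stack, times, model = c("monoexp", "ss_model"),
                    mask = NULL, paired_stack = NULL, method_label = "map") {
  model <- match.arg(model)
  d <- dim(image_stack)
  if (length(d) != 3 || d[1] != length(times))
    stop("fit_map: image_stack must be time x rows x cols with matching times")
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  if (!all(dim(mask) == d[2:3])) stop("fit_map: mask shape must match image shape")
  if (model == "ss_model") {
    if (is.null(paired_stack)) stop("fit_map: ss_model requires paired_stack (-Z)")
    if (!all(dim(paired_stack) == d)) stop("fit_map: paired_stack shape mismatch")
  }
  npx <- sum(mask)
  vals <- ssm <- s0m <- matrix(NA_real_, d[2], d[3])
  valid <- matrix(FALSE, d[2], d[3])
  if (npx == 0) {
    return(new_relax_map(vals, if (model == "ss_model") ssm else NULL,
                         s0m, valid, method_label, "s"))
  }
  flat <- matrix(image_stack, nrow = d[1])          # time x (rows*cols)
  idx <- which(as.vector(mask))
  Y <- flat[, idx, drop = FALSE]
  if (model == "ss_model") {
    Y <- rbind(Y, matrix(paired_stack, nrow = d[1])[, idx, drop = FALSE])
  }
  grid <- exp(seq(log(1e-2), log(1e4), length.out = 200))
  best_rss <- rep(Inf, length(idx))
  best_i <- rep(1L, length(idx))
  yss <- colSums(Y^2)
  for (gi in seq_along(grid)) {
    X <- if (model == "monoexp") cbind(exp(-grid[gi] * times))
         else ss_design(times, grid[gi])
    qrX <- qr(X)
    Q <- qr.Q(qrX)
    rss <- pmax(yss - colSums((crossprod(Q, Y))^2), 0)
    upd <- rss < best_rss
    best_rss[upd] <- rss[upd]
    best_i[upd] <- gi
  }
  res_T <- res_ss <- res_s0 <- rep(NA_real_, length(idx))
  res_ok <- rep(FALSE, length(idx))
  for (p in seq_along(idx)) {
    y <- Y[, p]
    rss_fun <- if (model == "monoexp") {
      function(R) { e <- exp(-R * times); a <- sum(e * y) / sum(e * e)
                    sum((a * e - y)^2) }
    } else {
      function(R) { X <- ss_design(times, R)
                    cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
                    if (is.null(cf)) return(sum(y^2))
                    sum((X %*% cf - y)^2) }
    }
    i0 <- best_i[p]
    lo <- grid[max(1L, i0 - 1L)]
    hi <- grid[min(length(grid), i0 + 1L)]
    opt <- stats::optimize(rss_fun, c(lo, hi), tol = 1e-13)
    R <- opt$minimum
    if (model == "monoexp") {
      e <- exp(-R * times)
      res_s0[p] <- sum(e * y) / sum(e * e)
    } else {
      cf <- unname(qr.solve(ss_design(times, R), y))
      res_s0[p] <- cf[1]
      res_ss[p] <- if (abs(cf[1]) > 0) abs(cf[3] / cf[1]) else NA_real_
    }
    res_T[p] <- 1 / R
    res_ok[p] <- !(i0 %in% c(1L, length(grid)))
  }
  vals[idx] <- ifelse(res_ok, res_T, NA_real_)
  s0m[idx] <- res_s0
  valid[idx] <- res_ok
  if (model == "ss_model") ssm[idx] <- res_ss
  new_relax_map(vals, if (model == "ss_model") ssm else NULL, s0m, valid,
                method_label, "s")
}

#' @export
print.relax_map <- function(x, ...) {
  cat(sprintf("<relax_map> %s: %d x %d pixels, %d fitted, median T = %.4g %s\n",
              x$method_label, nrow(x$values), ncol(x$values), sum(x$valid),
              stats::median(x$values[x$valid]), x$units))
  invisible(x)
}

## ---------------------------------------------------------------------------
## broom-style methods

#' Tidy methods for fit objects and maps
#'
#' `tidy()` returns one row per parameter (fits) or per pixel (maps);
#' `glance()` returns a one-row model summary.
#'
#' @param x a `raff_ss_fit`, `raff_monoexp_fit` or `relax_map`.
#' @param ... unused.
#' @name raffsim-tidiers
NULL

#' @rdname raffsim-tidiers
#' @exportS3Method generics::tidy
tidy.raff_ss_fit <- function(x, ...) {
  tibble::tibble(
    term = c("R", "SI0_plus", "SI0_minus", "S_SS", "SS_fraction"),
    estimate = c(x$R, x$SI0_plus, x$SI0_minus, x$S_SS, x$SS_fraction))
}

#' @rdname raffsim-tidiers
#' @exportS3Method generics::glance
glance.raff_ss_fit <- function(x, ...) {
  tibble::tibble(R = x$R, SS_fraction = x$SS_fraction,
                 residual_norm = x$residual_norm, converged = x$converged)
}

#' @rdname raffsim-tidiers
#' @exportS3Method generics::tidy
tidy.raff_monoexp_fit <- function(x, ...) {
  tibble::tibble(term = c("T", "S0"), estimate = c(x$T, x$S0))
}

#' @rdname raffsim-tidiers
#' @exportS3Method generics::glance
glance.raff_monoexp_fit <- function(x, ...) {
  tibble::tibble(T = x$T, S0 = x$S0, residual_norm = x$residual_norm,
                 converged = x$converged)
}

#' @rdname raffsim-tidiers
#' @exportS3Method generics::tidy
tidy.relax_map <- function(x, ...) {
  d <- dim(x$values)
  out <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(x$values),
    valid = as.vector(x$valid))
  if (!is.null(x$ss)) out$ss <- as.vector(x$ss)
  out
}
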