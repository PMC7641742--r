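## Circular-dichroism analyses: two-component population decomposition of a
## mixture spectrum and baseline-based melting-temperature extraction.

#' CD spectrum and melting-curve containers
#'
#' A `cd_spectrum` is a wavelength (nm) / molar-ellipticity series; a
#' `melt_curve` is a temperature (deg C) / ellipticity series recorded at a
#' fixed wavelength (conventionally 295 nm for quadruplexes). Both require
#' a strictly increasing grid.
#'
#' @param wavelength,temperature Strictly increasing numeric grid.
#' @param ellipticity Ellipticity values (arbitrary molar units).
#' @return An object of class `cd_spectrum` / `melt_curve`.
#' @export
cd_spectrum <- function(wavelength, ellipticity) {
  stopifnot(length(wavelength) == length(ellipticity),
            all(diff(wavelength) > 0))
  structure(data.frame(wavelength = wavelength, ellipticity = ellipticity),
            class = c("cd_spectrum", "data.frame"))
}

#' @rdname cd_spectrum
#' @export
melt_curve <- function(temperature, ellipticity) {
  stopifnot(length(temperature) == length(ellipticity),
            all(diff(temperature) > 0))
  structure(data.frame(temperature = temperature, ellipticity = ellipticity),
            class = c("melt_curve", "data.frame"))
}

.common_grid <- function(...) {
  specs <- list(...)
  lo <- max(vapply(specs, function(s) min(s$wavelength), 0))
  hi <- min(vapply(specs, function(s) max(s$wavelength), 0))
  if (lo >= hi) stop("spectra have no common wavelength support")
  grid <- sort(unique(unlist(lapply(specs, function(s)
    s$wavelength[s$wavelength >= lo & s$wavelength <= hi]))))
  lapply(specs, function(s)
    stats::approx(s$wavelength, s$ellipticity, xout = grid)$y)
}

#' Two-component population decomposition of a CD spectrum
#'
#' Models the mixture spectrum as a convex combination
#' `w1 * comp1 + w2 * comp2` with `w1 + w2 = 1` and `w1, w2 >= 0`, and
#' returns the least-squares weights (the estimated populations of the two
#' folded forms) plus the residual norm. Spectra are linearly interpolated
#' onto their common wavelength support before fitting. With the pure-form
#' spectra of the two PIM1 constructs as components, this is the estimator
#' behind the 81%/19% Form 1 / Form 2 population split of the natural
#' mixed sequence.
#'
#' @param mixture,comp1,comp2 [cd_spectrum()] objects.
#' @return Named list `w1`, `w2`, `residual` (L2 norm of the fit
#'   residual).
#' @export
decompose_two_state <- function(mixture, comp1, comp2) {
  g <- .common_grid(mixture, comp1, comp2)
  m <- g[[1]]; c1 <- g[[2]]; c2 <- g[[3]]
  d <- c1 - c2
  if (sqrt(mean(d^2)) < 1e-10 * max(1, sqrt(mean(c1^2))))
    stop("component spectra are (numerically) identical: degenerate design")
  # minimize ||m - c2 - w d||^2 over w in [0, 1]
  w1 <- sum((m - c2) * d) / sum(d * d)
  w1 <- min(1, max(0, w1))
  resid <- m - (w1 * c1 + (1 - w1) * c2)
  list(w1 = w1, w2 = 1 - w1, residual = sqrt(sum(resid^2)))
}

#' Folded / unfolded baselines of a melting curve
#'
#' Fits least-squares lines to the ellipticity over a low-temperature
#' window (completely folded state) and a high-temperature window
#' (completely unfolded state). Windows must not overlap and must each
#' contain at least 3 grid points.
#'
#' @param curve A [melt_curve()].
#' @param low_window,high_window Length-2 numeric ranges (deg C).
#' @return List with `folded` and `unfolded`, each `c(intercept, slope)`.
#' @export
fit_baselines <- function(curve, low_window, high_window) {
  stopifnot(length(low_window) == 2, length(high_window) == 2)
  if (max(low_window) > min(high_window))
    stop("baseline windows overlap")
  fit1 <- function(win) {
    sel <- curve$temperature >= win[1] & curve$temperature <= win[2]
    if (sum(sel) < 3)
      stop("baseline window [", win[1], ", ", win[2],
           "] contains fewer than 3 points")
    stats::coef(stats::lm(ellipticity ~ temperature, data = curve[sel, ]))
  }
  list(folded = unname(fit1(low_window)), unfolded = unname(fit1(high_window)))
}

#' Melting temperature from baseline-corrected folded fraction
#'
#' Converts the melting curve to a folded-fraction series
#' `theta(T) = (y(T) - y_unfolded(T)) / (y_folded(T) - y_unfolded(T))`
#' using the two fitted baselines, clips theta to [0, 1], and locates the
#' melting temperature Tm -- the temperature at which folded and unfolded
#' fractions are equal -- by linear interpolation between the grid points
#' bracketing theta = 0.5. The estimate is invariant to affine rescaling
#' of the ellipticity axis.
#'
#' @param curve A [melt_curve()].
#' @param baselines A [fit_baselines()] result.
#' @return List of class `melt_fit`: `tm` (deg C), `theta` (folded
#'   fraction per grid point), `baselines`.
#' @export
melt_tm <- function(curve, baselines) {
  tt <- curve$temperature
  yf <- baselines$folded[1] + baselines$folded[2] * tt
  yu <- baselines$unfolded[1] + baselines$unfolded[2] * tt
  denom <- yf - yu
  if (any(abs(denom) < 1e-12))
    stop("folded and unfolded baselines intersect inside the grid")
  theta <- (curve$ellipticity - yu) / denom
  theta <- pmin(1, pmax(0, theta))
  below <- theta <= 0.5
  cross <- which(below[-1] != below[-length(below)])
  if (!length(cross))
    stop("folded fraction never crosses 0.5: incomplete transition")
  i <- cross[1]
  t1 <- tt[i]; t2 <- tt[i + 1]; th1 <- theta[i]; th2 <- theta[i + 1]
  tm <- t1 + (0.5 - th1) * (t2 - t1) / (th2 - th1)
  structure(list(tm = tm, theta = theta, baselines = baselines,
                 temperature = tt),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("two-state melt fit: Tm = %.2f degC\n", x$tm))
  invisible(x)
}

#' Read / write two-column spectra and melting curves
#'
#' Tab-separated, single header row; columns `wavelength_nm, ellipticity`
#' for spectra and `temperature_C, ellipticity` for melting curves.
#'
#' @param path File path.
#' @param x A [cd_spectrum()] or [melt_curve()].
#' @return The read object, or `path` invisibly for writers.
#' @export
read_cd_spectrum <- function(path) {
  d <- utils::read.delim(path)
  cd_spectrum(d[[1]], d[[2]])
}

#' @rdname read_cd_spectrum
#' @export
read_melt_curve <- function(path) {
  d <- utils::read.delim(path)
  melt_curve(d[[1]], d[[2]])
}

#' @rdname read_cd_spectrum
#' @export
write_cd_spectrum <- function(x, path) {
  utils::write.table(data.frame(wavelength_nm = x$wavelength,
                                ellipticity = x$ellipticity),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_cd_spectrum
#' @export
write_melt_curve <- function(x, path) {
  utils::write.table(data.frame(temperature_C = x$temperature,
                                ellipticity = x$ellipticity),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
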