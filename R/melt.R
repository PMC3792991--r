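#' Thermal melting curve
#'
#' @param temperature strictly increasing temperatures (degrees C).
#' @param signal CD signal (e.g. at 235 nm), same length (>= 8 points).
#' @param ramp optional label, e.g. `"first"`/`"second"` heating.
#' @return An object of class `melting_curve`.
#' @export
melting_curve <- function(temperature, signal, ramp = NULL) {
  stopifnot(length(temperature) == length(signal), length(temperature) >= 8,
            all(diff(temperature) > 0))
  structure(list(temperature = temperature, signal = signal, ramp = ramp),
            class = "melting_curve")
}

#' Read a melting curve from two-column CSV
#'
#' Header required; first column temperature, second signal.
#'
#' @param path CSV file.
#' @inheritParams melting_curve
#' @return A [melting_curve()].
#' @export
read_melting_csv <- function(path, ramp = NULL) {
  tab <- utils::read.csv(path)
  melting_curve(tab[[1]], tab[[2]], ramp = ramp)
}

# four-parameter logistic: upper baseline before the transition, lower
# after, inflection at tm, transition width (> 0 for a decaying signal)
logistic4 <- function(temp, lower, upper, tm, width) {
  lower + (upper - lower) / (1 + exp((temp - tm) / width))
}

#' Simulate a thermal melting curve
#'
#' Four-parameter logistic with additive Gaussian noise scaled to the
#' transition amplitude. Defaults mirror a marginally stable single-domain
#' antibody (inflection at 45.9 degrees C) scanned from 25 to 85 degrees C
#' at 0.5-degree spacing with 1% noise.
#'
#' @param tm inflection temperature (degrees C).
#' @param width transition width (degrees C).
#' @param upper,lower pre-/post-transition baselines (arbitrary CD units).
#' @param temperature scan temperatures.
#' @param noise_sd noise standard deviation as a fraction of the amplitude.
#' @param seed root seed.
#' @return A [melting_curve()].
#' @export
simulate_melting_curve <- function(tm = 45.9, width = 2.2, upper = 1, lower = 0,
                                   temperature = seq(25, 85, by = 0.5),
                                   noise_sd = 0.01, seed = 1L) {
  y <- logistic4(temperature, lower, upper, tm, width)
  amp <- abs(upper - lower)
  y <- with_seed(derive_seed(seed, "simulate_melting_curve"),
                 y + stats::rnorm(length(y), sd = noise_sd * amp))
  melting_curve(temperature, y)
}

#' Fit a sigmoidal melting curve
#'
#' Least-squares fit of a four-parameter logistic (upper/lower baselines,
#' inflection temperature Tm, width); optionally with sloped baselines.
#' Starting values come from data quantiles; Tm is the inflection point of
#' the fitted sigmoid.
#'
#' @param curve a [melting_curve()].
#' @param sloped_baselines if `TRUE`, adds linear pre-/post-transition
#'   baseline slopes (six parameters).
#' @param noise_floor minimum ratio of apparent amplitude to point-to-point
#'   noise below which the curve is declared transition-free.
#' @return An object of class `melting_fit`: `tm`, `slope_at_inflection`,
#'   `baselines` (`upper`, `lower` and slopes if fitted), `amplitude`,
#'   `rss`, `converged`, plus the fitted model function.
#' @examples
#' fit_melting(simulate_melting_curve(tm = 50, seed = 7))$tm
#' @export
fit_melting <- function(curve, sloped_baselines = FALSE, noise_floor = 5) {
  stopifnot(inherits(curve, "melting_curve"))
  temp <- curve$temperature
  y <- curve$signal
  n <- length(y)
  k <- max(3L, n %/% 10L)
  pre <- mean(head(y, k))
  post <- mean(tail(y, k))
  noise <- stats::sd(diff(y)) / sqrt(2)
  if (!is.finite(noise)) noise <- 0
  if (abs(pre - post) <= noise_floor * max(noise, 1e-12)) {
    stop("no transition detected: baseline difference ", format(abs(pre - post)),
         " is below the noise floor")
  }
  mid <- (pre + post) / 2
  tm0 <- temp[which.min(abs(y - mid))]
  w0 <- diff(range(temp)) / 20
  if (sloped_baselines) {
    par0 <- c(lower = post, upper = pre, tm = tm0, width = w0,
              slope_lower = 0, slope_upper = 0)
    model <- function(p, temp) {
      frac <- 1 / (1 + exp((temp - p[["tm"]]) / p[["width"]]))
      lowb <- p[["lower"]] + p[["slope_lower"]] * (temp - p[["tm"]])
      uppb <- p[["upper"]] + p[["slope_upper"]] * (temp - p[["tm"]])
      lowb + (uppb - lowb) * frac
    }
  } else {
    par0 <- c(lower = post, upper = pre, tm = tm0, width = w0)
    model <- function(p, temp) {
      logistic4(temp, p[["lower"]], p[["upper"]], p[["tm"]], p[["width"]])
    }
  }
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(p) y - model(p, temp),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  p <- fit$par
  converged <- fit$info %in% 1:4
  if (!converged) warning("melting fit did not converge (info = ", fit$info, ")")
  tm <- p[["tm"]]
  if (tm < min(temp) || tm > max(temp)) {
    warning("fitted Tm ", format(tm), " lies outside the observed range")
  }
  amplitude <- p[["upper"]] - p[["lower"]]
  structure(list(
    tm = tm,
    slope_at_inflection = -amplitude / (4 * p[["width"]]),
    baselines = p[setdiff(names(p), c("tm", "width"))],
    width = p[["width"]],
    amplitude = amplitude,
    rss = sum(fit$fvec^2),
    converged = converged,
    model = function(temp) model(p, temp)
  ), class = "melting_fit")
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf("<melting_fit> Tm = %.2f C, amplitude = %.4g, width = %.2f C, rss = %.3g\n",
              x$tm, x$amplitude, x$width, x$rss))
  invisible(x)
}

#' Refolding fraction from two heating curves
#'
#' Ratio of the second ramp's transition amplitude to the first's. A value
#' of 1 means the first and second melting curves overlap, i.e. full
#' refolding after the first thermal unfolding.
#'
#' @param first,second converged [fit_melting()] results for the first and
#'   second heating ramps.
#' @return Non-negative fraction (typically in `[0, 1]`).
#' @export
refolding_fraction <- function(first, second) {
  stopifnot(inherits(first, "melting_fit"), inherits(second, "melting_fit"))
  if (!first$converged || !second$converged) {
    stop("both melting fits must have converged")
  }
  a1 <- abs(first$amplitude)
  if (a1 < 1e-12) stop("first-ramp amplitude is (near) zero")
  max(0, abs(second$amplitude) / a1)
}
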