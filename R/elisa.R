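#' Fit a logarithmic ELISA standard curve
#'
#' Ordinary least-squares fit of \code{absorbance = slope * ln(concentration)
#' + intercept} on a calibration series, the standard form for direct-binding
#' ELISA quantification of a surface receptor (concentration in micrograms
#' per millilitre). Replicate absorbances at the same concentration are
#' averaged before fitting, matching the usual report-the-triplicate-mean
#' convention; R-squared is computed on the absorbance scale.
#'
#' @param concentration positive concentrations (ug/mL), or a two-column
#'   data frame \code{(concentration, absorbance)}.
#' @param absorbance matching absorbances; ignored when the first argument
#'   is a data frame.
#' @return object of class \code{log_standard_curve} with components
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{n_points} (raw
#'   calibration points), \code{fit} (the underlying \code{lm}), and
#'   \code{data} (the averaged calibration series).
#' @examples
#' conc <- c(0.5, 1, 2, 4)
#' fit_log_curve(conc, 0.2657 * log(conc) + 1.072)
#' @export
fit_log_curve <- function(concentration, absorbance = NULL) {
  if (is.data.frame(concentration)) {
    if (ncol(concentration) < 2L) {
      stop("calibration data frame needs two columns")
    }
    absorbance <- concentration[[2L]]
    concentration <- concentration[[1L]]
  }
  if (length(concentration) != length(absorbance)) {
    stop("concentration and absorbance lengths differ")
  }
  if (length(concentration) < 3L) {
    stop("at least 3 calibration points are required")
  }
  if (anyNA(concentration) || any(concentration <= 0)) {
    stop("concentrations must be positive")
  }
  uc <- sort(unique(concentration))
  if (length(uc) < 2L) stop("calibration concentrations must not all be equal")
  ab <- vapply(uc, function(ci) mean(absorbance[concentration == ci]),
               numeric(1))
  fit <- stats::lm(ab ~ log(uc))
  # R^2 on the absorbance scale, computed directly so a perfect (noiseless)
  # calibration does not trip lm's near-singular summary heuristics
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((ab - mean(ab))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = 1 - rss / tss,
                 n_points = length(concentration),
                 fit = fit,
                 data = data.frame(concentration = uc, absorbance = ab)),
            class = "log_standard_curve")
}

#' @export
print.log_standard_curve <- function(x, ...) {
  cat(sprintf("Absorbance = %.4g ln(conc ug/mL) + %.4g   (R^2 = %.4f, %d points)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.log_standard_curve <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Predicted absorbance at a concentration
#'
#' @param object a [fit_log_curve()] fit.
#' @param concentration positive concentrations (ug/mL); defaults to the
#'   calibration concentrations.
#' @param ... ignored.
#' @return predicted absorbances \code{slope * ln(conc) + intercept}.
#' @export
predict.log_standard_curve <- function(object, concentration = NULL, ...) {
  if (is.null(concentration)) concentration <- object$data$concentration
  if (any(concentration <= 0)) stop("concentrations must be positive")
  object$slope * log(concentration) + object$intercept
}

#' Invert a standard curve: absorbance back to concentration
#'
#' @param curve a [fit_log_curve()] fit.
#' @param absorbance measured absorbances.
#' @return concentrations \code{exp((absorbance - intercept) / slope)}, the
#'   exact inverse of [predict.log_standard_curve()].
#' @export
invert_concentration <- function(curve, absorbance) {
  if (curve$slope == 0) stop("cannot invert a flat standard curve (slope 0)")
  exp((absorbance - curve$intercept) / curve$slope)
}

#' Percent of exposed nanoparticles bound to cells
#'
#' The bound fraction is inferred by depletion: particles still in the
#' supernatant after incubation did not bind, so
#' \code{100 * (exposed - supernatant) / exposed}.
#'
#' @param exposed concentration added to the culture (ug/mL), positive.
#' @param supernatant concentration recovered in the supernatant, between 0
#'   and \code{exposed}.
#' @return percentage in \code{[0, 100]}.
#' @examples
#' percent_bound(5, 3) # 40
#' @export
percent_bound <- function(exposed, supernatant) {
  if (any(exposed <= 0)) stop("exposed concentration must be positive")
  if (any(supernatant < 0)) stop("supernatant concentration must be nonnegative")
  if (any(supernatant > exposed)) {
    stop("inconsistent measurement: supernatant exceeds exposed concentration")
  }
  100 * (exposed - supernatant) / exposed
}

#' Read a two-column calibration file
#'
#' @param path CSV with columns concentration, absorbance (header optional).
#' @return data frame with columns \code{concentration}, \code{absorbance}.
#' @export
read_calibration <- function(path) {
  first <- strsplit(readLines(path, n = 1L), ",")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) < 2L) stop("calibration file needs two columns")
  stats::setNames(df[1:2], c("concentration", "absorbance"))
}
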