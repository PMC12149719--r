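#' Gaussian pencil-beam model
#'
#' A monoenergetic pencil beam is described by its lateral Gaussian widths
#' at the isocenter plane. Each spot deposits
#' \deqn{d(x, y) = w \exp\left(-\frac{(x-x_s)^2}{2\sigma_x^2}
#'   - \frac{(y-y_s)^2}{2\sigma_y^2}\right)}
#' where the spot weight \eqn{w} is the Gaussian amplitude, i.e. the dose
#' (Gy) the spot delivers at its own center. Depth dependence is out of
#' scope; all geometry lives on the 2D isocenter plane in millimetres.
#'
#' @param sigma_x,sigma_y Gaussian one-sigma beam widths in X and Y (mm),
#'   both strictly positive.
#' @return An object of class `beam_model`.
#' @examples
#' beam_model(3, 3)
#' @export
beam_model <- function(sigma_x, sigma_y = sigma_x) {
  stopifnot(is.numeric(sigma_x), length(sigma_x) == 1L, is.finite(sigma_x),
            is.numeric(sigma_y), length(sigma_y) == 1L, is.finite(sigma_y))
  if (sigma_x <= 0 || sigma_y <= 0)
    stop("beam sigmas must be strictly positive (mm)", call. = FALSE)
  structure(list(sigma_x = as.numeric(sigma_x), sigma_y = as.numeric(sigma_y)),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model> Gaussian pencil beam: sigma_x = %g mm, sigma_y = %g mm\n",
              x$sigma_x, x$sigma_y))
  invisible(x)
}

#' Spot-scanning timing model
#'
#' Times governing the delivery sequence. The beam-on time of a spot is
#' `t_spot_fixed + t_spot_per_gy * w`, where `w` is the weight (Gy)
#' delivered in that painting. Transits between consecutive spots in a row
#' cost `tau_x`; row changes cost `tau_y`; paintings of one field are
#' separated by `tau_repaint`; fields by `tau_field`.
#'
#' @param t_spot_fixed Fixed beam-on time per spot (ms).
#' @param t_spot_per_gy Dose-proportional beam-on time (ms/Gy).
#' @param tau_x Spot-change time within a row (ms).
#' @param tau_y Row-change time (ms); fly-back is counted as a single
#'   `tau_y`, whatever the row length.
#' @param n_repaint Number of paintings; each painting delivers `1/n_repaint`
#'   of every spot's weight and re-traverses the map in the same order.
#' @param tau_repaint Gap between consecutive paintings (ms).
#' @param tau_field Gap between consecutive fields (ms).
#' @return An object of class `timing_model`.
#' @examples
#' timing_model(t_spot_fixed = 1, t_spot_per_gy = 10, tau_x = 2, tau_y = 10)
#' @export
timing_model <- function(t_spot_fixed = 0, t_spot_per_gy = 0,
                         tau_x = 0, tau_y = 0,
                         n_repaint = 1L, tau_repaint = 0, tau_field = 0) {
  vals <- c(t_spot_fixed = t_spot_fixed, t_spot_per_gy = t_spot_per_gy,
            tau_x = tau_x, tau_y = tau_y, tau_repaint = tau_repaint,
            tau_field = tau_field)
  if (!all(is.finite(vals)) || any(vals < 0))
    stop("all timing parameters must be finite and >= 0", call. = FALSE)
  if (!is.numeric(n_repaint) || length(n_repaint) != 1L ||
      n_repaint < 1 || n_repaint != round(n_repaint))
    stop("n_repaint must be an integer >= 1", call. = FALSE)
  structure(list(t_spot_fixed = as.numeric(t_spot_fixed),
                 t_spot_per_gy = as.numeric(t_spot_per_gy),
                 tau_x = as.numeric(tau_x), tau_y = as.numeric(tau_y),
                 n_repaint = as.integer(n_repaint),
                 tau_repaint = as.numeric(tau_repaint),
                 tau_field = as.numeric(tau_field)),
            class = "timing_model")
}

#' @export
print.timing_model <- function(x, ...) {
  cat("<timing_model>\n")
  cat(sprintf("  beam-on per spot : %g ms + %g ms/Gy\n",
              x$t_spot_fixed, x$t_spot_per_gy))
  cat(sprintf("  spot change      : tau_x = %g ms, tau_y = %g ms\n",
              x$tau_x, x$tau_y))
  cat(sprintf("  repainting       : n = %d, gap = %g ms\n",
              x$n_repaint, x$tau_repaint))
  cat(sprintf("  field gap        : %g ms\n", x$tau_field))
  invisible(x)
}
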