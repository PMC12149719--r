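#' Construct a spot map from an explicit spot table
#'
#' A spot map is the ordered set of pencil-beam spots on the isocenter
#' plane: positions (mm) and weights (Gy, the Gaussian amplitude at the
#' spot center). Spots keep the order given; for grid-generated maps the
#' order is row-major starting at the minimum-`y` row, which is also the
#' nominal scan order used by [build_timeline()].
#'
#' @param x,y Numeric vectors of spot positions (mm).
#' @param weight Numeric vector of spot weights (Gy), all `>= 0`.
#' @param n_x,n_y,pitch_x,pitch_y Grid metadata, set by
#'   [generate_spot_map()]; `NA` for free-form maps.
#' @return An object of class `spot_map`: a data frame with columns
#'   `x`, `y`, `weight` and grid attributes.
#' @seealso [generate_spot_map()] for regular grids with rim/corner weights.
#' @export
spot_map <- function(x, y, weight,
                     n_x = NA_integer_, n_y = NA_integer_,
                     pitch_x = NA_real_, pitch_y = NA_real_) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(weight))
  n <- length(x)
  if (length(y) != n || length(weight) != n)
    stop("x, y and weight must have equal length", call. = FALSE)
  if (n > 0 && (!all(is.finite(c(x, y, weight))) || any(weight < 0)))
    stop("spot positions must be finite and weights finite and >= 0",
         call. = FALSE)
  out <- data.frame(x = as.numeric(x), y = as.numeric(y),
                    weight = as.numeric(weight))
  attr(out, "n_x") <- as.integer(n_x)
  attr(out, "n_y") <- as.integer(n_y)
  attr(out, "pitch_x") <- as.numeric(pitch_x)
  attr(out, "pitch_y") <- as.numeric(pitch_y)
  class(out) <- c("spot_map", "data.frame")
  out
}

#' Generate a regular rectangular spot map with rim/corner weight overrides
#'
#' Places `n_x * n_y` spots on a regular grid centered on the origin, in
#' row-major order starting at the minimum-`y` row. Spot weights follow a
#' three-level rule: the four extreme-corner spots (extreme in both index
#' directions) get `w_corner`, other boundary spots (extreme in exactly one
#' direction) get `w_rim`, interior spots get `w_center`. Degenerate grids
#' classify by the same rule: a 1x1 map is a single corner spot; every spot
#' of a 2x2 or a 1xN-end map extreme in both directions is a corner.
#'
#' @param n_x,n_y Number of spots in X and Y (`>= 1`).
#' @param pitch_x,pitch_y Spot spacing in X and Y (mm, `> 0`).
#' @param w_center Weight (Gy) of interior spots.
#' @param w_rim Weight of non-corner boundary spots (default `w_center`).
#' @param w_corner Weight of the extreme-corner spots (default `w_rim`).
#' @return A [spot_map()].
#' @examples
#' sm <- generate_spot_map(3, 3, 5, 5, w_center = 1, w_rim = 2, w_corner = 3)
#' table(sm$weight)
#' @export
generate_spot_map <- function(n_x, n_y, pitch_x, pitch_y,
                              w_center, w_rim = w_center, w_corner = w_rim) {
  if (!is.numeric(n_x) || !is.numeric(n_y) ||
      n_x < 1 || n_y < 1 || n_x != round(n_x) || n_y != round(n_y))
    stop("n_x and n_y must be integers >= 1", call. = FALSE)
  if (!is.numeric(pitch_x) || !is.numeric(pitch_y) ||
      pitch_x <= 0 || pitch_y <= 0)
    stop("pitch_x and pitch_y must be > 0 (mm)", call. = FALSE)
  if (any(c(w_center, w_rim, w_corner) < 0))
    stop("weights must be >= 0 (Gy)", call. = FALSE)
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  # grid centered on (0, 0)
  xs <- (seq_len(n_x) - (n_x + 1) / 2) * pitch_x
  ys <- (seq_len(n_y) - (n_y + 1) / 2) * pitch_y
  ix <- rep(seq_len(n_x), times = n_y)
  iy <- rep(seq_len(n_y), each = n_x)
  edge_x <- ix == 1L | ix == n_x
  edge_y <- iy == 1L | iy == n_y
  w <- ifelse(edge_x & edge_y, w_corner, ifelse(edge_x | edge_y, w_rim, w_center))
  spot_map(xs[ix], ys[iy], w, n_x = n_x, n_y = n_y,
           pitch_x = pitch_x, pitch_y = pitch_y)
}

#' @export
print.spot_map <- function(x, ...) {
  nx <- attr(x, "n_x"); ny <- attr(x, "n_y")
  grid <- if (!is.na(nx)) sprintf(" (%d x %d grid, pitch %g x %g mm)",
                                  nx, ny, attr(x, "pitch_x"), attr(x, "pitch_y"))
          else ""
  cat(sprintf("<spot_map> %d spots%s, total weight %g Gy\n",
              nrow(x), grid, sum(x$weight)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more spots\n", nrow(x) - 6L))
  invisible(x)
}

#' Read or write a spot table
#'
#' Spot tables are UTF-8 CSV files with the header
#' `x_mm,y_mm,weight_gy` and decimal points.
#'
#' @param path File path.
#' @param map A [spot_map()] (for writing).
#' @return `read_spot_table()` returns a [spot_map()];
#'   `write_spot_table()` returns `path` invisibly.
#' @export
read_spot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_mm", "y_mm", "weight_gy")
  if (!all(need %in% names(df)))
    stop("spot table must have header x_mm,y_mm,weight_gy", call. = FALSE)
  spot_map(df$x_mm, df$y_mm, df$weight_gy)
}

#' @rdname read_spot_table
#' @export
write_spot_table <- function(map, path) {
  stopifnot(inherits(map, "spot_map"))
  utils::write.csv(
    data.frame(x_mm = map$x, y_mm = map$y, weight_gy = map$weight),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
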