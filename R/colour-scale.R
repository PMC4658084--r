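#' Colour scale of a fish-finder display
#'
#' Recreational fish-finders classify echo intensity on a sequential numeric
#' colour scale with no reference to actual dB values. Index 0 is the weakest
#' echo (background), index `n_colours - 1` the strongest.
#'
#' @param n_colours Integer number of display colour indices (>= 2).
#' @param palette Optional numeric matrix (`n_colours` x 3, RGB in [0, 1])
#'   declaring the on-screen colour of each index, used to quantise RGB frame
#'   captures by nearest-colour match. Defaults to a grey ramp from black
#'   (index 0) to white (index `n_colours - 1`).
#' @return An object of class `colour_scale`.
#' @examples
#' sc <- colour_scale(8)
#' sc$n_colours
#' @export
colour_scale <- function(n_colours, palette = NULL) {
  n_colours <- as.integer(n_colours)
  if (is.na(n_colours) || n_colours < 2L)
    stop("`n_colours` must be an integer >= 2", call. = FALSE)
  if (is.null(palette)) {
    g <- seq(0, 1, length.out = n_colours)
    palette <- cbind(g, g, g)
  }
  palette <- as.matrix(palette)
  if (nrow(palette) != n_colours || ncol(palette) != 3L)
    stop("`palette` must be an n_colours x 3 RGB matrix", call. = FALSE)
  if (any(palette < 0) || any(palette > 1))
    stop("palette entries must lie in [0, 1]", call. = FALSE)
  structure(list(n_colours = n_colours, palette = palette),
            class = "colour_scale")
}

#' @export
print.colour_scale <- function(x, ...) {
  cat("<colour_scale> ", x$n_colours, " indices (0 = weakest echo)\n", sep = "")
  invisible(x)
}

#' Affine colour-index to Sv mapping
#'
#' Assigns a volume backscattering strength (Sv, dB re 1 m^-1) to each display
#' colour index. The weakest *retained* colour (index 1; index 0 is background
#' and always excluded) maps to `start_db`, and each further index adds
#' `step_db`:  `Sv(c) = start_db + step_db * (c - 1)` for `c >= 1`.
#'
#' @param start_db Sv of colour index 1, in dB re 1 m^-1.
#' @param step_db dB increment per colour index; must be > 0.
#' @return An object of class `pixel_mapping`.
#' @examples
#' m <- pixel_mapping(-65, 1.3)
#' sv_of_colour(1:4, m)
#' @export
pixel_mapping <- function(start_db, step_db) {
  start_db <- as.numeric(start_db)
  step_db <- as.numeric(step_db)
  if (!is.finite(start_db) || !is.finite(step_db) || step_db <= 0)
    stop("`start_db` must be finite and `step_db` > 0", call. = FALSE)
  structure(list(start_db = start_db, step_db = step_db),
            class = "pixel_mapping")
}

#' @export
print.pixel_mapping <- function(x, ...) {
  cat(sprintf("<pixel_mapping> Sv(c) = %.2f + %.2f * (c - 1) dB\n",
              x$start_db, x$step_db))
  invisible(x)
}

#' Sv value of colour indices under a mapping
#'
#' @param colour Integer vector of colour indices (>= 1; background 0 is not
#'   mapped and raises an error).
#' @param mapping A [pixel_mapping()].
#' @return Numeric vector of Sv values (dB re 1 m^-1).
#' @export
sv_of_colour <- function(colour, mapping) {
  stopifnot(inherits(mapping, "pixel_mapping"))
  if (any(colour < 1L))
    stop("colour index 0 is background and carries no Sv", call. = FALSE)
  mapping$start_db + mapping$step_db * (colour - 1)
}

#' Convert between Sv (dB) and the linear coefficient sv
#'
#' `Sv = 10 * log10(sv)`; `sv = 10^(Sv / 10)`.
#'
#' @param sv_db Sv in dB re 1 m^-1.
#' @param sv_linear sv in m^-1.
#' @return The converted value(s).
#' @export
db_to_linear <- function(sv_db) 10^(sv_db / 10)

#' @rdname db_to_linear
#' @export
linear_to_db <- function(sv_linear) 10 * log10(sv_linear)
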