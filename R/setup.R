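#' Rectangular simulation cell
#'
#' @param lengths three box edge lengths in Angstrom (> 0).
#' @return object of class `simulation_cell` with `lengths` and derived
#'   `volume` (Angstrom^3).
#' @examples
#' simulation_cell(c(139, 124, 187))
#' @export
simulation_cell <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3 || any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("lengths must be three positive numbers", call. = FALSE)
  }
  structure(list(lengths = lengths, volume = prod(lengths)),
            class = "simulation_cell")
}

#' @export
print.simulation_cell <- function(x, ...) {
  cat(sprintf("<simulation_cell> %.6g x %.6g x %.6g A (volume %.6g A^3)\n",
              x$lengths[1], x$lengths[2], x$lengths[3], x$volume))
  invisible(x)
}

#' Extra ions needed to reach a target concentration
#'
#' The total ion count for a molar concentration `c` in a cell of volume
#' `V` (Angstrom^3) is `round(c * V * 1e-27 L/A^3 * N_Avogadro)`; the
#' function returns how many must be *added* beyond those already placed
#' (never negative).
#'
#' @param cell a [simulation_cell()].
#' @param concentration molar concentration (mol/L), >= 0.
#' @param already_placed ions already present, >= 0.
#' @return integer count of extra ions.
#' @examples
#' cell <- simulation_cell(c(139, 124, 187))
#' ion_count_for_concentration(cell, 0.005, already_placed = 3) # 7
#' ion_count_for_concentration(cell, 0.005, already_placed = 2) # 8
#' @export
ion_count_for_concentration <- function(cell, concentration,
                                        already_placed = 0) {
  stopifnot(inherits(cell, "simulation_cell"))
  if (!is.numeric(concentration) || concentration < 0) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  if (!is.numeric(already_placed) || already_placed < 0) {
    stop("already_placed must be >= 0", call. = FALSE)
  }
  total <- round(concentration * cell$volume * 1e-27 * .avogadro)
  as.integer(max(total - already_placed, 0))
}

#' Molar concentration of an ion count in a cell
#'
#' Inverse of [ion_count_for_concentration()]: the concentration that a
#' given number of ions realises in the cell.
#'
#' @param cell a [simulation_cell()].
#' @param n_ions ion count, >= 0.
#' @return concentration in mol/L.
#' @export
concentration_for_ion_count <- function(cell, n_ions) {
  stopifnot(inherits(cell, "simulation_cell"), n_ions >= 0)
  n_ions / (cell$volume * 1e-27 * .avogadro)
}
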