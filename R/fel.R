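#' Boltzmann constant in kcal/mol/K
#' @keywords internal
KB_KCAL <- 0.0019872

#' Free-energy landscape over two reaction coordinates
#'
#' Bins the joint distribution of two collective coordinates (typically the
#' first two principal components) on a regular 2-D grid and converts
#' occupancy to relative free energy, `F = -kB * T * ln(P / P_max)` in
#' kcal/mol. The most populated bin sits at exactly 0; empty bins are masked
#' as `NA`.
#'
#' @param pc1,pc2 Equal-length numeric series of the two coordinates.
#' @param temperature_K Simulation temperature in Kelvin (default 310 K,
#'   body temperature).
#' @param bins Number of bins per axis (>= 2).
#' @return An object of class `free_energy_landscape` with `energy` and
#'   `probability` matrices (bins x bins), bin-centre vectors `pc1_centers`,
#'   `pc2_centers`, and the temperature.
#' @examples
#' fel <- free_energy_landscape(rnorm(500), rnorm(500), bins = 20)
#' min(fel$energy, na.rm = TRUE)  # 0
#' @export
free_energy_landscape <- function(pc1, pc2, temperature_K = 310, bins = 50L) {
  stopifnot(length(pc1) == length(pc2), length(pc1) >= 1, bins >= 2,
            temperature_K > 0)
  b1 <- .fel_breaks(pc1, bins)
  b2 <- .fel_breaks(pc2, bins)
  i1 <- findInterval(pc1, b1, rightmost.closed = TRUE, all.inside = TRUE)
  i2 <- findInterval(pc2, b2, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, bins, bins)
  for (k in seq_along(i1)) counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1
  p <- counts / sum(counts)
  energy <- matrix(NA_real_, bins, bins)
  occ <- p > 0
  energy[occ] <- -KB_KCAL * temperature_K * log(p[occ] / max(p))
  structure(
    list(energy = energy, probability = p,
         pc1_centers = (b1[-1] + b1[-length(b1)]) / 2,
         pc2_centers = (b2[-1] + b2[-length(b2)]) / 2,
         temperature_K = temperature_K),
    class = "free_energy_landscape"
  )
}

.fel_breaks <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)  # degenerate axis: one-bin spread
  seq(r[1], r[2], length.out = bins + 1)
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat(sprintf("<free_energy_landscape> %dx%d bins, T = %g K, %d occupied, max F = %.3f kcal/mol\n",
              nrow(x$energy), ncol(x$energy), x$temperature_K,
              sum(!is.na(x$energy)), max(x$energy, na.rm = TRUE)))
  invisible(x)
}

#' @rdname free_energy_landscape
#' @param x,object A `free_energy_landscape`.
#' @param ... Unused.
#' @method tidy free_energy_landscape
#' @export
tidy.free_energy_landscape <- function(x, ...) {
  nb <- length(x$pc1_centers)
  tibble::tibble(
    pc1 = rep(x$pc1_centers, times = nb),
    pc2 = rep(x$pc2_centers, each = nb),
    probability = as.vector(x$probability),
    energy = as.vector(x$energy)
  )
}

#' @rdname free_energy_landscape
#' @method autoplot free_energy_landscape
#' @export
autoplot.free_energy_landscape <- function(object, ...) {
  dat <- tidy.free_energy_landscape(object)
  ggplot2::ggplot(dat[!is.na(dat$energy), ],
                  ggplot2::aes(.data$pc1, .data$pc2, fill = .data$energy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1,
                                  name = "F (kcal/mol)") +
    ggplot2::labs(x = "PC1", y = "PC2")
}
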