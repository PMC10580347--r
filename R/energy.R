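ENERGY_COMPONENTS <- c("e_vdw", "e_ele", "g_pol", "g_np")

# printed strength ranges (kcal/mol): label, upper (less negative), lower
STRENGTH_RANGES <- data.frame(
  label = c("Weak", "Medium", "Strong", "Very strong"),
  upper = c(-1.36, -6.83, -9.56, -13.66),
  lower = c(-5.46, -8.19, -12.29, -16.39)
)

#' Aggregate MM-PBSA energy components into a binding free energy
#'
#' Sums the van der Waals, electrostatic, polar-solvation and
#' nonpolar-solvation terms into `g_bind` (kcal/mol) and attaches a binding
#' strength label. Full precision is retained in the returned column; round
#' to two decimals for display.
#'
#' @param components Data frame with columns `e_vdw`, `e_ele`, `g_pol`,
#'   `g_np` (kcal/mol) and optionally `complex_id`; one row per complex.
#' @return The input as a tibble with `g_bind` and `strength` columns added.
#' @examples
#' aggregate_binding_energy(
#'   data.frame(complex_id = "RAF-265/IAPP",
#'              e_vdw = -35.84, e_ele = -8.90, g_pol = 27.39, g_np = -3.46))
#' @export
aggregate_binding_energy <- function(components) {
  components <- tibble::as_tibble(components)
  missing <- setdiff(ENERGY_COMPONENTS, names(components))
  if (length(missing) > 0L) {
    stop("missing energy component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(components[ENERGY_COMPONENTS])
  if (any(!is.finite(vals))) {
    bad <- ENERGY_COMPONENTS[colSums(!is.finite(vals)) > 0]
    stop("non-finite value(s) in component(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(components,
                g_bind = .data$e_vdw + .data$e_ele + .data$g_pol + .data$g_np,
                strength = binding_strength(.data$g_bind))
}

#' Classify a binding free energy into a strength band
#'
#' Values inside a published band get its label; values falling in a gap
#' between bands, or beyond the strongest band, get the label of the nearest
#' band boundary with an `" (extrapolated)"` qualifier; values weaker than
#' the weakest bound are `"negligible"`. More negative energies never map to
#' a weaker label.
#'
#' @param g_bind Binding free energies in kcal/mol (vectorised).
#' @return Character labels.
#' @examples
#' binding_strength(c(-7.0, -22.18, -0.5))
#' @export
binding_strength <- function(g_bind) {
  stopifnot(all(is.finite(g_bind)))
  vapply(g_bind, function(g) {
    if (g > STRENGTH_RANGES$upper[1]) return("negligible")
    inside <- which(g <= STRENGTH_RANGES$upper & g >= STRENGTH_RANGES$lower)
    if (length(inside) > 0L) return(STRENGTH_RANGES$label[inside[1]])
    bounds <- c(rbind(STRENGTH_RANGES$upper, STRENGTH_RANGES$lower))
    lab <- rep(STRENGTH_RANGES$label, each = 2)
    paste0(lab[which.min(abs(bounds - g))], " (extrapolated)")
  }, character(1))
}

#' Read an MM-PBSA component table
#'
#' Expects a TSV with header `complex_id, e_vdw, e_ele, g_pol, g_np`
#' (an optional `frame` column marks a per-frame series).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_energy_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Average a per-frame energy series over its converged tail
#'
#' For each complex, keeps the last `ceiling(fraction * n_frames)` rows (in
#' `frame` order — the same trailing-window rule as [convergence_window()])
#' and averages each component before aggregating.
#'
#' @param series Data frame with `complex_id`, `frame` and the four component
#'   columns, one row per frame.
#' @param fraction Trailing fraction of frames to average over (default the
#'   last 20% of the run).
#' @return One aggregated row per complex, as from
#'   [aggregate_binding_energy()], plus `n_frames_used`.
#' @export
summarize_energy_series <- function(series, fraction = 0.2) {
  stopifnot(fraction > 0, fraction <= 1)
  series <- tibble::as_tibble(series)
  stopifnot(all(c("complex_id", "frame") %in% names(series)))
  # slice_tail(prop=) floors; the ceiling rule needs explicit n per group
  tail_mean <- series |>
    dplyr::group_by(.data$complex_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      n <- ceiling(fraction * nrow(df))
      out <- dplyr::summarise(utils::tail(df, n),
                              dplyr::across(dplyr::all_of(ENERGY_COMPONENTS),
                                            mean))
      out$n_frames_used <- n
      out
    }) |>
    dplyr::ungroup()
  aggregate_binding_energy(tail_mean)
}
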