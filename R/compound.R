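#' Lipinski rule-of-five drug-likeness evaluation
#'
#' Counts violations of the four rules — molecular weight > 500 Da,
#' LogP > 5, H-bond donors > 5, H-bond acceptors > 10 — and flags compounds
#' with at most one violation as passing. Descriptors are inputs, not
#' computed from structure; a pre-computed PAINS flag (`pains` column,
#' logical: `TRUE` = clean) is carried through when present.
#'
#' @param descriptors Data frame with columns `compound_id`, `mw` (Da, > 0),
#'   `logp`, `hbd`, `hba` (non-negative counts) and optionally `pains`.
#' @return The input as a tibble with `ro5_violations` (0-4) and `ro5_pass`
#'   added.
#' @examples
#' lipinski_ro5(data.frame(compound_id = "hypericin", mw = 504,
#'                         logp = 4.0, hbd = 4, hba = 8))
#' @export
lipinski_ro5 <- function(descriptors) {
  descriptors <- tibble::as_tibble(descriptors)
  needed <- c("mw", "logp", "hbd", "hba")
  missing <- setdiff(needed, names(descriptors))
  if (length(missing) > 0L) {
    stop("missing descriptor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- descriptors[needed]
  if (any(vapply(vals, function(v) any(!is.finite(v)), TRUE))) {
    stop("non-finite descriptor value", call. = FALSE)
  }
  if (any(descriptors$mw <= 0)) stop("mw must be positive", call. = FALSE)
  if (any(descriptors$hbd < 0) || any(descriptors$hba < 0)) {
    stop("hbd/hba must be non-negative", call. = FALSE)
  }
  dplyr::mutate(
    descriptors,
    ro5_violations = (.data$mw > 500) + (.data$logp > 5) +
      (.data$hbd > 5) + (.data$hba > 10),
    ro5_pass = .data$ro5_violations <= 1L
  )
}
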