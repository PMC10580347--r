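#' Cohen's d standardised mean difference
#'
#' Classic pooled-SD Cohen's d:
#' `d = (mean_case - mean_control) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`. The sign is
#' preserved (positive = higher in cases).
#'
#' @param case,control Numeric vectors with at least 2 values each.
#' @return The effect size, or `NA_real_` (with a warning) when the pooled
#'   SD is zero.
#' @examples
#' cohens_d(c(3, 4, 5), c(1, 2, 3))  # 2
#' @export
cohens_d <- function(case, control) {
  n1 <- length(case)
  n2 <- length(control)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 values per group", call. = FALSE)
  sp <- sqrt(((n1 - 1) * stats::var(case) + (n2 - 1) * stats::var(control)) /
               (n1 + n2 - 2))
  if (sp == 0) {
    warning("zero pooled SD: effect size undefined", call. = FALSE)
    return(NA_real_)
  }
  (mean(case) - mean(control)) / sp
}

#' Two-group test of one gene's expression
#'
#' Two-sided Welch (unequal-variance) t-test plus pooled-SD Cohen's d; a
#' gene is selected when `p < alpha` and `|d| > d_threshold`.
#'
#' @inheritParams cohens_d
#' @param alpha Significance threshold (default 0.05).
#' @param d_threshold Effect-size magnitude threshold (default 0.8).
#' @return One-row tibble: `mean_case`, `mean_control`, `cohens_d`,
#'   `p_value`, `selected`.
#' @export
gene_test <- function(case, control, alpha = 0.05, d_threshold = 0.8) {
  d <- suppressWarnings(cohens_d(case, control))
  p <- if (is.na(d)) NA_real_ else {
    stats::t.test(case, control, var.equal = FALSE)$p.value
  }
  tibble::tibble(
    mean_case = mean(case), mean_control = mean(control),
    cohens_d = d, p_value = p,
    selected = !is.na(d) & !is.na(p) & p < alpha & abs(d) > d_threshold
  )
}

#' Differential-expression screen with an effect-size gate
#'
#' Tests every gene of a two-group expression matrix with a two-sided Welch
#' t-test and pooled Cohen's d, selecting genes with `p < alpha` and
#' `|d| > d_threshold`. No multiple-testing correction is applied by default
#' (the selection thresholds are used as stated); set `adjust = TRUE` to add
#' a Benjamini-Hochberg adjusted p-value column and gate selection on it.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns; or an `expression_matrix` from [make_expression()].
#' @param group Per-sample labels, `"case"` / `"control"` (ignored when
#'   `values` is an `expression_matrix`).
#' @inheritParams gene_test
#' @param adjust Apply BH-FDR to the p-values and select on the adjusted
#'   value instead.
#' @return An `expression_screen` object; [generics::tidy()] returns the
#'   per-gene tibble, [generics::glance()] a one-row summary.
#' @export
expression_screen <- function(values, group = NULL, alpha = 0.05,
                              d_threshold = 0.8, adjust = FALSE) {
  if (inherits(values, "expression_matrix")) {
    group <- values$group
    values <- values$values
  }
  values <- as.matrix(values)
  stopifnot(!is.null(group), length(group) == ncol(values))
  group <- as.character(group)
  stopifnot(all(group %in% c("case", "control")))
  if (sum(group == "case") < 2L || sum(group == "control") < 2L) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  genes <- rownames(values)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(values)))
  case_idx <- group == "case"

  res <- purrr::map_dfr(seq_len(nrow(values)), function(i) {
    gene_test(values[i, case_idx], values[i, !case_idx],
              alpha = alpha, d_threshold = d_threshold)
  })
  res <- dplyr::mutate(res, gene = genes, .before = 1)
  n_undefined <- sum(is.na(res$cohens_d))
  if (n_undefined > 0L) {
    warning(sprintf("%d gene(s) with zero pooled SD excluded from selection",
                    n_undefined), call. = FALSE)
  }
  if (adjust) {
    res <- dplyr::mutate(
      res,
      p_adjusted = stats::p.adjust(.data$p_value, method = "BH"),
      selected = !is.na(.data$p_adjusted) & .data$p_adjusted < alpha &
        !is.na(.data$cohens_d) & abs(.data$cohens_d) > d_threshold
    )
  }
  structure(
    list(results = res,
         meta = list(alpha = alpha, d_threshold = d_threshold,
                     adjust = adjust,
                     n_case = sum(case_idx), n_control = sum(!case_idx))),
    class = "expression_screen"
  )
}

#' @export
print.expression_screen <- function(x, ...) {
  cat(sprintf("<expression_screen> %d gene(s) tested (%d/%d case/control), %d selected (p < %g, |d| > %g%s)\n",
              nrow(x$results), x$meta$n_case, x$meta$n_control,
              sum(x$results$selected), x$meta$alpha, x$meta$d_threshold,
              if (x$meta$adjust) ", BH-adjusted" else ""))
  invisible(x)
}

#' @rdname expression_screen
#' @param x,object An `expression_screen`.
#' @param ... Unused.
#' @method tidy expression_screen
#' @export
tidy.expression_screen <- function(x, ...) x$results

#' @rdname expression_screen
#' @method glance expression_screen
#' @export
glance.expression_screen <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$results),
    n_selected = sum(x$results$selected),
    n_undefined = sum(is.na(x$results$cohens_d)),
    alpha = x$meta$alpha,
    d_threshold = x$meta$d_threshold
  )
}

#' @rdname expression_screen
#' @method autoplot expression_screen
#' @export
autoplot.expression_screen <- function(object, ...) {
  dat <- object$results
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cohens_d,
                                    y = -log10(.data$p_value),
                                    colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$meta$d_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$meta$alpha),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d73027",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "Cohen's d", y = expression(-log[10]~p))
}

#' Read an expression matrix with a sample sheet
#'
#' The expression TSV has genes in the first column and one column per
#' sample; the sample sheet is a two-column TSV `sample<TAB>group` with
#' groups `case` / `control`.
#'
#' @param path Expression TSV path.
#' @param sample_sheet Sample-sheet TSV path.
#' @return An `expression_matrix` (list with `values` and `group`).
#' @export
read_expression_tsv <- function(path, sample_sheet) {
  tab <- utils::read.delim(path, check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  sheet <- utils::read.delim(sample_sheet, check.names = FALSE)
  grp <- as.character(sheet[[2]])
  names(grp) <- as.character(sheet[[1]])
  missing <- setdiff(colnames(values), names(grp))
  if (length(missing) > 0L) {
    stop("sample(s) without group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(values = values, group = unname(grp[colnames(values)])),
            class = "expression_matrix")
}

#' @rdname read_expression_tsv
#' @param mat An `expression_matrix`.
#' @export
write_expression_tsv <- function(mat, path, sample_sheet) {
  stopifnot(inherits(mat, "expression_matrix"))
  df <- data.frame(gene = rownames(mat$values), mat$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(mat$values), group = mat$group),
    sample_sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values), sum(x$group == "case"),
              sum(x$group == "control")))
  invisible(x)
}
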