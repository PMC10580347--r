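#' Degree-based weight of a drug target
#'
#' A target that is itself a disease gene contributes a negative weight
#' `-ln(D + 1)`, where `D` is its degree in the interaction network; any
#' other target has weight 0. The weight is what lets the drug-disease
#' distance go negative: a drug hitting well-connected disease genes scores
#' below zero and is flagged by the screen.
#'
#' @param degree Non-negative integer degree(s) in the network.
#' @param is_disease_gene Logical, recycled against `degree`.
#' @return Numeric weight(s), always `<= 0`.
#' @examples
#' target_weight(5, FALSE)  # 0
#' target_weight(1, TRUE)   # -log(2)
#' @export
target_weight <- function(degree, is_disease_gene) {
  if (any(is.na(degree)) || any(degree < 0)) {
    stop("`degree` must be non-negative", call. = FALSE)
  }
  ifelse(is_disease_gene, -log(degree + 1), 0)
}

# Closest-distance vector from the disease set: for every node v,
# min over s in S of d(s, v); NA when v is unreachable from all of S.
# Plus the weight vector w(v). Precomputing both makes screening and the
# reference distribution O(|T|) lookups per drug.
.proximity_cache <- function(net, disease_genes) {
  nodes <- network_nodes(net)
  s_in <- intersect(unique(disease_genes), nodes)
  if (length(s_in) == 0L) {
    stop("no disease gene is present in the network", call. = FALSE)
  }
  dmat <- igraph::distances(net$graph, v = s_in, to = nodes)
  min_d <- suppressWarnings(apply(dmat, 2, min))  # Inf when unreachable
  min_d[is.infinite(min_d)] <- NA_real_
  names(min_d) <- nodes
  deg <- network_degree(net)
  w <- target_weight(deg, nodes %in% s_in)
  names(w) <- nodes
  list(min_d = min_d, w = w, disease_in_network = s_in)
}

.drug_distance_cached <- function(cache, targets) {
  mapped <- intersect(unique(targets), names(cache$min_d))
  term <- cache$min_d[mapped] + cache$w[mapped]
  used <- mapped[!is.na(term)]
  list(
    distance = if (length(used)) mean(term[used]) else NA_real_,
    n_targets = length(unique(targets)),
    n_mapped = length(mapped),
    n_used = length(used)
  )
}

#' Weighted closest network distance between a drug and a disease gene set
#'
#' For each drug target `t` present in the network, the term is the minimum
#' shortest-path length from `t` to any disease gene, plus
#' [target_weight()] of `t`. The drug's distance is the mean of the terms
#' over its usable targets. A target that is itself a disease gene has
#' minimum distance 0, so it contributes only its (negative) weight.
#'
#' Targets absent from the network, and targets unreachable from every
#' disease gene, are dropped with a warning; if no target remains, the drug
#' is unscorable and `NA` is returned (never a silent 0).
#'
#' @param net An [interaction_network()].
#' @param disease_genes Character vector of disease gene symbols (members
#'   outside the network are ignored; at least one must map).
#' @param targets Character vector of the drug's target gene symbols.
#' @return A single numeric distance (possibly negative), or `NA_real_` when
#'   the drug cannot be scored. The number of targets used is attached as
#'   attribute `n_targets_used`.
#' @examples
#' net <- interaction_network(
#'   data.frame(a = c("A", "B", "C"), b = c("B", "C", "D")), quiet = TRUE)
#' drug_distance(net, disease_genes = "A", targets = "C")  # 2
#' @export
drug_distance <- function(net, disease_genes, targets) {
  cache <- .proximity_cache(net, disease_genes)
  res <- .drug_distance_cached(cache, targets)
  if (res$n_mapped < res$n_targets) {
    warning(sprintf("%d target(s) not in the network were dropped",
                    res$n_targets - res$n_mapped), call. = FALSE)
  }
  if (res$n_used < res$n_mapped) {
    warning(sprintf("%d target(s) unreachable from every disease gene were dropped",
                    res$n_mapped - res$n_used), call. = FALSE)
  }
  if (res$n_used == 0L) {
    warning("drug is unscorable: no usable target", call. = FALSE)
  }
  structure(res$distance, n_targets_used = res$n_used)
}

#' Size-matched random reference distribution of drug-disease distances
#'
#' Draws `n_samples` pseudo-drugs, each a uniform sample of `n_targets`
#' distinct network nodes, and scores each with the same weighted distance
#' used for real drugs (a sampled node that happens to be a disease gene
#' receives its weight). The resulting sample is the null against which a
#' real drug's distance is standardised.
#'
#' @inheritParams drug_distance
#' @param n_targets Number of nodes per random pseudo-drug (>= 1).
#' @param n_samples Number of random draws (>= 1).
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @param min_defined Warn when fewer than this many draws score to a defined
#'   value (e.g. all sampled nodes isolated).
#' @return Numeric vector of defined sample distances.
#' @export
reference_distribution <- function(net, disease_genes, n_targets, n_samples,
                                   seed = 1L, min_defined = 10L) {
  stopifnot(n_targets >= 1L, n_samples >= 1L)
  nodes <- network_nodes(net)
  if (length(nodes) < n_targets) {
    stop("network has fewer nodes than `n_targets`", call. = FALSE)
  }
  cache <- .proximity_cache(net, disease_genes)
  .reference_distribution_cached(cache, nodes, n_targets, n_samples, seed,
                                 min_defined)
}

.reference_distribution_cached <- function(cache, nodes, n_targets, n_samples,
                                           seed, min_defined = 10L) {
  rng <- .with_local_seed(seed)
  vals <- vapply(seq_len(n_samples), function(i) {
    draw <- sample(nodes, n_targets)
    .drug_distance_cached(cache, draw)$distance
  }, numeric(1))
  rng()
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop("no random draw produced a defined distance", call. = FALSE)
  }
  if (length(vals) < min_defined) {
    warning(sprintf("only %d of %d reference draws were defined",
                    length(vals), n_samples), call. = FALSE)
  }
  vals
}

# Set the RNG locally; returns a restorer to call when done.
.with_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Screen a table of drugs by network proximity to a disease gene set
#'
#' Scores every drug with the weighted closest distance, standardises each
#' against a size-matched random reference distribution (cached per
#' mapped-target count), and flags drugs with negative distance as selected.
#' Results are ranked ascending by distance with ties broken by drug id, so
#' the output is independent of input order.
#'
#' @inheritParams drug_distance
#' @param drug_targets Data frame with columns `drug_id` and `target` (extra
#'   columns ignored), one drug-target pair per row.
#' @param n_samples Reference draws per distinct mapped-target count; `0`
#'   skips the reference distribution (distance and selection are still
#'   produced, `ref_mean`/`ref_sd`/`z` come back `NA`).
#' @param seed Integer seed controlling the reference draws.
#' @return An object of class `proximity_screen`. [generics::tidy()] returns
#'   the ranked per-drug tibble (`drug_id`, `n_targets`, `n_targets_used`,
#'   `distance`, `ref_mean`, `ref_sd`, `z`, `selected`, `rank`);
#'   [generics::glance()] a one-row run summary. Unscorable drugs are kept in
#'   `$unscored`.
#' @examples
#' net <- interaction_network(
#'   data.frame(a = c("A", "A", "B"), b = c("B", "C", "C")), quiet = TRUE)
#' scr <- proximity_screen(net, disease_genes = c("A", "B"),
#'                         drug_targets = data.frame(drug_id = "d1", target = "A"),
#'                         n_samples = 50, seed = 1)
#' tidy(scr)
#' @export
proximity_screen <- function(net, disease_genes, drug_targets,
                             n_samples = 1000L, seed = 1L) {
  stopifnot(inherits(net, "interaction_network"))
  drug_targets <- as.data.frame(drug_targets)
  if (!all(c("drug_id", "target") %in% names(drug_targets))) {
    names(drug_targets)[1:2] <- c("drug_id", "target")
  }
  drug_targets$drug_id <- as.character(drug_targets$drug_id)
  drug_targets$target <- as.character(drug_targets$target)
  if (nrow(drug_targets) == 0L) stop("no drug-target pairs", call. = FALSE)

  cache <- .proximity_cache(net, disease_genes)
  nodes <- network_nodes(net)
  by_drug <- split(drug_targets$target, drug_targets$drug_id)

  scored <- purrr::map(by_drug, function(tg) .drug_distance_cached(cache, tg))
  res <- tibble::tibble(
    drug_id = names(by_drug),
    n_targets = unname(purrr::map_int(scored, "n_targets")),
    n_targets_used = unname(purrr::map_int(scored, "n_used")),
    distance = unname(purrr::map_dbl(scored, "distance"))
  )
  unscored <- dplyr::filter(res, is.na(.data$distance))
  res <- dplyr::filter(res, !is.na(.data$distance))
  if (nrow(res) == 0L) stop("no scorable drug", call. = FALSE)

  if (n_samples > 0L) {
    counts <- sort(unique(res$n_targets_used))
    # one cached reference per mapped-target count; seed offset by count so
    # references for different sizes are independent draws
    refs <- purrr::map(counts, function(k) {
      v <- .reference_distribution_cached(cache, nodes, k, n_samples,
                                          seed = seed + k)
      c(mean = mean(v), sd = stats::sd(v))
    })
    names(refs) <- as.character(counts)
    res <- dplyr::mutate(
      res,
      ref_mean = purrr::map_dbl(.data$n_targets_used,
                                ~ refs[[as.character(.x)]][["mean"]]),
      ref_sd = purrr::map_dbl(.data$n_targets_used,
                              ~ refs[[as.character(.x)]][["sd"]]),
      z = dplyr::if_else(.data$ref_sd > 0,
                         (.data$distance - .data$ref_mean) / .data$ref_sd,
                         NA_real_)
    )
  } else {
    res <- dplyr::mutate(res, ref_mean = NA_real_, ref_sd = NA_real_,
                         z = NA_real_)
  }

  res <- res |>
    dplyr::mutate(selected = .data$distance < 0) |>
    dplyr::arrange(.data$distance, .data$drug_id) |>
    dplyr::mutate(rank = dplyr::row_number())

  structure(
    list(results = res, unscored = unscored,
         meta = list(seed = seed, n_samples = n_samples,
                     n_disease_in_network = length(cache$disease_in_network),
                     n_nodes = length(nodes))),
    class = "proximity_screen"
  )
}

#' @export
print.proximity_screen <- function(x, ...) {
  cat(sprintf("<proximity_screen> %d drug(s) scored, %d selected (distance < 0), %d unscorable\n",
              nrow(x$results), sum(x$results$selected), nrow(x$unscored)))
  print(x$results, n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname proximity_screen
#' @param x,object A `proximity_screen`.
#' @param ... Unused.
#' @method tidy proximity_screen
#' @export
tidy.proximity_screen <- function(x, ...) x$results

#' @rdname proximity_screen
#' @method glance proximity_screen
#' @export
glance.proximity_screen <- function(x, ...) {
  tibble::tibble(
    n_drugs = nrow(x$results) + nrow(x$unscored),
    n_scored = nrow(x$results),
    n_selected = sum(x$results$selected),
    n_unscored = nrow(x$unscored),
    n_samples = x$meta$n_samples,
    seed = x$meta$seed
  )
}

#' @rdname proximity_screen
#' @method autoplot proximity_screen
#' @export
autoplot.proximity_screen <- function(object, ...) {
  dat <- object$results
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$distance,
                                    colour = .data$selected)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d73027",
                                            `FALSE` = "grey30"),
                                 name = "distance < 0") +
    ggplot2::labs(x = "rank (ascending distance)",
                  y = "weighted network distance to disease genes")
}
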