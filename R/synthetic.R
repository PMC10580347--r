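#' Simulate a PPI network with planted drug-disease proximity structure
#'
#' Builds a scale-free-ish interactome by preferential attachment (or a
#' degree-preserving configuration-model rewiring of it), plants a connected
#' disease-gene module, and creates drugs of three classes with known
#' ground truth:
#'
#' * `proximal_weighted` — every target is a disease gene with degree >= 1,
#'   so each target term is `0 - ln(D + 1) < 0` and the drug's weighted
#'   distance is negative by construction;
#' * `proximal_unweighted` — targets are non-disease first neighbours of the
#'   module (distance exactly 1, weight 0);
#' * `remote` — targets sit at least `remote_min_hops` hops from every
#'   disease gene.
#'
#' @param n_nodes Number of genes (default 200).
#' @param m Edges added per node in preferential attachment (default 2).
#' @param disease_module_size Size of the planted disease gene set
#'   (default 20).
#' @param drugs Data frame with columns `drug_id`, `class` (one of the three
#'   planted classes) and `n_targets`; default: three drugs per class with 3
#'   targets each.
#' @param remote_min_hops Minimum distance of remote-drug targets from the
#'   disease set (default 3).
#' @param model `"pa"` (preferential attachment) or `"config"`
#'   (configuration-model rewiring of the same degree sequence).
#' @param seed Integer seed; scenario + seed fully determine the output.
#' @return A list with `network` (an [interaction_network()]),
#'   `disease_genes` (character), `drug_targets` (tibble `drug_id`,
#'   `target`) and `truth` (tibble `drug_id`, `class`, `n_targets`).
#' @export
make_network <- function(n_nodes = 200L, m = 2L, disease_module_size = 20L,
                         drugs = NULL, remote_min_hops = 3L,
                         model = c("pa", "config"), seed = 1L) {
  model <- match.arg(model)
  stopifnot(disease_module_size < n_nodes, n_nodes >= 10L)
  if (is.null(drugs)) {
    drugs <- tibble::tibble(
      drug_id = c(paste0("PW", 1:3), paste0("PU", 1:3), paste0("RM", 1:3)),
      class = rep(c("proximal_weighted", "proximal_unweighted", "remote"),
                  each = 3),
      n_targets = 3L
    )
  }
  drugs <- tibble::as_tibble(drugs)
  stopifnot(all(drugs$class %in% c("proximal_weighted", "proximal_unweighted",
                                   "remote")))
  restore <- .with_local_seed(seed)
  on.exit(restore())

  g <- igraph::sample_pa(n_nodes, power = 1, m = m, directed = FALSE)
  if (model == "config") {
    g <- igraph::sample_degseq(igraph::degree(g), method = "vl")
  }
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n_nodes))

  # disease module: breadth-first ball around a peripheral (max-eccentricity)
  # node, guaranteeing a connected gene set while leaving nodes >= 3 hops
  # away for the remote drug class
  ecc <- igraph::eccentricity(g)
  start <- sample(which(ecc == max(ecc)), 1)
  bfs_order <- igraph::bfs(g, root = start, order = TRUE)$order
  disease <- igraph::V(g)$name[as.integer(bfs_order)[seq_len(disease_module_size)]]

  net <- interaction_network(igraph::as_data_frame(g, what = "edges"),
                             quiet = TRUE)
  min_d <- .proximity_cache(net, disease)$min_d
  nodes <- network_nodes(net)
  degn <- network_degree(net)

  disease_deg1 <- disease[degn[disease] >= 1]
  neighbours1 <- nodes[!is.na(min_d) & min_d == 1 & !(nodes %in% disease)]
  remote_pool <- nodes[is.na(min_d) | min_d >= remote_min_hops]

  pools <- list(proximal_weighted = disease_deg1,
                proximal_unweighted = neighbours1,
                remote = remote_pool)
  for (cl in unique(drugs$class)) {
    need <- max(drugs$n_targets[drugs$class == cl])
    if (length(pools[[cl]]) < need) {
      stop(sprintf("scenario unrealizable: only %d eligible node(s) for class %s (need %d)",
                   length(pools[[cl]]), cl, need), call. = FALSE)
    }
  }
  # proximal_weighted prefers hubs: sample weighted by degree
  dt <- purrr::pmap_dfr(drugs, function(drug_id, class, n_targets, ...) {
    pool <- pools[[class]]
    tg <- if (class == "proximal_weighted") {
      sample(pool, n_targets, prob = degn[pool])
    } else {
      sample(pool, n_targets)
    }
    tibble::tibble(drug_id = drug_id, target = tg)
  })
  list(network = net, disease_genes = disease, drug_targets = dt,
       truth = drugs[, c("drug_id", "class", "n_targets")])
}

#' Simulate a correlated Gaussian fluctuation trajectory
#'
#' One pseudo-atom (CA) per residue fluctuates around a random-walk
#' reference chain with planted per-residue fluctuation amplitudes and
#' planted inter-residue correlations. `sigma` is the target per-residue
#' RMSF in Angstrom (total 3-D amplitude; the per-axis SD is
#' `sigma / sqrt(3)`), so [rmsf_per_residue()] recovers it directly, and a
#' block with planted correlation `rho` is recovered by [dccm()].
#'
#' The displacement field is sampled axis-wise from a multivariate normal
#' with correlation matrix `R` (1 on the diagonal, `rho` between the
#' residues of each block pair), which gives residue-vector correlation
#' exactly `rho`. `R` must be positive semi-definite; offending blocks are
#' reported otherwise.
#'
#' @param n_residues Number of residues.
#' @param n_frames Number of frames (>= 1).
#' @param dt Frame spacing in ns (default 0.05 ns, i.e. 2000 frames = 100 ns).
#' @param sigma Per-residue RMSF in Angstrom, recycled to `n_residues`.
#' @param blocks List of correlation blocks, each
#'   `list(i = <residues>, j = <residues>, rho = <cor>)`; `i == j` plants a
#'   within-block correlation.
#' @param rotate Add a slow global rotation (about z, one full turn over the
#'   run) plus a linear translation drift, to exercise superposition.
#' @param expand_backbone Add N, C, O atoms at fixed offsets from each CA
#'   (rigid within the residue).
#' @param seed Integer seed.
#' @return An [md_trajectory()].
#' @export
make_trajectory <- function(n_residues = 40L, n_frames = 500L, dt = 0.05,
                            sigma = 1, blocks = list(), rotate = FALSE,
                            expand_backbone = FALSE, seed = 1L) {
  stopifnot(n_residues >= 2L, n_frames >= 1L)
  sigma <- rep_len(sigma, n_residues)
  stopifnot(all(sigma >= 0))
  restore <- .with_local_seed(seed)
  on.exit(restore())

  R <- diag(n_residues)
  for (b in blocks) {
    stopifnot(all(b$i >= 1 & b$i <= n_residues),
              all(b$j >= 1 & b$j <= n_residues), abs(b$rho) <= 1)
    R[b$i, b$j] <- b$rho
    R[b$j, b$i] <- b$rho
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("planted correlation matrix is not positive semi-definite; ",
         "check overlapping blocks", call. = FALSE)
  }
  # PSD square root tolerant of exactly-singular R
  es <- eigen(R, symmetric = TRUE)
  L <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), n_residues)

  ref <- .random_chain(n_residues)
  sd_axis <- sigma / sqrt(3)
  arr <- array(NA_real_, c(n_frames, n_residues, 3))
  for (k in 1:3) {
    z <- matrix(stats::rnorm(n_frames * n_residues), n_frames)
    disp <- z %*% t(L)                       # rows ~ N(0, R)
    disp <- sweep(disp, 2, sd_axis, `*`)
    arr[, , k] <- sweep(disp, 2, ref[, k], `+`)
  }
  if (rotate) {
    for (f in seq_len(n_frames)) {
      th <- 2 * pi * (f - 1) / max(n_frames - 1, 1)
      Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
      arr[f, , ] <- matrix(arr[f, , ], ncol = 3) %*% t(Rz) +
        matrix((f - 1) * 0.02, n_residues, 3)
    }
  }
  atoms <- tibble::tibble(name = "CA", resid = seq_len(n_residues),
                          element = "C")
  if (expand_backbone) {
    offsets <- rbind(N = c(-1.46, 0, 0), C = c(1.52, 0, 0), O = c(2.2, 1.0, 0))
    na0 <- n_residues * (1 + nrow(offsets))
    arr2 <- array(NA_real_, c(n_frames, na0, 3))
    name <- character(na0)
    resid <- integer(na0)
    idx <- 1L
    for (r in seq_len(n_residues)) {
      arr2[, idx, ] <- arr[, r, ]
      name[idx] <- "CA"; resid[idx] <- r; idx <- idx + 1L
      for (o in rownames(offsets)) {
        arr2[, idx, ] <- sweep(matrix(arr[, r, ], ncol = 3), 2, offsets[o, ],
                               `+`)
        name[idx] <- o; resid[idx] <- r; idx <- idx + 1L
      }
    }
    arr <- arr2
    atoms <- tibble::tibble(name = name, resid = resid,
                            element = substr(name, 1, 1))
  }
  md_trajectory(arr, atoms, dt)
}

# tethered random-walk CA chain: ~3.8 A steps with a pull toward the origin,
# giving a compact globule-like reference whose rigid-fit leverage is spread
# evenly across residues (a free walk concentrates it at the chain ends)
.random_chain <- function(n) {
  pos <- matrix(0, n, 3)
  p <- c(0, 0, 0)
  for (i in seq_len(n)) {
    u <- stats::rnorm(3)
    p <- 0.85 * p + 3.8 * u / sqrt(sum(u^2))
    pos[i, ] <- p
  }
  pos
}

#' Simulate a trajectory with planted principal modes
#'
#' Frames are `reference + sum_k a_k(t) v_k` with orthonormal mode vectors
#' `v_k` (orthogonalised against the six rigid-body motions of the reference,
#' so superposition does not absorb them) and independent Gaussian
#' amplitudes of the given variances. The PCA variance fractions then
#' recover `mode_variances / sum(mode_variances)`.
#'
#' @inheritParams make_trajectory
#' @param mode_variances Variances of the planted mode amplitudes
#'   (default `c(9, 1)`, a 9:1 two-mode system).
#' @return An [md_trajectory()].
#' @export
make_mode_trajectory <- function(n_residues = 40L, n_frames = 500L, dt = 0.05,
                                 mode_variances = c(9, 1), seed = 1L) {
  stopifnot(length(mode_variances) >= 1, all(mode_variances > 0),
            3 * n_residues >= length(mode_variances) + 6)
  restore <- .with_local_seed(seed)
  on.exit(restore())
  ref <- .random_chain(n_residues)
  n3 <- 3 * n_residues
  # rigid-body subspace: 3 translations + 3 rotation generators about the
  # reference centroid (coordinates stacked axis-major to match PCA)
  cen <- sweep(ref, 2, colMeans(ref))
  rigid <- matrix(0, n3, 6)
  for (k in 1:3) rigid[(k - 1) * n_residues + seq_len(n_residues), k] <- 1
  axes <- diag(3)
  for (k in 1:3) {
    gen <- t(apply(cen, 1, function(p) c(axes[k, 2] * p[3] - axes[k, 3] * p[2],
                                         axes[k, 3] * p[1] - axes[k, 1] * p[3],
                                         axes[k, 1] * p[2] - axes[k, 2] * p[1])))
    rigid[, 3 + k] <- as.vector(gen)  # column-major: axis-major stacking
  }
  basis <- qr.Q(qr(cbind(rigid,
                         matrix(stats::rnorm(n3 * length(mode_variances)),
                                n3))))
  modes <- basis[, 6 + seq_along(mode_variances), drop = FALSE]
  amp <- sapply(seq_along(mode_variances), function(k) {
    stats::rnorm(n_frames, sd = sqrt(mode_variances[k]))
  })
  flat <- matrix(rep(as.vector(ref), each = n_frames), n_frames) +
    amp %*% t(modes)
  arr <- array(flat, c(n_frames, n_residues, 3))
  md_trajectory(arr, tibble::tibble(name = "CA", resid = seq_len(n_residues),
                                    element = "C"), dt)
}

#' Simulate a two-group expression matrix with planted effect sizes
#'
#' Per-gene values are Gaussian noise; each signal gene's case mean is
#' shifted by `d * noise_sd`, so the planted value is the population
#' Cohen's d.
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Samples per group.
#' @param signal Named numeric vector of planted d values (names must be
#'   gene labels among `gene1 ... geneN`), or `NULL` for an all-null matrix.
#' @param noise_sd Within-group SD (default 1).
#' @param seed Integer seed.
#' @return An `expression_matrix` (list with `values`, `group`, `truth`).
#' @export
make_expression <- function(n_genes = 100L, n_case = 10L, n_control = 10L,
                            signal = NULL, noise_sd = 1, seed = 1L) {
  stopifnot(n_genes >= 1L, n_case >= 2L, n_control >= 2L, noise_sd > 0)
  genes <- paste0("gene", seq_len(n_genes))
  if (!is.null(signal)) {
    stopifnot(!is.null(names(signal)), all(names(signal) %in% genes))
  }
  restore <- .with_local_seed(seed)
  on.exit(restore())
  n <- n_case + n_control
  values <- matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n,
                   dimnames = list(genes,
                                   c(paste0("case", seq_len(n_case)),
                                     paste0("ctrl", seq_len(n_control)))))
  group <- rep(c("case", "control"), c(n_case, n_control))
  if (!is.null(signal)) {
    values[names(signal), group == "case"] <-
      values[names(signal), group == "case"] +
      signal * noise_sd
  }
  truth <- tibble::tibble(gene = genes,
                          planted_d = ifelse(genes %in% names(signal),
                                             signal[genes], 0))
  structure(list(values = values, group = group, truth = truth),
            class = "expression_matrix")
}
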