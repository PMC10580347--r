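# Independent oracles, deliberately naive: plain-R BFS / Floyd-Warshall /
# double-loop scoring / rotation search, sharing no code with the package.

# adjacency list from a two-column edge data frame (undirected, no loops)
adj_list <- function(edges) {
  nodes <- sort(unique(c(edges[[1]], edges[[2]])))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges[[1]][r]; b <- edges[[2]][r]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# breadth-first distances from one source; NA for unreachable
bfs_dist <- function(adj, src) {
  d <- stats::setNames(rep(NA_real_, length(adj)), names(adj))
  d[src] <- 0
  queue <- src
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) {
      if (is.na(d[u])) {
        d[u] <- d[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  d
}

# all-pairs shortest paths by Floyd-Warshall on the adjacency matrix
floyd_warshall <- function(edges) {
  nodes <- sort(unique(c(edges[[1]], edges[[2]])))
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    a <- edges[[1]][r]; b <- edges[[2]][r]
    if (a == b) next
    D[a, b] <- 1; D[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# literal double-loop weighted drug-disease distance over all (s, t) pairs
brute_drug_distance <- function(edges, disease, targets) {
  adj <- adj_list(edges)
  nodes <- names(adj)
  deg <- vapply(adj, length, 1L)
  s_in <- intersect(disease, nodes)
  terms <- c()
  for (t in intersect(unique(targets), nodes)) {
    dt <- bfs_dist(adj, t)
    best <- Inf
    for (s in s_in) if (!is.na(dt[s]) && dt[s] < best) best <- dt[s]
    if (is.infinite(best)) next
    w <- if (t %in% s_in) -log(deg[[t]] + 1) else 0
    terms <- c(terms, best + w)
  }
  if (length(terms) == 0) NA_real_ else mean(terms)
}

# random Erdos-Renyi-ish edge table over n nodes
random_edges <- function(n, p = 0.08) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(a = pairs[1, keep], b = pairs[2, keep],
             stringsAsFactors = FALSE)
}

# best RMSD over rotations by coarse Euler grid + Nelder-Mead polish,
# independent of the SVD route
gridsearch_rmsd <- function(mobile, reference) {
  Pc <- sweep(mobile, 2, colMeans(mobile))
  Qc <- sweep(reference, 2, colMeans(reference))
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((Pc %*% t(rot(ang)) - Qc)^2)))
  grid <- seq(0, 2 * pi, length.out = 7)[-7]
  best <- Inf
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best) { best <- v; start <- c(a1, a2, a3) }
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# small deterministic trajectory builders used across test files
path_graph_edges <- function(symbols) {
  data.frame(a = symbols[-length(symbols)], b = symbols[-1],
             stringsAsFactors = FALSE)
}

# apply one global rigid motion (rotation about a random axis + translation)
# to every frame of a trajectory
rigid_motion <- function(traj, angle = 1.1, axis = c(1, 2, 2),
                         shift = c(5, -3, 7)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  arr <- traj$coords
  for (f in seq_len(dim(arr)[1])) {
    arr[f, , ] <- sweep(matrix(arr[f, , ], ncol = 3) %*% t(R), 2, shift, `+`)
  }
  md_trajectory(arr, traj$atoms, traj$dt)
}
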