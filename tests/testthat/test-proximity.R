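test_that("target weight follows the disease-gene degree rule", {
  expect_identical(target_weight(5, FALSE), 0)
  expect_identical(target_weight(0, TRUE), 0)   # -ln(1)
  expect_equal(target_weight(1, TRUE), -log(2))
  expect_equal(target_weight(c(3, 3), c(TRUE, FALSE)), c(-log(4), 0))
  expect_error(target_weight(-1, TRUE), "non-negative")
})

test_that("drug distance on hand-built graphs matches analytic values", {
  # path A-B-C-D, disease {A}, target {C}: d = 2 + 0
  net <- interaction_network(path_graph_edges(c("A", "B", "C", "D")),
                             quiet = TRUE)
  expect_equal(as.numeric(drug_distance(net, "A", "C")), 2)

  # star: hub H, 3 leaves; disease {H}, target {H}: 0 - ln(3+1)
  star <- interaction_network(data.frame(a = "H", b = c("L1", "L2", "L3")),
                              quiet = TRUE)
  expect_equal(as.numeric(drug_distance(star, "H", "H")), -log(4))

  # a disease-gene target always contributes 0 + w
  expect_equal(as.numeric(drug_distance(net, c("A", "B"), c("B", "D"))),
               mean(c(-log(3), 2)))
})

test_that("unmapped and unreachable targets are dropped, never zero-filled", {
  net <- interaction_network(data.frame(a = c("A", "X"), b = c("B", "Y")),
                             quiet = TRUE)
  expect_warning(d <- drug_distance(net, "A", c("B", "NOPE")), "not in the network")
  expect_equal(as.numeric(d), 1)
  expect_equal(attr(d, "n_targets_used"), 1L)
  # X,Y unreachable from disease component
  expect_warning(expect_warning(
    d2 <- drug_distance(net, "A", c("X", "Y")), "unreachable"), "unscorable")
  expect_true(is.na(as.numeric(d2)))
  expect_error(drug_distance(net, "ZZZ", "B"), "no disease gene")
})

test_that("drug distance equals a literal double-loop brute force", {
  set.seed(91)
  for (rep in 1:10) {
    edges <- random_edges(40, p = 0.07)
    net <- interaction_network(edges, quiet = TRUE)
    nodes <- network_nodes(net)
    S <- sample(nodes, 5)
    T_ <- sample(nodes, 3)
    want <- brute_drug_distance(edges, S, T_)
    got <- suppressWarnings(as.numeric(drug_distance(net, S, T_)))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("reference distribution is seed-deterministic and analytic on K5", {
  k5 <- interaction_network(as.data.frame(t(utils::combn(paste0("V", 1:5), 2)),
                                          stringsAsFactors = FALSE),
                            quiet = TRUE)
  r1 <- reference_distribution(k5, "V1", n_targets = 1, n_samples = 40,
                               seed = 5, min_defined = 1)
  r2 <- reference_distribution(k5, "V1", n_targets = 1, n_samples = 40,
                               seed = 5, min_defined = 1)
  expect_identical(r1, r2)
  # every non-disease draw scores exactly 1; a draw of V1 itself 0 - ln(5)
  expect_true(all(r1 %in% c(1, -log(5))))
  expect_true(any(r1 == 1))
})

test_that("reference mean/sd match an independent re-implementation", {
  set.seed(13)
  edges <- random_edges(60, p = 0.06)
  net <- interaction_network(edges, quiet = TRUE)
  nodes <- network_nodes(net)
  S <- sample(nodes, 6)
  got <- reference_distribution(net, S, n_targets = 3, n_samples = 200,
                                seed = 99)
  # same RNG protocol, scoring via the brute-force oracle
  set.seed(99)
  want <- vapply(1:200, function(i) {
    brute_drug_distance(edges, S, sample(nodes, 3))
  }, numeric(1))
  want <- want[!is.na(want)]
  expect_equal(mean(got), mean(want), tolerance = 1e-12)
  expect_equal(stats::sd(got), stats::sd(want), tolerance = 1e-12)
})

test_that("screen applies the negative-distance rule and ranks stably", {
  net <- interaction_network(path_graph_edges(c("A", "B", "C", "D", "E")),
                             quiet = TRUE)
  dt <- data.frame(drug_id = c("neg", "pos"), target = c("A", "D"))
  scr <- proximity_screen(net, disease_genes = c("A", "B"), dt,
                          n_samples = 0, seed = 1)
  res <- tidy(scr)
  expect_equal(res$drug_id, c("neg", "pos"))      # ascending distance
  expect_equal(res$selected, c(TRUE, FALSE))
  expect_equal(sum(res$selected), 1L)
  expect_equal(res$rank, 1:2)
})

test_that("screen output is invariant to input drug order and seeded", {
  sc <- make_network(seed = 8)
  scr1 <- proximity_screen(sc$network, sc$disease_genes, sc$drug_targets,
                           n_samples = 100, seed = 3)
  shuffled <- sc$drug_targets[rev(seq_len(nrow(sc$drug_targets))), ]
  scr2 <- proximity_screen(sc$network, sc$disease_genes, shuffled,
                           n_samples = 100, seed = 3)
  expect_identical(tidy(scr1), tidy(scr2))
})

test_that("z-scores satisfy their defining identity and degraded mode works", {
  sc <- make_network(seed = 21)
  scr <- proximity_screen(sc$network, sc$disease_genes, sc$drug_targets,
                          n_samples = 150, seed = 4)
  res <- tidy(scr)
  expect_equal(res$z, (res$distance - res$ref_mean) / res$ref_sd)
  expect_equal(res$selected, res$distance < 0)

  res0 <- tidy(proximity_screen(sc$network, sc$disease_genes,
                                sc$drug_targets, n_samples = 0, seed = 4))
  expect_true(all(is.na(res0$z)))
  expect_equal(res0$distance,
               res[match(res0$drug_id, res$drug_id), ]$distance)
})

test_that("a drug with no disease-gene target has non-negative distance", {
  set.seed(55)
  for (rep in 1:8) {
    edges <- random_edges(30, p = 0.1)
    net <- interaction_network(edges, quiet = TRUE)
    nodes <- network_nodes(net)
    S <- sample(nodes, 4)
    T_ <- sample(setdiff(nodes, S), 3)
    d <- suppressWarnings(as.numeric(drug_distance(net, S, T_)))
    if (!is.na(d)) expect_gte(d, 0)
  }
})

test_that("negative distance implies a connected disease-gene target", {
  set.seed(56)
  n_negative <- 0L
  for (rep in 1:12) {
    edges <- random_edges(30, p = 0.1)
    net <- interaction_network(edges, quiet = TRUE)
    nodes <- network_nodes(net)
    S <- sample(nodes, 6)
    # bias targets toward S so negative totals actually occur
    T_ <- unique(c(sample(S, 2), sample(nodes, 1)))
    d <- suppressWarnings(as.numeric(drug_distance(net, S, T_)))
    if (!is.na(d) && d < 0) {
      n_negative <- n_negative + 1L
      deg <- network_degree(net, intersect(T_, S))
      expect_true(length(deg) > 0 && any(deg >= 1))
    }
  }
  expect_gt(n_negative, 0L)
})

test_that("enlarging the disease set never increases a drug's distance", {
  set.seed(77)
  for (rep in 1:8) {
    edges <- random_edges(35, p = 0.08)
    net <- interaction_network(edges, quiet = TRUE)
    nodes <- network_nodes(net)
    S <- sample(nodes, 4)
    extra <- sample(setdiff(nodes, S), 4)
    T_ <- sample(nodes, 3)
    d1 <- suppressWarnings(as.numeric(drug_distance(net, S, T_)))
    d2 <- suppressWarnings(as.numeric(drug_distance(net, c(S, extra), T_)))
    if (!is.na(d1) && !is.na(d2) &&
        attr(suppressWarnings(drug_distance(net, S, T_)), "n_targets_used") ==
        attr(suppressWarnings(drug_distance(net, c(S, extra), T_)),
             "n_targets_used")) {
      expect_lte(d2, d1 + 1e-12)
    }
  }
})

test_that("z-scores of reference samples have mean ~0 and sd ~1", {
  sc <- make_network(n_nodes = 150, seed = 30)
  ref <- reference_distribution(sc$network, sc$disease_genes, n_targets = 3,
                                n_samples = 1000, seed = 17)
  z <- (ref - mean(ref)) / stats::sd(ref)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
})
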