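test_that("edges are gated by persistency, adjacency and the |C| floor", {
  resno <- 1:5
  C <- manual_corr(resno, {
    M <- diag(5)
    M[1, 3] <- M[3, 1] <- 1        # W = 0 edge
    M[1, 4] <- M[4, 1] <- 0.5
    M[2, 4] <- M[4, 2] <- 0.9
    M[2, 5] <- M[5, 2] <- 0        # below floor: dropped
    M
  })
  contacts <- manual_contact_table(
    resno_a = c(1, 1, 2, 2, 1),
    resno_b = c(3, 4, 4, 5, 2),
    persistency = c(100, 74.9, 75.0, 80, 100))
  expect_warning(net <- build_network(C, contacts), "floor")
  e <- network_edges(net)
  # 1-2 consecutive excluded; 1-4 fails the 75% gate by 0.1; 2-5 floor-dropped
  expect_equal(e[, c("from", "to")],
               data.frame(from = c(1, 2), to = c(3, 4)),
               ignore_attr = TRUE)
  expect_equal(e$weight[e$from == 1], 0)               # -log(1)
  expect_equal(e$weight[e$from == 2], -log(0.9))
  # exactly 75.0% gates in
  expect_true(any(e$from == 2 & e$to == 4))
})

test_that("a consecutive-only chain yields an empty edge set", {
  C <- manual_corr(1:5, matrix(0.9, 5, 5) + diag(5) * 0.1)
  contacts <- manual_contact_table(1:4, 2:5, rep(100, 4))
  net <- build_network(C, contacts)
  expect_equal(igraph::ecount(net$graph), 0)
  # with exclusion off the same chain is fully connected
  net2 <- build_network(C, contacts,
                        network_params(exclude_consecutive = FALSE))
  expect_equal(igraph::ecount(net2$graph), 4)
})

test_that("raising the persistency threshold never adds edges", {
  set.seed(61)
  for (k in 1:5) {
    n <- 8
    pairs <- expand.grid(resno_a = 1:n, resno_b = 1:n)
    pairs <- pairs[pairs$resno_a < pairs$resno_b, ]
    contacts <- manual_contact_table(pairs$resno_a, pairs$resno_b,
                                     runif(nrow(pairs), 0, 100))
    M <- diag(n); M[upper.tri(M)] <- runif(n * (n - 1) / 2, 0.1, 0.9)
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    C <- manual_corr(1:n, M)
    prev <- Inf
    for (thr in c(25, 50, 75, 90)) {
      ec <- igraph::ecount(build_network(C, contacts,
               network_params(persistency_threshold = thr))$graph)
      expect_lte(ec, prev)
      prev <- ec
    }
  }
})

test_that("shortest paths match exhaustive enumeration with lexicographic ties", {
  net <- network_from_edges(data.frame(from = c(1, 2, 1), to = c(2, 3, 3),
                                       weight = c(1, 1, 3)))
  sp <- net_shortest_path(net, 1, 3)
  expect_equal(sp$path, c(1, 2, 3))
  expect_equal(sp$cost, 2)
  single <- network_from_edges(data.frame(from = 1, to = 2, weight = 0.4))
  expect_equal(net_shortest_path(single, 1, 2)$path, c(1, 2))
  # tie: 1-2-4 and 1-3-4 both cost 2; lexicographic pick is 1-2-4
  tie <- network_from_edges(data.frame(from = c(1, 1, 2, 3),
                                       to = c(2, 3, 4, 4), weight = 1))
  expect_equal(net_shortest_path(tie, 1, 4)$path, c(1, 2, 4))
  disc <- network_from_edges(data.frame(from = 1, to = 2, weight = 1),
                             nodes = 1:3)
  res <- net_shortest_path(disc, 1, 3)
  expect_false(res$found)
  expect_equal(res$cost, Inf)
  set.seed(62)
  for (k in 1:20) {
    n <- sample(6:12, 1)
    e <- random_test_graph(n)
    net <- network_from_edges(e, nodes = 1:n)
    st <- sample.int(n, 2)
    expect_equal(net_shortest_path(net, st[1], st[2])$cost,
                 bf_shortest_cost(e, n, st[1], st[2]), tolerance = 1e-9)
  }
})

test_that("suboptimal path ensembles equal exhaustive enumeration", {
  dia <- network_from_edges(data.frame(from = c(1, 1, 2, 3),
                                       to = c(2, 3, 4, 4), weight = 1))
  pe <- suboptimal_paths(dia, 1, 4, tolerance = 0)
  expect_equal(length(pe$paths), 2)
  expect_equal(pe$edge_usage$count, rep(1L, 4))
  pe0 <- suboptimal_paths(dia, 1, 4, tolerance = 0)
  expect_false(pe0$truncated)
  set.seed(63)
  for (k in 1:10) {
    n <- sample(6:10, 1)
    e <- random_test_graph(n)
    net <- network_from_edges(e, nodes = 1:n)
    st <- sample.int(n, 2)
    tol <- 1.0
    pe <- suboptimal_paths(net, st[1], st[2], tolerance = tol)
    bf <- bf_all_paths(e, n, st[1], st[2])
    keep <- bf$costs <= min(bf$costs) + tol + 1e-9
    expect_equal(length(pe$paths), sum(keep))
    expect_setequal(vapply(pe$paths, paste, "", collapse = "-"),
                    vapply(bf$paths[keep], paste, "", collapse = "-"))
  }
  # truncation guard flags capped enumerations
  pe_cap <- suboptimal_paths(dia, 1, 4, tolerance = 0, max_paths = 1L)
  expect_true(pe_cap$truncated)
})

test_that("edge betweenness matches hand counts and the brute-force oracle", {
  path3 <- network_from_edges(data.frame(from = c(1, 2), to = c(2, 3),
                                         weight = 1))
  b <- net_edge_betweenness(path3)
  expect_equal(b$betweenness, c(2, 2))   # pairs {1,2},{1,3} and {2,3},{1,3}
  star <- network_from_edges(data.frame(from = rep(1, 4), to = 2:5,
                                        weight = 0.7))
  bs <- net_edge_betweenness(star)
  expect_true(all(bs$betweenness == bs$betweenness[1]))
  set.seed(64)
  for (k in 1:10) {
    n <- sample(6:10, 1)
    e <- random_test_graph(n)
    net <- network_from_edges(e, nodes = 1:n)
    mine <- net_edge_betweenness(net)
    oracle <- bf_edge_betweenness(e, n)
    key <- paste(mine$from, mine$to, sep = ":")
    expect_equal(mine$betweenness, unname(oracle[key]), tolerance = 1e-9)
  }
})

test_that("Girvan-Newman separates cliques and resists over-splitting", {
  cl <- expand.grid(from = 1:10, to = 1:10)
  cl <- cl[cl$from < cl$to, ]
  edges <- rbind(cl, transform(cl, from = from + 10, to = to + 10),
                 data.frame(from = 1, to = 11))
  edges$corr <- 0.8
  net <- network_from_edges(edges)
  cm <- detect_communities(net)
  expect_equal(cm$n_communities, 2)
  expect_equal(partition_agreement(cm, rep(1:2, each = 10)), 1)
  # complete graph: no split improves modularity
  full <- network_from_edges(transform(cl, corr = 0.8))
  expect_equal(detect_communities(full)$n_communities, 1)
})

test_that("community labels are invariant under node relabelling", {
  net <- gen_planted_network(6, 2, 0.9, 0.05, seed = 65)
  e <- network_edges(net)
  perm <- sample(12)
  e2 <- data.frame(from = perm[e$from], to = perm[e$to], corr = e$corr)
  cm1 <- detect_communities(net)
  cm2 <- detect_communities(network_from_edges(e2, nodes = 1:12))
  # push detected labels back through the permutation and compare
  m2 <- cm2$membership[as.character(perm)]
  expect_equal(partition_agreement(cm1$membership, m2), 1)
  expect_equal(cm1$modularity, cm2$modularity, tolerance = 1e-12)
})

test_that("scaling all |C| by a constant shifts every weight equally", {
  M <- diag(4)
  M[1, 3] <- M[3, 1] <- 0.8; M[2, 4] <- M[4, 2] <- 0.5
  contacts <- manual_contact_table(c(1, 2), c(3, 4), c(100, 100))
  for (cc in c(0.25, 0.5, 1)) {
    net1 <- build_network(manual_corr(1:4, M), contacts)
    net2 <- build_network(manual_corr(1:4, M * cc + diag(4) * (1 - cc)),
                          contacts)
    shift <- network_edges(net2)$weight - network_edges(net1)$weight
    expect_equal(shift, rep(-log(cc), 2), tolerance = 1e-12)
  }
})

test_that("log-base change rescales weights but not paths or communities", {
  set.seed(66)
  for (k in 1:5) {
    n <- 8
    e <- random_test_graph(n, wmin = 0.1, wmax = 1.5)
    e$corr <- exp(-e$weight); e$weight <- NULL
    n_e <- network_from_edges(e, nodes = 1:n, log_base = exp(1))
    n_10 <- network_from_edges(e, nodes = 1:n, log_base = 10)
    expect_equal(network_edges(n_10)$weight,
                 network_edges(n_e)$weight / log(10), tolerance = 1e-12)
    st <- sample.int(n, 2)
    expect_identical(net_shortest_path(n_e, st[1], st[2])$path,
                     net_shortest_path(n_10, st[1], st[2])$path)
    expect_identical(detect_communities(n_e)$membership,
                     detect_communities(n_10)$membership)
  }
})

test_that("subnetworks induce, summarise and reject empty sets", {
  net <- gen_planted_network(5, 2, 1, 0.3, seed = 67)
  full <- subnetwork(net, 1:10)
  expect_equal(igraph::ecount(full$network$graph),
               igraph::ecount(net$graph))
  e <- network_edges(net)
  sub <- subnetwork(net, 1:5)
  expect_equal(sub$summary$edges, sum(e$from <= 5 & e$to <= 5))
  expect_error(subnetwork(net, 90:95), "empty induced")
  # edgeless induced set: nodes kept, no edges
  iso <- subnetwork(net, c(1, 10))
  expect_equal(iso$summary$nodes, 2)
})

test_that("network comparison classifies gained, lost and common edges", {
  e <- data.frame(from = c(1, 1, 2), to = c(3, 4, 4),
                  corr = c(0.9, 0.8, 0.7))
  a <- network_from_edges(e, nodes = 1:4)
  same <- compare_networks(a, a)
  expect_true(all(same$status == "common"))
  expect_equal(same$delta_w, rep(0, 3))
  b <- network_from_edges(e[-2, ], nodes = 1:4)
  d <- compare_networks(a, b)
  expect_equal(sum(d$status == "lost"), 1)
  expect_equal(d[d$status == "lost", c("from", "to")],
               data.frame(from = 1, to = 4), ignore_attr = TRUE)
  e2 <- rbind(e, data.frame(from = 3, to = 4, corr = 0.6))
  e2$corr[1] <- 0.5
  g <- compare_networks(a, network_from_edges(e2, nodes = 1:4))
  expect_equal(sum(g$status == "gained"), 1)
  expect_equal(g$delta_w[g$from == 1 & g$to == 3],
               -log(0.5) - -log(0.9), tolerance = 1e-12)
  disjoint <- network_from_edges(data.frame(from = 90, to = 91, corr = 0.5))
  expect_error(compare_networks(a, disjoint), "disjoint")
})
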