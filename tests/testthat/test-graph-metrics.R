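test_that("closed-form values on canonical graphs", {
  k3 <- complete_graph(3)
  expect_equal(nodal_clustering(k3), rep(1, 3))
  expect_equal(nodal_local_efficiency(k3), rep(1, 3))

  star <- matrix(0L, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1L
  expect_equal(nodal_clustering(star)[1], 0)
  expect_equal(nodal_local_efficiency(star)[1], 0)

  p3 <- path_graph(3)
  expect_equal(nodal_local_efficiency(p3)[2], 0)  # neighbours unconnected
  expect_equal(as.numeric(characteristic_path_length(p3)), 4 / 3)
  expect_equal(global_efficiency(p3), (1 + 1 + 1 / 2) / 3)

  k4 <- complete_graph(4)
  expect_equal(as.numeric(characteristic_path_length(k4)), 1)
  expect_equal(global_efficiency(k4), 1)
  expect_equal(mean(nodal_clustering(k4)), 1)

  two_k2 <- matrix(0L, 4, 4)
  two_k2[1, 2] <- two_k2[2, 1] <- two_k2[3, 4] <- two_k2[4, 3] <- 1L
  expect_equal(global_efficiency(two_k2), 1 / 3)
  lp <- characteristic_path_length(two_k2)
  expect_equal(as.numeric(lp), 1)  # reachable pairs only
  expect_equal(attr(lp, "n_unreachable"), 4)
  expect_equal(as.numeric(characteristic_path_length(two_k2, "harmonic")), 3)
  expect_equal(as.numeric(characteristic_path_length(two_k2, "inf")), Inf)
  # harmonic convention on connected graphs is the inverse efficiency
  expect_equal(as.numeric(characteristic_path_length(p3, "harmonic")),
               1 / global_efficiency(p3))
})

test_that("metrics equal brute-force enumeration on random graphs", {
  withr::with_seed(11, {
    for (k in 1:110) {
      n <- sample(4:15, 1)
      adj <- random_adjacency(n, runif(1, 0.15, 0.7))
      expect_equal(nodal_clustering(adj), brute_ncp(adj))
      expect_equal(nodal_local_efficiency(adj), brute_nle(adj))
      expect_equal(global_efficiency(adj), brute_eg(adj))
      expect_equal(as.numeric(characteristic_path_length(adj)),
                   brute_lp(adj))
    }
  })
})

test_that("null ensembles preserve degrees and reproduce under a seed", {
  withr::with_seed(12, adj <- random_adjacency(20, 0.3))
  nulls <- random_null_ensemble(adj, M = 20, seed = 99)
  deg0 <- rowSums(adj)
  for (h in nulls) {
    expect_equal(unname(igraph::degree(h)), unname(deg0))
  }
  nulls2 <- random_null_ensemble(adj, M = 20, seed = 99)
  expect_equal(lapply(nulls, igraph::as_edgelist),
               lapply(nulls2, igraph::as_edgelist))

  star <- matrix(0L, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1L
  expect_warning(random_null_ensemble(star, M = 3, seed = 1), "unchanged")
})

test_that("rewiring destroys lattice clustering", {
  ring <- igraph::sample_smallworld(1, 30, 3, 0)  # pure ring lattice
  adj <- igraph::as_adjacency_matrix(ring, sparse = FALSE)
  nulls <- random_null_ensemble(adj, M = 30, seed = 5)
  cp_null <- mean(vapply(nulls, function(h) mean(nodal_clustering(h)),
                         numeric(1)))
  expect_lt(cp_null, mean(nodal_clustering(adj)))
})

test_that("small-worldness behaves canonically", {
  withr::with_seed(13, adj <- random_adjacency(12, 0.4))
  expect_equal(small_worldness(adj, list(adj)), 1)  # self as sole null

  ws <- withr::with_seed(14,
    igraph::sample_smallworld(1, 50, 3, 0.1))
  ws_adj <- igraph::as_adjacency_matrix(ws, sparse = FALSE)
  nulls <- random_null_ensemble(ws_adj, M = 100, seed = 6)
  expect_gt(small_worldness(ws_adj, nulls), 1)

  er <- withr::with_seed(15, igraph::sample_gnp(50, 0.2))
  er_adj <- igraph::as_adjacency_matrix(er, sparse = FALSE)
  nulls_er <- random_null_ensemble(er_adj, M = 100, seed = 7)
  expect_equal(small_worldness(er_adj, nulls_er), 1, tolerance = 0.15)

  # bit-for-bit reproducible under fixed seed and M
  expect_identical(small_worldness(ws_adj, random_null_ensemble(ws_adj, 50, 8)),
                   small_worldness(ws_adj, random_null_ensemble(ws_adj, 50, 8)))
})

test_that("threshold-curve AUC follows the quadrature rules", {
  taus <- seq(0.4, 0.9, by = 0.05)
  expect_equal(auc_threshold(taus, rep(0.5, 11)), 0.25)
  lin <- seq(1, 0, length.out = 11)
  expect_equal(auc_threshold(taus, lin), 0.25)
  expect_equal(auc_threshold(taus, rep(0.5, 11), rule = "rectangle"), 0.25)
  expect_equal(auc_threshold(taus, lin, rule = "rectangle"),
               sum(0.05 * lin[1:10]))
})

test_that("metric curves: aggregation identities and monotonicity", {
  withr::with_seed(16, m <- matrix(rnorm(53 * 300), 53, 300))
  conn <- suppressWarnings(build_connectivity(m, packaged_atlas()))
  cv <- suppressWarnings(metric_curves(conn, null_M = 0))
  # Cp = mean(NCp) and Eloc = mean(NLe) at every threshold
  tau_grid <- unique(cv$global$threshold)
  for (tau in tau_grid[c(1, 5)]) {
    g <- threshold_graph(conn, tau)
    gl <- cv$global[cv$global$threshold == tau, ]
    expect_equal(gl$value[gl$metric == "cp"], mean(nodal_clustering(g)))
    expect_equal(gl$value[gl$metric == "eloc"],
                 mean(nodal_local_efficiency(g)))
  }
  # re-running with identical inputs reproduces the AUCs
  cv2 <- suppressWarnings(metric_curves(conn, null_M = 0))
  expect_identical(cv$global_auc, cv2$global_auc)
})

test_that("denser graphs never have larger Lp or smaller Eg", {
  withr::with_seed(17, {
    for (k in 1:20) {
      adj <- random_adjacency(12, 0.35)
      up <- which(upper.tri(adj) & adj == 0)
      if (!length(up)) next
      adj2 <- adj
      add <- sample(up, min(3, length(up)))
      adj2[add] <- 1L
      adj2 <- pmax(adj2, t(adj2))
      expect_gte(global_efficiency(adj2), global_efficiency(adj))
      lp1 <- as.numeric(characteristic_path_length(adj, "harmonic"))
      lp2 <- as.numeric(characteristic_path_length(adj2, "harmonic"))
      if (is.finite(lp1) && is.finite(lp2)) expect_lte(lp2, lp1)
    }
  })
})

test_that("region averaging of nodal AUCs", {
  atlas <- packaged_atlas()
  nodes <- atlas$channel[atlas$hemisphere != "midline"]
  aucs <- tibble::tibble(node = rep(nodes, 2),
                         metric = rep(c("ncp", "nle"), each = 50),
                         auc = 0.42)
  ra <- roi_average(aucs, atlas)
  expect_equal(nrow(ra), 20)  # 10 regions x 2 metrics
  expect_true(all(ra$value == 0.42))

  # region means average their channels, independent of row order
  reg <- atlas_regions(atlas)
  ch <- reg$channel[reg$region == "L_FPA"]
  aucs2 <- tibble::tibble(node = nodes, metric = "ncp", auc = 0.3)
  aucs2$auc[aucs2$node %in% ch[1:2]] <- c(0.2, 0.4)
  ra2 <- roi_average(aucs2, atlas)
  expect_equal(ra2$value[ra2$region == "L_FPA"], 0.3)
  aucs3 <- aucs2[sample(nrow(aucs2)), ]
  expect_equal(roi_average(aucs3, atlas), ra2)
  # an uncovered node is an error
  expect_error(roi_average(tibble::tibble(node = 999, metric = "ncp",
                                          auc = 1), atlas), "cover")
})
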