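# Worked examples with frozen expected values, then property checks
# against the naive oracles.

test_that("degree, strength, density and total strength on known graphs", {
  expect_equal(nodal_degree(connectome(matrix(0, 4, 4))),
               setNames(rep(0L, 4), paste0("node_", 1:4)))
  expect_equal(unname(nodal_degree(complete_connectome(4))), rep(3L, 4))
  chain <- edge_connectome(5, rbind(c(1, 2, 2), c(2, 3, 7), c(2, 4, 1)))
  expect_equal(unname(nodal_degree(chain)), c(1L, 3L, 1L, 1L, 0L))

  tri2 <- edge_connectome(3, cbind(c(1, 1, 2), c(2, 3, 3), 2))
  expect_equal(unname(nodal_strength(tri2)), c(4, 4, 4))
  expect_equal(total_strength(tri2), 6)
  expect_equal(unname(nodal_strength(connectome(matrix(0, 3, 3)))),
               rep(0, 3))

  expect_equal(edge_density(complete_connectome(4)), 1)
  expect_equal(edge_density(connectome(matrix(0, 4, 4))), 0)
  path4 <- edge_connectome(4, cbind(1:3, 2:4, 1))
  expect_equal(edge_density(path4), 0.5)
  expect_error(edge_density(connectome(matrix(0, 1, 1))), "N < 2")

  withr::with_seed(7, {
    conn <- random_connectome(6)
    expect_equal(unname(nodal_strength(conn)),
                 unname(rowSums(conn$weights)))
    expect_equal(total_strength(conn),
                 sum(conn$weights[upper.tri(conn$weights)]))
    expect_equal(total_strength(conn), sum(nodal_strength(conn)) / 2)
  })
})

test_that("Onnela clustering matches hand values and the binary special case", {
  tri <- complete_connectome(3)
  expect_equal(unname(nodal_clustering(tri)), c(1, 1, 1))
  expect_equal(global_clustering(tri), 1)

  star <- edge_connectome(4, cbind(1, 2:4, 1))
  expect_equal(unname(nodal_clustering(star)), rep(0, 4))
  expect_equal(global_clustering(star), 0)

  # geometric mean of 1 * 0.5 * 0.5 = 0.25^(1/3) at every node
  tri_w <- uneven_triangle()
  expect_equal(unname(nodal_clustering(tri_w, normalize_weights = TRUE)),
               rep(0.25^(1 / 3), 3), tolerance = 1e-12)

  # triangle + isolated node: average includes the zero
  tri_iso <- edge_connectome(4, rbind(c(1, 2, 1), c(1, 3, 1), c(2, 3, 1)))
  expect_equal(global_clustering(tri_iso), 3 / 4)

  # with 0/1 weights the weighted form reduces to binary clustering
  withr::with_seed(11, {
    for (rep in 1:5) {
      conn <- random_connectome(6)
      wb <- (conn$weights > 0) * 1
      cb <- connectome(wb)
      g <- igraph::graph_from_adjacency_matrix(wb, mode = "undirected")
      bin <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
      bin[igraph::degree(g) < 2] <- 0
      expect_equal(unname(nodal_clustering(cb)), unname(bin),
                   tolerance = 1e-12)
    }
  })
})

test_that("shortest paths, CPL and efficiency on known graphs", {
  tri_w <- uneven_triangle()
  d <- shortest_path_matrix(tri_w)
  expect_equal(unname(d), rbind(c(0, 1, 2), c(1, 0, 2), c(2, 2, 0)))

  expect_equal(unname(shortest_path_matrix(complete_connectome(4))),
               matrix(1, 4, 4) - diag(4))

  two_comp <- edge_connectome(4, rbind(c(1, 2, 1), c(3, 4, 1)))
  d2 <- shortest_path_matrix(two_comp)
  expect_true(is.infinite(d2[1, 3]) && is.infinite(d2[2, 4]))

  expect_equal(characteristic_path_length(complete_connectome(3)), 1)
  path3 <- edge_connectome(3, cbind(1:2, 2:3, 1))
  expect_equal(characteristic_path_length(path3), 4 / 3)
  expect_error(characteristic_path_length(connectome(matrix(0, 3, 3))),
               "undefined")

  # isolated node: excluded pairs with a warning
  tri_iso <- edge_connectome(4, rbind(c(1, 2, 1), c(1, 3, 1), c(2, 3, 1)))
  expect_warning(cpl <- characteristic_path_length(tri_iso), "unreachable")
  expect_equal(cpl, 1)

  expect_equal(unname(regional_efficiency(complete_connectome(5))), rep(1, 5))
  expect_equal(unname(regional_efficiency(tri_w)),
               c(mean(c(1, 0.5)), mean(c(1, 0.5)), mean(c(0.5, 0.5))))
  suppressWarnings(
    expect_equal(unname(regional_efficiency(tri_iso))[4], 0)
  )
})

test_that("small-worldness is the clustering / CPL ratio", {
  expect_equal(small_worldness(complete_connectome(3)), 1)
  star <- edge_connectome(4, cbind(1, 2:4, 1))
  expect_equal(small_worldness(star), 0)
  withr::with_seed(3, {
    conn <- random_connectome(8, density = 0.6)
    expect_equal(small_worldness(conn),
                 global_clustering(conn) / characteristic_path_length(conn))
  })
})

test_that("distances and clustering agree with naive oracles on random graphs", {
  withr::with_seed(101, {
    for (rep in 1:40) {
      n <- sample(3:6, 1)
      conn <- random_connectome(n, density = runif(1, 0.2, 0.9))
      expect_equal(unname(shortest_path_matrix(conn)),
                   floyd_warshall_oracle(conn$weights), tolerance = 1e-10)
      expect_equal(unname(nodal_clustering(conn)),
                   clustering_oracle(conn$weights), tolerance = 1e-10)
      expect_equal(unname(nodal_clustering(conn, normalize_weights = TRUE)),
                   clustering_oracle(conn$weights, normalize = TRUE),
                   tolerance = 1e-10)
    }
  })
})

test_that("nodal measures are permutation-equivariant, global ones invariant", {
  withr::with_seed(21, {
    conn <- random_connectome(7, density = 0.5)
    perm <- sample(7)
    wp <- conn$weights[perm, perm]
    cp <- connectome(wp, node_labels = conn$node_labels[perm])
    expect_equal(unname(nodal_degree(cp)), unname(nodal_degree(conn))[perm])
    expect_equal(unname(nodal_strength(cp)),
                 unname(nodal_strength(conn))[perm])
    expect_equal(unname(nodal_clustering(cp)),
                 unname(nodal_clustering(conn))[perm])
    expect_equal(unname(regional_efficiency(cp)),
                 unname(regional_efficiency(conn))[perm])
    expect_equal(edge_density(cp), edge_density(conn))
    expect_equal(global_clustering(cp), global_clustering(conn))
    expect_equal(characteristic_path_length(cp),
                 characteristic_path_length(conn))
  })
})

test_that("rescaling all weights by c scales each measure as expected", {
  withr::with_seed(22, {
    conn <- random_connectome(7, density = 0.6)
    cc <- 3.7
    scaled <- connectome(conn$weights * cc)
    expect_equal(nodal_degree(scaled), nodal_degree(conn),
                 ignore_attr = TRUE)
    expect_equal(edge_density(scaled), edge_density(conn))
    expect_equal(unname(nodal_strength(scaled)),
                 cc * unname(nodal_strength(conn)))
    expect_equal(total_strength(scaled), cc * total_strength(conn))
    expect_equal(characteristic_path_length(scaled),
                 characteristic_path_length(conn) / cc)
    expect_equal(unname(regional_efficiency(scaled)),
                 cc * unname(regional_efficiency(conn)))
    expect_equal(nodal_clustering(scaled, normalize_weights = TRUE),
                 nodal_clustering(conn, normalize_weights = TRUE),
                 ignore_attr = TRUE)
  })
})

test_that("compute_all_metrics bundles the individual calls", {
  tri <- complete_connectome(3)
  m <- compute_all_metrics(tri)
  expect_equal(nrow(m), 3 * 4 + 5)
  gv <- function(meas) m$value[m$scope == "global" & m$measure == meas]
  expect_equal(gv("edge_density"), 1)
  expect_equal(gv("total_strength"), 3)
  expect_equal(gv("clustering_coefficient"), 1)
  expect_equal(gv("characteristic_path_length"), 1)
  expect_equal(gv("small_worldness"), 1)
  expect_equal(m$value[m$measure == "degree"], rep(2, 3))
  expect_equal(m$value[m$measure == "strength"], rep(2, 3))

  withr::with_seed(31, {
    conn <- random_connectome(10, density = 0.4)
    m <- compute_all_metrics(conn)
    expect_equal(m$value[m$measure == "efficiency"],
                 unname(regional_efficiency(conn)))
    expect_equal(m$value[m$measure == "clustering" & m$scope == "nodal"],
                 unname(nodal_clustering(conn)))
    expect_equal(m$value[m$measure == "small_worldness"],
                 small_worldness(conn))
  })

  expect_error(compute_all_metrics(connectome(matrix(0, 3, 3))), "undefined")
})
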