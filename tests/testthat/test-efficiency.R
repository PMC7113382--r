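test_that("closed-form efficiencies are exact", {
  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(global_efficiency(k5), 1)

  empty <- matrix(0, 4, 4)
  expect_equal(global_efficiency(empty), 0)

  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(global_efficiency(path3), 5 / 6)

  # star S_4: hub at node 1
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(nodal_efficiency(star, 1), 1)
  expect_equal(nodal_efficiency(star, 2), 2 / 3)

  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(nodal_efficiency(iso, 3), 0)
})

test_that("distances come from BFS with Inf across components", {
  p3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  d <- shortest_path_lengths(p3)
  expect_equal(d[1, 3], 2)

  two_edges <- matrix(0, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- 1
  two_edges[3, 4] <- two_edges[4, 3] <- 1
  d2 <- shortest_path_lengths(two_edges)
  expect_equal(d2[1, 3], Inf)
  expect_equal(d2[2, 4], Inf)
  expect_equal(d2[1, 2], 1)
})

test_that("efficiencies match a literal formula over Floyd-Warshall distances", {
  set.seed(10)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    adj <- random_adjacency(n, p = runif(1, 0.05, 0.5))
    d_oracle <- oracle_floyd_warshall(adj)
    expect_equal(shortest_path_lengths(adj), d_oracle, ignore_attr = TRUE)
    expect_equal(global_efficiency(adj), oracle_efficiency(d_oracle))
    node <- sample(n, 1)
    expect_equal(nodal_efficiency(adj, node),
                 sum(1 / d_oracle[node, -node]) / (n - 1))
  }
})

test_that("global efficiency equals the mean of nodal efficiencies", {
  set.seed(11)
  for (rep in 1:10) {
    adj <- random_adjacency(sample(5:25, 1), 0.3)
    nodal <- vapply(seq_len(nrow(adj)), function(i) nodal_efficiency(adj, i),
                    numeric(1))
    expect_equal(global_efficiency(adj), mean(nodal))
  }
})

test_that("efficiency is bounded, monotone in edges, and permutation invariant", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    adj <- random_adjacency(n, 0.2)
    e <- global_efficiency(adj)
    expect_gte(e, 0); expect_lte(e, 1)
    # adding one absent edge never decreases efficiency
    absent <- which(upper.tri(adj) & adj == 0)
    if (length(absent)) {
      pick <- sample(length(absent), 1)
      adj2 <- adj
      adj2[absent[pick]] <- 1L
      adj2 <- pmax(adj2, t(adj2))
      expect_gte(global_efficiency(adj2), e - 1e-12)
    }
    perm <- sample(n)
    expect_equal(global_efficiency(adj[perm, perm]), e)
  }
  # E = 1 iff complete
  full <- matrix(1, 6, 6) - diag(6)
  expect_equal(global_efficiency(full), 1)
  full[1, 2] <- full[2, 1] <- 0
  expect_lt(global_efficiency(full), 1)
})

test_that("subnetwork efficiency honors induced vs restricted path definitions", {
  parcels <- make_parcel_table(6, c(DMN = 2, SN = 2))
  # DMN nodes 1-2 disconnected directly but joined through OTHER node 5
  adj <- matrix(0, 6, 6)
  adj[1, 5] <- adj[5, 1] <- 1
  adj[2, 5] <- adj[5, 2] <- 1
  adj[3, 4] <- adj[4, 3] <- 1
  expect_equal(subnetwork_efficiency(adj, parcels, "DMN", "induced"), 0)
  expect_equal(subnetwork_efficiency(adj, parcels, "DMN", "restricted"), 1 / 2)
  # SN forms a clique of two
  expect_equal(subnetwork_efficiency(adj, parcels, "SN", "induced"), 1)
})

test_that("both subnetwork modes match the literal formula on random graphs", {
  set.seed(13)
  parcels <- make_parcel_table(20, c(DMN = 6, SN = 4, FPN = 4))
  for (rep in 1:30) {
    adj <- random_adjacency(20, runif(1, 0.1, 0.4))
    members <- which(parcels$network == "DMN")
    d_ind <- oracle_floyd_warshall(adj[members, members])
    expect_equal(subnetwork_efficiency(adj, parcels, "DMN", "induced"),
                 oracle_efficiency(d_ind))
    d_full <- oracle_floyd_warshall(adj)
    expect_equal(subnetwork_efficiency(adj, parcels, "DMN", "restricted"),
                 oracle_efficiency(d_full, members))
    # more available intermediate nodes can only shorten paths
    expect_lte(subnetwork_efficiency(adj, parcels, "DMN", "induced"),
               subnetwork_efficiency(adj, parcels, "DMN", "restricted") + 1e-12)
  }
})

test_that("degenerate efficiency inputs raise errors", {
  expect_error(global_efficiency(matrix(0, 1, 1)), "2 nodes")
  adj <- random_adjacency(6, 0.5)
  expect_error(nodal_efficiency(adj, 9), "unknown node")
  parcels <- make_parcel_table(6, c(DMN = 2, SN = 2))
  expect_error(subnetwork_efficiency(adj, parcels, "VIS"), "VIS")
})

test_that("cohort efficiency tables carry one row per subject and network columns", {
  set.seed(14)
  parcels <- make_parcel_table(12, c(DMN = 4, SN = 3, FPN = 3))
  adjs <- list(S1 = random_adjacency(12, 0.3), S2 = random_adjacency(12, 0.3))
  eff <- cohort_efficiency(adjs, parcels)
  expect_equal(names(eff), c("subject_id", "E_global", "E_DMN", "E_SN", "E_FPN"))
  expect_equal(eff$subject_id, c("S1", "S2"))
  expect_true(all(unlist(eff[-1]) >= 0 & unlist(eff[-1]) <= 1))
})
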