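path3 <- binary_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
                      node_labels = c("a", "b", "c"))
triangle <- binary_graph(matrix(1, 3, 3) - diag(3))
star4 <- binary_graph(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
                            c(1, 0, 0, 0), c(1, 0, 0, 0)))
# triangle on 1-2-3 plus a pendant node hanging off node 1
tri_pendant <- binary_graph(rbind(c(0, 1, 1, 1), c(1, 0, 1, 0),
                                  c(1, 1, 0, 0), c(1, 0, 0, 0)))

test_that("density thresholding keeps the strongest edges with the lexicographic tie rule", {
  set.seed(21)
  w <- matrix(runif(16, 0.1, 1), 4)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  fc <- as_fc_matrix(w, "pearson_r")
  g <- threshold_by_density(fc, 0.5)
  expect_equal(sum(g$adjacency) / 2, 3)
  # sort-and-count oracle: the 3 largest off-diagonal weights survive
  ut <- w[upper.tri(w)]
  kept_w <- w[upper.tri(w) & (g$adjacency == 1)]
  expect_setequal(kept_w, sort(ut, decreasing = TRUE)[1:3])
  expect_equal(g$density, 0.5)

  # density 1 keeps everything positive
  expect_equal(sum(threshold_by_density(fc, 1)$adjacency) / 2, 6)

  # all weights equal: lexicographic tie rule picks (1,2),(1,3),(1,4)
  eq <- matrix(0.5, 4, 4)
  diag(eq) <- 1
  ge <- threshold_by_density(as_fc_matrix(eq, "pearson_r"), 0.5)
  expect_equal(ge$adjacency[1, ], c(R001 = 0, R002 = 1, R003 = 1,
                                    R004 = 1))
  expect_equal(sum(ge$adjacency[2:4, 2:4]), 0)
})

test_that("thresholding drops negatives and records achieved density on shortfall", {
  m <- matrix(-0.5, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.9
  m[3, 4] <- m[4, 3] <- 0.2
  diag(m) <- 1
  fc <- as_fc_matrix(m, "pearson_r")
  expect_warning(g <- threshold_by_density(fc, 0.9), "positive")
  expect_equal(sum(g$adjacency) / 2, 2)   # only the two positive edges
  expect_equal(g$density, 2 / 6)
})

test_that("edge sets are nested across increasing densities", {
  set.seed(33)
  r <- matrix(runif(100, -1, 1), 10)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  fc <- as_fc_matrix(r, "pearson_r")
  prev <- NULL
  for (d in c(0.1, 0.2, 0.4, 0.8)) {
    a <- suppressWarnings(threshold_by_density(fc, d))$adjacency
    if (!is.null(prev)) expect_true(all(a[prev == 1] == 1))
    prev <- a
  }
})

test_that("path length, efficiency, clustering, transitivity agree with hand values", {
  expect_equal(characteristic_path_length(triangle), 1)
  expect_equal(characteristic_path_length(path3), 4 / 3)
  expect_equal(global_efficiency(triangle), 1)
  expect_equal(global_efficiency(path3), 5 / 6)
  # two disjoint edges: only within-component pairs counted
  two_edges <- binary_graph(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                                  c(0, 0, 0, 1), c(0, 0, 1, 0)))
  expect_equal(characteristic_path_length(two_edges), 1)
  # edgeless: efficiency 0, path length undefined
  empty <- binary_graph(matrix(0, 3, 3))
  expect_equal(global_efficiency(empty), 0)
  expect_error(characteristic_path_length(empty), "edgeless")

  expect_equal(clustering_coefficient(triangle), 1)
  expect_equal(clustering_coefficient(star4), 0)
  expect_equal(clustering_coefficient(tri_pendant),
               (1 + 1 + 1 / 3 + 0) / 4)
  expect_equal(transitivity_coefficient(triangle), 1)
  expect_equal(transitivity_coefficient(star4), 0)
  expect_equal(transitivity_coefficient(tri_pendant), 3 / 5)
  no_triple <- binary_graph(rbind(c(0, 1), c(1, 0)))
  expect_error(transitivity_coefficient(no_triple), "triple")
})

test_that("Louvain recovers planted structure and its Q matches the formula", {
  a <- matrix(0, 8, 8)
  a[1:4, 1:4] <- 1
  a[5:8, 5:8] <- 1
  diag(a) <- 0
  g <- binary_graph(a)
  p <- modularity_louvain(g, seed = 5)
  expect_equal(p$q_value, 0.5)
  expect_equal(length(unique(p$assignment[1:4])), 1)
  expect_equal(length(unique(p$assignment[5:8])), 1)
  expect_false(p$assignment[1] == p$assignment[5])
  expect_equal(modularity_q(g, p$assignment), p$q_value)

  # complete graph: nothing to divide
  k5 <- binary_graph(matrix(1, 5, 5) - diag(5))
  expect_lte(modularity_louvain(k5, seed = 1)$q_value, 1e-12)

  # ring of 4 triangles joined by single edges: detected Q >= planted Q
  ring <- matrix(0, 12, 12)
  for (b in 0:3) {
    i <- 3 * b + 1
    ring[i, i + 1] <- ring[i + 1, i + 2] <- ring[i, i + 2] <- 1
  }
  ring[3, 4] <- ring[6, 7] <- ring[9, 10] <- ring[12, 1] <- 1
  ring <- ring + t(ring)
  ring[ring > 1] <- 1
  gr <- binary_graph(ring)
  planted <- rep(1:4, each = 3)
  expect_gte(modularity_louvain(gr, seed = 2)$q_value,
             modularity_q(gr, planted))
  expect_error(modularity_louvain(binary_graph(matrix(0, 3, 3))),
               "edgeless")
})

test_that("rewiring preserves the degree sequence and is seed-deterministic", {
  set.seed(8)
  a <- random_adjacency(12, 0.35, min_edges = 8)
  g <- binary_graph(a)
  nulls <- rewire_null(g, n_iter = 20, seed = 42)
  for (ng in nulls) {
    expect_identical(unname(rowSums(ng$adjacency)), unname(rowSums(a)))
    expect_true(all(diag(ng$adjacency) == 0))
    expect_true(all(ng$adjacency %in% c(0, 1)))
  }
  nulls2 <- rewire_null(g, n_iter = 20, seed = 42)
  expect_identical(lapply(nulls, `[[`, "adjacency"),
                   lapply(nulls2, `[[`, "adjacency"))

  # path 0-1-2-3: every null is one of the two simple graphs with
  # degrees (1,2,2,1) — the path itself or the triangle-plus-isolate is
  # excluded by degree, so only path relabellings appear
  pg <- binary_graph(rbind(c(0, 1, 0, 0), c(1, 0, 1, 0),
                           c(0, 1, 0, 1), c(0, 0, 1, 0)))
  pn <- rewire_null(pg, n_iter = 30, seed = 3)
  degs <- vapply(pn, function(x) paste(rowSums(x$adjacency),
                                       collapse = ""), "")
  expect_true(all(degs == "1221"))
  uniq <- unique(lapply(pn, `[[`, "adjacency"))
  expect_lte(length(uniq), 2)

  # a star admits no swap: degenerate ensemble of copies
  expect_message(sn <- rewire_null(star4, n_iter = 5, seed = 1),
                 "degenerate")
  expect_true(attr(sn, "degenerate"))
  expect_identical(sn[[1]]$adjacency, star4$adjacency)
})

test_that("attribute profiles normalize against the null mean with inverted path length", {
  set.seed(14)
  b <- generate_block_bold(c(A = 10, B = 10, C = 10), 400, 0.6, 0.05,
                           seed = 6)
  fc <- compute_fc(b)
  pr <- attribute_profile(fc, densities = c(0.1, 0.2), n_null = 15,
                          seed = 7, n_restarts = 4)
  expect_s3_class(pr, "attribute_profile")
  expect_equal(nrow(pr), 2 * 5)
  expect_equal(attr(pr, "n_null"), 15L)
  # normalization identity for the ratio-normalized attributes
  plain <- pr$attribute != "inv_char_path_length"
  expect_equal(pr$normalized[plain], (pr$raw / pr$null_mean)[plain])
  # a strongly modular matrix is more clustered than its degree-matched null
  cc <- pr[pr$attribute == "clustering_coefficient", ]
  expect_true(all(cc$normalized > 1))
  # raw equal to null mean would give exactly 1; check sign convention of
  # the inverted path length: null_mean(CPL) / raw(CPL)
  icpl <- pr[pr$attribute == "inv_char_path_length", ]
  g1 <- threshold_by_density(fc, 0.1)
  expect_equal(icpl$raw[1], 1 / characteristic_path_length(g1))
})

test_that("a 265-region matrix yields 4 densities x 5 attributes", {
  set.seed(2)
  r <- matrix(runif(265^2, 0, 0.9), 265)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  fc <- as_fc_matrix(r, "pearson_r")
  pr <- attribute_profile(fc, densities = c(0.05, 0.10, 0.15, 0.20),
                          n_null = 2, seed = 3, n_restarts = 1)
  expect_equal(dim(pr)[1], 20)
  expect_equal(sort(unique(pr$density)), c(0.05, 0.10, 0.15, 0.20))
  expect_equal(length(unique(pr$attribute)), 5)
})
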