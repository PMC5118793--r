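test_that("all generators emit simple graphs near the target mean degree", {
  for (m in c("random", "small_world", "scalefree", "geographical",
              "ba_0.5", "ba_2", "dm")) {
    g <- generate_network(m, 400, 8, seed = 11)
    expect_true(igraph::is_simple(g), info = m)
    expect_false(igraph::is_directed(g), info = m)
    expect_lt(abs(mean(igraph::degree(g)) - 8) / 8, 0.1)
  }
})

test_that("generators are reproducible per seed", {
  for (m in c("random", "small_world", "dm", "geographical")) {
    g1 <- generate_network(m, 150, 8, seed = 5)
    g2 <- generate_network(m, 150, 8, seed = 5)
    expect_equal(igraph::as_edgelist(g1), igraph::as_edgelist(g2), info = m)
  }
  expect_warning(generate_dm(100, 6, seed = 1), "not divisible by 4")
})

test_that("ER mean degree concentrates at (N-1) p over replicates", {
  ks <- sapply(1:30, function(i) {
    mean(igraph::degree(generate_er(500, 8, seed = 100 + i)))
  })
  se <- sqrt(2 * 8 / 500 / 30)  # rough SE of the replicate mean
  expect_lt(abs(mean(ks) - 8 * 499 / 500), 4 * se)
})

test_that("WS keeps the exact edge count and interpolates ring -> random", {
  g0 <- generate_ws(200, 4, rewire_p = 0, seed = 1)
  expect_equal(igraph::ecount(g0), 400)
  expect_equal(sort(unique(igraph::degree(g0))), 4)
  expect_gt(igraph::transitivity(g0, type = "global"), 0.4)  # ring lattice
  g1 <- generate_ws(500, 4, rewire_p = 0.1, seed = 2)
  expect_equal(igraph::ecount(g1), 1000)
  gf <- generate_ws(500, 4, rewire_p = 1, seed = 3)
  expect_gt(stats::var(igraph::degree(gf)), stats::var(igraph::degree(g1)))
  expect_error(generate_ws(100, 5, seed = 1), "even")
})

test_that("BA attachment exponent controls hub dominance", {
  g <- generate_ba(1000, 8, alpha = 1, seed = 4)
  expect_equal(igraph::ecount(g), 4 * 1000 - 10)  # m*(N-m) growth edges
  hubs <- sapply(1:10, function(i) {
    c(max(igraph::degree(generate_ba(800, 8, alpha = 2, seed = 200 + i))),
      max(igraph::degree(generate_ba(800, 8, alpha = 0.5, seed = 300 + i))))
  })
  expect_true(all(hubs[1, ] > hubs[2, ]))
})

test_that("BA degree tail exponent is near 3 for linear attachment", {
  g <- generate_ba(5000, 8, alpha = 1, seed = 5)
  d <- igraph::degree(g)
  fit <- igraph::fit_power_law(d, xmin = 8)
  expect_lt(abs(fit$alpha - 3), 0.5)
})

test_that("DM growth hits its mean degree and accumulates triangles", {
  ks <- sapply(1:10, function(i) {
    mean(igraph::degree(generate_dm(500, 8, seed = 400 + i)))
  })
  expect_true(all(ks >= 7.6 & ks <= 8.4))
  # every attachment closes a triangle: count grows with N
  t1 <- length(igraph::triangles(generate_dm(200, 4, seed = 1))) / 3
  t2 <- length(igraph::triangles(generate_dm(400, 4, seed = 1))) / 3
  expect_gt(t2, 1.5 * t1)
  expect_gt(t1, 150)  # at least one triangle per added node
})

test_that("geographical calibration hits the target degree; lambda localizes", {
  g <- generate_geographical(500, 8, lambda = 10, seed = 6)
  expect_lt(abs(mean(igraph::degree(g)) - 8) / 8, 0.05)
  mean_len <- function(lambda) {
    g <- generate_geographical(300, 6, lambda = lambda, seed = 7)
    xy <- cbind(igraph::V(g)$x, igraph::V(g)$y)
    el <- igraph::as_edgelist(g, names = FALSE)
    mean(sqrt(rowSums((xy[el[, 1], ] - xy[el[, 2], ])^2)))
  }
  lens <- sapply(c(0.5, 5, 20), mean_len)
  expect_true(all(diff(lens) < 0))
})

test_that("edge-noise perturbation preserves the edge count exactly", {
  g <- generate_er(300, 8, seed = 8)
  canon <- function(gg) {
    el <- igraph::as_edgelist(gg, names = FALSE)
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el[order(el[, 1], el[, 2]), ]
  }
  g0 <- perturb_network(g, 0, seed = 1)
  expect_equal(canon(g0), canon(g))
  E <- igraph::ecount(g)
  gp <- perturb_network(g, 0.1, seed = 2)
  expect_equal(igraph::ecount(gp), E)
  shared <- igraph::ecount(igraph::intersection(g, gp))
  expect_equal(E - shared, round(0.1 * E))
})

test_that("dataset builder expands the design with deterministic seeds", {
  spec <- synthetic_dataset_spec(mean_degrees = c(4, 8), Ns = 100,
                                 replicates = 3)
  ds <- build_dataset(spec, master_seed = 9)
  expect_equal(nrow(ds), 4 * 2 * 3)
  expect_equal(sum(ds$model == "random"), 6)
  expect_true(all(ds$seed >= 0 & ds$seed < 2^31))
  ds2 <- build_dataset(spec, master_seed = 9)
  expect_equal(igraph::as_edgelist(ds$graph[[5]]),
               igraph::as_edgelist(ds2$graph[[5]]))
  # full-size reference design: 11200 networks, 2800 per model
  full <- synthetic_dataset_spec()
  expect_equal(sum(full$replicates), 11200)
  expect_equal(sum(full$replicates[full$model == "random"]), 2800)
  sf <- scalefree_dataset_spec()
  expect_equal(sum(sf$replicates), 500)
  expect_equal(length(unique(sf$model)), 5)
})
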