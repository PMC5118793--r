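test_that("neighbourhood density is the alive-neighbour fraction", {
  p3 <- as_tessellation(rbind(c(0, 1), c(1, 2)))
  expect_equal(neighborhood_density(p3, c(1, 0, 1), nodes = 2), 1.0)
  expect_equal(neighborhood_density(p3, c(0, 0, 0)), c(0, 0, 0))
  star <- igraph::make_star(5, mode = "undirected")
  expect_equal(neighborhood_density(star, c(0, 1, 1, 0, 0), nodes = 1), 0.5)
  # isolated node takes density zero
  iso <- igraph::make_empty_graph(3, directed = FALSE)
  expect_equal(neighborhood_density(iso, c(1, 1, 1)), c(0, 0, 0))
})

test_that("initial state matches sigma and is seed-reproducible", {
  g <- igraph::make_ring(10000)
  expect_equal(initial_state(g, sigma = 0), rep(0L, 10000))
  expect_equal(initial_state(g, sigma = 1), rep(1L, 10000))
  s <- initial_state(g, sigma = 0.5, seed = 7)
  expect_equal(s, initial_state(g, sigma = 0.5, seed = 7))
  # binomial bound: 3 standard errors
  expect_lt(abs(mean(s) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("fixed points: no birth from extinction, full survival stays full", {
  g <- random_graph(60, 0.1, seed = 1)
  dead <- rep(0L, 60)
  expect_equal(llna_step(g, dead, "B3/S23"), dead)
  g2 <- igraph::make_ring(30)  # min degree 1
  alive <- rep(1L, 30)
  expect_equal(llna_step(g2, alive, "B3/S238"), alive)
})

test_that("empty rule kills everything after one step", {
  g <- random_graph(40, 0.2, seed = 2)
  d <- llna_evolve(g, "B/S", t = 5, seed = 3)
  expect_equal(unclass(d)[2:6, ], matrix(0L, 5, 40), ignore_attr = TRUE)
})

test_that("diagram has t+1 binary rows starting from the initial state", {
  g <- random_graph(30, 0.2, seed = 4)
  init <- initial_state(g, 0.5, seed = 5)
  d <- llna_evolve(g, "B3/S23", t = 7, init = init)
  expect_equal(dim(d), c(8L, 30L))
  expect_equal(unclass(d)[1, ], init, ignore_attr = TRUE)
  expect_true(all(unclass(d) %in% 0:1))
  d2 <- llna_evolve(g, "B3/S23", t = 7, sigma = 0.5, seed = 11)
  expect_equal(unclass(d2), unclass(llna_evolve(g, "B3/S23", t = 7,
                                                sigma = 0.5, seed = 11)))
})

test_that("compiled evolution agrees with the step function", {
  g <- random_graph(80, 0.08, seed = 6)
  init <- initial_state(g, 0.5, seed = 7)
  d <- llna_evolve(g, "B135678/S03456", t = 10, init = init)
  s <- init
  for (k in 1:10) {
    s <- llna_step(g, s, "B135678/S03456")
    expect_equal(unclass(d)[k + 1, ], s, ignore_attr = TRUE)
  }
})

test_that("vectorized step equals the naive per-node recomputation", {
  set.seed(99)
  rules <- enumerate_rules(sample(0:(2^18 - 1), 12))
  for (rep in 1:8) {
    g <- random_graph(sample(20:120, 1), runif(1, 0.03, 0.2), seed = 100 + rep)
    states <- as.integer(runif(igraph::vcount(g)) < 0.5)
    for (rl in sample(rules, 3)) {
      expect_equal(llna_step(g, states, rl), naive_step(g, states, rl),
                   info = rl)
    }
  }
})

test_that("LLNA on a Moore torus reduces to the classic Life-like CA", {
  g <- moore_torus(12)
  set.seed(8)
  m <- matrix(as.integer(runif(144) < 0.4), 12, 12)
  d <- llna_evolve(g, "B36/S23", t = 30, init = as.vector(t(m)))
  for (k in 1:30) {
    m <- gol_step(m, birth = c(3, 6), survive = c(2, 3))
    expect_equal(unclass(d)[k + 1, ], as.vector(t(m)), ignore_attr = TRUE)
  }
})

test_that("degree ordering is a column permutation for visualization only", {
  g <- random_graph(40, 0.15, seed = 9)
  d <- llna_evolve(g, "B3/S23", t = 5, seed = 10)
  od <- order_by_degree(d, g)
  expect_equal(sort(colSums(od)), sort(colSums(d)))
  expect_equal(unclass(od), unclass(d)[, order(igraph::degree(g))],
               ignore_attr = TRUE)
})
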