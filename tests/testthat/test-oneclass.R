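test_that("rebinning replicates band rows onto the 1 Hz grid and collapses", {
  sc <- uniform_scheme()
  set.seed(1)
  co <- matrix(rnorm(480), 10, 48)
  m <- toy_model(co, sc)
  # identical schemes: identity rebinning
  v <- rebin_efp(m, sc)
  expect_equal(as.numeric(v), as.numeric(t(co)))
  # a model band [1, 5) spreads its value over four 1 Hz rows
  sc2 <- band_scheme(c(1, 5, seq(9, 41, by = 4)))
  m2 <- toy_model(matrix(1:10, 10, 48), sc2)
  fine <- band_scheme(c(1, 3, 5, seq(9, 41, by = 4)))  # splits band 1 in two
  v2 <- rebin_efp(m2, fine)
  expect_equal(v2[1:48], rep(1, 48))   # first half of [1,5)
  expect_equal(v2[49:96], rep(1, 48))  # second half, same replicated value
  # random schemes equal a brute-force expand-then-average oracle
  set.seed(2)
  src <- equal_area_bands(exp(rnorm(40, sd = 0.5)), 10)
  uni <- uniform_scheme()
  mm <- toy_model(co, src)
  got <- matrix(rebin_efp(mm, uni), 10, 48, byrow = TRUE)
  grid_rows <- matrix(0, 40, 48)
  for (f in 1:40) {
    b <- max(which(src$edges_hz <= f))
    grid_rows[f, ] <- co[b, ]
  }
  for (u in 1:10) {
    rows <- which(1:40 >= uni$edges_hz[u] & 1:40 < uni$edges_hz[u + 1])
    expect_equal(got[u, ], colMeans(grid_rows[rows, , drop = FALSE]))
  }
  # idempotent when source and target coincide
  expect_equal(rebin_efp(toy_model(got, uni), uni), as.numeric(t(got)),
               ignore_attr = TRUE)
  expect_error(rebin_efp(m, band_scheme(c(1, 5, 30))), "range")
})

test_that("correlation distance is symmetric, bounded and affine-invariant", {
  set.seed(3)
  a <- rnorm(100)
  expect_equal(efp_distance(a, a), 0)
  expect_equal(efp_distance(a, -a), 2)
  expect_equal(efp_distance(a, 3 * a + 7), 0, tolerance = 1e-12)
  b <- rnorm(100)
  expect_equal(efp_distance(a, b), efp_distance(b, a))
  expect_gte(efp_distance(a, b), 0)
  expect_lte(efp_distance(a, b), 2)
  expect_error(efp_distance(a, rep(1, 100)), "zero-variance")
})

test_that("agglomerative clustering merges representatives as described", {
  set.seed(4)
  base <- rnorm(96)
  vecs <- list(s1 = base, s2 = base, s3 = rnorm(96))
  tree <- cluster_efps(vecs, stop_k = 1)
  expect_equal(nrow(tree$merges), 2)
  # identical pair merges first at distance 0
  expect_equal(sort(c(tree$merges$a[1], tree$merges$b[1])), c("s1", "s2"))
  expect_equal(tree$merges$distance[1], 0)
  # counting invariant for a larger set and several stop levels
  set.seed(5)
  vs <- setNames(lapply(1:8, function(i) rnorm(50)), sprintf("v%d", 1:8))
  for (k in c(1, 3, 6)) {
    expect_equal(nrow(cluster_efps(vs, stop_k = k)$merges), 8 - k)
  }
  # cut_clusters reproduces the partition of a direct partial run
  full <- cluster_efps(vs, stop_k = 1)
  part <- cluster_efps(vs, stop_k = 4)
  cut <- cut_clusters(full, 4)
  norm <- function(cl) sort(vapply(cl, function(x) paste(sort(x), collapse = "+"),
                                   character(1)))
  expect_equal(norm(cut), norm(part$clusters))
})

test_that("the knee rule finds a constructed slope break and falls back", {
  # piecewise-linear curve bending at step 6
  d <- c(seq(0.1, 0.6, by = 0.1), seq(1.6, 4.6, by = 1))
  k <- knee_stop(d, n_leaves = 11)
  expect_equal(attr(k, "step"), 6L)
  expect_equal(as.integer(k), 5L)  # 11 leaves - 6 executed merges
  # strictly linear curve: proportional default
  flat <- knee_stop(seq(0.1, 1, by = 0.1), n_leaves = 39)
  expect_equal(as.integer(flat), 24L)
  expect_true(is.na(attr(flat, "step")))
  expect_error(knee_stop(c(1, 2), 3), "3 merge steps")
})

test_that("positive-set selection matches the exhaustive subset oracle", {
  # a cluster of exactly n_select returns all members
  set.seed(6)
  vs <- setNames(lapply(1:6, function(i) rnorm(50)), sprintf("s%d", 1:6))
  tree <- cluster_efps(vs, stop_k = 6 - 1)  # one merge only
  tree$clusters <- list(names(vs))
  expect_equal(select_positive(tree, 6), sort(names(vs)))
  # duplicates of one vector win over distant extras
  base <- rnorm(50)
  vs2 <- c(setNames(lapply(1:4, function(i) base + rnorm(50, sd = 1e-6)),
                    sprintf("d%d", 1:4)),
           setNames(lapply(1:3, function(i) rnorm(50)), sprintf("x%d", 1:3)))
  tree2 <- cluster_efps(vs2, stop_k = 1)
  tree2$clusters <- list(names(vs2))
  expect_equal(select_positive(tree2, 4), sprintf("d%d", 1:4))
  # greedy max-internal-distance within 10% of the exhaustive optimum
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12
    vs3 <- setNames(lapply(1:n, function(i) rnorm(60)), sprintf("m%02d", 1:n))
    tr <- cluster_efps(vs3, stop_k = 1)
    tr$clusters <- list(names(vs3))
    sel <- select_positive(tr, 10)
    dm <- 1 - stats::cor(do.call(cbind, vs3))
    maxint <- function(ids) max(dm[ids, ids])
    got <- maxint(sel)
    best <- min(apply(utils::combn(names(vs3), 10), 2, maxint))
    expect_lte(got, best * 1.1)
  }
  # too-small cluster errors with sizes listed
  tree$clusters <- list(c("s1", "s2"), c("s3", "s4", "s5", "s6"))
  expect_error(select_positive(tree, 5), "cluster sizes")
})

test_that("planted two-group studies are recovered end to end", {
  # fingerprints built directly from planted truths plus small noise: the
  # clustering stage is isolated from regression estimation error here
  sc <- uniform_scheme()
  hits <- vapply(1:5, function(seed) {
    st <- simulate_study(sim_spec(15, 10, duration_s = 60, seed = seed,
                                  outlier_perturbation = 1))
    models <- lapply(seq_along(st$truths), function(i) {
      noisy <- st$truths[[i]]$coeffs +
        matrix(rnorm(480, sd = 0.02), 10, 48)
      toy_model(noisy, sc, session_id = st$sessions[[i]]$session_id)
    })
    sel <- oneclass_select(models, sc, n_select = 10)
    planted <- vapply(st$sessions[st$labels == "positive"],
                      function(d) d$session_id, character(1))
    sum(sel$selected %in% planted)
  }, numeric(1))
  expect_true(all(hits >= 9))
})

test_that("newick export writes a parseable tree with all leaves", {
  set.seed(7)
  vs <- setNames(lapply(1:5, function(i) rnorm(30)), sprintf("L%d", 1:5))
  tree <- cluster_efps(vs, stop_k = 1)
  nwk <- efp_newick(tree)
  expect_match(nwk, ";$")
  for (id in names(vs)) expect_match(nwk, id, fixed = TRUE)
  # balanced parentheses
  expect_equal(lengths(regmatches(nwk, gregexpr("\\(", nwk))),
               lengths(regmatches(nwk, gregexpr("\\)", nwk))))
})
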