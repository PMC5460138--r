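test_that("topology metrics on canonical small graphs", {
  tri <- interactome(data.frame(from = c("A", "B", "C"),
                                to = c("B", "C", "A")))
  t1 <- compute_topology(tri)
  expect_equal(t1$clustering, rep(1, 3))
  expect_equal(t1$betweenness, rep(0, 3))
  expect_equal(t1$degree, rep(2, 3))

  path <- interactome(data.frame(from = c("A", "B"), to = c("B", "C")))
  t2 <- compute_topology(path)
  expect_equal(t2$betweenness[t2$node == "B"], 1)
  expect_equal(t2$betweenness[t2$node != "B"], c(0, 0))
  expect_equal(t2$degree[t2$node == "B"], 2)
  expect_equal(t2$clustering, rep(0, 3))  # k<2 and open triple both 0
})

test_that("topology matches the brute-force oracle on random graphs", {
  set.seed(101)
  for (i in 1:10) {
    ed <- random_edge_df(sample(4:8, 1), runif(1, 0.3, 0.8))
    if (nrow(ed) == 0) next
    net <- interactome(ed)
    got <- compute_topology(net)
    want <- oracle_topology(net$edges)
    got <- got[match(want$node, got$node), ]
    expect_equal(got$degree, want$degree)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
    expect_equal(got$clustering, want$clustering, tolerance = 1e-12)
  }
})

test_that("direction flags never affect topology", {
  set.seed(77)
  ed <- random_edge_df(8, 0.5)
  ed$directed <- runif(nrow(ed)) < 0.5
  undirected <- ed; undirected$directed <- FALSE
  expect_equal(compute_topology(interactome(ed))$betweenness,
               compute_topology(interactome(undirected))$betweenness)
})

test_that("exact Wilcoxon enumeration agrees with known values", {
  # {5,6,7} vs {1,1,2}: maximal separation, one-sided p = 1/20
  w <- wilcox_compare(c(5, 6, 7), c(1, 1, 2), alternative = "greater")
  expect_equal(w$p_value, 1 / 20)
  expect_equal(w$method, "exact enumeration")
  # tie-free small samples must agree with the exact distribution of
  # stats::wilcox.test (independent implementation)
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:1000, sample(3:7, 1))
    y <- sample(2000:3000, sample(3:7, 1))
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(wilcox_compare(x, y, alternative = alt)$p_value,
                   wilcox.test(x, y, alternative = alt,
                               exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
  # identical tied groups: no assignment is more extreme than observed
  expect_equal(wilcox_compare(c(3, 3, 3), c(3, 3, 3))$p_value, 1)
})

test_that("class comparisons report medians, quartiles and stars", {
  topo <- data.frame(node = letters[1:9],
                     degree = c(9, 8, 7, 5, 5, 4, 1, 1, 2),
                     betweenness = 0, clustering = 0)
  cl <- structure(data.frame(
    node = letters[1:9],
    class = rep(c("cancer_related", "first_neighbour", "unaffected"),
                each = 3),
    is_mutated = FALSE, is_de = FALSE),
    class = c("classification", "data.frame"))
  res <- compare_classes(topo, cl, control = "unaffected",
                         classes = "first_neighbour",
                         metrics = "degree")
  expect_equal(res$n_class, 3)
  expect_equal(res$median_class, 5)
  expect_equal(res$median_control, 1)
  # two-sided exact enumeration over C(6,3)=20 assignments: the observed
  # split is the most extreme, and the tied {5,5} makes it unique -> 1/20
  expect_equal(res$wilcox_p,
               wilcox_exact_enumeration_ref(c(5, 5, 4), c(1, 1, 2)))
  # whole-network control may contain the class itself
  res2 <- compare_classes(topo, cl, control = "whole_network",
                          classes = "first_neighbour",
                          metrics = "degree")
  expect_equal(res2$n_control, 9)
  # identical groups give p near 1
  topo3 <- topo; topo3$degree <- rep(c(2, 4, 6), 3)
  res3 <- compare_classes(topo3, cl, control = "unaffected",
                          classes = "first_neighbour",
                          metrics = "degree")
  expect_equal(res3$wilcox_p, 1)
  # tiny classes are skipped with a warning
  cl2 <- cl; cl2$class[4:5] <- "unaffected"
  expect_warning(compare_classes(topo, cl2, control = "unaffected",
                                 classes = "first_neighbour",
                                 metrics = "degree"),
                 "fewer than 2")
})

test_that("giant-component ratio and degenerate Z-path", {
  # class {A,B,C} with induced edges only A-B: ratio 2/3
  net <- interactome(data.frame(from = c("A", "B", "C", "D"),
                                to = c("B", "D", "D", "E")))
  cl <- classify(net, mutated = c("A", "B", "C"))
  res <- giant_component_test(net, cl, "cancer_related", n_perm = 100,
                              rng_seed = 1)
  expect_equal(res$ratio_observed, 2 / 3)
  expect_true(res$p_empirical > 0 && res$p_empirical <= 1)

  # class = whole connected graph: observed and all null ratios are 1
  tri <- interactome(data.frame(from = c("A", "B", "C"),
                                to = c("B", "C", "A")))
  cl2 <- classify(tri, mutated = c("A", "B", "C"))
  res2 <- giant_component_test(tri, cl2, "cancer_related",
                               n_perm = 100, rng_seed = 1)
  expect_equal(res2$ratio_observed, 1)
  expect_equal(res2$sd_null, 0)
  expect_true(is.na(res2$z))
  expect_equal(res2$p_empirical, 1)
})

test_that("giant-component test is seed-reproducible and stable in n_perm", {
  ds <- tiny_dataset(seed = 21)
  cl <- classify(ds$interactome, mutated = ds$mutated)
  a <- giant_component_test(ds$interactome, cl, "first_neighbour",
                            n_perm = 200, rng_seed = 99)
  b <- giant_component_test(ds$interactome, cl, "first_neighbour",
                            n_perm = 200, rng_seed = 99)
  expect_identical(a$null_ratios, b$null_ratios)
  big <- giant_component_test(ds$interactome, cl, "first_neighbour",
                              n_perm = 400, rng_seed = 100)
  expect_lt(abs(a$p_empirical - big$p_empirical), 2 / sqrt(200))
})

test_that("randomization occurrence counts follow the star closed form", {
  n_leaves <- 9
  star <- interactome(data.frame(from = rep("c", n_leaves),
                                 to = paste0("l", seq_len(n_leaves))))
  cl <- classify(star, mutated = "l1")
  R <- 400
  res <- randomization_analysis(star, cl, n_draws = R, rng_seed = 31)
  expect_true(all(res$occurrence$count >= 0 &
                    res$occurrence$count <= R))
  # seed size 1 on K_{1,n}: centre is FN unless it is itself the seed,
  # P = n/(n+1); observed count within 3 binomial SDs
  p <- n_leaves / (n_leaves + 1)
  centre <- res$occurrence$count[res$occurrence$node == "c"]
  expect_lt(abs(centre - R * p), 3 * sqrt(R * p * (1 - p)) + 1e-9)

  res0 <- randomization_analysis(star, cl, n_draws = 0)
  expect_true(all(res0$occurrence$count == 0))
  expect_null(res0$comparisons)
})

test_that("real first neighbours recur under random seeding", {
  ds <- tiny_dataset(seed = 41, n_nodes = 400, n_seed = 40)
  cl <- classify(ds$interactome, mutated = ds$mutated)
  res <- randomization_analysis(ds$interactome, cl, n_draws = 100,
                                rng_seed = 7)
  cmp <- res$comparisons
  fn_ua <- cmp[cmp$group_b == "unaffected", ]
  expect_gt(fn_ua$median_a, fn_ua$median_b)
  expect_lt(fn_ua$wilcox_p, 0.01)
})

test_that("friendship paradox holds for uniform seeds on PA graphs", {
  hits <- 0
  for (s in 1:20) {
    cfg <- synthetic_config(n_nodes = 800, n_seed_proteins = 40,
                            rng_seed = s)
    net <- generate_interactome(cfg)
    cl <- classify(net, mutated = generate_mutations(cfg, net))
    deg <- igraph::degree(as_igraph(net))
    fn <- cl$node[cl$class == "first_neighbour"]
    if (median(deg[fn]) >= median(deg)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})
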