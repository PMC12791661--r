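path_net <- function() mb_network(c("a", "b", "c"),
                                  rbind(c("a", "b"), c("b", "c")))
star_net <- function() mb_network(c("hub", "l1", "l2", "l3", "l4"),
                                  cbind("hub", c("l1", "l2", "l3", "l4")))

test_that("centralities on a path and a star match path enumeration", {
  cp <- network_centralities(path_net())
  expect_equal(cp$degree, c(1, 2, 1))
  # only the a..c shortest path passes through b; normalization (n-1)(n-2)/2 = 1
  expect_equal(cp$betweenness, c(0, 1, 0))
  # harmonic closeness / (n - 1): ends (1 + 1/2)/2, middle (1 + 1)/2
  expect_equal(cp$closeness, c(0.75, 1, 0.75))
  expect_equal(sum(cp$pagerank), 1, tolerance = 1e-9)

  cs <- network_centralities(star_net())
  hub <- cs[cs$node == "hub", ]
  # all choose(4, 2) leaf pairs route through the hub; normalized to 1
  expect_equal(hub$betweenness, 1)
  expect_equal(hub$degree, 4)
  expect_true(all(cs$betweenness[cs$node != "hub"] == 0))
  expect_equal(hub$eigenvector, 1)
  expect_gt(hub$pagerank, max(cs$pagerank[cs$node != "hub"]))
})

test_that("centralities stay finite on edgeless and disconnected graphs", {
  lonely <- network_centralities(mb_network(c("a", "b", "c")))
  expect_equal(lonely$degree, c(0, 0, 0))
  expect_equal(lonely$closeness, c(0, 0, 0))
  expect_equal(lonely$eigenvector, c(0, 0, 0))
  expect_equal(sum(lonely$pagerank), 1, tolerance = 1e-9)

  two_comp <- mb_network(c("a", "b", "c", "d", "e"),
                         rbind(c("a", "b"), c("c", "d")))
  cc <- network_centralities(two_comp)
  expect_true(all(is.finite(as.matrix(cc[, -1]))))
  expect_equal(cc$eigenvector[cc$node == "e"], 0)
  expect_equal(cc$eigenvector[cc$node == "a"], 1)  # within its 2-node component
})

test_that("composite score reduces to single metrics and peaks at the star hub", {
  w_deg <- c(degree = 1, eigenvector = 0, pagerank = 0, closeness = 0,
             betweenness = 0)
  net <- mb_network(letters[1:5],
                    rbind(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c")))
  sc <- suppressWarnings(strategy2_composite(net, weights = w_deg, top_frac = 0.2))
  expect_equal(sc$node[order(-sc$score)], net$nodes[order(-network_centralities(net)$degree)])

  # star hub: every metric min-max scales to 1 there, so score = sum of weights
  st <- strategy2_composite(star_net(), top_frac = 0.2)
  expect_equal(st$score[st$node == "hub"], sum(composite_weights_default))
  expect_equal(st$score[st$node == "hub"], 1)
  expect_true(st$selected[st$node == "hub"])
  expect_equal(sum(st$selected), 1)  # ceiling(0.2 * 5)
  # leaves are symmetric: identical scores up to solver noise
  expect_equal(length(unique(round(st$score[st$node != "hub"], 10))), 1)
  expect_equal(unname(composite_weights_default),
               c(0.1, 0.1, 0.1, 0.2, 0.5))
})

test_that("vertex-transitive graphs give equal composite scores to all nodes", {
  cycle <- mb_network(letters[1:6],
                      cbind(letters[1:6], letters[c(2:6, 1)]))
  suppressWarnings(
    expect_warning(sc <- strategy2_composite(cycle), "constant across nodes"))
  expect_equal(length(unique(round(sc$score, 10))), 1)
})

test_that("differential centrality flags the taxon whose connectivity shifts", {
  nodes <- sprintf("t%02d", 1:10)
  base <- rbind(c("t01", "t02"), c("t02", "t03"), c("t04", "t05"),
                c("t06", "t07"), c("t08", "t09"))
  clean <- mb_network(nodes, base)
  # t10 gains 5 edges in the diseased network; everything else shifts by <= 1
  scab <- mb_network(nodes, rbind(base, cbind("t10", c("t01", "t03", "t05",
                                                       "t07", "t09"))))
  nets_c <- list(m1 = clean, m2 = clean)
  nets_s <- list(m1 = scab, m2 = scab)
  res <- strategy1_differential(nets_c, nets_s, top_frac = 0.2)
  expect_true("t10" %in% res$selected)
  expect_true(all(c("m1", "m2") %in% res$features$method[res$features$taxon == "t10"]))
  # degree is among the metrics responsible for t10
  expect_match(res$features$features[res$features$taxon == "t10"][1], "degree")

  # cross-method rule is intersection: a method seeing no difference for a
  # taxon can veto it
  flat <- strategy1_differential(list(m1 = clean, m2 = scab),
                                 list(m1 = scab, m2 = scab), top_frac = 0.2)
  expect_true(all(flat$selected %in% flat$per_method$m1))
  expect_true(all(flat$selected %in% flat$per_method$m2))

  # identical networks in both conditions: degenerate, everything ties
  expect_warning(
    degen <- strategy1_differential(list(m1 = clean), list(m1 = clean)),
    "degenerate")
  expect_setequal(degen$selected, nodes)
})

test_that("strategy 2 consensus intersects per-method top sets", {
  nets1 <- list(m1 = star_net(), m2 = star_net(), m3 = star_net())
  res <- strategy2_consensus(nets1, nets1, top_frac = 0.2)
  expect_equal(res$clean, "hub")
  expect_equal(res$scab, "hub")
  expect_equal(res$union, "hub")
  expect_equal(res$intersection, "hub")

  # a method with a disjoint top set empties the consensus
  other_hub <- mb_network(c("hub", "l1", "l2", "l3", "l4"),
                          cbind("l1", c("hub", "l2", "l3", "l4")))
  res2 <- strategy2_consensus(list(m1 = star_net(), m2 = other_hub),
                              list(m1 = star_net(), m2 = other_hub),
                              top_frac = 0.2)
  expect_equal(length(res2$clean), 0)

  # 3-method fixture equals brute-force intersection of per-method top lists
  set.seed(60)
  nets3c <- lapply(setNames(1:3, paste0("m", 1:3)), function(k)
    random_network(letters[1:10], 0.35, seed = 100 + k))
  nets3s <- lapply(setNames(1:3, paste0("m", 1:3)), function(k)
    random_network(letters[1:10], 0.35, seed = 200 + k))
  res3 <- suppressWarnings(strategy2_consensus(nets3c, nets3s, top_frac = 0.3))
  brute <- Reduce(intersect, lapply(nets3c, function(nn) {
    sc <- suppressWarnings(strategy2_composite(nn, top_frac = 0.3))
    sc$node[sc$selected]
  }))
  expect_setequal(res3$clean, brute)
})

test_that("final selection tiers equal brute-force set algebra", {
  taxa <- sprintf("t%02d", 1:12)
  ml <- c("t01", "t02", "t03", "t04")
  s1 <- c("t01", "t02", "t05", "t06")
  s2 <- c("t01", "t03", "t05", "t07")
  rep <- finalize_selection(ml, s1, s2, taxa)
  tier_of <- function(tx) rep$tier[rep$taxon == tx]
  expect_equal(tier_of("t01"), "a")  # all three routes
  expect_equal(tier_of("t02"), "b")  # ML and strategy 1
  expect_equal(tier_of("t03"), "c")  # ML and strategy 2
  expect_equal(tier_of("t05"), "d")  # both network strategies
  expect_true(is.na(tier_of("t08")))
  expect_false(rep$final_selected[rep$taxon == "t08"])
  expect_equal(rep$taxon[rep$final_selected], "t01")
  rep2 <- finalize_selection(ml, s1, s2, taxa, rule = "ml_and_any_network")
  expect_setequal(rep2$taxon[rep2$final_selected], c("t01", "t02", "t03"))
  expect_error(finalize_selection(c(ml, "zz"), s1, s2, taxa), "universe")
})

test_that("selection is invariant under taxon relabeling", {
  set.seed(15)
  nets_c <- lapply(setNames(1:2, c("m1", "m2")), function(k)
    random_network(letters[1:8], 0.4, seed = 300 + k))
  nets_s <- lapply(setNames(1:2, c("m1", "m2")), function(k)
    random_network(letters[1:8], 0.4, seed = 400 + k))
  res <- suppressWarnings(strategy1_differential(nets_c, nets_s, top_frac = 0.25))
  relabel <- function(net, map) {
    mb_network(unname(map[net$nodes]),
               tibble::tibble(from = unname(map[net$edges$from]),
                              to = unname(map[net$edges$to])))
  }
  map <- setNames(sprintf("x%02d", 8:1), letters[1:8])
  res2 <- suppressWarnings(strategy1_differential(
    lapply(nets_c, relabel, map = map), lapply(nets_s, relabel, map = map),
    top_frac = 0.25))
  expect_setequal(unname(map[res$selected]), res2$selected)
})
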