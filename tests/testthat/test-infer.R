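test_that("fit_cpds estimates match counts, with Laplace smoothing for empty configurations", {
  x <- cbind(A = c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0),
             B = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  dag <- bn_dag(c("A", "B"), rbind(c("A", "B")))
  mle <- fit_cpds(dag, x, alpha = 0)
  expect_equal(mle$cpts$A$p1, 0.7)
  expect_equal(mle$cpts$B$p1, c(0 / 3, 5 / 7))

  # configuration never observed: alpha = 0 -> NA, alpha = 1 -> 1/2
  x2 <- cbind(A = rep(1, 10), B = rbinom(10, 1, 0.5))
  dag2 <- bn_dag(c("A", "B"), rbind(c("A", "B")))
  f0 <- fit_cpds(dag2, x2, alpha = 0)
  expect_true(is.na(f0$cpts$B$p1[1]))
  f1 <- fit_cpds(dag2, x2, alpha = 1)
  expect_equal(f1$cpts$B$p1[1], 0.5)
})

test_that("joint_probability factorizes correctly and normalizes", {
  one <- bn_custom(bn_dag("A"), list(A = list(p1 = 0.3)))
  expect_equal(joint_probability(one, c(A = 1)), 0.3)
  expect_equal(joint_probability(one, c(A = 0)), 0.7)

  for (nm in truth_net_names()) {
    net <- make_truth_net(nm)
    j <- mitebn:::enumerate_joint(net)
    expect_equal(sum(j$p), 1, tolerance = 1e-12)
    # spot-check one assignment against the explicit product
    a <- setNames(j$assignments[17 %% nrow(j$assignments) + 1, ],
                  net$dag$nodes)
    expect_equal(joint_probability(net, a), j$p[17 %% nrow(j$assignments) + 1])
  }
})

test_that("queries on an edgeless network reduce to marginals; complements sum to 1", {
  net <- bn_custom(bn_dag(c("A", "B")),
                   list(A = list(p1 = 0.25), B = list(p1 = 0.6)))
  expect_equal(query(net, "A=1", "B=1")$probability, 0.25)
  q1 <- query(net, "A=1", "B=0")$probability
  q0 <- query(net, "A=0", "B=0")$probability
  expect_equal(q1 + q0, 1)
})

test_that("chain query P(Z=1 | X=1) equals the explicit sum over the middle node", {
  net <- bn_custom(
    bn_dag(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z"))),
    list(X = list(p1 = 0.7), Y = list(p1 = c(0.2, 0.9)),
         Z = list(p1 = c(0.2, 0.9)))
  )
  # sum over Y: P(Y=1|X=1)P(Z=1|Y=1) + P(Y=0|X=1)P(Z=1|Y=0)
  hand <- 0.9 * 0.9 + 0.1 * 0.2
  expect_equal(query(net, "Z=1", "X=1")$probability, hand)
  expect_equal(brute_force_query(net, "Z=1", "X=1")$probability, hand)
})

test_that("impossible evidence is flagged undefined, not returned as 0", {
  net <- bn_custom(bn_dag(c("A", "B"), rbind(c("A", "B"))),
                   list(A = list(p1 = 1), B = list(p1 = c(0.5, 0.5))))
  r <- query(net, "B=1", "A=0")
  expect_true(r$undefined)
  expect_true(is.na(r$probability))
  rb <- brute_force_query(net, "B=1", "A=0")
  expect_true(rb$undefined)
})

test_that("query argument validation: overlap, unknown nodes, string specs", {
  net <- make_truth_net("chain3")
  expect_error(query(net, "A=1", "A=0"), "overlap")
  expect_error(query(net, "Q=1"), "unknown node")
  expect_equal(query(net, c(A = 1), c(C = 1))$probability,
               query(net, "A=1", "C=1")$probability)
  expect_equal(query(net, "A=1", "C=1")$support_count, 4)
})

test_that("brute_force_query refuses oversized networks", {
  nodes <- paste0("N", 1:17)
  cpts <- setNames(lapply(nodes, function(v) list(p1 = 0.5)), nodes)
  big <- bn_custom(bn_dag(nodes), cpts)
  expect_error(brute_force_query(big, "N1=1"), "16")
})

test_that("ancestral sampling is reproducible and matches exact marginals", {
  ones <- bn_custom(bn_dag(c("A", "B"), rbind(c("A", "B"))),
                    list(A = list(p1 = 1), B = list(p1 = c(0, 1))))
  m <- sample_net(ones, 50, seed = 61)
  expect_true(all(m$x == 1L))

  net <- make_truth_net("strong5")
  m1 <- sample_net(net, 3000, seed = 62)
  m2 <- sample_net(net, 3000, seed = 62)
  expect_identical(m1$x, m2$x)

  truth <- mitebn:::bn_marginals(net)
  freq <- colMeans(m1$x)
  se <- sqrt(truth * (1 - truth) / nrow(m1$x))
  expect_true(all(abs(freq - truth) <= 3 * se + 1e-9))
})

test_that("sampling frequencies converge to the brute-force conditional", {
  net <- make_truth_net("chain3")
  n <- 200000
  m <- sample_net(net, n, seed = 63)
  sel <- m$x[, "A"] == 1
  emp <- mean(m$x[sel, "C"])
  p <- brute_force_query(net, "C=1", "A=1")$probability
  se <- sqrt(p * (1 - p) / sum(sel))
  expect_lt(abs(emp - p), 3 * se)
})
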