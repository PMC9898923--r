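test_that("every fixture network is a valid normalized Bayesian network", {
  for (nm in truth_net_names()) {
    net <- make_truth_net(nm)
    expect_s3_class(net, "bn_fit")
    expect_silent(mitebn:::topo_sort(net$dag))
    expect_equal(sum(mitebn:::enumerate_joint(net)$p), 1, tolerance = 1e-12)
  }
  expect_error(make_truth_net("nope"), "paper11")
})

test_that("chain3 has 3 nodes / 2 edges; paper11 keeps the root parentless", {
  c3 <- make_truth_net("chain3")
  expect_length(c3$dag$nodes, 3)
  expect_equal(nrow(dag_edges(c3$dag)), 2)

  p11 <- make_truth_net("paper11")
  expect_setequal(p11$dag$nodes, hdm_components())
  expect_length(parents_of(p11$dag, "Der p 23"), 0)
  # the root reaches every component except the standalone group-5 driver
  # Der p 21 and its leaf Der p 11-side path; check it is an ancestor of the
  # major components
  for (v in c("Der f 1", "Der f 2", "Der p 1", "Der p 2")) {
    expect_true(mitebn:::has_path_idx(p11$dag$A,
                                      match("Der p 23", p11$dag$nodes),
                                      match(v, p11$dag$nodes)))
  }
})

test_that("paper11 prevalences among >=1-positive profiles match the published shares to 2pp", {
  net <- make_truth_net("paper11")
  j <- mitebn:::enumerate_joint(net)
  anyp <- rowSums(j$assignments) > 0
  p_any <- sum(j$p[anyp])
  cond <- as.vector(crossprod(j$assignments, j$p)) / p_any
  names(cond) <- net$dag$nodes
  targets <- mitebn:::paper11_share_targets()
  expect_true(all(abs(cond[names(targets)] - targets) < 0.02))
})

test_that("CPT overrides on a leaf shift only that node's marginal", {
  net <- make_truth_net("paper11")
  base <- mitebn:::bn_marginals(net)
  # Der p 11 is a leaf (only child of Der f 2)
  newp <- pmin(net$cpts[["Der p 11"]]$p1 + 0.3, 1)
  net2 <- make_truth_net("paper11", overrides = list("Der p 11" = newp))
  shifted <- mitebn:::bn_marginals(net2)
  expect_gt(shifted[["Der p 11"]], base[["Der p 11"]])
  others <- setdiff(names(base), "Der p 11")
  expect_equal(shifted[others], base[others])
  # the original fixture object is untouched
  expect_equal(mitebn:::bn_marginals(make_truth_net("paper11")), base)
})

test_that("generate_cohort handles n = 0 and is reproducible", {
  p0 <- generate_cohort(cohort_config(0, seed = 1))
  expect_equal(nrow(p0), 0)
  pa <- generate_cohort(cohort_config(200, seed = 71))
  pb <- generate_cohort(cohort_config(200, seed = 71))
  expect_identical(as.data.frame(pa), as.data.frame(pb))
  pc <- generate_cohort(cohort_config(200, seed = 72))
  expect_false(identical(as.data.frame(pa), as.data.frame(pc)))
})

test_that("concentrations are consistent with the binary profiles by construction", {
  p <- generate_cohort(cohort_config(500, seed = 73))
  m <- binarize(p, 0.31)
  raw <- as.matrix(as.data.frame(p)[hdm_components()])
  expect_true(all(raw[m$x == 1L] >= 0.31))
  expect_true(all(raw[m$x == 0L] < 0.31))
  # sensitized patients have >= 1 positive; the rest are fully negative
  expect_true(all(rowSums(m$x) %in% 0:11))

  ph <- generate_cohort(cohort_config(100, seed = 73, hard_zeros = TRUE))
  rawh <- as.matrix(as.data.frame(ph)[hdm_components()])
  mh <- binarize(ph, 0.31)
  expect_true(all(rawh[mh$x == 0L] == 0))
})

test_that("per-component frequencies among the sensitized match the truth-net conditional marginals", {
  cfg <- cohort_config(50000, seed = 74)
  p <- generate_cohort(cfg)
  m <- filter_sensitized(binarize(p, 0.31))
  freq <- colMeans(m$x)

  net <- make_truth_net("paper11")
  j <- mitebn:::enumerate_joint(net)
  anyp <- rowSums(j$assignments) > 0
  cond <- as.vector(crossprod(j$assignments, j$p)) / sum(j$p[anyp])
  names(cond) <- net$dag$nodes
  se <- sqrt(cond * (1 - cond) / nrow(m$x))
  expect_true(all(abs(freq[names(cond)] - cond) <= 3 * se + 1e-9))

  # realized sensitized share near the configured rate
  pct <- nrow(m$x) / nrow(p)
  expect_lt(abs(pct - cfg$sensitized_fraction),
            3 * sqrt(0.2581 * (1 - 0.2581) / nrow(p)))
})

test_that("children carry roughly twice the positive sIgE of adults", {
  p <- generate_cohort(cohort_config(30000, seed = 75))
  raw <- as.data.frame(p)
  v <- raw[["Der f 2"]]
  pos <- v >= 0.31
  med_child <- stats::median(v[pos & raw$age < 18])
  med_adult <- stats::median(v[pos & raw$age >= 18])
  expect_gt(med_child / med_adult, 1.4)
  # and the child/adult mix is close to the configured fraction
  expect_lt(abs(mean(raw$age < 18) - 0.6805), 0.02)
})

test_that("cohort_config validates its parameters", {
  expect_error(cohort_config(10, sensitized_fraction = 0), "sensitized_fraction")
  expect_error(cohort_config(10, child_fraction = 1.2), "child_fraction")
  expect_error(cohort_config(10, sige_sdlog = -1), "scale")
  expect_error(cohort_config(10, truth_net = "chain3"), "11 catalog")
})
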