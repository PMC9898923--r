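test_that("binarize uses an inclusive threshold and carries ages through", {
  df <- tiny_panel_df(c("a", "b", "c"), c(2, 20, 50), sige = 0)
  df[["Der f 1"]] <- c(0.31, 0.309, 0)
  df[["Der p 23"]] <- c(0, 5, 0)
  m <- binarize(hdm_panel(df), 0.31)
  expect_equal(m$x[, "Der f 1"], c(1L, 0L, 0L))
  expect_equal(m$x[, "Der p 23"], c(0L, 1L, 0L))
  expect_equal(unname(rowSums(m$x)[3]), 0)
  expect_equal(m$ages, c(2, 20, 50))
})

test_that("binarize column sums match a naive per-cell recount and are monotone in threshold", {
  set.seed(11)
  p <- generate_cohort(cohort_config(400, seed = 11))
  m <- binarize(p, 0.31)
  raw <- as.matrix(as.data.frame(p)[hdm_components()])
  naive <- integer(ncol(raw))
  for (j in seq_len(ncol(raw))) {
    for (i in seq_len(nrow(raw))) {
      if (raw[i, j] >= 0.31) naive[j] <- naive[j] + 1L
    }
  }
  expect_equal(unname(colSums(m$x)), naive)
  for (thr in c(0.5, 1, 10)) {
    expect_true(all(binarize(p, thr)$x <= m$x))
  }
})

test_that("filter_sensitized keeps exactly the rows with >= 1 positive and is idempotent", {
  set.seed(12)
  p <- generate_cohort(cohort_config(300, seed = 12))
  m <- binarize(p, 0.31)
  f <- filter_sensitized(m)
  expect_equal(nrow(f$x), sum(rowSums(m$x) > 0))
  expect_true(all(rowSums(f$x) >= 1))
  expect_identical(filter_sensitized(f), f)

  allneg <- binarize(hdm_panel(tiny_panel_df(c("a", "b"), c(1, 2), sige = 0.1)))
  expect_equal(nrow(filter_sensitized(allneg)$x), 0)
})

test_that("share reproduces every printed share cell from its count over 5,170", {
  t1 <- table1_counts()
  expect_equal(share(t1$n_all, 5170), t1$share_all)
  expect_equal(share(t1$n_children, 5170), t1$share_children)
  expect_equal(share(t1$n_adults, 5170), t1$share_adults)
  expect_equal(share(0, 5170), 0)
  expect_error(share(1, 0), "denominator")
  expect_error(share(6, 5), "count")
})

test_that("cohort_summary reproduces the cohort-level arithmetic", {
  # cohort shaped like the study: 20,033 tested, 5,170 sensitized of whom
  # 3,518 are children and 1,652 adults
  n_sens_child <- 3518
  n_sens_adult <- 1652
  n_neg <- 20033 - n_sens_child - n_sens_adult
  df <- tiny_panel_df(sprintf("p%05d", seq_len(20033)),
                      c(rep(10, n_sens_child), rep(30, n_sens_adult),
                        rep(10, n_neg)),
                      sige = 0.1)
  df[["Der f 1"]][seq_len(n_sens_child + n_sens_adult)] <- 1.5
  p <- hdm_panel(df)
  m <- filter_sensitized(binarize(p))
  s <- cohort_summary(p, m)
  expect_equal(s$totals$n_total_tested, 20033)
  expect_equal(s$totals$n_sensitized, 5170)
  expect_equal(s$totals$pct_sensitized, 25.81)
  expect_equal(s$totals$n_children + s$totals$n_adults, 5170)
  expect_equal(s$totals$share_children, 68.05)
  expect_equal(s$totals$share_adults, 31.95)
  expect_equal(s$totals$child_adult_ratio, 2.13)
  i <- match("Der f 1", s$components$component)
  expect_equal(s$components$n_all[i], 5170)
  expect_equal(s$components$share_all[i], 100)
  expect_equal(s$components$n_children[i], 3518)
  expect_equal(s$components$share_children[i], 68.05)
})

test_that("stratum share denominators: whole sensitized sample by default, stratum size on request", {
  df <- tiny_panel_df(c("c1", "c2", "c3", "a1"), c(5, 6, 7, 40), sige = 0.1)
  df[["Der p 2"]] <- c(1, 1, 0.1, 1)
  df[["Der p 23"]] <- c(1, 0.1, 1, 0.1)
  p <- hdm_panel(df)
  m <- filter_sensitized(binarize(p))
  s <- cohort_summary(p, m)
  i <- match("Der p 2", s$components$component)
  expect_equal(s$components$share_children[i], share(2, 4))
  expect_equal(s$components$share_adults[i], share(1, 4))
  s2 <- cohort_summary(p, m, stratum_denominator = TRUE)
  expect_equal(s2$components$share_children[i], share(2, 3))
  expect_equal(s2$components$share_adults[i], share(1, 1))
})

test_that("per-component mean/SD among positives match a naive two-pass recount", {
  set.seed(13)
  p <- generate_cohort(cohort_config(500, seed = 13))
  m <- filter_sensitized(binarize(p))
  s <- cohort_summary(p, m)
  raw <- as.data.frame(p)
  sens_ids <- m$ids
  for (k in c("Der f 2", "Der p 23", "Der p 11")) {
    v <- raw[[k]][match(sens_ids, raw$id)]
    v <- v[v >= 0.31]
    i <- match(k, s$components$component)
    if (length(v) == 0) {
      expect_true(is.na(s$components$mean_sige_all[i]))
    } else {
      expect_equal(s$components$mean_sige_all[i], mean(v))
      expect_equal(s$components$sd_sige_all[i],
                   if (length(v) >= 2) sd(v) else NA_real_)
    }
  }
})

test_that("a single positive gives share 100 and an undefined SD", {
  df <- tiny_panel_df("solo", 9, sige = 0.1)
  df[["Der p 5"]] <- 2.2
  p <- hdm_panel(df)
  s <- cohort_summary(p, filter_sensitized(binarize(p)))
  i <- match("Der p 5", s$components$component)
  expect_equal(s$components$n_all[i], 1)
  expect_equal(s$components$share_all[i], 100)
  expect_equal(s$components$mean_sige_all[i], 2.2)
  expect_true(is.na(s$components$sd_sige_all[i]))
})

test_that("cohort_summary is invariant to patient row order", {
  set.seed(14)
  p <- generate_cohort(cohort_config(300, seed = 14))
  m <- filter_sensitized(binarize(p))
  s1 <- cohort_summary(p, m)
  perm <- sample(nrow(p))
  p2 <- hdm_panel(as.data.frame(p)[perm, ])
  m2 <- filter_sensitized(binarize(p2))
  s2 <- cohort_summary(p2, m2)
  expect_equal(s2$totals, s1$totals)
  expect_equal(s2$components, s1$components)
})

test_that("age bands partition [0, Inf) with half-open boundaries", {
  b <- age_bands()
  expect_equal(as.character(age_stratify(0.5, b)), "[0,1)")
  expect_equal(as.character(age_stratify(3, b)), "[3,6)")
  expect_equal(as.character(age_stratify(60, b)), "60+")
  expect_equal(as.character(age_stratify(17.999, b)), "[12,18)")
  expect_error(age_stratify(-1, b), "non-negative")
  expect_error(age_bands(c(3, 1)), "increasing")

  set.seed(15)
  ages <- runif(500, 0, 95)
  tab <- table(age_stratify(ages, b))
  expect_equal(sum(tab), 500)
})

test_that("group_frequency_table computes band frequencies with NA for empty bands", {
  df <- tiny_panel_df(c("a", "b", "c"), c(2, 2.5, 10), sige = 1)
  p <- hdm_panel(df)
  m <- filter_sensitized(binarize(p))
  prof <- group_frequency_table(m, age_bands(c(5)))
  expect_equal(unname(prof$band_sizes), c(2L, 1L))
  expect_true(all(prof$freq_within_band == 100))
  expect_equal(sum(prof$band_sizes), nrow(m$x))

  # an empty band is NA, not 0
  prof2 <- group_frequency_table(m, age_bands(c(5, 50)))
  expect_equal(unname(prof2$band_sizes), c(2L, 1L, 0L))
  expect_true(all(is.na(prof2$freq_within_band["50+", ])))
})

test_that("band frequencies behave binomially for independent coin-flip data", {
  set.seed(16)
  n <- 4000
  x <- matrix(rbinom(n * 3, 1, 0.5), n, 3,
              dimnames = list(NULL, c("K1", "K2", "K3")))
  x[rowSums(x) == 0, 1] <- 1L # keep every row sensitized
  m <- mitebn:::new_sens_matrix(x, ids = as.character(seq_len(n)),
                                ages = runif(n, 0, 10))
  prof <- group_frequency_table(m, age_bands(c(5)))
  # band membership is independent of the flips, so each band frequency is a
  # binomial draw around its column's overall rate
  p_col <- colMeans(x)
  for (b in seq_len(nrow(prof$freq_within_band))) {
    se <- sqrt(p_col * (1 - p_col) / prof$band_sizes[b]) * 100
    expect_true(all(abs(prof$freq_within_band[b, ] - p_col * 100) < 3 * se))
  }
})
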