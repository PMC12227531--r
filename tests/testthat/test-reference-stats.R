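test_that("descriptive summaries match rank-interpolation oracles", {
  m <- matrix(NA_real_, nrow = 24, ncol = 5,
              dimnames = list(dmoNames(), paste0("p", 1:5)))
  m["walking_duration", ] <- 1:5
  m["n_steps", ] <- 7
  m["speed_long", ] <- c(0.7, 0.9, 0.8, NA, 1.1)
  m[is.na(m)] <- 99  # fill the rest so no row is all-NA
  m["speed_long", 4] <- NA
  s <- summarizeDMOs(m)
  wd <- s[s$dmo == "walking_duration", ]
  expect_equal(wd$mean, 3); expect_equal(wd$median, 3)
  expect_equal(wd$p25, 2); expect_equal(wd$p75, 4)
  ns <- s[s$dmo == "n_steps", ]
  expect_equal(ns$sd, 0)
  expect_equal(ns$p25, ns$median)
  expect_equal(s[s$dmo == "speed_long", "n"], 4L)

  set.seed(17)
  for (rep in 1:10) {
    v <- rnorm(sample(4:60, 1), 10, 3)
    m2 <- matrix(rep(v, each = 24), nrow = 24, byrow = FALSE,
                 dimnames = list(dmoNames(), NULL))
    m2[1, ] <- v
    s2 <- summarizeDMOs(m2)[1, ]
    expect_equal(s2$median, oracleQuantile(v, 0.5), tolerance = 1e-12)
    expect_equal(s2$p25, oracleQuantile(v, 0.25), tolerance = 1e-12)
    expect_equal(s2$p75, oracleQuantile(v, 0.75), tolerance = 1e-12)
    expect_equal(s2$sd, oracleSd(v), tolerance = 1e-12)
  }
})

test_that("skewness gate fires on |skew| > 2 only and reports Shapiro-Wilk", {
  g0 <- skewnessGate(c(1, 2, 3))
  expect_false(g0$transformed)
  expect_equal(g0$skewness, 0, tolerance = 1e-12)

  g1 <- skewnessGate(c(1, 1, 1, 1, 100))
  expect_true(g1$transformed)
  expect_true(abs(g1$skewness) > 2)
  expect_equal(g1$values, log(c(1, 1, 1, 1, 100)))
  expect_false(is.na(g1$shapiro_p))

  # skewed but containing non-positives: cannot log-transform
  expect_error(skewnessGate(c(0, 1, 1, 1, 100)), "non-positive")

  if (requireNamespace("e1071", quietly = TRUE)) {
    set.seed(23)
    for (rep in 1:15) {
      x <- rlnorm(sample(10:200, 1), 0, runif(1, 0.2, 1.5))
      expect_equal(sampleSkewness(x), e1071::skewness(x, type = 2), tolerance = 1e-10)
    }
  }
})

test_that("ANCOVA group p equals the explicit projection-matrix partial F", {
  set.seed(29)
  for (rep in 1:15) {
    n <- sample(20:60, 1)
    g <- factor(sample(c("A", "B"), n, replace = TRUE, prob = c(0.5, 0.5)))
    while (min(table(g)) < 3) g <- factor(sample(c("A", "B"), n, replace = TRUE))
    covs <- data.frame(c1 = rnorm(n), c2 = runif(n))
    y <- 2 + 0.5 * (g == "B") + 0.8 * covs$c1 - 0.3 * covs$c2 + rnorm(n)
    res <- ancovaGroupTest(y, g, covs)
    expect_equal(res$raw_p, oracleAncovaP(y, g, covs), tolerance = 1e-10)
  }
})

test_that("ANCOVA reduces exactly to the two-sample t-test when covariates are constant", {
  set.seed(37)
  g <- factor(rep(c("A", "B"), c(14, 16)))
  y <- rnorm(30) + 0.8 * (g == "B")
  res <- ancovaGroupTest(y, g, data.frame(h = rep(5, 30)))
  expect_equal(res$covariates_dropped, "h")
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$raw_p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)

  # identical responses in both groups: no group effect
  y0 <- rep(rnorm(15), 2)
  res0 <- ancovaGroupTest(y0, factor(rep(c("A", "B"), each = 15)),
                          data.frame(c1 = rnorm(30)))
  expect_true(res0$raw_p > 0.9)

  # a covariate collinear with the group indicator is refused by name
  gg <- factor(rep(c("A", "B"), each = 10))
  expect_error(ancovaGroupTest(rnorm(20), gg,
                               data.frame(bad = as.numeric(gg == "B"))),
               "bad")

  # near-pure group signal is detected
  g2 <- factor(rep(c("A", "B"), each = 10))
  y2 <- 2 * (g2 == "B") + rnorm(20, 0, 1e-4)
  expect_lt(ancovaGroupTest(y2, g2)$raw_p, 1e-6)
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.03, 6)), rep(0.03, 6))
  expect_error(bhAdjust(c(0.1, 1.2)), "outside")

  set.seed(41)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, oracleBH(p), tolerance = 1e-12)
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))  # monotone in raw p
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  }
})

test_that("two-sample KS statistic equals the pooled-grid ECDF scan", {
  x <- rnorm(40)
  expect_equal(ksTwoSample(x, x)$D, 0)
  expect_equal(ksTwoSample(rnorm(30), rnorm(30) + 100)$D, 1)
  set.seed(43)
  for (rep in 1:10) {
    x <- rnorm(sample(10:50, 1)); y <- rnorm(sample(10:50, 1), 0.3)
    expect_equal(ksTwoSample(x, y)$D, oracleKSD(x, y), tolerance = 1e-12)
  }
})

test_that("height split is sex-specific, tie-goes-short, idempotent and permutation-invariant", {
  p <- data.frame(id = paste0("p", 1:6),
                  sex = factor(c("F", "F", "F", "M", "M", "M"), levels = c("F", "M")),
                  height = c(150, 155, 160, 165, 170, 175))
  sp <- splitByHeight(p)
  expect_equal(as.character(sp[c("p1", "p2", "p3")]), c("short", "short", "tall"))
  expect_equal(as.character(sp[c("p4", "p5", "p6")]), c("short", "short", "tall"))

  expect_warning(splitByHeight(data.frame(id = c("a", "b"),
                                          sex = factor(c("F", "F"), levels = c("F", "M")),
                                          height = c(150, 150))),
                 "all heights equal")

  set.seed(47)
  for (rep in 1:10) {
    n <- sample(c(10, 11, 20, 21), 1)
    p <- data.frame(id = paste0("p", 1:n),
                    sex = factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M")),
                    height = sample(seq(140, 190, by = 0.5), n))
    sp1 <- splitByHeight(p)
    perm <- sample(n)
    sp2 <- splitByHeight(p[perm, ])
    expect_equal(as.character(sp2[names(sp1)]), as.character(sp1))
    # sizes differ by at most one when heights are distinct within sex
    for (sx in c("F", "M")) {
      i <- p$sex == sx
      if (sum(i) >= 2)
        expect_lte(abs(sum(sp1[i] == "short") - sum(sp1[i] == "tall")), 1)
    }
  }
})

test_that("subgroup tables carry both stratum families with per-family FDR", {
  cfg <- syntheticConfig(nParticipants = 60)
  coh <- generateCohort(cfg, seed = 9)
  se <- suppressMessages(computeCohortTable(coh$participants, coh$bouts, coh$wear))
  sub <- buildSubgroupTables(se)
  expect_setequal(unique(sub$comparison), c("sex_within_age", "height_within_sex"))
  expect_equal(sum(sub$comparison == "height_within_sex"), 48L)  # 24 DMOs x 2 sexes
  # FDR is applied within each stratum family and preserves raw-p order
  for (st in unique(sub$stratum)) {
    fam <- sub[sub$stratum == st & sub$testable, ]
    if (nrow(fam) < 2) next
    expect_equal(fam$fdr_p, oracleBH(fam$raw_p), tolerance = 1e-12)
  }
  # group means are reported on the original scale even for transformed DMOs
  tr <- sub[sub$transformed & sub$testable, ]
  if (nrow(tr)) expect_true(all(tr$mean1 > 0 | tr$mean2 > 0, na.rm = TRUE))
  expect_true(all(sub$fdr_p >= sub$raw_p - 1e-12, na.rm = TRUE))
})
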