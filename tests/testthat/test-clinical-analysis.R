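test_that("propensity scores behave under null and confounded assignment", {
  set.seed(121)
  n <- 5000
  cl <- data.frame(age = rnorm(n, 60, 10), sofa = rpois(n, 7),
                   treated = rbinom(n, 1, 0.3))
  e <- estimate_propensity(cl, c("age", "sofa"))
  expect_lt(sd(e), 0.03)
  expect_lt(abs(mean(e) - mean(cl$treated)), 0.02)

  # strong single confounder: score monotone in it
  cl2 <- data.frame(x = rnorm(n))
  cl2$treated <- rbinom(n, 1, plogis(1.5 * cl2$x))
  e2 <- estimate_propensity(cl2, "x")
  expect_gt(coef(attr(e2, "model"))["x"], 0)
  expect_true(all(diff(e2[order(cl2$x)]) >= 0))

  # duplicated rows get identical scores
  cl3 <- rbind(cl[1:50, ], cl[1:50, ])
  e3 <- estimate_propensity(cl3, c("age", "sofa"))
  expect_equal(unname(e3[1:50]), unname(e3[51:100]))
})

test_that("nearest-neighbor matching picks the closest control within the caliper", {
  scores <- c(0.6, 0.55, 0.9, 0.3)
  treated <- c(1, 0, 0, 0)
  m <- nn_match(scores, treated, caliper_sd = 50)
  expect_equal(m$pairs$treated, 1)
  expect_equal(m$pairs$control, 2)

  # caliper 0: only exact-score pairs survive
  s2 <- c(0.4, 0.4, 0.7, 0.2)
  t2 <- c(1, 0, 1, 0)
  m2 <- nn_match(s2, t2, caliper_sd = 0)
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(m2$pairs$control, 2)
  expect_equal(m2$n_dropped, 1)

  # never pairs within one arm; equal counts per arm
  set.seed(122)
  s3 <- runif(200)
  t3 <- rbinom(200, 1, 0.4)
  m3 <- nn_match(s3, t3)
  expect_true(all(t3[m3$pairs$treated] == 1))
  expect_true(all(t3[m3$pairs$control] == 0))
  expect_equal(anyDuplicated(m3$pairs$control), 0)
})

test_that("matching balances the confounded synthetic cohort", {
  co <- small_cohort(seed = 123, n = 2000, g = 60, nsig = 5)
  cl <- co$clinical
  covs <- c("age", "sofa", "shock")
  e <- estimate_propensity(cl, covs)
  pre <- standardized_mean_diff(cl, covs)
  expect_gt(max(pre), 0.25)     # confounding is visible before matching
  m <- nn_match(e, cl$treated)
  idx <- c(m$pairs$treated, m$pairs$control)
  post <- standardized_mean_diff(cl[idx, ], covs, treated = cl$treated[idx])
  expect_true(all(post < 0.1))
})

test_that("logistic OR equals the 2x2 cross-product ratio exactly", {
  d <- data.frame(event = rep(c(1, 0, 1, 0), c(30, 70, 10, 90)),
                  treated = rep(c(1, 0), each = 100))
  f <- logistic_interaction(d, event ~ treated)
  expect_equal(f$coefficients$or[f$coefficients$term == "treated"],
               (30 * 90) / (70 * 10), tolerance = 1e-8)
  expect_error(logistic_interaction(data.frame(event = rep(1, 10),
                                               treated = rep(0:1, 5)),
                                    event ~ treated), "constant")
})

test_that("planted interaction log-odds are recovered within the Wald CI", {
  set.seed(124)
  n <- 2000
  d <- data.frame(treated = rbinom(n, 1, 0.5),
                  cts = factor(sample(paste0("CTS", 1:3), n, replace = TRUE)))
  beta <- c(b0 = -2, trt = 1.0, cts2 = 0.7, cts3 = 0.2, i2 = -0.6, i3 = -1.1)
  eta <- with(d, beta["b0"] + beta["trt"] * treated +
                beta["cts2"] * (cts == "CTS2") + beta["cts3"] * (cts == "CTS3") +
                beta["i2"] * treated * (cts == "CTS2") +
                beta["i3"] * treated * (cts == "CTS3"))
  d$event <- rbinom(n, 1, plogis(eta))
  f <- logistic_interaction(d)
  co <- f$coefficients
  expect_true(co$ci_lo[co$term == "treated:ctsCTS3"] < exp(beta["i3"]) &&
                exp(beta["i3"]) < co$ci_hi[co$term == "treated:ctsCTS3"])
  expect_true(all(co$ci_lo < co$or & co$or < co$ci_hi))
  expect_true(is.finite(f$aic))
})

test_that("Kaplan-Meier and log-rank match hand computations", {
  # no censoring, distinct death times: survival steps of exactly 1/n
  km <- km_logrank(c(1, 2, 3, 4, 5, 6), rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(sort(unique(round(diff(c(1, km$fit$surv[1:3])), 10))), -1/3)

  # identical groups: statistic 0, p = 1
  km0 <- km_logrank(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(km0$chisq, 0, tolerance = 1e-12)
  expect_equal(km0$p, 1)

  # 6-patient toy vs a hand-computed observed-vs-expected table
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 1, 1)
  grp <- c("A", "A", "A", "B", "B", "B")
  hand_logrank <- function(time, event, grp) {
    o_minus_e <- 0; v <- 0
    for (t in sort(unique(time[event == 1]))) {
      at_risk <- time >= t
      d <- sum(time == t & event == 1)
      n <- sum(at_risk)
      n1 <- sum(at_risk & grp == "A")
      o1 <- sum(time == t & event == 1 & grp == "A")
      e1 <- d * n1 / n
      o_minus_e <- o_minus_e + (o1 - e1)
      if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    o_minus_e^2 / v
  }
  km2 <- km_logrank(time, event, grp)
  expect_equal(km2$chisq, hand_logrank(time, event, grp), tolerance = 1e-10)
  expect_error(km_logrank(time, event, rep("A", 6)), ">= 2 groups")
})

test_that("chi-squared omnibus and Bonferroni post hoc follow the hand formulas", {
  same <- matrix(c(10, 20, 10, 20), 2, 2)
  expect_equal(chi2_posthoc(same)$statistic, 0, tolerance = 1e-12)

  tab <- matrix(c(10, 20, 20, 10), 2, 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi2_posthoc(tab)$statistic,
               sum((tab - expected)^2 / expected), tolerance = 1e-10)

  tab3 <- matrix(c(10, 20, 15, 15, 30, 5), 2, 3,
                 dimnames = list(NULL, c("c1", "c2", "c3")))
  ph <- chi2_posthoc(tab3)
  expect_equal(nrow(ph$pairwise), 3)
  raw12 <- chisq.test(tab3[, 1:2], correct = FALSE)$p.value
  expect_equal(ph$pairwise$p_adjusted[1], min(1, raw12 * 3), tolerance = 1e-12)
  expect_error(chi2_posthoc(matrix(c(1, 0, 1, 0), 2, 2)), "expected")
})

test_that("Dunn post hoc z equals the pooled-rank-mean formula", {
  vals <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  grp <- rep(c("a", "b", "c"), c(3, 3, 4))
  kd <- kruskal_dunn(vals, grp)
  # hand formula with tie correction
  N <- length(vals)
  r <- rank(vals)
  rbar <- tapply(r, grp, mean)
  ns <- table(grp)
  ties <- table(vals)
  sig2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  z_ab <- (rbar["a"] - rbar["b"]) / sqrt(sig2 * (1 / ns["a"] + 1 / ns["b"]))
  expect_equal(kd$pairwise$z[kd$pairwise$group_a == "a" &
                               kd$pairwise$group_b == "b"],
               unname(z_ab), tolerance = 1e-12)

  # identical groups: all adjusted p = 1
  same <- kruskal_dunn(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(same$pairwise$p_adjusted == 1))

  # shift alternative: power at the configured effect
  set.seed(125)
  hits <- mean(vapply(1:100, function(i) {
    v <- c(rnorm(30), rnorm(30) + 1.2, rnorm(30))
    g <- rep(c("a", "b", "c"), each = 30)
    kruskal_dunn(v, g)$kw$p < 0.05
  }, TRUE))
  expect_gt(hits, 0.8)
})

test_that("category-free NRI equals the exhaustive up/down tally", {
  r <- runif(10)
  y <- rbinom(10, 1, 0.5)
  y[1] <- 1
  expect_equal(nri_bootstrap(r, r, y, n_boot = 100, seed = 1)$nri, 0)

  # perfect reordering toward outcomes: maximal category-free NRI of 2
  old <- rep(0.5, 8)
  y8 <- c(1, 1, 1, 1, 0, 0, 0, 0)
  new <- c(rep(0.9, 4), rep(0.1, 4))
  expect_equal(nri_bootstrap(old, new, y8, n_boot = 100, seed = 2)$nri, 2)

  # 8-patient toy, hand tally
  old8 <- c(0.2, 0.4, 0.3, 0.6, 0.5, 0.1, 0.7, 0.2)
  new8 <- c(0.3, 0.3, 0.5, 0.6, 0.4, 0.3, 0.6, 0.1)
  y8b <- c(1, 1, 1, 0, 0, 0, 0, 1)
  ev <- y8b == 1
  up <- new8 > old8; down <- new8 < old8
  hand <- (mean(up[ev]) - mean(down[ev])) + (mean(down[!ev]) - mean(up[!ev]))
  out <- nri_bootstrap(old8, new8, y8b, n_boot = 500, seed = 3)
  expect_equal(out$nri, hand)
  expect_true(out$ci[1] <= out$nri && out$nri <= out$ci[2])
  expect_error(nri_bootstrap(old8, new8, rep(0, 8)), "no events")
})

test_that("Levene's test detects variance heterogeneity and not equality", {
  same <- levene_test(rep(c(1, 2, 3, 4), 2), rep(c("a", "b"), each = 4))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  set.seed(126)
  v <- c(rnorm(100, sd = 1), rnorm(100, sd = 3))
  g <- rep(c("a", "b"), each = 100)
  expect_lt(levene_test(v, g)$p, 0.01)
  skip_if_not_installed("car")
  ref <- car::leveneTest(v, factor(g), center = mean)
  expect_equal(levene_test(v, g)$statistic, ref$`F value`[1], tolerance = 1e-10)
})

test_that("table percentages use round-half-up to one decimal", {
  cl <- data.frame(dead = c(rep(1, 80), rep(0, 497 - 80),
                            rep(1, 61), rep(0, 213 - 61)))
  lab <- rep(c("CTS1", "CTS2"), c(497, 213))
  t1 <- table_one(cl, lab, variables = "dead")
  expect_equal(t1$pct[t1$cts == "CTS1"], 16.1)
  expect_equal(t1$pct[t1$cts == "CTS2"], 28.6)

  cl0 <- data.frame(flag = rep(0, 20))
  t0 <- table_one(cl0, rep("CTS1", 20), variables = "flag")
  expect_equal(t0$pct, 0)

  # continuous summaries and explicit denominators
  cl2 <- data.frame(age = c(60, 62, 64, 70), marker = c(1, 0, 1, 1))
  lab2 <- c("A", "A", "B", "B")
  t2 <- table_one(cl2, lab2)
  expect_equal(t2$mean[t2$variable == "age" & t2$cts == "A"], 61)
  t3 <- table_one(cl2, lab2, variables = "marker",
                  denominators = list(marker = c(4, 4)))
  expect_equal(t3$pct, c(25.0, 50.0))
  expect_error(table_one(cl2, lab2, variables = "marker",
                         denominators = list(marker = c(0, 4))),
               "denominator")
})

test_that("small-n tests keep their nominal type-I rates", {
  set.seed(127)
  reps <- 400
  lev <- mean(vapply(seq_len(reps), function(i) {
    levene_test(rnorm(60), rep(c("a", "b", "c"), each = 20))$p < 0.05
  }, TRUE))
  expect_lt(abs(lev - 0.05), 0.03)
  lr <- mean(vapply(seq_len(reps), function(i) {
    time <- rexp(40, 0.1)
    km_logrank(pmin(time, 28), as.integer(time <= 28),
               rep(c("a", "b"), each = 20))$p < 0.05
  }, TRUE))
  expect_lt(abs(lr - 0.05), 0.03)
})
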