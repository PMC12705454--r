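test_that("Kruskal-Wallis H matches the hand rank computation", {
  # ranks 1..6, R1 = 6, R2 = 15 -> H = 12/(6*7) * (36/3 + 225/3) - 21 = 3.857
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 3.857, tolerance = 5e-4)
  # identical groups: no separation
  kw0 <- kruskal_wallis(list(c(1, 5, 9), c(1, 5, 9)))
  expect_lt(kw0$H, 0.05)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("vectorized one-vs-all KW equals kruskal.test, including heavy ties", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 40
    x <- rbind(a = sample(1:4, n, replace = TRUE),  # ties-heavy
               b = rnorm(n),
               c = rep(3, n))                        # constant gene
    colnames(x) <- sprintf("s%02d", 1:n)
    grp <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(grp)) < 2) next
    ranks <- t(apply(x, 1, rank))
    tie_c <- apply(x, 1, function(v) {
      t <- table(v); 1 - sum(t^3 - t) / (n^3 - n)
    })
    got <- ctsepsis:::kw_rows_binary(ranks, grp, tie_c)
    for (g in c("a", "b")) {
      ref <- kruskal.test(x[g, ], factor(grp))
      expect_equal(got$H[[g]], unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$p[[g]], ref$p.value, tolerance = 1e-10)
    }
    expect_equal(got$H[["c"]], 0)   # constant gene: defined as no signal
  }
})

test_that("gene ranking recovers planted signatures and defaults to the top 5000", {
  set.seed(72)
  n <- 120
  lab <- factor(rep(c("CTS1", "CTS2", "CTS3"), each = n / 3))
  x <- matrix(rnorm(100 * n), 100, n,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%03d", 1:n)))
  sig <- sprintf("g%03d", 1:10)
  x[sig[1:4], lab == "CTS1"] <- x[sig[1:4], lab == "CTS1"] + 3
  x[sig[5:7], lab == "CTS2"] <- x[sig[5:7], lab == "CTS2"] + 3
  x[sig[8:10], lab == "CTS3"] <- x[sig[8:10], lab == "CTS3"] + 3
  r <- rank_genes(x, lab)
  expect_setequal(r$gene[1:10], sig)
  expect_equal(eval(formals(rank_genes)$top_n), 5000)

  # permuted labels: one-vs-all p-values behave uniformly
  set.seed(73)
  rp <- rank_genes(x[11:100, ], sample(lab))
  expect_gt(suppressWarnings(stats::ks.test(rp$p_CTS1, "punif"))$p.value, 0.01)
})

test_that("cross-validated selection finds a small panel on separable data", {
  co <- small_cohort(seed = 74, n = 300, g = 150, nsig = 10)
  lab <- factor(paste0("CTS", as.integer(co$true_subtype)))
  cv <- cv_panel_selection(co$expression, lab, grid = c(5, 10, 20, 30),
                           folds = 5, n_trees = 100, seed = 4)
  expect_lte(cv$selected, 20)
  expect_lt(cv$table$cv_error[cv$table$size == cv$selected], 0.05)
  expect_true(all(cv$table$brier >= 0 & cv$table$brier <= 2))
  # deterministic given the seed
  cv2 <- cv_panel_selection(co$expression, lab, grid = c(5, 10, 20, 30),
                            folds = 5, n_trees = 100, seed = 4)
  expect_identical(cv$table, cv2$table)
})

test_that("randomized labels drive CV error to the majority-class baseline", {
  co <- small_cohort(seed = 75, n = 240, g = 80, nsig = 5)
  set.seed(76)
  lab <- factor(sample(paste0("CTS", 1:3), 240, replace = TRUE,
                       prob = c(0.4, 0.3, 0.3)))
  expect_warning(
    cv <- cv_panel_selection(co$expression, lab, grid = c(10, 20),
                             folds = 5, n_trees = 100, seed = 5),
    "no panel size")
  baseline <- 1 - max(table(lab)) / length(lab)
  expect_gt(min(cv$table$cv_error), baseline - 0.1)
})

test_that("the final forest is reproducible and separates planted classes", {
  co <- small_cohort(seed = 77, n = 600, g = 120, nsig = 10)
  lab <- factor(paste0("CTS", as.integer(co$true_subtype)))
  panel <- unlist(co$signature_genes)
  m1 <- fit_cts_model(co$expression, lab, panel, n_trees = 300, seed = 6)
  m2 <- fit_cts_model(co$expression, lab, panel, n_trees = 300, seed = 6)
  expect_identical(m1$oob_error, m2$oob_error)
  expect_identical(m1$oob_votes, m2$oob_votes)
  expect_lt(m1$oob_error, 0.02)

  # permuted labels: OOB error near the majority baseline
  set.seed(78)
  labp <- sample(lab)
  mp <- fit_cts_model(co$expression, labp, panel, n_trees = 300, seed = 6)
  baseline <- 1 - max(table(labp)) / length(labp)
  expect_lt(abs(mp$oob_error - baseline), 0.05)

  expect_error(fit_cts_model(co$expression, lab, c(panel, "NOPE")), "NOPE")
  expect_error(fit_cts_model(co$expression, factor(lab, levels = c(levels(lab), "CTS9")),
                             panel), "CTS9")
})

test_that("prediction returns normalized posteriors and high resubstitution accuracy", {
  co <- small_cohort(seed = 79, n = 300, g = 120, nsig = 10)
  lab <- factor(paste0("CTS", as.integer(co$true_subtype)))
  m <- fit_cts_model(co$expression, lab, unlist(co$signature_genes),
                     n_trees = 200, seed = 7)
  pred <- predict(m, co$expression)
  expect_gte(mean(as.character(pred$cts) == as.character(lab)), 0.98)
  probs <- as.matrix(pred[, m$classes])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-12)
  expect_gt(attr(pred, "frac_confident"), 0.8)
  expect_error(predict(m, co$expression[-1, ]), m$panel[1])

  # single tree: posteriors are vote counts in {0, 1}
  m1 <- fit_cts_model(co$expression, lab, unlist(co$signature_genes),
                      n_trees = 1, seed = 8)
  p1 <- predict(m1, co$expression[, 1:20])
  expect_true(all(as.matrix(p1[, m1$classes]) %in% c(0, 1)))
})

test_that("Brier score spans 0 (perfect) to 2 (certain and wrong)", {
  classes <- c("CTS1", "CTS2", "CTS3")
  onehot <- diag(3)
  colnames(onehot) <- classes
  expect_equal(brier_score(onehot, classes), 0)
  expect_equal(brier_score(onehot[c(2, 3, 1), ], classes), 2)
  unif <- matrix(1 / 3, 3, 3, dimnames = list(NULL, classes))
  expect_equal(brier_score(unif, classes), 2 / 3)  # (2/3)^2 + 2 (1/3)^2
  expect_error(brier_score(onehot, c("CTS1", "CTS2", "XX")), "outside")
})

test_that("one-vs-all AUC equals exhaustive pair counting", {
  pair_auc <- function(score, pos) {
    num <- 0
    ip <- which(pos)
    ineg <- which(!pos)
    for (i in ip) for (j in ineg) {
      num <- num + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
    }
    num / (length(ip) * length(ineg))
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(80)
  for (rep in 1:10) {
    s <- sample(1:5, 12, replace = TRUE)  # ties included
    y <- sample(0:1, 12, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), pair_auc(s, y == 1), tolerance = 1e-12)
  }
  post <- cbind(CTS1 = c(0.9, 0.8, 0.1, 0.2), CTS2 = c(0.1, 0.2, 0.9, 0.8))
  auc <- one_vs_all_auc(post, c("CTS1", "CTS1", "CTS2", "CTS2"))
  expect_equal(unname(auc), c(1, 1))
  skip_if_not_installed("pROC")
  set.seed(81)
  s <- rnorm(40)
  y <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(s, y),
               as.numeric(suppressMessages(pROC::auc(y, s, direction = "<"))),
               tolerance = 1e-10)
})

test_that("panel derivation recovers planted signature genes across seeds", {
  overlaps <- vapply(c(91, 92, 93), function(s) {
    co <- small_cohort(seed = s, n = 300, g = 200, nsig = 10)
    lab <- factor(paste0("CTS", as.integer(co$true_subtype)))
    r <- rank_genes(co$expression, lab)
    panel <- r$gene[1:30]
    mean(panel %in% unlist(co$signature_genes))
  }, 0)
  expect_true(all(overlaps >= 0.8))
})
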