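## Subtype-stratified clinical statistics: propensity-matched treatment
## effects with interactions, survival analysis, post-hoc tests, risk
## discrimination and reclassification, and cohort description tables.

#' Estimate propensity scores by logistic regression
#'
#' Maximum-likelihood logistic model of treatment on the given covariates.
#'
#' @param clinical Data frame with a binary \code{treated} column and the
#'   covariates.
#' @param covariates Character vector of covariate column names.
#' @return Numeric vector of scores in (0, 1), one per row; the fitted
#'   \code{glm} is attached as attribute \code{model}.
#' @export
estimate_propensity <- function(clinical, covariates) {
  stop_if(!all(covariates %in% names(clinical)),
          "missing covariate column(s): ",
          paste(setdiff(covariates, names(clinical)), collapse = ", "))
  stop_if(length(unique(clinical$treated)) < 2,
          "both treated and untreated patients are required")
  f <- stats::reformulate(covariates, response = "treated")
  fit <- stats::glm(f, data = clinical, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  e <- stats::fitted(fit)
  if (any(e < 1e-8 | e > 1 - 1e-8)) {
    stop("(near-)perfect separation in the propensity model; review covariates",
         call. = FALSE)
  }
  attr(e, "model") <- fit
  e
}

#' Standardized mean differences between treated and untreated
#'
#' @param clinical Data frame.
#' @param covariates Columns to compare (numeric or binary; factors are
#'   expanded to level indicators).
#' @param treated Binary vector (defaults to \code{clinical$treated}).
#' @return Named vector of absolute standardized mean differences.
#' @export
standardized_mean_diff <- function(clinical, covariates,
                                   treated = clinical$treated) {
  x <- stats::model.matrix(stats::reformulate(covariates, intercept = FALSE),
                           data = clinical)
  t1 <- treated == 1
  smd <- vapply(colnames(x), function(cn) {
    m1 <- mean(x[t1, cn]); m0 <- mean(x[!t1, cn])
    s <- sqrt((stats::var(x[t1, cn]) + stats::var(x[!t1, cn])) / 2)
    if (s == 0) 0 else abs(m1 - m0) / s
  }, 0)
  smd
}

#' Greedy 1:1 nearest-neighbor propensity matching with a caliper
#'
#' Matches each treated patient (processed in order of descending propensity)
#' to the nearest unmatched control on the logit propensity scale, without
#' replacement. The caliper is \code{caliper_sd} standard deviations of the
#' logit propensity; treated patients with no control inside the caliper are
#' dropped (count reported).
#'
#' @param scores Propensity scores in (0, 1).
#' @param treated_flags Binary treatment indicator.
#' @param caliper_sd Caliper width in sd units of the logit propensity
#'   (default 1.2).
#' @return A \code{matched_cohort}: \code{pairs} (data frame of treated and
#'   control row indices with their score distance), \code{caliper} (on the
#'   logit scale), \code{n_dropped}.
#' @export
nn_match <- function(scores, treated_flags, caliper_sd = 1.2) {
  stop_if(length(scores) != length(treated_flags),
          "'scores' and 'treated_flags' must align")
  stop_if(!any(treated_flags == 1) || !any(treated_flags == 0),
          "both groups must be non-empty")
  lp <- stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  caliper <- caliper_sd * stats::sd(lp)
  trt <- which(treated_flags == 1)
  ctl <- which(treated_flags == 0)
  trt <- trt[order(scores[trt], decreasing = TRUE)]
  used <- rep(FALSE, length(ctl))
  pairs <- list()
  dropped <- 0L
  for (ti in trt) {
    d <- abs(lp[ctl] - lp[ti])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= caliper) {
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(treated = ti,
                                                control = ctl[j],
                                                distance = d[j])
    } else {
      dropped <- dropped + 1L
    }
  }
  stop_if(length(pairs) == 0, "no matches within the caliper")
  structure(list(pairs = do.call(rbind, pairs), caliper = caliper,
                 n_dropped = dropped),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("Propensity-matched cohort: %d pairs (caliper %.3f on logit scale, %d treated dropped)\n",
              nrow(x$pairs), x$caliper, x$n_dropped))
  invisible(x)
}

#' Logistic regression of outcome on treatment x subtype
#'
#' Fits \code{event ~ treated * cts} (or a supplied formula) with explicit
#' reference levels (first CTS level, untreated) and reports odds ratios
#' with Wald 95% confidence intervals and the model AIC.
#'
#' @param clinical Data frame containing the model variables; \code{cts}
#'   should be a factor.
#' @param formula Model formula (default \code{event ~ treated * cts}).
#' @return An \code{interaction_fit}: \code{coefficients} data frame (term,
#'   estimate, or, ci_lo, ci_hi, p), \code{aic}, \code{model}.
#' @export
logistic_interaction <- function(clinical, formula = event ~ treated * cts) {
  mf <- stats::model.frame(formula, data = clinical)
  y <- stats::model.response(mf)
  stop_if(length(unique(y)) < 2, "outcome is constant")
  if ("treated" %in% names(clinical) && "cts" %in% names(clinical)) {
    cells <- table(clinical$treated, clinical$cts)
    if (any(cells == 0)) {
      warning("empty treated x cts cell(s); estimates may be unstable")
    }
  }
  fit <- stats::glm(formula, data = clinical, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  est <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  coefs <- data.frame(term = rownames(est),
                      estimate = est[, "Estimate"],
                      or = exp(est[, "Estimate"]),
                      ci_lo = exp(est[, "Estimate"] - z * est[, "Std. Error"]),
                      ci_hi = exp(est[, "Estimate"] + z * est[, "Std. Error"]),
                      p = est[, "Pr(>|z|)"],
                      row.names = NULL)
  structure(list(coefficients = coefs, aic = stats::AIC(fit), model = fit),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("Treatment x subtype logistic model (Wald 95% CI):\n")
  df <- x$coefficients
  df$or <- round(df$or, 3); df$ci_lo <- round(df$ci_lo, 3)
  df$ci_hi <- round(df$ci_hi, 3); df$p <- signif(df$p, 3)
  print(df[, c("term", "or", "ci_lo", "ci_hi", "p")], row.names = FALSE)
  cat(sprintf("AIC: %.2f\n", x$aic))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group and the log-rank chi-squared
#' statistic with (groups - 1) degrees of freedom, via \pkg{survival}.
#'
#' @param time Follow-up time (> 0).
#' @param event Event indicator in \{0, 1\}.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List with \code{fit} (a \code{survfit}), \code{chisq}, \code{df},
#'   \code{p}.
#' @export
km_logrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  stop_if(nlevels(group) < 2, "need >= 2 groups")
  stop_if(any(table(group) == 0), "empty group")
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- nlevels(group) - 1
  list(fit = fit, chisq = unname(sd$chisq), df = dfree,
       p = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE))
}

#' Chi-squared omnibus test with Bonferroni-corrected pairwise post hoc
#'
#' Pearson chi-squared on an r x c count table, followed by tests of every
#' column pair (r x 2 subtables) with p-values multiplied by the number of
#' pairs and clipped at 1.
#'
#' @param table r x c matrix of non-negative counts.
#' @return List with \code{statistic}, \code{p} (omnibus) and
#'   \code{pairwise} (data frame: col_a, col_b, statistic, p_adjusted).
#' @export
chi2_posthoc <- function(table) {
  table <- as.matrix(table)
  stop_if(any(table < 0) || sum(table) == 0, "counts must be non-negative with a positive total")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  stop_if(any(expected == 0), "expected count of zero")
  omni <- stats::chisq.test(table, correct = FALSE)
  cols <- colnames(table) %||% as.character(seq_len(ncol(table)))
  pairs <- utils::combn(seq_len(ncol(table)), 2)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(i) {
    sub <- table[, pairs[, i], drop = FALSE]
    ct <- stats::chisq.test(sub, correct = FALSE)
    data.frame(col_a = cols[pairs[1, i]], col_b = cols[pairs[2, i]],
               statistic = unname(ct$statistic),
               p_adjusted = min(1, ct$p.value * m))
  }))
  list(statistic = unname(omni$statistic), p = omni$p.value, pairwise = pw)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Dunn z statistics from pooled-rank means with tie correction,
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T/(12(N-1)))
#' (1/n_i + 1/n_j)}} where \eqn{T = \sum (t^3 - t)} over tied groups, with
#' selectable multiplicity adjustment.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 3 groups for the post hoc step).
#' @param method Adjustment for the pairwise p-values: \code{"bonferroni"}
#'   or \code{"BH"}.
#' @return List with \code{kw} (H and p) and \code{pairwise} (data frame:
#'   group_a, group_b, z, p, p_adjusted).
#' @export
kruskal_dunn <- function(values, groups, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  groups <- droplevels(as.factor(groups))
  stop_if(any(table(groups) == 0), "group of size 0")
  stop_if(nlevels(groups) < 3, "post hoc comparisons need >= 3 groups")
  kt <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- table(groups)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties)
  sig2 <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    z <- (rbar[a] - rbar[b]) / sqrt(sig2 * (1 / ns[a] + 1 / ns[b]))
    data.frame(group_a = a, group_b = b, z = unname(z),
               p = 2 * stats::pnorm(-abs(unname(z))))
  }))
  pw$p_adjusted <- stats::p.adjust(pw$p, method = method)
  list(kw = list(H = unname(kt$statistic), p = kt$p.value), pairwise = pw)
}

#' ROC AUC of a score for a binary outcome
#'
#' Midrank Mann-Whitney formulation.
#'
#' @param score Numeric risk score.
#' @param outcome Binary outcome (both classes present).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(score, outcome) {
  auc_rank(score, outcome == 1)
}

#' Category-free net reclassification improvement with bootstrap CI
#'
#' \eqn{NRI = [P(up|event) - P(down|event)] + [P(down|nonevent) -
#' P(up|nonevent)]} where "up"/"down" mean the new risk is higher/lower than
#' the old; the confidence interval is a bootstrap percentile interval.
#'
#' @param risk_old,risk_new Risk vectors in [0, 1].
#' @param outcome Binary outcome with at least one event.
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return List with \code{nri}, \code{ci} (length 2), \code{n_boot}.
#' @export
nri_bootstrap <- function(risk_old, risk_new, outcome, n_boot = 1000,
                          conf = 0.95, seed = 1L) {
  stop_if(any(risk_old < 0 | risk_old > 1 | risk_new < 0 | risk_new > 1),
          "risks must lie in [0, 1]")
  stop_if(sum(outcome == 1) == 0, "no events")
  nri_of <- function(idx) {
    up <- risk_new[idx] > risk_old[idx]
    down <- risk_new[idx] < risk_old[idx]
    ev <- outcome[idx] == 1
    if (!any(ev) || all(ev)) return(NA_real_)
    (mean(up[ev]) - mean(down[ev])) + (mean(down[!ev]) - mean(up[!ev]))
  }
  est <- nri_of(seq_along(outcome))
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      nri_of(sample.int(length(outcome), replace = TRUE))
    }, 0)
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(nri = est, ci = ci, n_boot = n_boot)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group center (mean for the
#' classic test, median for the Brown-Forsythe variant).
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups of size >= 2).
#' @param center \code{"mean"} (default) or \code{"median"}.
#' @return List with \code{statistic} (F), \code{df}, \code{p}.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- droplevels(as.factor(groups))
  stop_if(nlevels(groups) < 2 || any(table(groups) < 2),
          "need >= 2 groups of size >= 2")
  cfun <- if (center == "mean") mean else stats::median
  centers <- tapply(values, groups, cfun)
  adev <- abs(values - centers[groups])
  fit <- stats::anova(stats::lm(adev ~ groups))
  list(statistic = fit$`F value`[1],
       df = c(fit$Df[1], fit$Df[2]),
       p = fit$`Pr(>F)`[1])
}

#' Cohort description table per consensus subtype
#'
#' Counts and percentages per CTS for categorical/binary variables, and
#' summary statistics for continuous ones. Percentages are
#' \code{100 * count / denominator}, rounded half-up to one decimal;
#' denominators default to the per-CTS sample size unless a
#' variable-specific denominator is supplied.
#'
#' @param clinical Data frame of per-patient variables.
#' @param labels Per-patient CTS labels covering all patients.
#' @param variables Columns to tabulate (default: all except identifiers).
#' @param denominators Optional named list: variable -> named vector of
#'   per-CTS denominators.
#' @return A \code{table_one} data frame: \code{variable}, \code{level},
#'   \code{cts}, \code{count}, \code{denominator}, \code{pct} (one decimal)
#'   for categorical rows; \code{mean}/\code{sd}/\code{median}/\code{q1}/
#'   \code{q3} columns for continuous rows.
#' @export
table_one <- function(clinical, labels, variables = NULL,
                      denominators = NULL) {
  stop_if(length(labels) != nrow(clinical),
          "labels must cover all patients")
  labels <- droplevels(as.factor(labels))
  variables <- variables %||% setdiff(names(clinical),
                                      c("sample_id", "patient_id"))
  n_by <- table(labels)
  stop_if(any(n_by == 0), "denominator 0 for some CTS")
  rows <- list()
  for (v in variables) {
    x <- clinical[[v]]
    is_binary <- is.logical(x) ||
      (is.numeric(x) && all(x %in% c(0, 1)))
    if (is_binary || is.factor(x) || is.character(x)) {
      if (is_binary) {
        lev <- "yes"
        memb <- list(yes = x == 1 | x == TRUE)
      } else {
        x <- as.factor(x)
        lev <- levels(x)
        memb <- lapply(lev, function(l) x == l)
        names(memb) <- lev
      }
      for (l in lev) {
        cnt <- tapply(memb[[l]], labels, sum)
        denom <- denominators[[v]] %||% as.vector(n_by)
        stop_if(any(denom == 0), sprintf("denominator 0 for '%s'", v))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = l, cts = names(n_by),
          count = as.vector(cnt), denominator = as.vector(denom),
          pct = round_half_up(100 * as.vector(cnt) / as.vector(denom), 1),
          mean = NA_real_, sd = NA_real_, median = NA_real_,
          q1 = NA_real_, q3 = NA_real_, row.names = NULL)
      }
    } else if (is.numeric(x)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "", cts = names(n_by),
        count = NA_integer_, denominator = as.vector(n_by), pct = NA_real_,
        mean = as.vector(tapply(x, labels, mean)),
        sd = as.vector(tapply(x, labels, stats::sd)),
        median = as.vector(tapply(x, labels, stats::median)),
        q1 = as.vector(tapply(x, labels, stats::quantile, 0.25)),
        q3 = as.vector(tapply(x, labels, stats::quantile, 0.75)),
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("table_one", "data.frame")
  out
}
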