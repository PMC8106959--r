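# Two-stage screen statistics: toxicity exclusion, rescue index and hit
# calling (stage 1), percent-of-control length and normality-gated group
# comparisons with post-hoc tests and observed power (stage 2).

#' Exclude toxic compounds from a screen
#'
#' Compounds whose embryos died, developed with delay or were severely
#' malformed are removed before scoring.
#'
#' @param records data.frame with columns `compound_id` and `toxicity`
#'   (`"none"`, `"death"`, `"delayed"`, `"malformed"`), one or more rows per
#'   compound.
#' @return List: `kept` and `excluded` record subsets, and `summary` with
#'   per-category compound counts and percent of all compounds.
#' @export
exclude_toxic <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("compound_id", "toxicity") %in% names(records)))
  bad <- setdiff(unique(records$toxicity),
                 c("none", "death", "delayed", "malformed"))
  if (length(bad)) stop("unknown toxicity state(s): ", paste(bad, collapse = ", "))
  comp_tox <- tapply(records$toxicity, records$compound_id, function(x) {
    t <- setdiff(unique(x), "none")
    if (length(t)) t[1] else "none"
  })
  n_total <- length(comp_tox)
  cats <- c("death", "delayed", "malformed")
  counts <- vapply(cats, function(ct) sum(comp_tox == ct), 0L)
  toxic_ids <- names(comp_tox)[comp_tox != "none"]
  summary <- data.frame(
    category = c(cats, "total_excluded"),
    n_compounds = c(counts, sum(counts)),
    percent = 100 * c(counts, sum(counts)) / n_total)
  list(kept = records[!records$compound_id %in% toxic_ids, , drop = FALSE],
       excluded = records[records$compound_id %in% toxic_ids, , drop = FALSE],
       summary = summary)
}

#' Rescue index of a treated group against the internal control
#'
#' The fraction of axons grown beyond the horizontal myoseptum in the treated
#' group, normalised to that fraction in the DMSO internal control. Counts are
#' pooled over embryos by default (`sum(crossed) / sum(scored)` per group);
#' `method = "per_embryo"` instead averages per-embryo fractions before taking
#' the ratio.
#'
#' @param treated,control data.frames with per-embryo columns `n_scored` and
#'   `n_crossed`.
#' @param method Aggregation mode, `"pooled"` (default) or `"per_embryo"`.
#' @return The rescue index. When the control crossing fraction is zero the
#'   index is undefined: `NA` is returned with attribute `reason`.
#' @examples
#' treated <- data.frame(n_scored = 8, n_crossed = 5)
#' control <- data.frame(n_scored = 8, n_crossed = 2)
#' rescue_index(treated, control) # 2.5
#' @export
rescue_index <- function(treated, control, method = c("pooled", "per_embryo")) {
  method <- match.arg(method)
  for (df in list(treated, control)) {
    stopifnot(is.data.frame(df), all(c("n_scored", "n_crossed") %in% names(df)),
              nrow(df) >= 1)
    if (any(df$n_crossed < 0 | df$n_crossed > df$n_scored | df$n_scored > 8)) {
      stop("require 0 <= n_crossed <= n_scored <= 8 per embryo")
    }
  }
  if (method == "pooled") {
    ft <- sum(treated$n_crossed) / sum(treated$n_scored)
    fc <- sum(control$n_crossed) / sum(control$n_scored)
  } else {
    ft <- mean(treated$n_crossed / treated$n_scored)
    fc <- mean(control$n_crossed / control$n_scored)
  }
  if (fc == 0) {
    warning("control crossing fraction is zero; rescue index undefined")
    return(structure(NA_real_, reason = "control crossing fraction is zero"))
  }
  ft / fc
}

#' Call screen hits from rescue indices
#'
#' A compound is a hit when its rescue index reaches the threshold
#' (inclusive: an index of exactly 2.5 is a hit at the default threshold) and
#' it was not excluded.
#'
#' @param results data.frame with columns `rescue_index` and either a logical
#'   `excluded` or a character `excluded_reason` (`NA` = not excluded).
#' @param threshold Hit threshold (default 2.5).
#' @return The input with a logical `hit` column added.
#' @export
call_hits <- function(results, threshold = 2.5) {
  stopifnot(is.data.frame(results), "rescue_index" %in% names(results),
            threshold > 0)
  excl <- if ("excluded" %in% names(results)) results$excluded
  else if ("excluded_reason" %in% names(results)) !is.na(results$excluded_reason)
  else rep(FALSE, nrow(results))
  results$hit <- !excl & !is.na(results$rescue_index) &
    results$rescue_index >= threshold
  results
}

#' Percent-of-control mean axon length
#'
#' @param treated,control Numeric vectors of per-embryo mean axon lengths.
#' @return `100 * mean(treated) / mean(control)`; `NA` with attribute
#'   `reason` when the control mean is zero.
#' @export
percent_of_control <- function(treated, control) {
  if (!length(treated) || !length(control)) stop("both groups must be non-empty")
  mc <- mean(control)
  if (mc == 0) {
    warning("control mean is zero; percent-of-control undefined")
    return(structure(NA_real_, reason = "control mean is zero"))
  }
  100 * mean(treated) / mc
}

#' Dunn's multiple-comparison test after Kruskal-Wallis
#'
#' Rank-sum z statistics with tie correction; reported p-values carry Dunn's
#' built-in multiplicity adjustment (Bonferroni over the comparisons made) and
#' no further correction.
#' @noRd
.dunn_test <- function(values, groups, pairs) {
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties)
  s2 <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  m <- nrow(pairs)
  out <- data.frame(comparison = character(m), z = numeric(m),
                    p_value = numeric(m))
  for (i in seq_len(m)) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    se <- sqrt(s2 * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    out$comparison[i] <- paste(a, "vs", b)
    out$z[i] <- z
    out$p_value[i] <- min(1, 2 * stats::pnorm(-abs(z)) * m)
  }
  out
}

#' Normality-gated group comparison
#'
#' Mirrors the assay's test-selection practice: every group is screened with
#' Shapiro-Wilk at `alpha`; if all groups look normal a parametric test is
#' used (Student's t for two groups; one-way ANOVA with Dunnett's test for
#' comparisons against the control, Tukey's HSD for all pairs), otherwise a
#' non-parametric one (Mann-Whitney U for two groups; Kruskal-Wallis with
#' Dunn's multiple-comparison test). The first group is treated as the
#' control. Observed (post-hoc) power at the measured effect size is appended.
#'
#' @param groups Named list (>= 2) of numeric vectors, each with n >= 3; the
#'   first element is the control group.
#' @param design `"vs-control"` (default) or `"all-pairs"`.
#' @param alpha Significance level for the normality gate and the tests.
#' @return A `stat_report` list: `normality`, `gate`, `test`, `statistic`,
#'   `p_value`, `posthoc` (data.frame), `power`, `design`, `alpha`.
#' @export
compare_groups <- function(groups, design = c("vs-control", "all-pairs"),
                           alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  ns <- lengths(groups)
  if (any(ns < 3)) stop("every group needs n >= 3 (normality test undefined)")
  k <- length(groups)

  norm <- do.call(rbind, lapply(names(groups), function(g) {
    sw <- stats::shapiro.test(groups[[g]])
    data.frame(group = g, n = length(groups[[g]]),
               W = unname(sw$statistic), p_value = sw$p.value)
  }))
  parametric <- all(norm$p_value > alpha)

  values <- unlist(groups, use.names = FALSE)
  gf <- factor(rep(names(groups), ns), levels = names(groups))
  pairs <- if (design == "vs-control") {
    cbind(names(groups)[-1], names(groups)[1])
  } else {
    t(utils::combn(names(groups), 2))
  }

  posthoc <- NULL
  if (parametric) {
    if (k == 2) {
      tt <- stats::t.test(groups[[2]], groups[[1]], var.equal = TRUE)
      test <- "Student t-test"; statistic <- unname(tt$statistic)
      p_value <- tt$p.value
    } else {
      fit <- stats::aov(values ~ gf)
      an <- summary(fit)[[1]]
      test <- if (design == "vs-control") "one-way ANOVA + Dunnett"
      else "one-way ANOVA + Tukey"
      statistic <- an$`F value`[1]; p_value <- an$`Pr(>F)`[1]
      if (design == "vs-control") {
        gl <- multcomp::glht(fit, linfct = multcomp::mcp(gf = "Dunnett"))
        sm <- summary(gl)
        posthoc <- data.frame(comparison = names(sm$test$coefficients),
                              estimate = unname(sm$test$coefficients),
                              statistic = unname(sm$test$tstat),
                              p_value = unname(sm$test$pvalues))
      } else {
        tk <- stats::TukeyHSD(fit)$gf
        posthoc <- data.frame(comparison = rownames(tk),
                              estimate = tk[, "diff"],
                              statistic = NA_real_,
                              p_value = tk[, "p adj"], row.names = NULL)
      }
    }
  } else {
    if (k == 2) {
      wt <- stats::wilcox.test(groups[[2]], groups[[1]], exact = FALSE)
      test <- "Mann-Whitney U"; statistic <- unname(wt$statistic)
      p_value <- wt$p.value
    } else {
      kw <- stats::kruskal.test(values, gf)
      test <- "Kruskal-Wallis + Dunn"
      statistic <- unname(kw$statistic); p_value <- kw$p.value
      dn <- .dunn_test(values, gf, pairs)
      posthoc <- data.frame(comparison = dn$comparison,
                            estimate = NA_real_, statistic = dn$z,
                            p_value = dn$p_value)
    }
  }

  power <- posthoc_power(n = ns,
                         mean = vapply(groups, mean, 0),
                         sd = vapply(groups, stats::sd, 0),
                         alpha = alpha)

  structure(list(normality = norm,
                 gate = if (parametric) "parametric" else "non-parametric",
                 test = test, statistic = statistic, p_value = p_value,
                 posthoc = posthoc, power = power,
                 design = design, alpha = alpha),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("stat_report:", x$test, sprintf("(gate: %s)\n", x$gate))
  cat("  omnibus statistic", round(x$statistic, 4), "p =",
      signif(x$p_value, 4), "\n")
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    for (i in seq_len(nrow(x$posthoc))) {
      cat("   ", x$posthoc$comparison[i], "p =",
          signif(x$posthoc$p_value[i], 4), "\n")
    }
  }
  cat("  observed power", round(x$power, 4), "\n")
  invisible(x)
}

#' Post-hoc (observed-effect) statistical power
#'
#' Power to detect the observed effect size at the observed group sizes and
#' `alpha`. For two groups the noncentral-t power of the two-sided two-sample
#' t-test at Cohen's d (pooled SD); for more groups the noncentral-F power of
#' the one-way ANOVA at Cohen's f. Documented as post-hoc power: it describes
#' the design at the measured effect, not the truth of the hypothesis.
#'
#' @param n,mean,sd Numeric vectors of per-group sizes, means and SDs.
#' @param alpha Significance level (default 0.05).
#' @return Power in \[alpha, 1\]; `NA` (with a warning) when the pooled SD is 0.
#' @export
posthoc_power <- function(n, mean, sd, alpha = 0.05) {
  k <- length(n)
  stopifnot(k >= 2, length(mean) == k, length(sd) == k, all(n >= 2))
  sp2 <- sum((n - 1) * sd^2) / sum(n - 1)
  if (sp2 == 0) {
    warning("pooled SD is zero; power undefined")
    return(NA_real_)
  }
  sp <- sqrt(sp2)
  if (k == 2) {
    d <- abs(mean[1] - mean[2]) / sp
    df <- sum(n) - 2
    ncp <- d / sqrt(1 / n[1] + 1 / n[2])
    crit <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  } else {
    N <- sum(n)
    gm <- sum(n * mean) / N
    f <- sqrt(sum(n * (mean - gm)^2) / N) / sp
    ncp <- f^2 * N
    crit <- stats::qf(1 - alpha, k - 1, N - k)
    1 - stats::pf(crit, k - 1, N - k, ncp)
  }
}
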