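# Group-comparison layer used for publication-style reporting: one-way
# ANOVA with Tukey HSD, Kruskal-Wallis with Dunn's post hoc z tests adjusted
# by Benjamini-Hochberg, two-way ANOVA interaction tests, and Student's t.

#' Compare metric values across experimental groups
#'
#' @param values numeric vector of per-neuron measurements.
#' @param group grouping factor (condition).
#' @param method one of `"oneway_anova_tukey"`, `"kruskal_dunn_bh"`,
#'   `"twoway_anova_interaction"`, `"student_t"`.
#' @param group2 second factor, required for the two-way interaction test.
#' @param metric label stored in the result.
#' @param alpha nominal significance level (stored, not used to gate output).
#' @return object of class `group_comparison`: per-group mean, SEM and n;
#'   omnibus statistic and p value; pairwise table with raw and adjusted p
#'   values where the method defines them.
#' @export
compare_groups <- function(values, group, method = c("oneway_anova_tukey",
                                                     "kruskal_dunn_bh",
                                                     "twoway_anova_interaction",
                                                     "student_t"),
                           group2 = NULL, metric = "value", alpha = 0.05) {
  method <- match.arg(method)
  group <- factor(group)
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  if (!is.null(group2)) group2 <- droplevels(factor(group2[ok]))
  ns <- table(group)
  if (length(ns) < 2) stop("need at least 2 groups")
  min_n <- if (method == "twoway_anova_interaction") 3L else 2L
  if (any(ns < min_n)) stop("each group needs n >= ", min_n)

  sem <- function(v) stats::sd(v) / sqrt(length(v))
  summary_tab <- data.frame(
    group = levels(group),
    n = as.integer(ns),
    mean = as.numeric(tapply(values, group, mean)),
    sem = as.numeric(tapply(values, group, sem)))

  pairs <- NULL; omnibus <- list(statistic = NA_real_, p = NA_real_,
                                 df = NA_real_)
  if (stats::sd(values) == 0) {
    # constant data: tests undefined; report identity comparisons
    omnibus <- list(statistic = 0, p = 1, df = NA_real_, note = "constant data")
  } else if (method == "student_t") {
    if (length(ns) != 2) stop("student_t requires exactly 2 groups")
    v1 <- values[group == levels(group)[1]]
    v2 <- values[group == levels(group)[2]]
    sp2 <- (sum((v1 - mean(v1))^2) + sum((v2 - mean(v2))^2)) /
      (length(v1) + length(v2) - 2)
    se <- sqrt(sp2 * (1 / length(v1) + 1 / length(v2)))
    df <- length(v1) + length(v2) - 2
    if (se == 0) {
      tstat <- if (mean(v1) == mean(v2)) 0 else NA_real_
      p <- if (mean(v1) == mean(v2)) 1 else NA_real_
    } else {
      tstat <- (mean(v1) - mean(v2)) / se
      p <- 2 * stats::pt(-abs(tstat), df)
    }
    omnibus <- list(statistic = tstat, p = p, df = df)
    pairs <- data.frame(group1 = levels(group)[1], group2 = levels(group)[2],
                        estimate = mean(v1) - mean(v2), p_raw = p, p_adj = p)
  } else if (method == "oneway_anova_tukey") {
    fit <- stats::aov(values ~ group)
    sm <- summary(fit)[[1]]
    omnibus <- list(statistic = sm$`F value`[1], p = sm$`Pr(>F)`[1],
                    df = sm$Df[1])
    tk <- stats::TukeyHSD(fit)$group
    cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairs <- data.frame(group1 = vapply(cmp, `[`, "", 1),
                        group2 = vapply(cmp, `[`, "", 2),
                        estimate = tk[, "diff"],
                        p_raw = tk[, "p adj"], p_adj = tk[, "p adj"],
                        row.names = NULL)
  } else if (method == "kruskal_dunn_bh") {
    kw <- stats::kruskal.test(values, group)
    omnibus <- list(statistic = unname(kw$statistic), p = kw$p.value,
                    df = unname(kw$parameter))
    pairs <- dunn_test(values, group, p_adjust = "BH")
  } else if (method == "twoway_anova_interaction") {
    if (is.null(group2)) stop("twoway_anova_interaction needs group2")
    fit <- stats::aov(values ~ group * group2)
    sm <- summary(fit)[[1]]
    irow <- grep(":", rownames(sm))
    omnibus <- list(statistic = sm$`F value`[irow], p = sm$`Pr(>F)`[irow],
                    df = sm$Df[irow])
  }

  out <- list(metric = metric, method = method, alpha = alpha,
              groups = summary_tab, omnibus = omnibus, pairs = pairs)
  class(out) <- "group_comparison"
  out
}

#' Dunn's post hoc rank test with tie correction
#'
#' Pairwise z statistics on mean ranks following a Kruskal-Wallis test;
#' two-sided p values, adjusted with the chosen `p.adjust` method.
#'
#' @param values numeric vector.
#' @param group factor.
#' @param p_adjust adjustment method (default Benjamini-Hochberg).
#' @return data.frame with `group1`, `group2`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_test <- function(values, group, p_adjust = "BH") {
  group <- factor(group)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, group, mean)
  ns <- table(group)
  lv <- levels(group)
  combs <- utils::combn(lv, 2)
  z <- numeric(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    a <- combs[1, k]; b <- combs[2, k]
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / sigma
  }
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = z,
             estimate = z,
             p_raw = p_raw, p_adj = stats::p.adjust(p_raw, method = p_adjust))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by %s\n", x$metric, x$method))
  print(x$groups, row.names = FALSE)
  cat(sprintf("omnibus: statistic=%.4g p=%.4g\n",
              x$omnibus$statistic[1], x$omnibus$p[1]))
  if (!is.null(x$pairs)) print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mean, SEM and n per condition group
#'
#' @param records data.frame of morphometry or dynamics rows.
#' @param keys character vector of grouping column names.
#' @param metrics numeric columns to summarize; defaults to all numeric
#'   columns not used as keys.
#' @return data.frame with one row per group x metric: `mean`, `sem`
#'   (NA for single-value groups), `n`.
#' @export
summarize_records <- function(records, keys, metrics = NULL) {
  stopifnot(nrow(records) > 0, all(keys %in% names(records)))
  if (is.null(metrics)) {
    metrics <- setdiff(names(records)[vapply(records, is.numeric, TRUE)], keys)
  }
  out <- list()
  for (m in metrics) {
    agg <- stats::aggregate(records[[m]],
                            by = records[keys],
                            FUN = function(v) {
                              v <- v[is.finite(v)]
                              c(mean = mean(v),
                                sem = if (length(v) > 1)
                                  stats::sd(v) / sqrt(length(v)) else NA_real_,
                                n = length(v))
                            })
    res <- data.frame(agg[keys], metric = m,
                      mean = agg$x[, "mean"], sem = agg$x[, "sem"],
                      n = as.integer(agg$x[, "n"]))
    out[[m]] <- res
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
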