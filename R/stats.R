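# Donor-level aggregation and gated group statistics. One value per donor
# per metric; the normality gate (Shapiro-Wilk per group at alpha = 0.05)
# selects one-way ANOVA + Tukey or Kruskal-Wallis + Dunn (Holm-adjusted).
# Paired within-donor contrasts use a random-intercept mixed model.

#' Aggregate a per-cell or per-islet table to one value per donor
#'
#' @param tab `data.frame`/`data.table` with a `donor_id` column.
#' @param metric name of the value column.
#' @param statistic `"mean"` or `"median"` over each donor's rows.
#' @param group_col optional grouping column carried through (e.g.
#'   `"group"`).
#' @return `data.table` with one row per donor: `donor_id`, optional group,
#'   `value`, `dispersion` (SD for mean, IQR for median) and `n`; donors
#'   with zero finite values yield `NA` with `n = 0`.
#' @export
aggregate_donor <- function(tab, metric, statistic = c("mean", "median"),
                            group_col = "group") {
  statistic <- match.arg(statistic)
  tab <- data.table::as.data.table(tab)
  if (!"donor_id" %in% names(tab)) stop("table must contain 'donor_id'")
  if (!metric %in% names(tab))
    stop("unknown metric '", metric, "'; available: ",
         paste(setdiff(names(tab), c("donor_id", group_col)), collapse = ", "))
  fun <- if (statistic == "mean") mean else median
  dfun <- if (statistic == "mean") sd else function(x) diff(quantile(x, c(.25, .75)))
  split_idx <- split(seq_len(nrow(tab)), tab$donor_id)
  out <- lapply(names(split_idx), function(d) {
    v <- tab[[metric]][split_idx[[d]]]
    v <- v[is.finite(v)]
    data.table::data.table(
      donor_id = d,
      value = if (length(v)) fun(v) else NA_real_,
      dispersion = if (length(v) > 1) as.numeric(dfun(v)) else NA_real_,
      n = length(v))
  })
  out <- data.table::rbindlist(out)
  if (group_col %in% names(tab)) {
    g <- tab[[group_col]][!duplicated(tab$donor_id)]
    names(g) <- tab$donor_id[!duplicated(tab$donor_id)]
    out[[group_col]] <- unname(g[out$donor_id])
  }
  attr(out, "metric") <- metric
  attr(out, "statistic") <- statistic
  out
}

# Dunn's post-hoc test after Kruskal-Wallis: pairwise z statistics on mean
# ranks with tie correction, Holm-adjusted.
dunn_test <- function(value, group) {
  g <- droplevels(as.factor(group))
  r <- rank(value)
  N <- length(value)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lv <- levels(g)
  res <- list()
  for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[i] + 1 / ns[j]))
    z <- (mr[i] - mr[j]) / se
    res[[length(res) + 1]] <- data.table::data.table(
      group1 = lv[i], group2 = lv[j], statistic = unname(z),
      p_raw = unname(2 * stats::pnorm(-abs(z))))
  }
  res <- data.table::rbindlist(res)
  res$p_adj <- p.adjust(res$p_raw, "holm")
  res
}

#' Compare donor-level values across groups with a normality-gated test
#'
#' Shapiro-Wilk per group at `alpha_normality` decides the omnibus test:
#' one-way ANOVA (all groups Gaussian-compatible) with Tukey HSD post hoc,
#' otherwise Kruskal-Wallis with Dunn's test (Holm adjustment). Groups with
#' fewer than 3 donors are excluded with a warning.
#'
#' @param summaries donor-level table from [aggregate_donor()] (columns
#'   `value` and a group column).
#' @param value_col,group_col column names.
#' @param alpha_normality significance level of the normality gate.
#' @return object of class `group_result`: list with `test_used`
#'   (`"one-way ANOVA"` or `"Kruskal-Wallis"`), `statistic`, `p_value`,
#'   `posthoc` (pairwise table), `normality` (per-group Shapiro p) and
#'   `groups`.
#' @export
compare_groups <- function(summaries, value_col = "value", group_col = "group",
                           alpha_normality = 0.05) {
  d <- data.table::as.data.table(summaries)
  if (!group_col %in% names(d)) stop("no group column '", group_col, "'")
  d <- d[is.finite(d[[value_col]])]
  cnt <- table(d[[group_col]])
  small <- names(cnt)[cnt < 3]
  if (length(small)) {
    warning("excluding group(s) with < 3 donors: ",
            paste(small, collapse = ", "))
    d <- d[!d[[group_col]] %in% small]
  }
  if (length(unique(d[[group_col]])) < 2)
    stop("need at least 2 groups with >= 3 donors")
  value <- d[[value_col]]
  group <- droplevels(as.factor(d[[group_col]]))
  norm_p <- vapply(split(value, group), function(v) {
    if (length(unique(v)) < 3) return(0)  # degenerate: treat as non-Gaussian
    shapiro.test(v)$p.value
  }, numeric(1))
  gaussian <- all(norm_p > alpha_normality)
  if (gaussian) {
    fit <- aov(value ~ group)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    posthoc <- data.table::data.table(group1 = cmp[, 2], group2 = cmp[, 1],
                                      statistic = tk[, "diff"],
                                      p_adj = tk[, "p adj"])
    res <- list(test_used = "one-way ANOVA",
                statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                posthoc = posthoc)
  } else {
    kw <- kruskal.test(value, group)
    res <- list(test_used = "Kruskal-Wallis",
                statistic = unname(kw$statistic), p_value = kw$p.value,
                posthoc = dunn_test(value, group))
  }
  res$normality <- norm_p
  res$groups <- levels(group)
  res$n <- as.integer(table(group))
  structure(res, class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test_used, x$statistic,
              x$p_value))
  cat("groups:", paste(sprintf("%s (n=%d)", x$groups, x$n), collapse = ", "),
      "\n")
  cat("normality (Shapiro p):",
      paste(sprintf("%s=%.3f", names(x$normality), x$normality),
            collapse = ", "), "\n")
  print(x$posthoc)
  invisible(x)
}

#' Paired within-donor contrast via a random-intercept mixed model
#'
#' Fits `value ~ condition + (1 | donor)` and reports the fixed-effect
#' contrast with a Wald t test on `n_donors - 1` degrees of freedom. A
#' paired t test on donor-level condition means is run alongside as a
#' validation (`paired_p`).
#'
#' @param tab per-cell table.
#' @param value_col value column name.
#' @param condition_col two-level condition column (e.g. PC1/3+ vs PC1/3-).
#' @param donor_col donor column name.
#' @return list of class `group_result` with `estimate` (fixed shift),
#'   `p_value`, `paired_p` and the fitted model.
#' @export
mixed_effects_paired <- function(tab, value_col, condition_col,
                                 donor_col = "donor_id") {
  d <- data.table::as.data.table(tab)
  d <- d[is.finite(d[[value_col]])]
  cond <- as.factor(d[[condition_col]])
  if (nlevels(droplevels(cond)) != 2)
    stop("condition must have exactly 2 observed levels")
  both <- tapply(cond, d[[donor_col]], function(x) length(unique(x)) == 2)
  if (sum(both, na.rm = TRUE) < 3)
    stop("need both conditions present in >= 3 donors")
  dd <- data.frame(value = d[[value_col]], condition = droplevels(cond),
                   donor = as.factor(d[[donor_col]]))
  fit <- lme4::lmer(value ~ condition + (1 | donor), data = dd,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  co <- summary(fit)$coefficients
  est <- co[2, "Estimate"]; tval <- co[2, "t value"]
  df <- length(unique(dd$donor)) - 1
  p <- 2 * pt(-abs(tval), df)
  # validation: paired t test on donor-level condition means
  m <- tapply(dd$value, list(dd$donor, dd$condition), mean)
  m <- m[complete.cases(m), , drop = FALSE]
  pp <- if (nrow(m) >= 3) stats::t.test(m[, 1], m[, 2], paired = TRUE)$p.value
        else NA_real_
  structure(list(test_used = "mixed-effects (random intercept per donor)",
                 estimate = unname(est), statistic = unname(tval),
                 p_value = unname(p), paired_p = pp, df = df, model = fit,
                 conditions = levels(dd$condition)),
            class = "group_result")
}

#' Phenotype trajectory across ordered disease-stage groups
#'
#' Per group, the mean over donors of the fraction of islet cells in each
#' of the `2^k` marker-flag combinations. Fractions sum to 1 within every
#' group; groups are ordered along the disease-stage sequence.
#'
#' @param counts per-donor phenotype counts: columns `donor_id`, `group`,
#'   `phenotype`, `n`.
#' @param group_order stage ordering (default
#'   `c("ND", "AAb+", "T1D_recent", "T1D_long", "T2D")`).
#' @return `data.table` with columns `group`, `phenotype`, `fraction`,
#'   ordered by stage.
#' @export
phenotype_trajectory <- function(counts,
                                 group_order = c("ND", "AAb+", "T1D_recent",
                                                 "T1D_long", "T2D")) {
  d <- data.table::as.data.table(counts)
  stopifnot(all(c("donor_id", "group", "phenotype", "n") %in% names(d)))
  classes <- sort(unique(d$phenotype))
  out <- list()
  for (g in intersect(group_order, unique(d$group))) {
    dg <- d[d$group == g]
    donors <- unique(dg$donor_id[dg$n > 0])
    if (length(donors) == 0) next
    fr <- matrix(0, length(donors), length(classes),
                 dimnames = list(donors, classes))
    for (dn in donors) {
      dd <- dg[dg$donor_id == dn]
      fr[dn, dd$phenotype] <- dd$n / sum(dd$n)
    }
    out[[g]] <- data.table::data.table(group = g, phenotype = classes,
                                       fraction = colMeans(fr))
  }
  out <- data.table::rbindlist(out)
  out$group <- factor(out$group, levels = intersect(group_order,
                                                    unique(out$group)))
  out[order(out$group, out$phenotype)]
}
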