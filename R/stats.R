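#' Mean, SEM and n of one group
#'
#' @param values numeric vector.
#' @return list with `mean`, `sem` (SD/sqrt(n); `NA` and flagged for a
#'   single value), `n`.
#' @export
summarize_cells <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) stop("no finite values")
  if (n == 1) {
    warning("single value: SEM undefined")
    return(list(mean = values, sem = NA_real_, n = 1L))
  }
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' Group comparison with normality-gated test selection
#'
#' Reproduces the conventional decision tree for cohort comparisons of
#' biophysical parameters: every group is screened with Shapiro-Wilk; if
#' any group rejects normality at p < 0.05 the rank-based branch is taken.
#' Two groups: unpaired t-test (pooled variance) or Mann-Whitney U.  More
#' than two: one-way ANOVA with Bonferroni-corrected pairwise t-tests
#' (pooled SD) or Kruskal-Wallis with Dunn's post hoc test
#' (Bonferroni-corrected rank-sum z statistics).  Test selection is a pure
#' function of the normality flags and is recorded in the output.
#'
#' @param samples named list of >= 2 numeric vectors, each of length >= 3.
#' @param alpha significance level recorded in the output (0.05).
#' @param branch "auto" (normality-gated, default), or force
#'   "parametric" / "rank".
#' @return object of class `cohort_table`: data.frame of per-group
#'   summaries (`label`, `mean`, `sem`, `n`, `shapiro_p`, `normal`), with
#'   attributes `comparisons` (data.frame `group1`, `group2`, `p`,
#'   `p_adjusted`, `test`), `omnibus_p`, `branch`.
#' @export
compare_groups <- function(samples, alpha = 0.05,
                           branch = c("auto", "parametric", "rank")) {
  branch <- match.arg(branch)
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- paste0("group", seq_along(samples))
  ns <- vapply(samples, length, 1L)
  if (any(ns < 3)) stop("every group needs n >= 3")

  sh <- vapply(samples, function(x) {
    if (length(unique(x)) == 1) return(0)      # degenerate: not normal
    stats::shapiro.test(x)$p.value
  }, 0)
  normal <- sh >= 0.05
  if (branch == "auto")
    branch <- if (all(normal)) "parametric" else "rank"
  g <- length(samples)
  labels <- names(samples)
  x <- unlist(samples, use.names = FALSE)
  grp <- factor(rep(labels, ns), levels = labels)

  if (g == 2) {
    if (branch == "parametric") {
      ht <- stats::t.test(samples[[1]], samples[[2]], var.equal = TRUE)
      comps <- data.frame(group1 = labels[1], group2 = labels[2],
                          p = ht$p.value, p_adjusted = ht$p.value,
                          test = "unpaired t-test")
      omni <- ht$p.value
    } else {
      ht <- suppressWarnings(stats::wilcox.test(samples[[1]], samples[[2]],
                                                exact = TRUE))
      comps <- data.frame(group1 = labels[1], group2 = labels[2],
                          p = ht$p.value, p_adjusted = ht$p.value,
                          test = "Mann-Whitney U")
      omni <- ht$p.value
    }
  } else {
    if (branch == "parametric") {
      omni <- summary(stats::aov(x ~ grp))[[1]][["Pr(>F)"]][1]
      pw <- stats::pairwise.t.test(x, grp, p.adjust.method = "bonferroni",
                                   pool.sd = TRUE)
      comps <- pairwise_to_df(pw$p.value, "ANOVA + Bonferroni t")
      raw <- stats::pairwise.t.test(x, grp, p.adjust.method = "none",
                                    pool.sd = TRUE)
      comps$p <- pairwise_to_df(raw$p.value, "")$p_adjusted
    } else {
      omni <- stats::kruskal.test(x, grp)$p.value
      comps <- dunn_test(x, grp)
    }
  }
  tab <- do.call(rbind, lapply(labels, function(l) {
    s <- summarize_cells(samples[[l]])
    data.frame(label = l, mean = s$mean, sem = s$sem, n = s$n,
               shapiro_p = sh[[l]], normal = normal[[l]])
  }))
  structure(tab, comparisons = comps, omnibus_p = omni, branch = branch,
            alpha = alpha, class = c("cohort_table", "data.frame"))
}

pairwise_to_df <- function(pm, test) {
  out <- NULL
  for (r in rownames(pm)) for (c in colnames(pm)) {
    if (!is.na(pm[r, c]))
      out <- rbind(out, data.frame(group1 = c, group2 = r,
                                   p = NA_real_, p_adjusted = pm[r, c],
                                   test = test))
  }
  out
}

## Dunn's post hoc: z statistics on mean ranks with tie correction,
## Bonferroni family-wise adjustment
dunn_test <- function(x, grp) {
  N <- length(x)
  rk <- rank(x)
  lev <- levels(grp)
  rbar <- tapply(rk, grp, mean)
  n <- tapply(rk, grp, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  m <- length(lev) * (length(lev) - 1) / 2
  out <- NULL
  for (a in seq_along(lev)) for (b in seq_along(lev)) {
    if (a >= b) next
    z <- (rbar[a] - rbar[b]) / sqrt(s2 * (1 / n[a] + 1 / n[b]))
    p <- 2 * stats::pnorm(-abs(z))
    out <- rbind(out, data.frame(group1 = lev[a], group2 = lev[b],
                                 p = p, p_adjusted = min(1, p * m),
                                 test = "Kruskal-Wallis + Dunn"))
  }
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> branch: %s | omnibus p = %.4g\n",
              attr(x, "branch"), attr(x, "omnibus_p")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("pairwise:\n")
  print.data.frame(attr(x, "comparisons"), row.names = FALSE, digits = 4)
  invisible(x)
}
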