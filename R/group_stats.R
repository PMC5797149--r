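#' Normality screen for a sample
#'
#' Shapiro-Wilk test at alpha = 0.05, used to route a metric to the
#' parametric or nonparametric branch.  Samples with n < 3 or zero variance
#' are routed nonparametric without testing.
#'
#' @param x numeric sample.
#' @param alpha significance level.
#' @return list(normal, statistic, p, degenerate).
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || stats::sd(x) == 0)
    return(list(normal = FALSE, statistic = NA_real_, p = NA_real_,
                degenerate = TRUE))
  s <- stats::shapiro.test(x)
  list(normal = s$p.value >= alpha, statistic = unname(s$statistic),
       p = s$p.value, degenerate = FALSE)
}

as_group_list <- function(samples) {
  if (is.data.frame(samples))
    samples <- split(samples$value, samples$group)
  if (is.null(names(samples)))
    names(samples) <- paste0("g", seq_along(samples))
  lapply(samples, function(x) x[!is.na(x)])
}

#' One-way ANOVA with Student-Newman-Keuls post-hoc test
#'
#' Classical one-way ANOVA (via \code{stats::aov}) followed by the
#' Student-Newman-Keuls stepwise procedure: group means are ordered and each
#' pair is tested with a studentized-range statistic whose critical
#' distribution uses the number of means spanned by the pair; a pair inside
#' a non-significant span is declared non-significant without testing
#' (blocking rule).  Reported adjusted p-values are the maximum of the
#' pair's own studentized-range p and the p of every containing span, which
#' makes the decision rule and the p-values consistent.  With two groups the
#' procedure reduces exactly to the pooled two-sample t-test.
#'
#' @param samples named list of numeric vectors, or data.frame with columns
#'   \code{group} and \code{value}.
#' @param alpha family significance level.
#' @return list of class \code{comparison_result}: test, F statistic, global
#'   p, df, and a pairwise data.frame (group1, group2, q, span, p_adj,
#'   significant).
#' @export
one_way_anova_snk <- function(samples, alpha = 0.05) {
  g <- as_group_list(samples)
  k <- length(g)
  if (k < 2L) stop("need >= 2 groups")
  if (any(lengths(g) < 2L)) stop("each group needs n >= 2")
  dat <- data.frame(value = unlist(g),
                    group = factor(rep(names(g), lengths(g))))
  fit <- stats::aov(value ~ group, data = dat)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  p_global <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][2]
  dfe <- an[["Df"]][2]
  means <- vapply(g, mean, numeric(1))
  ns <- lengths(g)
  ord <- order(means)                      # ascending rank of group means
  rank_of <- match(seq_len(k), ord)
  pairs <- utils::combn(k, 2)
  res <- data.frame(group1 = names(g)[pairs[1, ]],
                    group2 = names(g)[pairs[2, ]],
                    q = NA_real_, span = NA_integer_,
                    p_adj = NA_real_, significant = NA)
  span_p <- matrix(NA_real_, k, k)         # p by (low rank, high rank)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ra <- sort(c(rank_of[a], rank_of[b]))
    span <- ra[2] - ra[1] + 1L
    se <- sqrt(mse / 2 * (1 / ns[a] + 1 / ns[b]))
    if (mse == 0) {
      q <- if (means[a] == means[b]) 0 else Inf
      p <- if (is.infinite(q)) 0 else 1
    } else {
      q <- abs(means[a] - means[b]) / se
      p <- stats::ptukey(q, nmeans = span, df = dfe, lower.tail = FALSE)
    }
    res$q[j] <- q; res$span[j] <- span
    span_p[ra[1], ra[2]] <- p
  }
  # blocking: p of a pair is the max over all spans containing it
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ra <- sort(c(rank_of[a], rank_of[b]))
    containing <- span_p[row(span_p) <= ra[1] & col(span_p) >= ra[2]]
    res$p_adj[j] <- max(containing, na.rm = TRUE)
  }
  res$significant <- res$p_adj < alpha
  structure(list(test = "one-way ANOVA + Student-Newman-Keuls",
                 statistic = fstat, p = p_global,
                 df = c(k - 1L, dfe), mse = mse,
                 pairwise = res, adjustment = "SNK (studentized range)",
                 alpha = alpha),
            class = "comparison_result")
}

#' Two-way ANOVA with Sidak post-hoc comparisons
#'
#' Two-factor ANOVA with interaction (complete layout required) followed by
#' Sidak-adjusted pairwise comparisons of the levels of one factor within
#' each level of the other, using the pooled residual error.  The adjustment
#' is \eqn{p_{adj} = 1 - (1 - p)^m} with m the number of comparisons in the
#' reported family.
#'
#' @param samples data.frame with columns \code{value}, \code{factor1},
#'   \code{factor2}.
#' @param within which factor defines the strata: comparisons of the other
#'   factor's levels are made within each of its levels.
#' @param alpha family significance level.
#' @return \code{comparison_result} with main-effect/interaction F table and
#'   the Sidak-adjusted pairwise table.
#' @export
two_way_anova_sidak <- function(samples, within = "factor1", alpha = 0.05) {
  stopifnot(all(c("value", "factor1", "factor2") %in% names(samples)))
  samples$factor1 <- factor(samples$factor1)
  samples$factor2 <- factor(samples$factor2)
  tab <- table(samples$factor1, samples$factor2)
  if (any(tab == 0)) stop("incomplete two-factor layout: empty cells")
  fit <- stats::aov(value ~ factor1 * factor2, data = samples)
  an <- summary(fit)[[1]]
  mse <- an[["Mean Sq"]][4]
  dfe <- an[["Df"]][4]
  strata <- within
  across <- setdiff(c("factor1", "factor2"), within)
  res <- list()
  for (lev in levels(samples[[strata]])) {
    sub <- samples[samples[[strata]] == lev, , drop = FALSE]
    levs <- levels(droplevels(sub[[across]]))
    prs <- utils::combn(levs, 2)
    for (j in seq_len(ncol(prs))) {
      x1 <- sub$value[sub[[across]] == prs[1, j]]
      x2 <- sub$value[sub[[across]] == prs[2, j]]
      se <- sqrt(mse * (1 / length(x1) + 1 / length(x2)))
      tv <- (mean(x1) - mean(x2)) / se
      p <- 2 * stats::pt(abs(tv), dfe, lower.tail = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        stratum = lev, group1 = prs[1, j], group2 = prs[2, j],
        t = tv, p = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, res)
  m <- nrow(res)
  res$p_adj <- pmin(1 - (1 - res$p)^m, 1)
  res$significant <- res$p_adj < alpha
  structure(list(test = "two-way ANOVA + Sidak",
                 anova_table = an, mse = mse, df_error = dfe,
                 pairwise = res, adjustment = sprintf("Sidak (m = %d)", m),
                 alpha = alpha),
            class = "comparison_result")
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Rank-based H test (tie-corrected, via \code{stats::kruskal.test})
#' followed by Dunn's pairwise z statistics on mean ranks,
#' \eqn{z = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with tie correction \eqn{T = \sum (t^3 - t) / (12 (N - 1))}, adjusted for
#' multiplicity with the Sidak family-wise correction.
#'
#' @param samples named list of numeric vectors or data.frame
#'   (\code{group}, \code{value}).
#' @param alpha family significance level.
#' @return \code{comparison_result} with H, global p and the pairwise table.
#' @export
kruskal_dunn <- function(samples, alpha = 0.05) {
  g <- as_group_list(samples)
  k <- length(g)
  if (k < 2L) stop("need >= 2 groups")
  x <- unlist(g)
  grp <- factor(rep(names(g), lengths(g)))
  if (stats::sd(x) == 0) {
    H <- 0; p_global <- 1
  } else {
    kt <- stats::kruskal.test(x, grp)
    H <- unname(kt$statistic); p_global <- kt$p.value
  }
  N <- length(x)
  rk <- rank(x)
  mean_ranks <- tapply(rk, grp, mean)
  ns <- lengths(g)[levels(grp)]
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  prs <- utils::combn(levels(grp), 2)
  m <- ncol(prs)
  res <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    a <- prs[1, j]; b <- prs[2, j]
    se <- sqrt(v0 * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- if (se == 0) 0 else (mean_ranks[[a]] - mean_ranks[[b]]) / se
    res$z[j] <- z
    res$p[j] <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  res$p_adj <- pmin(1 - (1 - res$p)^m, 1)
  res$significant <- res$p_adj < alpha
  structure(list(test = "Kruskal-Wallis + Dunn",
                 statistic = H, p = p_global, df = k - 1L,
                 mean_ranks = mean_ranks,
                 pairwise = res, adjustment = sprintf("Sidak (m = %d)", m),
                 alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$test, "\n")
  if (!is.null(x$statistic))
    cat(sprintf("  global statistic %.4g, p = %.4g\n", x$statistic, x$p))
  pw <- x$pairwise
  pw$stars <- significance_stars(pw$p_adj)
  print(pw, row.names = FALSE)
  invisible(x)
}

#' Significance stars in the conventional coding
#'
#' @param p numeric p-values.
#' @return character: "***" p < 0.001, "**" p < 0.01, "*" p < 0.05, "" else.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Group descriptives
#'
#' The descriptive formats used in figures and tables: median with 5-95
#' percentiles, quartiles, and mean +/- SEM.
#'
#' @param samples named list of numeric vectors or data.frame
#'   (\code{group}, \code{value}).
#' @return data.frame, one row per group: n, mean, sem, median, p5, q1, q3,
#'   p95.
#' @export
describe_groups <- function(samples) {
  g <- as_group_list(samples)
  out <- lapply(names(g), function(nm) {
    x <- g[[nm]]
    qs <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(group = nm, n = length(x), mean = mean(x),
               sem = stats::sd(x) / sqrt(length(x)),
               median = qs[3], p5 = qs[1], q1 = qs[2], q3 = qs[4],
               p95 = qs[5], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
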