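#' Nonparametric group comparison with post-hoc analysis
#'
#' Two groups: two-sided Mann-Whitney U (exact for small samples without
#' ties). More than two groups: Kruskal-Wallis, followed by Dunn's multiple
#' comparison — pairwise z tests on mean ranks of the pooled ranking, with
#' tie correction and a multiplicity adjustment.
#'
#' @param groups Named list of numeric vectors, one per group; every group
#'   needs >= 2 observations.
#' @param p_adjust_method Multiplicity correction for Dunn's pairwise p
#'   values (default `"bonferroni"`; any [stats::p.adjust()] method).
#' @param alpha Significance threshold recorded in the result.
#' @return A `group_comparison` list: `metric` (test used), `statistic`,
#'   `p`, `n_groups`, `posthoc` (data.frame of pairwise comparisons with
#'   adjusted p values, only for > 2 groups), `alpha`.
#' @export
compare_groups <- function(groups, p_adjust_method = "bonferroni",
                           alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("need a list of >= 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stopf("group(s) with < 2 observations: %s",
          paste(names(groups)[sizes < 2L], collapse = ", "))
  k <- length(groups)
  if (k == 2L) {
    h <- stats::wilcox.test(groups[[1]], groups[[2]])
    out <- list(metric = "mann_whitney_u", statistic = unname(h$statistic),
                p = h$p.value, n_groups = 2L, posthoc = NULL, alpha = alpha)
  } else {
    h <- stats::kruskal.test(groups)
    out <- list(metric = "kruskal_wallis", statistic = unname(h$statistic),
                p = h$p.value, n_groups = k,
                posthoc = dunn_posthoc(groups, p_adjust_method),
                alpha = alpha)
  }
  class(out) <- "group_comparison"
  out
}

# Dunn's pairwise z tests on mean ranks with tie correction.
dunn_posthoc <- function(groups, p_adjust_method) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  mean_rank <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / n_i[[a]] + 1 / n_i[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = res["z", ],
             p = res["p", ],
             p_adjusted = stats::p.adjust(res["p", ],
                                          method = p_adjust_method),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g (%d groups)\n",
              x$metric, x$statistic, x$p, x$n_groups))
  if (!is.null(x$posthoc)) {
    cat("post-hoc (Dunn):\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided paired comparison of pre/post measurements (e.g. velocity
#' before and after a stimulation switch). With 12 or fewer nonzero
#' differences the p value is exact, computed by enumerating all sign
#' assignments of the (average-)ranked absolute differences — so ties do
#' not force an approximation; larger samples use the standard normal
#' approximation with tie correction. When all differences are zero the
#' comparison is degenerate: `p = 1`, flagged.
#'
#' @param pre,post Equal-length numeric vectors (>= 2 pairs).
#' @param exact_max Largest number of nonzero differences for which the
#'   exact enumeration is used (default 12).
#' @return list: `statistic` (V, rank sum of positive differences), `p`,
#'   `n` (nonzero-difference pairs), `exact`, `degenerate`.
#' @export
paired_test <- function(pre, post, exact_max = 12L) {
  if (length(pre) != length(post)) stopf("pre and post must pair up")
  if (length(pre) < 2L) stopf("need >= 2 pairs")
  d <- post - pre
  d <- d[d != 0]                      # standard zero-difference drop
  if (!length(d))
    return(list(statistic = NA_real_, p = 1, n = 0L, exact = TRUE,
                degenerate = TRUE))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
    exact <- TRUE
  } else {
    h <- stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE,
                            correct = TRUE)
    p <- h$p.value
    exact <- FALSE
  }
  list(statistic = v_obs, p = p, n = n, exact = exact, degenerate = FALSE)
}
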