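# Condition-comparison protocol: Kolmogorov-Smirnov (Lilliefors) normality
# screening, then rank-based omnibus tests — Kruskal-Wallis across
# independent conditions, Friedman across repeated recordings of the same
# pixels — followed, when the omnibus test is significant, by pairwise
# z-tests on mean ranks with Bonferroni correction (the procedures common
# statistics suites run behind "pairwise comparison with Bonferroni
# correction").

new_comparison_result <- function(test_name, statistic, df, p_value, alpha,
                                  groups, pairwise = NULL, extra = list()) {
  structure(
    c(list(test_name = test_name, statistic = unname(statistic),
           df = unname(df), p_value = unname(p_value), alpha = alpha,
           groups = groups, pairwise = pairwise), extra),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.4g, df %s, p %.4g (alpha %.2f)\n",
              x$test_name, x$statistic, format(x$df), x$p_value, x$alpha))
  if (!is.null(x$pairwise)) {
    sig <- sum(x$pairwise$significant)
    cat(sprintf("  %d pairwise comparison(s), %d significant after Bonferroni\n",
                nrow(x$pairwise), sig))
  } else {
    cat("  omnibus not significant: no pairwise comparisons\n")
  }
  invisible(x)
}

#' Normality screening of value groups
#'
#' Tests each group against a normal distribution with estimated mean and
#' SD. The default is the Lilliefors-corrected Kolmogorov-Smirnov test,
#' which accounts for the parameter estimation; `method = "ks"` runs the
#' plain KS test against the fitted normal (anti-conservative, provided
#' because some software defaults to it).
#'
#' @param samples A list of numeric vectors, optionally named. The
#'   Lilliefors test needs n >= 5 per group; `method = "ks"` needs n >= 4.
#' @param alpha Significance level for the nonnormal flag.
#' @param method `"lilliefors"` (default) or `"ks"`.
#' @return A data.frame with one row per group: `group`, `n`, `p_value`,
#'   `nonnormal` (`p_value <= alpha`).
#' @export
normality_screen <- function(samples, alpha = 0.05,
                             method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  if (!is.list(samples)) samples <- list(samples)
  ns <- lengths(samples)
  min_n <- if (method == "lilliefors") 5L else 4L
  if (any(ns < min_n)) {
    stop(sprintf("each group needs n >= %d for the %s normality screen",
                 min_n, method), call. = FALSE)
  }
  p <- vapply(samples, function(x) {
    if (method == "lilliefors") {
      nortest::lillie.test(x)$p.value
    } else {
      suppressWarnings(
        stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    }
  }, numeric(1))
  data.frame(
    group = names(samples) %||% paste0("group_", seq_along(samples)),
    n = as.integer(ns), p_value = unname(p),
    nonnormal = unname(p) <= alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Dunn-type pairwise z statistics on mean ranks after Kruskal-Wallis,
# with the tie correction sum(t^3 - t) / (12 (N - 1)) in the SE.
dunn_pairwise <- function(values, group, alpha) {
  N <- length(values)
  r <- rank(values)
  labs <- levels(group)
  n_i <- tabulate(group)
  rbar <- tapply(r, group, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(seq_along(labs), 2)
  npairs <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(npairs), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(base_var * (1 / n_i[i] + 1 / n_i[j]))
    z <- (rbar[i] - rbar[j]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_i = labs[i], group_j = labs[j], z = unname(z),
               p_raw = p, stringsAsFactors = FALSE)
  }))
  out$p_adjusted <- pmin(1, out$p_raw * npairs)
  out$significant <- out$p_adjusted <= alpha
  rownames(out) <- NULL
  out
}

#' Compare independent condition groups (Kruskal-Wallis + Dunn/Bonferroni)
#'
#' Tie-corrected Kruskal-Wallis omnibus test across three or more
#' independent groups (e.g. per-pixel random errors under different light
#' conditions). If the omnibus test is significant at `alpha`, Dunn-type
#' pairwise z-tests on mean ranks are run for every pair, with Bonferroni
#' multiplication by the number of pairs.
#'
#' @param groups Named list of >= 3 numeric vectors, each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @return A `comparison_result`; `pairwise` is `NULL` unless the omnibus
#'   p-value is `<= alpha`.
#' @export
compare_independent <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3L) {
    stop("need >= 3 independent groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2L)) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group_", seq_along(groups))
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- stats::kruskal.test(values, g)
  if (is.nan(kw$statistic)) {
    # fully tied data carry no ranking information: statistic 0, p 1
    kw$statistic <- 0; kw$p.value <- 1
  }
  pw <- if (is.finite(kw$p.value) && kw$p.value <= alpha) {
    dunn_pairwise(values, g, alpha)
  } else NULL
  new_comparison_result("kruskal_wallis", kw$statistic, kw$parameter,
                        kw$p.value, alpha, names(groups), pw)
}

# Pairwise z-tests on column mean ranks after Friedman, SE from
# k (k + 1) / (6 n); Bonferroni over all pairs.
friedman_pairwise <- function(ranks, labs, alpha) {
  n <- nrow(ranks); k <- ncol(ranks)
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  npairs <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(npairs), function(m) {
    i <- pairs[1, m]; j <- pairs[2, m]
    z <- (rbar[i] - rbar[j]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_i = labs[i], group_j = labs[j], z = z,
               p_raw = p, stringsAsFactors = FALSE)
  }))
  out$p_adjusted <- pmin(1, out$p_raw * npairs)
  out$significant <- out$p_adjusted <= alpha
  rownames(out) <- NULL
  out
}

#' Compare repeated recordings (Friedman + pairwise/Bonferroni)
#'
#' Tie-corrected Friedman omnibus test across three or more related samples
#' — the same observational units (e.g. pixels of one region) measured in
#' each recording. Rows containing any missing value are dropped and
#' counted. If the omnibus test is significant at `alpha`, pairwise z-tests
#' on within-row mean ranks follow, Bonferroni-corrected.
#'
#' @param blocks Numeric matrix or data.frame, rows = units (pixels),
#'   columns = recordings (>= 3); column names label the recordings.
#' @param alpha Significance level (default 0.05).
#' @return A `comparison_result` with extra field `n_dropped_rows`;
#'   `pairwise` is `NULL` unless the omnibus p-value is `<= alpha`.
#' @export
compare_repeated <- function(blocks, alpha = 0.05) {
  blocks <- as.matrix(blocks)
  if (ncol(blocks) < 3L) stop("need >= 3 repeated columns", call. = FALSE)
  if (is.null(colnames(blocks))) {
    colnames(blocks) <- paste0("recording_", seq_len(ncol(blocks)))
  }
  complete <- stats::complete.cases(blocks)
  n_dropped <- sum(!complete)
  blocks <- blocks[complete, , drop = FALSE]
  if (nrow(blocks) < 2L) {
    stop("fewer than 2 complete rows after dropping missing values",
         call. = FALSE)
  }
  fr <- stats::friedman.test(blocks)
  if (is.nan(fr$statistic)) {
    # every row fully tied (e.g. identical columns): statistic 0, p 1
    fr$statistic <- 0; fr$p.value <- 1
  }
  pw <- if (is.finite(fr$p.value) && fr$p.value <= alpha) {
    ranks <- t(apply(blocks, 1, rank))
    friedman_pairwise(ranks, colnames(blocks), alpha)
  } else NULL
  new_comparison_result("friedman", fr$statistic, fr$parameter, fr$p.value,
                        alpha, colnames(blocks), pw,
                        extra = list(n_dropped_rows = n_dropped))
}
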