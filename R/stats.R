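#' Bootstrap standard error of the median
#'
#' The SEM is the standard deviation of the sample median over `n_iter`
#' with-replacement resamples (default 10,000).
#'
#' @param values numeric vector; `NA`s are dropped.
#' @param n_iter bootstrap iterations.
#' @param seed optional seed (deterministic result when given).
#' @return List with `median`, `sem`, `n`; both `NA` if fewer than 2
#'   non-missing values.
#' @export
bootstrap_median_sem <- function(values, n_iter = 10000, seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    return(list(median = if (length(values)) values else NA_real_,
                sem = NA_real_, n = length(values)))
  run <- function() boot_median_sd(values, as.integer(n_iter))
  sem <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(median = median(values), sem = sem, n = length(values))
}

# exact null distribution of the rank-sum W of a size-m subset of ranks
# 1..N: dynamic programming over the subset-sum generating function.
# Returns probabilities over W = m(m+1)/2 .. m(2N-m+1)/2.
rank_sum_null <- function(m, N) {
  smax <- sum((N - m + 1):N)
  f <- matrix(0, m + 1, smax + 1)   # f[j+1, s+1] = #subsets size j, sum s
  f[1, 1] <- 1
  for (r in seq_len(N)) {
    jmax <- min(r, m)
    for (j in jmax:1) {
      idx <- which(f[j, ] > 0)
      if (!length(idx)) next
      tgt <- idx + r
      keep <- tgt <= smax + 1
      f[j + 1, tgt[keep]] <- f[j + 1, tgt[keep]] + f[j, idx[keep]]
    }
  }
  w <- (m * (m + 1) / 2):smax
  p <- f[m + 1, w + 1]
  list(w = w, prob = p / sum(p))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration of the rank-sum null distribution when the smaller
#' group has at most `exact_max` observations and there are no ties;
#' otherwise the normal approximation with tie correction (no continuity
#' correction).
#'
#' @param group_a,group_b numeric vectors (`NA`s dropped).
#' @param exact_max exact-path size limit for the smaller group.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(group_a, group_b, exact_max = 8) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  stopifnot(length(a) >= 1, length(b) >= 1)
  pooled <- c(a, b)
  N <- length(pooled)
  rk <- rank(pooled)
  w <- sum(rk[seq_along(a)])
  ties <- any(duplicated(pooled))
  if (!ties && min(length(a), length(b)) <= exact_max) {
    small_is_a <- length(a) <= length(b)
    m <- min(length(a), length(b))
    ws <- if (small_is_a) w else sum(rk[length(a) + seq_along(b)])
    dist <- rank_sum_null(m, N)
    p_lo <- sum(dist$prob[dist$w <= ws])
    p_hi <- sum(dist$prob[dist$w >= ws])
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  mu <- length(a) * (N + 1) / 2
  tie_tab <- table(pooled)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  v <- length(a) * length(b) / 12 * ((N + 1) - tie_corr)
  if (v <= 0) return(1)
  z <- (w - mu) / sqrt(v)
  2 * pnorm(-abs(z))
}

#' Wilcoxon signed-rank test for paired values (two-sided)
#'
#' Exact sign enumeration for up to `exact_max` non-zero differences
#' without tied magnitudes; otherwise the normal approximation with tie
#' correction.
#'
#' @param x,y paired numeric vectors.
#' @param exact_max exact-path limit.
#' @return Two-sided p-value.
#' @export
signed_rank_test <- function(x, y, exact_max = 15) {
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) return(1)
  rk <- rank(abs(d))
  v_stat <- sum(rk[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    # distribution of V over all 2^n sign assignments
    signs <- expand.grid(rep(list(c(0, 1)), n))
    vs <- as.matrix(signs) %*% rk
    p_lo <- mean(vs <= v_stat); p_hi <- mean(vs >= v_stat)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(rk)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  if (v <= 0) return(1)
  z <- (v_stat - mu) / sqrt(v)
  2 * pnorm(-abs(z))
}

#' Kruskal-Wallis test
#'
#' H statistic with tie correction; p from the chi-squared distribution on
#' k - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors (>= 2 groups, `NA`s dropped).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis_test <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  rk <- rank(pooled)
  grp <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (N * (N + 1)) *
    sum(tapply(rk, grp, sum)^2 / lengths(groups)) - 3 * (N + 1)
  tie_tab <- table(pooled)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (corr > 0) h <- h / corr else h <- 0
  df <- length(groups) - 1
  list(statistic = h, df = df, p_value = pchisq(h, df, lower.tail = FALSE))
}

#' Run-length cluster correction over ordered windows
#'
#' A window is cluster-significant iff it belongs to a maximal run of at
#' least `min_len` consecutive windows with `p < alpha` (strict). `NA`
#' p-values break runs. Runs touching the sequence edges count normally.
#'
#' @param p_values p-values in window order.
#' @param alpha significance level.
#' @param min_len minimum run length (default 3).
#' @return Logical mask.
#' @export
cluster_significant <- function(p_values, alpha, min_len = 3) {
  sig <- !is.na(p_values) & p_values < alpha
  r <- rle(sig)
  r$values <- r$values & r$lengths >= min_len
  inverse.rle(r)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Standard step-up rule for independent tests: with sorted p-values
#' `p_(1) <= ... <= p_(m)`, reject all `p <= p_(k*)` where
#' `k* = max{k : p_(k) <= k alpha / m}`.
#'
#' @param p_values p-values in `[0, 1]` (`NA` allowed, never rejected).
#' @param alpha FDR level.
#' @return Logical rejection mask.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  m <- length(p)
  out <- rep(FALSE, length(p_values))
  if (m == 0) return(out)
  o <- order(p)
  below <- p[o] <= seq_len(m) * alpha / m
  if (any(below)) {
    k_star <- max(which(below))
    out[ok] <- p <= p[o][k_star]
  }
  out
}

#' Linear regression of slope on age
#'
#' Ordinary least squares `y = beta1 + beta2 * x`; the p-value is from the
#' t statistic of `beta2` on `n - 2` degrees of freedom.
#'
#' @param ages predictor (years).
#' @param slopes response (aperiodic exponents); `NA` pairs dropped.
#' @return An object of class `regression_result`: `beta1`, `beta2`,
#'   `se_beta2`, `r_squared`, `p_value`, `n`.
#' @export
regress_slope_vs_age <- function(ages, slopes) {
  keep <- !is.na(ages) & !is.na(slopes)
  x <- ages[keep]; y <- slopes[keep]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (var(x) == 0) stop("degenerate design: age has zero variance")
  sxx <- sum((x - mean(x))^2)
  b2 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b1 <- mean(y) - b2 * mean(x)
  res <- y - b1 - b2 * x
  n <- length(x)
  sigma2 <- sum(res^2) / (n - 2)
  se2 <- sqrt(sigma2 / sxx)
  tval <- b2 / se2
  r2 <- if (var(y) == 0) 1 else 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(beta1 = b1, beta2 = b2, se_beta2 = se2, r_squared = r2,
                 p_value = 2 * pt(-abs(tval), n - 2), n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.4g + %.4g x, R2 = %.3f, p = %.3g (n = %d)\n",
              x$beta1, x$beta2, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Match cases to aggregated controls
#'
#' For each case, controls of the same gender within `age_tol` years are
#' pooled and their metric aggregated (median by default) into a single
#' control data point. Cases with no matching control are dropped with a
#' message.
#'
#' @param cases,controls data frames with columns `id`, `age`, `gender`.
#' @param metric named numeric vector (names = subject ids).
#' @param age_tol age tolerance in years (default 1).
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return Data frame with one row per matched case: `case_id`,
#'   `case_value`, `control_value`, `n_controls`.
#' @export
pair_case_controls <- function(cases, controls, metric, age_tol = 1,
                               aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "median") median else mean
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    sel <- controls$gender == cases$gender[i] &
      abs(controls$age - cases$age[i]) <= age_tol
    ctrl_vals <- metric[controls$id[sel]]
    ctrl_vals <- ctrl_vals[!is.na(ctrl_vals)]
    if (length(ctrl_vals) == 0L) {
      message("case ", cases$id[i],
              " dropped: no age/gender matched control")
      return(NULL)
    }
    data.frame(case_id = cases$id[i],
               case_value = unname(metric[cases$id[i]]),
               control_value = agg(ctrl_vals),
               n_controls = length(ctrl_vals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(case_id = character(0), case_value = numeric(0),
               control_value = numeric(0), n_controls = integer(0))
}

#' Subsample two groups to matching R-squared distributions
#'
#' Histogram matching on shared bins (default width 0.05): within each bin
#' each group retains `min(count_a, count_b)` observations, sampled without
#' replacement.
#'
#' @param values_a,values_b group values.
#' @param r2_a,r2_b per-observation goodness of fit.
#' @param bin_width histogram bin width.
#' @param seed optional seed.
#' @return List with `a` and `b` (indices into the original groups).
#' @export
subsample_match_r2 <- function(values_a, r2_a, values_b, r2_b,
                               bin_width = 0.05, seed = NULL) {
  stopifnot(length(values_a) == length(r2_a),
            length(values_b) == length(r2_b))
  lo <- floor(min(r2_a, r2_b, na.rm = TRUE) / bin_width) * bin_width
  breaks <- seq(lo, 1 + bin_width, by = bin_width)
  bin_a <- cut(r2_a, breaks, include.lowest = TRUE)
  bin_b <- cut(r2_b, breaks, include.lowest = TRUE)
  run <- function() {
    ia <- integer(0); ib <- integer(0)
    for (lv in levels(bin_a)) {
      wa <- which(bin_a == lv); wb <- which(bin_b == lv)
      k <- min(length(wa), length(wb))
      if (k == 0) next
      ia <- c(ia, if (length(wa) == k) wa else sample(wa, k))
      ib <- c(ib, if (length(wb) == k) wb else sample(wb, k))
    }
    list(a = sort(ia), b = sort(ib))
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (length(out$a) == 0)
    stop("no overlap between the two R-squared distributions")
  out
}

#' Compare slope profiles between groups, window by window
#'
#' Per window: group medians with bootstrap SEMs, a Kruskal-Wallis or
#' Wilcoxon rank-sum p-value (missing slopes dropped pairwise; windows with
#' fewer than 2 values per group get `NA`), and run-length cluster masks at
#' each alpha level.
#'
#' @param profiles subjects x windows matrix of exponents (`NA` = missing).
#' @param grouping factor/character of group membership per subject.
#' @param centres window centre frequencies (for the output table).
#' @param test `"kw"` or `"wrs"`.
#' @param alphas significance levels for clustering (default 0.05, 0.01).
#' @param min_len cluster rule minimum run length.
#' @param n_boot bootstrap iterations for the SEMs (0 skips them).
#' @param seed optional seed for the bootstrap.
#' @return An object of class `group_comparison`: `table` (per-window
#'   medians/SEMs/n/p), `clusters` (windows x alphas logical), `groups`.
#' @export
compare_groups <- function(profiles, grouping,
                           centres = seq_len(ncol(profiles)),
                           test = c("kw", "wrs"), alphas = c(0.05, 0.01),
                           min_len = 3, n_boot = 10000, seed = NULL) {
  test <- match.arg(test)
  grouping <- as.factor(grouping)
  lv <- levels(grouping)
  stopifnot(length(lv) >= 2, nrow(profiles) == length(grouping))
  if (test == "wrs" && length(lv) != 2)
    stop("rank-sum test needs exactly 2 groups")
  nw <- ncol(profiles)
  med <- sem <- nn <- matrix(NA_real_, nw, length(lv),
                             dimnames = list(NULL, lv))
  pv <- rep(NA_real_, nw)
  for (w in seq_len(nw)) {
    vals <- split(profiles[, w], grouping)
    vals <- lapply(vals, function(v) v[!is.na(v)])
    nn[w, ] <- lengths(vals)
    for (g in seq_along(lv)) {
      if (length(vals[[g]]) >= 1) med[w, g] <- median(vals[[g]])
      if (n_boot > 0 && length(vals[[g]]) >= 2)
        sem[w, g] <- bootstrap_median_sem(vals[[g]], n_boot,
                                          seed = if (!is.null(seed))
                                            seed + w * 131L + g)$sem
    }
    if (all(lengths(vals) >= 2)) {
      pv[w] <- if (test == "kw") kruskal_wallis_test(vals)$p_value
      else rank_sum_test(vals[[1]], vals[[2]])
    }
  }
  clusters <- vapply(alphas, function(a)
    cluster_significant(pv, a, min_len), logical(nw))
  colnames(clusters) <- paste0("alpha_", alphas)
  tab <- data.frame(centre = centres, p_value = pv)
  for (g in lv) {
    tab[[paste0("median_", g)]] <- med[, g]
    tab[[paste0("sem_", g)]] <- sem[, g]
    tab[[paste0("n_", g)]] <- nn[, g]
  }
  structure(list(table = tab, clusters = clusters, groups = lv,
                 test = test, alphas = alphas),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$test, "test,", nrow(x$table), "windows,",
      "groups:", paste(x$groups, collapse = " vs "), "\n")
  for (a in seq_along(x$alphas))
    cat(sprintf("  alpha %.2f: %d cluster-significant window(s)\n",
                x$alphas[a], sum(x$clusters[, a])))
  invisible(x)
}
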