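#' Two-way (2 x 2) repeated-measures ANOVA via within-subject contrasts
#'
#' For a fully-crossed 2 x 2 within-subject design, each effect (main
#' effect of each factor and the interaction) reduces to a single
#' within-subject contrast d_s per subject; the F statistic is the squared
#' one-sample t of that contrast, F = (mean d / SE(d))^2 with df (1, n-1).
#' This is algebraically identical to the textbook sums-of-squares
#' repeated-measures ANOVA for two-level factors (asserted against an
#' independent oracle in the test suite).
#'
#' @param df data.frame with columns `subject`, `condition`, `stimulus`,
#'   `value`; one row per subject x cell, all four cells present per subject
#' @return data.frame with one row per effect (`condition_main`,
#'   `stimulus_main`, `interaction`): F, df1, df2, p
#' @export
rm_anova_2x2 <- function(df) {
  need <- c("subject", "condition", "stimulus", "value")
  stopifnot(all(need %in% names(df)))
  cl <- sort(unique(df$condition)); sl <- sort(unique(df$stimulus))
  if (length(cl) != 2 || length(sl) != 2)
    stop("rm_anova_2x2 requires exactly 2 levels per factor", call. = FALSE)
  cells <- stats::xtabs(value ~ subject + condition + stimulus, df)
  cnt <- stats::xtabs(~ subject + condition + stimulus, df)
  if (any(cnt != 1))
    stop("each subject must contribute exactly one value per cell",
         call. = FALSE)
  m <- cells                                  # subjects x 2 x 2
  d_cond <- (m[, 2, 1] + m[, 2, 2] - m[, 1, 1] - m[, 1, 2]) / 2
  d_stim <- (m[, 1, 2] + m[, 2, 2] - m[, 1, 1] - m[, 2, 1]) / 2
  d_int  <- (m[, 2, 2] - m[, 2, 1]) - (m[, 1, 2] - m[, 1, 1])
  eff <- list(condition_main = d_cond, stimulus_main = d_stim,
              interaction = d_int)
  n <- nrow(m)
  out <- do.call(rbind, lapply(names(eff), function(e) {
    d <- eff[[e]]
    se <- stats::sd(d) / sqrt(n)
    f <- if (se == 0) 0 else (mean(d) / se)^2
    data.frame(effect = e, F = f, df1 = 1, df2 = n - 1,
               p = stats::pf(f, 1, n - 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-way repeated-measures ANOVA (two levels)
#'
#' The single within-subject contrast between the two levels; F equals the
#' squared paired t with df (1, n-1). Used e.g. for the noisy-vs-intact
#' contrast restricted to the passive condition.
#'
#' @param df data.frame with columns `subject`, `level`, `value`; two
#'   levels, one value per subject x level
#' @return one-row data.frame: effect, F, df1, df2, p
#' @export
rm_anova_oneway <- function(df) {
  stopifnot(all(c("subject", "level", "value") %in% names(df)))
  lv <- sort(unique(df$level))
  if (length(lv) != 2)
    stop("rm_anova_oneway requires exactly 2 levels", call. = FALSE)
  m <- stats::xtabs(value ~ subject + level, df)
  cnt <- stats::xtabs(~ subject + level, df)
  if (any(cnt != 1))
    stop("each subject must contribute exactly one value per level",
         call. = FALSE)
  d <- m[, 2] - m[, 1]
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  f <- if (se == 0) 0 else (mean(d) / se)^2
  data.frame(effect = "oneway", F = f, df1 = 1, df2 = n - 1,
             p = stats::pf(f, 1, n - 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Post hoc paired t-test
#'
#' @param x,y paired numeric vectors (same subjects, two cells)
#' @return list: t, df, p (two-sided)
#' @export
posthoc_paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  t <- if (se == 0) 0 else mean(d) / se
  list(t = t, df = n - 1,
       p = if (se == 0 && mean(d) == 0) 1
           else 2 * stats::pt(-abs(t), n - 1))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with a
#' two-sided p-value from the t approximation
#' t = r sqrt((n-2)/(1-r^2)) on n-2 df -- adequate for cohort sizes around
#' 20; an exact permutation p-value is available via `n_perm`.
#'
#' @param x,y numeric vectors, n >= 5
#' @param n_perm if > 0, additionally compute a permutation p-value from
#'   `n_perm` random permutations (add-one convention, two-sided)
#' @param seed seed for the permutation p-value
#' @return list: r, p, n (and `p_perm` when requested)
#' @export
spearman_correlation <- function(x, y, n_perm = 0, seed = 1L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5) stop("need at least 5 observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  if (sx == 0 || sy == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) / ((n - 1) * sx * sy)
  r <- max(min(r, 1), -1)
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  out <- list(r = r, p = p, n = n)
  if (n_perm > 0) {
    set.seed(seed)
    null_r <- vapply(seq_len(n_perm), function(i) {
      ryp <- rank(y)[sample.int(n)]
      sum((rx - mean(rx)) * (ryp - mean(ryp))) / ((n - 1) * sx * sy)
    }, numeric(1))
    out$p_perm <- (1 + sum(abs(null_r) >= abs(r))) / (1 + n_perm)
  }
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values: p_(i) * m / i, running minimum from the
#' largest ordered p downward, capped at 1. Applied as one family per
#' analysis (one test type across all ROI connection x time x frequency
#' comparisons).
#'
#' @param p numeric vector of raw p-values in (0, 1]
#' @return adjusted p-values, same order as input
#' @export
fdr_correct <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 1) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / (m:1)))
  adj[order(o)]
}

#' Signal-detection sensitivity d-prime
#'
#' d' = z(hit rate) - z(false-alarm rate). Rates of exactly 0 or 1 make z
#' infinite; with `correction = "loglinear"` and the per-class trial counts
#' supplied, degenerate inputs (either rate 0 or 1) cause both rates to be
#' recomputed from counts as (count + 0.5) / (N + 1), which keeps d'
#' finite. Non-degenerate rates are used as given.
#'
#' @param hit hit rate in [0, 1]
#' @param fa false-alarm rate in [0, 1]
#' @param n_signal,n_noise trial counts behind the two rates (required for
#'   the log-linear correction)
#' @param correction "loglinear" (default) or "none"
#' @return scalar d'
#' @export
dprime <- function(hit, fa, n_signal = NULL, n_noise = NULL,
                   correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  stopifnot(hit >= 0, hit <= 1, fa >= 0, fa <= 1)
  if (correction == "loglinear" && any(c(hit, fa) %in% c(0, 1))) {
    if (is.null(n_signal) || is.null(n_noise))
      stop("log-linear correction requires n_signal and n_noise",
           call. = FALSE)
    hit <- (hit * n_signal + 0.5) / (n_signal + 1)
    fa <- (fa * n_noise + 0.5) / (n_noise + 1)
  }
  stats::qnorm(hit) - stats::qnorm(fa)
}
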