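#' Enumerate all unidirectional orientations of a fully connected node set
#'
#' For n nodes, every unordered pair carries exactly one directed edge, and
#' each edge can point either way: 2^(n*(n-1)/2) model specifications. For
#' the three-node triangle this yields 8 candidate models, including the
#' two fully cyclic orderings. Restricting to unidirectional edges keeps
#' every candidate at the same degrees of freedom, so goodness-of-fit is
#' comparable across models.
#'
#' @param nodes ROI labels (default the three left-hemisphere areas of the
#'   loop analysis)
#' @param lag model lag in samples, stored with each spec
#' @return list of objects of class `loop_model`, each with `nodes`,
#'   `edges` (2-column from/to matrix) and `lag`; names encode the edges
#' @export
enumerate_loop_models <- function(nodes = c("AC", "TPJ", "vPMC"), lag = 12) {
  stopifnot(length(nodes) >= 2, !anyDuplicated(nodes))
  und <- utils::combn(nodes, 2)
  ne <- ncol(und)
  models <- vector("list", 2^ne)
  for (m in 0:(2^ne - 1)) {
    bits <- bitwAnd(bitwShiftR(m, 0:(ne - 1)), 1L)
    edges <- t(vapply(seq_len(ne), function(e) {
      if (bits[e] == 0) und[, e] else rev(und[, e])
    }, character(2)))
    colnames(edges) <- c("from", "to")
    models[[m + 1]] <- structure(list(nodes = nodes, edges = edges,
                                      lag = lag),
                                 class = "loop_model")
  }
  names(models) <- vapply(models, format_loop_model, character(1))
  models
}

format_loop_model <- function(model) {
  paste(apply(model$edges, 1, paste, collapse = "->"), collapse = ", ")
}

#' @export
print.loop_model <- function(x, ...) {
  cat(sprintf("<loop_model> %s (lag %d)\n", format_loop_model(x), x$lag))
  invisible(x)
}

# Edge list as node indices: matrix with columns (from, to), one row per
# directed edge. A node may have several parents (the acyclic triangle
# orientations) or none.
loop_edge_index <- function(model) {
  cbind(from = match(model$edges[, "from"], model$nodes),
        to = match(model$edges[, "to"], model$nodes))
}

# For the generator: list of parent indices per node.
loop_parents <- function(model) {
  ei <- loop_edge_index(model)
  lapply(seq_along(model$nodes), function(i) ei[ei[, "to"] == i, "from"])
}

#' Extract a standardized band-limited signal from a TF cube
#'
#' Real part of the wavelet coefficients averaged over the frequency bins
#' inside `freq_range`, restricted to `time_range`, and standardized to
#' zero mean / unit variance per trial and node. This keeps the SEM stage
#' in the same representation (same time and frequency range) as the
#' synchrony effect it follows up.
#'
#' @param tf a `tf_cube`
#' @param freq_range interval in Hz (inclusive)
#' @param time_range interval in ms, half-open
#' @param rois optional subset of ROI labels (default all)
#' @return numeric array trials x nodes x samples, dimnames on nodes;
#'   attribute `time` carries the sample times
#' @export
extract_band_signal <- function(tf, freq_range, time_range, rois = NULL) {
  stopifnot(inherits(tf, "tf_cube"))
  if (is.null(rois)) rois <- tf$rois
  ir <- match(rois, tf$rois)
  if (anyNA(ir)) stop("unknown ROI label(s)", call. = FALSE)
  jf <- which(tf$freqs >= freq_range[1] & tf$freqs <= freq_range[2])
  jt <- which(tf$time >= time_range[1] & tf$time < time_range[2])
  if (length(jf) == 0 || length(jt) == 0)
    stop("empty frequency or time range", call. = FALSE)
  sub <- tf$coef[, ir, jf, jt, drop = FALSE]
  sig <- apply(Re(sub), c(1, 2, 4), mean)         # trials x nodes x samples
  mu <- apply(sig, c(1, 2), mean)
  sdv <- apply(sig, c(1, 2), stats::sd)
  if (any(sdv == 0)) stop("zero-variance signal segment", call. = FALSE)
  sig <- (sig - as.vector(mu)) / as.vector(sdv)
  dimnames(sig) <- list(NULL, rois, NULL)
  attr(sig, "time") <- tf$time[jt]
  sig
}

# Pooled lagged regression slope: y(t) ~ x(t - lag), samples pooled over
# trials; returns the centered least-squares coefficient.
lagged_beta <- function(x, y, lag) {
  ns <- ncol(x)
  stopifnot(lag >= 1, lag < ns)
  xl <- as.vector(x[, 1:(ns - lag), drop = FALSE])
  yt <- as.vector(y[, (lag + 1):ns, drop = FALSE])
  vx <- stats::var(xl)
  if (vx == 0) stop("zero-variance regressor", call. = FALSE)
  stats::cov(xl, yt) / vx
}

#' Pairwise directionality from reciprocal lagged path coefficients
#'
#' Per subject, beta_A->B is the least-squares coefficient of B(t) on
#' A(t - lag) with samples pooled over trials (and beta_B->A symmetric).
#' Because consecutive samples within a trial are not independent,
#' bootstrap confidence intervals resample trials, not samples. The group
#' test is a paired sign-flip permutation t-test on
#' beta_A->B - beta_B->A across subjects.
#'
#' @param signals list of per-subject arrays trials x nodes x samples (as
#'   returned by [extract_band_signal()])
#' @param pair two node labels c(A, B)
#' @param lag lag in samples
#' @param n_boot bootstrap resamples per subject (default 1000)
#' @param n_perm sign-flip permutations for the group test (default 10000)
#' @param seed integer seed
#' @return object of class `pair_directionality`: per-subject `beta_ab`,
#'   `beta_ba`, bootstrap CIs (`ci_ab`, `ci_ba`, subjects x 2), group `t`,
#'   permutation `p`
#' @export
fit_pairwise <- function(signals, pair, lag, n_boot = 1000, n_perm = 10000,
                         seed = 1L) {
  stopifnot(is.list(signals), length(pair) == 2, length(signals) >= 2)
  set.seed(seed)
  n <- length(signals)
  beta_ab <- beta_ba <- numeric(n)
  ci_ab <- ci_ba <- matrix(NA_real_, n, 2)
  for (s in seq_len(n)) {
    sig <- signals[[s]]
    a <- sig[, pair[1], , drop = TRUE]
    b <- sig[, pair[2], , drop = TRUE]
    if (is.null(dim(a))) { a <- matrix(a, 1); b <- matrix(b, 1) }
    if (nrow(a) < 2) stop("need at least 2 trials per subject", call. = FALSE)
    beta_ab[s] <- lagged_beta(a, b, lag)
    beta_ba[s] <- lagged_beta(b, a, lag)
    if (n_boot > 0) {
      bb <- matrix(NA_real_, n_boot, 2)
      for (r in seq_len(n_boot)) {
        idx <- sample.int(nrow(a), replace = TRUE)
        bb[r, ] <- c(lagged_beta(a[idx, , drop = FALSE],
                                 b[idx, , drop = FALSE], lag),
                     lagged_beta(b[idx, , drop = FALSE],
                                 a[idx, , drop = FALSE], lag))
      }
      ci_ab[s, ] <- stats::quantile(bb[, 1], c(0.025, 0.975))
      ci_ba[s, ] <- stats::quantile(bb[, 2], c(0.025, 0.975))
    }
  }
  grp <- perm_t_paired(beta_ab - beta_ba, n_perm = n_perm)
  structure(list(pair = pair, lag = lag, beta_ab = beta_ab,
                 beta_ba = beta_ba, ci_ab = ci_ab, ci_ba = ci_ba,
                 t = grp$t, p = grp$p, n_perm = n_perm),
            class = "pair_directionality")
}

#' Paired-samples sign-flip permutation t-test
#'
#' Two-sided test of mean(d) = 0 against the sign-flip null: the t
#' statistic is recomputed under `n_perm` random sign assignments of the
#' paired differences and compared by absolute value, with the add-one
#' p-value convention. Uses the current RNG state (seed it upstream).
#'
#' @param d numeric vector of paired differences
#' @param n_perm number of random sign flips (default 10000)
#' @return list: t, df, p
#' @export
perm_t_paired <- function(d, n_perm = 10000) {
  n <- length(d)
  stopifnot(n >= 2)
  tstat <- function(z) {
    se <- stats::sd(z) / sqrt(n)
    if (se == 0) 0 else mean(z) / se
  }
  t_obs <- tstat(d)
  flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  t_null <- apply(flips * d, 2, tstat)
  list(t = t_obs, df = n - 1,
       p = (1 + sum(abs(t_null) >= abs(t_obs))) / (1 + n_perm))
}

# Implied covariance of the observed 2k-vector (y_t, x_{t-lag}) under a
# directed lagged path model: y = B x + e with one free path per directed
# edge, Psi diagonal, Phi (the exogenous lagged block) saturated.
sem_implied_cov <- function(beta, psi, phi, edge_idx) {
  k <- nrow(phi)
  B <- matrix(0, k, k)
  B[edge_idx[, c("to", "from"), drop = FALSE]] <- beta
  syy <- B %*% phi %*% t(B) + diag(psi, k)
  syx <- B %*% phi
  rbind(cbind(syy, syx), cbind(t(syx), phi))
}

sem_fml <- function(sigma, s) {
  p <- nrow(s)
  cs <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(cs)) return(1e10)
  logdet_sigma <- 2 * sum(log(diag(cs)))
  logdet_s <- determinant(s, logarithm = TRUE)$modulus
  val <- logdet_sigma + sum(diag(s %*% chol2inv(cs))) - as.numeric(logdet_s) - p
  if (!is.finite(val)) 1e10 else val
}

# Pack/unpack: beta (one per edge), log psi (k), Phi via Cholesky
# (log-diagonal + below-diagonal).
sem_unpack <- function(par, k, ne) {
  beta <- par[seq_len(ne)]
  psi <- exp(par[ne + seq_len(k)])
  L <- diag(exp(par[ne + k + seq_len(k)]), k)
  L[lower.tri(L)] <- par[(ne + 2 * k + 1):length(par)]
  list(beta = beta, psi = psi, phi = L %*% t(L))
}

#' Fit a directed lagged loop model by maximum likelihood
#'
#' The observed vector is (A_t, B_t, C_t, A_{t-lag}, B_{t-lag}, C_{t-lag});
#' free parameters are the directed lagged paths (one per node with a
#' parent), the endogenous residual variances, and the full covariance of
#' the exogenous lagged block. The ML discrepancy
#' F_ML = ln|Sigma(theta)| + tr(S Sigma(theta)^-1) - ln|S| - p
#' is minimized numerically (BFGS from regression-based starting values,
#' with jittered restarts on failure). chi^2 = (n_effective - 1) * F_ML,
#' df = p(p+1)/2 - n_par (9 for the three-node loop), and
#' RMSEA = sqrt(max(chi^2 - df, 0) / (df * (n_effective - 1))). The
#' effective sample size is the trial count, not the (serially dependent)
#' pooled sample count.
#'
#' @param model a `loop_model`
#' @param signals array trials x nodes x samples (node order must contain
#'   the model's nodes)
#' @param lag lag in samples (default the model's)
#' @param n_effective effective sample size (default: number of trials)
#' @return object of class `sem_fit`: model, beta (named by edge), psi,
#'   phi, chi_square, df, rmsea, n_effective, fml, convergence
#' @export
fit_loop_model <- function(model, signals, lag = model$lag,
                           n_effective = dim(signals)[1]) {
  stopifnot(inherits(model, "loop_model"), length(dim(signals)) == 3)
  nodes <- model$nodes
  sig <- signals[, nodes, , drop = FALSE]
  k <- length(nodes)
  edge_idx <- loop_edge_index(model)
  ne <- nrow(edge_idx)
  ns <- dim(sig)[3]
  stopifnot(lag >= 1, lag < ns)

  # pooled (y_t, x_{t-lag}) observations
  yt <- sapply(seq_len(k), function(i)
    as.vector(sig[, i, (lag + 1):ns]))
  xl <- sapply(seq_len(k), function(i)
    as.vector(sig[, i, 1:(ns - lag)]))
  obs <- cbind(yt, xl)
  s <- stats::cov(obs)
  fit_loop_cov(model, s, n_effective)
}

# Core ML fit from a 2k x 2k covariance of (y_t, x_{t-lag}); separated from
# the data path so it can be exercised on analytically implied covariances.
fit_loop_cov <- function(model, s, n_effective) {
  nodes <- model$nodes
  k <- length(nodes)
  edge_idx <- loop_edge_index(model)
  ne <- nrow(edge_idx)
  if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
    stop("sample covariance is singular", call. = FALSE)

  syx <- s[1:k, (k + 1):(2 * k)]
  sxx <- s[(k + 1):(2 * k), (k + 1):(2 * k)]
  # starting values: per-node joint OLS of the child on its parents
  beta0 <- numeric(ne)
  psi0 <- diag(s)[1:k]
  for (i in seq_len(k)) {
    rows <- which(edge_idx[, "to"] == i)
    if (length(rows) == 0) next
    ps <- edge_idx[rows, "from"]
    b <- solve(sxx[ps, ps, drop = FALSE], syx[i, ps])
    beta0[rows] <- b
    psi0[i] <- max(s[i, i] - sum(b * syx[i, ps]), 1e-4)
  }
  L0 <- t(chol(sxx))
  par0 <- c(beta0, log(psi0), log(diag(L0)), L0[lower.tri(L0)])

  objective <- function(par) {
    th <- sem_unpack(par, k, ne)
    sem_fml(sem_implied_cov(th$beta, th$psi, th$phi, edge_idx), s)
  }

  fit <- NULL
  for (attempt in 0:3) {
    start <- if (attempt == 0) par0 else
      par0 + stats::rnorm(length(par0), 0, 0.05 * attempt)
    res <- tryCatch(
      stats::optim(start, objective, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && res$value < 1e9) { fit <- res; break }
  }
  if (is.null(fit))
    stop("loop-model fit did not converge", call. = FALSE)

  th <- sem_unpack(fit$par, k, ne)
  fml <- max(fit$value, 0)
  chi2 <- (n_effective - 1) * fml
  n_par <- length(par0)
  df <- (2 * k) * (2 * k + 1) / 2 - n_par
  if (df <= 0)
    stop("model is saturated or over-parameterized (df <= 0)", call. = FALSE)
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (n_effective - 1)))

  beta <- th$beta
  names(beta) <- apply(model$edges, 1, paste, collapse = "->")

  structure(list(model = model, beta = beta, psi = th$psi, phi = th$phi,
                 chi_square = chi2, df = df, rmsea = rmsea,
                 n_effective = n_effective, fml = fml,
                 convergence = fit$convergence),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> %s\n  chi^2(%d) = %.3f, RMSEA = %.4f (n_eff = %d)\n",
              format_loop_model(x$model), x$df, x$chi_square, x$rmsea,
              x$n_effective))
  invisible(x)
}

#' RMSEA from a chi-square statistic
#'
#' sqrt(max(chi^2 - df, 0) / (df * (n - 1))); zero whenever chi^2 <= df.
#' Values below 0.07 are conventionally read as good fit.
#'
#' @param chi_square chi-square statistic
#' @param df model degrees of freedom (> 0)
#' @param n effective sample size
#' @return scalar RMSEA
#' @export
rmsea <- function(chi_square, df, n) {
  stopifnot(df > 0, n > 1)
  sqrt(max(chi_square - df, 0) / (df * (n - 1)))
}

#' Rank loop models by mean RMSEA
#'
#' Each candidate's fits (one per subject, or a single fit) are summarized
#' by mean and SD of RMSEA and sorted ascending; models with mean RMSEA
#' below the 0.07 cutoff are flagged as good fits.
#'
#' @param fits named list; each element a `sem_fit` or a list of `sem_fit`
#'   objects (one per subject) for one candidate model
#' @param cutoff good-fit threshold (default 0.07)
#' @return data.frame sorted by mean RMSEA: model, mean_rmsea, sd_rmsea,
#'   n_fits, good_fit
#' @export
compare_models <- function(fits, cutoff = 0.07) {
  stopifnot(is.list(fits), length(fits) >= 1)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "sem_fit")) f <- list(f)
    r <- vapply(f, function(x) x$rmsea, numeric(1))
    nm <- names(fits)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- format_loop_model(f[[1]]$model)
    data.frame(model = nm, mean_rmsea = mean(r),
               sd_rmsea = if (length(r) > 1) stats::sd(r) else NA_real_,
               n_fits = length(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$good_fit <- out$mean_rmsea < cutoff
  out <- out[order(out$mean_rmsea), ]
  rownames(out) <- NULL
  out
}
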