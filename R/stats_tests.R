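#' t-test between condition amplitude samples
#'
#' Thin wrapper around Student's t-test returning a uniform result record.
#' The three standard comparisons of the validation design map to:
#' no-stim vs stim-raw (independent, one-sided "greater" for the raw
#' artifact inflation), stim-raw vs stim-SASS (dependent, one-sided "less"
#' after cleaning), and no-stim vs stim-SASS (independent, two-sided; a
#' residual artifact would show as any difference).
#'
#' @param x,y numeric samples (x first group).
#' @param pairing `"independent"` or `"dependent"`.
#' @param sidedness `"two"`, `"greater"` or `"less"` (direction of y
#'   relative to x follows [stats::t.test()]'s `alternative` for x - y).
#' @return list of class `test_result`: `statistic`, `p_value`,
#'   `sidedness`, `pairing`, `n`.
#' @export
t_compare <- function(x, y, pairing = c("independent", "dependent"),
                      sidedness = c("two", "greater", "less")) {
  pairing <- match.arg(pairing)
  sidedness <- match.arg(sidedness)
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group")
  if (pairing == "dependent" && length(x) != length(y)) {
    stop("paired test needs equal lengths")
  }
  if (pairing == "dependent" && all(x == y)) {
    return(structure(list(statistic = 0, p_value = 1,
                          sidedness = sidedness, pairing = pairing,
                          n = c(length(x), length(y))),
                     class = "test_result"))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("zero variance in both groups")
  }
  alt <- switch(sidedness, two = "two.sided", greater = "greater",
                less = "less")
  tt <- stats::t.test(x, y, paired = pairing == "dependent",
                      alternative = alt)
  structure(list(statistic = unname(tt$statistic),
                 p_value = tt$p.value, sidedness = sidedness,
                 pairing = pairing, n = c(length(x), length(y))),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("statistic = %.4g, p = %.4g (%s, %s, n = %s)\n",
              x$statistic, x$p_value, x$sidedness, x$pairing,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Wallraff test for differences in angular concentration
#'
#' Nonparametric comparison of two circular samples: within each group the
#' angular distance of every phase to that group's own circular mean is
#' computed (`d = pi - |pi - |phi - mu||`), and the two distance samples
#' are compared with a Wilcoxon signed-rank test (dependent samples) or a
#' Mann-Whitney U test (independent samples). Sensitive to differences in
#' concentration around each group's center, not to the centers
#' themselves, and invariant to rotating both samples jointly.
#'
#' @param phases_a,phases_b radians (n >= 5 per group).
#' @param pairing `"independent"` or `"dependent"`.
#' @param center `"mean"` (circular mean, default) or `"median"`
#'   (circular median).
#' @return a `test_result`.
#' @export
wallraff_test <- function(phases_a, phases_b,
                          pairing = c("independent", "dependent"),
                          center = c("mean", "median")) {
  pairing <- match.arg(pairing)
  center <- match.arg(center)
  if (length(phases_a) < 5L || length(phases_b) < 5L) {
    stop("need >= 5 angles per group")
  }
  ang_dist <- function(phi) {
    mu <- if (center == "mean") {
      cm <- circ_mean(phi)
      if (cm$r < 1e-8) stop("degenerate resultant; group center undefined")
      cm$mean
    } else {
      circ_median(phi)
    }
    pi - abs(pi - abs(wrap_angle(phi - mu)))
  }
  da <- ang_dist(phases_a)
  db <- ang_dist(phases_b)
  if (pairing == "dependent") {
    if (length(da) != length(db)) stop("paired test needs equal lengths")
    if (all(da == db)) {
      return(structure(list(statistic = 0, p_value = 1, sidedness = "two",
                            pairing = pairing,
                            n = c(length(da), length(db))),
                       class = "test_result"))
    }
    wt <- stats::wilcox.test(da, db, paired = TRUE, exact = FALSE,
                             correct = TRUE)
  } else {
    wt <- stats::wilcox.test(da, db, exact = FALSE, correct = TRUE)
  }
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 sidedness = "two", pairing = pairing,
                 n = c(length(da), length(db))),
            class = "test_result")
}

# circular median: angle (among candidates) minimizing mean angular
# distance to the sample
circ_median <- function(phi) {
  d <- vapply(phi, function(m) {
    mean(pi - abs(pi - abs(wrap_angle(phi - m))))
  }, numeric(1))
  phi[which.min(d)]
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' For each sensor, integrates `extent^E * height^H` of the supra-threshold
#' cluster containing it over thresholds from `dh` to the map maximum in
#' steps of `dh` (default 0.1 of the maximum absolute value). Positive and
#' negative parts are enhanced separately and recombined with sign.
#'
#' @param tmap numeric statistic per sensor.
#' @param adjacency logical symmetric sensor adjacency matrix.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; NULL means `0.1 * max(|tmap|)`.
#' @return enhanced map, same length as `tmap`.
#' @export
tfce <- function(tmap, adjacency, E = 0.5, H = 2, dh = NULL) {
  mx <- max(abs(tmap))
  if (mx == 0) return(numeric(length(tmap)))
  if (is.null(dh)) dh <- 0.1 * mx
  out <- numeric(length(tmap))
  for (sgn in c(1, -1)) {
    v <- sgn * tmap
    if (max(v) < dh) next
    hs <- seq(dh, max(v), by = dh)
    for (h in hs) {
      supra <- v >= h
      if (!any(supra)) break
      comp <- label_components(supra, adjacency)
      sizes <- tabulate(comp)
      idx <- which(supra)
      out[idx] <- out[idx] + sgn * sizes[comp[idx]]^E * h^H * dh
    }
  }
  out
}

# connected components of a logical mask on an adjacency graph
label_components <- function(mask, adjacency) {
  n <- length(mask)
  comp <- integer(n)
  cur <- 0L
  for (s in which(mask)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- which(adjacency[v, ] & mask & comp == 0L)
      comp[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  comp
}

#' Spatial cluster permutation test with TFCE
#'
#' Per-sensor t-map between two trial-amplitude samples, TFCE transform,
#' and max-statistic permutation correction: condition labels are shuffled
#' (independent samples) or signs of paired differences flipped (dependent
#' samples), the maximum absolute TFCE value across sensors is collected
#' per permutation, and each sensor's corrected p-value is the fraction of
#' permutations whose maximum reaches its observed TFCE value.
#'
#' @param amplitudes_a,amplitudes_b trials x sensors matrices.
#' @param adjacency logical symmetric adjacency (see
#'   [sensor_adjacency()]).
#' @param n_perm number of permutations (default 1024).
#' @param pairing `"independent"` or `"dependent"`.
#' @param E,H,dh TFCE parameters, see [tfce()].
#' @param seed optional RNG seed.
#' @return list with `p_values` (per sensor, corrected), `tfce_obs`,
#'   `tmap`, `n_perm`.
#' @export
tfce_cluster_test <- function(amplitudes_a, amplitudes_b, adjacency,
                              n_perm = 1024,
                              pairing = c("independent", "dependent"),
                              E = 0.5, H = 2, dh = NULL, seed = NULL) {
  pairing <- match.arg(pairing)
  a <- as.matrix(amplitudes_a)
  b <- as.matrix(amplitudes_b)
  if (ncol(a) != ncol(b)) stop("sensor sets differ")
  ns <- ncol(a)
  if (ns < 2L) stop("need >= 2 sensors")
  if (!is.null(seed)) set.seed(seed)
  col_vars <- function(x) {
    n <- nrow(x)
    (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
  }
  tmap_indep <- function(xa, xb) {
    na <- nrow(xa); nb <- nrow(xb)
    se <- sqrt(col_vars(xa) / na + col_vars(xb) / nb)
    se[se == 0] <- Inf
    (colMeans(xa) - colMeans(xb)) / se
  }
  if (pairing == "dependent") {
    if (nrow(a) != nrow(b)) stop("paired test needs equal trial counts")
    d <- a - b
    nt <- nrow(d)
    d2s <- colSums(d^2)
    tmap_paired <- function(s) {
      m <- as.numeric(crossprod(s, d)) / nt
      se <- sqrt((d2s - nt * m^2) / (nt - 1) / nt)
      se[se == 0] <- Inf
      m / se
    }
    tobs <- tmap_paired(rep(1, nt))
  } else {
    tobs <- tmap_indep(a, b)
  }
  # fix dh from the observed map so the enhancement is comparable across
  # permutations
  if (is.null(dh)) dh <- 0.1 * max(abs(tobs))
  if (dh == 0) dh <- NULL
  tfce_obs <- tfce(tobs, adjacency, E, H, dh)
  if (n_perm < 1L) stop("no permutations possible")
  maxnull <- numeric(n_perm)
  if (pairing == "dependent") {
    for (p in seq_len(n_perm)) {
      s <- sample(c(-1, 1), nrow(a), replace = TRUE)
      maxnull[p] <- max(abs(tfce(tmap_paired(s), adjacency, E, H, dh)))
    }
  } else {
    pool <- rbind(a, b)
    na <- nrow(a)
    for (p in seq_len(n_perm)) {
      idx <- sample.int(nrow(pool), na)
      maxnull[p] <- max(abs(tfce(tmap_indep(pool[idx, , drop = FALSE],
                                            pool[-idx, , drop = FALSE]),
                                 adjacency, E, H, dh)))
    }
  }
  p_values <- vapply(abs(tfce_obs), function(v) {
    (1 + sum(maxnull >= v)) / (1 + n_perm)
  }, numeric(1))
  list(p_values = p_values, tfce_obs = tfce_obs, tmap = tobs,
       n_perm = n_perm)
}

#' Minimum detectable effect size of a two-sample t-test
#'
#' Smallest Cohen's d reaching the requested power for an
#' independent-samples t-test at the given group sizes and alpha, solved on
#' the noncentral t distribution by bisection (tolerance 1e-6). A normal
#' approximation is available for cross-checking.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level.
#' @param power target power.
#' @param sidedness `"two"` or `"one"`.
#' @param method `"noncentral_t"` (default) or `"normal"`.
#' @return Cohen's d.
#' @export
#' @examples
#' detectable_effect_size(200, 200)  # ~0.281
detectable_effect_size <- function(n1 = 200, n2 = 200, alpha = 0.05,
                                   power = 0.8,
                                   sidedness = c("two", "one"),
                                   method = c("noncentral_t", "normal")) {
  sidedness <- match.arg(sidedness)
  method <- match.arg(method)
  if (!(alpha > 0 && alpha < power && power < 1)) {
    stop("need 0 < alpha < power < 1")
  }
  if (n1 < 2L || n2 < 2L) stop("group sizes must be >= 2")
  nh <- 1 / (1 / n1 + 1 / n2)  # harmonic-mean based effective n
  if (method == "normal") {
    za <- stats::qnorm(1 - alpha / if (sidedness == "two") 2 else 1)
    return((za + stats::qnorm(power)) / sqrt(nh))
  }
  df <- n1 + n2 - 2
  tc <- stats::qt(1 - alpha / if (sidedness == "two") 2 else 1, df)
  pw <- function(d) {
    ncp <- d * sqrt(nh)
    p <- stats::pt(tc, df, ncp = ncp, lower.tail = FALSE)
    if (sidedness == "two") p <- p + stats::pt(-tc, df, ncp = ncp)
    p
  }
  if (pw(20) < power) stop("requested power unreachable")
  lo <- 0
  hi <- 20
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (pw(mid) < power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Detectable residual artifact in amplitude units
#'
#' Converts a detectable effect size into a detectable difference of mean
#' single-trial amplitudes: `d * pooled SD`, with the equal-group-size
#' pooled SD `sqrt((sd1^2 + sd2^2) / 2)`.
#'
#' @param d Cohen's d.
#' @param sd1,sd2 within-condition single-trial amplitude SDs, uV.
#' @return detectable mean difference, uV.
#' @export
residual_artifact_bound <- function(d, sd1, sd2) {
  if (any(c(sd1, sd2) <= 0)) stop("SDs must be positive")
  d * sqrt((sd1^2 + sd2^2) / 2)
}

#' Group-level mean and spread
#'
#' Arithmetic mean and population standard deviation (divide by N) of
#' per-participant summary values, the convention used for "mean +/- sd"
#' group reports.
#'
#' @param values numeric (n >= 2).
#' @return list with `mean` and `sd`.
#' @export
group_summary <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need >= 2 values")
  m <- mean(values)
  list(mean = m, sd = sqrt(mean((values - m)^2)))
}
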