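# In vitro tensile-test analysis: per-specimen mechanical metrics, group
# summaries, and the nonparametric comparisons between sub-tendons.

#' Tensile test curve
#'
#' @param time time, s (strictly increasing).
#' @param displacement grip displacement, mm (zero-referenced after preload).
#' @param force force, N.
#' @param gauge_length clamped free length, mm (test protocol: 60).
#' @param csa specimen cross-sectional area, mm^2.
#' @param preload preload force, N (10 N gastrocnemii / 20 N soleus in the
#'   emulated protocol).
#' @return a `test_curve` object.
#' @export
test_curve <- function(time, displacement, force, gauge_length = 60,
                       csa, preload = 0) {
  stopifnot(length(time) == length(displacement), length(time) == length(force))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (csa <= 0) stop("CSA must be positive")
  structure(list(time = time, displacement = displacement, force = force,
                 gauge_length = gauge_length, csa = csa, preload = preload),
            class = "test_curve")
}

#' Mechanical metrics of one failure test
#'
#' Failure force is the curve maximum (a subsequent drop of at least
#' `drop_frac` must be present for failure to be declared). Ultimate stress
#' is failure force over CSA; ultimate strain is the displacement at maximum
#' force over the gauge length. Stiffness is the maximum slope of a
#' straight-line fit slid over the ascending limb restricted to
#' 20-80 percent of the failure force (a deterministic reading of "the
#' linear region"); Young's modulus applies the same procedure to the
#' stress-strain curve, which for a uniform specimen equals
#' stiffness x gauge / CSA.
#'
#' @param curve a `test_curve`.
#' @param force_band force window (fractions of failure force) for the
#'   linear-region search.
#' @param window_frac sliding-window length as a fraction of the band.
#' @param drop_frac required post-peak force drop to declare failure.
#' @return tibble with `csa_mm2`, `failure_force_n`, `ultimate_stress_mpa`,
#'   `ultimate_strain_pct`, `modulus_mpa`, `stiffness_n_mm`.
#' @export
specimen_metrics <- function(curve, force_band = c(0.2, 0.8),
                             window_frac = 0.5, drop_frac = 0.2) {
  stopifnot(inherits(curve, "test_curve"))
  f <- curve$force; d <- curve$displacement
  imax <- which.max(f)
  fmax <- f[imax]
  if (fmax <= 0) stop("no failure detected: zero-force curve")
  post <- f[seq(imax, length(f))]
  if (min(post) > (1 - drop_frac) * fmax)
    stop("no failure detected: force never drops by the required fraction after the peak")

  band <- which(seq_along(f) <= imax & f >= force_band[1] * fmax & f <= force_band[2] * fmax)
  if (length(band) < 5) stop("linear-region window shorter than 5 samples")
  wlen <- max(5L, as.integer(round(window_frac * length(band))))
  slope_max <- function(x, y) {
    best <- -Inf
    for (s in seq_len(length(band) - wlen + 1L)) {
      ii <- band[s:(s + wlen - 1L)]
      sl <- stats::cov(x[ii], y[ii]) / stats::var(x[ii])
      if (is.finite(sl) && sl > best) best <- sl
    }
    best
  }
  stiffness <- slope_max(d, f)
  modulus <- slope_max(d / curve$gauge_length, f / curve$csa)
  tibble::tibble(csa_mm2 = curve$csa,
                 failure_force_n = fmax,
                 ultimate_stress_mpa = fmax / curve$csa,
                 ultimate_strain_pct = d[imax] / curve$gauge_length * 100,
                 modulus_mpa = modulus,
                 stiffness_n_mm = stiffness)
}

.metric_cols <- c("csa_mm2", "failure_force_n", "ultimate_stress_mpa",
                  "ultimate_strain_pct", "modulus_mpa", "stiffness_n_mm")

#' Packaged per-specimen mechanical dataset
#'
#' Per-specimen, per-sub-tendon mechanical testing results of five cadaveric
#' Achilles tendons (columns: specimen age-sex code, sub-tendon, CSA,
#' failure force, ultimate stress, ultimate strain, Young's modulus,
#' stiffness), stored at the 1-decimal precision of the published table.
#'
#' @return tibble with one row per specimen x sub-tendon.
#' @export
read_specimen_table <- function() {
  path <- system.file("extdata", "subtendon_mechanics.csv", package = "subtendon")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Mean and sample SD per metric and sub-tendon
#'
#' @param records tibble in the layout of [read_specimen_table()].
#' @return tibble with `sub_tendon`, `metric`, `mean`, `sd`, `n`
#'   (sample SD, n - 1 denominator).
#' @export
summarize_group <- function(records) {
  if (length(unique(records$specimen)) < 2) stop("need at least 2 specimens")
  rows <- list()
  for (st in unique(records$sub_tendon)) {
    sub <- records[records$sub_tendon == st, ]
    for (m in .metric_cols) {
      v <- sub[[m]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sub_tendon = st, metric = m, mean = mean(v), sd = stats::sd(v), n = length(v))
    }
  }
  do.call(rbind, rows)
}

# Exact null distribution of the rank-sum of n_a items from ranks 1..N
# (no ties): dynamic programming over subset sums; cached.
.ranksum_cache <- new.env(parent = emptyenv())
ranksum_null <- function(n_a, N) {
  key <- paste(n_a, N)
  if (!is.null(.ranksum_cache[[key]])) return(.ranksum_cache[[key]])
  maxs <- sum((N - n_a + 1):N)
  # f[k+1, s+1] = number of k-subsets of {1..j} with sum s, built up in j
  f <- matrix(0, n_a + 1L, maxs + 1L)
  f[1, 1] <- 1
  for (j in seq_len(N)) {
    for (k in rev(seq_len(min(j, n_a)))) {
      smax <- maxs - j
      idx <- 0:smax
      f[k + 1L, idx + j + 1L] <- f[k + 1L, idx + j + 1L] + f[k, idx + 1L]
    }
  }
  out <- f[n_a + 1L, ]
  .ranksum_cache[[key]] <- out
  out
}

#' Exact two-sided Mann-Whitney U test
#'
#' For combined sample sizes up to `exact_max` the permutation distribution
#' of the rank sum is evaluated exactly (dynamic programming without ties,
#' complete enumeration of rank assignments with ties); larger samples use
#' the normal approximation with tie correction. The two-sided p-value is
#' twice the smaller tail, capped at 1 (the convention of mainstream
#' statistics packages).
#'
#' @param a,b numeric vectors.
#' @param exact_max threshold on `length(a) + length(b)` for exactness.
#' @return list of class `nonparam_test`: `method`, `statistic` (U, the
#'   smaller of the two group U values), `p_value`, `groups`.
#' @export
mann_whitney_exact <- function(a, b, exact_max = 20L) {
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop("empty group")
  N <- na + nb
  r <- rank(c(a, b))
  wa <- sum(r[seq_len(na)])
  ua <- wa - na * (na + 1) / 2
  ub <- na * nb - ua
  ties <- anyDuplicated(c(a, b)) > 0
  if (N <= exact_max && !ties) {
    null <- ranksum_null(na, N)
    tot <- sum(null)
    lo <- sum(null[1:(wa + 1)]) / tot          # P(W <= wa)
    hi <- 1 - sum(null[1:wa]) / tot            # P(W >= wa)
    p <- min(1, 2 * min(lo, hi))
  } else if (N <= exact_max) {
    combs <- utils::combn(N, na)
    sums <- colSums(matrix(r[combs], nrow = na))
    lo <- mean(sums <= wa + 1e-9)
    hi <- mean(sums >= wa - 1e-9)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- na * nb / 2
    tie_tab <- table(c(a, b))
    sig2 <- na * nb / 12 * (N + 1 - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sig2 <= 0) { p <- 1 } else {
      z <- (ua - mu) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(list(method = "Mann-Whitney U (exact two-sided)",
                 statistic = min(ua, ub), p_value = p,
                 groups = c(n_a = na, n_b = nb)),
            class = "nonparam_test")
}

#' Kruskal-Wallis H test (mid-ranks, tie-corrected)
#'
#' @param groups list of at least two numeric vectors (each n >= 2).
#' @return `nonparam_test` with the H statistic and the chi-square p-value
#'   (df = number of groups - 1). Identical values across all groups give
#'   H = 0, p = 1.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  Rj <- tapply(r, g, sum)
  nj <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tie_tab <- table(x)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (corr <= 0) { H <- 0; p <- 1 } else {
    H <- H / corr
    p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  }
  structure(list(method = "Kruskal-Wallis H", statistic = H, p_value = p,
                 groups = nj), class = "nonparam_test")
}

#' @export
print.nonparam_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Post hoc comparisons of each gastrocnemius sub-tendon against the soleus
#'
#' Pairwise exact Mann-Whitney tests of LG and MG against SOL for every
#' metric, flagged significant at the Bonferroni-style threshold
#' (0.05 / 3 rounded to 0.017 in the emulated analysis).
#'
#' @param records tibble in the layout of [read_specimen_table()].
#' @param threshold significance threshold on the exact two-sided p.
#' @return tibble with `metric`, `sub_tendon`, `p_value`, `significant`.
#' @export
posthoc_vs_soleus <- function(records, threshold = 0.017) {
  if (!"SOL" %in% records$sub_tendon) {
    warning("no soleus rows: post hoc comparisons skipped")
    return(tibble::tibble(metric = character(0), sub_tendon = character(0),
                          p_value = numeric(0), significant = logical(0)))
  }
  sol <- records[records$sub_tendon == "SOL", ]
  rows <- list()
  for (m in .metric_cols) {
    for (st in c("LG", "MG")) {
      if (!st %in% records$sub_tendon) next
      g <- records[records$sub_tendon == st, ]
      tst <- mann_whitney_exact(g[[m]], sol[[m]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metric = m, sub_tendon = st, p_value = tst$p_value,
        significant = tst$p_value < threshold)
    }
  }
  do.call(rbind, rows)
}
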