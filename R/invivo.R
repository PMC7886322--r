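# In vivo stimulation analysis: peak musculotendinous-junction (MTJ)
# displacement per contraction cycle, normalization by the contracted
# muscle's own displacement, group comparison, and the a priori sample-size
# computation.

#' Stimulation trial
#'
#' A pair of displacement traces recorded during cyclic electrical muscle
#' stimulation: the soleus MTJ trace (the outcome) and the contracted
#' muscle's reference trace (the normalizer).
#'
#' @param participant participant id.
#' @param group `"young"` or `"old"`.
#' @param muscle stimulated muscle (`"LG"`, `"MG"`, `"SOL"`).
#' @param time shared time base, s.
#' @param mtj soleus MTJ displacement, mm.
#' @param reference contracted-muscle displacement, mm.
#' @param onsets stimulation onset times, s.
#' @param on_duration on-phase duration, s (protocol: 4 s on / 4 s off).
#' @return a `stim_trial` object.
#' @export
stim_trial <- function(participant, group, muscle, time, mtj, reference,
                       onsets, on_duration = 4) {
  stopifnot(group %in% c("young", "old"), muscle %in% SUB_TENDONS,
            length(time) == length(mtj), length(time) == length(reference))
  complete <- sum(onsets + on_duration <= max(time) + 1e-9)
  if (complete < 1) stop("no complete stimulation cycle in trace")
  structure(list(participant = participant, group = group, muscle = muscle,
                 time = time, mtj = mtj, reference = reference,
                 onsets = onsets, on_duration = on_duration),
            class = "stim_trial")
}

#' Peak displacement per stimulation cycle (median across cycles)
#'
#' For each complete on-phase, the peak is the maximum displacement relative
#' to the immediately preceding baseline (median over the 0.5 s before
#' onset); the trial value is the median of the per-cycle peaks.
#'
#' @param time,disp trace vectors (s, mm).
#' @param onsets onset times, s.
#' @param on_duration on-phase duration, s.
#' @param baseline_window pre-onset window used for the baseline, s.
#' @return peak displacement, mm.
#' @export
peak_displacement <- function(time, disp, onsets, on_duration = 4,
                              baseline_window = 0.5) {
  complete <- onsets[onsets + on_duration <= max(time) + 1e-9]
  if (!length(complete)) stop("no complete stimulation cycle")
  peaks <- vapply(complete, function(t0) {
    pre <- disp[time >= t0 - baseline_window & time < t0]
    base <- if (length(pre)) stats::median(pre) else 0
    on <- disp[time >= t0 & time <= t0 + on_duration]
    max(on) - base
  }, numeric(1))
  stats::median(peaks)
}

#' Normalized soleus-junction displacement of a trial
#'
#' Peak soleus MTJ displacement divided by the peak displacement of the
#' contracted muscle itself, isolating the sliding-dependent part of the
#' junction motion from the stimulation intensity.
#'
#' @param trial a `stim_trial`.
#' @return dimensionless ratio (> 0 for valid trials).
#' @export
normalized_displacement <- function(trial) {
  stopifnot(inherits(trial, "stim_trial"))
  ref <- peak_displacement(trial$time, trial$reference, trial$onsets, trial$on_duration)
  if (ref <= 0) stop("zero or negative reference peak displacement")
  peak_displacement(trial$time, trial$mtj, trial$onsets, trial$on_duration) / ref
}

#' Cohort table of normalized displacements
#'
#' @param trials list of `stim_trial`s.
#' @return tibble with `participant`, `group`, `muscle`,
#'   `normalized_displacement`.
#' @export
cohort_record <- function(trials) {
  rows <- lapply(trials, function(tr) tibble::tibble(
    participant = tr$participant, group = tr$group, muscle = tr$muscle,
    normalized_displacement = normalized_displacement(tr)))
  do.call(rbind, rows)
}

#' Young-versus-old comparison for one stimulated muscle
#'
#' Exact two-sided Mann-Whitney test (shared implementation with the in
#' vitro analysis) on the normalized soleus-junction displacements.
#'
#' @param cohort tibble from [cohort_record()].
#' @param muscle stimulated muscle to compare.
#' @return a `nonparam_test`.
#' @export
compare_groups <- function(cohort, muscle) {
  sub <- cohort[cohort$muscle == muscle, ]
  a <- sub$normalized_displacement[sub$group == "young"]
  b <- sub$normalized_displacement[sub$group == "old"]
  if (!length(a) || !length(b)) stop("empty group for muscle ", muscle)
  mann_whitney_exact(a, b)
}

#' A priori sample size for a two-group t-test (noncentral t)
#'
#' Smallest per-group n (returned as total 2n) such that a two-sample
#' t-test at effect size d attains the requested power, evaluated with the
#' noncentral t distribution (noncentrality d * sqrt(n/2), df = 2n - 2);
#' no normal approximation.
#'
#' @param d Cohen's d effect size (> 0).
#' @param alpha significance level.
#' @param power target power.
#' @param tails 1 or 2.
#' @param n_max search cap on the per-group n.
#' @return total sample size (2n, equal groups).
#' @export
sample_size_two_group_t <- function(d, alpha = 0.05, power = 0.90, tails = 1,
                                    n_max = 1e6) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1, tails %in% c(1, 2))
  for (n in 2:n_max) {
    if (power_two_group_t(n, d, alpha, tails) >= power) return(2L * n)
  }
  stop("requested power unreachable within n <= ", n_max)
}

#' Power of the two-group t-test at per-group size n
#' @inheritParams sample_size_two_group_t
#' @param n per-group sample size (>= 2).
#' @return power under the noncentral t distribution.
#' @export
power_two_group_t <- function(n, d, alpha = 0.05, tails = 1) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- stats::qt(1 - alpha / tails, df)
  pw <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  if (tails == 2) pw <- pw + stats::pt(-crit, df, ncp = ncp)
  pw
}
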