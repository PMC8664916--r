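## Summary metrics over trajectory sets: carrier frequency, window of
## protection, elimination probability/time, rebound time.

## [days x nG] adult counts for one sex in one patch; rep = index or "mean"
sex_counts <- function(traj, sex = c("F", "M"), patch = 1L, rep = "mean") {
  sex <- match.arg(sex)
  pick <- function(run) if (sex == "F") run$female[, , patch] else run$male[, , patch]
  if (identical(rep, "mean")) {
    Reduce(`+`, lapply(traj$runs, pick)) / length(traj$runs)
  } else {
    pick(traj$runs[[rep]])
  }
}

#' Daily carrier frequency of an allele
#'
#' Fraction of adults of one sex (females by default) carrying at least one
#' copy of an allele, per day in one patch. Days with no such adults alive are
#' returned as `NA` (flagged missing rather than 0/0). By default the
#' frequency is computed on the across-repetition mean trajectory.
#'
#' @param traj A `trajectory_set`.
#' @param locus,allele Allele to count carriers of; defaults to the
#'   architecture's effector allele.
#' @param patch Patch index.
#' @param sex `"F"` (default) or `"M"`.
#' @param rep Repetition index, or `"mean"` for the mean trajectory.
#' @return Numeric vector of length `horizon + 1` (day 0 first).
#' @export
carrier_frequency <- function(traj, locus = NULL, allele = NULL, patch = 1L,
                              sex = "F", rep = "mean") {
  if (is.null(locus)) {
    if (is.null(traj$effector)) stop("architecture has no effector allele; give locus/allele")
    locus <- traj$effector$locus
    allele <- traj$effector$allele
  }
  if (!locus %in% names(traj$gset$map$loci)) stop("unknown locus: ", locus)
  if (!allele %in% traj$gset$map$loci[[locus]]$alleles)
    stop("unknown allele '", allele, "' at locus '", locus, "'")
  carrier <- has_allele(traj$gset, locus, allele)
  cnt <- sex_counts(traj, sex, patch, rep)
  tot <- rowSums(cnt)
  num <- rowSums(cnt[, carrier, drop = FALSE])
  ifelse(tot > 0, num / tot, NA_real_)
}

#' Window of protection
#'
#' Duration for which a daily frequency series stays at or above a threshold
#' (default 90%). Both the total number of days above threshold (the headline
#' value) and the longest contiguous run are reported.
#'
#' @param series Daily frequency series (NAs count as below threshold).
#' @param threshold Frequency threshold, default 0.90.
#' @return List with `days` (total days at or above threshold), `longest_run`,
#'   and `threshold`.
#' @export
window_of_protection <- function(series, threshold = 0.90) {
  if (length(series) == 0) stop("empty series")
  above <- !is.na(series) & series >= threshold
  runs <- rle(above)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(days = sum(above), longest_run = longest, threshold = threshold)
}

#' Elimination probability and time
#'
#' A repetition counts as eliminated when every life stage in the target patch
#' reaches zero (an absorbing state). Reports the fraction of repetitions
#' eliminated by the end of the horizon and, over eliminated repetitions, the
#' mean time from the final release to elimination in weeks.
#'
#' @param traj A `trajectory_set` (stochastic runs).
#' @param patch Patch index.
#' @param final_release_day Day of the final release (defaults to the value
#'   recorded in `traj`).
#' @return List with `probability`, `mean_weeks` (NA if no repetition was
#'   eliminated), and per-repetition elimination days (`NA` = not reached).
#' @export
elimination_stats <- function(traj, patch = 1L,
                              final_release_day = traj$final_release_day) {
  elim_day <- vapply(traj$runs, function(run) {
    tot <- rowSums(run$female[, , patch, drop = FALSE]) +
      rowSums(run$male[, , patch, drop = FALSE]) +
      run$juvenile[, patch]
    i <- which(tot == 0)
    if (length(i)) i[1] - 1 else NA_real_
  }, 0)
  p <- mean(!is.na(elim_day))
  mw <- if (any(!is.na(elim_day))) {
    mean(elim_day[!is.na(elim_day)] - final_release_day) / 7
  } else NA_real_
  list(probability = p, mean_weeks = mw, elimination_day = elim_day)
}

#' Rebound time after transient suppression
#'
#' First day at or after the post-release minimum of a total-population series
#' at which the series recovers to `fraction` of its baseline, reported in
#' weeks from the final release. A series that never drops below
#' `fraction * baseline` rebounds at 0 weeks; one that never recovers is
#' flagged `NA`.
#'
#' @param series Daily total counts (day 0 first).
#' @param baseline Pre-release population size (> 0).
#' @param fraction Recovery fraction of baseline, default 0.95.
#' @param final_release_day Day of the final release.
#' @return List with `weeks` (NA if no rebound) and `rebounded`.
#' @export
rebound_time <- function(series, baseline, fraction = 0.95,
                         final_release_day = 0L) {
  stopifnot(baseline > 0, length(series) >= 1)
  target <- fraction * baseline
  post <- series[(final_release_day + 1L):length(series)]  # day f.r.d. onward
  if (all(post >= target, na.rm = TRUE)) {
    return(list(weeks = 0, rebounded = TRUE))
  }
  i_min <- which.min(post)
  rec <- which(post >= target)
  rec <- rec[rec >= i_min]
  if (length(rec) == 0) return(list(weeks = NA_real_, rebounded = FALSE))
  list(weeks = (rec[1] - 1) / 7, rebounded = TRUE)
}

#' Standard metric report for a trajectory set
#'
#' Computes the modification metrics (window of protection on the effector
#' carrier frequency among females; maximum carrier frequency) per patch on
#' the mean trajectory, and the suppression metrics (elimination statistics in
#' the release patch; rebound of total females to a fraction of baseline).
#'
#' @param traj A `trajectory_set`.
#' @param threshold WoP frequency threshold (default 0.90).
#' @param rebound_fraction Rebound fraction of baseline (default 0.95).
#' @param release_patch Patch that received releases (default 1).
#' @return A `metric_report` list.
#' @export
metric_report <- function(traj, threshold = 0.90, rebound_fraction = 0.95,
                          release_patch = 1L) {
  np <- traj$n_patches
  wop <- vector("list", np)
  max_cf <- numeric(np)
  for (p in seq_len(np)) {
    cf <- carrier_frequency(traj, patch = p)
    wop[[p]] <- window_of_protection(cf, threshold)
    max_cf[p] <- if (all(is.na(cf))) NA_real_ else max(cf, na.rm = TRUE)
  }
  baseline <- traj$lh$n_eq / 2
  fem_tot <- rowSums(sex_counts(traj, "F", release_patch, "mean"))
  reb <- rebound_time(fem_tot, baseline, rebound_fraction,
                      traj$final_release_day)
  elim <- if (traj$stochastic) elimination_stats(traj, release_patch) else NULL
  structure(list(arch_name = traj$arch_name,
                 wop = wop, max_carrier_frequency = max_cf,
                 elimination = elim, rebound = reb,
                 threshold = threshold, rebound_fraction = rebound_fraction,
                 release_patch = release_patch, reps = traj$reps),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> ", x$arch_name, " (", x$reps, " reps)\n", sep = "")
  for (p in seq_along(x$wop)) {
    cat(sprintf("  patch %d: WoP %d days (longest run %d); max carrier freq %s\n",
                p, x$wop[[p]]$days, x$wop[[p]]$longest_run,
                format(round(x$max_carrier_frequency[p], 3))))
  }
  if (!is.null(x$elimination)) {
    cat(sprintf("  elimination: p = %.2f, mean %.1f weeks after final release\n",
                x$elimination$probability,
                if (is.na(x$elimination$mean_weeks)) NA else x$elimination$mean_weeks))
  }
  if (!is.null(x$rebound)) {
    cat("  rebound to ", 100 * x$rebound_fraction, "% baseline: ",
        if (x$rebound$rebounded) paste0(round(x$rebound$weeks, 1), " weeks")
        else "not reached", "\n", sep = "")
  }
  invisible(x)
}
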