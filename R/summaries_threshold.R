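#' Totals and percentages for a trapping-effort table
#'
#' Given per-group integer counts (one row per year and trap type), appends a
#' grand-total row and derives the percentage columns from each row's own
#' integers: percent of surveys with non-zero abundance and percent of
#' trapped mosquitoes that are female, rounded to one decimal (half away from
#' zero).
#'
#' @param groups data.frame with columns \code{year}, \code{trap_type},
#'   \code{n_traps}, \code{n_surveys}, \code{n_nonzero}, \code{n_mosquitoes},
#'   \code{n_females}; \code{n_traps_total} optionally gives the number of
#'   unique traps overall (trap sets may overlap across years).
#' @param n_traps_total unique traps across all groups; defaults to the sum.
#' @return data.frame with the group rows plus a \code{"Totals"} row and
#'   columns \code{pct_nonzero}, \code{pct_female}.
#' @export
effort_totals <- function(groups, n_traps_total = NULL) {
  need <- c("year", "trap_type", "n_traps", "n_surveys", "n_nonzero",
            "n_mosquitoes", "n_females")
  stopifnot(all(need %in% names(groups)))
  tot <- data.frame(
    year = "Totals", trap_type = "all",
    n_traps = if (is.null(n_traps_total)) sum(groups$n_traps)
              else n_traps_total,
    n_surveys = sum(groups$n_surveys),
    n_nonzero = sum(groups$n_nonzero),
    n_mosquitoes = sum(groups$n_mosquitoes),
    n_females = sum(groups$n_females)
  )
  out <- rbind(groups[, need], tot)
  out$pct_nonzero <- ifelse(out$n_surveys > 0,
    round_half_up(100 * out$n_nonzero / out$n_surveys, 1), NA_real_)
  out$pct_female <- ifelse(out$n_mosquitoes > 0,
    round_half_up(100 * out$n_females / out$n_mosquitoes, 1), NA_real_)
  out
}

#' Summarize trapping effort by year and trap type
#'
#' Computes, per year and trap type: distinct traps, surveys (trapping
#' events), surveys with non-zero abundance (at least one male or female),
#' total mosquitoes, females, and the derived percentages; plus a grand-total
#' row using the number of unique traps overall.  The share of events with at
#' least one female is attached as attribute \code{"pct_female_positive"}
#' (with the count in \code{"n_female_positive"}).
#'
#' @param events trap-event data.frame (\code{\link{read_traps}} schema).
#' @return data.frame as described for \code{\link{effort_totals}}.
#' @export
summarize_effort <- function(events) {
  year <- format(events$collection_date, "%Y")
  key <- paste(year, events$trap_type, sep = "|")
  groups <- lapply(sort(unique(key)), function(k) {
    i <- key == k
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(
      year = parts[1], trap_type = parts[2],
      n_traps = length(unique(events$trap_id[i])),
      n_surveys = sum(i),
      n_nonzero = sum(events$female_count[i] + events$male_count[i] >= 1),
      n_mosquitoes = sum(events$female_count[i] + events$male_count[i]),
      n_females = sum(events$female_count[i])
    )
  })
  groups <- do.call(rbind, groups)
  out <- effort_totals(groups,
                       n_traps_total = length(unique(events$trap_id)))
  n_fpos <- sum(events$female_count >= 1)
  attr(out, "n_female_positive") <- n_fpos
  attr(out, "pct_female_positive") <-
    round_half_up(100 * n_fpos / nrow(events), 1)
  out
}

#' Monthly distributions of non-zero female counts
#'
#' Pools events across years by calendar month (1--12) and returns, per
#' month, the multiset of non-zero female counts together with the number of
#' zero-count events.  No plotting: this is the numeric backing of a
#' log-scale monthly activity figure.
#'
#' @param events trap-event data.frame.
#' @return list with \code{nonzero} (list of 12 integer vectors) and
#'   \code{n_zero} (integer vector of length 12).
#' @export
monthly_activity <- function(events) {
  m <- as.integer(format(events$collection_date, "%m"))
  nonzero <- lapply(1:12, function(mo)
    sort(events$female_count[m == mo & events$female_count > 0]))
  names(nonzero) <- month.abb
  list(nonzero = nonzero,
       n_zero = vapply(1:12, function(mo)
         sum(m == mo & events$female_count == 0), integer(1)))
}

#' Low-precipitation threshold from the running maximum count
#'
#' Let \eqn{M(t)} be the maximum female count among events whose 20-day
#' cumulative precipitation is at most \eqn{t}.  Where additional
#' precipitation does not change this maximum, trap outcomes are
#' precipitation-independent; the threshold is the largest candidate
#' \eqn{t^*} such that \eqn{M(t)} stays constant (within a relative
#' tolerance) on \eqn{(0, t^*]}.  Mosquitoes trapped below the threshold must
#' have developed in anthropogenic water.
#'
#' @param lagmat lag matrix with \code{cum20} and \code{female_count}.
#' @param candidate_grid ascending candidate thresholds in inches (default
#'   0.01 to 0.50 by 0.01).
#' @param tolerance relative plateau tolerance on \eqn{M(t)} (default 0.05;
#'   0 demands exact equality).
#' @return list of class \code{threshold_result}: \code{threshold},
#'   \code{pct_events_below} (of all events), \code{pct_females_below} (of
#'   all trapped females), \code{max_count_below}, \code{tolerance}.
#' @export
find_low_precip_threshold <- function(lagmat,
                                      candidate_grid = seq(0.01, 0.50, by = 0.01),
                                      tolerance = 0.05) {
  stopifnot(length(candidate_grid) >= 1,
            !is.unsorted(candidate_grid), all(candidate_grid > 0))
  cum20 <- lagmat$cum20
  counts <- lagmat$female_count
  if (!any(cum20 <= candidate_grid[1]))
    stop("no events at or below the smallest candidate threshold")
  M <- vapply(candidate_grid, function(t) {
    below <- cum20 <= t
    if (!any(below)) NA_real_ else max(counts[below])
  }, numeric(1))
  M_base <- M[which(!is.na(M))[1]]
  flat <- !is.na(M) & abs(M - M_base) <= tolerance * max(M_base, 1)
  # the plateau must be an unbroken prefix of the grid
  upto <- which(!flat)[1]
  last_flat <- if (is.na(upto)) length(candidate_grid) else upto - 1L
  if (last_flat < 1)
    stop("running maximum is not flat at the smallest candidate")
  t_star <- candidate_grid[last_flat]
  below <- cum20 <= t_star
  structure(list(
    threshold = t_star,
    pct_events_below = 100 * sum(below) / length(below),
    pct_females_below = 100 * sum(counts[below]) / sum(counts),
    max_count_below = M[last_flat],
    tolerance = tolerance,
    n_events = length(below),
    n_events_below = sum(below)
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(paste0("low-precipitation threshold: %.2f in ",
                     "(%.1f%% of events, %.1f%% of females, max count %g)\n"),
              x$threshold, x$pct_events_below, x$pct_females_below,
              x$max_count_below))
  invisible(x)
}

#' Fraction of females trapped below a precipitation threshold
#'
#' The share of all trapped females caught in events whose 20-day cumulative
#' precipitation is at or below the threshold: a lower bound on the fraction
#' of the population supported by anthropogenic water rather than rain.
#'
#' @param lagmat lag matrix with \code{cum20} and \code{female_count}.
#' @param threshold inches (cum20 scale), e.g. from
#'   \code{\link{find_low_precip_threshold}}.
#' @return percent of total females (0--100).
#' @export
anthropogenic_fraction <- function(lagmat, threshold) {
  total <- sum(lagmat$female_count)
  if (total == 0) stop("no females trapped: fraction undefined")
  100 * sum(lagmat$female_count[lagmat$cum20 <= threshold]) / total
}
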