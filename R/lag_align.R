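#' Assemble a store of daily surfaces
#'
#' A surface store maps ISO dates to \code{precip_surface} objects.  It can be
#' built from a list of surfaces or a directory of files named
#' \code{precip_YYYY-MM-DD.csv} written by \code{\link{write_surface}}.
#'
#' @param surfaces list of \code{precip_surface} objects, or NULL.
#' @param dir directory containing surface files, or NULL.
#' @return named list keyed by \code{"YYYY-MM-DD"}.
#' @export
surface_store <- function(surfaces = NULL, dir = NULL) {
  if (is.null(surfaces) && is.null(dir))
    stop("provide surfaces or a directory")
  if (is.null(surfaces)) {
    files <- list.files(dir, pattern = "^precip_\\d{4}-\\d{2}-\\d{2}\\.csv$",
                        full.names = TRUE)
    surfaces <- lapply(files, read_surface)
  }
  names(surfaces) <- vapply(surfaces, function(s) format(s$date), character(1))
  surfaces
}

lag_days <- 20L

#' Extract a trap event's 20-day precipitation history
#'
#' Reads the cleaned surface value at the grid cell containing the trap for
#' each of the 20 days before the collection date (day k = collection date
#' minus k days; the collection day itself is not included), and computes the
#' 10- and 20-day cumulative sums.
#'
#' @param events trap-event data.frame (\code{\link{read_traps}} schema).
#' @param surfaces a \code{\link{surface_store}}.
#' @return data.frame with columns \code{trap_id}, \code{collection_date},
#'   \code{female_count}, \code{presence}, \code{lag1..lag20}, \code{cum10},
#'   \code{cum20}.
#' @export
extract_lags <- function(events, surfaces) {
  need <- unique(format(rep(events$collection_date, each = lag_days) -
                          rep(seq_len(lag_days), times = nrow(events))))
  missing <- setdiff(need, names(surfaces))
  if (length(missing))
    stop(sprintf("missing precipitation surface(s) for date(s): %s",
                 paste(sort(missing), collapse = ", ")))
  lags <- matrix(NA_real_, nrow(events), lag_days,
                 dimnames = list(NULL, paste0("lag", seq_len(lag_days))))
  for (k in seq_len(lag_days)) {
    dk <- format(events$collection_date - k)
    for (d in unique(dk)) {
      i <- which(dk == d)
      lags[i, k] <- clean_precip(
        surface_at(surfaces[[d]], events$lon[i], events$lat[i]))
    }
  }
  out <- data.frame(trap_id = events$trap_id,
                    collection_date = events$collection_date,
                    female_count = events$female_count,
                    presence = events$female_count >= 1)
  out <- cbind(out, as.data.frame(lags))
  out$cum10 <- rowSums(lags[, 1:10, drop = FALSE])
  out$cum20 <- rowSums(lags)
  out
}

#' Thin trapping events to one per trap per calendar month
#'
#' Repeated weekly sampling of the same trap makes consecutive 20-day
#' precipitation windows overlap, inducing artificial 7-day autocorrelation in
#' the lag matrix.  Thinning keeps the earliest-dated event of each
#' (trap, year-month) group, ties broken by trap id then input order, so the
#' result is deterministic and idempotent.
#'
#' @param rows data.frame carrying \code{trap_id} and \code{collection_date}.
#' @return the surviving subset, ordered by trap id and date.
#' @export
thin_events <- function(rows) {
  stopifnot(all(c("trap_id", "collection_date") %in% names(rows)))
  if (nrow(rows) == 0) return(rows)
  month <- format(rows$collection_date, "%Y-%m")
  ord <- order(rows$trap_id, month, rows$collection_date, seq_len(nrow(rows)))
  rows <- rows[ord, , drop = FALSE]
  keep <- !duplicated(paste(rows$trap_id, format(rows$collection_date, "%Y-%m")))
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rectangular analysis table of lag rows
#'
#' Validates completeness, drops rows with missing lag values (logging the
#' count), recomputes the cumulative columns, and returns rows in stable
#' (trap_id, date) order.
#'
#' @param rows output of \code{\link{extract_lags}} (thinned or not).
#' @return data.frame with columns \code{trap_id}, \code{collection_date},
#'   \code{presence}, \code{female_count}, \code{lag1..lag20}, \code{cum10},
#'   \code{cum20}.
#' @export
build_lag_matrix <- function(rows) {
  lag_cols <- paste0("lag", seq_len(lag_days))
  stopifnot(all(c("trap_id", "collection_date", "female_count", lag_cols)
                %in% names(rows)))
  complete <- stats::complete.cases(rows[, lag_cols, drop = FALSE])
  if (any(!complete))
    message(sprintf("build_lag_matrix: dropped %d row(s) with missing lags",
                    sum(!complete)))
  rows <- rows[complete, , drop = FALSE]
  rows <- rows[order(rows$trap_id, rows$collection_date), , drop = FALSE]
  lags <- as.matrix(rows[, lag_cols, drop = FALSE])
  out <- data.frame(trap_id = rows$trap_id,
                    collection_date = rows$collection_date,
                    presence = rows$female_count >= 1,
                    female_count = rows$female_count)
  out <- cbind(out, as.data.frame(lags))
  out$cum10 <- unname(rowSums(lags[, 1:10, drop = FALSE]))
  out$cum20 <- unname(rowSums(lags))
  rownames(out) <- NULL
  out
}
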