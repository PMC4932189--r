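#' Round an HPD interval to integer million-year bounds
#'
#' Both HPD bounds are rounded to the closest full million years. Ties (x.5)
#' round half away from zero, so ages of 0.5 and 3.5 Ma become 1 and 4; base
#' R's round-half-to-even is deliberately not used, because a fixed,
#' direction-free tie rule keeps slice assignment deterministic. Rounding is
#' monotone, so the young bound never overtakes the old one.
#'
#' @param hpd_old numeric vector of older HPD bounds (Ma).
#' @param hpd_young numeric vector of younger HPD bounds (Ma).
#' @return A data frame with integer columns `young` and `old`.
#' @examples
#' round_interval(2.4, 0.6)   # covers slices 1..2
#' round_interval(3.5, 0.5)   # half away from zero: 1..4
#' @export
round_interval <- function(hpd_old, hpd_young) {
  if (any(hpd_young > hpd_old)) {
    stop("hpd_young must not exceed hpd_old", call. = FALSE)
  }
  half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  data.frame(young = as.integer(half_away(hpd_young)),
             old = as.integer(half_away(hpd_old)))
}

new_mde_series <- function(age, value, stage, label = "pooled", n_events = NA_integer_,
                           t_max = max(age), window = NULL, truncation_age = NULL) {
  stopifnot(length(age) == length(value))
  structure(
    list(age = as.integer(age), value = as.numeric(value), stage = stage,
         label = label, n_events = n_events, t_max = as.integer(t_max),
         window = window, truncation_age = truncation_age),
    class = "mde_series"
  )
}

#' Compute the raw MDE series from an event table
#'
#' The MDE (maximal number of observed dispersal events per Myr) at integer
#' time point `t` is the number of events whose rounded HPD interval covers
#' `t`: with rounded bounds `(y, o)`, the event contributes to every slice
#' `y <= t <= o` (inclusive at both ends, so a point interval covers exactly
#' one slice). Events are summed over all datasets and treated as independent
#' even when several come from the same phylogeny. The analysis span is `0 ..
#' t_max` Ma; intervals straddling `t_max` are clipped, and events whose
#' rounded interval lies entirely above `t_max` are dropped with a warning.
#'
#' Because an event counts once per covered slice, absolute MDE values reflect
#' dating uncertainty and lineage sampling as much as true dispersal flux
#' (the "pull to the present"); downstream analysis therefore looks at shifts
#' in the series, not at absolute levels.
#'
#' @param table an `event_table`.
#' @param t_max integer, oldest slice of the analysis span in Ma (default 70).
#' @param label series label carried into outputs.
#' @return An `mde_series` with `stage = "raw"`: integer counts at ages
#'   `0, 1, ..., t_max`.
#' @examples
#' tab <- event_table(event_id = c("a", "b"), dataset_id = "d",
#'                    taxon_group = "plant", direction = "asia_to_india",
#'                    hpd_old_ma = c(5, 3), hpd_young_ma = c(0.2, 2))
#' compute_mde(tab, t_max = 10)$value
#' @export
compute_mde <- function(table, t_max = 70L, label = "pooled") {
  validate_events(table)
  t_max <- as.integer(t_max)
  if (t_max < 1L) stop("t_max must be >= 1", call. = FALSE)
  counts <- integer(t_max + 1L)
  n_used <- 0L
  if (nrow(table)) {
    b <- round_interval(table$hpd_old_ma, table$hpd_young_ma)
    above <- b$young > t_max
    if (any(above)) {
      warning(sprintf(
        "%d event(s) lie entirely above the %d Ma analysis span and were dropped: %s",
        sum(above), t_max,
        paste(table$event_id[above], collapse = ", ")), call. = FALSE)
    }
    y <- pmin(pmax(b$young[!above], 0L), t_max)
    o <- pmin(b$old[!above], t_max)
    n_used <- length(y)
    # difference-array accumulation: +1 at y, -1 after o, then cumsum
    if (n_used) {
      d <- integer(t_max + 2L)
      add <- tabulate(y + 1L, nbins = t_max + 1L)
      rem <- tabulate(o + 2L, nbins = t_max + 2L)
      d[seq_len(t_max + 1L)] <- add
      counts <- cumsum(d[seq_len(t_max + 1L)] - rem[seq_len(t_max + 1L)])
      # rem at position 1 is impossible (o >= y >= 0), kept for symmetry
    }
  }
  new_mde_series(age = 0:t_max, value = counts, stage = "raw", label = label,
                 n_events = n_used, t_max = t_max)
}

#' Smooth an MDE series with a centred sliding-window mean
#'
#' Replaces each value by the mean over a window of `window_myr` consecutive
#' slices centred on it; at the series ends the window truncates to the
#' available points. Smoothing damps slice-to-slice jitter that would
#' otherwise be over-read as distributional change. A window of 1 is the
#' identity; even windows are rejected because the centre is undefined.
#'
#' @param series an `mde_series`.
#' @param window_myr odd integer window width in Myr (default 5).
#' @return An `mde_series` with `stage = "smoothed"` (real-valued).
#' @export
smooth_series <- function(series, window_myr = 5L) {
  stopifnot(inherits(series, "mde_series"))
  w <- as.integer(window_myr)
  if (w < 1L || w %% 2L == 0L) {
    stop("window_myr must be an odd integer >= 1", call. = FALSE)
  }
  h <- (w - 1L) %/% 2L
  n <- length(series$value)
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    mean(series$value[lo:hi])
  }, numeric(1))
  out <- series
  out$value <- sm
  out$stage <- "smoothed"
  out$window <- w
  out
}

#' Age below which avian sampling bias dominates
#'
#' Dense avian phylogenies (sampled to subspecies) keep recording dispersal
#' events close to the present, while sparser non-avian phylogenies
#' increasingly miss young splits. The bias cutoff is the youngest age at
#' which the smoothed avian and non-avian MDE curves cross: walking from the
#' present towards the past, the first time point where the sign of
#' `avian - non_avian` differs from the previous (strictly younger) sign.
#' Where the two curves are exactly equal over a plateau, the crossing
#' resolves to the youngest point of the plateau. If the avian series never
#' exceeds the non-avian one, there is no crossing and 0 is returned (no
#' truncation needed).
#'
#' @param avian smoothed `mde_series` for birds.
#' @param non_avian smoothed `mde_series` pooled over all other taxa.
#' @return Integer age in Ma; 0 means no truncation.
#' @seealso [truncate_series()]
#' @export
avian_bias_cutoff <- function(avian, non_avian) {
  stopifnot(inherits(avian, "mde_series"), inherits(non_avian, "mde_series"))
  if (!identical(avian$age, non_avian$age)) {
    stop("avian and non-avian series are on different time grids", call. = FALSE)
  }
  if (!identical(avian$stage, "smoothed") || !identical(non_avian$stage, "smoothed")) {
    stop("bias cutoff is defined on smoothed series; smooth both first",
         call. = FALSE)
  }
  s <- sign(avian$value - non_avian$value)
  prev_sign <- 0
  plateau_start <- NA_integer_
  for (i in seq_along(s)) {
    if (s[i] == 0) {
      if (is.na(plateau_start)) plateau_start <- i
      next
    }
    if (prev_sign != 0 && s[i] != prev_sign) {
      cross <- if (!is.na(plateau_start)) plateau_start else i
      return(avian$age[cross])
    }
    prev_sign <- s[i]
    plateau_start <- NA_integer_
  }
  0L
}

#' Truncate an MDE series below a cutoff age
#'
#' Removes all values at ages younger than `cutoff` (the series then spans
#' `cutoff .. t_max`) and records the truncation age in the result. Applied to
#' every series entering change-point analysis once a bias cutoff has been
#' determined, so that the artefactual recent upswing cannot masquerade as a
#' distributional shift.
#'
#' @param series an `mde_series`.
#' @param cutoff integer age in Ma; 0 is the identity.
#' @return The truncated `mde_series` with `truncation_age` set.
#' @export
truncate_series <- function(series, cutoff) {
  stopifnot(inherits(series, "mde_series"))
  cutoff <- as.integer(cutoff)
  if (cutoff > series$t_max) {
    stop(sprintf("cutoff (%d Ma) exceeds the series span (t_max = %d Ma)",
                 cutoff, series$t_max), call. = FALSE)
  }
  if (cutoff <= min(series$age)) {
    out <- series
    out$truncation_age <- max(cutoff, series$truncation_age %||% 0L)
    return(out)
  }
  keep <- series$age >= cutoff
  out <- series
  out$age <- series$age[keep]
  out$value <- series$value[keep]
  out$truncation_age <- cutoff
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified MDE series
#'
#' One raw MDE series per stratum (dispersal direction or taxon group),
#' including empty strata, so that the pointwise sum over strata always equals
#' the pooled series from [compute_mde()] on the full table.
#'
#' @param table an `event_table`.
#' @param t_max oldest slice in Ma (default 70).
#' @param by `"direction"` or `"taxon_group"`.
#' @return Named list of raw `mde_series`, one per stratum level.
#' @export
stratified_mde <- function(table, t_max = 70L, by = c("direction", "taxon_group")) {
  by <- match.arg(by)
  validate_events(table)
  levels <- if (by == "direction") mde_directions() else mde_taxa()
  out <- lapply(levels, function(lv) {
    sub <- table[table[[by]] == lv, , drop = FALSE]
    rownames(sub) <- NULL
    sub <- structure(sub, class = c("event_table", "data.frame"))
    compute_mde(sub, t_max = t_max, label = lv)
  })
  names(out) <- levels
  out
}

#' @export
print.mde_series <- function(x, ...) {
  cat(sprintf("MDE series [%s, %s]: %d slices spanning %d-%d Ma\n",
              x$label, x$stage, length(x$age), min(x$age), max(x$age)))
  if (!is.null(x$window)) cat(sprintf("  smoothing window: %d Myr\n", x$window))
  if (!is.null(x$truncation_age) && x$truncation_age > 0) {
    cat(sprintf("  truncated below %d Ma (avian sampling bias)\n",
                x$truncation_age))
  }
  cat(sprintf("  values: min %.3g, max %.3g (peak at %d Ma)\n",
              min(x$value), max(x$value), x$age[which.max(x$value)]))
  invisible(x)
}

#' @export
as.data.frame.mde_series <- function(x, ...) {
  data.frame(t_ma = x$age, value = x$value, label = x$label, stage = x$stage,
             stringsAsFactors = FALSE)
}

#' Plot an MDE series
#'
#' Age runs right-to-left (palaeo convention: the present at the right edge).
#'
#' @param x an `mde_series`.
#' @param change_points optional numeric vector of change-point ages (Ma) to
#'   mark with arrowheads.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mde_series <- function(x, change_points = NULL, ...) {
  args <- list(...)
  defaults <- list(x = x$age, y = x$value, type = "l",
                   xlim = c(max(x$age), min(x$age)),
                   xlab = "Age (Ma)", ylab = "MDE (events / Myr)",
                   main = sprintf("%s (%s)", x$label, x$stage))
  do.call(graphics::plot, utils::modifyList(defaults, args))
  if (length(change_points)) {
    y_at <- x$value[match(round(change_points), x$age)]
    y_at[is.na(y_at)] <- max(x$value)
    graphics::points(change_points, y_at + 0.04 * diff(range(x$value, 0)),
                     pch = 25, bg = "black")
  }
  invisible(x)
}
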