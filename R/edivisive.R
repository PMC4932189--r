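#' E-divisive multiple change-point estimation
#'
#' Divisive hierarchical estimation of multiple change points in a
#' time-ordered series, with significance assessed by permutation. At each
#' step the algorithm finds, over all current segments, the split maximising
#' the scaled energy divergence \eqn{\hat Q} between the two parts (see
#' [energy_divergence()] and [best_split()]); the observed maximum is compared
#' against its permutation distribution, obtained by independently shuffling
#' observations *within* each current segment (never across — conditioning on
#' the change points already accepted) and recomputing the maximal split
#' statistic. If the permutation p-value, computed with the add-one estimator
#' \eqn{p = (1 + \#\{q_r \ge q_{obs}\})/(R + 1)} so it is never exactly zero,
#' is at most `sig_level`, the change point is accepted, the segment is split,
#' and the search repeats; otherwise estimation stops. Every reported change
#' point is therefore significant at `sig_level`, consecutive change points
#' are at least `min_size` observations apart, and none lies within `min_size`
#' of either series end.
#'
#' For an [mde_series()][compute_mde] input, observations are analysed from
#' oldest to youngest (70 Ma first) and each change point is reported as the
#' age of the first observation of the younger regime.
#'
#' @param x an `mde_series`, or a plain numeric vector of time-ordered
#'   observations (analysed in the order given).
#' @param R maximum number of random permutations per tested change point
#'   (default 500).
#' @param sig_level significance level for accepting a change point
#'   (default 0.05).
#' @param min_size minimum number of observations between change points
#'   (default 5); prevents excessive identification of small-scale changes.
#' @param alpha moment index of the energy divergence, in (0, 2] (default 1).
#' @param seed optional integer; when given, the RNG is seeded once and all
#'   permutation draws descend from it, making p-values bitwise reproducible.
#' @return An object of class `edivisive`: a list with
#'   \describe{
#'     \item{estimates}{data frame of accepted change points in detection
#'       order: `order`, `index` (1-based position of the first observation of
#'       the younger/right regime in analysis order), `age_ma` (`NA` for plain
#'       numeric input), `q_hat`, `p_value`.}
#'     \item{k}{number of change points found.}
#'     \item{params}{the parameters used.}
#'     \item{series}{the analysed observations, analysis order.}
#'     \item{ages}{ages (Ma) in analysis order, or `NULL`.}
#'     \item{stop_p}{p-value of the first rejected candidate (`NA` if the
#'       series ran out of admissible splits).}
#'   }
#' @examples
#' set.seed(1)
#' z <- c(rpois(20, 2), rpois(20, 9))
#' fit <- e_divisive(z, R = 199, seed = 42)
#' fit
#' @export
e_divisive <- function(x, R = 500L, sig_level = 0.05, min_size = 5L,
                       alpha = 1, seed = NULL) {
  R <- as.integer(R)
  min_size <- as.integer(min_size)
  if (R < 1L) stop("R must be >= 1", call. = FALSE)
  if (sig_level <= 0 || sig_level >= 1) {
    stop("sig_level must be in (0, 1)", call. = FALSE)
  }
  if (min_size < 2L) stop("min_size must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha > 2) stop("alpha must be in (0, 2]", call. = FALSE)

  label <- NULL
  ages <- NULL
  if (inherits(x, "mde_series")) {
    # oldest first: reverse the young-to-old storage order
    z <- rev(x$value)
    ages <- rev(x$age)
    label <- x$label
  } else {
    z <- as.numeric(x)
  }
  n <- length(z)
  if (n < 2L * min_size) {
    stop(sprintf("series of length %d is too short for min_size = %d (needs >= %d)",
                 n, min_size, 2L * min_size), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  D <- abs(outer(z, z, "-"))^alpha
  segs <- list(c(1L, n))
  est <- list()
  k <- 0L
  stop_p <- NA_real_

  repeat {
    cand <- .best_over_segments(segs, D, min_size)
    if (is.null(cand)) break
    exceed <- 0L
    for (r in seq_len(R)) {
      qmax <- -Inf
      for (s in segs) {
        len <- s[2] - s[1] + 1L
        if (len < 2L * min_size) next
        idx <- (s[1]:s[2])[sample.int(len)]
        q <- split_stats(D[idx, idx], min_size)
        qmax <- max(qmax, max(q))
      }
      if (qmax >= cand$q_hat) exceed <- exceed + 1L
    }
    p_val <- (1L + exceed) / (R + 1L)
    if (p_val > sig_level) {
      stop_p <- p_val
      break
    }
    k <- k + 1L
    cut <- cand$seg[1] + cand$kappa - 1L        # last index of the left part
    est[[k]] <- data.frame(
      order = k,
      index = cut + 1L,
      age_ma = if (is.null(ages)) NA_real_ else as.numeric(ages[cut + 1L]),
      q_hat = cand$q_hat,
      p_value = p_val
    )
    segs <- c(segs[vapply(segs, function(s) !identical(s, cand$seg), logical(1))],
              list(c(cand$seg[1], cut), c(cut + 1L, cand$seg[2])))
    segs <- segs[order(vapply(segs, `[`, integer(1), 1L))]
  }

  structure(list(
    estimates = if (k) do.call(rbind, est) else
      data.frame(order = integer(), index = integer(), age_ma = numeric(),
                 q_hat = numeric(), p_value = numeric()),
    k = k,
    params = list(R = R, sig_level = sig_level, min_size = min_size,
                  alpha = alpha, seed = seed),
    series = z, ages = ages, label = label, stop_p = stop_p
  ), class = "edivisive")
}

# Globally best admissible split over a segmentation. Ties across segments
# resolve to the earliest segment; within a segment, best_split's smallest-
# kappa rule applies. Returns NULL when no segment admits a split.
.best_over_segments <- function(segs, D, min_size) {
  best <- NULL
  for (s in segs) {
    len <- s[2] - s[1] + 1L
    if (len < 2L * min_size) next
    idx <- s[1]:s[2]
    q <- split_stats(D[idx, idx], min_size)
    kk <- which.max(q)
    if (is.finite(q[kk]) && (is.null(best) || q[kk] > best$q_hat)) {
      best <- list(seg = s, kappa = as.integer(kk), q_hat = q[kk])
    }
  }
  best
}

#' @export
print.edivisive <- function(x, ...) {
  cat("E-divisive change-point estimation\n")
  cat(sprintf("  %d observations%s; R = %d permutations, sig = %g, min_size = %d, alpha = %g\n",
              length(x$series),
              if (!is.null(x$ages))
                sprintf(" (%d-%d Ma, oldest first)", x$ages[1], x$ages[length(x$ages)])
              else "",
              x$params$R, x$params$sig_level, x$params$min_size, x$params$alpha))
  if (x$k == 0L) {
    cat("  no significant change points\n")
  } else {
    cat(sprintf("  %d change point(s):\n", x$k))
    print(x$estimates, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.edivisive <- function(object, ...) {
  seg_bounds <- sort(c(1L, object$estimates$index, length(object$series) + 1L))
  segs <- data.frame(
    from = seg_bounds[-length(seg_bounds)],
    to = seg_bounds[-1L] - 1L
  )
  segs$mean <- mapply(function(a, b) mean(object$series[a:b]), segs$from, segs$to)
  if (!is.null(object$ages)) {
    segs$from_ma <- object$ages[segs$from]
    segs$to_ma <- object$ages[segs$to]
  }
  out <- list(fit = object, segments = segs)
  class(out) <- "summary.edivisive"
  out
}

#' @export
print.summary.edivisive <- function(x, ...) {
  print(x$fit)
  cat("  segment means:\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Plot an e-divisive fit
#'
#' The analysed series with accepted change points marked by arrowheads and
#' dashed verticals. When the input carried ages, the x axis is age in Ma,
#' reversed so the present sits at the right.
#'
#' @param x an `edivisive` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.edivisive <- function(x, ...) {
  if (!is.null(x$ages)) {
    xx <- x$ages
    xlim <- c(max(xx), min(xx))
    xlab <- "Age (Ma)"
    cp <- x$estimates$age_ma
  } else {
    xx <- seq_along(x$series)
    xlim <- range(xx)
    xlab <- "Index"
    cp <- x$estimates$index
  }
  defaults <- list(x = xx, y = x$series, type = "l", xlim = xlim,
                   xlab = xlab, ylab = "Value",
                   main = x$label %||% "E-divisive segmentation")
  do.call(graphics::plot, utils::modifyList(defaults, list(...)))
  if (x$k) {
    graphics::abline(v = cp, lty = 2, col = "grey40")
    graphics::points(cp, rep(max(x$series), x$k) + 0.03 * diff(range(x$series)),
                     pch = 25, bg = "black")
  }
  invisible(x)
}
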