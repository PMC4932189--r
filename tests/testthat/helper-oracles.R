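# Independent brute-force oracles and random-table generators. These stay
# deliberately naive (double loops, direct formula evaluation) so they share
# no code path with the package implementation they check.

random_event_table <- function(n, t_span = 70) {
  young <- runif(n, 0, t_span)
  old <- young + rexp(n, rate = 0.5)
  event_table(
    event_id = sprintf("r%04d", seq_len(n)),
    dataset_id = sample(sprintf("ds%02d", 1:8), n, replace = TRUE),
    taxon_group = sample(mde_taxa(), n, replace = TRUE),
    direction = sample(mde_directions(), n, replace = TRUE),
    hpd_old_ma = old,
    hpd_young_ma = young
  )
}

# per-event, per-slice double loop; half-away-from-zero rounding written out
brute_mde <- function(table, t_max) {
  counts <- integer(t_max + 1L)
  rnd <- function(x) floor(x + 0.5)   # ages are non-negative
  for (i in seq_len(nrow(table))) {
    y <- rnd(table$hpd_young_ma[i])
    o <- rnd(table$hpd_old_ma[i])
    if (y > t_max) next
    for (t in 0:t_max) {
      if (t >= y && t <= min(o, t_max)) counts[t + 1L] <- counts[t + 1L] + 1L
    }
  }
  counts
}

# literal transcription of the sample divergence, scalar loops
naive_e_hat <- function(x, y, alpha) {
  n <- length(x); m <- length(y)
  b <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) b <- b + abs(x[i] - y[j])^alpha
  wx <- 0
  for (i in seq_len(n - 1)) for (k in (i + 1):n) wx <- wx + abs(x[i] - x[k])^alpha
  wy <- 0
  for (j in seq_len(m - 1)) for (l in (j + 1):m) wy <- wy + abs(y[j] - y[l])^alpha
  2 * b / (n * m) - wx / choose(n, 2) - wy / choose(m, 2)
}

naive_q_hat <- function(x, y, alpha) {
  n <- length(x); m <- length(y)
  (n * m / (n + m)) * naive_e_hat(x, y, alpha)
}

# exhaustive split search via direct divergence evaluation per kappa
naive_best_split <- function(z, min_size, alpha) {
  L <- length(z)
  if (L < 2 * min_size) return(NULL)
  best_k <- NA_integer_
  best_q <- -Inf
  for (k in min_size:(L - min_size)) {
    q <- naive_q_hat(z[1:k], z[(k + 1):L], alpha)
    if (q > best_q) {
      best_q <- q
      best_k <- k
    }
  }
  list(kappa = best_k, q_hat = best_q)
}

# independent divisive recursion sharing no code with e_divisive(); accepts a
# change point when the permutation p-value clears sig_level
naive_e_divisive <- function(z, R, sig_level, min_size, alpha, seed) {
  set.seed(seed)
  segs <- list(c(1L, length(z)))
  cps <- integer(0)
  repeat {
    best <- NULL
    for (s in segs) {
      part <- z[s[1]:s[2]]
      bs <- naive_best_split(part, min_size, alpha)
      if (!is.null(bs) && (is.null(best) || bs$q_hat > best$q)) {
        best <- list(seg = s, kappa = bs$kappa, q = bs$q_hat)
      }
    }
    if (is.null(best)) break
    exceed <- 0L
    for (r in seq_len(R)) {
      qmax <- -Inf
      for (s in segs) {
        part <- z[s[1]:s[2]]
        if (length(part) < 2 * min_size) next
        bs <- naive_best_split(sample(part), min_size, alpha)
        qmax <- max(qmax, bs$q_hat)
      }
      if (qmax >= best$q) exceed <- exceed + 1L
    }
    if ((1 + exceed) / (R + 1) > sig_level) break
    cut <- best$seg[1] + best$kappa - 1L
    cps <- c(cps, cut + 1L)
    segs <- c(segs[!vapply(segs, identical, logical(1), best$seg)],
              list(c(best$seg[1], cut), c(cut + 1L, best$seg[2])))
  }
  sort(cps)
}
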