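# Independent brute-force oracles used across the test files. These are
# deliberately written as literal index-by-index scans, separate from the
# package's run-length implementations.

# ---- literal sleep-rescoring oracle ------------------------------------

# stage 1: first minute of a sleep period preceded by 4 awake minutes
oracle_rule1 <- function(x, direction) {
  out <- x
  n <- length(x)
  for (i in seq_len(n)) {
    if (is.na(x[i]) || x[i] != 1L) next
    is_start <- i == 1L || is.na(x[i - 1L]) || x[i - 1L] != 1L
    if (!is_start || i < 5L) next
    prev <- x[(i - 4L):(i - 1L)]
    if (!anyNA(prev) && all(prev == 0L)) {
      out[i] <- if (direction == "webster") 0L else 1L
    }
  }
  out
}

# stage 2: after >= 10 awake minutes, up to 3 following sleep minutes
# become awake (single pass over the input snapshot)
oracle_rule2 <- function(x) {
  out <- x
  n <- length(x)
  run <- 0L
  for (i in seq_len(n)) {
    if (!is.na(x[i]) && x[i] == 0L) run <- run + 1L else run <- 0L
    if (run >= 10L) {
      j <- i + 1L
      k <- 0L
      while (k < 3L && j <= n && !is.na(x[j]) && x[j] == 1L) {
        out[j] <- 0L
        j <- j + 1L
        k <- k + 1L
      }
    }
  }
  out
}

# stages 3/4 and 5: short sleep period with long awake flanks both sides
oracle_isolated <- function(x, max_sleep, min_flank) {
  out <- x
  n <- length(x)
  i <- 1L
  while (i <= n) {
    if (!is.na(x[i]) && x[i] == 1L) {
      j <- i
      while (j < n && !is.na(x[j + 1L]) && x[j + 1L] == 1L) j <- j + 1L
      len <- j - i + 1L
      if (len <= max_sleep) {
        nb <- 0L
        k <- i - 1L
        while (k >= 1L && !is.na(x[k]) && x[k] == 0L) { nb <- nb + 1L; k <- k - 1L }
        na_ <- 0L
        k <- j + 1L
        while (k <= n && !is.na(x[k]) && x[k] == 0L) { na_ <- na_ + 1L; k <- k + 1L }
        if (nb >= min_flank && na_ >= min_flank && i > 1L && j < n) {
          out[i:j] <- 0L
        }
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

oracle_rescore <- function(x, direction = "as_printed") {
  x <- oracle_rule1(x, direction)
  x <- oracle_rule2(x)
  x <- oracle_isolated(x, 5L, 16L)
  oracle_isolated(x, 9L, 21L)
}

oracle_onset_offset <- function(x) {
  n <- length(x)
  onset <- offset <- NA_integer_
  for (i in seq_len(max(n - 9L, 0L))) {
    seg <- x[i:(i + 9L)]
    if (!anyNA(seg) && all(seg == 1L)) { onset <- i; break }
  }
  if (n >= 10L) for (i in seq(n - 9L, 1L)) {
    seg <- x[i:(i + 9L)]
    if (!anyNA(seg) && all(seg == 1L)) { offset <- i + 9L; break }
  }
  list(onset = onset, offset = offset, valid = !is.na(onset))
}

oracle_sleep_metrics <- function(x, onset, offset, long_episode_min = 5L) {
  seg <- x[onset:offset]
  tst <- 0L
  for (v in seg) if (!is.na(v) && v == 1L) tst <- tst + 1L
  n_awak <- n_long <- 0L
  run <- 0L
  for (v in c(seg, NA)) { # NA sentinel flushes the last run
    if (!is.na(v) && v == 0L) run <- run + 1L
    else {
      if (run >= 2L) n_awak <- n_awak + 1L
      if (run >= long_episode_min) n_long <- n_long + 1L
      run <- 0L
    }
  }
  list(tst = tst, n_awakenings = n_awak, n_long = n_long,
       sfi = if (tst > 0) n_awak / tst else NA_real_,
       se = 100 * tst / (offset - onset + 1L))
}

# ---- exhaustive signed-rank distribution (n <= 8) ----------------------

oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% rk
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# ---- Fisher exact p by explicit hypergeometric enumeration -------------

oracle_fisher_p <- function(tab) {
  stopifnot(dim(tab) == c(2L, 2L))
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  dens <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  obs <- dens[support == tab[1, 1]]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# ---- small cohort factories --------------------------------------------

tiny_day_cohort <- function(seed = 1L, n = 6L, days = 12L, ...) {
  generate_cohort(sim_config(n_participants = n, n_days = days, seed = seed,
                             level = "day", ...))
}

random_sleep_seq <- function(len, p_sleep = 0.5, p_na = 0) {
  x <- sample(c(0L, 1L), len, replace = TRUE, prob = c(1 - p_sleep, p_sleep))
  if (p_na > 0) x[runif(len) < p_na] <- NA_integer_
  x
}
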