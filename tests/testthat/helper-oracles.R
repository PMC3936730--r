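# Independent oracles, kept free of the package's implementation paths.

# Pearson chi-square on a 2x2 by the direct formula (expected counts from
# margins), df = 1.
oracle_chisq_2x2 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(stat = NA_real_, p = NA_real_))
  }
  e <- outer(rs, cs) / n
  stat <- sum((tab - e)^2 / e)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Conditional exact test by full enumeration with binomial coefficients
# (no dhyper): two-sided by summing table probabilities <= observed;
# mid-p counts ties at half weight.
oracle_exact_2x2 <- function(tab, midp = TRUE) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) {
    return(NA_real_)
  }
  xs <- max(0, k - n):min(k, m)
  pr <- vapply(xs, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, 0)
  p_obs <- pr[xs == tab[1, 1]]
  eps <- 1e-9 * p_obs
  if (midp) {
    min(1, sum(pr[pr < p_obs - eps]) + 0.5 * sum(pr[abs(pr - p_obs) <= eps]))
  } else {
    min(1, sum(pr[pr <= p_obs + eps]))
  }
}

# Brute-force CpG-rich region scan: naive per-window substring counting,
# overlap merge, CpG-end trimming, full re-check. Mirrors the documented
# definition with none of the cumulative-sum machinery.
oracle_cpg_scan <- function(seq, min_gc = 55, min_oe = 0.65, min_len = 500,
                            window = 200, step = 1) {
  L <- nchar(seq)
  win_stat <- function(s0, len) {          # s0 0-based
    sub <- substr(seq, s0 + 1, s0 + len)
    nC <- lengths(regmatches(sub, gregexpr("C", sub)))
    nG <- lengths(regmatches(sub, gregexpr("G", sub)))
    nCpG <- length(gregexpr("(?=CG)", sub, perl = TRUE)[[1]])
    if (identical(gregexpr("(?=CG)", sub, perl = TRUE)[[1]][1], -1L)) {
      nCpG <- 0L
    }
    gc <- 100 * (nC + nG) / len
    oe <- if (nC == 0 || nG == 0) 0 else nCpG * len / (nC * nG)
    c(gc = gc, oe = oe)
  }
  pass_starts <- integer(0)
  for (s0 in seq(0, L - window, by = step)) {
    st <- win_stat(s0, window)
    if (st["gc"] >= min_gc && st["oe"] >= min_oe) {
      pass_starts <- c(pass_starts, s0)
    }
  }
  if (length(pass_starts) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  # merge strictly overlapping windows
  regions <- list(c(pass_starts[1], pass_starts[1] + window))
  for (s0 in pass_starts[-1]) {
    last <- regions[[length(regions)]]
    if (s0 < last[2]) {
      regions[[length(regions)]] <- c(last[1], s0 + window)
    } else {
      regions[[length(regions) + 1L]] <- c(s0, s0 + window)
    }
  }
  out <- list()
  for (r in regions) {
    s0 <- r[1]; e0 <- r[2]
    sub <- substr(seq, s0 + 1, e0)
    hits <- gregexpr("(?=CG)", sub, perl = TRUE)[[1]]
    if (hits[1] != -1L) {
      s0n <- s0 + hits[1] - 1L
      e0 <- s0 + hits[length(hits)] - 1L + 2L
      s0 <- s0n
    }
    len <- e0 - s0
    st <- win_stat(s0, len)
    if (st["gc"] >= min_gc && st["oe"] >= min_oe && len >= min_len) {
      out[[length(out) + 1L]] <-
        data.frame(start = s0, end = e0, gc_pct = unname(st["gc"]),
                   obs_exp = unname(st["oe"]))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0))
}
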