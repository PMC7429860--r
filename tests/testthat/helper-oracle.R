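# Independent brute-force reference implementations used only as oracles.
# Deliberately naive: plain loops, log-factorial table probabilities,
# literal step-up FDR, literal scan-merge. Kept free of any code path from
# the package functions they check.

# two-sided Fisher p by enumerating every table with the observed margins,
# probability of each from log-factorials
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; N <- r1 + r2
  lprob <- function(x) {
    # table [x, r1-x; c1-x, r2-c1+x]
    (lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
       lfactorial(N) - lfactorial(x) - lfactorial(r1 - x) -
       lfactorial(c1 - x) - lfactorial(r2 - c1 + x))
  }
  xs <- max(0, c1 - r2):min(c1, r1)
  probs <- exp(vapply(xs, lprob, 0))
  pobs <- exp(lprob(a))
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# literal Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  prev <- 1
  for (i in m:1) {
    q_sorted[i] <- min(prev, m * p[o[i]] / i, 1)
    prev <- q_sorted[i]
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# naive full DMR caller: per-window loops end to end
oracle_call_dmrs <- function(winA, winB, thresholds) {
  nA <- nrow(winA)
  testable <- logical(nA)
  p <- rep(NA_real_, nA)
  for (i in seq_len(nA)) {
    ok <- (winA$n_sites_cov_k[i] >= thresholds$min_sites ||
             winB$n_sites_cov_k[i] >= thresholds$min_sites) &&
      winA$sum_total[i] >= 1 && winB$sum_total[i] >= 1
    testable[i] <- ok
    if (ok)
      p[i] <- oracle_fisher(winA$sum_meth[i], winA$sum_total[i] - winA$sum_meth[i],
                            winB$sum_meth[i], winB$sum_total[i] - winB$sum_meth[i])
  }
  q <- rep(NA_real_, nA)
  q[testable] <- oracle_bh(p[testable])
  delta <- winB$level - winA$level
  ctx <- winA$context[1]
  thr <- thresholds$delta[[ctx]]
  sel <- which(testable & !is.na(q) & q < thresholds$fdr & abs(delta) >= thr)
  if (length(sel) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), direction = character(),
                      n_windows = integer(), delta = numeric(), q = numeric()))
  recs <- list()
  for (dirn in c("hyper_in_B", "hypo_in_B")) {
    ii <- sel[if (dirn == "hyper_in_B") delta[sel] > 0 else delta[sel] < 0]
    if (length(ii) == 0L) next
    ii <- ii[order(winA$chrom[ii], winA$start[ii])]
    runs <- list(ii[1])
    for (k in ii[-1]) {
      lastrun <- runs[[length(runs)]]
      last <- lastrun[length(lastrun)]
      if (winA$chrom[k] == winA$chrom[last] &&
          winA$start[k] - winA$end[last] <= thresholds$merge_gap) {
        runs[[length(runs)]] <- c(lastrun, k)
      } else {
        runs[[length(runs) + 1L]] <- k
      }
    }
    for (r in runs) {
      s <- winA$start[r[1]]; e <- winA$end[r[length(r)]]
      cn <- winA$chrom[r[1]]
      memb <- which(winA$chrom == cn & winA$start < e & winA$end > s)
      lA <- sum(winA$sum_meth[memb]) / sum(winA$sum_total[memb])
      lB <- sum(winB$sum_meth[memb]) / sum(winB$sum_total[memb])
      recs[[length(recs) + 1L]] <- data.table(
        chrom = cn, start = s, end = e, context = ctx, direction = dirn,
        n_windows = length(r), delta = lB - lA, q = min(q[r]))
    }
  }
  out <- rbindlist(recs)
  setorder(out, chrom, start)
  out[]
}
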