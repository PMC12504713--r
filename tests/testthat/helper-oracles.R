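# Brute-force oracles shared across test files: independent re-computations
# of statistics the package implements in closed form.

brute_force_cindex <- function(lp, time, event) {
  num <- den <- 0
  n <- length(lp)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    # comparable: the earlier time is an observed event
    ti <- time[i]; tj <- time[j]
    if (ti == tj && event[i] && event[j]) next  # tied event times: not comparable
    first <- if (ti < tj) i else j
    second <- if (ti < tj) j else i
    if (ti == tj) {
      if (!event[i] && !event[j]) next
      first <- if (event[i]) i else j
      second <- if (first == i) j else i
    }
    if (!event[first]) next
    den <- den + 1
    if (lp[first] > lp[second]) num <- num + 1
    else if (lp[first] == lp[second]) num <- num + 0.5
  }
  num / den
}


# Brute-force kappa: expand each row into rater labels and count agreeing
# pairs explicitly — an independent path to the closed-form statistic.
brute_force_kappa <- function(tab) {
  n <- sum(tab[1, ])
  pair_agreement <- apply(tab, 1, function(row) {
    labels <- rep(seq_along(row), row)
    pairs <- combn(n, 2)
    mean(labels[pairs[1, ]] == labels[pairs[2, ]])
  })
  P_bar <- mean(pair_agreement)
  p_j <- colSums(tab) / (nrow(tab) * n)
  Pe <- sum(p_j^2)
  (P_bar - Pe) / (1 - Pe)
}


# Step-up BH by direct enumeration: find the largest i with
# p_(i) <= i * alpha / m, reject everything at or below it.
brute_force_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * alpha / m)
  rejected <- logical(m)
  if (length(ok)) rejected[o[seq_len(max(ok))]] <- TRUE
  rejected
}

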