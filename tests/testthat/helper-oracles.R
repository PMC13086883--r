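# independent brute-force oracles shared across test files

auc_all_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

youden_scan <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best_j <- -Inf; best_t <- NA
  for (t in cand) {
    j <- mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  list(threshold = best_t, youden_j = best_j)
}

cindex_brute <- function(lp, times, events) {
  num <- 0; den <- 0
  n <- length(lp)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (events[i] != 1) next
    comparable <- times[j] > times[i] ||
      (times[j] == times[i] && events[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (lp[i] > lp[j]) num <- num + 1
    else if (lp[i] == lp[j]) num <- num + 0.5
  }
  num / den
}
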