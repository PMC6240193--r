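# Independent metric oracles used by the unit and acceptance tests.

# Brute-force O(n^2) pair-counting AUC oracle (ties count one half).
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exact strip-wise partial-AUC oracle for distinct scores: the ROC is a step
# function, so the area over FPR in ((j-1)/nn, j/nn) is the fraction of
# positives scoring above the j-th highest negative.
pauc_strips <- function(scores, labels, max_fpr = 0.1) {
  neg <- sort(scores[labels == 0], decreasing = TRUE)
  pos <- scores[labels == 1]
  nn <- length(neg)
  nstrips <- round(max_fpr * nn)
  stopifnot(abs(nstrips - max_fpr * nn) < 1e-9)  # exact strips only
  area <- 0
  for (j in seq_len(nstrips))
    area <- area + (1 / nn) * mean(pos > neg[j])
  area / max_fpr
}
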