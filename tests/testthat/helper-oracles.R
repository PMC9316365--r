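# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and closed forms only.

# all-pairs heavy-atom distance enumeration for interface labels
oracle_interface_labels <- function(structure, query_chain, partner_chains,
                                    cutoff = 4.0) {
  st <- structure[structure$element != "H", ]
  q <- st[st$chain == query_chain, ]
  p <- st[st$chain %in% partner_chains, ]
  res <- unique(paste(q$chain, q$resno, q$icode))
  labels <- integer(length(res))
  for (k in seq_along(res)) {
    qa <- q[paste(q$chain, q$resno, q$icode) == res[k], ]
    hit <- FALSE
    for (i in seq_len(nrow(qa))) {
      for (j in seq_len(nrow(p))) {
        d <- sqrt((qa$x[i] - p$x[j])^2 + (qa$y[i] - p$y[j])^2 +
                    (qa$z[i] - p$z[j])^2)
        if (d <= cutoff) { hit <- TRUE; break }
      }
      if (hit) break
    }
    labels[k] <- as.integer(hit)
  }
  labels
}

# exhaustive per-residue confusion tally
oracle_confusion <- function(calls, labels) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(calls)) {
    if (calls[i] == 1 && labels[i] == 1) tp <- tp + 1L
    else if (calls[i] == 1 && labels[i] == 0) fp <- fp + 1L
    else if (calls[i] == 0 && labels[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# metric formulas evaluated directly from counts
oracle_metrics <- function(tp, fp, fn, tn) {
  sdiv <- function(a, b) if (b == 0) 0 else a / b
  precision <- sdiv(tp, tp + fp)
  recall <- sdiv(tp, tp + fn)
  f <- sdiv(2 * precision * recall, precision + recall)
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
  c(precision = precision, recall = recall, f_score = f, mcc = mcc)
}

# Mann-Whitney rank statistic U / (n+ n-), ties counted half
oracle_auc_mw <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  r <- rank(scores)  # midranks
  u <- sum(r[labels == 1]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

# exhaustive pairwise version of the same statistic (small n only)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# brute-force two-sample KS D: sup of ECDF differences over all points
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  d <- 0
  for (x in pts) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# XOR-style interaction dataset: neither predictor is informative alone,
# their interaction is
make_interaction_table <- function(n, seed) {
  set.seed(seed)
  x1 <- runif(n); x2 <- runif(n)
  p <- ifelse(xor(x1 > 0.5, x2 > 0.5), 0.85, 0.10)
  tibble::tibble(protein_id = "pool", chain = "A", resno = seq_len(n),
                 icode = "", f1 = x1, f2 = x2,
                 label = rbinom(n, 1, p), R = n %/% 2L)
}
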