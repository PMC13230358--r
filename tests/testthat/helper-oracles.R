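# Independent brute-force oracles, written term-by-term from the
# definitions; deliberately naive (loops, O(n^2) pair counts) and kept
# separate from the package's implementations.

oracle_weights <- function(bacc) {
  m <- length(bacc)
  r <- integer(m)
  ord <- order(bacc, seq_len(m)) # ascending, earlier position wins ties
  for (i in seq_len(m)) r[ord[i]] <- i
  beta <- min(bacc)
  alpha <- numeric(m)
  for (j in seq_len(m)) alpha[j] <- (bacc[j] - beta + 1) * r[j]^2
  list(rank = r, beta = beta, alpha = alpha, w = alpha / sum(alpha))
}

oracle_bacc <- function(y, yhat, K) {
  rec <- numeric(K)
  for (k in 0:(K - 1)) {
    idx <- y == k
    rec[k + 1] <- sum(yhat[idx] == k) / sum(idx)
  }
  mean(rec)
}

oracle_ovr <- function(y, yhat, K) {
  n <- length(y)
  prec <- rec <- spec <- f1 <- wt <- numeric(K)
  for (k in 0:(K - 1)) {
    tp <- sum(y == k & yhat == k)
    fp <- sum(y != k & yhat == k)
    fn <- sum(y == k & yhat != k)
    tn <- n - tp - fp - fn
    i <- k + 1
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- tp / (tp + fn)
    spec[i] <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
    wt[i] <- sum(y == k) / n
  }
  list(precision = sum(wt * prec), recall = sum(wt * rec),
       specificity = sum(wt * spec), f1 = sum(wt * f1))
}

# Directed AUC by explicit positive/negative pair counting, ties 1/2.
oracle_auc_binary <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

oracle_auc_ovo <- function(probs, y) {
  K <- ncol(probs)
  vals <- c()
  for (a in 0:(K - 2)) for (b in (a + 1):(K - 1)) {
    keep <- y == a | y == b
    if (!any(y == a) || !any(y == b)) next
    ab <- oracle_auc_binary(probs[keep, a + 1], y[keep] == a)
    ba <- oracle_auc_binary(probs[keep, b + 1], y[keep] == b)
    vals <- c(vals, (ab + ba) / 2)
  }
  mean(vals)
}

# Per-bin loop ECE on fixed equal-width bins; last bin right-closed.
oracle_ece_fixed <- function(conf, correct, n_bins) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  n <- length(conf)
  total <- 0
  for (b in seq_len(n_bins)) {
    if (b < n_bins) {
      in_b <- conf >= edges[b] & conf < edges[b + 1]
    } else {
      in_b <- conf >= edges[b] & conf <= edges[b + 1]
    }
    if (any(in_b)) {
      total <- total + (sum(in_b) / n) *
        abs(mean(correct[in_b]) - mean(conf[in_b]))
    }
  }
  total
}

# Random valid prediction set + matching truth, for property loops.
rand_instance <- function(n, K, class_names = LETTERS[seq_len(K)]) {
  probs <- matrix(stats::rexp(n * K), n, K)
  probs <- probs / rowSums(probs)
  df <- as.data.frame(probs)
  names(df) <- class_names
  df <- cbind(data.frame(sample_id = sprintf("s%03d", seq_len(n))), df)
  list(
    ps = prediction_set(df),
    truth = label_set(df$sample_id, sample(0:(K - 1), n, replace = TRUE),
                      class_names)
  )
}

# Truth containing every class at least once.
rand_instance_full <- function(n, K, class_names = LETTERS[seq_len(K)]) {
  stopifnot(n >= K)
  inst <- rand_instance(n, K, class_names)
  y <- c(0:(K - 1), sample(0:(K - 1), n - K, replace = TRUE))
  inst$truth <- label_set(inst$truth$sample_id, sample(y), class_names)
  inst
}

toy_pred_set <- function(probs, class_names = LETTERS[seq_len(ncol(probs))]) {
  df <- as.data.frame(probs)
  names(df) <- class_names
  df <- cbind(data.frame(sample_id = sprintf("s%02d", seq_len(nrow(probs)))),
              df)
  prediction_set(df)
}
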