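# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# ROC AUC by brute-force pair counting (Mann-Whitney, ties counted one half)
oracle_roc_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# PR AUC by an independent threshold sweep + trapezoid over recall
oracle_pr_auc <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  rec <- prec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- scores >= ths[i]
    rec[i] <- sum(pred & labels == 1) / P
    prec[i] <- sum(pred & labels == 1) / sum(pred)
  }
  rec <- c(0, rec); prec <- c(prec[1], prec)
  sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
}

# Exact Shapley values by direct enumeration over all coalitions, for an
# arbitrary value function v(S) given as a function of an index vector.
oracle_shapley <- function(p, v) {
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1), function(code) which(bitwAnd(code, 2^(0:(p - 1))) > 0))
  for (i in seq_len(p)) {
    for (S in subsets) {
      if (i %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[i] <- phi[i] + w * (v(sort(c(S, i))) - v(S))
    }
  }
  phi
}

# A small labeled table with hand-set values, used by I/O and direction tests
tiny_table <- function() {
  tibble::tibble(
    subject_id = c("s1", "s2", "s3", "s4"),
    label = c(1L, 1L, 0L, 0L),
    f1 = c(2.0, 2.2, 1.0, 1.1),
    f2 = c(0.5, NA, 0.7, 0.9)
  )
}

# XOR-style dataset: the label is the sign of the product of two latent
# features; linear models cannot separate it, a one-hidden-layer MLP can.
xor_dataset <- function(n = 80, p_noise = 8, seed = 1) {
  withr::with_seed(seed, {
    x1 <- rnorm(n, rep(c(-1, 1, -1, 1), length.out = n), 0.25)
    x2 <- rnorm(n, rep(c(-1, -1, 1, 1), length.out = n), 0.25)
    y <- as.integer(x1 * x2 > 0)
    noise <- matrix(rnorm(n * p_noise), n, p_noise)
    tbl <- tibble::as_tibble(
      `colnames<-`(cbind(x1, x2, noise),
                   c("x1", "x2", sprintf("n%02d", seq_len(p_noise))))
    )
    dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("s%03d", seq_len(n)), label = y),
      tbl
    )
  })
}
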