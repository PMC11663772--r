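# Small in-code fixtures shared across tests.

# two-group Gaussian table with a planted standardized shift on `planted`
make_two_group <- function(n1, n2, p, d = 0, planted = integer(0), seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p,
              dimnames = list(NULL, sprintf("e%03d", seq_len(p))))
  if (length(planted))
    X[(n1 + 1):(n1 + n2), planted] <- X[(n1 + 1):(n1 + n2), planted] + d
  list(X = X, y = factor(rep(c("A", "B"), c(n1, n2))))
}

# coherence_map built directly from matrices, for cluster/lead unit tests
make_map <- function(coh, phase, mask = NULL, threshold = 0.7) {
  nr <- nrow(coh); nc <- ncol(coh)
  if (is.null(mask)) mask <- coh >= threshold
  structure(list(coh = coh, phase = phase, mask = mask,
                 in_coi = matrix(TRUE, nr, nc), scales = seq_len(nr),
                 periods = seq_len(nr), times = seq_len(nc) - 1,
                 coi = rep(nr, nc), threshold = threshold,
                 pair = c("x", "y")),
            class = "coherence_map")
}

# brute-force AUC by pair counting (independent oracle)
auc_brute <- function(scores, labels) {
  pos <- which(labels); neg <- which(!labels)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# independently coded greedy MRMR (relevance = point-biserial |cor|,
# redundancy = mean |cor| with the chosen set)
mrmr_oracle <- function(X, y01) {
  p <- ncol(X)
  rel <- abs(apply(X, 2, function(x) suppressWarnings(cor(x, y01))))
  rel[is.na(rel)] <- 0
  chosen <- integer(0)
  while (length(chosen) < p) {
    cand <- setdiff(seq_len(p), chosen)
    obj <- vapply(cand, function(j) {
      red <- if (!length(chosen)) 0
             else mean(abs(vapply(chosen, function(s) {
               r <- suppressWarnings(cor(X[, j], X[, s]))
               if (is.na(r)) 0 else r
             }, numeric(1))))
      rel[j] - red
    }, numeric(1))
    chosen <- c(chosen, cand[which.max(obj)])
  }
  chosen
}

# definitional Benjamini-Hochberg rejections at level alpha
bh_brute <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}
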