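# Independent oracles for the property tests.  These deliberately do not
# share code paths with the package: tree evaluation is a scalar recursive
# descent (the package uses a vectorized stack machine), and confusion
# counting is a per-sample loop.

# Evaluate a prefix-encoded program on a single feature vector by plain
# recursion, with the documented conventions: protected division
# (|b| < 1e-9 -> 1) and node outputs clamped to +/- 1e150.
naive_eval_code <- function(code, x) {
  rec <- function(i) {
    c0 <- code[i]
    if (c0 > 0) return(list(v = x[c0], nxt = i + 1L))
    l <- rec(i + 1L)
    r <- rec(l$nxt)
    v <- switch(-c0,
                l$v + r$v,
                l$v - r$v,
                l$v * r$v,
                if (abs(r$v) < 1e-9) 1 else l$v / r$v)
    list(v = max(-1e150, min(1e150, v)), nxt = r$nxt)
  }
  rec(1L)$v
}

# per-sample counting loop
naive_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1L && truth[i] == 1L) tp <- tp + 1L
    else if (pred[i] == 0L && truth[i] == 0L) tn <- tn + 1L
    else if (pred[i] == 1L && truth[i] == 0L) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# random 0/1 prediction/truth pair guaranteed non-degenerate (both vectors
# contain both values, so the Pearson correlation is defined)
random_binary_pair <- function(n) {
  repeat {
    truth <- rbinom(n, 1L, runif(1, 0.2, 0.8))
    pred <- ifelse(runif(n) < runif(1, 0.1, 0.9), truth, 1L - truth)
    if (length(unique(truth)) == 2L && length(unique(pred)) == 2L)
      return(list(pred = as.integer(pred), truth = as.integer(truth)))
  }
}
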