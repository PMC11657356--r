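# Shared fixtures: everything is generated in code at test time.

tiny_spec <- function(size = 32L) phantom_spec(image_size = size)

tiny_dataset <- function(n_per_class = rep(4L, 5), size = 32L, seed = 5L) {
  synth_dataset(n_per_class, tiny_spec(size), seed = seed)
}

tiny_model_cfg <- function(size = 16L) {
  dms_config(scales = c(1L, 3L), growth_rate = 2L, layers_per_block = 2L,
             num_blocks = 2L, stem_channels = 3L, input_size = size)
}

# Brute-force metric oracles: straight tallies and pairwise enumeration,
# sharing no code with the package implementations.
oracle_confusion <- function(true, pred, K) {
  cm <- matrix(0L, K, K)
  for (i in seq_along(true)) {
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  }
  cm
}

oracle_binary_counts <- function(true, pred, k) {
  list(TP = sum(true == k & pred == k), FP = sum(true != k & pred == k),
       FN = sum(true == k & pred != k), TN = sum(true != k & pred != k))
}

# AUC as the probability-of-correct-ranking statistic, half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
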