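# Shared fixtures and independent oracles.

# Small simulated study, cached per (seed, config label) for the test session.
.sim_cache <- new.env(parent = emptyenv())
tiny_sim <- function(seed = 1, ...) {
  key <- paste0("s", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (!exists(key, .sim_cache)) {
    assign(key, simulate_study(
      n_cells = 60, n_genes = 300, n_patterns = 6, n_markers = 8,
      depth = 2e5, upstream_len = 900, n_decoys = 6, seed = seed, ...
    ), .sim_cache)
  }
  get(key, .sim_cache)
}

# Benjamini-Hochberg step-up, written independently of p.adjust: sort
# descending, q_(i) = min(q_(i+1), p_(i) * m / rank_i).
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  prev <- 1
  for (i in seq_along(ord)) {
    rank <- m - i + 1
    prev <- min(prev, p[ord[i]] * m / rank)
    q[ord[i]] <- prev
  }
  q
}

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws.
hyper_oracle <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Null tail probabilities of a PWM's quantized score by enumerating all 4^L
# words (uniform background).
pwm_enum_tail <- function(pwm, score_int, floor = 1e-3, n_bins = 1e4) {
  lo <- popseq:::pwm_log_odds(pwm, floor)
  q <- popseq:::pwm_quantize(lo, n_bins)$q
  L <- ncol(q)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  tot <- integer(nrow(words))
  for (j in seq_len(L)) tot <- tot + q[cbind(words[, j], j)]
  vapply(score_int, function(s) mean(tot >= s), 0)
}

# quantized score of a specific word under a PWM
pwm_word_score <- function(pwm, word, floor = 1e-3, n_bins = 1e4) {
  lo <- popseq:::pwm_log_odds(pwm, floor)
  q <- popseq:::pwm_quantize(lo, n_bins)$q
  idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  sum(q[cbind(idx, seq_along(idx))])
}

expect_invalid <- function(expr) {
  testthat::expect_error(expr, class = "popseq_invalid_argument")
}
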