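# independent exhaustive-search oracle for the Otsu threshold: enumerate all
# 256 candidate splits and compute the between-class variance from direct
# per-class sums (no cumulative-histogram shortcuts)
otsu_exhaustive <- function(g) {
  v <- as.vector(g)
  best_t <- NA_integer_; best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    s <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  best_t
}
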