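# Shared fixtures: everything is generated in code at test time.

small_preset <- function(...) filament_preset(n_veg = 3, ...)

# a quiet phantom with no clusters at all
flat_preset <- function(...) {
  filament_preset(n_veg = 3, pk_count_range = c(0, 0),
                  ca_only_range = c(0, 0), fe_only_range = c(0, 0), ...)
}

# pixel matrix helper for toy masks
px_mat <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("row", "col")
  m
}

mask_from_px <- function(px, rows, cols) {
  m <- matrix(FALSE, rows, cols)
  m[px] <- TRUE
  m
}

# independent within-class SSE of a 1-D two-way split, for oracle comparison
split_sse <- function(v, lower_idx) {
  s <- sort(v)
  a <- s[seq_len(lower_idx)]
  b <- s[-seq_len(lower_idx)]
  sum((a - mean(a))^2) + sum((b - mean(b))^2)
}

best_split_sse <- function(v) {
  min(vapply(seq_len(length(v) - 1), function(i) split_sse(v, i), numeric(1)))
}

# Jaccard of two logical masks
jaccard <- function(a, b) sum(a & b) / sum(a | b)
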