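# independent brute-force oracles used to cross-check the implementation

# per-pixel loop over the masked coordinate list
oracle_pixel_summary <- function(image, mask) {
  idx <- which(mask, arr.ind = TRUE)
  vals <- numeric(nrow(idx))
  hist <- integer(256)
  for (i in seq_len(nrow(idx))) {
    v <- image[idx[i, 1], idx[i, 2]]
    vals[i] <- v
    hist[v + 1L] <- hist[v + 1L] + 1L
  }
  list(n = length(vals), mean = sum(vals) / length(vals),
       sd = if (length(vals) > 1) sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1)) else NA_real_,
       min = min(vals), max = max(vals), hist = hist)
}

# rank-sum H with the standard tie correction, written from the formula
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)  # mid-ranks
  rs <- tapply(r, g, sum)
  n_j <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(rs^2 / n_j) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# a small merged analysis table from the generator (shared fixture builder)
make_merged <- function(params) {
  g <- generate_thermal_observations(params)
  assemble_dataset(g$observations, g$covariates)
}
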