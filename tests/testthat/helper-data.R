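# Shared fixtures and independent oracles for the test suite.

# All 4^6 = 4096 hexamers, for exhaustive enumeration oracles.
all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  apply(g, 1, paste, collapse = "")
}

# Brute-force PWM score: per-position lookup and sum, written independently
# of score_hexamer().
oracle_score <- function(weights, hexamer) {
  bases <- strsplit(hexamer, "")[[1]]
  total <- 0
  for (i in 1:6)
    total <- total + weights[i, bases[i]]
  total
}

# Brute-force p-value: enumerate every hexamer, its exact background
# probability and score, and sum the mass at or above the threshold.
oracle_pvalue <- function(weights, background, threshold) {
  hx <- all_hexamers()
  scores <- vapply(hx, function(h) oracle_score(weights, h), numeric(1))
  probs <- vapply(hx, function(h) {
    prod(unclass(background)[strsplit(h, "")[[1]]])
  }, numeric(1))
  sum(probs[scores >= threshold - 1e-12])
}

# A small, irregular PWM used across oracle tests.
fixture_pwm <- function(seed = 42) {
  set.seed(seed)
  hx <- generate_hexamer_set(sigma70_profile("minus35"), 200, seed = seed)
  build_pwm(hx)
}

random_hexamer_strings <- function(n, seed) {
  set.seed(seed)
  replicate(n, paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                     collapse = ""))
}

# A synthetic feature table with known coefficients and optional noise.
synthetic_table <- function(n = 30, beta = c(1, 2, -3), sigma = 0, seed = 1) {
  set.seed(seed)
  s35 <- runif(n, -2, 10)
  s10 <- runif(n, -5, 10)
  y <- beta[1] + beta[2] * s35 + beta[3] * s10 + rnorm(n, 0, sigma)
  structure(
    data.frame(id = paste0("p", seq_len(n)), s35 = s35, s10 = s10,
               combined = s35 + s10, y = y, strength = exp(pmin(y, 0)),
               stringsAsFactors = FALSE),
    class = c("feature_table", "data.frame"))
}
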