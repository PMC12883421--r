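# Shared fixtures and independent oracles. Generated ROIs are cached per
# session because rendering is the slow part of the suite.

.fixture_cache <- new.env(parent = emptyenv())

# One ROI per default profile (seeded), reused by imaging/morphometry tests.
cached_rois <- function() {
  if (is.null(.fixture_cache$rois)) {
    prs <- make_default_profiles()
    .fixture_cache$rois <- lapply(seq_along(prs), function(i)
      generate_patient_rois(prs[[i]], n_rois = 1, seed = 100 + i)[[1]])
  }
  .fixture_cache$rois
}

# Rasterized disc mask.
disc_mask <- function(r, pad = 6) {
  n <- 2 * r + 2 * pad
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  matrix((xy$x - n / 2)^2 + (xy$y - n / 2)^2 <= r^2, n, n)
}

# Independent oracle for the five summary statistics, written from the
# definitions (population moments, n-1 SD, histogram entropy).
oracle_summary_stats <- function(v, bins = min(10, length(v))) {
  n <- length(v)
  mu <- sum(v) / n
  if (n == 1 || all(v == v[1]))
    return(c(mean = mu, sd = 0, skewness = 0, kurtosis = 0, entropy = 0))
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  br <- seq(min(v), max(v), length.out = bins + 1)
  cnt <- vapply(seq_len(bins), function(b) {
    if (b < bins) sum(v >= br[b] & v < br[b + 1]) else sum(v >= br[b] & v <= br[b + 1])
  }, numeric(1))
  p <- cnt[cnt > 0] / n
  c(mean = mu, sd = sqrt(sum((v - mu)^2) / (n - 1)),
    skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3,
    entropy = -sum(p * log(p)))
}

# Brute-force Kruskal-Wallis H with tie correction, from the rank formula.
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exhaustive pair-counting one-vs-rest AUC oracle.
oracle_auc <- function(scores, y, positive) {
  pos <- which(y == positive); neg <- which(y != positive)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# Random small nuclear-shape table for filter/density tests.
random_shapes <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    area_um2 = stats::runif(n, 10, 300),
    perimeter_um = stats::runif(n, 10, 120),
    circularity = stats::runif(n, 0.2, 1),
    eccentricity = stats::runif(n, 0, 0.99),
    max_caliper_um = stats::runif(n, 4, 40)
  )
}
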