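# Independent brute-force oracles, written deliberately apart from the
# package code paths they check.

# Jensen-Shannon divergence by direct term-by-term summation in base-2 logs,
# with the stabilising constant added to every probability term.
oracle_jsd <- function(p, q, eps = 1e-10) {
  m <- (p + q) / 2
  total <- 0
  for (i in seq_along(p)) {
    total <- total +
      0.5 * (p[i] + eps) * log2((p[i] + eps) / (m[i] + eps)) +
      0.5 * (q[i] + eps) * log2((q[i] + eps) / (m[i] + eps))
  }
  max(0, total)
}

# Product-moment correlation from the definitional sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Spearman: product-moment correlation of mid-ranks, ranks assigned by
# counting (ties get the average of their positions).
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) {
      sum(v < vi) + (sum(v == vi) + 1) / 2
    }, numeric(1))
  }
  oracle_pearson(midrank(x), midrank(y))
}

# A random probability vector over k categories.
random_prob <- function(k) {
  x <- stats::runif(k)
  x / sum(x)
}

# A tiny fully-observed record table; all defaults give complete data.
make_records <- function(n, age = 50, weight = 80, gender = "Male",
                         ethnicity = "WHITE", language = "ENGL",
                         religion = "CATHOLIC", marital_status = "MARRIED",
                         prefix = "R") {
  tibble::tibble(
    patient_id = sprintf("%s%04d", prefix, seq_len(n)),
    age = rep_len(age, n), gender = rep_len(gender, n),
    ethnicity = rep_len(ethnicity, n), weight = rep_len(weight, n),
    language = rep_len(language, n), religion = rep_len(religion, n),
    marital_status = rep_len(marital_status, n)
  )
}
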