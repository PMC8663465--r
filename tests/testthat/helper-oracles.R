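# Independent reference implementations ("oracles") used to verify the main
# code paths. Deliberately written with naive loops and textbook formulas,
# sharing no code with the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unsigned angle at vertex v between rays to p and q, by the law of cosines
# on the three side lengths (never via dot products).
oracle_angle_loc <- function(v, p, q) {
  a <- sqrt(sum((p - q)^2)) # side opposite the vertex
  b <- sqrt(sum((v - p)^2))
  c <- sqrt(sum((v - q)^2))
  acos(min(1, max(-1, (b^2 + c^2 - a^2) / (2 * b * c)))) * 180 / pi
}

# AUC as the brute-force pairwise concordance probability, ties 0.5.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# Exhaustive Youden sweep over every midpoint between adjacent distinct
# scores plus outside-the-range cuts; returns the maximal J.
oracle_youden_j <- function(scores, labels) {
  sc <- sort(unique(scores))
  cand <- c(min(sc) - 1, (utils::head(sc, -1) + utils::tail(sc, -1)) / 2,
            max(sc) + 1)
  best <- -Inf
  for (t in cand) {
    tpr <- sum(scores >= t & labels == 1) / sum(labels == 1)
    fpr <- sum(scores >= t & labels == 0) / sum(labels == 0)
    best <- max(best, tpr - fpr)
  }
  best
}

# Pixel-by-pixel uniform LBP histogram for one cell covering the whole
# patch (P = 8, R = 1). Bilinear sampling and transition counting written
# out longhand.
oracle_lbp_hist_p8r1 <- function(patch) {
  h <- nrow(patch)
  w <- ncol(patch)
  nuniform <- 0L
  # enumerate uniform codes in ascending order, as documented
  is_uniform <- function(code) {
    bits <- as.integer(intToBits(code)[1:8])
    sum(bits != c(bits[-1], bits[1])) <= 2
  }
  uni_codes <- Filter(is_uniform, 0:255)
  hist <- numeric(8 * 7 + 3)
  sample_at <- function(x, y) {
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    g <- function(xx, yy) {
      if (xx < 0 || xx > w - 1 || yy < 0 || yy > h - 1) return(0)
      patch[yy + 1, xx + 1]
    }
    (1 - fx) * (1 - fy) * g(x0, y0) + fx * (1 - fy) * g(x0 + 1, y0) +
      (1 - fx) * fy * g(x0, y0 + 1) + fx * fy * g(x0 + 1, y0 + 1)
  }
  for (r in 2:(h - 1)) {
    for (cc in 2:(w - 1)) {
      x <- cc - 1; y <- r - 1 # 0-based
      code <- 0L
      for (k in 0:7) {
        ang <- 2 * pi * k / 8
        nb <- sample_at(x + cos(ang), y - sin(ang))
        if (nb >= patch[r, cc]) code <- code + 2L^k
      }
      bin <- match(code, uni_codes)
      if (is.na(bin)) bin <- length(hist)
      hist[bin] <- hist[bin] + 1
    }
  }
  hist / sum(hist)
}

# Random plausible landmark set: a default synthetic face perturbed by
# smooth random jitter, guaranteed non-degenerate.
random_landmarks <- function(seed) {
  set.seed(seed)
  params <- sample_subject_params(cohort_config(rng_seed = seed), "control",
                                  seed)
  lm <- landmarks_from_params(params, runif(1))
  lm + matrix(rnorm(136, 0, 0.8), 68, 2)
}

# Apply a random similarity (rotation, scale, translation) to landmarks.
random_rigid <- function(lm, seed) {
  set.seed(seed)
  th <- runif(1, -pi, pi)
  s <- exp(runif(1, -0.7, 0.7))
  t <- runif(2, -40, 40)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(s * lm %*% t(R), 2, -t)
}

# Small deterministic cohort config for fast end-to-end tests.
tiny_config <- function(seed = 1, ...) {
  cohort_config(n_patient = 4, n_control = 4, n_frames = 7, rng_seed = seed,
                ...)
}
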