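# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and direct formula transcriptions, not
# the package's own code paths.

# Strip class/attributes from a glcm for plain-matrix comparison.
glcm_mat <- function(p) matrix(unclass(p), nrow(p))

# Co-occurrence counting by explicit pixel-pair enumeration.
brute_glcm <- function(img, n_levels, dr, dc, symmetric = TRUE,
                       normalize = TRUE) {
  h <- nrow(img); w <- ncol(img)
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        i <- img[r, c] + 1L; j <- img[r2, c2] + 1L
        counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  if (normalize) counts <- counts / sum(counts)
  counts
}

# Feature formulas computed cell-by-cell with explicit loops.
brute_glcm_features <- function(p) {
  n <- nrow(p)
  contrast <- energy <- homog <- mu <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    pij <- p[i + 1, j + 1]
    contrast <- contrast + pij * (i - j)^2
    energy <- energy + pij^2
    homog <- homog + pij / (1 + (i - j)^2)
    mu <- mu + i * pij
  }
  varr <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    varr <- varr + p[i + 1, j + 1] * (i - mu)^2
  }
  corr <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    corr <- corr + p[i + 1, j + 1] * (i - mu) * (j - mu)
  }
  corr <- if (varr > 0) corr / varr else NA_real_
  ent <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    pij <- p[i + 1, j + 1]
    if (pij > 0) ent <- ent - pij * log(pij)
  }
  list(contrast = contrast, correlation = corr, energy = energy,
       homogeneity = homog, glcm_mean = mu, std_dev = sqrt(varr),
       variance = varr, entropy = ent)
}

# AUC as the normalized Mann-Whitney pairwise comparison count.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == "diabetic"]
  neg <- scores[labels == "normal"]
  total <- 0
  for (sp in pos) {
    for (sn in neg) {
      total <- total + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  total / (length(pos) * length(neg))
}

# Per-pixel triple-range membership check.
brute_component_mask <- function(img, th) {
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      px <- img[r, c, ]
      if (px[1] >= th$r[1] && px[1] <= th$r[2] &&
          px[2] >= th$g[1] && px[2] <= th$g[2] &&
          px[3] >= th$b[1] && px[3] <= th$b[2]) {
        out[r, c] <- 1L
      }
    }
  }
  out
}

# Tie-corrected Kruskal-Wallis H from first principles.
brute_kw_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  rk <- rank(x)
  splits <- split(rk, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(splits, function(r) sum(r)^2 / length(r), numeric(1))) -
    3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Direct separable convolution with reflect padding (naive loops).
brute_gaussian_1d <- function(v, sigma) {
  radius <- ceiling(3 * sigma)
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2)); k <- k / sum(k)
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (o in -radius:radius) {
      j <- i + o
      while (j < 1 || j > n) {
        if (j < 1) j <- 2 - j
        if (j > n) j <- 2 * n - j
      }
      acc <- acc + k[o + radius + 1] * v[j]
    }
    out[i] <- acc
  }
  out
}

# Small deterministic thermogram fixtures built from the generator.
make_preset_image <- function(group, tst, seed, shape = c(96L, 96L),
                              palette = rainbow_palette()) {
  f <- sample_temperature_field(list(group = group, tst = tst),
                                shape = shape, seed = seed)
  temp_to_rgb(f, palette)
}
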