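# Independent brute-force oracles used by the unit and acceptance suites.
# These deliberately re-derive every quantity with plain loops and
# textbook formulas, sharing no code with the package implementation.

# Enumerate every in-mask pixel pair for one offset and build the
# symmetric co-occurrence matrix explicitly.
oracle_glcm_matrix <- function(levels, L, dr, dc) {
  P <- matrix(0, L, L)
  nr <- nrow(levels)
  nc <- ncol(levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + dr
      c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          !is.na(levels[r, c]) && !is.na(levels[r2, c2])) {
        a <- levels[r, c]
        b <- levels[r2, c2]
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
  }
  P
}

oracle_glcm_features <- function(P) {
  L <- nrow(P)
  p <- P / sum(P)
  px <- rowSums(p)
  mu <- sum((1:L) * px)
  sig <- sqrt(sum(((1:L) - mu)^2 * px))
  ac <- 0; ct <- 0; ds <- 0; en <- 0; ent <- 0; hg <- 0; vr <- 0; idn <- 0
  cp <- 0; cs <- 0
  for (i in 1:L) for (j in 1:L) {
    q <- p[i, j]
    ac <- ac + i * j * q
    ct <- ct + (i - j)^2 * q
    ds <- ds + abs(i - j) * q
    en <- en + q^2
    if (q > 0) ent <- ent - q * log(q)
    hg <- hg + q / (1 + (i - j)^2)
    vr <- vr + (i - mu)^2 * q
    idn <- idn + q / (1 + abs(i - j) / L)
    cp <- cp + (i + j - 2 * mu)^4 * q
    cs <- cs + (i + j - 2 * mu)^3 * q
  }
  corr <- if (sig > 0) (ac - mu^2) / sig^2 else 0
  ps <- sapply(2:(2 * L), function(k) {
    s <- 0
    for (i in 1:L) for (j in 1:L) if (i + j == k) s <- s + p[i, j]
    s
  })
  pd <- sapply(0:(L - 1), function(k) {
    s <- 0
    for (i in 1:L) for (j in 1:L) if (abs(i - j) == k) s <- s + p[i, j]
    s
  })
  sa <- sum((2:(2 * L)) * ps)
  sv <- sum(((2:(2 * L)) - sa)^2 * ps)
  se <- -sum(ifelse(ps > 0, ps * log(ps), 0))
  da <- sum((0:(L - 1)) * pd)
  dv <- sum(((0:(L - 1)) - da)^2 * pd)
  de <- -sum(ifelse(pd > 0, pd * log(pd), 0))
  hx <- -sum(ifelse(px > 0, px * log(px), 0))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    pp <- px[i] * px[j]
    if (pp > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log(pp)
      hxy2 <- hxy2 - pp * log(pp)
    }
  }
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - ent)), 0))
  c(Autocorrelation = ac, Contrast = ct, Correlation = corr,
    ClusterProminence = cp, ClusterShade = cs, Dissimilarity = ds,
    Energy = en, Entropy = ent, Homogeneity = hg,
    MaximumProbability = max(p), Variance = vr, SumAverage = sa,
    SumVariance = sv, SumEntropy = se, DifferenceVariance = dv,
    DifferenceEntropy = de, InformationMeasureCorrelation1 = imc1,
    InformationMeasureCorrelation2 = imc2, InverseDifferenceNormalized = idn)
}

oracle_glcm <- function(levels, L) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  acc <- NULL
  n_used <- 0
  for (o in offs) {
    P <- oracle_glcm_matrix(levels, L, o[1], o[2])
    if (sum(P) > 0) {
      f <- oracle_glcm_features(P)
      acc <- if (is.null(acc)) f else acc + f
      n_used <- n_used + 1
    }
  }
  acc / n_used
}

# Walk each scan line pixel by pixel and enumerate maximal constant runs.
oracle_grlm_runs <- function(levels, angle) {
  nr <- nrow(levels)
  nc <- ncol(levels)
  step <- switch(as.character(angle),
                 `0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                 `135` = c(-1, -1))
  # line starts: pixels with no predecessor along -step
  runs <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - step[1]
    pc <- c - step[2]
    if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc) next  # not a line start
    # walk the line
    cur_g <- NA
    cur_len <- 0
    rr <- r; cc <- c
    while (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
      g <- levels[rr, cc]
      if (!is.na(g) && !is.na(cur_g) && g == cur_g) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_g)) runs[[length(runs) + 1]] <- c(cur_g, cur_len)
        cur_g <- g
        cur_len <- if (is.na(g)) 0 else 1
      }
      rr <- rr + step[1]
      cc <- cc + step[2]
    }
    if (!is.na(cur_g)) runs[[length(runs) + 1]] <- c(cur_g, cur_len)
  }
  runs
}

oracle_grlm_features <- function(runs, n_px) {
  g <- sapply(runs, `[`, 1)
  l <- sapply(runs, `[`, 2)
  N <- length(runs)
  c(ShortRunEmphasis = sum(1 / l^2) / N,
    LongRunEmphasis = sum(l^2) / N,
    GrayLevelNonuniformity = sum(tapply(rep(1, N), g, sum)^2) / N,
    RunLengthNonuniformity = sum(tapply(rep(1, N), l, sum)^2) / N,
    RunPercentage = N / n_px,
    LowGrayLevelRunEmphasis = sum(1 / g^2) / N,
    HighGrayLevelRunEmphasis = sum(g^2) / N,
    ShortRunLowGrayLevelEmphasis = sum(1 / (g^2 * l^2)) / N,
    ShortRunHighGrayLevelEmphasis = sum(g^2 / l^2) / N,
    LongRunLowGrayLevelEmphasis = sum(l^2 / g^2) / N,
    LongRunHighGrayLevelEmphasis = sum(g^2 * l^2) / N)
}

oracle_grlm <- function(levels) {
  n_px <- sum(!is.na(levels))
  f <- lapply(c(0, 45, 90, 135), function(a) {
    oracle_grlm_features(oracle_grlm_runs(levels, a), n_px)
  })
  Reduce(`+`, f) / 4
}

# AUC as the fraction of concordant (positive, negative) score pairs,
# ties counted half.
oracle_auc <- function(scores, labels) {
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  tot <- 0
  for (x in xs) for (y in ys) {
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  tot / (length(xs) * length(ys))
}

# Otsu by exhaustive search over all 256-bin histogram boundaries: for each
# candidate boundary, recompute class weights and midpoint means from the
# binned counts directly.
oracle_otsu <- function(values, n_bins = 256) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  cnt <- numeric(n_bins)
  for (v in values) {
    b <- min(max(findInterval(v, edges, rightmost.closed = TRUE), 1), n_bins)
    cnt[b] <- cnt[b] + 1
  }
  best_v <- -Inf
  best_t <- NA
  for (t in 1:(n_bins - 1)) {
    n0 <- sum(cnt[1:t])
    n1 <- sum(cnt[(t + 1):n_bins])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(cnt[1:t] * mids[1:t]) / n0
    mu1 <- sum(cnt[(t + 1):n_bins] * mids[(t + 1):n_bins]) / n1
    w0 <- n0 / length(values)
    v <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (v > best_v + 1e-15) {
      best_v <- v
      best_t <- edges[t + 1]
    }
  }
  best_t
}

# Fisher 2x2 two-sided p by exhaustive hypergeometric enumeration.
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- sapply(support, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  })
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small random masked ROI for oracle-equivalence trials.
random_roi <- function(max_side = 8, L = 5) {
  nr <- sample(2:max_side, 1)
  nc <- sample(2:max_side, 1)
  lev <- matrix(sample(1:L, nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(stats::runif(nr * nc) < 0.8, nr, nc)
  if (sum(mask) < 2) mask[sample(nr * nc, 2)] <- TRUE
  lev[!mask] <- NA_integer_
  structure(list(levels = lev, L = L, constant = FALSE,
                 range = c(1, L)), class = "quantized_roi")
}
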