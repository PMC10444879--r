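# Independent reference implementations used as oracles. These deliberately
# take different algorithmic routes from the package code.

# Exhaustive peak oracle: list all strict local maxima, apply the amplitude
# floor, then repeatedly resolve the leftmost adjacent pair violating the
# minimum-gap or trough rule by removing the smaller peak, until stable.
oracle_peaks <- function(x, t_frame, min_gap_s = 0.1, floor_q = 0.25,
                         trough_frac = 0.2) {
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) cand <- c(cand, i)
  }
  floor_val <- quantile(x, floor_q, names = FALSE)
  cand <- cand[x[cand] > floor_val]
  drop_req <- trough_frac * IQR(x)
  repeat {
    if (length(cand) < 2) break
    violated <- NA
    for (j in 1:(length(cand) - 1)) {
      p <- cand[j]; q <- cand[j + 1]
      gap_ok <- (q - p) * t_frame >= min_gap_s
      seg <- x[(p + 1):(q - 1)]
      trough_ok <- length(seg) > 0 && min(seg) < x[p] - drop_req
      if (!gap_ok || !trough_ok) { violated <- j; break }
    }
    if (is.na(violated)) break
    p <- cand[violated]; q <- cand[violated + 1]
    cand <- setdiff(cand, if (x[q] > x[p]) p else q)
  }
  cand
}

# Smooth quasi-periodic random signal in degrees on [0, 180]-ish range
smooth_random_signal <- function(n = 240, t_frame = 1 / 30) {
  tt <- (seq_len(n) - 1) * t_frame
  f0 <- runif(1, 0.8, 2.5)
  x <- 60 + runif(1, 20, 50) * sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi))
  for (h in 1:2) {
    x <- x + runif(1, 2, 12) * sin(2 * pi * runif(1, 0.2, 4) * tt +
                                     runif(1, 0, 2 * pi))
  }
  x + 5 * sin(2 * pi * 0.05 * tt)
}

# Histogram Shannon entropy by explicit binning loop
oracle_hist_entropy <- function(v, bins = 10) {
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(0)
  counts <- numeric(bins)
  for (val in v) {
    b <- floor((val - lo) / (hi - lo) * bins) + 1
    if (b > bins) b <- bins
    counts[b] <- counts[b] + 1
  }
  p <- counts / length(v)
  -sum(ifelse(p > 0, p * log(p), 0))
}

# Spectral entropy via explicit DFT sums (no fft)
oracle_spectral_entropy <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  nh <- floor(n / 2)
  pw <- numeric(nh)
  for (k in seq_len(nh)) {
    re <- sum(x * cos(-2 * pi * k * (seq_len(n) - 1) / n))
    im <- sum(x * sin(-2 * pi * k * (seq_len(n) - 1) / n))
    pw[k] <- re^2 + im^2
  }
  p <- pw / sum(pw)
  p <- p[p > 0]
  -sum(p * log(p))
}

# ICC(2,1) oracle via aov() sums of squares + textbook formula
oracle_icc21 <- function(m) {
  df <- data.frame(y = as.vector(m),
                   video = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(aov(y ~ video + rater, data = df))[[1]]
  msr <- tab["video", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Krippendorff alpha oracle: direct enumeration of within-unit pairs with
# ordinal distances computed from scratch on the pooled value frequencies.
oracle_kripp_ordinal <- function(m) {
  mu <- rowSums(!is.na(m))
  m <- m[mu >= 2, , drop = FALSE]
  pooled <- as.vector(m)[!is.na(as.vector(m))]
  vals <- sort(unique(pooled))
  # marginal n_c: appearances of each value across pairable units
  nc <- setNames(vapply(vals, function(v) sum(pooled == v), numeric(1)),
                 vals)
  ntot <- sum(nc)
  dist2 <- function(a, b) {
    ia <- which(vals == a); ib <- which(vals == b)
    lo <- min(ia, ib); hi <- max(ia, ib)
    (sum(nc[lo:hi]) - (nc[ia] + nc[ib]) / 2)^2
  }
  d_o_num <- 0
  for (u in seq_len(nrow(m))) {
    r <- m[u, ][!is.na(m[u, ])]
    mu_u <- length(r)
    for (a in seq_len(mu_u)) {
      for (b in seq_len(mu_u)) {
        if (a != b) d_o_num <- d_o_num + dist2(r[a], r[b]) / (mu_u - 1)
      }
    }
  }
  d_o <- d_o_num / ntot
  d_e_num <- 0
  for (a in vals) {
    for (b in vals) {
      if (a != b) d_e_num <- d_e_num + nc[as.character(a)] *
          nc[as.character(b)] * dist2(a, b)
    }
  }
  d_e <- d_e_num / (ntot * (ntot - 1))
  unname(1 - d_o / d_e)
}

# Kendall tau-b oracle by pair enumeration
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# small fully-visible landmark series built from explicit coordinates
make_series <- function(coords, t_frame = 1 / 30, hand = "right",
                        presence = 1) {
  n <- nrow(coords$w)
  fr <- data.frame(frame = seq_len(n) - 1L, label = hand,
                   det_score = 1, presence = presence,
                   lm0_x = coords$w[, 1], lm0_y = coords$w[, 2],
                   lm1_x = coords$c[, 1], lm1_y = coords$c[, 2],
                   lm4_x = coords$t[, 1], lm4_y = coords$t[, 2],
                   lm8_x = coords$i[, 1], lm8_y = coords$i[, 2])
  landmarkSeries(fr, video_id = "T", hand = hand, t_frame = t_frame)
}

# apply a rigid/similarity transform to every landmark of a series
transform_series <- function(series, angle = 0, scale = 1, shift = c(0, 0)) {
  R <- scale * matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  fr <- series$frames
  for (id in c(0, 1, 4, 8)) {
    xc <- paste0("lm", id, "_x"); yc <- paste0("lm", id, "_y")
    pts <- cbind(fr[[xc]], fr[[yc]]) %*% t(R)
    fr[[xc]] <- pts[, 1] + shift[1]
    fr[[yc]] <- pts[, 2] + shift[2]
  }
  landmarkSeries(fr, series$video_id, series$participant_id, series$hand,
                 series$t_frame, series$metadata)
}
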