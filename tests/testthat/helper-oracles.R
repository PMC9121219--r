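# Independent straight-from-definition oracles used to cross-check the
# package implementations. These deliberately use naive loops and explicit
# formulas, never the package's own code paths.

# --- feature oracles -------------------------------------------------------

oracle_segment_strokes <- function(df) {
  on <- df$pressure > 0
  strokes <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    if (on[i]) {
      if (is.null(cur)) cur <- c(i, i) else cur[2L] <- i
    } else if (!is.null(cur)) {
      strokes[[length(strokes) + 1L]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) strokes[[length(strokes) + 1L]] <- cur
  strokes
}

oracle_speeds <- function(df, strokes) {
  speeds <- numeric()
  for (s in strokes) {
    if (s[2L] > s[1L]) {
      for (i in s[1L]:(s[2L] - 1L)) {
        d <- sqrt((df$x_mm[i + 1L] - df$x_mm[i])^2 +
                  (df$y_mm[i + 1L] - df$y_mm[i])^2)
        speeds <- c(speeds, d / (df$t_s[i + 1L] - df$t_s[i]))
      }
    }
  }
  speeds
}

oracle_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
}

# O(n^2) brute-force pause scan over one stroke under the anchor rule: from
# anchor i take the longest window [i, j] with every sample within `radius`
# of sample i, checking all pairs explicitly.
oracle_pause_scan <- function(x, y, t, radius = 0.25, min_dur = 0.1) {
  n <- length(x)
  out <- NULL
  i <- 1L
  while (i < n) {
    j <- i
    for (k in seq(i, n)) {
      ok <- TRUE
      for (q in seq(i, k)) {
        if (sqrt((x[q] - x[i])^2 + (y[q] - y[i])^2) > radius) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
      j <- k
    }
    if (t[j] - t[i] > min_dur) {
      out <- rbind(out, c(t[i], t[j]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) matrix(numeric(), 0L, 2L) else out
}

oracle_features <- function(stream, radius = 0.25, min_dur = 0.1) {
  df <- as.data.frame(stream)
  strokes <- oracle_segment_strokes(df)
  speeds <- oracle_speeds(df, strokes)
  m <- sum(speeds) / length(speeds)
  s <- sqrt(sum((speeds - m)^2) / (length(speeds) - 1L))

  p <- df$pressure[df$pressure > 0]
  med <- oracle_median(p)
  pmad <- oracle_median(abs(p - med))

  on <- df$pressure > 0
  ih <- df$incl_h_deg[on]; iv <- df$incl_v_deg[on]
  sd0 <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1L))

  within_total <- 0
  pause_total <- 0
  for (st in strokes) {
    idx <- st[1L]:st[2L]
    w <- oracle_pause_scan(df$x_mm[idx], df$y_mm[idx], df$t_s[idx],
                           radius, min_dur)
    if (nrow(w) > 0L) within_total <- within_total + sum(w[, 2L] - w[, 1L])
  }
  pause_total <- within_total
  if (length(strokes) > 1L) {
    for (k in seq_len(length(strokes) - 1L)) {
      pause_total <- pause_total +
        df$t_s[strokes[[k + 1L]][1L]] - df$t_s[strokes[[k]][2L]]
    }
  }
  stroke_dur <- sum(vapply(strokes, function(st) df$t_s[st[2L]] - df$t_s[st[1L]],
                           numeric(1L)))
  c(speed_mean = m, speed_cv = s / m, pressure_mad = pmad,
    incl_h_sd = sd0(ih), incl_v_sd = sd0(iv),
    pause_ratio = pause_total / (stroke_dur - within_total))
}

# --- statistics oracles ----------------------------------------------------

# Partial correlation by explicit normal-equation residualization.
oracle_partial_corr <- function(x, y, Z = NULL) {
  n <- length(x)
  D <- cbind(rep(1, n), Z)
  beta_x <- solve(t(D) %*% D, t(D) %*% x)
  beta_y <- solve(t(D) %*% D, t(D) %*% y)
  rx <- x - D %*% beta_x
  ry <- y - D %*% beta_y
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

# Direct step-up definition of the Benjamini-Hochberg adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in seq(m - 1L, 1L)) q[i] <- min(q[i], q[i + 1L])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# --- Shapley oracle --------------------------------------------------------

# Brute-force coalition enumeration for one sample: the value of coalition S
# is the background-averaged prediction with features in S fixed at x_row.
oracle_shapley_row <- function(model, x_row, background) {
  p <- ncol(background)
  value <- function(S) {
    X <- background
    for (j in S) X[[j]] <- x_row[[j]]
    mean(predict(model, data = X, num.threads = 1L)$predictions)
  }
  phi <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (size in 0:length(others)) {
      subsets <- if (size == 0L) list(integer()) else
        utils::combn(others, size, simplify = FALSE)
      w <- factorial(size) * factorial(p - size - 1L) / factorial(p)
      for (S in subsets) {
        phi[j] <- phi[j] + w * (value(c(S, j)) - value(S))
      }
    }
  }
  phi
}
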