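# Independent brute-force oracles. Deliberately written with plain
# loops and explicit formulas, sharing no code with the package paths
# they check.

# linear-interpolation quantile at rank 1 + p*(n-1), by hand
oracleQuantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  h <- 1 + p * (n - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracleSd <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

oracleCov <- function(x, minN = 2L) {
  if (length(x) < minN) return(NA_real_)
  m <- sum(x) / length(x)
  if (m <= 0) return(NA_real_)
  oracleSd(x) / m
}

# one day's 24 DMOs, straight from the daily-calculation text
oracleDaily <- function(bouts) {
  d <- bouts$duration
  all <- seq_along(d)
  g10 <- which(d > 10)
  g30 <- which(d > 30)
  g60 <- which(d > 60)
  sh <- which(d > 10 & d <= 30)
  mn <- function(v) if (length(v)) sum(v) / length(v) else NA_real_
  med <- function(v) if (length(v)) oracleQuantile(v, 0.5) else NA_real_
  p90 <- function(v) if (length(v)) oracleQuantile(v, 0.9) else NA_real_
  list(walking_duration = sum(d) / 3600,
       n_steps = sum(bouts$n_steps),
       n_wb = length(all),
       n_wb_gt10 = length(g10),
       n_wb_gt30 = length(g30),
       n_wb_gt60 = length(g60),
       wb_duration_median = med(d),
       wb_duration_p90 = p90(d),
       wb_duration_cov = oracleCov(d),
       speed_short = mn(bouts$speed[sh]),
       speed_long = mn(bouts$speed[g30]),
       speed_p90_gt10 = p90(bouts$speed[g10]),
       speed_p90_long = p90(bouts$speed[g30]),
       stride_len_short = mn(bouts$stride_length[sh]),
       stride_len_long = mn(bouts$stride_length[g30]),
       cadence_all = mn(bouts$cadence),
       cadence_long = mn(bouts$cadence[g30]),
       cadence_p90_long = p90(bouts$cadence[g30]),
       stride_dur_all = mn(bouts$stride_duration),
       stride_dur_long = mn(bouts$stride_duration[g30]),
       speed_cov_long = oracleCov(bouts$speed[g30]),
       stride_len_cov_long = oracleCov(bouts$stride_length[g30]),
       cadence_cov = oracleCov(bouts$cadence),
       stride_dur_cov = oracleCov(bouts$stride_duration))
}

# union of intervals measured on a one-minute bitmap (intervals must be
# minute-aligned); returns covered hours
oracleUnionHours <- function(startMin, endMin) {
  if (!length(startMin)) return(0)
  lo <- min(startMin)
  hi <- max(endMin)
  bitmap <- rep(FALSE, hi - lo)
  for (i in seq_along(startMin)) {
    idx <- seq(startMin[i] - lo + 1L, endMin[i] - lo)
    bitmap[idx] <- TRUE
  }
  sum(bitmap) / 60
}

# Benjamini-Hochberg by explicit step-up enumeration
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  running <- Inf
  for (j in m:1) {
    running <- min(running, m * sorted[j] / j)
    adj[ord[j]] <- min(running, 1)
  }
  adj
}

# partial F-test for the group term via explicit projection matrices
oracleAncovaP <- function(y, group, covs) {
  g <- as.numeric(factor(group)) - 1
  X1 <- cbind(1, as.matrix(covs))        # reduced model
  X2 <- cbind(X1, g)                     # full model
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    r <- y - X %*% beta
    sum(r^2)
  }
  n <- length(y)
  r1 <- rss(X1)
  r2 <- rss(X2)
  df2 <- n - ncol(X2)
  Fv <- (r1 - r2) / (r2 / df2)
  stats::pf(Fv, 1, df2, lower.tail = FALSE)
}

# two-sample KS D by scanning the pooled grid
oracleKSD <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Dm <- 0
  for (t in grid) {
    Fx <- sum(x <= t) / length(x)
    Fy <- sum(y <= t) / length(y)
    Dm <- max(Dm, abs(Fx - Fy))
  }
  Dm
}

# random participant-day bout tables for oracle comparisons; mixes
# empty days, boundary durations (exactly 10/30/60 s) and heavy tails
randomDayBouts <- function(n) {
  if (n == 0L)
    return(data.frame(duration = numeric(), n_steps = numeric(),
                      cadence = numeric(), speed = numeric(),
                      stride_length = numeric(), stride_duration = numeric()))
  pick <- runif(n)
  duration <- ifelse(pick < 0.1, sample(c(10, 30, 60), n, replace = TRUE),
                     exp(rnorm(n, log(9), 1.1)))
  duration <- pmax(duration, 1)
  cadence <- pmax(rnorm(n, 85, 12), 30)
  stride_length <- pmax(rnorm(n, 95, 15), 20)
  stride_duration <- 120 / cadence
  speed <- stride_length / 100 / stride_duration
  data.frame(duration = duration,
             n_steps = pmax(1, round(duration * cadence / 60)),
             cadence = cadence, speed = speed,
             stride_length = stride_length, stride_duration = stride_duration)
}

makeDay <- function(bouts, id = "p1", date = as.Date("2013-05-06"),
                    wear = 13, valid = TRUE) {
  list(participant_id = id, date = date, wear_hours = wear,
       valid = valid, bouts = bouts)
}

posix <- function(x) as.POSIXct(x, tz = "UTC")
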