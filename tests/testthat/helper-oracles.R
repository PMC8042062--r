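# Brute-force reference: score every 2^n state path and return the best.
brute_force_viterbi <- function(counts, params) {
  pc <- params$pseudocount
  x <- counts + pc
  n <- length(x)
  logB <- cbind(
    dgamma(x, shape = params$shape[1], scale = params$scale[1], log = TRUE),
    dgamma(x, shape = params$shape[2], scale = params$scale[2], log = TRUE)
  )
  logA <- log(params$transition)
  best <- -Inf
  best_path <- NULL
  for (code in 0:(2^n - 1)) {
    path <- as.integer(intToBits(code)[1:n]) + 1L
    s <- log(params$initial[path[1]]) + logB[1, path[1]]
    if (n > 1) {
      for (t in 2:n) s <- s + logA[path[t - 1], path[t]] + logB[t, path[t]]
    }
    if (s > best) {
      best <- s
      best_path <- path
    }
  }
  list(states = best_path - 1L, logprob = best)
}

rand_params <- function(seed) {
  set.seed(seed)
  p <- runif(2, 0.85, 0.99)
  structure(
    list(
      shape = c(runif(1, 0.5, 2), runif(1, 2, 6)),
      scale = c(runif(1, 0.3, 1), runif(1, 3, 10)),
      transition = matrix(c(p[1], 1 - p[1], 1 - p[2], p[2]), 2, byrow = TRUE),
      initial = c(0.7, 0.3),
      pseudocount = 0.25
    ),
    class = "tar_hmm"
  )
}


# Brute-force strand-aware merge: repeatedly union any two intervals on the
# same chrom/strand whose gap is within max_gap, until a fixed point.
brute_merge <- function(df, max_gap) {
  repeat {
    done <- TRUE
    i <- 1
    while (i <= nrow(df)) {
      j <- i + 1
      while (j <= nrow(df)) {
        same <- df$chrom[i] == df$chrom[j] & df$strand[i] == df$strand[j]
        gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j]) - 1
        if (same && gap <= max_gap) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, , drop = FALSE]
          done <- FALSE
        } else {
          j <- j + 1
        }
      }
      i <- i + 1
    }
    if (done) break
  }
  df[order(df$chrom, df$start, df$strand), ]
}


# Exact two-sided rank-sum p by full enumeration of all choose(m+n, m)
# assignments of the pooled (possibly tied) values to group A.
enum_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(length(pooled), m)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  lower <- mean(ws <= w_obs + 1e-9)
  upper <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

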