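#' Two-state gamma-emission hidden Markov model for transcription calling
#'
#' @description
#' \code{fit_baum_welch} fits a strand-specific two-state HMM to windowed
#' read-count tracks by Baum-Welch expectation maximization. State 0 models
#' untranscribed background, state 1 transcribed regions; each state emits
#' window counts from its own gamma distribution. Because the gamma density
#' is undefined at zero, emissions are evaluated on \code{counts +
#' pseudocount} (default 0.25). One parameter set is fitted jointly across
#' all tracks of a sample (chromosomes and strands are treated as
#' independent observation sequences), mirroring genome-wide fitting.
#'
#' @details
#' The forward/backward recursions use per-step scaling so that tracks with
#' millions of windows do not underflow. The M-step re-estimates each
#' state's gamma parameters by posterior-weighted maximum likelihood
#' (Newton iteration on the shape via the digamma function). After
#' convergence the states are relabeled, if necessary, so that state 1 has
#' the larger emission mean.
#'
#' With \code{init = "auto"} the untranscribed state is seeded from windows
#' below the 75th count percentile and the transcribed state from windows
#' above it; self-transition probabilities start at 0.999, encoding the
#' expectation that transcription units span many consecutive windows.
#'
#' @param tracks A list of \code{\link{window_count_track}} objects (or a
#'   single track, or a bare numeric vector of counts).
#' @param init \code{"auto"} or a list with elements \code{shape} (length
#'   2), \code{scale} (length 2), \code{transition} (2x2 row-stochastic)
#'   and \code{initial} (length-2 probability vector).
#' @param tol Convergence tolerance on the relative change of the
#'   log-likelihood (default 1e-4).
#' @param max_iter Maximum EM iterations (default 100).
#' @param pseudocount Value added to every count before evaluating the
#'   gamma density (default 0.25).
#' @return An object of class \code{tar_hmm}: a list with \code{shape},
#'   \code{scale} (length-2 vectors, state 0 first), \code{transition},
#'   \code{initial}, \code{loglik_trace}, \code{converged},
#'   \code{iterations}, \code{pseudocount} and a \code{degenerate} flag set
#'   when the two state means are indistinguishable.
#' @seealso \code{\link{decode}} for Viterbi decoding,
#'   \code{\link{states_to_intervals}} to materialize transcribed intervals.
#' @export
fit_baum_welch <- function(tracks, init = "auto", tol = 1e-4,
                           max_iter = 100, pseudocount = 0.25) {
  stopifnot(tol > 0, max_iter >= 1, pseudocount >= 0)
  seqs <- .as_count_sequences(tracks)
  if (!length(seqs) || sum(lengths(seqs)) < 2) {
    stop("need at least one track with >= 2 windows")
  }
  obs <- lapply(seqs, function(x) x + pseudocount)
  all_obs <- unlist(obs, use.names = FALSE)
  if (any(all_obs <= 0)) {
    stop(
      "non-positive observations after pseudocount; gamma emissions are ",
      "undefined at 0 - supply a positive 'pseudocount' (default 0.25)"
    )
  }

  par <- if (identical(init, "auto")) .hmm_auto_init(all_obs) else .hmm_check_init(init)

  loglik_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    es <- .hmm_estep(obs, par)
    if (!is.finite(es$loglik)) {
      stop("non-finite log-likelihood at EM iteration ", iter)
    }
    loglik_trace <- c(loglik_trace, es$loglik)
    if (iter > 1 &&
      abs(es$loglik - ll_prev) / (abs(ll_prev) + .Machine$double.eps) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- es$loglik
    par <- .hmm_mstep(obs, es, par)
  }

  means <- par$shape * par$scale
  if (means[1] > means[2]) { # relabel so state 1 (index 2) is transcribed
    par$shape <- rev(par$shape)
    par$scale <- rev(par$scale)
    par$initial <- rev(par$initial)
    par$transition <- par$transition[2:1, 2:1]
    means <- rev(means)
  }
  degenerate <- abs(means[2] - means[1]) <= 0.01 * max(means)
  if (degenerate) {
    warning("degenerate fit: the two state means are nearly identical; ",
            "the data carry no two-regime signal")
  }

  structure(
    list(
      shape = par$shape, scale = par$scale,
      transition = par$transition, initial = par$initial,
      loglik_trace = loglik_trace, converged = converged,
      iterations = length(loglik_trace), pseudocount = pseudocount,
      degenerate = degenerate, n_windows = length(all_obs)
    ),
    class = "tar_hmm"
  )
}

# Accept a track list, a single track, or a numeric vector.
.as_count_sequences <- function(tracks) {
  if (inherits(tracks, "window_count_track")) tracks <- list(tracks)
  if (is.numeric(tracks)) tracks <- list(tracks)
  lapply(tracks, function(tr) {
    if (inherits(tr, "window_count_track")) tr$counts else as.numeric(tr)
  })
}

.hmm_auto_init <- function(x) {
  q75 <- stats::quantile(x, 0.75, names = FALSE)
  lo <- x[x <= q75]
  hi <- x[x > q75]
  if (!length(hi)) hi <- max(x)
  list(
    shape = c(.gamma_mom(lo)$shape, .gamma_mom(hi)$shape),
    scale = c(.gamma_mom(lo)$scale, .gamma_mom(hi)$scale),
    transition = matrix(c(0.999, 0.001, 0.001, 0.999), 2, byrow = TRUE),
    initial = c(0.5, 0.5)
  )
}

.gamma_mom <- function(x) {
  m <- mean(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= 1e-12) v <- max(m^2 / 4, 1e-6)
  list(shape = m^2 / v, scale = v / m)
}

.hmm_check_init <- function(init) {
  stopifnot(
    is.list(init),
    all(c("shape", "scale", "transition", "initial") %in% names(init)),
    all(init$shape > 0), all(init$scale > 0),
    all(dim(init$transition) == c(2, 2)),
    all(abs(rowSums(init$transition) - 1) < 1e-8),
    abs(sum(init$initial) - 1) < 1e-8
  )
  init[c("shape", "scale", "transition", "initial")]
}

# Scaled forward-backward over independent sequences.
# Returns posteriors (gamma), expected transition counts and the loglik.
.hmm_estep <- function(obs, par) {
  A <- par$transition
  xi_sum <- matrix(0, 2, 2)
  gamma_list <- vector("list", length(obs))
  init_acc <- c(0, 0)
  loglik <- 0

  for (s in seq_along(obs)) {
    x <- obs[[s]]
    n <- length(x)
    B <- cbind(
      stats::dgamma(x, shape = par$shape[1], scale = par$scale[1]),
      stats::dgamma(x, shape = par$shape[2], scale = par$scale[2])
    )
    B[B < 1e-300] <- 1e-300

    alpha <- matrix(0, n, 2)
    beta <- matrix(0, n, 2)
    cvec <- numeric(n)

    a <- par$initial * B[1, ]
    cvec[1] <- sum(a)
    alpha[1, ] <- a / cvec[1]
    if (n >= 2) {
      for (t in 2:n) {
        a <- (alpha[t - 1, ] %*% A) * B[t, ]
        cvec[t] <- sum(a)
        alpha[t, ] <- a / cvec[t]
      }
    }
    beta[n, ] <- 1
    if (n >= 2) {
      for (t in (n - 1):1) {
        b <- A %*% (B[t + 1, ] * beta[t + 1, ])
        beta[t, ] <- b / cvec[t + 1]
      }
    }

    g <- alpha * beta
    g <- g / rowSums(g)
    gamma_list[[s]] <- g
    init_acc <- init_acc + g[1, ]
    loglik <- loglik + sum(log(cvec))

    # expected transition counts, accumulated across t
    if (n >= 2) {
      for (i in 1:2) {
        for (j in 1:2) {
          xi_sum[i, j] <- xi_sum[i, j] +
            sum(alpha[-n, i] * A[i, j] * B[-1, j] * beta[-1, j] / cvec[-1])
        }
      }
    }
  }

  list(gamma = gamma_list, xi_sum = xi_sum, init = init_acc, loglik = loglik)
}

.hmm_mstep <- function(obs, es, par) {
  A <- es$xi_sum / rowSums(es$xi_sum)
  initial <- es$init / sum(es$init)

  shape <- par$shape
  scale <- par$scale
  for (k in 1:2) {
    w <- unlist(lapply(es$gamma, function(g) g[, k]), use.names = FALSE)
    x <- unlist(obs, use.names = FALSE)
    sw <- sum(w)
    m <- sum(w * x) / sw
    mlog <- sum(w * log(x)) / sw
    fit <- .gamma_weighted_mle(m, mlog, shape[k])
    shape[k] <- fit$shape
    scale[k] <- fit$scale
  }
  list(shape = shape, scale = scale, transition = A, initial = initial)
}

# Weighted gamma MLE: solve log(k) - digamma(k) = log(mean) - mean(log)
# by Newton iteration; falls back to a near-point-mass fit when the
# weighted data are (almost) constant.
.gamma_weighted_mle <- function(m, mlog, k0) {
  s <- log(m) - mlog
  if (!is.finite(s) || s < 1e-10) {
    k <- 1e6
    return(list(shape = k, scale = m / k))
  }
  k <- if (is.finite(k0) && k0 > 0) k0 else (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    step <- f / fp
    knew <- k - step
    if (knew <= 0) knew <- k / 2
    if (abs(knew - k) < 1e-10 * k) {
      k <- knew
      break
    }
    k <- knew
  }
  k <- min(max(k, 1e-6), 1e6)
  list(shape = k, scale = m / k)
}

#' @export
print.tar_hmm <- function(x, ...) {
  cat("Two-state gamma-emission HMM (Baum-Welch fit)\n")
  cat(sprintf(
    "  windows: %d   iterations: %d   converged: %s%s\n",
    x$n_windows, x$iterations, x$converged,
    if (x$degenerate) "   [degenerate]" else ""
  ))
  cat(sprintf(
    "  state 0 (untranscribed): mean %.3f  (shape %.3f, scale %.3f)\n",
    x$shape[1] * x$scale[1], x$shape[1], x$scale[1]
  ))
  cat(sprintf(
    "  state 1 (transcribed):   mean %.3f  (shape %.3f, scale %.3f)\n",
    x$shape[2] * x$scale[2], x$shape[2], x$scale[2]
  ))
  cat(sprintf(
    "  self-transitions: %.5f / %.5f   log-likelihood: %.2f\n",
    x$transition[1, 1], x$transition[2, 2], utils::tail(x$loglik_trace, 1)
  ))
  invisible(x)
}

#' @export
summary.tar_hmm <- function(object, ...) {
  print(object)
  cat(sprintf(
    "  expected run lengths: %.0f windows (state 0), %.0f windows (state 1)\n",
    1 / (1 - object$transition[1, 1]), 1 / (1 - object$transition[2, 2])
  ))
  invisible(object)
}

#' @export
coef.tar_hmm <- function(object, ...) {
  list(
    shape = object$shape, scale = object$scale,
    mean = object$shape * object$scale,
    transition = object$transition, initial = object$initial
  )
}

#' @export
logLik.tar_hmm <- function(object, ...) {
  ll <- utils::tail(object$loglik_trace, 1)
  structure(ll, df = 7, nobs = object$n_windows, class = "logLik")
}

#' Simulate window counts from a fitted (or constructed) HMM
#'
#' Draws a state path from the Markov chain and continuous emission values
#' from the per-state gamma distributions, returning observations on the
#' count scale (the fitted pseudocount is subtracted back out). Useful for
#' parameter-recovery checks and posterior predictive inspection.
#'
#' @param object A \code{tar_hmm}.
#' @param nsim Number of windows to simulate.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list with \code{counts} (numeric vector) and \code{states}
#'   (0/1 vector).
#' @export
simulate.tar_hmm <- function(object, nsim = 1000, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  A <- object$transition
  st <- integer(nsim)
  st[1] <- sample(1:2, 1, prob = object$initial)
  for (t in seq_len(nsim)[-1]) {
    st[t] <- sample(1:2, 1, prob = A[st[t - 1], ])
  }
  y <- stats::rgamma(nsim,
    shape = object$shape[st],
    scale = object$scale[st]
  )
  list(counts = pmax(y - object$pseudocount, 0), states = st - 1L)
}

#' Viterbi decoding of a count track
#'
#' Computes the maximum-probability state path for one windowed count track
#' under a fitted HMM. Decoding is deterministic; ties are broken toward
#' the untranscribed state.
#'
#' @param track A \code{\link{window_count_track}} (or numeric count
#'   vector).
#' @param params A \code{tar_hmm} (fitted or hand-built via the same list
#'   structure).
#' @return A \code{state_path} object: list with \code{chrom},
#'   \code{strand}, \code{window_size} and a 0/1 \code{states} vector, one
#'   entry per window.
#' @export
decode <- function(track, params) {
  stopifnot(inherits(params, "tar_hmm") ||
    all(c("shape", "scale", "transition", "initial") %in% names(params)))
  if (is.numeric(track)) {
    track <- window_count_track("seq", "+", 1L, track)
  }
  pc <- if (!is.null(params$pseudocount)) params$pseudocount else 0.25
  x <- track$counts + pc
  n <- length(x)
  if (n == 0) {
    return(structure(
      list(
        chrom = track$chrom, strand = track$strand,
        window_size = track$window_size, states = integer(0)
      ),
      class = "state_path"
    ))
  }
  logB <- cbind(
    stats::dgamma(x, shape = params$shape[1], scale = params$scale[1], log = TRUE),
    stats::dgamma(x, shape = params$shape[2], scale = params$scale[2], log = TRUE)
  )
  logB[logB < log(1e-300)] <- log(1e-300) # keep path scores finite
  logA <- log(params$transition)
  v <- log(params$initial) + logB[1, ]
  back <- matrix(0L, n, 2)
  for (t in seq_len(n)[-1]) {
    cand <- v + logA # cand[i, j] = v[i] + logA[i, j]
    back[t, ] <- max.col(t(cand), ties.method = "first")
    v <- cand[cbind(back[t, ], 1:2)] + logB[t, ]
  }
  states <- integer(n)
  states[n] <- which.max(v) # which.max: first (lower state) on ties
  if (n > 1) {
    for (t in n:2) states[t - 1] <- back[t, states[t]]
  }
  structure(
    list(
      chrom = track$chrom, strand = track$strand,
      window_size = track$window_size, states = states - 1L,
      logprob = max(v)
    ),
    class = "state_path"
  )
}

#' @export
predict.tar_hmm <- function(object, tracks, ...) {
  if (inherits(tracks, "window_count_track") || is.numeric(tracks)) {
    return(decode(tracks, object))
  }
  lapply(tracks, decode, params = object)
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf(
    "<state_path> %s(%s)  %d windows, %d transcribed\n",
    x$chrom, x$strand, length(x$states), sum(x$states)
  ))
  invisible(x)
}

#' Turn a decoded state path into genomic intervals
#'
#' Maximal runs of the transcribed state become 0-based half-open genomic
#' intervals \code{[first_window*w, (last_window+1)*w)}, carried as a
#' sorted, strand-aware \code{GRanges}.
#'
#' @param path A \code{state_path} from \code{\link{decode}}.
#' @param seqlengths Optional named vector of chromosome lengths used to
#'   clip the last window to the chromosome end.
#' @return A \code{GRanges} of transcribed intervals (possibly empty).
#' @export
states_to_intervals <- function(path, seqlengths = NULL) {
  w <- path$window_size
  r <- rle(path$states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values == 1L
  if (!any(on)) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = path$chrom,
    ranges = IRanges::IRanges(
      start = (starts[on] - 1L) * w + 1L, # 1-based inclusive
      end = ends[on] * w
    ),
    strand = path$strand
  )
  if (!is.null(seqlengths) && path$chrom %in% names(seqlengths)) {
    GenomicRanges::end(gr) <- pmin(
      GenomicRanges::end(gr),
      seqlengths[[path$chrom]]
    )
  }
  sort(gr)
}

#' Indicator states over windows for a set of intervals
#'
#' The inverse of \code{\link{states_to_intervals}} on window-aligned
#' intervals: marks every window overlapping an interval as transcribed.
#'
#' @param intervals A \code{GRanges} on one chromosome/strand.
#' @param n_windows Number of windows in the track.
#' @param window_size Window width in bp.
#' @return An integer 0/1 vector of length \code{n_windows}.
#' @export
intervals_to_states <- function(intervals, n_windows, window_size) {
  states <- integer(n_windows)
  if (length(intervals)) {
    for (i in seq_along(intervals)) {
      from <- (GenomicRanges::start(intervals)[i] - 1L) %/% window_size + 1L
      to <- (GenomicRanges::end(intervals)[i] - 1L) %/% window_size + 1L
      states[from:min(to, n_windows)] <- 1L
    }
  }
  states
}
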