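#' Split a profile into maximal runs of consecutive non-missing bins
#'
#' Each arm boundary and each run of missing bins breaks a segment, so the
#' HMM never fills gaps over bins without Dam coverage and never bridges
#' arms. Length-1 segments are retained.
#'
#' @param profile a `RatioProfile`.
#' @param grid a `BinGrid`; defaults to the profile's own grid.
#' @return an `ObservationSegments` object: list of segments, each with
#'   `arm`, `first_bin` (global bin index), and `values`.
#' @export
segment_observations <- function(profile, grid = profile$grid) {
  stopifnot(inherits(profile, "RatioProfile"))
  if (profile$grid$n_bins != grid$n_bins)
    stop("profile is not aligned to the grid")
  segs <- list()
  a <- grid$assembly
  for (arm in a$arms) {
    n <- grid$n_per_arm[[arm]]
    off <- grid$offset[[arm]]
    ok <- !profile$mask[(off + 1):(off + n)]
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      idx <- (off + starts[k]):(off + ends[k])
      segs[[length(segs) + 1]] <- list(arm = arm, first_bin = idx[1],
                                       values = profile$value[idx])
    }
  }
  if (!length(segs)) warning("profile is fully masked: no segments")
  structure(segs, class = "ObservationSegments", grid = grid)
}

.gauss_dens <- function(y, means, vars) {
  # T x n matrix of emission densities, floored against total underflow
  B <- vapply(seq_along(means),
              function(j) stats::dnorm(y, means[j], sqrt(vars[j])),
              numeric(length(y)))
  if (is.null(dim(B))) B <- matrix(B, nrow = length(y))
  B[B < 1e-300] <- 1e-300
  B
}

# Scaled forward-backward for one segment. Returns loglik and sufficient
# statistics: gamma (T x n), summed xi (n x n), gamma at t = 1.
.forward_backward <- function(y, p) {
  n <- length(p$means)
  T <- length(y)
  B <- .gauss_dens(y, p$means, p$vars)
  A <- p$trans
  alpha <- matrix(0, T, n)
  cvec <- numeric(T)
  a <- p$init * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (T > 1) {
    for (t in 2:T) {
      a <- (alpha[t - 1, ] %*% A) * B[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
  }
  beta <- matrix(0, T, n)
  beta[T, ] <- 1
  if (T > 1) {
    for (t in (T - 1):1) {
      beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, n, n)
  if (T > 1) {
    W <- (B[2:T, , drop = FALSE] * beta[2:T, , drop = FALSE]) / cvec[2:T]
    xi <- A * (t(alpha[1:(T - 1), , drop = FALSE]) %*% W)
  }
  list(loglik = sum(log(cvec)), gamma = gamma, xi = xi, gamma1 = gamma[1, ])
}

#' Fit a Gaussian hidden Markov model to observation segments
#'
#' Baum-Welch EM over all segments jointly: parameters are shared, each
#' segment restarts its own chain from the initial distribution.
#' Initialization is deterministic — state means at the 25th/75th value
#' percentiles for two states (10th/50th/90th for three), all variances at
#' the global variance, self-transition probability 0.99, uniform initial
#' distribution — so refitting the same input reproduces the same model.
#' Iteration stops when the per-observation log-likelihood gain falls below
#' `tol` or after `max_iter` iterations. States are returned sorted by
#' ascending mean.
#'
#' @param segments an `ObservationSegments`.
#' @param n_states 2 or 3.
#' @param tol per-observation log-likelihood convergence threshold.
#' @param max_iter maximum EM iterations.
#' @param variance_floor lower bound on state variances (log2-ratio units
#'   squared), preventing emission collapse on constant runs.
#' @return an `HmmModel`: means, vars, trans, init, and fit metadata
#'   (`iterations`, `loglik`, `tol`, `converged`).
#' @export
fit_hmm <- function(segments, n_states = 2, tol = 1e-6, max_iter = 500,
                    variance_floor = 1e-3) {
  stopifnot(inherits(segments, "ObservationSegments"))
  stopifnot(n_states %in% c(2, 3))
  ys <- lapply(segments, `[[`, "values")
  obs <- unlist(ys)
  n_obs <- length(obs)
  if (n_obs < 10 * n_states)
    stop("need at least ", 10 * n_states, " observations to fit ",
         n_states, " states")
  gv <- stats::var(obs)
  if (!is.finite(gv) || gv < 1e-12)
    stop("degenerate data: observations have (near-)zero variance")
  probs <- if (n_states == 2) c(0.25, 0.75) else c(0.10, 0.50, 0.90)
  p <- list(means = unname(stats::quantile(obs, probs)),
            vars = pmax(rep(gv, n_states), variance_floor),
            trans = matrix(0.01 / (n_states - 1), n_states, n_states),
            init = rep(1 / n_states, n_states))
  diag(p$trans) <- 0.99
  ll_prev <- -Inf
  iter <- 0
  converged <- FALSE
  repeat {
    iter <- iter + 1
    ll <- 0
    xi_sum <- matrix(0, n_states, n_states)
    g1_sum <- numeric(n_states)
    s0 <- numeric(n_states); s1 <- numeric(n_states); s2 <- numeric(n_states)
    for (y in ys) {
      fb <- .forward_backward(y, p)
      ll <- ll + fb$loglik
      xi_sum <- xi_sum + fb$xi
      g1_sum <- g1_sum + fb$gamma1
      s0 <- s0 + colSums(fb$gamma)
      s1 <- s1 + colSums(fb$gamma * y)
      s2 <- s2 + colSums(fb$gamma * y^2)
    }
    # M step
    rs <- rowSums(xi_sum)
    newA <- p$trans
    upd <- rs > 0
    newA[upd, ] <- xi_sum[upd, , drop = FALSE] / rs[upd]
    p$trans <- newA
    p$init <- g1_sum / sum(g1_sum)
    mu <- s1 / s0
    p$means <- mu
    p$vars <- pmax(s2 / s0 - mu^2, variance_floor)
    if (is.finite(ll_prev) && (ll - ll_prev) / n_obs < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
  }
  o <- order(p$means)
  structure(list(n_states = n_states,
                 means = p$means[o], vars = p$vars[o],
                 trans = p$trans[o, o, drop = FALSE],
                 init = p$init[o],
                 iterations = iter, loglik = ll, tol = tol,
                 converged = converged,
                 variance_floor = variance_floor),
            class = "HmmModel")
}

#' @export
print.HmmModel <- function(x, ...) {
  cat("HmmModel:", x$n_states, "states;",
      x$iterations, "EM iterations; logLik", format(x$loglik), "\n")
  cat("  means:", paste(format(x$means, digits = 4), collapse = ", "), "\n")
  cat("  sds:  ", paste(format(sqrt(x$vars), digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Log-likelihood sequence across EM iterations
#'
#' Re-runs EM recording the per-iteration log-likelihood; used to check the
#' monotonicity guarantee of Baum-Welch.
#'
#' @inheritParams fit_hmm
#' @return numeric vector of log-likelihoods, one per iteration.
#' @export
hmm_loglik_trace <- function(segments, n_states = 2, max_iter = 20,
                             variance_floor = 1e-3) {
  ys <- lapply(segments, `[[`, "values")
  obs <- unlist(ys)
  gv <- stats::var(obs)
  probs <- if (n_states == 2) c(0.25, 0.75) else c(0.10, 0.50, 0.90)
  p <- list(means = unname(stats::quantile(obs, probs)),
            vars = pmax(rep(gv, n_states), variance_floor),
            trans = matrix(0.01 / (n_states - 1), n_states, n_states),
            init = rep(1 / n_states, n_states))
  diag(p$trans) <- 0.99
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    ll <- 0
    xi_sum <- matrix(0, n_states, n_states)
    g1_sum <- numeric(n_states)
    s0 <- numeric(n_states); s1 <- numeric(n_states); s2 <- numeric(n_states)
    for (y in ys) {
      fb <- .forward_backward(y, p)
      ll <- ll + fb$loglik
      xi_sum <- xi_sum + fb$xi
      g1_sum <- g1_sum + fb$gamma1
      s0 <- s0 + colSums(fb$gamma)
      s1 <- s1 + colSums(fb$gamma * y)
      s2 <- s2 + colSums(fb$gamma * y^2)
    }
    trace <- c(trace, ll)
    rs <- rowSums(xi_sum)
    upd <- rs > 0
    p$trans[upd, ] <- xi_sum[upd, , drop = FALSE] / rs[upd]
    p$init <- g1_sum / sum(g1_sum)
    mu <- s1 / s0
    p$means <- mu
    p$vars <- pmax(s2 / s0 - mu^2, variance_floor)
  }
  trace
}

#' Viterbi decoding of one observation sequence
#'
#' Most probable state path under an `HmmModel`, computed in log space.
#' States are indexed in the model's ascending-mean order.
#'
#' @param values numeric observation sequence.
#' @param model an `HmmModel`.
#' @return integer state path (1 = lowest-mean state).
#' @export
viterbi_path <- function(values, model) {
  n <- model$n_states
  T <- length(values)
  logB <- log(.gauss_dens(values, model$means, model$vars))
  logA <- log(model$trans)
  delta <- matrix(-Inf, T, n)
  psi <- matrix(0L, T, n)
  delta[1, ] <- log(model$init) + logB[1, ]
  if (T > 1) {
    for (t in 2:T) {
      m <- delta[t - 1, ] + logA  # n x n: [i, j]
      psi[t, ] <- max.col(t(m), ties.method = "first")
      delta[t, ] <- m[cbind(psi[t, ], seq_len(n))] + logB[t, ]
    }
  }
  path <- integer(T)
  path[T] <- which.max(delta[T, ])
  if (T > 1) for (t in (T - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Log-probability of a given state path
#'
#' Joint log density of path and observations under the model; used by the
#' exhaustive-enumeration oracle for Viterbi.
#'
#' @param values observation sequence.
#' @param path integer state path of equal length.
#' @param model an `HmmModel`.
#' @return log joint probability.
#' @export
hmm_path_logprob <- function(values, path, model) {
  logB <- log(.gauss_dens(values, model$means, model$vars))
  lp <- log(model$init[path[1]]) + logB[1, path[1]]
  if (length(values) > 1) {
    for (t in 2:length(values)) {
      lp <- lp + log(model$trans[path[t - 1], path[t]]) + logB[t, path[t]]
    }
  }
  lp
}

#' Call domains from a fitted model
#'
#' Viterbi-decodes every segment and merges runs of bins assigned the
#' highest-mean state into domain intervals. With three states only the top
#' state counts as domain — the middle state absorbs intermediate signal.
#' Domains never bridge missing runs or arm boundaries because decoding is
#' per segment.
#'
#' @param model an `HmmModel`.
#' @param segments the `ObservationSegments` the model was fitted on (or
#'   compatible).
#' @param grid the `BinGrid`; defaults to the segments' grid.
#' @param poi,cell_type labels for the returned `DomainSet`.
#' @return a `DomainSet`.
#' @export
decode_domains <- function(model, segments, grid = attr(segments, "grid"),
                           poi = "POI", cell_type = "sample") {
  stopifnot(inherits(model, "HmmModel"),
            inherits(segments, "ObservationSegments"))
  top <- which.max(model$means)
  mask <- logical(grid$n_bins)
  for (seg in segments) {
    path <- viterbi_path(seg$values, model)
    hit <- path == top
    if (any(hit)) {
      idx <- seg$first_bin + which(hit) - 1L
      mask[idx] <- TRUE
    }
  }
  domain_set(intervals_from_bins(grid, mask), poi = poi,
             cell_type = cell_type, assembly = grid$assembly)
}

#' Serialize a fitted model to JSON for audit
#'
#' @param model an `HmmModel`.
#' @param path output path.
#' @export
write_hmm_json <- function(model, path) {
  jsonlite::write_json(
    list(n_states = model$n_states, means = model$means, vars = model$vars,
         trans = model$trans, init = model$init,
         iterations = model$iterations, loglik = model$loglik,
         tol = model$tol, converged = model$converged),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' One-call domain calling from a profile
#'
#' Convenience wrapper: segment, fit, decode.
#'
#' @param profile a `RatioProfile`.
#' @param n_states 2 (Lam/HP1a) or 3 (Pc).
#' @param ... passed to [fit_hmm()].
#' @return list with `domains` (a `DomainSet`) and `model` (the `HmmModel`).
#' @export
call_domains <- function(profile, n_states = 2, ...) {
  segs <- segment_observations(profile)
  model <- fit_hmm(segs, n_states = n_states, ...)
  domains <- decode_domains(model, segs, poi = profile$poi,
                            cell_type = profile$cell_type)
  list(domains = domains, model = model)
}
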