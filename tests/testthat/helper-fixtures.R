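# Shared fixtures: tiny assemblies, random interval sets, and independent
# per-base / path-enumeration oracles the implementation is checked against.

tiny_assembly <- function(arms = c(A = 10000, B = 10000)) {
  genome_assembly(arms)
}

# random interval set on one 10-kb arm; bp-resolution coordinates
random_intervals <- function(arm, arm_len, n, max_len = 2000) {
  start <- floor(runif(n) * (arm_len - 1))
  len <- 1 + floor(runif(n) * pmin(max_len, arm_len - start - 1))
  interval_set(data.frame(arm = arm, start = start, end = start + len))
}

# plain arm/start/end data.frame, label attributes stripped
plain_intervals <- function(x) {
  data.frame(arm = x$arm, start = x$start, end = x$end,
             stringsAsFactors = FALSE)
}

# per-base boolean oracle: intervals on a single arm -> logical vector
as_base_vector <- function(x, arm, arm_len) {
  v <- logical(arm_len)
  rows <- x[x$arm == arm, , drop = FALSE]
  for (k in seq_len(nrow(rows))) {
    v[(rows$start[k] + 1):rows$end[k]] <- TRUE
  }
  v
}

base_vector_to_intervals <- function(v, arm) {
  if (!any(v)) return(interval_set(empty_intervals()))
  r <- rle(v)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  keep <- r$values
  interval_set(data.frame(arm = arm, start = s[keep], end = e[keep]))
}

# vectorized exhaustive enumeration of all state paths for short segments
brute_force_best_logprob <- function(y, model) {
  n <- model$n_states
  T <- length(y)
  P <- as.matrix(expand.grid(rep(list(seq_len(n)), T)))
  logB <- vapply(seq_len(n), function(j)
    dnorm(y, model$means[j], sqrt(model$vars[j]), log = TRUE),
    numeric(T))
  if (is.null(dim(logB))) logB <- matrix(logB, nrow = T)
  logA <- log(model$trans)
  lp <- log(model$init[P[, 1]]) + logB[cbind(1, P[, 1])]
  if (T > 1) {
    for (t in 2:T) {
      lp <- lp + logA[cbind(P[, t - 1], P[, t])] + logB[cbind(t, P[, t])]
    }
  }
  max(lp)
}

random_hmm_model <- function(n_states = 2) {
  means <- sort(rnorm(n_states, 0, 1.5))
  A <- matrix(runif(n_states^2, 0.05, 1), n_states)
  A <- A / rowSums(A)
  structure(list(n_states = n_states, means = means,
                 vars = runif(n_states, 0.05, 1), trans = A,
                 init = rep(1 / n_states, n_states)),
            class = "HmmModel")
}

# deterministic 3-bin grid for hand-computed normalization examples
three_bin_grid <- function() bin_grid(genome_assembly(c(A = 3000)), 1000)
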