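# Independent oracles: naive/brute-force re-derivations of the package's
# operations, kept deliberately separate from the implementation paths.

# Naive O(n^3) complete-linkage agglomeration: repeatedly merge the pair
# of clusters with the smallest maximum pairwise distance (ties: lowest
# cluster indices). Returns the merge sequence as sorted member sets with
# heights.
naive_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (is.null(best) || h < best$h) best <- list(i = i, j = j, h = h)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- list(members = merged, height = best$h)
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  merges
}

# Member sets and heights of an hclust tree's merge sequence.
hclust_merges <- function(tree) {
  n <- length(tree$order)
  members <- vector("list", n - 1L)
  lapply(seq_len(n - 1L), function(i) {
    get <- function(j) if (j < 0) -j else members[[j]]
    s <- sort(c(get(tree$merge[i, 1L]), get(tree$merge[i, 2L])))
    members[[i]] <<- s
    list(members = s, height = tree$height[i])
  })
}

# Hand-written Benjamini-Hochberg step-up adjustment.
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Hand product-limit estimator at the distinct event times.
hand_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# Brute-force Youden search by direct counting over every candidate
# threshold (midpoints of consecutive distinct values plus the extremes).
youden_brute <- function(values, labels) {
  v <- sort(unique(values))
  cands <- c(-Inf, if (length(v) > 1L) (v[-1L] + v[-length(v)]) / 2, Inf)
  best <- NULL
  for (cut in cands) {
    sens <- mean(values[labels == 1] >= cut)
    spec <- mean(values[labels == 0] < cut)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) best <- list(cut = cut, j = j)
  }
  best
}

# Exact Cox partial log-likelihood for untied data (one covariate).
cox_pll <- function(beta, times, events, x) {
  ll <- 0
  for (i in seq_along(times)) {
    if (events[i] == 1) {
      risk <- times >= times[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# Two-stage 1-D grid maximization of the Cox partial likelihood.
cox_grid_coef <- function(times, events, x, lo = -6, hi = 6) {
  coarse <- seq(lo, hi, by = 0.01)
  ll <- vapply(coarse, cox_pll, numeric(1L), times = times,
               events = events, x = x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-6)
  ll <- vapply(fine, cox_pll, numeric(1L), times = times,
               events = events, x = x)
  fine[which.max(ll)]
}

# Bernoulli log-likelihood for a two-group logistic model, maximized in
# closed form (group MLEs are the group response proportions).
logistic_group_lr <- function(y_high, n_high, y_low, n_low) {
  ll <- function(k, n) {
    p <- k / n
    if (p %in% c(0, 1)) return(0)
    k * log(p) + (n - k) * log(1 - p)
  }
  full <- ll(y_high, n_high) + ll(y_low, n_low)
  reduced <- ll(y_high + y_low, n_high + n_low)
  2 * (full - reduced)
}
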