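# Shared fixtures, built in code.

# Random subjects spanning both sexes with ages inside every registry band.
random_subjects <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    id = sprintf("R%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = runif(n, 18, 69.9),
    weight = runif(n, 40, 115),
    height = runif(n, 146, 192)
  )
}

# Brute-force steady-state oracle: evaluate every window with stats::sd
# directly and apply the same admission/tie rules as the implementation.
brute_force_window <- function(series, window = 600, cv_max = 0.10) {
  interval <- attr(series, "interval")
  nw <- as.integer(round(window / interval))
  starts <- seq_len(nrow(series) - nw + 1L)
  stats <- t(vapply(starts, function(i) {
    v1 <- series$vo2[i:(i + nw - 1L)]
    v2 <- series$vco2[i:(i + nw - 1L)]
    c(cv1 = if (mean(v1) > 0) sd(v1) / mean(v1) else Inf,
      cv2 = if (mean(v2) > 0) sd(v2) / mean(v2) else Inf)
  }, c(cv1 = 0, cv2 = 0)))
  ok <- stats[, "cv1"] <= cv_max & stats[, "cv2"] <= cv_max
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  best <- cand[which.min(stats[cand, "cv1"] + stats[cand, "cv2"])]
  list(start = series$t[best], cv_vo2 = stats[best, "cv1"],
       cv_vco2 = stats[best, "cv2"])
}

# Normal-equations OLS oracle: explicit solve of X'X b = X'y.
normal_equations_ols <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  b <- solve(t(X1) %*% X1, t(X1) %*% y)
  res <- y - X1 %*% b
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  list(coefficients = drop(b), r2 = 1 - sse / sst,
       rd = sqrt(sse / (length(y) - ncol(X1))))
}
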