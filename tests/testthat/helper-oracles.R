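# Independent brute-force oracles, deliberately written without reusing the
# package's code paths.

# closed-form simple OLS from raw sums
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ssr <- sum((fitted - mean(y))^2)
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - fitted)^2)
  list(slope = slope, intercept = intercept,
       r2_ssr = ssr / sst, r2_sse = 1 - sse / sst,
       resid_sd = sqrt(sse / (n - 2)))
}

# double-loop pixel-centre-in-circle count
circle_count_oracle <- function(side, diameter, center = rep((side - 1) / 2, 2)) {
  count <- 0
  for (r in 0:(side - 1)) {
    for (cc in 0:(side - 1)) {
      if (sqrt((r - center[1])^2 + (cc - center[2])^2) <= diameter / 2) {
        count <- count + 1
      }
    }
  }
  count
}

# uniform-colour strip image as a raw array
uniform_image <- function(rgb, side = 20) {
  array(rep(as.numeric(rgb), each = side * side), dim = c(side, side, 3))
}
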