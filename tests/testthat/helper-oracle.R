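# Independent brute-force Mamdani oracle. Shares no code with the engine:
# membership is evaluated region by region with scalar arithmetic, every
# rule is clipped on a dense grid in an explicit loop, and the centroid is
# the discrete center of mass of the aggregate.

oracle_mf <- function(mf, x) {
  k <- mf$knots
  if (mf$shape == "triangle") k <- c(k[1], k[2], k[2], k[3])
  a <- k[1]; b <- k[2]; cc <- k[3]; d <- k[4]
  y <- numeric(length(x))
  y[x >= b & x <= cc] <- 1
  rising <- x > a & x < b
  y[rising] <- (x[rising] - a) / (b - a)
  falling <- x > cc & x < d
  y[falling] <- (d - x[falling]) / (d - cc)
  y
}

oracle_infer <- function(fis, mda, donors) {
  res <- fis$options$resolution
  grid <- seq(fis$output$lower, fis$output$upper, length.out = res)
  clamp1 <- function(v, x) min(max(x, v$lower), v$upper)
  vals <- c(MDA = clamp1(fis$inputs$MDA, mda),
            DONORS_PROTONS = clamp1(fis$inputs$DONORS_PROTONS, donors))
  agg <- numeric(res)
  for (i in seq_len(nrow(fis$rules))) {
    s <- Inf
    for (v in names(fis$inputs)) {
      term <- fis$inputs[[v]]$terms[[fis$rules[[v]][i]]]
      s <- min(s, oracle_mf(term, vals[[v]]))
    }
    if (s > 0) {
      clipped <- pmin(s, oracle_mf(fis$output$terms[[fis$rules$consequent[i]]],
                                   grid))
      agg <- pmax(agg, clipped)
    }
  }
  sum(grid * agg) / sum(agg)
}

# Random in-universe input pairs, deterministic under seed.
random_inputs <- function(n, seed) {
  set.seed(seed)
  data.frame(MDA = runif(n, 1.1, 6.7),
             DONORS_PROTONS = runif(n, 38.5, 58.25))
}
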