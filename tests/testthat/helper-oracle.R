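# Independent brute-force oracles: explicit-loop implementations kept
# deliberately separate from the package's vectorised code paths.

naiveFeatures <- function(x, zc_t = 0, ssc_t = 0, wamp_t = 0, myop_t = 0,
                          v = 3) {
  n <- length(x)
  iemg <- 0; ssi <- 0
  for (xi in x) { iemg <- iemg + abs(xi); ssi <- ssi + xi^2 }
  mav <- iemg / n
  mmav1 <- 0; mmav2 <- 0
  for (i in seq_len(n)) {
    w1 <- if (i >= 0.25 * n && i <= 0.75 * n) 1 else 0.5
    w2 <- if (i >= 0.25 * n && i <= 0.75 * n) 1
          else if (i < 0.25 * n) 4 * i / n else 4 * (n - i) / n
    mmav1 <- mmav1 + w1 * abs(x[i])
    mmav2 <- mmav2 + w2 * abs(x[i])
  }
  mmav1 <- mmav1 / n; mmav2 <- mmav2 / n
  varr <- ssi / (n - 1); rms <- sqrt(ssi / n)
  mu <- sum(x) / n
  ss <- 0
  for (xi in x) ss <- ss + (xi - mu)^2
  stdv <- sqrt(ss / (n - 1))
  wl <- 0; d2 <- 0; zc <- 0; wamp <- 0
  for (i in seq_len(n - 1)) {
    d <- x[i + 1] - x[i]
    wl <- wl + abs(d); d2 <- d2 + d^2
    if (x[i] * x[i + 1] < 0 && abs(d) >= zc_t) zc <- zc + 1
    if (abs(d) >= wamp_t) wamp <- wamp + 1
  }
  dasdv <- sqrt(d2 / (n - 1)); aac <- wl / n
  lg <- 0
  for (xi in x) lg <- lg + log(abs(xi) + 1e-12)
  log_det <- exp(lg / n)
  iav <- 0
  for (i in seq_len(n - 1)) iav <- iav + (abs(x[i]) + abs(x[i + 1])) / 2
  vo <- 0
  for (xi in x) vo <- vo + abs(xi)^v
  vorder <- (vo / n)^(1 / v)
  ssc <- 0
  for (i in 2:(n - 1)) {
    p <- (x[i] - x[i - 1]) * (x[i] - x[i + 1])
    if (p >= ssc_t && p > 0) ssc <- ssc + 1
  }
  myop <- 0
  for (xi in x) if (abs(xi) >= myop_t) myop <- myop + 1
  myop <- myop / n
  m2 <- 0; m3 <- 0; m4 <- 0
  for (xi in x) {
    m2 <- m2 + (xi - mu)^2; m3 <- m3 + (xi - mu)^3; m4 <- m4 + (xi - mu)^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  kurt <- if (m2 == 0) NaN else m4 / m2^2
  skew <- if (m2 == 0) NaN else m3 / m2^1.5
  c(iemg = iemg, mav = mav, mmav1 = mmav1, mmav2 = mmav2, ssi = ssi,
    var = varr, rms = rms, std = stdv, wl = wl, dasdv = dasdv, aac = aac,
    log_det = log_det, iav = iav, vorder = vorder, zc = zc, ssc = ssc,
    wamp = wamp, myop = myop, kurt = kurt, skew = skew)
}

naiveFisher <- function(values, classes) {
  cl <- unique(classes)
  mu <- mean(values)
  num <- 0; den <- 0
  for (c in cl) {
    xi <- values[classes == c]
    ni <- length(xi); mui <- mean(xi)
    s2 <- 0
    for (v in xi) s2 <- s2 + (v - mui)^2
    s2 <- s2 / ni
    num <- num + ni * (mui - mu)^2
    den <- den + ni * s2
  }
  num / den
}

# average ranks computed from first principles (no rank())
naiveRanks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    below <- 0; ties <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) below <- below + 1
      if (x[j] == x[i]) ties <- ties + 1
    }
    r[i] <- below + (ties + 1) / 2
  }
  r
}

naiveSpearman <- function(a, b) {
  ra <- naiveRanks(a); rb <- naiveRanks(b)
  ma <- mean(ra); mb <- mean(rb)
  num <- sum((ra - ma) * (rb - mb))
  num / sqrt(sum((ra - ma)^2) * sum((rb - mb)^2))
}
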