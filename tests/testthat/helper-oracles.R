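# Independent oracles and tiny fixture builders shared across the suite.
# The brute-force log posterior below is deliberately written with explicit
# loops and raw lgamma arithmetic, independent of the package's likelihood
# path.

bruteNbLogPmf <- function(y, v, phi) {
  lgamma(y + phi) - lgamma(y + 1) - lgamma(phi) +
    phi * log(phi / (v + phi)) + y * log(v / (v + phi))
}

bruteLogPosterior <- function(state, data, hp) {
  ll <- 0
  for (i in seq_along(data$y)) {
    m <- data$members[[i]]
    th <- numeric(length(m))
    for (k in seq_along(m)) {
      eta <- state$beta0
      for (l in seq_len(ncol(data$X))) {
        eta <- eta + state$beta[l] * data$X[m[k], l]
      }
      th[k] <- exp(eta)
    }
    ll <- ll + bruteNbLogPmf(data$y[i], data$s[i] * mean(th), state$phi)
  }
  pr <- (hp@aPhi - 1) * log(state$phi) - hp@bPhi * state$phi +
    dnorm(state$beta0, 0, sqrt(hp@sigmaBetaSq), log = TRUE)
  for (l in seq_along(state$beta)) {
    pr <- pr + if (state$gamma[l] == 1L) {
      dnorm(state$beta[l], 0, sqrt(hp@sigmaBetaSq), log = TRUE) +
        log(hp@piGamma)
    } else {
      log(1 - hp@piGamma)
    }
  }
  ll + pr
}

# random small grouped-count instance with L covariates
tinyInstance <- function(seed, N = 3L, L = 2L, cellsPer = 2L) {
  set.seed(seed)
  M <- N * cellsPer
  members <- split(seq_len(M), rep(seq_len(N), each = cellsPer))
  names(members) <- NULL
  X <- matrix(rnorm(M * L), M, L,
              dimnames = list(NULL, paste0("cov_", seq_len(L))))
  list(y = rpois(N, 4), s = exp(rnorm(N, 0, 0.2)),
       members = members, X = X, celltypeColumns = integer(0))
}

randomState <- function(seed, L = 2L) {
  set.seed(seed)
  gamma <- rbinom(L, 1L, 0.6)
  beta <- ifelse(gamma == 1L, rnorm(L), 0)
  GeneModelState(beta0 = rnorm(1), beta = beta, gamma = gamma,
                 phi = exp(rnorm(1, 0.5, 0.4)))
}

# Monte-Carlo standard error of a chain mean via batch means
batchSE <- function(x, nBatch = 25L) {
  bm <- tapply(x, cut(seq_along(x), nBatch), mean)
  stats::sd(bm) / sqrt(nBatch)
}

# small cached simulated dataset shared by light-weight tests
.tinySimCache <- new.env(parent = emptyenv())
tinySim <- function() {
  if (is.null(.tinySimCache$sim)) {
    .tinySimCache$sim <- simulateDataset(
      SimulationConfig(nSpots = 30L, nGenes = 4L, seed = 42L))
  }
  .tinySimCache$sim
}
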