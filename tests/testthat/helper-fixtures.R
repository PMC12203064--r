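# small builders shared across tests

makeCM <- function(m, station = "S1", time = seq_len(ncol(m)) - 1, env = NULL) {
  if (is.null(dimnames(m)))
    dimnames(m) <- list(sprintf("t%02d", seq_len(nrow(m))),
                        sprintf("s%02d", seq_len(ncol(m))))
  CommunityMatrix(m, station = station, time = time, env = env)
}

makePM <- function(m, station = "S1", time = seq_len(ncol(m)) - 1) {
  if (is.null(dimnames(m)))
    dimnames(m) <- list(sprintf("t%02d", seq_len(nrow(m))),
                        sprintf("s%02d", seq_len(ncol(m))))
  PresenceMatrix(m, station = station, time = time)
}

# monthly-ish irregular day grid
monthlyTimes <- function(n, seed = 1) {
  withr::with_seed(seed, cumsum(c(0, round(runif(n - 1, 24, 37)))))
}

# smooth, wide salinity forcing used by process-model tests
seasonalEnv <- function(times, mean = 22, amp = 9, arSD = 1.5, seed = 3,
                        period = 365) {
  withr::with_seed(seed, {
    ar <- as.numeric(stats::arima.sim(list(ar = 0.9), length(times), sd = arSD))
    data.frame(salinity = pmax(mean + amp * sin(2 * pi * times / period) +
                                 1.5 * sin(2 * pi * times / 97) + ar, 0))
  })
}
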