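# shared fixture builders (all fixtures are generated in code)

makePings <- function(n, t0 = as.POSIXct("2014-03-05 10:00:00", tz = "UTC"),
                      lat0 = 14.5, lon0 = -17.5, dt = 2, dlon = 5e-5) {
  data.frame(ping_index = seq_len(n),
             time_utc = t0 + (seq_len(n) - 1) * dt,
             lat = rep(lat0, n),
             lon = lon0 + (seq_len(n) - 1) * dlon)
}

makeSvGrid <- function(svDb, frequency = 38, depthTop = 10, binM = 1,
                       pings = NULL) {
  svDb <- as.matrix(svDb)
  if (is.null(pings)) pings <- makePings(nrow(svDb))
  svGrid(frequency, svDb = svDb,
         depthEdges = depthTop + binM * (0:ncol(svDb)), pings = pings)
}

# build a cell grid directly from sum/delta dB matrices
makeCellGrid <- function(sumDb, deltaDb, depthTop = 10, binM = 1,
                         pings = NULL) {
  sumDb <- as.matrix(sumDb); deltaDb <- as.matrix(deltaDb)
  m38 <- (sumDb - deltaDb) / 2
  m120 <- (sumDb + deltaDb) / 2
  if (is.null(pings)) pings <- makePings(nrow(sumDb))
  new("BiFreqCellGrid", mvbs38 = m38, mvbs120 = m120, fLow = 38, fHigh = 120,
      depthEdges = depthTop + binM * (0:ncol(sumDb)), pings = pings)
}

# the synthetic scenario configuration used across end-to-end tests:
# integration floor below the simulated noise floor so the weak 38 kHz
# channel is retained
scenarioConfig <- function(...) {
  pipelineConfig(svThresholdDb = -140, ...)
}
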