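# R-side wrapper for the compiled LSTM. The fixed-length feature vector is
# folded into a (seq_len)-step sequence: features are chunked in order into
# seq_len timesteps of ceiling(n_features/seq_len) channels, zero-padded at
# the tail. seq_len = n_features recovers the one-scalar-per-timestep
# reading.

.fold_sequence <- function(x, n_steps) {
  n <- nrow(x); nf <- ncol(x)
  T <- min(n_steps, nf)
  C <- ceiling(nf / T)
  arr <- array(0, dim = c(n, C, T))
  for (t in seq_len(T)) {
    cols <- ((t - 1) * C + 1):min(t * C, nf)
    arr[, seq_along(cols), t] <- x[, cols]
  }
  arr
}

.lstm_fit_wrapper <- function(x, y, hp, seed) {
  arr <- .fold_sequence(x, hp$seq_len)
  fit <- lstm_fit_cpp(arr, as.numeric(y), as.integer(hp$units),
                      as.integer(hp$layers), hp$dropout, hp$learning_rate,
                      as.integer(hp$epochs), as.integer(hp$batch_size),
                      as.integer(seed))
  fit$seq_len <- hp$seq_len
  fit
}

.lstm_predict_wrapper <- function(state, x) {
  arr <- .fold_sequence(x, state$seq_len)
  as.numeric(lstm_predict_cpp(state, arr))
}
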