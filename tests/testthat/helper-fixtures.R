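# Shared fixtures: small simulated recordings and brute-force oracles.

# Identity-coupling config: each motion drives only its own channel.
identity_config <- function(diag_mv = 0.3, seed = NULL, ...) {
  m <- matrix(0, 5L, 5L,
              dimnames = list(default_motions(), paste0("Ch", 1:5)))
  diag(m) <- diag_mv
  sim_config(coupling = m, seed = seed, ...)
}

# Train a classifier from one simulated session; returns list(model, cfg).
trained_model <- function(cfg = sim_config(seed = 1),
                          plan = session_plan()) {
  rec <- make_training_session(cfg, plan)
  ts <- extract_training_set(rec, plan)
  list(model = fit_lda(ts$x, ts$y), training = ts, rec = rec)
}

# Brute-force loop oracles for the four time-domain features.
oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}
oracle_wl <- function(x) {
  s <- 0
  for (k in seq_len(length(x) - 1L)) s <- s + abs(x[k + 1L] - x[k])
  s
}
oracle_zc <- function(x, eps) {
  n <- 0L
  for (k in seq_len(length(x) - 1L))
    if (x[k] * x[k + 1L] < 0 && abs(x[k] - x[k + 1L]) >= eps) n <- n + 1L
  n
}
oracle_ssc <- function(x, eps) {
  n <- 0L
  for (k in 2:(length(x) - 1L)) {
    l <- x[k] - x[k - 1L]
    r <- x[k] - x[k + 1L]
    if (l * r > 0 && max(abs(l), abs(r)) >= eps) n <- n + 1L
  }
  n
}

# Full Gaussian log-density Bayes oracle with shared covariance:
# evaluates -0.5 (x-mu)' Sigma^{-1} (x-mu) + log pi_k by solve(), picks the
# argmax (first label on ties).
oracle_bayes <- function(m, x) {
  si <- solve(m$cov)
  apply(x, 1L, function(row) {
    ll <- vapply(seq_along(m$labels), function(k) {
      d <- row - m$means[k, ]
      -0.5 * drop(t(d) %*% si %*% d) + log(m$priors[k])
    }, numeric(1L))
    m$labels[which.max(ll)]
  })
}

# Sliding-window modal-label oracle for the majority vote (previous-output,
# then label-order tie-break), written as direct enumeration.
oracle_vote <- function(stream, L, labels) {
  out <- character(length(stream))
  prev <- NA_character_
  for (t in seq_along(stream)) {
    win <- stream[max(1L, t - L + 1L):t]
    best <- -1L
    tied <- character(0)
    for (lab in labels) {
      cnt <- sum(win == lab)
      if (cnt > best) {
        best <- cnt
        tied <- lab
      } else if (cnt == best) tied <- c(tied, lab)
    }
    out[t] <- if (!is.na(prev) && prev %in% tied) prev else tied[1L]
    prev <- out[t]
  }
  out
}
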