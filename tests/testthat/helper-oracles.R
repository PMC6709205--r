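# Independent oracles used across the test suite. These deliberately avoid
# the package's own computational paths: plain R loops, closed forms, a
# fine-step explicit-Euler integrator and a linear-programming formulation
# of the dip.

# ---- fine-step explicit Euler integration of the calcium/indicator model ----
euler_oracle <- function(params, protocol, duration, dt, refine = 100) {
  h <- dt / refine
  n_coarse <- as.integer(round(duration / dt))
  n_fine <- (n_coarse - 1L) * refine + 1L
  pulses <- build_pulse_train(protocol)
  # pulses at the same (coarse-grid) times the integrator uses; the oracle
  # refines the integration step, not the pulse quantisation
  is_pulse <- logical(n_fine)
  if (length(pulses)) {
    ps <- (as.integer(round(pulses / dt))) * refine + 1L
    is_pulse[ps[ps >= 1L & ps <= n_fine]] <- TRUE
  }
  k_tot <- params$k_serca + params$k_pmca
  cc <- (params$k_serca * params$baseline_ca + params$leak) / k_tot
  act <- params$indicator_kon * cc^params$hill_n
  bb <- params$indicator_total * act / (act + params$indicator_koff)
  amp <- params$influx_per_ap * params$bath_ca_factor
  c_out <- numeric(n_coarse)
  b_out <- numeric(n_coarse)
  j <- 1L
  for (s in seq_len(n_fine)) {
    if (is_pulse[s]) cc <- cc + amp
    if ((s - 1L) %% refine == 0L) {
      c_out[j] <- cc
      b_out[j] <- bb
      j <- j + 1L
    }
    dc <- -params$k_serca * (cc - params$baseline_ca) - params$k_pmca * cc + params$leak
    a <- params$indicator_kon * cc^params$hill_n
    db <- a * (params$indicator_total - bb) - params$indicator_koff * bb
    cc <- cc + h * dc
    bb <- bb + h * db
  }
  list(calcium = c_out, bound = b_out,
       fluor = params$f_rest + params$f_gain * b_out)
}

rel_sup_err <- function(a, b) max(abs(a - b)) / max(abs(b))

# ---- LP formulation of the dip: exact minimal sup-distance per mode ----
dip_lp_mode <- function(u, F_at, F_before, t, t_is_sample, maxiter = 400) {
  left_idx <- which(u < t)
  right_idx <- which(u > t)
  pL <- c(u[left_idx], t)
  pR <- c(t, u[right_idx])
  nL <- length(pL); nR <- length(pR)
  nv <- nL + nR + 1
  iD <- nv
  A <- NULL; b <- NULL
  row0 <- function() numeric(nv)
  if (t_is_sample) {
    j <- match(t, u)
    loA <- hiA <- F_before[j]
    loB <- hiB <- F_at[j]
  } else {
    cc <- if (length(left_idx)) F_at[max(left_idx)] else 0
    loA <- hiA <- cc; loB <- hiB <- cc
  }
  for (k in seq_along(left_idx)) {
    j <- left_idx[k]
    r <- row0(); r[k] <- -1; r[iD] <- -1; A <- rbind(A, r); b <- c(b, -F_at[j])
    r <- row0(); r[k] <- 1; r[iD] <- -1; A <- rbind(A, r); b <- c(b, F_before[j])
  }
  r <- row0(); r[nL] <- -1; r[iD] <- -1; A <- rbind(A, r); b <- c(b, -loA)
  r <- row0(); r[nL] <- 1; r[iD] <- -1; A <- rbind(A, r); b <- c(b, hiA)
  r <- row0(); r[nL + 1] <- -1; r[iD] <- -1; A <- rbind(A, r); b <- c(b, -loB)
  r <- row0(); r[nL + 1] <- 1; r[iD] <- -1; A <- rbind(A, r); b <- c(b, hiB)
  for (k in seq_along(right_idx)) {
    j <- right_idx[k]; vi <- nL + 1 + k
    r <- row0(); r[vi] <- -1; r[iD] <- -1; A <- rbind(A, r); b <- c(b, -F_at[j])
    r <- row0(); r[vi] <- 1; r[iD] <- -1; A <- rbind(A, r); b <- c(b, F_before[j])
  }
  allidx <- c(seq_len(nL), nL + seq_len(nR))
  for (k in seq_len(length(allidx) - 1)) {
    r <- row0(); r[allidx[k]] <- 1; r[allidx[k + 1]] <- -1; A <- rbind(A, r); b <- c(b, 0)
  }
  for (k in allidx) { r <- row0(); r[k] <- 1; A <- rbind(A, r); b <- c(b, 1) }
  if (nL >= 3) for (k in 1:(nL - 2)) {
    d1 <- pL[k + 1] - pL[k]; d2 <- pL[k + 2] - pL[k + 1]
    r <- row0(); r[k] <- -d2; r[k + 1] <- d2 + d1; r[k + 2] <- -d1
    A <- rbind(A, r); b <- c(b, 0)
  }
  if (nR >= 3) for (k in 1:(nR - 2)) {
    d1 <- pR[k + 1] - pR[k]; d2 <- pR[k + 2] - pR[k + 1]
    r <- row0(); r[nL + k] <- d2; r[nL + k + 1] <- -(d2 + d1); r[nL + k + 2] <- d1
    A <- rbind(A, r); b <- c(b, 0)
  }
  cc <- row0(); cc[iD] <- 1
  # pracma::linprog pivots randomly and occasionally fails; seed and retry
  for (att in 1:6) {
    res <- tryCatch({
      set.seed(1000 + att)
      pracma::linprog(cc, A = A, b = b, maxiter = maxiter * att)
    }, error = function(e) NULL)
    if (!is.null(res) && res$errno == 1) return(res$fval)
  }
  NA_real_
}

dip_lp_oracle <- function(x, gap_points = 5) {
  x <- sort(x)
  n <- length(x)
  u <- unique(x)
  if (length(u) == 1L) return(0)
  F_at <- vapply(u, function(v) sum(x <= v), 0) / n
  F_before <- vapply(u, function(v) sum(x < v), 0) / n
  modes <- u
  tis <- rep(TRUE, length(u))
  if (gap_points > 0 && length(u) > 1) {
    for (k in 1:(length(u) - 1)) {
      g <- seq(u[k], u[k + 1], length.out = gap_points + 2)[2:(gap_points + 1)]
      modes <- c(modes, g)
      tis <- c(tis, rep(FALSE, gap_points))
    }
  }
  vals <- mapply(function(t, s) dip_lp_mode(u, F_at, F_before, t, s), modes, tis)
  min(vals, na.rm = TRUE)
}

# ---- synthetic dF/F traces with known decay, in the standard sweep frame ----
make_decay_dff <- function(decay_fun, t_peak = 6.2, duration = 28.16,
                           dt = 28.16 / 20000, onset = 5, peak = 60) {
  time <- seq(0, duration - dt, by = dt)
  v <- numeric(length(time))
  ris <- time >= onset & time < t_peak
  v[ris] <- peak * (time[ris] - onset) / (t_peak - onset)
  dec <- time >= t_peak
  v[dec] <- decay_fun(time[dec] - t_peak)
  structure(list(values = v, f0 = 438, time = time,
                 stimulus = stimulus_protocol(onset_time = onset)),
            class = "dff_trace")
}

# analytic |H(f)|^2 gain of a Butterworth low-pass applied forward+backward
butter_gain2 <- function(f, cutoff, order) (1 / (1 + (f / cutoff)^(2 * order)))^1
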