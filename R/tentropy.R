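# equal-width discretization onto 1..bins
discretize <- function(v, bins) {
  r <- range(v)
  if (r[2] - r[1] < 1e-12) stop_tdcf("constant series cannot be binned",
                                     class = "tdcf_degenerate")
  pmin(bins, 1L + floor((v - r[1]) / (r[2] - r[1]) * bins))
}

# plug-in Shannon entropy (bits) of integer code vectors; extra columns are
# combined into joint codes
entropy_codes <- function(...) {
  cols <- list(...)
  code <- cols[[1]]
  if (length(cols) > 1L) {
    base <- max(code) + 1
    for (k in 2:length(cols)) {
      code <- code + cols[[k]] * base
      base <- base * (max(cols[[k]]) + 1)
    }
  }
  p <- tabulate(match(code, unique(code)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

# delay-embedded past matrix: row t holds x[t], x[t-tau], ..., x[t-(m-1)tau]
embed_delay <- function(x, m, tau) {
  n <- length(x)
  t0 <- (m - 1L) * tau + 1L
  idx <- outer(t0:n, (0:(m - 1L)) * tau, `-`)
  matrix(x[idx], ncol = m)
}

#' Minimal embedding dimension by false nearest neighbors
#'
#' Kennel-style estimate of the delay-embedding dimension of a scalar series:
#' for each trial dimension m the nearest neighbour of every delay vector is
#' found and declared false if the extra (m+1)-th coordinate either stretches
#' the neighbour distance by more than `rtol` or beyond `atol` standard
#' deviations. The smallest m whose false fraction falls below `threshold` is
#' returned; if none does below `max_m`, `max_m` is returned with a flag.
#'
#' @param x Numeric vector, [angle_series] or [fluctuations()] series.
#' @param max_m Largest dimension tried.
#' @param tau Embedding delay in samples.
#' @param threshold Acceptable false-neighbour fraction.
#' @param rtol,atol Kennel distance-ratio and loneliness criteria.
#' @param n_max Series longer than this are truncated before the O(n^2)
#'   neighbour search (truncation, not thinning, so the delay keeps its
#'   meaning in samples).
#' @return Integer m with attributes `fractions` (per trial dimension) and
#'   `converged`.
#' @export
fnn_embedding <- function(x, max_m = 6L, tau = 1L, threshold = 0.05,
                          rtol = 10, atol = 2, n_max = 600L) {
  if (inherits(x, "angle_series")) x <- fluctuations(x)
  if (inherits(x, "fluct_series")) x <- x$dev_deg
  if (stats::sd(x) < 1e-12)
    stop_tdcf("constant series has no embedding", class = "tdcf_degenerate")
  if (length(x) > n_max) x <- x[seq_len(n_max)]
  n <- length(x)
  if (n < (max_m + 1L) * tau + 10L) stop("series too short for max_m = ", max_m)
  sdx <- stats::sd(x)
  fracs <- numeric(max_m)
  for (m in seq_len(max_m)) {
    E <- embed_delay(x, m, tau)
    nxt <- x[seq((m - 1L) * tau + 1L, n) + m * tau]   # (m+1)-th coordinate
    keep <- seq_len(length(nxt[!is.na(nxt)]))
    E <- E[keep, , drop = FALSE]; nxt <- nxt[keep]
    dm <- as.matrix(stats::dist(E))
    diag(dm) <- Inf
    # Theiler window: exclude temporally adjacent points as neighbours
    w <- tau
    for (off in seq_len(w)) {
      ii <- seq_len(nrow(dm) - off)
      dm[cbind(ii, ii + off)] <- Inf
      dm[cbind(ii + off, ii)] <- Inf
    }
    nb <- apply(dm, 1, which.min)
    d0 <- dm[cbind(seq_along(nb), nb)]
    extra <- abs(nxt - nxt[nb])
    false <- (extra / pmax(d0, 1e-12) > rtol) |
             (sqrt(d0^2 + extra^2) / sdx > atol)
    fracs[m] <- mean(false)
    if (fracs[m] <= threshold)
      return(structure(m, fractions = fracs[seq_len(m)], converged = TRUE))
  }
  structure(max_m, fractions = fracs, converged = FALSE)
}

#' Delayed mutual information between two series
#'
#' Plug-in histogram mutual information (bits) between x(t) and y(t + delay)
#' over a grid of delays, and the delay at which MI is largest — the embedding
#' interval used for transfer entropy. At zero delay MI is symmetric in its
#' arguments; for y identical to x it equals the marginal entropy of binned x.
#'
#' @param x,y Numeric vectors, [angle_series] or fluctuation series on a
#'   common grid.
#' @param delays Integer delays (samples); may include negative values.
#' @param bins Histogram bins per axis.
#' @return List with `table` (delay, mi_bits), `tau_opt` (argmax delay) and
#'   `bins`.
#' @export
delayed_mi <- function(x, y, delays = 0:20, bins = 8L) {
  as_vec <- function(v) {
    if (inherits(v, "angle_series")) v <- fluctuations(v)
    if (inherits(v, "fluct_series")) v <- v$dev_deg
    v
  }
  x <- as_vec(x); y <- as_vec(y)
  n <- length(x)
  stopifnot(length(y) == n)
  bx <- discretize(x, bins); by <- discretize(y, bins)
  mi <- vapply(delays, function(d) {
    tx <- seq(max(1L, 1L - d), min(n, n - d))
    if (length(tx) < 10L) stop_tdcf("delay %d leaves no overlap", d,
                                    class = "tdcf_alignment")
    a <- bx[tx]; b <- by[tx + d]
    entropy_codes(a) + entropy_codes(b) - entropy_codes(a, b)
  }, numeric(1))
  list(table = data.frame(delay = delays, mi_bits = mi),
       tau_opt = delays[which.max(mi)], bins = bins)
}

#' Histogram transfer entropy
#'
#' Plug-in estimate of the information flow x to y,
#' \deqn{TE(x \to y) = H(y_{next} \mid y_{past}) - H(y_{next} \mid y_{past}, x_{past})}
#' with m-length, tau-spaced delay-embedded pasts and equal-width histograms
#' (`bins` per axis). The plug-in estimator is nonnegative by construction
#' and biased upward for sparse histograms; `n_shuffle > 0` additionally
#' reports the mean TE under circular shifts of x (the bias level, to which a
#' shuffled or independent source decays). A mean occupancy below 5 counts
#' per occupied joint bin triggers an undersampling warning.
#'
#' @param x,y Source and target series (vectors or series objects).
#' @param m Embedding dimension (see [fnn_embedding()]).
#' @param tau Embedding interval in samples (see [delayed_mi()]).
#' @param bins Histogram bins per axis.
#' @param n_shuffle Number of circular-shift surrogates for the bias estimate.
#' @param seed Seed for the surrogate offsets.
#' @return List with `te_bits`, `te_bias_bits` (NA when `n_shuffle = 0`),
#'   `m`, `tau`, `bins`, `n_samples`, `mean_occupancy`.
#' @export
transfer_entropy <- function(x, y, m = 1L, tau = 1L, bins = 8L,
                             n_shuffle = 0L, seed = 1L) {
  as_vec <- function(v) {
    if (inherits(v, "angle_series")) v <- fluctuations(v)
    if (inherits(v, "fluct_series")) v <- v$dev_deg
    v
  }
  x <- as_vec(x); y <- as_vec(y)
  n <- length(x)
  stopifnot(length(y) == n, m >= 1L, tau >= 1L)
  bx <- discretize(x, bins); by <- discretize(y, bins)
  te_of <- function(bx) {
    t0 <- (m - 1L) * tau + 1L
    tt <- t0:(n - 1L)                     # past ends at t, next is t + 1
    yp <- embed_delay(by, m, tau)[tt - t0 + 1L, , drop = FALSE]
    xp <- embed_delay(bx, m, tau)[tt - t0 + 1L, , drop = FALSE]
    yn <- by[tt + 1L]
    ypc <- do.call(entropy_joint_code, asplit(yp, 2))
    xpc <- do.call(entropy_joint_code, asplit(xp, 2))
    h_yn_yp <- entropy_codes(yn, ypc)
    h_yp <- entropy_codes(ypc)
    h_all <- entropy_codes(yn, ypc, xpc)
    h_yp_xp <- entropy_codes(ypc, xpc)
    list(te = (h_yn_yp - h_yp) - (h_all - h_yp_xp),
         occ = length(yn) / length(unique(yn + (bins + 1) * ypc +
                                          (bins + 1)^(m + 1) * xpc)))
  }
  obs <- te_of(bx)
  if (obs$occ < 5)
    warning(sprintf("undersampled histograms: mean occupancy %.1f counts per occupied bin",
                    obs$occ))
  bias <- NA_real_
  if (n_shuffle > 0L) {
    set.seed(seed)
    offs <- sample(seq(tau * m + 1L, n - tau * m), n_shuffle, replace = TRUE)
    bias <- mean(vapply(offs, function(o)
      te_of(bx[c(o:n, seq_len(o - 1L))])$te, numeric(1)))
  }
  list(te_bits = obs$te, te_bias_bits = bias, m = m, tau = tau, bins = bins,
       n_samples = n - (m - 1L) * tau - 1L, mean_occupancy = obs$occ)
}

# combine integer columns into a single joint code
entropy_joint_code <- function(...) {
  cols <- list(...)
  code <- as.integer(cols[[1]])
  base <- max(code) + 1L
  if (length(cols) > 1L) for (k in 2:length(cols)) {
    ck <- as.integer(cols[[k]])
    code <- code + ck * base
    base <- base * (max(ck) + 1L)
  }
  code
}

#' Direction assignment by transfer entropy, compared with the TDCF direction
#'
#' Computes transfer entropy in both directions for a residue pair (embedding
#' dimension from [fnn_embedding()] on each series, embedding interval from
#' the delayed-MI optimum), assigns the direction of information flow to the
#' larger TE magnitude, and — when the Laplace-domain comparison is requested
#' — flags whether it agrees with the TDCF direction (larger |F_ext|) for the
#' same pair. Symmetric outcomes are reported as ties.
#'
#' @param xi,xj The two series ([angle_series] or fluctuation series).
#' @param bins,max_m,delays Estimator knobs, see [transfer_entropy()],
#'   [fnn_embedding()], [delayed_mi()]. `max_m` caps the embedding dimension
#'   at a histogram-feasible value: the joint histogram has bins^(2m+1) cells,
#'   so plug-in estimates need m small unless the series is very long;
#'   noise-driven series rarely satisfy the false-neighbour criterion anyway
#'   (the FNN result and its convergence flag are reported).
#' @param n_shuffle Surrogates for the bias estimate (0 to skip).
#' @param compare_tdcf Also compute the TDCF direction for the pair.
#' @param max_lag_ns,n_s Passed to the TDCF route when comparing.
#' @param seed Seed for surrogate offsets.
#' @return Object of class `te_result`: m, tau_embed (samples and ns), both
#'   TEs (bits), `direction` (`"i->j"`/`"j->i"`), `tie`, and when compared,
#'   `tdcf_direction` and `agreement_with_tdcf`.
#' @export
direction_by_te <- function(xi, xj, bins = 8L, max_m = 2L, delays = 1:20,
                            n_shuffle = 0L, compare_tdcf = TRUE,
                            max_lag_ns = NULL, n_s = 120L, seed = 1L) {
  fi <- as_fluct(xi); fj <- as_fluct(xj)
  fnn_i <- fnn_embedding(fi, max_m = max_m)
  fnn_j <- fnn_embedding(fj, max_m = max_m)
  m <- max(fnn_i, fnn_j)
  stopifnot(all(delays >= 1L))
  tau <- delayed_mi(fi, fj, delays = delays, bins = bins)$tau_opt
  te_f <- transfer_entropy(fi, fj, m = m, tau = tau, bins = bins,
                           n_shuffle = n_shuffle, seed = seed)
  te_r <- transfer_entropy(fj, fi, m = m, tau = tau, bins = bins,
                           n_shuffle = n_shuffle, seed = seed + 1L)
  tie <- isTRUE(all.equal(abs(te_f$te_bits), abs(te_r$te_bits)))
  dir_te <- if (abs(te_f$te_bits) >= abs(te_r$te_bits)) "i->j" else "j->i"
  out <- list(i = fi$res_index, dof_i = fi$dof,
              j = fj$res_index, dof_j = fj$dof,
              m = m, fnn_converged = isTRUE(attr(fnn_i, "converged")) &&
                isTRUE(attr(fnn_j, "converged")),
              tau_embed = tau, tau_embed_ns = tau * fi$dt_ns,
              te_forward_bits = te_f$te_bits, te_reverse_bits = te_r$te_bits,
              te_forward_bias = te_f$te_bias_bits,
              te_reverse_bias = te_r$te_bias_bits,
              direction = dir_te, tie = tie, bins = bins)
  if (compare_tdcf) {
    f_f <- laplace_extremum(laplace_transform(
      tdcf_estimate(fi, fj, max_lag_ns), n_s = n_s))$F_ext
    f_r <- laplace_extremum(laplace_transform(
      tdcf_estimate(fj, fi, max_lag_ns), n_s = n_s))$F_ext
    out$tdcf_direction <- if (abs(f_f) >= abs(f_r)) "i->j" else "j->i"
    out$agreement_with_tdcf <- out$tdcf_direction == dir_te
  }
  structure(out, class = "te_result")
}

#' @export
print.te_result <- function(x, ...) {
  cat(sprintf("te_result %d-%d: m = %d, tau = %d, TE fwd %.3f rev %.3f bits -> %s%s\n",
              x$i, x$j, x$m, x$tau_embed, x$te_forward_bits,
              x$te_reverse_bits, x$direction,
              if (!is.null(x$agreement_with_tdcf))
                sprintf(" (TDCF %s, %s)", x$tdcf_direction,
                        if (x$agreement_with_tdcf) "agree" else "disagree")
              else ""))
  invisible(x)
}

#' @rdname direction_by_te
#' @param res A `te_result`.
#' @param path Output JSON file.
#' @export
write_te_json <- function(res, path) {
  jsonlite::write_json(unclass(res), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
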