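# derivative of MWC activity with respect to complex methylation
.dadm <- function(a, mwc) mwc$eps_m * a * (1 - a)

#' Linearize the mean-field model around its steady state
#'
#' Builds the ingredients of the linear noise approximation: the Jacobian
#' `A` of the deterministic drift at the steady state, the stoichiometry
#' matrix `S` of the elementary noise-carrying events, their steady-state
#' propensity vector `v`, and the diffusion matrix `D = S diag(v) S^T`.
#'
#' For the localized model the state is `(m, Rstar, Bstar)` (bulk CheB-P
#' adiabatically eliminated, its fluctuations folding into the CheB-P
#' tether-exchange channel) and the elementary events are: methylation and
#' demethylation (`m` changes by `+-2N/T_Tot` per catalytic event), CheR
#' tether binding/unbinding (`Rstar +- 1`), and CheB-P tether
#' binding/unbinding (`Bstar +- 1`).  Each event pair is tagged with its
#' noise channel (`"m"`, `"r"`, `"b"`); at stationarity the paired
#' propensities are equal.  For the B1 baseline the state is `(m, Bp)` with
#' channels `"m"` (catalysis) and `"b"` (phosphorylation/dephosphorylation).
#'
#' @param params [meanfield_params()] or [b1_params()].
#' @param steady the matching steady state ([mf_steady_state()] /
#'   [b1_steady_state()]); defaults to computing it at `L`.
#' @param L ligand (uM), used only if `steady` is missing.
#' @return Object of class `linearized_system`: list with `A`, `S`, `v`,
#'   `D`, `channels`, `state_names`, `steady`, `params`.
#' @export
mf_linearize <- function(params, steady = NULL, L = 0) {
  if (inherits(params, "b1_params")) return(.b1_linearize(params, steady, L))
  p <- params
  if (is.null(steady)) steady <- mf_steady_state(L, p)
  if (!steady$interior)
    stop("linearization requires an interior steady state", call. = FALSE)
  a <- steady$a0; Rs <- steady$Rstar; Bs <- steady$Bstar
  cc <- 2 * p$N / p$T_Tot
  dadm <- .dadm(a, p$mwc)
  phi <- p$a_p * a / (p$d_p + p$a_p * a)
  dphi <- p$a_p * p$d_p / (p$d_p + p$a_p * a)^2
  fr <- (1 - a) / ((1 - a) + p$K_r)     # CheR modsite occupancy fraction
  fb <- a / (a + p$K_b)                 # CheB-P modsite occupancy fraction
  dfr <- -p$K_r / ((1 - a) + p$K_r)^2   # d fr / d a
  dfb <- p$K_b / (a + p$K_b)^2          # d fb / d a
  # drift partials with respect to a, then chain through da/dm
  df1_da <- cc * (p$k_r * Rs * dfr - p$k_b * Bs * dfb)
  df2_da <- -p$k_t_minus_r * Rs * p$K_r / ((1 - a) + p$K_r)^2
  df3_da <- p$k_t_plus_b * (p$B_Tot - Bs) * dphi +
    p$k_t_minus_b * Bs * p$K_b / (a + p$K_b)^2
  A <- rbind(
    c(df1_da * dadm, cc * p$k_r * fr, -cc * p$k_b * fb),
    c(df2_da * dadm, -p$k_t_plus_r - p$k_t_minus_r * p$K_r / ((1 - a) + p$K_r), 0),
    c(df3_da * dadm, 0, -p$k_t_plus_b * phi - p$k_t_minus_b * p$K_b / (a + p$K_b)))
  v <- c(meth = p$k_r * steady$Rdouble,
         demeth = p$k_b * steady$Bdouble,
         r_bind = p$k_t_plus_r * (p$R_Tot - Rs),
         r_unbind = p$k_t_minus_r * Rs * p$K_r / ((1 - a) + p$K_r),
         b_bind = p$k_t_plus_b * steady$Bp,
         b_unbind = p$k_t_minus_b * Bs * p$K_b / (a + p$K_b))
  S <- cbind(c(cc, 0, 0), c(-cc, 0, 0),
             c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  channels <- c("m", "m", "r", "r", "b", "b")
  D <- S %*% diag(v) %*% t(S)
  structure(list(A = A, S = S, v = v, D = D, channels = channels,
                 state_names = c("m", "Rstar", "Bstar"),
                 steady = steady, params = p),
            class = "linearized_system")
}

.b1_linearize <- function(params, steady = NULL, L = 0) {
  p <- params
  if (is.null(steady)) steady <- b1_steady_state(L, p)
  if (!steady$interior)
    stop("linearization requires an interior steady state", call. = FALSE)
  a <- steady$a0; Bp <- steady$Bp
  cc <- 2 * p$N / p$T_Tot
  dadm <- .dadm(a, p$mwc)
  df1_da <- cc * (-p$k_r * p$R_Tot * p$K_r / ((1 - a) + p$K_r)^2 -
                    p$k_b * Bp * p$K_b / (a + p$K_b)^2)
  A <- rbind(c(df1_da * dadm, -cc * p$k_b * a / (a + p$K_b)),
             c(p$a_p * (p$B_Tot - Bp) * dadm, -p$a_p * a - p$d_p))
  v <- c(meth = p$k_r * p$R_Tot * (1 - a) / ((1 - a) + p$K_r),
         demeth = p$k_b * Bp * a / (a + p$K_b),
         phos = p$a_p * a * (p$B_Tot - Bp),
         dephos = p$d_p * Bp)
  S <- cbind(c(cc, 0), c(-cc, 0), c(0, 1), c(0, -1))
  channels <- c("m", "m", "b", "b")
  D <- S %*% diag(v) %*% t(S)
  structure(list(A = A, S = S, v = v, D = D, channels = channels,
                 state_names = c("m", "Bp"), steady = steady, params = p),
            class = "linearized_system")
}

#' Solve the stationary Lyapunov equation
#'
#' Computes the unique symmetric positive-semidefinite solution `sigma` of
#' `A sigma + sigma A^T + D = 0`, the stationary covariance of the
#' multivariate Ornstein-Uhlenbeck process `dx = A x dt + B dW` with
#' `B B^T = D`, for Hurwitz `A`.  Solved densely through the Kronecker
#' (vectorized) form; dimensions here are at most a handful, so no
#' iterative method is needed.  The residual is verified to `1e-10`
#' (relative).
#'
#' @param A square stable (Hurwitz) matrix.
#' @param D symmetric PSD diffusion matrix.
#' @return The covariance matrix `sigma`.
#' @export
solve_lyapunov <- function(A, D) {
  n <- nrow(A)
  stopifnot(ncol(A) == n, all(dim(D) == n))
  if (any(Re(eigen(A, only.values = TRUE)$values) >= 0))
    stop("A must be Hurwitz (all eigenvalues with negative real part)",
         call. = FALSE)
  I <- diag(n)
  M <- kronecker(I, A) + kronecker(A, I)
  sig <- matrix(solve(M, -as.vector(D)), n, n)
  sig <- (sig + t(sig)) / 2
  res <- A %*% sig + sig %*% t(A) + D
  scale <- max(abs(D), max(abs(sig)) * max(abs(A)), .Machine$double.eps)
  if (max(abs(res)) / scale > 1e-10)
    stop("Lyapunov residual too large: ", max(abs(res)) / scale,
         call. = FALSE)
  sig
}

#' Activity variance and its decomposition by noise source
#'
#' From the stationary covariance of the linearized system, the variance of
#' the output activity is `sigma_aa = (da/dm)^2 sigma_mm` (activity depends
#' on state only through the methylation level at fixed ligand).  Because
#' the Lyapunov equation is linear in the diffusion matrix, `sigma_aa`
#' decomposes exactly into the contributions of each noise channel: the
#' equation is re-solved with `D` restricted to one channel's columns of
#' the stoichiometry at a time, and the parts sum to the total by
#' construction (verified to `1e-10`).  For the localized model the
#' channels are fluctuations in localized CheR (`r`), localized CheB-P
#' (`b`) and intrinsic methylation noise (`m`).
#'
#' @param linearized a `linearized_system` from [mf_linearize()].
#' @return Object of class `covariance_result`: list with `sigma` (full
#'   state covariance), `sigma_aa`, `parts` (named by channel), `rel_noise`
#'   (`sqrt(sigma_aa)/a0`), `a0`.
#' @export
activity_variance <- function(linearized) {
  ln <- linearized
  stopifnot(inherits(ln, "linearized_system"))
  sig <- solve_lyapunov(ln$A, ln$D)
  dadm <- .dadm(ln$steady$a0, ln$params$mwc)
  sigma_aa <- dadm^2 * sig[1, 1]
  chs <- unique(ln$channels)
  parts <- setNames(numeric(length(chs)), chs)
  for (ch in chs) {
    keep <- ln$channels == ch
    Dk <- ln$S[, keep, drop = FALSE] %*% diag(ln$v[keep], sum(keep)) %*%
      t(ln$S[, keep, drop = FALSE])
    sk <- solve_lyapunov(ln$A, Dk)
    parts[ch] <- dadm^2 * sk[1, 1]
  }
  if (abs(sum(parts) - sigma_aa) > 1e-10 * max(sigma_aa, 1e-300))
    stop("variance decomposition does not sum to the total", call. = FALSE)
  structure(list(sigma = sig, sigma_aa = sigma_aa, parts = parts,
                 rel_noise = sqrt(sigma_aa) / ln$steady$a0,
                 a0 = ln$steady$a0),
            class = "covariance_result")
}

#' @export
print.covariance_result <- function(x, ...) {
  cat(sprintf("Activity noise: a0 = %.4f, sigma_aa = %.4g, sigma_a/a0 = %.2f%%\n",
              x$a0, x$sigma_aa, 100 * x$rel_noise))
  cat("  decomposition:",
      paste(sprintf("%s = %.3g", names(x$parts), x$parts), collapse = ", "),
      "\n")
  invisible(x)
}

#' One-call linear-noise analysis
#'
#' Convenience wrapper: steady state, linearization, Lyapunov solve and
#' variance decomposition for either model family.
#'
#' @param params [meanfield_params()] or [b1_params()].
#' @param L ligand (uM).
#' @return A `covariance_result` (see [activity_variance()]).
#' @export
mf_noise <- function(params, L = 0) {
  activity_variance(mf_linearize(params, L = L))
}

#' Simulate the mean-field Langevin equations
#'
#' Euler-Maruyama integration of the nonlinear mean-field model with
#' Gaussian noise sources whose instantaneous magnitudes are the square
#' roots of the elementary event propensities (the chemical Langevin
#' prescription), i.e. the stochastic differential equations whose
#' linearization is the LNA.  Used to validate the Lyapunov covariance and
#' to illustrate activity fluctuations; not a replacement for the exact
#' lattice simulation.
#'
#' @param params [meanfield_params()] or [b1_params()].
#' @param duration simulated time (s).
#' @param dt Euler step (s).
#' @param seed RNG seed.
#' @param L ligand (uM).
#' @param record_dt recording interval (s).
#' @param replicas number of independent replicate trajectories, integrated
#'   in parallel (vectorized); replicate 1 is returned in full, the others
#'   contribute to the ensemble statistics.
#' @return Data frame with `time`, `a` (replicate 1) and the state columns;
#'   the full ensemble activity matrix (time x replicas) is attached as
#'   attribute `"a_ensemble"`.
#' @export
mf_sde_simulate <- function(params, duration = 5000, dt = 0.05, seed,
                            L = 0, record_dt = 0.5, replicas = 1) {
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  b1 <- inherits(params, "b1_params")
  p <- params
  steady <- if (b1) b1_steady_state(L, p) else mf_steady_state(L, p)
  cc <- 2 * p$N / p$T_Tot
  R <- as.integer(replicas)
  # state rows; replicated columns
  m <- rep(steady$m0, R)
  if (b1) {
    Bp <- rep(steady$Bp, R)
  } else {
    Rs <- rep(steady$Rstar, R); Bs <- rep(steady$Bstar, R)
  }
  nstep <- ceiling(duration / dt)
  every <- max(1L, as.integer(round(record_dt / dt)))
  set.seed(seed)
  nrec <- nstep %/% every
  out_t <- numeric(nrec)
  out_a <- matrix(0, nrec, R)
  out_x1 <- matrix(0, nrec, if (b1) 2L else 3L)
  colnames(out_x1) <- if (b1) c("m", "Bp") else c("m", "Rstar", "Bstar")
  irec <- 0L
  sqdt <- sqrt(dt)
  act <- function(m) .clamp_a(mwc_activity(pmin(pmax(m, 0), 8 * p$N), L,
                                           p$mwc))
  for (i in seq_len(nstep)) {
    a <- act(m)
    if (b1) {
      Bp <- pmax(Bp, 0)
      v1 <- p$k_r * p$R_Tot * (1 - a) / ((1 - a) + p$K_r)
      v2 <- p$k_b * Bp * a / (a + p$K_b)
      v3 <- p$a_p * a * pmax(p$B_Tot - Bp, 0)
      v4 <- p$d_p * Bp
      m <- m + cc * (v1 - v2) * dt +
        cc * (sqrt(v1) * rnorm(R) - sqrt(v2) * rnorm(R)) * sqdt
      Bp <- Bp + (v3 - v4) * dt +
        (sqrt(v3) * rnorm(R) - sqrt(v4) * rnorm(R)) * sqdt
    } else {
      Rs <- pmax(Rs, 0); Bs <- pmax(Bs, 0)
      fr <- (1 - a) / ((1 - a) + p$K_r); fb <- a / (a + p$K_b)
      v1 <- p$k_r * Rs * fr
      v2 <- p$k_b * Bs * fb
      v3 <- p$k_t_plus_r * pmax(p$R_Tot - Rs, 0)
      v4 <- p$k_t_minus_r * Rs * p$K_r / ((1 - a) + p$K_r)
      phi <- p$a_p * a / (p$d_p + p$a_p * a)
      v5 <- p$k_t_plus_b * phi * pmax(p$B_Tot - Bs, 0)
      v6 <- p$k_t_minus_b * Bs * p$K_b / (a + p$K_b)
      m <- m + cc * (v1 - v2) * dt +
        cc * (sqrt(v1) * rnorm(R) - sqrt(v2) * rnorm(R)) * sqdt
      Rs <- Rs + (v3 - v4) * dt +
        (sqrt(v3) * rnorm(R) - sqrt(v4) * rnorm(R)) * sqdt
      Bs <- Bs + (v5 - v6) * dt +
        (sqrt(v5) * rnorm(R) - sqrt(v6) * rnorm(R)) * sqdt
    }
    m <- pmin(pmax(m, 0), 8 * p$N)
    if (i %% every == 0L) {
      irec <- irec + 1L
      out_t[irec] <- i * dt
      out_a[irec, ] <- act(m)
      out_x1[irec, ] <- if (b1) c(m[1], Bp[1]) else c(m[1], Rs[1], Bs[1])
    }
  }
  out <- data.frame(time = out_t, a = out_a[, 1], out_x1)
  attr(out, "a_ensemble") <- out_a
  out
}

#' Simulate a linear Ornstein-Uhlenbeck process
#'
#' Euler-Maruyama integration of `dx = A x dt + B dW` with `B` obtained
#' from the eigendecomposition of the PSD diffusion matrix `D = B B^T`.
#' Returns the empirical stationary covariance; the analytical answer is
#' [solve_lyapunov()].
#'
#' @param A Hurwitz drift matrix.
#' @param D diffusion matrix (symmetric PSD).
#' @param duration,dt integration horizon and step (time units of `A`).
#' @param seed RNG seed.
#' @param replicas number of independent replicate trajectories.
#' @return Estimated covariance matrix of the stationary process, pooled
#'   over time (after a one-fifth burn-in) and replicas.
#' @export
ou_covariance_sim <- function(A, D, duration = 500, dt = 0.005, seed,
                              replicas = 20) {
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  n <- nrow(A)
  es <- eigen((D + t(D)) / 2, symmetric = TRUE)
  B <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), n)
  nstep <- ceiling(duration / dt)
  burn <- nstep %/% 5
  set.seed(seed)
  X <- matrix(0, n, replicas)
  acc <- matrix(0, n, n); nacc <- 0
  sqdt <- sqrt(dt)
  for (i in seq_len(nstep)) {
    X <- X + (A %*% X) * dt + (B %*% matrix(rnorm(n * replicas), n)) * sqdt
    if (i > burn) { acc <- acc + X %*% t(X); nacc <- nacc + replicas }
  }
  acc / nacc
}
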