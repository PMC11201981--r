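# Generic damped Gauss-Newton (Levenberg-Marquardt) engine over a residual
# function.  Used by lma_fit() for the 4-parameter tumor problem and by the
# low-dimensional verification problems in the test suite.
#
# resid_fn(theta) -> numeric residual vector (same length every call)
# jac_fn(theta)   -> numeric matrix (n x p); defaults to central finite
#                    differences of resid_fn with per-parameter steps.
# project(theta)  -> parameter projection applied after every trial step
#                    (e.g. flooring a diameter); identity by default.
lm_control <- function(lambda0 = 1e-2, lambda_factor = 3, ftol = 1e-4,
                       xtol = 1e-4, maxit = 50, max_reject = 15) {
  list(lambda0 = lambda0, lambda_factor = lambda_factor, ftol = ftol,
       xtol = xtol, maxit = maxit, max_reject = max_reject)
}

fd_jacobian <- function(resid_fn, theta, steps, scheme = c("central", "forward"),
                        r0 = NULL) {
  scheme <- match.arg(scheme)
  p <- length(theta)
  cols <- vector("list", p)
  if (scheme == "forward" && is.null(r0)) r0 <- resid_fn(theta)
  for (j in seq_len(p)) {
    tp <- theta
    tp[j] <- theta[j] + steps[j]
    rp <- resid_fn(tp)
    if (scheme == "central") {
      tm <- theta
      tm[j] <- theta[j] - steps[j]
      rm <- resid_fn(tm)
      cols[[j]] <- (rp - rm) / (2 * steps[j])
    } else {
      cols[[j]] <- (rp - r0) / steps[j]
    }
  }
  do.call(cbind, cols)
}

lm_core <- function(resid_fn, theta0, scale, steps, project = identity,
                    jac_fn = NULL, control = lm_control()) {
  theta <- project(theta0)
  p <- length(theta)
  r <- resid_fn(theta)
  rms <- sqrt(mean(r^2))
  lambda <- control$lambda0
  traj <- list(data.frame(iteration = 0L, t(setNames(theta, paste0("p", seq_len(p)))),
                          rms = rms, lambda = lambda, accepted = TRUE))
  converged <- FALSE
  reason <- "maxit"
  nfev <- 1L
  it <- 0L

  if (rms == 0) {
    converged <- TRUE
    reason <- "zero-residual"
  } else {
    for (it in seq_len(control$maxit)) {
      J <- if (is.null(jac_fn)) fd_jacobian(resid_fn, theta, steps) else jac_fn(theta)
      nfev <- nfev + if (is.null(jac_fn)) 2L * p else 0L
      H <- crossprod(J)
      g <- crossprod(J, r)[, 1]
      dh <- diag(H)
      pos <- dh > 0
      dh[!pos] <- if (any(pos)) max(dh[pos]) * 1e-8 else 1

      accepted <- FALSE
      rejects <- 0L
      while (!accepted && rejects <= control$max_reject) {
        M <- H + lambda * diag(dh, p)
        delta <- tryCatch(solve(M, -g), error = function(e) NULL)
        if (is.null(delta)) {           # singular normal equations
          lambda <- lambda * control$lambda_factor
          rejects <- rejects + 1L
          next
        }
        theta_new <- project(theta + delta)
        r_new <- resid_fn(theta_new)
        nfev <- nfev + 1L
        rms_new <- sqrt(mean(r_new^2))
        traj[[length(traj) + 1L]] <- data.frame(
          iteration = it, t(setNames(theta_new, paste0("p", seq_len(p)))),
          rms = rms_new, lambda = lambda, accepted = rms_new < rms)
        if (rms_new < rms) {
          accepted <- TRUE
          drel <- (rms - rms_new) / max(rms, .Machine$double.eps)
          step_rel <- sqrt(sum(((theta_new - theta) / scale)^2))
          theta <- theta_new
          r <- r_new
          rms <- rms_new
          lambda <- max(lambda / control$lambda_factor, 1e-12)
          if (drel < control$ftol) {
            converged <- TRUE
            reason <- "ftol"
          } else if (step_rel < control$xtol) {
            converged <- TRUE
            reason <- "xtol"
          }
        } else {
          lambda <- lambda * control$lambda_factor
          rejects <- rejects + 1L
        }
      }
      if (!accepted) {
        reason <- "stalled"   # no step accepted at any damping level
        break
      }
      if (converged) break
    }
  }

  list(theta = theta, rms = rms, iterations = it, converged = converged,
       reason = reason, trajectory = do.call(rbind, traj), nfev = nfev,
       lambda = lambda)
}
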