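## Joint maximum-likelihood fitting.
##
## The free parameters are the model's shared log-weights plus, per marker,
## a mean effect delta and (random-effects mode) an unrestricted between-study
## variance tau2.  The log likelihood separates over markers given the
## weights, which the machinery below exploits twice: the finite-difference
## gradient obtains all per-marker partials from two vectorized corpus passes
## per block, and the information matrix is block-sparse (weights block,
## per-marker blocks, cross blocks) and inverted exactly by Schur complement.

PENALTY_NLL <- 1e10

default_fit_control <- function() {
  list(
    maxit = 300,          # BFGS iteration cap
    reltol = 1e-10,       # BFGS relative tolerance
    grad_step = 1e-6,     # central-difference step scale, gradient
    hess_step = 1e-4,     # central-difference step scale, information matrix
    gtol = 1e-5,          # gradient max-norm defining convergence
    newton_iter = 15,     # polishing Newton steps after BFGS
    warmup_rounds = 4,    # block-coordinate warm-up rounds before BFGS
    n_restarts = 3,       # jittered restarts when the Hessian check fails
    restart_sd = 0.25,    # jitter scale (log-weight / delta units)
    variance_floor = FALSE # constrain tau2 >= 0 instead of unrestricted ML
  )
}

## ---- parameter packing -----------------------------------------------------

theta_layout <- function(dat, model) {
  nw <- model$n_free_weights
  M <- dat$n_markers
  random <- model$effects == "random"
  list(
    nw = nw, M = M, random = random,
    n = nw + M + if (random) M else 0L,
    names = c(
      model$params,
      paste0("delta[", dat$markers, "]"),
      if (random) paste0("tau2[", dat$markers, "]")
    )
  )
}

unpack_theta <- function(theta, lay) {
  w <- if (lay$nw > 0) theta[seq_len(lay$nw)] else numeric(0)
  delta <- theta[lay$nw + seq_len(lay$M)]
  tau2 <- if (lay$random) theta[lay$nw + lay$M + seq_len(lay$M)] else
    rep(0, lay$M)
  list(w = w, delta = delta, tau2 = tau2)
}

pack_theta <- function(u, lay) {
  c(u$w, u$delta, if (lay$random) u$tau2)
}

## ---- starting values -------------------------------------------------------

## inverse-variance mean and DerSimonian-Laird moment estimate per marker
start_values <- function(dat, lay) {
  wts <- 1 / dat$s^2
  sw <- as.numeric(rowsum(wts, dat$im))
  swx <- as.numeric(rowsum(wts * dat$x, dat$im))
  sw2 <- as.numeric(rowsum(wts^2, dat$im))
  delta <- swx / sw
  tau2 <- rep(0, lay$M)
  if (lay$random) {
    q <- as.numeric(rowsum(wts * (dat$x - delta[dat$im])^2, dat$im))
    nm <- as.numeric(rowsum(rep(1, length(dat$x)), dat$im))
    cc <- sw - sw2 / sw
    tau2 <- ifelse(cc > 0, pmax(0, (q - (nm - 1)) / cc), 0) + 1e-6
  }
  list(w = rep(0, lay$nw), delta = delta, tau2 = tau2)
}

## ---- structured derivatives ------------------------------------------------

## largest safe symmetric tau2 step per marker (keeps all v > 0)
tau2_steps <- function(dat, tau2, scale) {
  h <- scale * pmax(1, abs(tau2))
  pmin(h, 0.45 * (dat$s2min + tau2))
}

## gradient of the log likelihood; per-marker partials come from two
## vectorized corpus passes per parameter block.  `ok` restricts the
## weight-parameter gradient to a marker subset (used by the polisher when
## boundary-chasing markers would contaminate the shared-weight coordinates).
grad_loglik <- function(dat, lay, u, step, ok = NULL) {
  tot <- if (is.null(ok)) function(f) f$total else
    function(f) sum(f$per_marker[ok])
  base <- NULL
  get_base <- function() {
    if (is.null(base)) base <<- eval_loglik(dat, u$w, u$delta, u$tau2)
    base
  }
  gw <- numeric(lay$nw)
  for (i in seq_len(lay$nw)) {
    h <- step * max(1, abs(u$w[i]))
    wp <- u$w; wp[i] <- wp[i] + h
    wm <- u$w; wm[i] <- wm[i] - h
    fp <- eval_loglik(dat, wp, u$delta, u$tau2)
    fm <- eval_loglik(dat, wm, u$delta, u$tau2)
    gw[i] <- if (fp$ok && fm$ok) (tot(fp) - tot(fm)) / (2 * h)
      else if (fp$ok && get_base()$ok) (tot(fp) - tot(get_base())) / h
      else if (fm$ok && get_base()$ok) (tot(get_base()) - tot(fm)) / h
      else NA_real_
  }
  hd <- step * pmax(1, abs(u$delta))
  fp <- eval_loglik(dat, u$w, u$delta + hd, u$tau2)
  fm <- eval_loglik(dat, u$w, u$delta - hd, u$tau2)
  gd <- if (fp$ok && fm$ok) (fp$per_marker - fm$per_marker) / (2 * hd)
    else rep(NA_real_, lay$M)
  gt <- NULL
  if (lay$random) {
    ht <- tau2_steps(dat, u$tau2, step)
    tp <- eval_loglik(dat, u$w, u$delta, u$tau2 + ht)
    tm <- eval_loglik(dat, u$w, u$delta, u$tau2 - ht)
    gt <- if (tp$ok && tm$ok) (tp$per_marker - tm$per_marker) / (2 * ht)
      else rep(NA_real_, lay$M)
  }
  c(gw, gd, gt)
}

## block-sparse Hessian of the log likelihood (central differences); `ok`
## restricts the weights block to a marker subset, as in grad_loglik
hessian_blocks <- function(dat, lay, u, step, ok = NULL) {
  ev <- function(w, delta, tau2) eval_loglik(dat, w, delta, tau2)
  tot <- if (is.null(ok)) function(f) f$total else
    function(f) sum(f$per_marker[ok])
  f0 <- ev(u$w, u$delta, u$tau2)
  if (!f0$ok) abort("Hessian requested at an invalid parameter point.")
  nw <- lay$nw
  M <- lay$M

  hw <- step * pmax(1, abs(u$w))
  shift_w <- function(i, s) { w <- u$w; w[i] <- w[i] + s * hw[i]; w }

  Hww <- matrix(0, nw, nw)
  if (nw > 0) {
    fwp <- lapply(seq_len(nw), function(i) ev(shift_w(i, 1), u$delta, u$tau2))
    fwm <- lapply(seq_len(nw), function(i) ev(shift_w(i, -1), u$delta, u$tau2))
    for (i in seq_len(nw)) {
      Hww[i, i] <- (tot(fwp[[i]]) - 2 * tot(f0) + tot(fwm[[i]])) / hw[i]^2
      if (i < nw) for (j in (i + 1):nw) {
        wpp <- shift_w(i, 1); wpp[j] <- wpp[j] + hw[j]
        wpm <- shift_w(i, 1); wpm[j] <- wpm[j] - hw[j]
        wmp <- shift_w(i, -1); wmp[j] <- wmp[j] + hw[j]
        wmm <- shift_w(i, -1); wmm[j] <- wmm[j] - hw[j]
        Hww[i, j] <- Hww[j, i] <-
          (tot(ev(wpp, u$delta, u$tau2)) - tot(ev(wpm, u$delta, u$tau2)) -
           tot(ev(wmp, u$delta, u$tau2)) + tot(ev(wmm, u$delta, u$tau2))) /
          (4 * hw[i] * hw[j])
      }
    }
  }

  hd <- step * pmax(1, abs(u$delta))
  fdp <- ev(u$w, u$delta + hd, u$tau2)
  fdm <- ev(u$w, u$delta - hd, u$tau2)
  Hdd <- (fdp$per_marker - 2 * f0$per_marker + fdm$per_marker) / hd^2

  Htt <- Hdt <- NULL
  ht <- NULL
  if (lay$random) {
    ht <- tau2_steps(dat, u$tau2, step)
    ftp <- ev(u$w, u$delta, u$tau2 + ht)
    ftm <- ev(u$w, u$delta, u$tau2 - ht)
    Htt <- (ftp$per_marker - 2 * f0$per_marker + ftm$per_marker) / ht^2
    fpp <- ev(u$w, u$delta + hd, u$tau2 + ht)
    fpm <- ev(u$w, u$delta + hd, u$tau2 - ht)
    fmp <- ev(u$w, u$delta - hd, u$tau2 + ht)
    fmm <- ev(u$w, u$delta - hd, u$tau2 - ht)
    Hdt <- (fpp$per_marker - fpm$per_marker - fmp$per_marker +
            fmm$per_marker) / (4 * hd * ht)
  }

  Hwd <- matrix(0, nw, M)
  Hwt <- if (lay$random) matrix(0, nw, M) else NULL
  for (i in seq_len(nw)) {
    pp <- ev(shift_w(i, 1), u$delta + hd, u$tau2)
    pm <- ev(shift_w(i, 1), u$delta - hd, u$tau2)
    mp <- ev(shift_w(i, -1), u$delta + hd, u$tau2)
    mm <- ev(shift_w(i, -1), u$delta - hd, u$tau2)
    Hwd[i, ] <- (pp$per_marker - pm$per_marker - mp$per_marker +
                 mm$per_marker) / (4 * hw[i] * hd)
    if (lay$random) {
      pp <- ev(shift_w(i, 1), u$delta, u$tau2 + ht)
      pm <- ev(shift_w(i, 1), u$delta, u$tau2 - ht)
      mp <- ev(shift_w(i, -1), u$delta, u$tau2 + ht)
      mm <- ev(shift_w(i, -1), u$delta, u$tau2 - ht)
      Hwt[i, ] <- (pp$per_marker - pm$per_marker - mp$per_marker +
                   mm$per_marker) / (4 * hw[i] * ht)
    }
  }

  list(Hww = Hww, Hdd = Hdd, Htt = Htt, Hdt = Hdt, Hwd = Hwd, Hwt = Hwt)
}

## Information matrix (negative Hessian) bookkeeping: per-marker blocks D_m,
## cross blocks b_m (nw x p), weights block A; exact inversion via the Schur
## complement S = A - sum_m b_m D_m^{-1} b_m'.  Markers in `active` sit on the
## tau2 >= 0 bound (variance-floor mode): their tau2 coordinate is treated as
## fixed, so only the delta curvature enters and se(tau2) is undefined.
info_decompose <- function(H, lay, active = NULL) {
  nw <- lay$nw
  M <- lay$M
  p <- if (lay$random) 2L else 1L
  if (is.null(active)) active <- rep(FALSE, M)
  A <- -H$Hww
  D <- vector("list", M)
  b <- vector("list", M)
  d_ok <- logical(M)
  for (m in seq_len(M)) {
    Dm <- if (lay$random) {
      -matrix(c(H$Hdd[m], H$Hdt[m], H$Hdt[m], H$Htt[m]), 2, 2)
    } else {
      matrix(-H$Hdd[m], 1, 1)
    }
    bm <- if (nw > 0) {
      if (lay$random) cbind(-H$Hwd[, m], -H$Hwt[, m])
      else matrix(-H$Hwd[, m], nw, 1)
    } else {
      matrix(0, 0, p)
    }
    if (lay$random && active[m]) {
      Dm[1, 2] <- Dm[2, 1] <- 0
      Dm[2, 2] <- 1e12
      if (nw > 0) bm[, 2] <- 0
    }
    ok <- all(is.finite(Dm)) &&
      (if (p == 2L) Dm[1, 1] > 0 && det(Dm) > 0 else Dm[1, 1] > 0)
    D[[m]] <- Dm
    b[[m]] <- bm
    d_ok[m] <- ok
  }
  list(A = A, D = D, b = b, d_ok = d_ok, p = p, active = active)
}

inv2 <- function(Dm) {
  if (nrow(Dm) == 1L) return(matrix(1 / Dm[1, 1], 1, 1))
  det <- Dm[1, 1] * Dm[2, 2] - Dm[1, 2]^2
  matrix(c(Dm[2, 2], -Dm[1, 2], -Dm[1, 2], Dm[1, 1]), 2, 2) / det
}

## Covariance pieces from the block information matrix.  Markers whose blocks
## are not positive definite are left out of the Schur sum and get NA
## standard errors; any such marker marks the fit as not converged.
info_covariance <- function(dec, lay) {
  nw <- lay$nw
  M <- lay$M
  S <- dec$A
  for (m in which(dec$d_ok)) {
    if (nw > 0) {
      S <- S - dec$b[[m]] %*% inv2(dec$D[[m]]) %*% t(dec$b[[m]])
    }
  }
  S <- (S + t(S)) / 2
  s_ok <- TRUE
  Sigma_w <- matrix(numeric(0), 0, 0)
  if (nw > 0) {
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      s_ok <- FALSE
    } else {
      Sigma_w <- chol2inv(ch)
      dimnames(Sigma_w) <- list(rownames(dec$A), rownames(dec$A))
    }
  }
  se_delta <- rep(NA_real_, M)
  se_tau2 <- rep(NA_real_, M)
  for (m in which(dec$d_ok)) {
    Dinv <- inv2(dec$D[[m]])
    V <- Dinv
    if (nw > 0 && s_ok) {
      C <- Dinv %*% t(dec$b[[m]])        # p x nw
      V <- Dinv + C %*% Sigma_w %*% t(C)
    }
    if (any(diag(V) < 0)) next
    se_delta[m] <- sqrt(V[1, 1])
    if (lay$random) se_tau2[m] <- sqrt(V[2, 2])
  }
  list(Sigma_w = Sigma_w, s_ok = s_ok, se_delta = se_delta, se_tau2 = se_tau2)
}

## ---- optimization ----------------------------------------------------------

## one vectorized round of damped per-marker Newton on (delta[, tau2]) at
## fixed weights; steps are accepted marker-wise, and invalid total variances
## are rejected per marker, so one pathological marker cannot stall the rest
marker_newton_round <- function(dat, lay, u, step) {
  f0 <- eval_loglik(dat, u$w, u$delta, u$tau2)
  if (!f0$ok) return(u)
  hd <- step * pmax(1, abs(u$delta))
  fdp <- eval_loglik(dat, u$w, u$delta + hd, u$tau2)
  fdm <- eval_loglik(dat, u$w, u$delta - hd, u$tau2)
  if (!fdp$ok || !fdm$ok) return(u)
  gd <- (fdp$per_marker - fdm$per_marker) / (2 * hd)
  hdd <- (fdp$per_marker - 2 * f0$per_marker + fdm$per_marker) / hd^2
  if (lay$random) {
    ht <- tau2_steps(dat, u$tau2, step)
    ftp <- eval_loglik(dat, u$w, u$delta, u$tau2 + ht)
    ftm <- eval_loglik(dat, u$w, u$delta, u$tau2 - ht)
    if (!ftp$ok || !ftm$ok) return(u)
    gt <- (ftp$per_marker - ftm$per_marker) / (2 * ht)
    htt <- (ftp$per_marker - 2 * f0$per_marker + ftm$per_marker) / ht^2
    fpp <- eval_loglik(dat, u$w, u$delta + hd, u$tau2 + ht)
    fmm <- eval_loglik(dat, u$w, u$delta - hd, u$tau2 - ht)
    fpm <- eval_loglik(dat, u$w, u$delta + hd, u$tau2 - ht)
    fmp <- eval_loglik(dat, u$w, u$delta - hd, u$tau2 + ht)
    if (!fpp$ok || !fmm$ok || !fpm$ok || !fmp$ok) return(u)
    hdt <- (fpp$per_marker - fpm$per_marker - fmp$per_marker +
            fmm$per_marker) / (4 * hd * ht)
    det <- hdd * htt - hdt^2
    pd <- is.finite(det) & det > 0 & hdd < 0
    sd_ <- ifelse(pd, -( htt * gd - hdt * gt) / det, gd * 0.01)
    st_ <- ifelse(pd, -(-hdt * gd + hdd * gt) / det, gt * 0.01)
  } else {
    pd <- is.finite(hdd) & hdd < 0
    sd_ <- ifelse(pd, -gd / hdd, gd * 0.01)
    st_ <- rep(0, lay$M)
  }
  ## cap runaway steps so boundary-chasers cannot derail the round
  sd_[!is.finite(sd_)] <- 0
  st_[!is.finite(st_)] <- 0
  sd_ <- pmin(pmax(sd_, -1), 1)
  st_ <- pmin(pmax(st_, -0.5), 0.5)
  ## keep tau2 candidates strictly inside the valid region
  if (lay$random) {
    lo <- -(dat$s2min + u$tau2) * 0.9
    st_ <- pmax(st_, lo)
  }
  accepted_d <- u$delta
  accepted_t <- u$tau2
  t_m <- rep(1, lay$M)
  todo <- rep(TRUE, lay$M)
  for (half in 1:10) {
    cand_d <- ifelse(todo, u$delta + t_m * sd_, accepted_d)
    cand_t <- ifelse(todo, u$tau2 + t_m * st_, accepted_t)
    bad_v <- (dat$s2min + cand_t) <= 0
    cand_t[bad_v] <- accepted_t[bad_v]
    cand_d[bad_v] <- accepted_d[bad_v]
    f1 <- eval_loglik(dat, u$w, cand_d, cand_t)
    if (!f1$ok) { t_m <- t_m / 2; next }
    better <- todo & !bad_v & (f1$per_marker >= f0$per_marker - 1e-12)
    accepted_d[better] <- cand_d[better]
    accepted_t[better] <- cand_t[better]
    todo <- todo & !better
    if (!any(todo)) break
    t_m[todo] <- t_m[todo] / 2
  }
  u$delta <- accepted_d
  u$tau2 <- accepted_t
  u
}

## weights-only BFGS at fixed per-marker parameters (nw is at most 14)
weights_step <- function(dat, lay, u, maxit = 40, ok = NULL) {
  if (lay$nw == 0) return(u)
  tot <- if (is.null(ok)) function(f) f$total else
    function(f) sum(f$per_marker[ok])
  fn <- function(w) {
    r <- eval_loglik(dat, w, u$delta, u$tau2)
    if (!r$ok) PENALTY_NLL else -tot(r)
  }
  o <- optim(u$w, fn, method = "BFGS",
             control = list(maxit = maxit, reltol = 1e-10))
  u$w <- o$par
  u
}

## block-coordinate warm-up before the joint BFGS
warmup <- function(dat, lay, u, ctrl) {
  for (round in seq_len(ctrl$warmup_rounds)) {
    u <- marker_newton_round(dat, lay, u, ctrl$grad_step)
    u <- weights_step(dat, lay, u)
  }
  u
}

## joint Newton polish using the block information matrix.  Markers whose
## 2x2 block is not positive definite (boundary-chasers, degenerate data) are
## frozen and masked out of both the step and the stopping rule; they end up
## flagged non-converged and handled by the exclusion protocol.
newton_polish <- function(dat, lay, u, ctrl) {
  masked_max <- function(g, ok) {
    keep <- c(rep(TRUE, lay$nw), ok, if (lay$random) ok)
    gg <- abs(g[keep])
    if (!length(gg) || anyNA(gg)) Inf else max(gg)
  }
  ## healthy-marker mask: positive-definite block, moderate gradient, total
  ## variance away from its lower boundary
  marker_mask <- function(g, dec) {
    gm <- matrix(g[lay$nw + seq_len(lay$M * dec$p)], nrow = lay$M)
    gnorm <- apply(gm, 1, function(r) if (all(is.finite(r))) max(abs(r)) else Inf)
    dec$d_ok & gnorm < 1e3 &
      (!lay$random | (dat$s2min + u$tau2) > 1e-4 * dat$s2min)
  }
  ok <- rep(TRUE, lay$M)
  for (it in seq_len(ctrl$newton_iter)) {
    g <- grad_loglik(dat, lay, u, ctrl$grad_step)
    if (anyNA(g)) return(list(u = u, grad = g, polished = FALSE))
    H <- hessian_blocks(dat, lay, u, ctrl$hess_step)
    dec <- info_decompose(H, lay)
    ok <- marker_mask(g, dec)
    if (!all(ok)) {
      ## recompute the shared-weight coordinates on the healthy subcorpus;
      ## boundary-chasing markers otherwise contaminate them
      g2 <- grad_loglik(dat, lay, u, ctrl$grad_step, ok = ok)
      if (!anyNA(g2)) g <- g2
      H <- hessian_blocks(dat, lay, u, ctrl$hess_step, ok = ok)
      dec <- info_decompose(H, lay)
    }
    if (masked_max(g, ok) < ctrl$gtol / 2) {
      return(list(u = u, grad = g, polished = TRUE))
    }
    if (!any(ok)) return(list(u = u, grad = g, polished = FALSE))
    nw <- lay$nw
    gw <- if (nw > 0) g[seq_len(nw)] else numeric(0)
    gm <- matrix(g[nw + seq_len(lay$M * dec$p)], nrow = lay$M)  # M x p
    ## solve I s = g blockwise over the healthy markers
    rhs_w <- gw
    S <- dec$A
    for (m in which(ok)) {
      Dinv <- inv2(dec$D[[m]])
      if (nw > 0) {
        S <- S - dec$b[[m]] %*% Dinv %*% t(dec$b[[m]])
        rhs_w <- rhs_w - dec$b[[m]] %*% Dinv %*% gm[m, ]
      }
    }
    s_w <- if (nw > 0) {
      sw <- tryCatch(solve((S + t(S)) / 2, rhs_w), error = function(e) NULL)
      if (is.null(sw)) return(list(u = u, grad = g, polished = FALSE))
      drop(sw)
    } else numeric(0)
    s_m <- matrix(0, lay$M, dec$p)
    for (m in which(ok)) {
      rm <- gm[m, ] - if (nw > 0) drop(t(dec$b[[m]]) %*% s_w) else 0
      s_m[m, ] <- drop(inv2(dec$D[[m]]) %*% rm)
    }
    mtot <- function(f) sum(f$per_marker[ok])
    f0 <- eval_loglik(dat, u$w, u$delta, u$tau2)
    t_step <- 1
    improved <- FALSE
    for (half in 1:12) {
      cand <- u
      if (nw > 0) cand$w <- u$w + t_step * s_w
      cand$delta <- u$delta + t_step * s_m[, 1]
      if (lay$random) cand$tau2 <- u$tau2 + t_step * s_m[, 2]
      f1 <- eval_loglik(dat, cand$w, cand$delta, cand$tau2)
      if (f1$ok && mtot(f1) >= mtot(f0) - 1e-10) {
        u <- cand
        improved <- mtot(f1) > mtot(f0) + 1e-12
        break
      }
      t_step <- t_step / 2
    }
    if (!improved) {
      ## joint step rejected: fall back to one block-coordinate round, which
      ## accepts improvements marker-wise and cannot be stalled by a single
      ## pathological marker
      u_alt <- weights_step(dat, lay,
                            marker_newton_round(dat, lay, u, ctrl$grad_step),
                            ok = ok)
      f_alt <- eval_loglik(dat, u_alt$w, u_alt$delta, u_alt$tau2)
      if (f_alt$ok && mtot(f_alt) > mtot(f0) + 1e-10) {
        u <- u_alt
      } else {
        g <- grad_loglik(dat, lay, u, ctrl$grad_step, ok = ok)
        return(list(u = u, grad = g, polished = masked_max(g, ok) < ctrl$gtol))
      }
    }
  }
  g <- grad_loglik(dat, lay, u, ctrl$grad_step,
                   ok = if (all(ok)) NULL else ok)
  list(u = u, grad = g, polished = masked_max(g, ok) < ctrl$gtol)
}

run_optimizer <- function(dat, lay, u0, ctrl) {
  nll <- function(theta) {
    uu <- unpack_theta(theta, lay)
    r <- eval_loglik(dat, uu$w, uu$delta, uu$tau2)
    if (!r$ok) PENALTY_NLL else -r$total
  }
  gr <- function(theta) {
    uu <- unpack_theta(theta, lay)
    g <- grad_loglik(dat, lay, uu, ctrl$grad_step)
    g[!is.finite(g)] <- 0
    -g
  }
  u <- warmup(dat, lay, u0, ctrl)
  ## coordinate scaling: log-weights O(1), delta O(0.1), tau2 O(0.01)
  pscale <- c(rep(1, lay$nw), rep(0.1, lay$M),
              if (lay$random) rep(0.02, lay$M))
  if (ctrl$variance_floor && lay$random) {
    u$tau2 <- pmax(u$tau2, 0)
    lower <- c(rep(-Inf, lay$nw + lay$M), rep(0, lay$M))
    opt <- optim(pack_theta(u, lay), nll, gr, method = "L-BFGS-B",
                 lower = lower,
                 control = list(maxit = ctrl$maxit, factr = 1e4))
    u <- unpack_theta(opt$par, lay)
    u$tau2 <- pmax(u$tau2, 0)
    ## Newton polishing is unconstrained; at an active bound it would step
    ## below the floor, so the constrained optimum is kept as-is
    g <- grad_loglik(dat, lay, u, ctrl$grad_step)
    return(list(u = u, grad = g, polished = opt$convergence == 0, optim = opt))
  }
  opt <- optim(pack_theta(u, lay), nll, gr, method = "BFGS",
               control = list(maxit = ctrl$maxit, reltol = ctrl$reltol,
                              parscale = pscale))
  u <- unpack_theta(opt$par, lay)
  pol <- newton_polish(dat, lay, u, ctrl)
  list(u = pol$u, grad = pol$grad, polished = pol$polished, optim = opt)
}

## ---- the fit object --------------------------------------------------------

#' Fit a selection model to a study corpus by maximum likelihood
#'
#' Jointly estimates the model's shared log-weights and every marker's mean
#' effect and (random-effects mode) between-study variance by maximizing the
#' combined log likelihood with BFGS, from neutral starting values
#' (inverse-variance means, DerSimonian-Laird variances, log-weights 0 — the
#' unbiased model is the optimizer's origin).  Standard errors come from a
#' numerically approximated information matrix (central differences,
#' symmetrized, inverted exactly via its block structure).  Convergence
#' requires optimizer success, a gradient max-norm below `control$gtol`, and
#' a positive-definite information matrix; markers with non-positive-definite
#' blocks, boundary-chasing variances or non-finite contributions are flagged
#' individually and reported — never dropped silently.
#'
#' @param corpus Study-level data frame (`marker_id`, `log_or`, `se`, plus
#'   `category` / `initial_sign` for multi-category models; see
#'   [categorize_studies()]).
#' @param model A [build_model()] specification (or a model name).
#' @param control Named list overriding optimizer defaults: `maxit`, `reltol`,
#'   `grad_step`, `hess_step`, `gtol`, `newton_iter`, `warmup_rounds`,
#'   `n_restarts`, `restart_sd`, `variance_floor` (constrain tau2 >= 0;
#'   default `FALSE`, the unrestricted likelihood).
#' @param restart_seed Seed for the jittered restarts attempted when the
#'   information-matrix check fails.
#' @return A `selection_fit` object; see [tidy.selection_fit()],
#'   [glance.selection_fit()], [autoplot.selection_fit()].
#' @export
fit_selection_model <- function(corpus, model = build_model("unbiased"),
                                control = list(), restart_seed = 1L) {
  if (is.character(model)) model <- build_model(model)
  stopifnot(inherits(model, "selectmeta_model"))
  ctrl <- modifyList(default_fit_control(), control)
  dat <- prepare_loglik_data(corpus, model)
  dat$s2min <- as.numeric(tapply(dat$s^2, dat$im, min))
  lay <- theta_layout(dat, model)
  u0 <- start_values(dat, lay)
  if (!lay$random) u0$tau2 <- rep(0, lay$M)

  res <- run_optimizer(dat, lay, u0, ctrl)
  fit <- assemble_fit(dat, lay, model, ctrl, res)

  ## jittered multi-start when the failure is not attributable to any marker
  if (!fit$converged && length(fit$nonconverged_markers) == 0L &&
      ctrl$n_restarts > 0) {
    withr::with_seed(restart_seed, {
      for (r in seq_len(ctrl$n_restarts)) {
        u_try <- res$u
        u_try$w <- u_try$w + rnorm(lay$nw, 0, ctrl$restart_sd)
        u_try$delta <- u_try$delta + rnorm(lay$M, 0, ctrl$restart_sd / 2)
        res_try <- run_optimizer(dat, lay, u_try, ctrl)
        fit_try <- assemble_fit(dat, lay, model, ctrl, res_try)
        fit_try$diagnostics$restarts <- r
        if (fit_try$loglik >= fit$loglik - 1e-8) fit <- fit_try
        if (fit$converged) break
      }
    })
  }
  fit
}

assemble_fit <- function(dat, lay, model, ctrl, res) {
  u <- res$u
  f <- eval_loglik(dat, u$w, u$delta, u$tau2)
  loglik <- if (f$ok) f$total else NA_real_
  per_marker_ll <- if (f$ok) f$per_marker else rep(NA_real_, lay$M)
  g <- res$grad
  gmax <- if (anyNA(g)) Inf else max(abs(g))

  ## markers sitting on the tau2 >= 0 bound under the variance floor
  active <- if (lay$random && isTRUE(ctrl$variance_floor)) u$tau2 <= 1e-10
    else rep(FALSE, lay$M)
  H <- hessian_blocks(dat, lay, u, ctrl$hess_step)
  dec <- info_decompose(H, lay, active = active)
  if (lay$nw > 0) {
    dimnames(dec$A) <- list(model$params, model$params)
  }
  cov <- info_covariance(dec, lay)
  if (any(active)) cov$se_tau2[active] <- NA_real_

  ## marker-level convergence; at an active bound only the delta gradient
  ## must vanish (the tau2 gradient legitimately pushes into the bound)
  nw <- lay$nw
  gm <- matrix(g[nw + seq_len(lay$M * dec$p)], nrow = lay$M)
  gm_check <- gm
  if (any(active)) gm_check[active, 2] <- 0
  near_boundary <- lay$random & (dat$s2min + u$tau2) < 1e-6 * dat$s2min
  marker_ok <- dec$d_ok & is.finite(per_marker_ll) & !near_boundary &
    apply(gm_check, 1, function(r) all(is.finite(r)) &&
            max(abs(r)) < ctrl$gtol * 10)

  ## fit-level gradient criterion over the weight coordinates and the
  ## healthy markers (flagged markers cannot have vanishing gradients)
  keep <- c(rep(TRUE, nw), marker_ok, if (lay$random) marker_ok & !active)
  gmax_kept <- if (anyNA(g[keep])) Inf else
    if (any(keep)) max(abs(g[keep])) else 0
  grad_ok <- gmax_kept < ctrl$gtol
  opt_ok <- res$optim$convergence == 0 || res$polished
  converged <- opt_ok && grad_ok && cov$s_ok && all(marker_ok)

  k <- lay$n
  markers_tbl <- tibble::tibble(
    marker_id = dat$markers,
    n_studies = as.numeric(table(dat$im)),
    delta = u$delta,
    se_delta = cov$se_delta,
    tau2 = if (lay$random) u$tau2 else 0,
    se_tau2 = if (lay$random) cov$se_tau2 else NA_real_,
    loglik = per_marker_ll,
    converged = marker_ok
  )
  weights_tbl <- tibble::tibble(
    term = model$params,
    estimate = u$w,
    std.error = if (lay$nw > 0 && cov$s_ok) sqrt(pmax(diag(cov$Sigma_w), 0))
      else rep(NA_real_, lay$nw)
  )

  structure(
    list(
      model = model,
      model_name = model$name,
      effects = model$effects,
      weights = weights_tbl,
      markers = markers_tbl,
      vcov_weights = cov$Sigma_w,
      info = dec,
      loglik = loglik,
      n_params = k,
      aic = 2 * k - 2 * loglik,
      n_studies = length(dat$x),
      n_markers = lay$M,
      converged = converged,
      nonconverged_markers = dat$markers[!marker_ok],
      corpus_fingerprint = corpus_fingerprint(dat),
      diagnostics = list(
        optim_convergence = res$optim$convergence,
        optim_counts = res$optim$counts,
        polished = res$polished,
        grad_max_norm = gmax,
        info_pd = cov$s_ok && all(dec$d_ok),
        restarts = 0L,
        control = ctrl
      )
    ),
    class = "selection_fit"
  )
}

corpus_fingerprint <- function(dat) {
  n_per <- as.integer(table(dat$im))
  paste0(
    dat$n_markers, ":", length(dat$x), ":",
    paste(sort(dat$markers), collapse = ","), ":",
    paste(n_per, collapse = ",")
  )
}

#' @export
print.selection_fit <- function(x, ...) {
  cat(sprintf(
    "<selection_fit> %s (%s effects): %d markers, %d studies\n",
    x$model_name, x$effects, x$n_markers, x$n_studies
  ))
  cat(sprintf(
    "  log L = %.3f  AIC = %.3f  (%d parameters)%s\n",
    x$loglik, x$aic, x$n_params,
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  if (nrow(x$weights) > 0) {
    w <- x$weights
    cat("  weights:\n")
    for (i in seq_len(nrow(w))) {
      cat(sprintf("    %-10s %8.4f (SE %.4f)\n",
                  w$term[i], w$estimate[i], w$std.error[i]))
    }
  }
  if (length(x$nonconverged_markers)) {
    cat("  non-converged markers:", toString(x$nonconverged_markers), "\n")
  }
  invisible(x)
}

#' Covariance matrix of a selection-model fit
#'
#' @param object A `selection_fit`.
#' @param full If `TRUE`, assemble the covariance over *all* free parameters
#'   (weights + per-marker blocks) from the block decomposition; otherwise
#'   (default) return the weight-parameter block.
#' @param ... Unused.
#' @export
vcov.selection_fit <- function(object, full = FALSE, ...) {
  if (!full) return(object$vcov_weights)
  dec <- object$info
  lay_random <- object$effects == "random"
  nw <- nrow(object$vcov_weights)
  M <- object$n_markers
  p <- dec$p
  n <- nw + p * M
  V <- matrix(NA_real_, n, n)
  if (nw > 0) V[seq_len(nw), seq_len(nw)] <- object$vcov_weights
  Sw <- object$vcov_weights
  for (m in seq_len(M)) {
    if (!dec$d_ok[m]) next
    idx <- nw + (m - 1L) * p + seq_len(p)
    Dinv <- inv2(dec$D[[m]])
    Vm <- Dinv
    if (nw > 0) {
      C <- Dinv %*% t(dec$b[[m]])
      Vm <- Dinv + C %*% Sw %*% t(C)
      cross <- -Sw %*% dec$b[[m]] %*% Dinv
      V[seq_len(nw), idx] <- cross
      V[idx, seq_len(nw)] <- t(cross)
    }
    V[idx, idx] <- Vm
  }
  nms <- c(
    object$model$params,
    as.vector(t(cbind(
      paste0("delta[", object$markers$marker_id, "]"),
      if (lay_random) paste0("tau2[", object$markers$marker_id, "]")
    )))
  )
  dimnames(V) <- list(nms, nms)
  V
}

#' @export
logLik.selection_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}
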