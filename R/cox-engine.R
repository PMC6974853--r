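# Breslow partial-likelihood engine with delayed entry, stratification and
# cluster-robust covariance. Everything landmark-shaped in the package (plain
# Cox fits, both supermodels, Breslow baselines, Schoenfeld and score
# residuals) is computed here.
#
# Risk-set convention: a row with (entry, exit] is at risk at t iff
# entry < t <= exit. Ties in event times use the Breslow approximation.

# Precompute per-stratum sort structures; these do not depend on beta.
cox_prep <- function(entry, exit, status, X, strata) {
  if (is.null(strata)) strata <- rep(1L, length(exit))
  sidx <- split(seq_along(exit), strata)
  strat <- lapply(names(sidx), function(snm) {
    i <- sidx[[snm]]
    e <- entry[i]; t <- exit[i]; d <- status[i]
    if (any(t <= e)) stop("exit must exceed entry for every row")
    et <- sort(unique(t[d == 1]))
    ev <- d == 1
    evt_idx <- match(t[ev], et)
    dt <- as.numeric(tabulate(evt_idx, nbins = length(et)))
    ordx <- order(t); orde <- order(e)
    list(name = snm, rows = i, entry = e, exit = t, status = d,
         X = X[i, , drop = FALSE], et = et, dt = dt,
         ev = which(ev), evt_idx = evt_idx,
         ordx = ordx, orde = orde,
         ix = findInterval(et, t[ordx], left.open = TRUE),
         ie = findInterval(et, e[orde], left.open = TRUE),
         xev_sum = if (ncol(X)) rowsum_safe(X[i, , drop = FALSE][ev, , drop = FALSE],
                                            evt_idx, length(et)) else NULL)
  })
  names(strat) <- names(sidx)
  strat
}

rowsum_safe <- function(x, group, ngroups) {
  out <- matrix(0, ngroups, ncol(x))
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# cumulative sums with a leading zero row
cum0 <- function(m) {
  if (is.null(dim(m))) return(c(0, cumsum(m)))
  rbind(0, apply(m, 2, cumsum))
}

# log-likelihood, score and information at beta for one prepared stratum
cox_stratum_derivs <- function(st, beta, want = c("all")) {
  p <- length(beta)
  n <- length(st$exit)
  lp <- if (p) drop(st$X %*% beta) else rep(0, n)
  w <- exp(lp)
  E <- length(st$et)
  if (E == 0)
    return(list(ll = 0, U = rep(0, p), I = matrix(0, p, p),
                S0 = numeric(0), M = matrix(0, 0, p), lp = lp, w = w))
  cwx <- c(0, cumsum(w[st$ordx]))
  cwe <- c(0, cumsum(w[st$orde]))
  S0 <- cwe[st$ie + 1] - cwx[st$ix + 1]
  ll <- sum(lp[st$ev]) - sum(st$dt * log(S0))
  if (p == 0)
    return(list(ll = ll, U = numeric(0), I = matrix(0, 0, 0),
                S0 = S0, M = matrix(0, E, 0), lp = lp, w = w))
  WX <- w * st$X
  CX <- cum0(WX[st$ordx, , drop = FALSE])
  CE <- cum0(WX[st$orde, , drop = FALSE])
  S1 <- CE[st$ie + 1, , drop = FALSE] - CX[st$ix + 1, , drop = FALSE]
  M <- S1 / S0
  U <- colSums(st$xev_sum) - colSums(st$dt * M)
  # information: pairwise second-moment cumsums
  Imat <- matrix(0, p, p)
  for (j in seq_len(p)) {
    WXj <- WX[, j] * st$X[, j:p, drop = FALSE]
    CXj <- cum0(WXj[st$ordx, , drop = FALSE])
    CEj <- cum0(WXj[st$orde, , drop = FALSE])
    S2j <- CEj[st$ie + 1, , drop = FALSE] - CXj[st$ix + 1, , drop = FALSE]
    for (kk in seq_len(p - j + 1)) {
      k <- j + kk - 1
      v <- sum(st$dt * (S2j[, kk] / S0 - M[, j] * M[, k]))
      Imat[j, k] <- Imat[k, j] <- v
    }
  }
  list(ll = ll, U = U, I = Imat, S0 = S0, M = M, lp = lp, w = w)
}

# per-row score residuals for one stratum at the converged fit
cox_stratum_score_resid <- function(st, der) {
  p <- ncol(st$X)
  n <- length(st$exit)
  if (p == 0) return(matrix(0, n, 0))
  if (!length(st$et)) return(matrix(0, n, p))
  h <- st$dt / der$S0
  cumh <- c(0, cumsum(h))
  cumhM <- cum0(h * der$M)
  kx <- findInterval(st$exit, st$et)
  ke <- findInterval(st$entry, st$et)
  G0 <- cumh[kx + 1] - cumh[ke + 1]
  G1 <- cumhM[kx + 1, , drop = FALSE] - cumhM[ke + 1, , drop = FALSE]
  res <- -der$w * (st$X * G0 - G1)
  res[st$ev, ] <- res[st$ev, , drop = FALSE] +
    st$X[st$ev, , drop = FALSE] - der$M[st$evt_idx, , drop = FALSE]
  res
}

#' @noRd
cox_engine <- function(entry, exit, status, X, strata = NULL, cluster = NULL,
                       init = NULL, tol = 1e-9, maxit = 100L) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- length(exit)
  if (is.null(entry)) entry <- rep(0, n)
  prep <- cox_prep(entry, exit, status, X, strata)
  beta <- if (is.null(init)) rep(0, p) else init
  total <- function(beta, keep_parts = FALSE) {
    parts <- lapply(prep, cox_stratum_derivs, beta = beta)
    ll <- sum(vapply(parts, `[[`, 0, "ll"))
    U <- Reduce(`+`, lapply(parts, `[[`, "U"))
    I <- Reduce(`+`, lapply(parts, `[[`, "I"))
    list(ll = ll, U = U, I = I, parts = if (keep_parts) parts)
  }
  cur <- total(beta)
  ll0 <- cur$ll
  iter <- 0L
  trace <- ll0
  if (p > 0) {
    repeat {
      iter <- iter + 1L
      step <- tryCatch(solve(cur$I, cur$U), error = function(e)
        stop("singular information matrix; check for collinear columns"))
      cand <- beta + step
      nxt <- total(cand)
      halve <- 0L
      while ((!is.finite(nxt$ll) || nxt$ll < cur$ll) && halve < 25L) {
        halve <- halve + 1L
        cand <- beta + step / 2^halve
        nxt <- total(cand)
      }
      trace <- c(trace, nxt$ll)
      done <- abs(nxt$ll - cur$ll) < tol * (abs(cur$ll) + tol)
      beta <- cand
      cur <- nxt
      if (done) break
      if (iter >= maxit)
        stop("Cox partial likelihood did not converge in ", maxit,
             " iterations; log-likelihood trace: ",
             paste(signif(trace, 8), collapse = ", "))
    }
  }
  cur <- total(beta, keep_parts = TRUE)
  var_model <- if (p) solve(cur$I) else matrix(0, 0, 0)

  # residuals, baselines, schoenfeld
  score_res <- matrix(0, n, p)
  schoen <- list(time = numeric(0), stratum = character(0),
                 resid = matrix(0, 0, p))
  baselines <- list()
  for (st in prep) {
    der <- cur$parts[[st$name]]
    if (p) score_res[st$rows, ] <- cox_stratum_score_resid(st, der)
    if (length(st$et)) {
      h <- st$dt / der$S0
      baselines[[st$name]] <- step_function(st$et, cumsum(h), 0, "cumhaz")
      if (p) {
        sr <- st$X[st$ev, , drop = FALSE] - der$M[st$evt_idx, , drop = FALSE]
        o <- order(st$exit[st$ev])
        schoen$time <- c(schoen$time, st$exit[st$ev][o])
        schoen$stratum <- c(schoen$stratum, rep(st$name, length(st$ev)))
        schoen$resid <- rbind(schoen$resid, sr[o, , drop = FALSE])
      }
    } else {
      baselines[[st$name]] <- step_function(numeric(0), numeric(0), 0, "cumhaz")
    }
  }
  var_robust <- NULL
  if (p) {
    grp <- if (is.null(cluster)) seq_len(n) else cluster
    Ug <- rowsum(score_res, grp)
    var_robust <- var_model %*% crossprod(Ug) %*% var_model
  }
  nev <- sum(status == 1)
  list(beta = beta, var = var_model, var_robust = var_robust,
       loglik = c(ll0, cur$ll), iter = iter, score = cur$U,
       info = cur$I, n = n, nevent = nev,
       baselines = baselines, schoenfeld = schoen,
       score_resid = score_res)
}
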