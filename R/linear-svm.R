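# Internal squared-hinge linear SVM solver.
#
# Objective (LiblineaR-style primal):
#   L1 penalty:  min_{w,b} ||w||_1      + C * sum_i max(0, 1 - y_i f_i)^2
#   L2 penalty:  min_{w,b} 0.5 ||w||_2^2 + C * sum_i max(0, 1 - y_i f_i)^2
# with f = X w + b, y in {-1, +1}.  The squared hinge makes the loss term
# differentiable; the L1 case is solved by FISTA (proximal gradient with
# soft-thresholding, intercept unpenalized), the L2 case by L-BFGS.

sqHingeLoss <- function(par, X, y, C) {
  w <- par[-length(par)]
  b <- par[length(par)]
  m <- pmax(0, 1 - y * (drop(X %*% w) + b))
  C * sum(m^2)
}

sqHingeGrad <- function(par, X, y, C) {
  w <- par[-length(par)]
  b <- par[length(par)]
  m <- pmax(0, 1 - y * (drop(X %*% w) + b))
  gi <- -2 * C * m * y
  c(drop(crossprod(X, gi)), sum(gi))
}

fitLinearSvm <- function(X, y, cost, penalty = c("l1", "l2"),
                         maxIter = 1000L, tol = 1e-7) {
  penalty <- match.arg(penalty)
  n <- nrow(X); p <- ncol(X)
  if (penalty == "l2") {
    obj <- function(par) 0.5 * sum(par[-(p + 1L)]^2) +
      sqHingeLoss(par, X, y, cost)
    grd <- function(par) c(par[-(p + 1L)], 0) + sqHingeGrad(par, X, y, cost)
    fit <- optim(rep(0, p + 1L), obj, grd, method = "L-BFGS-B",
                 control = list(maxit = maxIter, factr = 1e4))
    par <- fit$par
  } else {
    # FISTA: Lipschitz constant of the smooth part is bounded by
    # 2C * lambda_max([X 1]' [X 1]), estimated by power iteration
    X1 <- cbind(X, 1)
    v <- rep(1 / sqrt(p + 1), p + 1L)
    for (i in 1:30) {
      v <- drop(crossprod(X1, X1 %*% v))
      nv <- sqrt(sum(v^2))
      if (nv == 0) break
      v <- v / nv
    }
    L <- max(2 * cost * nv, .Machine$double.eps)
    step <- 1 / L
    par <- z <- rep(0, p + 1L)
    t0 <- 1
    lastObj <- Inf
    for (it in seq_len(maxIter)) {
      g <- sqHingeGrad(z, X, y, cost)
      cand <- z - step * g
      # soft-threshold the weights only; intercept stays unpenalized
      cand[1:p] <- sign(cand[1:p]) * pmax(abs(cand[1:p]) - step, 0)
      t1 <- (1 + sqrt(1 + 4 * t0^2)) / 2
      z <- cand + ((t0 - 1) / t1) * (cand - par)
      par <- cand
      t0 <- t1
      if (it %% 20L == 0L) {
        cur <- sum(abs(par[1:p])) + sqHingeLoss(par, X, y, cost)
        if (abs(lastObj - cur) < tol * (1 + abs(cur))) break
        lastObj <- cur
      }
    }
  }
  list(w = par[seq_len(p)], b = par[p + 1L], penalty = penalty, cost = cost)
}

predictLinearSvm <- function(fit, X) {
  drop(X %*% fit$w) + fit$b
}
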