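# Logistic mixed model with crossed random intercepts over persons and
# items, fit by Laplace approximation.
#
# Inner loop: penalized Newton (IRLS) on the joint mode of (beta, u) for
# fixed variances, exploiting the two-block sparse random-effects structure
# via block elimination: factor S = Z'WZ + D^{-1} once per iteration, then
# solve for beta through the (small, dense) Schur complement.  Under the
# default laplace = "full", the joint mode is followed by Newton corrector
# steps that drive the exact Laplace beta-gradient (including both
# log-determinant sensitivity terms) to zero, so the optimum matches
# Laplace maximum likelihood as in lme4's default glmer; "profiled" stops
# at the joint mode (lme4's nAGQ = 0 flavor), trading a small attenuation
# of beta for roughly half the cost.  Outer loop: derivative-free
# optimization of the Laplace log-likelihood over (log sigma_person,
# log sigma_item), with a boundary check at sigma = 0.

#' Conditional intraclass correlation on the latent logistic scale
#'
#' For a random-intercept variance `sigma2`, the correlation among latent
#' responses sharing that cluster, conditional on the other crossing
#' factor's effects, is `sigma2 / (sigma2 + pi^2 / 3)` -- the logistic
#' latent-residual variance being `pi^2 / 3`.
#'
#' @param sigma2 non-negative variance (vectorized).
#' @return ICC values in `[0, 1)`.
#' @export
#' @examples
#' conditional_icc(0.7)
#' conditional_icc(2.8)
conditional_icc <- function(sigma2) {
  if (any(sigma2 < 0)) stop_eirmrf("sigma2 must be non-negative", "value_error")
  sigma2 / (sigma2 + pi^2 / 3)
}

#' Fit a logistic mixed model with crossed random intercepts
#'
#' Maximizes the Laplace-approximate marginal likelihood of
#' `logit P(y = 1) = X beta + theta[person] + b[item]`,
#' `theta ~ N(0, sigma2_person)`, `b ~ N(0, sigma2_item)`.
#' The fixed coefficients are profiled jointly with the random-effect mode
#' search (penalized IRLS); the outer optimization runs over the two log
#' standard deviations.  Wald standard errors come from the Schur complement
#' of the joint negative Hessian at the optimum.
#'
#' @param y binary response vector (0/1).
#' @param X fixed-effects design matrix (full column rank; include the
#'   intercept column yourself).
#' @param person_index factor or vector identifying the person of each row.
#' @param item_index factor or vector identifying the item of each row.
#' @param control list; supported entries
#'   `fix_variances` (length-2 numeric, fixes `c(sigma2_person, sigma2_item)`
#'   and skips the outer optimization; zeros drop the corresponding block),
#'   `laplace` (`"full"` for Laplace maximum likelihood with the exact
#'   beta-gradient, the default; `"profiled"` evaluates at the joint
#'   (beta, u) mode, faster with a small attenuation of beta),
#'   `tol` (outer absolute log-likelihood tolerance, default `1e-6`),
#'   `inner_tol` (gradient norm tolerance of the mode search, default `1e-8`),
#'   `max_iter` (outer evaluation budget, default 100),
#'   `max_inner` (default 200),
#'   `start` (optional list with `beta`, `sigma2` warm starts).
#' @return an object of class `eirmrf_glmm`: list with `beta`, `se`,
#'   `beta_cov`, `sigma2_person`, `sigma2_item`, `person_modes`,
#'   `item_modes`, `laplace_loglik`, `converged`, `boundary`,
#'   `n_inner_iters`, `n_outer_iters`, `person_levels`, `item_levels`.
#' @export
fit_crossed_logit <- function(y, X, person_index, item_index, control = list()) {
  ctrl <- utils::modifyList(list(
    fix_variances = NULL, laplace = "full", tol = 1e-6, inner_tol = 1e-8,
    max_iter = 100L, max_inner = 200L, start = NULL
  ), control)
  laplace <- match.arg(ctrl$laplace, c("full", "profiled"))

  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_eirmrf("y must be binary 0/1", "value_error")
  if (all(y == y[1])) {
    stop_eirmrf("all responses identical: logistic fit is separated", "separation_error")
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) {
    stop_eirmrf("fixed-effect design matrix is rank deficient", "design_error")
  }
  pf <- factor(person_index)
  itf <- factor(item_index)
  stopifnot(length(pf) == n, length(itf) == n)
  J <- nlevels(pf)
  I <- nlevels(itf)
  if (J < 2 || I < 2) {
    stop_eirmrf("need at least 2 persons and 2 items", "design_error")
  }
  pidx <- as.integer(pf)
  iidx <- as.integer(itf)

  p <- ncol(X)
  beta0 <- ctrl$start$beta %||% start_beta(y, X)

  # inner fit for given variances; returns mode, loglik, pieces
  inner_fit <- function(sig2, beta_init, u_init = NULL, flavor = laplace) {
    pirls_crossed(
      y, X, pidx, iidx, J, I, sig2, beta_init, u_init,
      tol = ctrl$inner_tol, max_inner = ctrl$max_inner, laplace = flavor
    )
  }

  lower_ls <- log(1e-4)   # sigma floor during optimization (sigma^2 = 1e-8)
  upper_ls <- log(25)

  if (!is.null(ctrl$fix_variances)) {
    sig2 <- as.numeric(ctrl$fix_variances)
    if (length(sig2) != 2 || any(sig2 < 0)) {
      stop_eirmrf("fix_variances must be two non-negative values", "value_error")
    }
    fit <- inner_fit(sig2, beta0)
    n_outer <- 0L
    converged_outer <- TRUE
  } else {
    s2_start <- ctrl$start$sigma2 %||% c(0.5, 0.5)
    par0 <- pmin(pmax(0.5 * log(pmax(s2_start, 1e-6)), lower_ls), upper_ls)
    n_eval <- 0L
    warm <- new.env(parent = emptyenv())
    warm$beta <- beta0
    warm$u <- NULL
    make_objective <- function(flavor) {
      function(ls) {
        ls <- pmin(pmax(ls, lower_ls), upper_ls)
        n_eval <<- n_eval + 1L
        ft <- inner_fit(exp(2 * ls), warm$beta, warm$u, flavor = flavor)
        warm$beta <- ft$beta
        warm$u <- ft$u
        -ft$loglik
      }
    }
    # stage 1: locate the variance optimum on the cheap profiled objective
    opt <- stats::optim(
      par0, make_objective("profiled"), method = "Nelder-Mead",
      control = list(abstol = ctrl$tol, maxit = 40 * ctrl$max_iter,
                     warn.1d.NelderMead = FALSE)
    )
    ls_hat <- pmin(pmax(opt$par, lower_ls), upper_ls)
    if (laplace == "full") {
      # stage 2: coordinate-wise Newton polish of (log sigma) on the full
      # Laplace objective; the profiled and full optima sit ~1% apart, so a
      # few quadratic steps from the stage-1 fit suffice
      f_full <- make_objective("full")
      centre <- ls_hat
      fc <- f_full(centre)
      h <- 0.05
      for (round in 1:3) {
        moved <- FALSE
        for (k in seq_along(centre)) {
          if (centre[k] <= lower_ls + 1e-8) next
          up <- centre; up[k] <- min(centre[k] + h, upper_ls)
          dn <- centre; dn[k] <- max(centre[k] - h, lower_ls)
          fu <- f_full(up)
          fd <- f_full(dn)
          curv <- (fu - 2 * fc + fd)
          if (is.finite(curv) && curv > 1e-12) {
            step <- -h * (fu - fd) / (2 * curv)
            step <- max(min(step, 2 * h), -2 * h)
            cand <- centre
            cand[k] <- min(max(centre[k] + step, lower_ls), upper_ls)
            fcand <- f_full(cand)
            if (fcand <= fc) {
              centre <- cand
              fc <- fcand
              moved <- TRUE
            }
          } else if (fu < fc || fd < fc) {
            centre <- if (fu < fd) up else dn
            fc <- min(fu, fd)
            moved <- TRUE
          }
        }
        h <- h / 4
        if (!moved) break
      }
      ls_hat <- centre
    }
    sig2 <- exp(2 * ls_hat)
    # boundary handling: a sigma at (or squeezed against) the floor is a
    # zero-variance solution; drop the block and refit so modes are exactly 0
    sig2[sig2 < 1e-7] <- 0
    fit <- inner_fit(sig2, warm$beta, if (any(sig2 == 0)) NULL else warm$u)
    n_outer <- n_eval
    converged_outer <- opt$convergence == 0
  }

  boundary <- any(sig2 < 1e-8)
  theta <- fit$u_person
  b <- fit$u_item
  names(theta) <- levels(pf)
  names(b) <- levels(itf)
  beta <- fit$beta
  names(beta) <- colnames(X)
  beta_cov <- fit$beta_cov
  dimnames(beta_cov) <- list(colnames(X), colnames(X))

  structure(list(
    beta = beta,
    se = sqrt(pmax(diag(beta_cov), 0)),
    beta_cov = beta_cov,
    sigma2_person = sig2[1],
    sigma2_item = sig2[2],
    person_modes = theta,
    item_modes = b,
    laplace_loglik = fit$loglik,
    converged = converged_outer && fit$converged,
    boundary = boundary,
    n_inner_iters = fit$n_iter,
    n_outer_iters = n_outer,
    person_levels = levels(pf),
    item_levels = levels(itf),
    n_obs = n
  ), class = "eirmrf_glmm")
}

start_beta <- function(y, X) {
  # plain logistic start; fall back to zeros if the GLM itself complains
  b <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())$coefficients),
    error = function(e) rep(0, ncol(X))
  )
  b[!is.finite(b)] <- 0
  pmin(pmax(b, -10), 10)
}

# numerically safe log(1 + exp(x))
softplus <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

# Penalized IRLS on the augmented (beta, u) system for fixed variances.
# The two-block random-effect Hessian S = Z'WZ + D^{-1} is
# [diag(a_p), B; B', diag(a_i)] with B the person-by-item weight table, so
# every solve and the log-determinant reduce by block elimination to an
# I x I Cholesky -- no large factorization is ever formed.  Returns the
# joint mode, the Laplace log-likelihood ("profiled" at the joint mode, or
# "full" after exact-gradient Newton corrector steps on beta) and the Wald
# covariance of beta.
pirls_crossed <- function(y, X, pidx, iidx, J, I, sig2, beta_init,
                          u_init = NULL, tol = 1e-8, max_inner = 200L,
                          laplace = "full") {
  n <- length(y)
  p <- ncol(X)
  use_p <- sig2[1] > 0
  use_i <- sig2[2] > 0
  qp <- if (use_p) J else 0L
  qi <- if (use_i) I else 0L
  q <- qp + qi
  dinv <- c(rep(1 / sig2[1], qp), rep(1 / sig2[2], qi))

  beta <- beta_init
  if (length(beta) != p) beta <- rep(0, p)
  u <- if (!is.null(u_init) && length(u_init) == q) u_init else rep(0, q)

  # implicit Z operations through the cluster indices; group sums use a
  # precomputed ordering so no per-call group bookkeeping is needed
  group_sum <- function(idx, nb) {
    ord <- order(idx)
    ends <- cumsum(tabulate(idx, nb))
    function(v) {
      v <- as.matrix(v)
      out <- matrix(0, nb, ncol(v))
      for (k in seq_len(ncol(v))) {
        cs <- cumsum(v[ord, k])
        out[, k] <- cs[ends] - c(0, cs[ends[-nb]])
      }
      out
    }
  }
  gs_p <- if (use_p) group_sum(pidx, J) else NULL
  gs_i <- if (use_i) group_sum(iidx, I) else NULL
  cell <- (iidx - 1L) * J + pidx
  cells_unique <- !anyDuplicated(cell)

  Zu <- function(u) {
    out <- numeric(n)
    if (qp) out <- out + u[pidx]
    if (qi) out <- out + u[qp + iidx]
    out
  }
  Zt <- function(v) {
    out <- NULL
    if (qp) out <- gs_p(v)
    if (qi) out <- rbind(out, gs_i(v))
    out
  }

  # factorization handle for S = Z'WZ + D^{-1} at weights w: solves,
  # log-determinant, and the per-row quadratic forms z_n' S^{-1} z_n
  # needed by the full-Laplace correction
  S_ops <- function(w) {
    ap <- if (qp) as.numeric(gs_p(w)) + dinv[1] else NULL
    ai <- if (qi) as.numeric(gs_i(w)) + dinv[qp + 1] else NULL
    if (qp && qi) {
      B <- matrix(0, J, I)
      if (cells_unique) {
        B[cell] <- w
      } else {
        agg <- rowsum(w, cell)
        B[as.integer(rownames(agg))] <- agg
      }
      BA <- B / ap
      M <- diag(ai, I) - crossprod(B, BA)
      Mchol <- chol(M)
      solve_S <- function(b) {
        b <- as.matrix(b)
        bp <- b[seq_len(J), , drop = FALSE]
        bi <- b[J + seq_len(I), , drop = FALSE]
        xi <- backsolve(Mchol, forwardsolve(t(Mchol), bi - crossprod(BA, bp)))
        xp <- (bp - B %*% xi) / ap
        rbind(xp, xi)
      }
      drow <- function() {
        Minv <- chol2inv(Mchol)
        BM <- BA %*% Minv
        djj <- 1 / ap + rowSums(BM * BA)
        dii <- diag(Minv)
        djj[pidx] + dii[iidx] - 2 * BM[cbind(pidx, iidx)]
      }
      logdet <- sum(log(ap)) + 2 * sum(log(diag(Mchol)))
    } else if (qp) {
      solve_S <- function(b) as.matrix(b) / ap
      drow <- function() (1 / ap)[pidx]
      logdet <- sum(log(ap))
    } else {
      solve_S <- function(b) as.matrix(b) / ai
      drow <- function() (1 / ai)[iidx]
      logdet <- sum(log(ai))
    }
    list(solve = solve_S, drow = drow, logdet = logdet)
  }

  pen_loglik <- function(eta, u) {
    sum(y * eta - softplus(eta)) - 0.5 * sum(dinv * u^2)
  }

  eta <- as.numeric(X %*% beta) + if (q) Zu(u) else 0
  ll <- pen_loglik(eta, u)
  converged <- FALSE
  iter <- 0L
  gtol <- tol * max(1, n / 100)

  for (iter in seq_len(max_inner)) {
    mu <- invlogit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    res <- y - mu
    g_beta <- as.numeric(crossprod(X, res))
    XtWX <- crossprod(X * w, X)
    if (q) {
      g_u <- as.numeric(Zt(res)) - dinv * u
      ops <- S_ops(w)
      ZtWX <- Zt(X * w)
      Tm <- ops$solve(ZtWX)
      C <- XtWX - crossprod(ZtWX, Tm)
      d_beta <- solve(C, g_beta - as.numeric(crossprod(Tm, g_u)))
      d_u <- as.numeric(ops$solve(g_u - ZtWX %*% d_beta))
      grad_norm <- max(abs(g_beta), abs(g_u))
    } else {
      C <- XtWX
      d_beta <- solve(C, g_beta)
      d_u <- numeric(0)
      grad_norm <- max(abs(g_beta))
    }

    if (grad_norm < gtol) {
      converged <- TRUE
      break
    }

    # step-halving line search on the penalized log-likelihood
    step <- 1
    improved <- FALSE
    for (h in 1:25) {
      beta_new <- beta + step * as.numeric(d_beta)
      u_new <- u + step * d_u
      eta_new <- as.numeric(X %*% beta_new) + if (q) Zu(u_new) else 0
      ll_new <- pen_loglik(eta_new, u_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    delta <- abs(ll_new - ll)
    beta <- beta_new
    u <- u_new
    eta <- eta_new
    ll <- ll_new
    if (delta < 1e-12 * max(1, abs(ll))) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 1e3) {
      stop_eirmrf("fixed-effect estimates diverging: possible separation",
                  "separation_error")
    }
  }

  # Full-Laplace beta correction: Newton steps on the exact Laplace
  # beta-gradient, which adds the log-determinant sensitivity terms
  # (-1/2) [ d log|S| / d beta + (d log|S| / d u) du/d beta ] to the joint
  # mode's score.  The u mode is re-solved after each beta update.
  if (laplace == "full" && q) {
    ctol <- max(tol, 1e-7) * max(1, n / 100)
    for (corr_iter in 1:3) {
      mu <- invlogit(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      w3 <- w * (1 - 2 * mu)
      ops <- S_ops(w)
      d_row <- ops$drow()
      ZtWX <- Zt(X * w)
      sa <- ops$solve(as.numeric(Zt(w3 * d_row)))
      g_full <- as.numeric(crossprod(X, y - mu)) -
        0.5 * as.numeric(crossprod(X, w3 * d_row)) +
        0.5 * as.numeric(crossprod(ZtWX, sa))
      C <- crossprod(X * w, X) - crossprod(ZtWX, ops$solve(ZtWX))
      step <- tryCatch(solve(C, g_full), error = function(e) NULL)
      if (is.null(step)) break
      if (max(abs(g_full)) < ctol) break
      if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))
      beta <- beta + as.numeric(step)
      # re-find the u mode for the updated beta
      xb <- as.numeric(X %*% beta)
      for (uit in 1:10) {
        eta <- xb + Zu(u)
        mu_u <- invlogit(eta)
        w_u <- pmax(mu_u * (1 - mu_u), 1e-10)
        g_u <- as.numeric(Zt(y - mu_u)) - dinv * u
        if (max(abs(g_u)) < ctol) break
        u <- u + as.numeric(S_ops(w_u)$solve(g_u))
      }
      eta <- xb + Zu(u)
    }
  }

  # Laplace pieces at the mode (recompute weights there)
  mu <- invlogit(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  if (q) {
    ops <- S_ops(w)
    ZtWX <- Zt(X * w)
    C <- crossprod(X * w, X) - crossprod(ZtWX, ops$solve(ZtWX))
    logdet_D <- sum(log(1 / dinv))
    loglik <- sum(y * eta - softplus(eta)) - 0.5 * sum(dinv * u^2) -
      0.5 * logdet_D - 0.5 * ops$logdet
  } else {
    C <- crossprod(X * w, X)
    loglik <- sum(y * eta - softplus(eta))
  }
  beta_cov <- tryCatch(solve(C), error = function(e) {
    MASSish_ginv(C)
  })

  u_person <- rep(0, J)
  u_item <- rep(0, I)
  if (use_p && use_i) {
    u_person <- u[seq_len(J)]
    u_item <- u[J + seq_len(I)]
  } else if (use_p) {
    u_person <- u
  } else if (use_i) {
    u_item <- u
  }

  list(
    beta = as.numeric(beta), u = u, u_person = u_person, u_item = u_item,
    loglik = as.numeric(loglik), beta_cov = as.matrix(beta_cov),
    converged = converged, n_iter = iter, fitted = invlogit(eta)
  )
}

# Moore-Penrose fallback for a (nearly) singular Schur complement.
MASSish_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Predicted probabilities from a crossed logistic mixed model
#'
#' Inverse logit of `X beta` plus, when `include_random`, the conditional
#' modes of the person and item effects.  Persons or items unseen at fit
#' time contribute 0 on the logit scale (population-average prediction).
#'
#' @param fit an `eirmrf_glmm` object.
#' @param X fixed-effects design matrix for the rows to predict.
#' @param person_index,item_index identifiers of each row's clusters.
#' @param include_random add the conditional modes (default `TRUE`).
#' @return vector of probabilities.
#' @export
predict_prob <- function(fit, X, person_index, item_index, include_random = TRUE) {
  stopifnot(inherits(fit, "eirmrf_glmm"))
  X <- as.matrix(X)
  if (ncol(X) != length(fit$beta)) {
    stop_eirmrf("design matrix has the wrong number of columns", "design_error")
  }
  eta <- as.numeric(X %*% fit$beta)
  if (include_random) {
    th <- fit$person_modes[as.character(person_index)]
    bi <- fit$item_modes[as.character(item_index)]
    th[is.na(th)] <- 0
    bi[is.na(bi)] <- 0
    eta <- eta + as.numeric(th) + as.numeric(bi)
  }
  invlogit(eta)
}

#' @export
print.eirmrf_glmm <- function(x, ...) {
  cat("Crossed random-intercept logistic model (Laplace)\n")
  cat(sprintf("  n = %d, persons = %d, items = %d\n",
              x$n_obs, length(x$person_modes), length(x$item_modes)))
  coefs <- cbind(Estimate = x$beta, `Std.Error` = x$se, z = x$beta / x$se)
  print(round(coefs, 4))
  cat(sprintf("  sigma2_person = %.4f (ICC %.3f), sigma2_item = %.4f (ICC %.3f)\n",
              x$sigma2_person, conditional_icc(x$sigma2_person),
              x$sigma2_item, conditional_icc(x$sigma2_item)))
  cat(sprintf("  Laplace log-lik %.3f; converged: %s%s\n", x$laplace_loglik,
              x$converged, if (x$boundary) " (variance at boundary)" else ""))
  invisible(x)
}

#' Export a mixed-model fit summary as JSON
#'
#' @param fit an `eirmrf_glmm`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
glmm_summary_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "eirmrf_glmm"))
  out <- list(
    coefficients = as.list(fit$beta),
    se = as.list(stats::setNames(fit$se, names(fit$beta))),
    z = as.list(stats::setNames(fit$beta / fit$se, names(fit$beta))),
    sigma2_person = fit$sigma2_person,
    sigma2_item = fit$sigma2_item,
    icc_person = conditional_icc(fit$sigma2_person),
    icc_item = conditional_icc(fit$sigma2_item),
    laplace_loglik = fit$laplace_loglik,
    converged = fit$converged,
    boundary = fit$boundary
  )
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
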