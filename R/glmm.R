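# Random-intercept logistic regression fitted by maximizing the exact
# marginal likelihood with adaptive Gauss-Hermite quadrature.

#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch rule for the weight e^{-z^2}: eigen-decomposition of the
#' symmetric tridiagonal Jacobi matrix with off-diagonal sqrt(i/2).
#'
#' @param n Number of nodes (odd recommended).
#' @return List with `nodes` and `weights` (sum of weights = sqrt(pi)).
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(
    nodes = e$values[ord],
    weights = sqrt(pi) * e$vectors[1, ord]^2
  )
}

# Reorder rows so groups are contiguous; return 0-based offsets for C++.
group_layout <- function(group) {
  ord <- order(match(group, unique(group)))
  g <- group[ord]
  starts <- c(0L, which(diff(as.integer(factor(g, levels = unique(g)))) != 0))
  lens <- diff(c(starts, length(g)))
  list(order = ord, start = as.integer(starts), len = as.integer(lens))
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' For groups i with responses y_it and linear predictors x_it'beta, the
#' marginal likelihood integrates the Bernoulli likelihood over the
#' group-level intercept u ~ N(0, sigma_u^2):
#' sum_i log int prod_t Bernoulli(y_it | plogis(x_it'beta + u)) phi(u) du.
#' Each integral is evaluated by Gauss-Hermite quadrature recentred at the
#' group's posterior mode with curvature-based scaling. At `sigma_u = 0`
#' the plain logistic log-likelihood is evaluated analytically.
#'
#' @param beta Fixed-effect coefficient vector (matching columns of `X`).
#' @param sigma_u Random-intercept SD (>= 0).
#' @param y Binary response vector.
#' @param X Design matrix.
#' @param group Grouping vector (participant ids).
#' @param n_quad Number of quadrature nodes (default 25).
#' @return Scalar log-likelihood.
#' @export
glmm_marginal_loglik <- function(beta, sigma_u, y, X, group, n_quad = 25) {
  stopifnot(
    all(is.finite(beta)), is.finite(sigma_u), sigma_u >= 0,
    length(y) == nrow(X), length(group) == length(y)
  )
  eta0 <- drop(X %*% beta)
  if (sigma_u < 1e-8) {
    return(-logistic_nll_cpp(eta0, as.numeric(y)))
  }
  lay <- group_layout(group)
  gh <- gauss_hermite(n_quad)
  -glmm_nll_cpp(
    eta0[lay$order], as.numeric(y)[lay$order],
    lay$start, lay$len, sigma_u, gh$nodes, log(gh$weights)
  )
}

# Negative penalized marginal log-likelihood and its analytic gradient
# over par = c(beta, log_sigma). The returned closure caches the last
# evaluation so optim's separate fn/gr calls cost one kernel pass.
make_obj <- function(y, X, lay, gh, ridge = 0) {
  y <- as.numeric(y)[lay$order]
  Xo <- X[lay$order, , drop = FALSE]
  pen <- as.numeric(colnames(X) != "(Intercept)")
  cache_par <- NULL
  cache_val <- NULL
  function(par) {
    if (!is.null(cache_par) && identical(par, cache_par)) return(cache_val)
    p <- length(par) - 1
    beta <- par[seq_len(p)]
    sigma <- exp(par[p + 1])
    if (sigma < 1e-8) {
      eta0 <- drop(Xo %*% beta)
      pr <- plogis(eta0)
      val <- list(
        nll = logistic_nll_cpp(eta0, y),
        grad = c(-drop(crossprod(Xo, y - pr)), 0)
      )
    } else {
      val <- glmm_nll_grad_cpp(Xo, y, lay$start, lay$len, beta, par[p + 1],
        gh$nodes, log(gh$weights))
    }
    if (ridge > 0) {
      val$nll <- val$nll + ridge * sum(pen * beta^2)
      val$grad <- val$grad + c(2 * ridge * pen * beta, 0)
    }
    cache_par <<- par
    cache_val <<- val
    val
  }
}

# Hessian by central differences of the analytic gradient.
grad_hessian <- function(obj, x, h = 1e-5) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    H[, j] <- (obj(xp)$grad - obj(xm)$grad) / (2 * hj)
  }
  (H + t(H)) / 2
}

#' Fit a random-intercept logistic regression
#'
#' Maximizes the adaptive Gauss-Hermite marginal likelihood over
#' (beta, log sigma_u) with BFGS from a deterministic start (beta from a
#' plain logistic fit, sigma_u = 0.5), followed by Newton polish on a
#' finite-difference Hessian. If any coefficient exceeds
#' `separation_threshold` in absolute value (quasi-separation on z-scored
#' columns), the model is refitted with a ridge penalty on the
#' non-intercept coefficients and flagged `penalized`.
#'
#' @param data Data frame / tibble holding outcome, covariates and the
#'   grouping column.
#' @param formula Model formula, e.g.
#'   `outcome_event ~ hw_within + en_within + di_within + hw_between +
#'    en_between + di_between + weeks_since_baseline`.
#' @param group Name of the grouping column (default `"participant_id"`).
#' @param n_quad Quadrature nodes, odd, >= 5 (default 25).
#' @param ridge Ridge strength used only by the separation fallback
#'   (default 4).
#' @param separation_threshold Absolute coefficient bound beyond which the
#'   fit is considered quasi-separated (default 15).
#' @return Object of class `glmm_fit`: named `beta`, `se`, `vcov`,
#'   `sigma_u`, `loglik`, `converged`, `penalized`, `n_obs`, `n_groups`.
#' @examples
#' panel <- simulate_panel(sim_config(n_participants = 40, n_weeks = 10,
#'   event_intercept = -2, seed = 4))$panel
#' fit <- fit_glmm(panel, outcome_event ~ hw_within + weeks_since_baseline)
#' tidy(fit)
#' @export
fit_glmm <- function(data, formula, group = "participant_id", n_quad = 25,
                     ridge = 4, separation_threshold = 15) {
  stopifnot(n_quad >= 5, n_quad %% 2 == 1)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  keep <- as.integer(rownames(mf))
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  grp <- data[[group]][keep]
  if (length(unique(grp)) < 2) stop("need at least 2 groups", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    warning("dropping rank-deficient columns: ", paste(drop_cols, collapse = ", "),
      call. = FALSE
    )
  }

  lay <- group_layout(grp)
  gh <- gauss_hermite(n_quad)

  start_glm <- suppressWarnings(
    stats::glm.fit(X, y, family = binomial())
  )
  start <- c(start_glm$coefficients, log(0.5))
  start[!is.finite(start)] <- 0

  run <- function(pen) {
    # the penalized refit starts from the origin: the unpenalized glm start
    # is exactly what diverges under separation
    st <- if (pen > 0) c(rep(0, ncol(X)), log(0.5)) else start
    obj <- make_obj(y, X, lay, gh, ridge = pen)
    opt <- optim(st, function(p) obj(p)$nll, gr = function(p) obj(p)$grad,
      method = "BFGS", control = list(maxit = 300, reltol = 1e-10)
    )
    # Newton polish for a sharp optimum
    par <- opt$par
    last_step <- Inf
    for (i in 1:10) {
      g <- obj(par)$grad
      H <- grad_hessian(obj, par)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      cand <- par - step
      nll_cand <- obj(cand)$nll
      if (!is.finite(nll_cand) || nll_cand > obj(par)$nll + 1e-9) break
      par <- cand
      last_step <- max(abs(step))
      if (last_step < 1e-10) break
    }
    at <- obj(par)
    list(par = par, obj = obj, value = at$nll, grad = at$grad,
      last_step = last_step)
  }

  res <- run(0)
  p <- ncol(X)
  penalized <- any(abs(res$par[seq_len(p)]) > separation_threshold)
  if (penalized) res <- run(ridge)

  boundary <- exp(res$par[p + 1]) < 1e-4
  if (boundary) {
    # sigma_u has collapsed to the boundary: the marginal model degenerates
    # to plain logistic regression, which has an analytic branch
    res$par[p + 1] <- log(1e-12)
    obj0 <- make_obj(y, X, lay, gh, ridge = if (penalized) ridge else 0)
    beta_hat <- res$par[seq_len(p)]
    for (i in 1:25) {
      at <- obj0(c(beta_hat, log(1e-12)))
      g <- at$grad[seq_len(p)]
      eta <- drop(X[lay$order, , drop = FALSE] %*% beta_hat)
      w <- plogis(eta) * (1 - plogis(eta))
      Hb <- crossprod(X[lay$order, , drop = FALSE] * w, X[lay$order, , drop = FALSE])
      if (penalized) diag(Hb) <- diag(Hb) +
          2 * ridge * as.numeric(colnames(X) != "(Intercept)")
      step <- tryCatch(solve(Hb, g), error = function(e) NULL)
      if (is.null(step)) break
      beta_hat <- beta_hat - step
      res$last_step <- max(abs(step))
      if (res$last_step < 1e-10) break
    }
    res$par[seq_len(p)] <- beta_hat
    at <- obj0(c(beta_hat, log(1e-12)))
    res$value <- at$nll
    res$grad <- c(at$grad[seq_len(p)], 0)
    res$obj <- function(par) obj0(c(par[seq_len(p)], log(1e-12)))
  }

  beta <- setNames(res$par[seq_len(p)], colnames(X))
  sigma_u <- exp(res$par[p + 1])
  H <- grad_hessian(res$obj, res$par)
  if (boundary) H[p + 1, ] <- H[, p + 1] <- c(rep(0, p), 1)
  V <- tryCatch(solve(H)[seq_len(p), seq_len(p), drop = FALSE],
    error = function(e) NULL
  )
  if (is.null(V) || any(diag(V) <= 0)) {
    V <- tryCatch(solve(H[seq_len(p), seq_len(p), drop = FALSE]),
      error = function(e) matrix(NA_real_, p, p)
    )
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))

  grad_norm <- sqrt(sum(res$grad^2))
  loglik <- -res$value
  structure(list(
    beta = beta,
    se = sqrt(diag(V)),
    vcov = V,
    sigma_u = if (sigma_u < 1e-8) 0 else sigma_u,
    loglik = loglik,
    converged = grad_norm < 1e-6 && res$last_step < 1e-8,
    penalized = penalized,
    grad_norm = grad_norm,
    n_obs = length(y),
    n_groups = length(unique(grp)),
    n_quad = n_quad,
    formula = formula,
    group = group
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Random-intercept logistic regression (adaptive Gauss-Hermite,",
    x$n_quad, "nodes)\n")
  cat(sprintf(
    "  %d obs, %d groups; sigma_u = %.3f; logLik = %.2f%s%s\n",
    x$n_obs, x$n_groups, x$sigma_u, x$loglik,
    if (x$converged) "" else " [not converged]",
    if (x$penalized) " [ridge-penalized]" else ""
  ))
  print(report_or(x), n = Inf)
  invisible(x)
}

#' Odds-ratio report from a fitted model
#'
#' Adjusted odds ratios exp(beta) with Wald confidence intervals
#' exp(beta +/- z * SE) and two-sided Wald p-values, one row per term.
#'
#' @param fit A `glmm_fit`.
#' @param level Confidence level (default 0.95).
#' @return Tibble: `term`, `estimate` (log-odds), `std.error`, `or`,
#'   `or.low`, `or.high`, `p.value`.
#' @export
report_or <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!fit$converged && !fit$penalized) {
    stop("refusing to report a non-converged, non-penalized fit", call. = FALSE)
  }
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = names(fit$beta),
    estimate = unname(fit$beta),
    std.error = unname(fit$se),
    or = exp(.data$estimate),
    or.low = exp(.data$estimate - z * .data$std.error),
    or.high = exp(.data$estimate + z * .data$std.error),
    p.value = 2 * pnorm(-abs(.data$estimate / .data$std.error))
  )
}

#' @export
tidy.glmm_fit <- function(x, conf.int = TRUE, conf.level = 0.95,
                          exponentiate = FALSE, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = .data$estimate / .data$std.error,
    p.value = 2 * pnorm(-abs(.data$statistic))
  )
  if (conf.int) {
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  if (exponentiate) {
    out <- dplyr::mutate(out, dplyr::across(
      dplyr::any_of(c("estimate", "conf.low", "conf.high")), exp
    ))
  }
  out
}

#' @export
glance.glmm_fit <- function(x, ...) {
  tibble::tibble(
    sigma_u = x$sigma_u, logLik = x$loglik, nobs = x$n_obs,
    n_groups = x$n_groups, converged = x$converged, penalized = x$penalized
  )
}

#' Population-level predictions (fixed effects only)
#'
#' Risk scores from the fixed effects alone, i.e. with the random
#' intercept set to zero, as used when scoring held-out weeks so accuracy
#' is not driven by individual outcome histories.
#'
#' @param object A `glmm_fit`.
#' @param newdata Data frame with the model's covariates.
#' @param type `"link"` (log-odds, default) or `"response"`.
#' @param ... Unused.
#' @export
predict.glmm_fit <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  rhs <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(rhs, stats::model.frame(rhs, newdata,
    na.action = stats::na.pass
  ))
  X <- X[, names(object$beta), drop = FALSE]
  eta <- drop(X %*% object$beta)
  if (type == "response") plogis(eta) else eta
}

#' Temporal-lag and bidirectional association scan
#'
#' Forward direction: refits the event (or ideation) model at feature lags
#' 0-3 weeks, i.e. features in week T - L against the outcome in week T.
#' Reversed direction: linear models of each within-person feature term at
#' week T on the event indicator at week T - 1, testing whether events
#' precede mobility change rather than follow it. A failed fit at one lag
#' is recorded and the scan continues.
#'
#' @param decomposed Weekly table from [decompose_weekly()] +
#'   [outcome_weeks()].
#' @param lags Integer lags for the forward scan (default 0:3).
#' @param direction `"forward"` or `"reversed"`.
#' @param outcome `"event"` or `"ideation"` (forward only).
#' @param level Confidence level for Wald intervals.
#' @return Tibble: `direction`, `lag`, `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`, `penalized`, `error`.
#' @export
lag_scan <- function(decomposed, lags = 0:3,
                     direction = c("forward", "reversed"),
                     outcome = c("event", "ideation"), level = 0.95) {
  direction <- match.arg(direction)
  outcome <- match.arg(outcome)
  z <- qnorm(1 - (1 - level) / 2)
  if (direction == "forward") {
    purrr::map(lags, function(L) {
      panel <- build_panel(decomposed, lag = L, outcome = outcome)
      lhs <- paste0("outcome_", outcome)
      f <- as.formula(paste(
        lhs, "~ hw_within + en_within + di_within + hw_between + en_between",
        "+ di_between + weeks_since_baseline"
      ))
      fit <- tryCatch(fit_glmm(panel, f), error = function(e) e)
      if (inherits(fit, "error")) {
        return(tibble::tibble(
          direction = "forward", lag = L, term = NA_character_,
          estimate = NA_real_, std.error = NA_real_, conf.low = NA_real_,
          conf.high = NA_real_, p.value = NA_real_, penalized = NA,
          error = conditionMessage(fit)
        ))
      }
      tidy(fit, conf.level = level) |>
        dplyr::mutate(
          direction = "forward", lag = L, penalized = fit$penalized,
          error = NA_character_, .before = 1
        ) |>
        dplyr::select(-"statistic")
    }) |>
      dplyr::bind_rows()
  } else {
    purrr::map(c("hw_within", "en_within", "di_within"), function(feat) {
      rp <- build_reversed_panel(decomposed, feature = feat)
      fit <- tryCatch(lm(feature_value ~ event_prev + weeks_since_baseline,
        data = rp), error = function(e) e)
      if (inherits(fit, "error")) {
        return(tibble::tibble(
          direction = "reversed", lag = 1, term = feat, estimate = NA_real_,
          std.error = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
          p.value = NA_real_, penalized = NA, error = conditionMessage(fit)
        ))
      }
      sm <- summary(fit)$coefficients["event_prev", ]
      tibble::tibble(
        direction = "reversed", lag = 1, term = feat,
        estimate = sm[["Estimate"]], std.error = sm[["Std. Error"]],
        conf.low = sm[["Estimate"]] - z * sm[["Std. Error"]],
        conf.high = sm[["Estimate"]] + z * sm[["Std. Error"]],
        p.value = sm[["Pr(>|t|)"]], penalized = FALSE, error = NA_character_
      )
    }) |>
      dplyr::bind_rows()
  }
}
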