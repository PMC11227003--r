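#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights for \eqn{\int e^{-x^2} f(x) dx \approx \sum w_k f(x_k)},
#' computed by the Golub-Welsch eigen-decomposition of the Jacobi matrix.
#'
#' @param n number of nodes.
#' @return list with \code{nodes} and \code{weights}.
#' @export
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * (e$vectors[1, ord])^2)
}

# Bernoulli-logit data loglik per observation, numerically safe
bern_loglik <- function(eta, y) {
  # y*eta - log(1+exp(eta)) computed stably
  -log1p(exp(-abs(eta))) - pmax(eta, 0) + y * eta
}

# find the per-patient posterior mode of the random intercept by Newton,
# all patients simultaneously (each mode is one-dimensional)
inner_mode <- function(eta0, y, pid, m, sigma2, u = NULL,
                       max_iter = 50, tol = 1e-10) {
  if (is.null(u)) u <- numeric(m)
  for (it in seq_len(max_iter)) {
    eta <- eta0 + u[pid]
    mu <- stats::plogis(eta)
    grad <- rowsum(y - mu, pid, reorder = FALSE)[, 1] - u / sigma2
    W <- rowsum(mu * (1 - mu), pid, reorder = FALSE)[, 1]
    h <- W + 1 / sigma2
    step <- grad / h
    u_new <- u + step
    # safeguarded: halve steps that overshoot (objective is concave so
    # plain Newton converges; the cap guards early wild steps)
    u_new <- pmin(pmax(u_new, u - 5), u + 5)
    u <- u_new
    if (max(abs(grad)) < tol * max(1, max(abs(u)))) break
  }
  eta <- eta0 + u[pid]
  mu <- stats::plogis(eta)
  W <- rowsum(mu * (1 - mu), pid, reorder = FALSE)[, 1]
  ll_data <- rowsum(bern_loglik(eta, y), pid, reorder = FALSE)[, 1]
  list(u = u, W = W, ll_data = ll_data)
}

# corrected Laplace log-likelihood given linear predictor eta0; returns the
# total loglik and the per-patient modes for warm starting
laplace_ll <- function(eta0, y, pid, m, s2, u = NULL, correct = TRUE) {
  md <- inner_mode(eta0, y, pid, m, s2, u = u)
  h <- md$W + 1 / s2
  base <- md$ll_data - md$u^2 / (2 * s2) - 0.5 * log(s2) - 0.5 * log(h)
  if (!correct) return(list(ll = sum(base), u = md$u))
  eta <- eta0 + md$u[pid]
  mu <- stats::plogis(eta)
  v <- mu * (1 - mu)
  c3 <- rowsum(-v * (1 - 2 * mu), pid, reorder = FALSE)[, 1]
  c4 <- rowsum(-v * (1 - 6 * v), pid, reorder = FALSE)[, 1]
  c6 <- rowsum(-v * (1 - 30 * v + 120 * v^2), pid, reorder = FALSE)[, 1]
  tau <- 1 / h
  t2 <- c4 * tau^2 / 8
  t3 <- (5 * c3^2 + c6 / 2) * tau^3 / 24
  fac <- pmax(1 + t2 + t3, 0.3)
  ll <- base + log(fac)
  # blend weakly informative clusters (large correction => asymptotic series
  # unreliable) into an exact wide-grid Simpson evaluation
  cmag <- abs(t2) + abs(t3)
  w <- pmax(stats::plogis((cmag - 0.05) / 0.008),
            stats::plogis((tau - 0.45) / 0.03))
  flagged <- which(w > 0.05)
  if (length(flagged)) {
    ngrid <- 201L
    sw <- c(1, rep(c(4, 2), (ngrid - 3) / 2), 4, 1)   # Simpson weights
    for (i in flagged) {
      obs <- pid == i
      half <- 12 / sqrt(h[i])
      ugrid <- seq(md$u[i] - half, md$u[i] + half, length.out = ngrid)
      # grid x observation matrix of Bernoulli log-likelihood terms
      M <- outer(ugrid, eta0[obs], "+")
      L <- -log1p(exp(-abs(M))) - pmax(M, 0) +
        rep(y[obs], each = ngrid) * M
      gg <- rowSums(L) - ugrid^2 / (2 * s2) - 0.5 * log(2 * pi * s2)
      mx <- max(gg)
      step <- ugrid[2] - ugrid[1]
      ll_exact <- mx + log(sum(sw * exp(gg - mx)) * step / 3)
      ll[i] <- (1 - w[i]) * ll[i] + w[i] * ll_exact
    }
  }
  list(ll = sum(ll), u = md$u)
}

#' Marginal log-likelihood of the logistic random-intercept model
#'
#' Log-likelihood of \eqn{y_{ij} \sim Bernoulli(logit^{-1}(x_{ij}'\beta + u_i))}
#' with \eqn{u_i \sim N(0, \sigma_u^2)}, integrating each patient's random
#' intercept out.  The default \code{"laplace"} method is a sixth-order
#' Laplace approximation (mode plus curvature plus the skewness/kurtosis
#' correction terms of the Gaussian expansion); clusters so weakly
#' informative that the correction itself is non-negligible are smoothly
#' blended into a deterministic wide-grid Simpson integration of the same
#' one-dimensional integral.  \code{"aghq"} is adaptive Gauss-Hermite
#' quadrature centered and scaled at the Laplace mode, the independent
#' oracle used for verification.
#'
#' @param beta fixed-effect coefficients (conformable with \code{X}).
#' @param sigma_u random-intercept SD (\code{0} reduces exactly to plain
#'   logistic regression).
#' @param X fixed-effects design matrix.
#' @param y binary response vector.
#' @param patient patient identifier vector (factor/character/integer).
#' @param method \code{"laplace"} or \code{"aghq"}.
#' @param nodes quadrature nodes for \code{"aghq"} (>= 25 recommended).
#' @param correction \code{"sixth_order"} (default) or \code{"none"} (the
#'   plain mode-plus-curvature Laplace value, as in standard mixed-model
#'   software).
#' @return the marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(beta, sigma_u, X, y, patient,
                            method = c("laplace", "aghq"), nodes = 25,
                            correction = c("sixth_order", "none")) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  stopifnot(all(is.finite(beta)), is.finite(sigma_u), sigma_u >= 0)
  pid <- as.integer(factor(patient))
  m <- max(pid)
  eta0 <- as.numeric(X %*% beta)
  if (sigma_u == 0) return(sum(bern_loglik(eta0, y)))
  s2 <- sigma_u^2
  if (method == "laplace") {
    return(laplace_ll(eta0, y, pid, m, s2,
                      correct = (correction == "sixth_order"))$ll)
  }
  md <- inner_mode(eta0, y, pid, m, s2)
  h <- md$W + 1 / s2
  gh <- gauss_hermite(nodes)
  s_i <- 1 / sqrt(h)
  # log integrand at adapted nodes, patients x nodes
  logterms <- matrix(0, m, nodes)
  for (k in seq_len(nodes)) {
    u_k <- md$u + sqrt(2) * s_i * gh$nodes[k]
    eta <- eta0 + u_k[pid]
    ll <- rowsum(bern_loglik(eta, y), pid, reorder = FALSE)[, 1]
    logterms[, k] <- log(gh$weights[k]) + gh$nodes[k]^2 + ll -
      u_k^2 / (2 * s2) - 0.5 * log(2 * pi * s2)
  }
  mx <- apply(logterms, 1, max)
  sum(log(sqrt(2) * s_i) + mx + log(rowSums(exp(logterms - mx))))
}

#' Fit a logistic generalized linear mixed model with a patient random
#' intercept
#'
#' Maximizes the Laplace marginal likelihood over
#' \eqn{(\beta, \log\sigma_u)} by BFGS, with restarts from
#' \eqn{\sigma_u \in \{0.1, 1\}} on failure.  Standard errors come from the
#' inverse observed information at the optimum and p-values from two-sided
#' Wald tests.  Complete separation is flagged when any standardized
#' coefficient exceeds 10 in absolute value; flagged or non-converged fits
#' carry \code{converged = FALSE} and should not be interpreted.
#'
#' @param y binary response.
#' @param X design matrix (include the intercept column).
#' @param patient patient identifier vector.
#' @param start optional start for \code{c(beta, log_sigma)}.
#' @param reltol optimizer relative tolerance.
#' @param max_iter optimizer iteration cap.
#' @return object of class \code{glmm_fit}: \code{coefficients} data.frame
#'   (term, estimate, se, z, p), \code{sigma_u}, \code{loglik},
#'   \code{converged}, \code{separation}, \code{n_obs}, \code{n_patients}.
#' @export
fit_glmm <- function(y, X, patient, start = NULL, reltol = 1e-8,
                     max_iter = 500) {
  X <- as.matrix(X)
  pid <- as.integer(factor(patient))
  m <- max(pid)
  if (m < 2L) stop("need at least 2 patients")
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  p <- ncol(X)
  env <- new.env()
  env$u <- NULL
  negll <- function(par) {
    beta <- par[seq_len(p)]
    sigma2 <- exp(2 * par[p + 1L])
    if (any(!is.finite(beta)) || !is.finite(sigma2)) return(1e10)
    eta0 <- as.numeric(X %*% beta)
    res <- laplace_ll(eta0, y, pid, m, sigma2, u = env$u)
    env$u <- res$u
    if (!is.finite(res$ll)) return(1e10)
    -res$ll
  }
  if (is.null(start)) {
    b0 <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y,
                                      family = stats::binomial())$coefficients),
      error = function(e) rep(0, p))
    b0[!is.finite(b0)] <- 0
    start <- c(b0, log(0.5))
  }
  fit_once <- function(st) {
    env$u <- NULL
    stats::optim(st, negll, method = "BFGS",
                 control = list(maxit = max_iter, reltol = reltol))
  }
  opt <- fit_once(start)
  if (opt$convergence != 0) {
    for (s0 in c(0.1, 1)) {
      alt <- fit_once(c(start[seq_len(p)], log(s0)))
      if (alt$convergence == 0 && alt$value < opt$value) { opt <- alt; break }
      if (alt$value < opt$value) opt <- alt
    }
  }
  par <- opt$par
  beta <- par[seq_len(p)]
  sigma_u <- exp(par[p + 1L])
  separation <- any(abs(beta) > 10)
  H <- tryCatch(stats::optimHess(par, negll), error = function(e) NULL)
  se <- rep(NA_real_, p)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || any(diag(V)[seq_len(p)] <= 0)) {
      # sigma direction can be degenerate near the boundary; fall back to
      # the beta block at fixed sigma
      Vb <- tryCatch(solve(H[seq_len(p), seq_len(p), drop = FALSE]),
                     error = function(e) NULL)
      if (!is.null(Vb) && all(diag(Vb) > 0)) se <- sqrt(diag(Vb))
    } else {
      se <- sqrt(diag(V)[seq_len(p)])
    }
  }
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  terms <- colnames(X)
  if (is.null(terms)) terms <- paste0("b", seq_len(p))
  structure(list(
    coefficients = data.frame(term = terms, estimate = beta, se = se,
                              z = z, p = pval, stringsAsFactors = FALSE),
    sigma_u = sigma_u, loglik = -opt$value,
    converged = opt$convergence == 0 && !separation && all(is.finite(se)),
    separation = separation,
    n_obs = length(y), n_patients = m),
    class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("Logistic GLMM (Laplace), %d obs, %d patients, sigma_u = %.3f, loglik = %.2f%s\n",
              x$n_obs, x$n_patients, x$sigma_u, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

# modality -> confounder mapping: ambient temperature for the thermally
# sensitive channels, movement for heart rate, none for acceleration
confounder_for_modality <- function(modality) {
  switch(modality,
         eda = "ambient_mean", st = "ambient_mean",
         hr = "acc_sd", acc = NA_character_,
         NA_character_)
}

#' Fit one model per feature and outcome
#'
#' For every (signal, feature) x outcome combination in the analysis table,
#' fits a separate logistic GLMM with the standardized feature, the
#' categorical time block (reference block 1), and the modality-specific
#' confounder (ambient temperature for electrodermal and skin-temperature
#' features, acceleration-magnitude SD for heart-rate features, none for
#' acceleration features) as fixed effects, plus a patient random
#' intercept.  P-values are unadjusted (exploratory screen, no multiple
#' testing correction).
#'
#' @param rows analysis table from \code{\link{build_model_rows}}: one row
#'   per kept window x feature, with standardized values and outcomes.
#' @param outcomes outcome columns to model.
#' @return data.frame, one row per fitted model, sorted by (modality,
#'   signal, feature, outcome): feature-coefficient estimate, SE, Wald z
#'   and p, random-intercept SD, convergence flags, sizes.
#' @export
run_feature_screen <- function(rows,
                               outcomes = c("agitated", "motor_agitated",
                                            "verbal_agitated")) {
  combos <- unique(rows[c("modality", "signal", "feature")])
  combos <- combos[order(combos$modality, combos$signal, combos$feature), ]
  res <- list(); k <- 0L
  for (i in seq_len(nrow(combos))) {
    md <- combos$modality[i]; sg <- combos$signal[i]; ft <- combos$feature[i]
    sub <- rows[rows$modality == md & rows$signal == sg & rows$feature == ft, ]
    conf <- confounder_for_modality(md)
    for (oc in outcomes) {
      k <- k + 1L
      sub_oc <- sub[!is.na(sub$z) & !is.na(sub[[oc]]), ]
      if (!is.na(conf)) sub_oc <- sub_oc[!is.na(sub_oc[[paste0("z_", conf)]]), ]
      row <- data.frame(modality = md, signal = sg, feature = ft,
                        outcome = oc, estimate = NA_real_, se = NA_real_,
                        z = NA_real_, p = NA_real_, sigma_u = NA_real_,
                        converged = FALSE, separation = NA,
                        n_obs = nrow(sub_oc),
                        n_patients = length(unique(sub_oc$patient_id)),
                        stringsAsFactors = FALSE)
      fit <- if (nrow(sub_oc) == 0L) NULL else tryCatch({
        yv <- sub_oc[[oc]]
        tg <- factor(sub_oc$time_group, levels = 1:4)
        tg <- droplevels(tg)
        Xl <- list(`(Intercept)` = rep(1, nrow(sub_oc)), feature = sub_oc$z)
        if (nlevels(tg) > 1L) {
          mm <- stats::model.matrix(~ tg)[, -1, drop = FALSE]
          colnames(mm) <- paste0("time_group", levels(tg)[-1])
          for (cn in colnames(mm)) Xl[[cn]] <- mm[, cn]
        }
        if (!is.na(conf)) Xl[[conf]] <- sub_oc[[paste0("z_", conf)]]
        X <- do.call(cbind, Xl)
        colnames(X) <- names(Xl)
        fit_glmm(yv, X, sub_oc$patient_id)
      }, error = function(e) NULL)
      if (!is.null(fit)) {
        fr <- fit$coefficients[fit$coefficients$term == "feature", ]
        row$estimate <- fr$estimate; row$se <- fr$se
        row$z <- fr$z; row$p <- fr$p
        row$sigma_u <- fit$sigma_u
        row$converged <- fit$converged
        row$separation <- fit$separation
      }
      res[[k]] <- row
    }
  }
  out <- do.call(rbind, res)
  out[order(out$modality, out$signal, out$feature, out$outcome), ]
}
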