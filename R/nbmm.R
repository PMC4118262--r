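#' Negative-binomial log probability mass (NB2, gamma form)
#'
#' Log mass of the NB2 distribution with mean `mu` and size `k`
#' (variance `mu + mu^2/k`; `k -> Inf` recovers the Poisson). Written in the
#' gamma form and stabilised with `log1p` so it is usable at very large `k`.
#'
#' @param y nonnegative integer count(s).
#' @param mu positive mean(s).
#' @param k positive size (dispersion) parameter.
#' @return Log probability mass, vectorised over the longest argument.
#' @export
nb_log_pmf <- function(y, mu, k) {
  if (any(mu <= 0)) stop("nb_log_pmf: mu must be positive", call. = FALSE)
  if (any(k <= 0)) stop("nb_log_pmf: k must be positive", call. = FALSE)
  if (any(y < 0 | y != round(y))) {
    stop("nb_log_pmf: y must be a nonnegative integer", call. = FALSE)
  }
  # lgamma(y+k) - lgamma(k) - lgamma(y+1) + k*log(k/(k+mu)) + y*log(mu/(k+mu))
  ylog <- ifelse(y == 0, 0, y * (log(mu) - log(k + mu)))
  lgamma(y + k) - lgamma(k) - lgamma(y + 1) - k * log1p(mu / k) + ylog
}

# Gauss-Hermite nodes/weights (physicists' convention,
# integral e^{-z^2} f(z) dz ~= sum w_q f(z_q)). Q = 1 is the Laplace
# approximation (single node at the conditional mode).
gauss_hermite <- function(Q) {
  stopifnot(Q >= 1)
  if (Q == 1) return(list(x = 0, w = sqrt(pi)))
  gh <- pracma::gaussHermite(Q)
  list(x = gh$x, w = gh$w)
}

# Per-facility conditional mode of the random intercept and the (positive)
# curvature of -log integrand there, found by damped Newton. All quantities
# vectorised across facilities via rowsum on unit-level vectors.
find_modes <- function(y, eta, f, gi, k, sigma, b_start = NULL) {
  b <- b_start %||% numeric(nlevels(f))
  for (iter in 1:100) {
    mu <- exp(eta + b[gi])
    g1 <- rowsum_by(y - (y + k) * mu / (k + mu), f) - b / sigma^2
    h <- rowsum_by((y + k) * k * mu / (k + mu)^2, f) + 1 / sigma^2
    step <- g1 / h
    step <- pmin(pmax(step, -2), 2)
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- exp(eta + b[gi])
  list(b = b, h = rowsum_by((y + k) * k * mu / (k + mu)^2, f) + 1 / sigma^2)
}

# Marginal log-likelihood core shared by the exported wrapper and the
# optimiser (which warm-starts the mode search from the previous call).
# All Q quadrature nodes are evaluated in one n x Q matrix pass.
nbmm_loglik_core <- function(y, eta, f, gi, k, sigma_b, Q, b_start = NULL) {
  if (sigma_b < 1e-12) {
    return(list(ll = sum(nb_log_pmf(y, exp(eta), k)), b = NULL))
  }
  modes <- find_modes(y, eta, f, gi, k, sigma_b, b_start = b_start)
  tau <- 1 / sqrt(modes$h)
  gh <- gauss_hermite(Q)
  B <- modes$b + sqrt(2) * tau %o% gh$x            # G x Q node locations
  MU <- exp(eta + B[gi, , drop = FALSE])
  t1 <- log(MU) - log(k + MU)
  if (any(y == 0)) t1[y == 0, ] <- 0
  lp <- -k * log1p(MU / k) + y * t1                # unit x node log-mass
  lpsum <- rowsum(lp, f)
  lpsum <- lpsum[match(levels(f), rownames(lpsum)), , drop = FALSE]
  lpsum[is.na(lpsum)] <- 0                          # facility with no units
  lpsum <- lpsum + rowsum_by(lgamma(y + k) - lgamma(k) - lgamma(y + 1), f)
  lse <- sweep(lpsum + stats::dnorm(B, 0, sigma_b, log = TRUE), 2,
               log(gh$w) + gh$x^2, "+")
  m <- apply(lse, 1, max)
  list(ll = sum(log(sqrt(2) * tau) + m + log(rowSums(exp(lse - m)))),
       b = modes$b)
}

#' Marginal log-likelihood of the facility random-intercept NB model
#'
#' For each facility the resident-level NB2 likelihood is integrated over a
#' Gaussian random intercept `b ~ N(0, sigma_b^2)` by adaptive Gauss-Hermite
#' quadrature: nodes are centred at the facility's conditional mode and
#' scaled by the curvature there. With `sigma_b = 0` the integral collapses
#' to the independent NB log-likelihood at `b = 0`.
#'
#' @param y nonnegative integer response counts (one per unit).
#' @param X model matrix (units x coefficients, intercept included).
#' @param group factor or vector assigning each unit to a facility.
#' @param beta coefficient vector (length `ncol(X)`).
#' @param sigma_b random-intercept standard deviation (>= 0).
#' @param k NB2 size parameter (> 0).
#' @param offset optional per-unit offset on the log scale (e.g. log
#'   person-time); defaults to 0.
#' @param quadrature_points number of Gauss-Hermite nodes (default 15;
#'   1 = Laplace approximation).
#' @return The marginal log-likelihood (scalar).
#' @export
nbmm_loglik <- function(y, X, group, beta, sigma_b, k, offset = NULL,
                        quadrature_points = 15) {
  X <- as.matrix(X)
  stopifnot(length(beta) == ncol(X), sigma_b >= 0, k > 0)
  f <- as.factor(group)
  gi <- as.integer(f)
  G <- nlevels(f)
  offset <- offset %||% numeric(length(y))
  eta <- drop(X %*% beta) + offset
  if (any(!is.finite(eta))) {
    bad <- which(!is.finite(eta))[1]
    stop(sprintf("non-finite linear predictor at unit %d (facility %s)",
                 bad, levels(f)[gi[bad]]), call. = FALSE)
  }
  nbmm_loglik_core(y, eta, f, gi, k, sigma_b, quadrature_points)$ll
}

#' Control parameters for [nbmm_fit()]
#'
#' @param iter_max maximum optimiser iterations.
#' @param rel_tol relative convergence tolerance passed to [stats::nlminb()].
#' @param grad_tol infinity-norm tolerance on the (numerical) gradient per
#'   unit of log-likelihood magnitude used for the convergence flag.
#' @param sigma_lower lower bound for `sigma_b` during optimisation (the
#'   boundary stands in for a zero random effect).
#' @return A list of class `nbmm_control`.
#' @export
nbmm_control <- function(iter_max = 500, rel_tol = 1e-10, grad_tol = 1e-6,
                         sigma_lower = 1e-6) {
  structure(list(iter_max = iter_max, rel_tol = rel_tol, grad_tol = grad_tol,
                 sigma_lower = sigma_lower), class = "nbmm_control")
}

# Build (y, X, gi, offset) from a unit-level data frame.
prepare_nbmm_data <- function(data, covariates, response, group,
                              offset_mode, exposure) {
  miss <- setdiff(c(response, group, covariates,
                    if (offset_mode == "log_person_time") exposure), names(data))
  if (length(miss)) {
    stop("model data missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  y <- data[[response]]
  if (any(is.na(y) | y < 0 | y != round(y))) {
    stop("response must be nonnegative integer counts", call. = FALSE)
  }
  if (offset_mode == "log_person_time") {
    expo <- data[[exposure]]
    drop_units <- !is.finite(expo) | expo <= 0
    if (any(drop_units)) {
      warning(sprintf("dropping %d unit(s) with zero or missing exposure",
                      sum(drop_units)), call. = FALSE)
      data <- data[!drop_units, , drop = FALSE]
      y <- y[!drop_units]
      expo <- expo[!drop_units]
    }
    offset <- log(expo)
  } else {
    offset <- numeric(length(y))
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(data[covariates],
                                     check.names = FALSE)))
  storage.mode(X) <- "double"
  f <- factor(data[[group]])
  list(y = as.integer(round(y)), X = X, group = f, offset = offset)
}

#' Fit the negative-binomial facility random-intercept model
#'
#' Maximises the adaptive Gauss-Hermite marginal likelihood of an NB2 count
#' model with fixed covariate effects and a Gaussian facility random
#' intercept, by quasi-Newton iteration over `(beta, log sigma_b, log k)`.
#' Standard errors come from the inverse observed information (numerical
#' Hessian at the optimum); Wald p-values are two-sided normal.
#'
#' The model for unit \eqn{j} in facility \eqn{i} is
#' \deqn{y_{ij} ~ NB2(mu_{ij}, k), \quad
#'       \log mu_{ij} = x_{ij}'\beta + \log t_{ij} + b_i, \quad
#'       b_i ~ N(0, \sigma_b^2),}
#' with \eqn{t_{ij}} the person-time offset (omitted when
#' `offset_mode = "none"`). Units can be residents (the default reproduction
#' path: per-resident fit, facility-level prediction) or facilities, in which
#' case each "facility" group has a single unit and the random intercept
#' captures extra-NB overdispersion.
#'
#' @param data unit-level data frame.
#' @param covariates character vector of covariate column names (may be
#'   empty for an intercept-only model).
#' @param response name of the count response column.
#' @param group name of the facility identifier column.
#' @param offset_mode `"log_person_time"` (default; units with zero exposure
#'   are dropped with a warning) or `"none"`.
#' @param exposure name of the person-time column used when
#'   `offset_mode = "log_person_time"`.
#' @param quadrature_points Gauss-Hermite nodes (default 15; 1 = Laplace).
#' @param fix_sigma_b,fix_k optionally fix the random-intercept SD and/or the
#'   NB size parameter instead of estimating them (`fix_sigma_b = 0` gives an
#'   independent NB regression; `fix_k = 1e8` is numerically Poisson).
#' @param init optional list with starting values `beta`, `sigma_b`, `k`.
#' @param control an [nbmm_control()].
#' @return An object of class `nbmm`: coefficients (`beta`), `se`,
#'   `p_values`, `sigma_b`, `k`, `log_likelihood`, `vcov`, `converged`,
#'   `n_facilities`, `n_units`, plus the fitting metadata needed by
#'   [predict_facility_counts()].
#' @seealso [backward_eliminate()], [nbmm_loglik()]
#' @export
nbmm_fit <- function(data, covariates = character(),
                     response = "pah_count", group = "facility_id",
                     offset_mode = c("log_person_time", "none"),
                     exposure = "person_time",
                     quadrature_points = 15,
                     fix_sigma_b = NULL, fix_k = NULL,
                     init = NULL, control = nbmm_control()) {
  offset_mode <- match.arg(offset_mode)
  md <- prepare_nbmm_data(data, covariates, response, group,
                          offset_mode, exposure)
  y <- md$y; X <- md$X; f <- md$group; offset <- md$offset
  G <- nlevels(f)
  if (G < 2) stop("at least two facilities are required", call. = FALSE)
  p <- ncol(X)

  # starting values: Poisson GLM for beta, moment estimate for k
  beta0 <- init$beta %||% tryCatch(
    stats::glm.fit(X, y, offset = offset,
                   family = stats::poisson())$coefficients,
    error = function(e) c(log(max(mean(y), 0.01)) - mean(offset), rep(0, p - 1)))
  beta0[!is.finite(beta0)] <- 0
  mu0 <- exp(drop(X %*% beta0) + offset)
  k0 <- init$k %||% {
    excess <- sum((y - mu0)^2 - mu0)
    if (excess > 0) max(sum(mu0^2) / excess, 0.1) else 10
  }
  sigma0 <- init$sigma_b %||% 0.3

  est_sigma <- is.null(fix_sigma_b)
  est_k <- is.null(fix_k)
  par0 <- c(beta0,
            if (est_sigma) log(max(sigma0, control$sigma_lower)),
            if (est_k) log(k0))
  unpack <- function(par) {
    i <- p
    sigma_b <- if (est_sigma) exp(par[(i <- i + 1)]) else fix_sigma_b
    k <- if (est_k) exp(par[i + 1]) else fix_k
    list(beta = par[1:p], sigma_b = sigma_b, k = k)
  }
  gi <- as.integer(f)
  b_cache <- NULL
  nll <- function(par) {
    th <- unpack(par)
    eta <- drop(X %*% th$beta) + offset
    if (any(!is.finite(eta))) return(1e10)
    res <- tryCatch(
      nbmm_loglik_core(y, eta, f, gi, th$k, th$sigma_b, quadrature_points,
                       b_start = b_cache),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$ll)) return(1e10)
    b_cache <<- res$b
    -res$ll
  }
  lower <- c(rep(-Inf, p),
             if (est_sigma) log(control$sigma_lower),
             if (est_k) log(1e-4))
  upper <- c(rep(Inf, p),
             if (est_sigma) log(50),
             if (est_k) log(1e10))
  opt <- stats::nlminb(par0, nll, lower = lower, upper = upper,
                       control = list(iter.max = control$iter_max,
                                      eval.max = 4 * control$iter_max,
                                      rel.tol = control$rel_tol))
  th <- unpack(opt$par)
  ll_hat <- -opt$objective
  converged <- opt$convergence == 0
  if (!converged) {
    warning("nbmm_fit did not converge: ", opt$message, call. = FALSE)
  }

  H <- tryCatch(stats::optimHess(opt$par, nll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc)[1:p] <= 0)) {
    warning("observed information is singular; standard errors unavailable",
            call. = FALSE)
    se <- rep(NA_real_, p)
    vc <- NULL
  } else {
    se <- sqrt(diag(vc)[1:p])
  }
  z <- th$beta / se
  pvals <- 2 * stats::pnorm(-abs(z))
  names(th$beta) <- names(se) <- names(pvals) <- colnames(X)

  structure(list(beta = th$beta, se = se, p_values = pvals,
                 sigma_b = th$sigma_b, k = th$k,
                 log_likelihood = ll_hat, converged = converged,
                 vcov = vc,
                 n_facilities = G, n_units = length(y),
                 covariates = covariates, offset_mode = offset_mode,
                 exposure = exposure, response = response, group = group,
                 quadrature_points = quadrature_points,
                 fixed = list(sigma_b = fix_sigma_b, k = fix_k),
                 optim = list(iterations = opt$iterations,
                              message = opt$message)),
            class = "nbmm")
}

#' @export
print.nbmm <- function(x, ...) {
  cat("Negative-binomial facility random-intercept model\n")
  cat(sprintf("  units: %d in %d facilities; offset: %s; quadrature: %d nodes\n",
              x$n_units, x$n_facilities, x$offset_mode, x$quadrature_points))
  cat(sprintf("  log-likelihood: %.3f  (converged: %s)\n",
              x$log_likelihood, x$converged))
  cat(sprintf("  sigma_b: %.4f%s   k: %.4f%s\n",
              x$sigma_b, if (!is.null(x$fixed$sigma_b)) " (fixed)" else "",
              x$k, if (!is.null(x$fixed$k)) " (fixed)" else ""))
  tab <- data.frame(estimate = x$beta, se = x$se,
                    z = x$beta / x$se, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.nbmm <- function(object, ...) object$beta

#' @export
logLik.nbmm <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$beta) + is.null(object$fixed$sigma_b) +
              is.null(object$fixed$k),
            class = "logLik")
}

#' @export
vcov.nbmm <- function(object, ...) object$vcov

#' Backward elimination of model covariates
#'
#' Starting from the full candidate list, repeatedly refits the model after
#' removing the covariate with the largest Wald p-value (ties broken by the
#' smaller absolute standardised effect — the effect "closer to zero") until
#' every retained covariate has `p <= alpha`. The intercept is never removed.
#'
#' @inheritParams nbmm_fit
#' @param alpha retention threshold (default 0.05).
#' @param ... further arguments passed to [nbmm_fit()].
#' @return A list with `model` (the final [nbmm] fit), `trace` (data frame of
#'   removals: `step`, `removed`, `p_value`, `estimate`) and `retained`.
#'   If every candidate is eliminated the intercept-only model is returned
#'   with a note.
#' @export
backward_eliminate <- function(data, covariates, alpha = 0.05, ...) {
  stopifnot(length(covariates) >= 1, alpha > 0, alpha <= 1)
  # canonical order makes the retained set invariant to input listing order
  current <- sort(covariates)
  trace <- data.frame(step = integer(), removed = character(),
                      p_value = numeric(), estimate = numeric(),
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- nbmm_fit(data, covariates = current, ...)
    if (!length(current)) break
    pv <- fit$p_values[current]
    if (all(is.na(pv))) {
      warning("all candidate p-values unavailable; stopping elimination",
              call. = FALSE)
      break
    }
    if (max(pv, na.rm = TRUE) <= alpha) break
    zabs <- abs(fit$beta[current] / fit$se[current])
    worst <- current[order(-pv, zabs)][1]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = worst,
                                     p_value = unname(pv[worst]),
                                     estimate = unname(fit$beta[worst]),
                                     stringsAsFactors = FALSE))
    pah_log("backward_eliminate", step = step, removed = worst,
            p = signif(unname(pv[worst]), 3))
    current <- setdiff(current, worst)
  }
  note <- if (!length(current)) "all candidates eliminated; intercept-only model" else NULL
  if (!is.null(note)) pah_log("backward_eliminate", note = note)
  list(model = fit, trace = trace, retained = current, note = note)
}

#' Predict expected facility PAH counts
#'
#' Population-level prediction at random effect `b = 0`: expected count
#' `= exposure x exp(x'beta)`, with exposure the facility person-years when
#' the model used a log person-time offset and 1 otherwise. Resident-level
#' coefficients are applied to facility-level covariate proportions, turning
#' the fit into a per-facility predictive risk score.
#'
#' @param model an [nbmm] fit.
#' @param aggregates a [facility_aggregates][aggregate_facilities] table
#'   carrying every model covariate as a column.
#' @return Named numeric vector of expected counts, one per facility row.
#' @export
predict_facility_counts <- function(model, aggregates) {
  stopifnot(inherits(model, "nbmm"))
  miss <- setdiff(model$covariates, names(aggregates))
  if (length(miss)) {
    stop("aggregates missing model covariate(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  X <- cbind(1, as.matrix(as.data.frame(aggregates[model$covariates],
                                        check.names = FALSE)))
  expo <- if (model$offset_mode == "log_person_time") {
    aggregates$person_years
  } else {
    rep(1, nrow(aggregates))
  }
  pred <- expo * exp(drop(X %*% model$beta))
  names(pred) <- aggregates$facility_id
  pred
}

#' Serialise a fitted model to JSON
#'
#' @param model an [nbmm] fit.
#' @param path output file.
#' @param trace optional elimination trace from [backward_eliminate()].
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, trace = NULL) {
  out <- list(coefficients = as.list(model$beta),
              se = as.list(model$se),
              p_values = as.list(model$p_values),
              sigma_b = model$sigma_b, k = model$k,
              log_likelihood = model$log_likelihood,
              converged = model$converged,
              n_facilities = model$n_facilities, n_units = model$n_units,
              offset_mode = model$offset_mode,
              quadrature_points = model$quadrature_points)
  if (!is.null(trace)) out$elimination_trace <- trace
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
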