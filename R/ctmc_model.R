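# Likelihood and maximum-likelihood inference for the four-state
# continuous-time Markov chain with log-linear covariate effects on the
# transition intensities:
#
#   q_ij(z) = q0_ij * exp( sum_c beta_{c,ij} z_c )
#
# on the 8 permitted edges.  For fully observed trajectories the
# log-likelihood is
#
#   sum over sojourns [ -Lambda_i(z) * t + log q_ij(z) ]  - Lambda_i(z) * t_last
#
# (the final sojourn is right-censored), which in sufficient-statistic form
# is  sum_edges [ N_ij eta_ij - T_i exp(eta_ij) ]  with
# eta_ij = log q0_ij + sum_c beta_{c,ij} z_c.  Each edge's parameters enter
# only its own terms, so the likelihood is concave and block-diagonal by
# edge — a Poisson-regression structure that Newton-Raphson with analytic
# gradient and Hessian solves to gradient-norm 1e-8 in a handful of steps.

Q_FLOOR <- 1e-8  # intensity assigned to edges with no events anywhere

#' Construct an intensity model
#'
#' @param baseline Named numeric vector of baseline intensities
#'   `q0_ij` (per second, > 0) over (a subset of) the permitted [EDGES];
#'   unnamed edges default to [Q_FLOOR].
#' @param effects Named list mapping covariate names (e.g. `"satiated"`)
#'   to named numeric vectors of per-edge log-linear coefficients; edges
#'   absent from a coefficient vector get coefficient 0.
#' @return An object of class `intensity_model`.
#' @export
intensity_model <- function(baseline, effects = list()) {
  q0 <- stats::setNames(rep(Q_FLOOR, length(EDGES)), EDGES)
  if (length(baseline)) {
    bad <- setdiff(names(baseline), EDGES)
    if (length(bad)) stop(sprintf("not a permitted edge: %s",
                                  paste(bad, collapse = ", ")), call. = FALSE)
    if (any(baseline <= 0)) stop("baseline intensities must be > 0", call. = FALSE)
    q0[names(baseline)] <- baseline
  }
  effects <- lapply(effects, function(b) {
    bad <- setdiff(names(b), EDGES)
    if (length(bad)) stop(sprintf("not a permitted edge: %s",
                                  paste(bad, collapse = ", ")), call. = FALSE)
    full <- stats::setNames(rep(0, length(EDGES)), EDGES)
    full[names(b)] <- b
    full
  })
  structure(list(baseline = q0, effects = effects), class = "intensity_model")
}

#' Evaluate edge intensities at given covariate values
#'
#' @param model An [intensity_model()].
#' @param covariates Named numeric vector/list of covariate values; every
#'   covariate the model references must be supplied.
#' @return Named numeric vector of intensities over [EDGES].
#' @export
edge_intensities <- function(model, covariates = NULL) {
  eta <- log(model$baseline)
  for (cv in names(model$effects)) {
    z <- covariates[[cv]]
    if (is.null(z) || !is.finite(z)) {
      stop(sprintf("covariate '%s' missing or non-finite", cv), call. = FALSE)
    }
    eta <- eta + model$effects[[cv]] * z
  }
  q <- exp(eta)
  if (any(!is.finite(q))) stop("non-finite intensity", call. = FALSE)
  q
}

#' Log-likelihood of a trajectory under an intensity model
#'
#' @param model An [intensity_model()].
#' @param trajectory A [pair_trajectory()].
#' @param covariates Named covariate values for this trajectory (constant
#'   within a session).
#' @return The log-likelihood (finite for positive intensities).
#' @export
log_likelihood <- function(model, trajectory, covariates = NULL) {
  q <- edge_intensities(model, covariates)
  ss <- sufficient_statistics(trajectory)
  lam <- stats::setNames(numeric(4), as.character(STATES))
  for (e in EDGES) lam[as.character(edge_from(e))] <-
    lam[as.character(edge_from(e))] + q[e]
  sum(ss$counts * log(q)) - sum(ss$sojourn * lam)
}

#' Closed-form intensity estimates from sufficient statistics
#'
#' Without covariates the MLE is the crude rate `N_ij / T_i`.  States never
#' visited (`T_i = 0`) yield `NA` estimates, flagged in the `"undefined"`
#' attribute.
#'
#' @param stats A `sufficient_stats` object (see [sufficient_statistics()]),
#'   or a list with `counts` and `sojourn` in the same layout (e.g. pooled
#'   over trajectories).
#' @return Named numeric vector of estimates over [EDGES].
#' @export
closed_form_intensities <- function(stats) {
  out <- stats::setNames(numeric(length(EDGES)), EDGES)
  undef <- character(0)
  for (e in EDGES) {
    Ti <- stats$sojourn[as.character(edge_from(e))]
    N <- stats$counts[e]
    if (Ti > 0) {
      out[e] <- N / Ti
    } else if (N > 0) {
      stop(sprintf("inconsistent stats: N_%s > 0 with T_%d = 0", e, edge_from(e)),
           call. = FALSE)
    } else {
      out[e] <- NA_real_
      undef <- c(undef, e)
    }
  }
  attr(out, "undefined") <- undef
  out
}

pool_stats <- function(stats_list) {
  counts <- Reduce(`+`, lapply(stats_list, `[[`, "counts"))
  sojourn <- Reduce(`+`, lapply(stats_list, `[[`, "sojourn"))
  structure(list(counts = counts, sojourn = sojourn), class = "sufficient_stats")
}

# Newton-Raphson with analytic gradient/Hessian and step halving for one
# edge's concave Poisson-form log-likelihood  sum[N eta - T exp(eta)],
# eta = X theta.  Returns the working-scale estimate, covariance (inverse
# observed information), iteration count, convergence flag, and whether the
# information matrix was computationally singular.
newton_edge <- function(X, Ne, Te, max_iter = 100L, grad_tol = 1e-8) {
  p <- ncol(X)
  total_N <- sum(Ne)
  theta <- c(log(max(total_N / sum(Te), 1e-6)), rep(0, p - 1L))
  ll_fun <- function(th) {
    eta <- drop(X %*% th)
    sum(Ne * eta - Te * exp(eta))
  }
  iter <- 0L
  singular <- FALSE
  repeat {
    eta <- drop(X %*% theta)
    mu <- Te * exp(eta)
    g <- drop(crossprod(X, Ne - mu))
    if (max(abs(g)) <= grad_tol || iter >= max_iter) break
    H <- crossprod(X, X * mu)
    step <- tryCatch(solve(H, g), error = function(err) NULL)
    if (is.null(step) || any(!is.finite(step))) { singular <- TRUE; break }
    ll0 <- ll_fun(theta)
    s <- 1
    repeat {
      cand <- theta + s * step
      if (ll_fun(cand) >= ll0 - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    theta <- cand
    iter <- iter + 1L
  }
  eta <- drop(X %*% theta)
  mu <- Te * exp(eta)
  g <- drop(crossprod(X, Ne - mu))
  info <- crossprod(X, X * mu)
  V <- tryCatch(solve(info), error = function(err) NULL)
  if (is.null(V) || any(!is.finite(V)) ||
      kappa(info, exact = FALSE) > 1e12) {
    singular <- TRUE
    V <- matrix(NA_real_, p, p)
  }
  list(theta = theta, vcov = V, iter = iter,
       converged = max(abs(g)) <= grad_tol, singular = singular)
}

#' Maximum-likelihood fit of the covariate CTMC
#'
#' Maximizes the pooled fully observed log-likelihood over working-scale
#' parameters (`log q0_ij` plus one coefficient per covariate-edge in the
#' design) by per-edge Newton-Raphson with analytic gradient and Hessian
#' (the likelihood is concave and separates by edge).  Standard errors come
#' from the inverse observed information; 95% intervals are Wald intervals
#' on the working scale, exponentiated for baselines.
#'
#' Identifiability: an edge with no events anywhere has its baseline fixed
#' at the floor `1e-8`/s and is excluded from the information matrix.  A
#' binary covariate's coefficient on an edge is identifiable only if the
#' edge is observed at two distinct covariate values; a continuous
#' covariate's only if the covariate varies across trajectories.
#' Unidentifiable parameters are flagged, not silently dropped.
#'
#' @param trajectories List of [pair_trajectory()] objects.
#' @param covariates Data frame with one row per trajectory (same order)
#'   giving covariate values, or `NULL` for a covariate-free fit.
#' @param design Named list mapping covariate names to the character vector
#'   of edges they act on (default: every covariate on all 8 edges).
#' @param center Character vector of covariate names to centre at their
#'   sample mean before fitting (keeps baselines interpretable); centres
#'   are stored in the result.
#' @param max_iter,grad_tol Newton iteration cap and convergence threshold
#'   on the gradient max-norm.
#' @return An object of class `ctmc_fit`: list with `params` (data frame:
#'   `parameter`, `covariate`, `edge`, `estimate` working scale, `se`,
#'   `ci_lo`/`ci_hi` natural scale, `identifiable`), `vcov` (working
#'   scale), `log_lik`, `converged`, `n_iter`, `centers`, `n_trajectories`.
#' @export
fit_mle <- function(trajectories, covariates = NULL, design = NULL,
                    center = names(covariates), max_iter = 100L,
                    grad_tol = 1e-8) {
  n <- length(trajectories)
  stopifnot(n >= 1L)
  stats_list <- lapply(trajectories, sufficient_statistics)
  N <- do.call(rbind, lapply(stats_list, `[[`, "counts"))   # n x 8
  Tw <- do.call(rbind, lapply(stats_list, `[[`, "sojourn")) # n x 4
  covs <- character(0)
  Z <- NULL
  if (!is.null(covariates) && length(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    covs <- names(covariates)
    Z <- as.matrix(covariates)
    centers <- stats::setNames(numeric(length(covs)), covs)
    for (cv in intersect(center, covs)) {
      centers[cv] <- mean(Z[, cv])
      Z[, cv] <- Z[, cv] - centers[cv]
    }
  } else {
    centers <- stats::setNames(numeric(0), character(0))
  }
  if (is.null(design)) {
    design <- stats::setNames(lapply(covs, function(cv) EDGES), covs)
  } else {
    stopifnot(all(names(design) %in% covs))
    for (cv in names(design)) {
      bad <- setdiff(design[[cv]], EDGES)
      if (length(bad)) stop(sprintf("design references forbidden edge %s",
                                    paste(bad, collapse = ",")), call. = FALSE)
    }
  }

  params <- list()
  vcov_blocks <- list()
  log_lik <- 0
  converged <- TRUE
  n_iter_total <- 0L

  for (e in EDGES) {
    i <- as.character(edge_from(e))
    Ne <- N[, e]
    Te <- Tw[, i]
    cvs <- covs[vapply(covs, function(cv) e %in% design[[cv]], logical(1))]
    # identifiability screening
    total_N <- sum(Ne)
    if (total_N == 0L) {
      params[[e]] <- data.frame(
        parameter = "logq0", covariate = NA_character_, edge = e,
        estimate = log(Q_FLOOR), se = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_, identifiable = FALSE)
      if (length(cvs)) {
        params[[e]] <- rbind(params[[e]], data.frame(
          parameter = "coef", covariate = cvs, edge = e,
          estimate = 0, se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          identifiable = FALSE))
      }
      log_lik <- log_lik - sum(Te) * Q_FLOOR
      next
    }
    id_cv <- logical(length(cvs))
    names(id_cv) <- cvs
    for (cv in cvs) {
      z <- Z[, cv]
      vals <- unique(z)
      if (length(vals) < 2L) {
        id_cv[cv] <- FALSE
      } else if (length(vals) == 2L) {
        # binary-like: need events at both levels
        id_cv[cv] <- all(tapply(Ne, z, sum) > 0)
      } else {
        id_cv[cv] <- stats::sd(z[Te > 0]) > 0
      }
    }
    use_cv <- cvs[id_cv]
    # fit, dropping trailing covariate columns if the information matrix is
    # computationally singular (practically unidentifiable on these data)
    repeat {
      X <- cbind(`(logq0)` = rep(1, n))
      if (length(use_cv)) X <- cbind(X, Z[, use_cv, drop = FALSE])
      p <- ncol(X)
      res <- newton_edge(X, Ne, Te, max_iter = max_iter, grad_tol = grad_tol)
      if (!res$singular || length(use_cv) == 0L) break
      id_cv[use_cv[length(use_cv)]] <- FALSE
      use_cv <- use_cv[-length(use_cv)]
    }
    theta <- res$theta
    edge_conv <- res$converged
    converged <- converged && edge_conv
    n_iter_total <- n_iter_total + res$iter
    V <- res$vcov
    se <- sqrt(pmax(diag(V), 0))
    lo <- theta - 1.96 * se
    hi <- theta + 1.96 * se
    rows <- data.frame(
      parameter = c("logq0", rep("coef", p - 1L)),
      covariate = c(NA_character_, use_cv),
      edge = e,
      estimate = theta, se = se,
      ci_lo = c(exp(lo[1]), if (p > 1L) lo[-1]),
      ci_hi = c(exp(hi[1]), if (p > 1L) hi[-1]),
      identifiable = TRUE)
    drop_cv <- cvs[!id_cv]
    if (length(drop_cv)) {
      rows <- rbind(rows, data.frame(
        parameter = "coef", covariate = drop_cv, edge = e,
        estimate = NA_real_, se = NA_real_, ci_lo = NA_real_,
        ci_hi = NA_real_, identifiable = FALSE))
    }
    params[[e]] <- rows
    rownames(V) <- colnames(V) <- paste0(e, ":", c("logq0", use_cv))
    vcov_blocks[[e]] <- V
    eta_e <- drop(X %*% theta)
    log_lik <- log_lik + sum(Ne * eta_e - Te * exp(eta_e))
  }

  params <- do.call(rbind, params)
  rownames(params) <- NULL
  # assemble block-diagonal working-scale covariance
  all_names <- unlist(lapply(vcov_blocks, colnames))
  V <- matrix(0, length(all_names), length(all_names),
              dimnames = list(all_names, all_names))
  for (b in vcov_blocks) V[colnames(b), colnames(b)] <- b
  structure(
    list(params = params, vcov = V, log_lik = log_lik,
         converged = converged, n_iter = n_iter_total,
         centers = centers, design = design, n_trajectories = n),
    class = "ctmc_fit")
}

#' @export
print.ctmc_fit <- function(x, ...) {
  cat(sprintf("<ctmc_fit: %d trajectories, logLik %.2f, %s in %d Newton steps>\n",
              x$n_trajectories, x$log_lik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(utils::head(x$params, 16L))
  invisible(x)
}

#' @export
logLik.ctmc_fit <- function(object, ...) {
  structure(object$log_lik, df = sum(object$params$identifiable),
            class = "logLik")
}

#' Extract fitted baseline intensities on the natural scale
#'
#' @param fit A `ctmc_fit`.
#' @return Named numeric vector of `q0_ij` estimates over [EDGES].
#' @export
fitted_intensities <- function(fit) {
  p <- fit$params[fit$params$parameter == "logq0", ]
  stats::setNames(exp(p$estimate), p$edge)
}

#' Extract a fitted covariate coefficient
#'
#' @param fit A `ctmc_fit`.
#' @param covariate Covariate name.
#' @param edge Edge key such as `"12"`.
#' @return One-row data frame (estimate, se, ci, identifiability flag).
#' @export
fitted_coefficient <- function(fit, covariate, edge) {
  p <- fit$params
  row <- p[p$parameter == "coef" & !is.na(p$covariate) &
             p$covariate == covariate & p$edge == edge, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop(sprintf("no coefficient for covariate '%s' on edge %s", covariate,
                 edge), call. = FALSE)
  }
  row
}

#' Wald test of a covariate coefficient
#'
#' Two-sided z-test of `beta_{c,ij} = null_value` on the working scale.
#'
#' @param fit A `ctmc_fit`.
#' @param covariate Covariate name (e.g. `"satiated"`).
#' @param edge Edge key such as `"12"`.
#' @param null_value Null value (default 0).
#' @return List with `estimate`, `se`, `z`, `p`, `significant` (at 0.05).
#' @export
wald_test_coefficient <- function(fit, covariate, edge, null_value = 0) {
  row <- fitted_coefficient(fit, covariate, edge)
  if (!row$identifiable) {
    stop(sprintf("coefficient for '%s' on edge %s is not identifiable",
                 covariate, edge), call. = FALSE)
  }
  z <- (row$estimate - null_value) / row$se
  p <- 2 * stats::pnorm(-abs(z))
  list(estimate = row$estimate, se = row$se, z = z, p = p,
       significant = p < 0.05)
}

#' Wald test contrasting two baseline intensities
#'
#' Tests `log q0_a = log q0_b` by the delta method on the working scale
#' (the two log-baselines are asymptotically independent across edges, and
#' the stored covariance is used regardless).  The sign of the difference
#' is reported so directional claims (e.g. the bolder fish leaves cover at
#' a higher rate) can be read off.
#'
#' @param fit A `ctmc_fit`.
#' @param edge_a,edge_b Edge keys to contrast.
#' @return List with `log_diff` (`log q0_a - log q0_b`), `se`, `z`, `p`,
#'   `direction` (`"a<b"`, `"a>b"` or `"a=b"`), `significant`.
#' @export
wald_test_intensity_contrast <- function(fit, edge_a, edge_b) {
  p <- fit$params
  for (e in c(edge_a, edge_b)) {
    row <- p[p$parameter == "logq0" & p$edge == e, ]
    if (nrow(row) == 0L || !row$identifiable) {
      stop(sprintf("edge %s is not identifiable", e), call. = FALSE)
    }
  }
  na <- paste0(edge_a, ":logq0"); nb <- paste0(edge_b, ":logq0")
  la <- p$estimate[p$parameter == "logq0" & p$edge == edge_a]
  lb <- p$estimate[p$parameter == "logq0" & p$edge == edge_b]
  v <- fit$vcov[na, na] + fit$vcov[nb, nb] - 2 * fit$vcov[na, nb]
  d <- la - lb
  se <- sqrt(v)
  z <- if (d == 0) 0 else d / se
  list(log_diff = d, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       direction = if (d < 0) "a<b" else if (d > 0) "a>b" else "a=b",
       significant = 2 * stats::pnorm(-abs(z)) < 0.05)
}

#' Per-category fits of a study
#'
#' Pools both sessions of every pair within each pairing category and fits
#' the covariate model, with `satiated` as a 0/1 covariate on all edges and
#' focal/partner boldness (centred at the per-category sample mean) on all
#' edges, mirroring one model per temperament group.
#'
#' @param trajectories Named list from [read_event_log()].
#' @param meta Sessions data frame; defaults to the `"meta"` attribute.
#' @param use_boldness Include boldness covariates (default `TRUE`;
#'   automatically dropped when they do not vary).
#' @param per_pair Fit one model per pair instead of per category.
#' @return Named list of `ctmc_fit` objects (by category or pair id).
#' @export
fit_by_category <- function(trajectories, meta = attr(trajectories, "meta"),
                            use_boldness = TRUE, per_pair = FALSE) {
  if (is.null(meta)) stop("sessions metadata required", call. = FALSE)
  key <- vapply(trajectories, function(t) paste(t$pair_id, t$session, sep = "/"),
                character(1))
  mkey <- paste(meta$pair_id, meta$session, sep = "/")
  meta <- meta[match(key, mkey), , drop = FALSE]
  groups <- if (per_pair) meta$pair_id else meta$category
  out <- list()
  for (g in unique(groups)) {
    sel <- which(groups == g)
    covs <- data.frame(satiated = meta$focal_satiated[sel])
    if (use_boldness &&
        !anyNA(meta$focal_boldness[sel]) &&
        (stats::sd(meta$focal_boldness[sel]) > 0 ||
         stats::sd(meta$partner_boldness[sel]) > 0)) {
      covs$focal_boldness <- meta$focal_boldness[sel]
      covs$partner_boldness <- meta$partner_boldness[sel]
    }
    out[[g]] <- fit_mle(trajectories[sel], covariates = covs,
                        center = setdiff(names(covs), "satiated"))
  }
  out
}

#' Serialize fits to a tidy results table
#'
#' @param fits Named list of `ctmc_fit` objects (e.g. from
#'   [fit_by_category()]).
#' @return Data frame with columns `category,parameter,covariate,edge,
#'   estimate,se_working,ci95_lo,ci95_hi,p_value,identifiable` —
#'   `estimate` on the natural scale for baselines (per second) and on the
#'   log-linear scale for coefficients.
#' @export
fits_table <- function(fits) {
  rows <- lapply(names(fits), function(g) {
    p <- fits[[g]]$params
    est <- ifelse(p$parameter == "logq0", exp(p$estimate), p$estimate)
    z <- p$estimate / p$se
    data.frame(category = g, parameter = p$parameter,
               covariate = ifelse(is.na(p$covariate), "", p$covariate),
               edge = p$edge, estimate = est, se_working = p$se,
               ci95_lo = p$ci_lo, ci95_hi = p$ci_hi,
               p_value = ifelse(p$parameter == "coef" & p$identifiable,
                                2 * stats::pnorm(-abs(z)), NA_real_),
               identifiable = p$identifiable)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
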