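# Design matrix ------------------------------------------------------------

#' Build the determinants design matrix
#'
#' Encodes the determinants model for a CHE/MI flag: an urban dummy (rural
#' reference), income-quartile dummies Q2-Q4 (Q1 reference), family size,
#' log per-capita consumption expenditure, log per-capita food expenditure,
#' and province fixed-effect dummies (first province as reference). Rows
#' with nonpositive consumption or food per capita are outside the log
#' domain: dropped and counted.
#'
#' @param records validated household table with a `quartile` column (see
#'   [assign_income_quartiles()]).
#' @param outcome logical/0-1 vector aligned with `records` (a flag column).
#' @param province_fe include province dummies? (default TRUE)
#' @return list: `X` (model matrix incl. intercept), `y`, `weights`,
#'   `dummy_cols` (names of dummy covariates), `n_dropped_log_domain`,
#'   `warnings` (e.g. non-identified covariates).
#' @export
build_design <- function(records, outcome, province_fe = TRUE) {
  stopifnot(nrow(records) == length(outcome))
  if (!"quartile" %in% names(records))
    records$quartile <- assign_income_quartiles(records)
  cons_pc <- records$consumption_total / records$family_size
  food_pc <- records$food_expenditure / records$family_size
  ok <- cons_pc > 0 & food_pc > 0
  n_dropped <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  outcome <- as.numeric(outcome)[ok]
  cons_pc <- cons_pc[ok]; food_pc <- food_pc[ok]
  if (nrow(records) == 0L) stop("no rows left in log domain", call. = FALSE)
  if (length(unique(outcome)) < 2L)
    stop("outcome is constant; model not estimable", call. = FALSE)
  warn <- character()
  q <- factor(records$quartile, levels = paste0("Q", 1:4))
  X <- cbind(`(Intercept)` = 1,
             urban = as.numeric(records$urban),
             Q2 = as.numeric(q == "Q2"),
             Q3 = as.numeric(q == "Q3"),
             Q4 = as.numeric(q == "Q4"),
             family_size = records$family_size,
             log_cons_pc = log(cons_pc),
             log_food_pc = log(food_pc))
  dummy_cols <- c("urban", "Q2", "Q3", "Q4")
  if (province_fe) {
    prov <- factor(records$province)
    if (nlevels(prov) > 1L) {
      pd <- stats::model.matrix(~ prov)[, -1L, drop = FALSE]
      colnames(pd) <- paste0("province_", levels(prov)[-1L])
      X <- cbind(X, pd)
      dummy_cols <- c(dummy_cols, colnames(pd))
    }
  }
  const <- apply(X[, -1L, drop = FALSE], 2L, function(col)
    length(unique(col)) == 1L)
  if (any(const))
    warn <- c(warn, paste0("non-identified covariate(s) (constant column): ",
                           paste(names(const)[const], collapse = ", ")))
  list(X = X, y = outcome, weights = records$weight,
       dummy_cols = dummy_cols, n_dropped_log_domain = n_dropped,
       warnings = warn)
}

# Probit fit ----------------------------------------------------------------

#' Weighted probit with robust (sandwich) standard errors
#'
#' Maximizes the weight-scaled probit log-likelihood
#' sum_i w_i [y_i log Phi(x_i'b) + (1 - y_i) log(1 - Phi(x_i'b))]
#' by Newton-Raphson (observed Hessian), with weights normalized to mean 1
#' so robust standard errors are on the sample-size scale. Convergence is
#' declared at gradient max-norm < 1e-6, within 200 iterations. Collinear
#' columns are detected by pivoted QR and dropped with a report; a covariate
#' that perfectly separates the outcome raises an error naming it.
#'
#' @param X model matrix including intercept (from [build_design()]).
#' @param y 0/1 outcome.
#' @param weights positive weights (normalized internally to mean 1).
#' @param tol gradient max-norm tolerance.
#' @param max_iter Newton iteration cap.
#' @return Object of class `probit_fit`: `coefficients`, `vcov` (sandwich),
#'   `robust_se`, `n_used`, `converged`, `iterations`, `loglik`,
#'   `dropped_collinear`, plus the data needed for marginal effects.
#' @export
fit_probit <- function(X, y, weights = rep(1, length(y)),
                       tol = 1e-6, max_iter = 200L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), length(weights) == length(y),
            all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L)
    stop("outcome is constant; model not estimable", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  w <- weights / mean(weights)
  .check_separation(X, y)
  # drop collinear columns via pivoted QR of the weighted design
  qrx <- qr(X * sqrt(w))
  dropped <- character()
  if (qrx$rank < ncol(X)) {
    keep <- sort(qrx$pivot[seq_len(qrx$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    X <- X[, keep, drop = FALSE]
  }
  k <- ncol(X)
  b <- numeric(k)
  if ("(Intercept)" %in% colnames(X))
    b[match("(Intercept)", colnames(X))] <- stats::qnorm(
      min(max(stats::weighted.mean(y, w), 1e-4), 1 - 1e-4))
  converged <- FALSE
  iter <- 0L
  q <- 2 * y - 1
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    z <- q * eta
    # inverse Mills ratio, stable in the far tail via the log-density trick
    lambda <- q * exp(stats::dnorm(z, log = TRUE) -
                      stats::pnorm(z, log.p = TRUE))
    score <- colSums(X * (w * lambda))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    # observed information weight lambda_i (lambda_i + eta_i) is positive;
    # clamp tiny negatives from far-tail rounding
    info_w <- pmax(w * lambda * (lambda + eta), 1e-12)
    H <- crossprod(X * sqrt(info_w))
    step <- tryCatch(solve(H, score), error = function(e)
      solve(H + diag(1e-8, k), score))
    # step-halving on the weighted log-likelihood
    ll_old <- .probit_ll(X, y, b, w)
    s <- 1
    repeat {
      b_new <- b + s * step
      if (.probit_ll(X, y, b_new, w) >= ll_old - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    b <- b_new
  }
  eta <- drop(X %*% b)
  z <- q * eta
  lambda <- q * exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  info_w <- pmax(w * lambda * (lambda + eta), 1e-12)
  A <- crossprod(X * sqrt(info_w))            # -Hessian
  S <- X * (w * lambda)                        # score contributions
  B <- crossprod(S)
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(b, colnames(X)),
                 vcov = V, robust_se = sqrt(diag(V)),
                 n_used = nrow(X), converged = converged, iterations = iter,
                 loglik = .probit_ll(X, y, b, w),
                 dropped_collinear = dropped,
                 X = X, y = y, w = w),
            class = "probit_fit")
}

.probit_ll <- function(X, y, b, w) {
  z <- (2 * y - 1) * drop(X %*% b)
  sum(w * stats::pnorm(z, log.p = TRUE))
}

.check_separation <- function(X, y) {
  cols <- setdiff(colnames(X), "(Intercept)")
  for (cn in cols) {
    x <- X[, cn]
    if (length(unique(x)) < 2L) next
    if (min(x[y == 1]) > max(x[y == 0]) || max(x[y == 1]) < min(x[y == 0]))
      stop("perfect separation detected on covariate '", cn, "'",
           call. = FALSE)
  }
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Weighted probit fit:", x$n_used, "obs;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations\n")
  tab <- data.frame(coef = x$coefficients, robust_se = x$robust_se)
  print(round(tab, 4))
  invisible(x)
}

# Marginal effects -----------------------------------------------------------

#' Average marginal effects with delta-method robust standard errors
#'
#' For a continuous covariate j the AME is the weighted mean of
#' phi(x_i'b) b_j; for a dummy it is the weighted mean discrete change
#' Phi(x'b | d = 1) - Phi(x'b | d = 0). Standard errors come from the delta
#' method applied to the sandwich covariance of the fit.
#'
#' @param fit a converged [fit_probit()] object.
#' @param dummy_cols names of covariates to treat as discrete 0/1 changes.
#' @return `data.frame` with `term`, `ame`, `robust_se`, `z`, `p_value`,
#'   `stars` for every non-intercept covariate retained in the fit.
#' @export
marginal_effects <- function(fit, dummy_cols = character()) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!fit$converged)
    stop("marginal effects require a converged fit", call. = FALSE)
  X <- fit$X; b <- fit$coefficients; w <- fit$w
  sw <- sum(w)
  eta <- drop(X %*% b)
  phi <- stats::dnorm(eta)
  terms <- setdiff(colnames(X), "(Intercept)")
  res <- lapply(terms, function(j) {
    bj <- b[[j]]
    if (j %in% dummy_cols) {
      X1 <- X; X1[, j] <- 1
      X0 <- X; X0[, j] <- 0
      e1 <- drop(X1 %*% b); e0 <- drop(X0 %*% b)
      ame <- sum(w * (stats::pnorm(e1) - stats::pnorm(e0))) / sw
      grad <- colSums(w * (stats::dnorm(e1) * X1 - stats::dnorm(e0) * X0)) / sw
    } else {
      ame <- sum(w * phi * bj) / sw
      # d/db_k mean(phi(eta) b_j) = mean(-eta phi x_k b_j) + 1{k=j} mean(phi)
      grad <- colSums(w * (-eta * phi * bj) * X) / sw
      grad[j] <- grad[j] + sum(w * phi) / sw
    }
    se <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
    data.frame(term = j, ame = ame, robust_se = se)
  })
  out <- do.call(rbind, res)
  out$z <- out$ame / out$robust_se
  out$p_value <- 2 * stats::pnorm(-abs(out$z))
  out$stars <- significance_stars(out$p_value)
  rownames(out) <- NULL
  out
}

#' Fit the full determinants model for one indicator
#'
#' Convenience wrapper: builds the design ([build_design()]), fits the
#' weighted probit and computes AMEs. A cell-degenerate outcome (e.g. an
#' income quartile with zero events making the outcome constant) surfaces
#' as the documented "not estimable" error.
#'
#' @param records validated household table with quartiles assigned.
#' @param outcome logical flag vector aligned with `records`.
#' @param province_fe include province fixed effects?
#' @return list: `fit` (probit_fit), `ame` (AME table), `design` metadata.
#' @export
fit_determinants <- function(records, outcome, province_fe = TRUE) {
  d <- build_design(records, outcome, province_fe = province_fe)
  for (msg in d$warnings) warning(msg, call. = FALSE)
  fit <- fit_probit(d$X, d$y, d$weights)
  ame <- marginal_effects(fit, dummy_cols = d$dummy_cols)
  list(fit = fit, ame = ame,
       n_dropped_log_domain = d$n_dropped_log_domain,
       n_used = fit$n_used)
}
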