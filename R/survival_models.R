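#' Kaplan-Meier product-limit estimate
#'
#' Survival is re-estimated only at distinct event (death) times; censored
#' observations reduce the at-risk count without a survival step. With no
#' events the curve is identically 1 (zero-row grid).
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators (1 = death).
#' @return a `km_curve` data.frame: `time`, `n_risk`, `n_event`, `surv`
#'   (S(t) just after each event time).
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(times < 0)) stop("negative follow-up time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  et <- sort(unique(times[events == 1]))
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = et, n_risk = n_risk, n_event = n_event,
                       surv = surv),
            n = length(times), class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param t numeric vector of times.
#' @return S(t) for each time (right-continuous step function, S = 1 before
#'   the first event).
#' @export
km_surv <- function(curve, t) {
  vapply(t, function(tt) {
    i <- sum(curve$time <= tt)
    if (i == 0L) 1 else curve$surv[i]
  }, numeric(1))
}

#' k-group log-rank test
#'
#' The classical O-E statistic: at each distinct event time the observed
#' deaths per group are compared with their hypergeometric expectation given
#' the at-risk composition, and the summed discrepancies are combined with
#' the summed hypergeometric covariance into a chi-square on k-1 degrees of
#' freedom.
#'
#' @param times,events as in [km_estimate()].
#' @param groups grouping vector (>= 2 groups, each non-empty).
#' @return list: `chi_square`, `df`, `p_value`, `observed`, `expected`
#'   (per-group O and E).
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2L) stop("log-rank test needs at least 2 groups")
  if (length(times) != length(events) || length(times) != length(g)) {
    stop("times, events and groups differ in length")
  }
  et <- sort(unique(times[events == 1]))
  O <- E <- stats::setNames(numeric(k), levels(g))
  V <- matrix(0, k - 1, k - 1)
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    if (n <= 1L || d == 0L) next
    ng <- tapply(at_risk, g, sum)
    ng[is.na(ng)] <- 0
    dg <- tapply(times == t & events == 1, g, sum)
    dg[is.na(dg)] <- 0
    O <- O + dg
    E <- E + d * ng / n
    # hypergeometric covariance of the death counts, groups 1..k-1
    for (i in seq_len(k - 1)) {
      for (j in seq_len(k - 1)) {
        delta <- as.numeric(i == j)
        V[i, j] <- V[i, j] +
          d * (n - d) / (n - 1) * ng[i] * (n * delta - ng[j]) / n^2
      }
    }
  }
  z <- (O - E)[seq_len(k - 1)]
  chi <- if (all(V == 0)) 0 else {
    Vi <- tryCatch(solve(V), error = function(e) {
      s <- svd(V)
      pos <- s$d > max(s$d) * 1e-12
      s$v[, pos, drop = FALSE] %*%
        ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
    })
    drop(t(z) %*% Vi %*% z)
  }
  chi <- max(chi, 0)
  list(chi_square = chi, df = k - 1L,
       p_value = stats::pchisq(chi, df = k - 1L, lower.tail = FALSE),
       observed = O, expected = E)
}

# log partial likelihood, score vector and observed information at beta.
# Efron or Breslow handling of tied event times.
.cox_quantities <- function(times, events, X, beta, tie = "efron") {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)          # guard exp overflow; PL is shift-invariant
  w <- exp(eta)
  ut <- sort(unique(times), decreasing = TRUE)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  for (t in ut) {
    idx <- which(times == t)
    for (i in idx) {             # subjects enter the risk set at their time
      S0 <- S0 + w[i]
      S1 <- S1 + w[i] * X[i, ]
      S2 <- S2 + w[i] * tcrossprod(X[i, ])
    }
    D <- idx[events[idx] == 1]
    d <- length(D)
    if (d == 0L) next
    wD <- sum(w[D])
    S1D <- colSums(w[D] * X[D, , drop = FALSE])
    S2D <- matrix(0, p, p)
    for (i in D) S2D <- S2D + w[i] * tcrossprod(X[i, ])
    ll <- ll + sum(eta[D])
    U <- U + colSums(X[D, , drop = FALSE])
    fr <- if (tie == "efron") (seq_len(d) - 1) / d else rep(0, d)
    for (l in seq_len(d)) {
      phi <- S0 - fr[l] * wD
      a <- S1 - fr[l] * S1D
      b <- S2 - fr[l] * S2D
      ll <- ll - log(phi)
      U <- U - a / phi
      I <- I + b / phi - tcrossprod(a / phi)
    }
  }
  list(loglik = ll, score = U, info = I)
}

#' Cox proportional-hazards fit by Newton-Raphson on the partial likelihood
#'
#' Maximizes the Cox partial likelihood with Efron (default) or Breslow
#' handling of tied event times, with step-halving when a step would
#' decrease the likelihood. Convergence when the largest score component is
#' below `tol`. Standard errors come from the inverse observed information;
#' hazard ratios carry normal-approximation 95% intervals
#' `exp(beta +/- 1.96 se)` and Wald p-values. Diverging coefficients
#' (monotone likelihood / perfect separation) are flagged, never silent.
#'
#' @param times,events as in [km_estimate()].
#' @param covariates numeric matrix or data.frame (n x p); rows with any NA
#'   are dropped listwise.
#' @param tie_method `"efron"` or `"breslow"`.
#' @param tol score convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 50).
#' @return a `cox_fit` list: `table` (term, beta, se, hr, ci_lower,
#'   ci_upper, p), `loglik`, `converged`, `flag` (`"ok"`,
#'   `"monotone_likelihood"` or `"not_converged"`), `n`, `n_events`,
#'   `iterations`, `tie_method`.
#' @export
cox_fit <- function(times, events, covariates,
                    tie_method = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 50) {
  tie_method <- match.arg(tie_method)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  keep <- stats::complete.cases(X) & !is.na(times) & !is.na(events)
  X <- X[keep, , drop = FALSE]
  times <- times[keep]; events <- events[keep]
  if (any(times < 0)) stop("negative follow-up time")
  p <- ncol(X)
  const <- apply(X, 2, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    stop("constant covariate(s): ", paste(colnames(X)[const], collapse = ", "))
  }
  if (sum(events) < p) stop("fewer events than covariates")
  # center covariates for numerical stability; beta is unaffected
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)

  beta <- numeric(p)
  q <- .cox_quantities(times, events, Xc, beta, tie_method)
  flag <- "ok"; converged <- FALSE; iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (max(abs(q$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(q$info, q$score), error = function(e) NULL)
    if (is.null(step)) { flag <- "monotone_likelihood"; break }
    new_beta <- beta + step
    qn <- .cox_quantities(times, events, Xc, new_beta, tie_method)
    h <- 0
    while (qn$loglik < q$loglik - 1e-12 && h < 20) {
      h <- h + 1
      new_beta <- beta + step / 2^h
      qn <- .cox_quantities(times, events, Xc, new_beta, tie_method)
    }
    beta <- new_beta; q <- qn
    if (max(abs(beta)) > 15) { flag <- "monotone_likelihood"; break }
  }
  if (max(abs(q$score)) < tol) converged <- TRUE
  if (!converged && flag == "ok") flag <- "not_converged"
  se <- tryCatch(sqrt(diag(solve(q$info))), error = function(e) {
    if (flag == "ok") flag <<- "monotone_likelihood"
    rep(NA_real_, p)
  })
  z <- beta / se
  tab <- data.frame(
    term = colnames(X), beta = beta, se = se,
    hr = exp(beta),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, loglik = q$loglik, converged = converged,
                 flag = flag, n = length(times), n_events = sum(events),
                 iterations = iter, tie_method = tie_method),
            class = "cox_fit")
}

#' Cox score (Rao) test at beta = 0
#'
#' With a single binary covariate and no tied event times this equals the
#' two-group log-rank chi-square.
#'
#' @inheritParams cox_fit
#' @return list: `chi_square`, `df`, `p_value`.
#' @export
cox_score_test <- function(times, events, covariates,
                           tie_method = c("efron", "breslow")) {
  tie_method <- match.arg(tie_method)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  Xc <- sweep(X, 2, colMeans(X))
  q <- .cox_quantities(times, events, Xc, numeric(ncol(X)), tie_method)
  chi <- drop(t(q$score) %*% solve(q$info, q$score))
  list(chi_square = chi, df = ncol(X),
       p_value = stats::pchisq(chi, ncol(X), lower.tail = FALSE))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$tie_method, " ties), n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  cat("log partial likelihood:", format(x$loglik), "| converged:",
      x$converged, "| flag:", x$flag, "\n")
  print(x$table, digits = 4)
  invisible(x)
}
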