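# Penalized additive binomial model engine: cubic B-spline smooths
# with second-difference penalties (cyclic and shrinkage variants),
# by-factor smooths, ridge-penalized random intercepts, logit and
# complementary log-log links, penalized IRLS, and a REML-type
# smoothing-parameter search (coordinate descent on a log grid with
# golden-section refinement).

#' Specify a penalized smooth term
#'
#' @param covariate Name of the covariate column.
#' @param basis_dim Number of basis functions before the sum-to-zero
#'   constraint (>= 3; the constrained term has `basis_dim - 1`
#'   reference df).
#' @param cyclic Logical; wrap the basis so value and first/second
#'   derivatives match at 0 and `period` (diel and seasonal terms).
#' @param period Covariate period; required when `cyclic`.
#' @param by Optional name of a grouping factor: one smooth per level
#'   (a single smoothing parameter is shared across levels).
#' @param shrinkage Logical; add a small penalty on the null space so
#'   the whole term can shrink to zero and simple linear relationships
#'   can be selected where appropriate.
#' @return list of class `smooth_spec`.
#' @export
smooth_spec <- function(covariate, basis_dim = 10, cyclic = FALSE,
                        period = NULL, by = NULL, shrinkage = TRUE) {
  stopifnot(basis_dim >= 3)
  if (cyclic && is.null(period)) stop("cyclic smooths require a period")
  if (!is.null(period)) stopifnot(period > 0)
  structure(list(covariate = covariate, basis_dim = as.integer(basis_dim),
                 cyclic = cyclic, period = period, by = by,
                 shrinkage = shrinkage),
            class = "smooth_spec")
}

# second-order difference matrix, optionally cyclic (circulant)
diff2_matrix <- function(k, cyclic = FALSE) {
  if (cyclic) {
    D <- matrix(0, k, k)
    for (i in seq_len(k)) {
      D[i, i] <- 1
      D[i, (i %% k) + 1L] <- -2
      D[i, ((i + 1L) %% k) + 1L] <- 1
    }
    D
  } else {
    if (k < 3) stop("need at least 3 basis functions")
    D <- matrix(0, k - 2, k)
    for (i in seq_len(k - 2)) D[i, i + 0:2] <- c(1, -2, 1)
    D
  }
}

#' Build a spline basis and its penalty
#'
#' Cubic B-spline basis on equally spaced knots with a second-order
#' difference penalty (zero for straight lines). Cyclic bases wrap the
#' end basis functions and use a circulant penalty, so fitted curves
#' match in value and first two derivatives at 0 and `period`.
#' Shrinkage replaces the penalty's zero eigenvalues with a small
#' positive value so the null space is also (weakly) penalized.
#'
#' @param x Covariate values.
#' @param spec A [smooth_spec()].
#' @return list: `X` (basis matrix), `S` (penalty), `knots`, `spec`.
#' @export
build_basis <- function(x, spec) {
  stopifnot(inherits(spec, "smooth_spec"))
  k <- spec$basis_dim
  if (spec$cyclic) {
    p <- spec$period
    xm <- x %% p
    h <- p / k
    knots <- seq(-3 * h, p + 3 * h, by = h)
    B <- splines::splineDesign(knots, xm, ord = 4, outer.ok = TRUE)
    # fold the 3 wrap-around columns
    X <- B[, 1:k, drop = FALSE]
    X[, 1:3] <- X[, 1:3] + B[, k + 1:3, drop = FALSE]
    D <- diff2_matrix(k, cyclic = TRUE)
  } else {
    if (length(unique(x)) < k)
      stop("need at least basis_dim distinct covariate values")
    r <- range(x)
    if (diff(r) <= 0) stop("covariate is constant; basis is rank deficient")
    h <- diff(r) / (k - 3)
    knots <- seq(r[1] - 3 * h, r[2] + 3 * h, by = h)
    if (length(knots) != k + 4) knots <- seq(r[1] - 3 * h, by = h,
                                             length.out = k + 4)
    X <- splines::splineDesign(knots, x, ord = 4, outer.ok = TRUE)
    D <- diff2_matrix(k, cyclic = FALSE)
  }
  S <- crossprod(D)
  if (spec$shrinkage) {
    e <- eigen(S, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-10
    eps <- 0.01 * min(e$values[pos])
    vals <- ifelse(pos, e$values, eps)
    S <- e$vectors %*% (vals * t(e$vectors))
    S <- (S + t(S)) / 2
  }
  list(X = X, S = S, knots = knots, spec = spec)
}

# sum-to-zero constraint: reparameterize so colSums(X beta) = 0
constrain_basis <- function(basis) {
  cs <- colSums(basis$X)
  Q <- qr.Q(qr(matrix(cs, ncol = 1)), complete = TRUE)
  Z <- Q[, -1, drop = FALSE]
  list(X = basis$X %*% Z, S = t(Z) %*% basis$S %*% Z, Z = Z, basis = basis)
}

# evaluate the raw basis of a stored term at new covariate values
eval_basis <- function(basis, xnew) {
  spec <- basis$spec; k <- spec$basis_dim
  if (spec$cyclic) {
    B <- splines::splineDesign(basis$knots, xnew %% spec$period, ord = 4,
                               outer.ok = TRUE)
    X <- B[, 1:k, drop = FALSE]
    X[, 1:3] <- X[, 1:3] + B[, k + 1:3, drop = FALSE]
    X
  } else {
    xc <- pmin(max(basis$knots) - 1e-8, pmax(min(basis$knots) + 1e-8, xnew))
    splines::splineDesign(basis$knots, xc, ord = 4, outer.ok = TRUE)
  }
}

.pam_family <- function(link) {
  fam <- stats::binomial(link = link)
  list(linkinv = fam$linkinv, mu.eta = fam$mu.eta, linkfun = fam$linkfun)
}

# penalized IRLS for fixed smoothing parameters; returns beta and the
# weighted information pieces needed by the REML criterion
.pam_irls <- function(y, X, S_lambda, link, beta0 = NULL,
                      maxit = 200, tol = 1e-11) {
  fam <- .pam_family(link)
  n <- nrow(X); p <- ncol(X)
  beta <- if (is.null(beta0)) c(fam$linkfun(mean(y) * 0.98 + 0.01),
                                rep(0, p - 1)) else beta0
  pen_dev <- function(beta) {
    mu <- fam$linkinv(drop(X %*% beta))
    mu <- pmin(1 - 1e-10, pmax(1e-10, mu))
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)) +
      drop(t(beta) %*% S_lambda %*% beta)
  }
  pd <- pen_dev(beta)
  dev_trace <- pd
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- pmin(1 - 1e-10, pmax(1e-10, fam$linkinv(eta)))
    me <- pmax(fam$mu.eta(eta), 1e-10)
    w <- me^2 / (mu * (1 - mu))
    z <- eta + (y - mu) / me
    XtW <- t(X * w)
    H <- XtW %*% X
    beta_new <- tryCatch(
      solve(H + S_lambda + diag(1e-10, p), XtW %*% z),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    pd_new <- pen_dev(beta_new)
    step <- 1
    while (!is.finite(pd_new) || (pd_new > pd + 1e-10 && step > 1e-4)) {
      step <- step / 2
      beta_new <- beta + step * (beta_new - beta)
      pd_new <- pen_dev(beta_new)
    }
    dev_trace <- c(dev_trace, pd_new)
    if (abs(pd - pd_new) < tol * (abs(pd_new) + 0.1)) {
      beta <- beta_new; pd <- pd_new; converged <- TRUE; break
    }
    beta <- beta_new; pd <- pd_new
  }
  eta <- drop(X %*% beta)
  mu <- pmin(1 - 1e-10, pmax(1e-10, fam$linkinv(eta)))
  me <- pmax(fam$mu.eta(eta), 1e-10)
  w <- me^2 / (mu * (1 - mu))
  H <- t(X * w) %*% X
  list(beta = beta, mu = mu, H = H, pen_dev = pd,
       dev = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)),
       dev_trace = dev_trace, converged = converged)
}

# Laplace/REML-type criterion for one lambda configuration
.pam_reml <- function(y, X, terms, lambdas, link, beta0 = NULL) {
  S_lambda <- matrix(0, ncol(X), ncol(X))
  for (j in seq_along(terms)) {
    tj <- terms[[j]]
    S_lambda[tj$idx, tj$idx] <- S_lambda[tj$idx, tj$idx] +
      lambdas[j] * tj$S
  }
  fit <- .pam_irls(y, X, S_lambda, link, beta0 = beta0)
  pen <- drop(t(fit$beta) %*% S_lambda %*% fit$beta)
  ld_H <- determinant(fit$H + S_lambda + diag(1e-10, ncol(X)),
                      logarithm = TRUE)$modulus
  ld_S <- 0
  for (j in seq_along(terms)) {
    tj <- terms[[j]]
    ld_S <- ld_S + tj$rank * log(lambdas[j]) + tj$logdet
  }
  crit <- fit$dev / 2 + pen / 2 + 0.5 * as.numeric(ld_H) - 0.5 * ld_S
  list(crit = crit, fit = fit, S_lambda = S_lambda)
}

#' Fit a penalized additive binomial model
#'
#' Binary response modelled through a logit or complementary log-log
#' link with parametric (linear) terms, penalized spline smooths
#' ([smooth_spec()]), and optional ridge-penalized random intercepts
#' (grouping factors are concatenated, so `random = c("tag", "trip")`
#' nests trip within tag). Fitting is by penalized IRLS to convergence;
#' smoothing parameters (and the random-effect ridge) are chosen by a
#' REML-type criterion searched by coordinate descent on a log grid
#' with golden-section refinement, unless supplied fixed.
#'
#' @param data data.frame holding all variables.
#' @param response Name of the 0/1 response column.
#' @param linear Character vector of parametric term names.
#' @param smooths List of [smooth_spec()] objects.
#' @param random Character vector of grouping-factor names (nested in
#'   order) for random intercepts; `NULL` for none.
#' @param link `"logit"` or `"cloglog"`.
#' @param lambda Optional named numeric of fixed smoothing parameters
#'   (one per smooth term, plus `"random"`); `NULL` to select.
#' @param lambda_grid log10 grid searched during selection.
#' @return Object of class `pam_fit`: coefficients and standard
#'   errors, per-term effective degrees of freedom, log-likelihood,
#'   AIC, and the information needed to evaluate fitted smooths.
#' @export
pam_fit <- function(data, response, linear = character(),
                    smooths = list(), random = NULL,
                    link = c("logit", "cloglog"), lambda = NULL,
                    lambda_grid = seq(-3, 7, by = 1)) {
  link <- match.arg(link)
  y <- data[[response]]
  stopifnot(all(y %in% 0:1))
  n <- length(y)
  blocks <- list()   # per reported block: name, idx, type
  terms <- list()    # per penalized term: idx, S, rank, logdet, name
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  blocks[[1]] <- list(name = "(Intercept)", idx = 1L, type = "parametric")
  for (v in linear) {
    xv <- data[[v]]
    M <- if (is.factor(xv) || is.character(xv)) {
      mm <- stats::model.matrix(~f, data.frame(f = factor(xv)))[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, levels(factor(xv))[-1]); mm
    } else matrix(as.numeric(xv), ncol = 1, dimnames = list(NULL, v))
    idx <- ncol(X) + seq_len(ncol(M))
    X <- cbind(X, M)
    blocks[[length(blocks) + 1]] <- list(name = v, idx = idx,
                                         type = "parametric")
  }
  smooth_info <- list()
  for (sp in smooths) {
    x <- data[[sp$covariate]]
    if (is.null(sp$by)) {
      bb <- build_basis(x, sp)
      cb <- constrain_basis(bb)
      idx <- ncol(X) + seq_len(ncol(cb$X))
      nm <- paste0("s(", sp$covariate, ")")
      X <- cbind(X, cb$X)
      colnames(X)[idx] <- paste0(nm, ".", seq_along(idx))
      blocks[[length(blocks) + 1]] <- list(name = nm, idx = idx,
                                           type = "smooth")
      ev <- eigen(cb$S, symmetric = TRUE, only.values = TRUE)$values
      pos <- ev > max(ev) * 1e-10
      terms[[length(terms) + 1]] <- list(
        name = nm, idx = idx, S = cb$S, rank = sum(pos),
        logdet = sum(log(ev[pos])),
        sub_blocks = list(list(name = nm, idx = idx)))
      smooth_info[[nm]] <- list(spec = sp, basis = bb, Z = cb$Z, idx = idx,
                                by_level = NULL)
    } else {
      f <- factor(data[[sp$by]])
      bb <- build_basis(x, sp)
      cb <- constrain_basis(bb)
      sub <- list(); term_idx <- integer()
      Sterm <- NULL
      for (lev in levels(f)) {
        Xl <- cb$X * (f == lev)
        idx <- ncol(X) + seq_len(ncol(Xl))
        nm <- paste0("s(", sp$covariate, "):", lev)
        X <- cbind(X, Xl)
        colnames(X)[idx] <- paste0(nm, ".", seq_along(idx))
        blocks[[length(blocks) + 1]] <- list(name = nm, idx = idx,
                                             type = "smooth")
        sub[[length(sub) + 1]] <- list(name = nm, idx = idx)
        term_idx <- c(term_idx, idx)
        Sterm <- if (is.null(Sterm)) cb$S else
          rbind(cbind(Sterm, matrix(0, nrow(Sterm), ncol(cb$S))),
                cbind(matrix(0, nrow(cb$S), ncol(Sterm)), cb$S))
        smooth_info[[nm]] <- list(spec = sp, basis = bb, Z = cb$Z, idx = idx,
                                  by_level = lev)
      }
      ev <- eigen(Sterm, symmetric = TRUE, only.values = TRUE)$values
      pos <- ev > max(ev) * 1e-10
      terms[[length(terms) + 1]] <- list(
        name = paste0("s(", sp$covariate, "):", sp$by), idx = term_idx,
        S = Sterm, rank = sum(pos), logdet = sum(log(ev[pos])),
        sub_blocks = sub)
    }
  }
  if (!is.null(random)) {
    g <- interaction(data[random], drop = TRUE, sep = ":")
    M <- stats::model.matrix(~ g - 1)
    colnames(M) <- paste0("re.", levels(g))
    idx <- ncol(X) + seq_len(ncol(M))
    X <- cbind(X, M)
    blocks[[length(blocks) + 1]] <- list(name = "random", idx = idx,
                                         type = "random")
    terms[[length(terms) + 1]] <- list(
      name = "random", idx = idx, S = diag(ncol(M)), rank = ncol(M),
      logdet = 0, sub_blocks = list(list(name = "random", idx = idx)))
  }
  p <- ncol(X)
  if (qr(X)$rank < min(n, p) && p > n)
    warning("design has more columns than rows; fit is penalty-dominated")
  # --- smoothing-parameter selection ------------------------------------
  nt <- length(terms)
  if (nt == 0) {
    res <- .pam_irls(y, X, matrix(0, p, p), link)
    lambdas <- numeric()
    S_lambda <- matrix(0, p, p)
    fit <- res
  } else if (!is.null(lambda)) {
    lambdas <- rep_len(as.numeric(lambda), nt)
    r <- .pam_reml(y, X, terms, lambdas, link)
    fit <- r$fit; S_lambda <- r$S_lambda
  } else {
    lambdas <- rep(1, nt)
    beta0 <- NULL
    best <- .pam_reml(y, X, terms, lambdas, link, beta0)
    for (sweep in 1:2) {
      for (j in seq_len(nt)) {
        crits <- rep(NA_real_, length(lambda_grid))
        for (gi in seq_along(lambda_grid)) {
          lj <- lambdas; lj[j] <- 10^lambda_grid[gi]
          r <- .pam_reml(y, X, terms, lj, link, best$fit$beta)
          crits[gi] <- r$crit
          if (r$crit <= best$crit) { best <- r; lambdas <- lj }
        }
        # golden-section refinement around the grid optimum
        gi <- which.min(crits)
        lo <- lambda_grid[max(1, gi - 1)]; hi <- lambda_grid[min(length(lambda_grid), gi + 1)]
        if (hi > lo) {
          gr <- (sqrt(5) - 1) / 2
          a <- lo; b <- hi
          x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
          f_at <- function(lg) {
            lj <- lambdas; lj[j] <- 10^lg
            r <- .pam_reml(y, X, terms, lj, link, best$fit$beta)
            list(crit = r$crit, r = r, lj = lj)
          }
          r1 <- f_at(x1); r2 <- f_at(x2)
          for (gs in 1:6) {
            if (r1$crit < r2$crit) {
              b <- x2; x2 <- x1; r2 <- r1
              x1 <- b - gr * (b - a); r1 <- f_at(x1)
            } else {
              a <- x1; x1 <- x2; r1 <- r2
              x2 <- a + gr * (b - a); r2 <- f_at(x2)
            }
          }
          rb <- if (r1$crit < r2$crit) r1 else r2
          if (rb$crit <= best$crit) { best <- rb$r; lambdas <- rb$lj }
        }
      }
    }
    fit <- best$fit; S_lambda <- best$S_lambda
  }
  # --- summaries --------------------------------------------------------
  Vinv <- fit$H + S_lambda + diag(1e-10, p)
  Vb <- tryCatch(solve(Vinv), error = function(e) MASS_ginv(Vinv))
  A <- Vb %*% fit$H                       # edf matrix
  edf_all <- diag(A)
  se <- sqrt(pmax(0, diag(Vb)))
  mu <- fit$mu
  loglik <- sum(stats::dbinom(y, 1, mu, log = TRUE))
  # per-block table
  rows <- list()
  for (b in blocks) {
    edf_b <- sum(edf_all[b$idx])
    if (b$type == "parametric") {
      for (i in b$idx) {
        rows[[length(rows) + 1]] <- data.frame(
          term = colnames(X)[i], type = "parametric",
          estimate = fit$beta[i], se = se[i],
          z = fit$beta[i] / se[i],
          p = 2 * stats::pnorm(-abs(fit$beta[i] / se[i])),
          edf = edf_all[i], ref_df = 1)
      }
    } else {
      bi <- fit$beta[b$idx]
      Vbi <- Vb[b$idx, b$idx, drop = FALSE]
      ch <- tryCatch(drop(t(bi) %*% solve(Vbi + diag(1e-10, length(bi)), bi)),
                     error = function(e) NA_real_)
      dfw <- max(1, round(edf_b))
      rows[[length(rows) + 1]] <- data.frame(
        term = b$name, type = b$type, estimate = NA_real_, se = NA_real_,
        z = NA_real_,
        p = if (is.na(ch)) NA_real_ else stats::pchisq(ch, dfw, lower.tail = FALSE),
        edf = edf_b, ref_df = length(b$idx))
    }
  }
  term_table <- do.call(rbind, rows)
  edf_total <- sum(edf_all)
  lam <- if (nt) stats::setNames(lambdas,
                                 vapply(terms, `[[`, "", "name")) else numeric()
  structure(list(coefficients = stats::setNames(fit$beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 term_table = term_table,
                 edf_total = edf_total,
                 log_likelihood = loglik,
                 aic = -2 * loglik + 2 * edf_total,
                 link = link, lambdas = lam,
                 fitted = mu, deviance = fit$dev,
                 dev_trace = fit$dev_trace,
                 converged = fit$converged,
                 smooth_info = smooth_info,
                 response = y, response_name = response,
                 n = n), class = "pam_fit")
}

# minimal Moore-Penrose fallback (avoids importing MASS for one call)
MASS_ginv <- function(M, tol = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  pos <- e$values > max(abs(e$values)) * tol
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' Evaluate a fitted smooth on a grid
#'
#' @param fit A [pam_fit()] object.
#' @param term Smooth block name as shown in `fit$term_table`, e.g.
#'   `"s(hour_of_day)"` or `"s(hour_of_day):Jan"`.
#' @param x Covariate values at which to evaluate.
#' @return Numeric vector of the centred smooth contribution on the
#'   linear-predictor scale.
#' @export
pam_smooth_values <- function(fit, term, x) {
  si <- fit$smooth_info[[term]]
  if (is.null(si)) stop("no such smooth term: ", term)
  Xr <- eval_basis(si$basis, x)
  # apply the same centring as at fit time
  Xc <- Xr %*% si$Z
  off <- colMeans(si$basis$X %*% si$Z)
  drop(sweep(Xc, 2, off) %*% fit$coefficients[si$idx])
}

#' @export
print.pam_fit <- function(x, ...) {
  cat(sprintf("Penalized additive binomial model (%s link)\n", x$link))
  cat(sprintf("n = %d, edf = %.2f, logLik = %.2f, AIC = %.2f\n",
              x$n, x$edf_total, x$log_likelihood, x$aic))
  par <- x$term_table[x$term_table$type == "parametric", ]
  cat("\nParametric coefficients:\n")
  print(data.frame(Estimate = round(par$estimate, 4),
                   `Std.Error` = round(par$se, 4),
                   `z value` = round(par$z, 3),
                   `Pr(>|z|)` = signif(par$p, 3),
                   row.names = par$term, check.names = FALSE))
  sm <- x$term_table[x$term_table$type != "parametric", ]
  if (nrow(sm)) {
    cat("\nApproximate significance of smooth terms (Wald-type):\n")
    print(data.frame(edf = round(sm$edf, 3), Ref.df = sm$ref_df,
                     `p-value` = signif(sm$p, 3),
                     row.names = sm$term, check.names = FALSE))
  }
  invisible(x)
}

#' Rank fitted models
#'
#' Orders [pam_fit()] objects by AIC or log-likelihood. All fits must
#' be on the identical response vector; ties are broken in favour of
#' fewer effective parameters.
#'
#' @param fits Named list of `pam_fit` objects.
#' @param criterion `"aic"` (ascending) or `"loglik"` (descending).
#' @return data.frame ranked best first: model, log_likelihood, edf,
#'   aic.
#' @export
pam_compare <- function(fits, criterion = c("aic", "loglik")) {
  criterion <- match.arg(criterion)
  y0 <- fits[[1]]$response
  for (f in fits)
    if (length(f$response) != length(y0) || any(f$response != y0))
      stop("models were fitted to different response vectors")
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  tab <- data.frame(
    model = nm,
    log_likelihood = vapply(fits, `[[`, 0, "log_likelihood"),
    edf = vapply(fits, `[[`, 0, "edf_total"),
    aic = vapply(fits, `[[`, 0, "aic"))
  key <- if (criterion == "aic") tab$aic else -tab$log_likelihood
  ord <- order(key, tab$edf)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  tab
}
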