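# Poisson-LMM and NB-LMM: count GLMMs with a condition fixed effect and a
# subject random intercept, log link:
#   count_ij | b_i ~ family(mean = exp(beta0 + beta1 * condition_ij +
#                                      offset_ij + b_i))
#   b_i ~ Normal(0, sigma2)
# The marginal likelihood integrates the random intercept out by adaptive
# Gauss-Hermite quadrature centered at each subject's conditional mode.

.SIGMA2_FLOOR <- 1e-10

#' GLMM specification
#'
#' Parameters of the random-intercept count GLMM: intercept and condition
#' effect on the log scale, random-intercept variance, and (for the negative
#' binomial family) the dispersion of the conditional count distribution.
#'
#' @param beta0 Intercept (log mean at baseline).
#' @param beta1 Condition effect; `exp(beta1)` is the fold ratio.
#' @param sigma2 Random-intercept variance, >= 0.
#' @param phi Optional NB dispersion (> 0); `NULL` selects the Poisson family.
#' @return An object of class `"glmm_spec"`.
#' @export
glmm_spec <- function(beta0, beta1, sigma2, phi = NULL) {
  stopifnot(is.numeric(beta0), length(beta0) == 1L, is.finite(beta0),
            is.numeric(beta1), length(beta1) == 1L, is.finite(beta1))
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 < 0)
    stop("'sigma2' must be a single non-negative number", call. = FALSE)
  if (!is.null(phi) && (!is.numeric(phi) || length(phi) != 1L || phi <= 0))
    stop("'phi' must be a single positive number or NULL", call. = FALSE)
  structure(list(beta0 = beta0, beta1 = beta1, sigma2 = sigma2, phi = phi,
                 family = if (is.null(phi)) "poisson" else "negative_binomial"),
            class = "glmm_spec")
}

#' Long-format paired counts
#'
#' One record per (subject, condition) observation, the layout the GLMM
#' works on. [paired_to_long()] converts a [paired_counts()] object.
#'
#' @param subject Integer subject identifiers.
#' @param condition 0/1 condition indicator (0 = baseline).
#' @param count Non-negative integer counts.
#' @param offset Optional per-record log normalization offset (default 0).
#' @return A `data.frame` of class `"long_counts"`.
#' @export
long_counts <- function(subject, condition, count, offset = 0) {
  count <- check_counts(count, "count")
  if (!all(condition %in% c(0, 1)))
    stop("'condition' must be 0/1", call. = FALSE)
  n <- length(count)
  if (length(subject) != n || length(condition) != n)
    stop("subject, condition and count must have equal length", call. = FALSE)
  offset <- rep_len(offset, n)
  d <- data.frame(subject = as.integer(factor(subject)),
                  condition = as.numeric(condition),
                  count = count, offset = as.numeric(offset))
  class(d) <- c("long_counts", "data.frame")
  d
}

#' @rdname long_counts
#' @param data A [paired_counts()] object.
#' @export
paired_to_long <- function(data) {
  stopifnot(inherits(data, "paired_counts"))
  long_counts(subject = rep(seq_len(data$n), 2L),
              condition = rep(c(0, 1), each = data$n),
              count = c(data$x, data$y))
}

# Gauss-Hermite rule for weight exp(-z^2), cached per node count.
gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(n_nodes) {
  key <- as.character(n_nodes)
  if (is.null(gh_cache[[key]]))
    gh_cache[[key]] <- pracma::gaussHermite(n_nodes)
  gh_cache[[key]]
}

# log pmf of the conditional count family at log-mean eta
family_logpmf <- function(count, eta, phi) {
  if (is.null(phi)) {
    count * eta - exp(eta) - lgamma(count + 1)
  } else {
    stats::dnbinom(count, size = 1 / phi, mu = exp(eta), log = TRUE)
  }
}

# First/second derivatives wrt b of log f(count | eta), eta = lin + b
family_db <- function(count, eta, phi) {
  m <- exp(eta)
  if (is.null(phi)) {
    list(d1 = count - m, d2 = -m)
  } else {
    k <- 1 / phi
    list(d1 = k * (count - m) / (m + k),
         d2 = -k * m * (count + k) / (m + k)^2)
  }
}

#' Marginal log-likelihood of the random-intercept count GLMM
#'
#' Integrates the subject random intercept out of the conditional likelihood
#' by adaptive Gauss-Hermite quadrature: for each subject the integrand is
#' re-centered at the conditional mode of the random effect (found by Newton
#' iteration) and scaled by the Laplace curvature there, then the quadrature
#' rule is applied. Deterministic for fixed inputs and node count. With
#' `sigma2 = 0` the random effect is degenerate at zero and the exact
#' fixed-effects GLM log-likelihood is returned.
#'
#' @param data A [long_counts()] object (or [paired_counts()], converted).
#' @param spec A [glmm_spec()].
#' @param n_nodes Number of quadrature nodes (default 25).
#' @return The marginal log-likelihood (scalar).
#' @export
glmm_marginal_loglik <- function(data, spec, n_nodes = 25L) {
  if (inherits(data, "paired_counts")) data <- paired_to_long(data)
  stopifnot(inherits(data, "long_counts"), inherits(spec, "glmm_spec"))
  if (n_nodes < 1L) stop("'n_nodes' must be >= 1", call. = FALSE)
  glmm_loglik_raw(data$count, data$condition, data$offset, data$subject,
                  spec$beta0, spec$beta1, spec$sigma2, spec$phi, n_nodes)
}

# Core quadrature evaluation on raw vectors; subject must be 1..n_subj.
glmm_loglik_raw <- function(count, condition, offset, subject,
                            beta0, beta1, sigma2, phi, n_nodes = 25L) {
  lin <- beta0 + beta1 * condition + offset
  if (sigma2 <= 0) return(sum(family_logpmf(count, lin, phi)))
  n_subj <- max(subject)

  # conditional mode per subject: maximize log f(counts|b) - b^2/(2 sigma2)
  b <- numeric(n_subj)
  for (iter in 1:50) {
    d <- family_db(count, lin + b[subject], phi)
    g <- rowsum_vec(d$d1, subject, n_subj) - b / sigma2
    h <- rowsum_vec(d$d2, subject, n_subj) - 1 / sigma2
    step <- g / h
    # damped Newton: halve steps that do not move toward the mode
    step <- pmax(pmin(step, 5), -5)
    b_new <- b - step
    if (max(abs(b_new - b)) < 1e-10) { b <- b_new; break }
    b <- b_new
  }
  d <- family_db(count, lin + b[subject], phi)
  curv <- -(rowsum_vec(d$d2, subject, n_subj) - 1 / sigma2)  # > 0
  if (any(!is.finite(curv) | curv <= 0))
    stop(sprintf("quadrature mode finding failed for subject %d",
                 which(!is.finite(curv) | curv <= 0)[1L]), call. = FALSE)

  rule <- gh_rule(n_nodes)
  s <- sqrt(2 / curv)                      # n_subj
  K <- n_nodes
  bmat <- b + outer(s, rule$x)             # n_subj x K random-effect values
  eta <- matrix(lin, nrow = length(lin), ncol = K) + bmat[subject, , drop = FALSE]
  lf <- family_logpmf(count, eta, phi)
  q <- rowsum(lf, subject)                # n_subj x K conditional loglik
  q <- q - bmat^2 / (2 * sigma2) - 0.5 * log(2 * pi * sigma2)
  lw <- matrix(log(rule$w) + rule$x^2, nrow = n_subj, ncol = K, byrow = TRUE)
  a <- q + lw
  amax <- apply(a, 1L, max)
  sum(log(s) + amax + log(rowSums(exp(a - amax))))
}

rowsum_vec <- function(v, idx, n) {
  out <- numeric(n)
  r <- rowsum(v, idx)
  out[as.integer(rownames(r))] <- r
  out
}

# Fast likelihood core for the balanced paired design (one record per
# subject x condition), operating on n_subj x 2 matrices with a warm-started
# conditional mode kept in `env` across evaluations of the same fit.
glmm_ll_paired <- function(cm, lin, sigma2, phi, rule, env, grad = FALSE) {
  n <- nrow(cm)
  if (sigma2 <= 0) {
    m <- exp(lin)
    ll <- if (is.null(phi))
      sum(cm * lin - m - lgamma(cm + 1))
    else
      sum(stats::dnbinom(cm, size = 1 / phi, mu = m, log = TRUE))
    if (grad) {
      k <- if (is.null(phi)) NULL else 1 / phi
      d1 <- if (is.null(k)) cm - m else k * (cm - m) / (m + k)
      gp <- if (is.null(k)) NA_real_ else {
        -k * sum(digamma(cm + k) - digamma(k) + log(k) + 1 -
                   log(k + m) - (cm + k) / (k + m))
      }
      attr(ll, "gradient") <- c(beta0 = sum(d1), beta1 = sum(d1[, 2L]),
                                logsigma2 = 0, logphi = gp)
    }
    return(ll)
  }
  b <- env$b
  if (is.null(b) || length(b) != n) b <- numeric(n)
  k <- if (is.null(phi)) NULL else 1 / phi
  for (iter in 1:40) {
    m <- exp(lin + b)
    if (is.null(k)) {
      g <- (cm[, 1L] - m[, 1L]) + (cm[, 2L] - m[, 2L]) - b / sigma2
      h <- -(m[, 1L] + m[, 2L]) - 1 / sigma2
    } else {
      g <- k * ((cm[, 1L] - m[, 1L]) / (m[, 1L] + k) +
                (cm[, 2L] - m[, 2L]) / (m[, 2L] + k)) - b / sigma2
      h <- -k * (m[, 1L] * (cm[, 1L] + k) / (m[, 1L] + k)^2 +
                 m[, 2L] * (cm[, 2L] + k) / (m[, 2L] + k)^2) - 1 / sigma2
    }
    step <- g / h
    step[step > 5] <- 5; step[step < -5] <- -5
    b <- b - step
    if (max(abs(step)) < 1e-9) break
  }
  env$b <- b
  curv <- -h
  if (any(!is.finite(curv) | curv <= 0)) return(NA_real_)
  s <- sqrt(2 / curv)
  bmat <- b + tcrossprod(s, rule$x)        # n x K
  eta1 <- lin[, 1L] + bmat
  eta2 <- lin[, 2L] + bmat
  if (is.null(k)) {
    lf <- cm[, 1L] * eta1 - exp(eta1) + cm[, 2L] * eta2 - exp(eta2)
    const <- -sum(lgamma(cm + 1))
  } else {
    # NB logpmf split so lgamma terms (node-independent) are evaluated once
    lf <- cm[, 1L] * eta1 - (cm[, 1L] + k) * log(k + exp(eta1)) +
          cm[, 2L] * eta2 - (cm[, 2L] + k) * log(k + exp(eta2))
    const <- sum(lgamma(cm + k) - lgamma(k) - lgamma(cm + 1)) +
      2 * n * k * log(k)
  }
  a <- lf - bmat^2 / (2 * sigma2) +
    rep(log(rule$w) + rule$x^2, each = n)
  amax <- a[cbind(seq_len(n), max.col(a, ties.method = "first"))]
  ew <- exp(a - amax)
  rs <- rowSums(ew)
  ll <- sum(log(s) + amax + log(rs)) +
    n * (-0.5 * log(2 * pi * sigma2)) + const
  if (!grad) return(ll)

  # Gradient of the quadrature log-likelihood at frozen mode and scale: the
  # posterior-weighted complete-data score. The mode/scale dependence drops
  # out by integration by parts, up to quadrature error.
  p <- ew / rs
  m1 <- exp(eta1); m2 <- exp(eta2)
  if (is.null(k)) {
    d11 <- cm[, 1L] - m1
    d12 <- cm[, 2L] - m2
    g_phi <- NULL
  } else {
    d11 <- k * (cm[, 1L] - m1) / (m1 + k)
    d12 <- k * (cm[, 2L] - m2) / (m2 + k)
    A <- digamma(cm[, 1L] + k) + digamma(cm[, 2L] + k) - 2 * digamma(k) +
      2 * (log(k) + 1)
    nodedep <- -log(k + m1) - (cm[, 1L] + k) / (k + m1) -
      log(k + m2) - (cm[, 2L] + k) / (k + m2)
    g_phi <- -k * (sum(A) + sum(p * nodedep))
  }
  g_b0 <- sum(p * (d11 + d12))
  g_b1 <- sum(p * d12)
  g_ls2 <- sum(p * (bmat^2 / (2 * sigma2) - 0.5))
  attr(ll, "gradient") <- c(beta0 = g_b0, beta1 = g_b1, logsigma2 = g_ls2,
                            logphi = if (!is.null(g_phi)) g_phi else NA_real_)
  ll
}

# TRUE when the data are one record per subject per condition
is_balanced_paired <- function(data) {
  n_subj <- max(data$subject)
  nrow(data) == 2L * n_subj &&
    all(rowsum_vec(1 - data$condition, data$subject, n_subj) == 1) &&
    all(rowsum_vec(data$condition, data$subject, n_subj) == 1)
}

# Reshape long data into the n_subj x 2 count and offset matrices used by
# the fast path; column 1 = baseline condition, column 2 = treated.
paired_matrices <- function(data) {
  n_subj <- max(data$subject)
  cm <- matrix(0, n_subj, 2L)
  om <- matrix(0, n_subj, 2L)
  j <- data$condition + 1L
  cm[cbind(data$subject, j)] <- data$count
  om[cbind(data$subject, j)] <- data$offset
  list(cm = cm, om = om)
}

#' Simulate counts from a random-intercept count GLMM
#'
#' Draws one random intercept per subject and one count per
#' (subject, condition) cell of the paired design.
#'
#' @param spec A [glmm_spec()].
#' @param n_subjects Number of subjects.
#' @param seed Optional integer seed.
#' @return A [long_counts()] object with 2 records per subject.
#' @export
glmm_simulate <- function(spec, n_subjects, seed = NULL) {
  stopifnot(inherits(spec, "glmm_spec"))
  if (n_subjects < 1L) stop("'n_subjects' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  b <- stats::rnorm(n_subjects, 0, sqrt(spec$sigma2))
  subject <- rep(seq_len(n_subjects), 2L)
  condition <- rep(c(0, 1), each = n_subjects)
  mean_ij <- exp(spec$beta0 + spec$beta1 * condition + b[subject])
  count <- if (is.null(spec$phi)) {
    stats::rpois(2L * n_subjects, mean_ij)
  } else {
    stats::rnbinom(2L * n_subjects, size = 1 / spec$phi, mu = mean_ij)
  }
  long_counts(subject, condition, count)
}

# GLM warm start (sigma2 = 0 fixed-effects fit)
glmm_start <- function(data, family) {
  mx <- mean(data$count[data$condition == 0] * exp(-data$offset[data$condition == 0]))
  my <- mean(data$count[data$condition == 1] * exp(-data$offset[data$condition == 1]))
  beta0 <- log(max(mx, 0.25))
  beta1 <- log(max(my, 0.25)) - beta0
  phi0 <- NULL
  if (family == "negative_binomial") {
    mu_hat <- exp(beta0 + beta1 * data$condition + data$offset)
    z <- (data$count - mu_hat)^2 - mu_hat
    phi0 <- max(0.01, sum(z) / sum(mu_hat^2))
  }
  list(beta0 = beta0, beta1 = beta1, sigma2 = 0.25, phi = phi0)
}

#' Fit the random-intercept count GLMM by maximum likelihood
#'
#' Maximizes the adaptive-quadrature marginal likelihood over
#' (beta0, beta1, log sigma2) for the Poisson family, plus log phi for the
#' negative binomial family; `beta1_fixed` pins the condition effect for the
#' null fit. The variance is searched on the log scale with a floor at 1e-10,
#' which is treated as the sigma2 = 0 boundary and flagged.
#'
#' @param data A [long_counts()] or [paired_counts()] object.
#' @param family `"poisson"` or `"negative_binomial"`.
#' @param beta1_fixed Optional value at which to fix the condition effect.
#' @param n_nodes Quadrature nodes (default 25).
#' @param start Optional named list of starting values
#'   (`beta0`, `beta1`, `sigma2`, `phi`).
#' @return An object of class `"glmm_fit"` with fields `spec` (fitted
#'   [glmm_spec()]), `loglik`, `converged`, `n_evals`, `boundary_flag`,
#'   `beta1_fixed`, `family`.
#' @export
glmm_fit <- function(data, family = c("poisson", "negative_binomial"),
                     beta1_fixed = NULL, n_nodes = 25L, start = NULL) {
  family <- match.arg(family)
  if (inherits(data, "paired_counts")) data <- paired_to_long(data)
  stopifnot(inherits(data, "long_counts"))
  if (max(data$subject) < 2L)
    stop("at least 2 subjects are required to identify sigma2", call. = FALSE)
  if (sum(data$count) == 0)
    stop("all counts are zero: GLMM parameters are not identifiable",
         call. = FALSE)
  count <- data$count; condition <- data$condition
  offset <- data$offset; subject <- data$subject

  s0 <- glmm_start(data, family)
  if (!is.null(start)) s0[names(start)] <- start
  nb <- family == "negative_binomial"
  lfloor <- log(.SIGMA2_FLOOR)
  b <- .BNB_LOG_BOUND

  # theta layout: beta0, [beta1], log sigma2, [log phi]
  free_b1 <- is.null(beta1_fixed)
  theta0 <- c(s0$beta0,
              if (free_b1) s0$beta1,
              log(max(s0$sigma2, 1e-4)),
              if (nb) log(max(s0$phi, 0.01)))
  unpack <- function(th) {
    i <- 1L
    beta0 <- th[i]; i <- i + 1L
    beta1 <- if (free_b1) { v <- th[i]; i <- i + 1L; v } else beta1_fixed
    ls2 <- th[i]; i <- i + 1L
    phi <- if (nb) exp(th[i]) else NULL
    sigma2 <- if (ls2 <= lfloor + 1e-9) 0 else exp(ls2)
    list(beta0 = beta0, beta1 = beta1, sigma2 = sigma2, phi = phi)
  }
  fast <- is_balanced_paired(data)
  cache <- new.env(parent = emptyenv())
  if (fast) {
    pm <- paired_matrices(data)
    rule <- gh_rule(n_nodes)
    menv <- new.env(parent = emptyenv())
    # objective and gradient share one evaluation; gradient in theta layout
    # via chain rule (d/dlogsigma2 already, NB d/dlogphi already)
    evalboth <- function(th) {
      if (!is.null(cache$th) && identical(th, cache$th)) return()
      p <- unpack(th)
      lin <- cbind(p$beta0 + pm$om[, 1L],
                   p$beta0 + p$beta1 + pm$om[, 2L])
      ll <- glmm_ll_paired(pm$cm, lin, p$sigma2, p$phi, rule, menv,
                           grad = TRUE)
      cache$th <- th
      if (!is.finite(ll)) {
        cache$f <- 1e10
        cache$g <- rep(0, length(th))
        return()
      }
      g <- attr(ll, "gradient")
      cache$f <- -as.numeric(ll)
      cache$g <- -c(g[["beta0"]],
                    if (free_b1) g[["beta1"]],
                    g[["logsigma2"]],
                    if (nb) g[["logphi"]])
    }
    negll <- function(th) { evalboth(th); cache$f }
    gradfn <- function(th) { evalboth(th); cache$g }
  } else {
    negll <- function(th) {
      p <- unpack(th)
      ll <- tryCatch(
        glmm_loglik_raw(count, condition, offset, subject,
                        p$beta0, p$beta1, p$sigma2, p$phi, n_nodes),
        error = function(e) NA_real_)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    gradfn <- NULL
  }
  # NB dispersion shares the BNB cap: below phi ~ 3e-7 the conditional
  # family is numerically Poisson and its log-likelihood terms cancel
  lo <- c(-b, if (free_b1) -b, lfloor, if (nb) .BNB_LOGPHI_MIN)
  hi <- c(b, if (free_b1) b, 10, if (nb) b)
  opt <- stats::nlminb(theta0, negll, gradient = gradfn,
                       lower = lo, upper = hi,
                       control = list(rel.tol = 1e-9, iter.max = 200,
                                      eval.max = 600))
  p <- unpack(opt$par)
  at_bound <- opt$par <= lo + 1e-7 | opt$par >= hi - 1e-7
  # a variance collapsing to numerically-zero counts as a boundary fit even
  # when the optimizer stalls above the hard floor
  i_ls2 <- if (free_b1) 3L else 2L
  if (p$sigma2 <= 1e-8) at_bound[i_ls2] <- TRUE
  structure(list(spec = glmm_spec(p$beta0, p$beta1, p$sigma2, p$phi),
                 loglik = -opt$objective,
                 converged = opt$convergence == 0L ||
                   grepl("convergence", opt$message),
                 n_evals = unname(opt$evaluations[1L]),
                 boundary_flag = any(at_bound),
                 beta1_fixed = beta1_fixed,
                 family = family,
                 par = opt$par,
                 message = opt$message),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf(
    "%s GLMM fit%s: beta0 = %.4g, beta1 = %.4g, sigma2 = %.4g%s, loglik = %.4f%s%s\n",
    if (x$family == "poisson") "Poisson" else "NB",
    if (!is.null(x$beta1_fixed)) sprintf(" (beta1 fixed at %g)", x$beta1_fixed)
    else "",
    x$spec$beta0, x$spec$beta1, x$spec$sigma2,
    if (!is.null(x$spec$phi)) sprintf(", phi = %.4g", x$spec$phi) else "",
    x$loglik,
    if (!x$converged) " [NOT CONVERGED]" else "",
    if (x$boundary_flag) " [boundary]" else ""))
  invisible(x)
}

#' Likelihood ratio test of the condition effect in the GLMM
#'
#' Tests H0: beta1 = `beta1_null` by 2 * (loglik(full) - loglik(null)).
#' Under the Poisson family the null model is strictly nested and negative
#' values beyond -1e-6 are treated as optimizer failures (small negatives are
#' clamped to zero). Under the negative binomial family negative statistics
#' do occur — the null and full fits can settle on different random-effect /
#' dispersion trade-offs — and are returned as-is with a `"negative"`
#' attribute, so that empirical critical values reflect the test's actual
#' conservative behavior.
#'
#' @param data A [long_counts()] or [paired_counts()] object.
#' @param family `"poisson"` or `"negative_binomial"`.
#' @param beta1_null Null value of the condition effect (default 0).
#' @param n_nodes Quadrature nodes.
#' @return The LRT statistic (scalar).
#' @export
glmm_lrt <- function(data, family = c("poisson", "negative_binomial"),
                     beta1_null = 0, n_nodes = 25L) {
  family <- match.arg(family)
  if (inherits(data, "paired_counts")) data <- paired_to_long(data)
  null <- glmm_fit(data, family, beta1_fixed = beta1_null, n_nodes = n_nodes)
  # Poisson: warm-start the full fit from the null solution (strict nesting);
  # NB: independent GLM warm starts, preserving occasional negative LRTs
  full <- if (family == "poisson" && null$converged) {
    glmm_fit(data, family, n_nodes = n_nodes,
             start = list(beta0 = null$spec$beta0, beta1 = beta1_null,
                          sigma2 = max(null$spec$sigma2, 1e-8)))
  } else {
    glmm_fit(data, family, n_nodes = n_nodes)
  }
  if (!null$converged || !full$converged)
    stop("GLMM fit did not converge; LRT unavailable", call. = FALSE)
  if (family == "poisson" && full$loglik < null$loglik) {
    # restart the full fit from the null solution: the full model nests it
    restart <- glmm_fit(data, family, n_nodes = n_nodes,
                        start = list(beta0 = null$spec$beta0,
                                     beta1 = beta1_null,
                                     sigma2 = max(null$spec$sigma2, 1e-8)))
    if (restart$loglik > full$loglik) full <- restart
  }
  stat <- 2 * (full$loglik - null$loglik)
  if (family == "poisson") {
    if (stat < -1e-6)
      stop(sprintf("negative Poisson-LMM LRT (%.3g): optimizer failure",
                   stat), call. = FALSE)
    stat <- max(stat, 0)
  } else if (stat < 0) {
    attr(stat, "negative") <- TRUE
  }
  stat
}

#' Wald statistic for the GLMM condition effect (diagnostics only)
#'
#' Computes (beta1_hat - beta1_null)^2 / var_hat(beta1_hat) with the variance
#' from the inverse finite-difference observed information at the full MLE.
#' GLMM Wald statistics are numerically unstable in this design and are not
#' offered as power-analysis tests; the function exists to let users examine
#' that instability (e.g. on QQ plots) and must be opted into.
#'
#' @inheritParams glmm_lrt
#' @param diagnostics Must be set to `TRUE` to acknowledge that this
#'   statistic is unsuitable for inference here.
#' @return The Wald statistic (scalar).
#' @export
glmm_wald <- function(data, family = c("poisson", "negative_binomial"),
                      beta1_null = 0, n_nodes = 25L, diagnostics = FALSE) {
  if (!isTRUE(diagnostics))
    stop("GLMM Wald statistics are unstable in this design; ",
         "pass diagnostics = TRUE to compute them anyway", call. = FALSE)
  family <- match.arg(family)
  if (inherits(data, "paired_counts")) data <- paired_to_long(data)
  full <- glmm_fit(data, family, n_nodes = n_nodes)
  if (!full$converged)
    stop("GLMM fit did not converge; Wald statistic unavailable",
         call. = FALSE)
  count <- data$count; condition <- data$condition
  offset <- data$offset; subject <- data$subject
  nb <- family == "negative_binomial"
  lfloor <- log(.SIGMA2_FLOOR)
  negll <- function(th) {
    sigma2 <- if (th[3L] <= lfloor + 1e-9) 0 else exp(th[3L])
    -glmm_loglik_raw(count, condition, offset, subject,
                     th[1L], th[2L], sigma2, if (nb) exp(th[4L]) else NULL,
                     n_nodes)
  }
  H <- stats::optimHess(full$par, negll,
                        control = list(ndeps = rep(1e-4, length(full$par))))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || !is.finite(V[2L, 2L]) || V[2L, 2L] <= 0)
    stop("observed information singular; GLMM Wald unavailable", call. = FALSE)
  (full$spec$beta1 - beta1_null)^2 / V[2L, 2L]
}
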