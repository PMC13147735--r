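# Ridge-penalized multinomial logistic regression over binary symptom
# predictors. Deterministic Newton fit from zero initialization; the
# likelihood is aggregated over distinct predictor patterns (binary inputs
# give at most 2^p of them), which makes repeated refits cheap.

#' Multinomial model specification
#'
#' @param variables ordered character vector of symptom_ids used as 0/1
#'   predictors; non-empty, unique.
#' @param reference_class group whose logit is fixed at 0 (default
#'   `non_case`). Reference coding changes coefficients, never predicted
#'   probabilities.
#' @param ridge_penalty non-negative L2 penalty on slopes only (intercepts
#'   unpenalized). The default 1e-2 keeps coefficients finite under the
#'   quasi-complete separation the study cohort exhibits (e.g. splenomegaly
#'   in 0.4% of non-cases).
#' @param max_iterations,tolerance Newton iteration cap and gradient
#'   max-norm convergence tolerance.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(variables, reference_class = "non_case",
                       ridge_penalty = 1e-2, max_iterations = 100L,
                       tolerance = 1e-8) {
  stopifnot(length(variables) >= 0, !anyDuplicated(variables),
            reference_class %in% .groups, ridge_penalty >= 0,
            max_iterations >= 1, tolerance > 0)
  structure(list(variables = as.character(variables),
                 reference_class = reference_class,
                 ridge_penalty = ridge_penalty,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "model_spec")
}

# Row-wise maximum of a matrix against 0, via column pmax (fast for the
# small pattern matrices the solver sees).
.rowmax0 <- function(M) {
  out <- rep(0, nrow(M))
  for (j in seq_len(ncol(M))) out <- pmax(out, M[, j])
  out
}

# Newton solver on pattern-aggregated data.
# X: r x p design (intercept first column) over distinct patterns;
# N: r x K class-count matrix (reference class = column K).
# Maximizes sum_rk N[r,k] log P_k(x_r) - lambda/2 ||slopes||^2.
.multinom_newton <- function(X, N, lambda, tol = 1e-8, maxit = 100L) {
  r <- nrow(X); p <- ncol(X); K <- ncol(N); Km <- K - 1L
  tot <- rowSums(N)
  B <- matrix(0, p, Km)
  pen_mask <- rep(c(0, rep(1, p - 1L)), Km)   # intercept unpenalized
  pll <- function(B) {
    eta <- X %*% B
    m <- .rowmax0(eta)
    logd <- m + log(exp(-m) + rowSums(exp(eta - m)))
    sum(N[, seq_len(Km), drop = FALSE] * eta) - sum(tot * logd) -
      lambda / 2 * sum(B[-1, ]^2)
  }
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  f0 <- pll(B)
  for (iter in seq_len(maxit)) {
    eta <- X %*% B
    m <- .rowmax0(eta)
    logd <- m + log(exp(-m) + rowSums(exp(eta - m)))
    P <- exp(eta - logd)                      # r x Km
    G <- crossprod(X, N[, seq_len(Km), drop = FALSE] - tot * P) -
      lambda * rbind(0, B[-1, , drop = FALSE])
    g <- as.vector(G)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- matrix(0, p * Km, p * Km)
    for (k in seq_len(Km)) for (l in k:Km) {
      w <- tot * P[, k] * ((k == l) - P[, l])
      blk <- crossprod(X, X * w)
      ri <- (k - 1L) * p + seq_len(p); ci <- (l - 1L) * p + seq_len(p)
      H[ri, ci] <- blk
      if (l > k) H[ci, ri] <- t(blk)
    }
    diag(H) <- diag(H) + lambda * pen_mask + 1e-10
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    alpha <- 1
    for (h in 1:30) {
      Bn <- B + alpha * matrix(step, p, Km)
      fn <- pll(Bn)
      if (is.finite(fn) && fn >= f0 - 1e-12) break
      alpha <- alpha / 2
    }
    B <- Bn; f0 <- fn
    ll_trace <- c(ll_trace, fn)
  }
  list(B = B, penalized_loglik = f0,
       loglik = f0 + lambda / 2 * sum(B[-1, ]^2),
       trace = ll_trace, converged = converged, iterations = iter)
}

# Aggregate a 0/1 design matrix + class labels into distinct patterns with
# class counts. y: integer codes 1..K.
.aggregate_patterns <- function(V, y, K) {
  p <- ncol(V)
  id <- if (p == 0) rep(0, length(y)) else as.vector(V %*% 2^(seq_len(p) - 1))
  uid <- sort(unique(id))
  ridx <- match(id, uid)
  N <- matrix(0, length(uid), K)
  idx <- (y - 1L) * length(uid) + ridx
  cnt <- tabulate(idx, nbins = length(uid) * K)
  N[] <- cnt
  Xu <- if (p == 0) matrix(1, length(uid), 1)
        else cbind(1, V[match(uid, id), , drop = FALSE])
  list(X = Xu, N = N)
}

# Collapse an already-aggregated pattern set onto a column subset:
# Vfull r x p distinct 0/1 patterns with count matrix N; returns the
# distinct sub-patterns over columns `s` (intercept prepended) with summed
# counts. Equivalent to re-aggregating the raw rows, but O(r).
.collapse_patterns <- function(Vfull, N, s) {
  Vs <- Vfull[, s, drop = FALSE]
  id <- as.vector(Vs %*% 2^(seq_along(s) - 1))
  Ns <- rowsum(N, id)                         # rows ordered by unique id
  uid <- as.numeric(rownames(Ns))
  Xu <- matrix(1, length(uid), length(s) + 1L)
  for (j in seq_along(s)) Xu[, j + 1L] <- (uid %/% 2^(j - 1)) %% 2
  list(X = Xu, N = Ns)
}

#' Fit a multinomial risk model to a cohort
#'
#' Maximizes the multinomial log-likelihood minus
#' `ridge_penalty/2 * ||slopes||^2` by Newton iteration with step-halving
#' from a zero start; the objective is strictly concave for positive
#' penalty, so the fit is deterministic. Patients with an `unknown` entry
#' in any model variable are excluded (complete-case; the count is kept on
#' the fit).
#'
#' @param x an `asmd_cohort` containing at least two groups.
#' @param spec a [model_spec()].
#' @return An object of class `asmd_multinom` with `print`, `summary`,
#'   `coef`, `predict`, `logLik` and `simulate` methods. `coef` returns the
#'   (K-1) x (1 + p) matrix of reference-coded coefficients.
#' @export
fit_multinomial <- function(x, spec) {
  stopifnot(inherits(x, "asmd_cohort"), inherits(spec, "model_spec"))
  bad <- setdiff(spec$variables, x$catalog$symptom_id)
  if (length(bad)) stop("variables not in catalog: ", paste(bad, collapse = ", "))
  d <- x$data
  V <- as.matrix(d[, spec$variables, drop = FALSE])
  keep <- if (length(spec$variables)) stats::complete.cases(V) else rep(TRUE, nrow(d))
  n_excluded <- sum(!keep)
  d <- d[keep, , drop = FALSE]; V <- V[keep, , drop = FALSE]
  classes_present <- .groups[.groups %in% unique(d$group)]
  if (length(classes_present) < 2) stop("cohort must contain at least two groups")
  # reference class last
  ref <- if (spec$reference_class %in% classes_present) spec$reference_class
         else classes_present[length(classes_present)]
  classes <- c(setdiff(classes_present, ref), ref)
  y <- match(d$group, classes)
  agg <- .aggregate_patterns(V, y, length(classes))
  fit <- .multinom_newton(agg$X, agg$N, spec$ridge_penalty,
                          tol = spec$tolerance, maxit = spec$max_iterations)
  if (!fit$converged)
    warning("Newton iteration did not converge in ", spec$max_iterations,
            " iterations; partial fit returned")
  coefs <- t(fit$B)
  dimnames(coefs) <- list(classes[-length(classes)],
                          c("(intercept)", spec$variables))
  structure(list(spec = spec, classes = classes, reference_class = ref,
                 coefficients = coefs, converged = fit$converged,
                 iterations = fit$iterations,
                 train_log_likelihood = fit$loglik,
                 loglik_trace = fit$trace,
                 n_used = nrow(d), n_excluded = n_excluded),
            class = "asmd_multinom")
}

# Class probabilities for a 0/1 matrix over the model variables
# (columns in spec order). Returns n x K matrix in `object$classes` order.
.proba_matrix <- function(object, V) {
  B <- t(object$coefficients)                 # (1+p) x (K-1)
  eta <- cbind(1, V) %*% B
  m <- pmax(0, apply(eta, 1, max))
  d <- exp(-m) + rowSums(exp(eta - m))
  P <- cbind(exp(eta - m), exp(-m)) / d
  colnames(P) <- object$classes
  P
}

#' Predicted class probabilities for one symptom pattern
#'
#' @param object an `asmd_multinom` fit.
#' @param pattern named vector/list giving 0 or 1 for every model variable.
#' @return Named probability vector over the groups present in the fit
#'   (ordered case, control, non_case), summing to 1.
#' @export
predict_proba <- function(object, pattern) {
  stopifnot(inherits(object, "asmd_multinom"))
  pattern <- unlist(pattern)
  miss <- setdiff(object$spec$variables, names(pattern))
  if (length(miss)) stop("pattern lacks variable(s): ", paste(miss, collapse = ", "))
  v <- pattern[object$spec$variables]
  if (!all(v %in% c(0, 1))) stop("pattern values must be 0 or 1")
  p <- .proba_matrix(object, matrix(as.numeric(v), 1))[1, ]
  p[order(match(names(p), .groups))]
}

#' @export
predict.asmd_multinom <- function(object, newdata, type = c("probs", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "asmd_cohort")) newdata <- newdata$data
  V <- as.matrix(as.data.frame(newdata)[, object$spec$variables, drop = FALSE])
  if (!all(is.na(V) | V %in% c(0, 1))) stop("predictors must be coded 0/1")
  P <- matrix(NA_real_, nrow(V), length(object$classes),
              dimnames = list(NULL, object$classes))
  ok <- stats::complete.cases(V)
  if (any(ok)) P[ok, ] <- .proba_matrix(object, V[ok, , drop = FALSE])
  P <- P[, order(match(colnames(P), .groups)), drop = FALSE]
  if (type == "probs") P
  else factor(colnames(P)[apply(P, 1, which.max)], levels = .groups)
}

#' @export
coef.asmd_multinom <- function(object, ...) object$coefficients

#' @export
logLik.asmd_multinom <- function(object, ...) {
  structure(object$train_log_likelihood,
            df = length(object$coefficients), class = "logLik")
}

#' @export
print.asmd_multinom <- function(x, ...) {
  cat(sprintf("Multinomial risk model: %d variable(s), reference class '%s'\n",
              length(x$spec$variables), x$reference_class))
  cat(sprintf("  n = %d (%d excluded as unknown), ridge = %g, %sconverged in %d iteration(s)\n",
              x$n_used, x$n_excluded, x$spec$ridge_penalty,
              if (x$converged) "" else "NOT ", x$iterations))
  cat(sprintf("  train log-likelihood: %.3f\n", x$train_log_likelihood))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.asmd_multinom <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Simulate group labels from a fitted multinomial model
#'
#' Draws class labels for the supplied symptom patterns from the model's
#' predicted probabilities.
#'
#' @param object an `asmd_multinom` fit.
#' @param nsim number of simulated label vectors.
#' @param seed optional integer seed.
#' @param newdata data.frame of 0/1 values for the model variables.
#' @return data.frame with `nsim` columns of group labels.
#' @export
simulate.asmd_multinom <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- predict(object, newdata)
  out <- replicate(nsim, apply(P, 1, function(p) sample(colnames(P), 1, prob = p)))
  as.data.frame(out, stringsAsFactors = FALSE)
}

.model_schema <- "asmdsit-multinomial/1"

#' Save / load a fitted multinomial model as JSON
#'
#' Serialization keeps full double precision; `load_model(save_model(m))`
#' reproduces `m`'s predictions bit-for-bit. Files carry a schema-version
#' tag; mismatching or truncated files are rejected.
#'
#' @param object an `asmd_multinom`.
#' @param path file path.
#' @name model_io
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   reconstructed `asmd_multinom`.
NULL

#' @rdname model_io
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "asmd_multinom"))
  x <- list(schema_version = .model_schema,
            variables = object$spec$variables,
            reference_class = object$reference_class,
            classes = object$classes,
            coefficients = apply(object$coefficients, 1, identity, simplify = FALSE),
            ridge_penalty = object$spec$ridge_penalty,
            max_iterations = object$spec$max_iterations,
            tolerance = object$spec$tolerance,
            converged = object$converged,
            iterations = object$iterations,
            train_log_likelihood = object$train_log_likelihood,
            n_used = object$n_used, n_excluded = object$n_excluded)
  # I(17) significant digits round-trips doubles exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname model_io
#' @export
load_model <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("unreadable model file: ", conditionMessage(e)))
  if (!identical(x$schema_version, .model_schema))
    stop("model schema mismatch: expected '", .model_schema, "', got '",
         x$schema_version, "'")
  need <- c("variables", "reference_class", "classes", "coefficients", "ridge_penalty")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("model file lacks field(s): ", paste(miss, collapse = ", "))
  coefs <- do.call(rbind, x$coefficients)
  dimnames(coefs) <- list(x$classes[-length(x$classes)],
                          c("(intercept)", x$variables))
  spec <- model_spec(x$variables, reference_class = x$reference_class,
                     ridge_penalty = x$ridge_penalty,
                     max_iterations = x$max_iterations %||% 100L,
                     tolerance = x$tolerance %||% 1e-8)
  structure(list(spec = spec, classes = x$classes,
                 reference_class = x$reference_class, coefficients = coefs,
                 converged = isTRUE(x$converged),
                 iterations = x$iterations %||% NA_integer_,
                 train_log_likelihood = x$train_log_likelihood %||% NA_real_,
                 loglik_trace = numeric(0),
                 n_used = x$n_used %||% NA_integer_,
                 n_excluded = x$n_excluded %||% NA_integer_),
            class = "asmd_multinom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
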