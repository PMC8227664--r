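# Observed-variable path analysis by maximum likelihood.
#
# A model is a set of linear regressions among measured columns ("y ~ x1 +
# x2") plus optional covariances ("a ~~ b"). The implied covariance is
# Sigma(theta) = (I - B)^-1 Psi (I - B)^-T with B the directed-coefficient
# matrix (acyclic) and Psi the residual (co)variance matrix. The ML
# discrepancy F = log|Sigma| - log|S| + tr(S Sigma^-1) - p is minimized by
# quasi-Newton from equation-wise OLS starts; chi2 = (n - 1) * F_min.

#' Parse a path-model specification
#'
#' Plain-text syntax, one statement per line or semicolon-separated:
#' `y ~ x1 + x2` declares directed paths, `a ~~ b` a covariance. Variables
#' are auto-registered; every variable gets a free (residual) variance, and
#' covariances among exogenous variables are added automatically (as in the
#' usual SEM convention). The directed part must be acyclic.
#'
#' @param text model specification
#' @return object of class `path_model`: `variables`, `paths` (from, to),
#'   `covariances` (a, b), `exogenous`
#' @export
parse_model <- function(text) {
  if (!nzchar(trimws(text))) stop("empty model specification")
  stmts <- unlist(strsplit(text, "[;\n]"))
  stmts <- trimws(sub("#.*$", "", stmts))
  stmts <- stmts[nzchar(stmts)]
  paths <- list(); covs <- list()
  for (i in seq_along(stmts)) {
    s <- stmts[i]
    if (grepl("~~", s)) {
      pr <- trimws(strsplit(s, "~~")[[1]])
      if (length(pr) != 2 || !all(grepl("^[A-Za-z._][A-Za-z0-9._]*$", pr))) {
        stop("parse error at line ", i, ": ", s)
      }
      covs[[length(covs) + 1]] <- sort(pr)
    } else if (grepl("~", s)) {
      pr <- trimws(strsplit(s, "~")[[1]])
      if (length(pr) != 2) stop("parse error at line ", i, ": ", s)
      lhs <- pr[1]
      rhs <- trimws(strsplit(pr[2], "\\+")[[1]])
      toks <- c(lhs, rhs)
      bad <- toks[!grepl("^[A-Za-z._][A-Za-z0-9._]*$", toks)]
      if (length(bad)) stop("parse error at line ", i, ": unknown token '",
                            bad[1], "'")
      for (x in rhs) paths[[length(paths) + 1]] <- c(from = x, to = lhs)
    } else stop("parse error at line ", i, ": ", s)
  }
  paths <- if (length(paths)) unique(do.call(rbind, lapply(paths, function(p)
    data.frame(from = p[["from"]], to = p[["to"]],
               stringsAsFactors = FALSE)))) else
    data.frame(from = character(), to = character())
  covs <- if (length(covs)) unique(do.call(rbind, lapply(covs, function(p)
    data.frame(a = p[1], b = p[2], stringsAsFactors = FALSE)))) else
    data.frame(a = character(), b = character())
  vars <- unique(c(paths$from, paths$to, covs$a, covs$b))
  # cycle check by repeated leaf-stripping; report any remaining cycle
  check_acyclic(paths, vars)
  endo <- unique(paths$to)
  exo <- setdiff(vars, endo)
  if (length(exo) > 1) {
    auto <- t(utils::combn(sort(exo), 2))
    auto <- data.frame(a = auto[, 1], b = auto[, 2], stringsAsFactors = FALSE)
    covs <- unique(rbind(covs, auto))
  }
  structure(list(variables = vars, paths = paths, covariances = covs,
                 exogenous = exo, endogenous = endo),
            class = "path_model")
}

check_acyclic <- function(paths, vars) {
  remaining <- vars
  edges <- paths
  repeat {
    sinks <- setdiff(remaining, edges$from)
    if (!length(sinks)) break
    remaining <- setdiff(remaining, sinks)
    edges <- edges[!(edges$to %in% sinks), , drop = FALSE]
    if (!nrow(edges)) return(invisible(TRUE))
  }
  if (nrow(edges)) {
    stop("cyclic directed structure involving: ",
         paste(unique(c(edges$from, edges$to)), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("path_model: %d variables, %d directed paths, %d covariances\n",
              length(x$variables), nrow(x$paths), nrow(x$covariances)))
  invisible(x)
}

model_matrices <- function(model, theta) {
  v <- model$variables
  p <- length(v)
  np <- nrow(model$paths); nc <- nrow(model$covariances)
  B <- matrix(0, p, p, dimnames = list(v, v))   # B[to, from]
  if (np) for (i in seq_len(np)) {
    B[model$paths$to[i], model$paths$from[i]] <- theta[i]
  }
  Psi <- diag(theta[np + nc + seq_len(p)], p)
  dimnames(Psi) <- list(v, v)
  if (nc) for (i in seq_len(nc)) {
    Psi[model$covariances$a[i], model$covariances$b[i]] <- theta[np + i]
    Psi[model$covariances$b[i], model$covariances$a[i]] <- theta[np + i]
  }
  list(B = B, Psi = Psi)
}

implied_sigma <- function(model, theta) {
  m <- model_matrices(model, theta)
  p <- nrow(m$B)
  inv <- solve(diag(p) - m$B)
  inv %*% m$Psi %*% t(inv)
}

fml_discrepancy <- function(S, sigma) {
  p <- nrow(S)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  log_det_sigma <- 2 * sum(log(diag(ch)))
  log_det_s <- determinant(S, logarithm = TRUE)$modulus[1]
  as.numeric(log_det_sigma - log_det_s + sum(diag(S %*% chol2inv(ch))) - p)
}

ols_start <- function(model, S) {
  v <- model$variables
  np <- nrow(model$paths); nc <- nrow(model$covariances); p <- length(v)
  theta <- numeric(np + nc + p)
  resid_var <- stats::setNames(diag(S)[v], v)
  for (y in unique(model$paths$to)) {
    xs <- model$paths$from[model$paths$to == y]
    b <- solve(S[xs, xs, drop = FALSE], S[xs, y])
    theta[which(model$paths$to == y)] <-
      b[match(model$paths$from[model$paths$to == y], xs)]
    resid_var[y] <- max(0.05 * S[y, y],
                        S[y, y] - as.numeric(t(b) %*% S[xs, xs] %*% b))
  }
  if (nc) for (i in seq_len(nc)) {
    a <- model$covariances$a[i]; b <- model$covariances$b[i]
    exo_pair <- all(c(a, b) %in% model$exogenous)
    theta[np + i] <- if (exo_pair) S[a, b] else 0
  }
  theta[np + nc + seq_len(p)] <- resid_var[v]
  theta
}

#' Fit a path model by maximum likelihood
#'
#' Variables are z-scored before fitting (so estimates are standardized
#' coefficients), the sample covariance S uses the n-1 denominator, and the
#' ML discrepancy is minimized by BFGS from equation-wise OLS start values.
#' `chi2 = (n - 1) * F_min` with `df = p(p+1)/2 - #free parameters`, tested
#' against the chi-squared distribution; AIC is reported both as
#' `chi2 - 2 df` and as `-2 logLik + 2k`. Standard errors come from the
#' inverse observed information `(n - 1)/2 * Hessian(F)`.
#'
#' @param model a [parse_model()] result
#' @param data data.frame containing every model variable (complete cases
#'   used)
#' @param standardize z-score columns first (default TRUE)
#' @return object of class `path_fit`: `parameters` (estimate, se, z, p per
#'   free parameter), `chisq`, `df`, `p`, `aic`, `aic_loglik`, `n`,
#'   `converged`, `B`, `Psi`, `sigma`
#' @export
fit_path_model <- function(model, data, standardize = TRUE) {
  stopifnot(inherits(model, "path_model"))
  miss <- setdiff(model$variables, names(data))
  if (length(miss)) stop("model variables absent from data: ",
                         paste(miss, collapse = ", "))
  dat <- data[stats::complete.cases(data[model$variables]), model$variables]
  n <- nrow(dat)
  if (standardize) dat <- as.data.frame(scale(dat))
  S <- stats::cov(dat)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
    stop("sample covariance matrix is not positive definite")
  }
  p <- length(model$variables)
  np <- nrow(model$paths); nc <- nrow(model$covariances)
  n_free <- np + nc + p
  df <- p * (p + 1) / 2 - n_free
  if (df < 0) stop("model has more free parameters than covariance moments")
  var_idx <- np + nc + seq_len(p)
  obj <- function(theta) {
    if (any(theta[var_idx] <= 1e-10)) return(1e10)
    f <- fml_discrepancy(S, implied_sigma(model, theta))
    if (is.null(f) || !is.finite(f)) 1e10 else f
  }
  theta0 <- ols_start(model, S)
  opt <- stats::optim(theta0, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  # polish with a second pass; flat regions near the optimum are common
  opt <- stats::optim(opt$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  theta <- opt$par
  grad <- numeric_grad(obj, theta)
  converged <- opt$convergence == 0 && sqrt(sum(grad^2)) < 1e-4
  fmin <- max(0, obj(theta))
  chisq <- (n - 1) * fmin
  pval <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else 1
  H <- tryCatch(stats::optimHess(theta, obj), error = function(e) NULL)
  se <- rep(NA_real_, n_free)
  if (!is.null(H)) {
    acov <- tryCatch(solve((n - 1) / 2 * H), error = function(e) NULL)
    if (!is.null(acov)) {
      dg <- diag(acov)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  labels <- c(
    if (np) paste(model$paths$to, "~", model$paths$from),
    if (nc) paste(model$covariances$a, "~~", model$covariances$b),
    paste(model$variables, "~~", model$variables))
  types <- rep(c("path", "cov", "var"), c(np, nc, p))
  z <- theta / se
  params <- data.frame(
    label = labels, type = types,
    from = c(if (np) model$paths$from, if (nc) model$covariances$a,
             model$variables),
    to = c(if (np) model$paths$to, if (nc) model$covariances$b,
           model$variables),
    estimate = theta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  sigma <- implied_sigma(model, theta)
  sml <- stats::cov(dat) * (n - 1) / n
  ll <- -n / 2 * (determinant(sigma, logarithm = TRUE)$modulus[1] +
                    sum(diag(sml %*% solve(sigma))) + p * log(2 * pi))
  m <- model_matrices(model, theta)
  structure(list(parameters = params, chisq = chisq, df = df, p = pval,
                 aic = chisq - 2 * df,
                 aic_loglik = -2 * as.numeric(ll) + 2 * n_free,
                 loglik = as.numeric(ll), n = n, converged = converged,
                 B = m$B, Psi = m$Psi, sigma = sigma, S = S, model = model,
                 fmin = fmin),
            class = "path_fit")
}

numeric_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("path_fit: chi2(%d) = %.4f, p = %.3f, AIC = %.1f, n = %d%s\n",
              x$df, x$chisq, x$p, x$aic, x$n,
              if (x$converged) "" else " [NOT CONVERGED]"))
  pp <- x$parameters[x$parameters$type == "path", ]
  if (nrow(pp)) {
    cat("paths:\n")
    for (i in seq_len(nrow(pp))) {
      cat(sprintf("  %-30s %7.3f (se %.3f, p %.3g)\n",
                  pp$label[i], pp$estimate[i], pp$se[i], pp$p[i]))
    }
  }
  invisible(x)
}

#' Iteratively prune non-significant chemistry paths
#'
#' Refits after removing, one at a time, the least significant (largest p)
#' tagged edge whose p exceeds `alpha`, until all remaining tagged edges are
#' significant. Tagged edges are the directed paths touching a chemical
#' variable (chemistry -> ecology and elevation/plant-size -> chemistry);
#' `protected` edges (the ecological backbone) are never candidates. An edge
#' whose removal would strand a variable entirely (no remaining paths or
#' covariances) is skipped and logged.
#'
#' @param model full [parse_model()] model
#' @param data data.frame
#' @param alpha pruning level (default 0.05)
#' @param chemical_vars character vector naming the chemistry columns
#' @param protected character vector of edges "to~from" never removed
#' @return list: `fit` (final [fit_path_model()]), `initial_fit`, `log`
#'   (ordered data.frame of removals), `aic_initial`, `aic_final`,
#'   `aic_decreased`
#' @export
prune_chemistry_paths <- function(model, data, alpha = 0.05,
                                  chemical_vars, protected = character()) {
  stopifnot(inherits(model, "path_model"))
  edge_id <- function(paths) paste(paths$to, "~", paths$from)
  fit0 <- fit_path_model(model, data)
  fit <- fit0
  removal_log <- list()
  repeat {
    paths <- fit$model$paths
    ids <- edge_id(paths)
    tagged <- (paths$from %in% chemical_vars | paths$to %in% chemical_vars) &
      !(ids %in% protected)
    pp <- fit$parameters[fit$parameters$type == "path", ]
    pvals <- pp$p[match(ids, pp$label)]
    cand <- which(tagged & pvals > alpha)
    if (!length(cand)) break
    drop_i <- cand[which.max(pvals[cand])]
    new_paths <- paths[-drop_i, , drop = FALSE]
    # do not strand a variable: every variable must keep at least one edge
    touched <- c(paths$from[drop_i], paths$to[drop_i])
    stranded <- vapply(touched, function(v)
      !(v %in% c(new_paths$from, new_paths$to,
                 fit$model$covariances$a, fit$model$covariances$b)),
      logical(1))
    if (any(stranded)) {
      removal_log[[length(removal_log) + 1]] <- data.frame(
        edge = ids[drop_i], p = pvals[drop_i], action = "skipped (would strand)",
        stringsAsFactors = FALSE)
      # mark as protected to avoid an infinite loop
      protected <- c(protected, ids[drop_i])
      next
    }
    removal_log[[length(removal_log) + 1]] <- data.frame(
      edge = ids[drop_i], p = pvals[drop_i], action = "removed",
      stringsAsFactors = FALSE)
    new_model <- fit$model
    new_model$paths <- new_paths
    new_model$endogenous <- unique(new_paths$to)
    new_model$exogenous <- setdiff(new_model$variables, new_model$endogenous)
    fit <- fit_path_model(new_model, data)
  }
  log_df <- if (length(removal_log)) do.call(rbind, removal_log) else
    data.frame(edge = character(), p = numeric(), action = character())
  list(fit = fit, initial_fit = fit0, log = log_df,
       aic_initial = fit0$aic, aic_final = fit$aic,
       aic_decreased = fit$aic <= fit0$aic)
}

#' Direct, indirect, and total effect decomposition
#'
#' With B the directed-coefficient matrix, total effects are
#' `(I - B)^-1 - I` (the sum of coefficient products over all directed
#' routes), direct effects are B, and indirect = total - direct. Requires the
#' effect series to converge (spectral radius of B below 1).
#'
#' @param fit a converged [fit_path_model()]
#' @return data.frame of class `effect_table`: source, target, direct,
#'   indirect, total (rows where any effect is nonzero)
#' @export
effects_decomposition <- function(fit) {
  stopifnot(inherits(fit, "path_fit"))
  B <- fit$B
  if (max(abs(eigen(B, only.values = TRUE)$values)) >= 1) {
    stop("effect series does not converge: spectral radius of B >= 1")
  }
  p <- nrow(B)
  total <- solve(diag(p) - B) - diag(p)
  indirect <- total - B
  v <- rownames(B)
  rows <- list()
  for (src in v) for (tgt in v) {
    if (abs(total[tgt, src]) > 1e-12 || abs(B[tgt, src]) > 1e-12) {
      rows[[length(rows) + 1]] <- data.frame(
        source = src, target = tgt, direct = B[tgt, src],
        indirect = indirect[tgt, src], total = total[tgt, src],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), target = character(), direct = numeric(),
               indirect = numeric(), total = numeric())
  class(out) <- c("effect_table", "data.frame")
  out
}
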