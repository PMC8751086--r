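# Penalized Poisson fitting of cause-specific piece-wise exponential
# additive hazard models on PED rows. The penalized log-likelihood
#   sum_i [ delta_i * eta_i - exp(eta_i + offset_i) ] - 1/2 sum_j lambda_j b' S_j b
# is maximized by iteratively reweighted least squares; smoothing parameters
# are selected by Fellner-Schall (Laplace-approximate REML) updates, or held
# fixed for exact reproducibility. The ICU random intercept is a
# ridge-penalized indicator block (lambda = 1/sigma^2).

#' Model specification for a cause-specific hazard fit
#'
#' @param cause `"death"` or `"discharge"` (the PED indicator column the
#'   model treats as the event; the competing cause is censoring).
#' @param baseline `"ps"` (penalized cubic spline of interval midpoint,
#'   plus intercept) or `"factor"` (one unpenalized dummy per interval; the
#'   saturated piece-wise exponential baseline used by oracle checks).
#' @param baseline_k Basis size of the baseline P-spline.
#' @param smooth_confounders Continuous confounders modelled as centered
#'   P-splines; any subset of `apache2`, `age`, `bmi` (or other numeric
#'   PED columns).
#' @param smooth_k Basis size per confounder smooth.
#' @param factor_confounders Categorical confounders entered with treatment
#'   contrasts (reference = first factor level).
#' @param linear_confounders Numeric confounders entered linearly (the
#'   day-counts of mechanical ventilation, PN, oral feeding, propofol).
#' @param random_icu Gaussian ICU random intercept (ridge-penalized block)?
#' @param cumulative Include the cumulative protein-effect terms built by
#'   [build_cumulative_design()]?
#' @param cum_tv Time-varying cumulative coefficients? With `FALSE` (phase
#'   mode only) each phase/level cumulative covariate enters with a single
#'   constant coefficient -- the correctly specified model when per-day
#'   effects do not change over follow-up, used by recovery studies.
#' @param tvc_k Basis size of the time-varying coefficient (phase mode).
#' @param surface_k Length-2 marginal basis sizes of the (t, t_z) tensor
#'   surface (surface mode).
#' @param smoothing `"reml"` (Fellner-Schall updates) or `"fixed"`.
#' @param lambda Initial (reml) or fixed smoothing parameters; a single
#'   value or a vector recycled over penalties. `0` with
#'   `smoothing = "fixed"` gives the unpenalized fit.
#' @param max_iter Maximum IRLS iterations per inner fit.
#' @param max_outer Maximum REML updates.
#' @return Object of class `pamm_spec`.
#' @export
model_spec <- function(cause = c("death", "discharge"),
                       baseline = c("ps", "factor"),
                       baseline_k = 10,
                       smooth_confounders = c("apache2", "age", "bmi"),
                       smooth_k = 10,
                       factor_confounders = c("sex", "admission_category",
                                              "diagnosis", "year"),
                       linear_confounders = c("days_mv", "days_pn",
                                              "days_oral", "days_propofol"),
                       random_icu = TRUE,
                       cumulative = TRUE,
                       cum_tv = TRUE,
                       tvc_k = 5,
                       surface_k = c(5, 5),
                       smoothing = c("reml", "fixed"),
                       lambda = 10,
                       max_iter = 100,
                       max_outer = 30) {
  structure(list(
    cause = match.arg(cause), baseline = match.arg(baseline),
    baseline_k = baseline_k, smooth_confounders = smooth_confounders,
    smooth_k = smooth_k, factor_confounders = factor_confounders,
    linear_confounders = linear_confounders, random_icu = random_icu,
    cumulative = cumulative, cum_tv = cum_tv,
    tvc_k = tvc_k, surface_k = surface_k,
    smoothing = match.arg(smoothing), lambda = lambda,
    max_iter = max_iter, max_outer = max_outer
  ), class = "pamm_spec")
}

# ---------------------------------------------------------------------------
# Design construction. `info = NULL` builds from the fit data and records
# everything needed to rebuild rows for new data (knots, constraint bases,
# factor levels, covariate medians).

build_pamm_design <- function(data, spec, grid, basis_mode,
                              info = NULL, exclude_random = FALSE) {
  building <- is.null(info)
  if (building) {
    info <- list(terms = list(), basis_mode = basis_mode,
                 profile = list())
  }
  terms <- info$terms
  Xs <- list()
  n <- nrow(data)
  tr <- c(grid$cuts[1], grid$cuts[length(grid$cuts)])

  add <- function(tm, X) {
    colnames(X) <- paste0(tm$label, seq_len(ncol(X)))
    if (building) terms[[tm$label]] <<- tm
    Xs[[tm$label]] <<- X
  }

  # baseline
  if (spec$baseline == "factor") {
    if (building) {
      tm <- list(label = "baseline_int", type = "interval_factor",
                 n_int = grid$n, penalties = list(), penalized = FALSE)
    } else tm <- info$terms$baseline_int
    X <- outer(data$interval, seq_len(tm$n_int), `==`) * 1
    add(tm, X)
  } else {
    if (building) {
      tm_i <- list(label = "intercept", type = "intercept",
                   penalties = list(), penalized = FALSE)
      kn <- ps_knots(tr, spec$baseline_k)
      B <- ps_eval(data$tmid, kn)
      Z <- constraint_null(colMeans(B))
      tm_b <- list(label = "baseline_s", type = "smooth", var = "tmid",
                   knots = kn, Z = Z,
                   penalties = list(crossprod(Z, diff_penalty(spec$baseline_k) %*% Z)),
                   penalized = TRUE)
    } else {
      tm_i <- info$terms$intercept
      tm_b <- info$terms$baseline_s
    }
    add(tm_i, matrix(1, n, 1))
    add(tm_b, ps_eval(data$tmid, tm_b$knots) %*% tm_b$Z)
  }

  # smooth confounders
  for (v in spec$smooth_confounders) {
    lab <- paste0("s_", v)
    if (building) {
      x <- data[[v]]
      rng <- range(x)
      if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
      kn <- ps_knots(rng, spec$smooth_k)
      B <- ps_eval(x, kn)
      Z <- constraint_null(colMeans(B))
      tm <- list(label = lab, type = "smooth", var = v, knots = kn, Z = Z,
                 penalties = list(crossprod(Z, diff_penalty(spec$smooth_k) %*% Z)),
                 penalized = TRUE)
      info$profile[[v]] <- stats::median(x)
    } else tm <- info$terms[[lab]]
    add(tm, ps_eval(data[[tm$var]], tm$knots) %*% tm$Z)
  }

  # categorical confounders (treatment contrasts, reference = first level)
  for (v in spec$factor_confounders) {
    lab <- paste0("f_", v)
    if (building) {
      lv <- levels(factor(data[[v]]))
      tm <- list(label = lab, type = "factor", var = v, levels = lv,
                 penalties = list(), penalized = FALSE)
      info$profile[[v]] <- lv[1]
    } else tm <- info$terms[[lab]]
    xv <- as.character(data[[tm$var]])
    if (any(!xv %in% tm$levels)) {
      stop(sprintf("unseen category level in `%s`", tm$var), call. = FALSE)
    }
    X <- outer(xv, tm$levels[-1], `==`) * 1
    add(tm, X)
  }

  # linear confounders
  for (v in spec$linear_confounders) {
    lab <- paste0("l_", v)
    if (building) {
      tm <- list(label = lab, type = "linear", var = v,
                 penalties = list(), penalized = FALSE)
      info$profile[[v]] <- stats::median(data[[v]])
    } else tm <- info$terms[[lab]]
    add(tm, matrix(as.numeric(data[[tm$var]]), ncol = 1))
  }

  # ICU random intercept (ridge block); zeroed out for hypothetical-diet
  # predictions (random effect at its mean).
  if (spec$random_icu) {
    if (building) {
      lv <- levels(factor(data$icu_id))
      tm <- list(label = "re_icu", type = "random", var = "icu_id",
                 levels = lv, penalties = list(diag(length(lv))),
                 penalized = TRUE)
    } else tm <- info$terms$re_icu
    if (exclude_random) {
      X <- matrix(0, n, length(tm$levels))
    } else {
      X <- outer(as.character(data$icu_id), tm$levels, `==`) * 1
    }
    add(tm, X)
  }

  # cumulative protein effects
  if (spec$cumulative) {
    if (basis_mode == "phase" && !isTRUE(spec$cum_tv %||% TRUE)) {
      for (v in cum_col_names("phase")) {
        lab <- paste0("cl_", v)
        if (building) {
          tm <- list(label = lab, type = "linear", var = v,
                     penalties = list(), penalized = FALSE)
        } else tm <- info$terms[[lab]]
        add(tm, matrix(as.numeric(data[[tm$var]]), ncol = 1))
      }
    } else if (basis_mode == "phase") {
      for (v in cum_col_names("phase")) {
        lab <- paste0("tv_", v)
        if (building) {
          kn <- ps_knots(tr, spec$tvc_k)
          tm <- list(label = lab, type = "tvc", var = v, knots = kn,
                     penalties = list(diff_penalty(spec$tvc_k)),
                     penalized = TRUE)
        } else tm <- info$terms[[lab]]
        add(tm, as.numeric(data[[tm$var]]) * ps_eval(data$tmid, tm$knots))
      }
    } else {
      k1 <- spec$surface_k[1]; k2 <- spec$surface_k[2]
      for (d in c("II", "III")) {
        lab <- paste0("surf_", d)
        if (building) {
          tm <- list(label = lab, type = "surface", dummy = d,
                     knots_t = ps_knots(tr, k1),
                     knots_tz = ps_knots(c(1, 11), k2),
                     k1 = k1, k2 = k2,
                     penalties = list(
                       kronecker(diff_penalty(k1), diag(k2)),
                       kronecker(diag(k1), diff_penalty(k2))),
                     penalized = TRUE)
        } else tm <- info$terms[[lab]]
        A <- as.matrix(data[, paste0("cum", tm$dummy, "_tz", 1:11)])
        Btz <- ps_eval(1:11, tm$knots_tz)
        M <- A %*% Btz                       # n x k2
        Bt <- ps_eval(data$tmid, tm$knots_t) # n x k1
        X <- matrix(0, n, tm$k1 * tm$k2)
        for (r in seq_len(tm$k1)) {
          X[, (r - 1) * tm$k2 + seq_len(tm$k2)] <- Bt[, r] * M
        }
        add(tm, X)
      }
    }
  }

  X <- do.call(cbind, Xs)
  info$terms <- terms
  # column index ranges per term
  sizes <- vapply(Xs, ncol, integer(1))
  ends <- cumsum(sizes)
  cols <- Map(function(s, e) seq.int(e - s + 1L, e), sizes, ends)
  list(X = X, info = info, cols = cols)
}

# ---------------------------------------------------------------------------

#' Fit a cause-specific piece-wise exponential additive hazard model
#'
#' @param ped Model-ready PED from [make_ped()] (or [split_to_ped()] plus
#'   cumulative columns).
#' @param spec A [model_spec()].
#' @return Object of class `pamm_fit`: penalized coefficients, Bayesian
#'   posterior covariance (inverse penalized Fisher information), smoothing
#'   parameters, per-term effective degrees of freedom, the interval grid
#'   and all design metadata needed for prediction.
#' @export
fit_pamm <- function(ped, spec) {
  grid <- attr(ped, "grid")
  if (is.null(grid)) stop("`ped` must carry an interval grid attribute", call. = FALSE)
  basis_mode <- attr(ped, "basis_mode") %||% "phase"
  y <- ped[[spec$cause]]
  if (is.null(y)) stop(sprintf("no event column `%s` in ped", spec$cause), call. = FALSE)
  off <- ped$offset

  dm <- build_pamm_design(ped, spec, grid, basis_mode)
  X <- dm$X
  p <- ncol(X)

  # drop unpenalized all-zero columns (e.g. unused factor levels)
  zero <- colSums(abs(X)) == 0
  pen_cols <- unlist(dm$cols[vapply(dm$info$terms, `[[`, logical(1), "penalized")])
  drop_cols <- which(zero & !(seq_len(p) %in% pen_cols))
  keep <- setdiff(seq_len(p), drop_cols)
  if (length(drop_cols)) {
    warning(sprintf("dropping %d all-zero unpenalized column(s): %s",
                    length(drop_cols),
                    paste(colnames(X)[drop_cols], collapse = ", ")))
  }

  # penalty bookkeeping: each penalty j lives inside one term's column block
  pens <- list()
  for (lab in names(dm$info$terms)) {
    tm <- dm$info$terms[[lab]]
    for (S in tm$penalties) {
      pens[[length(pens) + 1L]] <- list(
        term = lab, cols = dm$cols[[lab]],
        S = S, rank = qr(S)$rank
      )
    }
  }
  n_pen <- length(pens)
  lambda <- rep_len(spec$lambda, max(n_pen, 1L))
  if (spec$smoothing == "fixed" && any(lambda < 0)) {
    stop("fixed smoothing parameters must be non-negative", call. = FALSE)
  }
  if (spec$smoothing == "reml") lambda <- pmax(lambda, 1e-4)

  Xk <- X[, keep, drop = FALSE]
  pk <- ncol(Xk)
  col_map <- match(seq_len(p), keep)        # original -> kept position

  S_full <- function(lam) {
    S <- matrix(0, pk, pk)
    for (j in seq_len(n_pen)) {
      cc <- col_map[pens[[j]]$cols]
      S[cc, cc] <- S[cc, cc] + lam[j] * pens[[j]]$S
    }
    S
  }

  irls <- function(lam, beta0 = NULL) {
    S <- S_full(lam)
    pen_dev <- function(beta) {
      eta <- pmin(drop(Xk %*% beta) + off, 30)
      ll <- sum(y * eta - exp(eta))
      pen <- 0
      for (j in seq_len(n_pen)) {
        cc <- col_map[pens[[j]]$cols]
        b <- beta[cc]
        pen <- pen + lam[j] * drop(crossprod(b, pens[[j]]$S %*% b))
      }
      list(dev = -2 * ll + pen, ll = ll)
    }
    beta <- if (is.null(beta0)) numeric(pk) else beta0
    if (is.null(beta0)) {
      init <- log(max(sum(y), 0.5) / sum(exp(off)))
      if ("intercept" %in% names(dm$cols)) {
        beta[col_map[dm$cols$intercept]] <- init
      } else if ("baseline_int" %in% names(dm$cols)) {
        cc <- col_map[dm$cols$baseline_int]
        beta[cc[!is.na(cc)]] <- init
      }
    }
    cur <- pen_dev(beta)
    for (it in seq_len(spec$max_iter)) {
      eta <- pmin(drop(Xk %*% beta) + off, 30)
      mu <- exp(eta)
      w <- mu
      # stable working response: w*z = w*(eta - off) + (y - mu), bounded
      # even when mu underflows on an event row
      wz <- w * (eta - off) + (y - mu)
      H <- crossprod(Xk * sqrt(w)) + S
      Hc <- tryCatch(chol(H), error = function(e) NULL)
      if (is.null(Hc)) {
        H <- H + diag(1e-8 * max(diag(H)), pk)
        Hc <- chol(H)
      }
      beta_new <- drop(backsolve(Hc, forwardsolve(t(Hc), crossprod(Xk, wz))))
      if (any(!is.finite(beta_new))) {
        stop(sprintf("IRLS diverged (cause %s): non-finite coefficients",
                     spec$cause), call. = FALSE)
      }
      # step halving keeps the penalized deviance monotone
      step <- beta_new - beta
      nxt <- pen_dev(beta_new)
      h <- 0
      while (!is.finite(nxt$dev) || nxt$dev > cur$dev + 1e-10) {
        h <- h + 1
        if (h > 30) break
        beta_new <- beta + step / 2^h
        nxt <- pen_dev(beta_new)
      }
      beta <- beta_new
      done <- abs(cur$dev - nxt$dev) < 1e-9 * (abs(nxt$dev) + 0.1)
      cur <- nxt
      if (done) {
        eta <- pmin(drop(Xk %*% beta) + off, 30)
        w <- exp(eta)
        H <- crossprod(Xk * sqrt(w)) + S
        Hc <- tryCatch(chol(H), error = function(e) chol(
          H + diag(1e-8 * max(diag(H)), pk)))
        return(list(beta = beta, H = H, Hc = Hc, ll = cur$ll, dev = cur$dev,
                    mu = w, iter = it, converged = TRUE))
      }
    }
    stop(sprintf(
      "IRLS failed to converge in %d iterations (cause %s, last penalized deviance %.6g)",
      spec$max_iter, spec$cause, cur$dev), call. = FALSE)
  }

  reml_trace <- NULL
  fit <- irls(lambda)
  if (spec$smoothing == "reml" && n_pen > 0) {
    for (outer in seq_len(spec$max_outer)) {
      Hinv <- chol2inv(fit$Hc)
      # per-term lambda-weighted total penalties (for the pseudo-inverse term)
      term_tot <- list()
      for (j in seq_len(n_pen)) {
        tl <- pens[[j]]$term
        term_tot[[tl]] <- (term_tot[[tl]] %||% 0) + lambda[j] * pens[[j]]$S
      }
      term_pinv <- lapply(term_tot, sym_pinv)
      new_lam <- lambda
      for (j in seq_len(n_pen)) {
        cc <- col_map[pens[[j]]$cols]
        Sj <- pens[[j]]$S
        tr_pinv <- sum(term_pinv[[pens[[j]]$term]] * Sj)
        tr_hinv <- sum(Hinv[cc, cc] * Sj)
        b <- fit$beta[cc]
        denom <- max(drop(crossprod(b, Sj %*% b)), 1e-12)
        num <- max(tr_pinv - tr_hinv, 1e-12)
        lam_new <- lambda[j] * num / denom
        # damp extreme moves
        lam_new <- min(max(lam_new, lambda[j] / 20), lambda[j] * 20)
        new_lam[j] <- min(max(lam_new, 1e-6), 1e7)
      }
      step <- max(abs(log(new_lam) - log(lambda)))
      reml_trace <- rbind(reml_trace, c(outer, step))
      lambda <- new_lam
      fit <- irls(lambda, beta0 = fit$beta)
      if (step < 2e-3) break
    }
  }

  Hinv <- chol2inv(fit$Hc)
  XtWX <- fit$H - S_full(lambda)
  Fmat <- Hinv %*% XtWX
  edf_term <- vapply(names(dm$cols), function(lab) {
    cc <- col_map[dm$cols[[lab]]]
    sum(diag(Fmat)[cc[!is.na(cc)]])
  }, numeric(1))

  coefs <- numeric(p)
  coefs[keep] <- fit$beta
  V <- matrix(0, p, p)
  V[keep, keep] <- Hinv
  names(coefs) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))

  names(lambda) <- vapply(pens, function(pp) pp$term, character(1))[seq_len(n_pen)]
  re_var <- if (spec$random_icu && "re_icu" %in% names(lambda)) {
    1 / unname(lambda["re_icu"])
  } else NA_real_

  structure(list(
    coefficients = coefs, V = V, lambda = lambda, edf = edf_term,
    edf_total = sum(edf_term), info = dm$info, spec = spec, grid = grid,
    basis_mode = basis_mode,
    window_mode = attr(ped, "window_mode") %||% "dynamic",
    outcome_set = attr(ped, "outcome_set") %||% "hospital",
    loglik = fit$ll, deviance = fit$dev, iter = fit$iter,
    converged = fit$converged, reml_trace = reml_trace,
    n_rows = nrow(ped), n_events = sum(y),
    dropped = colnames(X)[drop_cols], keep = keep,
    re_variance = re_var
  ), class = "pamm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pamm_fit <- function(x, ...) {
  cat("<pamm_fit> cause:", x$spec$cause,
      "| rows:", x$n_rows, "| events:", x$n_events, "\n")
  cat("  smoothing:", x$spec$smoothing,
      "| total edf:", round(x$edf_total, 1),
      "| log-likelihood:", round(x$loglik, 2), "\n")
  if (!is.na(x$re_variance)) {
    cat("  ICU random-intercept variance:", signif(x$re_variance, 3), "\n")
  }
  invisible(x)
}

#' Unpenalized Poisson log-likelihood of a fitted model
#'
#' Evaluates `sum(delta * eta - exp(eta))` with `eta` the full linear
#' predictor including the log-exposure offset. Up to the additive constant
#' `sum(delta * offset)` (independent of the coefficients) this equals the
#' piece-wise exponential survival log-likelihood
#' `sum(delta * log hazard(t_i) - cumulative_hazard(t_i))`.
#'
#' @param model A [fit_pamm()] object.
#' @param ped The PED the likelihood is evaluated on.
#' @param beta Optional coefficient vector (defaults to the fitted one).
#' @return Scalar log-likelihood.
#' @export
loglik_pamm <- function(model, ped, beta = NULL) {
  if (is.null(beta)) beta <- model$coefficients
  dm <- build_pamm_design(ped, model$spec, model$grid, model$basis_mode,
                          info = model$info)
  eta <- drop(dm$X %*% beta) + ped$offset
  y <- ped[[model$spec$cause]]
  sum(y * eta - exp(eta))
}

#' Predict the log hazard with standard errors
#'
#' Evaluates the linear predictor (without offset) for new PED-like rows.
#' The ICU random intercept is set to its mean (zero) unless
#' `exclude_random = FALSE` and an `icu_id` is supplied, as hypothetical
#' diet predictions are population-level statements.
#'
#' @param model A [fit_pamm()] object.
#' @param newdata Data frame with the columns the model's design needs
#'   (`tmid`, `interval`, confounders, cumulative design columns).
#' @param exclude_random Zero out the ICU random intercept?
#' @return Data frame with `eta` (log hazard) and `se`.
#' @export
predict_log_hazard <- function(model, newdata, exclude_random = TRUE) {
  dm <- build_pamm_design(newdata, model$spec, model$grid, model$basis_mode,
                          info = model$info, exclude_random = exclude_random)
  X <- dm$X
  eta <- drop(X %*% model$coefficients)
  se <- sqrt(pmax(rowSums((X %*% model$V) * X), 0))
  data.frame(eta = eta, se = se)
}

# ---------------------------------------------------------------------------
# JSON serialization (documented container for reuse across sessions).

#' Serialize a fitted hazard model to JSON
#'
#' Writes a self-contained JSON container (format `protpamm-model-1`) with
#' coefficients, covariance, smoothing parameters, interval grid and the
#' full design metadata (knots, constraint bases, factor levels), so the
#' model can be reloaded with [read_pamm_json()] and used for prediction.
#'
#' @param model A [fit_pamm()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pamm_json <- function(model, path) {
  payload <- jsonlite::serializeJSON(unclass(model), digits = NA)
  container <- list(
    format = "protpamm-model-1",
    cause = model$spec$cause,
    window_mode = model$window_mode,
    basis_mode = model$basis_mode,
    grid_cuts = model$grid$cuts,
    n_events = model$n_events,
    payload = as.character(payload)
  )
  writeLines(jsonlite::toJSON(container, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a fitted hazard model from JSON
#'
#' @param path Path written by [write_pamm_json()].
#' @return A `pamm_fit` object.
#' @export
read_pamm_json <- function(path) {
  container <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(container$format, "protpamm-model-1")) {
    stop("not a protpamm model container", call. = FALSE)
  }
  obj <- jsonlite::unserializeJSON(container$payload)
  class(obj$grid) <- "interval_grid"
  class(obj$spec) <- "pamm_spec"
  structure(obj, class = "pamm_fit")
}
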