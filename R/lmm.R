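#' Build the analysis table for one grouping scheme
#'
#' Joins the derived-quantities table to the sample metadata, restricts to
#' the scheme's subset, and attaches the group level. Only QC-passed
#' records are kept by default.
#'
#' @param derived Derived-quantities `data.frame` from [derive_mechanics()].
#' @param meta Canonical metadata `data.frame`.
#' @param scheme A `"group_scheme"` from [assign_scheme()].
#' @param qc_only Drop records with `qc_pass = FALSE` (default `TRUE`).
#' @return `data.frame` with `sample_id`, `plant_id`, `group`, `EI_Nm2`,
#'   `E_Pa`, `I_m4`.
#' @export
analysis_table <- function(derived, meta, scheme, qc_only = TRUE) {
  stopifnot(inherits(scheme, "group_scheme"))
  tab <- merge(derived, meta[, c("sample_id", "plant_id")], by = "sample_id")
  if (qc_only) tab <- tab[tab$qc_pass, , drop = FALSE]
  tab <- tab[tab$sample_id %in% names(scheme$assignment), , drop = FALSE]
  tab$group <- unname(scheme$assignment[tab$sample_id])
  tab$group <- factor(tab$group, levels = intersect(scheme$levels, unique(tab$group)))
  tab[, c("sample_id", "plant_id", "group", "EI_Nm2", "E_Pa", "I_m4")]
}

# ---- Satterthwaite machinery ------------------------------------------------
#
# Works on a single-random-intercept lmer fit. Variance parameters are the
# standard deviations varpar = (sd_group, sd_resid); their asymptotic
# covariance comes from a finite-difference Hessian of the REML criterion,
# and per-contrast denominator df from the usual Satterthwaite moment match
#   df = 2 v^2 / (g' A g),  v = l' Vcov(beta) l,  g = d v / d varpar.
# Multi-df F tests decompose the contrast covariance by eigenvectors and
# moment-match the sum of the resulting independent t^2 terms.

.fd_grad <- function(f, x, h = pmax(abs(x) * 1e-4, 1e-6)) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h[i]
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, 0)
}

.fd_hess <- function(f, x, h = pmax(abs(x) * 1e-4, 1e-6)) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in (i + 1L):k) {
      ej <- numeric(k); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

.sw_prepare <- function(model) {
  y <- lme4::getME(model, "y")
  X <- lme4::getME(model, "X")
  Z <- lme4::getME(model, "Z")
  n <- length(y); p <- ncol(X)
  ZZt <- Matrix::tcrossprod(Z)
  In <- Matrix::Diagonal(n)

  vcov_beta <- function(vp) {
    V <- vp[1]^2 * ZZt + vp[2]^2 * In
    Vi_X <- Matrix::solve(V, X)
    as.matrix(Matrix::solve(Matrix::crossprod(X, Vi_X)))
  }
  reml2 <- function(vp) {
    V <- vp[1]^2 * ZZt + vp[2]^2 * In
    ld_V <- as.numeric(Matrix::determinant(V, logarithm = TRUE)$modulus)
    Vi_y <- Matrix::solve(V, y)
    Vi_X <- Matrix::solve(V, X)
    XtViX <- as.matrix(Matrix::crossprod(X, Vi_X))
    ld_XtViX <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
    Xt_Vi_y <- as.numeric(Matrix::crossprod(X, Vi_y))
    yPy <- sum(y * as.numeric(Vi_y)) -
      as.numeric(t(Xt_Vi_y) %*% solve(XtViX, Xt_Vi_y))
    ld_V + ld_XtViX + yPy
  }

  varpar <- c(sd_group = unname(lme4::getME(model, "theta")[1]) * stats::sigma(model),
              sd_resid = stats::sigma(model))
  A <- NULL
  ok <- FALSE
  if (varpar[1] > 1e-8 * varpar[2]) {
    H <- tryCatch(.fd_hess(reml2, varpar), error = function(e) NULL)
    if (!is.null(H)) {
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      if (all(ev > 0)) { A <- 2 * solve(H); ok <- TRUE }
    }
  }
  list(varpar = varpar, A = A, ok = ok, n = n, p = p,
       vcov_beta = vcov_beta,
       beta = lme4::fixef(model), Sigma = vcov_beta(varpar))
}

# Satterthwaite df for one contrast vector l (falls back to residual df when
# the variance-parameter covariance is unavailable, e.g. singular fits).
.sw_df1 <- function(sw, l) {
  resid_df <- sw$n - sw$p
  if (!sw$ok) return(resid_df)
  v0 <- as.numeric(t(l) %*% sw$Sigma %*% l)
  g <- .fd_grad(function(vp) as.numeric(t(l) %*% sw$vcov_beta(vp) %*% l), sw$varpar)
  den <- as.numeric(t(g) %*% sw$A %*% g)
  if (!is.finite(den) || den <= 0) return(resid_df)
  df <- 2 * v0^2 / den
  if (!is.finite(df) || df <= 0) resid_df else df
}

# Satterthwaite F test for a q x p contrast matrix L.
.sw_F <- function(sw, L) {
  L <- rbind(L)
  Vc <- L %*% sw$Sigma %*% t(L)
  eg <- eigen(Vc, symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  pos <- eg$values > tol
  q <- sum(pos)
  P <- eg$vectors[, pos, drop = FALSE]
  d <- eg$values[pos]
  Lb <- as.numeric(L %*% sw$beta)
  tvals <- as.numeric(t(P) %*% Lb) / sqrt(d)
  Fstat <- sum(tvals^2) / q
  nu <- vapply(seq_len(q), function(i) {
    li <- as.numeric(t(L) %*% P[, i])
    .sw_df1(sw, li)
  }, 0)
  Eseq <- nu[nu > 2] / (nu[nu > 2] - 2)
  df2 <- if (length(Eseq) == q && sum(Eseq) > q) {
    E <- sum(Eseq)
    2 * E / (E - q)
  } else sw$n - sw$p
  list(F = Fstat, df1 = q, df2 = df2,
       p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
}

# ---- User-facing model interface -------------------------------------------

#' Fit the grouped mixed model for EI or E
#'
#' REML linear mixed model on the natural-log scale, with a per-plant
#' random intercept to absorb the correlation between the multiple samples
#' cut from one individual plant:
#' * `log_EI`: `log(EI) ~ group + log(I) + (1 | plant)` — the continuous
#'   log second-moment covariate controls for cross-sectional geometry so
#'   the group term isolates material-driven rigidity differences;
#' * `log_E`: `log(E) ~ group + (1 | plant)` — E is already
#'   geometry-normalized, so the covariate is dropped.
#'
#' Singular fits (plant variance estimated at zero) are flagged, not fatal;
#' denominator df then fall back from the Satterthwaite approximation to
#' residual df with a warning.
#'
#' @param tab Analysis table from [analysis_table()] (columns `group`,
#'   `plant_id`, `EI_Nm2`, `E_Pa`, `I_m4`).
#' @param response `"log_EI"` or `"log_E"`.
#' @return An object of class `"flex_lmm"`.
#' @export
fit_group_model <- function(tab, response = c("log_EI", "log_E")) {
  response <- match.arg(response)
  stopifnot(is.data.frame(tab),
            all(c("group", "plant_id") %in% names(tab)))
  raw <- if (response == "log_EI") tab$EI_Nm2 else tab$E_Pa
  if (any(!is.finite(raw)) || any(raw <= 0))
    stop("non-positive response values cannot be log-transformed")
  df <- data.frame(y = log(raw),
                   group = droplevels(factor(tab$group)),
                   plant = factor(tab$plant_id))
  if (nlevels(df$group) < 2L)
    stop("scheme has a single level in the analysis subset; nothing to compare")
  if (response == "log_EI") {
    if (any(!is.finite(tab$I_m4)) || any(tab$I_m4 <= 0))
      stop("non-positive I")
    df$log_I <- log(tab$I_m4)
    form <- y ~ group + log_I + (1 | plant)
  } else {
    form <- y ~ group + (1 | plant)
  }
  model <- lme4::lmer(form, data = df, REML = TRUE)
  singular <- lme4::isSingular(model, tol = 1e-4)
  sw <- .sw_prepare(model)
  if (singular && !sw$ok)
    warning("singular fit (plant variance ~ 0); ",
            "denominator df fall back to residual df")
  vc <- as.data.frame(lme4::VarCorr(model))
  structure(list(model = model, data = df, response = response,
                 formula = form, singular = singular, sw = sw,
                 var_plant = vc$vcov[vc$grp == "plant"],
                 var_resid = vc$vcov[vc$grp == "Residual"]),
            class = "flex_lmm")
}

#' @export
print.flex_lmm <- function(x, ...) {
  cat(sprintf("<flex_lmm %s ~ group%s + (1|plant): %d obs, %d plants, %d levels%s>\n",
              x$response, if (x$response == "log_EI") " + log_I" else "",
              nrow(x$data), nlevels(x$data$plant), nlevels(x$data$group),
              if (x$singular) ", SINGULAR" else ""))
  invisible(x)
}

#' Type-II ANOVA with Satterthwaite denominator df
#'
#' Marginal F test for each fixed-effect term after all other terms (the
#' models contain no interactions, so the type-II contrast for a term is
#' the joint Wald test of its coefficients). Denominator degrees of freedom
#' use the Satterthwaite moment-matching approximation, giving the
#' fractional df characteristic of mixed-model ANOVA tables; residual df
#' are used as a logged fallback when the approximation is unavailable.
#'
#' @param fit A `"flex_lmm"` from [fit_group_model()].
#' @return `data.frame` with columns `term`, `F`, `df1`, `df2`, `p`.
#' @export
anova_type2 <- function(fit) {
  stopifnot(inherits(fit, "flex_lmm"))
  X <- lme4::getME(fit$model, "X")
  asgn <- attr(X, "assign")
  labs <- attr(stats::terms(stats::as.formula(lme4::nobars(fit$formula))), "term.labels")
  p <- ncol(X)
  rows <- lapply(seq_along(labs), function(k) {
    idx <- which(asgn == k)
    L <- diag(p)[idx, , drop = FALSE]
    res <- .sw_F(fit$sw, L)
    data.frame(term = labs[k], F = res$F, df1 = res$df1, df2 = res$df2,
               p = res$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# model-matrix rows for the EMM reference grid: one row per group level,
# covariates at their grand mean.
.emm_linfct <- function(fit) {
  lv <- levels(fit$data$group)
  nd <- data.frame(group = factor(lv, levels = lv))
  if (!is.null(fit$data$log_I)) nd$log_I <- mean(fit$data$log_I)
  tt <- stats::delete.response(stats::terms(stats::as.formula(lme4::nobars(fit$formula))))
  G <- stats::model.matrix(tt, nd)
  rownames(G) <- lv
  G
}

#' Estimated marginal means on the log scale
#'
#' Model-based group means evaluated at the reference grid (covariates at
#' their grand mean), with standard errors and Satterthwaite df.
#'
#' @param fit A `"flex_lmm"`.
#' @return `data.frame` with columns `level`, `emm`, `SE`, `df`.
#' @export
emm_means <- function(fit) {
  stopifnot(inherits(fit, "flex_lmm"))
  G <- .emm_linfct(fit)
  est <- as.numeric(G %*% fit$sw$beta)
  se <- sqrt(rowSums((G %*% fit$sw$Sigma) * G))
  df <- vapply(seq_len(nrow(G)), function(i) .sw_df1(fit$sw, G[i, ]), 0)
  data.frame(level = rownames(G), emm = est, SE = se, df = df,
             stringsAsFactors = FALSE)
}

#' Tukey-adjusted pairwise EMM contrasts
#'
#' All pairwise differences of estimated marginal means (first level minus
#' second, in level order), with Satterthwaite df per contrast and
#' family-wise p adjustment from the studentized-range distribution. For a
#' two-level scheme the family has size one and the adjusted p equals the
#' unadjusted p.
#'
#' @param fit A `"flex_lmm"`.
#' @param adjust `"tukey"` (default) or `"none"`.
#' @return `data.frame` with columns `contrast`, `estimate`, `SE`, `df`,
#'   `t`, `p`, `p_adj`.
#' @export
emm_contrasts <- function(fit, adjust = c("tukey", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fit, "flex_lmm"))
  G <- .emm_linfct(fit)
  lv <- rownames(G)
  k <- length(lv)
  if (k < 2L) stop("scheme with one level has no contrasts")
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    l <- G[i1, ] - G[i2, ]
    est <- sum(l * fit$sw$beta)
    se <- sqrt(as.numeric(t(l) %*% fit$sw$Sigma %*% l))
    df <- .sw_df1(fit$sw, l)
    tval <- est / se
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    p_adj <- if (adjust == "tukey")
      stats::ptukey(sqrt(2) * abs(tval), k, df, lower.tail = FALSE)
    else p
    data.frame(contrast = paste(lv[i1], "-", lv[i2]),
               estimate = est, SE = se, df = df, t = tval,
               p = p, p_adj = min(p_adj, 1), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent rigidity difference between two group levels
#'
#' Back-transformed effect size: how much more (positive) or less
#' (negative) rigid level `b` is than level `a`, in percent.
#' `basis = "median"` uses raw group medians of the response,
#' `(median_b / median_a - 1) * 100`; `basis = "emm"` back-transforms the
#' log-scale EMM difference, `(exp(EMM_b - EMM_a) - 1) * 100`.
#'
#' @param x For `basis = "median"` a `data.frame` with columns `group` and
#'   `value` (raw response); for `basis = "emm"` a `"flex_lmm"` fit.
#' @param level_a Reference level.
#' @param level_b Comparison level.
#' @param basis `"median"` (default) or `"emm"`.
#' @return Percent difference (scalar).
#' @export
percent_rigidity_difference <- function(x, level_a, level_b,
                                        basis = c("median", "emm")) {
  basis <- match.arg(basis)
  if (basis == "emm") {
    stopifnot(inherits(x, "flex_lmm"))
    em <- emm_means(x)
    if (!all(c(level_a, level_b) %in% em$level))
      stop("missing level: ", paste(setdiff(c(level_a, level_b), em$level),
                                    collapse = ", "))
    d <- em$emm[em$level == level_b] - em$emm[em$level == level_a]
    return((exp(d) - 1) * 100)
  }
  stopifnot(is.data.frame(x), all(c("group", "value") %in% names(x)))
  if (!all(c(level_a, level_b) %in% x$group))
    stop("missing level: ", paste(setdiff(c(level_a, level_b), unique(x$group)),
                                  collapse = ", "))
  ma <- stats::median(x$value[x$group == level_a])
  mb <- stats::median(x$value[x$group == level_b])
  if (ma == 0) stop("zero median in reference level")
  (mb / ma - 1) * 100
}
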