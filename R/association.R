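# Metadata-association workflow: log10 transformation with a
# half-minimum pseudocount, a vectorized univariate OLS scan with
# global BH correction, bidirectional stepwise-AIC multivariable
# regression, and PERMANOVA on Bray-Curtis distances.

#' Log10-transform a relative abundance matrix
#'
#' log10(x + c); the pseudocount c defaults to half the smallest
#' non-zero value of the matrix so that zeros map to a finite floor
#' below every observed abundance.
#'
#' @param rel_abund non-negative samples x features matrix.
#' @param pseudocount numeric pseudocount, or "half_min_nonzero".
#' @return transformed matrix.
#' @export
log10_transform <- function(rel_abund, pseudocount = "half_min_nonzero") {
  if (any(rel_abund < 0)) stop("negative abundances")
  nz <- rel_abund[rel_abund > 0]
  if (!length(nz)) stop("all-zero abundance matrix")
  c0 <- if (identical(pseudocount, "half_min_nonzero")) min(nz) / 2
    else as.numeric(pseudocount)
  log10(rel_abund + c0)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up construction; q is monotone in p and q >= p.
#'
#' @param pvals p-values in [0, 1] (NAs preserved).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Univariate regression scan of features against metadata
#'
#' For every (feature, variable) pair an ordinary least-squares slope
#' t-test of the (already transformed) feature on the single variable;
#' BH correction is applied jointly over all pairs. Constant variables
#' or constant features give p = 1 with a warning.
#'
#' @param Y samples x features matrix of transformed abundances.
#' @param X data.frame of metadata variables (numeric; binary coded
#'   0/1).
#' @param fdr q-value threshold for flagging (default 0.05).
#' @return list with `p`, `q` (features x variables matrices), `beta`
#'   (slopes) and `flagged` (data.frame of pairs with q < fdr).
#' @export
univariate_scan <- function(Y, X, fdr = 0.05) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n != nrow(X)) stop("sample counts differ between Y and X")
  p <- matrix(NA_real_, ncol(Y), ncol(X),
              dimnames = list(colnames(Y), names(X)))
  beta <- p
  sy <- apply(Y, 2L, stats::sd)
  warned <- FALSE
  for (j in seq_along(X)) {
    x <- as.numeric(X[[j]])
    sx <- stats::sd(x)
    if (sx == 0) {
      p[, j] <- 1; beta[, j] <- 0
      warned <- TRUE
      next
    }
    r <- suppressWarnings(as.numeric(stats::cor(Y, x)))
    r[is.na(r)] <- 0
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    pj <- 2 * stats::pt(-abs(tstat), df = n - 2)
    pj[sy == 0] <- 1
    beta[, j] <- ifelse(sy == 0, 0, r * sy / sx)
    p[, j] <- pj
    if (any(sy == 0)) warned <- TRUE
  }
  if (warned) warning("constant feature(s) or variable(s): p set to 1")
  q <- matrix(bh_fdr(as.vector(p)), nrow(p), ncol(p),
              dimnames = dimnames(p))
  idx <- which(q < fdr, arr.ind = TRUE)
  flagged <- data.frame(feature = rownames(p)[idx[, 1L]],
                        variable = colnames(p)[idx[, 2L]],
                        beta = beta[idx], p = p[idx], q = q[idx],
                        stringsAsFactors = FALSE)
  list(p = p, q = q, beta = beta, flagged = flagged)
}

#' Multivariable regression with stepwise-AIC selection
#'
#' Fits the feature on all variables that passed the univariate FDR
#' gate, removes rank-deficient (later-listed) duplicates, then runs
#' bidirectional stepwise selection from the full model minimizing
#' AIC. Variables surviving selection are reported significant iff
#' their coefficient p-value is below 0.05.
#'
#' @param y transformed abundance vector of one feature.
#' @param X data.frame of metadata variables.
#' @param gated_vars names of variables that passed the univariate
#'   gate for this feature.
#' @param p_max significance threshold on retained coefficients.
#' @return data.frame with `variable`, `beta_multi`, `p_multi`,
#'   `selected`, `significant`; zero rows when no variable was gated.
#' @export
multivariable_fit <- function(y, X, gated_vars, p_max = 0.05) {
  gated_vars <- intersect(gated_vars, names(X))
  if (!length(gated_vars)) {
    return(data.frame(variable = character(), beta_multi = numeric(),
                      p_multi = numeric(), selected = logical(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  dat <- data.frame(.y = y, X[gated_vars], check.names = FALSE)
  full <- stats::lm(.y ~ ., data = dat)
  alias <- is.na(stats::coef(full))
  if (any(alias)) {
    drop <- names(stats::coef(full))[alias]
    warning("dropping collinear variable(s): ",
            paste(drop, collapse = ", "))
    keep <- setdiff(gated_vars, drop)
    if (!length(keep)) keep <- gated_vars[1L]
    dat <- data.frame(.y = y, X[keep], check.names = FALSE)
    full <- stats::lm(.y ~ ., data = dat)
  }
  sel <- stats::step(full, direction = "both", trace = 0)
  co <- summary(sel)$coefficients
  kept <- setdiff(rownames(co), "(Intercept)")
  out <- data.frame(variable = gated_vars, beta_multi = NA_real_,
                    p_multi = NA_real_, selected = FALSE,
                    significant = FALSE, stringsAsFactors = FALSE)
  for (v in kept) {
    i <- match(v, out$variable)
    if (is.na(i)) next
    out$beta_multi[i] <- co[v, "Estimate"]
    out$p_multi[i] <- co[v, "Pr(>|t|)"]
    out$selected[i] <- TRUE
    out$significant[i] <- co[v, "Pr(>|t|)"] < p_max
  }
  out
}

#' PERMANOVA of a distance matrix against one variable
#'
#' McArdle-Anderson formulation: with G the Gower-centred matrix
#' -J D^2 J / 2 and H the hat matrix of the design (intercept plus the
#' variable, dummy-coded when categorical), pseudo-F =
#' [tr(HGH)/(k-1)] / [tr((I-H)G(I-H))/(n-k)] and R2 = tr(HGH)/tr(G).
#' The p-value is obtained by permuting sample labels.
#'
#' @param D symmetric distance matrix (zero diagonal) or `dist`.
#' @param x variable (numeric, or factor/character for categorical).
#' @param n_perm permutations (default 10000).
#' @return list of class `permanova_result` with `pseudo_F`, `R2`,
#'   `p_perm`, `df`, `n_perm`.
#' @export
permanova <- function(D, x, n_perm = 10000L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    stop("D must be a symmetric distance matrix")
  }
  if (length(x) != n) stop("variable length does not match D")
  if (is.character(x)) x <- factor(x)
  if (is.factor(x) && nlevels(droplevels(x)) < 2L) {
    stop("categorical variable with a single level")
  }
  if (is.numeric(x) && stats::sd(x) == 0) {
    stop("constant variable")
  }
  X <- stats::model.matrix(~x, data.frame(x = x))
  k <- qr(X)$rank
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  ss_tot <- sum(diag(G))
  f_stat <- function(Xm) {
    H <- Xm %*% solve(crossprod(Xm), t(Xm))
    ss_exp <- sum(G * H)  # tr(GH), H symmetric idempotent
    ss_res <- ss_tot - ss_exp
    c(F = (ss_exp / (k - 1)) / (ss_res / (n - k)), ss_exp = ss_exp)
  }
  obs <- f_stat(X)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    if (f_stat(X[perm, , drop = FALSE])[["F"]] >= obs[["F"]] - 1e-12) {
      hits <- hits + 1L
    }
  }
  structure(list(pseudo_F = unname(obs[["F"]]),
                 R2 = unname(obs[["ss_exp"]] / ss_tot),
                 p_perm = (1 + hits) / (n_perm + 1),
                 df = c(k - 1L, n - k), n_perm = n_perm),
            class = "permanova_result")
}

#' PERMANOVA scan over a metadata table
#'
#' Runs [permanova()] for every variable and BH-adjusts the
#' permutation p-values across variables.
#'
#' @param D distance matrix.
#' @param meta data.frame of variables.
#' @param n_perm permutations per variable.
#' @return data.frame with `variable`, `pseudo_F`, `R2`, `p_perm`, `q`.
#' @export
permanova_scan <- function(D, meta, n_perm = 10000L) {
  res <- do.call(rbind, lapply(names(meta), function(v) {
    pr <- permanova(D, meta[[v]], n_perm = n_perm)
    data.frame(variable = v, pseudo_F = pr$pseudo_F, R2 = pr$R2,
               p_perm = pr$p_perm, stringsAsFactors = FALSE)
  }))
  res$q <- bh_fdr(res$p_perm)
  res
}
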