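# Dummy-variable QSAR: activity transforms, the tau gating matrix, ordinary
# least squares with leave-one-out validation, critical-point grid search,
# outlier refitting and relative-activity classification.

#' Relative potency of a cyclotide
#'
#' Potency relative to a reference (kalata B1 by convention):
#' `x = IC50_ref / IC50`, so larger x means more potent and a censored
#' ("> limit", non-active) record maps to x = 0.
#'
#' @param ic50 IC50 of the peptide, micromolar (ignored when censored).
#' @param ic50_ref IC50 of the reference peptide, micromolar.
#' @param censored logical: activity reported only as exceeding the highest
#'   tested concentration.
#' @return relative potency x >= 0.
#' @export
relative_potency <- function(ic50, ic50_ref, censored = FALSE) {
  if (ic50_ref <= 0) stop("reference IC50 must be positive", call. = FALSE)
  if (isTRUE(censored)) return(0)
  if (is.na(ic50) || ic50 <= 0) stop("IC50 must be positive", call. = FALSE)
  ic50_ref / ic50
}

#' Transform relative potency to the regression response
#'
#' Base transform `y0 = log10(x + 1)`, which maps non-active records (x = 0)
#' to 0. A Box-Cox exponent of `lambda = -0.5` selects the shifted-power path
#' `y = (x + 1)^(-0.5)`, which stays finite at x = 0 and inverts the ordering
#' (so a negative fitted coefficient then reflects a positive correlation
#' with potency); `lambda = 1` selects the log path unchanged.
#'
#' @param x relative potency, >= 0.
#' @param lambda 1 or -0.5.
#' @return transformed response y.
#' @export
transform_activity <- function(x, lambda = 1) {
  if (any(x < 0)) stop("relative potency must be non-negative", call. = FALSE)
  if (identical(lambda, 1) || identical(lambda, 1L)) {
    log10(x + 1)
  } else if (identical(lambda, -0.5)) {
    (x + 1)^(-0.5)
  } else {
    stop("unsupported lambda: ", lambda, " (use 1 or -0.5)", call. = FALSE)
  }
}

#' Classify relative activity
#'
#' Ratio `IC50 / IC50_ref` below 0.2 is highly active (A2), between 0.2 and
#' 1.0 (inclusive) moderately active (A1), above 1.0 low activity (A0);
#' missing measurements are An.
#'
#' @param ratio_ic50 IC50 ratio peptide / reference; NA for unknown.
#' @return character vector of classes `"A2"`, `"A1"`, `"A0"`, `"An"`.
#' @export
classify_activity <- function(ratio_ic50) {
  out <- ifelse(is.na(ratio_ic50), "An",
                ifelse(ratio_ic50 < 0.2, "A2",
                       ifelse(ratio_ic50 <= 1.0, "A1", "A0")))
  if (any(!is.na(ratio_ic50) & ratio_ic50 <= 0))
    stop("IC50 ratio must be positive", call. = FALSE)
  out
}

#' The tau dummy-variable diagonal
#'
#' `tau_i` is 0 if and only if both moments of record i are strictly below
#' the critical point, and 1 otherwise (moments equal to the critical value
#' count as "not below").
#'
#' @param moments data.frame or matrix with columns `L_M`, `E_M` (in that
#'   order if unnamed).
#' @param critical_point numeric length 2: `(L_M_c, E_M_c)`.
#' @return integer vector of 0/1.
#' @export
tau_diagonal <- function(moments, critical_point) {
  m <- as.matrix(as.data.frame(moments))
  if (!is.null(colnames(m)) && all(c("L_M", "E_M") %in% colnames(m)))
    m <- m[, c("L_M", "E_M"), drop = FALSE]
  as.integer(!(m[, 1] < critical_point[1] & m[, 2] < critical_point[2]))
}

# OLS of y on [1, tau*Lstar, tau*Es] with LOO statistics via hat values.
fit_dummy_core <- function(Lstar, Es, y, tau) {
  X <- cbind(1, tau * Lstar, tau * Es)
  qx <- qr(X)
  if (qx$rank < 3) stop("singular fit: rank-deficient design", call. = FALSE)
  beta <- qr.coef(qx, y)
  fit <- drop(X %*% beta)
  e <- y - fit
  h <- rowSums(qr.Q(qx)^2)
  tss <- sum((y - mean(y))^2)
  sse <- sum(e^2)
  press <- sum((e / pmax(1 - h, 1e-12))^2)
  n <- length(y)
  list(coef = c(k = beta[1], l = beta[2], m = beta[3]),
       fitted = fit, residuals = e, hat = h,
       r2 = 1 - sse / tss, q2 = 1 - press / tss,
       F = ((tss - sse) / 2) / (sse / (n - 3)),
       F_crit = stats::qf(0.95, 2, n - 3), n = n)
}

#' Fit the dummy-variable QSAR model
#'
#' Ordinary least squares of the transformed response on
#' `[1, tau * L_S*, tau * E_S]`, where the 0/1 gate tau is derived from the
#' moments and the critical point. Reports the coefficients (k, l, m), r^2,
#' the leave-one-out cross-validated q^2 (`1 - PRESS/TSS`), the model F
#' statistic `(SSR/2) / (SSE/(n-3))` and the 95% critical F value.
#'
#' @param records data.frame with columns `L_S_star`, `E_S`, `L_M`, `E_M`,
#'   `y` (and optionally `label`).
#' @param critical_point numeric length 2 `(L_M_c, E_M_c)`.
#' @return an object of class `dummy_model`.
#' @export
fit_dummy_model <- function(records, critical_point) {
  need <- c("L_S_star", "E_S", "L_M", "E_M", "y")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(records) < 5) stop("need at least 5 records", call. = FALSE)
  tau <- tau_diagonal(records[, c("L_M", "E_M")], critical_point)
  if (all(tau == 0))
    stop("degenerate model: all tau are zero at this critical point",
         call. = FALSE)
  core <- fit_dummy_core(records$L_S_star, records$E_S, records$y, tau)
  structure(c(core, list(critical_point = c(L_M_c = critical_point[1],
                                            E_M_c = critical_point[2]),
                         tau = tau,
                         labels = records$label)),
            class = "dummy_model")
}

#' @export
print.dummy_model <- function(x, ...) {
  cat(sprintf(
    "<dummy_model> n=%d  y = %.4g + %.4g tau*L_S* + %.4g tau*E_S\n",
    x$n, x$coef[1], x$coef[2], x$coef[3]))
  cat(sprintf("  critical point (%.5f, %.4f); %d of %d records gated out\n",
              x$critical_point[1], x$critical_point[2],
              sum(x$tau == 0), x$n))
  cat(sprintf("  r2 = %.3f  q2 = %.3f  F = %.2f (F_crit 95%% = %.2f)\n",
              x$r2, x$q2, x$F, x$F_crit))
  invisible(x)
}

#' Grid search for the critical point
#'
#' Fits the dummy-variable model at every node of a rectangular moment grid
#' and returns the node maximizing the cross-validated q^2 (ties broken by
#' r^2, then by lowest node index). Degenerate nodes (all-zero tau or a
#' rank-deficient design) are skipped.
#'
#' @param records as for [fit_dummy_model()].
#' @param grid_spec list with `L_M_max`, `E_M_max` and `n` (nodes per axis);
#'   default a 17 x 17 grid over (0, 0) to (0.050, 9.000), whose steps are
#'   0.003125 and 0.5625.
#' @return list with `best` (a `dummy_model`), `critical_point` and
#'   `surface` (data.frame of `L_M_c`, `E_M_c`, `r2`, `q2` for every
#'   evaluated node, NA where degenerate).
#' @export
grid_search_critical_point <- function(records,
                                       grid_spec = list(L_M_max = 0.050,
                                                        E_M_max = 9.000,
                                                        n = 17)) {
  lm_v <- seq(0, grid_spec$L_M_max, length.out = grid_spec$n)
  em_v <- seq(0, grid_spec$E_M_max, length.out = grid_spec$n)
  nodes <- expand.grid(L_M_c = lm_v, E_M_c = em_v)
  r2 <- q2 <- rep(NA_real_, nrow(nodes))
  Lstar <- records$L_S_star; Es <- records$E_S; y <- records$y
  mom <- as.matrix(records[, c("L_M", "E_M")])
  n_skipped <- 0L
  for (i in seq_len(nrow(nodes))) {
    tau <- as.integer(!(mom[, 1] < nodes$L_M_c[i] &
                          mom[, 2] < nodes$E_M_c[i]))
    if (all(tau == 0)) { n_skipped <- n_skipped + 1L; next }
    core <- tryCatch(fit_dummy_core(Lstar, Es, y, tau),
                     error = function(e) NULL)
    if (is.null(core)) { n_skipped <- n_skipped + 1L; next }
    r2[i] <- core$r2; q2[i] <- core$q2
  }
  if (all(is.na(q2)))
    stop("all grid nodes degenerate", call. = FALSE)
  if (n_skipped > 0)
    warning(n_skipped, " degenerate grid node(s) skipped", call. = FALSE)
  best <- order(-q2, -r2, seq_along(q2), na.last = TRUE)[1]
  cp <- as.numeric(nodes[best, ])
  list(best = fit_dummy_model(records, cp),
       critical_point = c(L_M_c = cp[1], E_M_c = cp[2]),
       surface = cbind(nodes, r2 = r2, q2 = q2))
}

#' Refit excluding outliers
#'
#' Refits the model on the complement of an exclusion list and reports both
#' models side by side, together with a convenience flagging of large
#' studentized residuals in the full model (never auto-applied).
#'
#' @param records as for [fit_dummy_model()] with a `label` column.
#' @param exclude character vector of labels to drop.
#' @param critical_point numeric length 2.
#' @param flag_threshold |studentized residual| threshold for flagging
#'   (default 3).
#' @return list with `full` and `refit` models, `excluded` labels and
#'   `flagged` labels.
#' @export
refit_excluding <- function(records, exclude, critical_point,
                            flag_threshold = 3) {
  if (is.null(records$label))
    stop("records must carry a 'label' column", call. = FALSE)
  unknown <- setdiff(exclude, records$label)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  full <- fit_dummy_model(records, critical_point)
  sigma <- sqrt(sum(full$residuals^2) / (full$n - 3))
  stud <- full$residuals / (sigma * sqrt(pmax(1 - full$hat, 1e-12)))
  flagged <- records$label[abs(stud) > flag_threshold]
  keep <- !(records$label %in% exclude)
  refit <- fit_dummy_model(records[keep, , drop = FALSE], critical_point)
  list(full = full, refit = refit, excluded = exclude, flagged = flagged)
}
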