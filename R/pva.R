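# Parameter variation analysis: Latin hypercube sampling over seven
# biological inputs (CCL19 production, CCL21 production, CCR7 per cell,
# ACKR4 per cell, matrix binding sites, and the two effective
# diffusivities), batch execution of the transport pipeline with the flow
# field frozen, and partial rank correlation coefficients with Student-t
# significance against eight gradient/content outputs.

PVA_PARAMS <- c("ccl19_production", "ccl21_production", "ccr7_per_cell",
                "ackr4_per_cell", "matrix_sites", "D_eff_19", "D_eff_21")

PVA_OUTPUTS <- c("ifr_slope_C19", "ifr_slope_C21b",
                 "bftc_slope_C19", "bftc_slope_C21b",
                 "total_CCL19_fmol", "total_CCL21_fmol",
                 "efferent_CCL19_nM", "efferent_CCL21_nM")

#' Latin-hypercube design for the parameter variation analysis
#'
#' @param n_samples number of parameter combinations (default 100).
#' @param lower,upper multiplicative bounds on the baseline value of each
#'   parameter (scalar or named per-parameter); sampling is log-uniform so
#'   that halving and doubling are equally likely.
#' @param seed RNG seed for reproducibility.
#' @return object of class `ln_pva_design` with the factor matrix
#'   (`n_samples` x 7).
#' @export
pva_design <- function(n_samples = 100, lower = 0.2, upper = 5, seed = 1) {
  if (n_samples < 2 * length(PVA_PARAMS))
    stop("pva_design: n_samples must be >= twice the number of parameters")
  lo <- rep_len(lower, length(PVA_PARAMS)); hi <- rep_len(upper, length(PVA_PARAMS))
  if (any(lo <= 0) || any(lo >= hi))
    stop("pva_design: bounds must satisfy 0 < lower < upper")
  set.seed(seed)
  u <- lhs::randomLHS(n_samples, length(PVA_PARAMS))
  fac <- exp(sweep(sweep(u, 2, log(hi / lo), "*"), 2, log(lo), "+"))
  colnames(fac) <- PVA_PARAMS
  structure(list(factors = fac, n = n_samples, lower = lo, upper = hi,
                 seed = seed), class = "ln_pva_design")
}

#' Latin-hypercube sample on the unit hypercube
#'
#' Thin stratified-sampling wrapper: one sample per equal-probability
#' stratum in every dimension, reproducible under a fixed seed.
#'
#' @param n_samples,n_params design size.
#' @param seed RNG seed.
#' @return `n_samples` x `n_params` matrix in `[0,1]`.
#' @export
lhs_sample <- function(n_samples, n_params, seed = 1) {
  set.seed(seed)
  lhs::randomLHS(n_samples, n_params)
}

# apply one row of multiplicative factors to maps/kinetics
apply_pva_factors <- function(maps, kin, fac) {
  for (fld in c("q19", "q21", "Rtot", "Mtot")) {
    key <- switch(fld, q19 = "ccl19_production", q21 = "ccl21_production",
                  Rtot = "ccr7_per_cell", Mtot = "matrix_sites")
    maps$region[[fld]] <- maps$region[[fld]] * fac[[key]]
    maps$cell[[fld]] <- maps$cell[[fld]] * fac[[key]]
  }
  maps$Atot <- maps$Atot * fac[["ackr4_per_cell"]]
  kin$D_eff_19 <- kin$D_eff_19 * fac[["D_eff_19"]]
  kin$D_eff_21 <- kin$D_eff_21 * fac[["D_eff_21"]]
  list(maps = maps, kin = kin)
}

#' Run the parameter-variation ensemble
#'
#' Executes the transport pipeline once per design row with the flow field
#' solved once and frozen (no flow-relevant parameter is varied). Failed
#' samples are logged and excluded; more than 10 percent failures aborts.
#'
#' @param design an `ln_pva_design`.
#' @param config configuration list; `config$resolution` sets the (usually
#'   reduced) ensemble mesh resolution.
#' @param mesh,maps,flow optional precomputed baseline stages.
#' @param progress print a one-line progress note every 10 samples.
#' @return object of class `ln_pva`: design, output matrix, PRCC and
#'   p-value matrices, the qualitative sign table, and failure log.
#' @export
run_ensemble <- function(design, config = default_config(), mesh = NULL,
                         maps = NULL, flow = NULL, progress = FALSE) {
  stopifnot(inherits(design, "ln_pva_design"))
  if (is.null(mesh))
    mesh <- build_mesh(do.call(geometry_params, config$geometry),
                       config$resolution)
  if (is.null(maps))
    maps <- build_field_maps(mesh, census = config_census(config),
                             maxima = do.call(per_cell_maxima, config$maxima))
  if (is.null(flow)) flow <- solve_flow(mesh, do.call(flow_params, config$flow))
  kin0 <- do.call(kinetic_params, config$kinetics)
  lines <- probe_lines(mesh)

  n <- design$n
  out <- matrix(NA_real_, n, length(PVA_OUTPUTS),
                dimnames = list(NULL, PVA_OUTPUTS))
  failures <- character(0)
  for (s in seq_len(n)) {
    fac <- as.list(design$factors[s, ])
    mod <- apply_pva_factors(maps, kin0, fac)
    res <- tryCatch({
      prob <- transport_problem(mesh, flow, mod$maps, mod$kin)
      st <- solve_steady(prob)
      sg <- summary_gradients(st, lines)
      unlist(sg[PVA_OUTPUTS])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("sample %d: %s", s, conditionMessage(res)))
    } else {
      out[s, ] <- res
    }
    if (progress && s %% 10 == 0)
      message(sprintf("  PVA sample %d/%d", s, n))
  }
  if (length(failures) > 0.1 * n)
    stop("run_ensemble: more than 10% of samples failed:\n",
         paste(head(failures, 5), collapse = "\n"))
  ok <- stats::complete.cases(out)
  pr <- prcc(design$factors[ok, , drop = FALSE], out[ok, , drop = FALSE])
  structure(list(design = design, outputs = out, ok = ok,
                 prcc = pr$prcc, p_value = pr$p_value,
                 sign_table = prcc_sign_table(pr$prcc, pr$p_value),
                 failures = failures),
            class = "ln_pva")
}

#' Partial rank correlation coefficients with significance
#'
#' Rank-transforms all columns; for each input/output pair the PRCC is the
#' correlation of the residuals after removing (linearly, on ranks) the
#' other inputs from both. Significance uses
#' `t = r * sqrt((n - 2 - p) / (1 - r^2))` on `n - 2 - p` degrees of
#' freedom, with `p` the number of inputs partialled out.
#'
#' @param X input matrix (samples x parameters).
#' @param Y output matrix (samples x outputs) or vector.
#' @return list with `prcc` and `p_value` matrices (parameters x outputs).
#' @export
prcc <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 2) stop("prcc: need more samples than parameters + 2")
  const <- apply(X, 2, function(x) diff(range(x)) == 0)
  Xr <- apply(X, 2, rank)
  Yr <- apply(Y, 2, rank)
  pr <- matrix(NA_real_, k, ncol(Y),
               dimnames = list(colnames(X), colnames(Y)))
  pv <- pr
  for (i in seq_len(k)) {
    if (const[i]) next                       # undefined for constant input
    others <- setdiff(which(!const), i)      # constants carry no rank signal
    Z <- cbind(1, Xr[, others, drop = FALSE])
    rx <- stats::lm.fit(Z, Xr[, i])$residuals
    RY <- Yr - Z %*% qr.coef(qr(Z), Yr)
    for (j in seq_len(ncol(Y))) {
      ry <- RY[, j]
      if (stats::sd(ry) == 0 || stats::sd(rx) == 0) next
      r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
      df <- n - 2 - length(others)
      tt <- r * sqrt(df / max(1 - r^2, 1e-15))
      pr[i, j] <- r
      pv[i, j] <- 2 * stats::pt(-abs(tt), df)
    }
  }
  list(prcc = pr, p_value = pv)
}

#' Qualitative sign table from PRCC results
#'
#' Renders the +/- notation: one, two or three symbols for
#' `0.001 < p < 0.01`, `0.0001 < p < 0.001` and `p < 0.0001`; blank where
#' not significant at 0.01.
#'
#' @param prcc_mat,p_mat matrices from [prcc()].
#' @return character matrix of the same shape.
#' @export
prcc_sign_table <- function(prcc_mat, p_mat) {
  stopifnot(all(dim(prcc_mat) == dim(p_mat)))
  out <- matrix("", nrow(prcc_mat), ncol(prcc_mat),
                dimnames = dimnames(prcc_mat))
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    p <- p_mat[i, j]; r <- prcc_mat[i, j]
    if (is.na(p) || is.na(r) || p >= 0.01) next
    nsym <- if (p < 1e-4) 3 else if (p < 1e-3) 2 else 1
    out[i, j] <- paste(rep(if (r > 0) "+" else "-", nsym), collapse = " ")
  }
  out
}

#' @export
print.ln_pva <- function(x, ...) {
  cat(sprintf("Parameter variation analysis: %d samples (%d ok)\n",
              x$design$n, sum(x$ok)))
  cat("sign table (rows: inputs, cols: outputs):\n")
  print(x$sign_table, quote = FALSE)
  invisible(x)
}
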