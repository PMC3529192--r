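## Multicollinearity screening with variance inflation factors computed
## under the repeated-measures structure of the data: each predictor is
## regressed on all others in a linear mixed model with random intercepts
## for social group and for individual nested in group.

VIF_CAP <- 1e6

#' Mixed-model variance inflation factors
#'
#' For each predictor j, a linear mixed model `j ~ all others +
#' (1 | group) + (1 | group:individual)` is fitted and
#' `VIF_j = 1 / (1 - R2_j)` computed, where `R2_j` is the share of
#' fixed-effects variance among fixed-effects plus residual variance.
#' Random-intercept variance is deliberately excluded from the denominator:
#' inflating it would understate collinearity among the fixed effects (an
#' alternative including it is available via `r2_denominator`). With zero
#' random-effect variance this reduces to the classical OLS VIF. Perfectly
#' collinear predictors receive a finite capped VIF (1e6) with a warning.
#'
#' @param table a feature table (or any data.frame) containing the
#'   predictors and the grouping columns
#' @param predictors character vector of numeric predictor columns
#' @param individual_column,group_column names of the nesting factors
#' @param r2_denominator `"fixed_resid"` (default) or `"fixed_resid_random"`
#' @return a `vif_report`: list with `vif` (named numeric), `retained`,
#'   `dropped` (empty here; filled by [select_noncollinear()])
#' @export
mixed_model_vif <- function(table, predictors,
                            individual_column = "individual_id",
                            group_column = "group_id",
                            r2_denominator = c("fixed_resid",
                                               "fixed_resid_random")) {
  r2_denominator <- match.arg(r2_denominator)
  if (length(predictors) < 2) stop("need at least 2 predictors")
  dat <- table[, c(predictors, individual_column, group_column), drop = FALSE]
  dat <- dat[complete.cases(dat[, predictors, drop = FALSE]), , drop = FALSE]
  if (length(unique(dat[[individual_column]])) < 2)
    stop("need at least 2 individuals")
  v <- vapply(predictors, function(p) var(dat[[p]]), numeric(1))
  if (any(v == 0))
    stop("constant predictor(s): ",
         paste(predictors[v == 0], collapse = ", "))
  dat$..grp <- factor(dat[[group_column]])
  dat$..ind <- factor(paste(dat[[group_column]], dat[[individual_column]],
                            sep = ":"))
  vif <- setNames(numeric(length(predictors)), predictors)
  for (j in predictors) {
    others <- setdiff(predictors, j)
    fml <- stats::as.formula(paste0(
      "`", j, "` ~ ", paste0("`", others, "`", collapse = " + "),
      " + (1 | ..grp) + (1 | ..ind)"))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = dat,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular =
                                                 lme4::.makeCC(action = "ignore", tol = 1e-4))))),
      error = function(e) NULL)
    if (is.null(fit)) {  # singular design: fall back to OLS fit
      ols <- stats::lm(stats::as.formula(paste0(
        "`", j, "` ~ ", paste0("`", others, "`", collapse = " + "))),
        data = dat)
      r2 <- summary(ols)$r.squared
    } else {
      fixed_var <- var(as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
      vc <- as.data.frame(lme4::VarCorr(fit))
      ## put the REML residual variance on the same (n - 1) denominator as
      ## var(); in the zero-random-variance limit this makes the VIF agree
      ## exactly with the classical OLS value
      nobs <- lme4::getME(fit, "n")
      p_fix <- length(lme4::fixef(fit))
      resid_var <- vc$vcov[vc$grp == "Residual"] * (nobs - p_fix) / (nobs - 1)
      random_var <- sum(vc$vcov[vc$grp != "Residual"])
      denom <- fixed_var + resid_var +
        if (r2_denominator == "fixed_resid_random") random_var else 0
      r2 <- fixed_var / denom
    }
    if (r2 >= 1 - 1 / VIF_CAP) {
      warning("predictor ", j, " is (near-)perfectly collinear; VIF capped")
      vif[j] <- VIF_CAP
    } else {
      vif[j] <- 1 / (1 - r2)
    }
  }
  structure(list(vif = vif, retained = predictors, dropped = character(),
                 threshold = NA_real_), class = "vif_report")
}

#' Greedy collinearity elimination
#'
#' Repeatedly drops the predictor with the largest VIF above `threshold`
#' (ties broken by the supplied predictor order) and recomputes, until all
#' remaining VIFs are at or below the threshold.
#'
#' @inheritParams mixed_model_vif
#' @param threshold maximum admissible VIF (default 2.5)
#' @return a `vif_report` with `retained` (all VIF <= threshold), `dropped`
#'   in drop order, and the final `vif` values
#' @export
select_noncollinear <- function(table, predictors, threshold = 2.5,
                                individual_column = "individual_id",
                                group_column = "group_id",
                                r2_denominator = "fixed_resid") {
  retained <- predictors
  dropped <- character()
  report <- NULL
  repeat {
    if (length(retained) < 2) {
      warning("fewer than 2 predictors remain; returning remainder")
      break
    }
    report <- suppressWarnings(
      mixed_model_vif(table, retained, individual_column, group_column,
                      r2_denominator = r2_denominator))
    if (max(report$vif) <= threshold) break
    worst <- retained[which.max(report$vif)]  # which.max: first max on ties
    dropped <- c(dropped, worst)
    retained <- setdiff(retained, worst)
  }
  structure(list(vif = if (is.null(report)) setNames(numeric(0), character(0))
                 else report$vif,
                 retained = retained, dropped = dropped,
                 threshold = threshold), class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat("VIF report", if (!is.na(x$threshold))
    sprintf("(threshold %.2f)", x$threshold), "\n")
  print(round(x$vif, 3))
  if (length(x$dropped))
    cat("Dropped (in order):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
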