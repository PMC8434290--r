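#' Per-cycle accuracy metrics
#'
#' Pearson r, RMSE (degrees) and range-normalized RMSE (percent,
#' `100 * RMSE / (max(ref) - min(ref))`) per output DoF, computed over the
#' unmasked samples only. A constant reference channel has undefined nRMSE;
#' it is returned as `NA` and flagged.
#'
#' @param pred,ref T x k predicted and reference angle matrices (degrees).
#' @param mask validity mask (length T); defaults to all valid.
#' @param dof_names optional column labels.
#' @return data.frame with columns `dof`, `r`, `rmse`, `nrmse`, `flagged`.
#' @export
cycle_metrics <- function(pred, ref, mask = NULL, dof_names = NULL) {
  pred <- as.matrix(pred); ref <- as.matrix(ref)
  if (!all(dim(pred) == dim(ref))) stop("cycle_metrics: shape mismatch")
  if (is.null(mask)) mask <- rep(1, nrow(ref))
  v <- mask > 0
  if (sum(v) < 3) stop("cycle_metrics: need at least 3 valid samples")
  if (is.null(dof_names)) {
    dof_names <- colnames(ref) %||% paste0("dof", seq_len(ncol(ref)))
  }
  out <- lapply(seq_len(ncol(ref)), function(j) {
    p <- pred[v, j]; r_ <- ref[v, j]
    rmse <- sqrt(mean((p - r_)^2))
    rng <- max(r_) - min(r_)
    flagged <- rng < 1e-9
    data.frame(dof = dof_names[j],
               r = if (stats::sd(r_) < 1e-12 || stats::sd(p) < 1e-12) NA_real_
                   else stats::cor(p, r_),
               rmse = rmse,
               nrmse = if (flagged) NA_real_ else 100 * rmse / rng,
               flagged = flagged)
  })
  do.call(rbind, out)
}

#' Aggregate per-cycle metrics into a summary table
#'
#' Mean and sample standard deviation (n-1) of each metric over test cycles,
#' per training variant and DoF, plus a per-joint `*_average` row (arithmetic
#' mean of the three DoF means). Flagged nRMSE values are excluded.
#'
#' @param records long data.frame with columns `variant`, `joint`, `dof`,
#'   `r`, `rmse`, `nrmse` (one row per cycle x DoF).
#' @return data.frame with per-variant, per-DoF mean/sd columns.
#' @export
aggregate_table <- function(records) {
  if (nrow(records) == 0) stop("aggregate_table: no records")
  agg <- function(df) {
    data.frame(n = nrow(df),
               r_mean = mean(df$r, na.rm = TRUE), r_sd = stats::sd(df$r),
               rmse_mean = mean(df$rmse), rmse_sd = stats::sd(df$rmse),
               nrmse_mean = mean(df$nrmse, na.rm = TRUE),
               nrmse_sd = stats::sd(df$nrmse[!is.na(df$nrmse)]))
  }
  rows <- list()
  for (variant in unique(records$variant)) {
    rv <- records[records$variant == variant, ]
    for (joint in unique(rv$joint)) {
      rj <- rv[rv$joint == joint, ]
      dof_rows <- list()
      for (dof in unique(rj$dof)) {
        a <- agg(rj[rj$dof == dof, ])
        dof_rows[[dof]] <- cbind(data.frame(variant = variant, joint = joint,
                                            dof = dof), a)
      }
      dr <- do.call(rbind, dof_rows)
      rows[[length(rows) + 1L]] <- dr
      # joint average: mean of the three per-DoF means
      rows[[length(rows) + 1L]] <- data.frame(
        variant = variant, joint = joint, dof = paste0(joint, "_average"),
        n = sum(dr$n), r_mean = mean(dr$r_mean), r_sd = mean(dr$r_sd),
        rmse_mean = mean(dr$rmse_mean), rmse_sd = mean(dr$rmse_sd),
        nrmse_mean = mean(dr$nrmse_mean), nrmse_sd = mean(dr$nrmse_sd))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MANOVA and Tukey HSD across training-set variants
#'
#' One-way MANOVA (Wilks' lambda with the F approximation) on the per-cycle
#' RMSE vectors (one dependent variable per kinematic DoF) with the training
#' variant as the factor, followed by per-DoF one-way ANOVA and Tukey HSD
#' pairwise contrasts at `alpha`.
#'
#' @param records long data.frame with columns `variant`, `cycle_id`, `dof`,
#'   `rmse`; every cycle must have one RMSE per DoF.
#' @param alpha significance level for the post-hoc tests.
#' @return list of class `comparison_result`: `manova` (`wilks`, `approx_f`,
#'   `df`, `p_value`, or `NULL` with a diagnostic if the within-group
#'   covariance is singular), `tukey` (per-DoF data.frame of pairwise
#'   differences and adjusted p), `anova_p` (per-DoF one-way ANOVA p).
#' @export
manova_tukey <- function(records, alpha = 0.05) {
  needed <- c("variant", "cycle_id", "dof", "rmse")
  if (!all(needed %in% names(records))) {
    stop("manova_tukey: records need columns ", paste(needed, collapse = ", "))
  }
  dofs <- unique(records$dof)
  wide <- stats::reshape(records[, needed], idvar = c("variant", "cycle_id"),
                         timevar = "dof", direction = "wide")
  ycols <- paste0("rmse.", dofs)
  wide <- wide[stats::complete.cases(wide[, ycols]), ]
  counts <- table(wide$variant)
  if (length(counts) < 2 || any(counts < 3)) {
    stop("manova_tukey: need >= 2 variants with >= 3 complete cycles each")
  }
  variant <- factor(wide$variant)
  Y <- as.matrix(wide[, ycols])
  man <- tryCatch({
    fit <- stats::manova(Y ~ variant)
    sm <- summary(fit, test = "Wilks")$stats
    list(wilks = unname(sm[1, "Wilks"]),
         approx_f = unname(sm[1, "approx F"]),
         df = unname(c(sm[1, "num Df"], sm[1, "den Df"])),
         p_value = unname(sm[1, "Pr(>F)"]))
  }, error = function(e) {
    warning("manova_tukey: MANOVA failed (", conditionMessage(e),
            "); reporting per-DoF ANOVA only")
    NULL
  })
  tukey <- list(); anova_p <- numeric(0)
  for (j in seq_along(dofs)) {
    df_j <- data.frame(rmse = Y[, j], variant = variant)
    fit_j <- stats::aov(rmse ~ variant, data = df_j)
    anova_p[dofs[j]] <- summary(fit_j)[[1]]["variant", "Pr(>F)"]
    tk <- stats::TukeyHSD(fit_j, conf.level = 1 - alpha)$variant
    tukey[[dofs[j]]] <- data.frame(contrast = rownames(tk),
                                   diff = tk[, "diff"], lwr = tk[, "lwr"],
                                   upr = tk[, "upr"], p_adj = tk[, "p adj"],
                                   significant = tk[, "p adj"] < alpha,
                                   row.names = NULL)
  }
  structure(list(manova = man, tukey = tukey, anova_p = anova_p,
                 alpha = alpha, n_per_variant = as.list(counts)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (!is.null(x$manova)) {
    cat(sprintf("MANOVA (Wilks): lambda = %.4f, F = %.2f, p = %.3g\n",
                x$manova$wilks, x$manova$approx_f, x$manova$p_value))
  } else {
    cat("MANOVA unavailable (singular covariance); per-DoF ANOVA only\n")
  }
  for (d in names(x$tukey)) {
    sig <- x$tukey[[d]]$contrast[x$tukey[[d]]$significant]
    cat(sprintf("  %s: ANOVA p = %.3g%s\n", d, x$anova_p[d],
                if (length(sig)) paste0("; significant: ",
                                        paste(sig, collapse = ", ")) else ""))
  }
  invisible(x)
}
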