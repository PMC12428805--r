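# Cohort-level analysis: normality screening, paired comparisons with
# effect sizes, a random-intercept linear mixed model across the three
# vascular slabs (CC as reference), per-eye classification by the slab of
# greatest displacement, and phenotype associations.

#' Shapiro-Wilk normality test
#'
#' Thin validated wrapper around the standard test; samples must have
#' 3 <= n <= 5000 and non-zero variance.
#' @param x numeric sample
#' @return list(W, p)
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("sample has zero variance")
  r <- stats::shapiro.test(x)
  list(W = unname(r$statistic), p = unname(r$p.value))
}

#' Paired t-test with Cohen's d
#'
#' Cohen's d is mean(diff) / sd(diff). A zero-variance difference is a
#' degenerate case: flagged, with p = 1 when the mean difference is also
#' zero and p = NA otherwise.
#'
#' @param x0,x1 paired samples (equal length, n >= 2)
#' @return list(mean_diff, ci95, t, p, cohens_d, degenerate)
#' @export
paired_t <- function(x0, x1) {
  if (length(x0) != length(x1)) stop("paired samples must have equal length")
  if (length(x0) < 2) stop("need n >= 2 pairs")
  d <- as.numeric(x1) - as.numeric(x0)
  if (stats::sd(d) == 0) {
    return(list(mean_diff = mean(d), ci95 = c(mean(d), mean(d)), t = NA_real_,
                p = if (mean(d) == 0) 1 else NA_real_,
                cohens_d = NA_real_, degenerate = TRUE))
  }
  r <- stats::t.test(x1, x0, paired = TRUE)
  list(mean_diff = unname(r$estimate), ci95 = as.numeric(r$conf.int),
       t = unname(r$statistic), p = unname(r$p.value),
       cohens_d = mean(d) / stats::sd(d), degenerate = FALSE)
}

#' Random-intercept linear mixed model across slabs
#'
#' Fits displacement ~ slab + (1 | patient) by REML with CC the reference
#' category, and reports estimated marginal means (EMMs) per slab with 95%
#' CI, contrasts vs CC, and variance components. On balanced data the
#' EMMs equal the raw slab means. CIs use a t quantile with
#' df = n_patients - 1 (the EMM of a balanced random-intercept design is a
#' mean of n_patients independent patient values); contrasts use
#' containment df = (n_patients - 1) * (n_slabs - 1). An (essentially)
#' zero-residual response is fitted by ordinary least squares with the
#' random-effect variance pinned at zero and `boundary = TRUE`.
#'
#' @param table cohort data.frame (canonical columns)
#' @param response_roi which ROI's records to model (default "whole")
#' @return object of class `LMMResult`: `emm` data.frame (slab, estimate,
#'   se, ci_lo, ci_hi), `contrasts` data.frame vs CC, `var_patient`,
#'   `var_residual`, `p_omnibus`, `boundary`
#' @export
fit_lmm <- function(table, response_roi = "whole") {
  tb <- table[table$roi == response_roi, , drop = FALSE]
  if (nrow(tb) == 0) stop("no records for roi '", response_roi, "'")
  tb$slab <- factor(tb$slab, levels = c("CC", "DCP", "SCP"))
  tb$patient_id <- factor(tb$patient_id)
  np <- nlevels(tb$patient_id)
  nslab <- nlevels(droplevels(tb$slab))
  if (np < 2 || any(table(tb$patient_id) < 2))
    stop("need >= 2 patients with >= 2 slabs each")

  boundary <- FALSE
  resid_sd <- stats::sd(stats::resid(stats::lm(displacement_um ~ slab, data = tb)))
  if (is.na(resid_sd) || resid_sd < 1e-10) {
    # no stochastic variation: OLS is exact, variances are zero
    f <- stats::lm(displacement_um ~ slab, data = tb)
    beta <- stats::coef(f)
    V <- matrix(0, length(beta), length(beta),
                dimnames = list(names(beta), names(beta)))
    var_patient <- 0; var_residual <- 0
    boundary <- TRUE
    p_omnibus <- NA_real_
  } else {
    f <- lme4::lmer(displacement_um ~ slab + (1 | patient_id), data = tb,
                    REML = TRUE)
    beta <- lme4::fixef(f)
    V <- as.matrix(stats::vcov(f))
    vc <- as.data.frame(lme4::VarCorr(f))
    var_patient <- vc$vcov[vc$grp == "patient_id"]
    var_residual <- vc$vcov[vc$grp == "Residual"]
    boundary <- lme4::isSingular(f)
    # omnibus slab effect: likelihood-ratio test of the ML refits
    f_ml <- stats::update(f, REML = FALSE)
    f0 <- stats::update(f_ml, . ~ . - slab)
    p_omnibus <- stats::anova(f0, f_ml)[2, "Pr(>Chisq)"]
  }

  slabs <- c("CC", "DCP", "SCP")
  L <- rbind(CC = c(1, 0, 0), DCP = c(1, 1, 0), SCP = c(1, 0, 1))
  colnames(L) <- names(beta)
  est <- as.numeric(L %*% beta)
  se <- sqrt(pmax(diag(L %*% V %*% t(L)), 0))
  tq <- stats::qt(0.975, df = np - 1)
  emm <- data.frame(slab = slabs, estimate = est, se = se,
                    ci_lo = est - tq * se, ci_hi = est + tq * se,
                    stringsAsFactors = FALSE)

  df_c <- (np - 1) * (nslab - 1)
  ct <- lapply(c("DCP", "SCP"), function(s) {
    j <- paste0("slab", s)
    b <- beta[[j]]; sse <- sqrt(V[j, j])
    tval <- if (sse > 0) b / sse else NA_real_
    data.frame(contrast = paste0(s, " - CC"), estimate = b, se = sse,
               t = tval,
               p = if (is.na(tval)) NA_real_ else
                 2 * stats::pt(-abs(tval), df = df_c),
               stringsAsFactors = FALSE)
  })
  structure(list(emm = emm, contrasts = do.call(rbind, ct),
                 var_patient = var_patient, var_residual = var_residual,
                 p_omnibus = p_omnibus, boundary = boundary,
                 n_patients = np),
            class = "LMMResult")
}

#' @export
print.LMMResult <- function(x, ...) {
  cat("Linear mixed model (REML), patient random intercept, CC reference\n")
  print(x$emm, row.names = FALSE)
  cat(sprintf("patient var %.3f, residual var %.3f%s\n", x$var_patient,
              x$var_residual, if (x$boundary) " [boundary fit]" else ""))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Classify each eye by the slab of greatest mean displacement
#'
#' Uses the whole-image records; ties are broken by the fixed order
#' CC > DCP > SCP and flagged. Eyes missing a slab are skipped with a
#' warning.
#'
#' @param table cohort data.frame
#' @return data.frame(eye_id, max_slab, tie)
#' @export
classify_max_slab <- function(table) {
  tb <- table[table$roi == "whole", , drop = FALSE]
  pref <- c("CC", "DCP", "SCP")
  out <- lapply(split(tb, tb$eye_id), function(e) {
    means <- tapply(e$displacement_um, e$slab, mean)
    if (!all(pref %in% names(means)) || any(is.na(means[pref]))) {
      warning("eye ", e$eye_id[1], " is missing a slab; skipped")
      return(NULL)
    }
    m <- means[pref]
    best <- pref[which.max(m)]   # which.max takes the first, i.e. CC > DCP > SCP
    data.frame(eye_id = e$eye_id[1], max_slab = best,
               tie = sum(m == max(m)) > 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Phenotype association with per-eye displacement classes
#'
#' Cross-tabulates a per-eye label (e.g. the max-displacement slab) with a
#' logical phenotype flag. Per label stratum: count, phenotype count,
#' percentage (one decimal, NA for empty strata) and the two-sided Fisher
#' exact p of the 2x2 collapse (this label vs the rest x flag). The choice
#' of Fisher's exact test is an artifact convention; the source analyses
#' do not name their test.
#'
#' @param labels character/factor vector, one entry per eye
#' @param flags logical vector, same length
#' @return list(table = label x flag contingency table, strata =
#'   data.frame(label, n, k, pct, fisher_p))
#' @export
phenotype_association <- function(labels, flags) {
  stopifnot(length(labels) == length(flags))
  labels <- as.character(labels)
  flags <- as.logical(flags)
  tab <- table(label = labels, flag = factor(flags, levels = c(FALSE, TRUE)))
  strata <- lapply(sort(unique(labels)), function(L) {
    n <- sum(labels == L)
    k <- sum(labels == L & flags)
    p <- if (length(unique(labels)) > 1 && n > 0 && n < length(labels)) {
      m <- matrix(c(k, n - k, sum(flags) - k,
                    sum(!flags) - (n - k)), 2, 2)
      stats::fisher.test(m)$p.value
    } else NA_real_
    data.frame(label = L, n = n, k = k,
               pct = if (n > 0) round(100 * k / n, 1) else NA_real_,
               fisher_p = p, stringsAsFactors = FALSE)
  })
  list(table = tab, strata = do.call(rbind, strata))
}

#' Compare displacement between phenotype groups in one slab
#'
#' Welch two-sample t-test of per-eye whole-image displacement in `slab`
#' by a phenotype flag (artifact convention; the source's test is
#' unstated).
#'
#' @param table cohort data.frame
#' @param slab slab to compare (default "DCP")
#' @param flag phenotype column name (default "rpd")
#' @return list(mean_flag, mean_noflag, t, p)
#' @export
compare_group_displacement <- function(table, slab = "DCP", flag = "rpd") {
  tb <- table[table$roi == "whole" & table$slab == slab, , drop = FALSE]
  g1 <- tb$displacement_um[tb[[flag]]]
  g0 <- tb$displacement_um[!tb[[flag]]]
  if (length(g1) < 2 || length(g0) < 2)
    stop("need >= 2 eyes per group for slab ", slab)
  r <- stats::t.test(g1, g0)
  list(mean_flag = mean(g1), mean_noflag = mean(g0),
       t = unname(r$statistic), p = unname(r$p.value))
}
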