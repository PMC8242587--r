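#' Kaplan-Meier curves and log-rank contrasts between groups
#'
#' Product-limit survival estimates per group and the log-rank chi-square
#' statistic (`df = groups - 1`). With three or more groups, all pairwise
#' log-rank contrasts are also reported, mirroring the convention of marking
#' the overall and every two-group p-value on a survival plot.
#'
#' @param clin Clinical tibble with `sample`, `time`, `event` (see
#'   [read_clinical()]).
#' @param groups Group labels: a tibble with `sample` plus one label column
#'   (e.g. from [classify_phenotypes()]), a vector named by sample, or the
#'   name of a column in `clin`.
#' @return An object of class `km_contrast`: list with `curves` (tibble:
#'   group, time, n_risk, n_event, survival), `overall` (statistic, df,
#'   p_value) and `pairwise`. Has [tidy()]/[glance()] methods.
#' @export
km_logrank <- function(clin, groups) {
  grp <- resolve_groups(clin, groups)
  d <- data.frame(time = clin$time, event = clin$event, group = grp)
  d <- d[!is.na(d$group), , drop = FALSE]
  d$group <- droplevels(factor(d$group))
  if (nlevels(d$group) < 2) abort_ip("need at least 2 non-empty groups")
  if (sum(d$event) == 0) abort_ip("no events; log-rank test undefined")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata_grp <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  curves <- tibble::tibble(
    group = strata_grp, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, survival = fit$surv
  )
  sd_all <- survival::survdiff(survival::Surv(time, event) ~ group, data = d, rho = 0)
  overall <- tibble::tibble(
    statistic = sd_all$chisq,
    df = nlevels(d$group) - 1L,
    p_value = stats::pchisq(sd_all$chisq, df = nlevels(d$group) - 1L,
                            lower.tail = FALSE)
  )
  pairwise <- NULL
  if (nlevels(d$group) >= 3) {
    pairs <- utils::combn(levels(d$group), 2, simplify = FALSE)
    pairwise <- purrr::map_dfr(pairs, function(p) {
      dd <- d[d$group %in% p, , drop = FALSE]
      dd$group <- droplevels(dd$group)
      s <- survival::survdiff(survival::Surv(time, event) ~ group, data = dd, rho = 0)
      tibble::tibble(group1 = p[1], group2 = p[2], statistic = s$chisq,
                     p_value = stats::pchisq(s$chisq, df = 1, lower.tail = FALSE))
    })
  }
  structure(list(curves = curves, overall = overall, pairwise = pairwise),
            class = "km_contrast")
}

resolve_groups <- function(clin, groups) {
  if (is.data.frame(groups)) {
    if (!"sample" %in% names(groups)) abort_ip("group table needs a 'sample' column")
    lab_col <- setdiff(names(groups), c("sample", "cluster_id"))[1]
    groups[[lab_col]][match(clin$sample, groups$sample)]
  } else if (is.character(groups) && length(groups) == 1 && groups %in% names(clin)) {
    clin[[groups]]
  } else if (!is.null(names(groups))) {
    groups[match(clin$sample, names(groups))]
  } else if (length(groups) == nrow(clin)) {
    groups
  } else {
    abort_ip("cannot resolve group labels against the clinical table")
  }
}

#' @export
print.km_contrast <- function(x, ...) {
  cat("log-rank test: chi-square = ", format(x$overall$statistic, digits = 4),
      ", df = ", x$overall$df, ", p = ", format(x$overall$p_value, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Univariable or multivariable Cox proportional-hazards summaries
#'
#' Fits Cox models by partial-likelihood maximisation with Breslow tie
#' handling and reports hazard ratios with Wald 95% confidence intervals and
#' p-values. In univariable mode each covariate is fit alone; in
#' multivariable mode all are fit jointly. Collinear or non-converging terms
#' are flagged (with `NA` hazard ratios) rather than raised, mirroring how
#' inestimable levels are reported as NA in cohort summary tables.
#'
#' @param clin Clinical tibble with `sample`, `time`, `event` and covariate
#'   columns. Factor reference levels are the first level (first-seen file
#'   order from [read_clinical()]).
#' @param covariates Character vector of covariate column names.
#' @param multivariable Fit jointly (`TRUE`) or one at a time (`FALSE`).
#' @return A tibble: `model`, `covariate`, `term`, `hr`, `ci_low`, `ci_high`,
#'   `p_value`, `flag` (`"ok"`, `"collinear"` or `"unstable"`).
#' @export
cox_regression <- function(clin, covariates, multivariable = FALSE) {
  missing_cov <- setdiff(covariates, names(clin))
  if (length(missing_cov)) {
    abort_ip("covariate(s) not in clinical table: ", paste(missing_cov, collapse = ", "))
  }
  model_lab <- if (multivariable) "multivariable" else "univariable"
  fits <- if (multivariable) list(covariates) else as.list(covariates)
  purrr::map_dfr(fits, function(cv) {
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(sprintf("`%s`", cv), collapse = " + ")))
    unstable <- FALSE
    fit <- withCallingHandlers(
      tryCatch(survival::coxph(fml, data = clin, ties = "breslow"),
               error = function(e) NULL),
      warning = function(w) {
        unstable <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    if (is.null(fit)) {
      return(tibble::tibble(model = model_lab, covariate = paste(cv, collapse = "+"),
                            term = NA_character_, hr = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p_value = NA_real_, flag = "unstable"))
    }
    s <- summary(fit)
    co <- stats::coef(fit)
    se <- sqrt(diag(fit$var))
    terms <- names(co)
    # map each term back to its covariate
    cov_of_term <- vapply(terms, function(tm) {
      hit <- cv[vapply(cv, function(v) startsWith(tm, v) || startsWith(tm, sprintf("`%s`", v)),
                       logical(1))]
      if (length(hit)) hit[1] else tm
    }, character(1))
    out <- tibble::tibble(
      model = model_lab,
      covariate = unname(cov_of_term),
      term = terms,
      hr = unname(exp(co)),
      ci_low = unname(exp(co - 1.96 * se)),
      ci_high = unname(exp(co + 1.96 * se)),
      p_value = unname(2 * stats::pnorm(-abs(co / se))),
      flag = unname(ifelse(is.na(co), "collinear",
                           if (unstable) "unstable" else "ok"))
    )
    out$hr[is.na(co)] <- NA_real_
    out
  })
}
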