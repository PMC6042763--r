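#' Build the nested fixed-effects design
#'
#' Constructs treatment-coded dummies for the two model families used to
#' compare ecotypes: a main ecotype contrast (reference: piscivorous), a sex
#' contrast (reference: female), and a factor nested within ecotype - either
#' stocking history (reference: unstocked) or genetic origin (reference:
#' stocked, so local and hybrid terms are contrasts against stocked fish).
#' Nested dummies are ecotype-specific: e.g. the hybrid effect is estimated
#' separately within piscivorous and within planktivorous populations, with
#' term labels of the form "Hybrid-planktivorous".
#'
#' @param data data.frame with columns lake, ecotype, sex and either
#'   `stocked` (logical) or `origin` (local/hybrid/stocked)
#' @param nested which factor is nested within ecotype
#' @return list with `data` (input plus dummy columns), `terms` (dummy
#'   column names, excluding the intercept) and `labels` (report labels,
#'   including "Intercept")
#' @export
build_design <- function(data, nested = c("stocking", "origin")) {
  nested <- match.arg(nested)
  check_levels <- function(x, allowed, field) {
    bad <- setdiff(unique(as.character(x)), allowed)
    if (length(bad) > 0) {
      stop(sprintf("build_design: unknown %s level(s): %s", field,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_levels(data$ecotype, c("piscivorous", "planktivorous"), "ecotype")
  check_levels(data$sex, c("female", "male"), "sex")
  d <- data
  d$ecotype_planktivorous <- as.numeric(d$ecotype == "planktivorous")
  d$sex_male <- as.numeric(d$sex == "male")
  terms <- c("ecotype_planktivorous", "sex_male")
  labels <- c("Intercept", "Ecotype (planktivorous)", "Sex (male)")
  if (nested == "stocking") {
    if (is.null(d$stocked)) {
      stop("build_design: column 'stocked' required for the stocking model",
           call. = FALSE)
    }
    for (eco in c("piscivorous", "planktivorous")) {
      col <- paste0("stocking_", eco)
      d[[col]] <- as.numeric(d$stocked & d$ecotype == eco)
      terms <- c(terms, col)
      labels <- c(labels, paste0("Stocking-", eco))
    }
  } else {
    if (is.null(d$origin)) {
      stop("build_design: column 'origin' required for the origin model",
           call. = FALSE)
    }
    check_levels(d$origin, c("local", "hybrid", "stocked"), "origin")
    for (org in c("hybrid", "local")) {
      for (eco in c("piscivorous", "planktivorous")) {
        col <- paste0(org, "_", eco)
        d[[col]] <- as.numeric(d$origin == org & d$ecotype == eco)
        terms <- c(terms, col)
        labels <- c(labels,
                    paste0(toupper(substring(org, 1, 1)), substring(org, 2),
                           "-", eco))
      }
    }
  }
  list(data = d, terms = terms, labels = labels, nested = nested)
}

#' Fit a nested linear mixed-effects model with lake as a random intercept
#'
#' Fits response ~ ecotype + nested-factor-within-ecotype + sex with a
#' random intercept per lake by REML, the model family used to compare
#' total length and age across stocking histories and to compare growth
#' parameters and condition across genetic origins. p-values use the fitted
#' model's t statistics with containment-style (inner-outer) denominator
#' degrees of freedom. If the random-intercept variance is unidentifiable
#' (e.g. one fish per lake) or the fit fails, the model falls back to
#' ordinary least squares on the same fixed effects with a logged warning.
#'
#' @param data data.frame with lake, ecotype, sex, the nested factor column
#'   and the response
#' @param response name of the response column (e.g. "tl_mm", "linf",
#'   "omega", "wr")
#' @param nested "stocking" or "origin"
#' @return object of class `stocking_mixed_model`: coefficient `table`
#'   (term, estimate, se, df, p), `method` ("REML" or "OLS"), `random_sd`,
#'   `n_grp`, `n_obs`, `response`
#' @export
fit_mixed <- function(data, response, nested = c("stocking", "origin")) {
  nested <- match.arg(nested)
  des <- build_design(data, nested)
  d <- des$data
  d$.y <- d[[response]]
  keep <- stats::complete.cases(d[c(".y", des$terms, "lake")])
  d <- d[keep, , drop = FALSE]
  fixed <- stats::as.formula(paste(".y ~", paste(des$terms, collapse = " + ")))

  result <- tryCatch({
    if (max(table(d$lake)) < 2) {
      stop("random-intercept variance unidentifiable: one fish per lake")
    }
    fit <- nlme::lme(fixed = fixed, random = ~ 1 | lake, data = d,
                     method = "REML")
    tt <- summary(fit)$tTable
    list(table = data.frame(term = des$labels,
                            estimate = tt[, "Value"],
                            se = tt[, "Std.Error"],
                            df = tt[, "DF"],
                            p = tt[, "p-value"],
                            stringsAsFactors = FALSE),
         method = "REML",
         random_sd = as.numeric(nlme::VarCorr(fit)["(Intercept)", "StdDev"]),
         fit = fit)
  }, error = function(e) NULL)

  if (is.null(result)) {
    warning("fit_mixed: mixed model unidentifiable or failed; ",
            "falling back to fixed-effects OLS")
    fit <- stats::lm(fixed, data = d)
    ct <- summary(fit)$coefficients
    result <- list(table = data.frame(term = des$labels,
                                      estimate = ct[, "Estimate"],
                                      se = ct[, "Std. Error"],
                                      df = stats::df.residual(fit),
                                      p = ct[, "Pr(>|t|)"],
                                      stringsAsFactors = FALSE),
                   method = "OLS", random_sd = NA_real_, fit = fit)
  }
  rownames(result$table) <- NULL
  structure(list(table = result$table, method = result$method,
                 df_method = "containment (inner-outer)",
                 random_sd = result$random_sd,
                 n_grp = length(unique(d$lake)), n_obs = nrow(d),
                 response = response, nested = nested, fit = result$fit),
            class = "stocking_mixed_model")
}

#' @export
print.stocking_mixed_model <- function(x, ...) {
  cat(sprintf("Nested mixed model (%s within ecotype), response: %s [%s]\n",
              x$nested, x$response, x$method))
  tab <- x$table
  tab$estimate <- round(tab$estimate, 3)
  tab$se <- round(tab$se, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Random intercept SD (lake): %s;  N_grp = %d;  Observations = %d\n",
              ifelse(is.na(x$random_sd), "-", sprintf("%.2f", x$random_sd)),
              x$n_grp, x$n_obs))
  invisible(x)
}

#' Tidy coefficient report across fitted mixed models
#'
#' Stacks the coefficient tables of one or more fitted models into the
#' shape of a published mixed-model table: one row per term per response,
#' with a significance flag at p < 0.05 and fit metadata.
#'
#' @param fits a `stocking_mixed_model` or a list of them
#' @return data.frame with response, term, estimate, se, p, significant,
#'   method, n_grp, n_obs
#' @export
report_tables <- function(fits) {
  if (inherits(fits, "stocking_mixed_model")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(response = f$response, f$table,
               significant = f$table$p < 0.05,
               method = f$method, n_grp = f$n_grp, n_obs = f$n_obs,
               stringsAsFactors = FALSE)
  }))
}
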