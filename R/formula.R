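#' Model formula for the two-state semi-Markov model
#'
#' Specifies the structure to be fitted: the sojourn family per transition
#' direction (both directions use the same family by default, with separate
#' parameters), the covariates entering each direction's scale link, whether
#' subject frailty is active per direction, how the log study-length term is
#' handled, and an optional attached dropout submodel.
#'
#' The log study-length term accounts for variation in how long individuals
#' stay in the study. With \code{study_length_term = "auto"} (default) the
#' term is included whenever study lengths vary across subjects and dropped
#' when they are constant — a constant column would make \eqn{\theta_0} and
#' its coefficient exactly confounded under the vague prior. Internally the
#' column is centred for sampling efficiency and \eqn{\theta_0} is reported
#' on the uncentred parameterisation.
#'
#' @param family Sojourn family for both directions (see [families]).
#' @param covariates1,covariates2 Character vectors of subject covariates for
#'   the 1 to 2 and 2 to 1 directions (subset of \code{treatment},
#'   \code{disease_stage}, \code{smoke}, \code{pack_years}, \code{season}).
#' @param frailty1,frailty2 Logical; subject frailty on the scale parameter
#'   per direction.
#' @param family2 Family for the 2 to 1 direction, when it should differ.
#' @param study_length_term \code{"auto"}, \code{"on"} or \code{"off"}.
#' @param dropout \code{NULL} or a [dropout_formula()] to fit jointly.
#' @return An object of class \code{"two_state_formula"}.
#' @examples
#' two_state_formula("loglogistic", covariates1 = c("treatment"))
#' @export
two_state_formula <- function(family = "loglogistic",
                              covariates1 = character(0),
                              covariates2 = character(0),
                              frailty1 = TRUE, frailty2 = TRUE,
                              family2 = family,
                              study_length_term = c("auto", "on", "off"),
                              dropout = NULL) {
  family <- match_family(family)
  family2 <- match_family(family2)
  study_length_term <- match.arg(study_length_term)
  for (cv in list(covariates1, covariates2)) {
    bad <- setdiff(cv, subject_covariate_names)
    if (length(bad))
      stop("unknown covariate(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(dropout) && !inherits(dropout, "dropout_formula"))
    stop("`dropout` must be a dropout_formula()", call. = FALSE)
  structure(list(family = c(family, family2),
                 covariates = list(covariates1, covariates2),
                 frailty = c(isTRUE(frailty1), isTRUE(frailty2)),
                 study_length_term = study_length_term,
                 dropout = dropout),
            class = "two_state_formula")
}

#' @export
print.two_state_formula <- function(x, ...) {
  for (k in 1:2) {
    cat(sprintf("  %d -> %d: %s(%s)%s\n", k, 3 - k, x$family[k],
                paste(c("1", x$covariates[[k]]), collapse = " + "),
                if (x$frailty[k]) " + frailty" else ""))
  }
  cat("  study-length term:", x$study_length_term, "\n")
  if (!is.null(x$dropout))
    cat("  dropout submodel:", x$dropout$family, "\n")
  invisible(x)
}

# resolve the study-length rule against a dataset
formula_sl_term <- function(formula, dataset) {
  switch(formula$study_length_term,
         on = TRUE, off = FALSE,
         auto = isTRUE(stats::var(log(dataset$subjects$study_length)) > 0))
}

#' Dropout model formula
#'
#' A standalone parametric time-to-dropout model. A subject is a dropout when
#' follow-up ends more than the dropout window before the nominal study end;
#' other subjects are right-censored at their observed end of follow-up.
#' Covariates may include the subject-level fields plus quantities derived
#' from the observed event history, treated as fixed covariates in the
#' separate-fit sense: \code{n_exacerbations} (number of symptomatic
#' episodes) and \code{state2_time} (total observed days in state 2).
#'
#' @param family \code{"exponential"}, \code{"weibull"} or
#'   \code{"loglogistic"} (the Gompertz family is not offered for dropout).
#' @param covariates Character vector from \code{treatment},
#'   \code{disease_stage}, \code{smoke}, \code{pack_years}, \code{season},
#'   \code{n_exacerbations}, \code{state2_time}.
#' @return An object of class \code{"dropout_formula"}.
#' @export
dropout_formula <- function(family = "loglogistic",
                            covariates = character(0)) {
  family <- match_family(family)
  if (family == "gompertz")
    stop("dropout family must be exponential, weibull or loglogistic",
         call. = FALSE)
  bad <- setdiff(covariates,
                 c(subject_covariate_names, "n_exacerbations", "state2_time"))
  if (length(bad))
    stop("unknown dropout covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(family = family, covariates = covariates),
            class = "dropout_formula")
}

#' Attach a dropout submodel to a two-state formula
#'
#' Under the missing-at-random assumption the joint likelihood factorises, so
#' the joint deviance is the sum of the two-state and dropout deviances at
#' identical parameters; fitting jointly re-estimates both blocks.
#'
#' @param formula A [two_state_formula()].
#' @param dropout A [dropout_formula()].
#' @return The formula with the dropout block attached.
#' @export
attach_dropout <- function(formula, dropout) {
  stopifnot(inherits(formula, "two_state_formula"),
            inherits(dropout, "dropout_formula"))
  formula$dropout <- dropout
  formula
}

# Dropout context: one row per subject. Event time = observed end of
# follow-up; event = dropout flag (window rule applied at dataset build).
dropout_context <- function(dataset, dformula, sl_term, center_sl = FALSE) {
  sub <- dataset$subjects
  soj <- dataset$sojourns
  fu <- tapply(soj$duration, soj$subject_id, sum)[sub$subject_id]
  fu[is.na(fu)] <- sub$study_length[is.na(fu)]
  miss <- setdiff(dformula$covariates,
                  c(names(sub), "n_exacerbations", "state2_time"))
  if (length(miss))
    stop("dropout covariate(s) absent from dataset: ",
         paste(miss, collapse = ", "), call. = FALSE)
  cols <- list()
  center <- 0
  if (sl_term) {
    lsl <- log(sub$study_length)
    if (center_sl) {
      center <- mean(lsl)
      lsl <- lsl - center
    }
    cols$log_study_length <- lsl
  }
  for (nm in dformula$covariates) {
    cols[[nm]] <- switch(nm,
      n_exacerbations = as.vector(
        tapply(soj$state == 2, soj$subject_id, sum)[sub$subject_id]),
      state2_time = as.vector(
        tapply(soj$duration * (soj$state == 2), soj$subject_id,
               sum)[sub$subject_id]),
      sub[[nm]])
    cols[[nm]][is.na(cols[[nm]])] <- 0
  }
  X <- if (length(cols)) do.call(cbind, cols) else matrix(0, nrow(sub), 0)
  list(t = as.numeric(fu), log_t = log(as.numeric(fu)),
       event = sub$dropout_flag,
       subj = seq_len(nrow(sub)), X = X, n_subjects = nrow(sub),
       n_rows = nrow(sub), sl_center = center)
}
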