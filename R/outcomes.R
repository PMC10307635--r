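#' Aggregate per-sample skill probabilities to the case level
#'
#' A surgical case has a single clinical outcome but many video samples;
#' this replaces Z1 by its within-case mean and validates that the
#' case-level covariates (Z2, Z3) and outcome (Y) are constant within
#' each case.
#'
#' @param records data.frame with columns \code{case_id}, \code{Z1},
#'   \code{Z2}, \code{Z3}, \code{Y}.
#' @return One row per case, same columns.
#' @export
aggregateCase <- function(records) {
  need <- c("case_id", "Z1", "Z2", "Z3", "Y")
  if (!all(need %in% names(records)))
    stop(sprintf("records must have columns: %s", paste(need, collapse = ", ")))
  out <- lapply(split(records, records$case_id), function(df) {
    for (col in c("Z2", "Z3", "Y")) {
      if (length(unique(df[[col]])) != 1)
        stop(sprintf("case '%s' has conflicting values of %s",
                     df$case_id[1], col))
    }
    data.frame(case_id = df$case_id[1], Z1 = mean(df$Z1), Z2 = df$Z2[1],
               Z3 = df$Z3[1], Y = df$Y[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Adjusted logistic association of decoded skill with a binary outcome
#'
#' Fits \code{Y ~ Z1 + Z2 + Z3} by maximum-likelihood logistic
#' regression, where Z1 is the decoded high-skill probability, Z2 the
#' surgeon caseload and Z3 the patient age. Reports the odds ratio
#' \code{exp(b1)} — the outcome odds under a high-skill versus a
#' low-skill assessment — with a Wald 95% confidence interval and
#' p-value. Standard errors are not adjusted for within-case
#' correlation in the per-sample variant, mirroring the unadjusted
#' analysis; use [aggregateCase()] first for the per-case variant.
#'
#' @param records data.frame with columns \code{Z1}, \code{Z2},
#'   \code{Z3}, \code{Y} (both outcome classes present; n > 4).
#' @param variant label recorded in the fit (\code{"per-sample"} or
#'   \code{"per-case"}).
#' @return List of class \code{"outcomeFit"} with \code{coefficients}
#'   (b0..b3), \code{se}, \code{or}, \code{ci} (95%), \code{p_value},
#'   \code{n}, \code{variant}, \code{separation} flag and the underlying
#'   \code{glm} fit.
#' @export
fitOutcomeModel <- function(records, variant = c("per-sample", "per-case")) {
  variant <- match.arg(variant)
  need <- c("Z1", "Z2", "Z3", "Y")
  if (!all(need %in% names(records)))
    stop(sprintf("records must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(records) <= 4) stop("more than 4 records are required")
  if (length(unique(records$Y)) < 2)
    stop("both outcome classes must be present")
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(Y ~ Z1 + Z2 + Z3, family = stats::binomial(), data = records),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)
  co <- sm$coefficients
  separation <- warned || any(abs(co[, "Estimate"]) > 15) ||
    any(co[, "Std. Error"] > 1e3)
  b1 <- co["Z1", "Estimate"]
  se1 <- co["Z1", "Std. Error"]
  if (separation) {
    warning("possible complete separation; odds ratio not estimable")
    or <- NA_real_; ci <- c(NA_real_, NA_real_); pv <- NA_real_
  } else {
    or <- exp(b1)
    ci <- exp(b1 + c(-1, 1) * stats::qnorm(0.975) * se1)
    pv <- co["Z1", "Pr(>|z|)"]
  }
  structure(list(
    coefficients = stats::setNames(co[, "Estimate"],
                                   c("b0", "b1", "b2", "b3")),
    se = stats::setNames(co[, "Std. Error"], c("b0", "b1", "b2", "b3")),
    or = or, ci = ci, p_value = pv, n = nrow(records), variant = variant,
    separation = separation, fit = fit
  ), class = "outcomeFit")
}

#' @export
print.outcomeFit <- function(x, ...) {
  cat(sprintf("Logistic outcome association (%s, n = %d)\n", x$variant, x$n))
  if (x$separation) {
    cat("  complete separation suspected; no estimate\n")
  } else {
    cat(sprintf("  OR (high vs low skill) = %.3f, 95%% CI %.3f-%.3f, p = %.4g\n",
                x$or, x$ci[1], x$ci[2], x$p_value))
  }
  invisible(x)
}

#' Read outcome records from TSV / write a fit report as JSON
#'
#' @param path file path.
#' @return \code{readOutcomeRecords} returns the records data.frame.
#' @export
readOutcomeRecords <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("case_id", "Z1", "Z2", "Z3", "Y")
  if (!all(need %in% names(df)))
    stop(sprintf("outcome TSV must have columns: %s",
                 paste(need, collapse = ", ")))
  if (any(df$Z1 < 0 | df$Z1 > 1)) stop("Z1 must lie in [0, 1]")
  if (!all(df$Y %in% c(0, 1))) stop("Y must be binary (0/1)")
  df
}

#' @rdname readOutcomeRecords
#' @param fitObj an \code{outcomeFit}.
#' @export
writeOutcomeFit <- function(fitObj, path) {
  jsonlite::write_json(list(
    variant = fitObj$variant, n = fitObj$n,
    coefficients = as.list(fitObj$coefficients),
    or = fitObj$or, ci_low = fitObj$ci[1], ci_high = fitObj$ci[2],
    p_value = fitObj$p_value, separation = fitObj$separation
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
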