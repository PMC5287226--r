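# Jonckheere-Terpstra statistic: sum over ordered group pairs (i < j) of
# Mann-Whitney counts of group-j values exceeding group-i values, ties
# counted 1/2.
jt_statistic <- function(values, groups) {
  lev <- levels(groups)
  J <- 0
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      if (i < j) {
        xi <- values[groups == lev[i]]
        xj <- values[groups == lev[j]]
        cmp <- outer(xi, xj, function(a, b) (a < b) + 0.5 * (a == b))
        J <- J + sum(cmp)
      }
    }
  }
  J
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend of a continuous value across ordered groups
#' (e.g. a metagene score across tumor grades 1 < 2 < 3). The statistic is
#' the sum over ordered group pairs of Mann-Whitney counts (ties 1/2). The
#' two-sided p uses the normal approximation with the tie-corrected variance;
#' when the total sample size is at most \code{exact_max} an exact permutation
#' p is computed instead by full enumeration of group-label assignments.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) whose level order declares the trend
#'   direction; at least 2 non-empty groups.
#' @param exact_max total-n ceiling for the exact enumeration (default 12).
#' @return list(statistic, p_value, method = "exact" | "normal", mean, sd).
#' @export
jonckheere_terpstra <- function(values, groups, exact_max = 12L) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty ordered groups")
  N <- length(values)
  ni <- as.vector(table(groups))
  J <- jt_statistic(values, groups)
  # tie-corrected null moments (Hollander & Wolfe)
  tj <- as.vector(table(values))
  mu <- (N^2 - sum(ni^2)) / 4
  v1 <- N * (N - 1) * (2 * N + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  v2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
  v3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
  sigma2 <- v1 / 72 +
    v2 / (36 * N * (N - 1) * (N - 2)) +
    v3 / (8 * N * (N - 1))
  if (N <= exact_max) {
    perms <- all_group_assignments(N, ni)
    stats <- vapply(perms, function(g) {
      jt_statistic(values, factor(levels(groups)[g], levels = levels(groups)))
    }, numeric(1))
    p_ge <- mean(stats >= J - 1e-9)
    p_le <- mean(stats <= J + 1e-9)
    p <- min(1, 2 * min(p_ge, p_le))
    return(list(statistic = J, p_value = p, method = "exact",
                mean = mu, sd = sqrt(sigma2)))
  }
  # continuity-corrected normal approximation; the 1/2 correction keeps the
  # approximation within ~0.01 of the exact tail at small n
  zstat <- (abs(J - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(zstat, 0)))
  list(statistic = J, p_value = p, method = "normal", mean = mu, sd = sqrt(sigma2))
}

# Enumerate all distinct assignments of N positions to groups with sizes ni.
# Returns a list of integer vectors (group index per position).
all_group_assignments <- function(N, ni) {
  assign_rec <- function(positions, sizes, gi) {
    if (length(sizes) == 1L) {
      res <- rep.int(gi, length(positions))
      names(res) <- positions
      return(list(res))
    }
    combs <- utils::combn(positions, sizes[1L], simplify = FALSE)
    out <- list()
    for (cc in combs) {
      rest <- assign_rec(setdiff(positions, cc), sizes[-1L], gi + 1L)
      for (r in rest) {
        res <- c(stats::setNames(rep.int(gi, length(cc)), cc), r)
        out <- c(out, list(res))
      }
    }
    out
  }
  raw <- assign_rec(seq_len(N), ni, 1L)
  lapply(raw, function(r) as.integer(r[as.character(seq_len(N))]))
}

#' Prepare a patient cohort for survival analysis
#'
#' Applies the 10-year horizon (administrative censoring at 120 months) and
#' the standard covariate codings: lymph node = 1 if at least one positive
#' node; tumor size = 1 if strictly greater than 2 cm.
#'
#' @param cohort data.frame with columns time (months), event (0/1), grade,
#'   and optionally node_count, tumor_size_cm.
#' @param horizon_months administrative censoring horizon (default 120).
#' @return The cohort with time/event truncated and node_bin / size_bin added.
#' @export
prepare_cohort <- function(cohort, horizon_months = 120) {
  stopifnot(all(c("time", "event") %in% names(cohort)))
  if (any(cohort$time <= 0)) stop("survival times must be positive")
  over <- cohort$time > horizon_months
  cohort$event[over] <- 0L
  cohort$time[over] <- horizon_months
  if ("node_count" %in% names(cohort)) {
    cohort$node_bin <- as.integer(cohort$node_count >= 1)
  }
  if ("tumor_size_cm" %in% names(cohort)) {
    cohort$size_bin <- as.integer(cohort$tumor_size_cm > 2)
  }
  cohort
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param time,event numeric survival times and 0/1 event flags.
#' @param group binary group label (factor or coercible, both groups
#'   nonempty).
#' @return list(curves = tidy data.frame(group, time, survival, at_risk),
#'   chisq, p_value).
#' @export
km_logrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("need exactly two nonempty groups")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata), time = fit$time,
                       survival = fit$surv, at_risk = fit$n.risk,
                       stringsAsFactors = FALSE)
  if (sum(event) == 0) {
    return(list(curves = curves, chisq = 0, p_value = 1))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, chisq = unname(sd_$chisq), p_value = p)
}

#' Dichotomize a metagene on the discovery cohort and validate
#'
#' Splits the discovery cohort at each candidate quantile of the score,
#' computes the two-group log-rank p at each, and selects the split with the
#' smallest discovery p (ties broken toward the quantile closest to 0.5;
#' splits leaving a group with zero events are skipped). The chosen cutoff
#' VALUE is then applied to the validation cohort.
#'
#' @param scores named or plain numeric vector of discovery metagene scores.
#' @param survival_df data.frame(time, event) aligned with \code{scores}.
#' @param config a \code{pipeline_config} (candidate quantiles).
#' @param validation optional list(scores, survival_df) for the validation
#'   cohort.
#' @return A \code{stratification_result}: list(quantile, cutoff, group_sizes,
#'   chisq, p_value, table (per-quantile p), km, validation_p (or NA),
#'   validation_km).
#' @export
dichotomize <- function(scores, survival_df, config = pipeline_config(),
                        validation = NULL) {
  stopifnot(all(c("time", "event") %in% names(survival_df)),
            length(scores) == nrow(survival_df))
  if (sum(survival_df$event) < 10) stop("need at least 10 events in discovery")
  qs <- config$cut_quantiles
  res <- data.frame(quantile = qs, cutoff = NA_real_, p_value = NA_real_,
                    n_low = NA_integer_, n_high = NA_integer_)
  for (i in seq_along(qs)) {
    cut <- stats::quantile(scores, qs[i], names = FALSE)
    grp <- factor(ifelse(scores > cut, "high", "low"), levels = c("low", "high"))
    if (any(table(grp) == 0L)) next
    ev <- tapply(survival_df$event, grp, sum)
    if (any(ev == 0)) next  # degenerate split: skip, logged in the table
    lr <- km_logrank(survival_df$time, survival_df$event, grp)
    res$cutoff[i] <- cut
    res$p_value[i] <- lr$p_value
    res$n_low[i] <- sum(grp == "low")
    res$n_high[i] <- sum(grp == "high")
  }
  ok <- which(!is.na(res$p_value))
  if (!length(ok)) stop("every candidate split was degenerate")
  best_p <- min(res$p_value[ok])
  cand <- ok[res$p_value[ok] <= best_p + 1e-12]
  best <- cand[which.min(abs(res$quantile[cand] - 0.5))]
  cut <- res$cutoff[best]
  grp <- factor(ifelse(scores > cut, "high", "low"), levels = c("low", "high"))
  km <- km_logrank(survival_df$time, survival_df$event, grp)
  out <- list(quantile = res$quantile[best], cutoff = cut,
              group_sizes = table(grp), chisq = km$chisq,
              p_value = km$p_value, table = res, km = km$curves,
              validation_p = NA_real_, validation_km = NULL)
  if (!is.null(validation)) {
    vg <- factor(ifelse(validation$scores > cut, "high", "low"),
                 levels = c("low", "high"))
    if (all(table(vg) > 0L)) {
      vkm <- km_logrank(validation$survival_df$time,
                        validation$survival_df$event, vg)
      out$validation_p <- vkm$p_value
      out$validation_km <- vkm$curves
    }
  }
  class(out) <- "stratification_result"
  out
}

#' Cox proportional-hazards fits for a metagene
#'
#' Univariate (metagene alone) and multivariate (metagene + tumor size +
#' grade + lymph node status) partial-likelihood fits with Efron tie
#' handling; significance by the Wald test. Covariates must already carry the
#' standard codings from \code{\link{prepare_cohort}}.
#'
#' @param cohort prepared cohort data.frame (time, event, grade, node_bin,
#'   size_bin).
#' @param scores numeric metagene score per patient.
#' @return A \code{cox_result}: list(univariate, multivariate) data.frames
#'   (term, coef, hr, se, wald_z, p_value), plus the coding record.
#' @export
cox_fit <- function(cohort, scores) {
  stopifnot(all(c("time", "event") %in% names(cohort)),
            length(scores) == nrow(cohort))
  if (sum(cohort$event) < 10) stop("need at least 10 events")
  d <- cohort
  d$metagene <- scores
  tidy <- function(fit) {
    s <- summary(fit)
    cf <- s$coefficients
    if (any(!is.finite(cf[, "se(coef)"])) || any(cf[, "se(coef)"] > 100)) {
      stop("separation detected in Cox fit (unbounded coefficient)")
    }
    data.frame(term = rownames(cf), coef = cf[, "coef"],
               hr = cf[, "exp(coef)"], se = cf[, "se(coef)"],
               wald_z = cf[, "z"], p_value = cf[, "Pr(>|z|)"],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  uni <- survival::coxph(survival::Surv(time, event) ~ metagene, data = d,
                         ties = "efron")
  multi_terms <- intersect(c("size_bin", "grade", "node_bin"), names(d))
  f <- stats::as.formula(paste("survival::Surv(time, event) ~ metagene +",
                               paste(multi_terms, collapse = " + ")))
  multi <- survival::coxph(f, data = d, ties = "efron")
  if (!is.null(multi$info) && isTRUE(multi$info$convergence > 0)) {
    stop("Cox fit did not converge")
  }
  structure(list(univariate = tidy(uni), multivariate = tidy(multi),
                 coding = c(node_bin = "1 if >= 1 positive node",
                            size_bin = "1 if tumor size > 2 cm")),
            class = "cox_result")
}

#' Read a patient cohort CSV
#'
#' Expected columns: patient_id, time, event, grade, subtype, node_count,
#' tumor_size_cm, then one column per gene (prefixed \code{expr_}).
#'
#' @param path CSV path.
#' @return list(clinical = data.frame, expression = genes x patients matrix).
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  expr_cols <- grep("^expr_", names(d), value = TRUE)
  expr <- t(as.matrix(d[expr_cols]))
  rownames(expr) <- sub("^expr_", "", expr_cols)
  colnames(expr) <- d$patient_id
  list(clinical = d[setdiff(names(d), expr_cols)], expression = expr)
}

#' Write stratification and Cox results
#' @param strat a \code{stratification_result}.
#' @param cox a \code{cox_result} (or NULL).
#' @param prefix output path prefix.
#' @export
write_clinical <- function(strat, cox = NULL, prefix) {
  utils::write.csv(strat$table, paste0(prefix, "_stratification.csv"),
                   row.names = FALSE)
  utils::write.csv(strat$km, paste0(prefix, "_km.csv"), row.names = FALSE)
  if (!is.null(cox)) {
    utils::write.csv(rbind(cbind(model = "univariate", cox$univariate),
                           cbind(model = "multivariate", cox$multivariate)),
                     paste0(prefix, "_cox.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(quantile = strat$quantile, cutoff = strat$cutoff,
                            p_value = strat$p_value,
                            validation_p = strat$validation_p),
                       paste0(prefix, "_stratification.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
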