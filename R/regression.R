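# Cross-domain performance comparison: pooled d-prime per experimental
# condition per domain, then least-squares regression of melody performance
# on rhythm performance with a framework interaction, plus the
# individual-participant variant.

#' Pooled d-prime per condition cell, paired across domains
#'
#' Computes pooled d-prime per framework side for each experimental factor
#' level (manipulation size, direction, contour impact, referent) in each
#' domain, and pairs the rhythm and melody values. `cells = "marginal"`
#' gives one row per factor level per framework side (each factor analysed
#' separately, marginalising over the others); `cells = "crossed"` crosses
#' referent, contour and manipulation size into joint cells.
#'
#' @param trials A trial table.
#' @param scale Reminder-design factor, see [dprime()].
#' @param cells `"marginal"` or `"crossed"`.
#' @return A data frame with columns `condition`, `framework_side`,
#'   `d_rhythm`, `d_melody`.
#' @export
condition_performance <- function(trials, scale = 2,
                                  cells = c("marginal", "crossed")) {
  cells <- match.arg(cells)
  pair_domains <- function(res, cond_cols) {
    res$condition <- do.call(paste, c(res[, cond_cols, drop = FALSE],
                                      sep = ":"))
    r <- res[res$domain == "rhythm", c("condition", "framework_class",
                                       "d_prime")]
    m <- res[res$domain == "melody", c("condition", "framework_class",
                                       "d_prime")]
    names(r)[3] <- "d_rhythm"
    names(m)[3] <- "d_melody"
    out <- merge(r, m, by = c("condition", "framework_class"))
    names(out)[names(out) == "framework_class"] <- "framework_side"
    out
  }
  if (cells == "crossed") {
    res <- sdt_analysis(trials, c("domain", "framework_class", "referent",
                                  "contour_class", "manipulation_size"),
                        scale = scale)
    return(pair_domains(res, c("referent", "contour_class",
                               "manipulation_size")))
  }
  factors <- c("manipulation_size", "manipulation_sign", "contour_class",
               "referent")
  out <- lapply(factors, function(f) {
    res <- sdt_analysis(trials, c("domain", "framework_class", f),
                        scale = scale)
    res$condition <- paste0(f, "=", res[[f]])
    pd <- pair_domains(res, "condition")
    pd
  })
  do.call(rbind, out)
}

#' Pooled d-prime per participant per framework side, paired across domains
#'
#' The individual-level analogue of [condition_performance()]: one row per
#' participant per framework side with that participant's pooled rhythm and
#' melody d-prime and the musical-training covariate.
#'
#' @inheritParams condition_performance
#' @return A data frame with columns `participant`, `trained`,
#'   `framework_side`, `d_rhythm`, `d_melody`.
#' @export
participant_performance <- function(trials, scale = 2) {
  res <- sdt_analysis(trials, c("participant", "domain", "framework_class"),
                      scale = scale)
  r <- res[res$domain == "rhythm", c("participant", "framework_class",
                                     "d_prime")]
  m <- res[res$domain == "melody", c("participant", "framework_class",
                                     "d_prime")]
  names(r)[3] <- "d_rhythm"
  names(m)[3] <- "d_melody"
  out <- merge(r, m, by = c("participant", "framework_class"))
  names(out)[names(out) == "framework_class"] <- "framework_side"
  trained <- unique(trials[, c("participant", "trained")])
  out <- merge(out, trained, by = "participant")
  out[order(out$participant, out$framework_side),
      c("participant", "trained", "framework_side", "d_rhythm", "d_melody")]
}

summarise_fit <- function(fit) {
  s <- summary(fit)
  co <- s$coefficients
  list(fit = fit,
       coefficients = co,
       adj_r_squared = s$adj.r.squared,
       p_values = co[, "Pr(>|t|)"],
       sigma = s$sigma)
}

#' Grouped cross-domain regression
#'
#' Least-squares fit of `d_melody ~ d_rhythm * framework_side` on a
#' condition-performance table: does performance on rhythm conditions
#' predict performance on the matching melody conditions, and does the
#' slope differ between in- and out-of-framework conditions? Reports the
#' coefficients, the out-of-framework simple slope, adjusted R-squared and
#' standard-theory p-values.
#'
#' @param perf A table from [condition_performance()] (or any data frame
#'   with `d_rhythm`, `d_melody`, `framework_side` with at least 3 rows per
#'   side).
#' @return A list with `fit` (the `lm` object), `coefficients`,
#'   `out_slope`, `adj_r_squared`, `p_values`.
#' @export
grouped_regression <- function(perf) {
  stopifnot(all(c("d_rhythm", "d_melody", "framework_side") %in%
                names(perf)))
  if (any(table(perf$framework_side) < 3)) {
    stop("need at least 3 condition rows per framework side")
  }
  perf$framework_side <- factor(perf$framework_side, levels = c("in", "out"))
  fit <- stats::lm(d_melody ~ d_rhythm * framework_side, data = perf)
  if (fit$rank < 4L) stop("rank-deficient design")
  out <- summarise_fit(fit)
  cf <- stats::coef(fit)
  out$out_slope <- unname(cf["d_rhythm"] + cf["d_rhythm:framework_sideout"])
  out
}

#' Individual-level cross-domain regression
#'
#' Least-squares fit of each participant's melody d-prime on their rhythm
#' d-prime with musical-training and framework-side covariates:
#' `d_melody ~ d_rhythm + trained + framework_side`.
#'
#' @param perf A table from [participant_performance()].
#' @return A list with `fit`, `coefficients`, `adj_r_squared`, `p_values`.
#' @export
individual_regression <- function(perf) {
  stopifnot(all(c("participant", "d_rhythm", "d_melody", "trained",
                  "framework_side") %in% names(perf)))
  if (length(unique(perf$participant)) < 3) {
    stop("need at least 3 participants")
  }
  perf$framework_side <- factor(perf$framework_side, levels = c("in", "out"))
  fit <- stats::lm(d_melody ~ d_rhythm + trained + framework_side,
                   data = perf)
  out <- summarise_fit(fit)
  if (out$sigma < sqrt(.Machine$double.eps)) {
    warning("zero residual variance: participants are identical, ",
            "inferential statistics are degenerate")
  }
  out
}
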