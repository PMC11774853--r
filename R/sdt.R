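# Signal-detection analysis of same/different trial tables: pooled
# hit/false-alarm counts per grouping cell, extreme-count correction,
# d-prime with the reminder-design scaling, bias c, percentage correct.

#' Pool hit and false-alarm counts per grouping cell
#'
#' Hits are different-trials answered "different"; false alarms are
#' same-trials answered "different". Counts are pooled across participants
#' (and any other variable not in `grouping`). Cells are defined by the
#' grouping values of the different trials; grouping variables that are
#' undefined on same trials (contour, framework, manipulation size -- all
#' `NA` there) select the different trials only, with the false-alarm pool
#' matched on the remaining variables. Cells with no matching same trials
#' are dropped with a warning.
#'
#' @param trials A trial table (see [simulate_responses()]; real exported
#'   data in the same schema works equally).
#' @param grouping Character vector of column names, e.g. `"domain"` or
#'   `c("domain", "framework_class")`. Empty for one overall cell.
#' @return A data frame with the grouping columns plus `n_same`, `n_diff`,
#'   `hits`, `false_alarms`.
#' @export
pool_counts <- function(trials, grouping = character(0)) {
  stopifnot(all(c("truth", "response") %in% names(trials)),
            all(grouping %in% names(trials)))
  diff <- trials[trials$truth == "different", , drop = FALSE]
  same <- trials[trials$truth == "same", , drop = FALSE]
  if (length(grouping) == 0) {
    return(data.frame(n_same = nrow(same), n_diff = nrow(diff),
                      hits = sum(diff$response == "different"),
                      false_alarms = sum(same$response == "different")))
  }
  # grouping variables that same trials actually carry
  same_vars <- grouping[vapply(grouping,
                               function(v) !anyNA(same[[v]]), logical(1))]
  cells <- unique(diff[, grouping, drop = FALSE])
  cells <- cells[do.call(order, cells), , drop = FALSE]
  rownames(cells) <- NULL
  res <- cells
  res$n_same <- res$n_diff <- res$hits <- res$false_alarms <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    in_diff <- rep(TRUE, nrow(diff))
    for (v in grouping) in_diff <- in_diff & diff[[v]] == cells[[v]][i]
    in_same <- rep(TRUE, nrow(same))
    for (v in same_vars) in_same <- in_same & same[[v]] == cells[[v]][i]
    res$n_diff[i] <- sum(in_diff)
    res$hits[i] <- sum(diff$response[in_diff] == "different")
    res$n_same[i] <- sum(in_same)
    res$false_alarms[i] <- sum(same$response[in_same] == "different")
  }
  empty <- res$n_same == 0L
  if (any(empty)) {
    warning(sum(empty), " cell(s) had no matching same trials and were ",
            "dropped")
    res <- res[!empty, , drop = FALSE]
  }
  res
}

#' Correct extreme hit / false-alarm counts
#'
#' Rates of exactly 0 or 1 make the probit transform infinite, so only the
#' asymptotic counts are adjusted: a count of 0 becomes 0.5 and a count of
#' `n` becomes `n - 0.5` before dividing by `n`. Non-extreme counts divide
#' unchanged. The corrected rates are therefore always strictly inside
#' (0, 1).
#'
#' @param hits,false_alarms Counts (vectorised).
#' @param n_diff,n_same Trial counts per cell.
#' @return A list with corrected rates `H` and `F`.
#' @examples
#' correct_rates(16, 16, 0, 16)  # H = 15.5/16, F = 0.5/16
#' @export
correct_rates <- function(hits, n_diff, false_alarms, n_same) {
  stopifnot(all(n_diff > 0), all(n_same > 0))
  fix <- function(k, n) ifelse(k == 0, 0.5, ifelse(k == n, n - 0.5, k)) / n
  list(H = fix(hits, n_diff), F = fix(false_alarms, n_same))
}

resolve_scale <- function(scale) {
  if (identical(scale, "sqrt2")) sqrt(2) else as.numeric(scale)
}

#' Sensitivity d-prime and bias c from corrected rates
#'
#' `dprime()` computes `scale * (z(H) - z(F))` with `z` the standard normal
#' quantile. The default `scale = 2` is the reminder-design transform used
#' with this paradigm (the first stimulus of each pair is always the
#' unmanipulated reference); pass `scale = "sqrt2"` for the sqrt(2)
#' convention common elsewhere in the differencing-model literature, or any
#' number. `c_bias()` is `-(z(H) + z(F)) / 2`; positive values favour
#' "same" responses.
#'
#' @param H,F Corrected hit and false-alarm rates, strictly in (0, 1).
#' @param scale Reminder-design factor: a number (default 2) or `"sqrt2"`.
#' @return Numeric vector.
#' @examples
#' dprime(pnorm(0.5), pnorm(-0.5))  # 2 at the default scale
#' @export
dprime <- function(H, F, scale = 2) {
  stopifnot(all(H > 0 & H < 1), all(F > 0 & F < 1))
  resolve_scale(scale) * (stats::qnorm(H) - stats::qnorm(F))
}

#' @rdname dprime
#' @export
c_bias <- function(H, F) {
  stopifnot(all(H > 0 & H < 1), all(F > 0 & F < 1))
  -(stats::qnorm(H) + stats::qnorm(F)) / 2
}

#' Pooled signal-detection analysis per grouping cell
#'
#' Pools counts with [pool_counts()], corrects extreme counts, and reports
#' corrected rates, d-prime, bias c and percentage correct per cell.
#'
#' @inheritParams pool_counts
#' @inheritParams dprime
#' @return A data frame: grouping columns, `n_same`, `n_diff`, `hits`,
#'   `false_alarms`, `H`, `F`, `d_prime`, `c_bias`, `pct_correct`, `scale`.
#' @export
sdt_analysis <- function(trials, grouping = "domain", scale = 2) {
  res <- pool_counts(trials, grouping)
  rates <- correct_rates(res$hits, res$n_diff, res$false_alarms, res$n_same)
  res$H <- rates$H
  res$F <- rates$F
  res$d_prime <- dprime(rates$H, rates$F, scale)
  res$c_bias <- c_bias(rates$H, rates$F)
  res$pct_correct <- (res$hits + (res$n_same - res$false_alarms)) /
    (res$n_same + res$n_diff)
  res$scale <- resolve_scale(scale)
  res
}

#' Percentage correct per grouping cell
#'
#' Correct means responding "different" on different trials and "same" on
#' same trials; same-trial pooling follows the [pool_counts()] matching
#' rules, so this equals `(hits + (n_same - false_alarms)) / (n_same +
#' n_diff)` on every cell.
#'
#' @inheritParams pool_counts
#' @return A data frame: grouping columns, `n_same`, `n_diff`,
#'   `pct_correct`.
#' @export
percent_correct <- function(trials, grouping = character(0)) {
  res <- pool_counts(trials, grouping)
  res$pct_correct <- (res$hits + (res$n_same - res$false_alarms)) /
    (res$n_same + res$n_diff)
  res[, c(grouping, "n_same", "n_diff", "pct_correct")]
}
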