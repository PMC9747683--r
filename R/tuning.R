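# Grid search over regularization multiplier x feature classes, and the
# composite best-model selection rule (AICc window + AUC/CBI gates with a
# deterministic tie-break chain).

#' Define a tuning grid
#'
#' The conventional grid crosses regularization multipliers 0.5-4 in steps
#' of 0.5 with the six feature-class sets L, LQ, LQH, H, LQHP, LQHPT
#' (8 x 6 = 48 combinations; dropping RM 0.5 gives 42).
#'
#' @param rm_values Numeric vector of regularization multipliers.
#' @param fc_sets Character vector of feature-class strings.
#' @return List of class `tuning_grid`.
#' @export
tuning_grid <- function(rm_values = seq(0.5, 4, by = 0.5),
                        fc_sets = c("L", "LQ", "LQH", "H", "LQHP", "LQHPT")) {
  stopifnot(length(rm_values) >= 1, length(fc_sets) >= 1)
  structure(list(rm_values = rm_values, fc_sets = fc_sets),
            class = "tuning_grid")
}

#' Run the tuning grid
#'
#' Evaluates every (rm, fc) combination under one partition and fills
#' delta AICc relative to the grid minimum over combinations with defined
#' AICc. Combinations with undefined AICc (k >= n - 1) are flagged.
#'
#' @param presence_env,background_env Covariate matrices.
#' @param grid A [tuning_grid()].
#' @param partition A `presence_partition` (see [make_partition()]).
#' @param ... Passed to [evaluate()] / [fit_maxent()].
#' @return data.frame of class `tuning_result`: one row per combination
#'   with rm, fc, the evaluation metrics and delta_aicc.
#' @export
run_grid <- function(presence_env, background_env, grid, partition, ...) {
  combos <- expand.grid(rm = grid$rm_values, fc = grid$fc_sets,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    rep_ <- evaluate(presence_env, background_env,
                     fc = combos$fc[i], rm = combos$rm[i],
                     partition = partition, ...)
    data.frame(rm = combos$rm[i], fc = combos$fc[i],
               auc_train = rep_$auc_train, auc_test = rep_$auc_test,
               auc_diff = rep_$auc_diff, or10 = rep_$or10, cbi = rep_$cbi,
               aicc = rep_$aicc, k = rep_$k,
               aicc_defined = !is.na(rep_$aicc),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  minaicc <- suppressWarnings(min(tab$aicc, na.rm = TRUE))
  tab$delta_aicc <- tab$aicc - minaicc
  class(tab) <- c("tuning_result", "data.frame")
  tab
}

#' Select the best model configuration
#'
#' Candidate set: combinations with delta AICc < `delta_window`, test AUC >
#' `auc_min` and CBI > `cbi_min`. Within the candidates (or, if none pass,
#' all combinations with defined AICc — logged as a gate relaxation), the
#' winner is the minimum delta AICc, ties broken by smaller AUC.diff, then
#' smaller OR10, then smaller rm, then fewer feature classes. Deterministic
#' given the table regardless of row order.
#'
#' @param result A `tuning_result` from [run_grid()].
#' @param auc_min AUC gate (default 0.9).
#' @param cbi_min CBI gate (default 0.5).
#' @param delta_window delta AICc window (default 2).
#' @return List with `rm`, `fc`, the selected `row`, and `trace` (character
#'   vector of rules applied).
#' @export
select_best <- function(result, auc_min = 0.9, cbi_min = 0.5,
                        delta_window = 2) {
  tab <- as.data.frame(result)
  defined <- tab[tab$aicc_defined, , drop = FALSE]
  if (!nrow(defined)) stop("no combination has a defined AICc")
  trace <- sprintf("gates: delta_aicc < %g, auc_test > %g, cbi > %g",
                   delta_window, auc_min, cbi_min)
  cand <- defined[defined$delta_aicc < delta_window &
                    defined$auc_test > auc_min &
                    !is.na(defined$cbi) & defined$cbi > cbi_min, , drop = FALSE]
  if (!nrow(cand)) {
    trace <- c(trace, "gates_relaxed: no combination passed; ranking all combos with defined AICc")
    cand <- defined
  } else {
    trace <- c(trace, sprintf("%d candidate(s) passed all gates", nrow(cand)))
  }
  n_classes <- nchar(cand$fc)
  ord <- order(cand$delta_aicc, cand$auc_diff, cand$or10, cand$rm, n_classes,
               cand$fc)
  best <- cand[ord[1L], , drop = FALSE]
  trace <- c(trace, sprintf("selected rm = %g, fc = %s (delta_aicc = %.3f, auc_test = %.3f)",
                            best$rm, best$fc, best$delta_aicc, best$auc_test))
  list(rm = best$rm, fc = best$fc, row = best, trace = trace)
}
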