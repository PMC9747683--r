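# Screening of candidate environmental variables: pairwise Pearson
# correlation over background cells, combined with model percent
# contributions, reduces a redundant bioclim stack to a working set.

#' Pairwise Pearson correlations between stack layers
#'
#' Computed over a set of sample cells (typically the model's background
#' sample, so the correlation structure matches the model's support).
#' Zero-variance layers yield NA correlations with a warning.
#'
#' @param stack An [env_stack()].
#' @param sample_cells Linear cell indices; default all jointly valid cells.
#' @return Symmetric correlation matrix with layer names.
#' @export
correlation_matrix <- function(stack, sample_cells = valid_cells(stack)) {
  env <- extract_env(stack, sample_cells)
  env <- env[stats::complete.cases(env), , drop = FALSE]
  if (nrow(env) < 3) stop("need at least 3 jointly non-missing cells")
  sds <- apply(env, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance layer(s): ",
            paste(colnames(env)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  suppressWarnings(stats::cor(env, use = "pairwise.complete.obs"))
}

#' Screen variables by correlation and contribution
#'
#' Deterministic greedy reduction following the usual two-rule protocol:
#' variables with percent contribution above `contrib_threshold` are
#' protected; among each strongly correlated pair (|r| >= `r_threshold`,
#' visited in descending |r|, alphabetical tie-break) the member with the
#' smaller contribution is dropped, unless it alone is protected (then the
#' unprotected one is dropped); pairs with both members protected are kept
#' and the conflict logged.
#'
#' @param corr Correlation matrix (named, symmetric).
#' @param contrib Named numeric vector of percent contributions covering the
#'   same variables.
#' @param r_threshold Absolute correlation above which a pair is redundant
#'   (default 0.8).
#' @param contrib_threshold Percent contribution above which a variable is
#'   protected (default 10).
#' @param always_keep Variable names exempt from dropping (expert judgment).
#' @return List with `kept` (character vector) and `log` (data.frame of
#'   actions: dropped/kept/conflict with the triggering pair and values).
#' @export
screen_variables <- function(corr, contrib, r_threshold = 0.8,
                             contrib_threshold = 10, always_keep = character()) {
  vars <- colnames(corr)
  if (length(vars) != length(contrib) || !setequal(vars, names(contrib)))
    stop("corr and contrib must cover the same variables")
  if (length(vars) == 0)
    return(list(kept = character(),
                log = data.frame(action = character(), dropped_variable = character(),
                                 kept_variable = character(), r = numeric(),
                                 contrib_dropped = numeric(), contrib_kept = numeric())))
  contrib <- contrib[vars]
  protected <- vars[contrib > contrib_threshold] |> union(always_keep)
  pairs <- which(upper.tri(corr) & abs(corr) >= r_threshold, arr.ind = TRUE)
  log <- data.frame(action = character(), dropped_variable = character(),
                    kept_variable = character(), r = numeric(),
                    contrib_dropped = numeric(), contrib_kept = numeric(),
                    stringsAsFactors = FALSE)
  present <- stats::setNames(rep(TRUE, length(vars)), vars)
  if (nrow(pairs)) {
    pr <- data.frame(a = vars[pairs[, "row"]], b = vars[pairs[, "col"]],
                     r = corr[pairs], stringsAsFactors = FALSE)
    swap <- pr$a > pr$b
    tmp <- pr$a[swap]; pr$a[swap] <- pr$b[swap]; pr$b[swap] <- tmp
    pr <- pr[order(-abs(pr$r), pr$a, pr$b), , drop = FALSE]
    for (k in seq_len(nrow(pr))) {
      a <- pr$a[k]; b <- pr$b[k]; r <- pr$r[k]
      if (!present[a] || !present[b]) next
      pa <- a %in% protected; pb <- b %in% protected
      if (pa && pb) {
        log <- rbind(log, data.frame(action = "conflict", dropped_variable = NA,
                                     kept_variable = paste(a, b, sep = "+"), r = r,
                                     contrib_dropped = NA, contrib_kept = NA))
        next
      }
      drop <- if (pa) b else if (pb) a
      else if (contrib[a] < contrib[b]) a
      else if (contrib[b] < contrib[a]) b
      else max(a, b)  # equal contributions: drop the alphabetically later
      keep <- setdiff(c(a, b), drop)
      present[drop] <- FALSE
      log <- rbind(log, data.frame(action = "drop", dropped_variable = drop,
                                   kept_variable = keep, r = r,
                                   contrib_dropped = unname(contrib[drop]),
                                   contrib_kept = unname(contrib[keep])))
    }
  }
  list(kept = vars[present[vars]], log = log)
}

#' Percent contribution of variables from a fitted model
#'
#' Convenience accessor: per-variable share of the training gain accumulated
#' during fitting, as percentages summing to 100.
#'
#' @param model A fitted `maxent_model` (see [fit_maxent()]).
#' @return Named numeric vector (percent).
#' @export
variable_contributions <- function(model) model$contributions
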