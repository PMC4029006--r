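# Attention-network-test (ANT, cued flanker) trial tables: session
# validation and conflict-effect scoring.

antCues <- c("none", "center", "double", "spatial")
antTargets <- c("congruent", "incongruent", "neutral")

checkTrialTable <- function(trials) {
  need <- c("block", "cue", "target", "rt_ms", "correct")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(trials$cue), antCues)
  if (length(bad)) stop("unknown cue condition(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(trials$target), antTargets)
  if (length(bad)) {
    stop("unknown target condition(s): ", paste(bad, collapse = ", "))
  }
  invisible(trials)
}

#' Score the flanker conflict effect from an ANT trial table
#'
#' Executive-attention (conflict) scores from the test-block trials:
#' `rtConflictMs` is the mean correct-trial RT in the incongruent condition
#' minus the congruent condition; `meanRt` is the mean RT over all correct
#' trials of all conditions; `rtConflictRatio` is their ratio; and
#' `accConflict` is incongruent accuracy minus congruent accuracy with all
#' presented trials of those conditions in the denominators. Only correct
#' responses contribute to RT means. Training-block trials (`block == 0`)
#' are excluded.
#'
#' Alerting (no-cue minus double-cue RT) and orienting (center-cue minus
#' spatial-cue RT) effects are computed when `includeCueEffects = TRUE`.
#'
#' @param trials data.frame with columns `block` (0 = training), `cue`,
#'   `target`, `rt_ms`, `correct` (logical).
#' @param includeCueEffects also return alerting/orienting (default FALSE).
#' @param denominator `"all"` (default: mean RT over all correct trials) or
#'   `"conflict"` (correct congruent + incongruent trials only) for the
#'   ratio denominator.
#' @return list with `rtConflictMs`, `rtConflictRatio`, `accConflict`,
#'   `meanRt`, `accuracy`, `nScored`, and optionally `alertingMs`,
#'   `orientingMs`.
#' @export
scoreConflict <- function(trials, includeCueEffects = FALSE,
                          denominator = c("all", "conflict")) {
  denominator <- match.arg(denominator)
  checkTrialTable(trials)
  scored <- trials[trials$block > 0, , drop = FALSE]
  for (cond in c("congruent", "incongruent")) {
    sel <- scored$target == cond
    if (!any(sel)) stop("no trials in target condition: ", cond)
    if (!any(scored$correct[sel])) {
      stop("no correct trials in target condition: ", cond)
    }
  }
  ok <- scored[scored$correct, , drop = FALSE]
  rtInc <- mean(ok$rt_ms[ok$target == "incongruent"])
  rtCon <- mean(ok$rt_ms[ok$target == "congruent"])
  rtConflict <- rtInc - rtCon
  meanRt <- if (denominator == "all") {
    mean(ok$rt_ms)
  } else {
    mean(ok$rt_ms[ok$target %in% c("congruent", "incongruent")])
  }
  accOf <- function(cond) mean(scored$correct[scored$target == cond])
  out <- list(
    rtConflictMs = rtConflict,
    rtConflictRatio = rtConflict / meanRt,
    accConflict = accOf("incongruent") - accOf("congruent"),
    meanRt = meanRt,
    accuracy = mean(scored$correct),
    nScored = nrow(scored)
  )
  if (includeCueEffects) {
    cueRt <- function(cue) mean(ok$rt_ms[ok$cue == cue])
    out$alertingMs <- cueRt("none") - cueRt("double")
    out$orientingMs <- cueRt("center") - cueRt("spatial")
  }
  out
}

#' Validate an ANT session against the balanced design
#'
#' Report-only check of a trial table against the standard session layout
#' (one 24-trial training block, three 96-trial test blocks, 12 cue-target
#' cells): per-cell counts of scored trials, response-time range violations
#' (responded RTs must lie in (0, 1700] ms), and the training trials
#' flagged for exclusion.
#'
#' @param trials data.frame as in [scoreConflict()]; may be empty.
#' @return list with `nScored`, `nTraining`, `cellCounts` (cue x target
#'   table of scored trials), `blockSizes`, and `violations` (character
#'   vector of findings; empty when the session conforms).
#' @export
validateSession <- function(trials) {
  if (!nrow(trials)) {
    return(list(
      nScored = 0L, nTraining = 0L,
      cellCounts = table(
        factor(character(), antCues),
        factor(character(), antTargets)
      ),
      blockSizes = integer(), violations = character()
    ))
  }
  checkTrialTable(trials)
  scored <- trials[trials$block > 0, , drop = FALSE]
  cells <- table(
    factor(scored$cue, antCues),
    factor(scored$target, antTargets)
  )
  violations <- character()
  badRt <- which(!is.na(trials$rt_ms) & (trials$rt_ms <= 0 | trials$rt_ms > 1700))
  if (length(badRt)) {
    violations <- c(violations, sprintf(
      "%d trial(s) with RT outside (0, 1700] ms (rows %s)",
      length(badRt), paste(utils::head(badRt, 5L), collapse = ", ")
    ))
  }
  blockSizes <- table(trials$block)
  testBlocks <- blockSizes[names(blockSizes) != "0"]
  if (length(testBlocks) != 3L || any(testBlocks != 96L)) {
    violations <- c(violations, "test blocks do not form 3 blocks of 96 trials")
  }
  if ("0" %in% names(blockSizes) && blockSizes[["0"]] != 24L) {
    violations <- c(violations, "training block does not have 24 trials")
  }
  list(
    nScored = nrow(scored),
    nTraining = sum(trials$block == 0),
    cellCounts = cells,
    blockSizes = as.integer(blockSizes),
    violations = violations
  )
}
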