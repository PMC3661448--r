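# Wild-type reference bounds and electrophysiological sorting of worms.
#
# The screen separates eat-4-like mutants from wild type on two metrics:
# mean pump duration (lengthened in the mutant) and P waves per pump (lost
# in the mutant). Bounds are one-sided - only the upper duration bound and
# the lower P bound decide - matching the direction of the mutant phenotype.

#' Fit wild-type reference bounds
#'
#' Per-metric mean and sample standard deviation across worms, with bounds
#' `mean +/- k * sd` (default `k = 3`). Only `duration` and `p_per_pump`
#' are fitted; the upper duration bound and lower P bound are the ones the
#' classifier uses.
#'
#' @param wild_type_params List (or data frame) of per-worm `epg_params`
#'   records from known wild-type worms; at least 3 worms.
#' @param k Bound width in standard deviations (default 3).
#' @param source Free-text provenance label.
#' @return An object of class `epg_bounds`.
#' @export
fit_reference <- function(wild_type_params, k = 3, source = "") {
  df <- if (is.data.frame(wild_type_params)) wild_type_params
        else do.call(rbind, wild_type_params)
  if (nrow(df) < 3L) stopf("need >= 3 wild-type worms to fit reference bounds")
  if (k < 0) stopf("k must be >= 0")
  fit1 <- function(v) {
    v <- v[!is.na(v)]
    m <- mean(v); s <- stats::sd(v)
    list(mean = m, sd = s, k = k, lower = m - k * s, upper = m + k * s)
  }
  structure(list(duration = fit1(df$duration), p_per_pump = fit1(df$p_per_pump),
                 k = k, n_worms = nrow(df), source = source),
            class = "epg_bounds")
}

#' Explicit classification thresholds
#'
#' Builds an `epg_bounds` object directly from published decision
#' thresholds rather than from data: a worm is called mutant when its mean
#' pump duration exceeds `duration_upper` and (under the default
#' conjunction rule) its P-wave count per pump falls below `p_lower`. The
#' defaults are the published screen thresholds, 0.1445 s and 0.169.
#'
#' @param duration_upper Upper duration bound in seconds (default 0.1445).
#' @param p_lower Lower P-per-pump bound (default 0.169).
#' @param source Provenance label.
#' @return An `epg_bounds` object with only the deciding bounds set.
#' @export
explicit_bounds <- function(duration_upper = 0.1445, p_lower = 0.169,
                            source = "published screen thresholds") {
  structure(list(duration = list(mean = NA_real_, sd = NA_real_, k = NA_real_,
                                 lower = -Inf, upper = duration_upper),
                 p_per_pump = list(mean = NA_real_, sd = NA_real_, k = NA_real_,
                                   lower = p_lower, upper = Inf),
                 k = NA_real_, n_worms = 0L, source = source),
            class = "epg_bounds")
}

#' @export
print.epg_bounds <- function(x, ...) {
  cat(sprintf("<epg_bounds> %s (n = %d)\n", x$source, x$n_worms))
  cat(sprintf("  duration upper %.4f s | P/pump lower %.4f\n",
              x$duration$upper, x$p_per_pump$lower))
  invisible(x)
}

#' Classify one worm against reference bounds
#'
#' Decision rule, with strict inequalities: `duration_out` when the worm's
#' mean pump duration exceeds the upper duration bound; `p_out` when its
#' P-wave count per pump falls below the lower P bound. Under the default
#' `"conjunction"` rule the worm is called mutant when both criteria hold
#' (the rule exactly as published); under `"disjunction"` when either does.
#' A worm with fewer than `min_pumps` pumps is unclassifiable (with few
#' pumps the P-per-pump metric is too granular to trust).
#'
#' @param params An `epg_params` record for the worm.
#' @param bounds An `epg_bounds` from [fit_reference()] or
#'   [explicit_bounds()].
#' @param rule `"conjunction"` (default) or `"disjunction"`.
#' @param min_pumps Minimum pump count to classify (default 5).
#' @return A list of class `epg_verdict`: worm_id, label (`wild_type`,
#'   `mutant` or `unclassifiable`), per-criterion flags, the metrics and
#'   thresholds used, and the rule.
#' @export
classify <- function(params, bounds, rule = c("conjunction", "disjunction"),
                     min_pumps = 5L) {
  rule <- match.arg(rule)
  stopifnot(inherits(bounds, "epg_bounds"))
  v <- list(worm_id = params$worm_id, label = NA_character_,
            duration_out = NA, p_out = NA,
            duration = params$duration, p_per_pump = params$p_per_pump,
            n_pumps = params$n_pumps,
            duration_upper = bounds$duration$upper,
            p_lower = bounds$p_per_pump$lower,
            rule = rule, reason = "ok")
  class(v) <- "epg_verdict"
  if (is.na(params$n_pumps) || params$n_pumps < min_pumps) {
    v$label <- "unclassifiable"
    v$reason <- "too_few_pumps"
    return(v)
  }
  v$duration_out <- params$duration > bounds$duration$upper
  v$p_out <- params$p_per_pump < bounds$p_per_pump$lower
  mutant <- if (rule == "conjunction") v$duration_out && v$p_out
            else v$duration_out || v$p_out
  v$label <- if (mutant) "mutant" else "wild_type"
  v
}

#' @export
print.epg_verdict <- function(x, ...) {
  cat(sprintf("<epg_verdict> %s: %s (rule %s)\n", x$worm_id, x$label, x$rule))
  cat(sprintf("  duration %.4f s vs > %.4f -> %s | P/pump %.3f vs < %.3f -> %s\n",
              x$duration, x$duration_upper, x$duration_out,
              x$p_per_pump, x$p_lower, x$p_out))
  invisible(x)
}

#' Screen a cohort of traces for mutants
#'
#' Runs the full per-worm pipeline: orientation gate, drift filtering,
#' pump detection, parameter extraction and classification. Worms failing
#' the orientation gate are rejected (counted, never classified); per-worm
#' failures are converted to `unclassifiable` verdicts rather than aborting
#' the cohort. When true labels are supplied a confusion matrix over the
#' classified worms is included (rejected worms are excluded from it).
#'
#' @param traces List of [epg_trace()]s, or a cohort from
#'   [generate_cohort()] (whose true labels are then used automatically,
#'   with the `tail` preset and any `eat4*` preset counted as
#'   tail/mutant truth respectively).
#' @param bounds An `epg_bounds`; default the published explicit thresholds.
#' @param cfg A [detection_config()].
#' @param rule Decision rule, see [classify()].
#' @param filter_spec A [filter_spec()] for drift removal, or `NULL` to
#'   skip filtering.
#' @param reference_amp Orientation-gate reference amplitude (mV).
#' @param true_labels Optional character vector of true labels
#'   (`"wild_type"`, `"mutant"`, `"tail"`) parallel to `traces`.
#' @param min_pumps Minimum pumps to classify.
#' @return A list of class `epg_screen`: per-worm verdicts, counts
#'   (analyzed, rejected, wild_type, mutant, unclassifiable), the rule and
#'   thresholds used, and optionally the confusion matrix plus false
#'   positive/negative counts.
#' @export
screen_cohort <- function(traces, bounds = explicit_bounds(),
                          cfg = detection_config(),
                          rule = c("conjunction", "disjunction"),
                          filter_spec = epgtools::filter_spec(),
                          reference_amp = 4.410, true_labels = NULL,
                          min_pumps = 5L) {
  rule <- match.arg(rule)
  if (length(traces) == 0L) stopf("no traces to screen")
  is_cohort <- is.list(traces[[1L]]) && !inherits(traces[[1L]], "epg_trace")
  if (is_cohort) {
    if (is.null(true_labels))
      true_labels <- vapply(traces, function(w) {
        if (w$true_label == "tail") "tail"
        else if (grepl("^eat4", w$true_label)) "mutant" else "wild_type"
      }, character(1))
    worm_ids <- vapply(traces, `[[`, character(1), "worm_id")
    traces <- lapply(traces, `[[`, "trace")
  } else worm_ids <- sprintf("worm%02d", seq_along(traces))

  verdicts <- vector("list", length(traces))
  gate <- character(length(traces))
  for (i in seq_along(traces)) {
    res <- tryCatch({
      tr <- traces[[i]]
      if (!is.null(filter_spec)) tr <- highpass(tr, filter_spec)
      events <- suppressWarnings(detect_pumps(tr, cfg, worm_id = worm_ids[i]))
      g <- orientation_gate(tr, cfg, reference_amp, events = events)
      if (g$verdict != "head") {
        list(gate = "rejected",
             verdict = structure(list(worm_id = worm_ids[i], label = "rejected",
                                      reason = g$reason, rule = rule),
                                 class = "epg_verdict"))
      } else {
        p <- compute_parameters(events, tr)
        p$worm_id <- worm_ids[i]
        list(gate = "head", verdict = classify(p, bounds, rule, min_pumps))
      }
    }, error = function(e) {
      list(gate = "failed",
           verdict = structure(list(worm_id = worm_ids[i], label = "unclassifiable",
                                    reason = conditionMessage(e), rule = rule),
                               class = "epg_verdict"))
    })
    gate[i] <- res$gate
    verdicts[[i]] <- res$verdict
  }
  labels <- vapply(verdicts, `[[`, character(1), "label")
  out <- list(verdicts = verdicts,
              counts = c(total = length(traces),
                         analyzed = sum(gate == "head"),
                         rejected = sum(gate == "rejected"),
                         wild_type = sum(labels == "wild_type"),
                         mutant = sum(labels == "mutant"),
                         unclassifiable = sum(labels == "unclassifiable")),
              rule = rule,
              thresholds = c(duration_upper = bounds$duration$upper,
                             p_lower = bounds$p_per_pump$lower))
  if (!is.null(true_labels)) {
    keep <- labels %in% c("wild_type", "mutant") & true_labels != "tail"
    cm <- table(truth = factor(true_labels[keep], c("wild_type", "mutant")),
                called = factor(labels[keep], c("wild_type", "mutant")))
    out$confusion <- cm
    out$false_positives <- cm["wild_type", "mutant"]
    out$false_negatives <- cm["mutant", "wild_type"]
  }
  class(out) <- "epg_screen"
  out
}

#' @export
print.epg_screen <- function(x, ...) {
  cat("<epg_screen>\n")
  cat(sprintf("  rule %s; thresholds: duration > %.4f s, P/pump < %.3f\n",
              x$rule, x$thresholds[["duration_upper"]], x$thresholds[["p_lower"]]))
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  if (!is.null(x$confusion)) {
    cat(sprintf("  false positives %d, false negatives %d\n",
                x$false_positives, x$false_negatives))
  }
  invisible(x)
}
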