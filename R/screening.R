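# Tone-presentation screening rules: extraction from a fitted tree,
# simulated administration, and fixed-cutoff comparison criteria.

.decision_node <- function(decision) {
  stopifnot(decision %in% c("pass", "refer"))
  list(type = "decision", decision = decision)
}

.tone_node <- function(freq_khz, level, heard, not_heard) {
  if (!freq_khz %in% tone_frequencies())
    stop("tone frequency must be one of 0.5, 1, 2, 4 kHz", call. = FALSE)
  if (level < .db_range[1] || level > .db_range[2])
    stop("presentation level must lie in [-10, 120] dB HL", call. = FALSE)
  list(type = "tone", freq_khz = freq_khz, level = level,
       heard = heard, not_heard = not_heard)
}

.new_rule <- function(root, ear_mode, provenance) {
  structure(list(root = root, ear_mode = ear_mode, provenance = provenance),
            class = "screening_rule")
}

#' Extract a two-step tone protocol from a fitted tree
#'
#' Each internal node (frequency f, threshold t) of a depth-<=2 tree becomes
#' a tone presentation at frequency f and level `rounding(t)`. A subject
#' hears a tone at level L iff their threshold at that frequency is <= L, so
#' the tree's "feature <= t, go left" convention maps onto the heard branch.
#' Leaves become terminal decisions: predicted positive -> refer, negative
#' -> pass.
#'
#' With the default `floor` rounding and 5-dB-quantized audiograms the
#' protocol's decisions remain identical to the tree's predictions, because
#' flooring a between-step midpoint never crosses a quantized data value.
#'
#' @param tree A fitted `hearing_tree` of depth at most 2.
#' @param level_rounding How to turn a split threshold into an integer
#'   presentation level: `"floor"` (default), `"nearest"`, or `"exact"`
#'   (no rounding; useful to verify decision equivalence on arbitrary
#'   data).
#' @param ear_mode Optional note of the ear-selection mode the tree was
#'   trained for.
#' @return A `screening_rule`.
#' @export
extract_rule <- function(tree, level_rounding = c("floor", "nearest", "exact"),
                         ear_mode = NA_character_) {
  stopifnot(inherits(tree, "hearing_tree"))
  level_rounding <- match.arg(level_rounding)
  if (tree_depth(tree) > 2L)
    stop("screening rules are extracted from trees of depth <= 2", call. = FALSE)
  lvl <- switch(level_rounding,
                floor = function(t) floor(t),
                nearest = function(t) round(t),
                exact = identity)
  conv <- function(nd) {
    if (nd$leaf)
      return(.decision_node(if (nd$class == "positive") "refer" else "pass"))
    .tone_node(nd$freq_khz, lvl(nd$threshold),
               heard = conv(nd$left), not_heard = conv(nd$right))
  }
  .new_rule(conv(tree$root), ear_mode,
            provenance = list(source = "tree", criterion = tree$criterion,
                              level_rounding = level_rounding))
}

#' Build a fixed-cutoff screening rule
#'
#' The comparison criterion from the screening literature: present a fixed
#' tone at each listed frequency (e.g. 40 dB HL at 2 kHz and 1 kHz) and
#' refer when the subject misses all of them (`combine = "all"`, the
#' default) or any of them (`combine = "any"`).
#'
#' @param levels Named numeric vector of presentation levels (dB HL); names
#'   are frequencies in kHz (`"0.5"`, `"1"`, `"2"`, `"4"`). Tones are
#'   presented in the order given.
#' @param combine `"all"` or `"any"`; see above.
#' @return A `screening_rule`.
#' @examples
#' fixed_cutoff_rule(c("2" = 40, "1" = 40))
#' @export
fixed_cutoff_rule <- function(levels, combine = c("all", "any")) {
  combine <- match.arg(combine)
  if (length(levels) < 1L || length(levels) > 4L || is.null(names(levels)))
    stop("levels must be 1-4 named presentation levels", call. = FALSE)
  freqs <- as.numeric(names(levels))
  if (anyNA(freqs) || !all(freqs %in% tone_frequencies()))
    stop("level names must be frequencies in kHz (0.5, 1, 2, 4)", call. = FALSE)
  build <- function(i) {
    last <- i == length(levels)
    if (combine == "all") {
      # refer only when every tone is missed
      .tone_node(freqs[i], levels[[i]],
                 heard = .decision_node("pass"),
                 not_heard = if (last) .decision_node("refer") else build(i + 1))
    } else {
      # refer as soon as any tone is missed
      .tone_node(freqs[i], levels[[i]],
                 heard = if (last) .decision_node("pass") else build(i + 1),
                 not_heard = .decision_node("refer"))
    }
  }
  .new_rule(build(1L), NA_character_,
            provenance = list(source = "fixed_cutoff", combine = combine,
                              levels = as.list(levels)))
}

#' @export
print.screening_rule <- function(x, ...) {
  cat("Tone-presentation screening rule")
  if (!is.na(x$ear_mode)) cat(" (", x$ear_mode, "-ear)", sep = "")
  cat(":\n")
  show <- function(nd, indent, label) {
    pad <- strrep("  ", indent)
    if (nd$type == "decision") {
      cat(sprintf("%s%s-> %s\n", pad, label, toupper(nd$decision)))
    } else {
      cat(sprintf("%s%spresent %g kHz at %g dB HL\n", pad, label,
                  nd$freq_khz, nd$level))
      show(nd$heard, indent + 1L, "heard: ")
      show(nd$not_heard, indent + 1L, "not heard: ")
    }
  }
  show(x$root, 0L, "")
  invisible(x)
}

#' Administer a screening rule to one audiogram
#'
#' Responses are deterministic threshold comparisons: the subject hears a
#' tone at level L iff their threshold at that frequency is <= L. The rule
#' is followed to a terminal decision.
#'
#' @param rule A `screening_rule`.
#' @param a An [audiogram] or numeric vector of four thresholds.
#' @return List with `decision` (`"refer"`/`"pass"`) and `tones` (number of
#'   tones presented).
#' @export
apply_rule <- function(rule, a) {
  stopifnot(inherits(rule, "screening_rule"))
  thr <- .as_thresholds(a)
  names(thr) <- NULL
  nd <- rule$root
  tones <- 0L
  while (nd$type == "tone") {
    tones <- tones + 1L
    j <- match(nd$freq_khz, tone_frequencies())
    nd <- if (thr[j] <= nd$level) nd$heard else nd$not_heard
  }
  list(decision = nd$decision, tones = tones)
}

#' Screen every participant of a cohort
#'
#' Applies the rule to the selected ear of each participant.
#'
#' @param rule A `screening_rule`.
#' @param c A [cohort].
#' @param mode Ear-selection mode, `"better"` or `"worse"`.
#' @return Data frame `id, decision, tones_presented`, in cohort order.
#' @export
screen_cohort <- function(rule, c, mode = c("better", "worse")) {
  mode <- match.arg(mode)
  s <- make_labeled_samples(c, mode)
  feat <- as.matrix(s[.freq_cols])
  res <- apply(feat, 1L, function(v) apply_rule(rule, v))
  data.frame(id = s$id,
             decision = vapply(res, `[[`, character(1), "decision"),
             tones_presented = vapply(res, `[[`, integer(1), "tones"),
             stringsAsFactors = FALSE)
}

#' Serialize / restore a screening rule (JSON)
#'
#' @param rule A `screening_rule`.
#' @param path JSON file path.
#' @return `write_rule` returns `path` invisibly; `read_rule` the rule.
#' @export
write_rule <- function(rule, path) {
  stopifnot(inherits(rule, "screening_rule"))
  jsonlite::write_json(unclass(rule), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule
#' @export
read_rule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$ear_mode <- if (is.null(obj$ear_mode)) NA_character_ else obj$ear_mode
  structure(obj, class = "screening_rule")
}
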