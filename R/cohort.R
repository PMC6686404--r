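# Domain objects for four-frequency pure-tone audiometric cohorts.

#' Audiometric frequencies used throughout the package
#'
#' The four air-conduction test frequencies (kHz) that enter the pure-tone
#' average: 0.5, 1, 2 and 4 kHz.
#'
#' @return Numeric vector of length 4.
#' @export
tone_frequencies <- function() c(0.5, 1, 2, 4)

# Internal column naming shared by audiograms, labeled samples and CSV I/O.
.freq_cols <- c("hz500", "hz1000", "hz2000", "hz4000")
.csv_cols <- c("id", "community", "age", "sex",
               "l500", "l1000", "l2000", "l4000",
               "r500", "r1000", "r2000", "r4000")
.db_range <- c(-10, 120)

#' Construct an audiogram
#'
#' An audiogram is one ear's air-conduction thresholds (dB HL) at 0.5, 1, 2
#' and 4 kHz. Thresholds must lie in the audiometer's intensity range of
#' -10 to 120 dB HL. Clinical data are stepped in 5-dB increments but any
#' numeric value in range is accepted here; only the synthetic generator
#' guarantees 5-dB quantization.
#'
#' @param thresholds Numeric vector of length 4, ordered 0.5, 1, 2, 4 kHz.
#' @return An object of class `audiogram` (a named numeric vector).
#' @examples
#' audiogram(c(25, 30, 45, 70))
#' @export
audiogram <- function(thresholds) {
  thresholds <- unname(unlist(thresholds, use.names = FALSE))
  if (length(thresholds) != 4L || anyNA(thresholds) || !is.numeric(thresholds))
    stop("an audiogram needs exactly four numeric thresholds (0.5, 1, 2, 4 kHz)",
         call. = FALSE)
  if (any(thresholds < .db_range[1]) || any(thresholds > .db_range[2]))
    stop("thresholds must lie in [-10, 120] dB HL", call. = FALSE)
  structure(stats::setNames(as.numeric(thresholds), .freq_cols),
            class = "audiogram")
}

#' @export
print.audiogram <- function(x, ...) {
  cat("Audiogram (dB HL):",
      paste(sprintf("%g kHz = %g", tone_frequencies(), unclass(x)),
            collapse = ", "),
      sprintf(" [PTA %.2f]\n", compute_pta(x)))
  invisible(x)
}

.as_thresholds <- function(a) {
  if (inherits(a, "audiogram")) return(unclass(a))
  audiogram(a)  # validates
  as.numeric(unlist(a, use.names = FALSE))
}

#' Four-frequency pure-tone average
#'
#' The unweighted arithmetic mean of the thresholds at 0.5, 1, 2 and 4 kHz,
#' kept at exact quarter-dB resolution (no rounding).
#'
#' @param a An [audiogram] or numeric vector of four thresholds.
#' @return PTA in dB HL.
#' @examples
#' compute_pta(c(25, 30, 45, 70))  # 42.5
#' @export
compute_pta <- function(a) mean(.as_thresholds(a))

#' WHO hearing-severity grade from a pure-tone average
#'
#' Grades follow the WHO convention on better-ear PTA: normal (<= 25),
#' mild (25, 40], moderate (40, 70], severe (70, 90], profound (> 90) dB HL.
#' Bounds are half-open real intervals so non-5-dB-multiple PTAs classify
#' unambiguously; the only boundary that drives the screening label is
#' PTA > 40 (moderate or worse).
#'
#' @param pta Numeric vector of PTAs in dB HL.
#' @return Ordered factor with levels normal < mild < moderate < severe <
#'   profound.
#' @examples
#' classify_who_severity(c(20, 40, 45, 80, 95))
#' @export
classify_who_severity <- function(pta) {
  if (any(pta < .db_range[1] | pta > .db_range[2]))
    stop("PTA outside [-10, 120] dB HL", call. = FALSE)
  cut(pta, breaks = c(-Inf, 25, 40, 70, 90, Inf),
      labels = c("normal", "mild", "moderate", "severe", "profound"),
      right = TRUE, ordered_result = TRUE)
}

#' Severity grades collapsed to the screening label
#'
#' Positive means moderate-to-profound hearing loss (PTA > 40 dB HL), the
#' condition the two-tone screen refers for; negative means normal-to-mild
#' (PTA <= 40 dB HL).
#'
#' @param pta Numeric vector of PTAs in dB HL.
#' @return Factor with levels `negative`, `positive`.
#' @export
screening_label <- function(pta) {
  factor(ifelse(pta > 40, "positive", "negative"),
         levels = c("negative", "positive"))
}

.left_audiogram <- function(row) {
  audiogram(as.numeric(row[c("l500", "l1000", "l2000", "l4000")]))
}
.right_audiogram <- function(row) {
  audiogram(as.numeric(row[c("r500", "r1000", "r2000", "r4000")]))
}

#' Select the better- or worse-hearing ear of a participant
#'
#' The better ear is the one with the lower PTA, the worse ear the one with
#' the higher PTA. Equal PTAs return the left ear under both modes, so
#' results never depend on record order.
#'
#' @param record A one-row data frame (or list) with the cohort threshold
#'   columns `l500..l4000`, `r500..r4000`.
#' @param mode `"better"` or `"worse"`.
#' @return A list with elements `audiogram`, `side` ("left"/"right") and
#'   `pta`.
#' @export
select_ear <- function(record, mode = c("better", "worse")) {
  mode <- match.arg(mode)
  left <- .left_audiogram(record)
  right <- .right_audiogram(record)
  lp <- compute_pta(left)
  rp <- compute_pta(right)
  # equal PTAs return the left ear under both modes
  take_left <- if (mode == "better") lp <= rp else lp >= rp
  if (take_left) list(audiogram = left, side = "left", pta = lp)
  else list(audiogram = right, side = "right", pta = rp)
}

#' Asymmetrical hearing loss indicator
#'
#' A participant's hearing is asymmetrical when the worse-ear PTA exceeds the
#' better-ear PTA by strictly more than 20 dB HL.
#'
#' @param record One participant row (see [select_ear]).
#' @return Logical.
#' @export
is_asymmetric <- function(record) {
  d <- select_ear(record, "worse")$pta - select_ear(record, "better")$pta
  d > 20
}

#' Assemble a cohort object
#'
#' A cohort is a data frame with one row per participant carrying an id,
#' community label, age (>= 60), sex, and bilateral four-frequency
#' thresholds. Participants missing either ear are excluded before a cohort
#' is built.
#'
#' @param df Data frame with columns
#'   `id,community,age,sex,l500,l1000,l2000,l4000,r500,r1000,r2000,r4000`.
#' @param provenance Optional list recording where the rows came from (file
#'   path, or generator configuration and seed).
#' @return A `cohort` object (data frame subclass).
#' @export
cohort <- function(df, provenance = list(source = "in-memory")) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.csv_cols, names(df))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[.csv_cols]
  if (nrow(df) == 0L) stop("cohort must be non-empty", call. = FALSE)
  if (anyDuplicated(df$id))
    stop("participant ids must be unique", call. = FALSE)
  if (any(df$age < 60))
    stop("cohort is restricted to adults aged 60 or older", call. = FALSE)
  thr <- as.matrix(df[, 5:12])
  if (anyNA(thr))
    stop("thresholds must be complete; drop incomplete rows before building a cohort",
         call. = FALSE)
  if (any(thr < .db_range[1] | thr > .db_range[2]))
    stop("thresholds must lie in [-10, 120] dB HL", call. = FALSE)
  df$id <- as.character(df$id)
  df$community <- as.character(df$community)
  df$age <- as.integer(df$age)
  df$sex <- as.character(df$sex)
  structure(df, class = c("cohort", "data.frame"), provenance = provenance)
}

#' @export
print.cohort <- function(x, ...) {
  prev <- tryCatch(cohort_prevalence(x), error = function(e) NULL)
  cat(sprintf("Audiometric cohort: %d participants, community %s\n",
              nrow(x), paste(unique(x$community), collapse = "/")))
  cat(sprintf("  age %d-%d (mean %.1f)\n", min(x$age), max(x$age), mean(x$age)))
  if (!is.null(prev))
    cat(sprintf("  moderate-to-profound prevalence: better ear %.1f%%, worse ear %.1f%%\n",
                100 * prev["better"], 100 * prev["worse"]))
  invisible(x)
}

#' Per-ear PTA columns for every participant
#'
#' @param c A [cohort].
#' @return Data frame with `id`, `left_pta`, `right_pta`, `better_pta`,
#'   `worse_pta`, `asymmetric`.
#' @export
cohort_ptas <- function(c) {
  lp <- rowMeans(as.matrix(c[, c("l500", "l1000", "l2000", "l4000")]))
  rp <- rowMeans(as.matrix(c[, c("r500", "r1000", "r2000", "r4000")]))
  data.frame(id = c$id,
             left_pta = lp, right_pta = rp,
             better_pta = pmin(lp, rp), worse_pta = pmax(lp, rp),
             asymmetric = (pmax(lp, rp) - pmin(lp, rp)) > 20,
             stringsAsFactors = FALSE)
}

#' Moderate-to-profound prevalence of a cohort
#'
#' Fraction of participants whose selected-ear PTA exceeds 40 dB HL, for the
#' better and the worse ear. By default the denominator is the whole cohort;
#' `among_hearing_loss = TRUE` restricts the denominator to participants
#' whose selected ear shows any hearing loss (PTA > 25 dB HL), the
#' convention some descriptive reports use for better-ear figures.
#'
#' @param c A [cohort].
#' @param among_hearing_loss Logical; see above.
#' @return Named numeric vector `c(better = , worse = )` of fractions.
#' @export
cohort_prevalence <- function(c, among_hearing_loss = FALSE) {
  p <- cohort_ptas(c)
  frac <- function(x) {
    denom <- if (among_hearing_loss) sum(x > 25) else length(x)
    sum(x > 40) / denom
  }
  c(better = frac(p$better_pta), worse = frac(p$worse_pta))
}

#' Asymmetrical-hearing fraction of a cohort
#'
#' Fraction of participants whose worse-minus-better ear PTA difference
#' exceeds 20 dB HL. Cohort tables conventionally report this among
#' participants with any hearing loss in the worse ear (PTA > 25 dB HL);
#' `among_hearing_loss = FALSE` uses the whole cohort instead.
#'
#' @param c A [cohort].
#' @param among_hearing_loss Logical; see above.
#' @return Fraction in `[0, 1]`.
#' @export
cohort_asymmetry <- function(c, among_hearing_loss = TRUE) {
  p <- cohort_ptas(c)
  keep <- if (among_hearing_loss) p$worse_pta > 25 else rep(TRUE, nrow(p))
  mean(p$asymmetric[keep])
}

#' Build labeled screening samples from a cohort
#'
#' One sample per participant, in cohort order: the four thresholds of the
#' selected ear as features, and the binary screening label derived from
#' that ear's PTA (positive iff PTA > 40 dB HL).
#'
#' @param c A [cohort].
#' @param mode Ear-selection mode, `"better"` or `"worse"`.
#' @return Data frame of class `labeled_samples` with columns `id`,
#'   `hz500..hz4000`, `pta`, `label`, plus attributes `ear_mode`.
#' @export
make_labeled_samples <- function(c, mode = c("better", "worse")) {
  mode <- match.arg(mode)
  lmat <- as.matrix(c[, c("l500", "l1000", "l2000", "l4000")])
  rmat <- as.matrix(c[, c("r500", "r1000", "r2000", "r4000")])
  lp <- rowMeans(lmat)
  rp <- rowMeans(rmat)
  take_left <- if (mode == "better") lp <= rp else lp >= rp
  feat <- lmat
  feat[!take_left, ] <- rmat[!take_left, ]
  colnames(feat) <- .freq_cols
  pta <- ifelse(take_left, lp, rp)
  out <- data.frame(id = c$id, feat, pta = pta,
                    label = screening_label(pta),
                    ear_side = ifelse(take_left, "left", "right"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("labeled_samples", "data.frame"), ear_mode = mode)
}

#' Read an audiometric cohort from CSV
#'
#' Expects the schema
#' `id,community,age,sex,l500,l1000,l2000,l4000,r500,r1000,r2000,r4000`
#' (header required, UTF-8, comma-delimited). Rows with one or more missing
#' thresholds are dropped with a warning giving the count; a non-numeric or
#' out-of-range threshold is an error naming the offending row.
#'
#' @param path CSV file path.
#' @return A [cohort] with file provenance.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!identical(names(df), .csv_cols))
    stop("malformed header: expected ", paste(.csv_cols, collapse = ","),
         call. = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  thr_cols <- .csv_cols[5:12]
  thr <- df[thr_cols]
  # distinguish missing (empty/NA -> drop) from unparseable (-> error)
  blank <- vapply(thr, function(x) is.na(x) | !nzchar(trimws(x)), logical(nrow(df)))
  blank <- matrix(blank, nrow = nrow(df))
  num <- suppressWarnings(vapply(thr, as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df))
  bad <- is.na(num) & !blank
  if (any(bad))
    stop("non-numeric threshold in row ", which(rowSums(bad) > 0)[1],
         " of ", path, call. = FALSE)
  oor <- !is.na(num) & (num < .db_range[1] | num > .db_range[2])
  if (any(oor))
    stop("threshold outside [-10, 120] dB HL in row ",
         which(rowSums(oor) > 0)[1], " of ", path, call. = FALSE)
  keep <- rowSums(blank) == 0
  if (any(!keep))
    warning(sum(!keep), " row(s) dropped due to missing thresholds",
            call. = FALSE)
  if (!any(keep)) stop("no complete rows in ", path, call. = FALSE)
  out <- df[keep, 1:4]
  out$age <- as.integer(out$age)
  out <- cbind(out, as.data.frame(num[keep, , drop = FALSE]))
  names(out) <- .csv_cols
  cohort(out, provenance = list(source = "file", path = path,
                                dropped_rows = sum(!keep)))
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort]; writing then reading reproduces every field.
#'
#' @param c A [cohort].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(c, path) {
  utils::write.csv(as.data.frame(c)[.csv_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
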