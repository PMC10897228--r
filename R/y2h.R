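# Fluorescence yeast-two-hybrid plate normalization.
#
# Readout: well fluorescence minus the empty-vector signal, divided by the
# mean signal over the wells. "Mean signal over all wells" is read, by
# default, as the mean of the background-subtracted non-empty-vector wells,
# which makes empty-vector wells map to ~0 and the mean of normalized
# non-empty wells exactly 1 (plate-comparable, dimensionless). The literal
# all-wells divisor is available via `divisor = "all"`.

#' Assemble a plate table
#'
#' @param sample Sample id per well.
#' @param clone Replicate clone id per well.
#' @param raw Raw fluorescence per well (finite).
#' @param is_empty_vector Logical: empty-vector control wells.
#' @return data.frame of class `plate_table`.
#' @export
plate_table <- function(sample, clone, raw, is_empty_vector) {
  n <- length(raw)
  if (length(sample) != n || length(clone) != n || length(is_empty_vector) != n)
    stop_invalid("plate columns differ in length")
  if (any(!is.finite(raw))) stop_invalid("raw fluorescence must be finite")
  if (!any(is_empty_vector)) stop_invalid("plate needs at least one empty-vector well")
  out <- data.frame(sample = as.character(sample), clone = as.character(clone),
                    raw = as.numeric(raw),
                    is_empty_vector = as.logical(is_empty_vector),
                    stringsAsFactors = FALSE)
  class(out) <- c("plate_table", "data.frame")
  out
}

#' Read a plate CSV
#'
#' Columns: `sample`, `clone`, `raw`, `is_empty_vector`.
#' @param path CSV path.
#' @return A [plate_table].
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  plate_table(df$sample, df$clone, df$raw, as.logical(df$is_empty_vector))
}

#' Normalize a fluorescence Y2H plate
#'
#' Per well: `(raw - mean(empty-vector raw)) / D`, where the divisor `D` is
#' the mean of background-subtracted values over the non-empty-vector wells
#' (default) or over all wells (`divisor = "all"`). By construction the mean
#' of normalized non-empty-vector wells is exactly 1 under the default.
#'
#' @param plate A [plate_table] (>= 2 non-empty-vector wells).
#' @param divisor `"non_empty"` (default) or `"all"`.
#' @return List with `wells` (per-well normalized table) and `samples`
#'   (per-sample mean, SEM over replicate clones, n).
#' @export
#' @examples
#' p <- plate_table(c("ev", "a", "a"), c(1, 1, 2), c(2, 4, 6),
#'                  c(TRUE, FALSE, FALSE))
#' normalize_fy2h(p)$wells$normalized  # 0, 0.667, 1.333
normalize_fy2h <- function(plate, divisor = c("non_empty", "all")) {
  stopifnot(inherits(plate, "plate_table") || is.data.frame(plate))
  divisor <- match.arg(divisor)
  empty <- plate$is_empty_vector
  if (sum(!empty) < 2L)
    stop_invalid("need at least 2 non-empty-vector wells")
  bg <- mean(plate$raw[empty])
  sub <- plate$raw - bg
  denom <- if (divisor == "non_empty") mean(sub[!empty]) else mean(sub)
  if (denom <= 0)
    stop_invalid(paste0("failed plate: mean background-subtracted signal is ",
                        "%.4g (<= 0); wells are indistinguishable from the ",
                        "empty-vector control"), denom)
  wells <- plate
  wells$background <- bg
  wells$normalized <- sub / denom
  ne <- wells[!empty, ]
  sp <- split(ne$normalized, ne$sample)
  samples <- data.frame(
    sample = names(sp),
    mean = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    n = lengths(sp),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(wells = wells, samples = samples, background = bg, divisor = denom)
}
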